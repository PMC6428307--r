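# Partially directed acyclic graphs over named nodes.
#
# Representation: integer adjacency matrix `amat` with dimnames = nodes.
# amat[i, j] == 1 and amat[j, i] == 0  ->  directed edge i -> j
# amat[i, j] == 1 and amat[j, i] == 1  ->  undirected edge i -- j
# both zero -> no edge. Diagonal is always zero.

#' Construct a partially directed graph
#'
#' @param nodes character vector of node names.
#' @param directed two-column matrix (or data.frame) of directed edges
#'   `from -> to`; may have zero rows.
#' @param undirected two-column matrix of undirected edges (unordered pairs).
#' @return An object of class `pdag` holding the nodes and an adjacency
#'   matrix; no self-loops, and no pair may be both directed and undirected.
#' @export
pdag <- function(nodes, directed = NULL, undirected = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicated node names")
  amat <- matrix(0L, length(nodes), length(nodes),
                 dimnames = list(nodes, nodes))
  add <- function(a, b, both) {
    if (a == b) stop("self-loop at node '", a, "'")
    if (!all(c(a, b) %in% nodes)) stop("edge endpoint not in node set")
    if (amat[a, b] != 0L || amat[b, a] != 0L)
      stop("pair {", a, ", ", b, "} specified twice")
    amat[a, b] <<- 1L
    if (both) amat[b, a] <<- 1L
  }
  if (!is.null(directed) && NROW(directed) > 0) {
    directed <- as.matrix(directed)
    for (i in seq_len(nrow(directed)))
      add(directed[i, 1], directed[i, 2], both = FALSE)
  }
  if (!is.null(undirected) && NROW(undirected) > 0) {
    undirected <- as.matrix(undirected)
    for (i in seq_len(nrow(undirected)))
      add(undirected[i, 1], undirected[i, 2], both = TRUE)
  }
  new_pdag(amat)
}

new_pdag <- function(amat) {
  diag(amat) <- 0L
  structure(list(nodes = rownames(amat), amat = amat), class = "pdag")
}

#' Extract the edges of a pdag
#'
#' @param g a `pdag`.
#' @return A list with `directed` (two-column character matrix, from/to) and
#'   `undirected` (two-column character matrix, each pair once with the
#'   lexicographically smaller name first).
#' @export
pdag_edges <- function(g) {
  a <- g$amat
  nd <- g$nodes
  dir <- und <- matrix(character(0), 0, 2)
  idx <- which(a == 1L, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    if (a[j, i] == 1L) {
      if (i < j) und <- rbind(und, c(nd[i], nd[j]))
    } else {
      dir <- rbind(dir, c(nd[i], nd[j]))
    }
  }
  ord <- order(dir[, 1], dir[, 2])
  dir <- dir[ord, , drop = FALSE]
  ord <- order(und[, 1], und[, 2])
  und <- und[ord, , drop = FALSE]
  colnames(dir) <- colnames(und) <- c("from", "to")
  list(directed = dir, undirected = und)
}

n_edges <- function(g) {
  e <- pdag_edges(g)
  nrow(e$directed) + nrow(e$undirected)
}

#' @export
print.pdag <- function(x, ...) {
  e <- pdag_edges(x)
  cat(sprintf("<pdag> %d nodes, %d directed + %d undirected edges\n",
              length(x$nodes), nrow(e$directed), nrow(e$undirected)))
  invisible(x)
}

#' @export
`==.pdag` <- function(e1, e2) {
  identical(sort(e1$nodes), sort(e2$nodes)) &&
    all(e1$amat[sort(e1$nodes), sort(e1$nodes)] ==
          e2$amat[sort(e2$nodes), sort(e2$nodes)])
}

# ---- plain-text edge-list serialization -------------------------------------

#' Write / read a pdag as a plain-text edge list
#'
#' Format: a `#`-prefixed header listing the node census, then one edge per
#' line, `A -> B` for directed and `A -- B` for undirected edges. The
#' round-trip is lossless; an empty graph writes a header-only file.
#'
#' @param g a `pdag`.
#' @param path file path.
#' @return `write_graph` returns `path` invisibly; `read_graph` returns the
#'   `pdag`. Malformed or duplicated edge lines raise an error naming the
#'   line number.
#' @export
write_graph <- function(g, path) {
  e <- pdag_edges(g)
  lines <- c(paste("# nodes:", paste(g$nodes, collapse = " ")),
             if (nrow(e$directed))
               paste(e$directed[, 1], "->", e$directed[, 2]),
             if (nrow(e$undirected))
               paste(e$undirected[, 1], "--", e$undirected[, 2]))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_graph
#' @export
read_graph <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "# nodes:"))
    stop("graph file must start with a '# nodes:' header")
  nodes <- strsplit(trimws(sub("^# nodes:", "", lines[1])), "\\s+")[[1]]
  nodes <- nodes[nzchar(nodes)]
  g <- pdag(nodes)
  amat <- g$amat
  body <- lines[-1]
  for (k in seq_along(body)) {
    ln <- trimws(body[k])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    parts <- strsplit(ln, "\\s+")[[1]]
    if (length(parts) != 3 || !parts[2] %in% c("->", "--"))
      stop("malformed edge on line ", k + 1L, ": '", ln, "'")
    a <- parts[1]; b <- parts[3]
    if (!all(c(a, b) %in% nodes))
      stop("unknown node on line ", k + 1L, ": '", ln, "'")
    if (amat[a, b] != 0L || amat[b, a] != 0L)
      stop("duplicate edge on line ", k + 1L, ": '", ln, "'")
    amat[a, b] <- 1L
    if (parts[2] == "--") amat[b, a] <- 1L
  }
  new_pdag(amat)
}
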