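#' @importFrom utils combn
NULL

sepset_key <- function(a, b) paste(sort(c(a, b)), collapse = "\r")

#' PC-stable skeleton search
#'
#' Order-independent (PC-stable) skeleton estimation. At level `k` the
#' candidate deletions are computed against the adjacency sets as they stood
#' at the start of the level and applied only at the end of the level, so the
#' result does not depend on the order in which variables are presented.
#' Conditioning subsets are drawn from the level-start neighbourhoods of both
#' endpoints and enumerated in sorted-name lexicographic order; the first
#' separating set with `p > alpha` is recorded.
#'
#' @param md a [mixed_data()] object.
#' @param test function `(x, y, Z) -> p value`; see [mixed_pc()] for the
#'   default symmetric-test closure.
#' @param alpha significance level in (0, 1).
#' @param max_k maximum conditioning-set size (default `p - 2`, i.e. no
#'   effective cap).
#' @return List with `graph` (undirected `pdag`), `sepsets` (environment
#'   keyed by node pair), and `n_tests` (tests performed per level).
#' @export
pc_skeleton <- function(md, test, alpha = 0.01,
                        max_k = length(md$specs) - 2L) {
  stopifnot(alpha > 0, alpha < 1)
  nodes <- sort(names(md$specs))
  p <- length(nodes)
  amat <- matrix(1L, p, p, dimnames = list(nodes, nodes))
  diag(amat) <- 0L
  sepsets <- new.env(parent = emptyenv())
  n_tests <- integer(0)
  pairs <- t(combn(nodes, 2))

  k <- 0L
  repeat {
    adj_start <- amat                        # level-start adjacency (stable)
    degrees <- rowSums(adj_start)
    if (k > max_k || !any(degrees >= k + 1L)) break
    ntk <- 0L
    to_delete <- matrix(character(0), 0, 2)
    for (r in seq_len(nrow(pairs))) {
      a <- pairs[r, 1]; b <- pairs[r, 2]
      if (amat[a, b] == 0L) next
      found <- FALSE
      tested <- character(0)                 # avoid re-testing the same subset
      for (side in c(a, b)) {
        other <- if (side == a) b else a
        nbrs <- sort(nodes[adj_start[side, ] == 1L])
        nbrs <- setdiff(nbrs, other)
        if (length(nbrs) < k) next
        subsets <- if (k == 0L) list(character(0)) else
          combn(nbrs, k, simplify = FALSE)
        for (S in subsets) {
          key <- paste(S, collapse = "\r")
          if (key %in% tested) next
          tested <- c(tested, key)
          ntk <- ntk + 1L
          pval <- test(a, b, S)
          if (pval > alpha) {
            assign(sepset_key(a, b), S, envir = sepsets)
            to_delete <- rbind(to_delete, c(a, b))
            found <- TRUE
            break
          }
        }
        if (found) break
      }
    }
    if (nrow(to_delete)) {
      for (r in seq_len(nrow(to_delete))) {
        amat[to_delete[r, 1], to_delete[r, 2]] <- 0L
        amat[to_delete[r, 2], to_delete[r, 1]] <- 0L
      }
    }
    n_tests <- c(n_tests, ntk)
    k <- k + 1L
  }
  list(graph = new_pdag(amat), sepsets = sepsets, n_tests = n_tests)
}

#' Orient v-structures (colliders) in a skeleton
#'
#' For every unshielded triple `X - Z - Y` (X and Y adjacent to Z but not to
#' each other) with `Z` not in the recorded separating set of `{X, Y}`, the
#' triple is oriented as the collider `X -> Z <- Y`. Conflicting arrowhead
#' claims on the same edge (one triple wants `X -> Z`, another `Z -> X`)
#' leave that edge undirected.
#'
#' @param skeleton undirected `pdag` from [pc_skeleton()].
#' @param sepsets separating-set environment from [pc_skeleton()]; a missing
#'   entry for a non-adjacent pair is an error.
#' @return A `pdag` with collider arrows applied.
#' @export
orient_v_structures <- function(skeleton, sepsets) {
  amat <- skeleton$amat
  nodes <- skeleton$nodes
  claims <- matrix(FALSE, length(nodes), length(nodes),
                   dimnames = dimnames(amat))
  for (z in nodes) {
    nbrs <- nodes[amat[z, ] == 1L & amat[, z] == 1L]
    if (length(nbrs) < 2L) next
    for (pr in combn(sort(nbrs), 2, simplify = FALSE)) {
      x <- pr[1]; y <- pr[2]
      if (amat[x, y] != 0L || amat[y, x] != 0L) next  # shielded
      key <- sepset_key(x, y)
      if (!exists(key, envir = sepsets, inherits = FALSE))
        stop("no separating set recorded for non-adjacent pair {",
             x, ", ", y, "}")
      S <- get(key, envir = sepsets, inherits = FALSE)
      if (!(z %in% S)) {
        claims[x, z] <- TRUE
        claims[y, z] <- TRUE
      }
    }
  }
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      if (i >= j) next
      if (claims[i, j] && claims[j, i]) {
        message("conflicting collider orientations on edge {",
                nodes[i], ", ", nodes[j], "}; left undirected")
      } else if (claims[i, j]) {
        amat[j, i] <- 0L
      } else if (claims[j, i]) {
        amat[i, j] <- 0L
      }
    }
  }
  new_pdag(amat)
}

# helpers on the 0/1 adjacency coding
has_edge  <- function(a, i, j) a[i, j] != 0L || a[j, i] != 0L
is_undir  <- function(a, i, j) a[i, j] == 1L && a[j, i] == 1L
is_dir    <- function(a, i, j) a[i, j] == 1L && a[j, i] == 0L   # i -> j

#' Apply Meek's orientation rules to a fixpoint
#'
#' Propagates orientations after collider detection without creating new
#' v-structures or directed cycles:
#' R1: `a -> b`, `b - c`, `a, c` non-adjacent: orient `b -> c`.
#' R2: `a -> c -> b` and `a - b`: orient `a -> b`.
#' R3: `a - b`, `a - c`, `a - d`, `c -> b`, `d -> b`, `c, d` non-adjacent:
#' orient `a -> b`.
#' R4: `a - b`, `a - c`, `c -> d`, `d -> b`, `b, c` non-adjacent: orient
#' `a -> b`.
#' Rules are applied repeatedly until no rule fires; existing arrowheads are
#' never removed or reversed.
#'
#' @param g a `pdag`.
#' @return The maximally oriented `pdag`.
#' @export
apply_meek_rules <- function(g) {
  a <- g$amat
  nodes <- g$nodes
  p <- length(nodes)
  repeat {
    changed <- FALSE
    for (i in seq_len(p)) for (j in seq_len(p)) {
      if (i == j || !is_undir(a, i, j)) next
      orient <- FALSE
      # R1: some k with k -> i, k and j non-adjacent
      for (k in seq_len(p)) {
        if (k == i || k == j) next
        if (is_dir(a, k, i) && !has_edge(a, k, j)) { orient <- TRUE; break }
      }
      # R2: directed path i -> k -> j
      if (!orient) for (k in seq_len(p)) {
        if (k == i || k == j) next
        if (is_dir(a, i, k) && is_dir(a, k, j)) { orient <- TRUE; break }
      }
      # R3: two non-adjacent k, l with i - k, i - l, k -> j, l -> j
      if (!orient) {
        ks <- which(vapply(seq_len(p), function(k)
          k != i && k != j && is_undir(a, i, k) && is_dir(a, k, j),
          logical(1)))
        if (length(ks) >= 2L) {
          for (u in seq_along(ks)) {
            for (v in seq_along(ks)) {
              if (u < v && !has_edge(a, ks[u], ks[v])) { orient <- TRUE; break }
            }
            if (orient) break
          }
        }
      }
      # R4: k, l with i - k, k -> l, l -> j, j and k non-adjacent
      if (!orient) {
        for (k in seq_len(p)) {
          if (k == i || k == j || !is_undir(a, i, k) || has_edge(a, k, j)) next
          for (l in seq_len(p)) {
            if (l == i || l == j || l == k) next
            if (is_dir(a, k, l) && is_dir(a, l, j)) { orient <- TRUE; break }
          }
          if (orient) break
        }
      }
      if (orient) {
        a[j, i] <- 0L   # i -> j
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  new_pdag(a)
}

#' Learn a PDAG from mixed data with PC-stable
#'
#' Runs the full pipeline: PC-stable skeleton search with a symmetric
#' conditional-independence test for mixed variable types, collider
#' orientation from the recorded separating sets, and Meek-rule completion.
#' Directional-test results are cached across the skeleton search (the
#' reduced model for one pair is the full model of another), which roughly
#' halves the number of regression fits.
#'
#' @param md a [mixed_data()] object.
#' @param alpha significance level of the individual tests (default 0.01).
#' @param method symmetric-test method: `"mm"` (default), `"min"`, `"max"`,
#'   or `"fast"`; see [symmetric_test()].
#' @param max_k cap on the conditioning-set size (default unbounded).
#' @return An object of class `mixedpc` with components `graph` (the learned
#'   `pdag`), `sepsets`, `n_tests` (tests per level), `alpha`, `method`,
#'   and `call`. Supports `print()`, `summary()` and `plot()` (the latter
#'   needs the igraph package).
#' @examples
#' dag <- sample_dag(5, avg_degree = 1.5, seed = 3)
#' eqs <- sample_parameters(dag, seed = 4)
#' md <- sample_data(dag, eqs, n = 500, seed = 5)
#' fit <- mixed_pc(md, alpha = 0.01, method = "mm")
#' print(fit)
#' @export
mixed_pc <- function(md, alpha = 0.01, method = c("mm", "min", "max", "fast"),
                     max_k = length(md$specs) - 2L) {
  method <- match.arg(method)
  cache <- new.env(parent = emptyenv())
  test <- function(x, y, S) {
    key <- paste(x, y, paste(S, collapse = "\r"), sep = "\n")
    if (!is.null(cache[[key]])) return(cache[[key]])
    p <- suppressWarnings(
      symmetric_test(x, y, S, md, method = method)$pvalue)
    cache[[key]] <- p
    p
  }
  sk <- pc_skeleton(md, test, alpha = alpha, max_k = max_k)
  gv <- orient_v_structures(sk$graph, sk$sepsets)
  g <- apply_meek_rules(gv)
  structure(list(graph = g, sepsets = sk$sepsets, n_tests = sk$n_tests,
                 alpha = alpha, method = method, nodes = g$nodes,
                 n_obs = nrow(md$data), call = match.call()),
            class = "mixedpc")
}

#' @export
print.mixedpc <- function(x, ...) {
  e <- pdag_edges(x$graph)
  cat("PC-stable causal structure learned from mixed data\n")
  cat(sprintf("  test method: %s, alpha = %g, n = %d\n",
              toupper(x$method), x$alpha, x$n_obs))
  cat(sprintf("  %d nodes; %d directed and %d undirected edges\n",
              length(x$nodes), nrow(e$directed), nrow(e$undirected)))
  cat(sprintf("  CI tests per level: %s\n",
              paste(x$n_tests, collapse = ", ")))
  invisible(x)
}

#' @export
summary.mixedpc <- function(object, ...) {
  e <- pdag_edges(object$graph)
  print(object)
  if (nrow(e$directed)) {
    cat("\nDirected edges:\n")
    cat(paste(" ", e$directed[, 1], "->", e$directed[, 2]), sep = "\n")
  }
  if (nrow(e$undirected)) {
    cat("\nUndirected edges:\n")
    cat(paste(" ", e$undirected[, 1], "--", e$undirected[, 2]), sep = "\n")
  }
  invisible(object)
}

#' @export
plot.mixedpc <- function(x, ...) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("plotting requires the igraph package")
  e <- pdag_edges(x$graph)
  edges <- rbind(e$directed, e$undirected, e$undirected[, 2:1, drop = FALSE])
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges), directed = TRUE,
    vertices = data.frame(name = x$nodes))
  # undirected edges drawn as reciprocal pairs without arrowheads
  arrow <- c(rep(1, nrow(e$directed)), rep(0, 2 * nrow(e$undirected)))
  igraph::plot.igraph(g, edge.arrow.mode = arrow, ...)
  invisible(x)
}
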