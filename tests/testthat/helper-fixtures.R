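# Small fixtures built in code, shared across test files.

spec_cont <- function(nm) variable_spec(nm, "continuous")
spec_nom <- function(nm, d) variable_spec(nm, "nominal", as.character(seq_len(d)))
spec_ord <- function(nm, d) variable_spec(nm, "ordinal", as.character(seq_len(d)))

# deterministic little mixed dataset: continuous x, binary g, 3-level ordinal o
tiny_mixed <- function(n = 40, seed = 101) {
  set.seed(seed)
  x <- rnorm(n)
  g <- sample(c("1", "2"), n, replace = TRUE)
  o <- as.character(sample(1:3, n, replace = TRUE))
  mixed_data(data.frame(x = x, g = g, o = o, stringsAsFactors = FALSE),
             list(spec_cont("x"), spec_nom("g", 2), spec_ord("o", 3)))
}

# brute-force least squares through the normal equations
ls_oracle <- function(y, X) {
  Xi <- cbind(1, X)
  solve(t(Xi) %*% Xi, t(Xi) %*% y)
}

# all DAGs over a given skeleton that share its v-structures, by enumeration;
# returns the consensus CPDAG amat (directed iff same direction in all
# equivalent DAGs). `amat` is a directed 0/1 adjacency matrix of a DAG.
cpdag_enum_oracle <- function(amat) {
  p <- nrow(amat)
  nodes <- rownames(amat)
  skel <- (amat + t(amat)) > 0
  pairs <- which(upper.tri(skel) & skel, arr.ind = TRUE)
  m <- nrow(pairs)
  vstructs <- function(a) {
    out <- character(0)
    for (z in seq_len(p)) {
      pa <- which(a[, z] == 1)
      if (length(pa) < 2) next
      for (cb in utils::combn(pa, 2, simplify = FALSE))
        if (!skel[cb[1], cb[2]])
          out <- c(out, paste(sort(cb), z, sep = "."))
    }
    sort(out)
  }
  is_acyclic <- function(a) {
    indeg <- colSums(a)
    left <- rep(TRUE, p)
    repeat {
      s <- which(left & indeg == 0)
      if (!length(s)) break
      for (v in s) { indeg <- indeg - a[v, ]; left[v] <- FALSE }
    }
    !any(left)
  }
  target_vs <- vstructs(amat)
  seen <- NULL
  for (mask in 0:(2^m - 1)) {
    a <- matrix(0L, p, p, dimnames = list(nodes, nodes))
    for (e in seq_len(m)) {
      i <- pairs[e, 1]; j <- pairs[e, 2]
      if (bitwAnd(mask, bitwShiftL(1L, e - 1L)) > 0) a[i, j] <- 1L
      else a[j, i] <- 1L
    }
    if (!is_acyclic(a)) next
    if (!identical(vstructs(a), target_vs)) next
    seen <- if (is.null(seen)) list(a) else c(seen, list(a))
  }
  cons <- Reduce(`+`, seen)
  out <- matrix(0L, p, p, dimnames = list(nodes, nodes))
  k <- length(seen)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (i == j || !skel[i, j]) next
    if (cons[i, j] == k) out[i, j] <- 1L            # always i -> j
    else if (cons[i, j] > 0 && cons[j, i] > 0) out[i, j] <- 1L  # reversible
  }
  out
}

# pdag from a directed 0/1 adjacency matrix (rownames = node names)
new_pdag_for_test <- function(amat) {
  idx <- which(amat == 1L, arr.ind = TRUE)
  ed <- cbind(rownames(amat)[idx[, 1]], rownames(amat)[idx[, 2]])
  pdag(rownames(amat), directed = if (nrow(ed)) ed else NULL)
}
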