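#' @importFrom stats cor setNames
NULL

#' Convert a DAG to its CPDAG (Markov equivalence class representative)
#'
#' Computes the completed PDAG of a DAG: compelled edges stay directed,
#' reversible edges become undirected. Construction: take the skeleton,
#' orient the DAG's v-structures (unshielded colliders), and close under the
#' Meek rules.
#'
#' @param dag either a `bn_dag` (from [sample_dag()]) or a `pdag` whose edges
#'   are all directed and acyclic.
#' @return A `pdag`.
#' @export
dag_to_cpdag <- function(dag) {
  if (inherits(dag, "bn_dag")) dag <- dag_as_pdag(dag)
  a <- dag$amat
  if (any(a == 1L & t(a) == 1L))
    stop("input must be fully directed")
  if (has_cycle(a)) stop("input graph is cyclic")
  nodes <- dag$nodes
  skel <- a | t(a)
  out <- matrix(as.integer(skel), nrow(a), dimnames = dimnames(a))
  # orient unshielded colliders x -> z <- y as in the DAG
  for (z in nodes) {
    pa <- nodes[a[, z] == 1L]
    if (length(pa) < 2L) next
    for (pr in combn(pa, 2, simplify = FALSE)) {
      x <- pr[1]; y <- pr[2]
      if (!skel[x, y]) {       # unshielded: collider is compelled
        out[z, x] <- 0L
        out[z, y] <- 0L
      }
    }
  }
  apply_meek_rules(new_pdag(out))
}

# cycle check on the directed part of a 0/1 adjacency matrix
has_cycle <- function(a) {
  d <- a == 1L & t(a) == 0L
  indeg <- colSums(d)
  left <- rep(TRUE, nrow(d))
  repeat {
    src <- which(left & indeg == 0)
    if (!length(src)) break
    for (s in src) {
      indeg <- indeg - d[s, ]
      left[s] <- FALSE
    }
  }
  any(left)   # every remaining node sits on a directed cycle
}

pair_mark <- function(a, i, j) {
  # 0 none, 1 undirected, 2 i->j, 3 j->i
  if (a[i, j] == 1L && a[j, i] == 1L) 1L
  else if (a[i, j] == 1L) 2L
  else if (a[j, i] == 1L) 3L
  else 0L
}

#' Compare a learned PDAG against the true one
#'
#' Skeleton precision/recall are computed on adjacencies (edge presence,
#' ignoring marks). Orientation precision/recall require the full edge mark
#' to match: the same pair must be present and carry the same
#' directed-with-same-head or undirected status. The structural Hamming
#' distance counts one unit for every pair whose status differs (missing,
#' extra, or wrongly marked edge). Precision with zero predicted edges is
#' reported as 1 (no prediction, no false positive).
#'
#' @param estimated,truth `pdag` objects over the same node set.
#' @param orientation `"exact"` (default) scores orientation P/R on full
#'   edge marks over all edges as described above; `"arrowhead"` scores
#'   individual arrowheads instead: an estimated arrowhead `i -> j` is a
#'   true positive when the true graph carries the same arrowhead, with
#'   precision/recall over the estimated/true arrowhead counts. The two
#'   conventions coincide on fully directed graphs.
#' @return An object of class `graph_metrics`: `skeleton_precision`,
#'   `skeleton_recall`, `orientation_precision`, `orientation_recall`,
#'   `shd`, plus the raw pair counts.
#' @export
graph_metrics <- function(estimated, truth,
                          orientation = c("exact", "arrowhead")) {
  orientation <- match.arg(orientation)
  if (!identical(sort(estimated$nodes), sort(truth$nodes)))
    stop("estimated and true graphs have different node sets")
  nodes <- sort(truth$nodes)
  ae <- estimated$amat[nodes, nodes]
  at <- truth$amat[nodes, nodes]
  p <- length(nodes)
  n_est <- 0L; n_true <- 0L; adj_tp <- 0L; mark_tp <- 0L; shd <- 0L
  ah_est <- 0L; ah_true <- 0L; ah_tp <- 0L
  for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
    me <- pair_mark(ae, i, j)
    mt <- pair_mark(at, i, j)
    if (me != 0L) n_est <- n_est + 1L
    if (mt != 0L) n_true <- n_true + 1L
    if (me != 0L && mt != 0L) {
      adj_tp <- adj_tp + 1L
      if (me == mt) mark_tp <- mark_tp + 1L
    }
    if (me != mt) shd <- shd + 1L
    if (me %in% c(2L, 3L)) ah_est <- ah_est + 1L
    if (mt %in% c(2L, 3L)) ah_true <- ah_true + 1L
    if (me %in% c(2L, 3L) && me == mt) ah_tp <- ah_tp + 1L
  }
  prec <- function(tp, den) if (den == 0L) 1 else tp / den
  op <- if (orientation == "exact") prec(mark_tp, n_est) else
    prec(ah_tp, ah_est)
  or_ <- if (orientation == "exact") prec(mark_tp, n_true) else
    prec(ah_tp, ah_true)
  structure(list(
    skeleton_precision = prec(adj_tp, n_est),
    skeleton_recall = prec(adj_tp, n_true),
    orientation_precision = op,
    orientation_recall = or_,
    orientation_convention = orientation,
    shd = shd,
    n_estimated_edges = n_est, n_true_edges = n_true),
    class = "graph_metrics")
}

#' @export
print.graph_metrics <- function(x, ...) {
  cat(sprintf(paste0("<graph_metrics> skeleton P/R = %.3f/%.3f  ",
                     "orientation P/R = %.3f/%.3f  SHD = %d\n"),
              x$skeleton_precision, x$skeleton_recall,
              x$orientation_precision, x$orientation_recall, x$shd))
  invisible(x)
}

# both directional p values for a pair structure dataset; the conditioning
# set is {Z} for the conditional structures, empty otherwise.
directional_pvalues <- function(md) {
  Z <- intersect("Z", names(md$specs))
  t1 <- suppressWarnings(asym_test("X", "Y", Z, md))
  t2 <- suppressWarnings(asym_test("Y", "X", Z, md))
  c(p1 = t1$pvalue, p2 = t2$pvalue)
}

#' Monte-Carlo calibration of the mixed-data tests
#'
#' For each requested sample size, repeatedly generates data from the chosen
#' pair structure, runs both directional tests and the combined symmetric
#' tests, and summarizes rejection rates, the Pearson correlation of the two
#' directional p values, and the proportion of replicates where the two
#' directional 5%-level decisions agree.
#'
#' @param pair model pair tag, see [make_pair_structure()].
#' @param case structure, see [make_pair_structure()].
#' @param n_grid vector of sample sizes.
#' @param reps Monte-Carlo replicates per sample size.
#' @param alpha rejection level for the rejection-rate summaries.
#' @param methods symmetric-test methods to summarize.
#' @param seed optional integer seed for the whole run.
#' @return A data.frame with one row per (n, method): columns `pair`, `case`,
#'   `n`, `method`, `rejection_rate`, `p_correlation`, `agreement`, `reps`,
#'   `alpha`. Methods `"p1"`/`"p2"` rows report the raw directional tests.
#' @export
run_calibration <- function(pair, case, n_grid, reps = 1000, alpha = 0.05,
                            methods = c("mm", "min", "max", "fast"),
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(reps >= 1)
  out <- list()
  for (n in n_grid) {
    P <- matrix(NA_real_, reps, 2)
    fastp <- rep(NA_real_, reps)
    for (r in seq_len(reps)) {
      md <- make_pair_structure(case, pair, n)
      P[r, ] <- directional_pvalues(md)
      if ("fast" %in% methods) {
        out_var <- fast_select(md$specs$X, md$specs$Y)
        fastp[r] <- if (out_var == "X") P[r, 1] else P[r, 2]
      }
    }
    agree <- mean((P[, 1] <= 0.05) == (P[, 2] <= 0.05))
    pcor <- suppressWarnings(cor(P[, 1], P[, 2]))
    comb <- list(
      p1 = P[, 1], p2 = P[, 2],
      mm = pmin(2 * pmin(P[, 1], P[, 2]), pmax(P[, 1], P[, 2])),
      min = pmin(P[, 1], P[, 2]),
      max = pmax(P[, 1], P[, 2]),
      fast = fastp)
    for (m in union(methods, c("p1", "p2"))) {
      out[[length(out) + 1L]] <- data.frame(
        pair = pair, case = case, n = n, method = m,
        rejection_rate = mean(comb[[m]] <= alpha),
        p_correlation = pcor, agreement = agree,
        reps = reps, alpha = alpha, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Benchmark PC-stable structure recovery on random mixed networks
#'
#' Generates random DAGs with [sample_dag()], draws parameters and data, runs
#' [mixed_pc()] with each requested test method, and scores the learned PDAG
#' against the true CPDAG with [graph_metrics()].
#'
#' @param p number of variables.
#' @param avg_degree expected average degree.
#' @param n sample size per network.
#' @param n_networks number of random networks.
#' @param methods symmetric-test methods to run.
#' @param alpha PC significance level (default 0.01).
#' @param max_k conditioning-set cap passed to [mixed_pc()].
#' @param type_probs type mixture passed to [sample_dag()].
#' @param seed optional integer seed.
#' @return A data.frame with one row per network x method carrying the five
#'   metrics; attribute `"summary"` holds per-method averages.
#' @export
run_bn_benchmark <- function(p, avg_degree, n, n_networks = 10,
                             methods = c("mm", "fast"), alpha = 0.01,
                             max_k = p - 2L,
                             type_probs = c(continuous = 0.5, nominal = 0,
                                            ordinal = 0.5),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_networks >= 1)
  rows <- list()
  for (net in seq_len(n_networks)) {
    dag <- sample_dag(p, avg_degree, type_probs)
    eqs <- sample_parameters(dag)
    md <- sample_data(dag, eqs, n)
    truth <- dag_to_cpdag(dag)
    for (m in methods) {
      fit <- mixed_pc(md, alpha = alpha, method = m, max_k = max_k)
      gm <- graph_metrics(fit$graph, truth)
      rows[[length(rows) + 1L]] <- data.frame(
        network = net, method = m, p = p, avg_degree = avg_degree, n = n,
        skeleton_precision = gm$skeleton_precision,
        skeleton_recall = gm$skeleton_recall,
        orientation_precision = gm$orientation_precision,
        orientation_recall = gm$orientation_recall,
        shd = gm$shd, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  metr <- c("skeleton_precision", "skeleton_recall",
            "orientation_precision", "orientation_recall", "shd")
  summ <- do.call(rbind, lapply(split(res, res$method), function(d)
    data.frame(method = d$method[1], p = p, avg_degree = avg_degree, n = n,
               t(colMeans(d[metr])), stringsAsFactors = FALSE)))
  rownames(summ) <- NULL
  attr(res, "summary") <- summ
  res
}
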