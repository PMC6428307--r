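#' @importFrom stats rnorm runif rexp quantile
NULL

#' Sample a random mixed-type DAG
#'
#' Draws a random topological order over `p` nodes and includes each
#' order-respecting pair as an edge independently with probability
#' `avg_degree / (p - 1)`, giving the requested expected average degree.
#' Variable types are drawn from `type_probs`; categorical variables take
#' 2-4 levels with equal probability.
#'
#' @param p number of variables (>= 2).
#' @param avg_degree expected average node degree, in (0, p).
#' @param type_probs named numeric weights for
#'   `c(continuous, nominal, ordinal)`; default the half-continuous /
#'   half-ordinal mixture used in the network benchmarks.
#' @param seed optional integer seed (full run reproducibility).
#' @return An object of class `bn_dag`: `specs` (named list of
#'   [variable_spec()]), `parents` (named list of parent-name vectors), and
#'   `order` (the topological order).
#' @export
sample_dag <- function(p, avg_degree,
                       type_probs = c(continuous = 0.5, nominal = 0,
                                      ordinal = 0.5),
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(p >= 2, avg_degree > 0, avg_degree < p)
  if (length(type_probs) != 3 || any(type_probs < 0) || sum(type_probs) <= 0)
    stop("type_probs must be 3 nonnegative weights (continuous, nominal, ordinal)")
  nodes <- sprintf("V%0*d", nchar(p), seq_len(p))
  ord <- sample(nodes)
  q <- avg_degree / (p - 1)
  types <- sample(c("continuous", "nominal", "ordinal"), p, replace = TRUE,
                  prob = type_probs / sum(type_probs))
  specs <- vector("list", p)
  names(specs) <- nodes
  for (i in seq_len(p)) {
    specs[[nodes[i]]] <- if (types[i] == "continuous") {
      variable_spec(nodes[i], "continuous")
    } else {
      d <- sample(2:4, 1)
      variable_spec(nodes[i], types[i], as.character(seq_len(d)))
    }
  }
  parents <- stats::setNames(vector("list", p), nodes)
  for (j in seq_len(p)) {
    pa <- character(0)
    if (j > 1) {
      sel <- runif(j - 1) < q
      pa <- ord[seq_len(j - 1)][sel]
    }
    parents[[ord[j]]] <- sort(pa)
  }
  structure(list(specs = specs, parents = parents, order = ord),
            class = "bn_dag")
}

#' @export
print.bn_dag <- function(x, ...) {
  ne <- sum(lengths(x$parents))
  cat(sprintf("<bn_dag> %d nodes, %d edges, avg degree %.2f\n",
              length(x$specs), ne, 2 * ne / length(x$specs)))
  invisible(x)
}

# Number of structural-equation coefficient columns a parent contributes:
# continuous and ordinal parents one each (ordinal parents enter as integer
# scores), nominal parents d - 1 (one per dummy).
parent_ncols <- function(spec) {
  if (spec$vtype == "nominal") length(spec$levels) - 1L else 1L
}

sample_coef <- function(k) {
  if (k == 0L) return(numeric(0))
  runif(k, 0.1, 1) * sample(c(-1, 1), k, replace = TRUE)
}

#' Sample structural-equation parameters for a DAG
#'
#' Every coefficient (intercept included) is drawn uniformly from
#' `[-1, -0.1] u [0.1, 1]`, so no generated effect is ever exactly zero.
#' Continuous and ordinal children get one coefficient vector over the parent
#' design (ordinal children are generated through a continuous latent);
#' nominal children with `d` levels get `d - 1` coefficient vectors, one per
#' non-reference category of a multinomial-logit mechanism.
#'
#' @param dag a `bn_dag`.
#' @param seed optional integer seed.
#' @return An object of class `bn_params`: per node either `NULL` (root) or a
#'   list with `b0` (intercepts) and `B` (coefficient matrix, one row per
#'   outcome component, one column per parent design column).
#' @export
sample_parameters <- function(dag, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  eqs <- stats::setNames(vector("list", length(dag$specs)), names(dag$specs))
  for (nm in dag$order) {         # deterministic generation order
    pa <- dag$parents[[nm]]
    if (length(pa) == 0L) next
    k <- sum(vapply(dag$specs[pa], parent_ncols, integer(1)))
    sp <- dag$specs[[nm]]
    rows <- if (sp$vtype == "nominal") length(sp$levels) - 1L else 1L
    eqs[[nm]] <- list(b0 = sample_coef(rows),
                      B = matrix(sample_coef(rows * k), nrow = rows))
  }
  structure(eqs, class = "bn_params")
}

# Parent design for data generation: continuous column as-is, ordinal as
# integer scores 0..d-1, nominal as d-1 dummies.
gen_parent_design <- function(dag, cols, pa) {
  if (length(pa) == 0L) return(NULL)
  do.call(cbind, lapply(pa, function(q) {
    sq <- dag$specs[[q]]
    v <- cols[[q]]
    if (sq$vtype == "continuous") matrix(v, ncol = 1)
    else if (sq$vtype == "ordinal")
      matrix(as.integer(factor(v, levels = sq$levels)) - 1L, ncol = 1)
    else encode_dummies(v, sq)
  }))
}

#' Randomly discretize a continuous column into ordered categories
#'
#' Implements the randomized discretization used for ordinal variables: the
#' category proportions are `0.15` plus a uniform (flat-Dirichlet) random
#' split of the remaining mass, so every category keeps at least 15% of the
#' observations (up to one-observation rounding). Observations are assigned
#' by rank, so a larger latent value never maps to a smaller category and the
#' order of the latent scale is preserved.
#'
#' @param latent numeric vector (the latent continuous variable).
#' @param n_levels number of ordered categories, in 2..4.
#' @param seed optional integer seed.
#' @return Ordered factor with levels `"1" < ... < "<n_levels>"`.
#' @export
discretize_ordinal <- function(latent, n_levels, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!n_levels %in% 2:4) stop("n_levels must be 2, 3 or 4")
  n <- length(latent)
  if (floor(0.15 * n) < 1L)
    stop("n too small to give every category at least 15% of observations")
  g <- rexp(n_levels)
  props <- 0.15 + (1 - 0.15 * n_levels) * g / sum(g)
  # largest-remainder apportionment of n observations to the categories
  raw <- props * n
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  cat_of_rank <- rep(seq_len(n_levels), counts)
  out <- integer(n)
  out[order(latent)] <- cat_of_rank
  factor(out, levels = seq_len(n_levels), ordered = TRUE)
}

#' Sample data from a DAG with structural equations
#'
#' Generates `n` samples in topological order. Roots: standard normal if
#' continuous, uniform over the levels if nominal, and a discretized standard
#' normal if ordinal. A non-root continuous child is
#' `b0 + X b + e, e ~ N(0, 1)` over the parent design; an ordinal child is
#' generated the same way as a continuous latent and then passed through
#' [discretize_ordinal()]; a nominal child is drawn from a multinomial-logit
#' mechanism whose category utilities are the linear predictors.
#'
#' @param dag a `bn_dag`.
#' @param eqs a `bn_params` from [sample_parameters()].
#' @param n sample size.
#' @param seed optional integer seed.
#' @return A [mixed_data()] object with one column per node.
#' @export
sample_data <- function(dag, eqs, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n >= 1)
  cols <- stats::setNames(vector("list", length(dag$specs)), names(dag$specs))
  for (nm in dag$order) {
    sp <- dag$specs[[nm]]
    pa <- dag$parents[[nm]]
    X <- gen_parent_design(dag, cols, pa)
    if (is.null(X)) {
      cols[[nm]] <- switch(sp$vtype,
        continuous = rnorm(n),
        nominal = sample(sp$levels, n, replace = TRUE),
        ordinal = as.character(discretize_ordinal(rnorm(n),
                                                  length(sp$levels))))
    } else {
      eq <- eqs[[nm]]
      eta <- sweep(X %*% t(eq$B), 2, eq$b0, `+`)   # n x rows
      cols[[nm]] <- switch(sp$vtype,
        continuous = as.numeric(eta[, 1] + rnorm(n)),
        ordinal = as.character(
          discretize_ordinal(eta[, 1] + rnorm(n), length(sp$levels))),
        nominal = {
          u <- cbind(0, eta)                        # reference utility 0
          pr <- exp(u - apply(u, 1, max))
          pr <- pr / rowSums(pr)
          # draw category per row from its probability vector
          cum <- t(apply(pr, 1, cumsum))
          r <- runif(n)
          idx <- rowSums(cum < r) + 1L
          sp$levels[idx]
        })
    }
  }
  df <- as.data.frame(cols, stringsAsFactors = FALSE)
  mixed_data(df, dag$specs)
}

#' The true PDAG edges of a `bn_dag`
#'
#' @param dag a `bn_dag`.
#' @return A `pdag` containing the DAG itself (all edges directed).
#' @export
dag_as_pdag <- function(dag) {
  ed <- do.call(rbind, lapply(names(dag$parents), function(ch) {
    pa <- dag$parents[[ch]]
    if (length(pa)) cbind(pa, rep(ch, length(pa))) else NULL
  }))
  pdag(names(dag$specs), directed = ed)
}

pair_spec_of_tag <- function(tag, name) {
  switch(tag,
    L = variable_spec(name, "continuous"),
    B = variable_spec(name, "nominal", c("1", "2")),
    M = variable_spec(name, "nominal", as.character(1:4)),
    O = variable_spec(name, "ordinal", as.character(1:4)),
    stop("unknown variable tag '", tag, "'"))
}

#' Generate data from one of the two/three-variable benchmark structures
#'
#' Builds the small structures used in the test-calibration study for a
#' given pair of variable types: `indep` (X and Y independent roots),
#' `dep_xy` (X -> Y), `dep_yx` (Y -> X), `collider` (X -> Z <- Y) and
#' `common_cause` (X <- Z -> Y). `Z` is always continuous. The pair tag
#' fixes the types of X and Y: `L` continuous, `B` binary, `M` nominal with
#' four levels, `O` ordinal with four levels (e.g. `"L-O"`: X continuous,
#' Y ordinal). Coefficients are redrawn from `[-1,-0.1] u [0.1, 1]` on every
#' call.
#'
#' @param case one of `"indep"`, `"dep_xy"`, `"dep_yx"`, `"collider"`,
#'   `"common_cause"`.
#' @param pair one of `"L-B"`, `"L-M"`, `"L-O"`, `"B-O"`, `"M-O"`.
#' @param n sample size.
#' @param seed optional integer seed.
#' @return A [mixed_data()] with columns `X`, `Y` and (for the conditional
#'   structures) `Z`.
#' @export
make_pair_structure <- function(case = c("indep", "dep_xy", "dep_yx",
                                         "collider", "common_cause"),
                                pair = c("L-B", "L-M", "L-O", "B-O", "M-O"),
                                n, seed = NULL) {
  case <- match.arg(case)
  pair <- match.arg(pair)
  if (!is.null(seed)) set.seed(seed)
  tags <- strsplit(pair, "-", fixed = TRUE)[[1]]
  specs <- list(X = pair_spec_of_tag(tags[1], "X"),
                Y = pair_spec_of_tag(tags[2], "Y"))
  parents <- list(X = character(0), Y = character(0))
  ord <- c("X", "Y")
  if (case %in% c("collider", "common_cause")) {
    specs$Z <- variable_spec("Z", "continuous")
    if (case == "collider") {
      parents$Z <- c("X", "Y"); ord <- c("X", "Y", "Z")
    } else {
      parents$Z <- character(0)
      parents$X <- "Z"; parents$Y <- "Z"; ord <- c("Z", "X", "Y")
    }
  } else if (case == "dep_xy") {
    parents$Y <- "X"
  } else if (case == "dep_yx") {
    parents$X <- "Y"; ord <- c("Y", "X")
  }
  dag <- structure(list(specs = specs, parents = parents, order = ord),
                   class = "bn_dag")
  eqs <- sample_parameters(dag)
  sample_data(dag, eqs, n)
}

#' A dependence that linear tests cannot see
#'
#' Generates the three-variable counterexample in which a uniform three-level
#' nominal variable `Y` drives two continuous children through its dummy
#' indicators `Y1 = 1{Y = 2}`, `Y2 = 1{Y = 3}`:
#' `X = -Y1 + Y2 + 0.1 e_X` and `Z = Y1 + Y2 + 0.1 e_Z`, `e ~ N(0,1)`.
#' The population correlation of `X` and `Z` is exactly zero although they
#' are unconditionally dependent, so any test based on linear regressions of
#' `X` on `Z` rejects only at the nominal rate.
#'
#' @param n sample size (>= 3).
#' @param seed optional integer seed.
#' @return A [mixed_data()] with columns `X` (continuous), `Y` (nominal,
#'   3 levels), `Z` (continuous).
#' @export
make_fig1_example <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n >= 3)
  y <- sample(as.character(1:3), n, replace = TRUE)
  y1 <- as.numeric(y == "2")
  y2 <- as.numeric(y == "3")
  x <- -y1 + y2 + 0.1 * rnorm(n)
  z <- y1 + y2 + 0.1 * rnorm(n)
  mixed_data(data.frame(X = x, Y = y, Z = z, stringsAsFactors = FALSE),
             list(variable_spec("X", "continuous"),
                  variable_spec("Y", "nominal", as.character(1:3)),
                  variable_spec("Z", "continuous")))
}
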