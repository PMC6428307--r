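#' @importFrom stats lm.fit glm.fit binomial pchisq pf
NULL

new_reg_fit <- function(family, loglik, n_params, n_obs, converged,
                        rss = NA_real_, coef = NULL, extra = list()) {
  structure(c(list(family = family, loglik = loglik, rss = rss,
                   n_params = as.integer(n_params), n_obs = as.integer(n_obs),
                   converged = isTRUE(converged), coef = coef), extra),
            class = "reg_fit")
}

#' @export
print.reg_fit <- function(x, ...) {
  cat(sprintf("<reg_fit> family=%s  logLik=%.4f  params=%d  n=%d%s%s\n",
              x$family, x$loglik, x$n_params, x$n_obs,
              if (is.finite(x$rss)) sprintf("  RSS=%.4f", x$rss) else "",
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Ordinary least-squares fit with Gaussian log-likelihood
#'
#' Fits `y ~ 1 + X` by least squares. The parameter count is the number of
#' mean parameters (intercept plus one per design column); the error variance
#' is profiled out and not counted, matching the degrees of freedom of the
#' nested F test. The Gaussian log-likelihood is evaluated at the maximum
#' likelihood variance estimate `RSS/n`.
#'
#' @param y numeric response.
#' @param X numeric design matrix without intercept (0 columns allowed:
#'   intercept-only model).
#' @return A `reg_fit` with `family = "linear"`, the residual sum of squares
#'   in `rss`, and `converged = FALSE` when the design is rank-deficient.
#' @export
fit_linear <- function(y, X) {
  y <- as.numeric(y)
  n <- length(y)
  p <- ncol(X) + 1L
  if (n < p + 1L)
    warning("fewer than n_params + 1 observations for a linear fit",
            call. = FALSE)
  if (ncol(X) == 0L) {
    rss <- sum((y - mean(y))^2)
    cf <- c(`(Intercept)` = mean(y))
    rank_ok <- TRUE
  } else {
    fit <- lm.fit(cbind(`(Intercept)` = 1, X), y)
    rss <- sum(fit$residuals^2)
    cf <- fit$coefficients
    rank_ok <- fit$rank == p
  }
  ll <- if (rss <= 0) Inf else -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  new_reg_fit("linear", ll, p, n, rank_ok, rss = rss, coef = cf)
}

# Closed-form log-likelihood of an intercept-only categorical model:
# each category probability is its sample frequency.
intercept_only_ll <- function(counts) {
  counts <- counts[counts > 0]
  sum(counts * log(counts / sum(counts)))
}

# Binary logistic fit on a design matrix (intercept added), via IRLS.
fit_binary_core <- function(y01, X) {
  n <- length(y01)
  if (ncol(X) == 0L) {
    k <- sum(y01)
    return(list(loglik = intercept_only_ll(c(k, n - k)),
                coef = c(`(Intercept)` = qlogis(k / n)),
                converged = k > 0 && k < n))
  }
  fit <- suppressWarnings(
    glm.fit(cbind(`(Intercept)` = 1, X), y01, family = binomial(),
            control = list(epsilon = 1e-8, maxit = 100))
  )
  list(loglik = -fit$deviance / 2, coef = fit$coefficients,
       converged = fit$converged && !fit$boundary &&
         fit$rank == ncol(X) + 1L)
}

# Multinomial logistic fit via nnet's optimizer (softmax network with skip
# connections and zero hidden layer, the same parameterization nnet::multinom
# uses), called on matrices directly.
fit_multinom_core <- function(y, X) {
  lev <- levels(y)
  K <- length(lev)
  n <- length(y)
  if (ncol(X) == 0L)
    return(list(loglik = intercept_only_ll(tabulate(y, K)),
                coef = NULL, converged = TRUE))
  Xi <- cbind(`(Intercept)` = 1, X)
  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), as.integer(y))] <- 1
  r <- ncol(Xi)
  mask <- c(rep(FALSE, r + 1L), rep(c(FALSE, rep(TRUE, r)), K - 1L))
  fit <- nnet::nnet.default(Xi, Y, rep(1, n), mask = mask, size = 0,
                            skip = TRUE, softmax = TRUE, censored = FALSE,
                            rang = 0, trace = FALSE, maxit = 200,
                            reltol = 1e-10)
  cf <- matrix(fit$wts, nrow = r + 1L)[-1L, -1L, drop = FALSE]
  dimnames(cf) <- list(colnames(Xi), lev[-1L])
  list(loglik = -fit$value, coef = cf, converged = fit$convergence == 0)
}

#' Binary or multinomial logistic fit
#'
#' Fits a logistic regression of a categorical (nominal) outcome on a design
#' matrix: binary logistic when the outcome has two observed levels,
#' multinomial logistic otherwise. The parameter count is
#' `(d - 1) * (ncol(X) + 1)` where `d` is the number of observed outcome
#' levels.
#'
#' @param y factor outcome with at least two observed levels.
#' @param X numeric design matrix without intercept (0 columns allowed).
#' @return A `reg_fit` with family `"binary_logit"` or `"multinomial"`.
#'   Non-convergence (e.g. separation) is reported through
#'   `converged = FALSE`; the best attained log-likelihood is retained.
#' @export
fit_logistic <- function(y, X) {
  y <- droplevels(as.factor(y))
  d <- nlevels(y)
  if (d < 2L) stop("outcome has fewer than 2 observed levels")
  n <- length(y)
  p <- (d - 1L) * (ncol(X) + 1L)
  if (d == 2L) {
    core <- fit_binary_core(as.integer(y) - 1L, X)
    new_reg_fit("binary_logit", core$loglik, p, n, core$converged,
                coef = core$coef)
  } else {
    core <- fit_multinom_core(y, X)
    new_reg_fit("multinomial", core$loglik, p, n, core$converged,
                coef = core$coef)
  }
}

#' Generalized ordered logit fit (series of binary splits)
#'
#' Fits an ordinal outcome with `d` ordered levels by `d - 1` binary logistic
#' regressions, one per cumulative split: cut `j` contrasts
#' `{levels 1..j}` against `{levels j+1..d}` (for four categories: 1 vs 234,
#' 12 vs 34, 123 vs 4). Each cut has its own intercept and slope vector, so
#' the proportional-odds (equal slopes) constraint is not imposed. The model
#' log-likelihood is scored as the sum of the cut log-likelihoods, which
#' keeps the parameter count at `(d - 1) * (ncol(X) + 1)` and makes nested
#' likelihood-ratio tests well-defined; this sum-of-cuts score is an
#' approximation to a jointly normalized likelihood (the cuts are fit
#' independently).
#'
#' @param y ordered factor outcome.
#' @param X numeric design matrix without intercept.
#' @return A `reg_fit` of family `"gen_ordered_logit"` carrying the per-cut
#'   fits in `$cut_fits`. A cut with an empty side (all observations on one
#'   side of the split) is flagged failed and the whole fit reports
#'   `converged = FALSE`.
#' @export
fit_ordered_logit <- function(y, X) {
  y <- as.factor(y)   # declared levels kept: an unobserved boundary level
  d <- nlevels(y)     # gives an empty cut side and flags the fit failed
  if (nlevels(droplevels(y)) < 2L)
    stop("outcome has fewer than 2 observed levels")
  if (d < 2L) stop("outcome has fewer than 2 observed levels")
  n <- length(y)
  yi <- as.integer(y)
  cuts <- vector("list", d - 1L)
  ll <- 0
  ok <- TRUE
  for (j in seq_len(d - 1L)) {
    z <- as.numeric(yi > j)
    if (all(z == 0) || all(z == 1)) {
      cuts[[j]] <- list(loglik = NA_real_, coef = NULL, converged = FALSE)
      ok <- FALSE
      next
    }
    core <- fit_binary_core(z, X)
    cuts[[j]] <- core
    ll <- ll + core$loglik
    ok <- ok && core$converged
  }
  if (anyNA(vapply(cuts, function(cc) cc$loglik, numeric(1)))) ll <- NA_real_
  new_reg_fit("gen_ordered_logit", ll, (d - 1L) * (ncol(X) + 1L), n, ok,
              extra = list(cut_fits = cuts))
}

check_nested <- function(fit0, fit1) {
  if (fit0$n_obs != fit1$n_obs)
    stop("fits are on different numbers of observations")
  if (fit0$n_params >= fit1$n_params)
    stop("models are not nested: reduced model must have fewer parameters")
}

#' Nested F test between two linear fits
#'
#' `F = (RSS0 - RSS1) * (n - Par1) / (RSS1 * (Par1 - Par0))`, referred to an
#' F distribution with `(Par1 - Par0, n - Par1)` degrees of freedom.
#'
#' @param fit0 reduced linear `reg_fit` (nested in `fit1`, same data).
#' @param fit1 full linear `reg_fit`.
#' @return List with `statistic`, `df1`, `df2`, `pvalue`, `reliable`.
#' @export
f_test <- function(fit0, fit1) {
  if (fit0$family != "linear" || fit1$family != "linear")
    stop("f_test requires two linear fits")
  check_nested(fit0, fit1)
  df1 <- fit1$n_params - fit0$n_params
  df2 <- fit1$n_obs - fit1$n_params
  if (fit1$rss <= 0) {
    warning("saturated full model (RSS = 0); p value set to 0", call. = FALSE)
    return(list(statistic = Inf, df1 = df1, df2 = df2, pvalue = 0,
                reliable = fit0$converged && fit1$converged))
  }
  stat <- (fit0$rss - fit1$rss) * df2 / (fit1$rss * df1)
  if (stat < 0) stat <- 0   # numerically tiny negative improvement
  list(statistic = stat, df1 = df1, df2 = df2,
       pvalue = pf(stat, df1, df2, lower.tail = FALSE),
       reliable = fit0$converged && fit1$converged)
}

#' Nested likelihood-ratio test
#'
#' `T = 2 * (LL(M1) - LL(M0))`, referred to a chi-squared distribution with
#' `Par(M1) - Par(M0)` degrees of freedom. `T` is clamped at zero when
#' numerically negative within tolerance (nested fits can come out a hair
#' below the reduced fit).
#'
#' @param fit0 reduced `reg_fit` (same family and data as `fit1`).
#' @param fit1 full `reg_fit`.
#' @param tol clamp tolerance for a negative statistic.
#' @return List with `statistic`, `df`, `pvalue`, `reliable` (FALSE when
#'   either fit failed to converge or the statistic was negative beyond
#'   tolerance).
#' @export
lr_test <- function(fit0, fit1, tol = 1e-6) {
  if (fit0$family != fit1$family)
    stop("lr_test requires fits from the same family")
  check_nested(fit0, fit1)
  df <- fit1$n_params - fit0$n_params
  reliable <- fit0$converged && fit1$converged
  stat <- 2 * (fit1$loglik - fit0$loglik)
  if (is.na(stat)) return(list(statistic = NA_real_, df = df, pvalue = 1,
                               reliable = FALSE))
  if (stat < 0) {
    if (stat < -tol) reliable <- FALSE
    stat <- 0
  }
  list(statistic = stat, df = df,
       pvalue = pchisq(stat, df, lower.tail = FALSE), reliable = reliable)
}
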