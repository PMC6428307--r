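test_that("dummy encoding uses first-level reference coding", {
  sp2 <- spec_nom("g", 2)
  expect_equal(unname(encode_dummies(c("1", "2", "1"), sp2)[, 1]), c(0, 1, 0))
  expect_equal(ncol(encode_dummies(as.character(1:4), spec_nom("h", 4))), 3L)
  sp3 <- spec_nom("k", 3)
  expect_equal(unname(encode_dummies("1", sp3)), matrix(c(0, 0), 1))
  expect_error(encode_dummies(c("1", "9"), sp2), "unseen level")
})

test_that("degrees of freedom add over variables", {
  expect_identical(dof(spec_cont("x")), 1L)
  expect_identical(dof(spec_nom("g", 4)), 3L)
  expect_identical(dof(list(spec_cont("x"), spec_nom("g", 3))), 3L)
  expect_identical(dof(list()), 0L)
})

test_that("linear fits match the normal-equations oracle", {
  set.seed(7)
  X <- matrix(rnorm(40), 20, 2)
  y <- 1 + X %*% c(0.5, -2) + rnorm(20)
  fit <- fit_linear(y, X)
  expect_equal(unname(fit$coef), as.numeric(ls_oracle(y, X)), tolerance = 1e-8)
  expect_equal(fit$n_params, 3L)
  # intercept-only model: rss is the centered sum of squares
  f0 <- fit_linear(y, matrix(numeric(0), 20, 0))
  expect_equal(f0$rss, sum((y - mean(y))^2))
  # y identically a predictor: perfect fit
  fs <- fit_linear(X[, 1], X)
  expect_equal(fs$rss, 0, tolerance = 1e-20)
  # rank-deficient design flagged
  fr <- fit_linear(y, cbind(X, X[, 1]))
  expect_false(fr$converged)
})

test_that("F statistic follows its closed form and limits", {
  mkfit <- function(rss, k, n) {
    f <- fit_linear(rnorm(n), matrix(numeric(0), n, 0))
    f$rss <- rss; f$n_params <- as.integer(k); f$n_obs <- as.integer(n)
    f
  }
  tt <- f_test(mkfit(10, 2, 20), mkfit(5, 3, 20))
  expect_equal(tt$statistic, 17)
  # no improvement: F = 0, p = 1
  t0 <- f_test(mkfit(5, 2, 20), mkfit(5, 3, 20))
  expect_equal(t0$statistic, 0)
  expect_equal(t0$pvalue, 1)
  # saturated full model
  expect_warning(ts <- f_test(mkfit(5, 2, 20), mkfit(0, 3, 20)), "RSS = 0")
  expect_equal(ts$pvalue, 0)
  expect_error(f_test(mkfit(5, 3, 20), mkfit(4, 3, 20)), "nested")
})

test_that("F test agrees with its chi-squared limit at large n", {
  set.seed(42)
  n <- 10000
  x <- rnorm(n); z <- rnorm(n)
  y <- 0.03 * x + 0.5 * z + rnorm(n)
  f0 <- fit_linear(y, cbind(z))
  f1 <- fit_linear(y, cbind(x, z))
  ft <- f_test(f0, f1)
  p_chi <- pchisq(ft$statistic * ft$df1, ft$df1, lower.tail = FALSE)
  expect_lt(abs(ft$pvalue - p_chi) / p_chi, 0.02)
})

test_that("binary logistic fit reproduces closed forms and the glm oracle", {
  set.seed(11)
  # intercept-only closed form
  y <- factor(c(rep("1", 7), rep("2", 13)))
  f0 <- fit_logistic(y, matrix(numeric(0), 20, 0))
  expect_equal(f0$loglik, 7 * log(7 / 20) + 13 * log(13 / 20))
  expect_equal(f0$n_params, 1L)
  # with predictors: same maximum as stats::glm
  n <- 100
  X <- matrix(rnorm(2 * n), n, 2)
  yb <- factor(rbinom(n, 1, plogis(0.3 + X %*% c(1, -0.5))))
  fit <- fit_logistic(yb, X)
  or <- stats::glm(yb ~ X, family = binomial())
  expect_equal(fit$loglik, as.numeric(logLik(or)), tolerance = 1e-6)
  expect_equal(fit$n_params, 3L)
})

test_that("parameter counts reproduce the (d_Y - 1)(Dof + 1) formulas on a grid", {
  set.seed(20)
  n <- 400
  for (d_y in 2:5) for (dof_z in 0:4) for (dof_x in 1:4) {
    par0 <- (d_y - 1) * (dof_z + 1)
    par1 <- (d_y - 1) * (dof_z + dof_x + 1)
    y <- factor(sample(seq_len(d_y), n, replace = TRUE))
    X0 <- if (dof_z == 0) matrix(numeric(0), n, 0) else
      matrix(rnorm(n * dof_z), n)
    X1 <- cbind(X0, matrix(rnorm(n * dof_x), n))
    f0 <- fit_logistic(y, X0)
    f1 <- fit_logistic(y, X1)
    expect_identical(f0$n_params, as.integer(par0))
    expect_identical(f1$n_params, as.integer(par1))
    expect_identical(lr_test(f0, f1)$df, as.integer((d_y - 1) * dof_x))
  }
  # the same counting holds for the generalized ordered logit
  y <- factor(sample(1:4, n, replace = TRUE), ordered = TRUE)
  X <- matrix(rnorm(n * 2), n)
  expect_identical(fit_ordered_logit(y, X)$n_params, 3L * 3L)
})

test_that("multinomial fit matches nnet::multinom and a numeric-maximization oracle", {
  set.seed(33)
  n <- 150
  X <- matrix(rnorm(n), n, 1)
  lin <- cbind(0, 0.8 * X[, 1] - 0.2, -0.5 * X[, 1] + 0.4)
  pr <- exp(lin) / rowSums(exp(lin))
  y <- factor(vapply(seq_len(n), function(i)
    sample(1:3, 1, prob = pr[i, ]), integer(1)))
  fit <- fit_logistic(y, X)
  or <- nnet::multinom(y ~ X, trace = FALSE, reltol = 1e-12)
  expect_equal(fit$loglik, as.numeric(logLik(or)), tolerance = 1e-6)
  expect_equal(fit$n_params, 4L)
  # independent numeric maximization of the multinomial log-likelihood
  nll <- function(th) {
    eta <- cbind(0, th[1] + th[2] * X[, 1], th[3] + th[4] * X[, 1])
    -sum(eta[cbind(seq_len(n), as.integer(y))] - log(rowSums(exp(eta))))
  }
  op <- optim(rep(0, 4), nll, method = "BFGS",
              control = list(reltol = 1e-14, maxit = 1000))
  expect_equal(fit$loglik, -op$value, tolerance = 1e-6)
})

test_that("generalized ordered logit fits one binary split per cut", {
  set.seed(55)
  n <- 300
  X <- matrix(rnorm(n), n, 1)
  lat <- 0.9 * X[, 1] + rnorm(n)
  y <- cut(lat, c(-Inf, -0.5, 0.4, 1.1, Inf), labels = 1:4,
           ordered_result = TRUE)
  fit <- fit_ordered_logit(y, X)
  expect_length(fit$cut_fits, 3L)
  expect_equal(fit$n_params, 3L * 2L)
  # each cut equals an independently refit binary logistic regression
  yi <- as.integer(y)
  ll <- 0
  for (j in 1:3) {
    z <- factor(as.integer(yi > j))
    ref <- fit_logistic(z, X)
    expect_equal(fit$cut_fits[[j]]$loglik, ref$loglik, tolerance = 1e-8)
    ll <- ll + ref$loglik
  }
  expect_equal(fit$loglik, ll)
  # two ordered categories collapse to plain binary logistic regression
  y2 <- factor(as.integer(yi > 2), ordered = TRUE)
  expect_equal(fit_ordered_logit(y2, X)$loglik,
               fit_logistic(factor(as.integer(yi > 2)), X)$loglik,
               tolerance = 1e-10)
  # a declared-but-unobserved top level leaves a cut one-sided: fit fails
  yc <- factor(rep(c(1, 1, 2, 3), 75), levels = 1:4, ordered = TRUE)
  fc <- fit_ordered_logit(yc, X)
  expect_false(fc$converged)
  expect_false(fc$cut_fits[[3]]$converged)
})

test_that("likelihood-ratio test has the chi-squared tail and clamps at zero", {
  mk <- function(ll, k, fam = "binary_logit") {
    f <- fit_logistic(factor(c(rep("a", 5), rep("b", 5))),
                      matrix(numeric(0), 10, 0))
    f$loglik <- ll; f$n_params <- as.integer(k); f$family <- fam
    f
  }
  expect_equal(lr_test(mk(-10, 1), mk(-10, 2))$pvalue, 1)
  expect_equal(lr_test(mk(-10, 1), mk(-10 + 3.8415 / 2, 2))$pvalue, 0.05,
               tolerance = 1e-4)
  expect_equal(lr_test(mk(-10, 1), mk(-10 + 5.9915 / 2, 3))$pvalue, 0.05,
               tolerance = 1e-4)
  # tiny negative improvement clamps to zero
  tt <- lr_test(mk(-10, 1), mk(-10 - 1e-9, 2))
  expect_equal(tt$statistic, 0)
  expect_error(lr_test(mk(-10, 2), mk(-9, 2)), "nested")
})

test_that("log-likelihood is monotone in nested designs", {
  set.seed(88)
  n <- 200
  for (rep in 1:5) {
    X <- matrix(rnorm(n * 3), n)
    yb <- factor(rbinom(n, 1, 0.5))
    ym <- factor(sample(1:3, n, TRUE))
    yo <- factor(sample(1:3, n, TRUE), ordered = TRUE)
    yc <- rnorm(n)
    for (k in 0:2) {
      X0 <- X[, seq_len(k), drop = FALSE]
      X1 <- X[, seq_len(k + 1), drop = FALSE]
      expect_gte(fit_logistic(yb, X1)$loglik, fit_logistic(yb, X0)$loglik - 1e-6)
      expect_gte(fit_logistic(ym, X1)$loglik, fit_logistic(ym, X0)$loglik - 1e-6)
      expect_gte(fit_ordered_logit(yo, X1)$loglik,
                 fit_ordered_logit(yo, X0)$loglik - 1e-6)
      expect_gte(fit_linear(yc, X1)$loglik, fit_linear(yc, X0)$loglik - 1e-6)
    }
  }
})

test_that("binary-logit coefficients recover generating values at large n", {
  set.seed(91)
  n <- 20000
  x <- rnorm(n)
  beta <- c(-0.4, 0.7)
  y <- factor(rbinom(n, 1, plogis(beta[1] + beta[2] * x)))
  fit <- fit_logistic(y, cbind(x))
  or <- stats::glm(y ~ x, family = binomial())
  se <- summary(or)$coefficients[, "Std. Error"]
  expect_true(all(abs(fit$coef - beta) < 3 * se))
})

test_that("F test and likelihood-ratio test agree for continuous outcomes at large n", {
  set.seed(95)
  n <- 2000
  x <- rnorm(n); z <- rnorm(n)
  y <- 0.05 * x + 0.4 * z + rnorm(n)
  f0 <- fit_linear(y, cbind(z)); f1 <- fit_linear(y, cbind(x, z))
  pf_ <- f_test(f0, f1)$pvalue
  pl_ <- lr_test(f0, f1)$pvalue
  expect_lt(abs(pf_ - pl_) / pf_, 0.1)
})
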