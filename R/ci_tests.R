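#' @importFrom stats qlogis
NULL

# Regression family for an outcome type, fit + directional test in one step.
# Returns list(statistic, df, pvalue, reliable, family).
fit_and_test <- function(outcome, predictors_reduced, predictors_full, md) {
  sp <- md$specs[[outcome]]
  X0 <- build_design(md, predictors_reduced)
  X1 <- build_design(md, predictors_full)
  if (sp$vtype == "continuous") {
    y <- md$data[[outcome]]
    f0 <- fit_linear(y, X0)
    f1 <- fit_linear(y, X1)
    tt <- f_test(f0, f1)
    list(statistic = tt$statistic, df = tt$df1, df2 = tt$df2,
         pvalue = tt$pvalue, reliable = tt$reliable, family = "linear")
  } else {
    y <- md$data[[outcome]]
    fit_fun <- if (sp$vtype == "nominal") fit_logistic else fit_ordered_logit
    f0 <- fit_fun(y, X0)
    f1 <- fit_fun(y, X1)
    tt <- lr_test(f0, f1)
    list(statistic = tt$statistic, df = tt$df, df2 = NA_integer_,
         pvalue = tt$pvalue, reliable = tt$reliable, family = f1$family)
  }
}

#' One-directional conditional-independence test
#'
#' Tests `outcome` independent of `other` given `Z` by comparing the
#' regression of `outcome` on `Z` (reduced model) against the regression on
#' `{other} u Z` (full model). The regression family follows the outcome
#' type: linear regression with an F test for continuous outcomes, binary or
#' multinomial logistic regression with a likelihood-ratio test for nominal
#' outcomes, and the generalized ordered logit with a likelihood-ratio test
#' for ordinal outcomes. `Z` may be empty (intercept-only reduced model).
#'
#' @param outcome name of the variable regressed on.
#' @param other name of the variable whose contribution is tested.
#' @param Z character vector of conditioning variable names (may be empty).
#' @param md a [mixed_data()] object.
#' @return An object of class `asym_test`: `outcome_var`, `statistic`, `df`,
#'   `pvalue`, `reliable`, `family`. If the fits fail outright the result
#'   carries `pvalue = 1` and `reliable = FALSE` with a warning.
#' @export
asym_test <- function(outcome, other, Z = character(), md) {
  if (outcome == other) stop("outcome and other must differ")
  if (outcome %in% Z || other %in% Z)
    stop("tested variables must not appear in the conditioning set")
  res <- tryCatch(
    fit_and_test(outcome, Z, c(other, Z), md),
    error = function(e) {
      warning("directional test regressing on '", outcome, "' failed (",
              conditionMessage(e), "); p value set to 1", call. = FALSE)
      list(statistic = NA_real_, df = NA_integer_, df2 = NA_integer_,
           pvalue = 1, reliable = FALSE, family = NA_character_)
    })
  structure(list(outcome_var = outcome, other_var = other, cond_vars = Z,
                 statistic = res$statistic, df = res$df, df2 = res$df2,
                 pvalue = res$pvalue, reliable = res$reliable,
                 family = res$family),
            class = "asym_test")
}

#' @export
print.asym_test <- function(x, ...) {
  cat(sprintf(
    "<asym_test> %s ~ %s | {%s}  family=%s  stat=%.4g  df=%s  p=%.4g%s\n",
    x$outcome_var, x$other_var, paste(x$cond_vars, collapse = ","),
    x$family, x$statistic, x$df, x$pvalue,
    if (x$reliable) "" else "  [unreliable]"))
  invisible(x)
}

#' Combine two dependent directional p values
#'
#' `combine_mm()` implements the MM rule
#' `p = min(2 * min(p1, p2), max(p1, p2))`, a combination rule for dependent
#' p values; `combine_min()` and `combine_max()` take the plain minimum and
#' maximum. All three are symmetric in their arguments and the result is
#' clamped to `[0, 1]`.
#'
#' @param p1,p2 p values in `[0, 1]`.
#' @return A single combined p value; `combine_min <= combine_mm <=
#'   combine_max` holds for every input pair.
#' @export
combine_mm <- function(p1, p2) {
  stopifnot(p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1)
  min(1, min(2 * min(p1, p2), max(p1, p2)))
}

#' @rdname combine_mm
#' @export
combine_min <- function(p1, p2) {
  stopifnot(p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1)
  min(p1, p2)
}

#' @rdname combine_mm
#' @export
combine_max <- function(p1, p2) {
  stopifnot(p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1)
  max(p1, p2)
}

#' Choose the outcome variable for the Fast single-direction strategy
#'
#' Priority: continuous > nominal > ordinal (the continuous-outcome model has
#' the fewest parameters and linear fits are the most accurate; ordinal
#' models are the hardest to fit). Between two categoricals of the same type
#' the one with fewer levels is regressed on; an exact tie is broken by the
#' lexicographically smaller name, which makes the choice deterministic and
#' invariant to argument order.
#'
#' @param spec_x,spec_y `var_spec` objects for the two variables.
#' @return The name of the variable to regress on.
#' @export
fast_select <- function(spec_x, spec_y) {
  rank_of <- function(s)
    match(s$vtype, c("continuous", "nominal", "ordinal"))
  rx <- rank_of(spec_x); ry <- rank_of(spec_y)
  if (rx != ry) return(if (rx < ry) spec_x$name else spec_y$name)
  if (rx > 1L) {  # both categorical of the same kind: fewer levels wins
    dx <- length(spec_x$levels); dy <- length(spec_y$levels)
    if (dx != dy) return(if (dx < dy) spec_x$name else spec_y$name)
  }
  min(spec_x$name, spec_y$name)
}

#' Symmetric conditional-independence test for mixed data
#'
#' Tests `x` independent of `y` given `Z` symmetrically. Methods `"mm"`,
#' `"min"` and `"max"` run both directional tests ([asym_test()] regressing
#' on `x` and on `y`) and combine the two p values with [combine_mm()],
#' [combine_min()] or [combine_max()]; method `"fast"` runs a single
#' directional test with the outcome chosen by [fast_select()]. When both
#' variables are continuous the two directions give identical p values
#' exactly, so a single F test is computed. The result is invariant to
#' swapping `x` and `y` for every method.
#'
#' If one direction's fit is unreliable the other direction's p value is
#' used (with a warning); if both fail the test returns `pvalue = 1`,
#' favouring edge deletion over a crash.
#'
#' @param x,y names of the two variables under test.
#' @param Z character vector of conditioning variable names (default empty).
#' @param md a [mixed_data()] object.
#' @param method one of `"mm"`, `"min"`, `"max"`, `"fast"`.
#' @return An object of class `sym_test`: `pvalue`, `method`, `p1`, `p2`
#'   (directional p values, `p2` absent for fast), `chosen_outcome`,
#'   `reliable`.
#' @examples
#' md <- make_pair_structure("indep", "L-B", n = 200, seed = 7)
#' symmetric_test("X", "Y", md = md, method = "mm")
#' @export
symmetric_test <- function(x, y, Z = character(), md,
                           method = c("mm", "min", "max", "fast")) {
  method <- match.arg(method)
  # canonical order: makes every code path independent of argument order
  if (x > y) { tmp <- x; x <- y; y <- tmp }
  sx <- md$specs[[x]]; sy <- md$specs[[y]]
  if (is.null(sx) || is.null(sy)) stop("unknown variable in symmetric_test")

  both_cont <- sx$vtype == "continuous" && sy$vtype == "continuous"
  if (method == "fast" || both_cont) {
    out <- if (both_cont) x else fast_select(sx, sy)
    oth <- if (out == x) y else x
    t1 <- asym_test(out, oth, Z, md)
    p1 <- t1$pvalue; reliable <- t1$reliable
    if (!reliable && !both_cont) {  # fall back to the opposite direction
      t2 <- asym_test(oth, out, Z, md)
      if (t2$reliable) {
        warning("fast direction unreliable; using the opposite direction",
                call. = FALSE)
        p1 <- t2$pvalue; out <- oth; reliable <- TRUE
      }
    }
    return(structure(list(pvalue = p1, method = method,
                          p1 = p1, p2 = if (both_cont) p1 else NA_real_,
                          chosen_outcome = out, x = x, y = y, Z = Z,
                          reliable = reliable),
                     class = "sym_test"))
  }

  t1 <- asym_test(x, y, Z, md)
  t2 <- asym_test(y, x, Z, md)
  p1 <- t1$pvalue; p2 <- t2$pvalue
  if (t1$reliable && t2$reliable) {
    p <- switch(method, mm = combine_mm(p1, p2), min = combine_min(p1, p2),
                max = combine_max(p1, p2))
    reliable <- TRUE
  } else if (t1$reliable || t2$reliable) {
    warning("one directional test unreliable; using the other direction's ",
            "p value", call. = FALSE)
    p <- if (t1$reliable) p1 else p2
    reliable <- TRUE
  } else {
    p <- 1
    reliable <- FALSE
  }
  structure(list(pvalue = min(1, max(0, p)), method = method,
                 p1 = p1, p2 = p2, chosen_outcome = NA_character_,
                 x = x, y = y, Z = Z, reliable = reliable),
            class = "sym_test")
}

#' @export
print.sym_test <- function(x, ...) {
  cat(sprintf("\n\tSymmetric conditional-independence test (%s)\n\n",
              toupper(x$method)))
  cat(sprintf("%s _||_ %s | {%s}\n", x$x, x$y, paste(x$Z, collapse = ", ")))
  if (!is.na(x$p2) && x$method != "fast")
    cat(sprintf("directional p values: p1 = %.4g (on %s), p2 = %.4g (on %s)\n",
                x$p1, x$x, x$p2, x$y))
  if (!is.na(x$chosen_outcome))
    cat(sprintf("outcome regressed on: %s\n", x$chosen_outcome))
  cat(sprintf("combined p value: %.4g%s\n", x$pvalue,
              if (x$reliable) "" else "  [unreliable]"))
  invisible(x)
}
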