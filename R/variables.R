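#' Declare a variable and its measurement type
#'
#' A variable specification records the name, the type (continuous, nominal or
#' ordinal) and, for categorical variables, the ordered set of admissible
#' levels. Specifications drive the choice of regression family when the
#' variable is an outcome, the dummy encoding when it is a predictor, and the
#' degrees-of-freedom accounting of the likelihood-ratio tests.
#'
#' @param name variable name (single string).
#' @param vtype one of `"continuous"`, `"nominal"`, `"ordinal"`.
#' @param levels character vector of category labels, in order (ordinal order
#'   is taken from this declaration, never from the data). Must be empty for
#'   continuous variables and have at least two entries otherwise.
#' @return An object of class `var_spec`.
#' @examples
#' variable_spec("age", "continuous")
#' variable_spec("stage", "ordinal", c("I", "II", "III"))
#' @export
variable_spec <- function(name, vtype = c("continuous", "nominal", "ordinal"),
                          levels = character()) {
  vtype <- match.arg(vtype)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  levels <- as.character(levels)
  if (vtype == "continuous") {
    if (length(levels) > 0L)
      stop("continuous variable '", name, "' must not declare levels")
  } else {
    if (length(levels) < 2L)
      stop(vtype, " variable '", name, "' needs at least 2 levels")
    if (anyDuplicated(levels))
      stop("duplicated levels for variable '", name, "'")
  }
  structure(list(name = name, vtype = vtype, levels = levels),
            class = "var_spec")
}

#' @export
print.var_spec <- function(x, ...) {
  if (x$vtype == "continuous") {
    cat(sprintf("<var_spec> %s: continuous\n", x$name))
  } else {
    cat(sprintf("<var_spec> %s: %s (%s)\n", x$name, x$vtype,
                paste(x$levels, collapse = " < ")))
  }
  invisible(x)
}

is_categorical <- function(spec) spec$vtype != "continuous"

#' Degrees of freedom of a set of variables
#'
#' A continuous variable contributes one degree of freedom; a categorical
#' variable with `d` levels contributes `d - 1` (the number of dummy columns
#' it expands to). The degrees of freedom of a set is the sum over its members.
#'
#' @param specs a single `var_spec` or a list of them; an empty list gives 0.
#' @return Integer degrees of freedom.
#' @examples
#' dof(variable_spec("x", "continuous"))                        # 1
#' dof(variable_spec("g", "nominal", c("a", "b", "c", "d")))    # 3
#' @export
dof <- function(specs) {
  if (inherits(specs, "var_spec")) specs <- list(specs)
  if (length(specs) == 0L) return(0L)
  sum(vapply(specs, function(s) {
    if (s$vtype == "continuous") 1L else length(s$levels) - 1L
  }, integer(1)))
}

#' Bind a sample table to its variable specifications
#'
#' Validates that every column of `data` has a specification, that all
#' categorical cells take declared levels, and that there are no missing
#' values (rejected at load: the tests have no missing-data machinery).
#' Categorical columns are stored as factors with levels in declared order;
#' ordinal columns as ordered factors.
#'
#' @param data a data.frame, one row per sample, one column per variable.
#' @param specs a list of [variable_spec()] objects, one per column of `data`
#'   (matched by name).
#' @return An object of class `mixed_data` with elements `data` and `specs`.
#' @export
mixed_data <- function(data, specs) {
  data <- as.data.frame(data)
  if (nrow(data) < 1L) stop("need at least one sample")
  if (inherits(specs, "var_spec")) specs <- list(specs)
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  missing_spec <- setdiff(names(data), names(specs))
  if (length(missing_spec))
    stop("no variable_spec for column(s): ", paste(missing_spec, collapse = ", "))
  specs <- specs[names(data)]
  for (nm in names(data)) {
    sp <- specs[[nm]]
    col <- data[[nm]]
    if (anyNA(col))
      stop("missing values in column '", nm, "' (row ",
           which(is.na(col))[1L], "); missing data are not supported")
    if (sp$vtype == "continuous") {
      if (!is.numeric(col))
        stop("column '", nm, "' declared continuous but is not numeric")
      data[[nm]] <- as.numeric(col)
    } else {
      col <- as.character(col)
      bad <- setdiff(unique(col), sp$levels)
      if (length(bad))
        stop("column '", nm, "' contains undeclared level(s): ",
             paste(bad, collapse = ", "))
      data[[nm]] <- factor(col, levels = sp$levels,
                           ordered = sp$vtype == "ordinal")
    }
  }
  structure(list(data = data, specs = specs), class = "mixed_data")
}

#' @export
print.mixed_data <- function(x, ...) {
  tps <- vapply(x$specs, `[[`, character(1), "vtype")
  cat(sprintf("<mixed_data> %d samples x %d variables (%s)\n",
              nrow(x$data), length(x$specs),
              paste(sprintf("%d %s", table(factor(tps, c("continuous", "nominal", "ordinal"))),
                            c("continuous", "nominal", "ordinal"))[table(factor(tps, c("continuous", "nominal", "ordinal"))) > 0],
                    collapse = ", ")))
  invisible(x)
}

#' @export
dim.mixed_data <- function(x) dim(x$data)

#' Dummy-encode a categorical column
#'
#' Expands a categorical variable with `d` levels into `d - 1` binary
#' indicator columns against a reference level, which is always the first
#' declared level. The indicator for level `l` is 1 where the value equals
#' `l`. A value equal to the reference level yields a row of zeros.
#'
#' @param column vector of values (character or factor).
#' @param spec the `var_spec` of the variable (nominal or ordinal).
#' @return Numeric matrix with `d - 1` columns named `<name>.<level>`.
#' @export
encode_dummies <- function(column, spec) {
  if (!is_categorical(spec))
    stop("encode_dummies: '", spec$name, "' is continuous")
  column <- as.character(column)
  bad <- setdiff(unique(column), spec$levels)
  if (length(bad))
    stop("unseen level(s) for '", spec$name, "': ", paste(bad, collapse = ", "))
  lv <- spec$levels[-1L]
  out <- matrix(0, nrow = length(column), ncol = length(lv),
                dimnames = list(NULL, paste(spec$name, lv, sep = ".")))
  for (j in seq_along(lv)) out[, j] <- as.numeric(column == lv[j])
  out
}

# Design matrix (no intercept column) for a set of predictor variables.
# Categorical predictors -- ordinal ones included -- are dummy-encoded;
# continuous predictors enter as-is. Column count equals dof(vars).
build_design <- function(md, vars) {
  n <- nrow(md$data)
  if (length(vars) == 0L)
    return(matrix(numeric(0), nrow = n, ncol = 0L))
  blocks <- lapply(vars, function(nm) {
    sp <- md$specs[[nm]]
    if (is.null(sp)) stop("unknown variable '", nm, "'")
    if (sp$vtype == "continuous") {
      matrix(md$data[[nm]], ncol = 1L, dimnames = list(NULL, nm))
    } else {
      encode_dummies(md$data[[nm]], sp)
    }
  })
  do.call(cbind, blocks)
}
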