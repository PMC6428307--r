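#' @importFrom utils read.csv write.table
NULL

#' Write a mixed dataset as CSV plus a JSON type sidecar
#'
#' The sample table is written as a comma-separated UTF-8 file with a header
#' row; continuous columns are printed with 17 significant digits so the
#' write/read round trip reproduces the doubles bit-exactly. The sidecar JSON
#' maps each column name to its `vtype` and declared `levels` — variable
#' types are never inferred from the data, because silently confusing ordinal
#' with nominal columns would change the regression family used by the tests.
#'
#' @param md a [mixed_data()] object.
#' @param data_path CSV output path.
#' @param types_path JSON output path.
#' @return `data_path` invisibly.
#' @export
write_mixed_data <- function(md, data_path, types_path) {
  df <- md$data
  out <- df
  for (nm in names(df)) {
    out[[nm]] <- if (md$specs[[nm]]$vtype == "continuous")
      sprintf("%.17g", df[[nm]]) else as.character(df[[nm]])
  }
  write.table(out, data_path, sep = ",", quote = TRUE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8")
  types <- lapply(md$specs, function(sp)
    list(vtype = sp$vtype, levels = sp$levels))
  jsonlite::write_json(types, types_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(data_path)
}

#' Read a mixed dataset from CSV plus a JSON type sidecar
#'
#' @param data_path CSV file with a header row.
#' @param types_path JSON file mapping column name to `vtype` and `levels`
#'   (as written by [write_mixed_data()]). Every data column must be listed;
#'   categorical level order is taken from the declaration, not from order of
#'   appearance in the data.
#' @return A validated [mixed_data()] object.
#' @export
read_mixed_data <- function(data_path, types_path) {
  df <- read.csv(data_path, stringsAsFactors = FALSE,
                 colClasses = "character", check.names = FALSE)
  types <- jsonlite::read_json(types_path, simplifyVector = TRUE)
  missing <- setdiff(names(df), names(types))
  if (length(missing))
    stop("column(s) missing from types file: ", paste(missing, collapse = ", "))
  specs <- lapply(names(df), function(nm) {
    tp <- types[[nm]]
    variable_spec(nm, tp$vtype, unlist(tp$levels))
  })
  for (nm in names(df)) {
    if (types[[nm]]$vtype == "continuous") {
      suppressWarnings(v <- as.numeric(df[[nm]]))
      if (anyNA(v) && !anyNA(df[[nm]]))
        stop("non-numeric value in continuous column '", nm, "'")
      df[[nm]] <- v
    }
  }
  mixed_data(df, specs)
}
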