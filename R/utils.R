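# Internal helpers: classed conditions, slugs, number formatting.

#' @noRd
cq_abort <- function(class, msg, ...) {
  data <- list(...)
  cond <- structure(
    class = c(class, "cq_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), data = data)
  )
  stop(cond)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Lower-case slug used for concept IDs and ontology IRIs: alphanumerics kept,
# runs of anything else collapsed to "_".
#' @noRd
slugify <- function(x) {
  s <- tolower(x)
  s <- gsub("[^a-z0-9]+", "_", s)
  gsub("^_+|_+$", "", s)
}

# Print a number the way the query dialect expects: no trailing ".0",
# no scientific notation.
#' @noRd
fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("null")
    format(v, scientific = FALSE, trim = TRUE, drop0trailing = TRUE)
  }, character(1))
}

#' @noRd
trimws2 <- function(x) trimws(x, which = "both")

# Case-insensitive header lookup; errors with the missing column's name.
#' @noRd
require_columns <- function(df, cols, what) {
  have <- tolower(trimws2(names(df)))
  for (col in cols) {
    if (!tolower(col) %in% have) {
      cq_abort("cq_schema_error",
               sprintf("%s: required column '%s' is missing", what, col),
               column = col)
    }
  }
  names(df) <- trimws2(names(df))
  df
}

#' @noRd
get_col <- function(df, col) {
  i <- match(tolower(col), tolower(names(df)))
  v <- df[[i]]
  if (is.null(v)) rep("", nrow(df)) else as.character(v)
}

#' @noRd
read_cq_csv <- function(path) {
  utils::read.csv(path, colClasses = "character", check.names = FALSE,
                  fileEncoding = "UTF-8")
}

#' @noRd
write_cq_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
}
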