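#' Resolve a short form name to its full name
#'
#' Some codebooks store the form (the grouping of a variable, e.g. a case
#' report form) under a short code such as `"a1"`. The resolver maps short
#' codes to full display names using a caller-supplied two-column lookup
#' table. Matching is exact but case-insensitive after trimming.
#'
#' @param short Character vector of short form codes.
#' @param lookup Data frame with columns `short`, `full`; defaults to the
#'   table shipped with the package (see [default_form_names()]).
#' @return Character vector of full form names.
#' @export
#' @examples
#' resolve_form_name("a1")
resolve_form_name <- function(short, lookup = default_form_names()) {
  lookup <- require_columns(lookup, c("short", "full"), "form-name lookup")
  key <- tolower(trimws2(get_col(lookup, "short")))
  idx <- match(tolower(trimws2(short)), key)
  if (anyNA(idx)) {
    bad <- short[is.na(idx)][1]
    cq_abort("cq_lookup_error",
             sprintf("unknown form short name: '%s'", bad), code = bad)
  }
  get_col(lookup, "full")[idx]
}

#' Shipped short-to-full form-name table
#'
#' A configurable stub covering the standard annual-visit forms; extend or
#' replace it by passing your own table to [resolve_form_name()] or
#' [parse_dictionary()].
#'
#' @return Data frame with columns `short`, `full`.
#' @export
default_form_names <- function() {
  path <- system.file("extdata", "form_names.csv", package = "cohortquery",
                      mustWork = TRUE)
  read_cq_csv(path)
}

# The uniform in-memory dictionary model is a plain data frame, one row per
# data element definition, with the code spec kept as its canonical string.
dict_cols <- c("source", "variable_name", "group_name", "descriptor",
               "data_type", "code_spec", "units", "table_name")

new_dictionary <- function(source, variable_name, group_name, descriptor,
                           code_spec_str, units, table_name) {
  specs <- lapply(code_spec_str, parse_code_spec)
  # Type inference: the dictionary type columns do not separate coded
  # categoricals from true numerics, so the parsed code spec decides.
  data_type <- vapply(specs, function(s) {
    if (s$kind == "categorical") "categorical" else "numeric"
  }, character(1))
  canon <- vapply(specs, format_code_spec, character(1))
  df <- data.frame(source = source, variable_name = trimws2(variable_name),
                   group_name = group_name, descriptor = descriptor,
                   data_type = data_type, code_spec = canon,
                   units = trimws2(units), table_name = trimws2(table_name),
                   stringsAsFactors = FALSE)
  key <- paste(df$source, df$table_name, df$variable_name, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df$variable_name[duplicated(key)][1]
    cq_abort("cq_duplicate_definition",
             sprintf("duplicate data element definition: '%s'", dup),
             variable = dup)
  }
  if (any(!nzchar(df$variable_name))) {
    cq_abort("cq_schema_error", "empty variable name in dictionary")
  }
  df
}

#' Parse a study data dictionary into the uniform model
#'
#' Reads tabular dictionary records in one of three schemas and normalizes
#' them into a data frame of data element definitions with columns
#' `source`, `variable_name`, `group_name`, `descriptor`, `data_type`,
#' `code_spec` (canonical string, see [format_code_spec()]), `units`,
#' `table_name`.
#'
#' * `"nacc"`: single-file style with columns `VariableName`, `Form`,
#'   `ShortDescriptor`, `DataType`, `AllowableCodes`. Short form codes are
#'   resolved to full names via `form_lookup`.
#' * `"adni"`: multi-table style with columns `FLDNAME`, `CRFNAME`, `TEXT`,
#'   `TYPE`, `CODE` (plus optional `TBLNAME`, `UNITS`, `Phase`, `LENGTH`).
#'   Descriptors are passed through [expand_concatenated()] to fix
#'   concatenated brain-region phrases.
#' * `"normalized"`: the package's own write-back format (a fixed point of
#'   parse/write/parse).
#'
#' The data type of every element is inferred from its parsed code spec:
#' categorical iff it enumerates categories and carries no range, else
#' numeric. Elements with an empty code spec are numeric and unconstrained.
#'
#' @param rows Data frame of dictionary records.
#' @param schema One of `"nacc"`, `"adni"`, `"normalized"`.
#' @param source Dataset name to tag definitions with; defaults to the
#'   upper-cased schema name (ignored for `"normalized"`, which carries its
#'   own `source` column).
#' @param form_lookup Short-to-full form-name table for the `"nacc"` schema.
#' @return Data frame of data element definitions (zero rows for empty
#'   input).
#' @export
parse_dictionary <- function(rows, schema = c("nacc", "adni", "normalized"),
                             source = NULL,
                             form_lookup = default_form_names()) {
  schema <- match.arg(schema)
  if (nrow(rows) == 0L) {
    df <- data.frame(matrix(character(), 0, length(dict_cols)),
                     stringsAsFactors = FALSE)
    names(df) <- dict_cols
    return(df)
  }
  if (schema == "nacc") {
    rows <- require_columns(rows, c("VariableName", "Form", "ShortDescriptor",
                                    "DataType", "AllowableCodes"),
                            "dictionary (nacc schema)")
    new_dictionary(source = source %||% "NACC",
                   variable_name = get_col(rows, "VariableName"),
                   group_name = resolve_form_name(get_col(rows, "Form"),
                                                  form_lookup),
                   descriptor = get_col(rows, "ShortDescriptor"),
                   code_spec_str = get_col(rows, "AllowableCodes"),
                   units = "", table_name = "")
  } else if (schema == "adni") {
    rows <- require_columns(rows, c("FLDNAME", "CRFNAME", "TEXT", "TYPE",
                                    "CODE"), "dictionary (adni schema)")
    has <- function(col) tolower(col) %in% tolower(names(rows))
    new_dictionary(source = source %||% "ADNI",
                   variable_name = get_col(rows, "FLDNAME"),
                   group_name = get_col(rows, "CRFNAME"),
                   descriptor = expand_concatenated(get_col(rows, "TEXT")),
                   code_spec_str = get_col(rows, "CODE"),
                   units = if (has("UNITS")) get_col(rows, "UNITS") else "",
                   table_name = if (has("TBLNAME")) get_col(rows, "TBLNAME")
                                else "")
  } else {
    rows <- require_columns(rows, dict_cols, "dictionary (normalized schema)")
    new_dictionary(source = get_col(rows, "source"),
                   variable_name = get_col(rows, "variable_name"),
                   group_name = get_col(rows, "group_name"),
                   descriptor = get_col(rows, "descriptor"),
                   code_spec_str = get_col(rows, "code_spec"),
                   units = get_col(rows, "units"),
                   table_name = get_col(rows, "table_name"))
  }
}

#' Write a normalized dictionary to CSV
#'
#' The output re-parses identically under
#' `parse_dictionary(schema = "normalized")`.
#'
#' @param defs Data frame as returned by [parse_dictionary()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dictionary <- function(defs, path) {
  stopifnot(all(dict_cols %in% names(defs)))
  write_cq_csv(defs[, dict_cols], path)
  invisible(path)
}

#' Read a dictionary CSV from disk
#'
#' @inheritParams parse_dictionary
#' @param path CSV file path.
#' @return Data frame of data element definitions.
#' @export
read_dictionary <- function(path, schema = c("nacc", "adni", "normalized"),
                            source = NULL,
                            form_lookup = default_form_names()) {
  parse_dictionary(read_cq_csv(path), schema = match.arg(schema),
                   source = source, form_lookup = form_lookup)
}
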