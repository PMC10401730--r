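# In-memory record store with document-database filter semantics: all
# datasets live in one collection; a record simply lacks the fields its
# source table does not carry, and a filter on a field never matches a
# record where that field is absent (NA).

#' Create an in-memory record store
#'
#' Holds one collection of visit records across all datasets, filterable by
#' conjunctive field predicates with distinct-patient retrieval. Absent
#' fields are `NA` and never satisfy a predicate. The store is
#' environment-backed: [import_records()] mutates it in place.
#'
#' @param registry Named character vector mapping each dataset name to its
#'   patient-identifier field (e.g. `c(NACC = "NACCID", ADNI = "RID")`).
#' @return An object of class `cq_record_store`.
#' @export
record_store <- function(registry) {
  stopifnot(is.character(registry), !is.null(names(registry)),
            all(nzchar(names(registry))))
  env <- new.env(parent = emptyenv())
  env$registry <- registry
  env$records <- data.frame(dataset = character(), .pid = character(),
                            stringsAsFactors = FALSE)
  class(env) <- "cq_record_store"
  env
}

#' @export
print.cq_record_store <- function(x, ...) {
  n <- nrow(x$records)
  cat(sprintf("<record_store> %d records, datasets: %s\n", n,
              paste(names(x$registry), collapse = ", ")))
  invisible(x)
}

#' Patient-identifier field of a dataset
#' @param store A [record_store()].
#' @param dataset Dataset name.
#' @return The field name.
#' @export
patient_id_field <- function(store, dataset) {
  f <- store$registry[dataset]
  if (is.na(f)) {
    cq_abort("cq_lookup_error",
             sprintf("dataset '%s' is not registered", dataset),
             dataset = dataset)
  }
  unname(f)
}

# rbind two data frames over the union of their columns, NA-filling.
rbind_fill <- function(a, b) {
  if (nrow(a) == 0L) return(b)
  for (col in setdiff(names(a), names(b))) b[[col]] <- a[[col]][NA_integer_]
  for (col in setdiff(names(b), names(a))) a[[col]] <- b[[col]][NA_integer_]
  rbind(a, b[, names(a), drop = FALSE])
}

#' Import study rows into the record store
#'
#' Applies the catalog's import-time harmonization before storing: unit
#' rules convert the raw measurements in place; bin rules add the
#' harmonized categorical code as a new column named
#' `<variable>__harmonized`; sentinel codes of numeric variables (e.g.
#' `99 = Unknown`) are moved to a shadow column `<variable>__special` and
#' the numeric field left absent, so they can never satisfy an interval
#' predicate. Mapped numeric variables are coerced to numeric, categorical
#' ones kept as text codes. Each record is tagged with its dataset.
#'
#' @param store A [record_store()].
#' @param rows Data frame of raw study rows (one per patient visit).
#' @param dataset Dataset name (must be registered).
#' @param cat A [catalog()].
#' @param table_name Source table the rows come from (multi-table style);
#'   `""` for single-file sources.
#' @return The store, invisibly.
#' @export
import_records <- function(store, rows, dataset, cat, table_name = "") {
  stopifnot(inherits(store, "cq_record_store"))
  pid_field <- patient_id_field(store, dataset)
  if (!pid_field %in% names(rows)) {
    cq_abort("cq_import_error",
             sprintf("patient identifier column '%s' missing from '%s' rows",
                     pid_field, dataset),
             field = pid_field, dataset = dataset)
  }
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  for (col in names(rows)) {
    rows[[col]] <- as.character(rows[[col]])
    rows[[col]][!nzchar(trimws2(rows[[col]]))] <- NA_character_
  }

  mp <- cat$mappings[cat$mappings$source == dataset &
                       cat$mappings$table_name == table_name, , drop = FALSE]
  var_key <- paste(cat$variables$source, cat$variables$table_name,
                   cat$variables$variable_name, sep = "\r")
  out <- rows
  for (i in seq_len(nrow(mp))) {
    var <- mp$variable_name[i]
    if (!var %in% names(out)) next
    vi <- match(paste(dataset, table_name, var, sep = "\r"), var_key)
    vdef <- cat$variables[vi, ]
    vspec <- parse_code_spec(vdef$code_spec)
    if (vdef$data_type == "numeric") {
      raw <- out[[var]]
      specials <- vspec$special_codes$code
      is_special <- !is.na(raw) & raw %in% specials
      num <- suppressWarnings(as.numeric(raw))
      num[is_special] <- NA_real_
      if (any(is_special)) {
        out[[paste0(var, "__special")]] <-
          ifelse(is_special, raw, NA_character_)
      }
      if (nzchar(mp$unit_factor[i])) {
        ur <- unit_rule(mp$concept_id[i], dataset,
                        factor = as.numeric(mp$unit_factor[i]),
                        direction = mp$unit_direction[i])
        num[!is.na(num)] <- convert_unit(num[!is.na(num)], ur)
      }
      if (nzchar(mp$bins[i])) {
        br <- bin_rule(mp$concept_id[i], dataset, parse_bins(mp$bins[i]))
        harm <- rep(NA_character_, length(num))
        harm[!is.na(num)] <- bin_numeric(num[!is.na(num)], br)
        # sentinels pass through into the harmonized categorical column
        harm[is_special] <- raw[is_special]
        out[[paste0(var, "__harmonized")]] <- harm
      }
      out[[var]] <- num
    }
  }
  out$dataset <- dataset
  out$.pid <- as.character(rows[[pid_field]])
  if (anyNA(out$.pid)) {
    cq_abort("cq_import_error",
             sprintf("empty patient identifier in '%s' rows", dataset),
             dataset = dataset)
  }
  store$records <- rbind_fill(store$records, out)
  invisible(store)
}
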