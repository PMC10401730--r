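# The harmonization catalog: common concepts, source variables,
# variable-to-concept mappings (carrying unit and binning rules), and the
# categorical value-harmonization table. Persisted as five CSV files.

catalog_files <- c(concepts = "concepts.csv",
                   variables = "variables.csv",
                   mappings = "mappings.csv",
                   permissible_values = "permissible_values.csv",
                   value_maps = "value_harmonization.csv")

empty_df <- function(cols) {
  df <- data.frame(matrix(character(), 0, length(cols)),
                   stringsAsFactors = FALSE)
  names(df) <- cols
  df
}

concept_cols <- c("concept_id", "label", "category", "data_type",
                  "code_spec", "units")
mapping_cols <- c("concept_id", "source", "variable_name", "table_name",
                  "unit_factor", "unit_direction", "raw_unit",
                  "harmonized_unit", "bins")
value_map_cols <- c("source", "concept_id", "raw_value", "raw_label",
                    "harmonized_value", "harmonized_label")

#' Construct a harmonization catalog
#'
#' A catalog bundles everything needed to answer concept-level queries over
#' raw per-source study data: the harmonized common concepts with their
#' value domains, the source data element definitions, the
#' variable-to-concept mappings (which also carry per-source unit-conversion
#' factors and numeric-to-categorical bin tables), and the per-source
#' raw-code to harmonized-code recoding table for categorical concepts with
#' inconsistent codings.
#'
#' @param concepts Data frame with columns `concept_id`, `label`,
#'   `category`, `data_type` (`"numeric"`/`"categorical"`), `code_spec`
#'   (canonical harmonized value domain string), `units`.
#' @param variables Data frame of data element definitions, as returned by
#'   [parse_dictionary()].
#' @param mappings Data frame with columns `concept_id`, `source`,
#'   `variable_name`, `table_name`, `unit_factor`, `unit_direction`,
#'   `raw_unit`, `harmonized_unit`, `bins` (serialized bin table, see
#'   [format_bins()]). Unit/bin columns are empty when no rule applies.
#' @param value_maps Data frame with columns `source`, `concept_id`,
#'   `raw_value`, `raw_label`, `harmonized_value`, `harmonized_label`.
#' @param validate Check invariants (referential integrity, functional
#'   value maps, domains) immediately.
#' @return An object of class `cq_catalog`.
#' @export
catalog <- function(concepts = NULL, variables = NULL, mappings = NULL,
                    value_maps = NULL, validate = TRUE) {
  cat <- structure(list(
    concepts = as_chr_df(concepts %||% empty_df(concept_cols), concept_cols),
    variables = as_chr_df(variables %||% empty_df(dict_cols), dict_cols),
    mappings = as_chr_df(mappings %||% empty_df(mapping_cols), mapping_cols),
    value_maps = as_chr_df(value_maps %||% empty_df(value_map_cols),
                           value_map_cols)
  ), class = "cq_catalog")
  if (validate) validate_catalog(cat)
  cat
}

as_chr_df <- function(df, cols) {
  for (col in cols) {
    if (is.null(df[[col]])) df[[col]] <- rep("", nrow(df))
    df[[col]] <- as.character(df[[col]])
    df[[col]][is.na(df[[col]])] <- ""
  }
  df <- df[, cols, drop = FALSE]
  rownames(df) <- NULL
  df
}

#' @export
print.cq_catalog <- function(x, ...) {
  cat(sprintf(paste0("<catalog> %d concepts, %d variables, %d mappings, ",
                     "%d value-map rows\n"),
              nrow(x$concepts), nrow(x$variables), nrow(x$mappings),
              nrow(x$value_maps)))
  invisible(x)
}

#' Parsed harmonized value domain of a concept
#'
#' @param cat A [catalog()].
#' @param concept_id Concept identifier.
#' @return A [code_spec()] object.
#' @export
concept_domain <- function(cat, concept_id) {
  i <- match(concept_id, cat$concepts$concept_id)
  if (is.na(i)) {
    cq_abort("cq_lookup_error",
             sprintf("unknown concept: '%s'", concept_id),
             concept = concept_id)
  }
  parse_code_spec(cat$concepts$code_spec[i])
}

# All permissible text codes of a concept (categories plus sentinels).
domain_codes <- function(spec) {
  c(spec$categories$code, spec$special_codes$code)
}

domain_label <- function(spec, code) {
  tab <- rbind(spec$categories, spec$special_codes)
  tab$label[match(code, tab$code)]
}

#' Validate catalog invariants
#'
#' Checks referential integrity (every mapping and value-map row points to
#' an existing concept and source variable), uniqueness (one variable per
#' concept and source; functional value maps), and that every harmonized
#' value lies in its concept's harmonized domain. Throws a classed
#' validation error listing all offending rows.
#'
#' @param cat A [catalog()].
#' @return `cat`, invisibly.
#' @export
validate_catalog <- function(cat) {
  problems <- character()
  cn <- cat$concepts
  if (anyDuplicated(cn$concept_id)) {
    problems <- c(problems, sprintf("duplicate concept_id: %s",
                                    cn$concept_id[duplicated(cn$concept_id)]))
  }
  if (any(!nzchar(cn$label))) {
    problems <- c(problems, "concept with empty label")
  }
  specs <- lapply(cn$code_spec, parse_code_spec)
  bad_cat <- cn$data_type == "categorical" &
    vapply(specs, function(s) nrow(s$categories), 0L) < 2L
  bad_num <- cn$data_type == "numeric" &
    vapply(specs, function(s) is.null(s$range), TRUE)
  problems <- c(problems,
    sprintf("categorical concept '%s' needs >= 2 permissible values",
            cn$concept_id[bad_cat]),
    sprintf("numeric concept '%s' needs a harmonized range",
            cn$concept_id[bad_num]))

  mp <- cat$mappings
  orphan <- !(mp$concept_id %in% cn$concept_id)
  problems <- c(problems,
    sprintf("mapping to nonexistent concept '%s'", mp$concept_id[orphan]))
  var_key <- paste(cat$variables$source, cat$variables$table_name,
                   cat$variables$variable_name, sep = "\r")
  map_var_key <- paste(mp$source, mp$table_name, mp$variable_name, sep = "\r")
  novar <- !(map_var_key %in% var_key)
  problems <- c(problems,
    sprintf("mapping for '%s' to undeclared variable '%s' (%s)",
            mp$concept_id[novar], mp$variable_name[novar], mp$source[novar]))
  cs_key <- paste(mp$concept_id, mp$source, sep = "\r")
  problems <- c(problems,
    sprintf("more than one variable mapped for concept '%s' in '%s'",
            mp$concept_id[duplicated(cs_key)], mp$source[duplicated(cs_key)]))
  bad_factor <- nzchar(mp$unit_factor) &
    (is.na(suppressWarnings(as.numeric(mp$unit_factor))) |
       suppressWarnings(as.numeric(mp$unit_factor)) <= 0)
  problems <- c(problems,
    sprintf("unit factor for '%s' must be a positive number",
            mp$concept_id[bad_factor]))

  vm <- cat$value_maps
  vm_orphan <- !(vm$concept_id %in% cn$concept_id)
  problems <- c(problems,
    sprintf("value map for nonexistent concept '%s'",
            unique(vm$concept_id[vm_orphan])))
  vm_key <- paste(vm$source, vm$concept_id, vm$raw_value, sep = "\r")
  problems <- c(problems,
    sprintf("value map for ('%s', '%s') maps raw value '%s' twice",
            vm$source[duplicated(vm_key)], vm$concept_id[duplicated(vm_key)],
            vm$raw_value[duplicated(vm_key)]))
  ok_concept <- vm$concept_id %in% cn$concept_id
  for (i in which(ok_concept)) {
    spec <- specs[[match(vm$concept_id[i], cn$concept_id)]]
    if (!(vm$harmonized_value[i] %in% domain_codes(spec))) {
      problems <- c(problems,
        sprintf("harmonized value '%s' for concept '%s' not in its domain",
                vm$harmonized_value[i], vm$concept_id[i]))
    }
  }
  for (i in which(nzchar(mp$bins))) {
    bins <- parse_bins(mp$bins[i])
    spec <- specs[[match(mp$concept_id[i], cn$concept_id)]]
    if (!is.null(spec) && !all(bins$code %in% domain_codes(spec))) {
      problems <- c(problems,
        sprintf("bin codes for concept '%s' outside its harmonized domain",
                mp$concept_id[i]))
    }
  }

  if (length(problems)) {
    cq_abort("cq_validation_error",
             paste0("catalog validation failed:\n  ",
                    paste(problems, collapse = "\n  ")),
             problems = problems)
  }
  invisible(cat)
}

#' Serialize and parse a bin table
#'
#' A bin table maps a source's numeric values onto the harmonized
#' categorical codes. The serialized form is interval notation joined by
#' `";"`, e.g. `"[0,0]=0;(0,0.5)=1;[0.5,1)=2"`, with brackets recording
#' which endpoints are closed.
#'
#' @param bins Data frame with columns `lower`, `upper`, `lower_closed`,
#'   `upper_closed`, `code`.
#' @return `format_bins()` a single string; `parse_bins()` the data frame.
#' @export
format_bins <- function(bins) {
  paste0(ifelse(bins$lower_closed, "[", "("), fmt_num(bins$lower), ",",
         fmt_num(bins$upper), ifelse(bins$upper_closed, "]", ")"), "=",
         bins$code, collapse = ";")
}

#' @rdname format_bins
#' @param text Serialized bin table.
#' @export
parse_bins <- function(text) {
  parts <- strsplit(text, ";", fixed = TRUE)[[1]]
  re <- "^([[(])(-?[0-9.]+),(-?[0-9.]+)([])])=(.+)$"
  m <- regmatches(parts, regexec(re, parts))
  bad <- vapply(m, length, 0L) == 0L
  if (any(bad)) {
    cq_abort("cq_parse_error",
             sprintf("unparseable bin fragment: '%s'", parts[bad][1]),
             fragment = parts[bad][1])
  }
  data.frame(lower = as.numeric(vapply(m, `[`, "", 3)),
             upper = as.numeric(vapply(m, `[`, "", 4)),
             lower_closed = vapply(m, `[`, "", 2) == "[",
             upper_closed = vapply(m, `[`, "", 5) == "]",
             code = vapply(m, `[`, "", 6),
             stringsAsFactors = FALSE)
}

# Mapping row lookup for (concept, source); NA row index when unmapped.
mapping_row <- function(cat, concept_id, source) {
  which(cat$mappings$concept_id == concept_id &
          cat$mappings$source == source)[1]
}

#' Save a catalog as five CSV files
#'
#' Writes `concepts.csv`, `variables.csv`, `mappings.csv`,
#' `permissible_values.csv` (the harmonized categorical domains and
#' sentinel codes, one row per concept and code) and
#' `value_harmonization.csv` into `directory`. [load_catalog()] restores an
#' equal catalog (modulo row order) and re-validates all invariants.
#'
#' @param cat A [catalog()].
#' @param directory Target directory (created if needed).
#' @return `directory`, invisibly.
#' @export
save_catalog <- function(cat, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  cn <- cat$concepts
  specs <- lapply(cn$code_spec, parse_code_spec)
  rng <- t(vapply(specs, function(s) s$range %||% c(NA_real_, NA_real_),
                  numeric(2)))
  concepts_out <- data.frame(
    concept_id = cn$concept_id, label = cn$label, category = cn$category,
    data_type = cn$data_type,
    range_min = ifelse(is.na(rng[, 1]), "", fmt_num(rng[, 1])),
    range_max = ifelse(is.na(rng[, 2]), "", fmt_num(rng[, 2])),
    units = cn$units, stringsAsFactors = FALSE)
  pv <- do.call(rbind, lapply(seq_len(nrow(cn)), function(i) {
    tab <- rbind(specs[[i]]$categories, specs[[i]]$special_codes)
    if (nrow(tab) == 0L) return(NULL)
    data.frame(concept_id = cn$concept_id[i], value = tab$code,
               label = tab$label,
               kind = rep(c("category", "special"),
                          c(nrow(specs[[i]]$categories),
                            nrow(specs[[i]]$special_codes))),
               stringsAsFactors = FALSE)
  }))
  pv <- pv %||% empty_df(c("concept_id", "value", "label", "kind"))
  write_cq_csv(concepts_out, file.path(directory, catalog_files["concepts"]))
  write_cq_csv(cat$variables, file.path(directory, catalog_files["variables"]))
  write_cq_csv(cat$mappings, file.path(directory, catalog_files["mappings"]))
  write_cq_csv(pv, file.path(directory, catalog_files["permissible_values"]))
  write_cq_csv(cat$value_maps, file.path(directory, catalog_files["value_maps"]))
  invisible(directory)
}

#' Load a catalog from its five-file directory
#'
#' @param directory Directory written by [save_catalog()].
#' @return A validated [catalog()].
#' @export
load_catalog <- function(directory) {
  paths <- file.path(directory, catalog_files)
  missing <- !file.exists(paths)
  if (any(missing)) {
    cq_abort("cq_file_error",
             sprintf("catalog file missing: %s",
                     paste(catalog_files[missing], collapse = ", ")),
             files = catalog_files[missing])
  }
  names(paths) <- names(catalog_files)
  concepts_in <- read_cq_csv(paths["concepts"])
  pv <- read_cq_csv(paths["permissible_values"])
  concepts_in <- require_columns(concepts_in,
                                 c("concept_id", "label", "category",
                                   "data_type", "range_min", "range_max",
                                   "units"), "concepts.csv")
  pv <- require_columns(pv, c("concept_id", "value", "label", "kind"),
                        "permissible_values.csv")
  code_spec_str <- vapply(seq_len(nrow(concepts_in)), function(i) {
    cid <- concepts_in$concept_id[i]
    rows <- pv[pv$concept_id == cid, , drop = FALSE]
    lo <- concepts_in$range_min[i]
    if (nzchar(lo)) {
      spec <- code_spec("numeric_range",
                        range = as.numeric(c(lo, concepts_in$range_max[i])),
                        special_codes = if (nrow(rows)) {
                          data.frame(code = rows$value, label = rows$label,
                                     stringsAsFactors = FALSE)
                        } else NULL)
    } else if (nrow(rows)) {
      spec <- code_spec("categorical",
                        categories = data.frame(code = rows$value,
                                                label = rows$label,
                                                stringsAsFactors = FALSE))
    } else {
      spec <- code_spec("unconstrained")
    }
    format_code_spec(spec)
  }, character(1))
  concepts <- data.frame(concept_id = concepts_in$concept_id,
                         label = concepts_in$label,
                         category = concepts_in$category,
                         data_type = concepts_in$data_type,
                         code_spec = code_spec_str,
                         units = concepts_in$units, stringsAsFactors = FALSE)
  catalog(concepts = concepts,
          variables = read_cq_csv(paths["variables"]),
          mappings = read_cq_csv(paths["mappings"]),
          value_maps = read_cq_csv(paths["value_maps"]))
}
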