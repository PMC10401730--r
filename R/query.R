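# Concept-level query criteria, their translation into per-dataset filter
# expressions via the mapping catalog, execution with distinct-patient
# counting, and result regrouping.

#' Build query criteria
#'
#' Criteria are a conjunction of term criteria evaluated against one or
#' more datasets. A categorical term selects a set of harmonized codes; a
#' numeric term selects an inclusive range on the harmonized scale.
#'
#' @param datasets Character vector of dataset names (non-empty).
#' @param terms List of terms from [term_values()] / [term_range()].
#' @return An object of class `cq_query_criteria`.
#' @export
#' @examples
#' query_criteria("NACC", list(term_range("years_of_education", 5, 15)))
query_criteria <- function(datasets, terms = list()) {
  if (length(datasets) < 1L || any(!nzchar(datasets))) {
    cq_abort("cq_criteria_error", "at least one dataset must be selected")
  }
  structure(list(datasets = as.character(datasets), terms = terms),
            class = "cq_query_criteria")
}

#' Term criteria
#'
#' @param concept_id Concept identifier (must exist in the catalog when the
#'   criteria are validated or translated).
#' @param values Character vector of selected harmonized codes.
#' @return A term criterion list.
#' @export
term_values <- function(concept_id, values) {
  stopifnot(length(values) >= 1L)
  list(concept = concept_id, kind = "categorical",
       values = as.character(values))
}

#' @rdname term_values
#' @param min,max Inclusive range bounds on the harmonized scale.
#' @export
term_range <- function(concept_id, min, max) {
  if (!is.finite(min) || !is.finite(max) || min > max) {
    cq_abort("cq_criteria_error", "term range needs finite min <= max")
  }
  list(concept = concept_id, kind = "numeric", min = min, max = max)
}

#' Validate criteria against a catalog
#'
#' Checks that every term's concept exists, that numeric ranges lie within
#' the concept's harmonized range, and that selected values lie in the
#' harmonized domain.
#'
#' @param criteria A [query_criteria()].
#' @param cat A [catalog()].
#' @return `criteria`, invisibly.
#' @export
validate_criteria <- function(criteria, cat) {
  stopifnot(inherits(criteria, "cq_query_criteria"))
  for (term in criteria$terms) {
    spec <- concept_domain(cat, term$concept)  # errors on unknown concept
    if (term$kind == "numeric") {
      if (is.null(spec$range)) {
        cq_abort("cq_criteria_error",
                 sprintf("concept '%s' is not numeric", term$concept))
      }
      if (term$min < spec$range[1] || term$max > spec$range[2]) {
        cq_abort("cq_criteria_error",
                 sprintf("range [%s, %s] outside harmonized domain of '%s'",
                         fmt_num(term$min), fmt_num(term$max), term$concept))
      }
    } else {
      bad <- setdiff(term$values, domain_codes(spec))
      if (length(bad)) {
        cq_abort("cq_criteria_error",
                 sprintf("value '%s' not in harmonized domain of '%s'",
                         bad[1], term$concept))
      }
    }
  }
  invisible(criteria)
}

#' Read and write criteria as JSON
#'
#' The JSON contract is `{"datasets": [...], "terms": [{"concept": id,
#' "values": [...]} | {"concept": id, "min": x, "max": y}]}` (schema
#' shipped under `inst/schema/criteria.schema.json`).
#'
#' @param json JSON string or file path.
#' @return A [query_criteria()].
#' @export
read_criteria <- function(json) {
  parsed <- tryCatch(jsonlite::fromJSON(json, simplifyVector = FALSE),
                     error = function(e) {
    cq_abort("cq_criteria_error",
             sprintf("invalid criteria JSON: %s", conditionMessage(e)))
  })
  if (is.null(parsed$datasets) || !length(parsed$datasets)) {
    cq_abort("cq_criteria_error", "criteria JSON must name >= 1 dataset")
  }
  terms <- lapply(parsed$terms %||% list(), function(t) {
    if (is.null(t$concept)) {
      cq_abort("cq_criteria_error", "criteria term lacks a concept")
    }
    if (!is.null(t$values)) {
      term_values(t$concept, unlist(t$values))
    } else if (!is.null(t$min) && !is.null(t$max)) {
      term_range(t$concept, as.numeric(t$min), as.numeric(t$max))
    } else {
      cq_abort("cq_criteria_error",
               sprintf("term for '%s' needs values or min/max", t$concept))
    }
  })
  query_criteria(unlist(parsed$datasets), terms)
}

#' @rdname read_criteria
#' @param criteria A [query_criteria()].
#' @export
write_criteria <- function(criteria) {
  terms <- lapply(criteria$terms, function(t) {
    if (t$kind == "categorical") {
      list(concept = t$concept, values = t$values)
    } else {
      list(concept = t$concept, min = t$min, max = t$max)
    }
  })
  as.character(jsonlite::toJSON(list(datasets = criteria$datasets,
                                     terms = terms),
                                auto_unbox = TRUE, digits = NA))
}

#' Translate criteria into per-dataset backend queries
#'
#' For each selected dataset the concept of every term is resolved to that
#' dataset's raw variable via the catalog's variable mappings; selected
#' harmonized codes are rewritten to the dataset's raw codes by inverting
#' the value-harmonization table (identity when the pair has no recoding
#' rows); numeric ranges pass through unchanged because unit and bin
#' harmonization were already applied at import. Terms whose source
#' variable carries a bin rule filter the imported `__harmonized` column
#' with the harmonized codes directly. Terms are combined conjunctively.
#'
#' A dataset in which some term's concept has no mapped variable is
#' excluded from the result; the exclusions are reported in the
#' `"notices"` attribute.
#'
#' @param criteria A [query_criteria()].
#' @param cat A [catalog()].
#' @param registry Named character vector dataset name -> patient-id field.
#' @return List of `cq_backend_query` objects (one per translatable
#'   dataset) with a `"notices"` attribute (character vector).
#' @export
translate <- function(criteria, cat, registry) {
  validate_criteria(criteria, cat)
  notices <- character()
  queries <- list()
  for (ds in criteria$datasets) {
    pid <- registry[ds]
    if (is.na(pid)) {
      cq_abort("cq_lookup_error",
               sprintf("dataset '%s' is not registered", ds), dataset = ds)
    }
    filters <- list()
    skip <- FALSE
    for (term in criteria$terms) {
      mi <- mapping_row(cat, term$concept, ds)
      if (is.na(mi)) {
        notices <- c(notices,
                     sprintf("concept '%s' is not mapped in dataset '%s'",
                             term$concept, ds))
        skip <- TRUE
        break
      }
      mp <- cat$mappings[mi, ]
      if (term$kind == "numeric") {
        filters[[length(filters) + 1L]] <-
          list(field = mp$variable_name, kind = "range",
               min = term$min, max = term$max)
      } else if (nzchar(mp$bins)) {
        filters[[length(filters) + 1L]] <-
          list(field = paste0(mp$variable_name, "__harmonized"),
               kind = "in", values = term$values)
      } else {
        vm <- cat$value_maps[cat$value_maps$source == ds &
                               cat$value_maps$concept_id == term$concept, ,
                             drop = FALSE]
        raw <- if (nrow(vm)) {
          hit <- vm$harmonized_value %in% term$values
          covered <- term$values %in% vm$harmonized_value
          if (!all(covered)) {
            cq_abort("cq_value_mapping_error",
                     sprintf(paste0("harmonized code '%s' of concept '%s' ",
                                    "has no raw preimage in '%s'"),
                             term$values[!covered][1], term$concept, ds))
          }
          unique(vm$raw_value[hit])
        } else {
          term$values
        }
        filters[[length(filters) + 1L]] <-
          list(field = mp$variable_name, kind = "in", values = raw)
      }
    }
    if (skip) next
    queries[[length(queries) + 1L]] <- structure(
      list(dataset = ds, patient_id_field = unname(pid), filters = filters),
      class = "cq_backend_query")
  }
  attr(queries, "notices") <- notices
  queries
}

#' Render a backend query as a document-database statement
#'
#' Emits the distinct-patient statement in the document-database dialect:
#' the dataset tag first, then one predicate per term in criteria order.
#' Intervals render as `{"$gte":min, "$lte":max}`; a single selected code
#' collapses to a scalar equality, several render as `{"$in":[...]}`.
#'
#' @param q A `cq_backend_query` from [translate()].
#' @return The statement as a single string.
#' @export
render_statement <- function(q) {
  stopifnot(inherits(q, "cq_backend_query"))
  parts <- sprintf('"dataset":"%s"', q$dataset)
  for (f in q$filters) {
    pred <- if (f$kind == "range") {
      sprintf('{"$gte":%s, "$lte":%s}', fmt_num(f$min), fmt_num(f$max))
    } else if (length(f$values) == 1L) {
      sprintf('"%s"', f$values)
    } else {
      sprintf('{"$in":[%s]}', paste(sprintf('"%s"', f$values),
                                    collapse = ", "))
    }
    parts <- c(parts, sprintf('"%s":%s', f$field, pred))
  }
  sprintf('db.records_collection.distinct("%s", {%s})',
          q$patient_id_field, paste(parts, collapse = ", "))
}

#' @export
print.cq_backend_query <- function(x, ...) {
  cat(render_statement(x), "\n")
  invisible(x)
}

#' Execute backend queries against the record store
#'
#' A patient qualifies in a dataset if at least one of their records
#' satisfies all of that dataset's filters simultaneously (same-record
#' conjunction); each qualifying patient is returned exactly once.
#'
#' @param queries List of `cq_backend_query` from [translate()].
#' @param store A [record_store()].
#' @return Named list mapping dataset name to a character vector of
#'   distinct patient identifiers.
#' @export
execute <- function(queries, store) {
  stopifnot(inherits(store, "cq_record_store"))
  recs <- store$records
  out <- list()
  for (q in queries) {
    mask <- recs$dataset == q$dataset
    for (f in q$filters) {
      if (!f$field %in% names(recs)) {
        cq_abort("cq_execution_error",
                 sprintf("unknown field in filter: '%s'", f$field),
                 field = f$field)
      }
      col <- recs[[f$field]]
      mask <- mask & if (f$kind == "range") {
        !is.na(col) & as.numeric(col) >= f$min & as.numeric(col) <= f$max
      } else {
        !is.na(col) & as.character(col) %in% f$values
      }
    }
    out[[q$dataset]] <- unique(recs$.pid[mask])
  }
  out
}

#' Regroup per-dataset patient-id sets into counts
#'
#' Patient identifiers are dataset-scoped; no cross-dataset identity is
#' assumed, so the total is the sum of per-dataset counts.
#'
#' @param results Named list of patient-id vectors from [execute()].
#' @return List with `per_dataset` (named integer vector) and `total`.
#' @export
regroup <- function(results) {
  counts <- vapply(results, function(ids) length(unique(ids)), 0L)
  list(per_dataset = counts, total = sum(counts))
}

#' Run criteria end to end
#'
#' Convenience wrapper: translate, execute, regroup.
#'
#' @param criteria A [query_criteria()].
#' @param cat A [catalog()].
#' @param store A [record_store()].
#' @return As [regroup()], with the translation `"notices"` attached as an
#'   attribute.
#' @export
run_query <- function(criteria, cat, store) {
  queries <- translate(criteria, cat, store$registry)
  res <- regroup(execute(queries, store))
  attr(res, "notices") <- attr(queries, "notices")
  res
}

#' Summarize a query term's value distribution in one dataset
#'
#' Categorical terms (including numeric source variables harmonized by a
#' bin rule) yield per-harmonized-category record counts; numeric terms
#' yield the five-number summary (minimum, lower hinge, median, upper
#' hinge, maximum; Tukey hinges as in [stats::fivenum()]) over the
#' non-sentinel values.
#'
#' @param concept_id Concept identifier.
#' @param dataset Dataset name.
#' @param store A [record_store()].
#' @param cat A [catalog()].
#' @return For categorical concepts a data frame with `value`, `label`,
#'   `count`; for numeric concepts a named numeric vector
#'   `c(min, q1, median, q3, max)` (all-`NA` when no records carry the
#'   variable).
#' @export
term_summary <- function(concept_id, dataset, store, cat) {
  mi <- mapping_row(cat, concept_id, dataset)
  if (is.na(mi)) {
    cq_abort("cq_unmapped_term",
             sprintf("concept '%s' is not mapped in dataset '%s'",
                     concept_id, dataset),
             concept = concept_id, dataset = dataset)
  }
  mp <- cat$mappings[mi, ]
  ci <- match(concept_id, cat$concepts$concept_id)
  recs <- store$records[store$records$dataset == dataset, , drop = FALSE]
  if (cat$concepts$data_type[ci] == "numeric") {
    col <- recs[[mp$variable_name]]
    vals <- as.numeric(col[!is.na(col)])
    if (!length(vals)) {
      return(stats::setNames(rep(NA_real_, 5),
                             c("min", "q1", "median", "q3", "max")))
    }
    stats::setNames(stats::fivenum(vals),
                    c("min", "q1", "median", "q3", "max"))
  } else {
    field <- if (nzchar(mp$bins)) {
      paste0(mp$variable_name, "__harmonized")
    } else {
      mp$variable_name
    }
    col <- recs[[field]]
    raw <- as.character(col[!is.na(col)])
    spec <- concept_domain(cat, concept_id)
    if (!length(raw)) {
      return(data.frame(value = character(), label = character(),
                        count = integer(), stringsAsFactors = FALSE))
    }
    harm <- if (nzchar(mp$bins)) {
      data.frame(harmonized_value = raw,
                 harmonized_label = domain_label(spec, raw),
                 stringsAsFactors = FALSE)
    } else {
      map_value(dataset, concept_id, raw, cat)
    }
    tab <- table(factor(harm$harmonized_value,
                        levels = unique(c(domain_codes(spec),
                                          harm$harmonized_value))))
    tab <- tab[tab > 0]
    data.frame(value = names(tab),
               label = domain_label(spec, names(tab)),
               count = as.integer(tab), stringsAsFactors = FALSE)
  }
}

#' Find query terms
#'
#' `search_terms()` matches concept labels case-insensitively by
#' substring, listing exact label matches first and the rest
#' alphabetically. `browse_terms()` returns the category-to-concepts tree
#' in alphabetical order, each concept exactly once.
#'
#' @param text Search text.
#' @param cat A [catalog()].
#' @return `search_terms()`: data frame of matching concept rows;
#'   `browse_terms()`: named list of character vectors of concept labels.
#' @export
search_terms <- function(text, cat) {
  cn <- cat$concepts
  hit <- grepl(tolower(text), tolower(cn$label), fixed = TRUE)
  res <- cn[hit, , drop = FALSE]
  exact <- tolower(res$label) == tolower(text)
  res <- res[order(!exact, res$label), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' @rdname search_terms
#' @export
browse_terms <- function(cat) {
  cn <- cat$concepts
  cats <- sort(unique(cn$category))
  out <- lapply(cats, function(cc) sort(cn$label[cn$category == cc]))
  names(out) <- cats
  out
}
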