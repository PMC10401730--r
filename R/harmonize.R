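# Value-harmonization operators: range widening, categorical recoding,
# unit conversion, and numeric-to-categorical binning.

#' Widen two numeric ranges
#'
#' When the same concept has different declared ranges in different sources
#' the harmonized domain keeps the wider range. For partially overlapping
#' ranges neither of which contains the other, the interval hull (the
#' smallest interval containing both) is used: it is the unique monotone
#' extension of the containment cases, and is commutative, associative and
#' idempotent.
#'
#' @param a,b Numeric length-2 vectors `c(min, max)`.
#' @return `c(min(a[1], b[1]), max(a[2], b[2]))`.
#' @export
#' @examples
#' widen_range(c(0, 36), c(0, 20))
widen_range <- function(a, b) {
  if (length(a) != 2L || length(b) != 2L || anyNA(a) || anyNA(b) ||
      a[1] > a[2] || b[1] > b[2]) {
    cq_abort("cq_contract_error", "widen_range needs two valid c(min, max) ranges")
  }
  c(min(a[1], b[1]), max(a[2], b[2]))
}

#' Map a raw categorical code to its harmonized code
#'
#' Applies the catalog's value-harmonization table for `(source,
#' concept_id)`. When no recoding row exists for the pair (the concept's
#' coding is identical across sources) the raw value passes through as
#' identity, provided it lies in the harmonized domain.
#'
#' @param source Dataset name.
#' @param concept_id Concept identifier.
#' @param raw_value Raw code (character scalar or vector).
#' @param cat A [catalog()].
#' @return A data frame with columns `harmonized_value`,
#'   `harmonized_label`, one row per element of `raw_value`.
#' @export
map_value <- function(source, concept_id, raw_value, cat) {
  raw_value <- as.character(raw_value)
  spec <- concept_domain(cat, concept_id)
  rows <- cat$value_maps[cat$value_maps$source == source &
                           cat$value_maps$concept_id == concept_id, ,
                         drop = FALSE]
  if (nrow(rows)) {
    idx <- match(raw_value, rows$raw_value)
    out <- data.frame(harmonized_value = rows$harmonized_value[idx],
                      harmonized_label = rows$harmonized_label[idx],
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(harmonized_value = rep(NA_character_, length(raw_value)),
                      harmonized_label = NA_character_,
                      stringsAsFactors = FALSE)
  }
  # identity fallback for codes already in the harmonized domain
  miss <- is.na(out$harmonized_value)
  in_dom <- raw_value %in% domain_codes(spec)
  fix <- miss & in_dom
  out$harmonized_value[fix] <- raw_value[fix]
  out$harmonized_label[fix] <- domain_label(spec, raw_value[fix])
  still <- is.na(out$harmonized_value)
  if (any(still)) {
    bad <- raw_value[still][1]
    cq_abort("cq_unmapped_value",
             sprintf("raw value '%s' of concept '%s' in '%s' has no harmonized image",
                     bad, concept_id, source),
             source = source, concept = concept_id, value = bad)
  }
  out
}

#' Unit conversion rule
#'
#' Converts a source's raw measurements to the harmonized unit, e.g.
#' dividing mm\eqn{^3} by 1000 to reach cc.
#'
#' @param concept_id,source Identify the mapping the rule applies to.
#' @param factor Positive conversion factor.
#' @param direction `"divide"` or `"multiply"`, applied to raw values.
#' @param raw_unit,harmonized_unit Unit labels.
#' @return An object of class `cq_unit_rule`.
#' @export
unit_rule <- function(concept_id = "", source = "", factor,
                      direction = c("divide", "multiply"),
                      raw_unit = "", harmonized_unit = "") {
  direction <- match.arg(direction)
  if (!is.numeric(factor) || length(factor) != 1L || is.na(factor) ||
      factor <= 0) {
    cq_abort("cq_contract_error", "unit rule factor must be a positive number")
  }
  structure(list(concept_id = concept_id, source = source, factor = factor,
                 direction = direction, raw_unit = raw_unit,
                 harmonized_unit = harmonized_unit),
            class = "cq_unit_rule")
}

#' Apply a unit conversion rule
#'
#' @param value Finite numeric vector of raw measurements.
#' @param rule A [unit_rule()].
#' @return Converted numeric vector.
#' @export
#' @examples
#' convert_unit(1000, unit_rule(factor = 1000, direction = "divide"))
convert_unit <- function(value, rule) {
  stopifnot(inherits(rule, "cq_unit_rule"))
  if (!all(is.finite(value))) {
    cq_abort("cq_contract_error", "convert_unit requires finite values")
  }
  if (rule$direction == "divide") value / rule$factor else value * rule$factor
}

#' Numeric-to-categorical bin rule
#'
#' @param concept_id,source Identify the mapping the rule applies to.
#' @param bins Data frame with columns `lower`, `upper`, `lower_closed`,
#'   `upper_closed`, `code`; intervals must not overlap.
#' @return An object of class `cq_bin_rule`.
#' @export
bin_rule <- function(concept_id = "", source = "", bins) {
  stopifnot(all(c("lower", "upper", "lower_closed", "upper_closed",
                  "code") %in% names(bins)))
  structure(list(concept_id = concept_id, source = source,
                 bins = bins[order(bins$lower), , drop = FALSE]),
            class = "cq_bin_rule")
}

#' Bin a numeric value into a harmonized categorical code
#'
#' @param value Numeric vector within the source's declared range.
#' @param rule A [bin_rule()].
#' @return Character vector of harmonized codes.
#' @export
bin_numeric <- function(value, rule) {
  stopifnot(inherits(rule, "cq_bin_rule"))
  b <- rule$bins
  out <- vapply(value, function(v) {
    lo_ok <- ifelse(b$lower_closed, v >= b$lower, v > b$lower)
    hi_ok <- ifelse(b$upper_closed, v <= b$upper, v < b$upper)
    hit <- which(lo_ok & hi_ok)
    if (length(hit) != 1L) NA_character_ else b$code[hit]
  }, character(1))
  if (anyNA(out)) {
    bad <- value[is.na(out)][1]
    cq_abort("cq_unbinnable_value",
             sprintf("value %s falls in no bin of the rule", fmt_num(bad)),
             value = bad)
  }
  out
}

#' Default packs-per-day bin table
#'
#' Groups a source's numeric packs-smoked-per-day values (0 to 10) into the
#' harmonized categorical codes `0` (no reported cigarette use) through `5`
#' (more than two packs). Bins are left-closed/right-open with the final
#' boundary closed; the 1.5-pack boundary belongs to the upper category
#' ("1 1/2 packs to 2 packs").
#'
#' @param concept_id,source Passed to [bin_rule()].
#' @return A [bin_rule()].
#' @export
packs_per_day_bins <- function(concept_id = "", source = "") {
  bin_rule(concept_id, source, data.frame(
    lower = c(0, 0, 0.5, 1, 1.5, 2),
    upper = c(0, 0.5, 1, 1.5, 2, 10),
    lower_closed = c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE),
    upper_closed = c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE),
    code = as.character(0:5), stringsAsFactors = FALSE))
}

# Rules attached to a catalog's mapping rows, as rule objects.

#' Harmonization rules stored in a catalog
#'
#' `unit_rules()` and `bin_rules()` extract the unit-conversion and bin
#' rules carried on the catalog's mapping rows as rule objects.
#'
#' @param cat A [catalog()].
#' @return A list of [unit_rule()] / [bin_rule()] objects.
#' @export
unit_rules <- function(cat) {
  mp <- cat$mappings
  idx <- which(nzchar(mp$unit_factor))
  lapply(idx, function(i) {
    unit_rule(mp$concept_id[i], mp$source[i],
              factor = as.numeric(mp$unit_factor[i]),
              direction = mp$unit_direction[i],
              raw_unit = mp$raw_unit[i],
              harmonized_unit = mp$harmonized_unit[i])
  })
}

#' @rdname unit_rules
#' @export
bin_rules <- function(cat) {
  mp <- cat$mappings
  idx <- which(nzchar(mp$bins))
  lapply(idx, function(i) {
    bin_rule(mp$concept_id[i], mp$source[i], parse_bins(mp$bins[i]))
  })
}

#' Count concepts needing each kind of harmonization
#'
#' A concept counts as numeric-harmonized if a bin rule applies to it or if
#' any mapped source variable declares a numeric range different from the
#' harmonized range (i.e. range widening was applied); as
#' categorical-harmonized if any value-map row recodes a raw value to a
#' different harmonized value; as unit-harmonized if any unit rule applies.
#' The categories may overlap.
#'
#' @param cat A [catalog()].
#' @return Named integer vector `c(numeric, categorical, unit)`.
#' @export
harmonization_profile <- function(cat) {
  mp <- cat$mappings
  unit_ids <- unique(mp$concept_id[nzchar(mp$unit_factor)])
  bin_ids <- unique(mp$concept_id[nzchar(mp$bins)])

  widened <- character()
  var_key <- paste(cat$variables$source, cat$variables$table_name,
                   cat$variables$variable_name, sep = "\r")
  for (i in seq_len(nrow(cat$concepts))) {
    cn <- cat$concepts[i, ]
    if (cn$data_type != "numeric") next
    harm <- parse_code_spec(cn$code_spec)$range
    rows <- which(mp$concept_id == cn$concept_id)
    for (j in rows) {
      vi <- match(paste(mp$source[j], mp$table_name[j], mp$variable_name[j],
                        sep = "\r"), var_key)
      if (is.na(vi)) next
      vspec <- parse_code_spec(cat$variables$code_spec[vi])
      rng <- vspec$range
      if (is.null(rng)) next
      if (nzchar(mp$unit_factor[j])) {
        ur <- unit_rule(factor = as.numeric(mp$unit_factor[j]),
                        direction = mp$unit_direction[j])
        rng <- sort(convert_unit(rng, ur))
      }
      if (!isTRUE(all.equal(rng, harm))) widened <- c(widened, cn$concept_id)
    }
  }

  vm <- cat$value_maps
  cat_ids <- unique(vm$concept_id[vm$raw_value != vm$harmonized_value])

  c(numeric = length(unique(c(bin_ids, widened))),
    categorical = length(unique(cat_ids)),
    unit = length(unit_ids))
}
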