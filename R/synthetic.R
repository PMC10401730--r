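# Self-contained two-source synthetic cohort: dictionaries, a harmonization
# catalog, raw study data and ground-truth query answers. Source "NACC"
# (single-file style) and source "ADNI" (multi-table style) share seven
# concepts with planted coding inconsistencies: a recoded categorical
# (banked postmortem CSF and the game-of-skill item), a mm3-vs-cc unit
# clash (right hippocampus volume, factor 1000), a numeric-vs-categorical
# clash (packs smoked per day, binned), and a range clash (years of
# education, 0-36 vs 0-20).

planted_concepts <- c("years_of_education", "marital_status",
                      "month_of_birth", "banked_postmortem_csf",
                      "games_difficulty", "right_hippocampus_volume",
                      "packs_per_day")

# ADNI-style table housing each concept's variable
adni_table_of <- c(years_of_education = "PTDEMOG", marital_status = "PTDEMOG",
                   month_of_birth = "PTDEMOG", banked_postmortem_csf = "NEUROPATH",
                   games_difficulty = "FAQ", right_hippocampus_volume = "UCSFFRESFR",
                   packs_per_day = "MEDHIST")
nacc_var_of <- c(years_of_education = "EDUC", marital_status = "MARISTAT",
                 month_of_birth = "BIRTHMO", banked_postmortem_csf = "NPCSFBANK",
                 games_difficulty = "GAMES", right_hippocampus_volume = "HIPVOLR",
                 packs_per_day = "PACKSPER")
adni_var_of <- c(years_of_education = "PTEDUCAT", marital_status = "PTMARRY",
                 month_of_birth = "PTDOBMM", banked_postmortem_csf = "NPBANKCSF",
                 games_difficulty = "FAQGAME", right_hippocampus_volume = "ST29SV",
                 packs_per_day = "PACKSDAY")

#' Specify a synthetic two-source cohort
#'
#' @param seed Integer RNG seed; equal specs generate byte-identical
#'   outputs.
#' @param n_patients Named integer vector, patients per source.
#' @param visits Length-2 integer range; each patient's visit count is
#'   drawn uniformly from it.
#' @param concepts Which planted concepts to include (defaults to all
#'   seven).
#' @param missing_rate Per-variable probability that a patient's value is
#'   missing (empty in the study CSVs).
#' @param sentinel_rate Per-variable probability that a patient's value is
#'   a sentinel code, for variables whose source declares sentinels.
#' @return An object of class `cq_cohort_spec`.
#' @export
cohort_spec <- function(seed = 1L,
                        n_patients = c(NACC = 2000L, ADNI = 2000L),
                        visits = c(1L, 4L),
                        concepts = planted_concepts,
                        missing_rate = 0.05,
                        sentinel_rate = 0.05) {
  if (any(n_patients < 1L) || length(n_patients) != 2L ||
      !setequal(names(n_patients), c("NACC", "ADNI"))) {
    cq_abort("cq_spec_error",
             "n_patients must be positive counts named NACC and ADNI")
  }
  if (length(visits) != 2L || visits[1] < 1L || visits[1] > visits[2]) {
    cq_abort("cq_spec_error", "visits must be a valid positive range")
  }
  unknown <- setdiff(concepts, planted_concepts)
  if (length(unknown)) {
    cq_abort("cq_spec_error",
             sprintf("unknown planted concept: '%s'", unknown[1]),
             concept = unknown[1])
  }
  if (missing_rate < 0 || missing_rate > 1 || sentinel_rate < 0 ||
      sentinel_rate > 1) {
    cq_abort("cq_spec_error", "rates must lie in [0, 1]")
  }
  structure(list(seed = as.integer(seed), n_patients = n_patients,
                 visits = as.integer(visits), concepts = concepts,
                 missing_rate = missing_rate, sentinel_rate = sentinel_rate),
            class = "cq_cohort_spec")
}

packs_label_spec <- paste(
  "0 = No reported cigarette use;",
  "1 = 1 cigarette to less than 1/2 pack;",
  "2 = 1/2 pack to less than 1 pack;",
  "3 = 1 pack to 1 1/2 packs;",
  "4 = 1 1/2 packs to 2 packs;",
  "5 = More than two packs;",
  "8 = Not applicable; 9 = Unknown; -4 = Not available")

# Static description of every planted concept: harmonized domain, per-source
# dictionary rows, recode tables and rules.
planted_def <- function(id) {
  switch(id,
    years_of_education = list(
      label = "Years of education", category = "Demographics",
      data_type = "numeric",
      harmonized = paste(fmt_num(widen_range(c(0, 36), c(0, 20))[1]), "-",
                         fmt_num(widen_range(c(0, 36), c(0, 20))[2]),
                         "; 99 = Unknown", sep = ""),
      units = "",
      nacc = list(form = "a1", desc = "Years of education",
                  codes = "0 - 36; 99 = Unknown"),
      adni = list(crf = "Participant Demographics",
                  desc = "Participant Education", codes = "0..20",
                  units = "")),
    marital_status = list(
      label = "Marital status", category = "Demographics",
      data_type = "categorical",
      harmonized = paste("1 = Married; 2 = Widowed; 3 = Divorced;",
                         "4 = Never married; 9 = Unknown"),
      units = "",
      nacc = list(form = "a1", desc = "Marital status",
                  codes = paste("1 = Married; 2 = Widowed; 3 = Divorced;",
                                "4 = Never married; 9 = Unknown")),
      adni = list(crf = "Participant Demographics",
                  desc = "Participant Marital Status",
                  codes = paste("1=Married(1); 2=Widowed(2); 3=Divorced(3);",
                                "4=Never married(4); 9=Unknown(9)"),
                  units = "")),
    month_of_birth = list(
      label = "Month of birth", category = "Demographics",
      data_type = "numeric", harmonized = "1 - 12", units = "",
      nacc = list(form = "a1", desc = "Subject month of birth",
                  codes = "1 - 12"),
      adni = list(crf = "Participant Demographics",
                  desc = "Participant Month of Birth", codes = "1..12",
                  units = "")),
    banked_postmortem_csf = list(
      label = "Banked postmortem CSF", category = "Neuropathology",
      data_type = "categorical",
      harmonized = "0 = No; 1 = Yes; 9 = Missing/unknown; -4 = Not available",
      units = "",
      nacc = list(form = "np", desc = "Banked postmortem CSF",
                  codes = paste("0 = No; 1 = Yes; 9 = Missing/unknown;",
                                "-4 = Not available")),
      adni = list(crf = "Neuropathology",
                  desc = "Banked postmortem CSF",
                  codes = "1=Yes(1); 2=No(2)", units = "")),
    games_difficulty = list(
      label = "Difficulty or need help with: Playing a game of skill",
      category = "Functional Assessment Scale", data_type = "categorical",
      harmonized = paste("0 = Normal; 1 = Has difficulty;",
                         "2 = Requires assistance; 3 = Dependent;",
                         "9 = Unknown"),
      units = "",
      nacc = list(form = "b7",
                  desc = "Playing a game of skill",
                  codes = paste("0 = Normal; 1 = Has difficulty;",
                                "2 = Requires assistance; 3 = Dependent;",
                                "9 = Unknown")),
      adni = list(crf = "Functional Assessment Questionnaire",
                  desc = "Game of skill such as bridge or chess",
                  codes = paste("1=Normal(1); 3=Has difficulty(3);",
                                "4=Requires assistance(4); 5=Dependent(5);",
                                "9=Unknown(9)"),
                  units = "")),
    right_hippocampus_volume = list(
      label = "Segmented right hippocampus volume (cc)",
      category = "Imaging", data_type = "numeric",
      harmonized = "0 - 8", units = "cc",
      nacc = list(form = "img",
                  desc = "Segmented right hippocampus volume (cc)",
                  codes = "0 - 8"),
      adni = list(crf = "Longitudinal FreeSurfer",
                  desc = "Volume (Cortical Parcellation) of RightHippocampus",
                  codes = "0 - 8000", units = "mm3")),
    packs_per_day = list(
      label = "Average number of packs smoked per day",
      category = "Medical History", data_type = "categorical",
      harmonized = packs_label_spec, units = "",
      nacc = list(form = "a5",
                  desc = "Average number of packs smoked per day",
                  codes = packs_label_spec),
      adni = list(crf = "Medical History",
                  desc = "Smoking: packs per day",
                  codes = "0 - 10; -4=Not available(-4)", units = "")),
    cq_abort("cq_spec_error", sprintf("unknown planted concept: '%s'", id)))
}

# Non-identity recode tables (Table-3 shape), per concept.
planted_value_maps <- function(id) {
  switch(id,
    banked_postmortem_csf = data.frame(
      source = c("ADNI", "ADNI", "NACC", "NACC", "NACC", "NACC"),
      concept_id = id,
      raw_value = c("1", "2", "0", "1", "9", "-4"),
      raw_label = c("Yes", "No", "No", "Yes", "Missing/unknown",
                    "Not available"),
      harmonized_value = c("1", "0", "0", "1", "9", "-4"),
      harmonized_label = c("Yes", "No", "No", "Yes", "Missing/unknown",
                           "Not available"),
      stringsAsFactors = FALSE),
    games_difficulty = data.frame(
      source = c(rep("ADNI", 5), rep("NACC", 5)),
      concept_id = id,
      raw_value = c("1", "3", "4", "5", "9", "0", "1", "2", "3", "9"),
      raw_label = c("Normal", "Has difficulty", "Requires assistance",
                    "Dependent", "Unknown", "Normal", "Has difficulty",
                    "Requires assistance", "Dependent", "Unknown"),
      harmonized_value = c("0", "1", "2", "3", "9", "0", "1", "2", "3", "9"),
      harmonized_label = c("Normal", "Has difficulty", "Requires assistance",
                           "Dependent", "Unknown", "Normal",
                           "Has difficulty", "Requires assistance",
                           "Dependent", "Unknown"),
      stringsAsFactors = FALSE),
    NULL)
}

#' Build the synthetic harmonization catalog
#'
#' Constructs the dictionaries for both sources, parses them through
#' [parse_dictionary()], and assembles the validated five-part catalog for
#' the requested planted concepts.
#'
#' @param concepts Planted concept ids to include.
#' @return List with elements `catalog`, `nacc_dictionary`,
#'   `adni_dictionary` (the raw dictionary data frames).
#' @export
synthetic_catalog <- function(concepts = planted_concepts) {
  defs <- lapply(concepts, planted_def)
  names(defs) <- concepts

  nacc_dict <- do.call(rbind, lapply(concepts, function(id) {
    d <- defs[[id]]
    data.frame(VariableName = nacc_var_of[id], Form = d$nacc$form,
               ShortDescriptor = d$nacc$desc, DataType = "Numeric",
               AllowableCodes = d$nacc$codes, stringsAsFactors = FALSE)
  }))
  adni_dict <- do.call(rbind, lapply(concepts, function(id) {
    d <- defs[[id]]
    data.frame(Phase = "ADNI1", FLDNAME = adni_var_of[id],
               TBLNAME = adni_table_of[id], CRFNAME = d$adni$crf,
               TEXT = d$adni$desc, TYPE = "N", LENGTH = "",
               CODE = d$adni$codes, UNITS = d$adni$units,
               stringsAsFactors = FALSE)
  }))

  variables <- rbind(parse_dictionary(nacc_dict, "nacc"),
                     parse_dictionary(adni_dict, "adni"))
  concepts_df <- do.call(rbind, lapply(concepts, function(id) {
    d <- defs[[id]]
    data.frame(concept_id = id, label = d$label, category = d$category,
               data_type = d$data_type,
               code_spec = format_code_spec(parse_code_spec(d$harmonized)),
               units = d$units, stringsAsFactors = FALSE)
  }))
  mappings <- do.call(rbind, lapply(concepts, function(id) {
    rbind(
      data.frame(concept_id = id, source = "NACC",
                 variable_name = nacc_var_of[id], table_name = "",
                 unit_factor = "", unit_direction = "", raw_unit = "",
                 harmonized_unit = "", bins = "", stringsAsFactors = FALSE),
      data.frame(concept_id = id, source = "ADNI",
                 variable_name = adni_var_of[id],
                 table_name = adni_table_of[id],
                 unit_factor = if (id == "right_hippocampus_volume") "1000"
                               else "",
                 unit_direction = if (id == "right_hippocampus_volume")
                                    "divide" else "",
                 raw_unit = if (id == "right_hippocampus_volume") "mm3"
                            else "",
                 harmonized_unit = if (id == "right_hippocampus_volume")
                                     "cc" else "",
                 bins = if (id == "packs_per_day")
                          format_bins(packs_per_day_bins()$bins) else "",
                 stringsAsFactors = FALSE))
  }))
  value_maps <- do.call(rbind, lapply(concepts, planted_value_maps))
  value_maps <- value_maps %||% empty_df(value_map_cols)

  list(catalog = catalog(concepts = concepts_df, variables = variables,
                         mappings = mappings, value_maps = value_maps),
       nacc_dictionary = nacc_dict, adni_dictionary = adni_dict)
}

draw <- function(n, codes, probs) sample(codes, n, replace = TRUE, prob = probs)

# Patient-level harmonized attributes for one source. Categorical columns
# hold harmonized codes as text (sentinels included); numeric columns hold
# measurements with NA for missing or sentinel.
gen_attributes <- function(source, n, concepts, missing_rate, sentinel_rate) {
  miss <- function() stats::runif(n) < missing_rate
  sent <- function() stats::runif(n) < sentinel_rate
  at <- list()
  raw <- list()
  for (id in concepts) {
    if (id == "years_of_education") {
      v <- if (source == "NACC") sample(0:36, n, TRUE) else sample(0:20, n, TRUE)
      v <- as.numeric(v)
      s <- if (source == "NACC") sent() else rep(FALSE, n)
      v[s] <- NA
      sc <- ifelse(s, "99", NA_character_)
      v[miss()] <- NA
      sc[is.na(v) & is.na(sc)] <- NA_character_
      at[[id]] <- v
      raw[[paste0(id, "__sentinel")]] <- sc
    } else if (id == "month_of_birth") {
      v <- as.numeric(sample(1:12, n, TRUE))
      v[miss()] <- NA
      at[[id]] <- v
    } else if (id == "right_hippocampus_volume") {
      v <- round(stats::runif(n, 2, 5), 3)
      v[miss()] <- NA
      at[[id]] <- v
    } else if (id == "marital_status") {
      v <- draw(n, c("1", "2", "3", "4"), c(0.55, 0.2, 0.15, 0.1))
      v[sent()] <- "9"
      v[miss()] <- NA_character_
      at[[id]] <- v
    } else if (id == "banked_postmortem_csf") {
      v <- draw(n, c("0", "1"), c(0.6, 0.4))
      if (source == "NACC") {
        s <- sent()
        v[s] <- draw(sum(s), c("9", "-4"), c(0.5, 0.5))
      }
      v[miss()] <- NA_character_
      at[[id]] <- v
    } else if (id == "games_difficulty") {
      v <- draw(n, c("0", "1", "2", "3"), c(0.6, 0.2, 0.15, 0.05))
      v[sent()] <- "9"
      v[miss()] <- NA_character_
      at[[id]] <- v
    } else if (id == "packs_per_day") {
      if (source == "NACC") {
        v <- draw(n, as.character(0:5), c(0.55, 0.1, 0.1, 0.1, 0.08, 0.07))
        s <- sent()
        v[s] <- draw(sum(s), c("8", "9", "-4"), c(0.4, 0.4, 0.2))
        v[miss()] <- NA_character_
        at[[id]] <- v
      } else {
        num <- round(stats::runif(n, 0, 10), 3)
        num[stats::runif(n) < 0.4] <- 0  # plenty of never-smokers
        code <- bin_numeric(num, packs_per_day_bins())
        s <- sent()
        code[s] <- "-4"
        num[s] <- NA
        m <- miss()
        code[m] <- NA_character_
        num[m] <- NA
        at[[id]] <- code
        raw[[paste0(id, "__raw")]] <- num
      }
    }
  }
  c(list(pid = character(n)), at, raw)
}

#' Generate the synthetic two-source cohort
#'
#' Deterministic per seed. Returns the two raw dictionaries, the validated
#' catalog, the raw study tables (source NACC as a single data frame,
#' source ADNI as a named list of per-table data frames), the dataset
#' registry, and a ground-truth object whose [ground_truth_answer()] gives
#' the closed-form answer to any criteria. When `dir` is given everything
#' is also written to disk (dictionaries and study data as CSV, the
#' catalog via [save_catalog()], the ground-truth attributes as JSON).
#'
#' @param spec A [cohort_spec()].
#' @param dir Optional output directory.
#' @return List with elements `catalog`, `dictionaries`, `study`,
#'   `registry`, `truth`.
#' @export
generate_cohort <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "cq_cohort_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(spec$seed)

  syn <- synthetic_catalog(spec$concepts)
  registry <- c(NACC = "NACCID", ADNI = "RID")
  sources <- names(spec$n_patients)

  attrs <- list()
  visits <- list()
  for (i in seq_along(sources)) {
    src <- sources[i]
    n <- spec$n_patients[[i]]
    a <- gen_attributes(src, n, spec$concepts, spec$missing_rate,
                        spec$sentinel_rate)
    a$pid <- if (src == "NACC") sprintf("N%06d", seq_len(n)) else
      sprintf("R%04d", seq_len(n))
    attrs[[src]] <- as.data.frame(a, stringsAsFactors = FALSE,
                                  check.names = FALSE)
    visits[[src]] <- sample(seq(spec$visits[1], spec$visits[2]), n,
                            replace = TRUE)
  }

  chr <- function(x) ifelse(is.na(x), "", as.character(x))
  num_chr <- function(x) ifelse(is.na(x), "", fmt_num(x))

  # NACC: one row per visit, all variables in one file
  a <- attrs$NACC
  rep_idx <- rep(seq_len(nrow(a)), visits$NACC)
  nacc_study <- data.frame(NACCID = a$pid[rep_idx],
                           VISITNO = sequence(visits$NACC),
                           stringsAsFactors = FALSE)
  for (id in spec$concepts) {
    var <- nacc_var_of[[id]]
    col <- a[[id]][rep_idx]
    if (id == "years_of_education") {
      sent_code <- a[["years_of_education__sentinel"]][rep_idx]
      nacc_study[[var]] <- ifelse(!is.na(sent_code), sent_code, num_chr(col))
    } else if (is.numeric(col)) {
      nacc_study[[var]] <- num_chr(col)
    } else {
      nacc_study[[var]] <- chr(col)
    }
  }

  # ADNI: one table per group of variables, same visit count in each table
  a <- attrs$ADNI
  rep_idx <- rep(seq_len(nrow(a)), visits$ADNI)
  base <- data.frame(RID = a$pid[rep_idx],
                     VISCODE = paste0("m", sequence(visits$ADNI) * 6 - 6),
                     stringsAsFactors = FALSE)
  adni_study <- list()
  for (id in spec$concepts) {
    tbl <- adni_table_of[[id]]
    var <- adni_var_of[[id]]
    if (is.null(adni_study[[tbl]])) adni_study[[tbl]] <- base
    col <- if (id == "packs_per_day") {
      raw_num <- a[["packs_per_day__raw"]][rep_idx]
      code <- a[[id]][rep_idx]
      ifelse(!is.na(code) & code == "-4", "-4", num_chr(raw_num))
    } else if (id == "right_hippocampus_volume") {
      num_chr(a[[id]][rep_idx] * 1000)  # raw unit mm3
    } else if (id == "banked_postmortem_csf") {
      unname(c(`0` = "2", `1` = "1")[chr(a[[id]][rep_idx])])
    } else if (id == "games_difficulty") {
      unname(c(`0` = "1", `1` = "3", `2` = "4", `3` = "5",
               `9` = "9")[chr(a[[id]][rep_idx])])
    } else if (is.numeric(a[[id]])) {
      num_chr(a[[id]][rep_idx])
    } else {
      chr(a[[id]][rep_idx])
    }
    col[is.na(col)] <- ""
    adni_study[[tbl]][[var]] <- col
  }

  truth <- structure(list(attributes = attrs,
                          n_patients = spec$n_patients,
                          concepts = spec$concepts,
                          adni_tables = adni_table_of[spec$concepts]),
                     class = "cq_ground_truth")

  out <- list(catalog = syn$catalog,
              dictionaries = list(nacc = syn$nacc_dictionary,
                                  adni = syn$adni_dictionary),
              study = list(NACC = nacc_study, ADNI = adni_study),
              registry = registry, truth = truth)

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_cq_csv(syn$nacc_dictionary, file.path(dir, "nacc_dictionary.csv"))
    write_cq_csv(syn$adni_dictionary, file.path(dir, "adni_dictionary.csv"))
    save_catalog(syn$catalog, file.path(dir, "catalog"))
    write_cq_csv(nacc_study, file.path(dir, "NACC.csv"))
    for (tbl in names(adni_study)) {
      write_cq_csv(adni_study[[tbl]], file.path(dir,
                                                paste0("ADNI_", tbl, ".csv")))
    }
    jsonlite::write_json(lapply(attrs, function(df) df),
                         file.path(dir, "ground_truth.json"),
                         dataframe = "columns", na = "null")
  }
  out
}

#' Closed-form ground-truth answer for query criteria
#'
#' Evaluates the criteria directly against the generator's patient-level
#' harmonized attributes. Reflects the engine's same-record conjunction:
#' in the multi-table source, terms whose variables live in different
#' tables can never be satisfied by one record, so such a query matches no
#' patients there.
#'
#' @param truth The `truth` element of [generate_cohort()]'s result.
#' @param criteria A [query_criteria()].
#' @return List with `per_dataset` counts and `total`, as [regroup()].
#' @export
ground_truth_answer <- function(truth, criteria) {
  stopifnot(inherits(truth, "cq_ground_truth"))
  counts <- integer(0)
  for (ds in criteria$datasets) {
    a <- truth$attributes[[ds]]
    if (is.null(a)) {
      counts[ds] <- 0L
      next
    }
    if (ds == "ADNI" && length(criteria$terms)) {
      tabs <- unique(truth$adni_tables[vapply(criteria$terms, `[[`, "",
                                              "concept")])
      if (length(tabs) > 1L) {
        counts[ds] <- 0L
        next
      }
    }
    mask <- rep(TRUE, nrow(a))
    for (term in criteria$terms) {
      col <- a[[term$concept]]
      if (is.null(col)) {
        mask[] <- FALSE
        break
      }
      mask <- mask & if (term$kind == "numeric") {
        !is.na(col) & col >= term$min & col <= term$max
      } else {
        !is.na(col) & as.character(col) %in% term$values
      }
    }
    counts[ds] <- sum(mask)
  }
  list(per_dataset = counts, total = sum(counts))
}

#' Brute-force oracle count over the raw study tables
#'
#' An independent implementation of the whole query pipeline: inverts the
#' value-harmonization table by hand, converts units and bins numeric
#' values while scanning the raw per-source rows, collects distinct
#' patient identifiers per dataset, and sums. Used to cross-check the
#' translate/execute/regroup path.
#'
#' @param criteria A [query_criteria()].
#' @param study The `study` element of [generate_cohort()]'s result (raw
#'   data frames as read from the CSVs).
#' @param cat The [catalog()].
#' @param registry Named dataset -> patient-id-field vector.
#' @return List with `per_dataset` counts and `total`.
#' @export
oracle_count <- function(criteria, study, cat, registry) {
  counts <- integer(0)
  var_key <- paste(cat$variables$source, cat$variables$table_name,
                   cat$variables$variable_name, sep = "\r")
  for (ds in criteria$datasets) {
    tables <- study[[ds]]
    if (is.data.frame(tables)) tables <- list(tables)
    ids <- character(0)
    for (tbl in tables) {
      ok <- TRUE
      mask <- rep(TRUE, nrow(tbl))
      for (term in criteria$terms) {
        mi <- mapping_row(cat, term$concept, ds)
        if (is.na(mi)) { ok <- FALSE; break }
        mp <- cat$mappings[mi, ]
        var <- mp$variable_name
        if (!var %in% names(tbl)) { ok <- FALSE; break }
        col <- as.character(tbl[[var]])
        vi <- match(paste(ds, mp$table_name, var, sep = "\r"), var_key)
        vspec <- parse_code_spec(cat$variables$code_spec[vi])
        if (term$kind == "numeric") {
          is_special <- col %in% vspec$special_codes$code
          num <- suppressWarnings(as.numeric(col))
          num[is_special | !nzchar(col)] <- NA
          if (nzchar(mp$unit_factor)) {
            fac <- as.numeric(mp$unit_factor)
            num <- if (mp$unit_direction == "divide") num / fac else
              num * fac
          }
          mask <- mask & !is.na(num) & num >= term$min & num <= term$max
        } else if (nzchar(mp$bins)) {
          bins <- parse_bins(mp$bins)
          is_special <- col %in% vspec$special_codes$code
          num <- suppressWarnings(as.numeric(col))
          hit <- vapply(seq_along(col), function(k) {
            if (!nzchar(col[k])) return(FALSE)
            if (is_special[k]) return(col[k] %in% term$values)
            v <- num[k]
            if (is.na(v)) return(FALSE)
            for (b in seq_len(nrow(bins))) {
              lo <- if (bins$lower_closed[b]) v >= bins$lower[b] else
                v > bins$lower[b]
              hi <- if (bins$upper_closed[b]) v <= bins$upper[b] else
                v < bins$upper[b]
              if (lo && hi) return(bins$code[b] %in% term$values)
            }
            FALSE
          }, logical(1))
          mask <- mask & hit
        } else {
          vm <- cat$value_maps[cat$value_maps$source == ds &
                                 cat$value_maps$concept_id == term$concept, ,
                               drop = FALSE]
          raw_codes <- if (nrow(vm)) {
            vm$raw_value[vm$harmonized_value %in% term$values]
          } else {
            term$values
          }
          mask <- mask & col %in% raw_codes
        }
      }
      if (ok) ids <- c(ids, tbl[[registry[ds]]][mask])
    }
    counts[ds] <- length(unique(ids))
  }
  list(per_dataset = counts, total = sum(counts))
}

#' Draw random query criteria over the planted concepts
#'
#' Uses the current RNG state. Picks a non-empty dataset subset, one to
#' three distinct concepts, and for each a random harmonized value subset
#' (categorical) or a random subrange of the harmonized range (numeric).
#'
#' @param cat A [catalog()].
#' @param datasets Dataset names to sample from.
#' @param max_terms Maximum number of terms.
#' @return A [query_criteria()].
#' @export
random_criteria <- function(cat, datasets = c("NACC", "ADNI"),
                            max_terms = 3L) {
  ds <- sample(datasets, sample(seq_along(datasets), 1L))
  n_terms <- sample.int(max_terms, 1L)
  ids <- sample(cat$concepts$concept_id,
                min(n_terms, nrow(cat$concepts)))
  terms <- lapply(ids, function(id) {
    i <- match(id, cat$concepts$concept_id)
    spec <- parse_code_spec(cat$concepts$code_spec[i])
    if (cat$concepts$data_type[i] == "numeric") {
      lo <- stats::runif(1, spec$range[1], spec$range[2])
      hi <- stats::runif(1, lo, spec$range[2])
      term_range(id, round(lo, 2), round(hi, 2))
    } else {
      # restrict to codes with a raw preimage in every selected dataset,
      # so the criteria satisfy the translation contract
      codes <- domain_codes(spec)
      for (d in ds) {
        mi <- mapping_row(cat, id, d)
        if (!is.na(mi) && !nzchar(cat$mappings$bins[mi])) {
          vm <- cat$value_maps[cat$value_maps$source == d &
                                 cat$value_maps$concept_id == id, ,
                               drop = FALSE]
          if (nrow(vm)) codes <- intersect(codes, vm$harmonized_value)
        }
      }
      term_values(id, sample(codes, sample.int(length(codes), 1L)))
    }
  })
  query_criteria(ds, terms)
}
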