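# Shared fixtures, generated in code. The small cohort is cached per call
# signature so independent test files do not regenerate it.

.cohort_cache <- new.env(parent = emptyenv())

small_cohort <- function(seed = 42L, n = 150L, visits = c(1L, 4L),
                         missing_rate = 0.05, sentinel_rate = 0.05) {
  key <- paste(seed, n, visits[1], visits[2], missing_rate, sentinel_rate)
  if (is.null(.cohort_cache[[key]])) {
    spec <- cohort_spec(seed = seed,
                        n_patients = c(NACC = n, ADNI = n),
                        visits = visits, missing_rate = missing_rate,
                        sentinel_rate = sentinel_rate)
    .cohort_cache[[key]] <- generate_cohort(spec)
  }
  .cohort_cache[[key]]
}

load_store <- function(res) {
  store <- record_store(res$registry)
  import_records(store, res$study$NACC, "NACC", res$catalog)
  for (tbl in names(res$study$ADNI)) {
    import_records(store, res$study$ADNI[[tbl]], "ADNI", res$catalog,
                   table_name = tbl)
  }
  store
}

# Minimal hand-built catalog holding only the banked-CSF recode table.
csf_catalog <- function() {
  synthetic_catalog("banked_postmortem_csf")$catalog
}

# Example dictionary rows in both source schemas.
nacc_example_rows <- function() {
  data.frame(
    VariableName = c("EDUC", "NORMCOG", "NACCVASC"),
    Form = c("a1", "d1", "np"),
    VariableType = "Original UDS question",
    ShortDescriptor = c("Years of education", "Normal cognition and behavior",
                        "Ischemic, hemorrhagic, or vascular pathology present"),
    DataType = c("Numeric cross-sectional", "Numeric longitudinal",
                 "Numeric cross-sectional"),
    AllowableCodes = c("0 - 36; 99 = Unknown", "0 = No; 1 = Yes",
                       "0 = No; 1 = One or more vascular pathology; 9 = Unknown"),
    stringsAsFactors = FALSE)
}

adni_example_rows <- function() {
  data.frame(
    Phase = c("ADNI1", "ADNI1", "ADNIGO"),
    FLDNAME = c("GDAFRAID", "ST127SV", "PTDOBMM"),
    TBLNAME = c("GDSCALE", "UCSFFRESFR", "PTDEMOG"),
    CRFNAME = c("Geriatric Depression Scale", "Longitudinal FreeSurfer",
                "Participant Demographics"),
    TEXT = c("6. Are you afraid that something bad is going to happen to you?",
             "Volume (WM Parcellation) of ThirdVentricle",
             "2a. Participant Month of Birth"),
    TYPE = "N", LENGTH = c("1", "8", "2"),
    CODE = c("1=Yes(1); 0=No(0)", "", "1..12"),
    UNITS = c("", "mm3", ""),
    stringsAsFactors = FALSE)
}
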