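test_that("range widening keeps the wider range and is a hull", {
  expect_equal(widen_range(c(0, 36), c(0, 20)), c(0, 36))
  expect_equal(widen_range(c(0, 20), c(5, 36)), c(0, 36))
  expect_equal(widen_range(c(3, 7), c(3, 7)), c(3, 7))
  expect_error(widen_range(c(5, 2), c(0, 1)), class = "cq_contract_error")

  # commutative, associative, idempotent, contains both inputs
  set.seed(11)
  for (i in 1:50) {
    a <- sort(stats::runif(2, -10, 10))
    b <- sort(stats::runif(2, -10, 10))
    d <- sort(stats::runif(2, -10, 10))
    expect_equal(widen_range(a, b), widen_range(b, a))
    expect_equal(widen_range(widen_range(a, b), d),
                 widen_range(a, widen_range(b, d)))
    expect_equal(widen_range(a, a), a)
    h <- widen_range(a, b)
    expect_true(h[1] <= min(a[1], b[1]) && h[2] >= max(a[2], b[2]))
  }
})

test_that("the banked-CSF recode table maps raw codes from both sources", {
  cat_obj <- csf_catalog()
  expect_equal(map_value("ADNI", "banked_postmortem_csf", "2", cat_obj),
               data.frame(harmonized_value = "0", harmonized_label = "No",
                          stringsAsFactors = FALSE))
  expect_equal(map_value("NACC", "banked_postmortem_csf", "9",
                         cat_obj)$harmonized_label, "Missing/unknown")
  err <- expect_error(map_value("ADNI", "banked_postmortem_csf", "7",
                                cat_obj),
                      class = "cq_unmapped_value")
  expect_match(conditionMessage(err), "7")
})

test_that("identity mapping applies when a concept has no recode rows", {
  cat_obj <- synthetic_catalog("marital_status")$catalog
  out <- map_value("ADNI", "marital_status", c("1", "9"), cat_obj)
  expect_equal(out$harmonized_value, c("1", "9"))
  expect_equal(out$harmonized_label, c("Married", "Unknown"))
  expect_error(map_value("ADNI", "marital_status", "77", cat_obj),
               class = "cq_unmapped_value")
})

test_that("unit conversion divides or multiplies by the factor", {
  mm3_to_cc <- unit_rule(factor = 1000, direction = "divide")
  expect_identical(convert_unit(1000, mm3_to_cc), 1.0)
  expect_identical(convert_unit(0, mm3_to_cc), 0)
  expect_equal(convert_unit(3215.0, mm3_to_cc), 3.215)
  inv <- unit_rule(factor = 1000, direction = "multiply")
  set.seed(3)
  x <- stats::runif(100, 0, 1e4)
  expect_equal(convert_unit(convert_unit(x, mm3_to_cc), inv), x,
               tolerance = 1e-12)
  expect_error(convert_unit(Inf, mm3_to_cc), class = "cq_contract_error")
  expect_error(unit_rule(factor = -1, direction = "divide"),
               class = "cq_contract_error")
})

test_that("packs-per-day binning follows the published category labels", {
  rule <- packs_per_day_bins()
  expect_equal(bin_numeric(0, rule), "0")
  expect_equal(bin_numeric(2.5, rule), "5")
  expect_equal(bin_numeric(0.75, rule), "2")
  expect_equal(bin_numeric(1.5, rule), "4")  # boundary joins the upper bin
  expect_equal(bin_numeric(2, rule), "4")
  expect_equal(bin_numeric(10, rule), "5")
  expect_error(bin_numeric(11, rule), class = "cq_unbinnable_value")
})

test_that("binning agrees with a brute-force scan of the bin table", {
  rule <- packs_per_day_bins()
  brute <- function(v) {
    b <- rule$bins
    for (i in seq_len(nrow(b))) {
      lo <- if (b$lower_closed[i]) v >= b$lower[i] else v > b$lower[i]
      hi <- if (b$upper_closed[i]) v <= b$upper[i] else v < b$upper[i]
      if (lo && hi) return(b$code[i])
    }
    NA_character_
  }
  set.seed(19)
  vals <- c(stats::runif(10000, 0, 10), 0, 0.5, 1, 1.5, 2, 10)
  expect_identical(bin_numeric(vals, rule),
                   vapply(vals, brute, character(1)))
})

test_that("every raw code of a mapped source has a harmonized image", {
  cat_obj <- small_cohort()$catalog
  vm <- cat_obj$value_maps
  for (key in unique(paste(vm$source, vm$concept_id, sep = "\r"))) {
    src <- sub("\r.*", "", key)
    cid <- sub(".*\r", "", key)
    mi <- which(cat_obj$mappings$source == src &
                  cat_obj$mappings$concept_id == cid)
    vrow <- cat_obj$variables[
      cat_obj$variables$source == src &
        cat_obj$variables$variable_name ==
          cat_obj$mappings$variable_name[mi], ]
    spec <- parse_code_spec(vrow$code_spec[1])
    raw_domain <- c(spec$categories$code, spec$special_codes$code)
    out <- map_value(src, cid, raw_domain, cat_obj)
    expect_false(anyNA(out$harmonized_value))
  }
})

test_that("the five-file catalog round-trips and validates integrity", {
  cat_obj <- small_cohort()$catalog
  dir <- withr::local_tempdir()
  save_catalog(cat_obj, dir)
  expect_setequal(list.files(dir),
                  c("concepts.csv", "variables.csv", "mappings.csv",
                    "permissible_values.csv", "value_harmonization.csv"))
  cat2 <- load_catalog(dir)
  expect_equal(cat2$concepts, cat_obj$concepts)
  expect_equal(cat2$variables, cat_obj$variables)
  expect_equal(cat2$mappings, cat_obj$mappings)
  expect_equal(cat2$value_maps, cat_obj$value_maps)

  unlink(file.path(dir, "mappings.csv"))
  err <- expect_error(load_catalog(dir), class = "cq_file_error")
  expect_match(conditionMessage(err), "mappings.csv")
})

test_that("a mapping to a nonexistent concept fails validation", {
  cat_obj <- csf_catalog()
  bad <- cat_obj$mappings[1, ]
  bad$concept_id <- "no_such_concept"
  err <- expect_error(
    catalog(concepts = cat_obj$concepts, variables = cat_obj$variables,
            mappings = rbind(cat_obj$mappings, bad),
            value_maps = cat_obj$value_maps),
    class = "cq_validation_error")
  expect_match(conditionMessage(err), "no_such_concept")
})

test_that("the harmonization profile counts rule kinds per concept", {
  expect_equal(harmonization_profile(catalog()),
               c(numeric = 0L, categorical = 0L, unit = 0L))

  one_unit <- synthetic_catalog("right_hippocampus_volume")$catalog
  expect_equal(harmonization_profile(one_unit)[["unit"]], 1L)

  full <- small_cohort()$catalog
  prof <- harmonization_profile(full)
  # education (widened range) + packs (bin rule); csf + games recodes;
  # hippocampus unit rule
  expect_equal(unname(prof), c(2L, 2L, 1L))
})
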