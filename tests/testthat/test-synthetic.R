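test_that("equal seeds give byte-identical generated fixtures", {
  spec <- cohort_spec(seed = 9, n_patients = c(NACC = 40L, ADNI = 40L))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_cohort(spec, dir = d1)
  generate_cohort(spec, dir = d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7),
                     label = f)
  }
  # and a different seed changes the data
  d3 <- withr::local_tempdir()
  generate_cohort(cohort_spec(seed = 10,
                              n_patients = c(NACC = 40L, ADNI = 40L)),
                  dir = d3)
  expect_false(identical(readBin(file.path(d1, "NACC.csv"), "raw", 1e7),
                         readBin(file.path(d3, "NACC.csv"), "raw", 1e7)))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- stats::runif(1)
  set.seed(123)
  invisible(generate_cohort(cohort_spec(seed = 5,
                                        n_patients = c(NACC = 10L,
                                                       ADNI = 10L))))
  expect_identical(stats::runif(1), before)
})

test_that("a zero sentinel rate leaves no sentinel codes in the study data", {
  res <- small_cohort(seed = 5, n = 80, sentinel_rate = 0)
  expect_false(any(res$study$NACC$EDUC == "99"))
  sentinel_only <- c("MARISTAT", "GAMES", "NPCSFBANK", "PACKSPER")
  expect_false(any(unlist(res$study$NACC[sentinel_only]) %in%
                     c("9", "-4", "8")))
  expect_false(any(res$study$ADNI$MEDHIST$PACKSDAY == "-4"))
  expect_false(any(res$study$ADNI$FAQ$FAQGAME == "9"))
})

test_that("generated dictionaries parse cleanly through the dictionary reader", {
  res <- small_cohort()
  nacc <- parse_dictionary(res$dictionaries$nacc, "nacc")
  adni <- parse_dictionary(res$dictionaries$adni, "adni")
  expect_equal(nrow(nacc), length(res$truth$concepts))
  expect_equal(nrow(adni), length(res$truth$concepts))
  expect_identical(rbind(nacc, adni), res$catalog$variables)
})

test_that("education values are uniform over the declared range", {
  rate <- 0.05
  res <- small_cohort(seed = 11, n = 2000, missing_rate = 0,
                      sentinel_rate = rate)
  v <- res$truth$attributes$NACC$years_of_education
  p <- (11 / 37) * (1 - rate)
  frac <- mean(!is.na(v) & v >= 5 & v <= 15)
  expect_lt(abs(frac - p), 3 * sqrt(p * (1 - p) / 2000))
})

test_that("the two independent oracles agree on random criteria", {
  res <- small_cohort()
  set.seed(77)
  for (i in 1:40) {
    crit <- random_criteria(res$catalog)
    a <- ground_truth_answer(res$truth, crit)
    b <- oracle_count(crit, res$study, res$catalog, res$registry)
    expect_equal(a, b, label = write_criteria(crit))
  }
})

test_that("the oracle answers degenerate criteria directly", {
  res <- small_cohort()
  all_crit <- query_criteria(c("NACC", "ADNI"))
  a <- oracle_count(all_crit, res$study, res$catalog, res$registry)
  expect_equal(unname(a$per_dataset),
               unname(as.integer(res$truth$n_patients[c("NACC", "ADNI")])))

  one <- oracle_count(query_criteria("NACC"), res$study, res$catalog,
                      res$registry)
  expect_equal(names(one$per_dataset), "NACC")

  none <- query_criteria("NACC",
                         list(term_range("right_hippocampus_volume", 7.9, 8)))
  expect_equal(oracle_count(none, res$study, res$catalog,
                            res$registry)$per_dataset[["NACC"]],
               ground_truth_answer(res$truth, none)$per_dataset[["NACC"]])
})

test_that("unknown planted concepts and invalid rates are rejected", {
  expect_error(cohort_spec(concepts = "blood_type"), class = "cq_spec_error")
  expect_error(cohort_spec(missing_rate = 1.5), class = "cq_spec_error")
  expect_error(cohort_spec(visits = c(3, 1)), class = "cq_spec_error")
})

test_that("the query engine matches the oracle end to end", {
  res <- small_cohort()
  store <- load_store(res)
  set.seed(1234)
  for (i in 1:60) {
    crit <- random_criteria(res$catalog)
    engine <- run_query(crit, res$catalog, store)
    oracle <- oracle_count(crit, res$study, res$catalog, res$registry)
    expect_equal(engine$per_dataset, oracle$per_dataset,
                 label = write_criteria(crit))
    expect_equal(engine$total, oracle$total)
    # total additivity
    expect_equal(engine$total, sum(engine$per_dataset))
  }
})

test_that("counts are monotone in the conjunction and the range width", {
  res <- small_cohort()
  store <- load_store(res)
  set.seed(4321)
  for (i in 1:20) {
    crit <- random_criteria(res$catalog, max_terms = 2)
    base <- run_query(crit, res$catalog, store)

    # adding a term never increases any count
    extra_id <- sample(setdiff(res$catalog$concepts$concept_id,
                               vapply(crit$terms, `[[`, "", "concept")), 1)
    spec <- concept_domain(res$catalog, extra_id)
    extra <- if (is.null(spec$range)) {
      term_values(extra_id, spec$categories$code[1])
    } else {
      term_range(extra_id, spec$range[1], mean(spec$range))
    }
    more <- query_criteria(crit$datasets, c(crit$terms, list(extra)))
    narrowed <- run_query(more, res$catalog, store)
    for (ds in names(narrowed$per_dataset)) {
      expect_lte(narrowed$per_dataset[[ds]], base$per_dataset[[ds]])
    }

    # widening a numeric range never decreases any count
    num_idx <- which(vapply(crit$terms, `[[`, "", "kind") == "numeric")
    if (length(num_idx)) {
      wide <- crit
      t <- wide$terms[[num_idx[1]]]
      dom <- concept_domain(res$catalog, t$concept)$range
      wide$terms[[num_idx[1]]] <- term_range(t$concept, dom[1], dom[2])
      wider <- run_query(wide, res$catalog, store)
      for (ds in names(base$per_dataset)) {
        expect_gte(wider$per_dataset[[ds]], base$per_dataset[[ds]])
      }
    }
  }
})
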