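res <- small_cohort()
cat_obj <- res$catalog
store <- load_store(res)

test_that("the numeric range statement renders in the backend dialect", {
  crit <- query_criteria("NACC",
                         list(term_range("years_of_education", 5, 15)))
  q <- translate(crit, cat_obj, res$registry)[[1]]
  expect_identical(
    render_statement(q),
    paste0('db.records_collection.distinct("NACCID", ',
           '{"dataset":"NACC", "EDUC":{"$gte":5, "$lte":15}})'))
})

test_that("match-all and categorical statements render deterministically", {
  crit <- query_criteria("NACC")
  q <- translate(crit, cat_obj, res$registry)[[1]]
  expect_identical(render_statement(q),
                   'db.records_collection.distinct("NACCID", {"dataset":"NACC"})')

  crit <- query_criteria("NACC", list(term_values("marital_status", "2")))
  q <- translate(crit, cat_obj, res$registry)[[1]]
  expect_identical(
    render_statement(q),
    'db.records_collection.distinct("NACCID", {"dataset":"NACC", "MARISTAT":"2"})')

  crit <- query_criteria("NACC",
                         list(term_values("marital_status", c("1", "2"))))
  q <- translate(crit, cat_obj, res$registry)[[1]]
  expect_identical(
    render_statement(q),
    paste0('db.records_collection.distinct("NACCID", ',
           '{"dataset":"NACC", "MARISTAT":{"$in":["1", "2"]}})'))
})

test_that("harmonized codes translate to each source's raw codes", {
  crit <- query_criteria(c("NACC", "ADNI"),
                         list(term_values("games_difficulty", "2")))
  qs <- translate(crit, cat_obj, res$registry)
  by_ds <- stats::setNames(qs, vapply(qs, `[[`, "", "dataset"))
  expect_equal(by_ds$NACC$filters[[1]]$field, "GAMES")
  expect_equal(by_ds$NACC$filters[[1]]$values, "2")
  expect_equal(by_ds$ADNI$filters[[1]]$field, "FAQGAME")
  expect_equal(by_ds$ADNI$filters[[1]]$values, "4")

  # recoded CSF criterion: harmonized "0" (No) is raw "2" in the
  # inconsistent source and raw "0" in the reference source
  crit <- query_criteria(c("NACC", "ADNI"),
                         list(term_values("banked_postmortem_csf", "0")))
  qs <- translate(crit, cat_obj, res$registry)
  by_ds <- stats::setNames(qs, vapply(qs, `[[`, "", "dataset"))
  expect_equal(by_ds$NACC$filters[[1]]$values, "0")
  expect_equal(by_ds$ADNI$filters[[1]]$values, "2")
})

test_that("a harmonized code with no raw preimage raises a mapping error", {
  crit <- query_criteria("ADNI",
                         list(term_values("banked_postmortem_csf", "9")))
  err <- expect_error(translate(crit, cat_obj, res$registry),
                      class = "cq_value_mapping_error")
  expect_match(conditionMessage(err), "ADNI")
})

test_that("criteria validation rejects unknown concepts, values and ranges", {
  expect_error(translate(query_criteria("NACC",
                                        list(term_values("nope", "1"))),
                         cat_obj, res$registry),
               class = "cq_lookup_error")
  expect_error(translate(query_criteria("NACC",
                                        list(term_values("marital_status",
                                                         "77"))),
                         cat_obj, res$registry),
               class = "cq_criteria_error")
  expect_error(translate(query_criteria("NACC",
                                        list(term_range("years_of_education",
                                                        -5, 10))),
                         cat_obj, res$registry),
               class = "cq_criteria_error")
  expect_error(query_criteria(character(0)), class = "cq_criteria_error")
})

test_that("criteria survive the JSON contract round trip", {
  crit <- query_criteria(c("NACC", "ADNI"),
                         list(term_range("years_of_education", 5, 15),
                              term_values("marital_status", c("1", "9"))))
  expect_equal(read_criteria(write_criteria(crit)), crit)
  expect_error(read_criteria("{"), class = "cq_criteria_error")
  expect_error(read_criteria('{"terms":[]}'), class = "cq_criteria_error")
  expect_error(read_criteria('{"datasets":["NACC"],"terms":[{"concept":"x"}]}'),
               class = "cq_criteria_error")
})

test_that("patients are counted once regardless of qualifying visits", {
  crit <- query_criteria("NACC",
                         list(term_range("years_of_education", 0, 36)))
  ids <- execute(translate(crit, cat_obj, res$registry), store)
  expect_false(anyDuplicated(ids$NACC) > 0)
  expect_lte(length(ids$NACC), res$truth$n_patients[["NACC"]])

  # replicate one patient's rows: counts unchanged
  store2 <- record_store(res$registry)
  dup <- res$study$NACC
  dup <- rbind(dup, dup[dup$NACCID == dup$NACCID[1], ])
  import_records(store2, dup, "NACC", cat_obj)
  ids2 <- execute(translate(crit, cat_obj, res$registry), store2)
  expect_setequal(ids2$NACC, ids$NACC)
})

test_that("sentinel codes never satisfy numeric interval predicates", {
  # the education sentinel (99) lies inside no interval, even one
  # covering the whole declared range
  crit <- query_criteria("NACC",
                         list(term_range("years_of_education", 0, 36)))
  n_all <- run_query(crit, cat_obj, store)$per_dataset[["NACC"]]
  att <- res$truth$attributes$NACC
  expect_equal(n_all, sum(!is.na(att$years_of_education)))
})

test_that("unit and bin harmonization happen at import", {
  raw <- res$study$ADNI$UCSFFRESFR
  stored <- store$records[store$records$dataset == "ADNI" &
                            !is.na(store$records$ST29SV), ]
  raw_num <- suppressWarnings(as.numeric(raw$ST29SV))
  expect_equal(sort(stored$ST29SV), sort(raw_num[!is.na(raw_num)] / 1000))

  packs <- store$records[store$records$dataset == "ADNI" &
                           !is.na(store$records$PACKSDAY__harmonized), ]
  expect_true(all(packs$PACKSDAY__harmonized %in%
                    c(as.character(0:5), "-4")))
  measured <- !is.na(packs$PACKSDAY)
  expect_identical(packs$PACKSDAY__harmonized[measured],
                   bin_numeric(packs$PACKSDAY[measured],
                               packs_per_day_bins()))
})

test_that("a dataset with an unmapped concept is excluded with a notice", {
  partial <- synthetic_catalog(c("years_of_education", "marital_status"))
  cat_p <- partial$catalog
  cat_p$mappings <- cat_p$mappings[!(cat_p$mappings$source == "ADNI" &
                                       cat_p$mappings$concept_id ==
                                         "marital_status"), ]
  crit <- query_criteria(c("NACC", "ADNI"),
                         list(term_values("marital_status", "1")))
  qs <- translate(crit, cat_p, res$registry)
  expect_equal(vapply(qs, `[[`, "", "dataset"), "NACC")
  expect_match(attr(qs, "notices"), "ADNI")
})

test_that("execution errors name unknown filter fields", {
  q <- structure(list(dataset = "NACC", patient_id_field = "NACCID",
                      filters = list(list(field = "NOPE", kind = "in",
                                          values = "1"))),
                 class = "cq_backend_query")
  err <- expect_error(execute(list(q), store), class = "cq_execution_error")
  expect_match(conditionMessage(err), "NOPE")
})

test_that("regrouping sums dataset-scoped counts", {
  expect_equal(regroup(list()), list(per_dataset = integer(0), total = 0L))
  r <- regroup(list(A = c("p1", "p2"), B = "q1"))
  expect_equal(r$per_dataset, c(A = 2L, B = 1L))
  expect_equal(r$total, 3L)
})

test_that("term summaries give category counts and five-number summaries", {
  s <- term_summary("marital_status", "NACC", store, cat_obj)
  att <- res$truth$attributes$NACC
  n_visits <- tabulate(match(store$records$.pid[
    store$records$dataset == "NACC" & !is.na(store$records$MARISTAT)],
    att$pid), nbins = nrow(att))
  expect_equal(sum(s$count), sum(n_visits))
  expect_true(all(s$value %in% c("1", "2", "3", "4", "9")))

  # five-number summary follows the Tukey hinge convention
  st <- record_store(c(NACC = "NACCID"))
  toy <- data.frame(NACCID = as.character(1:5), EDUC = as.character(1:5),
                    stringsAsFactors = FALSE)
  import_records(st, toy, "NACC", cat_obj)
  s <- term_summary("years_of_education", "NACC", st, cat_obj)
  expect_equal(unname(s), c(1, 2, 3, 4, 5))

  st0 <- record_store(c(NACC = "NACCID"))
  s0 <- term_summary("years_of_education", "NACC", st0, cat_obj)
  expect_true(all(is.na(s0)))
  expect_error(term_summary("years_of_education", "XX", store, cat_obj),
               class = "cq_unmapped_term")
})

test_that("term search and browse are deterministic", {
  hit <- search_terms("marital", cat_obj)
  expect_true("Marital status" %in% hit$label)
  exact <- search_terms("marital status", cat_obj)
  expect_equal(exact$label[1], "Marital status")
  expect_equal(nrow(search_terms("zzzz", cat_obj)), 0L)

  tree <- browse_terms(cat_obj)
  expect_setequal(unlist(tree, use.names = FALSE), cat_obj$concepts$label)
  expect_equal(length(unlist(tree)), nrow(cat_obj$concepts))
  expect_equal(names(tree), sort(names(tree)))
})
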