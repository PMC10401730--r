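test_that("the observed code-spec dialects parse correctly", {
  s <- parse_code_spec("0 = No; 1 = Yes")
  expect_equal(s$kind, "categorical")
  expect_equal(s$categories$code, c("0", "1"))
  expect_equal(s$categories$label, c("No", "Yes"))

  s <- parse_code_spec("1..12")
  expect_equal(s$kind, "numeric_range")
  expect_equal(s$range, c(1, 12))

  s <- parse_code_spec("0 - 36; 99 = Unknown")
  expect_equal(s$kind, "numeric_range")
  expect_equal(s$range, c(0, 36))
  expect_equal(s$special_codes$code, "99")
  expect_equal(s$special_codes$label, "Unknown")

  expect_equal(parse_code_spec("")$kind, "unconstrained")
  expect_equal(parse_code_spec(NA_character_)$kind, "unconstrained")
})

test_that("alias suffixes are stripped and negative codes bind to the code", {
  s <- parse_code_spec("1=Yes(1); 0=No(0)")
  expect_equal(s$categories$code, c("1", "0"))
  expect_equal(s$categories$label, c("Yes", "No"))

  s <- parse_code_spec("0 = No; -4 = Not available")
  expect_equal(s$kind, "categorical")
  expect_true("-4" %in% s$categories$code)
  expect_equal(s$categories$label[s$categories$code == "-4"],
               "Not available")

  s <- parse_code_spec("-4=Not available(-4)")
  expect_equal(s$categories$label, "Not available")
})

test_that("unparseable fragments raise a parse error naming the fragment", {
  err <- expect_error(parse_code_spec("0 = No; wat"),
                      class = "cq_parse_error")
  expect_match(conditionMessage(err), "wat")
  expect_error(parse_code_spec("5 - 2"), class = "cq_parse_error")
  expect_error(parse_code_spec("1 - 2; 3 - 4"), class = "cq_parse_error")
})

test_that("the canonical printer round-trips through the parser", {
  dialects <- c("0 = No; 1 = Yes", "1..12", "0 - 36; 99 = Unknown", "",
                "1=Yes(1); 0=No(0)",
                "0 = No; 1 = Yes; 9 = Missing/unknown; -4 = Not available",
                "0 - 10; -4=Not available(-4)")
  for (d in dialects) {
    spec <- parse_code_spec(d)
    expect_identical(parse_code_spec(format_code_spec(spec)), spec,
                     label = sprintf("round trip of '%s'", d))
  }
  # negative range endpoints survive via the dot-dot form
  spec <- code_spec("numeric_range", range = c(-2, 5))
  expect_identical(parse_code_spec(format_code_spec(spec)), spec)
})

test_that("randomly built code specs survive the grammar round trip", {
  set.seed(101)
  for (i in 1:50) {
    k <- sample(3, 1)
    spec <- if (k == 1) {
      n <- sample(1:6, 1)
      code_spec("categorical", categories = data.frame(
        code = as.character(sample(-5:99, n)),
        label = paste("Label", seq_len(n)), stringsAsFactors = FALSE))
    } else if (k == 2) {
      r <- sort(round(stats::runif(2, 0, 50), 2))
      sp <- if (stats::runif(1) < 0.5) {
        data.frame(code = "99", label = "Unknown", stringsAsFactors = FALSE)
      } else NULL
      code_spec("numeric_range", range = r, special_codes = sp)
    } else {
      code_spec("unconstrained")
    }
    expect_identical(parse_code_spec(format_code_spec(spec)), spec)
  }
})

test_that("camel-case expansion fixes concatenated descriptors idempotently", {
  expect_equal(expand_concatenated("Cortical Thickness Average of LeftIsthmusCingulate"),
               "Cortical Thickness Average of Left Isthmus Cingulate")
  expect_equal(expand_concatenated("Volume (WM Parcellation) of ThirdVentricle"),
               "Volume (WM Parcellation) of Third Ventricle")
  expect_equal(expand_concatenated("Years of education"), "Years of education")

  set.seed(7)
  for (i in 1:100) {
    s <- paste(sample(c(letters, LETTERS, 0:9, " ", "(", ")"), 30,
                      replace = TRUE), collapse = "")
    once <- expand_concatenated(s)
    expect_identical(expand_concatenated(once), once)
  }
})
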