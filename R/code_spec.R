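#' Construct a code specification
#'
#' A code specification describes the permissible values of one data element:
#' either an enumerated set of coded categories (categorical), a numeric
#' range optionally accompanied by sentinel codes such as `9 = Unknown`
#' (numeric_range), or nothing at all (unconstrained). Codes are always kept
#' as text so that signed sentinels like `-4` survive round trips.
#'
#' @param kind One of `"categorical"`, `"numeric_range"`, `"unconstrained"`.
#' @param categories Data frame with columns `code`, `label` (categorical
#'   specs), or `NULL`.
#' @param range Numeric length-2 vector `c(min, max)`, or `NULL`.
#' @param special_codes Data frame with columns `code`, `label` for sentinel
#'   codes that accompany a numeric range, or `NULL`.
#' @return An object of class `cq_code_spec`.
#' @export
code_spec <- function(kind = c("categorical", "numeric_range", "unconstrained"),
                      categories = NULL, range = NULL, special_codes = NULL) {
  kind <- match.arg(kind)
  empty <- data.frame(code = character(), label = character(),
                      stringsAsFactors = FALSE)
  categories <- categories %||% empty
  special_codes <- special_codes %||% empty
  categories$code <- as.character(categories$code)
  special_codes$code <- as.character(special_codes$code)

  if (kind == "categorical") {
    if (nrow(categories) < 1L) {
      cq_abort("cq_contract_error", "categorical code spec needs >= 1 category")
    }
    if (anyDuplicated(categories$code)) {
      cq_abort("cq_contract_error", "category codes must be pairwise distinct")
    }
    range <- NULL
  } else if (kind == "numeric_range") {
    if (is.null(range) || length(range) != 2L || anyNA(range) ||
        range[1] > range[2]) {
      cq_abort("cq_contract_error", "numeric_range needs c(min, max), min <= max")
    }
    range <- as.numeric(range)
    categories <- empty
  } else {
    categories <- empty
    range <- NULL
    special_codes <- empty
  }
  structure(list(kind = kind, categories = categories, range = range,
                 special_codes = special_codes),
            class = "cq_code_spec")
}

#' @export
print.cq_code_spec <- function(x, ...) {
  cat("<code_spec ", x$kind, "> ", format_code_spec(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.cq_code_spec <- function(x, ...) format_code_spec(x)

#' Test and compare code specifications
#' @param x Object.
#' @return `is_code_spec` returns `TRUE` for `cq_code_spec` objects.
#' @export
is_code_spec <- function(x) inherits(x, "cq_code_spec")

# One "a = b" fragment. ADNI writes labels with a trailing alias equal to the
# code ("1=Yes(1)"); the alias is stripped so labels match the plain style.
parse_category_entry <- function(entry) {
  m <- regmatches(entry, regexec("^(\\S+?)\\s*=\\s*(.*)$", entry))[[1]]
  code <- trimws2(m[2])
  label <- trimws2(m[3])
  alias <- paste0("\\(", gsub("([][{}()+*^$|\\\\?.-])", "\\\\\\1", code), "\\)$")
  label <- trimws2(sub(alias, "", label))
  list(code = code, label = label)
}

num_re <- "[0-9]+(\\.[0-9]+)?"

#' Parse an allowable-codes string into a code specification
#'
#' Understands the dialects observed in study data dictionaries:
#' `"0 = No; 1 = Yes"` (categories), `"0 - 36"` or `"1..12"` (numeric
#' ranges; `..` additionally admits negative endpoints), `"0 - 36; 99 =
#' Unknown"` (range plus sentinel codes), and `""` (unconstrained). A
#' leading `-` always binds to a code (`-4 = Not available`), never to a
#' range. Whitespace-insensitive; code text is preserved verbatim.
#'
#' @param text A single code-spec string.
#' @return A [code_spec()] object.
#' @export
#' @examples
#' parse_code_spec("0 = No; 1 = Yes")
#' parse_code_spec("0 - 36; 99 = Unknown")
parse_code_spec <- function(text) {
  stopifnot(length(text) == 1L)
  if (is.na(text) || !nzchar(trimws2(text))) return(code_spec("unconstrained"))

  entries <- trimws2(strsplit(text, ";", fixed = TRUE)[[1]])
  entries <- entries[nzchar(entries)]

  range <- NULL
  cats <- list()
  hyphen_range <- sprintf("^(%s)\\s*-\\s*(%s)$", num_re, num_re)
  dotdot_range <- sprintf("^(-?%s)\\.\\.(-?%s)$", num_re, num_re)
  for (entry in entries) {
    if (grepl("=", entry, fixed = TRUE)) {
      cats[[length(cats) + 1L]] <- parse_category_entry(entry)
    } else if (grepl(hyphen_range, entry) || grepl(dotdot_range, entry)) {
      re <- if (grepl(hyphen_range, entry)) hyphen_range else dotdot_range
      m <- regmatches(entry, regexec(re, entry))[[1]]
      lo <- as.numeric(m[2])
      hi <- as.numeric(m[4])
      if (!is.null(range)) {
        cq_abort("cq_parse_error",
                 sprintf("more than one range fragment in code spec: '%s'", entry),
                 fragment = entry)
      }
      if (lo > hi) {
        cq_abort("cq_parse_error",
                 sprintf("range lower bound exceeds upper bound: '%s'", entry),
                 fragment = entry)
      }
      range <- c(lo, hi)
    } else {
      cq_abort("cq_parse_error",
               sprintf("unparseable code-spec fragment: '%s'", entry),
               fragment = entry)
    }
  }

  cats_df <- if (length(cats)) {
    data.frame(code = vapply(cats, `[[`, "", "code"),
               label = vapply(cats, `[[`, "", "label"),
               stringsAsFactors = FALSE)
  } else NULL

  if (!is.null(range)) {
    code_spec("numeric_range", range = range, special_codes = cats_df)
  } else if (!is.null(cats_df)) {
    code_spec("categorical", categories = cats_df)
  } else {
    code_spec("unconstrained")
  }
}

#' Canonical printer for a code specification
#'
#' Emits a string that [parse_code_spec()] parses back to an equal object
#' (the grammar round trip). Negative range endpoints are printed with the
#' `..` separator so they cannot be confused with a code.
#'
#' @param spec A [code_spec()] object.
#' @return A single string; `""` for unconstrained specs.
#' @export
format_code_spec <- function(spec) {
  stopifnot(is_code_spec(spec))
  cat_str <- function(df) paste(df$code, "=", df$label, collapse = "; ")
  switch(spec$kind,
    unconstrained = "",
    categorical = cat_str(spec$categories),
    numeric_range = {
      sep_range <- if (spec$range[1] < 0) {
        paste0(fmt_num(spec$range[1]), "..", fmt_num(spec$range[2]))
      } else {
        paste(fmt_num(spec$range[1]), "-", fmt_num(spec$range[2]))
      }
      if (nrow(spec$special_codes)) {
        paste(sep_range, cat_str(spec$special_codes), sep = "; ")
      } else sep_range
    })
}

#' Insert spaces at camel-case word boundaries
#'
#' Imaging data elements sometimes concatenate words describing brain
#' regions (`"LeftIsthmusCingulate"`). This inserts a space at every
#' lower-to-upper case boundary inside an alphabetic run. Idempotent;
#' strings without such boundaries are returned unchanged.
#'
#' @param text Character vector of descriptors.
#' @return Character vector with boundaries expanded.
#' @export
#' @examples
#' expand_concatenated("Volume (WM Parcellation) of ThirdVentricle")
expand_concatenated <- function(text) {
  gsub("([a-z])([A-Z])", "\\1 \\2", text)
}
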