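#' Recode an ICD-10-CM code against the grouping lexicon
#'
#' Codes coming out of entity resolution do not always have an exact match
#' in the grouping lexicon (e.g. "C5091", breast cancer at an unspecified
#' site, where the lexicon carries only the more precise C50911/C50912/
#' C50919). Recoding aligns them by iterative last-character trimming: for
#' k = 0, 1, 2, ... take the code minus its last k characters and collect
#' lexicon codes beginning with that prefix, stopping at the smallest k
#' with at least one match. The code inherits the most common disease
#' category among the matches; ties are broken by the fixed category
#' priority order ([disease_categories()], then OTHER) and flagged. The
#' untrimmed code is tried as a prefix first (k = 0), which subsumes
#' trim-first behavior whenever trimming would be needed. If the prefix
#' shrinks to nothing without a match the code is unmatched.
#'
#' @param code a single ICD-10-CM code (dots tolerated).
#' @param lexicon an `icd_lexicon`.
#' @return list of class `recode_result`: `input_code`, `matched`
#'   (`"exact"`, `"prefix"` or `"none"`), `trims` (characters removed),
#'   `matching_codes`, `n_matches`, `disease_category` (`NA` when
#'   unmatched) and `tie`.
#' @examples
#' lex <- load_lexicon(system.file("extdata", "demo_lexicon.csv",
#'                                 package = "crowddx"))
#' recode("C5091", lex)$disease_category
#' @export
recode <- function(code, lexicon) {
  stopifnot(inherits(lexicon, "icd_lexicon"), length(code) == 1L)
  code <- normalize_code(code)
  if (!code_pattern_ok(code))
    stop("malformed ICD-10-CM code: ", code)

  res <- list(input_code = code, matched = "none", trims = nchar(code) - 1L,
              matching_codes = character(0), n_matches = 0L,
              disease_category = NA_character_, tie = FALSE)
  class(res) <- "recode_result"

  exact <- lexicon_entry(lexicon, code)
  if (nrow(exact) == 1L) {
    res$matched <- "exact"; res$trims <- 0L
    res$matching_codes <- exact$code; res$n_matches <- 1L
    res$disease_category <- exact$disease_category
    return(res)
  }
  for (k in 0:(nchar(code) - 1L)) {
    prefix <- substr(code, 1L, nchar(code) - k)
    hits <- codes_with_prefix(lexicon, prefix)
    if (nrow(hits) > 0L) {
      res$matched <- "prefix"; res$trims <- k
      res$matching_codes <- hits$code; res$n_matches <- nrow(hits)
      modal <- modal_category(hits$disease_category)
      res$disease_category <- modal$category
      res$tie <- modal$tie
      return(res)
    }
  }
  res
}

# most common category; ties broken by fixed priority order
modal_category <- function(cats) {
  tab <- table(cats)
  winners <- names(tab)[tab == max(tab)]
  prio <- c(disease_categories(), "OTHER")
  list(category = winners[which.min(match(winners, prio))],
       tie = length(winners) > 1L)
}

#' Recode a vector of codes, returning a log table
#'
#' @param codes character vector of ICD-10-CM codes.
#' @param lexicon an `icd_lexicon`.
#' @return data frame with columns `input_code`, `matched`, `trims`,
#'   `n_matches`, `disease_category`, `tie` (one row per input, in order).
#' @export
recode_codes <- function(codes, lexicon) {
  if (!length(codes))
    return(data.frame(input_code = character(0), matched = character(0),
                      trims = integer(0), n_matches = integer(0),
                      disease_category = character(0), tie = logical(0),
                      stringsAsFactors = FALSE))
  ucodes <- unique(normalize_code(codes))
  rows <- lapply(ucodes, function(cd) {
    r <- recode(cd, lexicon)
    data.frame(input_code = r$input_code, matched = r$matched,
               trims = r$trims, n_matches = r$n_matches,
               disease_category = r$disease_category, tie = r$tie,
               stringsAsFactors = FALSE)
  })
  log <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  log[match(normalize_code(codes), log$input_code), , drop = FALSE]
}

#' Summarize a recode log
#'
#' Tallies how many codes matched the grouping lexicon exactly, via prefix
#' trimming, or not at all, and the two headline percentages: the share of
#' codes with no exact match, and the share of those recovered by trimming
#' to a code with an identical stem.
#'
#' @param log recode log from [recode_codes()] (or any data frame with a
#'   `matched` column of `"exact"`/`"prefix"`/`"none"` values).
#' @return list with `n_total`, `n_exact`, `n_prefix`, `n_none`,
#'   `pct_no_exact_match`, `pct_recovered_by_trimming`.
#' @export
recode_summary <- function(log) {
  stopifnot("matched" %in% names(log))
  n_exact <- sum(log$matched == "exact")
  n_prefix <- sum(log$matched == "prefix")
  n_none <- sum(log$matched == "none")
  n_total <- nrow(log)
  n_un <- n_prefix + n_none
  list(n_total = n_total, n_exact = n_exact, n_prefix = n_prefix,
       n_none = n_none,
       pct_no_exact_match = if (n_total > 0) 100 * n_un / n_total else NA_real_,
       pct_recovered_by_trimming = if (n_un > 0) 100 * n_prefix / n_un else NA_real_)
}

#' @export
print.recode_result <- function(x, ...) {
  cat("recode(", x$input_code, "): ", x$matched, sep = "")
  if (x$matched != "none") {
    cat(", trims=", x$trims, ", ", x$n_matches, " match(es) -> ",
        x$disease_category, if (x$tie) " (tie)" else "", sep = "")
  }
  cat("\n")
  invisible(x)
}
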