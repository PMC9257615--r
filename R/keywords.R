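#' Keyword rules: treatment/procedure terms that imply a disease category
#'
#' Campaigns often state a treatment rather than a diagnosis ("started
#' dialysis", "halfway through chemo"). A keyword rule maps such a term to
#' the disease category it implies. Matching is case-insensitive and
#' word-boundary aligned; multi-word phrases tolerate any whitespace run
#' between tokens. Inflected forms are not stemmed: only the listed
#' alternates match, so "burnout" never fires "burn" and "crashing" never
#' fires "crash".
#'
#' @param rules data frame with columns `pattern` (a word or literal
#'   multi-word phrase) and `disease_category`.
#' @return object of class `keyword_rules` (the validated table with a
#'   precompiled regex column).
#' @export
keyword_rules <- function(rules) {
  stopifnot(is.data.frame(rules),
            all(c("pattern", "disease_category") %in% names(rules)))
  rules <- as.data.frame(rules, stringsAsFactors = FALSE)
  rules$pattern <- trimws(tolower(rules$pattern))
  if (any(!nzchar(rules$pattern))) stop("empty keyword pattern")
  bad <- setdiff(rules$disease_category, c(disease_categories(), "OTHER"))
  if (length(bad))
    stop("keyword rules target unknown categories: ",
         paste(bad, collapse = ", "))
  toks <- strsplit(rules$pattern, "\\s+")
  rules$regex <- vapply(toks, function(tt)
    paste0("\\b", paste(tt, collapse = "\\s+"), "\\b"), "")
  class(rules) <- c("keyword_rules", "data.frame")
  rules
}

#' The default treatment/procedure keyword rule set
#'
#' Twenty-one patterns over six disease categories: injuries and external
#' causes (accident, injury/injuries/injured, crash, collision,
#' burn/burns/burned), cardiovascular (heart transplant, heart surgery),
#' neoplasms (chemo/chemotherapy, radiation/radiotherapy, bone marrow
#' transplant), genitourinary (dialysis, kidney/renal transplant),
#' gastrointestinal (liver transplant) and respiratory (lung transplant).
#' Shipped as an editable CSV
#' (`system.file("extdata", "keyword_rules.csv", package = "crowddx")`).
#'
#' @return a `keyword_rules` object.
#' @export
default_keyword_rules <- function() {
  load_keyword_rules(system.file("extdata", "keyword_rules.csv",
                                 package = "crowddx"))
}

#' Read keyword rules from CSV
#'
#' @param path CSV with columns `pattern`, `disease_category`.
#' @return a `keyword_rules` object.
#' @export
load_keyword_rules <- function(path) {
  keyword_rules(read.csv(path, stringsAsFactors = FALSE))
}

#' Apply keyword rules to campaign text
#'
#' Returns the patterns found and the disease categories they imply. The
#' category set is what matters downstream (a category counts at most once
#' per campaign); the matched patterns are retained as provenance.
#'
#' @param campaign a list/one-row data frame with `text` (and optionally
#'   `campaign_id`), or a bare string.
#' @param rules a [keyword_rules()] object.
#' @return data frame with columns `disease_category`, `pattern`, one row
#'   per matched rule (0 rows when nothing matches).
#' @examples
#' apply_keyword_rules("my kidneys failing and having to start dialysis.",
#'                     default_keyword_rules())
#' @export
apply_keyword_rules <- function(campaign, rules) {
  stopifnot(inherits(rules, "keyword_rules"))
  text <- if (is.character(campaign) && length(campaign) == 1L) campaign
          else as.character(campaign$text)
  if (length(text) != 1L || is.na(text) || !nzchar(text))
    return(data.frame(disease_category = character(0),
                      pattern = character(0), stringsAsFactors = FALSE))
  hit <- vapply(rules$regex, function(rx)
    grepl(rx, text, ignore.case = TRUE, perl = TRUE), logical(1))
  out <- data.frame(disease_category = rules$disease_category[hit],
                    pattern = rules$pattern[hit], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
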