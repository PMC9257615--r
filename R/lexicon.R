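#' Build an indexed ICD-10-CM lexicon from a data frame
#'
#' The lexicon is the grouping table the whole pipeline leans on: one row
#' per ICD-10-CM code with its free-text description, its narrow CCSR
#' clinical category, and the broad disease category it maps to. Codes are
#' stored undotted and uppercase and kept in C-locale sorted order so that
#' prefix range queries (the backbone of the trimming recoder) are cheap.
#'
#' Each entry gets exactly one disease category, with precedence: an
#' explicit `disease_category` column, else a CCSR reassignment from the
#' scheme, else the chapter default for the code's stem, else `OTHER`.
#'
#' @param entries data frame with columns `code`, `description`,
#'   `ccsr_category`; optional `disease_category` and `synonyms`
#'   (pipe-separated alternate phrasings used by the detector/resolver).
#' @param scheme a [category_scheme()].
#' @return object of class `icd_lexicon`: the validated, sorted entry table
#'   plus the scheme used to derive categories.
#' @export
icd_lexicon <- function(entries, scheme = category_scheme()) {
  stopifnot(is.data.frame(entries), inherits(scheme, "category_scheme"))
  need <- c("code", "description", "ccsr_category")
  miss <- setdiff(need, names(entries))
  if (length(miss))
    stop("lexicon is missing columns: ", paste(miss, collapse = ", "))
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  entries$code <- normalize_code(entries$code)

  bad <- which(!code_pattern_ok(entries$code))
  if (length(bad))
    stop("malformed ICD-10-CM code(s) at row(s) ",
         paste(bad, collapse = ", "), ": ",
         paste(entries$code[bad], collapse = ", "))
  dup <- unique(entries$code[duplicated(entries$code)])
  if (length(dup))
    stop("duplicate code(s) in lexicon: ", paste(dup, collapse = ", "))

  if (!"synonyms" %in% names(entries))
    entries$synonyms <- character(nrow(entries))
  entries$synonyms[is.na(entries$synonyms)] <- ""

  derived <- scheme_category(scheme, entries$code, entries$ccsr_category)
  if ("disease_category" %in% names(entries)) {
    dc <- as.character(entries$disease_category)
    use_derived <- is.na(dc) | dc == ""
    dc[use_derived] <- derived[use_derived]
  } else {
    dc <- derived
  }
  bad <- setdiff(dc, c(scheme$categories, "OTHER"))
  if (length(bad))
    stop("disease_category outside the closed set: ",
         paste(bad, collapse = ", "))
  entries$disease_category <- dc
  entries$norm_description <- normalize_text(entries$description)

  ord <- order(entries$code, method = "radix")
  entries <- entries[ord, c("code", "description", "ccsr_category",
                            "disease_category", "synonyms",
                            "norm_description")]
  rownames(entries) <- NULL
  structure(list(entries = entries, scheme = scheme), class = "icd_lexicon")
}

#' Load an ICD-10-CM lexicon from CSV
#'
#' @param path CSV file with header and columns `code`, `description`,
#'   `ccsr_category`, optionally `disease_category` and `synonyms`.
#' @param scheme a [category_scheme()] supplying defaults for entries
#'   without an explicit `disease_category`.
#' @return an `icd_lexicon`.
#' @examples
#' lex <- load_lexicon(system.file("extdata", "demo_lexicon.csv",
#'                                 package = "crowddx"))
#' codes_with_prefix(lex, "C5091")$code
#' @export
load_lexicon <- function(path, scheme = category_scheme()) {
  entries <- read.csv(path, stringsAsFactors = FALSE,
                      colClasses = "character")
  icd_lexicon(entries, scheme)
}

#' Prefix range query over lexicon codes
#'
#' Returns all entries whose code begins with `prefix`, in lexicographic
#' code order. Locates the range start by binary search on the sorted code
#' column. An empty result is valid (and is what the recoder's trimming
#' loop iterates on).
#'
#' @param lexicon an `icd_lexicon`.
#' @param prefix code prefix, at least one character (dots tolerated).
#' @return data frame of matching lexicon entries (possibly 0 rows).
#' @export
codes_with_prefix <- function(lexicon, prefix) {
  stopifnot(inherits(lexicon, "icd_lexicon"))
  prefix <- normalize_code(prefix)
  if (length(prefix) != 1L || nchar(prefix) < 1L)
    stop("prefix must be a single string of length >= 1")
  codes <- lexicon$entries$code
  n <- length(codes)
  # binary search: first index with codes[i] >= prefix
  lo <- 1L; hi <- n + 1L
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (codes[mid] < prefix) lo <- mid + 1L else hi <- mid
  }
  i <- lo
  keep <- integer(0)
  while (i <= n && startsWith(codes[i], prefix)) {
    keep <- c(keep, i)
    i <- i + 1L
  }
  lexicon$entries[keep, , drop = FALSE]
}

lexicon_entry <- function(lexicon, code) {
  idx <- match(normalize_code(code), lexicon$entries$code)
  lexicon$entries[idx[!is.na(idx)], , drop = FALSE]
}

#' @export
print.icd_lexicon <- function(x, ...) {
  tab <- table(x$entries$disease_category)
  cat("ICD-10-CM lexicon: ", nrow(x$entries), " codes\n", sep = "")
  cat("  categories: ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}
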