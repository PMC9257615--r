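#' The eleven disease categories
#'
#' The closed set of system-level disease categories the pipeline assigns,
#' in the fixed priority order used for reporting and for deterministic
#' tie-breaking in the recoder. Codes falling outside these (pregnancy,
#' eye/ear, blood/immune, symptom, encounter codes, ...) map to `"OTHER"`
#' and are dropped from final campaign summaries.
#'
#' @return character vector of length 11.
#' @export
disease_categories <- function() {
  c("cardiovascular", "endocrine", "gastrointestinal", "genitourinary",
    "infections", "injuries_external", "mental_health", "musculoskeletal",
    "neoplasms", "nervous_system", "respiratory")
}

#' Category scheme: how ICD-10-CM codes map to disease categories
#'
#' A scheme bundles (1) the fixed list of eleven categories, (2) a default
#' chapter map assigning a category to each ICD-10-CM code from its
#' three-character stem range (shipped as an editable CSV,
#' `system.file("extdata", "chapter_categories.csv", package = "crowddx")`),
#' and (3) optional reassignments that override the chapter default for
#' named CCSR clinical categories (e.g. routing congenital cardiovascular
#' malformations to `cardiovascular` rather than `OTHER`).
#'
#' @param reassignments `NULL`, a named character vector
#'   (`names` = CCSR clinical category, values = disease category), or a
#'   data frame with columns `ccsr_category`, `disease_category`.
#' @param chapter_map data frame with columns `code_start`, `code_end`,
#'   `disease_category`; defaults to the shipped chapter table.
#' @return an object of class `category_scheme`.
#' @seealso [load_scheme()] to read reassignments from a CSV file.
#' @export
category_scheme <- function(reassignments = NULL, chapter_map = NULL) {
  cats <- disease_categories()
  if (is.null(chapter_map)) {
    path <- system.file("extdata", "chapter_categories.csv",
                        package = "crowddx")
    chapter_map <- read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("code_start", "code_end", "disease_category")
  if (!all(need %in% names(chapter_map)))
    stop("chapter_map needs columns: ", paste(need, collapse = ", "))
  bad <- setdiff(chapter_map$disease_category, c(cats, "OTHER"))
  if (length(bad))
    stop("chapter_map assigns unknown categories: ", paste(bad, collapse = ", "))

  if (is.data.frame(reassignments)) {
    if (!all(c("ccsr_category", "disease_category") %in% names(reassignments)))
      stop("reassignment table needs columns ccsr_category, disease_category")
    reassignments <- setNames(as.character(reassignments$disease_category),
                              as.character(reassignments$ccsr_category))
  }
  if (is.null(reassignments)) reassignments <- setNames(character(0), character(0))
  bad <- setdiff(reassignments, c(cats, "OTHER"))
  if (length(bad))
    stop("reassignment targets must be a disease category or OTHER; got: ",
         paste(bad, collapse = ", "))

  structure(list(categories = cats,
                 reassignments = reassignments,
                 chapter_map = chapter_map),
            class = "category_scheme")
}

#' Read a category scheme with reassignment overrides from CSV
#'
#' @param path CSV with columns `ccsr_category`, `disease_category`.
#' @param chapter_map optional chapter table passed to [category_scheme()].
#' @return a `category_scheme`.
#' @export
load_scheme <- function(path, chapter_map = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  category_scheme(reassignments = df, chapter_map = chapter_map)
}

#' Derive disease categories for codes under a scheme
#'
#' Applies the scheme's precedence: a CCSR-category reassignment when one
#' matches, otherwise the chapter default from the code's three-character
#' stem, otherwise `OTHER`. The operation is deterministic and idempotent.
#'
#' @param scheme a `category_scheme`.
#' @param code character vector of undotted uppercase ICD-10-CM codes.
#' @param ccsr_category character vector of CCSR clinical category labels
#'   (recycled; `NA` entries fall through to the chapter default).
#' @return character vector of disease categories (or `"OTHER"`).
#' @export
scheme_category <- function(scheme, code, ccsr_category = NA_character_) {
  stopifnot(inherits(scheme, "category_scheme"))
  code <- normalize_code(code)
  ccsr_category <- rep_len(as.character(ccsr_category), length(code))
  out <- rep("OTHER", length(code))
  stem <- substr(code, 1L, 3L)
  cm <- scheme$chapter_map
  for (i in seq_len(nrow(cm))) {
    sel <- stem >= cm$code_start[i] & stem <= cm$code_end[i]
    out[sel] <- cm$disease_category[i]
  }
  if (length(scheme$reassignments)) {
    hit <- match(ccsr_category, names(scheme$reassignments))
    out[!is.na(hit)] <- unname(scheme$reassignments[hit[!is.na(hit)]])
  }
  out
}

#' @export
print.category_scheme <- function(x, ...) {
  cat("Category scheme: 11 disease categories + OTHER\n")
  cat("  categories:   ", paste(x$categories, collapse = ", "), "\n", sep = "")
  cat("  chapter map:  ", nrow(x$chapter_map), " stem ranges\n", sep = "")
  cat("  reassignments:", length(x$reassignments), "CCSR category overrides\n")
  invisible(x)
}

# Uppercase, drop dots ("C50.911" -> "C50911"); trimming and prefix logic
# operate on the undotted form.
normalize_code <- function(code) {
  gsub(".", "", toupper(trimws(as.character(code))), fixed = TRUE)
}

code_pattern_ok <- function(code) {
  grepl("^[A-Z][0-9]{2}[A-Z0-9]{0,4}$", code)
}
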