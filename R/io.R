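#' Read a campaign table from JSONL or CSV
#'
#' JSONL files carry one JSON object per line with keys `campaign_id` and
#' `text`; CSV files carry the same columns. The format is inferred from
#' the file extension (`.jsonl`/`.json` vs `.csv`).
#'
#' @param path input file.
#' @return data frame with character columns `campaign_id`, `text`.
#' @export
read_campaigns <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("jsonl", "json")) {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(seq_along(lines), function(i) {
      obj <- tryCatch(jsonlite::fromJSON(lines[i]),
                      error = function(e) stop("bad JSON on line ", i, ": ",
                                               conditionMessage(e)))
      if (is.null(obj$campaign_id))
        stop("line ", i, " has no campaign_id")
      data.frame(campaign_id = as.character(obj$campaign_id),
                 text = as.character(obj$text %||% ""),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else if (ext == "csv") {
    out <- read.csv(path, stringsAsFactors = FALSE,
                    colClasses = "character")
    miss <- setdiff(c("campaign_id", "text"), names(out))
    if (length(miss))
      stop("campaign CSV is missing column(s): ",
           paste(miss, collapse = ", "))
    out <- out[, c("campaign_id", "text")]
  } else {
    stop("unsupported campaign file extension: .", ext)
  }
  dup <- unique(out$campaign_id[duplicated(out$campaign_id)])
  if (length(dup))
    stop("duplicate campaign_id in ", path, ": ",
         paste(head(dup, 10), collapse = ", "))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write campaigns as JSONL
#'
#' @param campaigns data frame with `campaign_id`, `text`.
#' @param path output file.
#' @export
write_campaigns <- function(campaigns, path) {
  stopifnot(all(c("campaign_id", "text") %in% names(campaigns)))
  lines <- vapply(seq_len(nrow(campaigns)), function(i)
    jsonlite::toJSON(list(campaign_id = campaigns$campaign_id[i],
                          text = campaigns$text[i]),
                     auto_unbox = TRUE), "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write assignment tables to CSV
#'
#' The wide file has one row per campaign: a 0/1 column per category plus
#' a `<category>_source` provenance column. The optional long file keeps
#' one row per present campaign-category pair with its evidence (codes
#' and/or matched keyword patterns).
#'
#' @param x a `disease_assignments` object.
#' @param path output CSV for the wide table.
#' @param evidence_path optional output CSV for the long evidence table.
#' @export
write_assignments <- function(x, path, evidence_path = NULL) {
  stopifnot(inherits(x, "disease_assignments"))
  wide <- assignments_wide(x)
  a <- x$assignments
  for (cat in x$categories) {
    sel <- a$disease_category == cat
    wide[[paste0(cat, "_source")]] <-
      a$source[sel][match(wide$campaign_id, a$campaign_id[sel])]
  }
  write.csv(wide, path, row.names = FALSE)
  if (!is.null(evidence_path)) {
    long <- a[a$present, c("campaign_id", "disease_category", "source",
                           "evidence"), drop = FALSE]
    write.csv(long, evidence_path, row.names = FALSE)
  }
  invisible(path)
}

#' Write a mention table to CSV
#'
#' @param mentions mention table from [detect_corpus()].
#' @param path output CSV (`campaign_id`, `start`, `end`, `surface`,
#'   `matched_term`, `edit_distance`).
#' @export
write_mentions <- function(mentions, path) {
  cols <- c("campaign_id", "start", "end", "surface", "matched_term",
            "edit_distance")
  write.csv(mentions[, cols], path, row.names = FALSE)
  invisible(path)
}

#' Read a reference label table
#'
#' @param path CSV with columns `campaign_id`, optionally `annotator_id`,
#'   and one 0/1 column per disease category.
#' @return data frame with the label columns coerced to integer.
#' @export
read_reference <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  if (!"campaign_id" %in% names(out))
    stop("reference CSV needs a campaign_id column")
  out$campaign_id <- as.character(out$campaign_id)
  for (cc in intersect(disease_categories(), names(out)))
    out[[cc]] <- as.integer(out[[cc]])
  miss <- setdiff(disease_categories(), names(out))
  if (length(miss))
    stop("reference CSV is missing category column(s): ",
         paste(miss, collapse = ", "))
  out
}
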