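#' Run the disease identification pipeline over a corpus
#'
#' End-to-end orchestration: (1) the NER path detects diagnosis mentions
#' ([detect_mentions()]), resolves each to its rank-1 ICD-10-CM code
#' ([resolve_mentions()]), recodes the result against the grouping lexicon
#' ([recode()]) and takes the inherited disease category; codes mapping to
#' OTHER are removed. (2) The keyword path flags categories implied by
#' treatment/procedure terms ([apply_keyword_rules()]). The two paths are
#' merged into a per-campaign present/absent call for each of the eleven
#' mutually inclusive categories, with per-category provenance
#' (`ner`, `keyword` or `both`) and the supporting codes/patterns.
#'
#' @param campaigns data frame with columns `campaign_id` (unique) and
#'   `text`.
#' @param lexicon an `icd_lexicon`.
#' @param rules a [keyword_rules()] object (`NULL` disables the keyword
#'   path).
#' @param max_edit_fraction detector spelling tolerance, see
#'   [detect_mentions()].
#' @param index optional prebuilt [build_term_index()] (rebuilt from
#'   `lexicon` when `NULL`).
#' @param verbose emit per-stage counts to stderr.
#' @return object of class `disease_assignments`: `$assignments` is the
#'   long table (campaign x category: `present`, `source`, `evidence`);
#'   `$mentions`, `$resolved` and `$recode_log` expose the intermediate
#'   stages; `$stats` holds the per-stage counts.
#' @export
identify_diseases <- function(campaigns, lexicon, rules = default_keyword_rules(),
                              max_edit_fraction = 0.3, index = NULL,
                              verbose = FALSE) {
  stopifnot(is.data.frame(campaigns), inherits(lexicon, "icd_lexicon"))
  miss <- setdiff(c("campaign_id", "text"), names(campaigns))
  if (length(miss))
    stop("campaigns table is missing column(s): ", paste(miss, collapse = ", "))
  ids <- as.character(campaigns$campaign_id)
  if (anyNA(ids) || any(!nzchar(ids))) {
    bad <- which(is.na(ids) | !nzchar(ids))
    stop("campaign row(s) without an id: row ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(ids))
    stop("duplicate campaign_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  campaigns$text <- ifelse(is.na(campaigns$text), "",
                           as.character(campaigns$text))
  cats <- disease_categories()
  if (is.null(index)) index <- build_term_index(lexicon)

  mentions <- detect_corpus(campaigns, index, max_edit_fraction)
  resolved <- resolve_mentions(mentions, lexicon, top_k = 1L)
  rlog <- if (nrow(resolved)) recode_codes(resolved$code, lexicon) else
    data.frame(input_code = character(0), matched = character(0),
               trims = integer(0), n_matches = integer(0),
               disease_category = character(0), tie = logical(0),
               stringsAsFactors = FALSE)
  n_none <- sum(rlog$matched == "none")
  if (n_none > 0)
    warning(n_none, " resolved code(s) had no prefix match in the lexicon ",
            "and were dropped")
  resolved$disease_category <- rlog$disease_category

  ner_long <- resolved[!is.na(resolved$disease_category) &
                         resolved$disease_category != "OTHER",
                       c("campaign_id", "disease_category", "code"),
                       drop = FALSE]

  kw_long <- data.frame(campaign_id = character(0),
                        disease_category = character(0),
                        pattern = character(0), stringsAsFactors = FALSE)
  if (!is.null(rules)) {
    kl <- lapply(seq_len(nrow(campaigns)), function(i) {
      k <- apply_keyword_rules(campaigns[i, ], rules)
      if (nrow(k)) cbind(campaign_id = ids[i], k, stringsAsFactors = FALSE)
      else NULL
    })
    kl <- kl[!vapply(kl, is.null, logical(1))]
    if (length(kl)) kw_long <- do.call(rbind, c(kl, list(make.row.names = FALSE)))
  }

  key <- function(id, cat) paste(id, cat, sep = "\r")
  ner_keys <- unique(key(ner_long$campaign_id, ner_long$disease_category))
  kw_keys <- unique(key(kw_long$campaign_id, kw_long$disease_category))
  ner_ev <- tapply(ner_long$code,
                   key(ner_long$campaign_id, ner_long$disease_category),
                   function(x) paste(unique(x), collapse = ";"))
  kw_ev <- tapply(kw_long$pattern,
                  key(kw_long$campaign_id, kw_long$disease_category),
                  function(x) paste(unique(x), collapse = ";"))

  grid <- expand.grid(disease_category = cats, campaign_id = ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- grid[, c("campaign_id", "disease_category")]
  gk <- key(grid$campaign_id, grid$disease_category)
  in_ner <- gk %in% ner_keys
  in_kw <- gk %in% kw_keys
  grid$present <- in_ner | in_kw
  grid$source <- ifelse(in_ner & in_kw, "both",
                        ifelse(in_ner, "ner",
                               ifelse(in_kw, "keyword", "none")))
  ev_n <- unname(ner_ev[gk]); ev_n[is.na(ev_n)] <- ""
  ev_k <- unname(kw_ev[gk]); ev_k[is.na(ev_k)] <- ""
  grid$evidence <- trimws(paste(ev_n, ev_k, sep = ";"))
  grid$evidence <- gsub("^;|;$", "", grid$evidence)
  rownames(grid) <- NULL

  stats <- list(n_campaigns = nrow(campaigns),
                n_mentions = nrow(mentions),
                n_codes = nrow(resolved),
                recode = recode_summary(rlog),
                n_other_dropped = sum(resolved$disease_category == "OTHER",
                                      na.rm = TRUE),
                n_unmatched_dropped = n_none)
  if (verbose) {
    message("campaigns: ", stats$n_campaigns,
            " | mentions: ", stats$n_mentions,
            " | codes resolved: ", stats$n_codes,
            " | recode exact/prefix/none: ", stats$recode$n_exact, "/",
            stats$recode$n_prefix, "/", stats$recode$n_none,
            " | OTHER dropped: ", stats$n_other_dropped)
  }
  structure(list(assignments = grid, mentions = mentions,
                 resolved = resolved, recode_log = rlog,
                 campaign_ids = ids, categories = cats, stats = stats),
            class = "disease_assignments")
}

#' @export
print.disease_assignments <- function(x, ...) {
  pres <- x$assignments[x$assignments$present, , drop = FALSE]
  cat("Disease assignments: ", length(x$campaign_ids), " campaigns, ",
      nrow(pres), " present campaign-category pairs\n", sep = "")
  if (nrow(pres)) {
    tab <- table(factor(pres$disease_category, levels = x$categories))
    for (nm in names(tab))
      cat(sprintf("  %-18s %5d\n", nm, tab[[nm]]))
  }
  invisible(x)
}

#' Wide 0/1 category matrix from assignments
#'
#' @param x a `disease_assignments` object.
#' @param source which provenance to count as present: `"any"` (default),
#'   `"ner"` (NER path, i.e. source ner or both) or `"keyword"`.
#' @return data frame: `campaign_id` plus one 0/1 column per category.
#' @export
assignments_wide <- function(x, source = c("any", "ner", "keyword")) {
  stopifnot(inherits(x, "disease_assignments"))
  source <- match.arg(source)
  a <- x$assignments
  pres <- switch(source,
                 any = a$present,
                 ner = a$source %in% c("ner", "both"),
                 keyword = a$source %in% c("keyword", "both"))
  out <- data.frame(campaign_id = x$campaign_ids, stringsAsFactors = FALSE)
  for (cat in x$categories) {
    sel <- a$disease_category == cat
    out[[cat]] <- as.integer(pres[sel][match(out$campaign_id,
                                             a$campaign_id[sel])])
  }
  out
}

#' Relative contribution of the NER and keyword paths per category
#'
#' For every campaign-category pair called present, tallies whether the
#' call came from the NER path only, both paths, or the keyword search
#' only, mirroring how a word search contributes beyond diagnosis NER.
#'
#' @param x a `disease_assignments` object, or a long data frame with
#'   columns `campaign_id`, `disease_category`, `source` (values `ner`,
#'   `keyword`, `both`; one row per present pair).
#' @return data frame per category: `n_total`, `n_ner_only`, `n_both`,
#'   `n_keyword_only` and the corresponding fractions (summing to 1).
#' @export
contribution_breakdown <- function(x) UseMethod("contribution_breakdown")

#' @export
contribution_breakdown.disease_assignments <- function(x) {
  a <- x$assignments[x$assignments$present, , drop = FALSE]
  contribution_breakdown(a[, c("campaign_id", "disease_category", "source")])
}

#' @export
contribution_breakdown.data.frame <- function(x) {
  need <- c("campaign_id", "disease_category", "source")
  stopifnot(all(need %in% names(x)))
  bad <- setdiff(unique(x$source), c("ner", "keyword", "both"))
  if (length(bad))
    stop("source must be ner/keyword/both; got: ", paste(bad, collapse = ", "))
  cats <- unique(x$disease_category)
  cats <- cats[order(match(cats, c(disease_categories(), "OTHER")), cats)]
  rows <- lapply(cats, function(cc) {
    s <- x$source[x$disease_category == cc]
    n <- length(s)
    data.frame(disease_category = cc, n_total = n,
               n_ner_only = sum(s == "ner"), n_both = sum(s == "both"),
               n_keyword_only = sum(s == "keyword"),
               frac_ner_only = sum(s == "ner") / n,
               frac_both = sum(s == "both") / n,
               frac_keyword_only = sum(s == "keyword") / n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Co-occurrence of NER-identified and keyword-identified categories
#'
#' Cell (r, c) is the percentage of campaigns with category `r` flagged by
#' the NER path whose text also has category `c` flagged by the keyword
#' search. Cells with a zero denominator (no campaign has `r` NER-flagged)
#' are omitted rather than reported as 0.
#'
#' @param x a `disease_assignments` object, or a long data frame with
#'   columns `campaign_id`, `disease_category`, `source` (one row per
#'   present pair).
#' @return data frame of cells: `row_category` (NER-identified),
#'   `col_category` (keyword-identified), `numerator`, `denominator`,
#'   `percentage`.
#' @export
cooccurrence_matrix <- function(x) UseMethod("cooccurrence_matrix")

#' @export
cooccurrence_matrix.disease_assignments <- function(x) {
  a <- x$assignments[x$assignments$present, , drop = FALSE]
  cooccurrence_matrix(a[, c("campaign_id", "disease_category", "source")])
}

#' @export
cooccurrence_matrix.data.frame <- function(x) {
  need <- c("campaign_id", "disease_category", "source")
  stopifnot(all(need %in% names(x)))
  cats <- unique(x$disease_category)
  cats <- cats[order(match(cats, c(disease_categories(), "OTHER")), cats)]
  ner <- x[x$source %in% c("ner", "both"), , drop = FALSE]
  kw <- x[x$source %in% c("keyword", "both"), , drop = FALSE]
  ner_by_cat <- split(ner$campaign_id, factor(ner$disease_category, cats))
  kw_by_cat <- split(kw$campaign_id, factor(kw$disease_category, cats))
  cells <- list()
  for (r in cats) {
    denom <- length(unique(ner_by_cat[[r]]))
    if (denom == 0L) next
    for (cc in cats) {
      num <- length(intersect(unique(ner_by_cat[[r]]),
                              unique(kw_by_cat[[cc]])))
      cells[[length(cells) + 1L]] <-
        data.frame(row_category = r, col_category = cc,
                   numerator = num, denominator = denom,
                   percentage = 100 * num / denom,
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(cells))
    return(data.frame(row_category = character(0),
                      col_category = character(0), numerator = integer(0),
                      denominator = integer(0), percentage = numeric(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, c(cells, list(make.row.names = FALSE)))
}
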