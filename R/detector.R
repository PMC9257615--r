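#' Normalize free text for matching
#'
#' Lowercases, replaces every run of non-alphanumeric characters with a
#' single space, and trims. All matching and similarity scoring in the
#' package happens on this normal form.
#'
#' @param x character vector.
#' @return normalized character vector.
#' @export
normalize_text <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(x)
}

#' Generic tokens excluded as standalone index terms
#'
#' Tokens too generic to stand alone as a diagnosis term (qualifiers such
#' as "unspecified", "right", "chronic", or bare "disease"). They still
#' contribute inside longer phrases ("crohn disease" is indexed; "disease"
#' alone is not).
#'
#' @return character vector of stop tokens.
#' @export
generic_terms <- function() {
  c("disease", "diseases", "disorder", "disorders", "syndrome",
    "unspecified", "specified", "other", "chronic", "acute", "severe",
    "right", "left", "bilateral", "upper", "lower", "site", "part",
    "region", "body", "person", "single", "episode", "status", "full",
    "term", "major", "minor", "stage", "end", "type", "primary",
    "secondary", "native", "essential", "related", "current",
    "complications", "complication", "uncomplicated", "intractable",
    "organism", "failure", "encounter")
}

# connective tokens a term may not start or end with
.connectives <- c("of", "the", "and", "or", "in", "on", "to", "with",
                  "without", "due", "not", "by", "for", "a", "an", "at",
                  "having")

#' Build the matchable term index from a lexicon
#'
#' Extracts the dictionary the mention detector matches against: for every
#' lexicon entry, the normalized description, any synonyms, and every
#' contiguous token subsequence of the description that (a) is at least 4
#' characters long, (b) does not start or end with a connective ("of",
#' "with", ...), (c) is not a standalone generic qualifier (see
#' [generic_terms()]), and (d) contains at least one non-generic token.
#' Each term is linked back to all source codes that produce it.
#'
#' @param lexicon a non-empty `icd_lexicon`.
#' @return object of class `term_index`.
#' @export
build_term_index <- function(lexicon) {
  stopifnot(inherits(lexicon, "icd_lexicon"))
  if (nrow(lexicon$entries) == 0L) stop("cannot index an empty lexicon")
  ent <- lexicon$entries
  stops <- generic_terms()

  term <- character(0); code <- character(0)
  for (i in seq_len(nrow(ent))) {
    full <- ent$norm_description[i]
    cand <- full
    syn <- ent$synonyms[i]
    if (nzchar(syn)) {
      syn <- normalize_text(strsplit(syn, "|", fixed = TRUE)[[1]])
      cand <- c(cand, syn[nzchar(syn)])
    }
    toks <- strsplit(full, " ", fixed = TRUE)[[1]]
    nt <- length(toks)
    if (nt > 1L) {
      for (a in seq_len(nt)) for (b in a:nt) {
        if (a == 1L && b == nt) next  # full description already added
        if (toks[a] %in% .connectives || toks[b] %in% .connectives) next
        sub <- toks[a:b]
        if (all(sub %in% c(stops, .connectives))) next
        cand <- c(cand, paste(sub, collapse = " "))
      }
    }
    cand <- unique(cand[nchar(cand) >= 4L &
                          !(cand %in% stops) & !(cand %in% .connectives)])
    term <- c(term, cand)
    code <- c(code, rep(ent$code[i], length(cand)))
  }

  codes_by_term <- split(code, term)
  terms <- names(codes_by_term)
  tdf <- data.frame(term = terms,
                    n_tokens = lengths(strsplit(terms, " ", fixed = TRUE)),
                    nchar = nchar(terms),
                    first_char = substr(terms, 1L, 1L),
                    stringsAsFactors = FALSE)
  structure(list(terms = tdf, codes = codes_by_term),
            class = "term_index")
}

#' @export
print.term_index <- function(x, ...) {
  cat("Term index: ", nrow(x$terms), " terms (",
      sum(x$terms$n_tokens == 1L), " single-token), token lengths ",
      min(x$terms$n_tokens), "-", max(x$terms$n_tokens), "\n", sep = "")
  invisible(x)
}

#' Detect diagnosis mentions in campaign text
#'
#' Spell-tolerant dictionary matching: candidate spans are token windows of
#' the text (matching is token-boundary aligned and case-insensitive), and
#' a window matches an indexed term when their optimal-string-alignment
#' edit distance is within `floor(max_edit_fraction * nchar(term))`, capped
#' at 2. Fuzzy matching is disabled for terms shorter than 6 characters
#' (exact only), which keeps short terms from generating false positives
#' while still catching two-edit misspellings like "aneruism" for
#' "aneurysm". Overlaps are resolved deterministically: earliest start
#' first, then longest span, then smallest edit distance, then
#' lexicographically smallest term.
#'
#' @param campaign a list or one-row data frame with `campaign_id` and
#'   `text` (or a bare string, in which case `campaign_id` is `NA`).
#' @param index a [build_term_index()] result.
#' @param max_edit_fraction allowed edits per term character, in
#'   `[0, 0.4]`; 0 reduces to exact dictionary matching.
#' @return data frame with columns `campaign_id`, `start`, `end` (0-based,
#'   half-open character offsets), `surface`, `matched_term`,
#'   `edit_distance`. Mentions never overlap and
#'   `substr(text, start + 1, end) == surface`.
#' @export
detect_mentions <- function(campaign, index, max_edit_fraction = 0.3) {
  stopifnot(inherits(index, "term_index"))
  if (is.character(campaign) && length(campaign) == 1L)
    campaign <- list(campaign_id = NA_character_, text = campaign)
  if (!(max_edit_fraction >= 0 && max_edit_fraction <= 0.4))
    stop("max_edit_fraction must be in [0, 0.4]")
  text <- as.character(campaign$text)
  id <- as.character(campaign$campaign_id)
  empty <- data.frame(campaign_id = character(0), start = integer(0),
                      end = integer(0), surface = character(0),
                      matched_term = character(0),
                      edit_distance = integer(0),
                      stringsAsFactors = FALSE)
  if (length(text) != 1L || is.na(text) || !nzchar(text)) return(empty)

  m <- gregexpr("[A-Za-z0-9]+", text)[[1]]
  if (m[1] == -1L) return(empty)
  tok_start <- as.integer(m)                      # 1-based
  tok_len <- attr(m, "match.length")
  toks <- tolower(substring(text, tok_start, tok_start + tok_len - 1L))
  ntok <- length(toks)

  tdf <- index$terms
  cand <- list()
  for (L in sort(unique(tdf$n_tokens))) {
    if (L > ntok) next
    tL <- tdf[tdf$n_tokens == L, , drop = FALSE]
    nw <- ntok - L + 1L
    idxs <- seq_len(nw)
    spans <- if (L == 1L) toks[idxs] else
      vapply(idxs, function(i) paste(toks[i:(i + L - 1L)], collapse = " "), "")
    s1 <- tok_start[idxs]                                   # 1-based start
    e1 <- tok_start[idxs + L - 1L] + tok_len[idxs + L - 1L] - 1L
    span_nchar <- nchar(spans)
    span_first <- substr(spans, 1L, 1L)

    # exact hits
    hit <- match(spans, tL$term)
    ex <- which(!is.na(hit))
    for (w in ex) {
      cand[[length(cand) + 1L]] <-
        list(start = s1[w], end = e1[w], term = tL$term[hit[w]],
             dist = 0L)
    }

    # fuzzy hits: cap per term, terms >= 6 chars, blocked on first char
    if (max_edit_fraction > 0) {
      caps <- pmin(2L, as.integer(floor(max_edit_fraction * tL$nchar)))
      fz <- which(tL$nchar >= 6L & caps >= 1L)
      if (length(fz)) {
        for (w in seq_len(nw)) {
          if (w %in% ex) next
          ok <- fz[tL$first_char[fz] == span_first[w] &
                     abs(tL$nchar[fz] - span_nchar[w]) <= caps[fz]]
          if (!length(ok)) next
          d <- osa_distance_cpp(rep(spans[w], length(ok)), tL$term[ok],
                                caps[ok])
          good <- which(d <= caps[ok])
          for (g in good) {
            cand[[length(cand) + 1L]] <-
              list(start = s1[w], end = e1[w], term = tL$term[ok[g]],
                   dist = d[g])
          }
        }
      }
    }
  }
  if (!length(cand)) return(empty)

  cd <- data.frame(start = vapply(cand, `[[`, 1L, "start"),
                   end = vapply(cand, `[[`, 1L, "end"),
                   term = vapply(cand, `[[`, "", "term"),
                   dist = vapply(cand, `[[`, 1L, "dist"),
                   stringsAsFactors = FALSE)
  cd <- cd[order(cd$start, -(cd$end - cd$start), cd$dist, cd$term,
                 method = "radix"), , drop = FALSE]
  last_end <- 0L
  keep <- logical(nrow(cd))
  for (i in seq_len(nrow(cd))) {
    if (cd$start[i] > last_end) {
      keep[i] <- TRUE
      last_end <- cd$end[i]
    }
  }
  cd <- cd[keep, , drop = FALSE]
  data.frame(campaign_id = rep(id, nrow(cd)),
             start = cd$start - 1L,                         # 0-based
             end = cd$end,                                  # half-open
             surface = substring(text, cd$start, cd$end),
             matched_term = cd$term,
             edit_distance = cd$dist,
             stringsAsFactors = FALSE)
}

#' Detect mentions across a corpus
#'
#' @param campaigns data frame with columns `campaign_id`, `text`.
#' @inheritParams detect_mentions
#' @return row-bound mention table (see [detect_mentions()]).
#' @export
detect_corpus <- function(campaigns, index, max_edit_fraction = 0.3) {
  stopifnot(is.data.frame(campaigns),
            all(c("campaign_id", "text") %in% names(campaigns)))
  out <- lapply(seq_len(nrow(campaigns)), function(i)
    detect_mentions(campaigns[i, ], index, max_edit_fraction))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
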