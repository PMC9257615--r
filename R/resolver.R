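#' Character-trigram cosine similarity
#'
#' Both strings are normalized (see [normalize_text()]) and decomposed into
#' overlapping character trigrams (a string shorter than 3 characters
#' contributes itself as a single gram). The score is the cosine of the two
#' trigram count vectors: symmetric, in `[0, 1]`, and exactly 1 iff the
#' normalized strings are identical. Trigram profiles degrade gracefully
#' under misspellings, which is what makes the resolver robust to lay text.
#'
#' @param a,b single strings, non-empty after normalization.
#' @return similarity in `[0, 1]`.
#' @examples
#' trigram_similarity("brain aneruism", "brain aneurysm")
#' @export
trigram_similarity <- function(a, b) {
  a <- normalize_text(a); b <- normalize_text(b)
  if (!nzchar(a) || !nzchar(b))
    stop("strings must be non-empty after normalization")
  ta <- table(trigrams_of(a))
  tb <- table(trigrams_of(b))
  shared <- intersect(names(ta), names(tb))
  if (!length(shared)) return(0)
  num <- sum(as.numeric(ta[shared]) * as.numeric(tb[shared]))
  num / sqrt(sum(as.numeric(ta)^2) * sum(as.numeric(tb)^2))
}

trigrams_of <- function(x) {
  n <- nchar(x)
  if (n < 3L) return(x)
  substring(x, 1:(n - 2L), 3:n)
}

# Precompute the entry-term trigram matrix for a lexicon: each entry is
# represented by its normalized description plus synonyms; an entry's score
# against a surface is the max over its terms.
resolver_terms <- function(lexicon) {
  ent <- lexicon$entries
  term <- character(0); entry <- integer(0)
  for (i in seq_len(nrow(ent))) {
    tt <- ent$norm_description[i]
    if (nzchar(ent$synonyms[i])) {
      syn <- normalize_text(strsplit(ent$synonyms[i], "|", fixed = TRUE)[[1]])
      tt <- c(tt, syn[nzchar(syn)])
    }
    tt <- unique(tt)
    term <- c(term, tt)
    entry <- c(entry, rep(i, length(tt)))
  }
  list(term = term, entry = entry)
}

trigram_count_matrix <- function(strings, vocab) {
  M <- matrix(0, nrow = length(strings), ncol = length(vocab))
  for (i in seq_along(strings)) {
    idx <- match(trigrams_of(strings[i]), vocab)
    M[i, ] <- tabulate(idx, nbins = length(vocab))
  }
  M / sqrt(pmax(rowSums(M^2), .Machine$double.eps))
}

#' Resolve diagnosis mentions to ICD-10-CM codes
#'
#' The entity-resolution stage: each mention surface is scored against every
#' lexicon entry by [trigram_similarity()] (an entry scores as the best of
#' its description and synonyms) and the `top_k` highest-scoring codes are
#' returned. Ties are broken deterministically by shorter code, then
#' lexicographically smaller code, so the output is invariant to lexicon
#' row order. Rank 1 is the code that flows into categorization.
#'
#' @param mentions mention table from [detect_mentions()] /
#'   [detect_corpus()] (only `surface` is required; other columns are
#'   carried through).
#' @param lexicon a non-empty `icd_lexicon`.
#' @param top_k number of ranked codes per mention.
#' @return data frame: the mention columns plus `code`, `score`, `rank`.
#' @export
resolve_mentions <- function(mentions, lexicon, top_k = 1L) {
  stopifnot(inherits(lexicon, "icd_lexicon"), top_k >= 1L)
  if (nrow(lexicon$entries) == 0L) stop("cannot resolve against an empty lexicon")
  if (!is.data.frame(mentions) || !"surface" %in% names(mentions))
    stop("mentions must be a data frame with a 'surface' column")
  if (nrow(mentions) == 0L) {
    out <- mentions
    out$code <- character(0); out$score <- numeric(0); out$rank <- integer(0)
    return(out)
  }
  ent <- lexicon$entries
  rt <- resolver_terms(lexicon)
  surf_norm <- normalize_text(mentions$surface)
  if (any(!nzchar(surf_norm)))
    stop("mention surface empty after normalization")
  usurf <- unique(surf_norm)

  vocab <- unique(c(unlist(lapply(rt$term, trigrams_of)),
                    unlist(lapply(usurf, trigrams_of))))
  Mt <- trigram_count_matrix(rt$term, vocab)
  Ms <- trigram_count_matrix(usurf, vocab)
  S <- Ms %*% t(Mt)                       # surfaces x terms

  top_k <- min(as.integer(top_k), nrow(ent))
  picks <- vector("list", length(usurf))
  code_len <- nchar(ent$code)
  for (i in seq_along(usurf)) {
    esc <- vapply(split(S[i, ], rt$entry), max, 0)   # per-entry max score
    escore <- as.numeric(esc)[order(as.integer(names(esc)))]
    ord <- order(-escore, code_len, ent$code, method = "radix")[seq_len(top_k)]
    picks[[i]] <- data.frame(code = ent$code[ord],
                             score = escore[ord],
                             rank = seq_len(top_k),
                             stringsAsFactors = FALSE)
  }
  rows <- rep(seq_len(nrow(mentions)), each = top_k)
  hit <- match(surf_norm, usurf)
  res <- do.call(rbind, picks[hit[seq_len(nrow(mentions))]])
  out <- cbind(mentions[rows, , drop = FALSE], res)
  rownames(out) <- NULL
  out
}

#' Resolve a single surface string
#'
#' Convenience wrapper around [resolve_mentions()] for one piece of text.
#'
#' @param surface text of a detected mention.
#' @inheritParams resolve_mentions
#' @return data frame with `code`, `score`, `rank`.
#' @export
resolve_surface <- function(surface, lexicon, top_k = 1L) {
  resolve_mentions(data.frame(surface = surface, stringsAsFactors = FALSE),
                   lexicon, top_k)
}
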