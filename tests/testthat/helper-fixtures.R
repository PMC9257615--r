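# Shared fixtures and independent reference implementations (oracles).

demo_lex <- local({
  lex <- NULL
  function() {
    if (is.null(lex))
      lex <<- load_lexicon(system.file("extdata", "demo_lexicon.csv",
                                       package = "crowddx"))
    lex
  }
})

# Independent optimal-string-alignment distance: plain O(nm) dynamic
# program, no banding or early abandoning.
r_osa <- function(a, b) {
  a <- strsplit(a, "", fixed = TRUE)[[1]]
  b <- strsplit(b, "", fixed = TRUE)[[1]]
  la <- length(a); lb <- length(b)
  d <- matrix(0L, la + 1L, lb + 1L)
  d[, 1L] <- 0:la; d[1L, ] <- 0:lb
  for (i in seq_len(la)) for (j in seq_len(lb)) {
    cost <- if (a[i] == b[j]) 0L else 1L
    d[i + 1L, j + 1L] <- min(d[i, j + 1L] + 1L, d[i + 1L, j] + 1L,
                             d[i, j] + cost)
    if (i > 1L && j > 1L && a[i] == b[j - 1L] && a[i - 1L] == b[j])
      d[i + 1L, j + 1L] <- min(d[i + 1L, j + 1L], d[i - 1L, j - 1L] + 1L)
  }
  d[la + 1L, lb + 1L]
}

# Independent trigram-cosine similarity built from first principles.
r_trigram_cosine <- function(a, b) {
  grams <- function(x) {
    n <- nchar(x)
    if (n < 3) return(x)
    vapply(1:(n - 2), function(i) substr(x, i, i + 2), "")
  }
  ga <- grams(a); gb <- grams(b)
  vocab <- union(ga, gb)
  va <- vapply(vocab, function(g) sum(ga == g), 0)
  vb <- vapply(vocab, function(g) sum(gb == g), 0)
  if (sum(va * vb) == 0) return(0)
  sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
}

# Brute-force recoder: walk prefixes of the code from longest to shortest,
# scan the entire entry table with startsWith, take the modal category
# with the fixed priority tie-break.
r_recode <- function(code, lexicon) {
  ent <- lexicon$entries
  if (code %in% ent$code) {
    return(list(matched = "exact", trims = 0L,
                disease_category = ent$disease_category[ent$code == code],
                tie = FALSE))
  }
  for (k in 0:(nchar(code) - 1L)) {
    prefix <- substr(code, 1L, nchar(code) - k)
    hits <- ent$disease_category[startsWith(ent$code, prefix)]
    if (length(hits)) {
      tab <- table(hits)
      winners <- names(tab)[tab == max(tab)]
      prio <- c(disease_categories(), "OTHER")
      return(list(matched = "prefix", trims = k,
                  disease_category = winners[which.min(match(winners, prio))],
                  tie = length(winners) > 1L))
    }
  }
  list(matched = "none", trims = nchar(code) - 1L,
       disease_category = NA_character_, tie = FALSE)
}

# Brute-force exact phrase scan: every token window of the text checked
# for normalized equality against the indexed terms, then the documented
# overlap resolution (earliest start, longest span, smallest term).
r_exact_scan <- function(text, index) {
  m <- gregexpr("[A-Za-z0-9]+", text)[[1]]
  if (m[1] == -1L)
    return(data.frame(start = integer(0), end = integer(0),
                      matched_term = character(0)))
  st <- as.integer(m); len <- attr(m, "match.length")
  toks <- tolower(substring(text, st, st + len - 1L))
  terms <- index$terms$term
  cand <- list()
  for (i in seq_along(toks)) for (j in i:length(toks)) {
    span <- paste(toks[i:j], collapse = " ")
    if (span %in% terms)
      cand[[length(cand) + 1L]] <- data.frame(
        start = st[i] - 1L, end = st[j] + len[j] - 1L,
        matched_term = span, stringsAsFactors = FALSE)
  }
  if (!length(cand))
    return(data.frame(start = integer(0), end = integer(0),
                      matched_term = character(0)))
  cd <- do.call(rbind, cand)
  cd <- cd[order(cd$start, -(cd$end - cd$start), cd$matched_term,
                 method = "radix"), , drop = FALSE]
  last_end <- -1L
  keep <- logical(nrow(cd))
  for (i in seq_len(nrow(cd))) {
    if (cd$start[i] >= last_end) { keep[i] <- TRUE; last_end <- cd$end[i] }
  }
  cd[keep, , drop = FALSE]
}

random_codes <- function(n, max_len = 7L) {
  vapply(seq_len(n), function(i) {
    len <- sample(3:max_len, 1L)
    extra <- if (len > 3L)
      paste(sample(c(LETTERS, 0:9), len - 3L, replace = TRUE),
            collapse = "") else ""
    paste0(sample(LETTERS, 1L), sprintf("%02d", sample(0:99, 1L)), extra)
  }, "")
}

# small in-code lexicon helper
mini_lexicon <- function(df, ...) icd_lexicon(df, ...)

withr_local_csv <- function(content) {
  path <- tempfile(fileext = ".csv")
  writeLines(content, path)
  path
}
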