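test_that("term index covers descriptions, synonyms and sub-phrases", {
  lex <- demo_lex()
  idx <- build_term_index(lex)
  terms <- idx$terms$term
  # full normalized descriptions are always indexed
  expect_true(all(lex$entries$norm_description %in% terms))
  # synonyms are indexed and linked to their source code
  expect_true("breast cancer" %in% terms)
  expect_true("C50911" %in% idx$codes[["breast cancer"]])
  # exhaustive enumeration: every non-generic contiguous token sequence of
  # a description (>= 4 chars, not framed by connectives) is indexed
  stops <- generic_terms()
  conn <- crowddx:::.connectives
  for (desc in lex$entries$norm_description) {
    toks <- strsplit(desc, " ", fixed = TRUE)[[1]]
    for (a in seq_along(toks)) for (b in a:length(toks)) {
      sub <- toks[a:b]
      phrase <- paste(sub, collapse = " ")
      if (nchar(phrase) < 4) next
      if (sub[1] %in% conn || sub[length(sub)] %in% conn) next
      if (all(sub %in% c(stops, conn))) next
      expect_true(phrase %in% terms, label = paste("indexed:", phrase))
    }
  }
  # generic qualifiers never stand alone
  expect_false(any(c("unspecified", "disease", "right") %in% terms))
  # empty lexicon cannot be indexed
  empty <- icd_lexicon(data.frame(code = character(0),
                                  description = character(0),
                                  ccsr_category = character(0)))
  expect_error(build_term_index(empty), "empty")
})

test_that("a shared description links one term to both codes", {
  lex <- mini_lexicon(data.frame(
    code = c("C50911", "C50912"),
    description = c("breast carcinoma", "breast carcinoma"),
    ccsr_category = "Breast cancer"))
  idx <- build_term_index(lex)
  expect_setequal(idx$codes[["breast carcinoma"]], c("C50911", "C50912"))
})

test_that("misspelled diagnoses are detected with their edit distance", {
  idx <- build_term_index(demo_lex())
  m <- detect_mentions(list(campaign_id = "x",
                            text = "He suffered a brain aneruism last week."),
                       idx, 0.3)
  expect_equal(nrow(m), 1L)
  expect_equal(m$matched_term, "brain aneurysm")
  expect_equal(m$edit_distance, 2L)
  expect_equal(m$surface, "brain aneruism")

  m2 <- detect_mentions(list(campaign_id = "y",
                             text = "diagnosed with myeloid lukemia"),
                        idx, 0.3)
  expect_true(any(grepl("leukemia", m2$matched_term)))

  expect_equal(nrow(detect_mentions(list(campaign_id = "z", text = ""),
                                    idx, 0.3)), 0L)
})

test_that("offsets round-trip and mentions never overlap", {
  lex <- demo_lex()
  idx <- build_term_index(lex)
  corp <- generate_corpus(corpus_config(n_campaigns = 40, seed = 5,
                                        misspelling_rate = 1), lex)
  for (i in seq_len(nrow(corp$campaigns))) {
    text <- corp$campaigns$text[i]
    m <- detect_mentions(corp$campaigns[i, ], idx, 0.3)
    if (!nrow(m)) next
    expect_identical(substring(text, m$start + 1L, m$end), m$surface)
    expect_true(all(m$start >= 0 & m$start < m$end & m$end <= nchar(text)))
    m <- m[order(m$start), ]
    if (nrow(m) > 1L)
      expect_true(all(m$start[-1] >= m$end[-nrow(m)]))
  }
})

test_that("zero edit tolerance equals a brute-force exact phrase scan", {
  lex <- demo_lex()
  idx <- build_term_index(lex)
  corp <- generate_corpus(corpus_config(n_campaigns = 100, seed = 13,
                                        misspelling_rate = 0.8), lex)
  for (i in seq_len(nrow(corp$campaigns))) {
    got <- detect_mentions(corp$campaigns[i, ], idx, 0)
    want <- r_exact_scan(corp$campaigns$text[i], idx)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$matched_term, want$matched_term)
    expect_true(all(got$edit_distance == 0L))
  }
})

test_that("raising the edit tolerance never loses detection coverage", {
  # With longest-match overlap resolution, a higher tolerance may replace
  # two exact fragments by one longer fuzzy span that subsumes them, so
  # span identity is not preserved -- but every span detected at a lower
  # tolerance must remain covered by a (same or wider) span at a higher
  # one, and exact matches never degrade to worse edit distances.
  lex <- demo_lex()
  idx <- build_term_index(lex)
  corp <- generate_corpus(corpus_config(n_campaigns = 60, seed = 21,
                                        misspelling_rate = 1), lex)
  covered <- function(lo, hi) {
    if (!nrow(lo)) return(TRUE)
    all(vapply(seq_len(nrow(lo)), function(i)
      any(hi$start <= lo$start[i] & hi$end >= lo$end[i]), logical(1)))
  }
  for (i in seq_len(nrow(corp$campaigns))) {
    m0 <- detect_mentions(corp$campaigns[i, ], idx, 0)
    m1 <- detect_mentions(corp$campaigns[i, ], idx, 0.15)
    m2 <- detect_mentions(corp$campaigns[i, ], idx, 0.3)
    expect_true(covered(m0, m1))
    expect_true(covered(m1, m2))
    expect_gte(nrow(m1), 0)  # never errors across tolerance levels
  }
})

test_that("max_edit_fraction is validated", {
  idx <- build_term_index(demo_lex())
  expect_error(detect_mentions(list(campaign_id = "a", text = "x"), idx, 0.5),
               "max_edit_fraction")
})
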