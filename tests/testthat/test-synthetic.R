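test_that("the generator is deterministic under a fixed seed", {
  lex <- demo_lex()
  cfg <- corpus_config(n_campaigns = 30, seed = 123)
  c1 <- generate_corpus(cfg, lex)
  c2 <- generate_corpus(cfg, lex)
  expect_identical(c1$campaigns, c2$campaigns)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$planted, c2$planted)
  c3 <- generate_corpus(corpus_config(n_campaigns = 30, seed = 124), lex)
  expect_false(identical(c1$campaigns$text, c3$campaigns$text))
})

test_that("noise-free mode plants verbatim lexicon phrases", {
  lex <- demo_lex()
  corp <- generate_corpus(corpus_config(n_campaigns = 50, seed = 31,
                                        misspelling_rate = 0,
                                        keyword_only_prob = 0), lex)
  legit <- c(lex$entries$description,
             unlist(strsplit(lex$entries$synonyms[
               nzchar(lex$entries$synonyms)], "|", fixed = TRUE)))
  expect_true(all(corp$planted$surface %in% legit))
  expect_true(all(corp$planted$mechanism == "diagnosis"))
  # the text contains every planted surface form
  for (i in seq_len(nrow(corp$planted))) {
    tx <- corp$campaigns$text[corp$campaigns$campaign_id ==
                                corp$planted$campaign_id[i]]
    expect_true(grepl(corp$planted$surface[i], tx, fixed = TRUE))
  }
  # every true label has at least one planted item
  for (i in seq_len(nrow(corp$truth))) {
    pos <- disease_categories()[corp$truth[i, disease_categories()] == 1]
    planted_cats <- corp$planted$disease_category[
      corp$planted$campaign_id == corp$truth$campaign_id[i]]
    expect_setequal(pos, unique(planted_cats))
  }
})

test_that("corrupt_term stays within the requested edit budget", {
  lex <- demo_lex()
  set.seed(41)
  terms <- sample(lex$entries$description, 1000, replace = TRUE)
  for (tt in terms) {
    k <- sample(1:2, 1)
    out <- corrupt_term(tt, k)
    expect_lte(r_osa(tt, out), k)
    expect_equal(substr(out, 1, 1), substr(tt, 1, 1))  # first char kept
  }
  expect_identical(corrupt_term("pneumonia", 0), "pneumonia")
  expect_warning(out <- corrupt_term("flu", 2), "too short")
  expect_identical(out, "flu")
  expect_error(corrupt_term("pneumonia", 3))
})

test_that("truth prevalence tracks the configured rates", {
  lex <- demo_lex()
  prev <- setNames(rep(0.1, 11), disease_categories())
  corp <- generate_corpus(corpus_config(n_campaigns = 2000,
                                        prevalence = prev,
                                        cooccurrence_boost = 1,
                                        seed = 55), lex)
  se <- sqrt(0.1 * 0.9 / 2000)
  for (cc in disease_categories()) {
    rate <- mean(corp$truth[[cc]])
    expect_lt(abs(rate - 0.1), 3 * se)
  }
})

test_that("an all-zero prevalence yields an all-negative corpus with warning", {
  lex <- demo_lex()
  prev <- setNames(rep(0, 11), disease_categories())
  expect_warning(
    corp <- generate_corpus(corpus_config(n_campaigns = 10,
                                          prevalence = prev, seed = 1), lex),
    "all-negative")
  expect_true(all(corp$truth[, disease_categories()] == 0))
  expect_equal(nrow(corp$planted), 0L)
})

test_that("noise-free corpora are recovered perfectly end to end", {
  lex <- demo_lex()
  corp <- generate_corpus(corpus_config(n_campaigns = 150, seed = 61,
                                        misspelling_rate = 0,
                                        keyword_only_prob = 0), lex)
  a <- identify_diseases(corp$campaigns, lex)
  ev <- evaluate_assignments(a, corp$truth)
  expect_true(all(ev$precision[!is.na(ev$precision)] == 1))
  expect_true(all(ev$recall[ev$n_reference_positive > 0] == 1))
})

test_that("keyword-only planted categories come back with keyword provenance", {
  # a lexicon whose terms share no token with the dialysis keyword
  lex <- mini_lexicon(data.frame(
    code = c("C189", "I509"),
    description = c("Malignant neoplasm of colon", "Cardiac decompensation"),
    ccsr_category = c("Colorectal cancer", "Heart failure")))
  rules <- keyword_rules(data.frame(pattern = "dialysis",
                                    disease_category = "genitourinary"))
  prev <- setNames(c(rep(0, 3), 1, rep(0, 7)), disease_categories())
  corp <- generate_corpus(corpus_config(n_campaigns = 25, prevalence = prev,
                                        keyword_only_prob = 1, seed = 71),
                          lex, rules)
  expect_true(all(corp$planted$mechanism == "keyword"))
  a <- identify_diseases(corp$campaigns, lex, rules = rules)
  gu <- a$assignments[a$assignments$disease_category == "genitourinary", ]
  expect_true(all(gu$present))
  expect_true(all(gu$source == "keyword"))
})
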