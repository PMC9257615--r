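make_labels <- function(ids, p, seed) {
  set.seed(seed)
  out <- data.frame(campaign_id = ids, stringsAsFactors = FALSE)
  for (cc in disease_categories())
    out[[cc]] <- rbinom(length(ids), 1, p)
  out
}

test_that("confusion counts match a brute-force per-item tally", {
  ids <- sprintf("c%03d", 1:400)
  ref <- make_labels(ids, 0.2, 501)
  pred <- ref
  # plant error rates: flip some labels
  set.seed(502)
  for (cc in disease_categories()) {
    flip <- runif(400) < 0.1
    pred[[cc]] <- ifelse(flip, 1L - pred[[cc]], pred[[cc]])
  }
  pred <- pred[sample(400), ]                # order must not matter
  for (cc in disease_categories()) {
    got <- confusion_counts(pred, ref, cc)
    p <- pred[[cc]][match(ids, pred$campaign_id)]
    r <- ref[[cc]]
    expect_equal(unname(got),
                 c(sum(p & r), sum(p & !r), sum(!p & r), sum(!p & !r)))
    expect_equal(sum(got), 400L)
  }
  # perfect predictions: no false calls
  g <- confusion_counts(ref, ref, "neoplasms")
  expect_equal(unname(g[c("fp", "fn")]), c(0L, 0L))
  # all-negative on both sides
  zero <- ref; for (cc in disease_categories()) zero[[cc]] <- 0L
  g0 <- confusion_counts(zero, zero, "neoplasms")
  expect_equal(unname(g0), c(0L, 0L, 0L, 400L))
  # id mismatch is an error listing the offenders
  expect_error(confusion_counts(pred[-1, ], ref, "neoplasms"),
               "id mismatch")
})

test_that("metric rows reproduce the published genitourinary row", {
  # counts implied by the published row: 35 reference positives, recall
  # 0.80, precision 28/29, accuracy 0.98 on 400 campaigns
  row <- metrics_row(c(tp = 28, fp = 1, fn = 7, tn = 364), total = 400,
                     category = "genitourinary")
  expect_equal(row$n_reference_positive, 35)
  expect_equal(round(row$precision, 2), 0.97)
  expect_equal(round(row$precision_low, 2), 0.90)
  expect_equal(round(row$precision_high, 2), 1.03)   # unclipped Wald
  expect_equal(row$recall, 0.8)
  expect_equal(round(row$recall_low, 2), 0.67)
  expect_equal(round(row$recall_high, 2), 0.93)
  expect_equal(row$accuracy, 0.98)
  expect_equal(round(row$accuracy_low, 2), 0.97)
  expect_equal(round(row$accuracy_high, 2), 0.99)
})

test_that("F1 from published neoplasms precision and recall", {
  expect_equal(round(f1_score(0.95, 0.98), 2), 0.96)
  expect_equal(f1_score(0, 0), 0)
  expect_true(is.na(f1_score(NA, 0.5)))
})

test_that("Wald intervals match the closed form and shrink as 1/sqrt(n)", {
  set.seed(91)
  for (i in 1:50) {
    n <- sample(5:500, 1)
    p <- runif(1)
    ci <- wald_ci(p, n)
    hw <- 1.96 * sqrt(p * (1 - p) / n)
    expect_equal(unname(ci), c(p - hw, p + hw), tolerance = 1e-12)
    wide <- diff(wald_ci(p, n)); narrow <- diff(wald_ci(p, 2 * n))
    if (p > 0 && p < 1)
      expect_equal(unname(wide / narrow), sqrt(2), tolerance = 1e-9)
  }
  # zero-variance case: recall 1.0 has a degenerate interval
  expect_equal(unname(wald_ci(1, 35)), c(1, 1))
  # undefined precision is flagged, not 0
  row <- metrics_row(c(tp = 0, fp = 0, fn = 5, tn = 395), 400)
  expect_true(is.na(row$precision))
  expect_true(is.na(row$precision_low))
  expect_error(metrics_row(c(tp = 1, fp = 1, fn = 1, tn = 1), 400),
               "inconsistent")
})

test_that("count-weighted averages reproduce the published summary", {
  rows <- data.frame(
    disease_category = disease_categories(),
    n_reference_positive = c(82, 19, 18, 35, 30, 53, 20, 45, 162, 66, 29),
    precision = c(0.92, 0.75, 0.56, 0.97, 0.56, 0.69, 0.48, 0.64, 0.95,
                  0.88, 0.92),
    recall = c(0.74, 0.63, 0.56, 0.80, 0.77, 0.92, 0.70, 0.51, 0.98, 0.42,
               0.76),
    f1 = c(0.82, 0.69, 0.56, 0.88, 0.65, 0.79, 0.57, 0.57, 0.96, 0.57,
           0.83),
    accuracy = c(0.94, 0.97, 0.96, 0.98, 0.94, 0.94, 0.95, 0.91, 0.97,
                 0.90, 0.98))
  w <- weighted_metrics(rows)
  expect_equal(round(unname(w), 2), c(0.83, 0.77, 0.78, 0.95))
  # ranges bracket the weighted averages
  expect_true(w[["precision"]] >= min(rows$precision) &&
                w[["precision"]] <= max(rows$precision))
  # constant metric: weighted average equals it for any weights
  rows$precision <- 0.6
  expect_equal(unname(weighted_metrics(rows)[["precision"]]), 0.6)
  # direct arithmetic oracle on random rows
  set.seed(92)
  r5 <- data.frame(n_reference_positive = sample(1:50, 5),
                   precision = runif(5), recall = runif(5), f1 = runif(5),
                   accuracy = runif(5))
  w5 <- weighted_metrics(r5)
  expect_equal(unname(w5[["recall"]]),
               sum(r5$n_reference_positive * r5$recall) /
                 sum(r5$n_reference_positive), tolerance = 1e-12)
  r5$n_reference_positive <- 0
  expect_error(weighted_metrics(r5), "all weights are zero")
})

test_that("Cohen's kappa: perfect, chance-level, and hand-computed cases", {
  a <- c(TRUE, FALSE, TRUE, TRUE, FALSE)
  expect_equal(cohen_kappa(a, a)$kappa, 1)
  # independent raters at 50/50 drift to zero agreement beyond chance
  set.seed(93)
  x <- runif(20000) < 0.5; y <- runif(20000) < 0.5
  expect_lt(abs(cohen_kappa(x, y)$kappa), 0.05)
  # 2x2 table a=40 b=10 c=5 d=45: p_o = .85, p_e = .5, kappa = .7
  ra <- rep(c(TRUE, TRUE, FALSE, FALSE), c(40, 10, 5, 45))
  rb <- rep(c(TRUE, FALSE, TRUE, FALSE), c(40, 10, 5, 45))
  k <- cohen_kappa(ra, rb)
  expect_equal(k$p_o, 0.85)
  expect_equal(k$p_e, 0.5)
  expect_equal(k$kappa, 0.7)
  # symmetric in raters; invariant to swapping the label convention
  expect_equal(cohen_kappa(rb, ra)$kappa, k$kappa)
  expect_equal(cohen_kappa(!ra, !rb)$kappa, k$kappa)
  # degenerate identical constant raters: undefined
  expect_true(is.na(cohen_kappa(rep(TRUE, 5), rep(TRUE, 5))$kappa))
})

test_that("per-category agreement and discrepancy listing", {
  ids <- sprintf("c%03d", 1:100)
  la <- make_labels(ids, 0.3, 94)
  lb <- la
  set.seed(95)
  lb$neoplasms <- ifelse(runif(100) < 0.1, 1L - lb$neoplasms, lb$neoplasms)
  ag <- agreement_by_category(la, lb)
  expect_equal(nrow(ag), 11L)
  expect_true(all(ag$kappa[ag$disease_category != "neoplasms"] == 1))
  expect_lt(ag$kappa[ag$disease_category == "neoplasms"], 1)
  d <- annotator_discrepancies(la, lb)
  expect_true(all(d$disease_category == "neoplasms"))
  expect_equal(nrow(d), sum(la$neoplasms != lb$neoplasms))
  expect_error(agreement_by_category(la, lb[-1, ]), "different campaigns")
})

test_that("F1 lies between precision and recall; evaluation table agrees", {
  set.seed(96)
  for (i in 1:30) {
    p <- runif(1); r <- runif(1)
    f <- f1_score(p, r)
    expect_gte(f + 1e-12, min(p, r))
    expect_lte(f - 1e-12, max(p, r))
  }
  ids <- sprintf("c%03d", 1:60)
  ref <- make_labels(ids, 0.3, 97)
  pred <- make_labels(ids, 0.3, 98)
  ev <- evaluate_assignments(pred, ref)
  expect_equal(nrow(ev), 11L)
  for (i in seq_len(nrow(ev))) {
    cc <- ev$disease_category[i]
    expect_equal(unname(confusion_counts(pred, ref, cc)[c("tp", "fp", "fn", "tn")]),
                 c(ev$tp[i], ev$fp[i], ev$fn[i], ev$tn[i]))
  }
  w <- attr(ev, "weighted")
  expect_equal(unname(w[["precision"]]),
               sum(ev$n_reference_positive * ev$precision) /
                 sum(ev$n_reference_positive))
})
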