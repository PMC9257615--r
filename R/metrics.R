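#' Per-category binary confusion counts
#'
#' Compares the algorithm's present/absent call for one disease category
#' against the reference labels over the same campaigns.
#'
#' @param predicted,reference wide tables (`campaign_id` plus one 0/1
#'   column per category); `predicted` may also be a
#'   `disease_assignments` object.
#' @param category the disease category column to compare.
#' @return named integer vector `c(tp, fp, fn, tn)`.
#' @export
confusion_counts <- function(predicted, reference, category) {
  if (inherits(predicted, "disease_assignments"))
    predicted <- assignments_wide(predicted)
  stopifnot(is.data.frame(predicted), is.data.frame(reference),
            "campaign_id" %in% names(predicted),
            "campaign_id" %in% names(reference))
  if (!category %in% names(predicted) || !category %in% names(reference))
    stop("category column not found: ", category)
  pid <- as.character(predicted$campaign_id)
  rid <- as.character(reference$campaign_id)
  only_p <- setdiff(pid, rid); only_r <- setdiff(rid, pid)
  if (length(only_p) || length(only_r))
    stop("campaign id mismatch; missing from reference: ",
         paste(head(only_p, 10), collapse = ", "),
         "; missing from predictions: ",
         paste(head(only_r, 10), collapse = ", "))
  p <- as.logical(predicted[[category]])[match(rid, pid)]
  r <- as.logical(reference[[category]])
  c(tp = sum(p & r), fp = sum(p & !r), fn = sum(!p & r), tn = sum(!p & !r))
}

#' 95% Wald confidence interval for a proportion
#'
#' The normal-approximation interval `p +/- 1.96 sqrt(p (1 - p) / n)`,
#' deliberately not clipped to `[0, 1]` (so a precision of 0.97 on n = 29
#' reports an upper bound of 1.03, and a proportion of 1 has a
#' zero-width interval).
#'
#' @param p proportion.
#' @param n the number of trials the proportion is based on.
#' @return numeric `c(low, high)` (`NA` when `n` is 0).
#' @export
wald_ci <- function(p, n) {
  if (is.na(p) || n <= 0) return(c(low = NA_real_, high = NA_real_))
  hw <- 1.96 * sqrt(p * (1 - p) / n)
  c(low = p - hw, high = p + hw)
}

#' F1 score from precision and recall
#'
#' @param precision,recall proportions.
#' @return `2 P R / (P + R)` (`NA` if either input is `NA`; 0 when both
#'   are 0).
#' @export
f1_score <- function(precision, recall) {
  if (is.na(precision) || is.na(recall)) return(NA_real_)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' One evaluation row for a disease category
#'
#' Computes precision, recall, F1 and accuracy with 95% Wald intervals
#' from confusion counts. Each interval uses the sample size its
#' proportion is actually based on: predicted positives for precision,
#' reference positives for recall, and all evaluated campaigns for
#' accuracy. A category with no predicted positives has undefined
#' precision (`NA`), not 0.
#'
#' @param counts named vector with `tp`, `fp`, `fn`, `tn` (from
#'   [confusion_counts()]).
#' @param total number of evaluated campaigns; must equal
#'   `tp + fp + fn + tn`.
#' @param category optional category label carried into the row.
#' @return one-row data frame with columns `disease_category`,
#'   `n_reference_positive`, `tp`, `fp`, `fn`, `tn`, `precision`,
#'   `precision_low`, `precision_high`, `recall`, `recall_low`,
#'   `recall_high`, `f1`, `accuracy`, `accuracy_low`, `accuracy_high`.
#' @export
metrics_row <- function(counts, total = sum(counts),
                        category = NA_character_) {
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  fn <- counts[["fn"]]; tn <- counts[["tn"]]
  if (tp + fp + fn + tn != total)
    stop("counts are inconsistent with total (", tp + fp + fn + tn,
         " vs ", total, ")")
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  accuracy <- (tp + tn) / total
  pci <- wald_ci(precision, tp + fp)
  rci <- wald_ci(recall, tp + fn)
  aci <- wald_ci(accuracy, total)
  data.frame(disease_category = category, n_reference_positive = tp + fn,
             tp = tp, fp = fp, fn = fn, tn = tn,
             precision = precision, precision_low = pci[["low"]],
             precision_high = pci[["high"]],
             recall = recall, recall_low = rci[["low"]],
             recall_high = rci[["high"]],
             f1 = f1_score(precision, recall),
             accuracy = accuracy, accuracy_low = aci[["low"]],
             accuracy_high = aci[["high"]],
             stringsAsFactors = FALSE)
}

#' Evaluate assignments against a reference label set
#'
#' Builds the full per-category evaluation table (one [metrics_row()] per
#' disease category) and attaches the count-weighted averages as the
#' `"weighted"` attribute.
#'
#' @param predicted a `disease_assignments` object or wide 0/1 table.
#' @param reference wide 0/1 reference table over the same campaigns.
#' @param categories category columns to evaluate.
#' @return data frame of per-category metric rows, with
#'   `attr(, "weighted")` holding the weighted summary (see
#'   [weighted_metrics()]).
#' @export
evaluate_assignments <- function(predicted, reference,
                                 categories = disease_categories()) {
  if (inherits(predicted, "disease_assignments"))
    predicted <- assignments_wide(predicted)
  rows <- lapply(categories, function(cc)
    metrics_row(confusion_counts(predicted, reference, cc),
                total = nrow(reference), category = cc))
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "weighted") <- weighted_metrics(out)
  out
}

#' Count-weighted average of per-category metrics
#'
#' Averages precision, recall, F1 and accuracy across categories, each
#' category weighted by how many reference campaigns mention it
#' (`n_reference_positive`).
#'
#' @param rows per-category metric table (needs `precision`, `recall`,
#'   `f1`, `accuracy` and, unless `weights` is given,
#'   `n_reference_positive`).
#' @param weights optional non-negative weights, one per row.
#' @return named numeric vector `precision`, `recall`, `f1`, `accuracy`.
#' @export
weighted_metrics <- function(rows, weights = NULL) {
  stopifnot(is.data.frame(rows), nrow(rows) >= 1L)
  if (is.null(weights)) weights <- rows$n_reference_positive
  if (length(weights) != nrow(rows))
    stop("need one weight per row")
  if (all(weights == 0)) stop("all weights are zero")
  c(precision = weighted.mean(rows$precision, weights),
    recall = weighted.mean(rows$recall, weights),
    f1 = weighted.mean(rows$f1, weights),
    accuracy = weighted.mean(rows$accuracy, weights))
}

#' Cohen's kappa for two raters' binary labels
#'
#' Chance-corrected agreement: `kappa = (p_o - p_e) / (1 - p_e)` with
#' observed agreement `p_o` and chance agreement `p_e` from the product of
#' the raters' marginal rates. Symmetric in the raters and invariant to
#' swapping the positive/negative convention. When `p_e = 1` (both raters
#' constant and identical) kappa is undefined and returned as `NA`.
#'
#' @param rater_a,rater_b logical/0-1 vectors over the same items.
#' @return list with `p_o`, `p_e`, `kappa`.
#' @export
cohen_kappa <- function(rater_a, rater_b) {
  a <- as.logical(rater_a); b <- as.logical(rater_b)
  if (length(a) != length(b)) stop("raters labeled different numbers of items")
  if (anyNA(a) || anyNA(b)) stop("labels contain NA")
  n <- length(a)
  if (n == 0L) stop("no items")
  p_o <- mean(a == b)
  pa <- mean(a); pb <- mean(b)
  p_e <- pa * pb + (1 - pa) * (1 - pb)
  kappa <- if (p_e < 1) (p_o - p_e) / (1 - p_e) else NA_real_
  list(p_o = p_o, p_e = p_e, kappa = kappa)
}

#' Per-category inter-rater agreement
#'
#' Computes [cohen_kappa()] for each category column shared by two
#' annotators' label tables (e.g. the two independent reviewers whose
#' consensus forms the reference set).
#'
#' @param labels_a,labels_b wide 0/1 tables (`campaign_id` + category
#'   columns) for the two annotators, over the same campaigns.
#' @param categories category columns to compare.
#' @return data frame: `disease_category`, `p_o`, `p_e`, `kappa`.
#' @export
agreement_by_category <- function(labels_a, labels_b,
                                  categories = disease_categories()) {
  stopifnot(is.data.frame(labels_a), is.data.frame(labels_b))
  ids_a <- as.character(labels_a$campaign_id)
  ids_b <- as.character(labels_b$campaign_id)
  if (!setequal(ids_a, ids_b)) stop("annotators labeled different campaigns")
  labels_b <- labels_b[match(ids_a, ids_b), , drop = FALSE]
  rows <- lapply(categories, function(cc) {
    k <- cohen_kappa(labels_a[[cc]], labels_b[[cc]])
    data.frame(disease_category = cc, p_o = k$p_o, p_e = k$p_e,
               kappa = k$kappa, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' List label discrepancies between two annotators
#'
#' The reconciliation report: every campaign-category pair on which the
#' two annotators disagree, for adjudication.
#'
#' @inheritParams agreement_by_category
#' @return data frame: `campaign_id`, `disease_category`, `label_a`,
#'   `label_b`.
#' @export
annotator_discrepancies <- function(labels_a, labels_b,
                                    categories = disease_categories()) {
  ids_a <- as.character(labels_a$campaign_id)
  ids_b <- as.character(labels_b$campaign_id)
  if (!setequal(ids_a, ids_b)) stop("annotators labeled different campaigns")
  labels_b <- labels_b[match(ids_a, ids_b), , drop = FALSE]
  out <- list()
  for (cc in categories) {
    dif <- which(as.logical(labels_a[[cc]]) != as.logical(labels_b[[cc]]))
    if (length(dif))
      out[[cc]] <- data.frame(campaign_id = ids_a[dif],
                              disease_category = cc,
                              label_a = as.integer(labels_a[[cc]][dif]),
                              label_b = as.integer(labels_b[[cc]][dif]),
                              stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(campaign_id = character(0),
                      disease_category = character(0),
                      label_a = integer(0), label_b = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
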