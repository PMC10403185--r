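#' Scored cohort container
#'
#' One model's per-lesion malignancy scores: `score` is P2, the softmax
#' probability of malignancy.
#'
#' @param case_id Unique lesion identifiers.
#' @param label `"benign"` / `"malignant"` truth.
#' @param score Numeric scores in \[0,1\].
#' @return A `ScoredCohort` data.frame.
#' @export
scored_cohort <- function(case_id, label, score) {
  stopifnot(length(case_id) == length(label),
            length(label) == length(score),
            all(label %in% c("benign", "malignant")),
            all(is.finite(score)))
  if (anyDuplicated(case_id)) stop("case_ids must be unique")
  if (any(score < 0 | score > 1)) stop("scores must lie in [0, 1]")
  structure(data.frame(case_id = case_id, label = label, score = score,
                       stringsAsFactors = FALSE),
            class = c("ScoredCohort", "data.frame"))
}

.as_scored <- function(x) {
  if (inherits(x, "ScoredCohort")) return(x)
  if (is.data.frame(x) && all(c("case_id", "label") %in% names(x))) {
    sc <- if ("score" %in% names(x)) x$score else x$P2
    return(scored_cohort(x$case_id, x$label, sc))
  }
  stop("expected a ScoredCohort or a data.frame with case_id/label/P2")
}

#' Threshold-based classification metrics
#'
#' Predicts malignant when `P2 >= threshold` (the tie rule `P1 <= P2 ->
#' malignant` at the default 0.5) and derives sensitivity, specificity,
#' PPV, NPV, accuracy, precision and recall from the confusion counts.
#' Sensitivity equals recall and PPV equals precision by definition; both
#' pairs are reported. A Youden-optimal operating point is included for
#' reference.
#'
#' @param scored A `ScoredCohort` (or data.frame with `case_id`, `label`,
#'   `P2`).
#' @param threshold Decision cutoff on P2 (default 0.5).
#' @return An `EvaluationReport` list: confusion counts, metric set, AUC
#'   with discrimination band, threshold, Youden point.
#' @export
confusion_metrics <- function(scored, threshold = 0.5) {
  sc <- .as_scored(scored)
  truth <- sc$label == "malignant"
  if (length(unique(truth)) < 2)
    stop("single-class cohort: both classes must be present")
  pred <- sc$score >= threshold
  tp <- sum(pred & truth); fp <- sum(pred & !truth)
  tn <- sum(!pred & !truth); fn <- sum(!pred & truth)
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  roc <- roc_auc(sc)
  structure(list(
    counts = c(TP = tp, FP = fp, TN = tn, FN = fn),
    threshold = threshold,
    metrics = c(AUC = roc$auc,
                sensitivity = safe(tp, tp + fn),
                specificity = safe(tn, tn + fp),
                PPV = safe(tp, tp + fp),
                NPV = safe(tn, tn + fn),
                accuracy = (tp + tn) / length(truth),
                precision = safe(tp, tp + fp),
                recall = safe(tp, tp + fn)),
    discrimination = roc$discrimination,
    youden = roc$youden),
    class = "EvaluationReport")
}

#' @export
print.EvaluationReport <- function(x, ...) {
  cat("<EvaluationReport>\n")
  cat(sprintf("  counts: TP=%d FP=%d TN=%d FN=%d (threshold %.2f)\n",
              x$counts["TP"], x$counts["FP"], x$counts["TN"], x$counts["FN"],
              x$threshold))
  m <- x$metrics
  cat(sprintf("  AUC %.3f (%s)  acc %.3f  sens %.3f  spec %.3f  PPV %.3f  NPV %.3f\n",
              m["AUC"], x$discrimination, m["accuracy"], m["sensitivity"],
              m["specificity"], m["PPV"], m["NPV"]))
  invisible(x)
}

# tie-corrected Mann-Whitney AUC from ranks
.auc_rank <- function(score, truth) {
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve and AUC
#'
#' AUC by the rank (Mann-Whitney) formulation counting ties as one half;
#' the curve is a sweep over all observed thresholds. Discrimination bands
#' follow the usual reading: AUC < 0.6 poor, 0.6-0.75 a certain degree of
#' discrimination, > 0.75 good.
#'
#' @inheritParams confusion_metrics
#' @return List with `auc`, `curve` (`data.frame`: threshold, fpr, tpr),
#'   `discrimination`, `youden` (threshold maximizing tpr - fpr).
#' @export
roc_auc <- function(scored) {
  sc <- .as_scored(scored)
  truth <- sc$label == "malignant"
  if (length(unique(truth)) < 2)
    stop("single-class cohort: both classes must be present")
  auc <- .auc_rank(sc$score, truth)
  thr <- c(Inf, sort(unique(sc$score), decreasing = TRUE))
  n1 <- sum(truth); n0 <- sum(!truth)
  tpr <- vapply(thr, function(t) sum(sc$score >= t & truth) / n1, 0)
  fpr <- vapply(thr, function(t) sum(sc$score >= t & !truth) / n0, 0)
  j <- which.max(tpr - fpr)
  band <- if (auc < 0.6) "poor" else if (auc <= 0.75)
    "certain degree of discrimination" else "good"
  list(auc = auc,
       curve = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
       discrimination = band,
       youden = list(threshold = thr[j], tpr = tpr[j], fpr = fpr[j],
                     J = tpr[j] - fpr[j]))
}

# placement values: for each positive, the fraction of negatives it beats
# (ties count one half), and vice versa
.placements <- function(score, truth) {
  x <- score[truth]; y <- score[!truth]
  v10 <- vapply(x, function(xi) mean((xi > y) + 0.5 * (xi == y)), 0)
  v01 <- vapply(y, function(yj) mean((x > yj) + 0.5 * (x == yj)), 0)
  list(v10 = v10, v01 = v01)
}

#' DeLong test for two correlated (paired) ROC curves
#'
#' Fast DeLong covariance via placement values: the variance of each AUC
#' and the covariance between the two models' AUCs are estimated from the
#' empirical placement vectors of the shared subjects; the AUC difference
#' is referred to a two-sided standard normal. Identical score vectors (or
#' otherwise zero variance of the difference) are flagged degenerate with
#' p = 1.
#'
#' @param scored_a,scored_b `ScoredCohort`s over the same lesions.
#' @return A `DeLongComparison` list: `auc_a`, `auc_b`, `var_diff`, `z`,
#'   `p_value`, `degenerate`.
#' @export
delong_test <- function(scored_a, scored_b) {
  a <- .as_scored(scored_a); b <- .as_scored(scored_b)
  if (nrow(a) != nrow(b)) stop("unpaired cohorts: different sizes")
  b <- b[match(a$case_id, b$case_id), ]
  if (any(is.na(b$case_id))) stop("unpaired cohorts: case_ids differ")
  if (!identical(a$label, b$label)) stop("labels disagree between cohorts")
  truth <- a$label == "malignant"
  if (length(unique(truth)) < 2) stop("single-class cohort")
  m <- sum(truth); n <- sum(!truth)
  pa <- .placements(a$score, truth)
  pb <- .placements(b$score, truth)
  auc_a <- mean(pa$v10); auc_b <- mean(pb$v10)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  S <- s10 / m + s01 / n
  var_diff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  degenerate <- !is.finite(var_diff) || var_diff <= .Machine$double.eps
  if (degenerate) {
    z <- 0; p <- 1
  } else {
    z <- (auc_a - auc_b) / sqrt(var_diff)
    p <- 2 * pnorm(-abs(z))
  }
  structure(list(auc_a = auc_a, auc_b = auc_b, var_diff = var_diff,
                 z = z, p_value = p, degenerate = degenerate),
            class = "DeLongComparison")
}

#' @export
print.DeLongComparison <- function(x, ...) {
  cat(sprintf("<DeLong: AUC %.3f vs %.3f  z=%.3f  p=%.4g%s>\n",
              x$auc_a, x$auc_b, x$z, x$p_value,
              if (x$degenerate) "  [degenerate]" else ""))
  invisible(x)
}

#' Per-class score histogram
#'
#' Counts scores in equal-width bins over \[0,1\], split by true class;
#' counts sum to the cohort size.
#'
#' @inheritParams confusion_metrics
#' @param bins Number of equal-width bins (default 10).
#' @return List with `breaks` and `counts` (matrix bins x 2: benign,
#'   malignant).
#' @export
score_histogram <- function(scored, bins = 10L) {
  sc <- .as_scored(scored)
  breaks <- seq(0, 1, length.out = bins + 1L)
  bin_of <- function(s) pmin(pmax(findInterval(s, breaks,
                                               rightmost.closed = TRUE), 1L),
                             bins)
  counts <- matrix(0L, bins, 2,
                   dimnames = list(NULL, c("benign", "malignant")))
  for (cl in c("benign", "malignant")) {
    tab <- tabulate(bin_of(sc$score[sc$label == cl]), nbins = bins)
    counts[, cl] <- tab
  }
  list(breaks = breaks, counts = counts)
}
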