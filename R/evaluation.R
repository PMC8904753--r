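check_scores_labels <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  keep <- !is.na(scores)
  list(scores = scores[keep], labels = labels[keep])
}

#' Point-biserial correlation between an index and case status
#'
#' Pearson correlation of a quantitative score with a 0/1 label, with the
#' two-sided p-value from the t-distribution on n - 2 degrees of freedom.
#'
#' @param scores Numeric score per sample (NA scores dropped).
#' @param labels 0/1 case status per sample.
#' @return list(r, p, n).
#' @export
pearson_with_label <- function(scores, labels) {
  d <- check_scores_labels(scores, labels)
  if (length(d$scores) < 3) stop("need at least 3 scored samples")
  if (length(unique(d$labels)) < 2) stop("both labels must be present")
  if (stats::sd(d$scores) == 0) stop("scores have zero variance")
  ct <- stats::cor.test(d$scores, d$labels, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(d$scores))
}

#' Pooled two-sample t-test of an index between cases and controls
#'
#' Two-sided Student (equal-variance) t-test, oriented cases minus controls.
#'
#' @inheritParams pearson_with_label
#' @return list(t, p, df, mean_case, mean_control).
#' @export
two_sample_test <- function(scores, labels) {
  d <- check_scores_labels(scores, labels)
  x <- d$scores[d$labels == 1]; y <- d$scores[d$labels == 0]
  if (length(x) < 2 || length(y) < 2) stop("each class needs >= 2 scored samples")
  tt <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_case = mean(x), mean_control = mean(y))
}

#' ROC curve and AUC of an index against case status
#'
#' AUC by the Mann-Whitney formulation: the probability that a random case
#' scores above a random control, ties counting one half. The empirical
#' (FPR, TPR) curve is returned for plotting.
#'
#' @inheritParams pearson_with_label
#' @return list(auc, curve = data.frame(fpr, tpr)).
#' @export
roc_auc <- function(scores, labels) {
  d <- check_scores_labels(scores, labels)
  if (length(unique(d$labels)) < 2) stop("both labels must be present")
  n1 <- sum(d$labels == 1); n0 <- sum(d$labels == 0)
  r <- rank(d$scores)                      # midranks handle ties -> 1/2
  auc <- (sum(r[d$labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(d$scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(d$scores[d$labels == 1] >= t), 0.0)
  fpr <- vapply(thr, function(t) mean(d$scores[d$labels == 0] >= t), 0.0)
  list(auc = auc,
       curve = data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1)))
}

#' Odds ratio of case status across a score dichotomization
#'
#' \code{median_split} dichotomizes the cohort at its median score (ties at
#' the median fall in the low group); \code{q4_vs_q1} keeps only the top and
#' bottom empirical quartiles (boundaries at the 25th/75th percentiles,
#' boundary ties to the lower bin) and contrasts them. The OR is ad/bc with a
#' Woolf (log-normal) 95% CI; any zero cell triggers the Haldane-Anscombe
#' 0.5 correction, flagged in the result.
#'
#' @inheritParams pearson_with_label
#' @param mode \code{"median_split"} or \code{"q4_vs_q1"}.
#' @return list(or, ci_low, ci_high, table, corrected).
#' @export
odds_ratio <- function(scores, labels, mode = c("median_split", "q4_vs_q1")) {
  mode <- match.arg(mode)
  d <- check_scores_labels(scores, labels)
  if (mode == "median_split") {
    high <- d$scores > stats::median(d$scores)
    lab <- d$labels
  } else {
    q <- stats::quantile(d$scores, c(0.25, 0.5, 0.75), type = 7)
    bin <- findInterval(d$scores, q, left.open = TRUE) + 1L
    keep <- bin %in% c(1L, 4L)
    high <- bin[keep] == 4L
    lab <- d$labels[keep]
  }
  if (all(high) || !any(high)) stop("all samples fall on one side of the cut")
  a <- sum(high & lab == 1); b <- sum(high & lab == 0)
  cc <- sum(!high & lab == 1); dd <- sum(!high & lab == 0)
  if (a + b == 0 || cc + dd == 0 || a + cc == 0 || b + dd == 0)
    stop("2x2 table has an empty margin")
  corrected <- any(c(a, b, cc, dd) == 0)
  if (corrected) { a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; dd <- dd + 0.5 }
  or <- (a * dd) / (b * cc)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / dd)
  list(or = or,
       ci_low = exp(log(or) - 1.96 * se),
       ci_high = exp(log(or) + 1.96 * se),
       table = matrix(c(a, cc, b, dd), 2, 2,
                      dimnames = list(c("high", "low"), c("case", "control"))),
       corrected = corrected)
}

#' Full cohort-level evaluation report for an index
#'
#' Bundles the point-biserial correlation, the pooled two-sample t-test, the
#' ROC AUC (with a seeded bootstrap percentile CI), both odds-ratio modes and
#' a per-SD logistic odds ratio into one report.
#'
#' @inheritParams pearson_with_label
#' @param n_boot Bootstrap resamples for the AUC CI (default 2000).
#' @param seed Seed for the bootstrap.
#' @return list of class \code{mdi_evaluation}.
#' @export
evaluate_index <- function(scores, labels, n_boot = 2000, seed = 1) {
  d <- check_scores_labels(scores, labels)
  pe <- pearson_with_label(d$scores, d$labels)
  tt <- two_sample_test(d$scores, d$labels)
  ro <- roc_auc(d$scores, d$labels)
  set.seed(seed)
  boot <- vapply(seq_len(n_boot), function(i) {
    idx <- sample(length(d$scores), replace = TRUE)
    if (length(unique(d$labels[idx])) < 2) return(NA_real_)
    roc_auc(d$scores[idx], d$labels[idx])$auc
  }, 0.0)
  auc_ci <- stats::quantile(boot, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  or_med <- odds_ratio(d$scores, d$labels, "median_split")
  or_q <- tryCatch(odds_ratio(d$scores, d$labels, "q4_vs_q1"),
                   error = function(e) NULL)
  fit <- suppressWarnings(
    stats::glm(d$labels ~ scale(d$scores), family = stats::binomial()))
  out <- list(
    pearson_r = pe$r, pearson_p = pe$p,
    t_statistic = tt$t, t_p = tt$p,
    auc = ro$auc, auc_ci = auc_ci, roc_curve = ro$curve,
    or_median_split = or_med[c("or", "ci_low", "ci_high", "corrected")],
    or_q4_vs_q1 = if (is.null(or_q)) NULL else
      or_q[c("or", "ci_low", "ci_high", "corrected")],
    or_per_sd = unname(exp(stats::coef(fit)[2])),
    n_cases = sum(d$labels == 1), n_controls = sum(d$labels == 0))
  class(out) <- "mdi_evaluation"
  out
}

#' @export
print.mdi_evaluation <- function(x, ...) {
  cat("Index evaluation (", x$n_cases, "cases /", x$n_controls, "controls )\n")
  cat(sprintf("  point-biserial r = %.3f (p = %.3g)\n", x$pearson_r, x$pearson_p))
  cat(sprintf("  two-sample t = %.3f (p = %.3g)\n", x$t_statistic, x$t_p))
  cat(sprintf("  AUC = %.3f [%.3f, %.3f]\n", x$auc, x$auc_ci[1], x$auc_ci[2]))
  cat(sprintf("  OR (median split) = %.2f [%.2f, %.2f]\n",
              x$or_median_split$or, x$or_median_split$ci_low,
              x$or_median_split$ci_high))
  if (!is.null(x$or_q4_vs_q1))
    cat(sprintf("  OR (Q4 vs Q1)     = %.2f [%.2f, %.2f]\n",
                x$or_q4_vs_q1$or, x$or_q4_vs_q1$ci_low, x$or_q4_vs_q1$ci_high))
  cat(sprintf("  OR per SD (logistic) = %.2f\n", x$or_per_sd))
  invisible(x)
}
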