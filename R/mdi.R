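#' mDI: methylation-derived depression index for one sample
#'
#' The index contrasts a sample's SIMPO scores over the "positive" gene set
#' against those over the "negative" set with a Welch-style t-statistic,
#' offset by 1 so that an index of exactly 1 means no contrast:
#' \deqn{mDI = 1 + \frac{\bar x - \bar y}{\sqrt{S_x^2/n + S_y^2/m}}}
#' with \eqn{\bar x, S_x^2, n} the mean, unbiased variance and count of the
#' positive-set values and \eqn{\bar y, S_y^2, m} those of the negative set.
#'
#' @param pos_values SIMPO scores of the positive-set genes in one sample.
#' @param neg_values SIMPO scores of the negative-set genes.
#' @return The mDI value, or \code{NA_real_} if either side has fewer than
#'   two valid values or the denominator is zero.
#' @examples
#' mdi_score(c(2, 3, 4), c(1, 1.5, 0.5))  # ~ 4.098
#' @export
mdi_score <- function(pos_values, neg_values) {
  x <- pos_values[!is.na(pos_values)]
  y <- neg_values[!is.na(neg_values)]
  n <- length(x); m <- length(y)
  if (n < 2 || m < 2) return(NA_real_)
  den <- sqrt(stats::var(x) / n + stats::var(y) / m)
  if (den == 0) return(NA_real_)
  1 + (mean(x) - mean(y)) / den
}

#' Score a cohort with a frozen mDI model
#'
#' Computes the per-sample mDI from a SIMPO matrix using the model's frozen
#' positive and negative gene sets. Genes absent from the cohort are dropped
#' with a warning naming them; if either set falls below two genes the cohort
#' cannot be scored and an error names the offending set. Only valid
#' (non-NA) SIMPO cells enter each sample's index; per-sample counts of the
#' genes actually used are returned alongside the score, and samples with an
#' undefined index are flagged as \code{NA} rather than silently scored.
#'
#' @param simpo Genes x samples SIMPO matrix of the cohort to score.
#' @param model An \code{mdi_model}, or any list with elements
#'   \code{positive_genes} and \code{negative_genes}.
#' @return data.frame with columns \code{sample_id}, \code{mdi},
#'   \code{n_positive_used}, \code{n_negative_used}.
#' @export
score_cohort <- function(simpo, model) {
  pos <- intersect(model$positive_genes, rownames(simpo))
  neg <- intersect(model$negative_genes, rownames(simpo))
  miss <- c(setdiff(model$positive_genes, pos), setdiff(model$negative_genes, neg))
  if (length(miss))
    warning("genes absent from cohort dropped: ", paste(miss, collapse = ", "))
  if (length(pos) < 2) stop("positive gene set reduced below 2 genes")
  if (length(neg) < 2) stop("negative gene set reduced below 2 genes")
  P <- simpo[pos, , drop = FALSE]
  N <- simpo[neg, , drop = FALSE]
  scores <- vapply(seq_len(ncol(simpo)),
                   function(j) mdi_score(P[, j], N[, j]), 0.0)
  data.frame(sample_id = colnames(simpo), mdi = scores,
             n_positive_used = colSums(!is.na(P)),
             n_negative_used = colSums(!is.na(N)),
             row.names = NULL, stringsAsFactors = FALSE)
}

# mDI score for every k in [k_min, k_max] at once, via cumulative sums over
# the selection-ranked genes, split by mean-t sign. Rows of the returned
# matrix are k values, columns samples. NA where a side has < 2 valid genes
# or the Welch denominator is zero.
k_score_matrix <- function(selection, simpo, k_min, k_max) {
  ranked <- selection$gene[order(selection$rank)][seq_len(k_max)]
  if (!all(ranked %in% rownames(simpo)))
    stop("ranked genes missing from SIMPO matrix")
  sgn <- selection$mean_t[order(selection$rank)][seq_len(k_max)] >= 0
  X <- simpo[ranked, , drop = FALSE]
  V <- !is.na(X)
  X0 <- ifelse(V, X, 0)
  cs <- function(M, rows) apply(M * rows, 2, cumsum)
  sum_p <- cs(X0, sgn);  sum_n <- cs(X0, !sgn)
  ssq_p <- cs(X0^2, sgn); ssq_n <- cs(X0^2, !sgn)
  cnt_p <- cs(V * 1, sgn); cnt_n <- cs(V * 1, !sgn)
  ks <- k_min:k_max
  np <- cnt_p[ks, , drop = FALSE]; nn <- cnt_n[ks, , drop = FALSE]
  mp <- sum_p[ks, , drop = FALSE] / np
  mn <- sum_n[ks, , drop = FALSE] / nn
  vp <- (ssq_p[ks, , drop = FALSE] - np * mp^2) / (np - 1)
  vn <- (ssq_n[ks, , drop = FALSE] - nn * mn^2) / (nn - 1)
  vp[vp < 0] <- 0; vn[vn < 0] <- 0   # guard tiny negative round-off
  den <- sqrt(vp / np + vn / nn)
  out <- 1 + (mp - mn) / den
  out[np < 2 | nn < 2 | den == 0] <- NA_real_
  rownames(out) <- ks
  out
}

# Pearson r of each row of a scores-by-k matrix with a 0/1 label vector.
curve_correlations <- function(Sk, labels) {
  suppressWarnings(as.vector(stats::cor(t(Sk), labels,
                                        use = "pairwise.complete.obs")))
}

#' Sweep the gene count K and fix the mDI model
#'
#' For every k in \code{[k_min, k_max]} (step 1) the top-k genes of the
#' selection are partitioned by sign, the cohort is scored, and the Pearson
#' correlation (point-biserial) between the index and the 0/1 label is
#' computed. The model is fixed at the k with the maximal signed correlation
#' (ties broken towards the smallest k); the full curve is returned for
#' plotting, where a plateau can be inspected by eye.
#'
#' @param selection A \code{simpo_selection}.
#' @param simpo Genes x samples SIMPO matrix of the training cohort.
#' @param labels 0/1 vector aligned with columns of \code{simpo}.
#' @param k_min,k_max Inclusive sweep bounds (defaults 10 and 500).
#' @return An object of class \code{mdi_model}: positive/negative gene sets,
#'   chosen \code{k}, \code{training_correlation}, the per-k \code{curve}
#'   (data.frame k, r) and selection provenance.
#' @export
sweep_k <- function(selection, simpo, labels, k_min = 10, k_max = 500) {
  if (k_max > nrow(selection)) stop("k_max exceeds the number of ranked genes")
  if (k_min < 1 || k_min > k_max) stop("invalid k range")
  Sk <- k_score_matrix(selection, simpo, k_min, k_max)
  r <- curve_correlations(Sk, labels)
  ks <- k_min:k_max
  if (all(is.na(r))) stop("index undefined at every k in the sweep")
  best <- ks[which.max(r)]   # which.max skips NA, first max = smallest k
  sets <- partition_signs(selection, best)
  model <- list(
    positive_genes = sets$positive,
    negative_genes = sets$negative,
    k = best,
    training_correlation = r[ks == best],
    curve = data.frame(k = ks, r = r),
    provenance = list(n_iter = attr(selection, "n_iter"),
                      fraction = attr(selection, "fraction"),
                      top_n = attr(selection, "top_n"),
                      seed = attr(selection, "seed")))
  class(model) <- "mdi_model"
  model
}

#' Fit a methylation-derived depression index
#'
#' End-to-end fit on a training cohort: resampling gene selection
#' ([resample_select()]) followed by the K-sweep ([sweep_k()]). The result is
#' a frozen index that can be applied to new cohorts with [predict.mdi_model()]
#' without any re-selection.
#'
#' @param simpo Genes x samples SIMPO matrix of the training cohort.
#' @param labels 0/1 case status aligned with the columns of \code{simpo}.
#' @param n_iter,fraction,top_n Resampling parameters, see [resample_select()].
#' @param k_min,k_max Sweep bounds, see [sweep_k()].
#' @param seed Integer seed making the whole fit reproducible.
#' @return An \code{mdi_model} (with the selection attached as
#'   \code{$selection}).
#' @export
mdi_fit <- function(simpo, labels, n_iter = 300, fraction = 0.9, top_n = 50,
                    k_min = 10, k_max = 500, seed = 1) {
  k_max <- min(k_max, nrow(simpo))
  sel <- resample_select(simpo, labels, n_iter = n_iter, fraction = fraction,
                         top_n = top_n, seed = seed)
  model <- sweep_k(sel, simpo, labels, k_min = k_min, k_max = k_max)
  model$selection <- sel
  model
}

#' @export
print.mdi_model <- function(x, ...) {
  cat("Methylation-derived depression index (mDI) model\n")
  cat("  k =", x$k, "genes:", length(x$positive_genes), "positive,",
      length(x$negative_genes), "negative\n")
  cat("  training point-biserial r =", format(x$training_correlation, digits = 3), "\n")
  p <- x$provenance
  cat("  selection:", p$n_iter, "iterations x", format(100 * p$fraction),
      "% subsamples, top", p$top_n, "(seed", paste0(p$seed, ")"), "\n")
  invisible(x)
}

#' @export
summary.mdi_model <- function(object, ...) {
  print(object)
  cat("  sweep: k in [", min(object$curve$k), ",", max(object$curve$k),
      "], max r =", format(max(object$curve$r, na.rm = TRUE), digits = 3), "\n")
  invisible(object)
}

#' @export
coef.mdi_model <- function(object, ...) {
  data.frame(gene = c(object$positive_genes, object$negative_genes),
             sign = rep(c(1, -1), c(length(object$positive_genes),
                                    length(object$negative_genes))),
             stringsAsFactors = FALSE)
}

#' Score a new cohort with a fitted mDI model
#'
#' @param object An \code{mdi_model}.
#' @param simpo Genes x samples SIMPO matrix of the cohort to score.
#' @param ... Unused.
#' @return data.frame as from [score_cohort()].
#' @export
predict.mdi_model <- function(object, simpo, ...) {
  score_cohort(simpo, object)
}

#' Plot the K-sweep correlation curve of a fitted index
#'
#' @param x An \code{mdi_model}.
#' @param ... Passed to [plot()].
#' @export
plot.mdi_model <- function(x, ...) {
  plot(x$curve$k, x$curve$r, type = "l", xlab = "number of genes K",
       ylab = "point-biserial r with case status", ...)
  graphics::abline(v = x$k, lty = 2)
  invisible(x)
}

#' Permutation null for the sweep-maximum correlation
#'
#' Recomputes the per-k correlation curve of a frozen gene ranking on a
#' cohort, then builds a null distribution for the curve maximum by
#' shuffling the cohort's labels. Because the gene ranking is frozen (taken
#' from a training cohort), the observed maximum on an independent cohort is
#' exchangeable with the permuted maxima under the null of no association.
#'
#' @param selection A \code{simpo_selection} (frozen ranking).
#' @param simpo SIMPO matrix of the cohort being evaluated.
#' @param labels 0/1 labels of that cohort.
#' @param k_min,k_max Sweep bounds.
#' @param n_perm Number of label permutations (default 200).
#' @param seed Integer seed for the permutations.
#' @return list(observed_max, perm_max = numeric vector, p = permutation
#'   p-value of the observed maximum).
#' @export
sweep_permutation_null <- function(selection, simpo, labels, k_min = 10,
                                   k_max = 500, n_perm = 200, seed = 1) {
  Sk <- k_score_matrix(selection, simpo, k_min, k_max)
  obs <- max(curve_correlations(Sk, labels), na.rm = TRUE)
  set.seed(seed)
  perm <- vapply(seq_len(n_perm), function(i)
    max(curve_correlations(Sk, sample(labels)), na.rm = TRUE), 0.0)
  list(observed_max = obs, perm_max = perm,
       p = (1 + sum(perm >= obs)) / (1 + n_perm))
}

#' Serialize / restore an mDI model as JSON
#'
#' The JSON carries the positive/negative gene arrays, the chosen k, the
#' training correlation and the selection provenance — everything needed to
#' apply the frozen index to a new cohort.
#'
#' @param model An \code{mdi_model}.
#' @param path Output path.
#' @export
write_mdi_model <- function(model, path) {
  obj <- list(positive_genes = model$positive_genes,
              negative_genes = model$negative_genes,
              k = model$k,
              training_correlation = model$training_correlation,
              provenance = model$provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mdi_model
#' @export
read_mdi_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- list(positive_genes = as.character(obj$positive_genes),
                negative_genes = as.character(obj$negative_genes),
                k = as.integer(obj$k),
                training_correlation = obj$training_correlation,
                curve = NULL,
                provenance = obj$provenance)
  class(model) <- "mdi_model"
  model
}
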