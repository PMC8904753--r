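#' Stratified subsample of sample indices
#'
#' Draws \code{floor(fraction * n)} distinct sample indices without
#' replacement, stratified by case/control label so that both classes keep
#' approximately their marginal proportion. Uses the current RNG stream
#' unless \code{seed} is given.
#'
#' @param labels Integer 0/1 vector of case status, one per sample.
#' @param fraction Fraction of samples to keep, in (0, 1].
#' @param seed Optional integer seed for reproducibility.
#' @return Sorted integer vector of retained sample indices.
#' @export
subsample_indices <- function(labels, fraction, seed = NULL) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  n <- length(labels)
  target <- floor(fraction * n)
  strata <- split(seq_len(n), labels)
  sizes <- vapply(strata, length, 0L)
  take <- floor(fraction * sizes)
  # top up largest fractional remainders so the total matches floor(f * n)
  short <- target - sum(take)
  if (short > 0) {
    rem <- fraction * sizes - take
    ord <- order(rem, decreasing = TRUE)
    for (j in ord) {
      if (short == 0) break
      if (take[j] < sizes[j]) { take[j] <- take[j] + 1; short <- short - 1 }
    }
  }
  if (any(take < 2))
    stop("subsample would leave a class with fewer than 2 members")
  idx <- unlist(lapply(seq_along(strata), function(j)
    sample(strata[[j]], take[j])), use.names = FALSE)
  sort(idx)
}

#' Per-gene case-vs-control t-tests of SIMPO scores
#'
#' For each gene (row of the SIMPO matrix), a two-sided pooled-variance
#' two-sample t-test of case vs control scores, oriented cases minus
#' controls, computed over valid (non-NA) cells only. Genes with fewer than
#' two valid cells in either class receive the sentinel \code{t = 0, p = 1}.
#'
#' @param simpo Genes x samples SIMPO matrix.
#' @param labels 0/1 vector aligned with the columns of \code{simpo}.
#' @param subset Optional integer vector of sample columns to use.
#' @return data.frame with columns \code{gene}, \code{t}, \code{p}.
#' @export
gene_case_control_t <- function(simpo, labels, subset = NULL) {
  if (!is.null(subset)) {
    simpo <- simpo[, subset, drop = FALSE]
    labels <- labels[subset]
  }
  A <- simpo[, labels == 1, drop = FALSE]   # cases
  B <- simpo[, labels == 0, drop = FALSE]   # controls
  n1 <- rowSums(!is.na(A)); n0 <- rowSums(!is.na(B))
  m1 <- rowMeans(A, na.rm = TRUE); m0 <- rowMeans(B, na.rm = TRUE)
  css1 <- rowSums((A - m1)^2, na.rm = TRUE)
  css0 <- rowSums((B - m0)^2, na.rm = TRUE)
  df <- n1 + n0 - 2
  sw2 <- (css1 + css0) / df
  se <- sqrt(sw2 * (1 / n1 + 1 / n0))
  t <- (m1 - m0) / se
  p <- 2 * stats::pt(abs(t), df, lower.tail = FALSE)
  bad <- n1 < 2 | n0 < 2
  degenerate <- !bad & sw2 <= 0
  t[degenerate & (m1 == m0)] <- 0
  p[degenerate & (m1 == m0)] <- 1
  t[degenerate & (m1 != m0)] <- sign(m1 - m0)[degenerate & (m1 != m0)] * Inf
  p[degenerate & (m1 != m0)] <- 0
  t[bad] <- 0; p[bad] <- 1
  data.frame(gene = rownames(simpo), t = t, p = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Resampling-based candidate gene selection
#'
#' Repeatedly subsamples a fraction of the cohort (without replacement,
#' stratified by label), ranks genes within each iteration by the p-value of
#' the case-vs-control t-test of SIMPO scores (ties broken by |t| descending,
#' then gene symbol), and counts how often each gene enters the top
#' \code{top_n}. The per-gene \code{mean_t} averages the t-statistic over ALL
#' iterations, not only those where the gene ranked highly, so its sign
#' estimates the population direction without selection bias.
#'
#' @param simpo Genes x samples SIMPO matrix.
#' @param labels 0/1 vector aligned with columns of \code{simpo}.
#' @param n_iter Number of resampling iterations (default 300).
#' @param fraction Subsample fraction per iteration (default 0.9).
#' @param top_n Size of each iteration's top list (default 50).
#' @param seed Integer seed; the whole selection is reproducible from it.
#' @return data.frame of class \code{simpo_selection} with columns
#'   \code{gene}, \code{occurrence_count}, \code{mean_t}, \code{rank},
#'   sorted by occurrence descending (ties by |mean_t| descending, then
#'   gene symbol).
#' @export
resample_select <- function(simpo, labels, n_iter = 300, fraction = 0.9,
                            top_n = 50, seed = 1) {
  if (n_iter < 1) stop("n_iter must be >= 1")
  set.seed(seed)
  genes <- rownames(simpo)
  occ <- integer(length(genes)); tsum <- numeric(length(genes))
  for (it in seq_len(n_iter)) {
    idx <- subsample_indices(labels, fraction)
    tt <- gene_case_control_t(simpo, labels, idx)
    ord <- order(tt$p, -abs(tt$t), tt$gene)
    occ[ord[seq_len(min(top_n, length(ord)))]] <-
      occ[ord[seq_len(min(top_n, length(ord)))]] + 1L
    tsum <- tsum + tt$t
  }
  mean_t <- tsum / n_iter
  out <- data.frame(gene = genes, occurrence_count = occ, mean_t = mean_t,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$occurrence_count, -abs(out$mean_t), out$gene), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "n_iter") <- n_iter
  attr(out, "fraction") <- fraction
  attr(out, "top_n") <- top_n
  attr(out, "seed") <- seed
  class(out) <- c("simpo_selection", "data.frame")
  out
}

#' Split the top-k selected genes by the sign of their mean t-score
#'
#' The "positive" set collects genes whose average case-vs-control t-score is
#' >= 0 (an exact zero is assigned to the positive side), the "negative" set
#' those with mean t < 0.
#'
#' @param selection A \code{simpo_selection} (or any data.frame with columns
#'   \code{gene}, \code{mean_t}, \code{rank}).
#' @param k Number of top-ranked genes to partition.
#' @return list(positive = character, negative = character).
#' @export
partition_signs <- function(selection, k) {
  if (k < 1 || k > nrow(selection)) stop("k out of range")
  top <- selection[order(selection$rank), ][seq_len(k), ]
  list(positive = top$gene[top$mean_t >= 0],
       negative = top$gene[top$mean_t < 0])
}
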