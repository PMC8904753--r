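# Small in-code fixtures shared across test files.

# Random valid beta matrix with dimnames.
random_beta <- function(n_probes, n_samples, missing_rate = 0) {
  m <- matrix(runif(n_probes * n_samples), n_probes, n_samples,
              dimnames = list(sprintf("cg%05d", seq_len(n_probes)),
                              sprintf("S%03d", seq_len(n_samples))))
  if (missing_rate > 0) m[runif(length(m)) < missing_rate] <- NA_real_
  m
}

# Hand-buildable selection object for partition/sweep tests.
make_selection <- function(genes, mean_t, occurrence = NULL,
                           n_iter = 10, fraction = 0.9, top_n = 50, seed = 1) {
  if (is.null(occurrence)) occurrence <- rev(seq_along(genes))
  out <- data.frame(gene = genes, occurrence_count = occurrence,
                    mean_t = mean_t, rank = seq_along(genes),
                    stringsAsFactors = FALSE)
  attr(out, "n_iter") <- n_iter; attr(out, "fraction") <- fraction
  attr(out, "top_n") <- top_n; attr(out, "seed") <- seed
  class(out) <- c("simpo_selection", "data.frame")
  out
}

# Simulated cohort reduced to (simpo, labels, truth) in one call.
cohort_simpo <- function(..., seed = 1) {
  sim <- simulate_methylation_cohort(..., seed = seed)
  idx <- build_gene_region_index(sim$annotation, sim$beta)
  list(simpo = suppressWarnings(simpo_matrix(sim$beta, idx)),
       labels = sim$phenotype$label,
       truth = sim$truth,
       sim = sim)
}

# Independent brute-force pooled two-sample t (the oracle formula written
# directly, kept separate from the package implementation).
oracle_pooled_t <- function(x, y) {
  m <- length(x); n <- length(y)
  sw2 <- ((m - 1) * var(x) + (n - 1) * var(y)) / (m + n - 2)
  (mean(x) - mean(y)) / (sqrt(sw2) * sqrt(1 / m + 1 / n))
}

# Brute-force all-pairs AUC.
oracle_auc <- function(scores, labels) {
  cs <- scores[labels == 1]; ct <- scores[labels == 0]
  tot <- 0
  for (a in cs) tot <- tot + sum(a > ct) + 0.5 * sum(a == ct)
  tot / (length(cs) * length(ct))
}
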