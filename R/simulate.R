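#' Simulate a probe-level 450K-style methylation cohort
#'
#' Generates a case/control cohort with the structure the index analysis
#' assumes: per gene, a random number of promoter (TSS1500/TSS200) and
#' other-region (Body/5'UTR/1stExon/3'UTR) probes; per probe, a logit-scale
#' mean drawn around the side's baseline; per sample, independent logit-scale
#' noise. For a subset of "causal" genes the promoter probes of case samples
#' are shifted by the effect size, half the causal genes upward and half
#' downward — only the promoter side moves, because the gene score contrasts
#' promoter against body, so an equal shift of both sides must carry no
#' signal. Beta values are the inverse-logit of mean plus noise, clipped to
#' (0.001, 0.999) to keep logit transforms finite.
#'
#' Default cohort sizes mirror a discovery cohort of 324 cases and 209
#' controls; gene and causal counts default to a desk-scale genome of 1,000
#' genes with 50 causal.
#'
#' @param n_cases,n_controls Samples per arm (defaults 324 / 209).
#' @param n_genes Number of genes (default 1000).
#' @param n_causal Number of causal genes, split evenly between directions
#'   (default 50).
#' @param probes_per_region Inclusive range of probes per side (default
#'   \code{c(2, 8)}, uniform).
#' @param mu_promoter,mu_other Baseline logit-scale means (defaults -1.0 and
#'   +0.5: promoters hypomethylated, bodies methylated).
#' @param probe_mean_sd SD of per-probe logit means around the baseline
#'   (default 0.5).
#' @param probe_sd Per-sample logit-scale noise SD (default 0.5).
#' @param effect_size Case-associated logit shift of causal promoter probes
#'   (default 1.0).
#' @param missing_rate Fraction of beta cells masked to NA (default 0).
#' @param truth Optional truth data.frame from a previous cohort (columns
#'   \code{gene}, \code{causal}, \code{direction}); when supplied, the same
#'   genes are causal in the same directions, so an independently seeded
#'   cohort follows the same generative law (e.g. a held-out test cohort for
#'   a frozen model).
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @return list(beta, annotation, phenotype, truth, config); \code{truth} is
#'   a data.frame (gene, causal, direction) with direction +1/-1/0.
#' @export
simulate_methylation_cohort <- function(n_cases = 324, n_controls = 209,
                                        n_genes = 1000, n_causal = 50,
                                        probes_per_region = c(2, 8),
                                        mu_promoter = -1.0, mu_other = 0.5,
                                        probe_mean_sd = 0.5, probe_sd = 0.5,
                                        effect_size = 1.0, missing_rate = 0,
                                        truth = NULL, seed = 1) {
  if (n_causal > n_genes) stop("n_causal exceeds n_genes")
  if (missing_rate < 0 || missing_rate > 1) stop("missing_rate outside [0, 1]")
  if (effect_size < 0) stop("effect_size must be >= 0")
  set.seed(seed)
  n <- n_cases + n_controls
  sample_ids <- sprintf("S%04d", seq_len(n))
  labels <- rep(c(1L, 0L), c(n_cases, n_controls))
  genes <- sprintf("G%04d", seq_len(n_genes))
  if (!is.null(truth)) {
    if (nrow(truth) != n_genes) stop("truth does not match n_genes")
    direction <- truth$direction
  } else {
    causal <- sort(sample.int(n_genes, n_causal))
    direction <- integer(n_genes)
    direction[causal] <- rep_len(c(1L, -1L), n_causal)
  }

  m_pro <- sample(probes_per_region[1]:probes_per_region[2], n_genes, TRUE)
  m_oth <- sample(probes_per_region[1]:probes_per_region[2], n_genes, TRUE)
  n_probes <- sum(m_pro) + sum(m_oth)
  beta <- matrix(NA_real_, nrow = n_probes, ncol = n)
  probe_ids <- character(n_probes)
  ann_probe <- character(n_probes); ann_gene <- character(n_probes)
  ann_group <- character(n_probes)

  row <- 0L
  pro_groups <- c("TSS1500", "TSS200")
  oth_groups <- c("Body", "5UTR", "1stExon", "3UTR")
  for (g in seq_len(n_genes)) {
    np <- m_pro[g]; no <- m_oth[g]
    mu_p <- stats::rnorm(np, mu_promoter, probe_mean_sd)
    mu_o <- stats::rnorm(no, mu_other, probe_mean_sd)
    shift <- if (direction[g] != 0) direction[g] * effect_size else 0
    for (j in seq_len(np)) {
      row <- row + 1L
      logit <- mu_p[j] + stats::rnorm(n, 0, probe_sd) + shift * labels
      beta[row, ] <- pmin(pmax(stats::plogis(logit), 0.001), 0.999)
      probe_ids[row] <- sprintf("cg%07d", row)
      ann_probe[row] <- probe_ids[row]; ann_gene[row] <- genes[g]
      ann_group[row] <- pro_groups[1 + (j %% 2)]
    }
    for (j in seq_len(no)) {
      row <- row + 1L
      logit <- mu_o[j] + stats::rnorm(n, 0, probe_sd)
      beta[row, ] <- pmin(pmax(stats::plogis(logit), 0.001), 0.999)
      probe_ids[row] <- sprintf("cg%07d", row)
      ann_probe[row] <- probe_ids[row]; ann_gene[row] <- genes[g]
      ann_group[row] <- oth_groups[1 + (j %% 4)]
    }
  }
  dimnames(beta) <- list(probe_ids, sample_ids)
  if (missing_rate > 0) {
    mask <- stats::runif(length(beta)) < missing_rate
    beta[mask] <- NA_real_
  }
  list(
    beta = beta,
    annotation = data.frame(probe_id = ann_probe, gene = ann_gene,
                            group = ann_group, stringsAsFactors = FALSE),
    phenotype = data.frame(sample_id = sample_ids, label = labels,
                           stringsAsFactors = FALSE),
    truth = data.frame(gene = genes, causal = direction != 0,
                       direction = direction, stringsAsFactors = FALSE),
    config = list(n_cases = n_cases, n_controls = n_controls,
                  n_genes = n_genes, n_causal = n_causal,
                  probes_per_region = probes_per_region,
                  mu_promoter = mu_promoter, mu_other = mu_other,
                  probe_mean_sd = probe_mean_sd, probe_sd = probe_sd,
                  effect_size = effect_size, missing_rate = missing_rate,
                  seed = seed))
}

rdirichlet1 <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), ncol = length(alpha),
              byrow = TRUE)
  g / rowSums(g)
}

#' Simulate a prospective cancer cohort around given index scores
#'
#' Draws blood cell proportions (monocytes, granulocytes, lymphocytes plus a
#' remainder) from a Dirichlet whose means mirror typical whole blood, a
#' CD4/CD8 ratio from a log-normal, and a binary cancer outcome from a
#' logistic model on the z-scored index and its interaction with the CD4/CD8
#' ratio. Diagnosed samples receive a uniform diagnosis year within the
#' follow-up window; the cohort size and follow-up default to 659 samples
#' over 11 years.
#'
#' @param scores data.frame (\code{sample_id}, \code{mdi}) or named numeric
#'   vector of index scores, one per participant.
#' @param follow_up_years Length of follow-up (default 11).
#' @param dirichlet_alpha Concentration for (mono, gran, lympho, other);
#'   default \code{c(8, 60, 30, 2)} giving means about 0.08/0.60/0.30/0.02.
#' @param cd4_cd8_meanlog,cd4_cd8_sdlog Log-normal parameters of the CD4/CD8
#'   ratio (defaults log(1.8) and 0.3).
#' @param b0 Logistic intercept; default \code{qlogis(235/659)}, the final
#'   case fraction of a 659-participant cohort with 235 diagnoses.
#' @param b_mdi,b_interaction Outcome coefficients on the z-scored index and
#'   the index-by-CD4/CD8 product (defaults 0.6037 and 0.5579).
#' @param seed Integer seed.
#' @return Phenotype data.frame: sample_id, label, diagnosis_year (NA =
#'   cancer-free), mono, gran, lympho, cd4, cd8.
#' @export
simulate_cancer_cohort <- function(scores, follow_up_years = 11,
                                   dirichlet_alpha = c(8, 60, 30, 2),
                                   cd4_cd8_meanlog = log(1.8),
                                   cd4_cd8_sdlog = 0.3,
                                   b0 = stats::qlogis(235 / 659),
                                   b_mdi = 0.6037, b_interaction = 0.5579,
                                   seed = 1) {
  if (is.numeric(scores)) scores <- data.frame(sample_id = names(scores), mdi = scores)
  set.seed(seed)
  n <- nrow(scores)
  props <- rdirichlet1(n, dirichlet_alpha)
  mono <- props[, 1]; gran <- props[, 2]; lympho <- props[, 3]
  ratio <- stats::rlnorm(n, cd4_cd8_meanlog, cd4_cd8_sdlog)
  cd8 <- 0.75 * lympho / (1 + ratio)
  cd4 <- ratio * cd8
  z_mdi <- z_transform(scores$mdi)
  z_ratio <- z_transform(ratio)
  p <- stats::plogis(b0 + b_mdi * z_mdi + b_interaction * z_mdi * z_ratio)
  y <- stats::rbinom(n, 1, p)
  diag_year <- ifelse(y == 1, sample.int(follow_up_years, n, replace = TRUE),
                      NA_integer_)
  validate_phenotype(data.frame(
    sample_id = scores$sample_id, label = y, diagnosis_year = diag_year,
    mono = mono, gran = gran, lympho = lympho, cd4 = cd4, cd8 = cd8,
    stringsAsFactors = FALSE))
}
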