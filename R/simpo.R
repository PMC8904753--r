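#' SIMPO score: pooled t-statistic contrasting promoter vs other-region probes
#'
#' For one gene in one sample, the score is the two-sample Student t-statistic
#' between the beta values of its promoter probes and those of its
#' gene-body/UTR probes:
#' \deqn{t = \frac{\bar x - \bar y}{S_w \sqrt{1/m + 1/n}}, \qquad
#'       S_w^2 = \frac{(m-1)S_1^2 + (n-1)S_2^2}{m+n-2}}
#' where \eqn{\bar x, S_1^2, m} are the mean, unbiased variance and count of
#' the promoter-probe values and \eqn{\bar y, S_2^2, n} those of the
#' other-region values. Missing values are dropped before counting.
#'
#' The score is undefined (returned as \code{NA}) when either side has fewer
#' than two non-missing values or the pooled variance is exactly zero:
#' constant-methylation genes carry no promoter-vs-body contrast, and an
#' infinite t cannot be consumed by the downstream tests.
#'
#' @param promoter_values Numeric beta values of the gene's promoter probes.
#' @param other_values Numeric beta values of the gene's other-region probes.
#' @return A single t-statistic, or \code{NA_real_} if undefined.
#' @examples
#' simpo_score(c(0.8, 0.6), c(0.2, 0.3, 0.1))  # ~ 4.743
#' @export
simpo_score <- function(promoter_values, other_values) {
  x <- promoter_values[!is.na(promoter_values)]
  y <- other_values[!is.na(other_values)]
  m <- length(x); n <- length(y)
  if (m < 2 || n < 2) return(NA_real_)
  sw2 <- ((m - 1) * stats::var(x) + (n - 1) * stats::var(y)) / (m + n - 2)
  if (sw2 <= 0) return(NA_real_)
  (mean(x) - mean(y)) / (sqrt(sw2) * sqrt(1 / m + 1 / n))
}

#' Gene-by-sample matrix of SIMPO scores
#'
#' Applies [simpo_score()] to every (gene, sample) cell using the probe
#' partition of a [build_gene_region_index()] result. Missing beta values are
#' dropped per (gene, sample, side), so the effective m and n can vary across
#' samples. Genes whose score is undefined in more than
#' \code{max_invalid_frac} of samples are dropped with a warning.
#'
#' @param beta Probes x samples beta matrix.
#' @param index \code{gene_region_index} built against \code{beta}.
#' @param max_invalid_frac Maximum tolerated fraction of invalid cells per
#'   gene (default 0.05).
#' @return Numeric genes x samples matrix of t-statistics; invalid cells are
#'   \code{NA}. Attributes \code{n_invalid} (count of invalid cells among
#'   retained genes) and \code{dropped_genes}.
#' @export
simpo_matrix <- function(beta, index, max_invalid_frac = 0.05) {
  if (length(index) == 0) stop("empty gene region index")
  genes <- names(index)
  S <- ncol(beta)
  out <- matrix(NA_real_, nrow = length(genes), ncol = S,
                dimnames = list(genes, colnames(beta)))
  for (i in seq_along(genes)) {
    e <- index[[i]]
    P <- beta[e$promoter, , drop = FALSE]
    O <- beta[e$other, , drop = FALSE]
    out[i, ] <- simpo_row(P, O)
  }
  invalid_frac <- rowMeans(is.na(out))
  drop <- invalid_frac > max_invalid_frac
  if (any(drop)) {
    warning(sum(drop), " gene(s) invalid in more than ",
            format(100 * max_invalid_frac), "% of samples; dropped")
  }
  res <- out[!drop, , drop = FALSE]
  attr(res, "n_invalid") <- sum(is.na(res))
  attr(res, "dropped_genes") <- genes[drop]
  res
}

# Vectorised pooled t across the sample columns of one gene's probe blocks.
# Two-pass variances (centred sums of squares) keep agreement with the
# scalar oracle at the 1e-10 level.
simpo_row <- function(P, O) {
  m <- colSums(!is.na(P)); n <- colSums(!is.na(O))
  xb <- colMeans(P, na.rm = TRUE); yb <- colMeans(O, na.rm = TRUE)
  css1 <- colSums(sweep(P, 2, xb, "-")^2, na.rm = TRUE)
  css2 <- colSums(sweep(O, 2, yb, "-")^2, na.rm = TRUE)
  sw2 <- (css1 + css2) / (m + n - 2)
  t <- (xb - yb) / (sqrt(sw2) * sqrt(1 / m + 1 / n))
  t[m < 2 | n < 2 | sw2 <= 0] <- NA_real_
  t
}

#' Read/write a SIMPO matrix as TSV
#'
#' Genes in rows, samples in columns, invalid cells as \code{NA}; first
#' column \code{gene}.
#'
#' @param simpo Genes x samples numeric matrix.
#' @param path File path.
#' @export
write_simpo_matrix <- function(simpo, path) {
  chr <- matrix(sprintf("%.17g", simpo), nrow(simpo), ncol(simpo),
                dimnames = dimnames(simpo))
  chr[is.na(simpo)] <- "NA"
  df <- data.frame(gene = rownames(simpo), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_simpo_matrix
#' @export
read_simpo_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
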