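# Illumina manifest region labels; promoter convention = TSS groups.
PROMOTER_GROUPS <- c("TSS1500", "TSS200")
OTHER_GROUPS    <- c("5UTR", "1stExon", "Body", "3UTR")
REGION_GROUPS   <- c(PROMOTER_GROUPS, OTHER_GROUPS)

normalize_group <- function(x) {
  x <- gsub("'", "", x, fixed = TRUE)   # 5'UTR -> 5UTR
  x <- gsub("′", "", x)            # prime character
  x
}

#' Validate a probe-by-sample beta-value matrix
#'
#' Checks the container invariants of a methylation beta matrix: a numeric
#' matrix with unique probe row names and unique sample column names, all
#' non-missing entries in \[0, 1\].
#'
#' @param values Numeric matrix, probes in rows, samples in columns.
#' @return The validated matrix, invisibly usable downstream.
#' @export
validate_beta_matrix <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("beta matrix must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("beta matrix needs probe row names and sample column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate probe ids in beta matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in beta matrix")
  v <- values[!is.na(values)]
  if (length(v) && (min(v) < 0 || max(v) > 1))
    stop("beta values must lie in [0, 1]")
  values
}

#' Read a beta-value matrix from tab-separated text
#'
#' Expects a header row of sample ids, a first column of probe ids, and
#' numeric cells (the literal \code{NA} marks a missing value). Values
#' outside \[0, 1\] and non-numeric cells are rejected.
#'
#' @param path Path to a TSV file with header \code{probe_id} then sample ids.
#' @return Numeric matrix (probes x samples) with dimnames.
#' @export
read_beta_matrix <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", na.strings = NULL)
  if (ncol(df) < 2) stop("beta matrix file needs a probe column and >= 1 sample")
  probes <- df[[1]]
  samples <- colnames(df)[-1]
  raw <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  bad <- !is.na(raw) & raw != "NA" & is.na(num)
  if (any(bad)) stop("non-numeric cell in beta matrix: ", raw[bad][1])
  dimnames(num) <- list(probes, samples)
  validate_beta_matrix(num)
}

#' Write a beta-value matrix as tab-separated text
#'
#' Inverse of [read_beta_matrix()]; missing values are written as \code{NA}.
#'
#' @param beta Numeric probes x samples matrix.
#' @param path Output path.
#' @export
write_beta_matrix <- function(beta, path) {
  validate_beta_matrix(beta)
  # %.17g keeps the read/write round trip bit-exact
  chr <- matrix(sprintf("%.17g", beta), nrow(beta), ncol(beta),
                dimnames = dimnames(beta))
  chr[is.na(beta)] <- "NA"
  df <- data.frame(probe_id = rownames(beta), chr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a manifest-style probe annotation table
#'
#' Parses a TSV with columns \code{probe_id}, \code{gene}, \code{group} where
#' the gene and group fields are semicolon-separated parallel lists, as in the
#' Illumina 450K manifest columns \code{UCSC_RefGene_Name} /
#' \code{UCSC_RefGene_Group}. One record is emitted per (probe, gene, group)
#' pair; exact duplicates are collapsed.
#'
#' @param path Path to the annotation TSV.
#' @return data.frame with columns \code{probe_id}, \code{gene}, \code{group}.
#' @export
read_probe_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  need <- c("probe_id", "gene", "group")
  if (!all(need %in% colnames(df)))
    stop("annotation file needs columns: ", paste(need, collapse = ", "))
  probe_annotation(df$probe_id, df$gene, df$group)
}

#' Build a probe annotation from manifest-dialect vectors
#'
#' @param probe_id Character vector of probe ids.
#' @param gene Semicolon-separated gene symbol lists, parallel to `group`.
#' @param group Semicolon-separated region-group lists.
#' @return data.frame with one row per (probe, gene, group) record.
#' @export
probe_annotation <- function(probe_id, gene, group) {
  genes  <- strsplit(gene,  ";", fixed = TRUE)
  groups <- strsplit(normalize_group(group), ";", fixed = TRUE)
  nl <- lengths(genes); ng <- lengths(groups)
  if (any(nl != ng))
    stop("probe ", probe_id[which(nl != ng)[1]], ": gene list length ",
         nl[which(nl != ng)[1]], " != group list length ", ng[which(nl != ng)[1]])
  out <- data.frame(
    probe_id = rep(probe_id, nl),
    gene     = unlist(genes, use.names = FALSE),
    group    = unlist(groups, use.names = FALSE),
    stringsAsFactors = FALSE)
  bad <- setdiff(unique(out$group), REGION_GROUPS)
  if (length(bad))
    stop("unknown region group label(s): ", paste(bad, collapse = ", "))
  unique(out)
}

#' Write a probe annotation back to manifest dialect
#'
#' Records for the same probe are re-joined into semicolon lists so that
#' [read_probe_annotation()] recovers the same set of records.
#'
#' @param ann Annotation data.frame (probe_id, gene, group).
#' @param path Output path.
#' @export
write_probe_annotation <- function(ann, path) {
  sp <- split(ann[c("gene", "group")], ann$probe_id)
  df <- data.frame(
    probe_id = names(sp),
    gene  = vapply(sp, function(d) paste(d$gene, collapse = ";"), ""),
    group = vapply(sp, function(d) paste(d$group, collapse = ";"), ""),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' CSV with header \code{sample_id,label,...}; \code{label} must be 0/1.
#' Optional columns (age, sex, diagnosis_year, cell proportions) may be
#' empty. Proportion columns are checked to lie in \[0, 1\].
#'
#' @param path Path to the CSV.
#' @return data.frame keyed by \code{sample_id}.
#' @export
read_phenotype <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_phenotype(df)
}

#' @rdname read_phenotype
#' @param pheno Phenotype data.frame to validate or write.
#' @export
validate_phenotype <- function(pheno) {
  if (!all(c("sample_id", "label") %in% colnames(pheno)))
    stop("phenotype needs sample_id and label columns")
  if (anyDuplicated(pheno$sample_id)) stop("duplicate sample ids in phenotype")
  if (!all(pheno$label %in% c(0L, 1L))) stop("label must be 0/1")
  prop_cols <- intersect(c("mono", "gran", "lympho", "cd4", "cd8",
                           "nk", "bcell", "tcell"), colnames(pheno))
  for (cl in prop_cols) {
    v <- pheno[[cl]][!is.na(pheno[[cl]])]
    if (length(v) && (min(v) < 0 || max(v) > 1))
      stop("cell proportion column ", cl, " outside [0, 1]")
  }
  pheno
}

#' @rdname read_phenotype
#' @export
write_phenotype <- function(pheno, path) {
  validate_phenotype(pheno)
  utils::write.csv(pheno, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Partition each gene's probes into promoter and other-region sets
#'
#' Promoter probes are those annotated TSS1500 or TSS200 for the gene; the
#' other side collects 5'UTR, 1stExon, Body and 3'UTR probes. A probe
#' annotated to both a promoter and a non-promoter group for the same gene
#' contributes to both sides (the manifest genuinely multi-labels probes).
#' Probes absent from the beta matrix are dropped, and genes with fewer than
#' \code{min_probes} on either side are excluded: both variance terms of the
#' per-gene contrast are undefined for singleton groups.
#'
#' @param ann Probe annotation data.frame (probe_id, gene, group).
#' @param beta Beta matrix whose row names define the available probes.
#' @param min_probes Minimum probes per side (default 2).
#' @return A named list (gene -> list(promoter, other)) of class
#'   \code{gene_region_index}, with attribute \code{n_excluded} giving the
#'   number of genes dropped by the threshold.
#' @export
build_gene_region_index <- function(ann, beta, min_probes = 2) {
  if (min_probes < 2) stop("min_probes must be >= 2")
  ann <- ann[ann$probe_id %in% rownames(beta), , drop = FALSE]
  if (nrow(ann) == 0) stop("no annotated probe is present in the beta matrix")
  ann <- ann[order(ann$gene, ann$probe_id), , drop = FALSE]
  promoter <- ann$group %in% PROMOTER_GROUPS
  by_gene_pro <- split(ann$probe_id[promoter],  ann$gene[promoter])
  by_gene_oth <- split(ann$probe_id[!promoter], ann$gene[!promoter])
  genes <- sort(union(names(by_gene_pro), names(by_gene_oth)))
  idx <- lapply(genes, function(g) {
    list(promoter = sort(unique(by_gene_pro[[g]])),
         other    = sort(unique(by_gene_oth[[g]])))
  })
  names(idx) <- genes
  keep <- vapply(idx, function(e)
    length(e$promoter) >= min_probes && length(e$other) >= min_probes, TRUE)
  out <- idx[keep]
  if (length(out) == 0) stop("no gene passes the min_probes threshold")
  attr(out, "n_excluded") <- sum(!keep)
  attr(out, "min_probes") <- min_probes
  class(out) <- "gene_region_index"
  out
}

#' @export
print.gene_region_index <- function(x, ...) {
  cat("Gene region index:", length(x), "genes (",
      attr(x, "n_excluded"), "excluded by min_probes =",
      attr(x, "min_probes"), ")\n")
  invisible(x)
}
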