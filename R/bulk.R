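#' Bulk gene-by-sample expression matrix
#'
#' Container for small bulk RNA-seq matrices (counts or RPKM) with the
#' per-gene lengths, per-sample mapped-read totals and replicate-group
#' assignments needed for RPKM, floor filtering, z-scoring and group fold
#' changes.
#'
#' @param values Numeric genes x samples matrix (row and column names
#'   required), non-negative.
#' @param gene_lengths Named or positional numeric vector of transcript
#'   lengths in bp, one per gene, all positive.
#' @param sample_totals Total mapped reads per sample; defaults to the
#'   column sums when `unit = "counts"` (a proxy when true mapped totals
#'   are unavailable).
#' @param sample_groups Named character vector mapping sample to replicate
#'   group (optional until [group_log2fc()] is used).
#' @param unit `"counts"` or `"rpkm"`.
#' @return An object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, gene_lengths, sample_totals = NULL,
                              sample_groups = NULL,
                              unit = c("counts", "rpkm")) {
  unit <- match.arg(unit)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must carry gene (row) and sample (column) names")
  }
  if (any(values < 0)) stop("expression values must be non-negative")
  gene_lengths <- as.numeric(gene_lengths)
  if (length(gene_lengths) != nrow(values) || any(gene_lengths <= 0)) {
    stop("gene_lengths must be positive, one per gene")
  }
  if (is.null(sample_totals)) {
    if (unit != "counts") stop("sample_totals required for RPKM input")
    sample_totals <- colSums(values)
  }
  sample_totals <- as.numeric(sample_totals)
  if (length(sample_totals) != ncol(values) || any(sample_totals <= 0)) {
    stop("sample_totals must be positive, one per sample")
  }
  if (!is.null(sample_groups)) {
    if (is.null(names(sample_groups))) {
      names(sample_groups) <- colnames(values)
    }
    if (!all(colnames(values) %in% names(sample_groups))) {
      stop("sample_groups must cover every sample")
    }
    sample_groups <- sample_groups[colnames(values)]
  }
  structure(list(values = values, gene_lengths = gene_lengths,
                 sample_totals = sample_totals,
                 sample_groups = sample_groups, unit = unit),
            class = "expr_matrix")
}

#' Reads per kilobase per million mapped reads
#'
#' `RPKM = count * 1e9 / (gene_length * sample_total)`.
#'
#' @param m An [expression_matrix()] in counts.
#' @return The same object with `unit = "rpkm"`.
#' @export
rpkm <- function(m) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$unit != "counts") stop("input must be in counts")
  v <- m$values * 1e9 / outer(m$gene_lengths, m$sample_totals)
  out <- m
  out$values <- v
  out$unit <- "rpkm"
  out
}

#' Remove genes at or below an RPKM floor in every sample of a subset
#'
#' A gene is removed when its value is `<= threshold` in EVERY sample of
#' the subset (default: all samples); a single sample above the floor
#' rescues the gene.
#'
#' @param m An [expression_matrix()] in RPKM.
#' @param threshold RPKM floor (default 1).
#' @param sample_subset Optional character vector of sample names the rule
#'   is evaluated over.
#' @return The filtered [expression_matrix()] with attribute
#'   `removed_genes`.
#' @export
rpkm_floor_filter <- function(m, threshold = 1, sample_subset = NULL) {
  stopifnot(inherits(m, "expr_matrix"))
  if (m$unit != "rpkm") stop("filter operates on RPKM values")
  if (is.null(sample_subset)) sample_subset <- colnames(m$values)
  if (length(sample_subset) == 0L) stop("sample subset must be non-empty")
  if (!all(sample_subset %in% colnames(m$values))) {
    stop("unknown sample in subset")
  }
  drop <- rowSums(m$values[, sample_subset, drop = FALSE] > threshold) == 0
  out <- m
  out$values <- m$values[!drop, , drop = FALSE]
  out$gene_lengths <- m$gene_lengths[!drop]
  attr(out, "removed_genes") <- rownames(m$values)[drop]
  out
}

#' Per-gene z-scores across samples
#'
#' `z[g, s] = (x[g, s] - mean_g) / sd_g` with the mean and standard
#' deviation taken per gene over all samples. The sample (n-1) standard
#' deviation is the default convention; set `sd_type = "population"` for
#' the n-denominator variant. Zero-variance genes cannot be scaled and are
#' returned as `NA` rows, listed in the `flagged_genes` attribute.
#'
#' @param m An [expression_matrix()].
#' @param sd_type `"sample"` (default) or `"population"`.
#' @return Numeric matrix of z-scores, same dimnames as the input.
#' @export
gene_zscore <- function(m, sd_type = c("sample", "population")) {
  stopifnot(inherits(m, "expr_matrix"))
  sd_type <- match.arg(sd_type)
  v <- m$values
  if (ncol(v) < 2L) stop("need at least two samples")
  mu <- rowMeans(v)
  s <- apply(v, 1, stats::sd)
  if (sd_type == "population") {
    s <- s * sqrt((ncol(v) - 1) / ncol(v))
  }
  flagged <- s == 0
  z <- (v - mu) / s
  z[flagged, ] <- NA_real_
  attr(z, "flagged_genes") <- rownames(v)[flagged]
  z
}

#' Replicate-averaged log2 fold change between two groups
#'
#' `log2((mean_A + eps) / (mean_B + eps))` per gene, with the means taken
#' over the replicate samples of each group and `eps` a small pseudocount
#' guarding against division by zero.
#'
#' @param m An [expression_matrix()] (RPKM) with `sample_groups` set.
#' @param group_a,group_b Replicate group labels.
#' @param pseudocount RPKM pseudocount `eps` (default 0.01).
#' @return Named numeric vector of per-gene log2 fold changes.
#' @export
group_log2fc <- function(m, group_a, group_b, pseudocount = 0.01) {
  stopifnot(inherits(m, "expr_matrix"))
  if (is.null(m$sample_groups)) stop("sample_groups not set")
  if (!group_a %in% m$sample_groups || !group_b %in% m$sample_groups) {
    stop("unknown replicate group")
  }
  ma <- rowMeans(m$values[, m$sample_groups == group_a, drop = FALSE])
  mb <- rowMeans(m$values[, m$sample_groups == group_b, drop = FALSE])
  log2((ma + pseudocount) / (mb + pseudocount))
}
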