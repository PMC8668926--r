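#' Quality-control filter for a per-cell table
#'
#' Removes cells expressing fewer than `min_genes` genes, cells with a
#' mitochondrial read fraction above `mito_max` (dying cells) and cells
#' with a mitochondrial fraction below `mito_min` (blood contaminants).
#' The removal bounds are exclusive: a cell at exactly `min_genes`,
#' `mito_min` or `mito_max` is kept. Row order of survivors is preserved.
#'
#' @param cells Data frame with at least `n_genes` and `mito_frac` columns.
#' @param min_genes Minimum detected-gene count (default 200).
#' @param mito_min,mito_max Inclusive bounds on the mitochondrial fraction
#'   (defaults 0.01 and 0.15).
#' @return The filtered data frame, with a `qc_log` attribute listing
#'   per-rule removal counts (a cell failing several rules is counted under
#'   each) and totals.
#' @export
qc_filter <- function(cells, min_genes = 200L, mito_min = 0.01,
                      mito_max = 0.15) {
  if (!all(c("n_genes", "mito_frac") %in% names(cells))) {
    stop("`cells` must carry n_genes and mito_frac QC fields")
  }
  if (any(!is.finite(cells$n_genes)) || any(!is.finite(cells$mito_frac))) {
    stop("QC fields contain missing values")
  }
  low_genes <- cells$n_genes < min_genes
  high_mito <- cells$mito_frac > mito_max
  low_mito <- cells$mito_frac < mito_min
  keep <- !(low_genes | high_mito | low_mito)
  out <- cells[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "qc_log") <- list(
    n_input = nrow(cells),
    removed_low_genes = sum(low_genes),
    removed_high_mito = sum(high_mito),
    removed_low_mito = sum(low_mito),
    n_removed = sum(!keep),
    n_kept = sum(keep)
  )
  out
}

#' Per-cell log normalization of the target-gene count
#'
#' The standard droplet scRNA-seq normalization: counts per cell are scaled
#' to a common library size and log-transformed,
#' `norm_expr = ln(1 + target_count / total_count * scale)`.
#'
#' @param cells Data frame with `target_count` and `total_count` columns.
#' @param scale Scale factor (default 1e4 counts per cell).
#' @return `cells` with a `norm_expr` column appended. Cells with
#'   `total_count == 0` cannot be normalized and are dropped with a
#'   warning naming how many were removed.
#' @export
log_normalize <- function(cells, scale = 1e4) {
  if (!all(c("target_count", "total_count") %in% names(cells))) {
    stop("`cells` must carry target_count and total_count")
  }
  bad <- cells$total_count <= 0
  if (any(bad)) {
    warning(sum(bad), " cell(s) with zero total count removed before ",
            "normalization")
    cells <- cells[!bad, , drop = FALSE]
    rownames(cells) <- NULL
  }
  cells$norm_expr <- log1p(cells$target_count / cells$total_count * scale)
  cells
}
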