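#' Expression-class thresholds
#'
#' The two cut points on the log1p normalized-expression scale separating
#' non/low- from intermediate- and intermediate- from high-expressing
#' cells. The shipped defaults (0.3 and 1.45) are the frozen density-plot
#' intersection points; re-deriving them from data with
#' [find_intersection()] is an explicit opt-in.
#'
#' @param t_low,t_high Cut points, `0 < t_low < t_high`.
#' @return An object of class `expression_thresholds`.
#' @export
expression_thresholds <- function(t_low = 0.3, t_high = 1.45) {
  t_low <- as.numeric(t_low); t_high <- as.numeric(t_high)
  if (!(is.finite(t_low) && is.finite(t_high) && 0 < t_low &&
        t_low < t_high)) {
    stop("need 0 < t_low < t_high")
  }
  structure(list(t_low = t_low, t_high = t_high),
            class = "expression_thresholds")
}

#' Three-class expression call per cell
#'
#' Assigns each cell to one of three classes from its normalized
#' expression: `nonlow` if `norm_expr <= t_low`, `intermediate` if
#' `t_low < norm_expr <= t_high`, `high` otherwise. Both boundaries belong
#' to the lower class.
#'
#' @param cells Data frame with a `norm_expr` column (see
#'   [log_normalize()]).
#' @param thresholds An [expression_thresholds()] object.
#' @return `cells` with a `class` factor column
#'   (`nonlow`/`intermediate`/`high`) appended.
#' @export
classify_cells <- function(cells, thresholds = expression_thresholds()) {
  if (!"norm_expr" %in% names(cells)) {
    stop("`cells` must carry norm_expr; run log_normalize() first")
  }
  if (any(!is.finite(cells$norm_expr)) || any(cells$norm_expr < 0)) {
    stop("norm_expr must be finite and non-negative")
  }
  stopifnot(inherits(thresholds, "expression_thresholds"))
  v <- cells$norm_expr
  cls <- ifelse(v <= thresholds$t_low, "nonlow",
                ifelse(v <= thresholds$t_high, "intermediate", "high"))
  cells$class <- factor(cls, levels = c("nonlow", "intermediate", "high"))
  cells
}

condition_label <- function(cells) {
  if ("condition" %in% names(cells)) return(cells$condition)
  if (all(c("genotype", "tissue") %in% names(cells))) {
    return(paste(cells$genotype, cells$tissue, sep = "-"))
  }
  stop("cells need either a condition column or genotype + tissue")
}

#' Class proportions per (condition, group)
#'
#' Tabulates the fractions of non/low-, intermediate- and high-expressing
#' cells within each condition, split by cluster, by proximo-distal axis,
#' or pooled per condition.
#'
#' @param cells Classified cell table (see [classify_cells()]).
#' @param group_by One of `"cluster"`, `"axis"`, `"condition"`.
#' @return Data frame keyed by (`condition`, `group`) with `n_cells` and
#'   the three class fractions (each row sums to 1). For
#'   `group_by = "axis"`, cells without an axis call are dropped with a
#'   warning.
#' @export
class_proportions <- function(cells,
                              group_by = c("cluster", "axis", "condition")) {
  group_by <- match.arg(group_by)
  if (!"class" %in% names(cells)) {
    stop("`cells` must carry class calls; run classify_cells() first")
  }
  cond <- condition_label(cells)
  grp <- switch(group_by,
    cluster = cells$cluster,
    axis = cells$axis,
    condition = cond
  )
  if (group_by == "axis" && anyNA(grp)) {
    warning(sum(is.na(grp)), " cell(s) without an axis call omitted")
    keep <- !is.na(grp)
    cells <- cells[keep, , drop = FALSE]
    cond <- cond[keep]; grp <- grp[keep]
  }
  key <- interaction(cond, grp, drop = TRUE, sep = "\r")
  tab <- table(key, cells$class)
  n <- rowSums(tab)
  parts <- do.call(rbind, strsplit(rownames(tab), "\r", fixed = TRUE))
  out <- data.frame(
    condition = parts[, 1], group = parts[, 2], n_cells = as.integer(n),
    frac_nonlow = tab[, "nonlow"] / n,
    frac_intermediate = tab[, "intermediate"] / n,
    frac_high = tab[, "high"] / n,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(out$condition, out$group), , drop = FALSE]
}

#' Fold change in the non/low-expressing fraction between two conditions
#'
#' For each group shared by the two proportion tables, the ratio of the
#' alternative (e.g. enhancer-deleted) non/low fraction to the reference
#' (wildtype) one. Groups where the reference fraction is zero are flagged
#' `undefined` and carry `NA` instead of a number.
#'
#' @param ref,alt [class_proportions()] tables, same group keys.
#' @return Data frame with `group`, both fractions, `fold` and an
#'   `undefined` flag.
#' @export
fold_change_nonlow <- function(ref, alt) {
  need <- c("group", "frac_nonlow")
  if (!all(need %in% names(ref)) || !all(need %in% names(alt))) {
    stop("inputs must be class_proportions() tables")
  }
  if (!setequal(ref$group, alt$group) || anyDuplicated(ref$group) ||
      anyDuplicated(alt$group)) {
    stop("group keys of the two tables must match one-to-one")
  }
  m <- merge(ref[, c("group", "frac_nonlow")],
             alt[, c("group", "frac_nonlow")],
             by = "group", suffixes = c("_ref", "_alt"))
  m$undefined <- m$frac_nonlow_ref == 0
  m$fold <- ifelse(m$undefined, NA_real_,
                   m$frac_nonlow_alt / m$frac_nonlow_ref)
  names(m)[names(m) == "frac_nonlow_ref"] <- "ref_frac_nonlow"
  names(m)[names(m) == "frac_nonlow_alt"] <- "alt_frac_nonlow"
  m[, c("group", "ref_frac_nonlow", "alt_frac_nonlow", "fold", "undefined")]
}
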