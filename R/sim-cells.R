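#' Configuration for the single-cell generator
#'
#' Builds the full parameter set consumed by [gen_cells()]. The defaults
#' emulate an E12.5 limb-bud mesenchyme experiment with four
#' genotype/tissue conditions (wildtype fore- and hindlimb, enhancer-deleted
#' hindlimb, knockout hindlimb) and nine mesenchymal clusters split along
#' the proximo-distal axis. Per-(condition, cluster) class weights place
#' roughly 21% / 40% / 39% of wildtype hindlimb cells in the non/low,
#' intermediate and high expression classes, with the enhancer deletion
#' inflating the non/low fraction preferentially in the proximal ICT and
#' PPP clusters (3.5x and 2x).
#'
#' Expression is generated on the natural-log `log(1 + x)` normalized scale
#' as a three-component mixture per cell class:
#' * non/low: a point mass at 0 (probability `nonlow_q_zero`) plus a
#'   uniform tail on `(0, nonlow_max]`;
#' * intermediate: a normal truncated to `(t_low, t_high]`;
#' * high: a normal truncated to `(t_high, high_upper]`.
#' Component locations sit away from the 0.3 / 1.45 class boundaries so
#' that reconstructing integer UMI counts (and re-normalizing) only rarely
#' moves a cell across a boundary.
#'
#' @param conditions Data frame with columns `genotype`
#'   (`"WT"`, `"PenDel"`, `"KO"`) and `tissue` (`"FL"`, `"HL"`). Default:
#'   WT-FL, WT-HL, PenDel-HL, KO-HL.
#' @param n_per_condition Total cells drawn per condition (split across
#'   clusters by `cluster_shares`).
#' @param clusters Data frame with columns `cluster`, `axis`
#'   (`"proximal"`, `"distal"`, or `NA`).
#' @param cluster_shares Named list (by condition label `"genotype-tissue"`)
#'   of numeric vectors of per-cluster population shares summing to 1.
#' @param class_weights Named list (by condition label) of 3-column matrices
#'   (`nonlow`, `intermediate`, `high`), one row per cluster, rows on the
#'   simplex.
#' @param on_components List with elements `intermediate` and `high`, each
#'   `list(mean=, sd=)` on the log1p scale, plus `high_upper` truncation.
#' @param nonlow_q_zero Probability of an exact zero within the non/low
#'   class.
#' @param nonlow_max Upper end of the non/low uniform tail (must be
#'   `<= t_low`).
#' @param t_low,t_high Class boundaries on the log1p scale used to place
#'   the components (defaults 0.3 and 1.45).
#' @param library_size `list(meanlog=, sdlog=)` for log-normal total UMI
#'   counts (default median 1e4).
#' @param scale Normalization scale factor the downstream pipeline will use
#'   (counts are reconstructed against it), default 1e4.
#' @param qc List of parameters for detected-gene counts and mitochondrial
#'   fractions (see Details in the package vignette).
#' @param seed Integer seed; required.
#' @return A list of class `cell_sim_config`.
#' @seealso [gen_cells()]
#' @export
cell_sim_config <- function(conditions = NULL,
                            n_per_condition = 2000L,
                            clusters = NULL,
                            cluster_shares = NULL,
                            class_weights = NULL,
                            on_components = list(
                              intermediate = list(mean = 1.0, sd = 0.22),
                              high = list(mean = 2.3, sd = 0.5),
                              high_upper = 6
                            ),
                            nonlow_q_zero = 0.8,
                            nonlow_max = 0.2,
                            t_low = 0.3,
                            t_high = 1.45,
                            library_size = list(meanlog = log(1e4), sdlog = 0.3),
                            scale = 1e4,
                            qc = list(genes_meanlog = log(3000),
                                      genes_sdlog = 0.25,
                                      low_quality_frac = 0.02,
                                      mito_shape1 = 2.5,
                                      mito_shape2 = 45,
                                      blood_frac = 0.02),
                            seed = NULL) {
  if (is.null(conditions)) {
    conditions <- data.frame(
      genotype = c("WT", "WT", "PenDel", "KO"),
      tissue   = c("FL", "HL", "HL", "HL"),
      stringsAsFactors = FALSE
    )
  }
  if (is.null(clusters)) clusters <- default_clusters()
  cond_labels <- paste(conditions$genotype, conditions$tissue, sep = "-")
  if (anyDuplicated(cond_labels)) stop("duplicated conditions")
  if (!all(conditions$genotype %in% c("WT", "PenDel", "KO"))) {
    stop("genotype must be one of WT, PenDel, KO")
  }
  if (!all(conditions$tissue %in% c("FL", "HL"))) {
    stop("tissue must be FL or HL")
  }
  if (is.null(cluster_shares)) {
    cluster_shares <- lapply(cond_labels, default_cluster_shares,
                             clusters = clusters)
    names(cluster_shares) <- cond_labels
  }
  if (is.null(class_weights)) {
    class_weights <- lapply(cond_labels, default_class_weights,
                            clusters = clusters)
    names(class_weights) <- cond_labels
  }
  if (is.null(seed)) stop("`seed` is required for reproducible generation")
  seed <- as.integer(seed)
  n_per_condition <- as.integer(n_per_condition)
  if (n_per_condition <= 0) stop("n_per_condition must be positive")
  if (nonlow_max > t_low) stop("nonlow_max must not exceed t_low")
  for (lab in cond_labels) {
    w <- class_weights[[lab]]
    if (is.null(w) || nrow(w) != nrow(clusters)) {
      stop("class_weights for ", lab, " must have one row per cluster")
    }
    if (any(w < 0) || any(abs(rowSums(w) - 1) > 1e-8)) {
      stop("class weights for ", lab, " must be non-negative and sum to 1")
    }
    s <- cluster_shares[[lab]]
    if (length(s) != nrow(clusters) || any(s < 0) ||
        abs(sum(s) - 1) > 1e-8) {
      stop("cluster_shares for ", lab, " must be a simplex over clusters")
    }
  }
  structure(list(
    conditions = conditions, condition_labels = cond_labels,
    n_per_condition = n_per_condition, clusters = clusters,
    cluster_shares = cluster_shares, class_weights = class_weights,
    on_components = on_components, nonlow_q_zero = nonlow_q_zero,
    nonlow_max = nonlow_max, t_low = t_low, t_high = t_high,
    library_size = library_size, scale = scale, qc = qc, seed = seed
  ), class = "cell_sim_config")
}

#' Default mesenchymal cluster table
#'
#' Nine limb-bud mesenchymal clusters with their proximo-distal axis call:
#' ICT, TP, PPP, PC proximal; DP, DPP, EDC, LDC distal; Ms unassigned.
#'
#' @return Data frame with columns `cluster` and `axis`.
#' @export
default_clusters <- function() {
  data.frame(
    cluster = c("ICT", "TP", "PPP", "PC", "DP", "DPP", "EDC", "LDC", "Ms"),
    axis = c("proximal", "proximal", "proximal", "proximal",
             "distal", "distal", "distal", "distal", NA),
    stringsAsFactors = FALSE
  )
}

# Population shares per cluster. The enhancer deletion shifts mass from the
# differentiated ICT cluster to its PPP progenitors (delayed
# differentiation); the knockout shifts proximal and distal progenitors up.
default_cluster_shares <- function(label, clusters) {
  base <- c(ICT = 0.14, TP = 0.10, PPP = 0.12, PC = 0.09,
            DP = 0.12, DPP = 0.11, EDC = 0.12, LDC = 0.10, Ms = 0.10)
  s <- switch(label,
    "PenDel-HL" = c(ICT = 0.105, TP = 0.10, PPP = 0.155, PC = 0.09,
                    DP = 0.12, DPP = 0.11, EDC = 0.12, LDC = 0.10, Ms = 0.10),
    "KO-HL" = c(ICT = 0.11, TP = 0.10, PPP = 0.15, PC = 0.07,
                DP = 0.12, DPP = 0.14, EDC = 0.12, LDC = 0.08, Ms = 0.11),
    base
  )
  unname(s[clusters$cluster])
}

# Per-cluster class weights (nonlow, intermediate, high) per condition.
default_class_weights <- function(label, clusters) {
  prox <- clusters$axis %in% "proximal"
  dist <- clusters$axis %in% "distal"
  w <- matrix(NA_real_, nrow(clusters), 3,
              dimnames = list(clusters$cluster,
                              c("nonlow", "intermediate", "high")))
  if (label %in% c("WT-FL", "KO-HL")) {
    # the target gene is silent: forelimbs do not express it and the
    # knockout removes it
    off <- if (label == "WT-FL") c(0.96, 0.03, 0.01) else c(0.97, 0.025, 0.005)
    w[] <- rep(off, each = nrow(clusters))
    return(w)
  }
  if (label == "WT-HL") {
    w[prox, ] <- rep(c(0.13, 0.21, 0.66), each = sum(prox))
    w[dist, ] <- rep(c(0.29, 0.57, 0.14), each = sum(dist))
    w["Ms", ] <- c(0.21, 0.40, 0.39)
    return(w)
  }
  if (label == "PenDel-HL") {
    w[prox, ] <- rep(c(0.20, 0.26, 0.54), each = sum(prox))
    w["ICT", ] <- c(0.455, 0.245, 0.30)
    w["PPP", ] <- c(0.26, 0.24, 0.50)
    w[dist, ] <- rep(c(0.45, 0.43, 0.12), each = sum(dist))
    w["Ms", ] <- c(0.33, 0.37, 0.30)
    return(w)
  }
  stop("no default class weights for condition ", label)
}

# inverse-CDF truncated normal
rtruncnorm <- function(n, mean, sd, lower, upper) {
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  stats::qnorm(pl + stats::runif(n) * (pu - pl), mean, sd)
}

#' Generate a synthetic per-cell table with ground truth
#'
#' Draws, for every (condition, cluster) pair, a latent expression class
#' per cell from the configured class weights, a normalized expression
#' value from that class's component, a log-normal library size, and
#' reconstructs an integer UMI count as
#' `round((exp(v) - 1) * total / scale)` so the downstream pathway
#' (counts -> [log_normalize()] -> [classify_cells()]) is exercised end to
#' end. QC fields (detected genes, mitochondrial fraction) are drawn
#' independently of the class, including small low-quality and blood-like
#' contaminant fractions that the QC filter is meant to remove.
#'
#' @param config A [cell_sim_config()].
#' @return A list with elements
#'   * `cells`: data frame with columns `cell_id`, `genotype`, `tissue`,
#'     `cluster`, `axis`, `n_genes`, `mito_frac`, `target_count`,
#'     `total_count`;
#'   * `truth`: data frame of configured class weights and cell counts per
#'     (condition, cluster).
#' Output is byte-identical under a fixed `config$seed`.
#' @examples
#' res <- gen_cells(cell_sim_config(n_per_condition = 200, seed = 1))
#' head(res$cells)
#' @export
gen_cells <- function(config) {
  if (!inherits(config, "cell_sim_config")) {
    stop("`config` must be a cell_sim_config")
  }
  set.seed(config$seed)
  comp <- config$on_components
  out <- vector("list", length(config$condition_labels) * nrow(config$clusters))
  truth <- out
  k <- 0L
  for (ci in seq_along(config$condition_labels)) {
    lab <- config$condition_labels[ci]
    shares <- config$cluster_shares[[lab]]
    weights <- config$class_weights[[lab]]
    n_cl <- round(shares * config$n_per_condition)
    for (cl in seq_len(nrow(config$clusters))) {
      n <- n_cl[cl]
      if (n <= 0) next
      k <- k + 1L
      w <- weights[cl, ]
      cls <- sample.int(3L, n, replace = TRUE, prob = w)
      v <- numeric(n)
      i_non <- which(cls == 1L)
      if (length(i_non)) {
        zero <- stats::runif(length(i_non)) < config$nonlow_q_zero
        v[i_non] <- ifelse(zero, 0,
                           stats::runif(length(i_non), 0, config$nonlow_max))
      }
      i_int <- which(cls == 2L)
      if (length(i_int)) {
        v[i_int] <- rtruncnorm(length(i_int), comp$intermediate$mean,
                               comp$intermediate$sd, config$t_low,
                               config$t_high)
      }
      i_hi <- which(cls == 3L)
      if (length(i_hi)) {
        v[i_hi] <- rtruncnorm(length(i_hi), comp$high$mean, comp$high$sd,
                              config$t_high, comp$high_upper)
      }
      total <- pmax(500, round(stats::rlnorm(n, config$library_size$meanlog,
                                             config$library_size$sdlog)))
      target <- round(expm1(v) * total / config$scale)
      lowq <- stats::runif(n) < config$qc$low_quality_frac
      n_genes <- ifelse(lowq,
                        sample(50:199, n, replace = TRUE),
                        pmax(200, round(stats::rlnorm(n, config$qc$genes_meanlog,
                                                      config$qc$genes_sdlog))))
      blood <- stats::runif(n) < config$qc$blood_frac
      mito <- ifelse(blood,
                     stats::runif(n, 0, 0.0099),
                     stats::rbeta(n, config$qc$mito_shape1,
                                  config$qc$mito_shape2))
      out[[k]] <- data.frame(
        cell_id = sprintf("%s_%s_%04d", lab, config$clusters$cluster[cl],
                          seq_len(n)),
        genotype = config$conditions$genotype[ci],
        tissue = config$conditions$tissue[ci],
        cluster = config$clusters$cluster[cl],
        axis = config$clusters$axis[cl],
        n_genes = as.integer(n_genes),
        mito_frac = mito,
        target_count = as.integer(target),
        total_count = as.integer(total),
        stringsAsFactors = FALSE
      )
      truth[[k]] <- data.frame(
        condition = lab, cluster = config$clusters$cluster[cl],
        n_cells = n, w_nonlow = w[1], w_intermediate = w[2], w_high = w[3],
        stringsAsFactors = FALSE
      )
    }
  }
  cells <- do.call(rbind, out[seq_len(k)])
  rownames(cells) <- NULL
  truth <- do.call(rbind, truth[seq_len(k)])
  rownames(truth) <- NULL
  list(cells = cells, truth = truth)
}
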