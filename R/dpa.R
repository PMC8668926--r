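#' Cluster label set for one condition
#'
#' @param condition Single condition label.
#' @param clusters Character vector of per-cell cluster labels.
#' @return An object of class `label_set`.
#' @export
label_set <- function(condition, clusters) {
  stopifnot(is.character(condition), length(condition) == 1L)
  clusters <- as.character(clusters)
  if (length(clusters) == 0L) stop("label set must be non-empty")
  structure(list(condition = condition, clusters = clusters),
            class = "label_set")
}

#' Differential proportion analysis between two conditions
#'
#' Permutation test for shifts in cluster composition. The observed
#' statistic per cluster is the difference of within-condition proportions
#' (second argument minus first). The null is built by redrawing, each
#' iteration, a full label multiset for every condition from the mixture
#' `p_mix * own-condition proportions + (1 - p_mix) * pooled proportions`
#' (multinomial of the condition's size), and recomputing the statistic.
#' The two-sided empirical p-value uses add-one smoothing,
#' `(1 + #\{|null| >= |obs|\}) / (n_perm + 1)`, so it is never exactly 0.
#'
#' Internally the two conditions are processed in a canonical
#' (alphabetical) order so that swapping the arguments under the same seed
#' negates every statistic and leaves all p-values unchanged.
#'
#' @param a,b [label_set()] objects with distinct condition labels.
#' @param n_perm Number of permutations (study setting 100,000; reduce for
#'   quick runs).
#' @param p_mix Mixing proportion retained from each condition's own label
#'   distribution, in `(0, 1]` (study setting 0.1).
#' @param seed Integer seed (required; the test is deterministic given it).
#' @return Data frame of class `dpa_result` with one row per cluster:
#'   `cluster`, `n_a`, `n_b`, `prop_a`, `prop_b`, `statistic`
#'   (`prop_b - prop_a`), `p_value`. Settings are attached as the
#'   `settings` attribute.
#' @export
dpa_test <- function(a, b, n_perm = 1e5, p_mix = 0.1, seed = NULL) {
  stopifnot(inherits(a, "label_set"), inherits(b, "label_set"))
  if (identical(a$condition, b$condition)) {
    stop("the two label sets must carry distinct condition labels")
  }
  n_perm <- as.integer(n_perm)
  if (is.na(n_perm) || n_perm < 1L) stop("n_perm must be >= 1")
  if (!(p_mix > 0 && p_mix <= 1)) stop("p_mix must be in (0, 1]")
  if (is.null(seed)) stop("`seed` is required")

  flipped <- a$condition > b$condition
  first <- if (flipped) b else a
  second <- if (flipped) a else b

  vocab <- sort(unique(c(first$clusters, second$clusters)))
  c1 <- table(factor(first$clusters, levels = vocab))
  c2 <- table(factor(second$clusters, levels = vocab))
  n1 <- sum(c1); n2 <- sum(c2)
  p1 <- as.numeric(c1) / n1
  p2 <- as.numeric(c2) / n2
  pooled <- as.numeric(c1 + c2) / (n1 + n2)

  set.seed(as.integer(seed))
  mix1 <- p_mix * p1 + (1 - p_mix) * pooled
  mix2 <- p_mix * p2 + (1 - p_mix) * pooled
  null1 <- stats::rmultinom(n_perm, n1, mix1) / n1
  null2 <- stats::rmultinom(n_perm, n2, mix2) / n2
  null_stat <- null2 - null1
  obs <- p2 - p1
  p_val <- (1 + rowSums(abs(null_stat) >= abs(obs))) / (n_perm + 1)

  sign_flip <- if (flipped) -1 else 1
  out <- data.frame(
    cluster = vocab,
    n_a = if (flipped) as.integer(c2) else as.integer(c1),
    n_b = if (flipped) as.integer(c1) else as.integer(c2),
    prop_a = if (flipped) p2 else p1,
    prop_b = if (flipped) p1 else p2,
    statistic = sign_flip * obs,
    p_value = p_val,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "settings") <- list(
    condition_a = a$condition, condition_b = b$condition,
    n_perm = n_perm, p_mix = p_mix, seed = as.integer(seed)
  )
  class(out) <- c("dpa_result", class(out))
  out
}

#' Pairwise differential proportion analysis
#'
#' Runs [dpa_test()] on every unordered pair of conditions, deriving the
#' pair seed as `seed + pair index` (pairs enumerated in `combn` order), so
#' each pair's result is reproducible in isolation.
#'
#' @param conditions List of [label_set()] objects (>= 2, distinct labels).
#' @param n_perm,p_mix,seed As in [dpa_test()].
#' @return Named list of `dpa_result` objects, names `"A_vs_B"`.
#' @export
pairwise_dpa <- function(conditions, n_perm = 1e5, p_mix = 0.1,
                         seed = NULL) {
  if (length(conditions) < 2L) stop("need at least two conditions")
  labels <- vapply(conditions, function(x) x$condition, character(1))
  if (anyDuplicated(labels)) stop("duplicate condition labels")
  if (is.null(seed)) stop("`seed` is required")
  idx <- utils::combn(length(conditions), 2)
  out <- vector("list", ncol(idx))
  nm <- character(ncol(idx))
  for (k in seq_len(ncol(idx))) {
    i <- idx[1, k]; j <- idx[2, k]
    out[[k]] <- dpa_test(conditions[[i]], conditions[[j]], n_perm = n_perm,
                         p_mix = p_mix, seed = as.integer(seed) + k)
    nm[k] <- paste(labels[i], labels[j], sep = "_vs_")
  }
  names(out) <- nm
  out
}

#' Write a DPA result as TSV with a settings header line
#'
#' @param x A `dpa_result` from [dpa_test()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dpa_result <- function(x, path) {
  s <- attr(x, "settings")
  hdr <- sprintf("# dpa %s vs %s: n_perm=%d p_mix=%g seed=%d",
                 s$condition_a, s$condition_b, s$n_perm, s$p_mix, s$seed)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
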