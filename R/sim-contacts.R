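#' Configuration for the contact-pair generator
#'
#' Parameters for [gen_contacts()], which emulates capture Hi-C mate pairs
#' over one genomic region: genomic distances follow a truncated power law
#' (the standard Hi-C distance decay) and selected anchor pairs ("loops",
#' e.g. a promoter-enhancer contact) are over-sampled by an enrichment
#' factor.
#'
#' @param region A [genomic_interval()] the pairs live in.
#' @param n_pairs Number of mate pairs to draw (`>= 0`).
#' @param decay_exponent Power-law exponent of the distance decay
#'   (default -1, i.e. density proportional to 1/distance).
#' @param min_dist Minimum pair separation in bp (default 20000; shorter
#'   products are dominated by self-ligation artefacts and are filtered
#'   out upstream in real pipelines).
#' @param loops List of loops, each
#'   `list(anchor_a = <genomic_interval>, anchor_b = <genomic_interval>,
#'   enrichment = <factor >= 1>)`. Anchors must lie within `region`.
#' @param condition_tag Free-text label carried through to the output.
#' @param seed Integer seed; required.
#' @return A list of class `contact_sim_config`.
#' @export
contact_sim_config <- function(region, n_pairs, decay_exponent = -1,
                               min_dist = 20000, loops = list(),
                               condition_tag = "synthetic", seed = NULL) {
  stopifnot(inherits(region, "genomic_interval"))
  n_pairs <- as.integer(n_pairs)
  if (is.na(n_pairs) || n_pairs < 0) stop("n_pairs must be >= 0")
  if (decay_exponent >= 0) stop("decay_exponent must be negative")
  if (min_dist <= 0 || min_dist >= gi_length(region)) {
    stop("min_dist must be in (0, region length)")
  }
  for (lp in loops) {
    if (!gi_within(lp$anchor_a, region) || !gi_within(lp$anchor_b, region)) {
      stop("loop anchors must lie within the region")
    }
    if (is.null(lp$enrichment) || lp$enrichment < 1) {
      stop("loop enrichment must be >= 1")
    }
  }
  if (is.null(seed)) stop("`seed` is required for reproducible generation")
  structure(list(region = region, n_pairs = n_pairs,
                 decay_exponent = decay_exponent, min_dist = min_dist,
                 loops = loops, condition_tag = condition_tag,
                 seed = as.integer(seed)),
            class = "contact_sim_config")
}

# inverse-CDF sampler for a power law f(d) ~ d^decay on [dmin, dmax]
rpowerlaw <- function(n, decay, dmin, dmax) {
  u <- stats::runif(n)
  a <- -decay
  if (abs(a - 1) < 1e-12) {
    dmin * (dmax / dmin)^u
  } else {
    (dmin^(1 - a) + u * (dmax^(1 - a) - dmin^(1 - a)))^(1 / (1 - a))
  }
}

pair_in_loop <- function(pos_a, pos_b, loop) {
  (gi_contains(loop$anchor_a, pos_a) & gi_contains(loop$anchor_b, pos_b)) |
    (gi_contains(loop$anchor_a, pos_b) & gi_contains(loop$anchor_b, pos_a))
}

#' Generate synthetic contact mate pairs with ground truth
#'
#' Pairs are drawn by rejection sampling: one mate uniform in the region, a
#' separation from the configured power-law decay, a random direction, and
#' acceptance weight proportional to the largest loop enrichment the pair
#' hits (1 outside all loops). Because out-of-region proposals are
#' rejected, the realized distance density is proportional to
#' `f(d) * (L - d)` for region length `L` -- the usual finite-window edge
#' effect, which the goodness-of-fit oracle in the test-suite integrates
#' explicitly.
#'
#' @param config A [contact_sim_config()].
#' @return A list with elements
#'   * `pairs`: a `contact_pairs` object (see [contact_pairs()]);
#'   * `truth`: list with the configured loops and decay.
#' Deterministic under a fixed `config$seed`.
#' @export
gen_contacts <- function(config) {
  if (!inherits(config, "contact_sim_config")) {
    stop("`config` must be a contact_sim_config")
  }
  set.seed(config$seed)
  region <- config$region
  L <- gi_length(region)
  n_target <- config$n_pairs
  max_enr <- max(c(1, vapply(config$loops, function(lp) lp$enrichment,
                             numeric(1))))
  pos_a <- numeric(0)
  pos_b <- numeric(0)
  guard <- 0L
  while (length(pos_a) < n_target) {
    guard <- guard + 1L
    if (guard > 1000L) stop("contact sampler failed to accumulate pairs")
    need <- n_target - length(pos_a)
    m <- ceiling(need * max_enr * 1.3) + 100L
    a <- region$start + stats::runif(m) * (L - 1)
    d <- rpowerlaw(m, config$decay_exponent, config$min_dist, L - 1)
    s <- sample(c(-1, 1), m, replace = TRUE)
    b <- a + s * d
    keep <- b >= region$start & b <= region$end
    w <- rep(1, m)
    for (lp in config$loops) {
      hit <- pair_in_loop(a, b, lp)
      w[hit] <- pmax(w[hit], lp$enrichment)
    }
    keep <- keep & stats::runif(m) < w / max_enr
    pos_a <- c(pos_a, a[keep])
    pos_b <- c(pos_b, b[keep])
  }
  pos_a <- round(pos_a[seq_len(n_target)])
  pos_b <- round(pos_b[seq_len(n_target)])
  pos_a <- pmin(pmax(pos_a, region$start), region$end)
  pos_b <- pmin(pmax(pos_b, region$start), region$end)
  list(
    pairs = contact_pairs(region, pos_a, pos_b,
                          condition_tag = config$condition_tag),
    truth = list(loops = config$loops,
                 decay_exponent = config$decay_exponent,
                 min_dist = config$min_dist)
  )
}
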