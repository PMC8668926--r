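#' Virtual 4C profile from contact pairs
#'
#' Counts, for one viewpoint, every pair with exactly one mate inside the
#' viewpoint (pairs with both mates inside contribute nothing), assigns
#' the outside mate to a fine raw bin, and smooths by averaging the raw
#' bin counts within consecutive `interval_size` windows -- the two-scale
#' count-then-average structure of fragment-based virtual 4C, with a fixed
#' raw bin standing in for restriction fragments.
#'
#' @param pairs A [contact_pairs()] object.
#' @param viewpoint A [genomic_interval()] inside the pair region; the
#'   shipped promoter preset is `region_preset("pitx1-promoter-mm9")`.
#' @param raw_bin Raw counting resolution in bp (default 1000).
#' @param interval_size Smoothing window in bp (default 5000); must be a
#'   multiple of `raw_bin`.
#' @param normalize `"none"` (raw counts, default) or `"per_million"`
#'   (counts per million qualifying pairs).
#' @return An object of class `v4c_profile` with one value per
#'   `interval_size` window over the region, the per-raw-bin counts
#'   (`raw_counts`), the number of qualifying pairs (`n_qualifying`) and a
#'   flag per interval marking overlap with the viewpoint
#'   (`viewpoint_overlap`).
#' @export
virtual_4c <- function(pairs, viewpoint, raw_bin = 1000,
                       interval_size = 5000,
                       normalize = c("none", "per_million")) {
  stopifnot(inherits(pairs, "contact_pairs"),
            inherits(viewpoint, "genomic_interval"))
  normalize <- match.arg(normalize)
  region <- pairs$region
  if (!gi_within(viewpoint, region)) stop("viewpoint outside region")
  if (interval_size %% raw_bin != 0) {
    stop("interval_size must be a multiple of raw_bin")
  }
  in_a <- gi_contains(viewpoint, pairs$pos_a)
  in_b <- gi_contains(viewpoint, pairs$pos_b)
  qual <- xor(in_a, in_b)
  outside <- ifelse(in_a, pairs$pos_b, pairs$pos_a)[qual]
  nraw <- n_bins(region, raw_bin)
  raw_counts <- tabulate(pos_to_bin(outside, region, raw_bin) + 1L,
                         nbins = nraw)
  n_int <- n_bins(region, interval_size)
  ratio <- interval_size / raw_bin
  grp <- rep(seq_len(n_int), each = ratio)[seq_len(nraw)]
  values <- as.numeric(tapply(raw_counts, grp, mean))
  n_qual <- sum(qual)
  if (normalize == "per_million") {
    if (n_qual == 0L) stop("no qualifying pairs to normalize by")
    values <- values * 1e6 / n_qual
  }
  starts <- region$start + (seq_len(n_int) - 1) * interval_size
  ends <- pmin(starts + interval_size - 1, region$end)
  overlap <- starts <= viewpoint$end & ends >= viewpoint$start
  structure(list(viewpoint = viewpoint, region = region,
                 interval_size = interval_size, raw_bin = raw_bin,
                 values = values, viewpoint_overlap = overlap,
                 n_qualifying = n_qual, raw_counts = raw_counts,
                 normalize = normalize),
            class = "v4c_profile")
}

#' @export
print.v4c_profile <- function(x, ...) {
  cat("<v4c_profile> viewpoint ", format(x$viewpoint), " over ",
      format(x$region), "; ", length(x$values), " x ", x$interval_size,
      " bp intervals, ", x$n_qualifying, " qualifying pairs\n", sep = "")
  invisible(x)
}

#' Subtraction of two virtual 4C profiles
#'
#' Elementwise `a - b`; requires identical viewpoint, region and interval
#' geometry.
#'
#' @param a,b [virtual_4c()] profiles.
#' @return A signed `v4c_profile` (raw counts and qualifying-pair count
#'   dropped).
#' @export
profile_subtract <- function(a, b) {
  stopifnot(inherits(a, "v4c_profile"), inherits(b, "v4c_profile"))
  if (!gi_identical(a$viewpoint, b$viewpoint) ||
      !gi_identical(a$region, b$region) ||
      a$interval_size != b$interval_size || a$raw_bin != b$raw_bin) {
    stop("profiles differ in viewpoint or interval geometry")
  }
  structure(list(viewpoint = a$viewpoint, region = a$region,
                 interval_size = a$interval_size, raw_bin = a$raw_bin,
                 values = a$values - b$values,
                 viewpoint_overlap = a$viewpoint_overlap,
                 n_qualifying = NA_integer_, raw_counts = NULL,
                 normalize = a$normalize),
            class = "v4c_profile")
}

#' Write a virtual 4C profile as bedGraph
#'
#' bedGraph uses 0-based half-open intervals; the conversion from the
#' internal 1-based inclusive coordinates is exact (`start - 1`, `end`).
#'
#' @param profile A [virtual_4c()] profile.
#' @param path Output file.
#' @param track_name Optional name for a `track` header line.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(profile, path, track_name = NULL) {
  stopifnot(inherits(profile, "v4c_profile"))
  n <- length(profile$values)
  starts0 <- profile$region$start - 1 + (seq_len(n) - 1) * profile$interval_size
  ends <- pmin(starts0 + profile$interval_size, profile$region$end)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(track_name)) {
    writeLines(sprintf('track type=bedGraph name="%s"', track_name), con)
  }
  writeLines(sprintf("%s\t%d\t%d\t%g", profile$region$chrom,
                     as.integer(starts0), as.integer(ends),
                     profile$values), con)
  invisible(path)
}
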