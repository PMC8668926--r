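#' Genomic interval (1-based, inclusive)
#'
#' A minimal record for a genomic interval in the 1-based, fully inclusive
#' convention used by genome browsers and by capture Hi-C probe designs.
#' Internal bin indices are 0-based half-open; see [pos_to_bin()] and
#' [bin_to_interval()] for the exact converters.
#'
#' @param chrom Chromosome name, e.g. `"chr13"`.
#' @param start,end 1-based inclusive coordinates, `1 <= start <= end`.
#' @return An object of class `genomic_interval`.
#' @examples
#' gi <- genomic_interval("chr13", 54000001, 57300000)
#' gi_length(gi)
#' @export
genomic_interval <- function(chrom, start, end) {
  if (!is.character(chrom) || length(chrom) != 1L || is.na(chrom)) {
    stop("`chrom` must be a single chromosome name")
  }
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(start) != 1L || length(end) != 1L || !is.finite(start) ||
      !is.finite(end) || start < 1 || end < start) {
    stop("invalid interval: need 1 <= start <= end")
  }
  structure(list(chrom = chrom, start = start, end = end),
            class = "genomic_interval")
}

#' @export
format.genomic_interval <- function(x, ...) {
  sprintf("%s:%s-%s", x$chrom, format(x$start, big.mark = ",", scientific = FALSE),
          format(x$end, big.mark = ",", scientific = FALSE))
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat("<genomic_interval> ", format(x), "  (", format(gi_length(x),
      big.mark = ","), " bp)\n", sep = "")
  invisible(x)
}

#' Length of a genomic interval in bp
#' @param x A [genomic_interval()].
#' @return Numeric length `end - start + 1`.
#' @export
gi_length <- function(x) x$end - x$start + 1

#' Does an interval contain the given positions?
#' @param x A [genomic_interval()].
#' @param pos Numeric vector of 1-based positions.
#' @return Logical vector.
#' @export
gi_contains <- function(x, pos) pos >= x$start & pos <= x$end

#' Is `inner` fully inside `outer`?
#' @param inner,outer [genomic_interval()] objects.
#' @return Single logical.
#' @export
gi_within <- function(inner, outer) {
  identical(inner$chrom, outer$chrom) &&
    inner$start >= outer$start && inner$end <= outer$end
}

gi_identical <- function(a, b) {
  identical(a$chrom, b$chrom) && a$start == b$start && a$end == b$end
}

gi_overlaps <- function(a, b) {
  identical(a$chrom, b$chrom) && a$start <= b$end && b$start <= a$end
}

#' Parse a "chrom:start-end" region string
#'
#' Accepts commas in the coordinates. Coordinates are taken as 1-based
#' inclusive.
#'
#' @param s A single string such as `"chr13:54,000,001-57,300,000"`.
#' @return A [genomic_interval()].
#' @export
parse_region <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  m <- regmatches(s, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", s))[[1]]
  if (length(m) != 4L) stop("cannot parse region string: ", s)
  num <- function(z) as.numeric(gsub(",", "", z))
  genomic_interval(m[2], num(m[3]), num(m[4]))
}

#' Named region presets
#'
#' Shipped coordinate presets (mm9 assembly):
#' * `"pitx1-mm9"`: the captured region around the locus,
#'   chr13:54,000,001-57,300,000.
#' * `"pitx1-promoter-mm9"`: the 10 kb promoter viewpoint,
#'   chr13:55,930,001-55,940,000.
#'
#' @param name Preset name.
#' @return A [genomic_interval()].
#' @export
region_preset <- function(name = c("pitx1-mm9", "pitx1-promoter-mm9")) {
  name <- match.arg(name)
  switch(name,
    "pitx1-mm9" = genomic_interval("chr13", 54000001, 57300000),
    "pitx1-promoter-mm9" = genomic_interval("chr13", 55930001, 55940000)
  )
}

#' Convert 1-based positions to 0-based bin indices
#'
#' Bin 0 starts at `region$start`; a position `p` falls in bin
#' `floor((p - start) / bin_size)`. The first position of the region maps to
#' bin 0 exactly.
#'
#' @param pos Numeric vector of 1-based positions inside `region`.
#' @param region A [genomic_interval()].
#' @param bin_size Bin width in bp.
#' @return Integer vector of 0-based bin indices.
#' @export
pos_to_bin <- function(pos, region, bin_size) {
  if (any(pos < region$start | pos > region$end)) {
    bad <- which(pos < region$start | pos > region$end)[1]
    stop("position outside region at index ", bad)
  }
  as.integer(floor((pos - region$start) / bin_size))
}

#' Genomic interval covered by a 0-based bin
#'
#' Inverse of [pos_to_bin()]; the last bin is clipped at the region end.
#'
#' @param bin 0-based bin index (single value).
#' @param region A [genomic_interval()].
#' @param bin_size Bin width in bp.
#' @return A [genomic_interval()].
#' @export
bin_to_interval <- function(bin, region, bin_size) {
  stopifnot(length(bin) == 1L, bin >= 0)
  s <- region$start + bin * bin_size
  genomic_interval(region$chrom, s, min(s + bin_size - 1, region$end))
}

#' Number of bins tiling a region
#' @param region A [genomic_interval()].
#' @param bin_size Bin width in bp.
#' @return Integer bin count, `ceiling(length / bin_size)`.
#' @export
n_bins <- function(region, bin_size) as.integer(ceiling(gi_length(region) / bin_size))
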