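#' Construct a density curve
#'
#' Container for a gridded probability density of normalized expression.
#' Used both for KDE output ([estimate_density()]) and for analytically
#' tabulated densities.
#'
#' @param grid Strictly increasing numeric grid.
#' @param density Non-negative densities, same length as `grid`; the
#'   trapezoidal integral over the grid must lie in `[0.98, 1.02]`.
#' @param bandwidth Kernel bandwidth (NA for analytic curves).
#' @param n_cells Number of observations behind the curve (NA if analytic).
#' @return An object of class `density_curve`.
#' @export
density_curve <- function(grid, density, bandwidth = NA_real_,
                          n_cells = NA_integer_) {
  grid <- as.numeric(grid)
  density <- as.numeric(density)
  if (length(grid) != length(density) || length(grid) < 2L) {
    stop("grid and density must have equal length >= 2")
  }
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  if (any(density < 0)) stop("density must be non-negative")
  integral <- trapz(grid, density)
  if (integral < 0.98 || integral > 1.02) {
    stop(sprintf("density integrates to %.4f, outside [0.98, 1.02]",
                 integral))
  }
  structure(list(grid = grid, density = density, bandwidth = bandwidth,
                 n_cells = n_cells),
            class = "density_curve")
}

trapz <- function(x, y) sum(diff(x) * (head2(y) + tail2(y)) / 2)
head2 <- function(y) y[-length(y)]
tail2 <- function(y) y[-1]

#' Gaussian kernel density estimate on an even grid
#'
#' Evaluates the exact kernel sum
#' `f(g) = (1 / (n * bw)) * sum_i phi((g - v_i) / bw)` at every grid point
#' by direct summation (no FFT binning approximation), on an even grid
#' spanning `[min(values) - 3 bw, max(values) + 3 bw]`.
#'
#' @param values Numeric vector of at least 2 finite observations.
#' @param bandwidth Either `"auto"` (Silverman's rule-of-thumb,
#'   `stats::bw.nrd0`) or a positive number.
#' @param n_grid Number of grid points (default 512).
#' @return A [density_curve()].
#' @export
estimate_density <- function(values, bandwidth = "auto", n_grid = 512L) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least two values")
  if (any(!is.finite(values))) stop("values must be finite")
  if (identical(bandwidth, "auto")) {
    if (stats::sd(values) == 0) {
      stop("zero variance: automatic bandwidth undefined, supply one")
    }
    bw <- stats::bw.nrd0(values)
  } else {
    bw <- as.numeric(bandwidth)
    if (!is.finite(bw) || bw <= 0) stop("bandwidth must be positive")
  }
  n_grid <- as.integer(n_grid)
  grid <- seq(min(values) - 3 * bw, max(values) + 3 * bw,
              length.out = n_grid)
  dens <- numeric(n_grid)
  # chunk the grid so the (chunk x n) kernel matrix stays small
  n <- length(values)
  chunk <- max(1L, as.integer(floor(5e6 / n)))
  for (s in seq(1L, n_grid, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n_grid)
    dens[idx] <- rowMeans(stats::dnorm(outer(grid[idx], values, "-") / bw)) / bw
  }
  density_curve(grid, dens, bandwidth = bw, n_cells = n)
}

#' First crossing point of two density curves
#'
#' Re-interpolates `b` onto `a`'s grid (linear), forms the difference
#' `d(x) = a(x) - b(x)` and returns the smallest `x` in the open search
#' window where `d` changes sign, located by linear interpolation between
#' the bracketing grid points. All crossings found are attached as the
#' `crossings` attribute. Two identical curves (`d` identically zero) have
#' no crossing and raise an error.
#'
#' @param a,b [density_curve()] objects.
#' @param search Numeric `c(lo, hi)` search window; defaults to the full
#'   overlap of the two grids.
#' @return The smallest crossing (numeric scalar) with attribute
#'   `crossings` holding all of them.
#' @export
find_intersection <- function(a, b, search = NULL) {
  stopifnot(inherits(a, "density_curve"), inherits(b, "density_curve"))
  g <- a$grid
  by <- stats::approx(b$grid, b$density, xout = g)$y
  ok <- !is.na(by)
  g <- g[ok]
  d <- a$density[ok] - by[ok]
  if (length(g) < 2L) stop("density grids do not overlap")
  if (is.null(search)) search <- range(g)
  lo <- search[1]; hi <- search[2]
  if (!(lo < hi)) stop("search window must satisfy lo < hi")
  inside <- g > lo & g < hi
  if (sum(inside) < 2L) stop("search window contains fewer than two grid points")
  g <- g[inside]; d <- d[inside]
  crossings <- numeric(0)
  for (i in seq_len(length(g) - 1L)) {
    if (d[i] == 0 && i > 1L && d[i - 1L] * d[i + 1L] < 0) {
      crossings <- c(crossings, g[i])
    } else if (d[i] * d[i + 1L] < 0) {
      x <- g[i] + (g[i + 1L] - g[i]) * d[i] / (d[i] - d[i + 1L])
      crossings <- c(crossings, x)
    }
  }
  crossings <- sort(unique(crossings))
  if (length(crossings) == 0L) {
    stop("no intersection of the two densities in the search window")
  }
  structure(crossings[1], crossings = crossings)
}
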