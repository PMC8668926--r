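#' Contact mate pairs over one region
#'
#' @param region A [genomic_interval()].
#' @param pos_a,pos_b Numeric vectors of 1-based mate positions, both
#'   within `region`.
#' @param condition_tag Optional free-text label.
#' @return An object of class `contact_pairs`.
#' @export
contact_pairs <- function(region, pos_a, pos_b, condition_tag = NULL) {
  stopifnot(inherits(region, "genomic_interval"))
  if (length(pos_a) != length(pos_b)) stop("mate vectors differ in length")
  out_a <- which(!gi_contains(region, pos_a))
  out_b <- which(!gi_contains(region, pos_b))
  if (length(out_a) || length(out_b)) {
    stop("pair position outside region at index ",
         min(c(out_a, out_b)))
  }
  structure(list(region = region, pos_a = as.numeric(pos_a),
                 pos_b = as.numeric(pos_b),
                 condition_tag = condition_tag),
            class = "contact_pairs")
}

#' @export
print.contact_pairs <- function(x, ...) {
  cat("<contact_pairs> ", length(x$pos_a), " pairs in ", format(x$region),
      if (!is.null(x$condition_tag)) paste0(" [", x$condition_tag, "]"),
      "\n", sep = "")
  invisible(x)
}

new_contact_matrix <- function(region, bin_size, M, mask,
                               normalized = FALSE, bias = NULL,
                               scaled = FALSE, signed = FALSE) {
  nb <- n_bins(region, bin_size)
  stopifnot(nrow(M) == nb, ncol(M) == nb, length(mask) == nb)
  if (max(abs(M - t(M))) > 1e-9) stop("contact matrix must be symmetric")
  if (!signed && any(M < 0)) stop("contact matrix must be non-negative")
  structure(list(region = region, bin_size = bin_size, M = M, mask = mask,
                 normalized = normalized, bias = bias, scaled = scaled,
                 signed = signed),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat("<contact_matrix> ", format(x$region), " @ ", x$bin_size, " bp (",
      nrow(x$M), " bins, ", sum(!x$mask), " masked)",
      if (x$normalized) " balanced", if (x$scaled) " subdiag-scaled",
      if (x$signed) " signed", "\n", sep = "")
  invisible(x)
}

same_geometry <- function(a, b) {
  gi_identical(a$region, b$region) && a$bin_size == b$bin_size &&
    identical(a$mask, b$mask)
}

#' Bin contact pairs into a symmetric contact matrix
#'
#' Each pair increments `M[i, j]` and `M[j, i]` for the bins holding its
#' two mates (`i != j`); pairs with both mates in one bin increment the
#' diagonal once. The upper-triangle mass (including the diagonal) equals
#' the pair count.
#'
#' @param pairs A [contact_pairs()] object.
#' @param bin_size Bin width in bp (e.g. 5000).
#' @return A `contact_matrix` (raw counts, nothing masked).
#' @export
bin_pairs <- function(pairs, bin_size) {
  stopifnot(inherits(pairs, "contact_pairs"))
  region <- pairs$region
  nb <- n_bins(region, bin_size)
  i <- pos_to_bin(pairs$pos_a, region, bin_size) + 1L
  j <- pos_to_bin(pairs$pos_b, region, bin_size) + 1L
  M <- matrix(0, nb, nb)
  if (length(i)) {
    lo <- pmin(i, j); hi <- pmax(i, j)
    key <- (lo - 1L) * nb + hi
    tt <- tabulate(key, nbins = nb * nb)
    nz <- which(tt > 0L)
    lo_nz <- (nz - 1L) %/% nb + 1L
    hi_nz <- (nz - 1L) %% nb + 1L
    M[cbind(lo_nz, hi_nz)] <- tt[nz]
    M[cbind(hi_nz, lo_nz)] <- tt[nz]
  }
  new_contact_matrix(region, bin_size, M, mask = rep(TRUE, nb))
}

# Knight-Ruiz balancing of a symmetric non-negative matrix with strictly
# positive marginals: inner-outer Newton iteration with a CG inner solve.
# Returns x with rowSums(diag(x) %*% A %*% diag(x)) == 1.
kr_bias_vector <- function(A, tol = 1e-8, max_iter = 100L, delta = 0.1,
                           Delta = 3) {
  n <- nrow(A)
  e <- rep(1, n)
  x <- e
  rt <- tol^2
  v <- x * as.vector(A %*% x)
  rk <- 1 - v
  rho_km1 <- sum(rk * rk)
  rho_km2 <- rho_km1
  rout <- rho_km1
  rold <- rout
  g <- 0.9; etamax <- 0.1; eta <- etamax
  stop_tol <- tol * 0.5
  outer_it <- 0L
  while (rout > rt) {
    outer_it <- outer_it + 1L
    if (outer_it > max_iter) {
      stop("Knight-Ruiz balancing did not converge in ", max_iter,
           " outer iterations (residual ", signif(sqrt(rout), 3), ")")
    }
    k <- 0L
    y <- e
    innertol <- max(eta^2 * rout, rt)
    while (rho_km1 > innertol) {
      k <- k + 1L
      if (k == 1L) {
        Z <- rk / v
        p <- Z
        rho_km1 <- sum(rk * Z)
      } else {
        beta <- rho_km1 / rho_km2
        p <- Z + beta * p
      }
      w <- x * as.vector(A %*% (x * p)) + v * p
      alpha <- rho_km1 / sum(p * w)
      ap <- alpha * p
      ynew <- y + ap
      if (min(ynew) <= delta) {
        if (delta == 0) break
        ind <- which(ap < 0)
        gamma <- min((delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      if (max(ynew) >= Delta) {
        ind <- which(ynew > Delta)
        gamma <- min((Delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      y <- ynew
      rk <- rk - alpha * w
      rho_km2 <- rho_km1
      Z <- rk / v
      rho_km1 <- sum(rk * Z)
      if (k > 500L) break
    }
    x <- x * y
    v <- x * as.vector(A %*% x)
    rk <- 1 - v
    rho_km1 <- sum(rk * rk)
    rout <- rho_km1
    rat <- rout / rold
    rold <- rout
    res_norm <- sqrt(rout)
    eta_o <- eta
    eta <- g * rat
    if (g * eta_o^2 > 0.1) eta <- max(eta, g * eta_o^2)
    eta <- max(min(eta, etamax), stop_tol / res_norm)
  }
  attr(x, "iterations") <- outer_it
  attr(x, "residual") <- sqrt(rout)
  x
}

#' Knight-Ruiz balancing of a contact matrix
#'
#' Computes a per-bin bias vector `b` such that the balanced matrix
#' `N[i, j] = M[i, j] * b[i] * b[j]` has equal row sums on all unmasked
#' bins; the common row sum is fixed by preserving the total unmasked
#' mass of `M`. Bins with a zero marginal are masked before balancing and
#' re-inserted as zero rows with an `NA` bias. Non-convergence raises an
#' error rather than returning a partial result.
#'
#' @param m A `contact_matrix` of raw counts.
#' @param tol Residual tolerance on the balanced row sums (relative),
#'   default 1e-8.
#' @param max_iter Maximum outer Newton iterations.
#' @return A balanced `contact_matrix` (`normalized = TRUE`) with `bias`
#'   filled in and attributes `iterations` and `residual`.
#' @references Knight, P.A. and Ruiz, D. (2013) A fast algorithm for
#'   matrix balancing. IMA Journal of Numerical Analysis 33, 1029-1047.
#' @export
kr_balance <- function(m, tol = 1e-8, max_iter = 100L) {
  stopifnot(inherits(m, "contact_matrix"))
  if (m$normalized) stop("matrix is already balanced")
  keep <- m$mask & rowSums(m$M) > 0
  if (sum(keep) < 2L) stop("fewer than two unmasked bins with signal")
  A <- m$M[keep, keep, drop = FALSE]
  x <- kr_bias_vector(A, tol = tol, max_iter = max_iter)
  S <- sum(A)
  nk <- sum(keep)
  # rescale so the balanced matrix keeps the raw total mass
  xs <- as.numeric(x) * sqrt(S / nk)
  N <- matrix(0, nrow(m$M), ncol(m$M))
  N[keep, keep] <- A * outer(xs, xs)
  bias <- rep(NA_real_, length(keep))
  bias[keep] <- xs
  out <- new_contact_matrix(m$region, m$bin_size, N, mask = keep,
                            normalized = TRUE, bias = bias)
  attr(out, "iterations") <- attr(x, "iterations")
  attr(out, "residual") <- attr(x, "residual")
  out
}

diag_band_index <- function(nb, d) {
  i <- seq_len(nb - d)
  cbind(i, i + d)
}

#' Joint per-subdiagonal scaling of two balanced maps
#'
#' For every diagonal offset `d`, the two maps' entries at that offset are
#' rescaled to their common target `t(d) = (m_a(d) + m_b(d)) / 2`, where
#' `m_x(d)` is the mean over unmasked entries of map `x` at offset `d`.
#' This removes any residual distance-decay imbalance between the two
#' conditions before subtraction; it is symmetric in the inputs and leaves
#' two identical maps unchanged. Offsets where either mean is zero are
#' left unscaled and reported in the `flagged_offsets` attribute.
#'
#' @param a,b Balanced `contact_matrix` objects with identical geometry.
#' @return List with elements `a` and `b` (both with `scaled = TRUE` and
#'   the `flagged_offsets` attribute).
#' @export
subdiagonal_scale <- function(a, b) {
  stopifnot(inherits(a, "contact_matrix"), inherits(b, "contact_matrix"))
  if (!same_geometry(a, b)) stop("maps differ in region, bin size or mask")
  if (!a$normalized || !b$normalized) stop("both maps must be balanced first")
  nb <- nrow(a$M)
  A <- a$M; B <- b$M
  mask <- a$mask
  flagged <- integer(0)
  for (d in 0:(nb - 1L)) {
    idx <- diag_band_index(nb, d)
    ok <- mask[idx[, 1]] & mask[idx[, 2]]
    if (!any(ok)) next
    sel <- idx[ok, , drop = FALSE]
    ma <- mean(A[sel])
    mb <- mean(B[sel])
    if (ma == 0 || mb == 0) {
      flagged <- c(flagged, d)
      next
    }
    tgt <- (ma + mb) / 2
    A[sel] <- A[sel] * (tgt / ma)
    B[sel] <- B[sel] * (tgt / mb)
    if (d > 0L) {
      sel_t <- sel[, 2:1, drop = FALSE]
      A[sel_t] <- A[sel_t] * (tgt / ma)
      B[sel_t] <- B[sel_t] * (tgt / mb)
    }
  }
  out_a <- new_contact_matrix(a$region, a$bin_size, A, mask,
                              normalized = TRUE, bias = a$bias,
                              scaled = TRUE)
  out_b <- new_contact_matrix(b$region, b$bin_size, B, mask,
                              normalized = TRUE, bias = b$bias,
                              scaled = TRUE)
  attr(out_a, "flagged_offsets") <- flagged
  attr(out_b, "flagged_offsets") <- flagged
  list(a = out_a, b = out_b)
}

#' Subtraction contact map
#'
#' Entrywise `a - b` of two jointly scaled, balanced maps; the result is a
#' signed symmetric matrix with the shared mask. By default both inputs
#' must have been through [subdiagonal_scale()] (set `force = TRUE` to
#' subtract unscaled maps deliberately).
#'
#' @param a,b `contact_matrix` objects with identical geometry.
#' @param force Skip the joint-scaling check.
#' @return A signed `contact_matrix`.
#' @export
subtract_maps <- function(a, b, force = FALSE) {
  stopifnot(inherits(a, "contact_matrix"), inherits(b, "contact_matrix"))
  if (!same_geometry(a, b)) stop("maps differ in region, bin size or mask")
  if (!force && (!a$scaled || !b$scaled)) {
    stop("maps must be scaled together (subdiagonal_scale) before ",
         "subtraction; use force = TRUE to override")
  }
  new_contact_matrix(a$region, a$bin_size, a$M - b$M, a$mask,
                     normalized = a$normalized && b$normalized,
                     scaled = a$scaled && b$scaled, signed = TRUE)
}

#' Truncate a contact map at a percentile (display export)
#'
#' Entries above the `q`-th percentile of the unmasked upper-triangle
#' entries (linear-interpolation quantile) are clipped to that percentile
#' value.
#'
#' @param m A `contact_matrix`.
#' @param q Percentile in `(0, 100)`, default 99.
#' @return The clipped `contact_matrix` with attribute `cutoff`.
#' @export
truncate_percentile <- function(m, q = 99) {
  stopifnot(inherits(m, "contact_matrix"))
  if (!(q > 0 && q < 100)) stop("q must be in (0, 100)")
  nb <- nrow(m$M)
  ut <- upper.tri(m$M, diag = TRUE) & outer(m$mask, m$mask, "&")
  vals <- m$M[ut]
  if (length(vals) == 0L) stop("all bins are masked")
  cut <- as.numeric(stats::quantile(vals, q / 100, type = 7))
  M <- m$M
  clip <- outer(m$mask, m$mask, "&") & M > cut
  M[clip] <- cut
  out <- new_contact_matrix(m$region, m$bin_size, M, m$mask,
                            normalized = m$normalized, bias = m$bias,
                            scaled = m$scaled, signed = m$signed)
  attr(out, "cutoff") <- cut
  out
}
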