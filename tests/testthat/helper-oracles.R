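# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain alternating scaling instead of the KR
# Newton iteration, direct double loops instead of the vectorised kernels.

# alternating (Sinkhorn-style) scaling to a doubly stochastic matrix
sinkhorn_balance <- function(A, tol = 1e-12, max_iter = 50000L) {
  r <- rep(1, nrow(A))
  cc <- rep(1, ncol(A))
  for (it in seq_len(max_iter)) {
    r <- 1 / as.vector(A %*% cc)
    cc <- 1 / as.vector(t(A) %*% r)
    N <- A * outer(r, cc)
    if (max(abs(rowSums(N) - 1)) < tol && max(abs(colSums(N) - 1)) < tol) {
      return(N)
    }
  }
  stop("sinkhorn oracle did not converge")
}

# direct kernel-sum density oracle
kde_oracle <- function(values, bw, grid) {
  n <- length(values)
  sapply(grid, function(g) sum(dnorm((g - values) / bw)) / (n * bw))
}

# analytic crossing of two normal pdfs with unequal variances: the root of
# a quadratic in x
normal_crossings <- function(m1, s1, m2, s2) {
  a <- 1 / s1^2 - 1 / s2^2
  b <- -2 * (m1 / s1^2 - m2 / s2^2)
  cc <- m1^2 / s1^2 - m2^2 / s2^2 + 2 * log(s1 / s2)
  disc <- b^2 - 4 * a * cc
  sort((-b + c(-1, 1) * sqrt(disc)) / (2 * a))
}

# brute-force virtual 4C: enumerate pairs and window membership
v4c_oracle <- function(pairs, viewpoint, raw_bin, interval_size) {
  region <- pairs$region
  nraw <- ceiling((region$end - region$start + 1) / raw_bin)
  raw <- numeric(nraw)
  n_qual <- 0L
  for (k in seq_along(pairs$pos_a)) {
    pa <- pairs$pos_a[k]
    pb <- pairs$pos_b[k]
    ina <- pa >= viewpoint$start && pa <= viewpoint$end
    inb <- pb >= viewpoint$start && pb <= viewpoint$end
    if (ina == inb) next
    n_qual <- n_qual + 1L
    pos <- if (ina) pb else pa
    bin <- floor((pos - region$start) / raw_bin) + 1
    raw[bin] <- raw[bin] + 1
  }
  n_int <- ceiling((region$end - region$start + 1) / interval_size)
  vals <- numeric(n_int)
  ratio <- interval_size / raw_bin
  for (i in seq_len(n_int)) {
    idx <- ((i - 1) * ratio + 1):min(i * ratio, nraw)
    vals[i] <- mean(raw[idx])
  }
  list(values = vals, raw = raw, n_qualifying = n_qual)
}

# plain-loop differential proportion test (same null model, unvectorised,
# its own draw order)
dpa_oracle <- function(a, b, n_perm, p_mix, seed) {
  vocab <- sort(unique(c(a$clusters, b$clusters)))
  c1 <- table(factor(a$clusters, levels = vocab))
  c2 <- table(factor(b$clusters, levels = vocab))
  n1 <- sum(c1); n2 <- sum(c2)
  p1 <- as.numeric(c1) / n1
  p2 <- as.numeric(c2) / n2
  pooled <- as.numeric(c1 + c2) / (n1 + n2)
  obs <- p2 - p1
  set.seed(seed)
  exceed <- numeric(length(vocab))
  for (it in seq_len(n_perm)) {
    l1 <- sample(vocab, n1, replace = TRUE,
                 prob = p_mix * p1 + (1 - p_mix) * pooled)
    l2 <- sample(vocab, n2, replace = TRUE,
                 prob = p_mix * p2 + (1 - p_mix) * pooled)
    q1 <- as.numeric(table(factor(l1, levels = vocab))) / n1
    q2 <- as.numeric(table(factor(l2, levels = vocab))) / n2
    exceed <- exceed + (abs(q2 - q1) >= abs(obs))
  }
  list(statistic = obs, p_value = (1 + exceed) / (n_perm + 1),
       clusters = vocab)
}

# small helper: raw contact_matrix straight from a dense symmetric matrix
toy_contact_matrix <- function(A, bin_size = 1000, chrom = "chrT") {
  n <- nrow(A)
  region <- genomic_interval(chrom, 1, n * bin_size)
  pairs <- contact_pairs(region, numeric(0), numeric(0))
  m <- bin_pairs(pairs, bin_size)
  m$M <- A
  stopifnot(max(abs(A - t(A))) < 1e-9)
  m
}
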