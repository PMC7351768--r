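# Independent oracles used by the tests. Each recomputes a quantity by a
# different algorithm than the implementation under test.

# Brute-force local thickness: explicit distance matrices, no distance
# transform. Same convention as the implementation (inscribed radius =
# centre-to-centre EDT distance - 1/2; coverage |q - p| < d(p), strict).
oracleLocalThickness <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  fg <- which(m > 0, arr.ind = TRUE)
  bg <- which(m == 0, arr.ind = TRUE)
  out <- matrix(0, nr, nc)
  if (!nrow(fg)) return(out)
  if (!nrow(bg)) stop("oracle needs at least one background pixel")
  d2 <- outer(fg[, 1], bg[, 1], "-")^2 + outer(fg[, 2], bg[, 2], "-")^2
  r2 <- apply(d2, 1, min)                  # integer squared distances
  dia <- 2 * sqrt(r2) - 1
  dq <- outer(fg[, 1], fg[, 1], "-")^2 + outer(fg[, 2], fg[, 2], "-")^2
  for (q in seq_len(nrow(fg)))
    out[fg[q, 1], fg[q, 2]] <- max(dia[dq[q, ] < r2])
  out
}

# All-pairs shortest paths by Floyd-Warshall over an explicit adjacency
# matrix of the skeleton pixels (1 orthogonal, sqrt(2) diagonal); returns
# the graph diameter in px. Independent of igraph.
oracleLongestShortestPath <- function(skel) {
  idx <- which(skel > 0, arr.ind = TRUE)
  n <- nrow(idx)
  if (n <= 1L) return(0)
  D <- matrix(Inf, n, n); diag(D) <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    dr <- abs(idx[i, 1] - idx[j, 1]); dc <- abs(idx[i, 2] - idx[j, 2])
    if (dr <= 1L && dc <= 1L) D[i, j] <- D[j, i] <- sqrt(dr + dc)
  }
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], "+"))
  m <- max(D[is.finite(D)])
  m
}

# Exhaustive permutation p-value of the two-sample KS test: enumerate all
# ways to split the pooled sample, P(D* >= D_obs).
oracleKsPermutation <- function(a, b) {
  ksD <- function(x, y) {
    v <- sort(unique(c(x, y)))
    Fa <- vapply(v, function(t) mean(x <= t), numeric(1))
    Fb <- vapply(v, function(t) mean(y <= t), numeric(1))
    max(abs(Fa - Fb))
  }
  pool <- c(a, b)
  n <- length(a)
  obs <- ksD(a, b)
  splits <- utils::combn(length(pool), n)
  ds <- apply(splits, 2, function(ix) ksD(pool[ix], pool[-ix]))
  mean(ds >= obs - 1e-12)
}

# Hand-computed Pearson chi-square of a 2 x k table.
oraclePearsonChisq <- function(tab) {
  exp <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - exp)^2 / exp)
}

# Fourier sub-pixel shift of a periodic image (phase-ramp oracle used to
# create known fractional displacements).
fourierShift <- function(img, dxPx, dyPx) {
  nr <- nrow(img); nc <- ncol(img)
  kx <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1)) / nc
  ky <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1)) / nr
  ramp <- exp(-2i * pi * (outer(rep(1, nr), kx) * dxPx +
                          outer(ky, rep(1, nc)) * dyPx))
  Re(stats::fft(stats::fft(img) * ramp, inverse = TRUE)) / (nr * nc)
}
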