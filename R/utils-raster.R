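# Internal raster utilities shared across modules.
#
# Raster convention used package-wide: a binary/grey image is a numeric
# matrix indexed [row, col]; physical coordinates are continuous and in nm,
# with x running along columns, y along rows, and the centre of pixel
# [1, 1] at (x, y) = (0, 0): x_nm = (col - 1) * pixelSize.

#' @noRd
.pxToNm <- function(index, pixelSize) (index - 1) * pixelSize

#' @noRd
.nmToPx <- function(nm, pixelSize) nm / pixelSize + 1

# Exact squared Euclidean distance transform (two-pass separable lower
# envelope of parabolas). Returns, for every pixel, the squared distance in
# pixel units from its centre to the centre of the nearest background
# (zero) pixel; squared distances between pixel centres are integers, so
# the result is exact.
#' @noRd
.edtSquared <- function(mask) {
  stopifnot(is.matrix(mask))
  INF <- .Machine$double.xmax / 4
  f <- ifelse(mask > 0, INF, 0)
  g <- apply(f, 2, .edt1d, INF = INF)
  t(apply(t(g), 2, .edt1d, INF = INF))
}

# 1D squared distance transform of sampled function f (Felzenszwalb &
# Huttenlocher lower envelope).
#' @noRd
.edt1d <- function(f, INF) {
  n <- length(f)
  d <- numeric(n)
  v <- integer(n); z <- numeric(n + 1L)
  k <- 1L; v[1L] <- 1L; z[1L] <- -INF; z[2L] <- INF
  for (q in 2:n) {
    repeat {
      s <- ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2 * q - 2 * v[k])
      if (s <= z[k]) { k <- k - 1L; if (k < 1L) { k <- 1L; v[1L] <- q; z[1L] <- -INF; z[2L] <- INF; break } }
      else { k <- k + 1L; v[k] <- q; z[k] <- s; z[k + 1L] <- INF; break }
    }
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

# Connected-component labelling of a binary matrix, 8- or 4-connectivity.
# Breadth-first flood fill over pixel index sets (vectorised frontier).
#' @noRd
.labelComponents <- function(mask, connectivity = 8L) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  fg <- which(mask > 0)
  if (!length(fg)) return(lab)
  if (connectivity == 8L) {
    dr <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L); dc <- c(0L, 0L, -1L, 1L)
  }
  cur <- 0L
  remaining <- logical(nr * nc); remaining[fg] <- TRUE
  for (seed in fg) {
    if (!remaining[seed]) next
    cur <- cur + 1L
    frontier <- seed
    remaining[seed] <- FALSE
    lab[seed] <- cur
    while (length(frontier)) {
      r <- ((frontier - 1L) %% nr) + 1L
      cl <- ((frontier - 1L) %/% nr) + 1L
      nxt <- integer(0)
      for (k in seq_along(dr)) {
        rr <- r + dr[k]; cc <- cl + dc[k]
        ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
        idx <- (cc[ok] - 1L) * nr + rr[ok]
        idx <- idx[remaining[idx]]
        if (length(idx)) {
          remaining[idx] <- FALSE
          lab[idx] <- cur
          nxt <- c(nxt, idx)
        }
      }
      frontier <- unique(nxt)
    }
  }
  lab
}

# Zhang-Suen morphological thinning to a 1-px-wide 8-connected skeleton.
#' @noRd
.thinSkeleton <- function(mask) {
  img <- (mask > 0) * 1L
  nr <- nrow(img); nc <- ncol(img)
  pad <- function(m) { out <- matrix(0L, nr + 2L, nc + 2L); out[2:(nr + 1L), 2:(nc + 1L)] <- m; out }
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p <- pad(img)
      ctr <- p[2:(nr + 1L), 2:(nc + 1L)]
      P2 <- p[1:nr, 2:(nc + 1L)]           # north
      P3 <- p[1:nr, 3:(nc + 2L)]           # north-east
      P4 <- p[2:(nr + 1L), 3:(nc + 2L)]    # east
      P5 <- p[3:(nr + 2L), 3:(nc + 2L)]    # south-east
      P6 <- p[3:(nr + 2L), 2:(nc + 1L)]    # south
      P7 <- p[3:(nr + 2L), 1:nc]           # south-west
      P8 <- p[2:(nr + 1L), 1:nc]           # west
      P9 <- p[1:nr, 1:nc]                  # north-west
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (P2 == 0L & P3 == 1L) + (P3 == 0L & P4 == 1L) + (P4 == 0L & P5 == 1L) +
           (P5 == 0L & P6 == 1L) + (P6 == 0L & P7 == 1L) + (P7 == 0L & P8 == 1L) +
           (P8 == 0L & P9 == 1L) + (P9 == 0L & P2 == 1L)
      if (sub == 1L) {
        cond <- ctr == 1L & B >= 2L & B <= 6L & A == 1L &
          (P2 * P4 * P6 == 0L) & (P4 * P6 * P8 == 0L)
      } else {
        cond <- ctr == 1L & B >= 2L & B <= 6L & A == 1L &
          (P2 * P4 * P8 == 0L) & (P2 * P6 * P8 == 0L)
      }
      if (any(cond)) { img[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  img
}

# Elliptical (asymmetric) 2D Gaussian, peak amplitude `amp`, evaluated on
# pixel-centre grids. theta is the major-axis angle in radians measured
# from the +x (column) axis.
#' @noRd
.asymGauss <- function(xs, ys, x0, y0, sMaj, sMin, theta, amp, bkg) {
  dx <- outer(rep(1, length(ys)), xs - x0)
  dy <- outer(ys - y0, rep(1, length(xs)))
  u <- cos(theta) * dx + sin(theta) * dy
  v <- -sin(theta) * dx + cos(theta) * dy
  bkg + amp * exp(-(u^2 / (2 * sMaj^2) + v^2 / (2 * sMin^2)))
}

# Normalized Gaussian kernel matrix with given sigma (px), truncated at
# `cut` sigmas, peak value 1 (unit amplitude).
#' @noRd
.gaussKernel <- function(sigmaPx, cut = 4) {
  r <- max(1L, ceiling(cut * sigmaPx))
  g <- exp(-(seq(-r, r))^2 / (2 * sigmaPx^2))
  outer(g, g)
}

#' @noRd
.fwhmToSigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' @noRd
.sigmaToFwhm <- function(sigma) sigma * 2 * sqrt(2 * log(2))

# 2D convolution, 'same' size, zero padding, via FFT.
#' @noRd
.conv2same <- function(img, kernel) {
  nr <- nrow(img) + nrow(kernel) - 1L
  nc <- ncol(img) + ncol(kernel) - 1L
  pa <- matrix(0, nr, nc); pa[seq_len(nrow(img)), seq_len(ncol(img))] <- img
  pk <- matrix(0, nr, nc); pk[seq_len(nrow(kernel)), seq_len(ncol(kernel))] <- kernel
  full <- Re(fft(fft(pa) * fft(pk), inverse = TRUE)) / (nr * nc)
  r0 <- (nrow(kernel) - 1L) %/% 2L
  c0 <- (ncol(kernel) - 1L) %/% 2L
  full[r0 + seq_len(nrow(img)), c0 + seq_len(ncol(img))]
}

#' @noRd
.chkScalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0) stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}
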