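# Morphometry of segmented (EM-like) binary ECS masks.

#' Read a binary mask from TIFF or PNG
#'
#' @param path image file (.tif/.tiff/.png); any nonzero pixel is
#'   foreground.
#' @param pixelSizeNm physical pixel size (nm); EM-scale masks use 1.42.
#' @return an \linkS4class{EcsMask}.
#' @export
readEcsMask <- function(path, pixelSizeNm = 1.42) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported mask format: ", ext))
  if (length(dim(img)) == 3L) img <- img[, , 1]
  new("EcsMask", mask = (img > 0) * 1, pixelSize = pixelSizeNm)
}

#' ECS volume fraction of a mask
#'
#' Area of ECS compartments divided by the total image area (the 2D proxy
#' for the volume fraction alpha).
#'
#' @param mask an \linkS4class{EcsMask} or binary matrix.
#' @return fraction in [0, 1].
#' @export
volumeFraction <- function(mask) {
  m <- if (is(mask, "EcsMask")) maskPixels(mask) else mask
  if (!length(m)) stop("empty mask")
  mean(m > 0)
}

# Skeleton graph of one component's pixel set; vertices are skeleton
# pixels, edges connect 8-neighbours with weight 1 (orthogonal) or
# sqrt(2) (diagonal).
#' @noRd
.skeletonGraph <- function(skel) {
  idx <- which(skel > 0, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0L) return(NULL)
  key <- paste(idx[, 1], idx[, 2])
  lookup <- seq_len(n); names(lookup) <- key
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (k in seq_len(8)) {
    dr <- c(-1, -1, -1, 0, 0, 1, 1, 1)[k]
    dc <- c(-1, 0, 1, -1, 1, -1, 0, 1)[k]
    nb <- paste(idx[, 1] + dr, idx[, 2] + dc)
    hit <- !is.na(match(nb, key))
    if (any(hit)) {
      a <- lookup[key[hit]]; b <- lookup[nb[hit]]
      sel <- a < b                         # undirected, once
      from <- c(from, a[sel]); to <- c(to, b[sel])
      w <- c(w, rep(sqrt(dr^2 + dc^2), sum(sel)))
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(from))
    g <- igraph::add_edges(g, rbind(from, to), weight = w)
  g
}

#' Longest shortest path of each ECS compartment
#'
#' Per 8-connected component: the mask is skeletonized (Zhang-Suen
#' thinning) and the skeleton's longest shortest path -- the weighted
#' graph diameter with steps of 1 px (orthogonal) and sqrt(2) px
#' (diagonal) -- is measured and converted to um. Single-pixel components
#' have length 0. Components touching the image border are measured as-is
#' and flagged (EM fields are crops).
#'
#' @param mask an \linkS4class{EcsMask} or binary matrix.
#' @param pixelSizeNm pixel size (nm) if \code{mask} is a bare matrix.
#' @return data.frame: component id, area_nm2, length_um, touches_border.
#' @export
compartmentLengths <- function(mask, pixelSizeNm = 1.42) {
  if (is(mask, "EcsMask")) { px <- pixelSize(mask); m <- maskPixels(mask) }
  else { px <- pixelSizeNm; m <- (mask > 0) * 1 }
  lab <- .labelComponents(m, 8L)
  nComp <- max(lab)
  if (nComp == 0L)
    return(data.frame(component = integer(0), area_nm2 = numeric(0),
                      length_um = numeric(0), touches_border = logical(0)))
  out <- vector("list", nComp)
  for (i in seq_len(nComp)) {
    compMask <- (lab == i) * 1
    pix <- which(compMask > 0, arr.ind = TRUE)
    touches <- any(pix[, 1] %in% c(1L, nrow(m))) ||
      any(pix[, 2] %in% c(1L, ncol(m)))
    len <- 0
    if (nrow(pix) > 1L) {
      skel <- .thinSkeleton(compMask)
      if (sum(skel) == 0L) skel[pix[1, 1], pix[1, 2]] <- 1L
      g <- .skeletonGraph(skel)
      if (!is.null(g) && igraph::vcount(g) > 1L) {
        d <- igraph::distances(g)
        d[!is.finite(d)] <- 0              # guard: skeleton fragments
        len <- max(d)
      }
    }
    out[[i]] <- data.frame(component = i,
                           area_nm2 = nrow(pix) * px^2,
                           length_um = len * px / 1000,
                           touches_border = touches)
  }
  do.call(rbind, out)
}

#' Exact local thickness of a binary mask
#'
#' For every foreground pixel, the diameter of the largest disc that lies
#' entirely inside the foreground and contains the pixel -- the classical
#' local-thickness definition ("iteratively fitting the largest circle in
#' each portion of the compartment"). Computed exactly: the squared
#' Euclidean distance transform gives each pixel's centre-to-centre
#' distance d(p) to the nearest background pixel (integer squared
#' distances, so no rounding); the inscribed radius extends to the edge
#' of that background pixel, r(p) = d(p) - 1/2, giving a disc diameter of
#' 2 d(p) - 1 px (a 5-px slab reads 5). Diameters are propagated over the
#' discs they cover in decreasing order; a pixel q is covered by the disc
#' at p when |q - p| < d(p) (strict), which guarantees the disc lies in
#' the foreground.
#'
#' @param mask an \linkS4class{EcsMask} or binary matrix.
#' @param pixelSizeNm pixel size (nm) if \code{mask} is a bare matrix.
#' @return list: \code{map} (matrix of local thickness, nm; 0 outside),
#'   \code{widths_nm} (per-foreground-pixel thickness values).
#' @export
localThickness <- function(mask, pixelSizeNm = 1.42) {
  if (is(mask, "EcsMask")) { px <- pixelSize(mask); m <- maskPixels(mask) }
  else { px <- pixelSizeNm; m <- (mask > 0) * 1 }
  nr <- nrow(m); nc <- ncol(m)
  d2 <- .edtSquared(m)                     # integer-exact squared distance
  fg <- which(m > 0)
  thick <- matrix(0, nr, nc)               # diameter in px
  if (length(fg)) {
    ord <- fg[order(d2[fg], decreasing = TRUE)]
    for (p in ord) {
      r2 <- d2[p]
      dia <- 2 * sqrt(r2) - 1
      pr <- ((p - 1L) %% nr) + 1L
      pc <- ((p - 1L) %/% nr) + 1L
      rad <- ceiling(sqrt(r2))
      rlo <- max(1L, pr - rad); rhi <- min(nr, pr + rad)
      clo <- max(1L, pc - rad); chi <- min(nc, pc + rad)
      rows <- rlo:rhi; cols <- clo:chi
      dd <- outer((rows - pr)^2, (cols - pc)^2, "+")
      cover <- dd < r2
      sub <- thick[rows, cols]
      sub[cover & sub < dia] <- dia
      thick[rows, cols] <- sub
    }
  }
  map <- thick * px
  list(map = map, widths_nm = map[fg])
}

#' Categorize ECS widths into channels and pools
#'
#' Width categories of the channels-and-pools description: channels below
#' 100 nm, small pools 100-200 nm, large pools above 200 nm, expressed as
#' percentage of ECS. The 100 nm boundary belongs to small pools and the
#' 200 nm boundary to small pools (closed interval), a convention the
#' printed bounds "<100", "100-200", ">200" leave open.
#'
#' @param widthsNm numeric vector of local widths (nm), >= 0.
#' @return named numeric: percentages for \code{channels},
#'   \code{small_pools}, \code{large_pools}; sums to 100.
#' @export
categorizeWidths <- function(widthsNm) {
  if (!length(widthsNm)) stop("empty width vector")
  if (any(widthsNm < 0)) stop("widths must be >= 0")
  n <- length(widthsNm)
  c(channels = 100 * sum(widthsNm < 100) / n,
    small_pools = 100 * sum(widthsNm >= 100 & widthsNm <= 200) / n,
    large_pools = 100 * sum(widthsNm > 200) / n)
}

#' Chi-square comparison of two width-category tables
#'
#' Pearson chi-square test (no continuity correction) on a 2 x k count
#' table, e.g. channel / small-pool / large-pool counts of two groups
#' (df = 2 for three categories).
#'
#' @param countsA,countsB nonnegative count vectors of equal length.
#' @return list: statistic, df, p.value, expected.
#' @export
compareCategoryTables <- function(countsA, countsB) {
  if (length(countsA) != length(countsB))
    stop("count vectors must have equal length")
  tab <- rbind(countsA, countsB)
  if (any(tab < 0)) stop("counts must be nonnegative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal in the category table")
  ht <- stats::chisq.test(tab, correct = FALSE)
  if (any(ht$expected < 1))
    stop("expected counts below 1; chi-square approximation invalid")
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value, expected = ht$expected)
}
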