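#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Label connected components of a binary image (8-connectivity)
#'
#' Two-pass union-find labeling. Diagonal neighbours belong to the same
#' component, which matters for thin diagonal vessel segments that a
#' 4-connected labeling would fragment.
#'
#' @param mask logical or 0/1 matrix.
#' @return integer matrix of component labels (0 = background).
#' @export
label_components8 <- function(mask) {
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  parent <- integer(0)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  nxt <- 0L
  for (c in seq_len(nc)) {
    for (r in seq_len(nr)) {
      if (!mask[r, c]) next
      # prior neighbours in scan order: N (r-1,c), W (r,c-1), NW (r-1,c-1), SW (r+1,c-1)
      nb <- integer(0)
      if (r > 1L && lab[r - 1L, c]) nb <- c(nb, lab[r - 1L, c])
      if (c > 1L) {
        if (lab[r, c - 1L]) nb <- c(nb, lab[r, c - 1L])
        if (r > 1L && lab[r - 1L, c - 1L]) nb <- c(nb, lab[r - 1L, c - 1L])
        if (r < nr && lab[r + 1L, c - 1L]) nb <- c(nb, lab[r + 1L, c - 1L])
      }
      if (!length(nb)) {
        nxt <- nxt + 1L
        parent[nxt] <- nxt
        lab[r, c] <- nxt
      } else {
        roots <- vapply(unique(nb), find_root, integer(1))
        m <- min(roots)
        lab[r, c] <- m
        for (ro in roots) parent[ro] <- m
      }
    }
  }
  if (nxt == 0L) return(lab)
  roots <- vapply(seq_len(nxt), find_root, integer(1))
  relab <- integer(nxt)
  relab[sort(unique(roots))] <- seq_along(unique(roots))
  pos <- which(lab > 0L)
  lab[pos] <- relab[roots[lab[pos]]]
  lab
}

#' Truncated Gaussian smoothing kernel on a square support
#'
#' @param size side length of the support in pixels.
#' @param sigma standard deviation in pixels.
#' @return normalized kernel matrix; even sizes are embedded in an
#'   odd-sized array (zero-padded last row/column) so convolution is
#'   well-centred.
#' @export
gaussian_kernel <- function(size = 20, sigma = 5) {
  ctr <- (size + 1) / 2
  d <- seq_len(size) - ctr
  k <- exp(-outer(d^2, d^2, "+") / (2 * sigma^2))
  k <- k / sum(k)
  if (size %% 2 == 0) {
    kk <- matrix(0, size + 1, size + 1)
    kk[seq_len(size), seq_len(size)] <- k
    k <- kk
  }
  k
}

# distance from each pixel to its nearest and second-nearest seed of a
# jittered-grid (blue-noise) point set; returns d2 - d1, the Voronoi
# ridge coordinate. Seeds are indexed by their grid cell, so the two
# nearest seeds of any pixel lie within a 5x5 cell neighbourhood
# (jitter is bounded by 0.45 cell), giving an O(25 n) search.
nearest_two_gap_grid <- function(px, py, sx, sy, ngx, ngy, cell) {
  n <- length(px)
  SX <- matrix(sx, ngx, ngy); SY <- matrix(sy, ngx, ngy)
  ci <- pmin(pmax(round((px - 0.5) / cell) + 1, 1L), ngx)
  cj <- pmin(pmax(round((py - 0.5) / cell) + 1, 1L), ngy)
  m1 <- rep(Inf, n); m2 <- rep(Inf, n)
  for (di in -2:2) for (dj in -2:2) {
    ii <- ci + di; jj <- cj + dj
    ok <- ii >= 1L & ii <= ngx & jj >= 1L & jj <= ngy
    d <- rep(Inf, n)
    lin <- ii[ok] + (jj[ok] - 1L) * ngx
    d[ok] <- (px[ok] - SX[lin])^2 + (py[ok] - SY[lin])^2
    lo <- pmin(m1, d)
    m2 <- pmin(m2, pmax(m1, d))
    m1 <- lo
  }
  sqrt(m2) - sqrt(m1)
}

# deterministic md5 of an R object (provenance hashes)
object_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, "wb")
  serialize(x, con, version = 3L)
  close(con)
  unname(tools::md5sum(f))
}
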