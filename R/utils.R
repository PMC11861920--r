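# Internal helpers: classed conditions, 8-connected labeling, kernels.

cd_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "chromadens_error"),
                      call = call))
}

cd_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "chromadens_warning")))
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Union-find with path compression over integer ids 1..n.
uf_new <- function(n) seq_len(n)

uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}

uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i)
  rj <- uf_find(parent, j)
  if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  parent
}

uf_flatten <- function(parent) {
  for (i in seq_along(parent)) parent[i] <- uf_find(parent, i)
  parent
}

#' Label 8-connected components of a binary mask
#'
#' [EBImage::bwlabel()] labels 4-connected components; the location taxonomy
#' and altered-region extraction require 8-connectivity, so labels that touch
#' diagonally are merged with a union-find pass.
#'
#' @param mask logical or 0/1 matrix.
#' @return integer matrix of labels, 0 = background, components numbered
#'   consecutively from 1.
#' @keywords internal
#' @noRd
label_components8 <- function(mask) {
  mask <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  l <- EBImage::bwlabel(mask)
  l <- matrix(as.integer(round(l)), nrow(mask), ncol(mask))
  nmax <- max(l)
  if (nmax > 1L) {
    nr <- nrow(l); nc <- ncol(l)
    a1 <- l[-nr, -nc]; b1 <- l[-1, -1]     # \ diagonal
    a2 <- l[-1, -nc];  b2 <- l[-nr, -1]    # / diagonal
    s1 <- a1 > 0L & b1 > 0L & a1 != b1
    s2 <- a2 > 0L & b2 > 0L & a2 != b2
    if (any(s1) || any(s2)) {
      parent <- uf_new(nmax)
      pairs <- rbind(cbind(a1[s1], b1[s1]), cbind(a2[s2], b2[s2]))
      pairs <- unique(pairs)
      for (r in seq_len(nrow(pairs)))
        parent <- uf_union(parent, pairs[r, 1], pairs[r, 2])
      parent <- uf_flatten(parent)
      ids <- sort(unique(parent))
      remap <- integer(nmax)
      remap[ids] <- seq_along(ids)
      nz <- l > 0L
      l[nz] <- remap[parent[l[nz]]]
    }
  }
  l
}

# Truncated, renormalized Gaussian kernel: window (2*radius+1)^2.
gaussian_kernel <- function(sigma, radius) {
  stopifnot(sigma > 0, radius >= 1)
  x <- seq(-radius, radius)
  g <- exp(-x^2 / (2 * sigma^2))
  k <- outer(g, g)
  k / sum(k)
}

# Pixel coordinate matrices <-> linear keys (for fast set operations).
px_key <- function(px, nr) (px[, 2] - 1L) * nr + px[, 1]

# Build a bounding-box submask from an n x 2 (row, col) pixel matrix.
# Returns list(mask, r0, c0) with mask[r - r0 + 1, c - c0 + 1].
px_submask <- function(px, pad = 0L) {
  r0 <- min(px[, 1]) - pad
  c0 <- min(px[, 2]) - pad
  m <- matrix(FALSE, max(px[, 1]) - r0 + 1L + pad, max(px[, 2]) - c0 + 1L + pad)
  m[cbind(px[, 1] - r0 + 1L, px[, 2] - c0 + 1L)] <- TRUE
  list(mask = m, r0 = r0, c0 = c0)
}

# Inverse of px_submask: mask + offsets -> global (row, col) pixels.
submask_px <- function(mask, r0, c0) {
  w <- which(mask, arr.ind = TRUE)
  cbind(row = w[, 1] + r0 - 1L, col = w[, 2] + c0 - 1L)
}

# Population (divisor n) standard deviation.
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
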