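# Independent brute-force oracles used to freeze expected values.

# Between-class-variance scan over 256 bins (independent Otsu oracle).
# When the maximizer is a plateau (an empty gap between modes), any
# threshold on the plateau is optimal; the midpoint is returned.
brute_otsu <- function(v, levels = 256) {
  breaks <- seq(0, 1, length.out = levels + 1)
  h <- hist(v, breaks = breaks, plot = FALSE)$counts
  mids <- (breaks[-1] + breaks[-(levels + 1)]) / 2
  n <- sum(h)
  bcv <- rep(-Inf, levels - 1)
  for (t in 1:(levels - 1)) {
    w0 <- sum(h[1:t]) / n
    w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(h[1:t] * mids[1:t]) / sum(h[1:t])
    mu1 <- sum(h[(t + 1):levels] * mids[(t + 1):levels]) /
      sum(h[(t + 1):levels])
    bcv[t] <- w0 * w1 * (mu0 - mu1)^2
  }
  plateau <- which(bcv >= max(bcv) - 1e-12)
  list(threshold = mean(breaks[plateau + 1]),
       plateau = range(breaks[plateau + 1]))
}

# Brute-force erosion of a pixel set by the 4-connected cross.
brute_erode_cross <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c]) next
    ok <- r > 1 && r < nr && c > 1 && c < nc &&
      mask[r - 1, c] && mask[r + 1, c] && mask[r, c - 1] && mask[r, c + 1]
    out[r, c] <- ok
  }
  out
}

# Brute-force rank-sum reference selection over explicit head stats.
brute_reference <- function(mu, cv, K) {
  score <- rank(-mu, ties.method = "average") +
    rank(cv, ties.method = "average")
  ord <- order(score, -mu, seq_along(mu))
  sel <- ord[seq_len(min(K, length(mu)))]
  list(selected = sort(sel), reference = mean(mu[sel]))
}

# A minimal in-memory sperm_head for unit tests.
make_head <- function(mask, values = NULL, label = 1L) {
  px <- which(mask, arr.ind = TRUE)
  colnames(px) <- c("row", "col")
  iv <- if (is.null(values)) rep(0.5, nrow(px)) else values[px]
  mu <- mean(iv)
  structure(list(label = label, pixels = px, pixels_raw = px,
                 centroid = c(mean(px[, 1]), mean(px[, 2])),
                 area_px = nrow(px), mean_intensity = mu,
                 cv_intensity = if (mu > 0) sqrt(mean((iv - mu)^2)) / mu
                                else 0),
            class = "sperm_head")
}

# A sperm_head directly from an n x 2 pixel matrix.
make_head_from_px <- function(px, label = 1L, mean_intensity = 0.75,
                              cv_intensity = 0.01) {
  colnames(px) <- c("row", "col")
  structure(list(label = label, pixels = px, pixels_raw = px,
                 centroid = c(mean(px[, 1]), mean(px[, 2])),
                 area_px = nrow(px), mean_intensity = mean_intensity,
                 cv_intensity = cv_intensity),
            class = "sperm_head")
}

# Ellipse mask on an (nr x nc) grid, semi-axes (a, b), axis-aligned.
ellipse_mask <- function(nr, nc, ctr, a, b, theta = 0) {
  g <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  dr <- g$row - ctr[1]; dc <- g$col - ctr[2]
  u <- dr * cos(theta) + dc * sin(theta)
  v <- -dr * sin(theta) + dc * cos(theta)
  m <- matrix(FALSE, nr, nc)
  m[cbind(g$row, g$col)] <- (u / a)^2 + (v / b)^2 <= 1
  m
}

# Match recovered heads to phantom ground truth by nearest centroid.
match_to_gt <- function(analysis, gt_table, max_dist = 5) {
  res <- analysis$results
  heads <- analysis$heads$heads
  out <- data.frame(label = res$label, gt_category = NA_character_,
                    dist = NA_real_)
  for (i in seq_len(nrow(res))) {
    h <- heads[[i]]
    d <- sqrt((gt_table$centroid_row - h$centroid[1])^2 +
                (gt_table$centroid_col - h$centroid[2])^2)
    j <- which.min(d)
    if (d[j] <= max_dist) {
      out$gt_category[i] <- gt_table$category[j]
      out$dist[i] <- d[j]
    }
  }
  out
}
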