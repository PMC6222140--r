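# Independent brute-force oracles, deliberately naive.

# Ring oracle: per-pixel Euclidean set-distance enumeration over all
# (pixel, nucleus-pixel) pairs. erosion via the same exhaustive definition.
oracle_rings <- function(nuclei, width, erosion = 0) {
  nr <- nrow(nuclei); nc <- ncol(nuclei)
  labs <- sort(unique(nuclei[nuclei > 0]))
  cores <- lapply(labs, function(k) {
    px <- which(nuclei == k, arr.ind = TRUE)
    if (erosion > 0) {
      keep <- apply(px, 1, function(p) {
        for (di in -floor(erosion):floor(erosion))
          for (dj in -floor(erosion):floor(erosion)) {
            if (di^2 + dj^2 > erosion^2) next
            ii <- p[1] + di; jj <- p[2] + dj
            if (ii < 1 || ii > nr || jj < 1 || jj > nc) return(FALSE)
            if (nuclei[ii, jj] != k) return(FALSE)
          }
        TRUE
      })
      px <- px[keep, , drop = FALSE]
    }
    px
  })
  out <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (nuclei[i, j] > 0) next
    best <- Inf; bl <- 0L
    for (k in seq_along(labs)) {
      px <- cores[[k]]
      if (!nrow(px)) next
      d2 <- min((px[, 1] - i)^2 + (px[, 2] - j)^2)
      if (d2 <= width^2 && d2 < best) { best <- d2; bl <- labs[k] }
    }
    out[i, j] <- as.integer(bl)
  }
  out
}

# Change-point oracle: plain exhaustive search with per-segment means,
# no shared code with the detector.
oracle_changepoints <- function(y, min_segment_len = 3) {
  n <- length(y)
  rss <- function(seg) sum((seg - mean(seg))^2)
  best <- list(m = 0L, rss = rss(y), c1 = NA, c2 = NA)
  fits <- list(`0` = list(rss = rss(y), c1 = NA, c2 = NA))
  b1 <- list(rss = Inf, c1 = NA)
  for (c1 in seq_len(n)) {
    if (c1 - 1 < min_segment_len || n - c1 + 1 < min_segment_len) next
    r <- rss(y[1:(c1 - 1)]) + rss(y[c1:n])
    if (r < b1$rss - 1e-12) b1 <- list(rss = r, c1 = c1)
  }
  fits$`1` <- b1
  b2 <- list(rss = Inf, c1 = NA, c2 = NA)
  for (c1 in seq_len(n)) for (c2 in seq_len(n)) {
    if (c1 - 1 < min_segment_len || c2 - c1 < min_segment_len ||
        n - c2 + 1 < min_segment_len) next
    r <- rss(y[1:(c1 - 1)]) + rss(y[c1:(c2 - 1)]) + rss(y[c2:n])
    if (r < b2$rss - 1e-12) b2 <- list(rss = r, c1 = c1, c2 = c2)
  }
  fits$`2` <- b2
  floor_rss <- n * (1e-10 * max(abs(y))^2 + 1e-300)
  bic <- vapply(0:2, function(m)
    n * log(max(fits[[as.character(m)]]$rss, floor_rss) / n) +
      (2 * m + 1) * log(n), numeric(1))
  m <- which.min(bic) - 1L
  list(m = m, c1 = fits[[as.character(m)]]$c1,
       c2 = if (m == 2) fits$`2`$c2 else NA)
}

# random non-overlapping blob label maps for ring fixtures
random_nucleus_map <- function(shape = c(32, 32), n_blobs = 3, rmax = 5,
                               seed = 1) {
  set.seed(seed)
  m <- matrix(0L, shape[1], shape[2])
  placed <- 0L; tries <- 0
  centers <- NULL
  while (placed < n_blobs && tries < 200) {
    tries <- tries + 1
    r <- runif(1, 2, rmax)
    ci <- runif(1, r + 1, shape[1] - r); cj <- runif(1, r + 1, shape[2] - r)
    if (!is.null(centers) &&
        min((centers[, 1] - ci)^2 + (centers[, 2] - cj)^2) < (2 * rmax + 2)^2)
      next
    placed <- placed + 1L
    centers <- rbind(centers, c(ci, cj))
    d2 <- outer((seq_len(shape[1]) - ci)^2, (seq_len(shape[2]) - cj)^2, "+")
    m[d2 <= r^2 & m == 0L] <- placed
  }
  m
}

# map predicted labels to ground-truth labels by maximal pixel overlap
overlap_label_map <- function(pred, truth) {
  p <- as.integer(pred); t <- as.integer(truth)
  both <- p > 0 & t > 0
  if (!any(both)) return(integer(0))
  tab <- table(p[both], t[both])
  out <- apply(tab, 1, function(row) as.integer(colnames(tab)[which.max(row)]))
  stats::setNames(out, rownames(tab))
}

demo_layout <- function(n_neg = 4, n_pos = 4) {
  data.frame(
    well_id = sprintf("%s%02d", rep(c("B", "C"), c(n_neg, n_pos)),
                      c(seq_len(n_neg), seq_len(n_pos))),
    role = rep(c("negative_control", "positive_control"), c(n_neg, n_pos)),
    treatment_label = rep(c("mock", "max_response"), c(n_neg, n_pos)),
    concentration = "")
}
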