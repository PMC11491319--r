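# Independent brute-force oracles used to cross-check the implementation.

# between-class variance by direct per-class summation
bf_between_class_variance <- function(hist, thresholds) {
  L <- length(hist)
  p <- hist / sum(hist)
  levels <- 0:(L - 1)
  mu_T <- sum(p * levels)
  bounds <- c(-1, thresholds, L - 1)
  total <- 0
  for (j in seq_len(length(thresholds) + 1)) {
    sel <- levels > bounds[j] & levels <= bounds[j + 1]
    w <- sum(p[sel])
    if (w > 0) {
      mu <- sum(p[sel] * levels[sel]) / w
      total <- total + w * (mu - mu_T)^2
    }
  }
  total
}

# median filter by explicit window gathering with edge replication
bf_median_filter <- function(img, window) {
  r <- window %/% 2
  H <- nrow(img); W <- ncol(img)
  out <- img
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      ii <- pmin(pmax((i - r):(i + r), 1), H)
      jj <- pmin(pmax((j - r):(j + r), 1), W)
      out[i, j] <- median(img[ii, jj])
    }
  }
  out
}

# LBP map by naive per-pixel double loop (east-start counterclockwise, R = 1)
bf_lbp_map <- function(img, H = 8, R = 1) {
  ang <- 2 * pi * (0:(H - 1)) / H
  drs <- round(-R * sin(ang)); dcs <- round(R * cos(ang))
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(NA_integer_, nr, nc)
  for (i in (R + 1):(nr - R)) {
    for (j in (R + 1):(nc - R)) {
      code <- 0
      for (h in seq_len(H)) {
        nb <- img[i + drs[h], j + dcs[h]]
        if (nb - img[i, j] >= 0) code <- code + 2^(h - 1)
      }
      out[i, j] <- code
    }
  }
  out
}

# Mann-Whitney AUC: P(score+ > score-) + 0.5 P(tie) over all pairs
mw_auc <- function(scores, truth) {
  sp <- scores[truth == "malignant"]
  sn <- scores[truth == "benign"]
  cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# small on-disk phantom dataset for classifier/pipeline tests
make_tiny_dataset <- function(n = 16, size = 32, radius = 3, seed = 1,
                              dir = tempfile("lungcbo_fix_")) {
  spec <- phantom_spec("benign", image_size = size, nodule_radius_px = radius)
  m <- generate_dataset(n, 0.5, spec, dir, seed = seed)
  attr(m, "dir") <- dir
  m
}
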