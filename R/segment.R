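#' Between-class variance of a thresholded histogram
#'
#' The Otsu criterion: for thresholds `t_1 < ... < t_k`, the intensity range
#' splits into `k+1` classes (class `j` holds levels in `(t_{j-1}, t_j]`,
#' with `t_0 = -1`, `t_{k+1} = L-1`) and the between-class variance is
#' `sigma_B^2 = sum_j w_j (mu_j - mu_T)^2` with `w_j` the class probability
#' mass and `mu_j` its mean level. Empty classes contribute zero.
#'
#' @param hist Normalized histogram from [compute_histogram()] (raw counts
#'   also work; the criterion's argmax is scale-invariant, values are not).
#' @param thresholds Strictly increasing integer thresholds in `[0, L-2]`.
#' @return `sigma_B^2` as a scalar.
#' @export
between_class_variance <- function(hist, thresholds) {
  L <- length(hist)
  validate_thresholds(thresholds, L)
  total <- sum(hist)
  if (total <= 0) abort("`hist` has no mass.")
  p <- hist / total
  levels <- 0:(L - 1L)
  cw <- cumsum(p)
  cm <- cumsum(p * levels)
  mu_T <- cm[L]
  bounds <- c(0L, thresholds + 1L, L)      # class j = levels[bounds[j]..bounds[j+1]-1]
  hi <- bounds[-1]                          # index of cumulative at class end
  lo <- bounds[-length(bounds)]             # index just before class start
  w <- cw[hi] - c(0, cw)[lo + 1L]
  m <- cm[hi] - c(0, cm)[lo + 1L]
  nz <- w > 0
  sum((m[nz] - mu_T * w[nz])^2 / w[nz])
}

validate_thresholds <- function(thresholds, L) {
  if (length(thresholds) < 1L) abort("need at least one threshold.")
  if (any(thresholds != floor(thresholds))) abort("thresholds must be integers.")
  if (any(thresholds < 0) || any(thresholds > L - 2L)) {
    abort(sprintf("thresholds must lie in [0, %d].", L - 2L))
  }
  if (is.unsorted(thresholds, strictly = TRUE)) {
    abort("thresholds must be strictly increasing.")
  }
  invisible(thresholds)
}

#' Exhaustive bilevel Otsu threshold
#'
#' Scans every candidate threshold `t` in `[0, L-2]` and returns the one
#' maximizing the between-class variance; ties resolve to the smallest `t`.
#'
#' @inheritParams between_class_variance
#' @return The optimal integer threshold.
#' @export
otsu_bilevel_exhaustive <- function(hist) {
  L <- length(hist)
  if (sum(hist > 0) < 2L) abort("histogram must occupy at least two levels.")
  p <- hist / sum(hist)
  levels <- 0:(L - 1L)
  w <- cumsum(p)[seq_len(L - 1L)]
  m <- cumsum(p * levels)[seq_len(L - 1L)]
  mu_T <- sum(p * levels)
  denom <- w * (1 - w)
  sigma <- ifelse(denom > 0, (mu_T * w - m)^2 / denom, 0)
  which.max(sigma) - 1L   # which.max takes the first (smallest t) maximum
}

# Repair a continuous CBO position into a valid ThresholdSet: round, clamp,
# sort, and nudge duplicates to the nearest free level in [0, L-2].
repair_thresholds <- function(pos, L) {
  t <- sort(pmin(pmax(round(pos), 0), L - 2))
  k <- length(t)
  if (k > 1L) {
    taken <- rep(FALSE, L - 1L)           # levels 0..L-2 -> index level+1
    for (i in seq_len(k)) {
      v <- t[i]
      if (!taken[v + 1L]) { taken[v + 1L] <- TRUE; next }
      for (d in seq_len(L - 1L)) {        # nearest free level, prefer lower
        lo <- v - d; hi <- v + d
        if (lo >= 0 && !taken[lo + 1L]) { t[i] <- lo; taken[lo + 1L] <- TRUE; break }
        if (hi <= L - 2 && !taken[hi + 1L]) { t[i] <- hi; taken[hi + 1L] <- TRUE; break }
      }
    }
    t <- sort(t)
  }
  as.integer(t)
}

#' CBO-optimized multilevel Otsu thresholding
#'
#' Searches for `k` thresholds maximizing the between-class variance by
#' running Colliding Bodies Optimization over continuous positions in
#' `[0, L-2]^k`. Positions are repaired (rounded, sorted, duplicates nudged
#' to the nearest free level) before each evaluation, and the minimized
#' fitness is `1 / (1 + sigma_B^2)`, which is positive as the body-mass rule
#' requires while being monotone in the Otsu objective.
#'
#' @param image Integer intensity matrix.
#' @param k Number of thresholds (>= 1, fewer than the number of distinct
#'   intensity levels present).
#' @param config Optional [cbo_config()]; default uses 20 bodies and 100
#'   iterations.
#' @param seed Seed used when `config` is not supplied.
#' @param L Number of gray levels.
#' @return List with `thresholds` (integer vector, strictly increasing),
#'   `sigma_b2`, and the underlying `cbo_result`.
#' @export
cbo_multilevel_threshold <- function(image, k = 1L, config = NULL, seed = 1L,
                                     L = 256L) {
  check_gray_image(image, L)
  if (k < 1L) abort("`k` must be at least 1.")
  n_levels <- length(unique(as.integer(image)))
  if (n_levels <= k) abort("image must have more distinct levels than thresholds.")
  hist <- compute_histogram(image, L)
  if (is.null(config)) {
    config <- cbo_config(n = 20L, dims = k, lower = rep(0, k),
                         upper = rep(L - 2, k), max_iters = 100L, seed = seed)
  }
  objective <- function(pos) {
    1 / (1 + between_class_variance(hist, repair_thresholds(pos, L)))
  }
  res <- cbo_optimize(objective, config, lower_bound = 0)
  thresholds <- repair_thresholds(res$best_position, L)
  list(thresholds = thresholds,
       sigma_b2 = between_class_variance(hist, thresholds),
       cbo = res)
}

#' Apply thresholds to an image
#'
#' Pixel value `v` receives label `j` where `t_{j-1} < v <= t_j`
#' (labels `0..k` for `k` thresholds).
#'
#' @inheritParams cbo_multilevel_threshold
#' @param thresholds Strictly increasing integer thresholds.
#' @return Integer label matrix of the same shape.
#' @export
apply_thresholds <- function(image, thresholds, L = 256L) {
  check_gray_image(image, L)
  validate_thresholds(thresholds, L)
  lab <- findInterval(as.integer(image) - 1L, thresholds) # count of t < v
  matrix(as.integer(lab), nrow(image), ncol(image))
}

#' Extract nodule regions from a label image
#'
#' Connected components of the chosen foreground label under 8-connectivity.
#' Components smaller than `min_area` are dropped; the rest are returned
#' sorted by area, largest first. Coordinates are 0-based `(row, col)`;
#' bounding boxes are half-open `[min_row, max_row) x [min_col, max_col)`.
#'
#' @param label_image Integer label matrix (e.g. from [apply_thresholds()]).
#' @param foreground_label Label value treated as nodule tissue.
#' @param min_area Minimum component area in pixels.
#' @param intensity_image Optional original intensity image for
#'   `mean_intensity` (otherwise `NA`).
#' @return Tibble with columns `area`, `centroid_row`, `centroid_col`,
#'   `bbox_min_row`, `bbox_min_col`, `bbox_max_row`, `bbox_max_col`,
#'   `equivalent_diameter`, `mean_intensity`, and a list-column `pixel_idx`
#'   of linear pixel indices (for masking downstream feature extraction).
#' @export
extract_nodules <- function(label_image, foreground_label = NULL, min_area = 1L,
                            intensity_image = NULL) {
  if (!is.matrix(label_image)) abort("`label_image` must be a matrix.")
  if (is.null(foreground_label)) foreground_label <- max(label_image)
  fg <- label_image == foreground_label
  comp <- cpp_label_components(fg)
  n <- max(comp)
  if (n == 0L) return(empty_nodule_table())
  rows0 <- row(comp) - 1L
  cols0 <- col(comp) - 1L
  regions <- purrr::map(seq_len(n), function(id) {
    idx <- which(comp == id)
    area <- length(idx)
    if (area < min_area) return(NULL)
    r <- rows0[idx]; c <- cols0[idx]
    tibble(
      area = area,
      centroid_row = mean(r), centroid_col = mean(c),
      bbox_min_row = min(r), bbox_min_col = min(c),
      bbox_max_row = max(r) + 1L, bbox_max_col = max(c) + 1L,
      equivalent_diameter = sqrt(4 * area / pi),
      mean_intensity = if (is.null(intensity_image)) NA_real_
                       else mean(intensity_image[idx]),
      pixel_idx = list(idx)
    )
  })
  out <- dplyr::bind_rows(regions)
  if (nrow(out) == 0L) return(empty_nodule_table())
  dplyr::arrange(out, dplyr::desc(.data$area))
}

empty_nodule_table <- function() {
  tibble(
    area = integer(), centroid_row = double(), centroid_col = double(),
    bbox_min_row = integer(), bbox_min_col = integer(),
    bbox_max_row = integer(), bbox_max_col = integer(),
    equivalent_diameter = double(), mean_intensity = double(),
    pixel_idx = list()
  )
}
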