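#' Local binary pattern neighbor offsets
#'
#' Sampling points lie on a circle of radius `R` around the centre pixel;
#' neighbor `h = 0` sits due east and the index proceeds counterclockwise
#' (in the usual Cartesian sense; image rows grow downward, so the row
#' offset is the negated sine). Circle points are snapped to the nearest
#' pixel (nearest-neighbor sampling).
#'
#' @param H Number of sampling points (>= 4).
#' @param R Circle radius in pixels (>= 1).
#' @return Integer matrix `H x 2` of `(row, col)` offsets.
#' @export
lbp_offsets <- function(H = 8L, R = 1L) {
  if (H < 4L) abort("`H` must be at least 4.")
  if (R < 1L) abort("`R` must be at least 1.")
  h <- 0:(H - 1L)
  angle <- 2 * pi * h / H
  cbind(row = as.integer(round(-R * sin(angle))),
        col = as.integer(round(R * cos(angle))))
}

#' LBP code of a single pixel
#'
#' `code = sum_h G(p_h - p_c) * 2^h` with `G(x) = 1` when `x >= 0` and 0
#' otherwise: each neighbor at least as bright as the centre sets its bit.
#' Note `G(0) = 1`, so a flat patch codes to `2^H - 1`.
#'
#' @param center Centre pixel intensity.
#' @param neighbors Intensities `p_0 .. p_{H-1}` in neighbor order.
#' @return Integer code in `[0, 2^H - 1]`.
#' @export
#' @examples
#' lbp_code(5, c(6, 4, 5, 7, 2, 5, 9, 1))  # 109
lbp_code <- function(center, neighbors) {
  H <- length(neighbors)
  if (H < 1L) abort("`neighbors` must be non-empty.")
  bits <- as.integer(neighbors - center >= 0)
  sum(bits * 2^(seq_len(H) - 1L))
}

#' LBP code image
#'
#' Codes every interior pixel (at least `R` from each border); border pixels
#' are left `NA` rather than padded, since padding would fabricate texture
#' at the image edge.
#'
#' @param image Integer intensity matrix, larger than `2R + 1` per side.
#' @inheritParams lbp_offsets
#' @return Matrix of codes, same shape as `image`, `NA` on the border.
#' @export
lbp_map <- function(image, H = 8L, R = 1L) {
  check_gray_image(image, L = max(image) + 1)
  nr <- nrow(image); nc <- ncol(image)
  if (nr <= 2 * R + 1 || nc <= 2 * R + 1) {
    abort("image too small for the requested LBP radius.")
  }
  off <- lbp_offsets(H, R)
  ri <- (R + 1):(nr - R)
  ci <- (R + 1):(nc - R)
  centre <- image[ri, ci, drop = FALSE]
  codes <- matrix(0L, length(ri), length(ci))
  for (h in seq_len(H)) {
    nb <- image[ri + off[h, 1], ci + off[h, 2], drop = FALSE]
    codes <- codes + as.integer(nb - centre >= 0) * 2L^(h - 1L)
  }
  out <- matrix(NA_integer_, nr, nc)
  out[ri, ci] <- codes
  out
}

#' LBP code histogram
#'
#' Normalized `2^H`-bin histogram of the coded pixels, optionally restricted
#' to a mask.
#'
#' @param code_image Code matrix from [lbp_map()] (`NA` entries ignored).
#' @param mask Optional logical matrix (or vector of linear indices)
#'   selecting pixels; intersected with the coded region.
#' @param H Number of sampling points the codes were built with.
#' @return Numeric vector of `2^H` fractions summing to 1, named by code.
#' @export
lbp_histogram <- function(code_image, mask = NULL, H = 8L) {
  codes <- code_image
  if (!is.null(mask)) {
    codes <- if (is.logical(mask)) code_image[mask] else code_image[mask]
  }
  codes <- codes[!is.na(codes)]
  if (length(codes) == 0L) abort("no coded pixels in the requested region.")
  nbins <- 2L^H
  counts <- tabulate(codes + 1L, nbins = nbins)
  setNames(counts / length(codes), 0:(nbins - 1L))
}

#' Nodule feature vector
#'
#' Concatenates the LBP histogram over the nodule's pixels with its shape
#' and intensity summary: `(2^H bins, area, equivalent_diameter,
#' centroid_row, centroid_col, mean_intensity)` - length `2^H + 5`.
#'
#' @param image Intensity image the region was extracted from.
#' @param nodule One row of the tibble returned by [extract_nodules()].
#' @inheritParams lbp_offsets
#' @return Named numeric vector of length `2^H + 5`.
#' @export
feature_vector <- function(image, nodule, H = 8L, R = 1L) {
  if (nrow(nodule) != 1L) abort("`nodule` must be a single region (one row).")
  codes <- lbp_map(image, H = H, R = R)
  idx <- nodule$pixel_idx[[1]]
  coded <- idx[!is.na(codes[idx])]
  if (length(coded) == 0L) abort("nodule region does not intersect the coded area.")
  hist <- lbp_histogram(codes, mask = coded, H = H)
  mean_int <- if (is.na(nodule$mean_intensity)) mean(image[idx]) else nodule$mean_intensity
  c(hist,
    area = as.numeric(nodule$area),
    equivalent_diameter = nodule$equivalent_diameter,
    centroid_row = nodule$centroid_row,
    centroid_col = nodule$centroid_col,
    mean_intensity = mean_int)
}
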