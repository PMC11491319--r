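#' Read and write 8-bit grayscale images
#'
#' Thin PNG wrappers: images are plain integer matrices with intensities in
#' `[0, L-1]`. Multi-channel PNGs are reduced to their first channel.
#'
#' @param path File path.
#' @param image Integer matrix.
#' @param L Number of gray levels (default 256).
#' @return `read_gray_image()` returns an integer matrix;
#'   `write_gray_image()` returns `path` invisibly.
#' @export
read_gray_image <- function(path, L = 256L) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  matrix(as.integer(round(px * (L - 1))), nrow(px), ncol(px))
}

#' @rdname read_gray_image
#' @export
write_gray_image <- function(image, path, L = 256L) {
  check_gray_image(image, L)
  png::writePNG(image / (L - 1), path)
  invisible(path)
}

#' Normalized intensity histogram
#'
#' `Z[n+1]` is the fraction of pixels at intensity `n`, for `n = 0..L-1`;
#' the entries sum to one.
#'
#' @param image Integer matrix with intensities in `[0, L-1]`.
#' @param L Number of gray levels.
#' @return Numeric vector of length `L` (names are the intensity levels).
#' @export
#' @examples
#' compute_histogram(matrix(c(0, 1, 1, 3), 2), L = 4)
compute_histogram <- function(image, L = 256L) {
  check_gray_image(image, L)
  counts <- tabulate(as.integer(image) + 1L, nbins = L)
  setNames(counts / length(image), 0:(L - 1L))
}

# round half away from zero (intensities are non-negative here)
round_half_up <- function(x) floor(x + 0.5)

#' Histogram equalization
#'
#' Remaps each intensity `v` to `round((L-1) * CDF(v))` where `CDF` is the
#' image's cumulative normalized histogram, rounding half away from zero.
#' The mapping is monotone non-decreasing; no CDF-minimum renormalization is
#' applied, so a constant image maps to intensity `L-1`.
#'
#' @inheritParams compute_histogram
#' @return The equalized image (integer matrix, same shape).
#' @export
#' @examples
#' equalize(matrix(c(0, 1, 1, 3), 2), L = 4)  # -> 1, 2, 2, 3
equalize <- function(image, L = 256L) {
  Z <- compute_histogram(image, L)
  cdf <- cumsum(Z)
  map <- as.integer(pmin(pmax(round_half_up((L - 1) * cdf), 0), L - 1L))
  matrix(map[as.integer(image) + 1L], nrow(image), ncol(image))
}

#' Median filter
#'
#' Each output pixel is the median of the `window x window` neighborhood
#' centred on it; image borders are handled by edge replication.
#'
#' @inheritParams compute_histogram
#' @param window Odd window size, at least 3.
#' @return Filtered image (integer matrix).
#' @export
median_filter <- function(image, window = 3L, L = 256L) {
  check_gray_image(image, L)
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) {
    abort("`window` must be an odd integer >= 3.")
  }
  storage.mode(image) <- "integer"
  cpp_median_filter(image, window)
}

#' Kolmogorov-Smirnov distance to the uniform intensity distribution
#'
#' Sup-distance between the image's discrete intensity CDF and the uniform
#' CDF on `0..L-1`; used to quantify how much equalization flattens an
#' image's histogram.
#'
#' @inheritParams compute_histogram
#' @return A scalar in `[0, 1]`.
#' @export
ks_uniform_distance <- function(image, L = 256L) {
  cdf <- cumsum(compute_histogram(image, L))
  uniform <- (seq_len(L)) / L
  max(abs(cdf - uniform))
}
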