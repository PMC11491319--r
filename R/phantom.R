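#' Specify a synthetic lung-CT phantom
#'
#' Builds the parameter set for one synthetic axial "CT slice": two dark
#' elliptical lung fields on a brighter soft-tissue background, a single
#' circular nodule inside the left lung field, intra-nodule texture, additive
#' Gaussian noise and a low-frequency multiplicative bias field. Malignant
#' phantoms differ from benign ones by a spiculated (radially perturbed)
#' margin and stronger intra-nodule texture; benign nodules are smooth and
#' near-homogeneous, mirroring the margin/texture cues radiologists use.
#'
#' Class-conditional defaults: benign phantoms get
#' `spiculation_amplitude = 0`, `texture_contrast = 8`; malignant phantoms get
#' `spiculation_amplitude = 0.3`, `texture_contrast = 45`. Explicit arguments
#' always override these.
#'
#' @param nodule_class `"benign"` or `"malignant"`.
#' @param image_size Pixels per side (square image), at least 32.
#' @param background_level Soft-tissue intensity (0..L-1).
#' @param lung_level Lung-field intensity, darker than the background.
#' @param nodule_level Mean nodule intensity.
#' @param nodule_radius_px Nodule radius in pixels; 0 means no nodule.
#' @param spiculation_amplitude Relative radial margin perturbation (>= 0);
#'   0 gives a perfect disk.
#' @param texture_contrast Amplitude of intra-nodule texture (intensity units).
#' @param noise_sd Additive Gaussian noise standard deviation.
#' @param bias_amplitude Peak intensity excursion of the multiplicative
#'   low-frequency shading field.
#' @param seed Integer seed; identical specs give bit-identical phantoms.
#' @param L Number of gray levels (default 256).
#'
#' @return An object of class `phantom_spec` (a named list).
#' @export
#' @examples
#' spec <- phantom_spec("malignant", seed = 7)
#' ph <- generate_phantom(spec)
#' dim(ph$image)
phantom_spec <- function(nodule_class = c("benign", "malignant"),
                         image_size = 128L,
                         background_level = 180,
                         lung_level = 60,
                         nodule_level = 140,
                         nodule_radius_px = 10,
                         spiculation_amplitude = NULL,
                         texture_contrast = NULL,
                         noise_sd = 5,
                         bias_amplitude = 30,
                         seed = 1L,
                         L = 256L) {
  nodule_class <- match.arg(nodule_class)
  if (is.null(spiculation_amplitude)) {
    spiculation_amplitude <- if (nodule_class == "malignant") 0.3 else 0
  }
  if (is.null(texture_contrast)) {
    texture_contrast <- if (nodule_class == "malignant") 45 else 8
  }
  spec <- structure(
    list(
      nodule_class = nodule_class,
      image_size = as.integer(image_size),
      background_level = background_level,
      lung_level = lung_level,
      nodule_level = nodule_level,
      nodule_radius_px = nodule_radius_px,
      spiculation_amplitude = spiculation_amplitude,
      texture_contrast = texture_contrast,
      noise_sd = noise_sd,
      bias_amplitude = bias_amplitude,
      seed = as.integer(seed),
      L = as.integer(L)
    ),
    class = "phantom_spec"
  )
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (spec$image_size < 32L) abort("`image_size` must be at least 32.")
  lv <- c(spec$background_level, spec$lung_level, spec$nodule_level,
          spec$texture_contrast, spec$noise_sd, spec$bias_amplitude)
  if (any(lv < 0) || any(lv > spec$L - 1)) {
    abort(sprintf("all intensity parameters must lie in [0, %d].", spec$L - 1L))
  }
  if (spec$spiculation_amplitude < 0) abort("`spiculation_amplitude` must be >= 0.")
  if (spec$nodule_radius_px < 0) abort("`nodule_radius_px` must be >= 0.")
  geo <- phantom_geometry(spec$image_size)
  r_max <- spec$nodule_radius_px * (1 + spec$spiculation_amplitude)
  if (r_max > 0.9 * min(geo$a, geo$b)) {
    abort(sprintf(
      "nodule (max radius %.1f px) does not fit inside the lung field (limit %.1f px).",
      r_max, 0.9 * min(geo$a, geo$b)
    ))
  }
  invisible(spec)
}

# Lung-field geometry: two ellipses, nodule hosted at the left lung centre.
phantom_geometry <- function(S) {
  list(
    a = 0.32 * S,                   # ellipse semi-axis, rows
    b = 0.16 * S,                   # ellipse semi-axis, cols
    c_row = 0.5 * S,
    left_col = 0.30 * S,
    right_col = 0.70 * S,
    nodule_row = 0.5 * S,
    nodule_col = 0.30 * S
  )
}

#' Generate one synthetic lung phantom
#'
#' Renders the phantom described by a [phantom_spec()]: ground-truth nodule
#' mask plus the quantized 8-bit image. The nodule boundary is
#' `r(theta) = r0 * (1 + a * s(theta))` where `s` is a seeded sum of two
#' sinusoidal lobes; `a = 0` (benign default) rasterizes an exact disk. A
#' pixel belongs to the mask when its centre lies inside that boundary.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `image` (integer matrix), `mask` (logical
#'   matrix, `TRUE` on nodule pixels) and `label` (the nodule class).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  validate_phantom_spec(spec)
  S <- spec$image_size
  L <- spec$L
  geo <- phantom_geometry(S)

  rows <- matrix(seq_len(S) - 1, S, S)        # 0-based pixel-centre coords
  cols <- matrix(seq_len(S) - 1, S, S, byrow = TRUE)

  in_left  <- ((rows - geo$c_row) / geo$a)^2 + ((cols - geo$left_col)  / geo$b)^2 <= 1
  in_right <- ((rows - geo$c_row) / geo$a)^2 + ((cols - geo$right_col) / geo$b)^2 <= 1

  img <- matrix(spec$background_level, S, S)
  img[in_left | in_right] <- spec$lung_level

  withr::with_seed(spec$seed, {
    # nodule margin: radius perturbed by two random sinusoidal lobes
    k1 <- sample(5:9, 1)
    k2 <- sample(11:15, 1)
    ph1 <- runif(1, 0, 2 * pi)
    ph2 <- runif(1, 0, 2 * pi)
    dr <- rows - geo$nodule_row
    dc <- cols - geo$nodule_col
    dist <- sqrt(dr^2 + dc^2)
    theta <- atan2(-dr, dc)   # counterclockwise angle in Cartesian convention
    perturb <- (sin(k1 * theta + ph1) + 0.5 * sin(k2 * theta + ph2)) / 1.5
    r_bound <- spec$nodule_radius_px * (1 + spec$spiculation_amplitude * perturb)
    mask <- spec$nodule_radius_px > 0 & dist <= r_bound

    # intra-nodule texture: iid uniform field scaled by texture_contrast
    texture <- matrix(runif(S * S, -1, 1), S, S)
    img[mask] <- spec$nodule_level + spec$texture_contrast * texture[mask]

    # low-frequency multiplicative shading
    if (spec$bias_amplitude > 0) {
      shade <- 2 * sin(pi * rows / S) * sin(pi * cols / S) - 1
      img <- img * (1 + (spec$bias_amplitude / (L - 1)) * shade)
    }

    if (spec$noise_sd > 0) {
      img <- img + matrix(rnorm(S * S, 0, spec$noise_sd), S, S)
    }
  })

  img <- matrix(as.integer(pmin(pmax(round(img), 0), L - 1)), S, S)
  list(image = img, mask = mask, label = spec$nodule_class)
}

#' Generate a phantom dataset on disk
#'
#' Writes `n` phantom images (and their ground-truth masks) as 8-bit
#' grayscale PNGs plus a `manifest.csv`, and returns the manifest as a
#' tibble. Per-image seeds are derived from the master seed by a counter
#' (`seed + i`), so any subset regenerates identically regardless of order.
#'
#' @param n Number of images (>= 2).
#' @param class_balance Fraction of malignant images, in (0, 1);
#'   `round(n * class_balance)` phantoms are malignant.
#' @param base_spec Template [phantom_spec()]; class, seed and per-class
#'   texture/spiculation defaults are overridden per image.
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed.
#' @return A manifest tibble with columns `image_path`, `label`, `split`,
#'   `fold`; the directory is carried in attribute `"dir"`.
#' @export
generate_dataset <- function(n, class_balance = 0.5, base_spec = phantom_spec(),
                             out_dir, seed = 1L) {
  if (n < 2) abort("`n` must be at least 2.")
  if (class_balance <= 0 || class_balance >= 1) {
    abort("`class_balance` must be strictly between 0 and 1.")
  }
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create output directory '%s'.", out_dir))
  }
  n_mal <- round(n * class_balance)
  labels <- rep(c("malignant", "benign"), c(n_mal, n - n_mal))
  # deterministic interleaving: alternate classes as far as counts allow
  labels <- labels[order(c(seq_len(n_mal) * 2 - 1,
                           seq_len(n - n_mal) * 2))]

  records <- purrr::map(seq_len(n), function(i) {
    # per-class texture/spiculation defaults re-derived for each image
    tmpl <- phantom_spec(labels[i],
      image_size = base_spec$image_size,
      background_level = base_spec$background_level,
      lung_level = base_spec$lung_level,
      nodule_level = base_spec$nodule_level,
      nodule_radius_px = base_spec$nodule_radius_px,
      noise_sd = base_spec$noise_sd,
      bias_amplitude = base_spec$bias_amplitude,
      seed = as.integer(seed + i), L = base_spec$L
    )
    ph <- generate_phantom(tmpl)
    stem <- sprintf("img_%04d", i)
    write_gray_image(ph$image, file.path(out_dir, paste0(stem, ".png")), L = tmpl$L)
    png::writePNG(ifelse(ph$mask, 1, 0), file.path(out_dir, paste0(stem, "_mask.png")))
    tibble(image_path = paste0(stem, ".png"), label = labels[i],
           split = "unassigned", fold = NA_integer_)
  })
  manifest <- dplyr::bind_rows(records)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  attr(manifest, "dir") <- out_dir
  manifest
}

#' Read / write a dataset manifest
#'
#' The manifest CSV has header `image_path,label,split,fold`; image paths are
#' relative to the manifest's directory.
#'
#' @param manifest Manifest tibble.
#' @param path CSV file path.
#' @return `read_manifest()` returns the manifest tibble (directory in
#'   attribute `"dir"`); `write_manifest()` returns `path` invisibly.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  write.csv(manifest[, c("image_path", "label", "split", "fold")],
            path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(image_path = "character", label = "character",
                                split = "character", fold = "integer"))
  df$split[is.na(df$split) | df$split == ""] <- "unassigned"
  manifest <- as_tibble(df)
  validate_manifest(manifest)
  attr(manifest, "dir") <- dirname(path)
  manifest
}

validate_manifest <- function(manifest) {
  need <- c("image_path", "label", "split", "fold")
  if (!all(need %in% names(manifest))) {
    abort("manifest must have columns image_path, label, split, fold.")
  }
  if (anyDuplicated(manifest$image_path)) abort("manifest image paths must be unique.")
  if (!all(manifest$label %in% c("benign", "malignant"))) {
    abort("labels must be 'benign' or 'malignant'.")
  }
  if (!all(manifest$split %in% c("train", "val", "test", "unassigned"))) {
    abort("splits must be train, val, test or unassigned.")
  }
  invisible(manifest)
}

# Largest-remainder apportionment of N items to fractions; ties go to the
# earliest listed fraction.
largest_remainder_counts <- function(N, fractions) {
  q <- fractions * N
  base <- floor(q)
  rem <- N - sum(base)
  if (rem > 0) {
    frac <- q - base
    ord <- order(-frac, seq_along(frac))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Assign train/validation/test splits
#'
#' Shuffles the manifest with the given seed and apportions records to the
#' three splits by largest-remainder apportionment of `fraction * N`: each
#' split first receives the floor of its quota, then the remaining records go
#' to the largest fractional parts, ties broken in train, val, test order.
#' With N = 1135 and fractions (0.70, 0.10, 0.20) this yields 795/113/227.
#'
#' @param manifest Manifest tibble.
#' @param fractions Numeric length-3 vector `(train, val, test)`, positive,
#'   summing to 1.
#' @param seed Shuffle seed.
#' @return The manifest with its `split` column assigned.
#' @export
split_dataset <- function(manifest, fractions = c(0.70, 0.10, 0.20), seed = 1L) {
  validate_manifest(manifest)
  if (length(fractions) != 3 || any(fractions <= 0)) {
    abort("`fractions` must be three positive numbers (train, val, test).")
  }
  if (abs(sum(fractions) - 1) > 1e-9) abort("`fractions` must sum to 1.")
  N <- nrow(manifest)
  if (N < 3) abort("need at least 3 records for three non-empty splits.")
  counts <- largest_remainder_counts(N, fractions)
  perm <- withr::with_seed(seed, sample.int(N))
  split <- character(N)
  split[perm[seq_len(counts[1])]] <- "train"
  split[perm[counts[1] + seq_len(counts[2])]] <- "val"
  split[perm[counts[1] + counts[2] + seq_len(counts[3])]] <- "test"
  manifest$split <- split
  manifest
}

#' Assign cross-validation folds
#'
#' Shuffles records and deals them into `k` folds whose sizes differ by at
#' most one (the first `N %% k` folds take the extra record). With `k = 5`
#' each held-out fold is ~20% of the data, the four-folds-train /
#' one-fold-test arrangement.
#'
#' @param manifest Manifest tibble.
#' @param k Number of folds (>= 2, <= N).
#' @param seed Shuffle seed.
#' @return The manifest with its `fold` column set to values in `1..k`.
#' @export
kfold_assign <- function(manifest, k, seed = 1L) {
  validate_manifest(manifest)
  N <- nrow(manifest)
  if (k < 2) abort("`k` must be at least 2.")
  if (k > N) abort("`k` cannot exceed the number of records.")
  sizes <- rep(N %/% k, k) + c(rep(1L, N %% k), rep(0L, k - N %% k))
  perm <- withr::with_seed(seed, sample.int(N))
  fold <- integer(N)
  fold[perm] <- rep(seq_len(k), sizes)
  manifest$fold <- fold
  manifest
}
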