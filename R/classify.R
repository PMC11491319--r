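#' Configure a DenseNet-style classifier
#'
#' A small densely connected convolutional network for benign/malignant
#' image classification: an initial 3x3 convolution to `initial_channels`
#' feature maps followed by a 2x2 average-pool downsampling, `num_blocks`
#' dense blocks (each layer applies batch normalization, ReLU and a 3x3
#' convolution producing `growth_rate` maps, concatenated with every earlier
#' map in the block, so layer `l` sees `k_in + (l-1) * growth_rate` input
#' channels), compression transitions between blocks (1x1 convolution to
#' `ceil(compression * channels)` then 2x2 average pooling), and a final
#' batch-norm/ReLU/global-average-pool/2-way-softmax head.
#'
#' The default geometry (2 blocks x 2 layers, growth 8, 64x64 input) is
#' sized for CPU training on synthetic phantoms; every field is
#' configurable.
#'
#' @param input_size Input side length in pixels; must be divisible by
#'   `2^num_blocks` (one halving from the initial pool plus one per
#'   transition).
#' @param initial_channels Feature maps after the initial convolution.
#' @param num_blocks Number of dense blocks.
#' @param layers_per_block Convolutional layers per dense block.
#' @param growth_rate Feature maps added by each dense-block layer.
#' @param compression Transition compression factor in `(0, 1]`.
#' @param num_classes Number of output classes (2: benign, malignant).
#' @param seed Weight-initialization seed.
#' @return Object of class `densenet_config`.
#' @export
densenet_config <- function(input_size = 64L, initial_channels = 16L,
                            num_blocks = 2L, layers_per_block = 2L,
                            growth_rate = 8L, compression = 0.5,
                            num_classes = 2L, seed = 1L) {
  cfg <- list(
    input_size = as.integer(input_size),
    initial_channels = as.integer(initial_channels),
    num_blocks = as.integer(num_blocks),
    layers_per_block = as.integer(layers_per_block),
    growth_rate = as.integer(growth_rate),
    compression = compression,
    num_classes = as.integer(num_classes),
    seed = as.integer(seed)
  )
  if (any(unlist(cfg[1:5]) < 1L)) abort("all architecture sizes must be positive.")
  if (cfg$compression <= 0 || cfg$compression > 1) {
    abort("`compression` must lie in (0, 1].")
  }
  if (cfg$input_size %% 2L^cfg$num_blocks != 0L) {
    abort("`input_size` must be divisible by 2^num_blocks.")
  }
  if (cfg$input_size / 2L^cfg$num_blocks < 1L) abort("`input_size` too small.")
  structure(cfg, class = "densenet_config")
}

# Walk the architecture and report every parameter's shape, in the canonical
# flat order shared with the C++ kernels. Returns a list of lists
# (name, type = "conv"/"vec"/"bn", dims).
dn_param_plan <- function(config) {
  plan <- list()
  add <- function(name, rows, cols = NULL) {
    plan[[length(plan) + 1L]] <<- list(name = name, rows = rows, cols = cols)
  }
  add("conv0_W", config$initial_channels, 9L)
  add("conv0_b", config$initial_channels)
  C <- config$initial_channels
  for (b in seq_len(config$num_blocks)) {
    for (l in seq_len(config$layers_per_block)) {
      pre <- sprintf("b%d_l%d", b, l)
      add(paste0(pre, "_gamma"), C)
      add(paste0(pre, "_beta"), C)
      add(paste0(pre, "_W"), config$growth_rate, 9L * C)
      add(paste0(pre, "_b"), config$growth_rate)
      C <- C + config$growth_rate
    }
    if (b < config$num_blocks) {
      Ct <- as.integer(ceiling(config$compression * C))
      pre <- sprintf("t%d", b)
      add(paste0(pre, "_gamma"), C)
      add(paste0(pre, "_beta"), C)
      add(paste0(pre, "_W"), Ct, C)
      add(paste0(pre, "_b"), Ct)
      C <- Ct
    }
  }
  add("final_gamma", C)
  add("final_beta", C)
  add("fc_W", config$num_classes, C)
  add("fc_b", config$num_classes)
  plan
}

#' Build a DenseNet-style model
#'
#' Initializes all weights (He-scaled Gaussians for convolutions and the
#' classifier, unit gain / zero shift for batch-norm) from the config seed.
#'
#' @param config A [densenet_config()].
#' @return Object of class `densenet` with elements `config`, `params`
#'   (named list of weight arrays), `rstats` (batch-norm running statistics)
#'   and `history` (`NULL` until trained).
#' @export
build_densenet <- function(config) {
  stopifnot(inherits(config, "densenet_config"))
  plan <- dn_param_plan(config)
  params <- withr::with_seed(config$seed, {
    purrr::map(plan, function(p) {
      if (!is.null(p$cols)) {
        fan_in <- p$cols
        matrix(rnorm(p$rows * p$cols, sd = sqrt(2 / fan_in)), p$rows, p$cols)
      } else if (grepl("_gamma$", p$name)) {
        rep(1, p$rows)
      } else {
        rep(0, p$rows)
      }
    })
  })
  names(params) <- purrr::map_chr(plan, "name")
  n_bn <- sum(grepl("_gamma$", names(params)))
  rstats <- vector("list", 2L * n_bn)
  bn_dims <- purrr::map_int(plan[grepl("_gamma$", purrr::map_chr(plan, "name"))],
                            "rows")
  for (i in seq_len(n_bn)) {
    rstats[[2L * i - 1L]] <- rep(0, bn_dims[i])  # running mean
    rstats[[2L * i]] <- rep(1, bn_dims[i])       # running variance
  }
  structure(
    list(config = config, params = params, rstats = rstats, history = NULL),
    class = "densenet"
  )
}

#' @export
print.densenet <- function(x, ...) {
  cfg <- x$config
  n_par <- sum(purrr::map_int(x$params, length))
  cat("<densenet>", cfg$num_blocks, "blocks x", cfg$layers_per_block,
      "layers, growth", cfg$growth_rate, ", input",
      paste0(cfg$input_size, "x", cfg$input_size), "\n")
  cat("  parameters:", n_par,
      if (is.null(x$history)) " (untrained)" else sprintf(
        " (trained %d epochs)", max(x$history$epoch)), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.densenet <- function(x, ...) {
  tibble(
    parameter = names(x$params),
    shape = purrr::map_chr(x$params, function(p) {
      if (is.matrix(p)) paste(dim(p), collapse = "x") else as.character(length(p))
    }),
    n = purrr::map_int(x$params, length)
  )
}

#' @exportS3Method generics::glance
glance.densenet <- function(x, ...) {
  h <- x$history
  tibble(
    n_parameters = sum(purrr::map_int(x$params, length)),
    epochs = if (is.null(h)) 0L else max(h$epoch),
    selected_epoch = if (is.null(x$selected_epoch)) NA_integer_
                     else as.integer(x$selected_epoch),
    final_train_loss = if (is.null(h)) NA_real_ else tail(h$train_loss, 1),
    final_val_acc = if (is.null(h)) NA_real_ else tail(h$val_acc, 1)
  )
}

# Nearest-neighbor resize to a square side; identity when already that size.
resize_nearest <- function(image, size) {
  if (nrow(image) == size && ncol(image) == size) return(image)
  ri <- pmin(pmax(round((seq_len(size) - 0.5) * nrow(image) / size + 0.5), 1),
             nrow(image))
  ci <- pmin(pmax(round((seq_len(size) - 0.5) * ncol(image) / size + 0.5), 1),
             ncol(image))
  image[ri, ci, drop = FALSE]
}

# Input contract shared by training and prediction: equalize, resize to the
# network input size, map intensities to [-0.5, 0.5].
dn_prepare_image <- function(image, input_size, equalize_input = TRUE,
                             L = 256L) {
  if (equalize_input) image <- equalize(image, L)
  image <- resize_nearest(image, input_size)
  as.numeric(image) / (L - 1) - 0.5
}

dn_load_split <- function(manifest, split, input_size, dir, equalize_input,
                          L = 256L) {
  rows <- manifest[manifest$split %in% split, , drop = FALSE]
  if (nrow(rows) == 0L) return(NULL)
  X <- vapply(rows$image_path, function(p) {
    dn_prepare_image(read_gray_image(file.path(dir, p), L), input_size,
                     equalize_input, L)
  }, numeric(input_size^2))
  list(X = matrix(X, input_size^2, nrow(rows)),
       y = as.integer(rows$label == "malignant"),
       labels = rows$label)
}

#' Train a DenseNet-style classifier
#'
#' Minimizes softmax cross-entropy by mini-batch Adam. Images are read from
#' the manifest's `train` split, equalized, resized to the network input
#' size and scaled to `[-0.5, 0.5]`; validation uses the `val` split when
#' present, otherwise a seeded fraction of the training records. Per-epoch
#' train/validation loss and accuracy are logged in `model$history`.
#'
#' @param model A [build_densenet()] model.
#' @param manifest Manifest tibble with assigned splits; image paths resolve
#'   against `dir`.
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param learning_rate Adam step size.
#' @param validation_fraction Fraction of training records held out when the
#'   manifest has no `val` split, in `[0, 1)`.
#' @param seed Seed for shuffling and the optimizer.
#' @param dir Dataset directory; defaults to the manifest's `"dir"` attribute.
#' @param equalize_input Apply histogram equalization before the network
#'   (the default preprocessing path).
#' @param select_best Restore the parameters from the epoch with the lowest
#'   validation loss (standard early-stopping-style model selection); only
#'   applies when a validation set exists.
#' @return The trained model (history attached; the selected epoch is
#'   reported by [glance()]).
#' @export
densenet_train <- function(model, manifest, epochs = 10L, batch_size = 32L,
                           learning_rate = 1e-3, validation_fraction = 0.2,
                           seed = 1L, dir = attr(manifest, "dir"),
                           equalize_input = TRUE, select_best = TRUE) {
  stopifnot(inherits(model, "densenet"))
  validate_manifest(manifest)
  if (epochs < 1L || batch_size < 1L || learning_rate <= 0) {
    abort("`epochs`, `batch_size` and `learning_rate` must be positive.")
  }
  if (validation_fraction < 0 || validation_fraction >= 1) {
    abort("`validation_fraction` must lie in [0, 1).")
  }
  if (is.null(dir)) abort("dataset directory unknown; pass `dir`.")
  cfg <- model$config

  train <- dn_load_split(manifest, "train", cfg$input_size, dir, equalize_input)
  if (is.null(train)) abort("manifest has no train split.")
  val <- dn_load_split(manifest, "val", cfg$input_size, dir, equalize_input)
  if (is.null(val) && validation_fraction > 0) {
    n <- ncol(train$X)
    idx <- withr::with_seed(seed, sample.int(n, max(1L, round(validation_fraction * n))))
    val <- list(X = train$X[, idx, drop = FALSE], y = train$y[idx])
    train <- list(X = train$X[, -idx, drop = FALSE], y = train$y[-idx])
  }
  if (length(unique(train$y)) < 2L) {
    abort("training split must contain both classes.")
  }

  params <- model$params
  rstats <- model$rstats
  m_adam <- purrr::map(params, function(p) p * 0)
  v_adam <- purrr::map(params, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  history <- vector("list", epochs)
  n_train <- ncol(train$X)
  best_val <- Inf
  best_state <- NULL

  withr::with_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      perm <- sample.int(n_train)
      ep_loss <- 0; ep_correct <- 0
      for (start in seq(1L, n_train, by = batch_size)) {
        idx <- perm[start:min(start + batch_size - 1L, n_train)]
        res <- dn_run(train$X[, idx, drop = FALSE], train$y[idx],
                      params, rstats, unclass(cfg),
                      training = TRUE, want_grads = TRUE)
        if (!is.finite(res$loss)) {
          abort(sprintf("non-finite training loss at epoch %d.", ep))
        }
        rstats <- res$rstats
        step <- step + 1L
        corr <- learning_rate * sqrt(1 - b2^step) / (1 - b1^step)
        for (i in seq_along(params)) {
          gr <- res$grads[[i]]
          m_adam[[i]] <- b1 * m_adam[[i]] + (1 - b1) * gr
          v_adam[[i]] <- b2 * v_adam[[i]] + (1 - b2) * gr^2
          params[[i]] <- params[[i]] - corr * m_adam[[i]] / (sqrt(v_adam[[i]]) + eps)
        }
        ep_loss <- ep_loss + res$loss * length(idx)
        pred <- as.integer(res$probs[2, ] >= 0.5)
        ep_correct <- ep_correct + sum(pred == train$y[idx])
      }
      val_loss <- NA_real_; val_acc <- NA_real_
      if (!is.null(val)) {
        vres <- dn_run(val$X, val$y, params, rstats, unclass(cfg),
                       training = FALSE, want_grads = FALSE)
        val_loss <- vres$loss
        val_acc <- mean(as.integer(vres$probs[2, ] >= 0.5) == val$y)
      }
      history[[ep]] <- tibble(
        epoch = ep,
        train_loss = ep_loss / n_train,
        train_acc = ep_correct / n_train,
        val_loss = val_loss,
        val_acc = val_acc
      )
      if (select_best && !is.na(val_loss) && val_loss < best_val) {
        best_val <- val_loss
        best_state <- list(params = params, rstats = rstats, epoch = ep)
      }
    }
  })

  if (!is.null(best_state)) {
    params <- best_state$params
    rstats <- best_state$rstats
  }

  model$params <- params
  model$rstats <- rstats
  model$history <- dplyr::bind_rows(history)
  model$selected_epoch <- if (!is.null(best_state)) best_state$epoch else epochs
  model$equalize_input <- equalize_input
  model
}

#' Predict benign/malignant for one image
#'
#' Applies the documented input contract (equalize, resize to the network
#' input size, scale to `[-0.5, 0.5]`) and runs the network in inference
#' mode. A tie at probability 0.5 resolves to malignant - the cautious
#' screening choice.
#'
#' @param object A `densenet` model.
#' @param image Integer intensity matrix.
#' @param L Number of gray levels.
#' @param ... Unused.
#' @return Object of class `densenet_prediction`: `label`, `probabilities`
#'   (named, summing to 1) and `message` - exactly `"Tumor is BENIGN"` or
#'   `"Tumor is MALIGNANT"`.
#' @export
predict.densenet <- function(object, image, L = 256L, ...) {
  check_gray_image(image, L)
  eq <- if (is.null(object$equalize_input)) TRUE else object$equalize_input
  x <- dn_prepare_image(image, object$config$input_size, eq, L)
  res <- dn_run(matrix(x, ncol = 1), integer(0), object$params, object$rstats,
                unclass(object$config), training = FALSE, want_grads = FALSE)
  p <- as.numeric(res$probs)
  names(p) <- c("benign", "malignant")
  label <- if (p["malignant"] >= 0.5) "malignant" else "benign"
  structure(
    list(label = label, probabilities = p,
         message = if (label == "malignant") "Tumor is MALIGNANT"
                   else "Tumor is BENIGN"),
    class = "densenet_prediction"
  )
}

#' @export
print.densenet_prediction <- function(x, ...) {
  cat(x$message, sprintf(" (P(malignant) = %.3f)\n", x$probabilities["malignant"]))
  invisible(x)
}

#' Predict over a manifest split
#'
#' @param model A trained `densenet`.
#' @param manifest Manifest tibble.
#' @param split Which split(s) to score.
#' @param dir Dataset directory.
#' @param L Number of gray levels.
#' @return Tibble with `image_path`, `label` (truth), `predicted`,
#'   `prob_malignant`, `message`.
#' @export
densenet_predict_manifest <- function(model, manifest, split = "test",
                                      dir = attr(manifest, "dir"), L = 256L) {
  stopifnot(inherits(model, "densenet"))
  if (is.null(dir)) abort("dataset directory unknown; pass `dir`.")
  rows <- manifest[manifest$split %in% split, , drop = FALSE]
  if (nrow(rows) == 0L) abort("no records in the requested split.")
  eq <- if (is.null(model$equalize_input)) TRUE else model$equalize_input
  X <- vapply(rows$image_path, function(p) {
    dn_prepare_image(read_gray_image(file.path(dir, p), L),
                     model$config$input_size, eq, L)
  }, numeric(model$config$input_size^2))
  res <- dn_run(matrix(X, model$config$input_size^2, nrow(rows)), integer(0),
                model$params, model$rstats, unclass(model$config),
                training = FALSE, want_grads = FALSE)
  prob_mal <- res$probs[2, ]
  predicted <- ifelse(prob_mal >= 0.5, "malignant", "benign")
  tibble(
    image_path = rows$image_path,
    label = rows$label,
    predicted = predicted,
    prob_malignant = prob_mal,
    message = ifelse(predicted == "malignant",
                     "Tumor is MALIGNANT", "Tumor is BENIGN")
  )
}

#' Training-history plot
#'
#' @param object A trained `densenet`.
#' @param ... Unused.
#' @return ggplot of train/validation loss per epoch.
#' @exportS3Method ggplot2::autoplot
autoplot.densenet <- function(object, ...) {
  if (is.null(object$history)) abort("model has no training history yet.")
  long <- tidyr::pivot_longer(object$history,
                              c("train_loss", "val_loss"),
                              names_to = "series", values_to = "loss")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "cross-entropy loss",
                  title = "Training history") +
    ggplot2::theme_minimal()
}

#' Save / load a model
#'
#' Serializes the model (weights, running statistics, config, history) with
#' R's native RDS format.
#'
#' @param model A `densenet`.
#' @param path File path.
#' @return `load_densenet()` returns the model; `save_densenet()` returns
#'   `path` invisibly.
#' @export
save_densenet <- function(model, path) {
  stopifnot(inherits(model, "densenet"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_densenet
#' @export
load_densenet <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "densenet")) abort("file does not contain a densenet model.")
  model
}
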