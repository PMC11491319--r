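#' In-process mock IoT transport
#'
#' Records every channel update it receives and returns a success status,
#' so pipeline and transmission logic are testable without any network.
#'
#' @return Object of class `iot_transport` whose `send(update)` appends to
#'   an internal log; inspect it with `transport$env$calls`.
#' @export
mock_transport <- function() {
  env <- new.env(parent = emptyenv())
  env$calls <- list()
  structure(
    list(
      env = env,
      send = function(update) {
        env$calls[[length(env$calls) + 1L]] <- update
        list(status_code = 200L, entry_id = length(env$calls))
      }
    ),
    class = "iot_transport"
  )
}

#' ThingSpeak-style HTTP transport
#'
#' Posts form-encoded channel updates (`api_key` plus `field1..field8`
#' parameters, the public ThingSpeak update convention) via the system
#' `curl` binary. Provided for real deployments; all tests use
#' [mock_transport()].
#'
#' @param endpoint Update URL.
#' @return An `iot_transport`.
#' @export
http_transport <- function(endpoint = "https://api.thingspeak.com/update") {
  structure(
    list(
      env = new.env(parent = emptyenv()),
      send = function(update) {
        form <- c(paste0("api_key=", utils::URLencode(update$api_key, reserved = TRUE)),
                  purrr::imap_chr(update$fields, function(v, k) {
                    paste0(k, "=", format(v))
                  }))
        args <- c("-s", "-o", "-", unlist(purrr::map(form, function(f) c("-d", f))),
                  endpoint)
        body <- suppressWarnings(system2("curl", args, stdout = TRUE, stderr = TRUE))
        id <- suppressWarnings(as.integer(paste(body, collapse = "")))
        if (is.na(id) || id <= 0) stop("channel update rejected")
        list(status_code = 200L, entry_id = id)
      }
    ),
    class = "iot_transport"
  )
}

#' Format a channel update from a metrics report
#'
#' Maps chosen metrics onto the `field1..field8` slots of a ThingSpeak-style
#' channel, as percentages rounded to 2 decimals. Only scalar metrics are
#' ever transmitted - never image data or anything patient-identifying.
#'
#' @param metrics A `metrics_report`.
#' @param mapping Named character vector `metric name -> "fieldN"`; each
#'   field slot may be used once.
#' @param api_key Channel write key.
#' @return Object of class `channel_update`: `api_key`, `fields` (named
#'   numeric list), `created_at` (POSIXct).
#' @export
#' @examples
#' m <- metrics(confusion_counts(TP = 50, TN = 40, FP = 5, FN = 5))
#' format_channel_update(m, c(accuracy = "field1"), "KEY")$fields
format_channel_update <- function(metrics,
                                  mapping = c(accuracy = "field1",
                                              sensitivity = "field2",
                                              specificity = "field3",
                                              precision = "field4"),
                                  api_key = "") {
  stopifnot(inherits(metrics, "metrics_report"))
  if (length(mapping) > 8L) abort("at most 8 metrics can be mapped.")
  if (length(mapping) > 0) {
    if (!all(mapping %in% paste0("field", 1:8))) {
      abort("mapping values must be field1..field8.")
    }
    if (anyDuplicated(mapping)) abort("each field slot may be assigned once.")
    if (!all(names(mapping) %in% c("accuracy", "sensitivity", "specificity",
                                   "precision", "auc"))) {
      abort("unknown metric name in mapping.")
    }
  }
  fields <- list()
  for (m in names(mapping)) {
    v <- metrics[[m]]
    if (is.na(v)) next                      # undefined metrics are not sent
    fields[[mapping[[m]]]] <- round(100 * v, 2)
  }
  if (length(fields) && any(!is.finite(unlist(fields)))) {
    abort("field values must be finite.")
  }
  structure(
    list(api_key = api_key, fields = fields, created_at = Sys.time()),
    class = "channel_update"
  )
}

#' Transmit a channel update
#'
#' Sends through the given transport while honoring the channel's minimum
#' update interval (free-tier ThingSpeak pacing): a send arriving too early
#' either waits (`policy = "delay"`) or is rejected with a rate-limited
#' status (`policy = "reject"`). Transport failures are caught and reported
#' as a failed status - transmission never interrupts an analysis pipeline.
#'
#' @param update A [format_channel_update()] result.
#' @param transport An `iot_transport`.
#' @param min_interval_seconds Minimum seconds between sends.
#' @param policy `"delay"` or `"reject"`.
#' @return List with `status` (`"sent"`, `"rate_limited"` or `"failed"`),
#'   `entry_id` (or `NA`), and `detail`.
#' @export
transmit <- function(update, transport, min_interval_seconds = 15,
                     policy = c("delay", "reject")) {
  stopifnot(inherits(update, "channel_update"), inherits(transport, "iot_transport"))
  policy <- match.arg(policy)
  now <- as.numeric(Sys.time())
  last <- transport$env$last_send
  if (!is.null(last) && now - last < min_interval_seconds) {
    if (policy == "reject") {
      return(list(status = "rate_limited", entry_id = NA_integer_,
                  detail = sprintf("minimum interval of %s s not elapsed",
                                   min_interval_seconds)))
    }
    Sys.sleep(min_interval_seconds - (now - last))
  }
  result <- tryCatch(
    transport$send(update),
    error = function(e) e
  )
  transport$env$last_send <- as.numeric(Sys.time())
  if (inherits(result, "error")) {
    warn(paste("channel update failed:", conditionMessage(result)))
    return(list(status = "failed", entry_id = NA_integer_,
                detail = conditionMessage(result)))
  }
  list(status = "sent", entry_id = result$entry_id, detail = "ok")
}

#' Configure an end-to-end pipeline run
#'
#' Bundles the per-stage settings for [run_pipeline()]. The input is either
#' an existing dataset manifest or a phantom-generation request; IoT
#' transmission is disabled unless explicitly enabled.
#'
#' @param manifest_path Path to an existing `manifest.csv` (or `NULL` to
#'   generate phantoms).
#' @param phantom List for phantom generation: `n`, `class_balance`, plus
#'   arguments for [phantom_spec()] (e.g. `image_size`, `nodule_radius_px`).
#' @param workdir Directory for generated data and outputs.
#' @param preprocessing Character vector, applied in order; subset of
#'   `"equalize"`, `"median"`.
#' @param segmentation List: `k` (thresholds), `n` (CBO bodies),
#'   `max_iters`, `min_area`.
#' @param lbp List: `H`, `R`.
#' @param classifier A [densenet_config()], or `NULL` for the default sized
#'   to the phantom images.
#' @param training List: `epochs`, `batch_size`, `learning_rate`; or
#'   `NULL` with `weights_path` to skip training.
#' @param weights_path Optional path to a saved model (skips training).
#' @param splits Train/val/test fractions.
#' @param iot List: `enabled`, `transport`, `api_key`, `mapping`,
#'   `min_interval_seconds`, `policy`.
#' @param seed Master seed; every stage derives its own seed from it.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(manifest_path = NULL,
                            phantom = list(n = 40, class_balance = 0.5,
                                           image_size = 64, nodule_radius_px = 7),
                            workdir = tempfile("lungcbo_run_"),
                            preprocessing = "equalize",
                            segmentation = list(k = 1, n = 20, max_iters = 100,
                                                min_area = 5),
                            lbp = list(H = 8, R = 1),
                            classifier = NULL,
                            training = list(epochs = 10, batch_size = 32,
                                            learning_rate = 1e-3),
                            weights_path = NULL,
                            splits = c(0.70, 0.10, 0.20),
                            iot = list(enabled = FALSE),
                            seed = 1L) {
  if (!is.null(manifest_path) && !file.exists(manifest_path)) {
    abort(sprintf("manifest '%s' does not exist.", manifest_path))
  }
  if (!all(preprocessing %in% c("equalize", "median"))) {
    abort("preprocessing steps must be 'equalize' and/or 'median'.")
  }
  if (!is.null(weights_path) && !file.exists(weights_path)) {
    abort(sprintf("weights file '%s' does not exist.", weights_path))
  }
  iot <- utils::modifyList(
    list(enabled = FALSE, transport = NULL, api_key = "",
         mapping = c(accuracy = "field1", sensitivity = "field2",
                     specificity = "field3", precision = "field4"),
         min_interval_seconds = 15, policy = "delay"),
    iot
  )
  structure(
    list(manifest_path = manifest_path, phantom = phantom, workdir = workdir,
         preprocessing = preprocessing, segmentation = segmentation,
         lbp = lbp, classifier = classifier, training = training,
         weights_path = weights_path, splits = splits, iot = iot,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

apply_preprocessing <- function(image, steps, L = 256L) {
  for (s in steps) {
    image <- switch(s,
      equalize = equalize(image, L),
      median = median_filter(image, 3L, L)
    )
  }
  image
}

#' Run the full analysis pipeline
#'
#' Executes ingest/generate, preprocessing, CBO-Otsu segmentation, nodule
#' extraction, LBP feature extraction, classification and evaluation on the
#' test split, and (optionally) IoT transmission of the resulting metrics.
#' Every stage seeds itself from the master seed, so a config reproduces its
#' report exactly (apart from timestamps).
#'
#' @param config A [pipeline_config()].
#' @return Object of class `pipeline_report`: `predictions` tibble
#'   (including message strings), `nodules` tibble, `thresholds` tibble,
#'   `metrics`, `roc`, `transmission`, `history`, `config_used`, `seed`.
#'   Also written as JSON to `<workdir>/run_report.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  L <- 256L

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  # --- ingest / generate ---
  manifest <- stage("ingest", {
    if (!is.null(config$manifest_path)) {
      read_manifest(config$manifest_path)
    } else {
      ph <- config$phantom
      spec_args <- ph[setdiff(names(ph), c("n", "class_balance"))]
      base_spec <- do.call(phantom_spec, c(list("benign"), spec_args))
      generate_dataset(ph$n, ph$class_balance %||% 0.5, base_spec,
                       out_dir = file.path(config$workdir, "data"),
                       seed = seed)
    }
  })
  dir <- attr(manifest, "dir")
  if (all(manifest$split == "unassigned")) {
    manifest <- split_dataset(manifest, config$splits, seed = seed + 1L)
  }

  # --- classifier: load or train ---
  img0 <- read_gray_image(file.path(dir, manifest$image_path[1]), L)
  cls_cfg <- config$classifier %||%
    densenet_config(input_size = nrow(img0), seed = seed + 2L)
  model <- stage("classify", {
    if (!is.null(config$weights_path)) {
      load_densenet(config$weights_path)
    } else {
      tr <- config$training
      densenet_train(build_densenet(cls_cfg), manifest,
                     epochs = tr$epochs, batch_size = tr$batch_size,
                     learning_rate = tr$learning_rate,
                     seed = seed + 3L, dir = dir,
                     equalize_input = "equalize" %in% config$preprocessing)
    }
  })

  # --- per-test-image segmentation, localization, features, prediction ---
  test_rows <- manifest[manifest$split == "test", , drop = FALSE]
  if (nrow(test_rows) == 0L) abort("pipeline stage 'segment' failed: no test split.")
  seg <- config$segmentation
  per_image <- purrr::imap(test_rows$image_path, function(path, i) {
    stage(paste0("segment:", path), {
      raw <- read_gray_image(file.path(dir, path), L)
      pre <- apply_preprocessing(raw, config$preprocessing, L)
      cbo_cfg <- cbo_config(n = seg$n, dims = seg$k, lower = 0, upper = L - 2,
                            max_iters = seg$max_iters, seed = seed + 10L + i)
      th <- cbo_multilevel_threshold(pre, k = seg$k, config = cbo_cfg, L = L)
      labs <- apply_thresholds(pre, th$thresholds, L)
      nod <- extract_nodules(labs, foreground_label = seg$k,
                             min_area = seg$min_area, intensity_image = raw)
      # localization: the body wall shares the bright class and always
      # touches the image border; candidate nodules are interior regions
      if (nrow(nod) > 0) {
        interior <- nod$bbox_min_row > 0 & nod$bbox_min_col > 0 &
          nod$bbox_max_row < nrow(raw) & nod$bbox_max_col < ncol(raw)
        nod <- nod[interior, , drop = FALSE]
      }
      feats <- if (nrow(nod) > 0) {
        feature_vector(pre, nod[1, ], H = config$lbp$H, R = config$lbp$R)
      } else NULL
      prd <- predict(model, raw, L = L)
      list(
        thresholds = tibble(image_path = path,
                            threshold = th$thresholds,
                            sigma_b2 = th$sigma_b2),
        nodules = if (nrow(nod) > 0) {
          dplyr::mutate(dplyr::select(nod, -"pixel_idx"),
                        image_path = path, .before = 1)
        } else NULL,
        features = feats,
        prediction = tibble(image_path = path, label = test_rows$label[i],
                            predicted = prd$label,
                            prob_malignant = unname(prd$probabilities["malignant"]),
                            message = prd$message)
      )
    })
  })

  predictions <- dplyr::bind_rows(purrr::map(per_image, "prediction"))
  nodules <- dplyr::bind_rows(purrr::map(per_image, "nodules"))
  thresholds <- dplyr::bind_rows(purrr::map(per_image, "thresholds"))

  # --- evaluation ---
  report_metrics <- stage("evaluate", {
    cm <- confusion(predictions$label, predictions$predicted)
    roc <- tryCatch(roc_curve(predictions$prob_malignant, predictions$label),
                    error = function(e) NULL)
    metrics(cm, auc = if (is.null(roc)) NULL else roc$auc)
  })
  roc <- tryCatch(roc_curve(predictions$prob_malignant, predictions$label),
                  error = function(e) NULL)

  # --- iot transmission ---
  transmission <- list(status = "disabled", entry_id = NA_integer_)
  if (isTRUE(config$iot$enabled)) {
    transport <- config$iot$transport %||% mock_transport()
    update <- format_channel_update(report_metrics, config$iot$mapping,
                                    config$iot$api_key)
    transmission <- transmit(update, transport,
                             config$iot$min_interval_seconds,
                             config$iot$policy)
    transmission$fields <- update$fields
  }

  report <- structure(
    list(
      predictions = predictions,
      nodules = nodules,
      thresholds = thresholds,
      metrics = report_metrics,
      roc = roc,
      transmission = transmission,
      history = model$history,
      seed = seed,
      config_used = serialize_pipeline_config(config),
      manifest_dir = dir
    ),
    class = "pipeline_report"
  )
  if (!dir.exists(config$workdir)) {
    dir.create(config$workdir, recursive = TRUE, showWarnings = FALSE)
  }
  write_run_report(report, file.path(config$workdir, "run_report.json"))
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# config as plain serializable data (transport objects replaced by a tag)
serialize_pipeline_config <- function(config) {
  cfg <- unclass(config)
  if (!is.null(cfg$iot$transport)) cfg$iot$transport <- "external"
  cfg$classifier <- if (is.null(cfg$classifier)) NULL else unclass(cfg$classifier)
  cfg
}

#' Write a pipeline run report as JSON
#'
#' @param report A `pipeline_report`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  out <- list(
    seed = report$seed,
    config = report$config_used,
    thresholds = report$thresholds,
    predictions = report$predictions,
    nodules = report$nodules,
    metrics = tidy(report$metrics),
    auc = if (is.null(report$roc)) NA else report$roc$auc,
    transmission = report$transmission[setdiff(names(report$transmission), "fields")],
    transmitted_fields = report$transmission$fields,
    history = report$history
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, null = "null",
                       POSIXt = "ISO8601")
  invisible(path)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>", nrow(x$predictions), "test images\n")
  print(x$metrics)
  cat("  transmission:", x$transmission$status, "\n")
  invisible(x)
}
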