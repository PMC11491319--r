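test_that("dense-block channel bookkeeping matches the closed form", {
  cfg <- densenet_config(input_size = 32, initial_channels = 16, num_blocks = 1,
                         layers_per_block = 4, growth_rate = 12)
  plan <- lungcbo:::dn_param_plan(cfg)
  shapes <- setNames(lapply(plan, function(p) c(p$rows, p$cols)),
                     vapply(plan, function(p) p$name, character(1)))
  # one block of 4 layers at growth 12: output channels 16 + 4 * 12 = 64
  expect_equal(shapes$final_gamma[1], 64)
  # layer l consumes k_in + (l - 1) * g input channels
  expect_equal(shapes$b1_l1_W, c(12, 9 * 16))
  expect_equal(shapes$b1_l3_W, c(12, 9 * (16 + 2 * 12)))

  # transition at compression 0.5 on 64 channels emits 32
  cfg2 <- densenet_config(input_size = 32, initial_channels = 16,
                          num_blocks = 2, layers_per_block = 4,
                          growth_rate = 12, compression = 0.5)
  plan2 <- lungcbo:::dn_param_plan(cfg2)
  shapes2 <- setNames(lapply(plan2, function(p) c(p$rows, p$cols)),
                      vapply(plan2, function(p) p$name, character(1)))
  expect_equal(shapes2$t1_W, c(32, 64))
  expect_equal(shapes2$b2_l1_gamma[1], 32)

  # randomized configs: every layer input channel count follows the formula
  for (s in 1:5) {
    p <- withr::with_seed(s, list(k0 = sample(4:20, 1), B = sample(1:3, 1),
                                  Lb = sample(1:3, 1), g = sample(2:10, 1)))
    cfgr <- densenet_config(input_size = 32, initial_channels = p$k0,
                            num_blocks = p$B, layers_per_block = p$Lb,
                            growth_rate = p$g, compression = 1)
    planr <- lungcbo:::dn_param_plan(cfgr)
    C <- p$k0
    for (b in seq_len(p$B)) {
      for (l in seq_len(p$Lb)) {
        nm <- sprintf("b%d_l%d_W", b, l)
        W <- planr[[which(vapply(planr, function(q) q$name, character(1)) == nm)]]
        expect_equal(W$cols, 9 * C)
        C <- C + p$g
      }
    }
  }

  expect_error(densenet_config(input_size = 30), "divisible")
})

test_that("predictions are structurally valid even for untrained weights", {
  model <- build_densenet(densenet_config(input_size = 16, initial_channels = 4,
                                          num_blocks = 2, layers_per_block = 1,
                                          growth_rate = 4, seed = 8))
  img <- withr::with_seed(1, matrix(sample(0:255, 1024, TRUE), 32, 32))
  pr <- predict(model, img)
  expect_equal(sum(pr$probabilities), 1, tolerance = 1e-6)
  expect_true(pr$message %in% c("Tumor is BENIGN", "Tumor is MALIGNANT"))
  expect_equal(pr$label, names(which.max(pr$probabilities))[1])
  expect_equal(pr$message == "Tumor is MALIGNANT",
               unname(pr$probabilities["malignant"] >= 0.5))
  # deterministic given fixed weights and input
  expect_identical(pr$probabilities, predict(model, img)$probabilities)
})

test_that("analytic gradients match finite differences", {
  cfg <- densenet_config(input_size = 8, initial_channels = 3, num_blocks = 2,
                         layers_per_block = 2, growth_rate = 2, seed = 42)
  model <- build_densenet(cfg)
  N <- 3
  X <- withr::with_seed(1, matrix(rnorm(64 * N, 0, 0.5), 64, N))
  y <- c(0L, 1L, 0L)
  res <- lungcbo:::dn_run(X, y, model$params, model$rstats, unclass(cfg),
                          TRUE, TRUE)
  eps <- 1e-5
  worst <- 0
  withr::with_seed(2, {
    for (pi in seq_along(model$params)) {
      p <- model$params[[pi]]
      for (ix in sample(length(p), min(3, length(p)))) {
        pp <- model$params; pp[[pi]][ix] <- pp[[pi]][ix] + eps
        lp <- lungcbo:::dn_run(X, y, pp, model$rstats, unclass(cfg),
                               TRUE, FALSE)$loss
        pm <- model$params; pm[[pi]][ix] <- pm[[pi]][ix] - eps
        lm <- lungcbo:::dn_run(X, y, pm, model$rstats, unclass(cfg),
                               TRUE, FALSE)$loss
        num <- (lp - lm) / (2 * eps)
        ana <- res$grads[[pi]][ix]
        if (abs(num) + abs(ana) > 1e-6) {
          worst <- max(worst, abs(num - ana) / (abs(num) + abs(ana)))
        }
      }
    }
  })
  expect_lt(worst, 1e-5)
})

test_that("training reduces the loss on a separable phantom task", {
  man <- make_tiny_dataset(n = 60, size = 32, radius = 3, seed = 9)
  man <- split_dataset(man, c(0.7, 0.15, 0.15), seed = 1)
  dir <- attr(man, "dir")
  cfg <- densenet_config(input_size = 32, initial_channels = 8, num_blocks = 2,
                         layers_per_block = 2, growth_rate = 8, seed = 3)
  model <- densenet_train(build_densenet(cfg), man, epochs = 5,
                          batch_size = 16, seed = 4, dir = dir)
  h <- model$history
  expect_equal(nrow(h), 5)
  expect_lte(h$train_loss[5], h$train_loss[1])
  expect_gt(tail(h$train_acc, 1), 0.8)

  preds <- densenet_predict_manifest(model, man, "test", dir)
  expect_true(all(preds$message %in% c("Tumor is BENIGN", "Tumor is MALIGNANT")))
  expect_equal(nrow(preds), sum(man$split == "test"))

  # broom-style accessors
  expect_gt(glance(model)$n_parameters, 0)
  expect_equal(glance(model)$epochs, 5L)
  expect_s3_class(tidy(model), "tbl_df")
})

test_that("training rejects a single-class split", {
  man <- make_tiny_dataset(n = 8, size = 32, radius = 3, seed = 2)
  man$split <- "train"
  man <- man[man$label == "benign", ]
  model <- build_densenet(densenet_config(input_size = 32, initial_channels = 4,
                                          num_blocks = 1, layers_per_block = 1,
                                          growth_rate = 2))
  expect_error(
    densenet_train(model, man, epochs = 1, validation_fraction = 0,
                   dir = attr(man, "dir")),
    "both classes"
  )
})

test_that("models round-trip through serialization", {
  model <- build_densenet(densenet_config(input_size = 16, initial_channels = 4,
                                          num_blocks = 1, layers_per_block = 1,
                                          growth_rate = 2, seed = 5))
  path <- tempfile(fileext = ".rds")
  save_densenet(model, path)
  back <- load_densenet(path)
  img <- matrix(100L, 20, 20)
  expect_identical(predict(model, img)$probabilities,
                   predict(back, img)$probabilities)
})
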