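test_that("between-class variance matches direct summation and its identities", {
  # constant image: one occupied class, sigma_B^2 = 0
  h_const <- compute_histogram(matrix(99, 4, 4))
  expect_equal(between_class_variance(h_const, 128L), 0)

  # two deltas at 50 and 200, threshold 50
  h2 <- rep(0, 256); h2[51] <- 0.5; h2[201] <- 0.5
  expect_equal(between_class_variance(h2, 50L), 5625)

  # random 16-level histogram vs the independent oracle, every threshold
  h16 <- withr::with_seed(8, c(runif(16), rep(0, 240)))
  h16 <- h16 / sum(h16)
  for (t in 0:254) {
    expect_equal(between_class_variance(h16, t),
                 bf_between_class_variance(h16, t))
  }
  # and for threshold pairs on a coarse grid
  for (t1 in c(3, 60, 140)) {
    for (t2 in c(80, 200, 254)) {
      if (t2 > t1) {
        expect_equal(between_class_variance(h16, c(t1, t2)),
                     bf_between_class_variance(h16, c(t1, t2)))
      }
    }
  }
})

test_that("sigma_B^2 is bounded by the total variance", {
  for (s in 1:20) {
    h <- withr::with_seed(s, runif(256))
    h <- h / sum(h)
    lev <- 0:255
    sigma_T <- sum(h * lev^2) - sum(h * lev)^2
    t <- withr::with_seed(s, sort(sample(0:254, 2)))
    expect_lte(between_class_variance(h, t), sigma_T + 1e-9)
  }
})

test_that("exhaustive bilevel Otsu breaks ties low and is scale invariant", {
  h2 <- rep(0, 256); h2[51] <- 0.5; h2[201] <- 0.5
  expect_equal(otsu_bilevel_exhaustive(h2), 50L)

  # bimodal Gaussian mixture: threshold lands between the modes and matches
  # an argmax over the brute-force oracle
  x <- withr::with_seed(5, round(c(rnorm(5000, 60, 10), rnorm(5000, 180, 10))))
  x <- pmin(pmax(x, 0), 255)
  h <- tabulate(x + 1, 256) / length(x)
  t_star <- otsu_bilevel_exhaustive(h)
  expect_gte(t_star, 90)
  expect_lte(t_star, 150)
  bf <- vapply(0:254, function(t) bf_between_class_variance(h, t), numeric(1))
  expect_equal(t_star, which.max(bf) - 1L)

  # counts vs normalized histogram give the same argmax
  expect_equal(otsu_bilevel_exhaustive(h * length(x)), t_star)
  expect_error(otsu_bilevel_exhaustive(c(1, rep(0, 255))), "two levels")
})

test_that("CBO thresholding attains the exhaustive optimum on small images", {
  hits <- 0
  for (i in 1:10) {
    img <- withr::with_seed(300 + i, matrix(sample(0:255, 32 * 32, TRUE), 32, 32))
    h <- compute_histogram(img)
    opt <- between_class_variance(h, otsu_bilevel_exhaustive(h))
    res <- cbo_multilevel_threshold(img, k = 1, seed = 400 + i)
    expect_true(is.integer(res$thresholds))
    expect_true(all(res$thresholds >= 0 & res$thresholds <= 254))
    if (res$sigma_b2 >= (1 - 1e-6) * opt) hits <- hits + 1
  }
  expect_gte(hits, 9)

  # three-delta histogram, k = 2: CBO separates the three masses and matches
  # the exhaustive pair-scan optimum
  img3 <- matrix(rep(c(30, 120, 220), length.out = 1024), 32, 32)
  res2 <- cbo_multilevel_threshold(img3, k = 2, seed = 7)
  h3 <- compute_histogram(img3)
  expect_length(res2$thresholds, 2)
  expect_true(res2$thresholds[1] >= 30 && res2$thresholds[1] < 120)
  expect_true(res2$thresholds[2] >= 120 && res2$thresholds[2] < 220)
  best <- max(vapply(0:253, function(a) {
    max(vapply((a + 1):254, function(b) {
      bf_between_class_variance(h3, c(a, b))
    }, numeric(1)))
  }, numeric(1)))
  expect_equal(res2$sigma_b2, best, tolerance = 1e-12)

  expect_error(cbo_multilevel_threshold(matrix(c(0, 1), 2, 2), k = 2),
               "distinct levels")
})

test_that("CBO thresholds dominate random threshold sets", {
  img <- withr::with_seed(77, matrix(sample(0:255, 1024, TRUE), 32, 32))
  h <- compute_histogram(img)
  res <- cbo_multilevel_threshold(img, k = 2, seed = 78)
  rnd <- withr::with_seed(79, replicate(1000, {
    between_class_variance(h, sort(sample(0:254, 2)))
  }))
  expect_gte(res$sigma_b2, max(rnd) - 1e-9)
})

test_that("threshold application labels the induced classes", {
  img <- matrix(c(50, 150, 150, 250), 2)
  expect_equal(apply_thresholds(img, 100L), matrix(c(0L, 1L, 1L, 1L), 2))
  lab <- apply_thresholds(img, c(100L, 200L))
  expect_equal(sort(unique(as.integer(lab))), c(0L, 1L, 2L))
  # label range always within 0..k
  img2 <- withr::with_seed(3, matrix(sample(0:255, 100, TRUE), 10, 10))
  lab2 <- apply_thresholds(img2, c(40L, 90L, 200L))
  expect_true(all(lab2 %in% 0:3))
})

test_that("nodule extraction computes area, centroid and diameter exactly", {
  expect_equal(nrow(extract_nodules(matrix(0L, 10, 10), 1)), 0)

  # solid 5x5 square at rows 2-6, cols 3-7 (0-based)
  lab <- matrix(0L, 12, 12)
  lab[3:7, 4:8] <- 1L
  reg <- extract_nodules(lab, 1)
  expect_equal(nrow(reg), 1)
  expect_equal(reg$area, 25L)
  expect_equal(reg$centroid_row, 4.0)
  expect_equal(reg$centroid_col, 5.0)
  expect_equal(reg$bbox_min_row, 2L)
  expect_equal(reg$bbox_max_row, 7L)   # half-open
  expect_equal(reg$equivalent_diameter, sqrt(100 / pi))

  # diagonal touch merges under 8-connectivity
  diag2 <- matrix(0L, 6, 6)
  diag2[2, 2] <- 1L; diag2[3, 3] <- 1L
  expect_equal(nrow(extract_nodules(diag2, 1)), 1)

  # min_area filtering and conservation of foreground area
  lab2 <- lab; lab2[10, 10] <- 1L
  regs <- extract_nodules(lab2, 1, min_area = 1)
  expect_equal(sum(regs$area), sum(lab2 == 1))
  expect_equal(nrow(extract_nodules(lab2, 1, min_area = 2)), 1)
})

test_that("connected components agree with an igraph oracle on random blobs", {
  skip_if_not_installed("igraph")
  for (s in 1:5) {
    fg <- withr::with_seed(s, matrix(runif(400) < 0.35, 20, 20))
    lab <- matrix(as.integer(fg), 20, 20)
    regs <- extract_nodules(lab, 1)
    # oracle: 8-neighbour graph over foreground pixels
    idx <- which(fg)
    if (length(idx) == 0) {
      expect_equal(nrow(regs), 0)
      next
    }
    coord <- arrayInd(idx, dim(fg))
    edges <- c()
    for (a in seq_along(idx)) {
      for (b in seq_len(a - 1L)) {
        if (max(abs(coord[a, ] - coord[b, ])) <= 1) edges <- c(edges, a, b)
      }
    }
    g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
    if (length(edges)) g <- igraph::add_edges(g, edges)
    comps <- igraph::components(g)
    expect_equal(nrow(regs), comps$no)
    expect_equal(sort(regs$area), sort(unname(as.integer(comps$csize))))
  }
})
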