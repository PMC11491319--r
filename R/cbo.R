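#' Configure a Colliding Bodies Optimization run
#'
#' Colliding Bodies Optimization (CBO) is a population metaheuristic that
#' models candidate solutions as bodies undergoing pairwise 1-D collisions.
#' Each iteration the population is sorted by fitness, the better half sits
#' stationary, the worse half moves onto its stationary partner, and
#' post-collision velocities follow momentum conservation with a coefficient
#' of restitution `epsilon`; masses are inverse-fitness normalized. The
#' algorithm is memoryless and has no tuned parameters beyond the population
#' size, iteration budget and the `epsilon` schedule.
#'
#' @param n Population size; must be even (the population splits into two
#'   equal halves) and at least 4.
#' @param dims Problem dimensionality.
#' @param lower,upper Numeric vectors of per-dimension box bounds
#'   (recycled to `dims`).
#' @param max_iters Iteration budget (>= 1).
#' @param epsilon Either a function `(iter, max_iters) -> value in [0, 1]`
#'   or a single fixed value. Default: linearly decreasing,
#'   `1 - iter / max_iters` (elastic early, plastic late).
#' @param seed Integer seed; identical configs reproduce identical runs.
#' @return An object of class `cbo_config`.
#' @export
cbo_config <- function(n = 30L, dims, lower, upper, max_iters = 200L,
                       epsilon = NULL, seed = 1L) {
  n <- as.integer(n)
  dims <- as.integer(dims)
  lower <- rep_len(as.numeric(lower), dims)
  upper <- rep_len(as.numeric(upper), dims)
  if (n < 4L || n %% 2L != 0L) {
    abort("`n` must be an even integer >= 4 (the population splits into two halves).")
  }
  if (any(lower >= upper)) abort("each lower bound must be below its upper bound.")
  if (max_iters < 1L) abort("`max_iters` must be at least 1.")
  if (is.null(epsilon)) {
    epsilon <- function(iter, max_iters) 1 - iter / max_iters
  } else if (is.numeric(epsilon)) {
    eps_val <- epsilon
    if (eps_val < 0 || eps_val > 1) abort("`epsilon` must lie in [0, 1].")
    epsilon <- function(iter, max_iters) eps_val
  }
  structure(
    list(n = n, dims = dims, lower = lower, upper = upper,
         max_iters = as.integer(max_iters), epsilon = epsilon,
         seed = as.integer(seed)),
    class = "cbo_config"
  )
}

#' Initialize a CBO population
#'
#' Draws every coordinate uniformly within its box bounds; velocities start
#' at zero.
#'
#' @param config A [cbo_config()].
#' @return A list with `positions` (n x dims matrix), `velocities` (zeros),
#'   `fitnesses` and `masses` (NULL until evaluated); class `cbo_population`.
#' @export
cbo_initialize <- function(config) {
  stopifnot(inherits(config, "cbo_config"))
  positions <- withr::with_seed(config$seed, {
    matrix(runif(config$n * config$dims), config$n, config$dims)
  })
  positions <- sweep(sweep(positions, 2, config$upper - config$lower, "*"),
                     2, config$lower, "+")
  structure(
    list(positions = positions,
         velocities = matrix(0, config$n, config$dims),
         fitnesses = NULL, masses = NULL),
    class = "cbo_population"
  )
}

#' Body masses from fitness values
#'
#' Mass is inverse fitness, normalized to sum to one:
#' `m_k = (1 / fit_k) / sum_i (1 / fit_i)`. Better (smaller-fitness) bodies
#' are heavier, so collisions push the population toward them.
#'
#' @param fitnesses Strictly positive fitness values.
#' @return Masses summing to 1.
#' @export
#' @examples
#' cbo_masses(c(1, 2, 4))  # 4/7, 2/7, 1/7
cbo_masses <- function(fitnesses) {
  if (any(!is.finite(fitnesses)) || any(fitnesses <= 0)) {
    abort("all fitness values must be finite and > 0 (positivize the objective).")
  }
  inv <- 1 / fitnesses
  inv / sum(inv)
}

#' One CBO collision step
#'
#' Requires the population sorted ascending by fitness. The lower (better)
#' half is stationary with zero pre-collision velocity; each upper-half body
#' `i` moves onto its partner `i - n/2` with velocity
#' `v_i = x_{i-n/2} - x_i`. Post-collision velocities follow the 1-D
#' collision laws with coefficient of restitution `epsilon`:
#' moving `v'_i = (m_i - eps * m_{i-n/2}) v_i / (m_i + m_{i-n/2})`,
#' stationary `v'_i = (m_{i+n/2} + eps * m_{i+n/2}) v_{i+n/2} /
#' (m_i + m_{i+n/2})`. New positions perturb along these velocities with a
#' fresh uniform `[-1, 1]` vector per body (stationary bodies move from
#' their own position, moving bodies from their partner's), then clip to the
#' box bounds.
#'
#' @param pop A `cbo_population` with `fitnesses` and `masses` set, sorted
#'   ascending by fitness.
#' @param epsilon Coefficient of restitution in `[0, 1]`.
#' @param lower,upper Box bounds.
#' @param rand Optional `n x dims` matrix overriding the random perturbation
#'   factors (used for deterministic worked examples and tests).
#' @return Matrix of new positions (n x dims).
#' @export
cbo_collide <- function(pop, epsilon, lower, upper, rand = NULL) {
  stopifnot(inherits(pop, "cbo_population"))
  fit <- pop$fitnesses
  m <- pop$masses
  if (is.null(fit) || is.null(m)) abort("population must be evaluated first.")
  if (is.unsorted(fit)) {
    abort("contract violation: population must be sorted ascending by fitness.")
  }
  x <- pop$positions
  n <- nrow(x)
  dims <- ncol(x)
  half <- n %/% 2L
  stat <- seq_len(half)
  mov <- half + seq_len(half)

  v_mov <- x[stat, , drop = FALSE] - x[mov, , drop = FALSE]
  m_stat <- m[stat]
  m_mov <- m[mov]
  vp_mov <- ((m_mov - epsilon * m_stat) / (m_mov + m_stat)) * v_mov
  vp_stat <- ((m_mov + epsilon * m_mov) / (m_stat + m_mov)) * v_mov

  if (is.null(rand)) rand <- matrix(runif(n * dims, -1, 1), n, dims)
  new_x <- x
  new_x[stat, ] <- x[stat, , drop = FALSE] + rand[stat, , drop = FALSE] * vp_stat
  new_x[mov, ] <- x[stat, , drop = FALSE] + rand[mov, , drop = FALSE] * vp_mov
  new_x <- pmin(pmax(new_x, matrix(lower, n, dims, byrow = TRUE)),
                matrix(upper, n, dims, byrow = TRUE))
  new_x
}

#' Run Colliding Bodies Optimization
#'
#' Minimizes `objective` over the configured box. Each iteration evaluates
#' the population, converts fitness to masses, sorts ascending, collides the
#' two halves, and clips to bounds; the best solution ever evaluated is
#' tracked externally for reporting (the population itself is memoryless).
#'
#' The mass rule needs strictly positive fitness. If `lower_bound` (a known
#' finite lower bound of the objective) is given, the internal fitness is
#' `raw - lower_bound + 1`; otherwise, if non-positive values appear, an
#' exponentially rescaled rank (`exp(rank / n)`) is used. Reported best
#' fitness is always on the raw objective scale.
#'
#' @param objective Function mapping a length-`dims` numeric vector to a
#'   finite scalar.
#' @param config A [cbo_config()].
#' @param lower_bound Optional finite lower bound of `objective`, used to
#'   positivize fitness.
#' @return An object of class `cbo_result`: `best_position`, `best_fitness`,
#'   `history` (best-so-far per iteration, non-increasing), `config`.
#' @export
#' @examples
#' sphere <- function(x) 1 + sum(x^2)
#' cfg <- cbo_config(n = 10, dims = 2, lower = -5, upper = 5,
#'                   max_iters = 50, seed = 3)
#' res <- cbo_optimize(sphere, cfg, lower_bound = 1)
#' res$best_fitness
cbo_optimize <- function(objective, config, lower_bound = NULL) {
  stopifnot(inherits(config, "cbo_config"))
  pop <- cbo_initialize(config)
  x <- pop$positions
  best_fit <- Inf
  best_pos <- x[1, ]
  history <- numeric(config$max_iters)

  withr::with_seed(config$seed + 1L, {
    for (iter in seq_len(config$max_iters)) {
      raw <- apply(x, 1, objective)
      if (any(!is.finite(raw))) {
        bad <- which(!is.finite(raw))[1]
        abort(sprintf(
          "objective returned a non-finite value at position (%s).",
          paste(signif(x[bad, ], 6), collapse = ", ")
        ))
      }
      if (min(raw) < best_fit) {
        best_fit <- min(raw)
        best_pos <- x[which.min(raw), ]
      }
      history[iter] <- best_fit

      fit <- if (!is.null(lower_bound) && is.finite(lower_bound)) {
        raw - lower_bound + 1
      } else if (any(raw <= 0)) {
        exp(rank(raw, ties.method = "first") / length(raw))
      } else {
        raw
      }
      ord <- order(fit)
      pop$positions <- x[ord, , drop = FALSE]
      pop$fitnesses <- fit[ord]
      pop$masses <- cbo_masses(pop$fitnesses)
      eps <- config$epsilon(iter, config$max_iters)
      x <- cbo_collide(pop, eps, config$lower, config$upper)
    }
  })

  structure(
    list(best_position = best_pos, best_fitness = best_fit,
         history = history, config = config),
    class = "cbo_result"
  )
}

#' @export
print.cbo_result <- function(x, ...) {
  cat("<cbo_result>\n")
  cat("  best fitness:", format(x$best_fitness, digits = 8), "\n")
  cat("  best position:", paste(signif(x$best_position, 6), collapse = ", "), "\n")
  cat("  iterations:", length(x$history), "\n")
  invisible(x)
}

#' Tidy a CBO convergence history
#'
#' @param x A `cbo_result`.
#' @param ... Unused.
#' @return Tibble with columns `iteration`, `best_fitness`.
#' @exportS3Method generics::tidy
tidy.cbo_result <- function(x, ...) {
  tibble(iteration = seq_along(x$history), best_fitness = x$history)
}

#' @rdname tidy.cbo_result
#' @exportS3Method generics::glance
glance.cbo_result <- function(x, ...) {
  tibble(best_fitness = x$best_fitness,
         iterations = length(x$history),
         n_bodies = x$config$n, dims = x$config$dims)
}

#' Convergence plot for a CBO run
#'
#' @param object A `cbo_result`.
#' @param ... Unused.
#' @return A ggplot of best-so-far fitness against iteration.
#' @exportS3Method ggplot2::autoplot
autoplot.cbo_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$iteration, y = .data$best_fitness)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration", y = "best fitness (so far)",
                  title = "CBO convergence") +
    ggplot2::theme_minimal()
}
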