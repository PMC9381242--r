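# Whale optimization algorithm (WOA) and its Levy-flight variant (LWOA).
# Each whale updates by one of three moves: encircling the best-so-far
# solution, a random-search move toward a random whale, or a logarithmic
# spiral around the best. The Levy variant replaces the uniform draw inside
# the coefficient H by a heavy-tailed Mantegna step and swaps the linear
# convergence-factor schedule for one that decays slowly early and
# exponentially late.

#' Convergence-factor schedules
#'
#' \code{linear_h} is the classic schedule h = 2 - 2 t / T_max.
#' \code{modified_h} is the schedule used by the Levy variant:
#' h(t) = 2 exp(0.15 - (t / T_max)^4 log(10)), which starts near
#' 2 e^0.15 ~ 2.32, decreases slowly over the first half of the run
#' (quartic ramp) and exponentially at the end. The exact closed form of
#' this schedule is a design choice constrained only by that behavioural
#' contract; \code{h_schedules()} lists the registered alternatives.
#'
#' @param t Current iteration (0 <= t <= t_max for linear, 1 <= t <= t_max
#'   for modified).
#' @param t_max Maximum iterations.
#' @return Convergence factor h.
#' @export
linear_h <- function(t, t_max) 2 - 2 * t / t_max

#' @rdname linear_h
#' @export
modified_h <- function(t, t_max) 2 * exp(0.15 - (t / t_max)^4 * log(10))

#' @rdname linear_h
#' @export
h_schedules <- function() {
  list(linear = linear_h,
       quartic_exp = modified_h,
       # alternative reading: log10 ramp instead of a quartic power ramp
       log_ramp = function(t, t_max)
         2 * exp(0.15 - log10(1 + 9 * t / t_max)^4))
}

#' Mantegna scale parameter for Levy-stable steps
#'
#' Closed form
#' sigma_mu = [ Gamma(1 + beta) sin(pi beta / 2) /
#'              (Gamma((1 + beta) / 2) beta 2^((beta - 1) / 2)) ]^(1 / beta),
#' the standard-deviation of the numerator Gaussian in Mantegna's sampler
#' for symmetric Levy-stable steps of index beta. At beta = 1.5 it equals
#' 0.6966 (~0.7).
#'
#' @param beta Stability index in (0, 2].
#' @return Positive scale.
#' @examples
#' round(mantegna_sigma_mu(1.5), 1)  # 0.7
#' @export
mantegna_sigma_mu <- function(beta) {
  assert_number(beta, "beta", lower = 0, upper = 2, strict_lower = TRUE)
  (gamma(1 + beta) * sin(pi * beta / 2) /
     (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
}

#' Levy-flight steps by the Mantegna algorithm
#'
#' s = mu / |nu|^(1 / beta) with mu ~ N(0, sigma_mu^2) and nu ~ N(0, 1),
#' which approximates a symmetric Levy-stable step with tail exponent beta.
#' Uses the current R random stream.
#'
#' @param n Number of steps.
#' @param beta Stability index in (0, 2].
#' @param sigma_mu Scale of the numerator Gaussian; defaults to the
#'   Mantegna closed form for \code{beta}.
#' @return Numeric vector of heavy-tailed steps.
#' @export
levy_step <- function(n = 1L, beta = 1.5, sigma_mu = mantegna_sigma_mu(beta)) {
  assert_number(beta, "beta", lower = 0, upper = 2, strict_lower = TRUE)
  stats::rnorm(n, 0, sigma_mu) / abs(stats::rnorm(n))^(1 / beta)
}

# Branch selector for one whale update; pure, so it can be exercised
# directly in Monte-Carlo tests of the branch partition.
select_branch <- function(p, H) {
  if (p >= 0.5) "spiral" else if (abs(H) < 1) "encircle" else "search"
}

# One whale's position update given the shared iteration state.
update_position <- function(x, best, x_rand, h, t, t_max, spiral_b,
                            variant, beta, sigma_mu) {
  r1 <- stats::runif(1)
  r2 <- stats::runif(1)
  r3 <- stats::runif(1)
  p <- stats::runif(1)
  H <- if (variant == "levy")
    2 * h * levy_step(1L, beta, sigma_mu) - h else 2 * h * r1 - h
  C <- 2 * r2
  h2 <- -1 - t / t_max
  l <- (h2 - 1) * r3 + 1
  switch(select_branch(p, H),
         encircle = best - H * abs(C * best - x),
         search = x_rand - H * abs(C * x_rand - x),
         spiral = best + abs(best - x) * exp(spiral_b * l) * cos(2 * pi * l))
}

#' Whale optimization of a bounded objective
#'
#' Minimizes a d-dimensional objective over a box by the whale optimization
#' algorithm. \code{variant = "standard"} is classic WOA (uniform draws in
#' the coefficient H, linear convergence-factor schedule); \code{variant =
#' "levy"} draws the H coefficient from a Mantegna Levy-stable step and
#' uses the slow-early / exponential-late schedule, which preserves the
#' ability to take long exploratory jumps past the midpoint of the run.
#' The best-so-far solution is updated immediately whenever any whale finds
#' a better feasible position; positions are clipped to the box after every
#' move.
#'
#' @param fn Objective function taking a numeric vector, returning a finite
#'   scalar to minimize.
#' @param lower,upper Numeric vectors of box bounds (equal length).
#' @param population Number of whales (>= 2, default 20).
#' @param max_iter Iterations (default 100).
#' @param variant "levy" (default) or "standard".
#' @param spiral_b Spiral shape constant (default 1).
#' @param beta Levy stability index (default 1.5).
#' @param sigma_mu Mantegna scale (default 0.7, the rounded closed-form
#'   value at beta = 1.5).
#' @param h_schedule Optional schedule function(t, t_max); defaults to
#'   \code{linear_h} for the standard variant and \code{modified_h} for the
#'   Levy variant.
#' @param seed Integer seed; NULL uses the current stream.
#' @param retries Resampling attempts per whale when the objective returns
#'   a non-finite value.
#' @return Object of class \code{"woa"}: list with \code{par},
#'   \code{value}, per-iteration best-fitness \code{trace}, and settings.
#' @examples
#' fit <- woa_optimize(function(x) sum(x^2), c(-10, -10), c(10, 10),
#'                     max_iter = 50, seed = 1)
#' fit$value
#' @export
woa_optimize <- function(fn, lower, upper, population = 20, max_iter = 100,
                         variant = c("levy", "standard"), spiral_b = 1,
                         beta = 1.5, sigma_mu = 0.7, h_schedule = NULL,
                         seed = NULL, retries = 20L) {
  variant <- match.arg(variant)
  population <- assert_count(population, "population", min = 2L)
  max_iter <- assert_count(max_iter, "max_iter", min = 1L)
  lower <- as.numeric(lower)
  upper <- as.numeric(upper)
  if (length(lower) != length(upper) || any(lower >= upper))
    stop("bounds must satisfy lower < upper elementwise")
  d <- length(lower)
  sched <- h_schedule %||% if (variant == "levy") modified_h else linear_h
  local_seed(seed, {
    X <- matrix(stats::runif(population * d, rep(lower, each = population),
                             rep(upper, each = population)),
                nrow = population)
    fitv <- numeric(population)
    for (i in seq_len(population)) {
      f <- fn(X[i, ])
      tries <- 0L
      while (!is.finite(f) && tries < retries) {
        X[i, ] <- stats::runif(d, lower, upper)
        f <- fn(X[i, ])
        tries <- tries + 1L
      }
      if (!is.finite(f))
        stop("objective returned non-finite values after bounded retries")
      fitv[i] <- f
    }
    ib <- which.min(fitv)
    best <- X[ib, ]
    best_fit <- fitv[ib]
    trace <- numeric(max_iter)
    for (t in seq_len(max_iter)) {
      h <- sched(t, max_iter)
      for (i in seq_len(population)) {
        jr <- sample.int(population, 1L)
        xnew <- update_position(X[i, ], best, X[jr, ], h, t, max_iter,
                                spiral_b, variant, beta, sigma_mu)
        xnew <- pmin(pmax(xnew, lower), upper)
        f <- fn(xnew)
        tries <- 0L
        while (!is.finite(f) && tries < retries) {
          xnew <- stats::runif(d, lower, upper)
          f <- fn(xnew)
          tries <- tries + 1L
        }
        if (!is.finite(f))
          stop("objective returned non-finite values after bounded retries")
        X[i, ] <- xnew
        if (f < best_fit) {      # update the best immediately
          best_fit <- f
          best <- xnew
        }
      }
      trace[t] <- best_fit
    }
    structure(list(par = best, value = best_fit, trace = trace,
                   variant = variant, population = population,
                   max_iter = max_iter, lower = lower, upper = upper,
                   beta = beta, sigma_mu = sigma_mu, seed = seed),
              class = "woa")
  })
}

#' @export
print.woa <- function(x, ...) {
  cat(sprintf("%s whale optimization: population %d, %d iterations\n",
              if (x$variant == "levy") "Levy-flight" else "Standard",
              x$population, x$max_iter))
  cat(sprintf("  best value %.6g at (%s)\n", x$value,
              paste(signif(x$par, 6), collapse = ", ")))
  invisible(x)
}

#' @export
plot.woa <- function(x, ...) {
  graphics::plot(seq_along(x$trace), x$trace, type = "l",
                 xlab = "iteration", ylab = "best fitness",
                 main = sprintf("WOA convergence (%s variant)", x$variant),
                 ...)
  invisible(x)
}

#' Write an optimizer trace as CSV
#'
#' @param woa A \code{woa} result.
#' @param path CSV path.
#' @export
write_woa_trace <- function(woa, path) {
  utils::write.csv(data.frame(iteration = seq_along(woa$trace),
                              best_fitness = woa$trace),
                   path, row.names = FALSE)
  invisible(path)
}
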