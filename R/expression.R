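#' Noise amplitudes of stochastic gene expression
#'
#' Standard deviations of the natural-log multiplicative noise acting on the
#' perceived inducer level: `eta_in` for the intrinsic component (independent
#' per gene copy) and `eta_ex` for the extrinsic component (shared by all
#' copies in a cell). Typical experimentally reported amplitudes lie in
#' 0.1-0.5; both default to 0 (deterministic expression).
#'
#' @param eta_in intrinsic noise amplitude (SD of ln z, >= 0).
#' @param eta_ex extrinsic noise amplitude (SD of ln z, >= 0).
#' @return an object of class `noise_params`.
#' @export
noise_params <- function(eta_in = 0, eta_ex = 0) {
  check_nonneg(eta_in, "eta_in"); check_nonneg(eta_ex, "eta_ex")
  structure(list(eta_in = eta_in, eta_ex = eta_ex), class = "noise_params")
}

#' @export
print.noise_params <- function(x, ...) {
  cat(sprintf("Expression noise: eta_in = %g, eta_ex = %g (SD of ln z)\n",
              x$eta_in, x$eta_ex))
  invisible(x)
}

#' Per-copy maximal expression levels of a genotype
#'
#' One entry per gene copy, in units of the ancestral singleton's maximal
#' expression. The three canonical genotypes are the singleton `c(1)`, the
#' dosage-sharing duplicate `c(0.5, 0.5)` (total expression conserved) and
#' the doubling duplicate `c(1, 1)` (expression doubled).
#'
#' @param y_max numeric vector of per-copy maximal expression levels (> 0).
#' @return an object of class `copy_spec`.
#' @examples
#' copy_spec(c(0.5, 0.5))  # dosage sharing
#' @export
copy_spec <- function(y_max = 1) {
  check_pos(y_max, "y_max")
  structure(list(y_max = as.numeric(y_max)), class = "copy_spec")
}

#' @export
print.copy_spec <- function(x, ...) {
  cat(sprintf("Genotype with %d gene cop%s: y_max = [%s]\n",
              length(x$y_max), if (length(x$y_max) == 1) "y" else "ies",
              paste(format(x$y_max), collapse = ", ")))
  invisible(x)
}

as_copy_spec <- function(x) {
  if (inherits(x, "copy_spec")) x else copy_spec(x)
}

# Hill response of the perceived dose u = x * z_in * z_ex
hill_response <- function(u, params) {
  un <- u^params$n
  ifelse(u > 0, un / (params$x0^params$n + un), 0)
}

#' Deterministic dose-response of a genotype
#'
#' `y = (sum of y_max) * x^n / (x0^n + x^n)`: the regulated Hill response,
#' scaled by the genotype's total maximal expression. No expression in
#' absence of lactose.
#'
#' @param x lactose concentration (mM), vectorised.
#' @param params a [fitness_params()] object.
#' @param copies a [copy_spec()] (or bare numeric vector of y_max values).
#' @return numeric vector of normalised expression levels.
#' @examples
#' deterministic_response(0.13)          # Hill midpoint: 0.5
#' deterministic_response(0.26, copies = copy_spec(c(0.5, 0.5)))
#' @export
deterministic_response <- function(x, params = fitness_params(),
                                   copies = copy_spec(1)) {
  check_nonneg(x, "x")
  copies <- as_copy_spec(copies)
  sum(copies$y_max) * hill_response(x, params)
}

# Draw n cells' worth of noise multipliers for a genotype with nc copies.
# eta = 0 consumes no random numbers (multiplier exactly 1), so that with
# purely extrinsic noise a dosage-sharing duplicate and a singleton read the
# same RNG stream and give bit-identical responses.
draw_noise <- function(n, nc, noise) {
  z0 <- if (noise$eta_ex > 0) exp(stats::rnorm(n, 0, noise$eta_ex)) else rep(1, n)
  z <- if (noise$eta_in > 0)
    matrix(exp(stats::rnorm(n * nc, 0, noise$eta_in)), nrow = n, ncol = nc)
  else matrix(1, n, nc)
  list(z0 = z0, z = z)
}

# Total expression of n cells given doses x (length n or 1) and a noise draw.
expression_from_draw <- function(x, params, copies, draw) {
  y <- 0
  for (i in seq_along(copies$y_max))
    y <- y + copies$y_max[i] * hill_response(x * draw$z[, i] * draw$z0, params)
  y
}

#' Stochastic expression response of single cells
#'
#' Steady-state total expression of `n` independent cells at dose(s) `x`.
#' Each cell draws one extrinsic multiplier `z0` shared by all its gene
#' copies and one intrinsic multiplier per copy, all log-normal with zero
#' log-mean; copy `i` contributes
#' `y_max[i] * (x*z_i*z0)^n / (x0^n + (x*z_i*z0)^n)`.
#'
#' @param x lactose concentration (mM); scalar or vector of length `n`.
#' @param params a [fitness_params()] object.
#' @param copies a [copy_spec()].
#' @param noise a [noise_params()].
#' @param n number of cells to draw (defaults to `length(x)`).
#' @param seed optional integer seed (RNG state restored afterwards).
#' @return a list with `y` (numeric vector of total expression, length `n`),
#'   `z0` (extrinsic multipliers) and `z` (n x copies matrix of intrinsic
#'   multipliers).
#' @examples
#' stochastic_response(0.13, noise = noise_params(0.5, 0), n = 3, seed = 1)
#' @export
stochastic_response <- function(x, params = fitness_params(),
                                copies = copy_spec(1),
                                noise = noise_params(),
                                n = length(x), seed = NULL) {
  check_nonneg(x, "x")
  copies <- as_copy_spec(copies)
  stopifnot(length(x) == 1L || length(x) == n)
  with_seed(seed, {
    draw <- draw_noise(n, length(copies$y_max), noise)
    y <- expression_from_draw(x, params, copies, draw)
    list(y = y, z0 = draw$z0, z = draw$z)
  })
}

#' Coefficient of variation of stochastic expression
#'
#' Gene-expression noise in the usual sense: sample SD over sample mean of
#' the single-cell expression at a fixed dose.
#'
#' @inheritParams stochastic_response
#' @param n_samples number of cells (>= 2).
#' @return the CV (dimensionless), or `NA` with a warning when the mean
#'   expression is zero (e.g. `x = 0`).
#' @examples
#' expression_cv(0.13, noise = noise_params(0.5, 0.5), n_samples = 1e4, seed = 1)
#' @export
expression_cv <- function(x, params = fitness_params(), copies = copy_spec(1),
                          noise = noise_params(), n_samples = 1e4,
                          seed = NULL) {
  stopifnot(n_samples >= 2)
  y <- stochastic_response(x, params, copies, noise, n = n_samples,
                           seed = seed)$y
  m <- mean(y)
  if (m == 0) {
    warning("mean expression is zero; CV undefined")
    return(NA_real_)
  }
  stats::sd(y) / m
}

#' Median dose-response curve of a stochastic genotype
#'
#' Per-dose median of single-cell expression, the model's analogue of a
#' population-level dose-response measurement.
#'
#' @param doses increasing vector of positive lactose doses (mM).
#' @inheritParams expression_cv
#' @param n_samples cells per dose (>= 100).
#' @return a data.frame with columns `x` and `y` (median expression).
#' @export
median_dose_response <- function(doses, params = fitness_params(),
                                 copies = copy_spec(1),
                                 noise = noise_params(),
                                 n_samples = 1000, seed = NULL) {
  check_pos(doses, "doses")
  stopifnot(!is.unsorted(doses), n_samples >= 100)
  with_seed(seed, {
    med <- vapply(doses, function(xd)
      stats::median(stochastic_response(xd, params, copies, noise,
                                        n = n_samples)$y),
      numeric(1))
    data.frame(x = doses, y = med)
  })
}

#' Effective Hill coefficient and midpoint slope of a dose-response curve
#'
#' Least-squares fit of a Hill function `y = Y * x^m / (K^m + x^m)` to a
#' curve (trust-region Levenberg-Marquardt), returning the fitted effective
#' Hill coefficient `m` and the slope of `y` against normalised dose `x/K`
#' at the fitted midpoint, which equals `m*Y/4`.
#'
#' @param curve data.frame with columns `x` and `y`, spanning at least one
#'   decade around the midpoint.
#' @param params a [fitness_params()] used for starting values.
#' @return a list with `n_eff`, `slope`, `Y` (fitted amplitude) and
#'   `midpoint` (fitted EC50, mM).
#' @examples
#' crv <- data.frame(x = exp(seq(log(0.013), log(1.3), length.out = 40)))
#' crv$y <- deterministic_response(crv$x)
#' hill_slope_at_x0(crv)   # n_eff = 4, slope = 1
#' @export
hill_slope_at_x0 <- function(curve, params = fitness_params()) {
  stopifnot(is.data.frame(curve), all(c("x", "y") %in% names(curve)))
  if (max(curve$x) / min(curve$x) < 10)
    stop("curve must span at least one decade of doses", call. = FALSE)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ Y * x^m / (K^m + x^m), data = curve,
                      start = list(Y = max(curve$y), m = params$n,
                                   K = params$x0),
                      lower = c(1e-6, 0.1, 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e)
      stop("Hill fit failed (non-sigmoidal curve?): ", conditionMessage(e),
           call. = FALSE))
  cf <- stats::coef(fit)
  list(n_eff = unname(cf["m"]),
       slope = unname(cf["m"] * cf["Y"] / 4),
       Y = unname(cf["Y"]),
       midpoint = unname(cf["K"]))
}

#' Rank of the wild-type regulation among random dose-response curves
#'
#' How unusually close the wild-type regulated response is to the optimal
#' one: sample `m` alternative EC50 values log-uniformly from `x0_range`,
#' measure each candidate curve's Euclidean distance to the optimal curve
#' over a log-spaced dose grid, and report the fraction of candidates at
#' least as close as the wild type. A small fraction means most alternative
#' regulations deviate more from the optimum than the actual one.
#'
#' @param x0_range length-2 range of candidate EC50 values (mM).
#' @param m number of sampled candidate curves (>= 100).
#' @param params a [fitness_params()] object (its `x0` is the wild type).
#' @param dose_grid dose grid for the distance (default 50 log-spaced points
#'   in 0.001-10 mM).
#' @param seed optional integer seed.
#' @return a list with `p` (fraction of candidates at least as close as the
#'   wild type), `wt_distance` and `distances`.
#' @export
curve_deviation_test <- function(x0_range = c(0.01, 1), m = 1000,
                                 params = fitness_params(),
                                 dose_grid = exp(seq(log(0.001), log(10),
                                                     length.out = 50)),
                                 seed = NULL) {
  stopifnot(length(x0_range) == 2, all(x0_range > 0), m >= 100)
  opt <- optimal_expression(dose_grid, params)
  dist_for <- function(x0c) {
    p2 <- params; p2$x0 <- x0c
    sqrt(sum((hill_response(dose_grid, p2) - opt)^2))
  }
  with_seed(seed, {
    x0s <- exp(stats::runif(m, log(x0_range[1]), log(x0_range[2])))
    d <- vapply(x0s, dist_for, numeric(1))
    wt <- dist_for(params$x0)
    list(p = mean(d <= wt), wt_distance = wt, distances = d)
  })
}

#' Variance reduction of total expression upon duplication
#'
#' Fractional reduction of the single-cell expression variance of a
#' dosage-sharing duplicate relative to a singleton at the same dose and
#' noise. With purely intrinsic noise the duplicate's variance is exactly
#' half the singleton's (two iid halved responses); shared extrinsic noise
#' dilutes the effect.
#'
#' @inheritParams expression_cv
#' @return `1 - Var(duplicate)/Var(singleton)` from `n_samples` draws each.
#' @export
variance_reduction <- function(x, params = fitness_params(),
                               noise = noise_params(), n_samples = 1e5,
                               seed = NULL) {
  with_seed(seed, {
    vs <- stats::var(stochastic_response(x, params, copy_spec(1), noise,
                                         n = n_samples)$y)
    vd <- stats::var(stochastic_response(x, params, copy_spec(c(0.5, 0.5)),
                                         noise, n = n_samples)$y)
    1 - vd / vs
  })
}
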