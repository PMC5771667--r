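#' Growth-rate model parameters for the lactose utilisation system
#'
#' Container for the seven experimentally fitted constants of the cost-benefit
#' growth-rate model of the *E. coli* lac operon, plus an optional haploid
#' genome size used to rescale the expression-cost ceiling for other
#' organisms.
#'
#' The model: benefit of lactose metabolism `B = a*y*x/(k + x)`
#' (Michaelis-Menten in the lactose dose `x`, linear in the normalised LacZ
#' expression `y`), cost of expression `C = b*y/(h - y)` (diverging as `y`
#' approaches the resource ceiling `h`), and growth rate
#' `W = W0*(1 + B - C)`, with `W = 0` whenever `y > h`. The regulated
#' deterministic response is a Hill function with midpoint `x0` and
#' coefficient `n`.
#'
#' @param W0 basal growth rate in absence of lactose (1/h).
#' @param a benefit scale (dimensionless).
#' @param k Michaelis constant of the benefit (mM).
#' @param b cost scale (dimensionless).
#' @param h resource ceiling of the cost (dimensionless expression units).
#' @param x0 lactose EC50 of the regulated response (mM).
#' @param n Hill coefficient of the regulated response (>= 1).
#' @param G optional haploid genome size (Mbp); `NA` when not used.
#' @return an object of class `fitness_params` (a named list).
#' @examples
#' p <- fitness_params()      # the fitted E. coli values
#' fitness(0.13, 0.5, p)
#' @export
fitness_params <- function(W0 = 1, a = 0.17, k = 0.40, b = 0.036,
                           h = 1.80, x0 = 0.13, n = 4, G = NA_real_) {
  for (nm in c("W0", "a", "k", "b", "h", "x0", "n"))
    check_pos(get(nm), nm)
  if (n < 1) stop("`n` must be >= 1", call. = FALSE)
  if (!is.na(G)) check_pos(G, "G")
  structure(list(W0 = W0, a = a, k = k, b = b, h = h, x0 = x0, n = n, G = G),
            class = "fitness_params")
}

#' @export
print.fitness_params <- function(x, ...) {
  cat("Fitness model parameters (lac operon cost-benefit model)\n")
  cat(sprintf("  W0 = %g 1/h, a = %g, k = %g mM, b = %g, h = %g, x0 = %g mM, n = %g\n",
              x$W0, x$a, x$k, x$b, x$h, x$x0, x$n))
  if (!is.na(x$G)) cat(sprintf("  genome size G = %g Mbp\n", x$G))
  invisible(x)
}

#' Load fitness parameters from a flat YAML or JSON config block
#'
#' Keys `W0, a, k, b, h, x0, n, G` override the fitted *E. coli* defaults;
#' missing keys keep their default.
#'
#' @param path path to a YAML (`.yml`/`.yaml`) or JSON file.
#' @return a [fitness_params()] object.
#' @export
fitness_params_from_config <- function(path) {
  stopifnot(file.exists(path))
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- c("W0", "a", "k", "b", "h", "x0", "n", "G")
  bad <- setdiff(names(cfg), allowed)
  if (length(bad))
    stop("unknown fitness parameter key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(fitness_params, cfg)
}

#' Benefit and cost components of the growth-rate model
#'
#' @param x lactose concentration (mM), vectorised.
#' @param y normalised LacZ expression (dimensionless), vectorised.
#' @param params a [fitness_params()] object.
#' @return a list with numeric vectors `B` (benefit) and `C` (cost); `C` is
#'   `NA` at and beyond the cost pole `y >= h`, where the cost is undefined.
#' @examples
#' fitness_components(0.13, 0.5, fitness_params())
#' @export
fitness_components <- function(x, y, params = fitness_params()) {
  check_nonneg(x, "x"); check_nonneg(y, "y")
  B <- params$a * y * x / (params$k + x)
  C <- ifelse(y < params$h, params$b * y / (params$h - y), NA_real_)
  list(B = B, C = C)
}

#' Growth rate (fitness) as a function of lactose dose and expression
#'
#' `W = W0*(1 + B - C)` for `y <= h`, floored at zero (growth rates cannot be
#' negative); `W = 0` for `y > h`, where expression demand exceeds cellular
#' resources.
#'
#' @inheritParams fitness_components
#' @return numeric vector of growth rates (1/h).
#' @examples
#' fitness(0.13, 0.5)   # slightly above the basal rate of 1/h
#' fitness(5, 0)        # no expression: exactly W0 whatever the dose
#' @export
fitness <- function(x, y, params = fitness_params()) {
  check_nonneg(x, "x"); check_nonneg(y, "y")
  B <- params$a * y * x / (params$k + x)
  denom <- params$h - y
  C <- ifelse(denom > 0, params$b * y / denom, Inf)
  W <- params$W0 * (1 + B - C)
  W[y > params$h] <- 0
  pmax(W, 0)
}

#' Optimal expression level at a given lactose dose
#'
#' The expression maximising `W` at dose `x`, from the closed form
#' `y_opt = h - sqrt(b*h*(k + x)/(a*x))` obtained by setting `dW/dy = 0`.
#' The closed form is negative at low doses, where any expression costs more
#' than it earns; the value is clamped to `[0, h]` so that the returned
#' optimum is the biologically meaningful one (no expression).
#'
#' @param x lactose concentration (mM), vectorised; `x = 0` returns 0.
#' @param params a [fitness_params()] object.
#' @return numeric vector of optimal expression levels.
#' @examples
#' optimal_expression(0.13)   # ~0.553 at the EC50
#' optimal_expression(0.01)   # 0: too little lactose to pay for expression
#' @export
optimal_expression <- function(x, params = fitness_params()) {
  check_nonneg(x, "x")
  y <- ifelse(x > 0,
              params$h - sqrt(params$b * params$h * (params$k + x) /
                                (params$a * x)),
              0)
  pmin(pmax(y, 0), params$h)
}

#' Slope of the optimal dose-response curve against normalised lactose
#'
#' Analytic derivative `x0 * d(y_opt)/dx`, i.e. the local slope of the
#' optimal curve when the dose axis is expressed in units of the EC50.
#' In the clamped region (`y_opt = 0`) the optimal response is flat and the
#' slope is zero, with a warning.
#'
#' @param x lactose concentration (mM), vectorised.
#' @param params a [fitness_params()] object.
#' @return numeric vector of slopes (dimensionless).
#' @examples
#' optimal_slope_at(0.13)   # ~0.470
#' @export
optimal_slope_at <- function(x, params = fitness_params()) {
  check_pos(x, "x")
  g <- params$b * params$h * (params$k + x) / (params$a * x)
  # d y_opt/dx = (b*h*k/a) / (2 x^2 sqrt(g))
  slope <- params$x0 * (params$b * params$h * params$k / params$a) /
    (2 * x^2 * sqrt(g))
  clamped <- optimal_expression(x, params) <= 0
  if (any(clamped)) {
    warning("y_opt clamped at 0 for some doses; slope reported as 0 there")
    slope[clamped] <- 0
  }
  slope
}

#' Selection coefficient between two growth rates
#'
#' `S = W_adv/W_ref - 1`, the relative fitness excess of a challenger
#' genotype over a reference. A dead challenger (`W_adv = 0`) gives `S = -1`;
#' a dead reference leaves the pair undefined and is an error.
#'
#' @param W_adv growth rate of the challenger genotype (1/h), vectorised.
#' @param W_ref growth rate of the reference genotype (1/h), vectorised.
#' @return numeric vector of selection coefficients.
#' @export
selection_coefficient <- function(W_adv, W_ref) {
  check_nonneg(W_adv, "W_adv")
  if (any(!is.finite(W_ref)) || any(W_ref <= 0))
    stop("`W_ref` must be positive; a zero-fitness reference leaves S undefined",
         call. = FALSE)
  W_adv / W_ref - 1
}

#' Rescale the cost ceiling to a genome size
#'
#' Organisms with larger genomes have more resources to accommodate extra
#' expression; the cost ceiling scales as `h = 0.36*G` with `G` the haploid
#' genome size in Mbp (`G ~ 5` recovers the *E. coli* value `h = 1.8`).
#'
#' @param G haploid genome size (Mbp).
#' @param params a [fitness_params()] object.
#' @return a new `fitness_params` with `h = 0.36*G` and `G` recorded.
#' @examples
#' scale_to_genome(3000)$h   # 1080 for a human-sized genome
#' @export
scale_to_genome <- function(G, params = fitness_params()) {
  check_pos(G, "G")
  params$h <- 0.36 * G
  params$G <- G
  params
}
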