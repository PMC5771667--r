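#' Monte-Carlo distribution of the selection coefficient between genotypes
#'
#' For each of `n` trials a lactose dose is drawn from the environment (or
#' held constant), the challenger and the reference genotype each receive an
#' independent stochastic expression draw — both intrinsic and extrinsic
#' multipliers independent between the two, as competing genotypes live in
#' distinct cells; only the dose is shared — their growth rates are
#' evaluated, and `S = W_challenger/W_reference - 1` is recorded.
#'
#' @param challenger,reference [copy_spec()] genotypes (or bare y_max
#'   vectors).
#' @param noise a [noise_params()].
#' @param params a [fitness_params()].
#' @param env an [environment_spec()] supplying the dose distribution.
#' @param n number of trials (>= 2; the headline analyses use 1e4).
#' @param seed optional integer seed.
#' @param keep_samples return the raw S values (default TRUE).
#' @return an object of class `selection_summary`: list with `mean_S`,
#'   `skewness` (Fisher-Pearson g1), `n`, `n_excluded` (trials with a
#'   zero-fitness reference, dropped with a warning) and optionally
#'   `samples`. Also carries `mean_S_ratio_of_means`, the ratio-of-mean-
#'   fitness diagnostic `mean(W_chal)/mean(W_ref) - 1`.
#' @examples
#' sel <- selection_distribution(copy_spec(c(0.5, 0.5)), copy_spec(1),
#'                               noise_params(0.5, 0), n = 2000, seed = 1)
#' sel$mean_S
#' @export
selection_distribution <- function(challenger, reference = copy_spec(1),
                                   noise = noise_params(),
                                   params = fitness_params(),
                                   env = environment_spec(0.13, 1),
                                   n = 1e4, seed = NULL,
                                   keep_samples = TRUE) {
  challenger <- as_copy_spec(challenger); reference <- as_copy_spec(reference)
  stopifnot(n >= 2)
  with_seed(seed, {
    x <- sample_lactose(env, n)
    y_ref <- stochastic_response(x, params, reference, noise, n = n)$y
    y_chal <- stochastic_response(x, params, challenger, noise, n = n)$y
    W_ref <- fitness(x, y_ref, params)
    W_chal <- fitness(x, y_chal, params)
    ok <- W_ref > 0
    n_excluded <- sum(!ok)
    if (n_excluded > 0)
      warning(sprintf("%d trial(s) excluded: reference fitness was 0",
                      n_excluded))
    S <- W_chal[ok] / W_ref[ok] - 1
    structure(list(mean_S = mean(S),
                   skewness = if (length(S) >= 2) sample_skewness(S) else NA_real_,
                   n = length(S), n_excluded = n_excluded,
                   mean_S_ratio_of_means = mean(W_chal[ok]) / mean(W_ref[ok]) - 1,
                   samples = if (keep_samples) S else NULL),
              class = "selection_summary")
  })
}

#' @export
print.selection_summary <- function(x, ...) {
  cat(sprintf("Selection summary over %d trials: mean S = %.3g (%.3g%%), skewness = %.3g\n",
              x$n, x$mean_S, 100 * x$mean_S, x$skewness))
  if (x$n_excluded > 0)
    cat(sprintf("  (%d trials excluded for zero reference fitness)\n",
                x$n_excluded))
  invisible(x)
}

#' Mean-selection landscape over median dose and intrinsic noise
#'
#' Mean selection coefficient of a genotype pair on a grid of fluctuating-
#' environment medians and intrinsic-noise amplitudes, at fixed extrinsic
#' noise.
#'
#' @param x_medians vector of median lactose doses (mM).
#' @param eta_in_grid vector of intrinsic noise amplitudes.
#' @param eta_ex fixed extrinsic noise amplitude (default 0.3).
#' @param challenger,reference genotypes as in [selection_distribution()].
#' @param params a [fitness_params()].
#' @param delta_x dose fluctuation amplitude (default 1).
#' @param n trials per grid cell.
#' @param seed optional integer seed.
#' @return a data.frame in long format: `x_median`, `eta_in`, `mean_S`, `n`.
#' @export
mean_selection_landscape <- function(x_medians, eta_in_grid, eta_ex = 0.3,
                                     challenger = copy_spec(c(0.5, 0.5)),
                                     reference = copy_spec(1),
                                     params = fitness_params(),
                                     delta_x = 1, n = 1e4, seed = NULL) {
  stopifnot(length(x_medians) >= 1, length(eta_in_grid) >= 1)
  with_seed(seed, {
    g <- expand.grid(x_median = x_medians, eta_in = eta_in_grid)
    g$mean_S <- mapply(function(xm, ei)
      selection_distribution(challenger, reference, noise_params(ei, eta_ex),
                             params, environment_spec(xm, delta_x), n = n,
                             keep_samples = FALSE)$mean_S,
      g$x_median, g$eta_in)
    g$n <- n
    g
  })
}

#' Mean selection of a doubling duplication along the dose axis
#'
#' `<S>` of the doubling duplicate `c(1, 1)` versus the singleton `c(1)` at
#' each constant dose of `x_grid`. At `x = 0` neither genotype expresses and
#' the duplication is strictly neutral (`S = 0` exactly, no sampling).
#'
#' @param x_grid vector of doses (mM, >= 0).
#' @param noise a [noise_params()].
#' @param params a [fitness_params()].
#' @param n trials per dose.
#' @param seed optional integer seed.
#' @return data.frame with `x`, `mean_S`, `n`.
#' @export
dosage_selection_curve <- function(x_grid, noise = noise_params(),
                                   params = fitness_params(), n = 1e4,
                                   seed = NULL) {
  check_nonneg(x_grid, "x_grid")
  with_seed(seed, {
    mean_S <- vapply(x_grid, function(xd) {
      if (xd == 0) return(0)
      selection_distribution(copy_spec(c(1, 1)), copy_spec(1), noise, params,
                             environment_spec(xd, 0), n = n,
                             keep_samples = FALSE)$mean_S
    }, numeric(1))
    data.frame(x = x_grid, mean_S = mean_S, n = n)
  })
}

#' Mean selection versus expression imbalance between duplicate copies
#'
#' `<S>` of a duplicate whose two copies share a total maximal expression of
#' 1 in ratio `r = y_max1/y_max2`, against the singleton, at a constant dose
#' and (by default) high noise. Copy exchange symmetry makes ratios `r` and
#' `1/r` equivalent.
#'
#' @param ratio_grid positive vector of expression ratios.
#' @param x constant lactose dose (mM, default 0.13).
#' @param noise a [noise_params()] (default high noise, eta_in = eta_ex = 1).
#' @param params a [fitness_params()].
#' @param n trials per ratio.
#' @param seed optional integer seed.
#' @return data.frame with `ratio`, `mean_S`, `n`.
#' @export
imbalance_selection_curve <- function(ratio_grid, x = 0.13,
                                      noise = noise_params(1, 1),
                                      params = fitness_params(), n = 1e4,
                                      seed = NULL) {
  check_pos(ratio_grid, "ratio_grid")
  with_seed(seed, {
    mean_S <- vapply(ratio_grid, function(r) {
      y1 <- r / (1 + r)
      selection_distribution(copy_spec(c(y1, 1 - y1)), copy_spec(1), noise,
                             params, environment_spec(x, 0), n = n,
                             keep_samples = FALSE)$mean_S
    }, numeric(1))
    data.frame(ratio = ratio_grid, mean_S = mean_S, n = n)
  })
}

#' Mean selection of promoter mutants against the wild type
#'
#' For each mutant maximal activity `y_max` (e.g. drawn with
#' [sample_promoter_activity()]), the mean selection coefficient of the
#' mutant genotype versus the wild-type singleton: without duplication the
#' mutant is the singleton `c(y_max)`; with duplication it carries two
#' copies of the mutant promoter, `c(y_max, y_max)`.
#'
#' @param y_max_values positive vector of mutant maximal activities.
#' @param with_duplication if TRUE the mutant has duplicated the gene.
#' @param env an [environment_spec()].
#' @param noise a [noise_params()].
#' @param params a [fitness_params()].
#' @param n trials per mutant.
#' @param seed optional integer seed.
#' @return data.frame with `y_max`, `mean_S`, `n`.
#' @export
promoter_mutant_selection <- function(y_max_values, with_duplication = FALSE,
                                      env = environment_spec(0.13, 0),
                                      noise = noise_params(1, 1),
                                      params = fitness_params(), n = 1e4,
                                      seed = NULL) {
  check_pos(y_max_values, "y_max_values")
  with_seed(seed, {
    mean_S <- vapply(y_max_values, function(ym) {
      chal <- if (with_duplication) copy_spec(c(ym, ym)) else copy_spec(ym)
      selection_distribution(chal, copy_spec(1), noise, params, env, n = n,
                             keep_samples = FALSE)$mean_S
    }, numeric(1))
    data.frame(y_max = y_max_values, mean_S = mean_S, n = n)
  })
}

#' Effectively neutral region for a doubling duplication
#'
#' Flags, on a grid of expression levels and genome sizes, where a
#' duplication that doubles a gene's expression is effectively neutral:
#' `|<N> * <S>| < 1`, with the effective population size `<N>` and the cost
#' ceiling `h` both scaled to genome size `G`, and no metabolic benefit
#' (`a = 0`; the gene is expressed but earns nothing). With no benefit the
#' fully induced response equals the maximal expression irrespective of
#' noise, so `S` reduces to the deterministic cost ratio
#' `(1 - C(2y)) / (1 - C(y)) - 1`.
#'
#' @param y_grid singleton expression levels (>= 0; the duplicate expresses
#'   `2*y`).
#' @param G_grid genome sizes (Mbp).
#' @param params a [fitness_params()]; its `a` is set to 0 internally.
#' @return data.frame with `y`, `G`, `S`, `N_eff`, `drift_product`
#'   (`N_eff*S`) and logical `neutral`.
#' @export
neutral_region <- function(y_grid, G_grid, params = fitness_params()) {
  check_nonneg(y_grid, "y_grid"); check_pos(G_grid, "G_grid")
  g <- expand.grid(y = y_grid, G = G_grid)
  res <- mapply(function(y, G) {
    p <- scale_to_genome(G, params); p$a <- 0
    W1 <- fitness(1, y, p)        # dose immaterial at a = 0
    W2 <- fitness(1, 2 * y, p)
    S <- if (y == 0) 0 else if (W1 > 0) W2 / W1 - 1 else NA_real_
    c(S = S, N_eff = effective_population_size(G))
  }, g$y, g$G)
  g$S <- res["S", ]; g$N_eff <- res["N_eff", ]
  g$drift_product <- g$N_eff * g$S
  # a cell whose singleton expression already exceeds the resource ceiling
  # is inviable before duplicating: not an effectively neutral condition
  g$neutral <- ifelse(is.na(g$S), FALSE, abs(g$drift_product) < 1)
  g
}
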