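#' Configuration-driven experiment runner
#'
#' Regenerates a figure-level dataset and its headline statistics from a
#' short configuration, writing tidy CSV output, a `summary.json` with the
#' headline numbers and a `manifest.json` (experiment id, overrides, seed,
#' package version) from which the run can be reproduced exactly.
#'
#' Available experiment ids:
#' \describe{
#'   \item{tradeoff_curves}{deterministic, optimal and median dose-response
#'     curves, with midpoint slopes and the curve-deviation rank p.}
#'   \item{selection_distribution}{S distribution of the dosage-sharing
#'     duplicate vs the singleton (mean, skewness).}
#'   \item{mi_transfer}{mutual information of the singleton and duplicate
#'     channels, with the Fisher z comparison.}
#'   \item{selection_landscape}{`<S>` over (median dose, intrinsic noise).}
#'   \item{evolve_sweep}{serial-dilution evolution trajectories and the
#'     analytic comparison.}
#'   \item{dosage_curves}{`<S>` of the doubling duplication along the dose
#'     axis at moderate and high noise.}
#'   \item{duplication_balance}{formation-deletion balance and dynamics.}
#'   \item{promoter_path}{promoter-mutant activities and their selection
#'     with and without duplication.}
#'   \item{neutral_region}{the effectively neutral |<N>*<S>| < 1 region over
#'     expression and genome size.}
#' }
#'
#' @param experiment one of the ids above.
#' @param out_dir output directory (created if missing).
#' @param seed integer seed governing all randomness of the run.
#' @param overrides named list of experiment-specific parameter overrides
#'   (unknown keys are an error). Common keys: `n` (Monte-Carlo trials),
#'   `eta_in`, `eta_ex`, `x_median`, `delta_x`, `n_passages`, `replicates`,
#'   `N`, `D`.
#' @return (invisibly) the summary list written to `summary.json`.
#' @export
run_experiment <- function(experiment, out_dir, seed = 1,
                           overrides = list()) {
  ids <- c("tradeoff_curves", "selection_distribution", "mi_transfer",
           "selection_landscape", "evolve_sweep", "dosage_curves",
           "duplication_balance", "promoter_path", "neutral_region")
  if (!experiment %in% ids)
    stop("unknown experiment id: ", experiment, call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  opt <- function(key, default) {
    if (key %in% names(overrides)) overrides[[key]] else default
  }
  runner <- get(paste0("exp_", experiment),
                envir = asNamespace("dupsel"))
  known <- names(formals(runner))
  bad <- setdiff(names(overrides), known)
  if (length(bad))
    stop("invalid override key(s) for ", experiment, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  summary <- do.call(runner, c(list(out_dir = out_dir, seed = seed),
                               overrides))
  manifest <- list(experiment = experiment, seed = seed,
                   overrides = overrides,
                   package_version = as.character(utils::packageVersion("dupsel")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(summary)
}

write_tidy_csv <- function(df, out_dir, name) {
  utils::write.csv(df, file.path(out_dir, paste0(name, ".csv")),
                   row.names = FALSE)
}

exp_tradeoff_curves <- function(out_dir, seed, n = 1000) {
  params <- fitness_params()
  doses <- exp(seq(log(params$x0 / 30), log(30 * params$x0),
                   length.out = 60))
  det <- deterministic_response(doses, params)
  opt <- optimal_expression(doses, params)
  med1 <- median_dose_response(doses, params, copy_spec(1),
                               noise_params(0.5, 0), n_samples = n,
                               seed = seed)
  med2 <- median_dose_response(doses, params, copy_spec(c(0.5, 0.5)),
                               noise_params(0.5, 0), n_samples = n,
                               seed = seed + 1)
  write_tidy_csv(data.frame(x = doses, deterministic = det, optimal = opt,
                            median_singleton = med1$y,
                            median_duplicate = med2$y),
                 out_dir, "dose_response")
  dev <- curve_deviation_test(seed = seed + 2, params = params)
  fit2 <- hill_slope_at_x0(med2, params)
  list(slope_deterministic = params$n / 4,
       slope_optimal = optimal_slope_at(params$x0, params),
       slope_duplicate_median = fit2$slope,
       n_eff_duplicate = fit2$n_eff,
       curve_deviation_p = dev$p)
}

exp_selection_distribution <- function(out_dir, seed, n = 1e4,
                                       eta_in = 0.5, eta_ex = 0,
                                       x_median = 0.13, delta_x = 1) {
  sel <- selection_distribution(copy_spec(c(0.5, 0.5)), copy_spec(1),
                                noise_params(eta_in, eta_ex),
                                env = environment_spec(x_median, delta_x),
                                n = n, seed = seed)
  write_tidy_csv(data.frame(S = sel$samples), out_dir, "selection_samples")
  list(mean_S = sel$mean_S, mean_S_percent = 100 * sel$mean_S,
       skewness = sel$skewness, n = sel$n)
}

exp_mi_transfer <- function(out_dir, seed, n = 1e4, eta_in = 0.5,
                            eta_ex = 0, delta_x = 1, bins = 48) {
  env <- environment_spec(0.13, delta_x)
  noise <- noise_params(eta_in, eta_ex)
  x1 <- sample_lactose(env, n, seed = seed)
  y1 <- stochastic_response(x1, copies = copy_spec(1), noise = noise,
                            seed = seed + 1)$y
  x2 <- sample_lactose(env, n, seed = seed + 2)
  y2 <- stochastic_response(x2, copies = copy_spec(c(0.5, 0.5)),
                            noise = noise, seed = seed + 3)$y
  I1 <- mutual_information(x1, y1, bins)$I
  I2 <- mutual_information(x2, y2, bins)$I
  sig <- mi_significance(I1, I2, n)
  write_tidy_csv(data.frame(x = c(x1, x2), y = c(y1, y2),
                            genotype = rep(c("singleton", "duplicate"),
                                           each = n)),
                 out_dir, "channel_samples")
  list(I_singleton = I1, I_duplicate = I2, z = sig$z, p = sig$p,
       bins = bins, n = n)
}

exp_selection_landscape <- function(out_dir, seed, n = 5000,
                                    eta_ex = 0.3) {
  land <- mean_selection_landscape(
    x_medians = exp(seq(log(0.013), log(1.3), length.out = 7)),
    eta_in_grid = seq(0, 1, by = 0.25), eta_ex = eta_ex, n = n, seed = seed)
  write_tidy_csv(land, out_dir, "landscape")
  best <- land[which.max(land$mean_S), ]
  list(max_mean_S = best$mean_S, at_x_median = best$x_median,
       at_eta_in = best$eta_in)
}

exp_evolve_sweep <- function(out_dir, seed, N = 1e5, D = 100,
                             n_passages = 150, replicates = 3,
                             eta_in = 0.5, eta_ex = 0, x_median = 0.13,
                             delta_x = 1, n_S = 2e4) {
  cfg <- sim_config(N = N, D = D, noise = noise_params(eta_in, eta_ex),
                    env = environment_spec(x_median, delta_x),
                    n_passages = n_passages, replicates = replicates)
  traj <- run_evolution(cfg, seed = seed)
  write_tidy_csv(as.data.frame(traj), out_dir, "trajectory")
  S <- selection_distribution(cfg$challenger, cfg$reference, cfg$noise,
                              env = cfg$env, n = n_S, seed = seed + 1,
                              keep_samples = FALSE)$mean_S
  cmp <- theory_comparison(traj, S)
  f_final <- cmp$f_mean[length(cmp$f_mean)]
  list(mean_S = S, f_final = f_final,
       generations = max(traj$generation),
       max_abs_residual = cmp$max_abs_residual,
       within_envelope = cmp$within_envelope)
}

exp_dosage_curves <- function(out_dir, seed, n = 5000) {
  x_grid <- c(0, exp(seq(log(1e-3), log(10), length.out = 15)))
  moderate <- dosage_selection_curve(x_grid, noise_params(0.3, 0.3), n = n,
                                     seed = seed)
  high <- dosage_selection_curve(x_grid, noise_params(1, 1), n = n,
                                 seed = seed + 1)
  moderate$noise <- "moderate"; high$noise <- "high"
  write_tidy_csv(rbind(moderate, high), out_dir, "dosage_selection")
  list(S_no_noise_x0 = selection_coefficient(fitness(0.13, 1),
                                             fitness(0.13, 0.5)),
       min_mean_S_moderate = min(moderate$mean_S),
       min_mean_S_high = min(high$mean_S))
}

exp_duplication_balance <- function(out_dir, seed, mu_c = 3e-4,
                                    mu_d = 4.4e-2, S = 0, t_max = 300) {
  bal <- duplication_balance(mu_c, mu_d, S)
  dyn <- duplication_frequency_dynamics(mu_c, mu_d, S, 0, t_max)
  write_tidy_csv(dyn, out_dir, "balance_dynamics")
  list(f_eq = bal$f_eq, t_eq = bal$t_eq,
       f_final = dyn$f[nrow(dyn)])
}

exp_promoter_path <- function(out_dir, seed, n_mutants = 200, n = 2000) {
  acts <- sample_promoter_activity(promoter_mutant_spec(), max(n_mutants, 100),
                                   seed = seed)[seq_len(max(n_mutants, 100))]
  solo <- promoter_mutant_selection(acts, FALSE, n = n, seed = seed + 1)
  dup <- promoter_mutant_selection(acts, TRUE, n = n, seed = seed + 2)
  solo$path <- "mutant"; dup$path <- "mutant+duplication"
  write_tidy_csv(rbind(solo, dup), out_dir, "promoter_selection")
  half <- selection_distribution(copy_spec(c(0.5, 0.5)), copy_spec(1),
                                 noise_params(1, 1),
                                 env = environment_spec(0.13, 0),
                                 n = 1e4, seed = seed + 3,
                                 keep_samples = FALSE)
  list(mean_S_restored = half$mean_S,
       skewness_activities = sample_skewness(acts),
       frac_half = mean(acts >= 0.4 & acts <= 0.6))
}

exp_neutral_region <- function(out_dir, seed) {
  reg <- neutral_region(y_grid = seq(0, 2, by = 0.1),
                        G_grid = exp(seq(log(1), log(3000),
                                         length.out = 15)))
  write_tidy_csv(reg, out_dir, "neutral_region")
  list(frac_neutral = mean(reg$neutral))
}
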