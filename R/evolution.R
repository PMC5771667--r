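#' Configuration of an in silico serial-dilution evolution experiment
#'
#' Two genotypes compete in a culture of carrying capacity `N` diluted
#' `D`-fold every passage (one day). Each passage allows
#' `log2(D)` generations of growth; the lactose dose is redrawn from the
#' environment once per passage and shared by all cells.
#'
#' @param N carrying capacity (cells, default 1e5).
#' @param D dilution factor (default 100); founders per passage `N/D`
#'   (must be >= 10).
#' @param reference,challenger the two competing genotypes
#'   ([copy_spec()]); the frequency `f` tracks the challenger.
#' @param noise a [noise_params()].
#' @param env an [environment_spec()].
#' @param f0 initial challenger frequency (default 0.5).
#' @param n_passages number of serial-dilution passages.
#' @param replicates number of independent replicate populations (default 3).
#' @param params a [fitness_params()].
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(N = 1e5, D = 100,
                       reference = copy_spec(1),
                       challenger = copy_spec(c(0.5, 0.5)),
                       noise = noise_params(0.5, 0),
                       env = environment_spec(0.13, 1),
                       f0 = 0.5, n_passages = 150, replicates = 3,
                       params = fitness_params()) {
  check_pos(N, "N"); check_pos(D, "D")
  if (N / D < 10) stop("founder population N/D must be >= 10", call. = FALSE)
  stopifnot(f0 >= 0, f0 <= 1, n_passages >= 1, replicates >= 1)
  structure(list(N = N, D = D, reference = as_copy_spec(reference),
                 challenger = as_copy_spec(challenger), noise = noise,
                 env = env, f0 = f0, n_passages = n_passages,
                 replicates = replicates, params = params,
                 gen_per_passage = log2(D)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("Serial-dilution simulation: N = %g, D = %g ",
                     "(%.2f generations/passage), %d passages x %d replicates\n"),
              x$N, x$D, x$gen_per_passage, x$n_passages, x$replicates))
  invisible(x)
}

# One passage at cell-cycle resolution. Founders grow synchronously: each
# full 1 h step every cell draws its own stochastic expression, hence its own
# growth rate W, multiplies its volume by 2^W and splits into two daughters
# (each of which redraws noise next step); the final fractional step
# (log2(D) - floor(log2(D)) h) multiplies volume without a redraw. The next
# founders are then drawn binomially with probability proportional to the
# genotype volume shares.
#' Simulate one serial-dilution passage
#'
#' @param founders integer vector `c(reference, challenger)` of founder cell
#'   counts (their sum must equal `N/D`).
#' @param dose lactose dose of the passage (mM).
#' @param config a [sim_config()].
#' @return integer vector `c(reference, challenger)` of next founders.
#' @export
run_passage <- function(founders, dose, config) {
  stopifnot(length(founders) == 2)
  if (sum(founders) != config$N / config$D)
    stop("founders must sum to N/D cells", call. = FALSE)
  genotype <- rep.int(c(1L, 2L), founders)
  vol <- rep.int(1, length(genotype))
  specs <- list(config$reference, config$challenger)
  n_full <- floor(config$gen_per_passage)
  frac <- config$gen_per_passage - n_full
  grow <- function(gt, v, dt) {
    W <- numeric(length(gt))
    for (g in 1:2) {
      idx <- gt == g
      if (!any(idx)) next
      y <- stochastic_response(dose, config$params, specs[[g]],
                               config$noise, n = sum(idx))$y
      W[idx] <- fitness(dose, y, config$params)
    }
    list(v = v * 2^(W * dt), W = W)
  }
  W_last <- NULL
  for (s in seq_len(n_full)) {
    gw <- grow(genotype, vol, 1)
    W_last <- gw$W
    # synchronous division: two daughters of half volume each
    genotype <- rep(genotype, each = 2)
    vol <- rep(gw$v / 2, each = 2)
    W_last <- rep(W_last, each = 2)
  }
  if (frac > 0) {
    if (is.null(W_last)) W_last <- grow(genotype, vol, 0)$W
    vol <- vol * 2^(W_last * frac)
  }
  V <- c(sum(vol[genotype == 1L]), sum(vol[genotype == 2L]))
  if (sum(V) <= 0) stop("population extinct: all growth rates were zero",
                        call. = FALSE)
  n0 <- config$N / config$D
  k <- stats::rbinom(1, n0, V[2] / sum(V))
  c(n0 - k, k)
}

#' Run a replicated in silico evolution experiment
#'
#' Chains [run_passage()] for `n_passages`, redrawing the lactose dose from
#' the environment each passage, for each replicate population.
#'
#' @param config a [sim_config()].
#' @param seed optional integer seed.
#' @return a data.frame of class `evolution_trajectory` with columns
#'   `replicate`, `passage`, `generation`, `f` (challenger frequency among
#'   founders at the start of the passage) and `dose` (mM used in the
#'   passage just run; `NA` on the passage-0 row).
#' @examples
#' cfg <- sim_config(N = 2000, D = 100, n_passages = 5, replicates = 2)
#' traj <- run_evolution(cfg, seed = 1)
#' @export
run_evolution <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n0 <- config$N / config$D
  with_seed(seed, {
    rows <- vector("list", config$replicates)
    for (rep_i in seq_len(config$replicates)) {
      k0 <- round(config$f0 * n0)
      founders <- c(n0 - k0, k0)
      f <- numeric(config$n_passages + 1)
      dose <- rep(NA_real_, config$n_passages + 1)
      f[1] <- founders[2] / n0
      for (p in seq_len(config$n_passages)) {
        d <- sample_lactose(config$env, 1)
        founders <- run_passage(founders, d, config)
        f[p + 1] <- founders[2] / n0
        dose[p + 1] <- d
      }
      rows[[rep_i]] <- data.frame(replicate = rep_i,
                                  passage = 0:config$n_passages,
                                  generation = (0:config$n_passages) *
                                    config$gen_per_passage,
                                  f = f, dose = dose)
    }
    out <- do.call(rbind, rows)
    class(out) <- c("evolution_trajectory", "data.frame")
    attr(out, "config") <- config
    out
  })
}

#' Compare a simulated trajectory with the analytic prediction
#'
#' The analytic competition curve `f(t) = 1/(1 + (1/f0 - 1)*2^(-S*t))` at
#' the independently estimated mean selection coefficient is compared with
#' the replicate mean of the simulated challenger frequency: residuals at
#' every recorded generation, their maximum magnitude, and whether the
#' analytic curve stays inside the replicate mean +/- 2 SD envelope
#' throughout.
#'
#' @param trajectory an `evolution_trajectory` from [run_evolution()].
#' @param S_mean mean selection coefficient, computed under the same
#'   environment and noise settings (e.g. via [selection_distribution()]).
#' @return list with `generation`, `f_mean`, `f_sd`, `f_pred`, `residuals`,
#'   `max_abs_residual`, `envelope_coverage` (fraction of recorded
#'   generations at which the analytic curve lies inside the envelope) and
#'   `within_envelope` (TRUE when the coverage is 1). With few replicates
#'   the per-generation SD is itself a noisy 2-df estimate, so a small
#'   number of pointwise misses is expected even under perfect agreement;
#'   `envelope_coverage` is the robust summary.
#' @export
theory_comparison <- function(trajectory, S_mean) {
  stopifnot(inherits(trajectory, "evolution_trajectory"))
  cfg <- attr(trajectory, "config")
  if (cfg$f0 <= 0 || cfg$f0 >= 1)
    stop("theory comparison needs 0 < f0 < 1", call. = FALSE)
  gens <- sort(unique(trajectory$generation))
  agg <- function(fun) vapply(gens, function(g)
    fun(trajectory$f[trajectory$generation == g]), numeric(1))
  f_mean <- agg(mean); f_sd <- agg(stats::sd)
  f_pred <- competition_dynamics(f0 = cfg$f0, S = S_mean, t = gens)$f
  resid <- f_mean - f_pred
  inside <- abs(resid) <= 2 * f_sd | (f_sd == 0 & abs(resid) < 1e-12)
  list(generation = gens, f_mean = f_mean, f_sd = f_sd, f_pred = f_pred,
       residuals = resid, max_abs_residual = max(abs(resid)),
       envelope_coverage = mean(inside),
       within_envelope = all(inside))
}
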