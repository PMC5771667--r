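#' Deterministic competition dynamics between two genotypes
#'
#' With constant selection coefficient `S`, the ratio of the advantaged
#' genotype to the other grows as `r(t) = r0 * 2^(S*t)` (t in generations)
#' and its frequency is `f = 1/(1 + 1/r)`.
#'
#' @param r0 initial ratio (> 0). Alternatively give `f0`, the initial
#'   frequency, from which `r0 = f0/(1 - f0)`.
#' @param S selection coefficient.
#' @param t vector of times in generations.
#' @param f0 optional initial frequency in (0, 1); overrides `r0`.
#' @return data.frame with columns `t`, `r`, `f`.
#' @examples
#' competition_dynamics(1, 0.001, c(0, 1000))  # f: 0.5 -> 2/3
#' @export
competition_dynamics <- function(r0 = 1, S, t, f0 = NULL) {
  if (!is.null(f0)) {
    stopifnot(f0 > 0, f0 < 1)
    r0 <- f0 / (1 - f0)
  }
  check_pos(r0, "r0")
  r <- r0 * 2^(S * t)
  data.frame(t = t, r = r, f = 1 / (1 + 1 / r))
}

#' Effective population size of a serial-dilution culture, from genome size
#'
#' Interspecific scaling `<N> = 3e9 / G^1.44` (cells), linking organismal
#' complexity (haploid genome size `G`, Mbp) to the effective population
#' size that sets the drift threshold.
#'
#' @param G haploid genome size (Mbp).
#' @return effective population size (cells).
#' @examples
#' effective_population_size(5)   # ~3e8 for E. coli
#' @export
effective_population_size <- function(G) {
  check_pos(G, "G")
  3e9 / G^1.44
}

#' Fixation probability and time under the model's closed-form regimes
#'
#' Haldane-style closed forms for a serial-dilution population with
#' effective size `<N>`:
#' \describe{
#'   \item{punctual}{a single beneficial mutant: `P_fix = 2S`,
#'     `t_fix = log2(<N>^2)/S`, `t_half = t_fix/2`.}
#'   \item{neutral}{`P_fix = 1/<N>`, `t_fix = 2<N>`.}
#'   \item{recurrent}{beneficial mutants recur at rate `mu_b`: `P_fix = 1`,
#'     `t_fix = log2(<N>*S/mu_b)/S`.}
#'   \item{duplication}{duplicates recur (rate `mu_c`) and are deleted (rate
#'     `mu_d`); the punctual forms apply with the effective selection
#'     coefficient `S' = S - mu_d`, so `P_fix = 2*S'`. Requires `S > mu_d`;
#'     otherwise the duplicate cannot fix and `fixable = FALSE` is returned
#'     with `P_fix = 0`.}
#' }
#'
#' @param S selection coefficient (required except in the neutral regime).
#' @param N_eff effective population size `<N>`.
#' @param regime one of "punctual", "neutral", "recurrent", "duplication".
#' @param mu_b beneficial-mutation rate (recurrent regime).
#' @param mu_c duplication formation rate (duplication regime; recorded).
#' @param mu_d duplication deletion rate (duplication regime).
#' @return list with `P_fix`, `t_fix`, `t_half`, `S_eff`, `fixable`.
#' @examples
#' fixation_stats(N_eff = 2e8, regime = "neutral")$P_fix   # 5e-9
#' fixation_stats(S = 0.0019, N_eff = 2e8, regime = "duplication",
#'                mu_d = 4.1e-4)
#' @export
fixation_stats <- function(S = NULL, N_eff, regime = c("punctual", "neutral",
                                                       "recurrent",
                                                       "duplication"),
                           mu_b = NULL, mu_c = NULL, mu_d = NULL) {
  regime <- match.arg(regime)
  check_pos(N_eff, "N_eff")
  out <- switch(regime,
    punctual = {
      check_pos(S, "S")
      list(P_fix = 2 * S, t_fix = log2(N_eff^2) / S, S_eff = S, fixable = TRUE)
    },
    neutral = list(P_fix = 1 / N_eff, t_fix = 2 * N_eff, S_eff = 0,
                   fixable = TRUE),
    recurrent = {
      check_pos(S, "S"); check_pos(mu_b, "mu_b")
      list(P_fix = 1, t_fix = log2(N_eff * S / mu_b) / S, S_eff = S,
           fixable = TRUE)
    },
    duplication = {
      stopifnot(!is.null(S), !is.null(mu_d))
      check_nonneg(mu_d, "mu_d")
      S_eff <- S - mu_d
      if (S_eff <= 0)
        list(P_fix = 0, t_fix = Inf, S_eff = S_eff, fixable = FALSE)
      else
        list(P_fix = 2 * S_eff, t_fix = log2(N_eff^2) / S_eff, S_eff = S_eff,
             fixable = TRUE)
    })
  out$t_half <- out$t_fix / 2
  out$regime <- regime
  out
}

#' Frequency dynamics of recurrently produced beneficial mutants
#'
#' Two supply regimes, selected by the per-generation mutant supply
#' `mu_b*N`:
#' large supply (`mu_b*N > 1`): `r(t) = mu_b * 2^(S*t) / S` (each passage
#' regenerates many independent mutants); small supply: the punctual
#' dynamics delayed by the mean waiting time for a mutant,
#' `r(t) = 2^(S*(t - T)) / <N>` with `T = log2(D) / (mu_b*N)`.
#'
#' @param mu_b beneficial-mutation rate (per genome per generation).
#' @param N maximal population size.
#' @param D dilution factor; `<N> = N/sqrt(D)`.
#' @param S selection coefficient (> 0).
#' @param t vector of times in generations.
#' @return data.frame with `t`, `r`, `f`, plus attributes `regime` and
#'   (small-supply) `delay`.
#' @export
recurrent_mutant_dynamics <- function(mu_b, N, D, S, t) {
  check_pos(S, "S"); check_pos(N, "N"); check_pos(D, "D")
  check_nonneg(mu_b, "mu_b")
  supply <- mu_b * N
  if (supply > 1) {
    r <- mu_b * 2^(S * t) / S
    out <- data.frame(t = t, r = r, f = 1 / (1 + 1 / r))
    attr(out, "regime") <- "large-supply"
  } else {
    N_eff <- N / sqrt(D)
    T_delay <- log2(D) / supply
    r <- 2^(S * (t - T_delay)) / N_eff
    out <- data.frame(t = t, r = r, f = 1 / (1 + 1 / r))
    attr(out, "regime") <- "small-supply"
    attr(out, "delay") <- T_delay
  }
  out
}

#' Total time for successive fixations
#'
#' When `m` beneficial mutations accumulate one after another, each can
#' start fixing once its predecessor has invaded half the population:
#' `t_total = t_fix(m) + t_half(m-1) + ... + t_half(1)`.
#'
#' @param S_list selection coefficients of the successive mutations, in
#'   order of appearance (all > 0).
#' @param N_eff effective population size.
#' @return total generations (0 for an empty list).
#' @export
successive_fixation_time <- function(S_list, N_eff) {
  if (length(S_list) == 0) return(0)
  check_pos(S_list, "S_list"); check_pos(N_eff, "N_eff")
  m <- length(S_list)
  t_fix_last <- log2(N_eff^2) / S_list[m]
  if (m == 1) return(t_fix_last)
  t_half_prev <- log2(N_eff) / S_list[seq_len(m - 1)]
  t_fix_last + sum(t_half_prev)
}

#' Formation-deletion balance of gene duplicates
#'
#' Stationary duplicate frequency under recurrent formation (rate `mu_c`)
#' and deletion (rate `mu_d`): `f_eq = mu_c/(mu_c + mu_d)` for neutral
#' duplicates (`S = 0`) and `f_eq = mu_c/(mu_c + mu_d - S)` for deleterious
#' ones (`S < 0`). The equilibrium is approached in about `t_eq = 3/mu_d`
#' generations. A duplicate with `S > mu_d` escapes the balance entirely
#' (runaway fixation) and no equilibrium exists.
#'
#' @param mu_c duplication formation rate (per gene per generation, > 0).
#' @param mu_d duplication deletion rate (per gene per generation, > 0).
#' @param S selection coefficient of the duplicate (default 0; <= 0 for a
#'   true balance).
#' @return list with `f_eq`, `r_eq` (= f/(1-f)), `t_eq`, `equilibrium`
#'   (FALSE when `S > mu_d`, with `f_eq = NA`).
#' @examples
#' duplication_balance(3e-4, 4.4e-2)$f_eq    # ~0.68%
#' duplication_balance(3e-4, 4.1e-4)$f_eq    # ~42%
#' @export
duplication_balance <- function(mu_c, mu_d, S = 0) {
  check_pos(mu_c, "mu_c"); check_pos(mu_d, "mu_d")
  if (S > mu_d)
    return(list(f_eq = NA_real_, r_eq = NA_real_, t_eq = NA_real_,
                equilibrium = FALSE))
  f_eq <- if (S == 0) mu_c / (mu_c + mu_d) else mu_c / (mu_c + mu_d - S)
  list(f_eq = f_eq, r_eq = f_eq / (1 - f_eq), t_eq = 3 / mu_d,
       equilibrium = TRUE)
}

#' Time-dependent duplicate frequency under formation, deletion, selection
#'
#' Per-generation two-class recurrence: duplicate mass grows by `(1 + S)`,
#' a fraction `mu_d` of it reverts to singleton, a fraction `mu_c` of the
#' singleton mass converts to duplicate, and the population is renormalised:
#' `f' = [f*(1+S)*(1-mu_d) + (1-f)*mu_c] / [f*(1+S) + (1-f)]`.
#' Its stationary point reproduces [duplication_balance()] to first order in
#' the rates; with `mu_c = mu_d = 0` it reduces exactly to
#' [competition_dynamics()].
#'
#' @param mu_c,mu_d formation and deletion rates in `[0, 1)`.
#' @param S selection coefficient of the duplicate.
#' @param f0 initial duplicate frequency in `[0, 1]`.
#' @param t_max number of generations to iterate.
#' @return data.frame with `t` (0..t_max) and `f`.
#' @examples
#' tail(duplication_frequency_dynamics(3e-4, 4.4e-2, 0, 0, 200), 1)
#' @export
duplication_frequency_dynamics <- function(mu_c, mu_d, S = 0, f0 = 0,
                                           t_max = 1000) {
  stopifnot(mu_c >= 0, mu_c < 1, mu_d >= 0, mu_d < 1, f0 >= 0, f0 <= 1,
            t_max >= 1)
  f <- numeric(t_max + 1)
  f[1] <- f0
  for (i in seq_len(t_max)) {
    fd <- f[i] * (1 + S)
    fs <- 1 - f[i]
    f[i + 1] <- (fd * (1 - mu_d) + fs * mu_c) / (fd + fs)
  }
  data.frame(t = 0:t_max, f = f)
}

#' Expected supply of expression-halving mutants
#'
#' From a per-base mutation rate `mu` and `n_sites` base pairs whose
#' mutation halves the expression of the gene, the beneficial-mutation rate
#' is `mu_b = n_sites*mu` and the expected number of such mutants present in
#' the population per generation is `mu_b * <N>`.
#'
#' @param mu per-base mutation rate (mutations/bp/generation).
#' @param n_sites number of relevant base pairs.
#' @param N_eff effective population size.
#' @return list with `mu_b` and `supply`.
#' @examples
#' mutant_supply(1e-10, 10, 2e8)$supply   # 0.2 mutants per generation
#' @export
mutant_supply <- function(mu, n_sites, N_eff) {
  check_nonneg(mu, "mu"); check_nonneg(n_sites, "n_sites")
  check_pos(N_eff, "N_eff")
  mu_b <- n_sites * mu
  list(mu_b = mu_b, supply = mu_b * N_eff)
}

#' Concurrence of promoter mutation and duplication, and global fixation
#'
#' Two-step path to an adaptive duplication: a promoter mutation first
#' halves expression (`n_mut` such mutants expected per generation), then a
#' duplication restores the ancestral total. The probability that both
#' concur in the same cell in a generation (duplication after mutation) is
#' `p_concur = n_mut * p_dup / 2`, with `p_dup` the per-cell probability of
#' carrying/gaining the duplication; the global fixation probability is
#' `P_fix = 2*(S - mu_d) * p_concur`, zero (not fixable) when the advantage
#' does not exceed the deletion rate.
#'
#' @param n_mut expected expression-halving mutants per generation.
#' @param p_dup per-cell duplication probability (rate or standing
#'   frequency).
#' @param S selection coefficient of the restored-expression duplicate.
#' @param mu_d duplication deletion rate.
#' @return list with `p_concur`, `P_fix_global`, `fixable`.
#' @examples
#' concurrence_and_global_fixation(0.2, 1e-3, 0.0019, 4.1e-4)
#' @export
concurrence_and_global_fixation <- function(n_mut, p_dup, S, mu_d) {
  check_nonneg(n_mut, "n_mut"); check_nonneg(p_dup, "p_dup")
  check_nonneg(mu_d, "mu_d")
  p_concur <- n_mut * p_dup / 2
  if (S <= mu_d)
    list(p_concur = p_concur, P_fix_global = 0, fixable = FALSE)
  else
    list(p_concur = p_concur, P_fix_global = 2 * (S - mu_d) * p_concur,
         fixable = TRUE)
}
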