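test_that("competition dynamics follow r0 * 2^(S*t) with consistent
           frequency bookkeeping", {
  flat <- competition_dynamics(1, 0, c(0, 100, 1000))
  expect_true(all(flat$f == 0.5))
  step <- competition_dynamics(1, 0.001, 1000)
  expect_equal(step$r, 2)
  expect_equal(step$f, 2 / 3)
  # f(r) and r(f) are mutual inverses along a trajectory
  traj <- competition_dynamics(f0 = 0.1, S = 0.01, t = 0:500)
  expect_true(all(traj$f >= 0 & traj$f <= 1))
  expect_equal(traj$f / (1 - traj$f), traj$r, tolerance = 1e-9)
  expect_equal(traj$f[1], 0.1, tolerance = 1e-12)
})

test_that("effective population size scales as 3e9 / G^1.44", {
  expect_equal(effective_population_size(1), 3e9)
  expect_equal(effective_population_size(5), 3e9 / 5^1.44, tolerance = 1e-12)
  expect_equal(effective_population_size(5), 3.0e8, tolerance = 0.05)
  G <- c(1, 5, 50, 3000)
  expect_true(all(diff(effective_population_size(G)) < 0))
})

test_that("fixation statistics dispatch the four closed-form regimes", {
  # neutral: P = 1/<N>, t = 2<N>
  neu <- fixation_stats(N_eff = 2e8, regime = "neutral")
  expect_equal(neu$P_fix, 5e-9)
  expect_equal(neu$t_fix, 4e8)
  # punctual: P = 2S, t = log2(<N>^2)/S, half-invasion at t/2
  pun <- fixation_stats(S = 0.0019, N_eff = 2e8, regime = "punctual")
  expect_equal(pun$P_fix, 0.0038)
  expect_equal(pun$t_fix, log2((2e8)^2) / 0.0019, tolerance = 1e-12)
  expect_equal(pun$t_half, log2(2e8) / 0.0019, tolerance = 1e-12)
  expect_equal(pun$t_half, pun$t_fix / 2)
  # recurrent supply: certain fixation, shorter characteristic time
  rec <- fixation_stats(S = 0.0019, N_eff = 2e8, regime = "recurrent",
                        mu_b = 1e-9)
  expect_equal(rec$P_fix, 1)
  expect_equal(rec$t_fix, log2(2e8 * 0.0019 / 1e-9) / 0.0019,
               tolerance = 1e-12)
  # duplication: effective coefficient S' = S - mu_d
  dup <- fixation_stats(S = 0.0019, N_eff = 2e8, regime = "duplication",
                        mu_d = 4.1e-4)
  expect_equal(dup$S_eff, 0.00149, tolerance = 1e-9)
  expect_equal(dup$P_fix, 0.00298, tolerance = 1e-9)
  # reduces exactly to the punctual regime when deletion vanishes
  dup0 <- fixation_stats(S = 0.0019, N_eff = 2e8, regime = "duplication",
                         mu_d = 0)
  expect_equal(dup0[c("P_fix", "t_fix", "t_half")],
               pun[c("P_fix", "t_fix", "t_half")])
  # deletion faster than selection: the duplicate cannot fix
  stuck <- fixation_stats(S = 0.0019, N_eff = 2e8, regime = "duplication",
                          mu_d = 0.044)
  expect_false(stuck$fixable)
  expect_identical(stuck$P_fix, 0)
  expect_error(fixation_stats(S = -0.1, N_eff = 1e8, regime = "punctual"))
})

test_that("recurrent-mutant dynamics pick the right supply branch", {
  # large supply at S*t = 0: r = mu_b / S
  big <- recurrent_mutant_dynamics(mu_b = 1e-4, N = 1e5, D = 100,
                                   S = 0.01, t = 0)
  expect_equal(big$r, 1e-4 / 0.01)
  expect_identical(attr(big, "regime"), "large-supply")
  # small supply: delayed punctual dynamics, T = log2(D)/(mu_b*N)
  small <- recurrent_mutant_dynamics(mu_b = 1e-7, N = 1e5, D = 100,
                                     S = 0.01, t = c(0, 1000))
  expect_identical(attr(small, "regime"), "small-supply")
  expect_equal(attr(small, "delay"), log2(100) / 0.01, tolerance = 1e-9)
  expect_equal(attr(small, "delay"), 664, tolerance = 1e-3)
  # branches agree in order of magnitude at the boundary mu_b*N = 1
  t_probe <- 2000
  a <- recurrent_mutant_dynamics(1.0001e-5, 1e5, 100, 0.01, t_probe)$r
  b <- recurrent_mutant_dynamics(0.9999e-5, 1e5, 100, 0.01, t_probe)$r
  expect_lt(abs(log10(a / b)), 1.5)
})

test_that("successive fixations stack one full time plus earlier half
           times", {
  N_eff <- 1e4
  one <- successive_fixation_time(0.01, N_eff)
  expect_equal(one, log2(N_eff^2) / 0.01, tolerance = 1e-12)
  t_half <- log2(N_eff) / 0.01
  expect_equal(successive_fixation_time(c(0.01, 0.01), N_eff),
               one + t_half, tolerance = 1e-12)
  expect_equal(successive_fixation_time(rep(0.01, 3), N_eff),
               one + 2 * t_half, tolerance = 1e-12)
  expect_identical(successive_fixation_time(numeric(0), N_eff), 0)
})

test_that("formation-deletion balance reproduces the printed equilibria", {
  # high deletion rate: ~0.68% standing duplicates
  hi <- duplication_balance(3e-4, 4.4e-2)
  expect_equal(hi$f_eq, 0.0068, tolerance = 0.01)
  expect_equal(hi$t_eq, 68, tolerance = 0.005)
  # low deletion rate: ~42%
  lo <- duplication_balance(3e-4, 4.1e-4)
  expect_equal(lo$f_eq, 0.42, tolerance = 0.01)
  # deleterious duplicates: 0.09-0.11%
  del_hi <- duplication_balance(3e-4, 4.4e-2, S = -0.28)
  del_lo <- duplication_balance(3e-4, 4.1e-4, S = -0.28)
  expect_equal(del_hi$f_eq, 0.000925, tolerance = 0.01)
  expect_equal(del_lo$f_eq, 0.00107, tolerance = 0.01)
  # selection stronger than deletion: runaway, no equilibrium
  run <- duplication_balance(3e-4, 4.1e-4, S = 0.0019)
  expect_false(run$equilibrium)
  expect_true(is.na(run$f_eq))
})

test_that("duplicate-frequency recurrence matches the balance point and
           collapses to pure competition without rearrangements", {
  # neutral: stationary point is exactly mu_c/(mu_c + mu_d)
  dyn <- duplication_frequency_dynamics(3e-4, 4.4e-2, 0, 0, 500)
  expect_equal(dyn$f[501], duplication_balance(3e-4, 4.4e-2)$f_eq,
               tolerance = 1e-9)
  expect_true(all(dyn$f >= 0 & dyn$f <= 1))
  # deleterious: agrees with the closed form to first order in the rates
  for (S in c(-0.05, -0.28)) {
    dyn_d <- duplication_frequency_dynamics(3e-4, 4.4e-2, S, 0, 2000)
    expect_equal(dyn_d$f[2001], duplication_balance(3e-4, 4.4e-2, S)$f_eq,
                 tolerance = 0.06)
  }
  # positive selection far above deletion (S >> mu_d): sweeps to fixation,
  # up to the small standing singleton mass regenerated by deletion
  sweep <- duplication_frequency_dynamics(3e-4, 4.1e-4, 0.10, 0.001, 2000)
  expect_gt(sweep$f[2001], 0.99)
  # deletion comparable to selection: mutation-selection balance far from 1
  partial <- duplication_frequency_dynamics(3e-4, 4.4e-2, 0.10, 0.001, 2000)
  expect_lt(partial$f[2001], 0.6)
  expect_gt(partial$f[2001], 0.4)
  # mu_c = mu_d = 0 reduces to competition dynamics (per-generation growth
  # factor 1 + S corresponds to 2^(S') with S' = log2(1 + S))
  pure <- duplication_frequency_dynamics(0, 0, 0.05, 0.3, 100)
  ref <- competition_dynamics(f0 = 0.3, S = log2(1.05), t = 0:100)
  expect_equal(pure$f, ref$f, tolerance = 1e-9)
})

test_that("mutant supply and concurrence arithmetic reproduce the worked
           examples", {
  sup <- mutant_supply(1e-10, 10, 2e8)
  expect_equal(sup$mu_b, 1e-9)
  expect_equal(sup$supply, 0.2)
  expect_equal(mutant_supply(1e-10, 1, 2e8)$supply, 0.02)
  expect_identical(mutant_supply(1e-10, 0, 2e8)$supply, 0)
  # E. coli: 0.2 mutants/generation, duplication probability 1e-3
  con <- concurrence_and_global_fixation(0.2, 1e-3, 0.0019, 4.1e-4)
  expect_equal(con$p_concur, 1e-4)
  expect_equal(con$P_fix_global, 3e-7, tolerance = 0.01)
  # fly: standing duplicate frequency 0.1 in the population
  fly <- concurrence_and_global_fixation(0.05, 0.1, 0.0019, 1e-6)
  expect_equal(fly$p_concur, 2.5e-3)
  # no fixation when deletion outpaces selection
  blocked <- concurrence_and_global_fixation(0.2, 1e-3, 0.0019, 0.044)
  expect_false(blocked$fixable)
  expect_identical(blocked$P_fix_global, 0)
})
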