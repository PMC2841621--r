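# The clock-off constant-coefficient limit has closed-form oracles
# (characteristic growth rate, asynchronous phase fractions); the clocked
# runs are checked for conservation-style invariants: periodicity,
# linearity, determinism and step-size convergence.

test_that("clock-off growth matches the characteristic-equation root", {
  p <- toy_clockoff()
  lam <- characteristic_growth_rate(p)
  # independent check of the root itself
  expect_equal(lam, -p$kappa_mean + 2 * p$kappa_mean * exp(-lam * 12),
               tolerance = 1e-12)
  tr <- simulate_population(p, circ, NULL, t_end = 240, dt = 0.02)
  expect_equal(growth_rate(tr, c(168, 240)), lam, tolerance = 1e-3)
})

test_that("clock-off fractions settle to the asynchronous oracle", {
  p <- toy_clockoff(death_s = 0.002, death_g2 = 0.001, death_m = 0.001,
                    g1_loss_rate = 0.01)
  tr <- simulate_population(p, circ, NULL, t_end = 192, dt = 0.02)
  fr <- phase_fractions(tr)
  n <- nrow(fr)
  # drift below 1e-3 per 24 h once transients passed (~5 division cycles)
  i0 <- which.min(abs(fr$time - 144))
  expect_lt(abs(fr$frac_s[n] - fr$frac_s[i0]) / 2, 1e-3)
  want <- asynchronous_fractions(p)
  expect_equal(fr$frac_g1[n], want[["g1"]], tolerance = 1e-3)
  expect_equal(fr$frac_s[n], want[["s"]], tolerance = 1e-3)
  expect_equal(fr$frac_g2[n], want[["g2"]], tolerance = 1e-3)
})

test_that("asynchronous oracle matches simulation on random kinetics", {
  set.seed(7)
  for (i in 1:5) {
    p <- clock_off(random_preset())
    tr <- simulate_population(p, circ, NULL, t_end = 260, dt = 0.02)
    fr <- phase_fractions(tr)
    got <- unlist(fr[nrow(fr), c("frac_g1", "frac_s", "frac_g2",
                                 "frac_m")])
    expect_equal(unname(got), unname(asynchronous_fractions(p)),
                 tolerance = 1e-3)
  }
  # fractions always sum to one
  expect_equal(sum(asynchronous_fractions(toy_clockoff())), 1)
})

test_that("phase fractions sum to 1 and respect degenerate initialisations", {
  p <- shipped_preset("host")
  tr <- simulate_population(p, circ, NULL, t_end = 120, dt = 0.02)
  fr <- phase_fractions(tr)
  expect_lt(max(abs(fr$frac_g1 + fr$frac_s + fr$frac_g2 + fr$frac_m - 1)),
            1e-9)
  # kappa = 0: nothing ever leaves G1
  p0 <- cell_cycle_preset(kappa_mean = 0, g1_loss_rate = 0, label = "still")
  tr0 <- simulate_population(p0, circ, NULL, t_end = 60, dt = 0.05)
  expect_equal(phase_fractions(tr0)$frac_g1, rep(1, length(tr0$times)))
})

test_that("clocked fractions are 24 h-periodic after the transient", {
  p <- shipped_preset("host")
  tr <- simulate_population(p, circ, NULL, t_end = 168, dt = 0.02)
  fr <- phase_fractions(tr)
  a <- fr$frac_s[fr$time >= 96 & fr$time < 120]
  b <- fr$frac_s[fr$time >= 120 & fr$time < 144]
  expect_equal(a, b, tolerance = 1e-3)
  # peak-to-peak separation of 24 h (within a step)
  pk1 <- fr$time[fr$time >= 96 & fr$time < 120][which.max(a)]
  pk2 <- fr$time[fr$time >= 120 & fr$time < 144][which.max(b)]
  expect_equal(pk2 - pk1, 24, tolerance = 0.05)
})

test_that("trajectories are linear in the initial state and deterministic", {
  p <- toy_clocked()
  tr1 <- simulate_population(p, circ, NULL, t_end = 120, dt = 0.02)
  tr3 <- simulate_population(p, circ, NULL, t_end = 120, dt = 0.02,
                             n_init = 3)
  expect_equal(3 * total_cells(tr1), total_cells(tr3), tolerance = 1e-12)
  tr1b <- simulate_population(p, circ, NULL, t_end = 120, dt = 0.02)
  expect_identical(tr1$states, tr1b$states)  # bit-identical rerun
})

test_that("halving the step changes late totals by less than 0.1%", {
  p <- shipped_preset("tumor_fast")
  sch <- schedule(target_phase = "S", start_time = 8)
  n1 <- total_cells(simulate_population(p, circ, sch, t_end = 168,
                                        dt = 0.04), 168)
  n2 <- total_cells(simulate_population(p, circ, sch, t_end = 168,
                                        dt = 0.02), 168)
  expect_lt(abs(n1 - n2) / n2, 1e-3)
})

test_that("growth_rate recovers exact exponentials and is window-phase free", {
  p <- toy_clockoff()
  lam <- characteristic_growth_rate(p)
  tr <- simulate_population(p, circ, NULL, t_end = 240, dt = 0.02)
  # late windows agree to high precision once on the exponential attractor
  expect_equal(growth_rate(tr, c(168, 216)), growth_rate(tr, c(192, 240)),
               tolerance = 1e-6)
  pc <- shipped_preset("host")
  trc <- simulate_population(pc, circ, NULL, t_end = 192, dt = 0.02)
  expect_equal(growth_rate(trc, c(96, 120)), growth_rate(trc, c(120, 144)),
               tolerance = 1e-6)
  expect_error(growth_rate(trc, c(300, 400)), "window")
})

test_that("trajectory CSV and JSON sidecar round-trip the run", {
  p <- toy_clocked()
  tr <- simulate_population(p, circ, schedule(target_phase = "S"),
                            t_end = 100, dt = 0.05, out_every = 10)
  f <- tempfile(fileext = ".csv")
  write_trajectory(tr, f)
  back <- read.csv(f)
  expect_named(back, c("time", "n_g1", "n_s", "n_g2", "n_m", "total",
                       "frac_g1", "frac_s", "frac_g2m"))
  expect_equal(nrow(back), length(tr$times))
  meta <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(meta$preset$label, "toy-clocked")
  expect_equal(meta$dt, 0.05)
})

test_that("oversized steps and bad states are rejected", {
  p <- toy_clocked()
  expect_error(simulate_population(p, circ, NULL, t_end = 50, dt = 0.1),
               "dt")
  expect_error(simulate_population(p, circ, NULL, t_end = 50, dt = 0.02,
                                   n_init = -1), "n_init")
})
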