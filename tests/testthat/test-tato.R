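# The period-averaged analysis has closed forms under sinusoidal gating;
# every closed form is cross-checked against direct numerics (Riemann
# sums, grid searches, an independent Euler integration of the clock-free
# toy model).

test_that("S-phase closed-form extrema follow the half-duration rule", {
  pred <- s_phase_extrema(14, 8)
  expect_equal(pred$best_time, 18)   # max kill: t_kappa + ts/2
  expect_equal(pred$worst_time, 6)   # max sparing: 12 h later
  # extrema always 12 h apart, for any phase and duration
  set.seed(11)
  for (i in 1:20) {
    pr <- s_phase_extrema(runif(1, 0, 24), runif(1, 0.5, 40))
    if (!pr$degenerate)
      expect_equal(circ_dist(pr$best_time, pr$worst_time), 12)
  }
  expect_true(s_phase_extrema(14, 24)$degenerate)
  expect_true(s_phase_extrema(14, 48)$degenerate)
})

test_that("durations beyond 24 h shift the extrema off the naive rule", {
  # the +12 h branch coincides with the (ts - 24) rule and sits 12 h from
  # the naive sub-24 h formula extended past 24 h
  pred26 <- s_phase_extrema(14, 26)
  expect_equal(pred26$best_time, s_phase_extrema(14, 2)$best_time)
  naive26 <- clock_time(14 + 26 / 2)
  expect_equal(circ_dist(pred26$best_time, naive26), 12)
})

test_that("perturbation integral: zero cases and Riemann oracle", {
  p <- toy_clocked()
  sch <- schedule(target_phase = "S", k_max = 0.3)
  # clock off: the oscillatory transition rate vanishes
  expect_equal(periodic_growth_contribution(clock_off(p), circ, sch, 5), 0)
  # ts = 24 h: every cohort collects the same daily hazard
  p24 <- p; p24$ts <- 24
  v24 <- vapply(seq(0, 21, by = 3), function(t0)
    periodic_growth_contribution(p24, circ, sch, t0), numeric(1))
  expect_lt(diff(range(v24)), 1e-10)

  # 1e5-point Riemann oracle on random presets
  set.seed(3)
  for (i in 1:5) {
    pr <- random_preset()
    t0 <- runif(1, 0, 24)
    tt <- seq(0, 24, length.out = 1e5 + 1)[-1]
    prof <- chronocycle:::daily_profile(pr, sch, t0)
    s_day <- stage_survival(tt, pr, prof, circ)
    kt <- chronocycle:::kappa_tilde(
      tt - sgm_total_delay(tt, pr, circ), pr, circ)
    oracle <- mean((s_day - mean(s_day)) * kt)
    expect_equal(periodic_growth_contribution(pr, circ, sch, t0), oracle,
                 tolerance = 1e-8)
  }
})

test_that("closed-form and numeric extrema agree within half an hour", {
  sch <- schedule(target_phase = "S", k_max = 0.3)
  for (pars in list(c(amp = 0.2, tk = 14, ts = 8),
                    c(amp = 0.3, tk = 3, ts = 12))) {
    p <- cell_cycle_preset(kappa_mean = 0.05, kappa_mod_amp = pars["amp"],
                           kappa_mod_phase = pars["tk"], ts = pars["ts"],
                           tg2_mean = 3, tm = 1, label = "cf")
    ex <- chronocycle:::numeric_extrema(function(t0)
      periodic_growth_contribution(p, circ, sch, t0), grid_step = 0.5)
    cf <- s_phase_extrema(pars[["tk"]], pars[["ts"]])
    expect_lte(circ_dist(ex$t_min, cf$best_time), 0.5)
    expect_lte(circ_dist(ex$t_max, cf$worst_time), 0.5)
  }
})

test_that("phase_extrema handles all targets and degenerate gating", {
  p <- shipped_preset("tumor_fast")
  # S target delegates to the closed form
  pred_s <- phase_extrema("S", p, circ, schedule())
  expect_equal(pred_s$method, "closed_form")
  expect_equal(pred_s$best_time,
               clock_time(p$kappa_mod_phase + p$ts / 2))
  expect_gt(pred_s$amplitude, 0)
  # G2M target found numerically, 12 h-separated for sinusoidal gating
  pred_g2m <- phase_extrema("G2M", p, circ, schedule(), grid_step = 1)
  expect_equal(pred_g2m$method, "numeric")
  expect_lte(abs(circ_dist(pred_g2m$best_time, pred_g2m$worst_time) - 12),
             0.2)
  # no gating at all: timing cannot matter
  expect_true(phase_extrema("G1", clock_off(p), circ, schedule())$degenerate)
})

test_that("timing-effect amplitude is symmetric in ts and vanishes at 24 h", {
  expect_equal(outcome_amplitude(24), 0, tolerance = 1e-12)
  for (ts in c(4, 8, 12, 16, 20)) {
    a <- outcome_amplitude(ts)
    expect_gt(a, 0)
    expect_equal(a, outcome_amplitude(24 - ts), tolerance = 1e-8)
  }
  # the leverage is largest for intermediate durations
  expect_gt(outcome_amplitude(12), outcome_amplitude(2))
})

test_that("equivalent start time advances 2 h per interval hour at n = 5", {
  expect_equal(as.numeric(equivalent_start_time(24, 5, 7)), 7)
  # +1 h of interval -> 2 h advance of the start (slope -(n-1)/2)
  expect_equal(as.numeric(equivalent_start_time(25, 5, 2)), 0)
  d <- as.numeric(equivalent_start_time(25, 5, 10)) -
    as.numeric(equivalent_start_time(24, 5, 10))
  expect_equal((d + 12) %% 24 - 12, -2)
  expect_true(attr(equivalent_start_time(25, 5, 2), "valid"))
  expect_false(attr(equivalent_start_time(30, 5, 2), "valid"))
})

test_that("uniform-phase intervals spread administrations evenly", {
  expect_equal(uniform_phase_intervals(5), c(19.2, 28.8))
  expect_equal(uniform_phase_intervals(2), c(12, 36))
  for (iv in uniform_phase_intervals(5)) {
    phases <- sort(clock_time(3 + iv * 0:4))
    gaps <- diff(c(phases, phases[1] + 24))
    expect_equal(gaps, rep(24 / 5, 5), tolerance = 1e-12)
  }
})

test_that("clock-free minimum matches Lambert-W identity and Euler oracle", {
  for (pars in list(c(8, 0.05), c(12, 0.1), c(20, 0.02))) {
    ts <- pars[1]; kap <- pars[2]
    tstar <- clock_free_min_sensitive_time(ts, kap)
    expect_lte(abs(attr(tstar, "residual")), 1e-6)
    # numerical minimization of the refilling sensitive fraction
    num <- optimize(function(t)
      chronocycle:::clockfree_sensitive_fraction(t, ts, kap),
      c(ts, 2 * ts), tol = 1e-12)$minimum
    expect_equal(as.numeric(tstar), num, tolerance = 1e-6)
  }
  # independent Euler integration of the toy model: kill all S cells at
  # t = 0, exponential G1 with rate kappa, S transit ts, doubling on exit
  ts <- 8; kap <- 0.05; dt <- 1e-3
  nt <- round(2 * ts / dt)
  g1 <- numeric(nt + 1); g1[1] <- 1
  for (i in seq_len(nt)) {
    t <- (i - 1) * dt
    refill <- if (t >= ts) 2 * kap * g1[i - round(ts / dt) + 1] else 0
    g1[i + 1] <- g1[i] + dt * (-kap * g1[i] + refill)
  }
  tgrid <- (0:nt) * dt
  ns <- kap * dt * (cumsum(g1) -
                      c(rep(0, round(ts / dt)),
                        cumsum(g1)[1:(nt + 1 - round(ts / dt))]))
  frac <- ns / (g1 + ns)
  sel <- tgrid > ts
  t_euler <- tgrid[sel][which.min(frac[sel])]
  expect_equal(as.numeric(clock_free_min_sensitive_time(8, 0.05)), t_euler,
               tolerance = 1e-2)
  # sensitive fraction is empty right after a total kill
  expect_equal(chronocycle:::clockfree_sensitive_fraction(0, 8, 0.05), 0)
})

test_that("administration intervals at or below ts leave no surviving cohort", {
  # delta-like administrations every tau hours kill every cell in S; a
  # cohort survives only if its ts-long window dodges all administrations,
  # impossible when tau <= ts
  covered <- function(tau, ts) {
    entries <- seq(0, tau, by = 0.01)
    all(vapply(entries, function(u)
      any(seq(0, ceiling((u + ts) / tau)) * tau >= u &
            seq(0, ceiling((u + ts) / tau)) * tau <= u + ts),
      logical(1)))
  }
  expect_true(covered(6, 8))
  expect_true(covered(8, 8))
  expect_false(covered(10, 8))
})

test_that("sign of the perturbation integral predicts the full model", {
  # across random configurations the integral and the simulated growth
  # shift (relative to the mean-hazard prediction) move together; the
  # sign agrees whenever both are resolved (first-order theory)
  set.seed(42)
  I <- d <- numeric(10)
  for (i in 1:10) {
    p <- cell_cycle_preset(kappa_mean = runif(1, 0.04, 0.08),
                           kappa_mod_amp = runif(1, 0.15, 0.35),
                           kappa_mod_phase = runif(1, 0, 24),
                           ts = runif(1, 6, 14), tg2_mean = 3, tm = 1,
                           label = "r")
    t0 <- runif(1, 0, 24)
    sch <- schedule(target_phase = "S", start_time = t0, n_admin = 9,
                    k_max = 0.15, start_day = 0)
    I[i] <- periodic_growth_contribution(p, circ, sch, t0)
    tr <- simulate_population(p, circ, sch, t_end = 216, dt = 0.02)
    st <- chronocycle:::survival_stats(p, circ, sch, t0)
    lam_mean <- chronocycle:::char_root(p$kappa_mean, p$g1_loss_rate,
                                        p$ts + p$tg2_mean + p$tm,
                                        2 * st$sbar * p$kappa_mean)
    d[i] <- growth_rate(tr, c(120, 192)) - lam_mean
  }
  expect_gt(cor(I, d), 0.7)
  resolved <- abs(I) > 5e-4 & abs(d) > 5e-4
  expect_true(any(resolved))
  expect_true(all(sign(I[resolved]) == sign(d[resolved])))
})
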