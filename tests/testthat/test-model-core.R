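test_that("clock-gated rates: constant limits, peaks, and period means", {
  p <- toy_clocked(kappa_mean = 0.1, kappa_mod_amp = 0.5,
                   kappa_mod_phase = 14)
  p0 <- clock_off(p)
  tt <- seq(0, 48, by = 0.25)
  expect_equal(g1s_transition_rate(tt, p0, circ), rep(0.1, length(tt)))
  expect_equal(g1s_transition_rate(14, p, circ), 0.15)  # peak kappa*(1+a)
  # mean over one period is kappa_mean for any amplitude
  fine <- seq(0, 24, length.out = 100001)[-1]
  expect_equal(mean(g1s_transition_rate(fine, p, circ)), 0.1,
               tolerance = 1e-9)

  g <- cell_cycle_preset(kappa_mean = 0.05, tg2_mean = 3, g2_mod_amp = 0.2,
                         g2_mod_phase = 14, label = "g")
  expect_equal(g2_duration(14, g, circ), 3.6)
  expect_equal(g2_duration(tt, g, circ), g2_duration(tt + 24, g, circ),
               tolerance = 1e-14)
  expect_error(cell_cycle_preset(kappa_mean = 0.05, g2_mod_amp = 1.0),
               "g2_mod_amp")
})

test_that("total S+G2+M transit time follows the G2 modulation", {
  p <- cell_cycle_preset(kappa_mean = 0.05, ts = 8, tg2_mean = 3, tm = 1,
                         g2_mod_amp = 0.2, g2_mod_phase = 14, label = "p")
  expect_equal(sgm_total_delay(14, p, circ), 12.6)  # 8 + 3.6 + 1
  expect_equal(sgm_total_delay(10, clock_off(p), circ), 12)
  tt <- seq(0, 48, by = 0.05)
  expect_equal(min(sgm_total_delay(tt, p, circ)), 8 + 3 * 0.8 + 1,
               tolerance = 1e-6)
})

test_that("entry time is a strict order isomorphism and inverts cleanly", {
  p <- cell_cycle_preset(kappa_mean = 0.05, ts = 8, tg2_mean = 3, tm = 1,
                         g2_mod_amp = 0.2, g2_mod_phase = 14, label = "p")
  expect_equal(entry_time(20, clock_off(p), circ), 8)  # T = 12, constant
  for (nm in c("host", "tumor_fast", "tumor_slow")) {
    sp <- shipped_preset(nm)
    te <- entry_time(seq(0, 48, by = 0.1), sp, circ)
    expect_true(all(diff(te) > 0), info = nm)
  }
  # round trip against a bisection oracle
  bisect_div <- function(te, preset) {
    uniroot(function(v) v - sgm_total_delay(v, preset, circ) - te,
            c(te, te + 50), tol = 1e-12)$root
  }
  for (te in c(0, 5.3, 17.8, 30.1)) {
    v_newton <- division_time(te, p, circ)
    expect_equal(v_newton, bisect_div(te, p), tolerance = 1e-9)
    expect_lt(abs(entry_time(v_newton, p, circ) - te), 1e-6)
  }
})

test_that("stage survival: closed forms and quadrature oracle", {
  p <- cell_cycle_preset(kappa_mean = 0.05, ts = 8, tg2_mean = 3, tm = 1,
                         death_s = 0, death_g2 = 0, death_m = 0,
                         label = "p")
  expect_equal(stage_survival(10, p, death_rate_profile(p), circ), 1)
  p2 <- cell_cycle_preset(kappa_mean = 0.05, ts = 8, tg2_mean = 3, tm = 1,
                          death_s = 0.05, death_g2 = 0, death_m = 0,
                          label = "p2")
  expect_equal(stage_survival(c(3, 17), p2, death_rate_profile(p2), circ),
               rep(exp(-0.4), 2))

  # chronomodulated S-phase drug: closed-form hazard integral vs a
  # 1e4-step Riemann sum over the cohort's S window
  sch <- schedule(target_phase = "S", start_time = 10, k_max = 0.3)
  prof <- death_rate_profile(p2, sch)
  for (tdiv in c(80, 93.5, 101.2)) {
    te <- tdiv - sgm_total_delay(tdiv, p2, circ)
    u <- seq(te, te + p2$ts, length.out = 10001)
    rate <- 0.05 + chrono_death_rate(u, sch)
    haz_riemann <- mean((rate[-1] + rate[-length(u)]) / 2) * p2$ts
    expect_equal(stage_survival(tdiv, p2, prof, circ), exp(-haz_riemann),
                 tolerance = 1e-6)
  }

  # survival in (0,1] and 24 h-periodic under a daily periodic hazard
  dly <- chronocycle:::daily_profile(p2, sch, 10)
  tt <- seq(0, 24, by = 0.5)
  s1 <- stage_survival(tt, p2, dly, circ)
  s2 <- stage_survival(tt + 24, p2, dly, circ)
  expect_true(all(s1 > 0 & s1 <= 1))
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("effective death rates attach the drug to its target phase only", {
  p <- toy_clocked()
  t <- seq(70, 90, by = 0.5)
  for (ph in c("S", "G1", "G2M")) {
    sch <- schedule(target_phase = ph, start_time = 6, k_max = 0.2)
    d <- effective_death_rates(t, p, sch)
    drug <- chrono_death_rate(t, sch)
    expect_true(any(drug > 0))
    base <- effective_death_rates(t, p, NULL)
    if (ph == "S") {
      expect_equal(d$s, base$s + drug)
      expect_equal(d$g2, base$g2); expect_equal(d$m, base$m)
    } else if (ph == "G1") {
      expect_equal(d$g1, base$g1 + drug)
      expect_equal(d$s, base$s)
    } else {
      expect_equal(d$g2, base$g2 + drug)
      expect_equal(d$m, base$m + drug)
      expect_equal(d$s, base$s)
    }
  }
})

test_that("preset YAML round trip validates fields", {
  p <- shipped_preset("host")
  f <- tempfile(fileext = ".yaml")
  save_preset(p, f)
  q <- load_preset(f)
  expect_equal(unclass(q), unclass(p))
  y <- yaml::read_yaml(f)
  y$not_a_field <- 1
  yaml::write_yaml(y, f)
  expect_error(load_preset(f), "unknown preset keys")
  y$not_a_field <- NULL
  y$kappa_mean <- NULL
  yaml::write_yaml(y, f)
  expect_error(load_preset(f), "missing preset keys")
})
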