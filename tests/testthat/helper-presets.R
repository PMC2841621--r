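# Shared fixtures: small presets built in code, circular helpers, and a
# memoized copy of the expensive full best/worst table used by several
# acceptance checks.

circ <- circadian_input()

# clock-off toy: exponential G1 (kappa 0.1/h), 12 h deterministic S+G2+M
toy_clockoff <- function(...) {
  args <- modifyList(list(kappa_mean = 0.1, g1_loss_rate = 0, ts = 8,
                          tg2_mean = 3, tm = 1, death_s = 0, death_g2 = 0,
                          death_m = 0, label = "toy"), list(...))
  do.call(cell_cycle_preset, args)
}

# clocked preset resembling a renewing host tissue
toy_clocked <- function(...) {
  args <- modifyList(list(kappa_mean = 0.05, kappa_mod_amp = 0.3,
                          kappa_mod_phase = 14, ts = 8, tg2_mean = 3,
                          tm = 1, label = "toy-clocked"), list(...))
  do.call(cell_cycle_preset, args)
}

circ_dist <- function(a, b) {
  d <- abs(a - b) %% 24
  pmin(d, 24 - d)
}

# random valid preset under a fixed seed (callers set the seed)
random_preset <- function() {
  cell_cycle_preset(kappa_mean = runif(1, 0.04, 0.09),
                    kappa_mod_amp = runif(1, 0.1, 0.35),
                    kappa_mod_phase = runif(1, 0, 24),
                    ts = runif(1, 6, 14),
                    tg2_mean = runif(1, 2, 4), tm = 1,
                    g1_loss_rate = runif(1, 0, 0.02),
                    death_s = runif(1, 0, 0.003),
                    death_g2 = runif(1, 0, 0.003),
                    death_m = runif(1, 0, 0.003),
                    label = "random")
}

# memoized expensive objects shared by the acceptance checks
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_table <- function() {
  if (is.null(.acceptance_cache$tab)) {
    .acceptance_cache$tab <- best_worst_table(
      shipped_preset("host"),
      list(fast = shipped_preset("tumor_fast"),
           slow = shipped_preset("tumor_slow")),
      circ, schedule(), grid_step = 0.5, dt = 0.01)
  }
  .acceptance_cache$tab
}
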