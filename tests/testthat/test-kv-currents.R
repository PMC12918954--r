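make_ramp_recording <- function(current_fun, dt = 0.5, capacitance = 20,
                                n_trials = 1) {
  tm <- seq(0, 1200, by = dt)
  cmd <- pmin(-100 + 0.1 * tm, 20)
  dat <- purrr::map_dfr(seq_len(n_trials), function(tr) {
    tibble::tibble(trial = tr, sweep = 1L, label = "ramp", time = tm,
                   command = cmd, recorded = current_fun(cmd))
  })
  new_recording(dat, dt = dt, mode = "VC", capacitance = capacitance,
                metadata = list(prepulse_ms = 0, ramp_start_mV = -100,
                                ramp_stop_mV = 20))
}

test_that("P/N subtraction cancels a purely ohmic response exactly", {
  sim_one <- function(p, vt) {
    pr <- step_vc_protocol(holding_mV = -100, prepulse_mV = -100,
                           test_start_mV = vt, test_stop_mV = vt + 10,
                           test_step_mV = 10)
    get_sweep(simulate_voltage_clamp(p, pr, dt = 0.02, noise = no_noise(),
                                     n_trials = 1), 1, 1)
  }
  ohm <- passive_params(g_leak = 2)
  test <- sim_one(ohm, 50)
  subs <- lapply(1:5, function(i) sim_one(ohm, -70))
  corr <- leak_subtract_p_over_n(test, subs, 5)
  expect_lt(max(abs(corr$recorded)), 1e-9)
})

test_that("P/N subtraction is the identity for silent subsweeps and checks its inputs", {
  tm <- seq(0, 10, by = 0.1)
  test <- tibble::tibble(time = tm, command = ifelse(tm > 5, 50, 0),
                         recorded = ifelse(tm > 5, 120, 0))
  silent <- tibble::tibble(time = tm, command = ifelse(tm > 5, 10, 0),
                           recorded = 0)
  corr <- leak_subtract_p_over_n(test, rep(list(silent), 5), 5)
  expect_equal(corr$recorded, test$recorded)
  expect_error(leak_subtract_p_over_n(test, rep(list(silent), 4), 5),
               "expected 5")
  wrong_amp <- dplyr::mutate(silent, command = command * 3)
  expect_error(leak_subtract_p_over_n(test, rep(list(wrong_amp), 5), 5),
               "amplitude")
})

test_that("P/5 correction recovers the A-current-only response", {
  sim_one <- function(p, vt) {
    pr <- step_vc_protocol(holding_mV = -100, prepulse_mV = -100,
                           test_start_mV = vt, test_stop_mV = vt + 10,
                           test_step_mV = 10)
    get_sweep(simulate_voltage_clamp(p, pr, dt = 0.02, noise = no_noise(),
                                     n_trials = 1), 1, 1)
  }
  leak_a <- params_variant(g_Na = 0, g_Kdr = 0)
  test <- sim_one(leak_a, 50)
  subs <- lapply(1:5, function(i) sim_one(leak_a, -70))
  corr <- leak_subtract_p_over_n(test, subs, 5)
  pure <- sim_one(a_only_params(), 50)
  base <- mean(pure$recorded[pure$time < 600])
  sel <- test$time >= 600
  expect_equal(max(corr$recorded[sel]),
               max(pure$recorded[sel] - base), tolerance = 0.02)
})

test_that("prepulse subtraction is exact on identical families and rejects swaps", {
  fam <- vc_family(a_only_params(), -100, key = "aonly_m100")
  fam40 <- vc_family(a_only_params(), -40, key = "aonly_m40")
  zero <- isolate_ia(fam, fam)
  # identical input families cancel except for the relabelled prepulse
  zero2 <- fam
  zero2$data$recorded <- 0
  expect_equal(zero$data$recorded, zero2$data$recorded)
  expect_error(isolate_ia(fam40, fam), "swapped")
})

test_that("isolated I_A matches the A-current-only simulation within 5%", {
  ft <- vc_family(na_blocked_params(), -100, key = "nab_m100")
  fk <- vc_family(na_blocked_params(), -40, key = "nab_m40")
  ia <- step_iv(isolate_ia(ft, fk), "peak")
  pure <- step_iv(vc_family(a_only_params(), -100, key = "aonly_m100"),
                  "peak")
  at50 <- function(iv) iv$density[iv$voltage == 50]
  expect_equal(at50(ia), at50(pure), tolerance = 0.05)
})

test_that("step I-V summaries are baseline-subtracted current densities", {
  tm <- seq(0, 1100, by = 1)
  dat <- purrr::map_dfr(c(-60, -50), function(vt) {
    tibble::tibble(test_mV = vt, time = tm,
                   command = ifelse(tm >= 600, vt, -100),
                   recorded = ifelse(tm >= 600, 450, 50))
  })
  fam <- new_step_family(dat, prepulse_mV = -100, capacitance = 20,
                         dt = 1, t_test_on = 600, t_test_off = 1100)
  expect_equal(step_iv(fam, "peak")$density, c(20, 20))
  expect_equal(step_iv(fam, "sustained")$density, c(20, 20))
  fam2 <- fam
  fam2$capacitance <- 40
  expect_equal(step_iv(fam2, "peak")$density, c(10, 10))
})

test_that("peak A-current density matches the fine-grid gate maximum within 5%", {
  coarse <- step_iv(vc_family(a_only_params(), -100, key = "aonly_m100"),
                    "peak")
  fine <- step_iv(vc_family(a_only_params(), -100, dt = 0.005,
                            key = "aonly_m100_fine"), "peak")
  at <- function(iv, v) iv$density[iv$voltage == v]
  expect_equal(at(coarse, -10), at(fine, -10), tolerance = 0.05)
})

test_that("ramp binning has 1200 bins and reproduces closed forms", {
  const <- make_ramp_recording(function(v) rep(100, length(v)))
  iv <- ramp_iv(const)
  expect_equal(nrow(iv), 1200L)
  expect_true(all(abs(iv$density - 5) < 1e-12))
  # linear conductance g = 2 nS, E = -90: density = g (V - E) / C
  lin <- make_ramp_recording(function(v) 2 * (v + 90))
  ivl <- ramp_iv(lin)
  expected <- 2 * (ivl$voltage + 90) / 20
  expect_lt(max(abs(ivl$density - expected)), 2 * 0.1 / 20)
})

test_that("ramp binning is invariant to sampling refinement", {
  rec1 <- cached("ramp_nab_02", simulate_voltage_clamp(
    na_blocked_params(), ramp_vc_protocol(), dt = 0.02,
    noise = no_noise(), n_trials = 1))
  rec2 <- cached("ramp_nab_01", simulate_voltage_clamp(
    na_blocked_params(), ramp_vc_protocol(), dt = 0.01,
    noise = no_noise(), n_trials = 1))
  d1 <- ramp_iv(rec1)$density
  d2 <- ramp_iv(rec2)$density
  expect_lt(max(abs(d1 - d2)) / max(abs(d2)), 0.005)
})

test_that("degenerate ramps are rejected", {
  wobble <- make_ramp_recording(function(v) v)
  wobble$data$command[500] <- wobble$data$command[400]
  expect_error(ramp_iv(wobble), "monotonically")
  coarse <- make_ramp_recording(function(v) v, dt = 2)
  expect_error(ramp_iv(coarse), "empty")
})

test_that("the blocker-sensitive component recovers the blocked conductance", {
  rv <- function(p, key) cached(key, simulate_voltage_clamp(
    p, ramp_vc_protocol(), dt = 0.02, noise = no_noise(), n_trials = 1))
  before <- rv(na_blocked_params(), "ramp_nab_02")
  ga_only <- ramp_iv(rv(a_only_params(), "ramp_aonly"))
  same <- toxin_sensitive(before, before)
  expect_true(all(same$density == 0))
  full <- toxin_sensitive(before, rv(scale_kv4(na_blocked_params(), 0),
                                     "ramp_nab_block0"))
  half <- toxin_sensitive(before, rv(scale_kv4(na_blocked_params(), 0.5),
                                     "ramp_nab_block05"))
  scale_ref <- max(abs(ga_only$density))
  expect_lt(max(abs(full$density - ga_only$density)) / scale_ref, 0.05)
  expect_lt(max(abs(half$density - 0.5 * ga_only$density)) /
              (0.5 * scale_ref), 0.05)
})

test_that("I-V linearity: sustained summaries of I_Total decompose into I_K + I_A", {
  ft <- vc_family(na_blocked_params(), -100, key = "nab_m100")
  fk <- vc_family(na_blocked_params(), -40, key = "nab_m40")
  ia <- isolate_ia(ft, fk)
  s_tot <- step_iv(ft, "sustained")$density
  s_k <- step_iv(fk, "sustained")$density
  s_a <- step_iv(ia, "sustained")$density
  expect_equal(s_tot, s_k + s_a, tolerance = 1e-10)
})

test_that("isolated I_A peak density is proportional to g_A within 5%", {
  dens <- vapply(c(1, 2, 4), function(s) {
    ft <- vc_family(a_only_params(s), -100,
                    key = paste0("aonly_scale_", s))
    iv <- step_iv(ft, "peak")
    iv$density[iv$voltage == 50]
  }, numeric(1))
  expect_equal(dens[2] / dens[1], 2, tolerance = 0.05)
  expect_equal(dens[3] / dens[1], 4, tolerance = 0.05)
})

test_that("the I_A share of a current increase is a guarded grid-point ratio", {
  mk <- function(d_tot, d_ia) {
    list(total = structure(tibble::tibble(voltage = c(-20, -10, 0),
                                          density = c(1, 10, 20) + d_tot),
                           class = c("iv_curve", "tbl_df", "tbl", "data.frame")),
         ia = structure(tibble::tibble(voltage = c(-20, -10, 0),
                                       density = c(0, 5, 10) + d_ia),
                        class = c("iv_curve", "tbl_df", "tbl", "data.frame")))
  }
  expect_equal(ia_fraction_at(mk(0, 0), mk(10, 7.6), v = -10), 0.76)
  expect_error(ia_fraction_at(mk(0, 0), mk(0, 0), v = -10), "zero change")
  expect_error(ia_fraction_at(mk(0, 0), mk(10, 7.6), v = -15), "grid")
})

test_that("the simulated I_A fraction matches the component-wise oracle within 2%", {
  fams <- function(p, tag) {
    ft <- vc_family(p, -100, key = paste0(tag, "_m100"))
    fk <- vc_family(p, -40, key = paste0(tag, "_m40"))
    list(total = step_iv(ft, "peak"), ia = step_iv(isolate_ia(ft, fk), "peak"))
  }
  ctrl <- fams(na_blocked_params(), "nab")
  trt <- fams(scale_kv4(na_blocked_params(), 1.5), "nab15")
  frac <- ia_fraction_at(ctrl, trt, v = -10)
  # oracle: single-conductance simulations of the A-current alone
  a1 <- step_iv(vc_family(a_only_params(), -100, key = "aonly_m100"),
                "peak")
  a15 <- step_iv(vc_family(a_only_params(1.5), -100, key = "aonly15_m100"),
                 "peak")
  at <- function(iv) iv$density[iv$voltage == -10]
  d_ia_oracle <- at(a15) - at(a1)
  d_tot_oracle <- at(step_iv(vc_family(scale_kv4(na_blocked_params(), 1.5),
                                       -100, key = "nab15_m100"), "peak")) -
    at(step_iv(vc_family(na_blocked_params(), -100, key = "nab_m100"),
               "peak"))
  expect_equal(frac, d_ia_oracle / d_tot_oracle, tolerance = 0.02)
})
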