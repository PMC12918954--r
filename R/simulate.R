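# Command waveforms are defined as functions of absolute time and sampled
# at t = k*dt, so the same protocol yields the same stimulus values at
# shared sample times regardless of dt (needed for convergence checks).
ramp_cc_command <- function(protocol, dt) {
  ramp_ms <- if (protocol$ramp_rate > 0) {
    (protocol$max_current - protocol$onset_current) / protocol$ramp_rate
  } else 0
  total <- protocol$pre_stim_ms + ramp_ms + protocol$post_stim_ms
  tm <- seq(0, total + dt / 2, by = dt)
  t0 <- protocol$pre_stim_ms
  on_ramp <- tm >= t0 & tm <= t0 + ramp_ms
  out <- numeric(length(tm))
  out[on_ramp] <- protocol$onset_current + protocol$ramp_rate * (tm[on_ramp] - t0)
  out
}

step_vc_commands <- function(protocol, dt, holding_ms = 100) {
  tests <- seq(protocol$test_start_mV, protocol$test_stop_mV,
               by = protocol$test_step_mV)
  t1 <- holding_ms
  t2 <- holding_ms + protocol$prepulse_ms
  total <- t2 + protocol$test_ms
  tm <- seq(0, total + dt / 2, by = dt)
  lapply(tests, function(vt) {
    ifelse(tm < t1, protocol$holding_mV,
           ifelse(tm < t2, protocol$prepulse_mV, vt))
  }) %>% setNames(as.character(tests))
}

ramp_vc_command <- function(protocol, dt) {
  rate <- protocol$ramp_rate_mV_per_s / 1000 # mV/ms
  ramp_ms <- (protocol$ramp_stop_mV - protocol$ramp_start_mV) / rate
  total <- protocol$prepulse_ms + ramp_ms
  tm <- seq(0, total + dt / 2, by = dt)
  t0 <- protocol$prepulse_ms
  ifelse(tm < t0, protocol$prepulse_mV,
         pmin(protocol$ramp_start_mV + rate * (tm - t0),
              protocol$ramp_stop_mV))
}

add_trial_noise <- function(base, n_trials, sd, seed) {
  # all noise drawn in one seeded block: same seed => bit-identical record
  nper <- length(base)
  if (sd == 0) {
    return(lapply(seq_len(n_trials), function(i) base))
  }
  withr::with_seed(seed, {
    lapply(seq_len(n_trials), function(i) base + rnorm(nper, sd = sd))
  })
}

#' Simulate a current-clamp ramp recording
#'
#' Integrates the conductance model under the ramp current-injection
#' protocol with fixed-step fourth-order Runge-Kutta, starting from the
#' model's resting state, and returns a current-clamp [new_recording()].
#' Integration is deterministic; seeded Gaussian noise is added to the
#' recorded voltage afterwards, independently per trial.
#'
#' @param params A [neuron_params()] object.
#' @param protocol A [ramp_cc_protocol()].
#' @param dt Integration and sampling step (ms), must be in (0, 0.05].
#' @param noise A [noise_spec()].
#' @param n_trials Number of repeated trials (noise realisations); the
#'   conventional protocol records 5 trials per cell.
#' @return A `recording` in CC mode. `rmp_measured` holds the model's true
#'   resting potential.
#' @export
simulate_current_clamp <- function(params, protocol, dt = 0.005,
                                   noise = noise_spec(), n_trials = 5L) {
  stopifnot(inherits(params, "neuron_params"),
            inherits(protocol, "ramp_cc_protocol"),
            inherits(noise, "noise_spec"))
  if (dt <= 0 || dt > 0.05) abort("dt must be in (0, 0.05] ms")
  cmd <- ramp_cc_command(protocol, dt)
  rest <- resting_state(params)
  v <- sim_cc_cpp(pack_params(params), cmd, dt, rest$V)
  traces <- add_trial_noise(v, n_trials, noise$voltage_noise_sd, noise$seed)
  tm <- (seq_along(cmd) - 1) * dt
  data <- purrr::map_dfr(seq_len(n_trials), function(i) {
    tibble(trial = i, sweep = 1L, label = "ramp", time = tm,
           command = cmd, recorded = traces[[i]])
  })
  new_recording(data, dt = dt, mode = "CC", capacitance = params$C_m,
                rmp_measured = rest$V,
                metadata = list(protocol = "ramp_cc",
                                ramp_rate = protocol$ramp_rate,
                                noise_seed = noise$seed))
}

#' Simulate a voltage-clamp recording
#'
#' Integrates the gate kinetics under an ideal voltage clamp (membrane
#' voltage equals the command exactly; no series-resistance error) and
#' records the total membrane current (ionic + leak). Step protocols yield
#' one sweep per test potential, labelled by the test potential in mV.
#'
#' @param params A [neuron_params()] object.
#' @param protocol A [step_vc_protocol()] or [ramp_vc_protocol()].
#' @param dt Sampling step (ms), in (0, 0.05].
#' @param noise A [noise_spec()]; SD applies to the recorded current.
#' @param n_trials Number of repeated trials.
#' @param holding_ms Duration at the holding potential before the prepulse
#'   (step protocols only).
#' @return A `recording` in VC mode.
#' @export
simulate_voltage_clamp <- function(params, protocol, dt = 0.005,
                                   noise = noise_spec(), n_trials = 5L,
                                   holding_ms = 100) {
  stopifnot(inherits(params, "neuron_params"), inherits(noise, "noise_spec"))
  if (dt <= 0 || dt > 0.05) abort("dt must be in (0, 0.05] ms")
  pv <- pack_params(params)
  if (inherits(protocol, "step_vc_protocol")) {
    cmds <- step_vc_commands(protocol, dt, holding_ms)
  } else if (inherits(protocol, "ramp_vc_protocol")) {
    cmds <- list(ramp = ramp_vc_command(protocol, dt))
  } else {
    abort("protocol must be a step_vc_protocol or ramp_vc_protocol")
  }
  currents <- lapply(cmds, function(cmd) sim_vc_cpp(pv, cmd, dt))
  data <- purrr::imap_dfr(cmds, function(cmd, lab) {
    idx <- match(lab, names(cmds))
    base <- currents[[lab]]
    # per-sweep noise seed offset keeps sweeps independent yet reproducible
    traces <- add_trial_noise(base, n_trials, noise$current_noise_sd,
                              noise$seed + idx)
    tm <- (seq_along(cmd) - 1) * dt
    purrr::map_dfr(seq_len(n_trials), function(i) {
      tibble(trial = i, sweep = idx, label = lab, time = tm,
             command = cmd, recorded = traces[[i]])
    })
  })
  meta <- list(protocol = class(protocol)[1], noise_seed = noise$seed)
  if (inherits(protocol, "step_vc_protocol")) {
    meta$prepulse_mV <- protocol$prepulse_mV
    meta$test_ms <- protocol$test_ms
    meta$prepulse_ms <- protocol$prepulse_ms
    meta$holding_ms <- holding_ms
  } else {
    meta$prepulse_ms <- protocol$prepulse_ms
    meta$ramp_start_mV <- protocol$ramp_start_mV
    meta$ramp_stop_mV <- protocol$ramp_stop_mV
  }
  new_recording(data, dt = dt, mode = "VC", capacitance = params$C_m,
                metadata = meta)
}
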