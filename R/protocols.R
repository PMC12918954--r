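#' Stimulation protocols
#'
#' Constructors for the three stimulation protocols used throughout the
#' excitability experiments.
#'
#' `ramp_cc_protocol()` is the current-clamp ramp used to evoke action
#' potentials: after a stimulus-free baseline the injected current steps to
#' a hyperpolarizing onset and then ramps up linearly at `ramp_rate`
#' (default 0.15 pA/ms) until `max_current`.
#'
#' `step_vc_protocol()` is the voltage-clamp step family used to measure
#' voltage-dependent potassium currents: a 500-ms prepulse (-100 mV to make
#' the A-current available, or -40 mV to inactivate it) followed by 500-ms
#' test pulses from -60 to +50 mV in 10-mV increments.
#'
#' `ramp_vc_protocol()` is the slow voltage ramp (-100 to +20 mV at
#' 100 mV/s, after a -100 mV prepulse) used to approximate the
#' quasi-steady-state current.
#'
#' @param onset_current Onset current (pA, must be <= 0: hyperpolarizing).
#' @param ramp_rate Current ramp rate (pA/ms), > 0.
#' @param max_current Current at which the ramp stops (pA).
#' @param pre_stim_ms,post_stim_ms Baseline durations before/after (ms).
#' @return A protocol object (`ramp_cc_protocol`, `step_vc_protocol` or
#'   `ramp_vc_protocol`).
#' @name protocols
NULL

#' @rdname protocols
#' @export
ramp_cc_protocol <- function(onset_current = -40, ramp_rate = 0.15,
                             max_current = 150, pre_stim_ms = 200,
                             post_stim_ms = 100) {
  if (ramp_rate < 0) abort("ramp_rate must be non-negative")
  if (onset_current > 0) abort("onset_current must be hyperpolarizing (<= 0)")
  if (ramp_rate == 0 && max_current != onset_current) {
    abort("a zero-rate protocol must have max_current == onset_current")
  }
  if (max_current < onset_current) abort("max_current must be >= onset")
  structure(list(onset_current = onset_current, ramp_rate = ramp_rate,
                 max_current = max_current, pre_stim_ms = pre_stim_ms,
                 post_stim_ms = post_stim_ms),
            class = "ramp_cc_protocol")
}

#' @rdname protocols
#' @param holding_mV Holding potential before the prepulse (mV).
#' @param prepulse_mV Prepulse potential (mV); -100 makes the A-current
#'   available, -40 inactivates it.
#' @param prepulse_ms Prepulse duration (ms).
#' @param test_start_mV,test_stop_mV,test_step_mV Test-pulse range and
#'   increment (mV).
#' @param test_ms Test-pulse duration (ms).
#' @export
step_vc_protocol <- function(holding_mV = -60, prepulse_mV = -100,
                             prepulse_ms = 500, test_start_mV = -60,
                             test_stop_mV = 50, test_step_mV = 10,
                             test_ms = 500) {
  if (test_step_mV <= 0) abort("test_step_mV must be positive")
  if (prepulse_ms <= 0) abort("prepulse_ms must be positive")
  span <- test_stop_mV - test_start_mV
  if (span < 0 || abs(span / test_step_mV - round(span / test_step_mV)) > 1e-9) {
    abort("test range must be divisible by test_step_mV")
  }
  structure(list(holding_mV = holding_mV, prepulse_mV = prepulse_mV,
                 prepulse_ms = prepulse_ms, test_start_mV = test_start_mV,
                 test_stop_mV = test_stop_mV, test_step_mV = test_step_mV,
                 test_ms = test_ms),
            class = "step_vc_protocol")
}

#' @rdname protocols
#' @param ramp_start_mV,ramp_stop_mV Voltage ramp range (mV).
#' @param ramp_rate_mV_per_s Ramp speed (mV/s).
#' @export
ramp_vc_protocol <- function(prepulse_mV = -100, prepulse_ms = 500,
                             ramp_start_mV = -100, ramp_stop_mV = 20,
                             ramp_rate_mV_per_s = 100) {
  if (ramp_stop_mV <= ramp_start_mV) abort("ramp_stop must exceed ramp_start")
  if (ramp_rate_mV_per_s <= 0) abort("ramp rate must be positive")
  structure(list(prepulse_mV = prepulse_mV, prepulse_ms = prepulse_ms,
                 ramp_start_mV = ramp_start_mV, ramp_stop_mV = ramp_stop_mV,
                 ramp_rate_mV_per_s = ramp_rate_mV_per_s),
            class = "ramp_vc_protocol")
}

#' Additive recording-noise specification
#'
#' Gaussian noise added to the recorded channel after deterministic
#' integration, seeded for bit reproducibility. Defaults mimic a quiet
#' whole-cell rig: 2 pA on current records, 0.2 mV on voltage records.
#'
#' @param current_noise_sd Noise SD on recorded current (pA), >= 0.
#' @param voltage_noise_sd Noise SD on recorded voltage (mV), >= 0.
#' @param seed Integer seed; identical seeds give bit-identical recordings.
#' @return A `noise_spec` object.
#' @export
noise_spec <- function(current_noise_sd = 2, voltage_noise_sd = 0.2,
                       seed = 1L) {
  if (current_noise_sd < 0 || voltage_noise_sd < 0) {
    abort("noise standard deviations must be non-negative")
  }
  structure(list(current_noise_sd = current_noise_sd,
                 voltage_noise_sd = voltage_noise_sd,
                 seed = as.integer(seed)),
            class = "noise_spec")
}

#' Zero-noise specification
#' @return A `noise_spec` with both SDs zero.
#' @export
no_noise <- function() noise_spec(0, 0, 0L)
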