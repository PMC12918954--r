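#' Step-family container for voltage-clamp test-pulse series
#'
#' A `step_family` holds one trial-averaged current trace per test
#' potential, plus the timing needed to summarise the test pulse. Build it
#' from a step-protocol VC recording with `step_family()`, or assemble one
#' directly with `new_step_family()`.
#'
#' @param rec A VC [new_recording()] made with a [step_vc_protocol()].
#' @return A `step_family` object.
#' @export
step_family <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  if (rec$mode != "VC") abort("step_family needs a VC recording")
  md <- rec$metadata
  for (k in c("prepulse_mV", "prepulse_ms", "holding_ms", "test_ms")) {
    if (is.null(md[[k]])) abort(paste("recording metadata lacks", k))
  }
  avg <- average_trials(rec)
  data <- avg$data %>%
    mutate(test_mV = as.numeric(.data$label)) %>%
    select("test_mV", "time", "command", "recorded") %>%
    arrange(.data$test_mV, .data$time)
  t_on <- md$holding_ms + md$prepulse_ms
  new_step_family(data, prepulse_mV = md$prepulse_mV,
                  capacitance = rec$capacitance, dt = rec$dt,
                  t_test_on = t_on, t_test_off = t_on + md$test_ms,
                  n_trials = dplyr::n_distinct(rec$data$trial))
}

#' @rdname step_family
#' @param data Tibble with columns `test_mV`, `time`, `command`,
#'   `recorded` (pA), one trace per test potential.
#' @param prepulse_mV Prepulse potential (mV).
#' @param capacitance Cell capacitance (pF).
#' @param dt Sampling interval (ms).
#' @param t_test_on,t_test_off Test-pulse window within each trace (ms).
#' @param n_trials Number of trials averaged into the traces.
#' @export
new_step_family <- function(data, prepulse_mV, capacitance, dt,
                            t_test_on, t_test_off, n_trials = 1L) {
  data <- as_tibble(data)
  pots <- sort(unique(data$test_mV))
  if (length(pots) < 2L) abort("step family needs >= 2 test potentials")
  spc <- diff(pots)
  if (any(spc <= 0) || max(spc) - min(spc) > 1e-9) {
    abort("test potentials must be strictly increasing, uniformly spaced")
  }
  lens <- dplyr::count(data, .data$test_mV)
  if (dplyr::n_distinct(lens$n) != 1L) {
    abort("all sweeps in a step family must have equal length")
  }
  structure(list(data = data, test_mV = pots, prepulse_mV = prepulse_mV,
                 capacitance = capacitance, dt = dt, t_test_on = t_test_on,
                 t_test_off = t_test_off, n_trials = n_trials),
            class = "step_family")
}

#' P/N leak subtraction
#'
#' Corrects a test sweep for linear leak and capacitive current using `n`
#' scaled subpulses (the P/5 protocol for `n = 5`): each subsweep's command
#' excursion is 1/n of the test excursion, so the leak-scaled average of
#' the subsweeps, multiplied by n, estimates the linear component of the
#' test response, which is subtracted pointwise.
#'
#' Commands and responses are taken as excursions from each sweep's own
#' baseline: the command excursion is relative to the first sample's level
#' and each recorded trace has its pre-step holding current (mean over the
#' samples at the initial command level) removed before the scaled
#' subtraction, as a P/N-capable amplifier does. The returned trace is the
#' baseline-free nonlinear component of the test response.
#'
#' @param test Sweep tibble (`time`, `command`, `recorded`).
#' @param subsweeps List of `n` sweep tibbles with 1/n-amplitude commands.
#' @param n Number of subpulses (default 5).
#' @param amp_tol Relative tolerance on the subpulse amplitude check.
#' @return The corrected test sweep tibble.
#' @export
leak_subtract_p_over_n <- function(test, subsweeps, n = 5L, amp_tol = 0.01) {
  if (length(subsweeps) != n) {
    abort(paste0("expected ", n, " subsweeps, got ", length(subsweeps)))
  }
  sweep_base <- function(s) {
    mean(s$recorded[s$command == s$command[1]])
  }
  amp_test <- test$command - test$command[1]
  ref <- max(abs(amp_test))
  sub_mean <- rep(0, nrow(test))
  for (s in subsweeps) {
    if (nrow(s) != nrow(test)) abort("subsweep length mismatch")
    amp_sub <- s$command - s$command[1]
    if (ref > 0 && max(abs(amp_sub - amp_test / n)) > amp_tol * ref) {
      abort("subsweep command amplitude is not 1/n of the test amplitude")
    }
    sub_mean <- sub_mean + (s$recorded - sweep_base(s)) / n
  }
  dplyr::mutate(test,
                recorded = (.data$recorded - sweep_base(test)) - n * sub_mean)
}

#' Isolate the A-type current by prepulse subtraction
#'
#' The transient A-type current is available after a hyperpolarized
#' prepulse (-100 mV) but inactivated after a depolarized prepulse
#' (-40 mV); the delayed-rectifier component is unaffected. Pointwise
#' subtraction of the depolarized-prepulse family (I_K) from the
#' hyperpolarized-prepulse family (I_Total) therefore yields I_A.
#'
#' @param total Step family recorded after the hyperpolarized prepulse
#'   (I_Total).
#' @param ik Step family recorded after the depolarized prepulse (I_K).
#' @return A `step_family` holding I_A = I_Total - I_K.
#' @export
isolate_ia <- function(total, ik) {
  stopifnot(inherits(total, "step_family"), inherits(ik, "step_family"))
  if (!isTRUE(all.equal(total$test_mV, ik$test_mV))) {
    abort("families have mismatched test potentials")
  }
  if (total$dt != ik$dt) abort("families have mismatched dt")
  if (nrow(total$data) != nrow(ik$data)) {
    abort("families have mismatched sweep lengths")
  }
  if (total$prepulse_mV > ik$prepulse_mV) {
    abort(paste("prepulse labels look swapped: I_Total needs the",
                "hyperpolarized prepulse and I_K the depolarized one"))
  }
  out <- total
  out$data$recorded <- total$data$recorded - ik$data$recorded
  out$label <- "I_A"
  out
}

#' Capacitance-normalized I-V curve from a step family
#'
#' Per test potential, subtracts the baseline holding current (mean over
#' the 50 ms before the test step), summarises the test-pulse current as
#' its maximum (`"peak"`, appropriate for the transient A-current and the
#' total current) or the mean over the last `sustained_ms` of the pulse
#' (`"sustained"`, appropriate for the delayed rectifier), and divides by
#' the cell capacitance to give a current density in pA/pF.
#'
#' @param family A [step_family()].
#' @param summary_mode `"peak"` or `"sustained"`.
#' @param baseline_ms Pre-step window for the holding-current baseline (ms).
#' @param sustained_ms Tail window for the sustained summary (ms).
#' @return An `iv_curve` tibble with columns `voltage` (mV) and `density`
#'   (pA/pF).
#' @export
step_iv <- function(family, summary_mode = c("peak", "sustained"),
                    baseline_ms = 50, sustained_ms = 50) {
  stopifnot(inherits(family, "step_family"))
  summary_mode <- match.arg(summary_mode)
  if (family$capacitance <= 0) abort("capacitance must be positive")
  t_on <- family$t_test_on
  t_off <- family$t_test_off
  if (sustained_ms > t_off - t_on) abort("summary window exceeds the pulse")
  if (baseline_ms > t_on) abort("baseline window exceeds the pre-step data")
  out <- family$data %>%
    group_by(.data$test_mV) %>%
    summarise(
      baseline = mean(.data$recorded[.data$time >= t_on - baseline_ms &
                                       .data$time < t_on]),
      summary = if (summary_mode == "peak") {
        max(.data$recorded[.data$time >= t_on & .data$time <= t_off])
      } else {
        mean(.data$recorded[.data$time >= t_off - sustained_ms &
                              .data$time <= t_off])
      },
      .groups = "drop") %>%
    mutate(density = (.data$summary - .data$baseline) / family$capacitance) %>%
    select(voltage = "test_mV", "density") %>%
    arrange(.data$voltage)
  attr(out, "summary_mode") <- summary_mode
  class(out) <- c("iv_curve", class(out))
  out
}

#' Quasi-steady-state I-V curve from a slow voltage ramp
#'
#' Trials are averaged pointwise first; ramp-segment samples are then
#' assigned to half-open `bin_width`-mV command-voltage bins (0.1 mV by
#' default, giving 1200 bins over the standard -100 to +20 mV ramp) and
#' averaged within bins; the binned current is divided by the cell
#' capacitance. This approximates the quasi-steady-state current density.
#'
#' @param rec A VC ramp [new_recording()].
#' @param bin_width Bin width (mV).
#' @return A `ramp_iv` tibble with columns `voltage` (bin centers, mV) and
#'   `density` (pA/pF); attribute `n_trials_averaged`.
#' @export
ramp_iv <- function(rec, bin_width = 0.1) {
  stopifnot(inherits(rec, "recording"))
  if (rec$mode != "VC") abort("ramp_iv needs a VC recording")
  md <- rec$metadata
  if (is.null(md$ramp_start_mV) || is.null(md$ramp_stop_mV)) {
    abort("recording metadata lacks ramp_start_mV/ramp_stop_mV")
  }
  n_trials <- dplyr::n_distinct(rec$data$trial)
  avg <- average_trials(rec)$data
  start <- md$ramp_start_mV
  stop_v <- md$ramp_stop_mV
  ramp_on <- if (!is.null(md$prepulse_ms)) md$prepulse_ms else 0
  seg <- avg %>% filter(.data$time >= ramp_on, .data$command < stop_v)
  if (any(diff(seg$command) <= 0)) {
    abort("command is not monotonically increasing over the ramp segment")
  }
  nbins <- round((stop_v - start) / bin_width)
  bin <- floor((seg$command - start) / bin_width)
  bin[bin >= nbins] <- nbins - 1L
  if (length(unique(bin)) < nbins) {
    abort("empty voltage bins: sampling too coarse for this bin width")
  }
  dens <- tapply(seg$recorded, bin, mean) / rec$capacitance
  out <- tibble(voltage = start + (as.numeric(names(dens)) + 0.5) * bin_width,
                density = as.numeric(dens)) %>%
    arrange(.data$voltage)
  attr(out, "n_trials_averaged") <- n_trials
  class(out) <- c("ramp_iv", class(out))
  out
}

#' Toxin-sensitive current component from paired ramps
#'
#' The Kv4-mediated (blocker-sensitive) component is the binwise
#' difference between the quasi-steady-state I-V curves recorded before
#' and during blocker application (before - during).
#'
#' @param before,during VC ramp recordings with identical protocols and
#'   capacitance.
#' @param bin_width Bin width (mV).
#' @return A `ramp_iv` tibble of the difference current density.
#' @export
toxin_sensitive <- function(before, during, bin_width = 0.1) {
  for (k in c("ramp_start_mV", "ramp_stop_mV", "prepulse_ms")) {
    if (!identical(before$metadata[[k]], during$metadata[[k]])) {
      abort("before/during ramp protocols do not match")
    }
  }
  if (!isTRUE(all.equal(before$capacitance, during$capacitance))) {
    abort("before/during capacitance mismatch")
  }
  a <- ramp_iv(before, bin_width)
  b <- ramp_iv(during, bin_width)
  out <- a
  out$density <- a$density - b$density
  out
}

#' Fraction of a total-current change carried by the A-current
#'
#' At a probe potential `v` (by default -10 mV, near the AP threshold
#' level where active potassium currents gate AP initiation), returns
#' \eqn{\Delta I_A(v) / \Delta I_{Total}(v)} where \eqn{\Delta} is the
#' treated-minus-control difference of the capacitance-normalized I-V
#' curves.
#'
#' @param control,treated Lists `list(total = , ia = )` of [step_iv()]
#'   curves on matching voltage grids.
#' @param v Probe potential (mV); must be a grid point.
#' @return The dimensionless fraction.
#' @export
ia_fraction_at <- function(control, treated, v = -10) {
  grab <- function(curve, nm) {
    i <- which(abs(curve$voltage - v) < 1e-9)
    if (!length(i)) abort(paste0(nm, " curve has no grid point at ", v, " mV"))
    curve$density[i]
  }
  d_total <- grab(treated$total, "treated total") -
    grab(control$total, "control total")
  d_ia <- grab(treated$ia, "treated I_A") - grab(control$ia, "control I_A")
  if (d_total == 0) {
    abort("zero change in total current at the probe potential")
  }
  d_ia / d_total
}
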