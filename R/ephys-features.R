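#' Action-potential detection criteria
#'
#' The AP threshold criterion follows the standard rise-speed definition:
#' the threshold is the voltage at which dV/dt first reaches 5 mV/ms on the
#' rise leading to the peak. dV/dt is computed by central differences on a
#' locally polynomial-smoothed trace (Savitzky-Golay), because the 5 mV/ms
#' criterion is sensitive to recording noise. An accepted AP is a local
#' maximum above `peak_min` preceded within `lookback_ms` by a 5 mV/ms
#' crossing, with refractory separation of at least `refractory_ms` between
#' successive peaks.
#'
#' @param dvdt_threshold Rise-speed threshold (mV/ms).
#' @param peak_min Minimum peak voltage to accept an AP (mV).
#' @param lookback_ms Maximum threshold-to-peak separation (ms).
#' @param refractory_ms Minimum peak-to-peak separation (ms).
#' @param smooth_ms Savitzky-Golay window (ms); 0 disables smoothing.
#' @param smooth_order Polynomial order of the smoother.
#' @return An `ap_criteria` list.
#' @export
ap_criteria <- function(dvdt_threshold = 5, peak_min = -10, lookback_ms = 10,
                        refractory_ms = 2, smooth_ms = 0.5,
                        smooth_order = 2) {
  structure(list(dvdt_threshold = dvdt_threshold, peak_min = peak_min,
                 lookback_ms = lookback_ms, refractory_ms = refractory_ms,
                 smooth_ms = smooth_ms, smooth_order = smooth_order),
            class = "ap_criteria")
}

sweep_dt <- function(sweep) {
  d <- diff(sweep$time)
  if (length(d) < 1L || any(d <= 0)) abort("sweep time must be increasing")
  median(d)
}

smooth_voltage <- function(v, dt, criteria) {
  if (criteria$smooth_ms <= 0) return(v)
  n <- max(criteria$smooth_order + 2, round(criteria$smooth_ms / dt))
  if (n %% 2 == 0) n <- n + 1
  if (n >= length(v)) return(v)
  signal::sgolayfilt(v, p = criteria$smooth_order, n = n)
}

central_dvdt <- function(v, dt) {
  n <- length(v)
  d <- numeric(n)
  d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt)
  d[1] <- (v[2] - v[1]) / dt
  d[n] <- (v[n] - v[n - 1]) / dt
  d
}

# linear interpolation of the time at which y crosses level upward between
# samples i-1 and i
cross_time_up <- function(t, y, i, level) {
  if (i == 1L || y[i] == y[i - 1]) return(t[i])
  frac <- (level - y[i - 1]) / (y[i] - y[i - 1])
  t[i - 1] + frac * (t[i] - t[i - 1])
}

# parabolic refinement of a local maximum at index i
refine_peak <- function(t, v, i) {
  n <- length(v)
  if (i <= 1L || i >= n) return(list(time = t[i], value = v[i]))
  denom <- v[i - 1] - 2 * v[i] + v[i + 1]
  if (denom >= 0) return(list(time = t[i], value = v[i]))
  delta <- 0.5 * (v[i - 1] - v[i + 1]) / denom
  dt <- t[i] - t[i - 1]
  list(time = t[i] + delta * dt,
       value = v[i] - 0.25 * (v[i - 1] - v[i + 1]) * delta)
}

#' Detect action potentials in a current-clamp sweep
#'
#' Scans the (smoothed) voltage trace for local maxima exceeding the peak
#' criterion and pairs each with the preceding upward crossing of the
#' rise-speed threshold; peaks without a crossing within the lookback
#' window, or closer than the refractory separation to an accepted peak,
#' are rejected. An empty result is valid (subthreshold sweep).
#'
#' @param sweep Tibble with columns `time` (ms), `command`, `recorded`
#'   (mV), e.g. from [get_sweep()].
#' @param criteria An [ap_criteria()] object.
#' @return Tibble with columns `threshold_time`, `threshold_V`,
#'   `peak_time`, `peak_V`, one row per AP, ordered in time.
#' @export
detect_aps <- function(sweep, criteria = ap_criteria()) {
  dt <- sweep_dt(sweep)
  v <- smooth_voltage(sweep$recorded, dt, criteria)
  tm <- sweep$time
  dvdt <- central_dvdt(v, dt)
  n <- length(v)
  is_peak <- c(FALSE, v[2:(n - 1)] >= v[1:(n - 2)] & v[2:(n - 1)] > v[3:n],
               FALSE) & v > criteria$peak_min
  peak_idx <- which(is_peak)
  look_n <- max(1L, round(criteria$lookback_ms / dt))
  events <- list()
  last_peak_time <- -Inf
  for (p in peak_idx) {
    # find the suprathreshold rise segment leading to this peak
    j <- p
    lo <- max(1L, p - look_n)
    while (j > lo && dvdt[j] < criteria$dvdt_threshold) j <- j - 1L
    if (dvdt[j] < criteria$dvdt_threshold) next # no rise fast enough
    while (j > 1L && dvdt[j - 1L] >= criteria$dvdt_threshold) j <- j - 1L
    pk <- refine_peak(tm, v, p)
    if (pk$time - last_peak_time < criteria$refractory_ms) next
    t_thr <- cross_time_up(tm, dvdt, j, criteria$dvdt_threshold)
    v_thr <- approx(tm, v, xout = t_thr)$y
    last_peak_time <- pk$time
    events[[length(events) + 1L]] <-
      tibble(threshold_time = t_thr, threshold_V = v_thr,
             peak_time = pk$time, peak_V = pk$value)
  }
  if (!length(events)) {
    return(tibble(threshold_time = double(), threshold_V = double(),
                  peak_time = double(), peak_V = double()))
  }
  bind_rows(events)
}

#' Resting membrane potential from a stimulus-free baseline window
#'
#' In-silico surrogate for the RMP read immediately after whole-cell
#' formation: the mean recorded voltage over a pre-stimulus window.
#'
#' @param sweep Sweep tibble (`time`, `command`, `recorded`).
#' @param window Length-2 numeric, window start/end times (ms). The window
#'   must lie within the sweep, cover at least 10 samples and contain no
#'   nonzero command.
#' @return Mean voltage (mV).
#' @export
resting_potential <- function(sweep, window) {
  stopifnot(length(window) == 2L, window[2] > window[1])
  inside <- sweep$time >= window[1] & sweep$time <= window[2]
  if (window[1] < min(sweep$time) || window[2] > max(sweep$time)) {
    abort("window lies outside the sweep")
  }
  if (sum(inside) < 10L) abort("window too short: need >= 10 samples")
  if (any(sweep$command[inside] != 0)) {
    abort("window overlaps nonzero command; RMP needs a stimulus-free baseline")
  }
  mean(sweep$recorded[inside])
}

#' Waveform parameters of one action potential
#'
#' Computes the rise-speed threshold, peak, maximal rise rate, amplitude
#' (peak minus threshold voltage), duration at half height (time between
#' the rising and falling crossings of `threshold_V + amplitude/2`) and the
#' fast afterhyperpolarization (threshold voltage minus the voltage minimum
#' within 5 ms after the peak). Only the requested AP (by default the first
#' in the train, the convention that avoids cumulative channel
#' inactivation) is analysed. Crossing times are linearly interpolated
#' between samples.
#'
#' @inheritParams detect_aps
#' @param event_index Which AP to analyse (1 = first).
#' @param fahp_window_ms Post-peak window for the fAHP minimum (ms).
#' @return One-row tibble: `threshold_time`, `threshold_V`, `peak_time`,
#'   `peak_V`, `max_rise_rate`, `amplitude`, `duration_half`, `fahp`.
#' @export
ap_waveform_params <- function(sweep, event_index = 1L,
                               criteria = ap_criteria(),
                               fahp_window_ms = 5) {
  aps <- detect_aps(sweep, criteria)
  if (nrow(aps) < event_index) {
    abort(paste0("no AP at index ", event_index, " (found ", nrow(aps), ")"))
  }
  ev <- aps[event_index, ]
  dt <- sweep_dt(sweep)
  v <- smooth_voltage(sweep$recorded, dt, criteria)
  tm <- sweep$time
  dvdt <- central_dvdt(v, dt)
  amplitude <- ev$peak_V - ev$threshold_V
  if (amplitude <= 0) abort("non-positive AP amplitude")
  seg <- tm >= ev$threshold_time & tm <= ev$peak_time
  max_rise <- max(dvdt[seg])
  half <- ev$threshold_V + amplitude / 2
  next_limit <- if (nrow(aps) > event_index) {
    aps$threshold_time[event_index + 1L]
  } else max(tm)
  # rising crossing of the half level between threshold and peak
  rise_idx <- which(tm > ev$threshold_time & tm <= ev$peak_time &
                      v >= half & dplyr::lag(v) < half)
  if (!length(rise_idx)) abort("rising half-height crossing not found")
  t_rise <- cross_time_up(tm, v, rise_idx[1], half)
  fall_idx <- which(tm >= ev$peak_time & tm <= next_limit &
                      v <= half & dplyr::lag(v) > half)
  if (!length(fall_idx)) {
    abort("falling half-height crossing not found before the next AP")
  }
  i <- fall_idx[1]
  frac <- (half - v[i - 1]) / (v[i] - v[i - 1])
  t_fall <- tm[i - 1] + frac * (tm[i] - tm[i - 1])
  post <- tm > ev$peak_time & tm <= ev$peak_time + fahp_window_ms
  if (!any(post)) abort("no samples in the fAHP window")
  fahp <- ev$threshold_V - min(v[post])
  tibble(threshold_time = ev$threshold_time, threshold_V = ev$threshold_V,
         peak_time = ev$peak_time, peak_V = ev$peak_V,
         max_rise_rate = max_rise, amplitude = amplitude,
         duration_half = t_fall - t_rise, fahp = fahp)
}

#' Rheobase, normalized rheobase and rheobase charge transfer
#'
#' The rheobase is read from the ramp as the injected-current difference
#' between the first-AP threshold point and the last preceding time at
#' which the membrane voltage crosses the resting potential on the rise;
#' the rheobase charge transfer is the trapezoidal integral of the
#' injected current over that interval, in pC; the normalized rheobase is
#' the rheobase divided by the cell capacitance.
#'
#' @inheritParams detect_aps
#' @param capacitance Cell capacitance (pF).
#' @param rmp Resting membrane potential (mV); if `NULL`, estimated from
#'   the initial zero-command baseline of the sweep.
#' @return One-row tibble: `rheobase` (pA), `rheobase_norm` (pA/pF),
#'   `charge_transfer` (pC), `t_rmp`, `t_thr` (ms).
#' @export
rheobase_measures <- function(sweep, capacitance, rmp = NULL,
                              criteria = ap_criteria()) {
  if (capacitance <= 0) abort("capacitance must be positive")
  aps <- detect_aps(sweep, criteria)
  if (nrow(aps) == 0L) abort("no AP in sweep; rheobase undefined")
  if (is.null(rmp)) rmp <- baseline_rmp(sweep)
  dt <- sweep_dt(sweep)
  v <- smooth_voltage(sweep$recorded, dt, criteria)
  tm <- sweep$time
  t_thr <- aps$threshold_time[1]
  before <- which(tm < t_thr)
  ups <- before[-1][v[before[-1]] >= rmp & v[before[-1] - 1L] < rmp]
  if (!length(ups)) {
    abort("voltage never crosses the resting potential before threshold")
  }
  i <- max(ups)
  t_rmp <- cross_time_up(tm, v, i, rmp)
  i_at <- function(t0) approx(tm, sweep$command, xout = t0)$y
  rheo <- i_at(t_thr) - i_at(t_rmp)
  # trapezoidal integral of command from t_rmp to t_thr; pA*ms -> pC / 1000
  grid <- c(t_rmp, tm[tm > t_rmp & tm < t_thr], t_thr)
  ivals <- approx(tm, sweep$command, xout = grid)$y
  charge <- sum(diff(grid) * (head(ivals, -1) + tail(ivals, -1)) / 2) / 1000
  tibble(rheobase = rheo, rheobase_norm = rheo / capacitance,
         charge_transfer = charge, t_rmp = t_rmp, t_thr = t_thr)
}

# RMP from the initial run of zero command (at least 10 samples)
baseline_rmp <- function(sweep) {
  nz <- which(sweep$command != 0)
  end_idx <- if (length(nz)) nz[1] - 1L else length(sweep$command)
  if (end_idx < 10L) abort("no usable zero-command baseline in sweep")
  mean(sweep$recorded[seq_len(end_idx)])
}

#' State-dependent input resistance from the ramp response
#'
#' Ordinary least-squares slope of recorded voltage against injected
#' current over the samples whose voltage lies 2-12 mV below the resting
#' potential (`state = "hyper"`) or 5-15 mV above it (`state = "depol"`),
#' restricted to the stimulated rising phase before the first AP
#' threshold. Returned in GOhm (mV/pA).
#'
#' @inheritParams rheobase_measures
#' @param state `"hyper"` or `"depol"`.
#' @return Input resistance (GOhm).
#' @export
input_resistance <- function(sweep, state = c("hyper", "depol"), rmp = NULL,
                             criteria = ap_criteria()) {
  state <- match.arg(state)
  if (is.null(rmp)) rmp <- baseline_rmp(sweep)
  dt <- sweep_dt(sweep)
  v <- smooth_voltage(sweep$recorded, dt, criteria)
  tm <- sweep$time
  aps <- detect_aps(sweep, criteria)
  t_lim <- if (nrow(aps)) aps$threshold_time[1] else max(tm)
  bounds <- if (state == "hyper") c(rmp - 12, rmp - 2) else c(rmp + 5, rmp + 15)
  stim_on <- sweep$command != 0
  first_stim <- if (any(stim_on)) tm[which(stim_on)[1]] else Inf
  # rising phase only: from the voltage minimum after stimulus onset (the
  # hyperpolarizing-onset sag) up to the first AP threshold
  pre <- which(tm >= first_stim & tm < t_lim)
  if (!length(pre)) abort("no stimulated samples before the first AP")
  t_min <- tm[pre[which.min(v[pre])]]
  sel <- stim_on & tm >= t_min & tm < t_lim & v >= bounds[1] & v <= bounds[2]
  if (sum(sel) < 10L) {
    abort(paste0("fewer than 10 samples in the ", state, " voltage window"))
  }
  i_sel <- sweep$command[sel]
  if (var(i_sel) == 0) abort("degenerate command (zero variance) in window")
  unname(stats::coef(stats::lm(v[sel] ~ i_sel))[2])
}

#' Full excitability profile of a recorded cell
#'
#' Computes, per trial: AP count, AP1-AP2 peak-to-peak interval, the
#' first-AP waveform parameters, rheobase measures, resting potential and
#' state-dependent input resistances; every scalar is then averaged
#' arithmetically across trials (trials on which a feature is undefined,
#' e.g. no AP, are excluded from that feature's mean), the convention when
#' recordings are repeated over several trials per cell.
#'
#' @param rec A CC-mode [new_recording()], e.g. from
#'   [simulate_current_clamp()].
#' @param criteria An [ap_criteria()] object.
#' @return A one-row tibble of class `excitability_profile` with columns
#'   `ap_count`, `ap1_ap2_interval`, `rheobase`, `rheobase_norm`,
#'   `charge_transfer`, `rmp`, `rin_hyper`, `rin_depol`, `capacitance`,
#'   `threshold_V`, `peak_V`, `max_rise_rate`, `amplitude`,
#'   `duration_half`, `fahp`, `n_trials`.
#' @export
excitability_profile <- function(rec, criteria = ap_criteria()) {
  stopifnot(inherits(rec, "recording"))
  if (rec$mode != "CC") abort("excitability_profile needs a CC recording")
  trials <- sort(unique(rec$data$trial))
  if (!length(trials)) abort("recording has zero trials")
  per_trial <- purrr::map_dfr(trials, function(tr) {
    sw <- get_sweep(rec, trial = tr, sweep = 1L)
    rmp <- tryCatch(baseline_rmp(sw), error = function(e) NA_real_)
    aps <- detect_aps(sw, criteria)
    out <- tibble(ap_count = nrow(aps),
                  ap1_ap2_interval = if (nrow(aps) >= 2L) {
                    aps$peak_time[2] - aps$peak_time[1]
                  } else NA_real_,
                  rmp = rmp)
    wf <- tryCatch(ap_waveform_params(sw, 1L, criteria),
                   error = function(e) NULL)
    if (!is.null(wf)) {
      out <- dplyr::bind_cols(out, wf[, c("threshold_V", "peak_V",
                                          "max_rise_rate", "amplitude",
                                          "duration_half", "fahp")])
    }
    rh <- tryCatch(rheobase_measures(sw, rec$capacitance, rmp, criteria),
                   error = function(e) NULL)
    if (!is.null(rh)) {
      out <- dplyr::bind_cols(out, rh[, c("rheobase", "rheobase_norm",
                                          "charge_transfer")])
    }
    out$rin_hyper <- tryCatch(input_resistance(sw, "hyper", rmp, criteria),
                              error = function(e) NA_real_)
    out$rin_depol <- tryCatch(input_resistance(sw, "depol", rmp, criteria),
                              error = function(e) NA_real_)
    out
  })
  cols <- c("ap_count", "ap1_ap2_interval", "rheobase", "rheobase_norm",
            "charge_transfer", "rmp", "rin_hyper", "rin_depol",
            "threshold_V", "peak_V", "max_rise_rate", "amplitude",
            "duration_half", "fahp")
  prof <- purrr::map_dbl(cols, function(cl) {
    if (!cl %in% names(per_trial)) return(NA_real_)
    x <- per_trial[[cl]]
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  })
  out <- as_tibble(as.list(setNames(prof, cols)))
  out$capacitance <- rec$capacitance
  out$n_trials <- length(trials)
  class(out) <- c("excitability_profile", class(out))
  out
}

#' @export
tidy.excitability_profile <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(unclass(x)), dplyr::everything(),
                      names_to = "feature", values_to = "value")
}

#' @export
glance.excitability_profile <- function(x, ...) {
  as_tibble(unclass(x))[, c("ap_count", "rheobase", "rmp", "n_trials")]
}
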