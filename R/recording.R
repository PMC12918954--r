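#' Recording container
#'
#' A `recording` bundles one or more trials of one or more sweeps in a long
#' tibble (`trial`, `sweep`, `label`, `time`, `command`, `recorded`)
#' together with acquisition metadata. In current clamp (`mode = "CC"`) the
#' command channel is injected current (pA) and the recorded channel is
#' membrane voltage (mV); in voltage clamp (`mode = "VC"`) the command is
#' voltage (mV) and the recorded channel is membrane current (pA).
#'
#' @param data Tibble with columns `trial`, `sweep`, `label`, `time`,
#'   `command`, `recorded`. All sweeps must share the sampling interval.
#' @param dt Sampling interval (ms), > 0.
#' @param mode `"CC"` or `"VC"`.
#' @param capacitance Cell membrane capacitance (pF), > 0.
#' @param rmp_measured Optional resting membrane potential (mV).
#' @param metadata Free-form named list.
#' @return An object of class `recording`.
#' @export
new_recording <- function(data, dt, mode = c("CC", "VC"), capacitance,
                          rmp_measured = NULL, metadata = list()) {
  mode <- match.arg(mode)
  data <- as_tibble(data)
  need <- c("trial", "sweep", "label", "time", "command", "recorded")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(paste("recording data is missing columns:",
                paste(missing_cols, collapse = ", ")))
  }
  if (!is.numeric(dt) || dt <= 0) abort("dt must be positive")
  if (!is.numeric(capacitance) || capacitance <= 0) {
    abort("capacitance must be positive")
  }
  lens <- dplyr::count(data, .data$trial, .data$sweep)
  if (nrow(lens) == 0L) abort("recording must contain at least one sweep")
  if (any(lens$n < 2L)) abort("every sweep must have length >= 2")
  structure(list(data = data[need], dt = dt, mode = mode,
                 capacitance = capacitance, rmp_measured = rmp_measured,
                 metadata = metadata),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  ns <- dplyr::n_distinct(x$data$sweep)
  nt <- dplyr::n_distinct(x$data$trial)
  cat(sprintf("<recording> mode %s, %d trial(s) x %d sweep(s), dt = %g ms, C = %g pF\n",
              x$mode, nt, ns, x$dt, x$capacitance))
  invisible(x)
}

#' Extract one sweep of one trial as a tibble
#'
#' @param rec A [new_recording()] object.
#' @param trial,sweep Trial and sweep indices.
#' @return Tibble with columns `time`, `command`, `recorded`.
#' @export
get_sweep <- function(rec, trial = 1L, sweep = 1L) {
  stopifnot(inherits(rec, "recording"))
  out <- dplyr::filter(rec$data, .data$trial == !!trial,
                       .data$sweep == !!sweep)
  if (nrow(out) == 0L) abort("no such trial/sweep in recording")
  dplyr::select(out, "time", "command", "recorded")
}

#' Average trials pointwise
#'
#' Averages the recorded channel across trials for each sweep, as done when
#' recordings are averaged over repeated trials per cell.
#'
#' @param rec A [new_recording()] object.
#' @return A `recording` with a single (averaged) trial.
#' @export
average_trials <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  dat <- arrange(rec$data, .data$sweep, .data$trial, .data$time)
  trials <- unique(dat$trial)
  nt <- length(trials)
  avg <- dat %>%
    group_by(.data$sweep) %>%
    dplyr::group_modify(function(df, key) {
      ns <- nrow(df) / nt
      if (ns != round(ns)) abort("unequal sweep lengths across trials")
      first <- df[seq_len(ns), ]
      tibble(trial = 1L, label = first$label, time = first$time,
             command = first$command,
             recorded = rowMeans(matrix(df$recorded, nrow = ns)))
    }) %>%
    ungroup() %>%
    select("trial", "sweep", "label", "time", "command", "recorded")
  new_recording(avg, dt = rec$dt, mode = rec$mode,
                capacitance = rec$capacitance,
                rmp_measured = rec$rmp_measured, metadata = rec$metadata)
}
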