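#' von Frey filament set
#'
#' The standard mouse set of logarithmically spaced filaments from 0.02 to
#' 1.4 g. `delta` is the mean log10 spacing used by the up-down estimator.
#'
#' @param forces Strictly increasing filament forces (g), >= 4 of them.
#' @return A `filament_set` list with `forces`, `log10_forces`, `delta`.
#' @export
von_frey_filaments <- function(forces = c(0.02, 0.04, 0.07, 0.16, 0.4,
                                          0.6, 1.0, 1.4)) {
  if (length(forces) < 4L) abort("need at least 4 filaments")
  if (any(forces <= 0) || any(diff(forces) <= 0)) {
    abort("forces must be positive and strictly increasing")
  }
  lf <- log10(forces)
  structure(list(forces = forces, log10_forces = lf,
                 delta = mean(diff(lf))),
            class = "filament_set")
}

#' Simulate an up-down von Frey session
#'
#' Draws withdraw/no-withdraw responses from a logistic psychometric
#' function of log10 force,
#' \eqn{P(withdraw) = logistic(slope \cdot (\log_{10} F - \log_{10} T))},
#' and walks the filament staircase by the up-down rule: step down one
#' filament after a withdrawal, up one after none, clamped at the set
#' bounds. Testing continues for four trials past the first response
#' reversal (the standard stopping rule); a session that pushes against a
#' boundary before any reversal terminates there.
#'
#' @param true_threshold_g True 50 percent threshold (g).
#' @param slope Psychometric slope per log10 unit of force; `Inf` gives a
#'   deterministic step responder.
#' @param filaments A [von_frey_filaments()] set.
#' @param start_index Index of the first filament (default: middle of the
#'   set).
#' @param seed Integer seed; identical seeds give identical sessions.
#' @param max_trials Safety cap on session length.
#' @return An `updown_session` tibble (`trial`, `filament_index`,
#'   `force_g`, `withdraw`).
#' @export
simulate_updown_session <- function(true_threshold_g, slope = 10,
                                    filaments = von_frey_filaments(),
                                    start_index = NULL, seed = 1L,
                                    max_trials = 20L) {
  nf <- length(filaments$forces)
  if (is.null(start_index)) start_index <- ceiling(nf / 2)
  if (start_index < 1L || start_index > nf) abort("invalid start index")
  lt <- log10(true_threshold_g)
  p_withdraw <- function(i) {
    if (is.infinite(slope)) {
      as.numeric(filaments$log10_forces[i] > lt)
    } else {
      stats::plogis(slope * (filaments$log10_forces[i] - lt))
    }
  }
  withr::with_seed(seed, {
    idx <- start_index
    rows <- list()
    reversal_seen <- FALSE
    post_reversal <- 0L
    prev <- NA
    for (tr in seq_len(max_trials)) {
      resp <- runif(1) < p_withdraw(idx)
      rows[[tr]] <- tibble(trial = tr, filament_index = idx,
                           force_g = filaments$forces[idx],
                           withdraw = resp)
      if (!is.na(prev) && resp != prev) reversal_seen <- TRUE
      if (reversal_seen) {
        post_reversal <- post_reversal + 1L
        if (post_reversal > 4L) break
      }
      nxt <- idx + ifelse(resp, -1L, 1L)
      if (!reversal_seen && (nxt < 1L || nxt > nf)) break
      idx <- min(max(nxt, 1L), nf)
      prev <- resp
    }
  })
  out <- bind_rows(rows)
  class(out) <- c("updown_session", class(out))
  out
}

validate_updown <- function(session, filaments) {
  need <- c("trial", "filament_index", "withdraw")
  if (!all(need %in% names(session))) {
    abort("session needs columns trial, filament_index, withdraw")
  }
  nf <- length(filaments$forces)
  idx <- session$filament_index
  if (any(idx < 1L | idx > nf)) abort("filament index out of range")
  if (nrow(session) > 1L) {
    for (i in 2:nrow(session)) {
      expect <- min(max(idx[i - 1] + ifelse(session$withdraw[i - 1],
                                            -1L, 1L), 1L), nf)
      if (idx[i] != expect) {
        abort(paste0("up-down rule violated at trial ", session$trial[i]))
      }
    }
  }
  invisible(TRUE)
}

#' 50 percent paw withdrawal threshold from an up-down session
#'
#' Estimates the 50 percent withdrawal threshold as
#' \eqn{10^{X_f + k\delta}} where \eqn{X_f} is the log10 force of the final
#' filament, \eqn{\delta} the mean log10 filament spacing, and \eqn{k}
#' the Dixon coefficient for the session. The coefficient is obtained by
#' its defining construction — the maximum-likelihood location of a
#' normal psychometric with SD equal to the step size, evaluated on a
#' fine grid over the whole response sequence — rather than from a
#' transcribed lookup table. Sessions with no withdrawal anywhere return
#' the ceiling force; sessions with withdrawals only (driven to the
#' lowest filament) return the floor force.
#'
#' @param session An `updown_session` tibble (`filament_index`,
#'   `withdraw`, ...).
#' @param filaments The [von_frey_filaments()] set used.
#' @return One-row tibble (`pwt_g`, `k`, `final_force_g`, `n_trials`,
#'   `boundary` in `"none"`, `"floor"`, `"ceiling"`).
#' @export
pwt_updown <- function(session, filaments = von_frey_filaments()) {
  validate_updown(session, filaments)
  nf <- length(filaments$forces)
  n <- nrow(session)
  xf <- filaments$log10_forces[session$filament_index[n]]
  delta <- filaments$delta
  base <- tibble(final_force_g = filaments$forces[session$filament_index[n]],
                 n_trials = n)
  if (!any(session$withdraw)) {
    return(dplyr::bind_cols(tibble(pwt_g = filaments$forces[nf],
                                   k = NA_real_),
                            base, tibble(boundary = "ceiling")))
  }
  if (all(session$withdraw)) {
    return(dplyr::bind_cols(tibble(pwt_g = filaments$forces[1],
                                   k = NA_real_),
                            base, tibble(boundary = "floor")))
  }
  x <- filaments$log10_forces[session$filament_index]
  y <- session$withdraw
  lo <- min(filaments$log10_forces) - 2 * delta
  hi <- max(filaments$log10_forces) + 2 * delta
  grid <- seq(lo, hi, by = delta / 200)
  ll <- vapply(grid, function(mu) {
    p <- stats::pnorm((x - mu) / delta)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    sum(ifelse(y, log(p), log(1 - p)))
  }, numeric(1))
  mu_hat <- grid[which.max(ll)]
  dplyr::bind_cols(tibble(pwt_g = 10^mu_hat, k = (mu_hat - xf) / delta),
                   base, tibble(boundary = "none"))
}

#' Clamp response latencies at a cutoff
#'
#' Plate-test latencies are clamped at the protocol cutoff (40 s hot
#' plate, 20 s cold plate) and flagged as censored at or above it.
#'
#' @param latencies Non-negative latencies (s).
#' @param cutoff Cutoff time (s).
#' @return Tibble (`latency_s`, `censored`).
#' @export
latency_with_cutoff <- function(latencies, cutoff) {
  if (any(latencies < 0)) abort("latencies must be non-negative")
  if (cutoff <= 0) abort("cutoff must be positive")
  tibble(latency_s = pmin(latencies, cutoff),
         censored = latencies >= cutoff)
}
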