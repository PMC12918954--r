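# Shared fixtures: parameter variants and cached simulations (several test
# files probe the same seeded recordings; integrate each once).

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) {
    assign(key, force(expr), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

passive_params <- function(g_leak = 2, C_m = 25, E_leak = -55) {
  neuron_params(C_m = C_m, g_Na = 0, g_Kdr = 0, g_A = 0, g_leak = g_leak,
                E_Na = 60, E_K = -90, E_leak = E_leak,
                gates = gliamod:::default_gates())
}

# single-conductance and channel-blocked variants of the control preset
params_variant <- function(g_Na = NULL, g_Kdr = NULL, g_A = NULL,
                           g_leak = NULL) {
  p <- default_neuron_params("control")
  if (!is.null(g_Na)) p$g_Na <- g_Na
  if (!is.null(g_Kdr)) p$g_Kdr <- g_Kdr
  if (!is.null(g_A)) p$g_A <- g_A
  if (!is.null(g_leak)) p$g_leak <- g_leak
  p
}

a_only_params <- function(scale = 1) {
  scale_kv4(params_variant(g_Na = 0, g_Kdr = 0, g_leak = 0), scale)
}

na_blocked_params <- function() params_variant(g_Na = 0)

cc_ramp_recording <- function(factor = 1, dt = 0.005, n_trials = 1,
                              noise = no_noise()) {
  key <- paste("cc", factor, dt, n_trials, noise$seed,
               noise$voltage_noise_sd, sep = "_")
  cached(key, simulate_current_clamp(
    scale_kv4(default_neuron_params("control"), factor),
    ramp_cc_protocol(), dt = dt, noise = noise, n_trials = n_trials))
}

cc_profile <- function(factor = 1, dt = 0.005) {
  key <- paste("prof", factor, dt, sep = "_")
  cached(key, excitability_profile(cc_ramp_recording(factor, dt)))
}

vc_family <- function(params, prepulse = -100, dt = 0.02, key = NULL) {
  if (is.null(key)) {
    key <- paste("fam", substitute(params)[[1]], prepulse, dt, sep = "_")
  }
  cached(key, step_family(simulate_voltage_clamp(
    params, step_vc_protocol(prepulse_mV = prepulse), dt = dt,
    noise = no_noise(), n_trials = 1)))
}

# a flat-topped triangular AP train for constructed-trace tests:
# rise at +10 mV/ms, fall at -10 mV/ms, baseline -60 mV
triangle_train <- function(peak_times_ms, peak_V = 20, dt = 0.1,
                           total_ms = max(peak_times_ms) + 20,
                           baseline = -60) {
  tm <- seq(0, total_ms, by = dt)
  v <- rep(baseline, length(tm))
  for (pt in peak_times_ms) {
    tri <- peak_V - 10 * abs(tm - pt)
    v <- pmax(v, tri)
  }
  tibble::tibble(time = tm, command = 0, recorded = v)
}

no_smooth <- function() ap_criteria(smooth_ms = 0)
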