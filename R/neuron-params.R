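#' Construct a conductance-model parameter set for a DRG neuron
#'
#' Bundles the passive properties, maximal conductances, reversal potentials
#' and gate kinetics of a single-compartment model of a small/medium dorsal
#' root ganglion (DRG) sensory neuron. The model carries a fast sodium
#' current (gates m, h), a delayed-rectifier potassium current (gate n), a
#' Kv4-like transient A-type potassium current (activation a, inactivation
#' b) and an ohmic leak.
#'
#' Each gate is parameterised by a Boltzmann steady state
#' \eqn{x_\infty(V) = 1 / (1 + \exp(-(V - V_h)/k))} (a negative slope `k`
#' makes it an inactivation gate) and a bell-shaped voltage-dependent time
#' constant \eqn{\tau(V) = \tau_b + \tau_a \exp(-((V - V_\tau)/\sigma)^2)}
#' in ms.
#'
#' @param C_m Membrane capacitance (pF).
#' @param g_Na,g_Kdr,g_A,g_leak Maximal conductances (nS).
#' @param E_Na,E_K,E_leak Reversal potentials (mV).
#' @param gates Named list of five gate parameter sets (`m`, `h`, `n`, `a`,
#'   `b`), each a list with elements `vhalf`, `slope`, `tau_base`,
#'   `tau_amp`, `tau_vmax`, `tau_width`.
#' @return An object of class `neuron_params`.
#' @seealso [default_neuron_params()], [scale_kv4()]
#' @export
neuron_params <- function(C_m, g_Na, g_Kdr, g_A, g_leak,
                          E_Na, E_K, E_leak, gates) {
  stopifnot(is.numeric(C_m), length(C_m) == 1L)
  if (C_m <= 0) abort("C_m must be positive")
  for (g in c(g_Na, g_Kdr, g_A, g_leak)) {
    if (!is.numeric(g) || length(g) != 1L || g < 0 || !is.finite(g)) {
      abort("conductances must be finite non-negative scalars")
    }
  }
  if (!(E_Na > 0 && E_K < 0)) abort("require E_Na > 0 > E_K")
  need <- c("m", "h", "n", "a", "b")
  if (!identical(sort(names(gates)), sort(need))) {
    abort("gates must be a named list with elements m, h, n, a, b")
  }
  fields <- c("vhalf", "slope", "tau_base", "tau_amp", "tau_vmax", "tau_width")
  for (nm in need) {
    if (!all(fields %in% names(gates[[nm]]))) {
      abort(paste0("gate '", nm, "' is missing kinetic fields"))
    }
  }
  structure(
    list(C_m = C_m, g_Na = g_Na, g_Kdr = g_Kdr, g_A = g_A, g_leak = g_leak,
         E_Na = E_Na, E_K = E_K, E_leak = E_leak, gates = gates[need]),
    class = "neuron_params"
  )
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("<neuron_params>\n")
  cat(sprintf("  C_m = %.1f pF; g_Na = %.0f, g_Kdr = %.1f, g_A = %.1f, g_leak = %.2f nS\n",
              x$C_m, x$g_Na, x$g_Kdr, x$g_A, x$g_leak))
  cat(sprintf("  E_Na = %.0f, E_K = %.0f, E_leak = %.0f mV\n",
              x$E_Na, x$E_K, x$E_leak))
  invisible(x)
}

# flatten to the 38-element vector the compiled integrator expects
pack_params <- function(params) {
  stopifnot(inherits(params, "neuron_params"))
  gv <- unlist(lapply(params$gates[c("m", "h", "n", "a", "b")], function(g) {
    c(g$vhalf, g$slope, g$tau_base, g$tau_amp, g$tau_vmax, g$tau_width)
  }), use.names = FALSE)
  c(params$C_m, params$g_Na, params$g_Kdr, params$g_A, params$g_leak,
    params$E_Na, params$E_K, params$E_leak, gv)
}

# Default gate kinetics of the DRG neuron model. The A-current inactivation
# gate is nearly fully available at -100 mV and nearly fully inactivated at
# -40 mV, so that the -100/-40 mV prepulse subtraction isolates I_A.
default_gates <- function() {
  list(
    m = list(vhalf = -26, slope = 5.5, tau_base = 0.10, tau_amp = 0.25,
             tau_vmax = -35, tau_width = 30),
    h = list(vhalf = -48, slope = -6.5, tau_base = 0.8, tau_amp = 8,
             tau_vmax = -50, tau_width = 22),
    n = list(vhalf = -15, slope = 7, tau_base = 1.2, tau_amp = 4.5,
             tau_vmax = -40, tau_width = 30),
    a = list(vhalf = -42, slope = 10, tau_base = 0.4, tau_amp = 1.6,
             tau_vmax = -50, tau_width = 25),
    b = list(vhalf = -65, slope = -6, tau_base = 12, tau_amp = 40,
             tau_vmax = -65, tau_width = 25)
  )
}

#' Preset parameter sets for the excitability experiments
#'
#' Returns one of three frozen parameter presets. `"control"` is a
#' small/medium DRG neuron that fires a train of action potentials under the
#' standard 0.15 pA/ms current ramp, with resting potential between -65 and
#' -50 mV and capacitance in the 15-40 pF range typical of these cells.
#' `"high_kv4"` models an enhanced Kv4 conductance (as after treatment with
#' an A-current-potentiating secreted factor): identical to control except
#' the A-current maximal conductance `g_A` is scaled by 1.5. `"no_kv4"` has
#' `g_A = 0`, the limit of a complete Kv4 block.
#'
#' @param condition One of `"control"`, `"high_kv4"`, `"no_kv4"`.
#' @return A [neuron_params()] object.
#' @examples
#' p <- default_neuron_params("control")
#' resting_state(p)$V
#' @export
default_neuron_params <- function(condition = c("control", "high_kv4",
                                                "no_kv4")) {
  condition <- match.arg(condition)
  base <- neuron_params(
    C_m = 25, g_Na = 900, g_Kdr = 90, g_A = 60, g_leak = 2,
    E_Na = 60, E_K = -90, E_leak = -55,
    gates = default_gates()
  )
  switch(condition,
    control  = base,
    high_kv4 = scale_kv4(base, 1.5),
    no_kv4   = scale_kv4(base, 0)
  )
}

#' Scale the Kv4 (A-type) conductance
#'
#' Multiplies `g_A` by `factor`, leaving every other parameter untouched.
#' `factor < 1` models pharmacological Kv4 block (e.g. Phrixotoxin-1, a
#' selective Kv4.2/Kv4.3 blocker; `factor = 0` is a complete block), while
#' `factor > 1` models an enhanced A-type conductance.
#'
#' @param params A [neuron_params()] object.
#' @param factor Non-negative scale factor.
#' @return A modified copy of `params`.
#' @export
scale_kv4 <- function(params, factor) {
  stopifnot(inherits(params, "neuron_params"))
  if (!is.numeric(factor) || length(factor) != 1L || factor < 0) {
    abort("factor must be a non-negative scalar")
  }
  params$g_A <- params$g_A * factor
  params
}

#' Resting state of the model neuron
#'
#' Solves the zero-current balance \eqn{I_{ion}(V, x_\infty(V)) = 0} for the
#' resting membrane potential by root bracketing, and returns the gate
#' steady states there. This is the state the simulator starts from.
#'
#' @param params A [neuron_params()] object.
#' @param interval Search interval in mV.
#' @return A list with elements `V` (mV) and `gates` (named vector).
#' @export
resting_state <- function(params, interval = c(-90, -20)) {
  pv <- pack_params(params)
  f <- function(v) ss_current_cpp(pv, v)
  # bracket the most hyperpolarized zero crossing on a 1-mV scan; the
  # current balance can have several roots once the Na window engages
  grid <- seq(interval[1], interval[2], by = 1)
  vals <- vapply(grid, f, numeric(1))
  flip <- which(vals[-length(vals)] * vals[-1] <= 0)
  if (!length(flip)) abort("no resting potential in the search interval")
  root <- uniroot(f, interval = c(grid[flip[1]], grid[flip[1] + 1]),
                  tol = 1e-10)
  list(V = root$root, gates = gate_inf_cpp(pv, root$root))
}
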