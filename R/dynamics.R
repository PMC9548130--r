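# Network dynamics: single-compartment leaky units coupled by ohmic gap
# junctions and graded chemical synapses with first-order activation
# kinetics and a sigmoidal release function,
#
#   C dV_i/dt = -G_leak (V_i - E_cell)
#               - sum_j g_gap gap_ij (V_i - V_j)
#               - sum_j g_syn chem_ji s_j (V_i - E_rev(j)) + I_ext_i(t)
#   ds_i/dt   = a_r phi(V_i) (1 - s_i) - a_d s_i,
#   phi(V)    = 1 / (1 + exp(-beta (V - V_th,i)))
#
# with E_rev(j) chosen by the presynaptic neuron's inhibitory flag.
# Units: pF, pS, mV, s; injected nA enter as I * 1e6 (pS*mV).

NA_PER_UNIT <- 1e6  # 1 nA expressed in pS*mV

# Precompute the weighted coupling structure for one (possibly ablated)
# connectome under one parameter set.
network_terms <- function(connectome, params) {
  gap_w <- connectome$gap * params$gap_unit_conductance
  chem_w <- connectome$chem * params$syn_unit_conductance
  e_syn <- ifelse(connectome$neurons$inhibitory,
                  params$syn_reversal_inh, params$syn_reversal_exc)
  list(n = nrow(connectome$neurons), names = connectome$neurons$name,
       gap_w = gap_w, gap_row = rowSums(gap_w), chem_w = chem_w,
       e_syn = e_syn)
}

# Equilibrium of the model under a constant injected-current vector
# (internal units, pS*mV). Under the half-activation ansatz every release
# sigmoid sits at phi = 1/2 at the equilibrium, which fixes the activation
# s_eq = a_r / (a_r + 2 a_d) uniformly and reduces the voltage equilibrium
# to a linear system.
equilibrium_state <- function(tm, params, i_ext = 0) {
  s_eq <- params$syn_rise / (params$syn_rise + 2 * params$syn_decay)
  cs <- as.vector(crossprod(tm$chem_w, rep(s_eq, tm$n)))
  cse <- as.vector(crossprod(tm$chem_w, rep(s_eq, tm$n) * tm$e_syn))
  m <- diag(params$leak_conductance + tm$gap_row + cs, tm$n) - tm$gap_w
  b <- params$leak_conductance * params$leak_reversal + cse + i_ext
  v_eq <- tryCatch(solve(m, b), error = function(e)
    stop("equilibrium linear solve failed (", conditionMessage(e),
         "); review conductance parameters", call. = FALSE))
  v_eq <- as.vector(v_eq)
  names(v_eq) <- tm$names
  state <- list(voltages = v_eq,
                activations = stats::setNames(rep(s_eq, tm$n), tm$names),
                thresholds = v_eq)
  class(state) <- "network_state"
  state
}

#' Resting state of a network
#'
#' Solves for the zero-input equilibrium of the model. Under the
#' half-activation convention each release sigmoid sits at phi = 1/2 at
#' rest, which fixes the resting activation s_eq = a_r / (a_r + 2 a_d)
#' uniformly and makes the voltage equilibrium a linear system; its
#' solution defines the initial voltages and, for unstimulated runs, the
#' per-neuron half-activation thresholds V_th. By construction the
#' returned state is an exact fixed point of the zero-input dynamics, so
#' zero-input simulations hold it indefinitely.
#'
#' Stimulated runs anchor their thresholds at the equilibrium computed
#' *with* the injected currents instead (see [simulate_network()]): the
#' sigmoids then operate at full gain around the stimulated state, whose
#' voltages sit far from the synaptic reversal potentials, and strong
#' stimulation can destabilize network loops into oscillation while the
#' zero-input rest remains quiescent.
#'
#' @param connectome a `connectome` (ablated or not).
#' @param params a [model_params()].
#' @return A list (`network_state`) with `voltages`, `activations`,
#'   `thresholds`, each a named vector of length N.
#' @export
resting_state <- function(connectome, params) {
  equilibrium_state(network_terms(connectome, params), params, i_ext = 0)
}

# Right-hand side shared by simulate() and linearized_simulate().
make_rhs <- function(tm, params, thresholds, i_ext, t_on, t_off,
                     frozen_s = NULL) {
  gc <- params$leak_conductance; ec <- params$leak_reversal
  cap <- params$capacitance; beta <- params$sigmoid_gain
  a_r <- params$syn_rise; a_d <- params$syn_decay
  n <- tm$n
  if (!is.null(frozen_s)) {
    cs0 <- as.vector(crossprod(tm$chem_w, frozen_s))
    cse0 <- as.vector(crossprod(tm$chem_w, frozen_s * tm$e_syn))
  }
  function(t, y, parms) {
    v <- y[seq_len(n)]
    stim_on <- t >= t_on && t < t_off
    i_t <- if (stim_on) i_ext else 0
    if (is.null(frozen_s)) {
      s <- y[n + seq_len(n)]
      cs <- as.vector(crossprod(tm$chem_w, s))
      cse <- as.vector(crossprod(tm$chem_w, s * tm$e_syn))
      phi <- 1 / (1 + exp(-beta * (v - thresholds)))
      ds <- a_r * phi * (1 - s) - a_d * s
    } else {
      cs <- cs0; cse <- cse0; ds <- numeric(n)
    }
    dv <- (-gc * (v - ec) - (tm$gap_row * v - as.vector(tm$gap_w %*% v)) -
             (cs * v - cse) + i_t) / cap
    list(c(dv, ds))
  }
}

integrate_network <- function(connectome, params, stimulus, ablations,
                              protocol_id, frozen = FALSE) {
  if (!is.null(ablations)) {
    if (is.list(ablations)) ablations <- ablations$members
    connectome <- ablate(connectome, ablations)
  }
  stim <- stimulus$injections
  dropped <- intersect(names(stim), connectome$ablated)
  if (length(dropped)) {
    warning("stimulated neuron(s) are ablated, dropping their injections: ",
            paste(dropped, collapse = ", "))
    stim <- stim[setdiff(names(stim), dropped)]
  }
  unknown <- setdiff(names(stim), connectome$neurons$name)
  if (length(unknown))
    stop("stimulus names not in connectome: ", paste(unknown, collapse = ", "))

  tm <- network_terms(connectome, params)
  rest <- equilibrium_state(tm, params, i_ext = 0)
  i_ext <- numeric(tm$n)
  i_ext[match(names(stim), tm$names)] <- stim * NA_PER_UNIT
  t_off <- if (is.na(stimulus$t_off)) params$duration else stimulus$t_off
  # a stimulus held to the end of the run stays on through the final
  # integration step (otherwise the last stage evaluations at t = duration
  # would see it switched off mid-step)
  if (t_off >= params$duration) t_off <- Inf
  # thresholds anchor at the equilibrium under the protocol's currents, so
  # the release sigmoids are half-activated around the stimulated state;
  # with zero stimulus this is exactly the resting anchor
  thresholds <- if (any(i_ext != 0))
    equilibrium_state(tm, params, i_ext)$thresholds
  else rest$thresholds

  # stability heuristic for the explicit fixed-step scheme: the fastest
  # membrane time scale at resting synaptic load must resolve within dt
  s_eq <- rest$activations[1]
  g_eff <- params$leak_conductance + tm$gap_row +
    as.vector(crossprod(tm$chem_w, rep(s_eq, tm$n)))
  lambda_max <- max(max(g_eff) / params$capacitance,
                    params$syn_rise + params$syn_decay)
  if (params$dt > 2.5 / lambda_max)
    stop("dt = ", params$dt, " s is too coarse for the fastest time scale ",
         signif(1 / lambda_max, 3), " s; use dt <= ",
         signif(2.5 / lambda_max, 3), " s")

  rhs <- make_rhs(tm, params, thresholds, i_ext, stimulus$t_on, t_off,
                  frozen_s = if (frozen) rest$activations else NULL)
  times <- seq(0, params$duration, by = params$dt)
  y0 <- c(rest$voltages, rest$activations)
  sol <- deSolve::rk4(y = unname(y0), times = times, func = rhs, parms = NULL)
  bad <- which(!is.finite(sol[, -1, drop = FALSE]), arr.ind = TRUE)
  if (nrow(bad)) {
    first <- bad[which.min(bad[, 1]), ]
    stop("non-finite state at t = ", times[first[1]], " s (neuron ",
         tm$names[(first[2] - 1) %% tm$n + 1],
         "); the integration is unstable, reduce dt or conductances")
  }
  volt <- t(sol[, 1 + seq_len(tm$n), drop = FALSE])
  act <- t(sol[, 1 + tm$n + seq_len(tm$n), drop = FALSE])
  if (frozen) act <- matrix(rest$activations, tm$n, length(times))
  rownames(volt) <- rownames(act) <- tm$names
  trace_set(times, volt, act, protocol_id = protocol_id,
            params_fingerprint = params_fingerprint(params),
            ablated = connectome$ablated)
}

#' Simulate network dynamics under a stimulation protocol
#'
#' Integrates the full nonlinear system with a fixed-step classical
#' fourth-order Runge-Kutta scheme on a uniform grid of step `dt`, starting
#' from the resting state of the (ablated) network so that ablation screens
#' carry no transient from a stale equilibrium. Injected currents apply on
#' `[t_on, t_off)`; the half-activation thresholds are anchored at the
#' equilibrium computed under those currents (see [resting_state()]), the
#' convention of this simulator family under which stimulation can ignite
#' network oscillations. The run is fully deterministic: identical inputs
#' give bit-identical trace sets.
#'
#' @param connectome a `connectome`.
#' @param params a [model_params()].
#' @param stimulus a [stimulus_plan()].
#' @param ablations optional neuron names (or [resolve_group()] result) to
#'   ablate structurally before simulating.
#' @param protocol_id label recorded on the output.
#' @return A [trace_set()] with voltages and activations sampled every `dt`.
#' @export
simulate_network <- function(connectome, params,
                             stimulus = stimulus_plan(),
                             ablations = NULL, protocol_id = "adhoc") {
  integrate_network(connectome, params, stimulus, ablations, protocol_id,
                    frozen = FALSE)
}

#' Simulate with synaptic activations frozen at rest
#'
#' Identical to [simulate_network()] except that every graded activation is
#' held at its resting value, which makes the voltage subsystem linear and
#' time-invariant. Small networks in this mode admit an exact
#' matrix-exponential solution, which serves as an independent cross-check
#' of the integrator; with no chemical synapses the two modes coincide.
#'
#' @inheritParams simulate_network
#' @return A [trace_set()].
#' @export
linearized_simulate <- function(connectome, params,
                                stimulus = stimulus_plan(),
                                ablations = NULL,
                                protocol_id = "adhoc-linearized") {
  integrate_network(connectome, params, stimulus, ablations, protocol_id,
                    frozen = TRUE)
}
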