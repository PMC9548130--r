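# Download-free fixtures: four-layer toy connectomes (sensor pair ->
# interneuron pair -> command set -> motor classes with mixed
# excitatory/inhibitory members) and surrogate oscillatory trace sets with
# known period and phase.

#' Generate a four-layer toy connectome
#'
#' Builds the layered sensorimotor topology used throughout the test
#' fixtures: sensors couple to interneurons by gap junctions, interneurons
#' project chemically onto the command set, and commands project chemically
#' onto the motor neurons; `n_motor_inh` of the motors carry the inhibitory
#' (GABAergic) flag, standing in for the VD/DD classes. Consecutive layers
#' are fully connected with the stated weights. With `bilateral = TRUE`
#' every layer is doubled into an L and an R copy with mirror wiring, so
#' the connectome is symmetric under the L/R name swap. An optional
#' bystander pair is gap-coupled to the sensors but has no path to the
#' motors, giving ablation screens a guaranteed negative control. The
#' generator is fully deterministic; `seed` is recorded in the version tag
#' for provenance of derived fixtures.
#'
#' @param n_sensor,n_inter,n_command,n_motor_exc,n_motor_inh layer sizes.
#' @param gap_weight gap-junction contacts per sensor-interneuron (and
#'   sensor-bystander) pair.
#' @param chem_weight chemical contacts per inter-command and command-motor
#'   edge.
#' @param bilateral double each layer into mirror-wired L/R copies.
#' @param bystander add a bystander pair coupled only to the sensors.
#' @param seed integer recorded on the version tag.
#' @return A [connectome()]. Classes are `SN` (sensory), `IN`, `CM`
#'   (inter), `ME`, `MI` (motor) and `BY` (inter, bystanders).
#' @export
make_toy_connectome <- function(n_sensor = 1, n_inter = 1, n_command = 1,
                                n_motor_exc = 1, n_motor_inh = 0,
                                gap_weight = 1, chem_weight = 1,
                                bilateral = FALSE, bystander = FALSE,
                                seed = 1L) {
  stopifnot(n_sensor >= 0, n_inter >= 0, n_command >= 0,
            n_motor_exc >= 0, n_motor_inh >= 0)
  sides <- if (bilateral) c("L", "R") else ""
  layer <- function(class, n, category, inhibitory = FALSE) {
    if (n == 0) return(NULL)
    do.call(rbind, lapply(sides, function(sd)
      data.frame(name = paste0(class, seq_len(n), sd), class = class,
                 category = category, inhibitory = inhibitory, side = sd)))
  }
  neurons <- rbind(layer("SN", n_sensor, "sensory"),
                   layer("IN", n_inter, "inter"),
                   layer("CM", n_command, "inter"),
                   layer("ME", n_motor_exc, "motor"),
                   layer("MI", n_motor_inh, "motor", inhibitory = TRUE),
                   if (bystander) layer("BY", 1, "inter"))
  n <- nrow(neurons)
  gap <- chem <- matrix(0, n, n, dimnames = list(neurons$name, neurons$name))
  connect <- function(mat, from_class, to_class, w) {
    for (sd in sides) {
      from <- neurons$name[neurons$class == from_class & neurons$side == sd]
      to <- neurons$name[neurons$class == to_class & neurons$side == sd]
      mat[from, to] <- w
    }
    mat
  }
  gap <- connect(gap, "SN", "IN", gap_weight)
  gap <- pmax(gap, t(gap))
  chem <- connect(chem, "IN", "CM", chem_weight)
  chem <- connect(chem, "CM", "ME", chem_weight)
  chem <- connect(chem, "CM", "MI", chem_weight)
  if (bystander) {
    bg <- connect(matrix(0, n, n, dimnames = dimnames(gap)),
                  "SN", "BY", gap_weight)
    gap <- pmax(gap, bg, t(bg))
  }
  connectome(neurons[setdiff(names(neurons), "side")], gap, chem,
             version_tag = sprintf("toy4layer-seed%d", as.integer(seed)))
}

#' Generate surrogate oscillatory traces with known ground truth
#'
#' Each neuron's trace is `amplitude * sin(2*pi*t/period + phase) +`
#' seeded Gaussian noise on a uniform grid; phases of 0 and pi give exact
#' in-phase/anti-phase pairs for validating the analytics. Deterministic
#' for a fixed seed (the generator draws through a local RNG state and does
#' not disturb the session RNG).
#'
#' @param phase_map named numeric vector, neuron name -> phase offset in
#'   radians (conventionally 0 or pi).
#' @param period oscillation period, s; must exceed `2 * dt`.
#' @param amplitude sinusoid amplitude, mV.
#' @param noise_sd Gaussian noise standard deviation, mV.
#' @param duration,dt time grid, s.
#' @param seed integer RNG seed.
#' @return A [trace_set()] (no activation matrix).
#' @export
make_surrogate_traces <- function(phase_map, period = 2.5, amplitude = 10,
                                  noise_sd = 0, duration = 12, dt = 0.01,
                                  seed = 1L) {
  if (period <= 2 * dt) stop("period must exceed 2 * dt to be resolvable")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(names(phase_map)) || any(!nzchar(names(phase_map))))
    stop("phase_map must be a named vector (neuron -> phase in radians)")
  time <- seq(0, duration, by = dt)
  volt <- withr_seed(seed, {
    t(vapply(phase_map, function(ph)
      amplitude * sin(2 * pi * time / period + ph) +
        if (noise_sd > 0) stats::rnorm(length(time), 0, noise_sd) else 0,
      numeric(length(time))))
  })
  rownames(volt) <- names(phase_map)
  trace_set(time, volt,
            protocol_id = sprintf("surrogate-p%g-seed%d", period,
                                  as.integer(seed)))
}

# evaluate expr under a local RNG state, restoring the caller's
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' The tuned oscillator toy connectome
#'
#' The shipped reference fixture for protocol and screening tests: a
#' four-layer network whose command layer participates in a three-link
#' feedback loop routed through the interneurons (IN -> CM1 excitatory,
#' CM1 -> CM2 and CM2 -> IN inhibitory). Under co-stimulation of the
#' sensors and the command set the loop crosses a Hopf instability and the
#' motor neurons oscillate, the excitatory MA/MB classes in anti-phase
#' with the inhibitory MD class (MD is driven by CM3, an excitatory twin
#' of CM1 with identical inputs); sensor-only stimulation stays
#' sub-threshold. Ablating the interneuron layer (INL/INR) cuts the loop
#' structurally and abolishes the oscillation, while ablating the
#' bystander pair (BY1/BY2, gap-coupled to the sensors only) does not.
#' The weights were tuned once against these criteria and are frozen; the
#' same wiring ships as CSV under `inst/extdata` and this constructor
#' regenerates it bit-identically.
#'
#' @return A [connectome()] of 14 neurons.
#' @seealso [toy_protocol_currents()] for the matching stimulus currents.
#' @export
make_oscillator_toy <- function() {
  neurons <- rbind(
    data.frame(name = c("SNL", "SNR"), class = "SN", category = "sensory",
               inhibitory = FALSE),
    data.frame(name = c("INL", "INR"), class = "IN", category = "inter",
               inhibitory = FALSE),
    data.frame(name = c("CM1", "CM2"), class = "CM", category = "inter",
               inhibitory = TRUE),
    data.frame(name = "CM3", class = "CM", category = "inter",
               inhibitory = FALSE),
    data.frame(name = c("MA1", "MA2"), class = "MA", category = "motor",
               inhibitory = FALSE),
    data.frame(name = "MB1", class = "MB", category = "motor",
               inhibitory = FALSE),
    data.frame(name = c("MD1", "MD2"), class = "MD", category = "motor",
               inhibitory = TRUE),
    data.frame(name = c("BY1", "BY2"), class = "BY", category = "inter",
               inhibitory = FALSE))
  n <- nrow(neurons)
  gap <- chem <- matrix(0, n, n, dimnames = list(neurons$name, neurons$name))
  gap["SNL", "INL"] <- gap["SNR", "INR"] <- 3
  gap["SNL", "BY1"] <- gap["SNR", "BY2"] <- 3
  gap <- pmax(gap, t(gap))
  chem[c("INL", "INR"), "CM1"] <- 4
  chem[c("INL", "INR"), "CM3"] <- 4
  chem["CM1", "CM2"] <- 8
  chem["CM2", c("INL", "INR")] <- 8
  chem["CM1", c("MA1", "MA2", "MB1")] <- 4
  chem["CM3", c("MD1", "MD2")] <- 4
  connectome(neurons, gap, chem, version_tag = "oscillator-toy-1")
}

#' Stimulus currents of the oscillator-toy protocols
#'
#' The frozen currents matched to [make_oscillator_toy()]: 0.05 nA per
#' sensor and 0.02 nA per command neuron, the analogue of the
#' sensor-plus-command co-stimulation protocol at the toy's synaptic load.
#'
#' @return named list with `sensor_nA` and `command_nA`.
#' @export
toy_protocol_currents <- function() list(sensor_nA = 0.05, command_nA = 0.02)

#' Load the shipped oscillator-toy fixture from its CSV files
#'
#' Reads the frozen copy of [make_oscillator_toy()] distributed under
#' `inst/extdata` through the standard loader, so tests and examples
#' exercise the same file dialect users supply their own wiring in.
#'
#' @return A [connectome()].
#' @export
toy_oscillator <- function() {
  load_connectome(
    system.file("extdata", "toy_oscillator_neurons.csv",
                package = "wormcircuit", mustWork = TRUE),
    system.file("extdata", "toy_oscillator_edges.csv",
                package = "wormcircuit", mustWork = TRUE),
    version_tag = "oscillator-toy-1")
}
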