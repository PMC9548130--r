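#' Biophysical and integration parameters
#'
#' Constants of the single-compartment membrane/synapse model and the
#' fixed-step integrator. Units follow the field's convention for this model
#' family: capacitance in pF, conductances in pS, voltages in mV, rates and
#' times in 1/s and s, injected currents in nA. Internally a current of
#' I nA enters the voltage equation as I * 1e6 pS*mV, the factor that makes
#' pF, pS, mV and s mutually consistent (1 nA = 1e6 pS * mV); the
#' single-neuron closed form V_ss = E_cell + I/G_leak is tested in exactly
#' these units.
#'
#' Defaults are the conventional constants for graded-synapse nematode
#' network models: 10 pS leak, 1 pF capacitance, 100 pS per synaptic
#' contact, sigmoid gain 0.125 / mV, activation rise/decay 1 and 5 per unit
#' time, leak reversal -35 mV, excitatory reversal 0 mV, inhibitory
#' reversal -45 mV. All are plain config values and can be overridden per
#' call or from a YAML/JSON file.
#'
#' @param capacitance membrane capacitance, pF.
#' @param leak_conductance leak conductance, pS.
#' @param leak_reversal leak (cell) reversal potential, mV.
#' @param gap_unit_conductance conductance per gap-junction contact, pS.
#' @param syn_unit_conductance conductance per chemical contact, pS.
#' @param syn_reversal_exc excitatory synaptic reversal, mV.
#' @param syn_reversal_inh inhibitory synaptic reversal, mV.
#' @param sigmoid_gain gain of the presynaptic release sigmoid, 1/mV.
#' @param syn_rise activation rise rate a_r.
#' @param syn_decay activation decay rate a_d.
#' @param dt integration step, s.
#' @param duration simulated time, s (protocols default to at least 12 s).
#' @return An object of class `model_params`.
#' @export
model_params <- function(capacitance = 1, leak_conductance = 10,
                         leak_reversal = -35, gap_unit_conductance = 100,
                         syn_unit_conductance = 100, syn_reversal_exc = 0,
                         syn_reversal_inh = -45, sigmoid_gain = 0.125,
                         syn_rise = 1, syn_decay = 5, dt = 0.001,
                         duration = 12) {
  p <- list(capacitance = capacitance, leak_conductance = leak_conductance,
            leak_reversal = leak_reversal,
            gap_unit_conductance = gap_unit_conductance,
            syn_unit_conductance = syn_unit_conductance,
            syn_reversal_exc = syn_reversal_exc,
            syn_reversal_inh = syn_reversal_inh,
            sigmoid_gain = sigmoid_gain, syn_rise = syn_rise,
            syn_decay = syn_decay, dt = dt, duration = duration)
  if (!all(vapply(p, function(v) is.numeric(v) && length(v) == 1 && is.finite(v),
                  logical(1))))
    stop("every model parameter must be a finite scalar")
  positive <- c("capacitance", "leak_conductance", "gap_unit_conductance",
                "syn_unit_conductance", "sigmoid_gain", "syn_rise",
                "syn_decay", "dt", "duration")
  bad <- positive[vapply(p[positive], function(v) v <= 0, logical(1))]
  if (length(bad))
    stop("parameter(s) must be > 0: ", paste(bad, collapse = ", "))
  if (!(p$syn_reversal_inh < p$leak_reversal &&
        p$leak_reversal < p$syn_reversal_exc))
    warning("expected ordering syn_reversal_inh < leak_reversal < ",
            "syn_reversal_exc is violated; check reversal potentials")
  if (p$dt >= p$duration) stop("dt must be smaller than duration")
  structure(p, class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>", params_fingerprint(x), "\n")
  invisible(x)
}

#' Canonical fingerprint of a parameter set
#'
#' A deterministic `key=value` string over all fields, recorded on every
#' trace set so that runs are attributable to the exact constants used.
#'
#' @param params a `model_params`.
#' @return A single string.
#' @export
params_fingerprint <- function(params) {
  paste(names(params),
        vapply(params, function(v) format(v, digits = 15), character(1)),
        sep = "=", collapse = " ")
}

#' Read model parameters from a YAML or JSON config file
#'
#' The file holds a flat mapping of `model_params` field names to values;
#' unspecified fields keep their defaults. `overrides` (named list or
#' `key=value` strings, as from a CLI `--param` flag) win over the file.
#'
#' @param path config file (`.yaml`/`.yml` or `.json`), or `NULL` for
#'   defaults only.
#' @param overrides named list, or character vector of `key=value` strings.
#' @return A `model_params`.
#' @export
read_params <- function(path = NULL, overrides = NULL) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("no such config file: ", path)
    vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
      yaml::read_yaml(path)
    else jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.character(overrides)) {
    kv <- strsplit(overrides, "=", fixed = TRUE)
    overrides <- stats::setNames(
      lapply(kv, function(x) as.numeric(x[2])),
      vapply(kv, `[`, character(1), 1))
  }
  vals[names(overrides)] <- overrides
  unknown <- setdiff(names(vals), names(formals(model_params)))
  if (length(unknown))
    stop("unknown parameter(s) in config: ", paste(unknown, collapse = ", "))
  do.call(model_params, lapply(vals, as.numeric))
}

#' Write model parameters to a YAML or JSON config file
#'
#' @param params a `model_params`.
#' @param path destination; format chosen by extension.
#' @return Invisibly, `path`.
#' @export
write_params <- function(params, path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(unclass(params), path)
  else jsonlite::write_json(unclass(params), path, auto_unbox = TRUE,
                            digits = NA)
  invisible(path)
}

#' Stimulation plan
#'
#' Per-neuron injected currents with common on/off timing. The default
#' timing holds the current for the whole run (`t_on = 0`,
#' `t_off = duration`), the continuous-stimulation convention of the
#' simulated aversion protocols; currents apply on `[t_on, t_off)`.
#'
#' @param injections named numeric vector, current in nA per neuron name.
#'   Each named neuron receives the stated current individually (a
#'   bilateral class stimulated "at 5 nA" means 5 nA into each member).
#' @param t_on,t_off stimulus window, s; `t_off = NA` means end of run.
#' @return An object of class `stimulus_plan`.
#' @export
stimulus_plan <- function(injections = numeric(), t_on = 0, t_off = NA) {
  injections <- unlist(injections)
  if (length(injections) && (is.null(names(injections)) ||
                             any(!nzchar(names(injections)))))
    stop("injections must be a named vector (neuron name -> nA)")
  if (length(injections) && any(!is.finite(injections)))
    stop("injection currents must be finite")
  if (!is.na(t_off) && t_on >= t_off) stop("t_on must be < t_off")
  structure(list(injections = injections, t_on = t_on, t_off = t_off),
            class = "stimulus_plan")
}
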