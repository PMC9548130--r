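# Named in silico experiments: sensor/command co-stimulation protocols and
# the ablation screen that identifies which interneurons complete the
# sensorimotor circuit.

#' Construct a protocol specification
#'
#' A protocol names the stimulated groups and their per-neuron currents,
#' the structural ablations, the run duration and the motor classes read
#' out. Groups are stored by name and resolved against a concrete
#' connectome at run time, so one protocol applies to any wiring that
#' carries the referenced classes.
#'
#' @param protocol_id identifier recorded on all outputs.
#' @param stimulus named numeric vector: group name (class, alias or
#'   neuron) -> current in nA injected into *each* member.
#' @param ablations character vector of group names to ablate.
#' @param duration simulated time, s; protocols default to 12 s, the
#'   minimum used for the oscillation readouts.
#' @param readout_classes character vector of class names whose members
#'   enter the oscillation report.
#' @param t_on,t_off stimulus window, s (`NA` end = full run).
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(protocol_id, stimulus, ablations = character(),
                          duration = 12, readout_classes, t_on = 0,
                          t_off = NA) {
  stimulus <- unlist(stimulus)
  if (length(stimulus) && is.null(names(stimulus)))
    stop("stimulus must be named (group -> nA)")
  if (duration < 12)
    warning("duration ", duration, " s is below the conventional 12 s ",
            "minimum for oscillation readouts")
  structure(list(protocol_id = as.character(protocol_id),
                 stimulus = stimulus,
                 ablations = as.character(ablations),
                 duration = as.numeric(duration),
                 readout_classes = as.character(readout_classes),
                 t_on = t_on, t_off = t_off),
            class = "protocol_spec")
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat("<protocol_spec> ", x$protocol_id, ": ",
      paste(names(x$stimulus), "@", x$stimulus, "nA", collapse = ", "),
      if (length(x$ablations)) paste0("; ablate ",
                                      paste(x$ablations, collapse = ",")),
      "; ", x$duration, " s; readout ",
      paste(x$readout_classes, collapse = ","), "\n", sep = "")
  invisible(x)
}

#' Path of the shipped protocol registry
#' @return file path of the installed `protocols.yaml`.
#' @export
protocol_registry_path <- function() {
  system.file("extdata", "protocols.yaml", package = "wormcircuit",
              mustWork = TRUE)
}

#' Look up a named protocol in the registry
#'
#' The registry (YAML, shipped as data so users can add protocols without
#' code changes) covers the simulated aversion experiments: `awb_only`
#' (AWB sensory pair at 5.0 nA), `awb_ci` (AWB at 5.0 nA plus each
#' AVA/AVD/AVE command interneuron at 0.9 nA), the sensory controls
#' `awc_ci`, `asi_ci`, `ase_ci`, the `ash_ci` positive control, the
#' `awb_ci_minus_<GROUP>` ablation variants (AUA, RMG, AIB, AVB, SMB), and
#' the oscillator-toy analogues `toy_sensor_only`, `toy_coactivation` and
#' their ablation variants.
#'
#' @param protocol_id registry key.
#' @param registry_path YAML registry to read; defaults to the shipped one.
#' @return A [protocol_spec()].
#' @export
named_protocol <- function(protocol_id, registry_path = protocol_registry_path()) {
  reg <- yaml::read_yaml(registry_path)
  if (!protocol_id %in% names(reg))
    stop("unknown protocol '", protocol_id, "'; registry contains: ",
         paste(sort(names(reg)), collapse = ", "))
  entry <- reg[[protocol_id]]
  stim <- vapply(entry$stimulus, function(s) s$current_nA, numeric(1))
  names(stim) <- vapply(entry$stimulus, function(s) s$group, character(1))
  protocol_spec(protocol_id, stim,
                ablations = unlist(entry$ablations) %||% character(),
                duration = entry$duration %||% 12,
                readout_classes = unlist(entry$readout_classes))
}

# expand a protocol's group-level stimulus into per-neuron injections
resolve_stimulus <- function(connectome, spec) {
  inj <- numeric()
  for (g in names(spec$stimulus)) {
    members <- resolve_group(connectome, g)$members
    add <- stats::setNames(rep(spec$stimulus[[g]], length(members)), members)
    inj <- c(inj, add)
  }
  # a neuron named via several groups receives the summed current
  total <- tapply(inj, names(inj), sum)
  stats::setNames(as.numeric(total), names(total))
}

#' Run a protocol: simulate, then analyze
#'
#' Resolves the protocol's groups against the connectome, simulates the
#' (ablated) network for the protocol's duration, and builds the
#' oscillation report over the readout classes. Pure in its inputs:
#' repeated runs give identical traces and reports. When `out_dir` is
#' given, the trace CSV and report JSON are persisted under the
#' protocol id.
#'
#' @param connectome a `connectome`.
#' @param params a [model_params()]; its `duration` is overridden by the
#'   protocol's.
#' @param spec a [protocol_spec()] or a registry id string.
#' @param out_dir optional output directory.
#' @param ... analysis options passed to [build_report()].
#' @return list with `traces` ([trace_set()]) and `report`
#'   (`oscillation_report`).
#' @export
run_protocol <- function(connectome, params, spec, out_dir = NULL, ...) {
  if (is.character(spec)) spec <- named_protocol(spec)
  params$duration <- spec$duration
  abl <- unique(unlist(lapply(spec$ablations, function(g)
    resolve_group(connectome, g)$members)))
  inj <- resolve_stimulus(connectome, spec)
  stim <- stimulus_plan(inj, t_on = spec$t_on, t_off = spec$t_off)
  traces <- simulate_network(connectome, params, stim, ablations = abl,
                             protocol_id = spec$protocol_id)
  classes <- lapply(spec$readout_classes, function(cl)
    resolve_group(connectome, cl))
  report <- build_report(traces, classes, ...)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_traces(traces, file.path(out_dir,
                                   paste0(spec$protocol_id, "_traces.csv")))
    write_report(report, file.path(out_dir,
                                   paste0(spec$protocol_id, "_report.json")))
  }
  list(traces = traces, report = report)
}

#' Screen candidate neuron groups by in silico ablation
#'
#' Runs the base protocol once, then once per candidate group with that
#' group ablated on top of the base ablations. A candidate is called a
#' circuit member when its ablation flips the verdict away from
#' `oscillatory` — the binary present/lost reading of the motor-neuron
#' heatmaps; amplitude changes are reported alongside for inspection but
#' do not drive the call.
#'
#' @param connectome a `connectome`.
#' @param params a [model_params()].
#' @param base a [protocol_spec()] or registry id; should yield an
#'   oscillatory baseline for membership calls to be meaningful.
#' @param candidates character vector of group names to ablate one at a
#'   time.
#' @param out_dir optional directory; every run's traces and report are
#'   persisted and independently reloadable.
#' @param ... analysis options passed to [build_report()].
#' @return An object of class `screen_result`: `baseline` report,
#'   `per_ablation` (named list of reports), `circuit_members`, and
#'   `summary` (data.frame with verdicts and median amplitudes).
#' @export
ablation_screen <- function(connectome, params, base, candidates,
                            out_dir = NULL, ...) {
  if (is.character(base)) base <- named_protocol(base)
  baseline <- run_protocol(connectome, params, base, out_dir = out_dir, ...)
  per_ablation <- lapply(candidates, function(cand) {
    spec <- base
    spec$ablations <- union(spec$ablations, cand)
    spec$protocol_id <- paste0(base$protocol_id, "_minus_", cand)
    run_protocol(connectome, params, spec, out_dir = out_dir, ...)$report
  })
  names(per_ablation) <- candidates
  verdicts <- vapply(per_ablation, `[[`, character(1), "circuit_verdict")
  med_amp <- function(rep) stats::median(rep$per_neuron$amplitude)
  summary <- data.frame(
    candidate = c("(none)", candidates),
    verdict = c(baseline$report$circuit_verdict, verdicts),
    median_amplitude = c(med_amp(baseline$report),
                         vapply(per_ablation, med_amp, numeric(1))),
    row.names = NULL)
  members <- candidates[verdicts != "oscillatory"]
  if (baseline$report$circuit_verdict != "oscillatory")
    warning("baseline verdict is '", baseline$report$circuit_verdict,
            "', not oscillatory; circuit membership calls are not meaningful")
  res <- structure(list(baseline = baseline$report,
                        per_ablation = per_ablation,
                        circuit_members = members, summary = summary),
                   class = "screen_result")
  if (!is.null(out_dir))
    utils::write.csv(summary,
                     file.path(out_dir, paste0(base$protocol_id,
                                               "_screen_summary.csv")),
                     row.names = FALSE)
  res
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result> baseline:", x$baseline$circuit_verdict,
      "| circuit members:",
      if (length(x$circuit_members)) paste(x$circuit_members, collapse = ", ")
      else "(none)", "\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
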