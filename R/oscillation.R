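# Oscillation analytics over membrane-voltage traces: peak amplitude,
# period, and in-phase/anti-phase classification across motor-neuron
# classes, the readouts used to call backward-locomotion activity.

#' Maximum membrane voltage of a trace
#'
#' Taken over the full simulated interval, transient included: the largest
#' voltage excursions occur at stimulus onset, so the onset peak is part of
#' the readout.
#'
#' @param trace numeric voltage series, mV.
#' @return maximum voltage, mV.
#' @export
max_voltage <- function(trace) {
  if (!length(trace)) stop("empty trace")
  if (any(!is.finite(trace))) stop("non-finite sample(s) in trace")
  max(trace)
}

#' Find local maxima filtered by topographic prominence
#'
#' A sample is a peak when it strictly exceeds its left neighbour and is at
#' least its right neighbour (plateaus resolve to their earliest sample).
#' Prominence is the drop from the peak to the highest of the two lowest
#' points separating it from higher ground on either side (window edges
#' count as higher ground barriers).
#'
#' @param x numeric series.
#' @param min_prominence minimum prominence a peak must reach.
#' @return integer indices of the retained peaks, in time order.
#' @export
find_peaks <- function(x, min_prominence = 0) {
  n <- length(x)
  if (n < 3) return(integer())
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1
  if (!length(cand)) return(integer())
  prom <- vapply(cand, function(i) {
    h <- x[i]
    left <- x[seq_len(i - 1)]
    higher <- which(left > h)
    lmin <- min(left[seq(if (length(higher)) max(higher) else 1, i - 1)])
    right <- x[seq(i + 1, n)]
    higher <- which(right > h)
    rmin <- min(right[seq_len(if (length(higher)) min(higher) else n - i)])
    h - max(lmin, rmin)
  }, numeric(1))
  cand[prom >= min_prominence]
}

# centered moving-average smoothing; width rounded to an odd sample count,
# edge samples (incomplete windows) dropped by the caller via NA
smooth_series <- function(x, k) {
  if (k <= 1) return(x)
  if (k %% 2 == 0) k <- k + 1
  as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
}

window_index <- function(time, window) {
  idx <- which(time >= window[1] & time <= window[2])
  if (!length(idx)) stop("analysis window [", window[1], ", ", window[2],
                         "] contains no samples")
  idx
}

#' Estimate the oscillation period of a voltage trace
#'
#' Restricts to the analysis window, subtracts the windowed mean, lightly
#' smooths (centered moving average of width `smooth_s`) to keep sample
#' noise from spawning spurious peaks, and detects prominence-filtered
#' peaks; the period is the mean inter-peak interval, with each peak
#' location refined by local parabolic interpolation. Returns `NA` when
#' fewer than two peaks survive. The estimate is invariant to constant
#' offsets and positive rescaling of the trace.
#'
#' @param trace numeric voltage series, mV.
#' @param time sample times, s (same length as `trace`).
#' @param window `c(t_start, t_end)`; should span at least two expected
#'   periods.
#' @param min_prominence_frac peak prominence floor, as a fraction of the
#'   window's peak-to-trough range.
#' @param smooth_s smoothing width, s.
#' @return period in s, or `NA_real_`.
#' @export
estimate_period <- function(trace, time, window = range(time),
                            min_prominence_frac = 0.1, smooth_s = 0.15) {
  stopifnot(length(trace) == length(time))
  idx <- window_index(time, window)
  v <- trace[idx]; t <- time[idx]
  if (any(!is.finite(v))) stop("non-finite sample(s) in trace window")
  v <- v - mean(v)
  dt <- if (length(t) > 1) t[2] - t[1] else 0
  k <- if (dt > 0) round(smooth_s / dt) else 1
  vs <- smooth_series(v, k)
  ok <- which(!is.na(vs))
  if (length(ok) < 3) return(NA_real_)
  vs <- vs[ok]; ts <- t[ok]
  rng <- diff(range(vs))
  if (rng == 0) return(NA_real_)
  pk <- find_peaks(vs, min_prominence = min_prominence_frac * rng)
  if (length(pk) < 2) return(NA_real_)
  # sub-sample refinement: least-squares parabola over a neighbourhood of
  # each peak (20% of the raw inter-peak spacing), which localizes crests
  # far below the sample-noise jitter of the raw argmax
  half <- max(1L, round(0.2 * stats::median(diff(pk))))
  loc <- vapply(pk, function(i) {
    lo <- max(1L, i - half); hi <- min(length(vs), i + half)
    x <- ts[lo:hi] - ts[i]
    fit <- stats::lm.fit(cbind(1, x, x^2), vs[lo:hi])
    a <- fit$coefficients[3]; b <- fit$coefficients[2]
    vertex <- if (is.finite(a) && a < 0) -b / (2 * a) else 0
    # keep the refinement local: never move a crest past its neighbourhood
    ts[i] + max(min(vertex, ts[hi] - ts[i]), ts[lo] - ts[i])
  }, numeric(1))
  mean(diff(loc))
}

#' Per-neuron oscillation metrics
#'
#' A neuron counts as oscillating when its windowed peak-to-trough
#' amplitude reaches `amp_threshold` and at least two prominence-filtered
#' peaks survive in the window. The default 0.5 mV separates, with a wide
#' margin, tapering sub-0.1 mV responses from the tens-of-mV oscillatory
#' regime.
#'
#' @param trace numeric voltage series, mV.
#' @param time sample times, s.
#' @param window analysis window, s (post-transient by convention).
#' @param amp_threshold minimum peak-to-trough amplitude, mV.
#' @param min_prominence_frac,smooth_s passed to [estimate_period()].
#' @return list with `max_voltage` (full run), `oscillating`, `amplitude`,
#'   `period`, `n_peaks`.
#' @export
oscillation_metrics <- function(trace, time, window = c(3, max(time)),
                                amp_threshold = 0.5,
                                min_prominence_frac = 0.1, smooth_s = 0.15) {
  idx <- window_index(time, window)
  v <- trace[idx]
  amplitude <- diff(range(v))
  period <- estimate_period(trace, time, window,
                            min_prominence_frac = min_prominence_frac,
                            smooth_s = smooth_s)
  n_peaks <- if (amplitude > 0) {
    vd <- v - mean(v)
    dt <- time[2] - time[1]
    vs <- smooth_series(vd, round(smooth_s / dt))
    ok <- !is.na(vs)
    rng <- diff(range(vs[ok]))
    if (rng > 0)
      length(find_peaks(vs[ok], min_prominence = min_prominence_frac * rng))
    else 0L
  } else 0L
  list(max_voltage = max_voltage(trace),
       oscillating = amplitude >= amp_threshold && n_peaks >= 2 &&
         !is.na(period),
       amplitude = amplitude, period = period, n_peaks = as.integer(n_peaks))
}

#' Classify the phase relation between two traces
#'
#' Zero-lag Pearson correlation of the detrended windowed traces; the
#' relation is `in_phase` when the correlation reaches `+threshold`,
#' `anti_phase` at or below `-threshold`, otherwise `undetermined`
#' (quadrature signals land here by construction). When either trace fails
#' the oscillation criterion in the window — including the zero-variance
#' case — the relation is `undetermined` with correlation 0.
#'
#' @param trace_a,trace_b numeric voltage series, mV.
#' @param time sample times, s.
#' @param window analysis window, s.
#' @param threshold correlation magnitude needed for a sign call.
#' @param amp_threshold oscillation amplitude floor, mV (see
#'   [oscillation_metrics()]).
#' @param min_prominence_frac,smooth_s peak-detection settings, see
#'   [estimate_period()].
#' @return list with `relation` and `correlation`; the classification is
#'   symmetric in its two arguments.
#' @export
classify_phase <- function(trace_a, trace_b, time, window = range(time),
                           threshold = 0.5, amp_threshold = 0.5,
                           min_prominence_frac = 0.1, smooth_s = 0.15) {
  idx <- window_index(time, window)
  a <- trace_a[idx]; b <- trace_b[idx]
  undet <- list(relation = "undetermined", correlation = 0)
  if (stats::var(a) == 0 || stats::var(b) == 0) return(undet)
  ma <- oscillation_metrics(trace_a, time, window, amp_threshold,
                            min_prominence_frac, smooth_s)
  mb <- oscillation_metrics(trace_b, time, window, amp_threshold,
                            min_prominence_frac, smooth_s)
  if (!ma$oscillating || !mb$oscillating) return(undet)
  r <- stats::cor(a - mean(a), b - mean(b))
  relation <- if (r >= threshold) "in_phase"
  else if (r <= -threshold) "anti_phase"
  else "undetermined"
  list(relation = relation, correlation = r)
}

#' Build an oscillation report over motor-neuron classes
#'
#' Computes per-neuron metrics in the post-transient analysis window
#' (maximum voltage uses the full run), per-class oscillating fractions and
#' median periods, all pairwise phase relations among oscillating readout
#' neurons (within and across classes), and a circuit verdict:
#' `oscillatory` when at least `majority` of the readout neurons oscillate,
#' `silent` when no readout neuron reaches the amplitude floor, `weak`
#' otherwise.
#'
#' @param traces a [trace_set()].
#' @param classes list of neuron groups (each `list(group_name, members)`,
#'   as from [resolve_group()]), or a named list of character vectors.
#' @param window analysis window, s; default `[3 s, end]`, past the onset
#'   transient.
#' @param amp_threshold oscillation amplitude floor, mV.
#' @param phase_threshold correlation magnitude for phase calls.
#' @param majority fraction of readout neurons that must oscillate for an
#'   `oscillatory` verdict.
#' @param min_prominence_frac,smooth_s peak-detection settings, see
#'   [estimate_period()].
#' @return An object of class `oscillation_report` with `per_neuron`
#'   (data.frame), `per_class` (data.frame), `phase_pairs` (data.frame) and
#'   `circuit_verdict`.
#' @export
build_report <- function(traces, classes,
                         window = c(3, max(traces$time)),
                         amp_threshold = 0.5, phase_threshold = 0.5,
                         majority = 0.5, min_prominence_frac = 0.1,
                         smooth_s = 0.15) {
  if (is.null(names(classes)) && all(vapply(classes, is.list, logical(1))))
    classes <- stats::setNames(lapply(classes, `[[`, "members"),
                               vapply(classes, `[[`, character(1),
                                      "group_name"))
  missing <- setdiff(unlist(classes), rownames(traces$voltage))
  if (length(missing))
    stop("readout neuron(s) absent from traces: ",
         paste(missing, collapse = ", "))
  per_neuron <- do.call(rbind, lapply(names(classes), function(cl) {
    do.call(rbind, lapply(classes[[cl]], function(nm) {
      m <- oscillation_metrics(traces$voltage[nm, ], traces$time, window,
                               amp_threshold, min_prominence_frac, smooth_s)
      data.frame(neuron = nm, class = cl, max_voltage = m$max_voltage,
                 oscillating = m$oscillating, amplitude = m$amplitude,
                 period = m$period, n_peaks = m$n_peaks)
    }))
  }))
  per_class <- do.call(rbind, lapply(names(classes), function(cl) {
    rows <- per_neuron[per_neuron$class == cl, ]
    data.frame(class = cl,
               oscillating_fraction = mean(rows$oscillating),
               median_period = stats::median(rows$period[rows$oscillating]))
  }))
  osc <- per_neuron$neuron[per_neuron$oscillating]
  phase_pairs <- if (length(osc) >= 2) {
    pairs <- utils::combn(osc, 2)
    do.call(rbind, apply(pairs, 2, function(pr) {
      ph <- classify_phase(traces$voltage[pr[1], ], traces$voltage[pr[2], ],
                           traces$time, window, phase_threshold,
                           amp_threshold, min_prominence_frac, smooth_s)
      data.frame(neuron_a = pr[1], neuron_b = pr[2],
                 relation = ph$relation, correlation = ph$correlation)
    }, simplify = FALSE))
  } else data.frame(neuron_a = character(), neuron_b = character(),
                    relation = character(), correlation = numeric())
  verdict <- if (mean(per_neuron$oscillating) >= majority) "oscillatory"
  else if (all(per_neuron$amplitude < amp_threshold)) "silent"
  else "weak"
  structure(list(per_neuron = per_neuron, per_class = per_class,
                 phase_pairs = phase_pairs, circuit_verdict = verdict,
                 window = window, protocol_id = traces$protocol_id),
            class = "oscillation_report")
}

#' @export
print.oscillation_report <- function(x, ...) {
  cat("<oscillation_report> protocol '", x$protocol_id, "': verdict ",
      x$circuit_verdict, " (", sum(x$per_neuron$oscillating), "/",
      nrow(x$per_neuron), " readout neurons oscillating)\n", sep = "")
  invisible(x)
}

#' Write an oscillation report
#'
#' JSON carries the full report (per-neuron metrics, per-class summaries,
#' phase pairs, verdict); the optional CSV is the flat per-neuron table.
#'
#' @param report an `oscillation_report`.
#' @param json_path destination JSON file.
#' @param csv_path optional destination for the per-neuron CSV.
#' @return Invisibly, `json_path`.
#' @export
write_report <- function(report, json_path, csv_path = NULL) {
  jsonlite::write_json(
    list(protocol_id = report$protocol_id,
         circuit_verdict = report$circuit_verdict,
         window = report$window, per_neuron = report$per_neuron,
         per_class = report$per_class, phase_pairs = report$phase_pairs),
    json_path, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(csv_path))
    utils::write.csv(report$per_neuron, csv_path, row.names = FALSE)
  invisible(json_path)
}
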