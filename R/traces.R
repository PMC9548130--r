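#' Trace set: per-neuron state trajectories with protocol metadata
#'
#' Container for simulator output (or surrogate signals): a uniform time
#' grid plus neuron-by-time matrices of membrane voltage (mV) and, when
#' persisted, graded synaptic activation. Rows are neurons in matrix order;
#' columns are samples.
#'
#' @param time numeric vector of sample times, s; strictly increasing with
#'   uniform step.
#' @param voltage N x T matrix of membrane voltages, mV, with rownames.
#' @param activation optional N x T matrix of activations in `[0, 1]`.
#' @param protocol_id free-text identifier of the run.
#' @param params_fingerprint string from [params_fingerprint()].
#' @param ablated character vector of structurally ablated neuron names.
#' @return An object of class `trace_set`.
#' @export
trace_set <- function(time, voltage, activation = NULL,
                      protocol_id = "adhoc", params_fingerprint = "",
                      ablated = character()) {
  voltage <- as.matrix(voltage)
  if (length(time) != ncol(voltage))
    stop("time length must equal the number of voltage columns")
  if (length(time) > 1) {
    steps <- diff(time)
    if (any(steps <= 0) ||
        max(steps) - min(steps) > 1e-9 * max(steps))
      stop("time must be strictly increasing with uniform step")
  }
  if (is.null(rownames(voltage)))
    stop("voltage matrix must carry neuron names as rownames")
  if (!is.null(activation)) {
    activation <- as.matrix(activation)
    if (!identical(dim(activation), dim(voltage)))
      stop("activation matrix shape must match voltage matrix")
    rownames(activation) <- rownames(voltage)
  }
  structure(list(time = as.numeric(time), voltage = voltage,
                 activation = activation,
                 protocol_id = as.character(protocol_id),
                 params_fingerprint = as.character(params_fingerprint),
                 ablated = as.character(ablated)),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat("<trace_set> ", nrow(x$voltage), " neurons x ", length(x$time),
      " samples (", signif(utils::tail(x$time, 1), 4), " s), protocol '",
      x$protocol_id, "'\n", sep = "")
  if (length(x$ablated))
    cat("  ablated:", paste(x$ablated, collapse = ", "), "\n")
  invisible(x)
}

#' Extract one neuron's voltage trace
#' @param traces a `trace_set`.
#' @param neuron neuron name.
#' @return numeric vector of voltages, mV.
#' @export
get_trace <- function(traces, neuron) {
  if (!neuron %in% rownames(traces$voltage))
    stop("no trace for neuron '", neuron, "'")
  traces$voltage[neuron, ]
}

#' Write a trace set as wide CSV
#'
#' First column `time_s`, one column per neuron (header = neuron names).
#' Protocol metadata (`protocol_id`, `ablated`, `params_fingerprint`) is
#' carried in `#`-prefixed comment lines above the header so a read
#' round-trip restores the full object. Activations, when present, go to a
#' sibling `<path>.activation.csv` in the same layout.
#'
#' @param traces a `trace_set`.
#' @param path output CSV path.
#' @return Invisibly, `path`.
#' @export
write_traces <- function(traces, path) {
  meta <- c(paste0("# protocol_id: ", traces$protocol_id),
            paste0("# ablated: ", paste(traces$ablated, collapse = ",")),
            paste0("# params_fingerprint: ", traces$params_fingerprint))
  write_one <- function(mat, p) {
    con <- file(p, "w")
    on.exit(close(con))
    writeLines(meta, con)
    df <- data.frame(time_s = traces$time, t(mat), check.names = FALSE)
    utils::write.csv(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     con, row.names = FALSE, quote = FALSE)
  }
  write_one(traces$voltage, path)
  if (!is.null(traces$activation))
    write_one(traces$activation, paste0(path, ".activation.csv"))
  invisible(path)
}

#' Read a trace set written by [write_traces()]
#' @param path CSV path.
#' @return A `trace_set`.
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) stop("no such trace file: ", path)
  header <- readLines(path, n = 10)
  meta_lines <- grep("^#", header, value = TRUE)
  get_meta <- function(key) {
    line <- grep(paste0("^# ", key, ":"), meta_lines, value = TRUE)
    if (!length(line)) return("")
    trimws(sub(paste0("^# ", key, ":"), "", line[1]))
  }
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  volt <- t(as.matrix(df[-1]))
  ablated <- get_meta("ablated")
  ablated <- if (nzchar(ablated)) strsplit(ablated, ",")[[1]] else character()
  act_path <- paste0(path, ".activation.csv")
  activation <- NULL
  if (file.exists(act_path)) {
    adf <- utils::read.csv(act_path, comment.char = "#", check.names = FALSE)
    activation <- t(as.matrix(adf[-1]))
  }
  trace_set(df$time_s, volt, activation,
            protocol_id = get_meta("protocol_id"),
            params_fingerprint = get_meta("params_fingerprint"),
            ablated = ablated)
}
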