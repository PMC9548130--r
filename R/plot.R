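#' Heatmap of neuron-by-time membrane voltage
#'
#' Renders a trace set in the conventional readout style: one row per
#' neuron, time on the horizontal axis, color mapping membrane voltage in
#' mV. Useful for eyeballing which motor classes oscillate and their
#' phase structure.
#'
#' @param traces a [trace_set()].
#' @param neurons neuron names to show (rows, top to bottom); defaults to
#'   all, in matrix order.
#' @param downsample keep every k-th sample for drawing; the default
#'   thins to roughly 2000 columns.
#' @return A ggplot object.
#' @export
plot_trace_heatmap <- function(traces, neurons = rownames(traces$voltage),
                               downsample = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_trace_heatmap needs the ggplot2 package")
  if (is.null(downsample))
    downsample <- max(1L, floor(length(traces$time) / 2000))
  keep <- seq(1, length(traces$time), by = downsample)
  df <- do.call(rbind, lapply(neurons, function(nm)
    data.frame(neuron = nm, time_s = traces$time[keep],
               voltage_mV = traces$voltage[nm, keep])))
  df$neuron <- factor(df$neuron, levels = rev(neurons))
  ggplot2::ggplot(df, ggplot2::aes(x = time_s, y = neuron,
                                   fill = voltage_mV)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "mV") +
    ggplot2::labs(x = "time (s)", y = NULL, title = traces$protocol_id) +
    ggplot2::theme_minimal()
}

#' Waveform plot of selected voltage traces
#'
#' @param traces a [trace_set()].
#' @param neurons neuron names to draw.
#' @return A ggplot object with one panel per neuron.
#' @export
plot_waveforms <- function(traces, neurons) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_waveforms needs the ggplot2 package")
  df <- do.call(rbind, lapply(neurons, function(nm)
    data.frame(neuron = nm, time_s = traces$time,
               voltage_mV = traces$voltage[nm, ])))
  df$neuron <- factor(df$neuron, levels = neurons)
  ggplot2::ggplot(df, ggplot2::aes(x = time_s, y = voltage_mV)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(neuron), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "membrane voltage (mV)",
                  title = traces$protocol_id) +
    ggplot2::theme_minimal()
}
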