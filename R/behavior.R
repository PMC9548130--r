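# Behavioral indices of the aversion assays, kept in the package so
# simulation predictions and behavioral observations share one reporting
# layer.

#' Response index of a dry-drop aversion assay
#'
#' Fraction of stimulus presentations that elicited backward movement,
#' N_responses / N_drops (conventionally ten drops per animal). Computed
#' as the exact ratio; scale-invariant in its two counts.
#'
#' @param n_responses number of drops answered with backward movement.
#' @param n_drops number of drops presented; must be > 0.
#' @return fraction in `[0, 1]`.
#' @export
response_index <- function(n_responses, n_drops) {
  check_counts(n_responses, n_drops, "n_responses", "n_drops")
  n_responses / n_drops
}

#' Occupancy index of a lawn-avoidance assay
#'
#' Fraction of animals on the bacterial lawn, N_on_lawn / N_total.
#'
#' @param n_on_lawn animals on the lawn.
#' @param n_total animals scored; must be > 0.
#' @return fraction in `[0, 1]`.
#' @export
occupancy_index <- function(n_on_lawn, n_total) {
  check_counts(n_on_lawn, n_total, "n_on_lawn", "n_total")
  n_on_lawn / n_total
}

check_counts <- function(num, den, num_name, den_name) {
  if (any(den <= 0)) stop(den_name, " must be > 0")
  if (any(num < 0) || any(num > den))
    stop("need 0 <= ", num_name, " <= ", den_name)
  if (any(num != round(num)) || any(den != round(den)))
    stop(num_name, " and ", den_name, " must be whole counts")
  invisible(NULL)
}

#' Summarize per-animal behavioral counts by group
#'
#' Reads a CSV with one row per animal (or plate) and columns `group` plus
#' either `n_responses,n_drops` or `n_on_lawn,n_total`, computes the
#' matching index per row, and writes (optionally) per-group means and
#' standard deviations.
#'
#' @param path input CSV.
#' @param out_path optional output CSV of the per-group summary.
#' @return data.frame with `group`, `n`, `mean_index`, `sd_index`.
#' @export
summarize_behavior <- function(path, out_path = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"group" %in% names(df)) stop("input needs a 'group' column")
  idx <- if (all(c("n_responses", "n_drops") %in% names(df)))
    mapply(response_index, df$n_responses, df$n_drops)
  else if (all(c("n_on_lawn", "n_total") %in% names(df)))
    mapply(occupancy_index, df$n_on_lawn, df$n_total)
  else stop("input needs n_responses,n_drops or n_on_lawn,n_total columns")
  agg <- do.call(rbind, lapply(split(idx, df$group), function(v)
    data.frame(n = length(v), mean_index = mean(v),
               sd_index = stats::sd(v))))
  agg <- cbind(group = rownames(agg), agg)
  rownames(agg) <- NULL
  if (!is.null(out_path))
    utils::write.csv(agg, out_path, row.names = FALSE)
  agg
}
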