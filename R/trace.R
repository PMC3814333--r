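#' Uniformly sampled time series
#'
#' Lightweight container pairing a numeric vector with its sampling rate.
#'
#' @param values Numeric samples.
#' @param fs Sampling rate (Hz).
#' @return An object of class `signal_trace` with `values`, `fs` and
#'   `times` (s).
#' @export
signal_trace <- function(values, fs) {
  stopifnot(is.numeric(values), fs > 0)
  structure(list(values = as.numeric(values), fs = fs,
                 times = (seq_along(values) - 1) / fs),
            class = "signal_trace")
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace> %d samples at %g Hz (%.3f s)\n",
              length(x$values), x$fs, length(x$values) / x$fs))
  invisible(x)
}

#' Ordered spike event times
#'
#' @param times Event times (s), strictly increasing.
#' @param unit Optional unit identifier.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(times, unit = NA) {
  times <- as.numeric(times)
  if (is.unsorted(times, strictly = TRUE)) stop("spike times must be strictly increasing")
  structure(list(times = times, unit = unit), class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes", length(x$times)))
  if (length(x$times) > 1) {
    cat(sprintf(" over %.2f s (%.1f Hz)", diff(range(x$times)),
                (length(x$times) - 1) / diff(range(x$times))))
  }
  cat("\n")
  invisible(x)
}

#' Write a signal trace as two-column text
#'
#' @param trace A [signal_trace()].
#' @param path Output file.
#' @export
write_trace <- function(trace, path) {
  utils::write.table(data.frame(time_s = trace$times, value = trace$values),
                     path, row.names = FALSE, quote = FALSE, sep = "\t")
}

#' Write spike trains as two-column event text (unit id, time)
#'
#' @param trains A list of [spike_train()]s (or numeric time vectors).
#' @param path Output file.
#' @export
write_spikes <- function(trains, path) {
  df <- do.call(rbind, lapply(seq_along(trains), function(i) {
    tt <- if (inherits(trains[[i]], "spike_train")) trains[[i]]$times else trains[[i]]
    if (length(tt) == 0) return(NULL)
    data.frame(unit_id = i, time_s = tt)
  }))
  utils::write.table(df, path, row.names = FALSE, quote = FALSE, sep = "\t")
}
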