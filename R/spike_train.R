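#' Spike train
#'
#' An ordered set of spike times over a recording of known duration. Spike
#' trains are the currency between simulation, pattern statistics and the
#' secretion model.
#'
#' @param times strictly increasing spike times (s) in `[0, duration]`.
#' @param duration record length (s).
#' @param label free-text provenance label.
#' @return A `spike_train` object.
#' @export
spike_train <- function(times, duration, label = "") {
  times <- as.numeric(times)
  if (length(times) > 0) {
    if (any(!is.finite(times))) stop("spike times must be finite")
    if (any(diff(times) <= 0)) stop("spike times must be strictly increasing")
    if (times[1] < 0 || times[length(times)] > duration) {
      stop("spike times must lie within [0, duration]")
    }
  }
  if (!is.numeric(duration) || length(duration) != 1 || duration <= 0) {
    stop("duration must be a positive number")
  }
  structure(list(times = times, duration = duration, label = as.character(label)),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %d spikes over %g s (%.3f spikes/s)%s\n",
              length(x$times), x$duration, mean_rate(x),
              if (nzchar(x$label)) paste0(" [", x$label, "]") else ""))
  invisible(x)
}

#' Mean firing rate of a spike train
#' @param train a `spike_train`.
#' @return Spikes per second over the full record.
#' @export
mean_rate <- function(train) length(train$times) / train$duration

#' Restrict a spike train to a time window
#'
#' Keeps the spikes in `[from, to)` and re-references them to a record
#' starting at `from`.
#'
#' @param train a `spike_train`.
#' @param from,to window bounds (s).
#' @return A `spike_train` of duration `to - from`.
#' @export
window_train <- function(train, from, to) {
  if (from < 0 || to > train$duration || to <= from) {
    stop("window must lie within the record")
  }
  keep <- train$times >= from & train$times < to
  spike_train(train$times[keep] - from, to - from, label = train$label)
}

#' Read and write spike-train text files
#'
#' Plain-text format: one spike time in seconds per line, with `#`-prefixed
#' header lines carrying `duration` and `label`.
#'
#' @param path file path.
#' @return `read_spike_train()` returns a `spike_train`.
#' @export
read_spike_train <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  duration <- NA_real_
  label <- ""
  for (h in hdr) {
    if (grepl("^#\\s*duration\\s*=", h)) {
      duration <- as.numeric(sub("^#\\s*duration\\s*=\\s*", "", h))
    } else if (grepl("^#\\s*label\\s*=", h)) {
      label <- trimws(sub("^#\\s*label\\s*=\\s*", "", h))
    }
  }
  body <- trimws(lines[!grepl("^#", lines)])
  times <- as.numeric(body[nzchar(body)])
  if (is.na(duration)) {
    stop("spike-train file has no '# duration = <s>' header")
  }
  spike_train(times, duration, label)
}

#' @param train a `spike_train`.
#' @rdname read_spike_train
#' @export
write_spike_train <- function(train, path) {
  lines <- c(sprintf("# duration = %.15g", train$duration),
             sprintf("# label = %s", train$label),
             sprintf("%.15g", train$times))
  writeLines(lines, path)
  invisible(path)
}
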