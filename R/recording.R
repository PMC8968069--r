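#' Construct an SEEG recording object
#'
#' A recording holds a channels-by-samples signal matrix (microvolts), the
#' sampling rate, and per-channel depth-electrode metadata (shaft label and
#' contact index within the shaft).  Sample indices are 0-based throughout the
#' package and all time intervals are half-open \code{[start, end)}.
#'
#' @param data numeric matrix, channels x samples (microvolts).
#' @param fs sampling rate in Hz.
#' @param channels data.frame with columns \code{id}, \code{shaft},
#'   \code{contact}; one row per row of \code{data}.  Contact indices must be
#'   consecutive within each shaft.
#' @return an object of class \code{seeg_recording}.
#' @export
seeg_recording <- function(data, fs, channels) {
  stopifnot(is.matrix(data), is.numeric(data))
  if (is.null(fs) || !is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a positive sampling rate in Hz", call. = FALSE)
  stopifnot(is.data.frame(channels),
            all(c("id", "shaft", "contact") %in% names(channels)),
            nrow(channels) == nrow(data))
  if (anyNA(data)) stop("recording contains missing samples", call. = FALSE)
  for (sh in unique(channels$shaft)) {
    ct <- sort(channels$contact[channels$shaft == sh])
    if (length(ct) > 1L && any(diff(ct) != 1L))
      stop("contact indices must be consecutive within shaft '", sh, "'",
           call. = FALSE)
  }
  rownames(data) <- channels$id
  structure(list(data = data, fs = fs, channels = channels),
            class = "seeg_recording")
}

#' @export
print.seeg_recording <- function(x, ...) {
  cat(sprintf("<seeg_recording> %d channels x %d samples @ %g Hz (%.1f s), %d shafts\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              length(unique(x$channels$shaft))))
  invisible(x)
}

#' @export
dim.seeg_recording <- function(x) dim(x$data)

#' Construct an event table
#'
#' @param onset_sample 0-based sample index of each stimulus onset.
#' @param type stimulus type label per event.
#' @param duration_ms stimulus duration in ms per event.
#' @param fs sampling rate the onsets refer to (Hz).
#' @return data.frame of class \code{event_table} with columns
#'   \code{onset_sample}, \code{type}, \code{duration_ms}, \code{onset_s}.
#' @export
event_table <- function(onset_sample, type, duration_ms, fs) {
  stopifnot(length(onset_sample) == length(type),
            length(duration_ms) %in% c(1L, length(type)))
  ev <- data.frame(onset_sample = as.integer(onset_sample),
                   type = as.character(type),
                   duration_ms = rep_len(as.numeric(duration_ms), length(type)),
                   onset_s = onset_sample / fs)
  attr(ev, "fs") <- fs
  class(ev) <- c("event_table", "data.frame")
  ev
}

#' Build a continuous trace set
#'
#' @param data channels x samples matrix.
#' @param fs sampling rate (Hz).
#' @param channels channel metadata data.frame (id, shaft, contact).
#' @param kind one of \code{"high_gamma"}, \code{"beta"}, \code{"alpha"}
#'   (band-power traces, units uV^2) or \code{"erp"} (voltage trace, uV).
#' @return object of class \code{trace_set}.
#' @export
trace_set <- function(data, fs, channels, kind) {
  kind <- match.arg(kind, c("high_gamma", "beta", "alpha", "erp"))
  if (kind != "erp" && any(data < 0))
    stop("power traces must be nonnegative", call. = FALSE)
  rownames(data) <- channels$id
  structure(list(data = data, fs = fs, channels = channels, kind = kind),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("<trace_set:%s> %d channels x %d samples @ %g Hz%s\n", x$kind,
              nrow(x$data), ncol(x$data), x$fs,
              if (isTRUE(attr(x, "normalized"))) " (z-scored)" else ""))
  invisible(x)
}

#' Write a simulated session to disk
#'
#' The signal array goes into a compressed container (\code{signal.rds});
#' events and channel metadata are written as tab-separated sidecars
#' (\code{events.tsv}: onset_sample, type, duration_ms;
#' \code{channels.tsv}: id, shaft, contact).
#'
#' @param session list with elements \code{recording}, \code{events}, and
#'   optionally \code{truth} (as returned by [simulate_session()]).
#' @param dir output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rec <- session$recording
  saveRDS(list(data = rec$data, fs = rec$fs), file.path(dir, "signal.rds"))
  ev <- session$events
  utils::write.table(ev[, c("onset_sample", "type", "duration_ms")],
                     file.path(dir, "events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(rec$channels, file.path(dir, "channels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(session$truth))
    saveRDS(session$truth, file.path(dir, "truth.rds"))
  invisible(dir)
}

#' Read a session written by [write_session()]
#'
#' @param dir directory containing \code{signal.rds}, \code{events.tsv} and
#'   \code{channels.tsv}.
#' @return list with \code{recording}, \code{events} and, if present,
#'   \code{truth}.
#' @export
read_session <- function(dir) {
  sig <- readRDS(file.path(dir, "signal.rds"))
  channels <- utils::read.delim(file.path(dir, "channels.tsv"),
                                stringsAsFactors = FALSE)
  rec <- seeg_recording(sig$data, sig$fs, channels)
  ev <- utils::read.delim(file.path(dir, "events.tsv"),
                          stringsAsFactors = FALSE)
  events <- event_table(ev$onset_sample, ev$type, ev$duration_ms, sig$fs)
  truth_path <- file.path(dir, "truth.rds")
  out <- list(recording = rec, events = events)
  if (file.exists(truth_path)) out$truth <- readRDS(truth_path)
  out
}
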