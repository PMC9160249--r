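#' Epoched multi-channel data
#'
#' An `eeg_epochs` object wraps a trials x channels x samples array with its
#' sampling rate, lock event ("stimulus" or "movement"), the time of the
#' first sample relative to the lock (`t0`, seconds), channel names and a
#' `trial_meta` table joining back into the behavioral table. The sample
#' convention is half-open `[t0, t1)` with 1-based indices: the sample at
#' the lock time is index `round(-t0 * sfreq) + 1`.
#'
#' @param data numeric array, trials x channels x samples.
#' @param sfreq sampling rate, Hz.
#' @param lock "stimulus" or "movement".
#' @param t0 time of the first sample relative to the lock, s.
#' @param channel_names character vector, one per channel.
#' @param trial_meta data.frame with one row per trial (may be NULL).
#' @export
new_epochs <- function(data, sfreq, lock = c("stimulus", "movement"),
                       t0, channel_names, trial_meta = NULL) {
  lock <- match.arg(lock)
  stopifnot(length(dim(data)) == 3, dim(data)[2] == length(channel_names))
  if (!is.null(trial_meta)) stopifnot(nrow(trial_meta) == dim(data)[1])
  dimnames(data)[[2]] <- channel_names
  structure(list(data = data, sfreq = sfreq, lock = lock, t0 = t0,
                 channel_names = channel_names, trial_meta = trial_meta),
            class = "eeg_epochs")
}

#' Time axis of an epochs object (seconds, relative to the lock)
#' @param x an `eeg_epochs`.
#' @export
epoch_times <- function(x) {
  stopifnot(inherits(x, "eeg_epochs"))
  x$t0 + (seq_len(dim(x$data)[3]) - 1) / x$sfreq
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %d trials x %d channels x %d samples, %g Hz, %s-locked [%.3g, %.3g) s\n",
              d[1], d[2], d[3], x$sfreq, x$lock, x$t0, x$t0 + d[3] / x$sfreq))
  invisible(x)
}

#' Standard epoch windows per lock event
#'
#' Stimulus-locked epochs span [-1.2, 1.6) s around target onset and
#' movement-locked epochs [-2.0, 0.8) s around movement onset (2.8 s each).
#' @param lock "stimulus" or "movement".
#' @return numeric c(t0, t1).
#' @export
epoch_window <- function(lock = c("stimulus", "movement")) {
  lock <- match.arg(lock)
  if (lock == "stimulus") c(-1.2, 1.6) else c(-2.0, 0.8)
}

#' Crop epochs to a time range
#'
#' Keeps samples with `tlim[1] <= t < tlim[2]`. Useful to trim epochs to
#' the union of baseline, period of interest and wavelet edge zone before a
#' decomposition.
#' @param x an `eeg_epochs`.
#' @param tlim c(from, to) seconds relative to the lock.
#' @export
crop_epochs <- function(x, tlim) {
  stopifnot(inherits(x, "eeg_epochs"))
  tax <- epoch_times(x)
  keep <- which(tax >= tlim[1] & tax < tlim[2])
  if (!length(keep)) stop("empty crop window")
  x$data <- x$data[, , keep, drop = FALSE]
  x$t0 <- tax[keep[1]]
  x
}

#' Save / load an epochs container
#'
#' The array is serialized as RDS next to a JSON sidecar holding `sfreq`,
#' `t0`, `lock`, `channel_names` and the `trial_meta` table, so the metadata
#' stays inspectable as plain text.
#' @param x an `eeg_epochs`.
#' @param path base path; `<path>.rds` and `<path>.json` are written.
#' @export
write_epochs <- function(x, path) {
  stopifnot(inherits(x, "eeg_epochs"))
  saveRDS(x$data, paste0(path, ".rds"))
  meta <- list(sfreq = x$sfreq, lock = x$lock, t0 = x$t0,
               channel_names = x$channel_names, trial_meta = x$trial_meta)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  data <- readRDS(paste0(path, ".rds"))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  tm <- if (is.null(meta$trial_meta)) NULL else as.data.frame(meta$trial_meta)
  new_epochs(data, meta$sfreq, meta$lock, meta$t0, meta$channel_names, tm)
}
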