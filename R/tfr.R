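#' Time-frequency analysis specification
#'
#' Frequency grid, wavelet cycle schedule, analysis bands, periods of
#' interest and baseline windows. The defaults follow the standard
#' decomposition of this design: Morlet wavelets on a 4-80 Hz grid in 1-Hz
#' steps with the cycle count rising in 0.1 steps from 3 (at 4 Hz) to 10.6
#' (at 80 Hz), i.e. `cycles(f) = 3 + 0.1 * (f - 4)`; theta band 4-8 Hz
#' analyzed stimulus-locked over 0 to 0.5 s with baseline -0.5 to 0 s; beta
#' band 15-30 Hz analyzed movement-locked over -0.5 to 0 s with baseline
#' -1.3 to -0.8 s.
#'
#' @param freqs integer frequency grid, Hz.
#' @param cycles wavelet cycles per frequency (same length as `freqs`).
#' @param band_theta,band_beta analysis bands, Hz.
#' @param poi named list of periods of interest (s) per lock.
#' @param baseline named list of baseline windows (s) per lock.
#' @return object of class `tfr_spec`.
#' @export
tfr_spec <- function(freqs = 4:80,
                     cycles = 3 + 0.1 * (freqs - 4),
                     band_theta = c(4, 8), band_beta = c(15, 30),
                     poi = list(stimulus = c(0, 0.5), movement = c(-0.5, 0)),
                     baseline = list(stimulus = c(-0.5, 0),
                                     movement = c(-1.3, -0.8))) {
  stopifnot(length(freqs) == length(cycles))
  if (any(diff(cycles) <= 0)) stop("cycles must be strictly increasing")
  structure(list(freqs = freqs, cycles = cycles, band_theta = band_theta,
                 band_beta = band_beta, poi = poi, baseline = baseline),
            class = "tfr_spec")
}

#' @export
print.tfr_spec <- function(x, ...) {
  cat(sprintf("<tfr_spec> %d-%d Hz (%d steps), cycles %.1f-%.1f\n",
              min(x$freqs), max(x$freqs), length(x$freqs),
              min(x$cycles), max(x$cycles)))
  invisible(x)
}

# complex Morlet wavelet, unit energy, support +-3 sigma_t
morlet_wavelet <- function(f, cycles, sfreq) {
  sigma_t <- cycles / (2 * pi * f)
  half <- max(1L, floor(3 * sigma_t * sfreq))
  t <- (-half:half) / sfreq
  w <- exp(2i * pi * f * t) * exp(-t^2 / (2 * sigma_t^2))
  w / sqrt(sum(Mod(w)^2))
}

# half-length (s) of the longest wavelet among the given frequencies;
# defines the edge-artifact zone at the epoch borders
wavelet_edge <- function(spec, freqs = spec$freqs) {
  i <- match(freqs, spec$freqs)
  max(3 * spec$cycles[i] / (2 * pi * freqs))
}

#' Morlet wavelet power
#'
#' Per-trial (induced) power: squared magnitude of the convolution of each
#' trial x channel trace with complex Morlet wavelets (unit energy per
#' frequency), computed by FFT. Fails if the period of interest for the
#' epoch's lock overlaps the edge-artifact zone (one wavelet half-length
#' from the epoch borders at the lowest analyzed frequency).
#'
#' @param epochs an `eeg_epochs`.
#' @param spec a [tfr_spec()].
#' @param freqs frequencies to compute (subset of `spec$freqs`); defaults to
#'   the full grid.
#' @param check_poi verify the edge-artifact precondition (default TRUE).
#' @return numeric array trials x channels x frequencies x samples.
#' @export
morlet_power <- function(epochs, spec = tfr_spec(), freqs = spec$freqs,
                         check_poi = TRUE) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  fi <- match(freqs, spec$freqs)
  if (anyNA(fi)) stop("freqs must be a subset of spec$freqs")
  d <- dim(epochs$data)
  ns <- d[3]
  tax <- epoch_times(epochs)
  if (check_poi) {
    edge <- wavelet_edge(spec, freqs)
    poi <- spec$poi[[epochs$lock]]
    if (poi[1] < tax[1] + edge || poi[2] > tax[ns] - edge)
      stop(sprintf(paste0("period of interest [%g, %g] s overlaps the ",
                          "edge-artifact zone (%.0f ms) of the %s epoch"),
                   poi[1], poi[2], 1000 * edge, epochs$lock))
  }
  wl <- lapply(seq_along(freqs), function(k)
    morlet_wavelet(freqs[k], spec$cycles[fi[k]], epochs$sfreq))
  maxlen <- max(lengths(wl))
  nfft <- stats::nextn(ns + maxlen - 1, c(2, 3, 5))
  flat <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = ns) # samples x (tr*ch)
  Fd <- stats::mvfft(rbind(flat, matrix(0, nfft - ns, ncol(flat))))
  out <- array(0, c(d[1], d[2], length(freqs), ns))
  for (k in seq_along(freqs)) {
    w <- wl[[k]]
    wf <- stats::fft(c(w, rep(0, nfft - length(w))))
    conv <- stats::mvfft(Fd * wf, inverse = TRUE) / nfft
    ctr <- (length(w) - 1L) / 2L
    pw <- Mod(conv[ctr + seq_len(ns), , drop = FALSE])^2
    out[, , k, ] <- aperm(array(pw, c(ns, d[1], d[2])), c(2, 3, 1))
  }
  dimnames(out) <- list(NULL, epochs$channel_names, freqs, NULL)
  out
}

#' Relative-change baseline normalization
#'
#' `out = (P - B) / B` where `B` is the mean power over the baseline window,
#' computed per every leading dimension (e.g. per channel x frequency). The
#' result is a unitless relative change bounded below by -1 for
#' non-negative power, and invariant to any positive rescaling of `P`.
#' Alternatively a precomputed baseline array `B` (shape = leading
#' dimensions of `power`) may be supplied, e.g. to normalize trial-level
#' power by its condition's baseline.
#'
#' @param power numeric array with time as the last dimension.
#' @param times time axis (s), length = last dimension of `power`.
#' @param window c(from, to) seconds, inclusive of `from`, exclusive of `to`.
#' @param baseline optional precomputed baseline means.
#' @return array like `power`.
#' @export
baseline_relative <- function(power, times, window, baseline = NULL) {
  d <- dim(power)
  ns <- d[length(d)]
  stopifnot(length(times) == ns)
  flat <- matrix(power, ncol = ns)
  if (is.null(baseline)) {
    sel <- times >= window[1] & times < window[2]
    if (!any(sel)) stop("baseline window contains no samples")
    B <- rowMeans(flat[, sel, drop = FALSE])
  } else {
    B <- as.numeric(baseline)
    stopifnot(length(B) == nrow(flat))
  }
  if (any(B == 0)) stop("zero baseline mean: cannot form relative change")
  out <- (flat - B) / B
  array(out, d, dimnames = dimnames(power))
}

#' Average power over a frequency band
#'
#' Unweighted mean over the band's integer frequencies (inclusive edges) of
#' a trials x channels x frequencies x samples power array.
#'
#' @param power output of [morlet_power()] (needs frequency dimnames).
#' @param band c(lo, hi) Hz.
#' @return array trials x channels x samples.
#' @export
band_average <- function(power, band) {
  fr <- as.numeric(dimnames(power)[[3]])
  if (is.null(fr)) stop("power array lacks frequency dimnames")
  sel <- which(fr >= band[1] & fr <= band[2])
  if (!length(sel)) stop("band outside the computed frequency grid")
  need <- seq(ceiling(band[1]), floor(band[2]))
  if (!all(need %in% fr[sel]))
    stop("band not fully covered by the computed frequency grid")
  out <- apply(power[, , sel, , drop = FALSE], c(1, 2, 4), mean)
  dimnames(out) <- dimnames(power)[c(1, 2, 4)]
  out
}

#' Region-of-interest scalar
#'
#' Mean over a channel set and a time window of a (participant or trial) x
#' channel x time array; returns one scalar per row of the first dimension.
#'
#' @param map array n x channels x samples with channel dimnames.
#' @param channels character vector of ROI channels.
#' @param times time axis (s) for the last dimension.
#' @param window c(from, to) seconds (from inclusive, to exclusive).
#' @export
extract_roi <- function(map, channels, times, window) {
  chn <- dimnames(map)[[2]]
  if (is.null(chn)) stop("map lacks channel dimnames")
  if (!length(channels)) stop("empty ROI channel set")
  ci <- match(channels, chn)
  if (anyNA(ci)) stop("ROI channels not in map: ",
                      paste(channels[is.na(ci)], collapse = ", "))
  ti <- which(times >= window[1] & times < window[2])
  if (!length(ti)) stop("ROI window contains no samples")
  sub <- map[, ci, ti, drop = FALSE]
  apply(sub, 1, mean)
}
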