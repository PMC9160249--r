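#' Zero-phase band-pass and notch filtering
#'
#' Applies a forward-backward (zero-phase) Butterworth band-pass followed by
#' a band-stop notch to each channel. Defaults give the 1-125 Hz band-pass
#' with a 59-61 Hz notch used on raw recordings; pass-band ripple between 4
#' and 30 Hz is well under 1 dB because Butterworth responses are monotone
#' and the corners are far away.
#'
#' @param x numeric matrix, channels x samples, or an `eeg_epochs` object
#'   (filtered trial-wise).
#' @param sfreq sampling rate, Hz; must exceed twice the upper band edge.
#' @param band band-pass edges, Hz.
#' @param notch band-stop edges, Hz (NULL to skip).
#' @param order Butterworth order per edge.
#' @return the filtered object, same shape as the input.
#' @export
bandpass_notch <- function(x, sfreq, band = c(1, 125), notch = c(59, 61),
                           order = 4) {
  if (inherits(x, "eeg_epochs")) {
    for (i in seq_len(dim(x$data)[1]))
      x$data[i, , ] <- bandpass_notch(x$data[i, , , drop = TRUE], x$sfreq,
                                      band, notch, order)
    return(x)
  }
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  nyq <- sfreq / 2
  if (band[2] >= nyq)
    stop("upper band edge must be below Nyquist (sfreq/2); increase sfreq")
  min_len <- 3 * (2 * order + 1)
  if (ncol(x) < min_len)
    stop(sprintf("signal too short to filter: need at least %d samples", min_len))
  bp <- signal::butter(order, band / nyq, type = "pass")
  out <- x
  for (ch in seq_len(nrow(x)))
    out[ch, ] <- signal::filtfilt(bp, x[ch, ])
  if (!is.null(notch)) {
    bs <- signal::butter(2, notch / nyq, type = "stop")
    for (ch in seq_len(nrow(x)))
      out[ch, ] <- signal::filtfilt(bs, out[ch, ])
  }
  out
}

#' Re-reference to the average scalp potential
#'
#' Subtracts the across-channel mean at every sample, so the channel mean of
#' the output is zero everywhere. Idempotent.
#'
#' @param x channels x samples matrix or an `eeg_epochs`.
#' @export
rereference_average <- function(x) {
  if (inherits(x, "eeg_epochs")) {
    d <- dim(x$data)
    flat <- matrix(aperm(x$data, c(2, 1, 3)), nrow = d[2]) # chan x (tr*samp)
    flat <- sweep(flat, 2, colMeans(flat))
    x$data <- aperm(array(flat, c(d[2], d[1], d[3])), c(2, 1, 3))
    dimnames(x$data)[[2]] <- x$channel_names
    return(x)
  }
  stopifnot(nrow(x) >= 2)
  sweep(x, 2, colMeans(x))
}

#' Cut epochs out of a continuous recording
#'
#' Sample convention is half-open `[t0, t1)`: an epoch has
#' `round((t1 - t0) * sfreq)` samples and the sample at the lock time sits
#' at index `round(-t0 * sfreq) + 1`. Events whose window exceeds the
#' recording are dropped with a warning.
#'
#' @param continuous channels x samples matrix.
#' @param events integer vector of lock-sample indices (1-based).
#' @param lock "stimulus" or "movement"; sets the default window.
#' @param sfreq sampling rate, Hz.
#' @param window c(t0, t1) seconds relative to the lock; defaults to
#'   [epoch_window()] for the lock.
#' @param channel_names optional channel names.
#' @param trial_meta optional data.frame, one row per event.
#' @return an `eeg_epochs`.
#' @export
epoch_data <- function(continuous, events, lock = c("stimulus", "movement"),
                       sfreq, window = NULL, channel_names = NULL,
                       trial_meta = NULL) {
  lock <- match.arg(lock)
  if (is.null(window)) window <- epoch_window(lock)
  if (is.null(channel_names))
    channel_names <- rownames(continuous) %||%
      paste0("ch", seq_len(nrow(continuous)))
  nsamp <- round((window[2] - window[1]) * sfreq)
  off <- round(window[1] * sfreq)
  ok <- events + off >= 1 & events + off + nsamp - 1 <= ncol(continuous)
  if (any(!ok))
    warning(sprintf("%d event(s) dropped: epoch window outside the recording",
                    sum(!ok)))
  events <- events[ok]
  if (!is.null(trial_meta)) trial_meta <- trial_meta[ok, , drop = FALSE]
  data <- array(0, c(length(events), nrow(continuous), nsamp))
  for (i in seq_along(events))
    data[i, , ] <- continuous[, events[i] + off + seq_len(nsamp) - 1]
  new_epochs(data, sfreq, lock, off / sfreq, channel_names, trial_meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Spherical-spline surface Laplacian (current source density)
#'
#' Perrin-style spherical-spline estimate of the scalp current source
#' density: per sample, a spline of order `m` (Legendre series truncated at
#' `L`, ridge `lambda`) is fitted to the potentials and its surface
#' Laplacian evaluated at the electrodes. The transform is linear, so it is
#' precomputed once as a channels x channels matrix. Sign convention:
#' positive output = current source (a focal positive potential maps to a
#' positive CSD peak). Output is scaled by the squared head radius.
#'
#' A spatially uniform potential maps to (numerically) zero, and the
#' transform leaves channel-mean-zero data unchanged by prior average
#' referencing because the fit carries an explicit constant term.
#'
#' @param x an `eeg_epochs` or channels x samples matrix.
#' @param montage an `eeg_montage` covering all channels of `x`.
#' @param m spline order (default 4).
#' @param L Legendre series truncation (default 50).
#' @param lambda ridge regularization (default 1e-5).
#' @return same shape as the input, CSD units.
#' @export
surface_laplacian <- function(x, montage, m = 4, L = 50, lambda = 1e-5) {
  if (inherits(x, "eeg_epochs")) {
    tm <- laplacian_matrix(montage, x$channel_names, m, L, lambda)
    d <- dim(x$data)
    flat <- matrix(aperm(x$data, c(2, 1, 3)), nrow = d[2]) # ch x (tr*samp)
    x$data <- aperm(array(tm %*% flat, c(d[2], d[1], d[3])), c(2, 1, 3))
    dimnames(x$data)[[2]] <- x$channel_names
    return(x)
  }
  tm <- laplacian_matrix(montage, rownames(x) %||% montage$names, m, L, lambda)
  tm %*% x
}

# linear CSD operator for the given channel set
laplacian_matrix <- function(montage, channels, m = 4, L = 50, lambda = 1e-5) {
  if (!all(channels %in% montage$names))
    stop("montage does not cover all channels: ",
         paste(setdiff(channels, montage$names), collapse = ", "))
  co <- montage$coords[channels, , drop = FALSE]
  R <- montage$sphere_radius
  cosang <- tcrossprod(co) / R^2
  cosang[cosang > 1] <- 1; cosang[cosang < -1] <- -1
  gh <- legendre_gh(cosang, L, m)
  n <- length(channels)
  K <- rbind(cbind(gh$G + diag(lambda, n), rep(1, n)), c(rep(1, n), 0))
  Ki <- solve(K)
  ## coefficients c = Ki[1:n, 1:n] %*% v ; CSD = H c / R^2
  (gh$H %*% Ki[seq_len(n), seq_len(n), drop = FALSE]) / R^2
}

# G and H kernel matrices of the spherical spline: Legendre series
# sum (2l+1) P_l(x) / (l(l+1))^m  and  sum (2l+1) P_l(x) / (l(l+1))^(m-1),
# both over l = 1..L, scaled by 1/(4*pi)
legendre_gh <- function(x, L, m) {
  G <- matrix(0, nrow(x), ncol(x)); H <- G
  Pm1 <- matrix(1, nrow(x), ncol(x)); P <- x
  for (l in seq_len(L)) {
    ll <- l * (l + 1)
    G <- G + (2 * l + 1) / ll^m * P
    H <- H + (2 * l + 1) / ll^(m - 1) * P
    Pn <- ((2 * l + 1) * x * P - l * Pm1) / (l + 1)
    Pm1 <- P; P <- Pn
  }
  list(G = G / (4 * pi), H = H / (4 * pi))
}

#' Integer-factor downsampling
#'
#' Keeps every `factor`-th sample starting from the first; `sfreq` is
#' divided and `t0` preserved. The caller is responsible for the signal
#' being band-limited below the new Nyquist (the standard pipeline low-pass
#' filters at 125 Hz before going from 500 to 250 Hz).
#'
#' @param x an `eeg_epochs`.
#' @param factor positive integer decimation factor.
#' @export
downsample <- function(x, factor) {
  stopifnot(inherits(x, "eeg_epochs"))
  if (length(factor) != 1 || factor != round(factor) || factor < 1)
    stop("factor must be a positive integer")
  if (factor == 1) return(x)
  keep <- seq(1, dim(x$data)[3], by = factor)
  x$data <- x$data[, , keep, drop = FALSE]
  x$sfreq <- x$sfreq / factor
  x
}
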