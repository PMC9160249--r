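#' Simulate EEG epochs for a behavioral table
#'
#' Builds, per eligible trial, a continuous multi-channel segment spanning
#' both epoch windows and cuts stimulus- and/or movement-locked epochs from
#' it. Each channel carries an independent 1/f background (white noise
#' spectrally shaped to power ~ 1/f^`noise_exponent`); channel independence
#' is deliberate because the analysis operates after the surface Laplacian,
#' which suppresses long-range correlations. On top of the background:
#'
#' * a Hanning-windowed theta burst (carrier `theta_freq`, random per-trial
#'   phase) at the midfrontal channels Fz, F1, F2 over `theta_window`
#'   seconds post-stimulus, with amplitude `theta_amp * (1 + theta_effect)`
#'   in Instructed Hard and `theta_amp` in every other condition;
#' * an ongoing beta oscillation (carrier `beta_freq`, random per-trial
#'   phase) at the left sensorimotor channels C1, C3, Cz, FC1, CP1 whose
#'   amplitude dips pre-movement by a raised-cosine notch over the 600 ms
#'   before movement onset, of depth
#'   `beta_erd_depth + beta_rt_coupling * (rt - rt_ref)` (clipped to
#'   [0, 0.95]).
#'
#' Random phases make the bursts induced (non-phase-locked) activity, which
#' is what per-trial wavelet power measures. Eligible trials are, as in the
#' analyzed design, non-aborted right-directed trials; left-directed trials
#' get no EEG.
#'
#' @param cfg a [sim_config()].
#' @param behavior table from [simulate_behavior()].
#' @param montage an `eeg_montage`; must contain the effect channels when
#'   the corresponding amplitude is non-zero.
#' @param lock which epoch sets to produce.
#' @param participants subset of participant ids (default all present).
#' @return named list of `eeg_epochs` (elements "stimulus" and/or
#'   "movement"), trials pooled over the selected participants in table
#'   order, with `trial_meta` carrying the behavior rows.
#' @export
simulate_epochs <- function(cfg, behavior, montage,
                            lock = c("stimulus", "movement"),
                            participants = NULL) {
  stopifnot(inherits(cfg, "sim_config"), inherits(montage, "eeg_montage"))
  lock <- match.arg(lock, several.ok = TRUE)
  theta_ch <- names(cfg$theta_profile)
  beta_ch <- names(cfg$beta_profile)
  if (cfg$theta_amp > 0 && !all(theta_ch %in% montage$names))
    stop("montage lacks midfrontal effect channels: ",
         paste(setdiff(theta_ch, montage$names), collapse = ", "))
  if (cfg$beta_amp > 0 && !all(beta_ch %in% montage$names))
    stop("montage lacks sensorimotor effect channels: ",
         paste(setdiff(beta_ch, montage$names), collapse = ", "))

  elig <- !grepl("aborted", behavior$flags) & behavior$choice == "right"
  behavior <- behavior[elig, , drop = FALSE]
  if (is.null(participants)) participants <- unique(behavior$participant)
  behavior <- behavior[behavior$participant %in% participants, , drop = FALSE]
  if (nrow(behavior) == 0) stop("no eligible (non-aborted, right-directed) trials")

  sf <- cfg$sfreq
  span <- if ("movement" %in% lock) c(-2.0, 1.6) else c(-1.2, 1.6)
  ns <- round(diff(span) * sf)
  tax <- span[1] + (seq_len(ns) - 1) / sf
  nc <- length(montage$names)

  out <- list()
  for (lk in lock) {
    w <- epoch_window(lk)
    out[[lk]] <- array(0, c(nrow(behavior), nc, round(diff(w) * sf)))
  }

  row0 <- 0L
  for (p in participants) {
    bt <- behavior[behavior$participant == p, , drop = FALSE]
    nt <- nrow(bt)
    set.seed(seeds_for_participant(cfg, p))
    cont <- simulate_continuous(cfg, bt, montage, tax, theta_ch, beta_ch)
    for (lk in lock) {
      w <- epoch_window(lk)
      ne <- round(diff(w) * sf)
      for (i in seq_len(nt)) {
        shift <- if (lk == "stimulus") 0L else round(bt$rt[i] / 1000 * sf)
        start <- shift + round((w[1] - span[1]) * sf) + 1L
        out[[lk]][row0 + i, , ] <- t(cont[start:(start + ne - 1L),
                                          (i - 1L) * nc + seq_len(nc)])
      }
    }
    row0 <- row0 + nt
  }
  for (lk in names(out)) {
    w <- epoch_window(lk)
    out[[lk]] <- new_epochs(out[[lk]], sf, lk, w[1], montage$names, behavior)
  }
  out
}

seeds_for_participant <- function(cfg, p) {
  (cfg$seed + 1000003L * p + 13L) %% .Machine$integer.max
}

# continuous segment for one participant: samples x (trial * channel) matrix,
# trial-major column blocks of width n_channels
simulate_continuous <- function(cfg, bt, montage, tax, theta_ch, beta_ch) {
  sf <- cfg$sfreq
  ns <- length(tax)
  nc <- length(montage$names)
  nt <- nrow(bt)
  cont <- one_over_f_noise(ns, nt * nc, sf, cfg$noise_sd, cfg$noise_exponent)
  if (cfg$noise_sd > 0 && cfg$noise_spatial_cm > 0) {
    M <- spatial_mixing(montage, cfg$noise_spatial_cm)
    for (i in seq_len(nt)) {
      cols <- (i - 1L) * nc + seq_len(nc)
      cont[, cols] <- cont[, cols] %*% M # M symmetric: rows = output channels
    }
  }

  th_idx <- match(theta_ch, montage$names)
  be_idx <- match(beta_ch, montage$names)
  rt_s <- round(bt$rt / 1000 * sf) / sf # sample-quantized movement onset

  if (cfg$theta_amp > 0) {
    tw <- cfg$theta_window
    sel <- tax >= tw[1] & tax < tw[2]
    env <- hann_env((tax[sel] - tw[1]) / diff(tw))
    phases <- stats::runif(nt, 0, 2 * pi)
    hard <- bt$context == "Instructed" & !is.na(bt$difficulty) &
      bt$difficulty == "Hard"
    gains <- cfg$theta_amp * (1 + cfg$theta_effect * hard)
    for (i in seq_len(nt)) {
      burst <- gains[i] * env *
        cos(2 * pi * cfg$theta_freq * (tax[sel] - tw[1]) + phases[i])
      cols <- (i - 1L) * nc + th_idx
      cont[sel, cols] <- cont[sel, cols] +
        outer(burst, unname(cfg$theta_profile))
    }
  }

  if (cfg$beta_amp > 0) {
    phases <- stats::runif(nt, 0, 2 * pi)
    depth <- pmin(0.95, pmax(0, cfg$beta_erd_depth +
                               cfg$beta_rt_coupling * (rt_s - cfg$rt_ref)))
    for (i in seq_len(nt)) {
      u <- (tax - (rt_s[i] - 0.6)) / 0.6
      envdip <- 1 - depth[i] * hann_env(u)
      osc <- cfg$beta_amp * envdip * cos(2 * pi * cfg$beta_freq * tax + phases[i])
      cols <- (i - 1L) * nc + be_idx
      cont[, cols] <- cont[, cols] + outer(osc, unname(cfg$beta_profile))
    }
  }
  cont
}

# Gaussian distance kernel over electrodes, rows scaled to unit norm so the
# per-channel noise RMS is preserved under iid inputs; emulates the spatial
# coherence of a volume-conducted background
spatial_mixing <- function(montage, length_cm) {
  D <- as.matrix(stats::dist(montage$coords))
  K <- exp(-(D / length_cm)^2)
  K / sqrt(rowSums(K^2))
}

# raised cosine bump on [0, 1], zero outside
hann_env <- function(u) {
  out <- numeric(length(u))
  inb <- u >= 0 & u <= 1
  out[inb] <- 0.5 * (1 - cos(2 * pi * u[inb]))
  out
}

# spectrally shaped Gaussian noise: power ~ 1/f^exponent, per-column RMS = sd
one_over_f_noise <- function(ns, ncols, sfreq, sd, exponent,
                             block = 4096L) {
  if (sd == 0 || ncols == 0) return(matrix(0, ns, ncols))
  k <- seq_len(ns) - 1L
  f <- pmin(k, ns - k) * sfreq / ns # symmetric |frequency| per FFT bin
  amp <- c(0, f[-1]^(-exponent / 2)) # DC removed
  scale <- sd / sqrt(mean(amp^2))
  out <- matrix(0, ns, ncols)
  for (j0 in seq(1L, ncols, by = block)) {
    jj <- j0:min(ncols, j0 + block - 1L)
    w <- matrix(stats::rnorm(ns * length(jj)), ns)
    X <- stats::mvfft(w) * amp
    out[, jj] <- Re(stats::mvfft(X, inverse = TRUE)) / ns * scale
  }
  out
}
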