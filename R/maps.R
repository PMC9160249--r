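#' Condition-averaged band-power maps from the generator
#'
#' Convenience wrapper running the analysis chain from a (simulated or
#' user-supplied) behavior table to participant x channel x time band-power
#' maps per condition: eligible trials (surviving rejection, right-directed),
#' epoch simulation, optional preprocessing (zero-phase filtering when the
#' sampling rate allows the 125-Hz edge, average reference, surface
#' Laplacian, downsampling), Morlet power over the band's integer
#' frequencies, condition averaging, relative-change baseline per channel x
#' frequency, band averaging, and cropping to the lock's period of
#' interest.
#'
#' @param cfg a [sim_config()].
#' @param montage an `eeg_montage`.
#' @param behavior behavior table with rejection flags; `NULL` simulates
#'   and applies [reject_trials()] internally.
#' @param band frequency band c(lo, hi) Hz.
#' @param lock "stimulus" or "movement".
#' @param spec a [tfr_spec()].
#' @param conditions condition labels to map (`context` pasted to
#'   `difficulty`, or "OneTarget").
#' @param preprocess run re-referencing and surface Laplacian (and the
#'   band-pass/notch when `cfg$sfreq` exceeds 252 Hz).
#' @param analysis_sfreq downsample to this rate before the decomposition
#'   (`NULL` = keep `cfg$sfreq`).
#' @param use_rtcor exclude `rtcor_removed` trials from the averages.
#' @param crop trim each epoch to baseline/period-of-interest plus the
#'   wavelet edge margin before decomposing (default TRUE). Values inside
#'   the analyzed windows are unchanged because the wavelet support never
#'   crosses the trimmed borders; it only saves computation.
#' @return list: `maps` (named list of participant x channel x time
#'   arrays), `times` (s), `participants`.
#' @export
condition_band_maps <- function(cfg, montage, behavior = NULL,
                                band = c(4, 8), lock = "stimulus",
                                spec = tfr_spec(),
                                conditions = c("InstructedEasy",
                                               "InstructedHard",
                                               "FreeEasy", "FreeHard"),
                                preprocess = FALSE, analysis_sfreq = NULL,
                                use_rtcor = FALSE, crop = TRUE) {
  if (is.null(behavior))
    behavior <- reject_trials(simulate_behavior(cfg),
                              rt_deadline = cfg$rt_deadline)
  elig <- surviving(behavior, ignore = "rtcor_removed")
  elig <- elig[elig$choice == "right", , drop = FALSE]
  ids <- sort(unique(elig$participant))
  fint <- seq(band[1], band[2])
  maps <- stats::setNames(vector("list", length(conditions)), conditions)
  times <- NULL
  for (pi in seq_along(ids)) {
    p <- ids[pi]
    bt <- elig[elig$participant == p, , drop = FALSE]
    ep <- simulate_epochs(cfg, bt, montage, lock = lock,
                          participants = p)[[lock]]
    if (preprocess) {
      if (cfg$sfreq > 252) ep <- bandpass_notch(ep, ep$sfreq)
      ep <- rereference_average(ep)
      ep <- surface_laplacian(ep, montage)
    }
    if (!is.null(analysis_sfreq) && analysis_sfreq != cfg$sfreq)
      ep <- downsample(ep, cfg$sfreq / analysis_sfreq)
    if (isTRUE(crop)) {
      edge <- wavelet_edge(spec, fint)
      lim <- range(spec$baseline[[lock]], spec$poi[[lock]])
      ep <- crop_epochs(ep, c(lim[1] - edge - 0.02, lim[2] + edge + 0.02))
    }
    tax <- epoch_times(ep)
    pw <- morlet_power(ep, spec, freqs = fint)
    bwin <- spec$baseline[[lock]]
    poi <- spec$poi[[lock]]
    bsel <- tax >= bwin[1] & tax < bwin[2]
    psel <- tax >= poi[1] & tax < poi[2]
    cond <- ifelse(ep$trial_meta$context == "OneTarget", "OneTarget",
                   paste0(ep$trial_meta$context, ep$trial_meta$difficulty))
    nch <- dim(pw)[2]; nf <- dim(pw)[3]; ns <- dim(pw)[4]
    pwm <- matrix(pw, nrow = dim(pw)[1]) # trials x (chan*freq*time)
    for (cn in conditions) {
      tsel <- which(cond == cn)
      if (use_rtcor)
        tsel <- tsel[!has_flag(ep$trial_meta$flags[tsel], "rtcor_removed")]
      if (!length(tsel)) next
      ba <- band_map_of(colMeans(pwm[tsel, , drop = FALSE]), nch, nf, bsel)
      ba <- ba[, psel, drop = FALSE]
      if (is.null(maps[[cn]]))
        maps[[cn]] <- array(NA_real_, c(length(ids), nrow(ba), ncol(ba)),
                            dimnames = list(ids, montage$names, NULL))
      maps[[cn]][pi, , ] <- ba
    }
    times <- tax[psel]
  }
  list(maps = maps, times = times, participants = ids)
}

# condition-average power vector (chan*freq*time) -> baseline-normalised,
# band-averaged channels x time map
band_map_of <- function(avg, nch, nf, bsel) {
  m2 <- matrix(avg, nch * nf) # (chan, freq) x time
  B <- rowMeans(m2[, bsel, drop = FALSE])
  if (any(B == 0)) stop("zero baseline mean: cannot form relative change")
  rel <- m2 / B - 1
  rel3 <- aperm(array(rel, c(nch, nf, ncol(m2))), c(2, 1, 3))
  matrix(colMeans(matrix(rel3, nf)), nch)
}
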