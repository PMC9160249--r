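#' Simulation configuration
#'
#' `sim_config()` collects every parameter of the synthetic study in one
#' validated object. Defaults encode the study design: a 2x2
#' within-participant factorial (Instructed/Free x Easy/Hard) plus
#' one-target control trials, an 800-ms response deadline, condition
#' reaction-time means of 453/495/483/486 ms, choices drawn from a logistic
#' in (left-target distance - PSE) with a rightward bias calibrated so that
#' P(right | distance = PSE) = 0.578, and 64-channel EEG with a 1/f
#' background, a stimulus-locked midfrontal theta burst whose gain is raised
#' only in Instructed Hard, and a movement-locked sensorimotor beta
#' desynchronization whose depth grows with the trial's RT.
#'
#' Setting `theta_effect = 0` and `beta_rt_coupling = 0` yields a null
#' dataset: no condition carries any EEG effect beyond exchangeable noise.
#'
#' @param n_participants number of participants.
#' @param sfreq EEG sampling rate, Hz.
#' @param trial_counts named list with `instructed` (easy_right, easy_left,
#'   hard_right, hard_left), `free` (pse_m4, pse_p4, pse_m05, pse_0, pse_p05)
#'   and `one_target` (count per target position).
#' @param rt_means,rt_sds named numeric vectors (ms) per condition
#'   (InstructedEasy, InstructedHard, FreeEasy, FreeHard, OneTarget).
#'   `rt_sds` is the within-participant trial-to-trial SD.
#' @param rt_participant_sd SD (ms) of the per-participant RT offset shared
#'   by all conditions.
#' @param rt_deadline response deadline, ms; trials drawn above it are
#'   flagged aborted.
#' @param pse_mean,pse_sd across-participant distribution of the point of
#'   subjective equality, cm.
#' @param psycho_slope logistic slope of the choice rule, 1/cm.
#' @param right_bias log-odds offset toward the right target
#'   (default `qlogis(0.578)`).
#' @param instructed_error_rate probability that an instructed trial's
#'   choice disobeys the cue.
#' @param theta_effect dimensionless gain increment of the Instructed-Hard
#'   midfrontal theta burst (amplitude multiplied by `1 + theta_effect`).
#' @param theta_amp burst amplitude, signal units; `theta_freq` carrier Hz;
#'   `theta_window` burst support in s after stimulus onset.
#' @param theta_profile named weights giving the burst's spatial topography
#'   (channel = weight). The default peaks at Fz with shoulders at F1/F2:
#'   a focal source, so the current-source-density transform preserves
#'   rather than cancels it (a patch of equal amplitudes would be flattened
#'   by the surface Laplacian).
#' @param beta_profile named weights for the beta topography, peaked at C1
#'   over the left sensorimotor set.
#' @param beta_amp amplitude of the ongoing sensorimotor beta oscillation;
#'   `beta_freq` carrier Hz.
#' @param beta_erd_depth baseline depth (0..1) of the pre-movement beta
#'   amplitude reduction.
#' @param beta_rt_coupling slope (1/s) of the desynchronization depth on the
#'   trial's RT (centred at `rt_ref` seconds). The study this design
#'   emulates does not quantify this coupling; the default is a free
#'   parameter of the generator, not an empirical claim.
#' @param rt_ref centre (s) of the RT term in the beta depth rule.
#' @param noise_sd RMS amplitude of the 1/f background per channel;
#'   `noise_exponent` its spectral slope (power ~ 1/f^exponent).
#' @param noise_spatial_cm spatial coherence length of the background (cm):
#'   channel noise is mixed by a Gaussian distance kernel with this scale,
#'   emulating volume conduction so the surface Laplacian suppresses the
#'   background relative to focal sources, as it does on real scalp data.
#'   0 gives channel-independent noise.
#' @param seed master seed; per-participant streams are derived from it
#'   deterministically.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_participants = 30,
                       sfreq = 500,
                       trial_counts = list(
                         instructed = c(easy_right = 50, easy_left = 40,
                                        hard_right = 50, hard_left = 40),
                         free = c(pse_m4 = 40, pse_p4 = 50, pse_m05 = 40,
                                  pse_0 = 40, pse_p05 = 40),
                         one_target = 20),
                       rt_means = c(InstructedEasy = 453, InstructedHard = 495,
                                    FreeEasy = 483, FreeHard = 486,
                                    OneTarget = 440),
                       rt_sds = c(InstructedEasy = 80, InstructedHard = 80,
                                  FreeEasy = 80, FreeHard = 80,
                                  OneTarget = 80),
                       rt_participant_sd = 25,
                       rt_deadline = 800,
                       pse_mean = 8, pse_sd = 1.2,
                       psycho_slope = 0.6,
                       right_bias = stats::qlogis(0.578),
                       instructed_error_rate = 0.02,
                       theta_effect = 0.6,
                       theta_amp = 5, theta_freq = 6,
                       theta_window = c(0.3, 0.5),
                       theta_profile = c(Fz = 1, F1 = 0.5, F2 = 0.5),
                       beta_amp = 2, beta_freq = 20,
                       beta_profile = c(C1 = 1, C3 = 0.5, Cz = 0.5,
                                        FC1 = 0.5, CP1 = 0.5),
                       beta_erd_depth = 0.5,
                       beta_rt_coupling = 1.0,
                       rt_ref = 0.48,
                       noise_sd = 6, noise_exponent = 1,
                       noise_spatial_cm = 4,
                       seed = 1L) {
  ## accept list-shaped inputs (e.g. parsed from YAML) for the named vectors
  trial_counts <- lapply(trial_counts, unlist)
  rt_means <- unlist(rt_means); rt_sds <- unlist(rt_sds)
  theta_profile <- unlist(theta_profile); beta_profile <- unlist(beta_profile)
  theta_window <- unlist(theta_window)
  cfg <- list(n_participants = as.integer(n_participants), sfreq = sfreq,
              trial_counts = trial_counts, rt_means = rt_means,
              rt_sds = rt_sds, rt_participant_sd = rt_participant_sd,
              rt_deadline = rt_deadline, pse_mean = pse_mean, pse_sd = pse_sd,
              psycho_slope = psycho_slope, right_bias = right_bias,
              instructed_error_rate = instructed_error_rate,
              theta_effect = theta_effect, theta_amp = theta_amp,
              theta_freq = theta_freq, theta_window = theta_window,
              theta_profile = theta_profile,
              beta_amp = beta_amp, beta_freq = beta_freq,
              beta_profile = beta_profile,
              beta_erd_depth = beta_erd_depth,
              beta_rt_coupling = beta_rt_coupling, rt_ref = rt_ref,
              noise_sd = noise_sd, noise_exponent = noise_exponent,
              noise_spatial_cm = noise_spatial_cm,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (!all(c("easy_right", "easy_left", "hard_right", "hard_left") %in%
             names(cfg$trial_counts$instructed)) ||
      !all(c("pse_m4", "pse_p4", "pse_m05", "pse_0", "pse_p05") %in%
             names(cfg$trial_counts$free)))
    stop("trial_counts$instructed and $free must be named (easy_right/... and pse_m4/...)")
  counts <- c(cfg$trial_counts$instructed, cfg$trial_counts$free,
              cfg$trial_counts$one_target)
  if (any(counts <= 0)) stop("all trial counts must be > 0")
  if (cfg$n_participants < 1) stop("n_participants must be >= 1")
  if (any(cfg$rt_sds < 0)) stop("rt_sds must be >= 0")
  conds <- c("InstructedEasy", "InstructedHard", "FreeEasy", "FreeHard",
             "OneTarget")
  if (!all(conds %in% names(cfg$rt_means)) ||
      !all(conds %in% names(cfg$rt_sds)))
    stop("rt_means and rt_sds must name all five conditions")
  if (cfg$rt_deadline <= 0) stop("rt_deadline must be positive")
  if (cfg$sfreq <= 0) stop("sfreq must be positive")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d participants, sfreq %g Hz, seed %d\n",
              x$n_participants, x$sfreq, x$seed))
  cat(sprintf("  PSE %.1f +/- %.1f cm, slope %.2f /cm, right bias %.3f\n",
              x$pse_mean, x$pse_sd, x$psycho_slope, x$right_bias))
  cat(sprintf("  theta_effect %.2f, beta_rt_coupling %.2f /s, noise_sd %.1f\n",
              x$theta_effect, x$beta_rt_coupling, x$noise_sd))
  invisible(x)
}

# deterministic per-participant seed stream (kept below 2^31)
participant_seeds <- function(cfg) {
  (cfg$seed + 1000003L * seq_len(cfg$n_participants)) %% .Machine$integer.max
}
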