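#' Simulate the behavioral table of the choice task
#'
#' Generates, per participant, a pseudo-randomised trial sequence in which
#' the same target configuration never occurs twice in a row, draws choices
#' from a logistic in (left-target distance - PSE) plus a rightward bias,
#' and draws reaction times from a truncated normal per condition (truncated
#' at 0; draws above the deadline are kept in the table and flagged
#' `aborted`). Instructed trials disobey their cue with probability
#' `instructed_error_rate`. A block of one-target control trials follows the
#' main block.
#'
#' @param cfg a [sim_config()].
#' @return A `data.frame` with one row per trial: `participant`,
#'   `trial_index`, `phase` ("main"/"control"), `context`
#'   ("Instructed"/"Free"/"OneTarget"), `difficulty` ("Easy"/"Hard"/NA),
#'   `distance_cond` (configuration label, e.g. "PSE+4" or "RIGHT10"),
#'   `left_distance` (cm; NA for the right-only control target),
#'   `cue_direction`, `choice`, `rt` (ms), `flags` (semicolon-separated
#'   tokens). The per-participant true PSEs are attached as
#'   `attr(x, "pse")`.
#' @export
simulate_behavior <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  seeds <- participant_seeds(cfg)
  set.seed(cfg$seed)
  pse <- stats::rnorm(cfg$n_participants, cfg$pse_mean, cfg$pse_sd)
  rt_off <- stats::rnorm(cfg$n_participants, 0, cfg$rt_participant_sd)
  out <- vector("list", cfg$n_participants)
  for (p in seq_len(cfg$n_participants)) {
    set.seed(seeds[p])
    out[[p]] <- simulate_participant(cfg, p, pse[p], rt_off[p])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "pse") <- pse
  res
}

main_configs <- function(cfg) {
  ins <- cfg$trial_counts$instructed
  fre <- cfg$trial_counts$free
  data.frame(
    config = c("IE_r", "IE_l", "IH_r", "IH_l",
               "F_m4", "F_p4", "F_m05", "F_0", "F_p05"),
    context = c(rep("Instructed", 4), rep("Free", 5)),
    difficulty = c("Easy", "Easy", "Hard", "Hard",
                   "Easy", "Easy", "Hard", "Hard", "Hard"),
    distance_cond = c("PSE", "PSE", "PSE", "PSE",
                      "PSE-4", "PSE+4", "PSE-0.5", "PSE", "PSE+0.5"),
    offset = c(0, 0, 0, 0, -4, 4, -0.5, 0, 0.5),
    cue = c("right", "left", "right", "left", NA, NA, NA, NA, NA),
    count = c(ins[["easy_right"]], ins[["easy_left"]],
              ins[["hard_right"]], ins[["hard_left"]],
              fre[["pse_m4"]], fre[["pse_p4"]], fre[["pse_m05"]],
              fre[["pse_0"]], fre[["pse_p05"]]),
    stringsAsFactors = FALSE)
}

control_configs <- function(cfg) {
  n <- cfg$trial_counts$one_target
  data.frame(
    config = c("T_right", "T_m4", "T_0", "T_p4"),
    context = "OneTarget", difficulty = NA_character_,
    distance_cond = c("RIGHT10", "PSE-4", "PSE", "PSE+4"),
    offset = c(NA, -4, 0, 4),
    cue = c("right", "left", "left", "left"),
    count = rep(n, 4), stringsAsFactors = FALSE)
}

# random sequence of config ids with no immediate repeat:
# shuffle, then repair adjacent duplicates by swapping with a later
# compatible position; reshuffle on failure
no_repeat_sequence <- function(ids) {
  counts <- table(ids)
  n <- length(ids)
  if (2 * max(counts) > n + 1)
    stop("trial counts cannot satisfy the no-immediate-repeat constraint")
  for (attempt in 1:200) {
    s <- sample(ids)
    ok <- TRUE
    i <- 2L
    while (i <= n) {
      if (s[i] == s[i - 1L]) {
        j <- which(s != s[i] & c("", s[-n]) != s[i] &
                     c(s[-1], "") != s[i])
        j <- j[j > i]
        if (!length(j)) { ok <- FALSE; break }
        j <- j[1L]
        tmp <- s[i]; s[i] <- s[j]; s[j] <- tmp
      }
      i <- i + 1L
    }
    if (ok && !any(s[-1] == s[-n])) return(s)
  }
  stop("trial counts cannot satisfy the no-immediate-repeat constraint")
}

# normal truncated below at 0 (deadline handled by flagging, not truncation)
rtrunc_pos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(lo + stats::runif(n) * (1 - lo), mean, sd)
}

simulate_participant <- function(cfg, p, pse, rt_off) {
  blocks <- list(main = main_configs(cfg), control = control_configs(cfg))
  rows <- list()
  idx0 <- 0L
  for (phase in names(blocks)) {
    cf <- blocks[[phase]]
    seqv <- no_repeat_sequence(rep(cf$config, cf$count))
    k <- match(seqv, cf$config)
    n <- length(k)
    context <- cf$context[k]
    difficulty <- cf$difficulty[k]
    offset <- cf$offset[k]
    cue <- cf$cue[k]
    left_distance <- ifelse(is.na(offset), NA_real_, pse + offset)

    cond <- ifelse(context == "OneTarget", "OneTarget",
                   paste0(context, difficulty))
    rt <- numeric(n)
    for (cc in unique(cond)) {
      sel <- cond == cc
      rt[sel] <- rtrunc_pos(sum(sel), cfg$rt_means[[cc]] + rt_off,
                            cfg$rt_sds[[cc]])
    }

    choice <- character(n)
    ins <- context == "Instructed"
    if (any(ins)) {
      err <- stats::runif(sum(ins)) < cfg$instructed_error_rate
      choice[ins] <- ifelse(err, ifelse(cue[ins] == "right", "left", "right"),
                            cue[ins])
    }
    fre <- context == "Free"
    if (any(fre)) {
      pr <- stats::plogis(cfg$psycho_slope * (left_distance[fre] - pse) +
                            cfg$right_bias)
      choice[fre] <- ifelse(stats::runif(sum(fre)) < pr, "right", "left")
    }
    ot <- context == "OneTarget"
    if (any(ot)) choice[ot] <- cue[ot]

    flags <- ifelse(rt > cfg$rt_deadline, "aborted", "")
    rows[[phase]] <- data.frame(
      participant = p, trial_index = idx0 + seq_len(n), phase = phase,
      context = context, difficulty = difficulty,
      distance_cond = cf$distance_cond[k], left_distance = left_distance,
      cue_direction = cue, choice = choice, rt = rt, flags = flags,
      stringsAsFactors = FALSE)
    idx0 <- idx0 + n
  }
  do.call(rbind, rows)
}

#' Simulate the preliminary psychometric phase
#'
#' Two-target trials with the left target at each of the given distances.
#' Choices follow the participant's logistic preference without the
#' rightward bias: the preliminary phase is what *defines* the PSE, so the
#' configured `pse_mean`/`pse_sd` describe its 50% crossing. The rightward
#' bias is a main-test phenomenon relative to that measured PSE — it is
#' what makes the right target win 57.8% of the time when the left target
#' sits exactly at the PSE. Returns right-choice counts per participant and
#' distance, the input format of [fit_psychometric()].
#'
#' @param cfg a [sim_config()].
#' @param distances left-target distances in cm.
#' @param trials_per_distance trials at each distance.
#' @return data.frame with `participant`, `distance`, `n_right`, `n_total`;
#'   true PSEs in `attr(x, "pse")`.
#' @export
simulate_preliminary <- function(cfg, distances = c(4, 6, 7, 8, 9, 10, 11, 13),
                                 trials_per_distance = 25) {
  stopifnot(inherits(cfg, "sim_config"))
  seeds <- participant_seeds(cfg)
  set.seed(cfg$seed)
  pse <- stats::rnorm(cfg$n_participants, cfg$pse_mean, cfg$pse_sd)
  out <- vector("list", cfg$n_participants)
  for (p in seq_len(cfg$n_participants)) {
    set.seed(seeds[p] + 7L)
    pr <- stats::plogis(cfg$psycho_slope * (distances - pse[p]))
    out[[p]] <- data.frame(participant = p, distance = distances,
                           n_right = stats::rbinom(length(distances),
                                                   trials_per_distance, pr),
                           n_total = trials_per_distance)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "pse") <- pse
  res
}

#' Simulate trial-level ROI power for mixed-model validation
#'
#' Generates a trial table in which baseline-normalised ROI power follows a
#' Gaussian linear mixed model with a participant random intercept: known
#' fixed effects of context, difficulty, their interaction and RT, plus
#' planted variance components. Used to validate the mixed-model fitting
#' machinery by parameter recovery; this shortcut bypasses the waveform
#' generator deliberately so the planted variances are exact.
#'
#' @param n_participants,trials_per_participant design size.
#' @param beta named fixed effects on the +-0.5-coded factors and the RT
#'   covariate in seconds: intercept, context, difficulty, interaction, rt.
#' @param sigma_u SD of the participant random intercept.
#' @param sigma_e residual SD.
#' @param rt_range uniform RT range, seconds.
#' @param seed RNG seed.
#' @return data.frame with `participant`, `context`, `difficulty`, `rt`
#'   (seconds) and `power`.
#' @export
simulate_roi_trials <- function(n_participants = 30,
                                trials_per_participant = 48,
                                beta = c(intercept = 0.2, context = 0.1,
                                         difficulty = 0.05, interaction = 0,
                                         rt = -0.5),
                                sigma_u = 0.15, sigma_e = 0.3,
                                rt_range = c(0.3, 0.7), seed = 1L) {
  set.seed(seed)
  stopifnot(trials_per_participant %% 4 == 0)
  u <- stats::rnorm(n_participants, 0, sigma_u)
  cells <- expand.grid(context = c("Instructed", "Free"),
                       difficulty = c("Easy", "Hard"),
                       stringsAsFactors = FALSE)
  per_cell <- trials_per_participant / 4
  out <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    idx <- rep(seq_len(4), each = per_cell)
    ctx <- cells$context[idx]; dif <- cells$difficulty[idx]
    rt <- stats::runif(trials_per_participant, rt_range[1], rt_range[2])
    xc <- ifelse(ctx == "Instructed", 0.5, -0.5)
    xd <- ifelse(dif == "Hard", 0.5, -0.5)
    mu <- beta[["intercept"]] + beta[["context"]] * xc +
      beta[["difficulty"]] * xd + beta[["interaction"]] * xc * xd +
      beta[["rt"]] * rt + u[p]
    out[[p]] <- data.frame(participant = p, context = ctx, difficulty = dif,
                           rt = rt,
                           power = mu + stats::rnorm(trials_per_participant,
                                                     0, sigma_e))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
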