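#' Fit a two-parameter logistic psychometric function
#'
#' Maximum-likelihood logistic fit of right-choice probability against
#' left-target distance; the point of subjective equality (PSE) is the
#' distance at which the fitted curve crosses 0.5 (`-intercept/slope`), so
#' `fitted_curve(pse) == 0.5` exactly. No lapse-rate parameters. Perfectly
#' separated data (every distance fully left or fully right of the
#' crossing) has no finite ML slope; the fit is then flagged `boundary`
#' with a warning and the PSE is taken as the midpoint between the two
#' distances bracketing the crossing, or `NA` when all choices fall on one
#' side.
#'
#' @param counts data.frame with columns `distance` (cm), `n_right`,
#'   `n_total`; at least 2 distinct distances with `n_total > 0`.
#' @return object of class `psychometric_fit` with elements `pse` (cm),
#'   `slope` (1/cm), `intercept`, `boundary`, `fit` (the glm, when
#'   non-degenerate) and `data`.
#' @examples
#' counts <- data.frame(distance = c(6, 8, 10), n_right = c(2, 10, 18),
#'                      n_total = 20)
#' fit <- fit_psychometric(counts)
#' coef(fit)
#' @export
fit_psychometric <- function(counts) {
  stopifnot(all(c("distance", "n_right", "n_total") %in% names(counts)))
  counts <- counts[counts$n_total > 0, , drop = FALSE]
  if (length(unique(counts$distance)) < 2)
    stop("need at least 2 distinct distances with trials")
  if (any(counts$n_right < 0 | counts$n_right > counts$n_total))
    stop("n_right must lie in [0, n_total]")
  sep <- is_separated(counts)
  if (sep$separated) {
    warning("choices are perfectly separated: boundary fit, no finite slope")
    res <- list(pse = sep$pse, slope = if (is.na(sep$pse)) NA_real_ else Inf,
                intercept = NA_real_, boundary = TRUE, fit = NULL,
                data = counts)
    return(structure(res, class = "psychometric_fit"))
  }
  fit <- suppressWarnings(
    stats::glm(cbind(n_right, n_total - n_right) ~ distance,
               family = stats::binomial(), data = counts))
  co <- stats::coef(fit)
  structure(list(pse = -co[[1]] / co[[2]], slope = co[[2]],
                 intercept = co[[1]], boundary = FALSE, fit = fit,
                 data = counts),
            class = "psychometric_fit")
}

# perfect separation: ordered by distance, the observed proportions never
# strictly cross through the interior (all 0s then all 1s, or one-sided)
is_separated <- function(counts) {
  agg <- stats::aggregate(cbind(n_right, n_total) ~ distance, counts, sum)
  agg <- agg[order(agg$distance), ]
  p <- agg$n_right / agg$n_total
  interior <- p > 0 & p < 1
  if (any(interior)) return(list(separated = FALSE, pse = NA_real_))
  if (all(p == 1) || all(p == 0))
    return(list(separated = TRUE, pse = NA_real_))
  ## all proportions are exactly 0 or 1: monotone split -> bracketing pair
  last0 <- max(which(p == 0)); first1 <- min(which(p == 1))
  pse <- mean(c(agg$distance[last0], agg$distance[first1]))
  list(separated = TRUE, pse = pse)
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("<psychometric_fit> PSE = %s cm, slope = %s /cm%s\n",
              format(x$pse, digits = 4), format(x$slope, digits = 4),
              if (x$boundary) " [boundary]" else ""))
  invisible(x)
}

#' @export
coef.psychometric_fit <- function(object, ...) {
  c(pse = object$pse, slope = object$slope)
}

#' @export
predict.psychometric_fit <- function(object, distance, ...) {
  if (object$boundary)
    stop("boundary fit has no finite curve")
  stats::plogis(object$intercept + object$slope * distance)
}

#' @export
plot.psychometric_fit <- function(x, ...) {
  p <- x$data$n_right / x$data$n_total
  graphics::plot(x$data$distance, p, xlab = "left-target distance (cm)",
                 ylab = "P(choose right)", ylim = c(0, 1), pch = 16, ...)
  if (!x$boundary) {
    d <- seq(min(x$data$distance), max(x$data$distance), length.out = 200)
    graphics::lines(d, predict(x, d))
    graphics::abline(v = x$pse, h = 0.5, lty = 3)
  }
  invisible(x)
}

flag_tokens <- c("aborted", "rt_outlier", "missed", "instructed_error",
                 "left_directed", "pse_band_excluded", "participant_excluded",
                 "rtcor_removed")

has_flag <- function(flags, token) {
  vapply(strsplit(flags, ";", fixed = TRUE), function(x) token %in% x,
         logical(1))
}

add_flag <- function(flags, where, token) {
  ifelse(where & !has_flag(flags, token),
         ifelse(flags == "", token, paste(flags, token, sep = ";")), flags)
}

strip_flags <- function(flags, tokens) {
  vapply(strsplit(flags, ";", fixed = TRUE), function(x)
    paste(setdiff(x, tokens), collapse = ";"), character(1))
}

#' Apply the trial-rejection rules
#'
#' Populates the `flags` column in order: `aborted` (RT above the deadline),
#' `rt_outlier` (RT outside median +- 3 SD within participant x condition,
#' both computed on non-aborted trials), `instructed_error` (choice
#' disobeys the cue), `left_directed` (left-target movement, excluded from
#' EEG analysis), `pse_band_excluded` (Free-Hard target positions whose
#' right-choice percentage for that participant falls below 25% or above
#' 75%), and `participant_excluded` (participants with under 75% right
#' choice at PSE + 4 cm, flagged on all their trials). The "3 standard
#' deviations from the median" rule is applied literally: centre = median,
#' spread = SD. Re-applying the function yields identical flags
#' (idempotent); any pre-existing tokens it owns are recomputed, while a
#' `missed` flag set upstream is preserved.
#'
#' @param table a behavior table (see [simulate_behavior()]).
#' @param rt_deadline ms (default 800).
#' @param sd_mult outlier spread multiplier (default 3).
#' @param band right-choice percentage band kept in Free Hard (default
#'   c(25, 75), exclusive bounds).
#' @param pse4_min minimum right-choice percentage at PSE + 4 cm (default 75).
#' @return the table with `flags` populated.
#' @export
reject_trials <- function(table, rt_deadline = 800, sd_mult = 3,
                          band = c(25, 75), pse4_min = 75) {
  fl <- strip_flags(table$flags, setdiff(flag_tokens, "missed"))
  fl <- add_flag(fl, table$rt > rt_deadline, "aborted")

  ok <- !has_flag(fl, "aborted")
  grp <- interaction(table$participant, table$context,
                     ifelse(is.na(table$difficulty), "none",
                            table$difficulty), drop = TRUE)
  for (g in levels(grp)) {
    sel <- grp == g & ok
    if (sum(sel) < 2) next
    med <- stats::median(table$rt[sel])
    s <- stats::sd(table$rt[sel])
    out <- sel & abs(table$rt - med) > sd_mult * s
    fl <- add_flag(fl, out, "rt_outlier")
  }

  fl <- add_flag(fl, table$context == "Instructed" &
                   table$choice != table$cue_direction, "instructed_error")
  fl <- add_flag(fl, table$choice == "left", "left_directed")

  ## Free-Hard positions with extreme preference, per participant
  fh <- table$context == "Free" & !is.na(table$difficulty) &
    table$difficulty == "Hard" & ok
  for (p in unique(table$participant[fh])) {
    for (dc in unique(table$distance_cond[fh & table$participant == p])) {
      sel <- fh & table$participant == p & table$distance_cond == dc
      pct <- 100 * mean(table$choice[sel] == "right")
      if (pct < band[1] || pct > band[2])
        fl <- add_flag(fl, table$participant == p &
                         table$distance_cond == dc & fh, "pse_band_excluded")
    }
  }

  ## participants without a marked right preference at PSE + 4 cm
  fe4 <- table$context == "Free" & table$distance_cond == "PSE+4" & ok
  for (p in unique(table$participant)) {
    sel <- fe4 & table$participant == p
    if (!any(sel)) next
    if (100 * mean(table$choice[sel] == "right") < pse4_min)
      fl <- add_flag(fl, table$participant == p, "participant_excluded")
  }

  dropped <- tapply(fl == "" | fl == "missed", grp, sum)
  if (any(stats::na.omit(dropped) == 0))
    warning("condition(s) with no surviving trials: ",
            paste(names(dropped)[which(dropped == 0)], collapse = ", "))
  table$flags <- fl
  table
}

#' Trials surviving the rejection flags
#'
#' Rows of a behavior table carrying none of the rejection tokens (optionally
#' ignoring some, e.g. `"rtcor_removed"` or `"left_directed"`).
#' @param table behavior table with flags applied.
#' @param ignore flag tokens that should not cause exclusion.
#' @export
surviving <- function(table, ignore = character()) {
  tokens <- setdiff(flag_tokens, ignore)
  keep <- !Reduce(`|`, lapply(tokens, function(tk) has_flag(table$flags, tk)))
  table[keep, , drop = FALSE]
}

#' RT-matching of the Free conditions (RTcorFree)
#'
#' Within each participant's surviving right-directed Free trials, flags as
#' `rtcor_removed` the `floor(0.25 * n)` longest-RT trials in Free Easy and
#' the `floor(0.25 * n)` shortest-RT trials in Free Hard — but only when the
#' condition holds more than 30 trials. This re-introduces an RT difference
#' between Free Hard and Free Easy comparable to the Instructed conditions.
#' Instructed trials are never touched. Ties are broken by trial order.
#'
#' @param table a behavior table with rejection flags applied.
#' @param min_trials removal happens only when n exceeds this (default 30).
#' @param frac fraction removed (default 0.25, count rounded down).
#' @return table with `rtcor_removed` flags added.
#' @export
rtcor_free <- function(table, min_trials = 30, frac = 0.25) {
  fl <- strip_flags(table$flags, "rtcor_removed")
  table$flags <- fl
  surv <- surviving(table)
  surv <- surv[surv$context == "Free" & surv$choice == "right", , drop = FALSE]
  remove_idx <- integer()
  for (p in unique(surv$participant)) {
    for (dif in c("Easy", "Hard")) {
      sel <- surv[surv$participant == p & surv$difficulty == dif, ,
                  drop = FALSE]
      n <- nrow(sel)
      if (n <= min_trials) next
      k <- floor(frac * n)
      if (k == 0) next
      ord <- order(sel$rt, sel$trial_index,
                   decreasing = (dif == "Easy"))
      remove_idx <- c(remove_idx,
                      which(table$participant == p &
                              table$trial_index %in%
                                sel$trial_index[ord[seq_len(k)]]))
    }
  }
  where <- seq_len(nrow(table)) %in% remove_idx
  table$flags <- add_flag(table$flags, where, "rtcor_removed")
  table
}

#' Within-participant 2x2 ANOVA from paired contrasts
#'
#' Each 1-df effect (factor A, factor B, interaction) of a fully
#' within-participant 2x2 design is a paired contrast across participants;
#' its F equals the squared contrast t, and partial eta squared is
#' `SS_effect / (SS_effect + SS_error) = F / (F + df_error)`. Participants
#' with a missing cell are excluded with a warning.
#'
#' @param cells numeric matrix or data.frame, participants x 4, columns
#'   ordered A1B1, A1B2, A2B1, A2B2 (e.g. Instructed Easy, Instructed Hard,
#'   Free Easy, Free Hard).
#' @param effects names for the three effects.
#' @return data.frame with one row per effect: `effect`, `F`, `df1`, `df2`,
#'   `p`, `eta_p`.
#' @export
anova_2x2 <- function(cells, effects = c("Context", "Difficulty",
                                         "Interaction")) {
  cells <- as.matrix(cells)
  stopifnot(ncol(cells) == 4)
  miss <- rowSums(is.na(cells)) > 0
  if (any(miss)) {
    warning(sum(miss), " participant(s) with missing cells excluded")
    cells <- cells[!miss, , drop = FALSE]
  }
  n <- nrow(cells)
  if (n < 2) stop("need at least 2 complete participants")
  contrasts <- list(c(1, 1, -1, -1) / 2,   # main effect of A
                    c(-1, 1, -1, 1) / 2,   # main effect of B
                    c(-1, 1, 1, -1) / 2)   # interaction (A1 diff - A2 diff)
  out <- lapply(seq_along(contrasts), function(k) {
    x <- drop(cells %*% contrasts[[k]])
    tt <- one_sample_t(x, 0)
    data.frame(effect = effects[k], F = tt$statistic^2, df1 = 1, df2 = n - 1,
               p = tt$p, eta_p = tt$statistic^2 / (tt$statistic^2 + n - 1))
  })
  do.call(rbind, out)
}

#' Paired and one-sample t-tests with Cohen's d
#'
#' Closed-form paired t on the differences: `d = mean(diff) / sd(diff)` and
#' `t = d * sqrt(n)` exactly. Zero variance with a non-zero mean yields an
#' infinite t (reported as such, p = 0). A Bonferroni-corrected p
#' `min(1, m * p)` is included; with the default family size it can equal
#' 1.0 exactly.
#'
#' @param x,y per-participant paired values.
#' @param m Bonferroni family size (default 1 = uncorrected).
#' @return list of class `stat_result`: `statistic` (t), `df`, `p`,
#'   `p_bonferroni`, `d`, `n`.
#' @export
paired_t <- function(x, y, m = 1) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  one_sample_t(x - y, 0, m)
}

#' @rdname paired_t
#' @param null_value hypothesised mean.
#' @export
one_sample_t <- function(x, null_value = 0, m = 1) {
  stopifnot(length(x) >= 2)
  n <- length(x)
  diff <- x - null_value
  mu <- mean(diff)
  s <- stats::sd(diff)
  d <- if (s == 0) { if (mu == 0) 0 else sign(mu) * Inf } else mu / s
  t <- d * sqrt(n)
  p <- if (is.infinite(t)) 0 else 2 * stats::pt(-abs(t), n - 1)
  structure(list(statistic = t, df = n - 1, p = p,
                 p_bonferroni = min(1, m * p), d = d, n = n),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("t(%d) = %.3g, p = %.3g (Bonferroni %.3g), d = %.3g\n",
              x$df, x$statistic, x$p, x$p_bonferroni, x$d))
  invisible(x)
}

#' Choice-history analysis of Free Hard trials
#'
#' Per participant, the right-choice percentage in surviving Free-Hard
#' trials split by the choice made on the immediately preceding trial (any
#' context; the previous trial must exist in the same phase). Branches with
#' no qualifying trials omit the participant with a warning. Also returns
#' one-sample t-tests of each branch against 50% and a paired t-test
#' between branches (on participants contributing to both).
#'
#' @param table a behavior table with rejection flags applied.
#' @return list: `per_participant` (participant, pct_prev_right,
#'   pct_prev_left), `test_prev_right`, `test_prev_left` (vs 50%),
#'   `test_between` (paired).
#' @export
choice_history <- function(table) {
  main <- table[table$phase == "main", , drop = FALSE]
  main <- main[order(main$participant, main$trial_index), , drop = FALSE]
  res <- lapply(unique(main$participant), function(p) {
    bt <- main[main$participant == p, , drop = FALSE]
    prev_choice <- c(NA, bt$choice[-nrow(bt)])
    prev_gap <- c(NA, diff(bt$trial_index)) # must be the immediate trial
    fh <- bt$context == "Free" & !is.na(bt$difficulty) &
      bt$difficulty == "Hard" & !has_flag(bt$flags, "aborted") &
      !has_flag(bt$flags, "pse_band_excluded") &
      !has_flag(bt$flags, "participant_excluded")
    use <- fh & !is.na(prev_choice) & prev_gap == 1
    pr <- function(branch) {
      sel <- use & prev_choice == branch
      if (!any(sel)) NA_real_ else 100 * mean(bt$choice[sel] == "right")
    }
    data.frame(participant = p, pct_prev_right = pr("right"),
               pct_prev_left = pr("left"))
  })
  pp <- do.call(rbind, res)
  if (anyNA(pp[, -1]))
    warning("participant(s) without qualifying trials omitted from a branch")
  both <- stats::complete.cases(pp)
  tst <- function(x, f) if (length(x) >= 2) f(x) else NULL
  list(per_participant = pp,
       test_prev_right = tst(stats::na.omit(pp$pct_prev_right),
                             function(x) one_sample_t(x, 50)),
       test_prev_left = tst(stats::na.omit(pp$pct_prev_left),
                            function(x) one_sample_t(x, 50)),
       test_between = if (sum(both) >= 2)
         paired_t(pp$pct_prev_right[both], pp$pct_prev_left[both]))
}

#' Per-participant condition RT means from a behavior table
#'
#' Means of surviving trials (optionally respecting `rtcor_removed`) for
#' the four main cells, as the participants x 4 matrix [anova_2x2()] takes.
#'
#' @param table behavior table with flags applied.
#' @param use_rtcor drop `rtcor_removed` trials too (default FALSE).
#' @param right_only restrict to right-directed trials (default FALSE; the
#'   RT analysis of the full design uses all surviving trials).
#' @return matrix participants x c(InstructedEasy, InstructedHard,
#'   FreeEasy, FreeHard).
#' @export
condition_rt_means <- function(table, use_rtcor = FALSE, right_only = FALSE) {
  ignore <- if (use_rtcor) character() else "rtcor_removed"
  ignore <- c(ignore, if (right_only) character() else "left_directed")
  surv <- surviving(table, ignore = ignore)
  surv <- surv[surv$context %in% c("Instructed", "Free"), , drop = FALSE]
  cells <- c("InstructedEasy", "InstructedHard", "FreeEasy", "FreeHard")
  ids <- sort(unique(table$participant))
  out <- matrix(NA_real_, length(ids), 4, dimnames = list(ids, cells))
  cond <- paste0(surv$context, surv$difficulty)
  for (i in seq_along(ids)) for (j in seq_len(4)) {
    sel <- surv$participant == ids[i] & cond == cells[j]
    if (any(sel)) out[i, j] <- mean(surv$rt[sel])
  }
  out
}
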