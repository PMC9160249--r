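test_that("psychometric fit recovers symmetry and satisfies its invariant", {
  d <- data.frame(distance = c(5, 6, 7, 9, 10, 11),
                  n_right = c(2, 5, 8, 12, 15, 18), n_total = 20)
  ## counts symmetric around 8 cm (p and 1-p mirrored)
  fit <- fit_psychometric(d)
  expect_equal(fit$pse, 8, tolerance = 1e-6)
  expect_equal(predict(fit, fit$pse), 0.5, tolerance = 1e-12)
  ## monotone curve
  grid <- predict(fit, seq(4, 13, 0.5))
  expect_true(all(diff(grid) > 0))
})

test_that("ML fit agrees with a grid-search likelihood oracle on the 8x25 design", {
  set.seed(42)
  distances <- c(4, 6, 7, 8, 9, 10, 11, 13)
  p <- plogis(1.2 * (distances - 7.5))
  d <- data.frame(distance = distances,
                  n_right = rbinom(8, 25, p), n_total = 25)
  fit <- fit_psychometric(d)
  ## oracle: brute-force ML over a (pse, slope) grid on the same draws
  loglik <- function(pse, slope) {
    pr <- plogis(slope * (d$distance - pse))
    sum(dbinom(d$n_right, d$n_total, pr, log = TRUE))
  }
  pses <- seq(6, 9, by = 0.01); slopes <- seq(0.3, 3, by = 0.01)
  ll <- outer(pses, slopes, Vectorize(loglik))
  best <- which(ll == max(ll), arr.ind = TRUE)[1, ]
  expect_equal(fit$pse, pses[best[1]], tolerance = 0.02)
  expect_equal(fit$slope, slopes[best[2]], tolerance = 0.02)
})

test_that("perfectly separated choices yield a boundary fit", {
  all_right <- data.frame(distance = c(4, 8, 13), n_right = 10, n_total = 10)
  expect_warning(f <- fit_psychometric(all_right), "separated")
  expect_true(f$boundary)
  expect_false(is.finite(f$slope))
  step <- data.frame(distance = c(4, 6, 10, 13),
                     n_right = c(0, 0, 10, 10), n_total = 10)
  expect_warning(f2 <- fit_psychometric(step), "separated")
  expect_equal(f2$pse, 8) # midpoint of the bracketing distances 6 and 10
})

test_that("rejection flags follow the deadline, outlier and error rules", {
  tb <- toy_table(c(rep(500, 9), 850), context = "Instructed",
                  difficulty = "Easy")
  tb <- reject_trials(tb)
  expect_identical(grepl("aborted", tb$flags), tb$rt == 850)

  ## identical RTs: SD = 0, no outliers
  tb2 <- reject_trials(toy_table(rep(480, 12)))
  expect_false(any(grepl("rt_outlier", tb2$flags)))

  ## hand-computed outlier: 9 values tightly spread plus one extreme.
  rts <- c(496, 498, 499, 500, 500, 501, 502, 504, 500, 640)
  ## median 500, sd = sd(rts); only 640 exceeds median +/- 3 sd
  expect_identical(abs(rts - 500) > 3 * sd(rts),
                   rts == 640)
  tb3 <- reject_trials(toy_table(rts))
  expect_identical(grepl("rt_outlier", tb3$flags), rts == 640)

  ## instructed errors and left-directed movements
  tb4 <- toy_table(rep(500, 4), context = "Instructed", difficulty = "Hard")
  tb4$choice <- c("right", "left", "right", "left")
  tb4 <- reject_trials(tb4)
  expect_identical(grepl("instructed_error", tb4$flags),
                   tb4$choice != tb4$cue_direction)
  expect_identical(grepl("left_directed", tb4$flags), tb4$choice == "left")
})

test_that("rejection is idempotent and respects the preference-band rules", {
  cfg <- small_cfg(seed = 2, n_participants = 4)
  beh <- simulate_behavior(cfg)
  once <- reject_trials(beh)
  twice <- reject_trials(once)
  expect_identical(once$flags, twice$flags)

  ## participant whose PSE+4 preference is weak gets excluded entirely
  tb <- toy_table(rep(500, 20), difficulty = "Easy",
                  distance_cond = "PSE+4")
  tb$choice <- rep(c("right", "left"), 10) # 50% right at PSE+4
  tb <- reject_trials(tb)
  expect_true(all(grepl("participant_excluded", tb$flags)))

  ## Free-Hard position with an extreme preference is excluded
  tb2 <- rbind(toy_table(rep(500, 10), distance_cond = "PSE-0.5"),
               toy_table(rep(500, 10), distance_cond = "PSE"))
  tb2$trial_index <- seq_len(20)
  tb2$choice[1:10] <- "right"                      # 100% right at PSE-0.5
  tb2$choice[11:20] <- rep(c("right", "left"), 5)  # 50% at PSE
  tb2 <- reject_trials(tb2)
  expect_true(all(grepl("pse_band_excluded",
                        tb2$flags[tb2$distance_cond == "PSE-0.5"])))
  expect_false(any(grepl("pse_band_excluded",
                         tb2$flags[tb2$distance_cond == "PSE"])))
})

test_that("RTcorFree removes floor(0.25 n) trials from the correct tail", {
  ## boundary: exactly 30 trials -> untouched
  tb30 <- toy_table(seq(400, 690, by = 10), difficulty = "Easy")
  expect_false(any(grepl("rtcor_removed", rtcor_free(tb30)$flags)))

  ## Free Easy with 40 known RTs: the 10 largest go
  rts <- sample(seq(301, 700, by = 10))
  tb40 <- toy_table(rts, difficulty = "Easy")
  out <- rtcor_free(tb40)
  removed <- out$rt[grepl("rtcor_removed", out$flags)]
  expect_length(removed, 10)
  expect_setequal(removed, sort(rts, decreasing = TRUE)[1:10])
  kept_mean <- mean(out$rt[!grepl("rtcor_removed", out$flags)])
  expect_equal(kept_mean, mean(sort(rts)[1:30]))

  ## Free Hard with 32 trials: the 8 shortest go
  tb32 <- toy_table(sample(seq(400, 710, by = 10)), difficulty = "Hard")
  out32 <- rtcor_free(tb32)
  removed32 <- out32$rt[grepl("rtcor_removed", out32$flags)]
  expect_length(removed32, 8)
  expect_setequal(removed32, sort(tb32$rt)[1:8])

  ## Instructed conditions are never touched
  ti <- toy_table(seq(300, 700, length.out = 41), context = "Instructed",
                  difficulty = "Easy")
  expect_false(any(grepl("rtcor_removed", rtcor_free(ti)$flags)))
})

test_that("RT matching restores a Free Hard minus Free Easy separation", {
  cfg <- small_cfg(seed = 3, n_participants = 6,
                   trial_counts = list(
                     instructed = c(easy_right = 5, easy_left = 2,
                                    hard_right = 5, hard_left = 2),
                     free = c(pse_m4 = 2, pse_p4 = 45, pse_m05 = 15,
                              pse_0 = 15, pse_p05 = 15),
                     one_target = 2))
  beh <- rtcor_free(reject_trials(simulate_behavior(cfg)))
  pre <- condition_rt_means(beh, use_rtcor = FALSE, right_only = TRUE)
  post <- condition_rt_means(beh, use_rtcor = TRUE, right_only = TRUE)
  dpre <- mean(pre[, "FreeHard"] - pre[, "FreeEasy"], na.rm = TRUE)
  dpost <- mean(post[, "FreeHard"] - post[, "FreeEasy"], na.rm = TRUE)
  expect_gt(dpost, dpre)
})

test_that("the within-participant 2x2 ANOVA matches the textbook decomposition", {
  ## all cells identical: F = 0 for every effect
  flat <- matrix(5, nrow = 6, ncol = 4)
  expect_true(all(anova_2x2(flat)$F == 0))

  set.seed(7)
  cells <- matrix(rnorm(20, 500, 40), 5, 4)
  res <- anova_2x2(cells)
  ## oracle: full repeated-measures sums-of-squares via aov with an
  ## Error(participant) stratum
  long <- data.frame(
    y = as.vector(cells),
    s = factor(rep(1:5, 4)),
    A = factor(rep(c("a1", "a1", "a2", "a2"), each = 5)),
    B = factor(rep(c("b1", "b2", "b1", "b2"), each = 5)))
  fit <- summary(aov(y ~ A * B + Error(s / (A * B)), data = long))
  fs <- c(fit[["Error: s:A"]][[1]]["A", "F value"],
          fit[["Error: s:B"]][[1]]["B", "F value"],
          fit[["Error: s:A:B"]][[1]]["A:B", "F value"])
  ps <- c(fit[["Error: s:A"]][[1]]["A", "Pr(>F)"],
          fit[["Error: s:B"]][[1]]["B", "Pr(>F)"],
          fit[["Error: s:A:B"]][[1]]["A:B", "Pr(>F)"])
  expect_equal(res$F, fs, tolerance = 1e-9)
  expect_equal(res$p, ps, tolerance = 1e-9)
  ## eta_p from the same SS decomposition: F/(F + df_err)
  expect_equal(res$eta_p, fs / (fs + 4), tolerance = 1e-9)

  ## adding a per-participant constant to all four cells changes nothing
  shifted <- cells + rnorm(5) * 100
  expect_equal(anova_2x2(shifted)$F, res$F, tolerance = 1e-9)
})

test_that("the default RT structure yields the context x difficulty interaction", {
  ## difficulty slows Instructed (453 -> 495 ms) but barely Free
  ## (483 -> 486 ms): at the study's n the interaction is detected reliably
  for (seed in 1:3) {
    cfg <- sim_config(n_participants = 30, seed = 200 + seed)
    beh <- suppressWarnings(reject_trials(simulate_behavior(cfg)))
    an <- anova_2x2(condition_rt_means(beh))
    expect_lt(an$p[an$effect == "Interaction"], 0.05)
    expect_gt(an$eta_p[an$effect == "Interaction"], 0.5)
  }
})

test_that("paired t, Cohen's d and the t = d sqrt(n) identity are exact", {
  x <- rnorm(8, 500, 30); y <- x
  same <- paired_t(x, y)
  expect_equal(same$statistic, 0)
  expect_equal(same$d, 0)

  set.seed(9)
  y2 <- x + rnorm(8, 10, 20)
  res <- paired_t(x, y2, m = 4)
  expect_equal(res$statistic, res$d * sqrt(8), tolerance = 1e-12)
  oracle <- t.test(x, y2, paired = TRUE)
  expect_equal(res$statistic, unname(oracle$statistic), tolerance = 1e-9)
  expect_equal(res$p, oracle$p.value, tolerance = 1e-9)
  expect_equal(res$p_bonferroni, min(1, 4 * oracle$p.value))

  ## zero variance of differences with nonzero mean: infinite t
  inf <- paired_t(c(1, 2, 3), c(2, 3, 4))
  expect_true(is.infinite(inf$statistic))
  expect_equal(inf$p, 0)

  ## Bonferroni-corrected p can be exactly 1.0
  nearnull <- one_sample_t(c(-1, 1, -1, 1, 0.01), 0, m = 4)
  expect_equal(nearnull$p_bonferroni, 1.0)
})

test_that("choice history conditions on the immediately preceding trial", {
  ## strict alternation: every right choice follows a left one
  tb <- toy_table(rep(500, 12))
  tb$choice <- rep(c("left", "right"), 6)
  ch <- choice_history(tb)
  expect_equal(ch$per_participant$pct_prev_left, 100)
  expect_equal(ch$per_participant$pct_prev_right, 0)

  ## manual enumeration on a 12-trial sequence
  tb2 <- toy_table(rep(500, 12))
  tb2$choice <- c("right", "right", "left", "right", "right", "left",
                  "left", "right", "left", "right", "right", "right")
  ## prev=right at indices 2,3,5,6,9,11,12 -> right chosen at 2,5,11,12 (4/7)
  ## prev=left at indices 4,7,8,10 -> right chosen at 4,8,10 (3/4)
  ch2 <- choice_history(tb2)
  expect_equal(ch2$per_participant$pct_prev_right, 100 * 4 / 7)
  expect_equal(ch2$per_participant$pct_prev_left, 100 * 3 / 4)

  ## deterministic always-right chooser: defined branch at 100%, the
  ## prev=left branch has no qualifying trials
  tb3 <- toy_table(rep(500, 8))
  tb3$choice <- "right"
  expect_warning(ch3 <- choice_history(tb3), "omitted")
  expect_equal(ch3$per_participant$pct_prev_right, 100)
  expect_true(is.na(ch3$per_participant$pct_prev_left))
})
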