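test_that("correlation topography recovers exact and tied cases", {
  set.seed(1)
  drt <- c(10, 25, 5, 40, 30, 15)
  dp <- array(rnorm(6 * 3 * 5, sd = 0.1), c(6, 3, 5),
              dimnames = list(NULL, c("CP1", "CP3", "CPz"), NULL))
  dp[, 2, ] <- 0.01 * drt # exact proportionality at CP3
  cm <- correlation_topography(dp, drt)
  t2 <- cm$table[cm$table$electrode == "CP3", ]
  expect_true(all(t2$rho == 1))
  expect_true(all(abs(t2$r - 1) < 1e-12))
  expect_true("CP3" %in% cm$peak_electrodes)

  ## midrank (tied) Spearman against a hand computation
  x <- c(1, 2, 2, 4, 5)
  y <- c(2, 1, 4, 3, 5)
  dp5 <- array(0, c(5, 1, 1), dimnames = list(NULL, "Fz", NULL))
  dp5[, 1, 1] <- x
  cm5 <- correlation_topography(dp5, y)
  rx <- c(1, 2.5, 2.5, 4, 5) # midranks of x
  ry <- rank(y)
  byhand <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(cm5$table$rho, byhand, tolerance = 1e-12)

  ## antisymmetry under sign flip of the power differences
  cm_neg <- correlation_topography(-dp, drt)
  expect_equal(cm_neg$table$rho, -cm$table$rho, tolerance = 1e-12)
  expect_equal(cm_neg$table$r, -cm$table$r, tolerance = 1e-12)

  ## zero variance is reported as missing, not an error
  dp0 <- dp; dp0[, 1, ] <- 3
  cm0 <- correlation_topography(dp0, drt)
  expect_true(all(is.na(cm0$table$rho[cm0$table$electrode == "CP1"])))

  ## peak selection is covariant under electrode relabelling
  perm <- c(3, 1, 2)
  dp_perm <- dp[, perm, ]
  dimnames(dp_perm)[[2]] <- dimnames(dp)[[2]][perm]
  cm_perm <- correlation_topography(dp_perm, drt)
  expect_setequal(cm_perm$peak_electrodes, cm$peak_electrodes)

  expect_error(correlation_topography(dp[1:4, , ], drt[1:4]), "at least 5")
})

test_that("Spearman coefficients are invariant to monotone transforms", {
  set.seed(8)
  drt <- rnorm(10)
  dp <- array(rexp(10 * 2 * 3), c(10, 2, 3),
              dimnames = list(NULL, c("a", "b"), NULL))
  cm <- correlation_topography(dp, drt)
  cm_t <- correlation_topography(dp^3, exp(drt))
  expect_equal(cm_t$table$rho, cm$table$rho, tolerance = 1e-12)
})

test_that("the trial-level mixed model degrades gracefully and recovers truth", {
  ## zero between-participant variance: singular fit falls back to OLS
  d0 <- simulate_roi_trials(n_participants = 10, trials_per_participant = 20,
                            sigma_u = 0, sigma_e = 0.3, seed = 2)
  expect_warning(g0 <- fit_power_glmm(d0), "singular")
  ols <- lm(power ~ context * difficulty + rt, data = d0)
  expect_equal(unname(fitted(g0$model)), unname(fitted(ols)),
               tolerance = 1e-6)

  ## planted RT coupling with no factor effects: only RT comes out
  hits_rt <- 0; hits_factor <- 0
  for (s in 1:5) {
    d <- simulate_roi_trials(
      n_participants = 20, trials_per_participant = 40,
      beta = c(intercept = 0.2, context = 0, difficulty = 0,
               interaction = 0, rt = -1.0),
      sigma_u = 0.1, sigma_e = 0.25, seed = 100 + s)
    tab <- fit_power_glmm(d)$table
    hits_rt <- hits_rt + (tab$p[tab$effect == "rt_c"] < 0.05)
    hits_factor <- hits_factor +
      any(tab$p[tab$effect %in% c("context", "difficulty")] < 0.05)
  }
  expect_equal(hits_rt, 5)
  expect_lt(hits_factor, 3)
})

test_that("GLMM F for a balanced factor equals the paired-contrast t squared", {
  ## no covariate, no random-slope terms, balanced cells
  d <- simulate_roi_trials(n_participants = 12, trials_per_participant = 40,
                           beta = c(intercept = 0, context = 0.2,
                                    difficulty = 0, interaction = 0, rt = 0),
                           sigma_u = 0.2, sigma_e = 0.3, seed = 9)
  opts <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(opts))
  ## on participant x context cell means the REML residual is exactly half
  ## the variance of the paired differences, so F = t^2 holds exactly
  agg <- aggregate(power ~ participant + context, d, mean)
  agg$context <- factor(agg$context)
  agg$participant <- factor(agg$participant)
  fit <- lmerTest::lmer(power ~ context + (1 | participant), data = agg)
  an <- anova(fit, type = 3)
  wide <- reshape(agg, idvar = "participant", timevar = "context",
                  direction = "wide")
  tt <- paired_t(wide$power.Instructed, wide$power.Free)
  expect_equal(an["context", "F value"], tt$statistic^2, tolerance = 1e-6)
  expect_equal(an["context", "DenDF"], tt$df, tolerance = 1e-6)
})

test_that("pattern x context control ANOVA matches the SS oracle", {
  roi <- expand.grid(participant = 1:6,
                     pattern = c("theta", "beta"),
                     context = c("Instructed", "Free"),
                     stringsAsFactors = FALSE)
  flat <- transform(roi, value = 1)
  expect_true(all(pattern_context_anova(flat)$anova$F == 0))

  set.seed(4)
  roi$value <- rnorm(nrow(roi))
  res <- pattern_context_anova(roi)
  long <- transform(roi, s = factor(participant), A = factor(pattern),
                    B = factor(context))
  fit <- summary(aov(value ~ A * B + Error(s / (A * B)), data = long))
  fs <- c(fit[["Error: s:A"]][[1]]["A", "F value"],
          fit[["Error: s:B"]][[1]]["B", "F value"],
          fit[["Error: s:A:B"]][[1]]["A:B", "F value"])
  expect_equal(res$anova$F, fs, tolerance = 1e-9)
  expect_length(res$posthoc, 2)

  expect_error(pattern_context_anova(roi[-1, ]), "one-target")
})
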