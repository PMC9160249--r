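#' Windowed correlation topography between power and RT differences
#'
#' Across participants, Spearman and Pearson correlations between the
#' difficulty-related change in band power (Hard - Easy within a context)
#' and the matching change in RT, per electrode and 100-ms window over the
#' period of interest. The peak electrode set is the `n_peak` electrodes
#' with the highest |rho| averaged over windows (ties broken by label
#' order). Zero variance in either variable leaves the coefficient missing.
#'
#' @param delta_power array participants x electrodes x windows (channel
#'   dimnames required).
#' @param delta_rt per-participant RT difference (same participant order).
#' @param n_peak size of the peak electrode set (default 3).
#' @return object of class `correlation_map`: data.frame `table`
#'   (electrode, window, rho, p_rho, r, p_r) and `peak_electrodes`.
#' @export
correlation_topography <- function(delta_power, delta_rt, n_peak = 3) {
  stopifnot(length(dim(delta_power)) == 3,
            dim(delta_power)[1] == length(delta_rt))
  if (length(delta_rt) < 5) stop("need at least 5 participants")
  electrodes <- dimnames(delta_power)[[2]]
  if (is.null(electrodes)) stop("delta_power lacks electrode dimnames")
  nw <- dim(delta_power)[3]
  rows <- list()
  for (e in seq_along(electrodes)) for (w in seq_len(nw)) {
    x <- delta_power[, e, w]
    y <- delta_rt
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      rows[[length(rows) + 1]] <- data.frame(
        electrode = electrodes[e], window = w, rho = NA_real_,
        p_rho = NA_real_, r = NA_real_, p_r = NA_real_)
      next
    }
    sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                           exact = FALSE))
    pe <- stats::cor.test(x, y, method = "pearson")
    rows[[length(rows) + 1]] <- data.frame(
      electrode = electrodes[e], window = w,
      rho = unname(sp$estimate), p_rho = sp$p.value,
      r = unname(pe$estimate), p_r = pe$p.value)
  }
  tab <- do.call(rbind, rows)
  mean_abs <- tapply(abs(tab$rho), tab$electrode, mean)
  mean_abs <- mean_abs[electrodes] # restore montage order
  ord <- order(-mean_abs, names(mean_abs), na.last = TRUE)
  peak <- sort(names(mean_abs)[ord[seq_len(min(n_peak, length(ord)))]])
  structure(list(table = tab, peak_electrodes = peak, n_peak = n_peak),
            class = "correlation_map")
}

#' @export
print.correlation_map <- function(x, ...) {
  cat(sprintf("<correlation_map> %d electrodes x %d windows; peak: %s\n",
              length(unique(x$table$electrode)), max(x$table$window),
              paste(x$peak_electrodes, collapse = ", ")))
  invisible(x)
}

#' Trial-level linear mixed model of ROI power
#'
#' Gaussian linear mixed model of baseline-normalised ROI power with
#' Context, Difficulty, their interaction and RT (seconds, centred) as
#' fixed effects and a participant random intercept, fitted by REML via
#' lme4 with Satterthwaite F-tests (lmerTest, type III, sum contrasts). A
#' singular random-intercept fit falls back to the fixed-intercept linear
#' model with a warning (F-tests then via the same type-III contrasts).
#'
#' @param trials data.frame with columns `power`, `context`, `difficulty`,
#'   `rt` (seconds or ms; values above 10 are treated as ms and converted)
#'   and `participant`.
#' @return list of class `power_glmm`: `table` (effect, F, df1, df2, p),
#'   `model`, `singular`.
#' @export
fit_power_glmm <- function(trials) {
  need <- c("power", "context", "difficulty", "rt", "participant")
  stopifnot(all(need %in% names(trials)))
  d <- trials
  if (stats::median(d$rt) > 10) d$rt <- d$rt / 1000
  d$context <- factor(d$context)
  d$difficulty <- factor(d$difficulty)
  d$participant <- factor(d$participant)
  d$rt_c <- d$rt - mean(d$rt)
  opts <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(opts))
  fit <- lmerTest::lmer(power ~ context * difficulty + rt_c +
                          (1 | participant), data = d, REML = TRUE)
  singular <- lme4::isSingular(fit)
  if (singular) {
    warning("singular random-intercept variance; falling back to a fixed-intercept model")
    lmfit <- stats::lm(power ~ context * difficulty + rt_c, data = d)
    an <- stats::drop1(lmfit, scope = ~ ., test = "F")
    an <- an[-1, , drop = FALSE]
    tab <- data.frame(effect = rownames(an), F = an[["F value"]],
                      df1 = an$Df, df2 = stats::df.residual(lmfit),
                      p = an[["Pr(>F)"]])
    model <- lmfit
  } else {
    an <- stats::anova(fit, type = 3)
    tab <- data.frame(effect = rownames(an), F = an[["F value"]],
                      df1 = an$NumDF, df2 = an$DenDF, p = an[["Pr(>F)"]])
    model <- fit
  }
  rownames(tab) <- NULL
  structure(list(table = tab, model = model, singular = singular),
            class = "power_glmm")
}

#' @export
print.power_glmm <- function(x, ...) {
  cat("<power_glmm>", if (x$singular) "(singular fallback)" else "", "\n")
  print(transform(x$table, F = round(F, 2), df2 = round(df2, 1),
                  p = signif(p, 3)), row.names = FALSE)
  invisible(x)
}

#' Activity-pattern x Context control ANOVA
#'
#' Within-participant 2x2 ANOVA of ROI power (expressed relative to
#' one-target control trials) with factors activity pattern (midfrontal
#' theta vs sensorimotor beta) and Context (Instructed vs Free), via the
#' same paired-contrast machinery as the RT ANOVA, followed by
#' Bonferroni-corrected paired t-tests of Instructed vs Free within each
#' pattern.
#'
#' @param roi data.frame with columns `participant`, `pattern` (two
#'   levels), `context` (two levels), `value` (choice-minus-one-target ROI
#'   power). Every participant needs all four cells.
#' @param m Bonferroni family size for the post-hocs (default 2, one test
#'   per pattern).
#' @return list: `anova` (effects table), `posthoc` (named `stat_result`s).
#' @export
pattern_context_anova <- function(roi, m = 2) {
  need <- c("participant", "pattern", "context", "value")
  stopifnot(all(need %in% names(roi)))
  pats <- sort(unique(roi$pattern)); ctxs <- sort(unique(roi$context))
  if (length(pats) != 2 || length(ctxs) != 2)
    stop("pattern and context must each have exactly two levels")
  ids <- unique(roi$participant)
  cells <- matrix(NA_real_, length(ids), 4)
  k <- 0
  for (pa in pats) for (cx in ctxs) {
    k <- k + 1
    v <- roi$value[roi$pattern == pa & roi$context == cx]
    idx <- match(roi$participant[roi$pattern == pa & roi$context == cx], ids)
    cells[idx, k] <- v
  }
  if (anyNA(cells)) stop("missing pattern x context cell(s); the control contrast needs the one-target condition for every participant")
  an <- anova_2x2(cells, effects = c("Pattern", "Context", "Interaction"))
  post <- list()
  for (pa in pats) {
    a <- cells[, which(pats == pa) * 2 - 1]
    b <- cells[, which(pats == pa) * 2]
    post[[paste0(pa, ": ", ctxs[1], " vs ", ctxs[2])]] <- paired_t(a, b, m)
  }
  list(anova = an, posthoc = post)
}
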