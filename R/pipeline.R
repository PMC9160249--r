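#' Run configuration
#'
#' One structured document collecting every parameter of the pipeline:
#' the generator settings (`sim`), the time-frequency settings (`tfr`) and
#' the analysis settings (`analysis`), plus the master `seed`. Defaults
#' reproduce the design constants exactly: 800-ms deadline, 4-cm neighbour
#' threshold, 1000 permutations, theta 4-8 Hz on stimulus-locked 0 to 0.5 s
#' (baseline -0.5 to 0 s), beta 15-30 Hz on movement-locked -0.5 to 0 s
#' (baseline -1.3 to -0.8 s). Unknown keys anywhere in the overrides are a
#' hard error, listing the offending names.
#'
#' @param overrides named list (possibly nested) of values to change, or a
#'   path to a YAML file of the same shape.
#' @return object of class `run_config` with a `config_hash` attribute
#'   recorded in every artifact.
#' @export
run_config <- function(overrides = list()) {
  if (is.character(overrides)) overrides <- yaml::read_yaml(overrides)
  defaults <- list(
    seed = 1L,
    sim = formals_defaults(sim_config),
    tfr = list(band_theta = c(4, 8), band_beta = c(15, 30),
               poi = list(stimulus = c(0, 0.5), movement = c(-0.5, 0)),
               baseline = list(stimulus = c(-0.5, 0),
                               movement = c(-1.3, -0.8))),
    analysis = list(alpha_form = 0.05, n_perm = 1000,
                    neighbor_threshold_cm = 4, min_electrodes = 2,
                    max_type = "joint", bonferroni_m = 4, n_peak = 3,
                    analysis_sfreq = 250, preprocess = TRUE,
                    montage = "default", use_rtcor = FALSE,
                    roi_theta = list(channels = c("Fz", "F1", "F2"),
                                     window = c(0.3, 0.5)),
                    roi_beta = list(channels = c("C1", "C3", "Cz", "FC1",
                                                 "CP1"),
                                    window = c(-0.4, -0.2))))
  cfg <- merge_config(defaults, overrides, path = "")
  ## the generator follows the master seed unless explicitly overridden
  if (!(is.list(overrides$sim) && !is.null(overrides$sim$seed)))
    cfg$sim$seed <- cfg$seed
  attr(cfg, "config_hash") <- config_hash(cfg)
  structure(cfg, class = "run_config")
}

formals_defaults <- function(fn) {
  fl <- formals(fn)
  lapply(fl, function(x) eval(x, envir = asNamespace("choiceEEG")))
}

merge_config <- function(defaults, overrides, path) {
  if (!length(overrides)) return(defaults)
  bad <- setdiff(names(overrides), names(defaults))
  if (length(bad))
    stop("unknown config key(s): ",
         paste(paste0(sub("^\\.", "", paste0(path, ".", bad))), collapse = ", "))
  for (nm in names(overrides)) {
    if (is.list(defaults[[nm]]) && is.list(overrides[[nm]]) &&
        !is.null(names(defaults[[nm]])))
      defaults[[nm]] <- merge_config(defaults[[nm]], overrides[[nm]],
                                     paste0(path, ".", nm))
    else defaults[[nm]] <- overrides[[nm]]
  }
  defaults
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> hash %s, seed %d, %d participants\n",
              attr(x, "config_hash"), x$seed, x$sim$n_participants))
  invisible(x)
}

# 32-bit FNV-1a over the deparsed configuration, carried as 16-bit halves
# to stay inside exact double arithmetic
config_hash <- function(cfg) {
  s <- paste(deparse(unclass(cfg)), collapse = "\n")
  bytes <- utf8ToInt(s)
  hi <- 33052; lo <- 40389 # 0x811C9DC5
  for (b in bytes) {
    lo <- bitwXor(lo, b)
    res <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 2^32
    hi <- res %/% 65536; lo <- res %% 65536
  }
  sprintf("%04x%04x", hi, lo)
}

sim_config_from <- function(cfg) {
  do.call(sim_config, cfg$sim)
}

tfr_spec_from <- function(cfg) {
  tfr_spec(band_theta = cfg$tfr$band_theta, band_beta = cfg$tfr$band_beta,
           poi = cfg$tfr$poi, baseline = cfg$tfr$baseline)
}

montage_from <- function(cfg) {
  switch(cfg$analysis$montage,
         default = default_montage(),
         reduced = reduced_montage(),
         read_montage(cfg$analysis$montage))
}

#' Behavior table TSV round-trip
#'
#' One row per trial, flags as semicolon-separated tokens (empty string =
#' no flag).
#' @param table behavior data.frame.
#' @param path TSV path.
#' @export
write_behavior <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_behavior
#' @export
read_behavior <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "NA")
  df$flags[is.na(df$flags)] <- ""
  df$flags <- as.character(df$flags)
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

artifact <- function(out_dir, name) file.path(out_dir, name)

require_artifact <- function(out_dir, name, producer) {
  p <- artifact(out_dir, name)
  if (!file.exists(p))
    stop(sprintf("missing artifact '%s'; run the '%s' subcommand first",
                 name, producer), call. = FALSE)
  p
}

#' Run the analysis pipeline
#'
#' Orchestrates generator, behavioral statistics, time-frequency
#' extraction, cluster permutation contrasts, correlation topographies and
#' trial-level mixed models, writing TSV/RDS+JSON artifacts into `out_dir`.
#' Every artifact records the configuration hash and master seed; the run
#' manifest also logs trial counts surviving each rejection rule in the
#' order applied. Stage `"all"` runs everything in order.
#'
#' @param cfg a [run_config()] (or overrides list passed to it).
#' @param out_dir output directory (created if needed).
#' @param stages character vector among "simulate", "behavior", "tfr",
#'   "cluster", "correlate", "glmm", "report", or "all".
#' @return invisibly, the output directory.
#' @export
run_pipeline <- function(cfg = run_config(), out_dir, stages = "all") {
  if (!inherits(cfg, "run_config")) cfg <- run_config(cfg)
  all_stages <- c("simulate", "behavior", "tfr", "cluster", "correlate",
                  "glmm", "report")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (st in stages)
    switch(st,
           simulate = stage_simulate(cfg, out_dir),
           behavior = stage_behavior(cfg, out_dir),
           tfr = stage_tfr(cfg, out_dir),
           cluster = stage_cluster(cfg, out_dir),
           correlate = stage_correlate(cfg, out_dir),
           glmm = stage_glmm(cfg, out_dir),
           report = stage_report(cfg, out_dir))
  invisible(out_dir)
}

stage_simulate <- function(cfg, out_dir) {
  simcfg <- sim_config_from(cfg)
  if (simcfg$n_participants < 3)
    warning("n_participants < 3: simulation artifacts are valid but inferential stages need n >= 3")
  beh <- simulate_behavior(simcfg)
  write_behavior(beh, artifact(out_dir, "behavior.tsv"))
  write_tsv(data.frame(participant = seq_along(attr(beh, "pse")),
                       pse_true = attr(beh, "pse")),
            artifact(out_dir, "pse_true.tsv"))
  prel <- simulate_preliminary(simcfg)
  write_tsv(prel, artifact(out_dir, "preliminary.tsv"))
  write_montage(montage_from(cfg), artifact(out_dir, "montage.tsv"))
  invisible(NULL)
}

stage_behavior <- function(cfg, out_dir) {
  beh <- read_behavior(require_artifact(out_dir, "behavior.tsv", "simulate"))
  simcfg <- sim_config_from(cfg)
  beh <- reject_trials(beh, rt_deadline = simcfg$rt_deadline)
  beh <- rtcor_free(beh)
  write_behavior(beh, artifact(out_dir, "behavior_flagged.tsv"))

  prel <- utils::read.table(require_artifact(out_dir, "preliminary.tsv",
                                             "simulate"),
                            sep = "\t", header = TRUE)
  fits <- do.call(rbind, lapply(split(prel, prel$participant), function(d) {
    f <- fit_psychometric(d)
    data.frame(participant = d$participant[1], pse = f$pse, slope = f$slope,
               boundary = f$boundary)
  }))
  write_tsv(fits, artifact(out_dir, "pse_fits.tsv"))

  cells <- condition_rt_means(beh)
  if (sum(stats::complete.cases(cells)) >= 3) {
    an <- anova_2x2(cells)
    write_tsv(an, artifact(out_dir, "rt_anova.tsv"))
    m <- cfg$analysis$bonferroni_m
    cc <- cells[stats::complete.cases(cells), , drop = FALSE]
    ph <- rbind(
      posthoc_row("InstructedHard_vs_InstructedEasy",
                  paired_t(cc[, "InstructedHard"], cc[, "InstructedEasy"], m)),
      posthoc_row("FreeHard_vs_FreeEasy",
                  paired_t(cc[, "FreeHard"], cc[, "FreeEasy"], m)),
      posthoc_row("InstructedHard_vs_FreeHard",
                  paired_t(cc[, "InstructedHard"], cc[, "FreeHard"], m)),
      posthoc_row("InstructedEasy_vs_FreeEasy",
                  paired_t(cc[, "InstructedEasy"], cc[, "FreeEasy"], m)))
    write_tsv(ph, artifact(out_dir, "rt_posthoc.tsv"))
  }
  ch <- choice_history(beh)
  write_tsv(ch$per_participant, artifact(out_dir, "choice_history.tsv"))
  invisible(NULL)
}

posthoc_row <- function(name, tt) {
  data.frame(comparison = name, t = tt$statistic, df = tt$df, p = tt$p,
             p_bonferroni = tt$p_bonferroni, d = tt$d)
}

# per-participant condition-averaged, baseline-normalised, band-averaged
# power maps plus trial-level ROI scalars
stage_tfr <- function(cfg, out_dir) {
  beh <- read_behavior(require_artifact(out_dir, "behavior_flagged.tsv",
                                        "behavior"))
  mont <- read_montage(require_artifact(out_dir, "montage.tsv", "simulate"))
  simcfg <- sim_config_from(cfg)
  spec <- tfr_spec_from(cfg)
  factor <- simcfg$sfreq / cfg$analysis$analysis_sfreq
  if (factor != round(factor))
    stop("sfreq must be an integer multiple of analysis_sfreq")

  message("artifact removal (ICA) is not part of this pipeline; stage skipped")
  elig <- surviving(beh, ignore = "rtcor_removed")
  elig <- elig[elig$choice == "right", , drop = FALSE]
  ids <- sort(unique(elig$participant))
  bands <- list(theta = list(lock = "stimulus", band = spec$band_theta,
                             roi = cfg$analysis$roi_theta),
                beta = list(lock = "movement", band = spec$band_beta,
                            roi = cfg$analysis$roi_beta))
  conds <- c("InstructedEasy", "InstructedHard", "FreeEasy", "FreeHard",
             "OneTarget")
  maps <- list(); times <- list(); roi_rows <- list()
  for (bn in names(bands)) maps[[bn]] <- list()

  for (pi in seq_along(ids)) {
    p <- ids[pi]
    btp <- elig[elig$participant == p, , drop = FALSE]
    ep <- simulate_epochs(simcfg, btp, mont,
                          lock = c("stimulus", "movement"), participants = p)
    for (lk in names(ep)) {
      x <- ep[[lk]]
      if (isTRUE(cfg$analysis$preprocess)) {
        if (simcfg$sfreq > 252) x <- bandpass_notch(x, x$sfreq)
        x <- rereference_average(x)
        x <- surface_laplacian(x, mont)
      }
      ep[[lk]] <- downsample(x, factor)
    }
    meta <- ep[[1]]$trial_meta
    cond <- ifelse(meta$context == "OneTarget", "OneTarget",
                   paste0(meta$context, meta$difficulty))
    for (bn in names(bands)) {
      bd <- bands[[bn]]
      x <- ep[[bd$lock]]
      tax <- epoch_times(x)
      fint <- seq(bd$band[1], bd$band[2])
      pw <- morlet_power(x, spec, freqs = fint)
      bwin <- spec$baseline[[bd$lock]]
      bsel <- tax >= bwin[1] & tax < bwin[2]
      poi <- spec$poi[[bd$lock]]
      psel <- tax >= poi[1] & tax < poi[2]
      for (cn in conds) {
        tsel <- which(cond == cn)
        use_rt <- tsel
        if (isTRUE(cfg$analysis$use_rtcor))
          use_rt <- tsel[!has_flag(meta$flags[tsel], "rtcor_removed")]
        if (!length(use_rt)) next
        avg <- apply(pw[use_rt, , , , drop = FALSE], c(2, 3, 4), mean)
        B <- apply(avg[, , bsel, drop = FALSE], c(1, 2), mean)
        rel <- (avg - as.vector(B)) / as.vector(B)
        bandavg <- apply(rel, c(1, 3), mean) # channels x time
        if (is.null(maps[[bn]][[cn]]))
          maps[[bn]][[cn]] <- array(NA_real_,
                                    c(length(ids), nrow(bandavg), sum(psel)),
                                    dimnames = list(ids, mont$names, NULL))
        maps[[bn]][[cn]][pi, , ] <- bandavg[, psel]
        ## trial-level ROI scalars, normalised by the condition baseline
        for (i in tsel) {
          reli <- (pw[i, , , ] - as.vector(B)) / as.vector(B)
          bi <- apply(reli, c(1, 3), mean)
          dimnames(bi) <- list(mont$names, NULL)
          roi_rows[[length(roi_rows) + 1]] <- data.frame(
            participant = p, band = bn, condition = cn,
            context = meta$context[i], difficulty = meta$difficulty[i],
            rt = meta$rt[i], trial_index = meta$trial_index[i],
            rtcor_removed = has_flag(meta$flags[i], "rtcor_removed"),
            power = extract_roi(array(bi, c(1, dim(bi)),
                                      dimnames = c(list(NULL),
                                                   dimnames(bi))),
                                bd$roi$channels, tax, bd$roi$window))
        }
      }
      times[[bn]] <- tax[psel]
    }
  }
  saveRDS(maps, artifact(out_dir, "maps.rds"))
  jsonlite::write_json(
    list(config_hash = attr(cfg, "config_hash"), seed = cfg$seed,
         participants = ids, times = times,
         bands = lapply(bands, function(b) b[c("lock", "band")])),
    artifact(out_dir, "maps.json"), auto_unbox = TRUE, digits = NA)
  write_tsv(do.call(rbind, roi_rows), artifact(out_dir, "roi_trials.tsv"))
  invisible(NULL)
}

stage_cluster <- function(cfg, out_dir) {
  maps <- readRDS(require_artifact(out_dir, "maps.rds", "tfr"))
  meta <- jsonlite::read_json(artifact(out_dir, "maps.json"),
                              simplifyVector = TRUE)
  mont <- read_montage(require_artifact(out_dir, "montage.tsv", "simulate"))
  graph <- build_neighbors(mont, cfg$analysis$neighbor_threshold_cm)
  for (bn in names(maps)) {
    ## only participants with all four choice conditions enter the contrasts
    need <- c("InstructedEasy", "InstructedHard", "FreeEasy", "FreeHard")
    have <- intersect(need, names(Filter(Negate(is.null), maps[[bn]])))
    ok <- Reduce(`&`, lapply(maps[[bn]][have], function(a)
      stats::complete.cases(a[, 1, ])))
    if (sum(ok) < 3) {
      warning("fewer than 3 participants with complete ", bn,
              " maps; skipping cluster contrasts for this band")
      next
    }
    mm <- lapply(maps[[bn]][have], function(a) a[ok, , , drop = FALSE])
    res <- run_contrasts(mm, graph, n_perm = cfg$analysis$n_perm,
                         seed = cfg$seed + 100 * match(bn, names(maps)),
                         alpha_form = cfg$analysis$alpha_form,
                         min_electrodes = cfg$analysis$min_electrodes,
                         max_type = cfg$analysis$max_type,
                         times = meta$times[[bn]])
    write_cluster_report(res, artifact(out_dir,
                                       paste0("clusters_", bn, ".tsv")))
  }
  invisible(NULL)
}

stage_correlate <- function(cfg, out_dir) {
  maps <- readRDS(require_artifact(out_dir, "maps.rds", "tfr"))
  meta <- jsonlite::read_json(artifact(out_dir, "maps.json"),
                              simplifyVector = TRUE)
  beh <- read_behavior(require_artifact(out_dir, "behavior_flagged.tsv",
                                        "behavior"))
  cells <- condition_rt_means(beh, use_rtcor = isTRUE(cfg$analysis$use_rtcor),
                              right_only = TRUE)
  cells <- cells[rownames(cells) %in% meta$participants, , drop = FALSE]
  for (bn in names(maps)) {
    tax <- meta$times[[bn]]
    for (ctx in c("Instructed", "Free")) {
      hard <- maps[[bn]][[paste0(ctx, "Hard")]]
      easy <- maps[[bn]][[paste0(ctx, "Easy")]]
      if (is.null(hard) || is.null(easy)) next
      dp <- window_average(hard - easy, tax, 0.1)
      drt <- cells[, paste0(ctx, "Hard")] - cells[, paste0(ctx, "Easy")]
      ok <- stats::complete.cases(dp[, 1, ]) & !is.na(drt)
      if (sum(ok) < 5) next
      cm <- correlation_topography(dp[ok, , , drop = FALSE], drt[ok],
                                   n_peak = cfg$analysis$n_peak)
      out <- cm$table
      out$peak <- out$electrode %in% cm$peak_electrodes
      write_tsv(out, artifact(out_dir,
                              sprintf("correlation_%s_%s.tsv", bn,
                                      tolower(ctx))))
    }
  }
  invisible(NULL)
}

# average a participant x channel x time array into consecutive windows of
# the given width (s)
window_average <- function(x, times, width) {
  breaks <- seq(times[1], times[length(times)] + 1e-9, by = width)
  nw <- length(breaks) - 1
  out <- array(NA_real_, c(dim(x)[1], dim(x)[2], nw),
               dimnames = c(dimnames(x)[1:2], list(NULL)))
  for (w in seq_len(nw)) {
    sel <- times >= breaks[w] & times < breaks[w + 1]
    out[, , w] <- apply(x[, , sel, drop = FALSE], c(1, 2), mean)
  }
  out
}

stage_glmm <- function(cfg, out_dir) {
  roi <- utils::read.table(require_artifact(out_dir, "roi_trials.tsv", "tfr"),
                           sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  choice <- roi[roi$condition != "OneTarget", , drop = FALSE]
  if (isTRUE(cfg$analysis$use_rtcor))
    choice <- choice[!choice$rtcor_removed, , drop = FALSE]
  for (bn in unique(choice$band)) {
    d <- choice[choice$band == bn, , drop = FALSE]
    g <- fit_power_glmm(d)
    write_tsv(g$table, artifact(out_dir, paste0("glmm_", bn, ".tsv")))
  }
  ## pattern x context control analysis against one-target trials
  agg <- stats::aggregate(power ~ participant + band + condition, roi, mean)
  ctrl <- list()
  for (bn in unique(agg$band)) {
    a <- agg[agg$band == bn, ]
    ot <- a$power[a$condition == "OneTarget"][match(unique(a$participant),
      a$participant[a$condition == "OneTarget"])]
    names(ot) <- unique(a$participant)
    for (ctx in c("Instructed", "Free")) {
      ch <- a[a$condition == paste0(ctx, "Hard"), ]
      if (!nrow(ch)) next
      ctrl[[length(ctrl) + 1]] <- data.frame(
        participant = ch$participant, pattern = bn, context = ctx,
        value = ch$power - ot[as.character(ch$participant)])
    }
  }
  ctrl <- do.call(rbind, ctrl)
  if (!is.null(ctrl) && !anyNA(ctrl$value) &&
      length(unique(ctrl$pattern)) == 2) {
    pc <- try(pattern_context_anova(ctrl), silent = TRUE)
    if (!inherits(pc, "try-error"))
      write_tsv(pc$anova, artifact(out_dir, "pattern_context_anova.tsv"))
  }
  invisible(NULL)
}

stage_report <- function(cfg, out_dir) {
  beh <- read_behavior(require_artifact(out_dir, "behavior_flagged.tsv",
                                        "behavior"))
  order_applied <- c("aborted", "rt_outlier", "missed", "instructed_error",
                     "left_directed", "pse_band_excluded",
                     "participant_excluded", "rtcor_removed")
  remaining <- integer(0)
  alive <- rep(TRUE, nrow(beh))
  counts <- list(total = nrow(beh))
  for (tk in order_applied) {
    alive <- alive & !has_flag(beh$flags, tk)
    counts[[paste0("after_", tk)]] <- sum(alive)
  }
  manifest <- list(config_hash = attr(cfg, "config_hash"), seed = cfg$seed,
                   n_participants = length(unique(beh$participant)),
                   rejection_counts = counts,
                   artifacts = list.files(out_dir))
  jsonlite::write_json(manifest, artifact(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

#' Command-line entry point
#'
#' Thin argument parser over [run_pipeline()]:
#' `choiceEEG <subcommand> --config <yaml> --out <dir> [--seed <int>]` with
#' subcommands simulate, behavior, tfr, cluster, correlate, glmm, report,
#' all. An `Rscript` wrapper is installed under `inst/cli/`.
#'
#' @param args character vector (default `commandArgs(trailingOnly=TRUE)`).
#' @return exit status, invisibly (0 on success).
#' @export
pipeline_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: choiceEEG <subcommand> [--config file.yaml] --out dir [--seed int]")
    return(invisible(1L))
  }
  sub <- args[1]
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i)) args[i + 1] else default
  }
  overrides <- list()
  cfgfile <- opt("--config")
  if (!is.null(cfgfile)) overrides <- yaml::read_yaml(cfgfile)
  seed <- opt("--seed")
  if (!is.null(seed)) {
    overrides$seed <- as.integer(seed)
    overrides$sim <- c(overrides$sim %||% list(),
                       list(seed = as.integer(seed)))
  }
  out <- opt("--out")
  if (is.null(out)) stop("--out is required")
  cfg <- run_config(overrides)
  run_pipeline(cfg, out, stages = sub)
  invisible(0L)
}
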