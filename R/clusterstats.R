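#' Point-wise paired t-map over channel x time
#'
#' Paired t statistics across participants at every (channel, time) point of
#' two participant x channel x time arrays, with the cluster-forming mask at
#' a two-sided threshold. Degenerate points (zero variance of the paired
#' differences) give t = +-Inf, clamped to +-1e12 so cluster masses stay
#' finite; a zero difference with zero variance gives t = 0.
#'
#' @param a,b numeric arrays, participants x channels x time, same shape and
#'   participant order.
#' @param alpha_form two-sided cluster-forming alpha (default 0.05).
#' @return list with `t_map` (channels x time), `mask` (logical),
#'   `df`, `t_crit`.
#' @export
pointwise_paired_t <- function(a, b, alpha_form = 0.05) {
  stopifnot(identical(dim(a), dim(b)), length(dim(a)) == 3)
  n <- dim(a)[1]
  if (n < 3) stop("need at least 3 participants for the paired t-map")
  D <- matrix(a - b, nrow = n)
  mu <- colMeans(D)
  v <- (colSums(D^2) - n * mu^2) / (n - 1)
  v[v < 0] <- 0
  t <- ifelse(v == 0, ifelse(mu == 0, 0, sign(mu) * 1e12),
              mu / sqrt(v / n))
  t <- pmin(pmax(t, -1e12), 1e12)
  t_map <- matrix(t, dim(a)[2], dim(a)[3],
                  dimnames = list(dimnames(a)[[2]], NULL))
  t_crit <- stats::qt(1 - alpha_form / 2, n - 1)
  list(t_map = t_map, mask = abs(t_map) > t_crit, df = n - 1, t_crit = t_crit)
}

# 0-based channel adjacency list for the C++ grid labelling
adj_list_of <- function(graph) {
  lapply(seq_len(nrow(graph$adj)), function(c) which(graph$adj[c, ]) - 1L)
}

#' Form spatio-temporal clusters from a thresholded t-map
#'
#' Connected components of supra-threshold points sharing the same sign,
#' under the adjacency "same electrode at consecutive time samples OR
#' neighbouring electrodes at the same time sample". Components spanning
#' fewer than `min_electrodes` distinct electrodes are discarded.
#'
#' @param t_map channels x time t matrix.
#' @param mask logical matrix of supra-threshold points.
#' @param graph a [build_neighbors()] graph aligned with the rows of `t_map`.
#' @param min_electrodes minimum distinct electrodes per cluster (default 2).
#' @return list of clusters, each a list with `members` (two-column matrix
#'   of channel/time indices), `electrodes` (labels), `sign`, `t_sum`,
#'   `n_electrodes`; ordered by decreasing |t_sum|.
#' @export
form_clusters <- function(t_map, mask, graph, min_electrodes = 2) {
  stopifnot(identical(dim(t_map), dim(mask)),
            nrow(t_map) == length(graph$names))
  state <- matrix(0L, nrow(t_map), ncol(t_map))
  state[mask & t_map > 0] <- 1L
  state[mask & t_map < 0] <- -1L
  labels <- cpp_label_clusters(state, adj_list_of(graph))
  out <- list()
  for (lab in seq_len(max(labels))) {
    pts <- which(labels == lab, arr.ind = TRUE)
    electrodes <- sort(unique(graph$names[pts[, 1]]))
    if (length(electrodes) < min_electrodes) next
    out[[length(out) + 1]] <- list(
      members = unname(pts), electrodes = electrodes,
      sign = if (t_map[pts[1, 1], pts[1, 2]] > 0) "positive" else "negative",
      t_sum = sum(t_map[pts]), n_electrodes = length(electrodes))
  }
  out[order(-abs(vapply(out, `[[`, numeric(1), "t_sum")))]
}

#' Cluster-mass permutation test for a paired contrast
#'
#' Spatio-temporal cluster inference over participant x channel x time maps:
#' point-wise paired t, cluster formation over the electrode neighbourhood
#' graph, and a Monte-Carlo sign-flip null of the maximum |sum of t| over
#' clusters. Each cluster's `p_perm = (1 + #\{null >= |t_sum|\}) /
#' (1 + n_perm)`; by default positive and negative clusters are referred to
#' the same max-|t_sum| null (`max_type = "joint"`), optionally to
#' sign-specific maxima (`"separate"`). Ties count against rejection.
#'
#' @param a,b participant x channel x time arrays (paired by row).
#' @param graph electrode neighbourhood graph.
#' @param n_perm number of Monte-Carlo permutations (>= 100).
#' @param seed required RNG seed for the permutation stream.
#' @param alpha_form cluster-forming two-sided alpha.
#' @param min_electrodes minimum distinct electrodes per cluster.
#' @param max_type null statistic: joint max over both signs, or per sign.
#' @param times optional time axis (s) for reporting.
#' @return object of class `cluster_test`: `clusters` (each with `p_perm`),
#'   `null` (permutation maxima), plus the test's parameters.
#' @export
permutation_test <- function(a, b, graph, n_perm = 1000, seed,
                             alpha_form = 0.05, min_electrodes = 2,
                             max_type = c("joint", "separate"),
                             times = NULL) {
  max_type <- match.arg(max_type)
  if (missing(seed)) stop("seed is required for the permutation stream")
  if (n_perm < 100) stop("n_perm must be at least 100")
  pt <- pointwise_paired_t(a, b, alpha_form)
  clusters <- form_clusters(pt$t_map, pt$mask, graph, min_electrodes)
  n <- dim(a)[1]
  D <- matrix(a - b, nrow = n)
  set.seed(seed)
  nullmat <- cpp_perm_null(D, dim(a)[2], dim(a)[3], adj_list_of(graph),
                           pt$t_crit, as.integer(n_perm),
                           as.integer(min_electrodes))
  joint <- pmax(nullmat[, 1], nullmat[, 2])
  for (i in seq_along(clusters)) {
    obs <- abs(clusters[[i]]$t_sum)
    ref <- if (max_type == "joint") joint
           else if (clusters[[i]]$sign == "positive") nullmat[, 1]
           else nullmat[, 2]
    clusters[[i]]$p_perm <- (1 + sum(ref >= obs)) / (1 + n_perm)
  }
  structure(list(clusters = clusters, null = nullmat, n_perm = n_perm,
                 seed = seed, alpha_form = alpha_form, t_crit = pt$t_crit,
                 df = pt$df, max_type = max_type, times = times,
                 channel_names = graph$names),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("<cluster_test> %d cluster(s), %d permutations, seed %s, df %d\n",
              length(x$clusters), x$n_perm, format(x$seed), x$df))
  if (length(x$clusters)) {
    df <- summary(x)
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.cluster_test <- function(object, ...) {
  cl <- object$clusters
  df <- data.frame(
    sign = vapply(cl, `[[`, character(1), "sign"),
    t_sum = round(vapply(cl, `[[`, numeric(1), "t_sum"), 1),
    p_perm = vapply(cl, `[[`, numeric(1), "p_perm"),
    n_electrodes = vapply(cl, `[[`, numeric(1), "n_electrodes"))
  if (!is.null(object$times)) {
    df$t_start <- vapply(cl, function(k) object$times[min(k$members[, 2])],
                         numeric(1))
    df$t_end <- vapply(cl, function(k) object$times[max(k$members[, 2])],
                       numeric(1))
  }
  df$electrodes <- vapply(cl, function(k)
    paste(k$electrodes, collapse = ","), character(1))
  df
}

#' The five paired contrasts of the 2x2 design
#'
#' Runs cluster-mass permutation tests for: Instructed vs Free, Hard vs
#' Easy, the interaction (Instructed Hard - Instructed Easy) vs (Free Hard -
#' Free Easy), Instructed Hard vs Instructed Easy, and Free Hard vs Free
#' Easy. Band/lock pairing (theta on stimulus-locked maps over 0 to 0.5 s,
#' beta on movement-locked maps over -0.5 to 0 s) is the caller's
#' responsibility: `maps` should already be restricted to the period of
#' interest.
#'
#' @param maps named list of participant x channel x time arrays with
#'   elements `InstructedEasy`, `InstructedHard`, `FreeEasy`, `FreeHard`.
#' @param graph electrode neighbourhood graph.
#' @param n_perm,seed,alpha_form,min_electrodes,max_type,times passed to
#'   [permutation_test()]; each contrast uses `seed + k` (k = 0..4).
#' @return named list of `cluster_test` objects.
#' @export
run_contrasts <- function(maps, graph, n_perm = 1000, seed,
                          alpha_form = 0.05, min_electrodes = 2,
                          max_type = "joint", times = NULL) {
  if (missing(seed)) stop("seed is required for the permutation stream")
  need <- c("InstructedEasy", "InstructedHard", "FreeEasy", "FreeHard")
  have <- intersect(need, names(maps))
  defs <- list(
    instructed_vs_free = function(m)
      list(a = (m$InstructedEasy + m$InstructedHard) / 2,
           b = (m$FreeEasy + m$FreeHard) / 2),
    hard_vs_easy = function(m)
      list(a = (m$InstructedHard + m$FreeHard) / 2,
           b = (m$InstructedEasy + m$FreeEasy) / 2),
    interaction = function(m)
      list(a = m$InstructedHard - m$InstructedEasy,
           b = m$FreeHard - m$FreeEasy),
    instructed_hard_vs_easy = function(m)
      list(a = m$InstructedHard, b = m$InstructedEasy),
    free_hard_vs_easy = function(m)
      list(a = m$FreeHard, b = m$FreeEasy))
  needed <- list(instructed_vs_free = need, hard_vs_easy = need,
                 interaction = need,
                 instructed_hard_vs_easy = need[1:2],
                 free_hard_vs_easy = need[3:4])
  out <- list()
  k <- 0L
  for (nm in names(defs)) {
    if (!all(needed[[nm]] %in% have)) {
      warning("missing condition map(s); skipping contrast ", nm)
      k <- k + 1L
      next
    }
    ab <- defs[[nm]](maps)
    out[[nm]] <- permutation_test(ab$a, ab$b, graph, n_perm, seed + k,
                                  alpha_form, min_electrodes, max_type, times)
    k <- k + 1L
  }
  out
}

#' Write a cluster report as TSV
#'
#' One row per cluster: contrast, sign, t_sum, p_perm, n_electrodes, time
#' extent (s, when a time axis is attached) and member electrodes.
#'
#' @param contrasts named list of `cluster_test` objects (or one object).
#' @param path output TSV path.
#' @export
write_cluster_report <- function(contrasts, path) {
  if (inherits(contrasts, "cluster_test")) contrasts <- list(result = contrasts)
  rows <- list()
  for (nm in names(contrasts)) {
    s <- summary(contrasts[[nm]])
    if (nrow(s)) rows[[nm]] <- cbind(contrast = nm, s)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contrast = character(), sign = character(), t_sum = numeric(),
               p_perm = numeric(), n_electrodes = numeric(),
               electrodes = character())
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
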