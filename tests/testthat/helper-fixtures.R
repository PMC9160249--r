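# shared fixtures: small configurations and toy tables built in code

small_cfg <- function(seed = 1, n_participants = 2, sfreq = 250,
                      trial_counts = list(
                        instructed = c(easy_right = 6, easy_left = 2,
                                       hard_right = 6, hard_left = 2),
                        free = c(pse_m4 = 2, pse_p4 = 6, pse_m05 = 2,
                                 pse_0 = 2, pse_p05 = 2),
                        one_target = 2),
                      ...) {
  sim_config(n_participants = n_participants, sfreq = sfreq, seed = seed,
             trial_counts = trial_counts, ...)
}

# minimal behavior table for rule-level tests
toy_table <- function(rt, context = "Free", difficulty = "Hard",
                      choice = "right", participant = 1,
                      distance_cond = "PSE", phase = "main") {
  n <- length(rt)
  data.frame(participant = rep_len(participant, n), trial_index = seq_len(n),
             phase = rep_len(phase, n), context = rep_len(context, n),
             difficulty = rep_len(difficulty, n),
             distance_cond = rep_len(distance_cond, n),
             left_distance = 8, cue_direction = rep_len("right", n),
             choice = rep_len(choice, n), rt = rt,
             flags = "", stringsAsFactors = FALSE)
}

# tiny square montage on a sphere: 4 electrodes near the vertex
square_montage <- function(spacing_deg = 15, r = 9.2) {
  th <- spacing_deg * pi / 180
  co <- rbind(
    A = c(-sin(th), 0, cos(th)) * r,
    B = c(sin(th), 0, cos(th)) * r,
    C = c(0, sin(th), cos(th)) * r,
    D = c(0, -sin(th), cos(th)) * r)
  new_montage(rownames(co), co, r)
}

# independent flood-fill clustering oracle (pure R, breadth-first)
oracle_clusters <- function(t_map, mask, adj, min_electrodes = 2) {
  nch <- nrow(mask); nt <- ncol(mask)
  lab <- matrix(0L, nch, nt); nxt <- 0L
  for (c0 in seq_len(nch)) for (t0 in seq_len(nt)) {
    if (!mask[c0, t0] || lab[c0, t0] != 0) next
    nxt <- nxt + 1L
    queue <- list(c(c0, t0)); lab[c0, t0] <- nxt
    s0 <- sign(t_map[c0, t0])
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      cand <- list()
      if (p[2] > 1) cand <- c(cand, list(c(p[1], p[2] - 1)))
      if (p[2] < nt) cand <- c(cand, list(c(p[1], p[2] + 1)))
      for (nb in which(adj[p[1], ])) cand <- c(cand, list(c(nb, p[2])))
      for (q in cand) {
        if (mask[q[1], q[2]] && lab[q[1], q[2]] == 0 &&
            sign(t_map[q[1], q[2]]) == s0) {
          lab[q[1], q[2]] <- nxt
          queue <- c(queue, list(q))
        }
      }
    }
  }
  out <- list()
  for (l in seq_len(nxt)) {
    pts <- which(lab == l, arr.ind = TRUE)
    if (length(unique(pts[, 1])) < min_electrodes) next
    out[[length(out) + 1]] <- list(t_sum = sum(t_map[pts]),
                                   n_electrodes = length(unique(pts[, 1])),
                                   electrodes = sort(unique(pts[, 1])))
  }
  out
}
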