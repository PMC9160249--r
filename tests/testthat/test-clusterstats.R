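test_that("point-wise paired t matches the closed form and handles degeneracy", {
  a <- array(rnorm(24), c(4, 2, 3))
  same <- pointwise_paired_t(a, a)
  expect_true(all(same$t_map == 0))
  expect_false(any(same$mask))

  set.seed(2)
  b <- a + array(rnorm(24, 0.3), c(4, 2, 3))
  pt <- pointwise_paired_t(a, b)
  for (ch in 1:2) for (ti in 1:3) {
    d <- a[, ch, ti] - b[, ch, ti]
    expect_equal(pt$t_map[ch, ti], mean(d) / (sd(d) / 2), tolerance = 1e-9)
  }
  expect_equal(pt$t_crit, qt(0.975, 3))

  ## constant shift with zero noise: clamped +Inf handled as mask-true
  shifted <- a + 1
  deg <- pointwise_paired_t(shifted, a)
  expect_true(all(deg$t_map == 1e12))
  expect_true(all(deg$mask))

  expect_error(pointwise_paired_t(a[1:2, , ], a[1:2, , ]), "at least 3")
})

test_that("cluster formation matches a flood-fill oracle on random masks", {
  m <- reduced_montage()
  g <- build_neighbors(m)
  set.seed(77)
  for (rep in 1:25) {
    t_map <- matrix(rnorm(16 * 12, sd = 3), 16, 12,
                    dimnames = list(m$names, NULL))
    mask <- abs(t_map) > 2
    got <- form_clusters(t_map, mask, g)
    want <- oracle_clusters(t_map, mask, g$adj)
    expect_equal(sort(vapply(got, `[[`, numeric(1), "t_sum")),
                 sort(vapply(want, `[[`, numeric(1), "t_sum")),
                 tolerance = 1e-12)
    expect_equal(sort(vapply(got, `[[`, numeric(1), "n_electrodes")),
                 sort(vapply(want, `[[`, numeric(1), "n_electrodes")))
  }
})

test_that("single-electrode runs are discarded; empty masks give no clusters", {
  m <- reduced_montage()
  g <- build_neighbors(m)
  t_map <- matrix(0, 16, 10, dimnames = list(m$names, NULL))
  expect_length(form_clusters(t_map, t_map > 0, g), 0)
  ## one electrode supra-threshold over 10 consecutive samples
  t_map["Fz", ] <- 5
  cl <- form_clusters(t_map, t_map > 2, g)
  expect_length(cl, 0)
  ## two neighbouring electrodes at one sample qualify
  t_map2 <- matrix(0, 16, 10, dimnames = list(m$names, NULL))
  t_map2[c("Fz", "F1"), 4] <- 5
  cl2 <- form_clusters(t_map2, t_map2 > 2, g)
  expect_length(cl2, 1)
  expect_equal(cl2[[1]]$t_sum, 10)
  expect_setequal(cl2[[1]]$electrodes, c("Fz", "F1"))
  ## same-sign rule: adjacent opposite signs form separate (discarded) parts
  t_map3 <- matrix(0, 16, 10, dimnames = list(m$names, NULL))
  t_map3["Fz", 4] <- 5; t_map3["F1", 4] <- -5
  expect_length(form_clusters(t_map3, abs(t_map3) > 2, g), 0)
})

test_that("permutation p-values are deterministic, valid and relabel-invariant", {
  m <- reduced_montage()
  g <- build_neighbors(m)
  set.seed(10)
  a <- array(rnorm(20 * 16 * 25), c(20, 16, 25),
             dimnames = list(NULL, m$names, NULL))
  b <- a + array(rnorm(20 * 16 * 25, 0.15, 0.5), c(20, 16, 25))
  r1 <- permutation_test(a, b, g, n_perm = 300, seed = 5)
  r2 <- permutation_test(a, b, g, n_perm = 300, seed = 5)
  expect_identical(summary(r1), summary(r2))
  ps <- vapply(r1$clusters, `[[`, numeric(1), "p_perm")
  expect_true(all(ps > 0 & ps <= 1))
  expect_true(all(ps >= 1 / 301))
  ## swapping the two conditions flips cluster signs, not p-values
  r3 <- permutation_test(b, a, g, n_perm = 300, seed = 5)
  s1 <- summary(r1); s3 <- summary(r3)
  expect_equal(s3$t_sum, -s1$t_sum)
  expect_equal(s3$p_perm, s1$p_perm)
  ## reported clusters exceed the forming threshold in mass
  for (cl in r1$clusters)
    expect_gt(abs(cl$t_sum), r1$t_crit * nrow(cl$members))

  expect_error(permutation_test(a, b, g, n_perm = 50, seed = 1), "100")
  expect_error(permutation_test(a, b, g, n_perm = 300), "seed")
})

test_that("the five contrasts are wired to the right condition algebra", {
  m <- reduced_montage()
  g <- build_neighbors(m)
  set.seed(3)
  base <- function() array(rnorm(10 * 16 * 20, sd = 0.3), c(10, 16, 20),
                           dimnames = list(NULL, m$names, NULL))
  ## plant a strong Instructed-Hard-only midfrontal increase
  maps <- list(InstructedEasy = base(), InstructedHard = base(),
               FreeEasy = base(), FreeHard = base())
  maps$InstructedHard[, c("Fz", "F1", "F2"), 5:15] <-
    maps$InstructedHard[, c("Fz", "F1", "F2"), 5:15] + 2
  res <- run_contrasts(maps, g, n_perm = 200, seed = 17)
  expect_named(res, c("instructed_vs_free", "hard_vs_easy", "interaction",
                      "instructed_hard_vs_easy", "free_hard_vs_easy"))
  sig_pos <- function(ct) {
    any(vapply(ct$clusters, function(x)
      x$p_perm <= 0.05 && x$sign == "positive" &&
        sum(c("Fz", "F1", "F2") %in% x$electrodes) >= 2, logical(1)))
  }
  expect_true(sig_pos(res$instructed_hard_vs_easy))
  expect_true(sig_pos(res$interaction))
  ps_free <- vapply(res$free_hard_vs_easy$clusters, `[[`, numeric(1), "p_perm")
  expect_true(!length(ps_free) || min(ps_free) > 0.05)

  ## identical maps everywhere: no spurious certainty
  flat <- list(InstructedEasy = maps$FreeEasy, InstructedHard = maps$FreeEasy,
               FreeEasy = maps$FreeEasy, FreeHard = maps$FreeEasy)
  res0 <- run_contrasts(flat, g, n_perm = 200, seed = 18)
  expect_length(res0$instructed_vs_free$clusters, 0)

  ## a missing condition skips dependent contrasts with a warning
  expect_warning(res1 <- run_contrasts(maps[c("InstructedEasy",
                                              "InstructedHard")],
                                       g, n_perm = 200, seed = 19),
                 "skipping")
  expect_named(res1, "instructed_hard_vs_easy")
})

test_that("growing a planted effect never shrinks the recovered cluster mass", {
  m <- reduced_montage()
  g <- build_neighbors(m)
  effects <- c(0.5, 1.0, 2.0)
  mass <- matrix(NA_real_, 6, length(effects))
  for (s in 1:6) {
    set.seed(400 + s)
    a <- array(rnorm(12 * 16 * 20), c(12, 16, 20),
               dimnames = list(NULL, m$names, NULL))
    bump <- array(rnorm(12 * 16 * 20, 0, 0.1), c(12, 16, 20),
                  dimnames = dimnames(a))
    for (k in seq_along(effects)) {
      b <- a
      b[, c("Fz", "F1", "F2"), 5:15] <- b[, c("Fz", "F1", "F2"), 5:15] +
        effects[k] + bump[, c("Fz", "F1", "F2"), 5:15]
      r <- permutation_test(b, a, g, n_perm = 200, seed = s)
      masses <- vapply(r$clusters, `[[`, numeric(1), "t_sum")
      mass[s, k] <- if (length(masses)) max(masses) else 0
    }
  }
  avg <- colMeans(mass)
  expect_true(all(diff(avg) > 0))
})
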