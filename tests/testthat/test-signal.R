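test_that("band-pass/notch attenuates DC and 60 Hz but passes 10 Hz", {
  sf <- 500
  t <- seq(0, 4, by = 1 / sf)
  mid <- seq(round(length(t) * 0.25), round(length(t) * 0.75))
  rms <- function(x) sqrt(mean(x^2))

  dc <- matrix(1, 1, length(t))
  expect_lt(rms(bandpass_notch(dc, sf)[mid]), 10^(-20 / 20))

  hum <- matrix(sin(2 * pi * 60 * t), 1)
  expect_lt(rms(bandpass_notch(hum, sf)[mid]) / rms(hum[mid]), 10^(-20 / 20))

  alpha <- matrix(sin(2 * pi * 10 * t), 1)
  expect_equal(rms(bandpass_notch(alpha, sf)[mid]) / rms(alpha[mid]), 1,
               tolerance = 0.05)
})

test_that("filtering preconditions fail loudly", {
  expect_error(bandpass_notch(matrix(0, 1, 1000), sfreq = 250), "Nyquist")
  expect_error(bandpass_notch(matrix(0, 1, 10), sfreq = 500), "too short")
})

test_that("average reference zeroes the channel mean and is idempotent", {
  x <- matrix(rnorm(12), 3, 4)
  ref <- rereference_average(x)
  expect_equal(ref, sweep(x, 2, colMeans(x)), tolerance = 1e-12)
  expect_lt(max(abs(colMeans(ref))), 1e-10)
  expect_equal(rereference_average(ref), ref, tolerance = 1e-12)
  same <- matrix(rep(rnorm(5), each = 3), 3)
  expect_equal(rereference_average(same), matrix(0, 3, 5), tolerance = 1e-12)
})

test_that("filtering and average referencing commute on linear signals", {
  set.seed(6)
  x <- matrix(rnorm(4 * 2000), 4, 2000)
  a <- rereference_average(bandpass_notch(x, 500))
  b <- bandpass_notch(rereference_average(x), 500)
  expect_equal(a, b, tolerance = 1e-8)
})

test_that("epoching follows the half-open window convention", {
  sf <- 500
  cont <- matrix(0, 2, 5000)
  cont[, 2500] <- 1 # impulse at the event sample
  ep <- epoch_data(cont, events = 2500, lock = "stimulus", sfreq = sf)
  expect_equal(dim(ep$data)[3], 1400) # 2.8 s x 500 Hz
  lock_idx <- round(-ep$t0 * sf) + 1
  expect_equal(which(ep$data[1, 1, ] != 0), lock_idx)

  ## movement lock 1.0 s before the end of the recording: post-lock span
  ## (0.8 s) fits, pre-lock span (2 s) decides; at sample 600 it does not
  expect_warning(ep2 <- epoch_data(cont, events = c(600, 2500),
                                   lock = "movement", sfreq = sf),
                 "dropped")
  expect_equal(dim(ep2$data)[1], 1)
})

test_that("surface Laplacian nulls a uniform potential and keeps mean-zero data", {
  m <- reduced_montage()
  x <- matrix(rep(3.7, 16 * 5), 16, 5)
  rownames(x) <- m$names
  out <- surface_laplacian(x, m)
  expect_lt(max(abs(out)), 1e-6 * 3.7)

  ## average referencing first changes nothing: the spline has a constant term
  set.seed(1)
  y <- matrix(rnorm(16 * 10), 16, 10, dimnames = list(m$names, NULL))
  expect_equal(surface_laplacian(rereference_average(y), m),
               surface_laplacian(y, m), tolerance = 1e-8)
})

test_that("a low-order spherical harmonic is an approximate eigenfunction", {
  m <- default_montage()
  z <- m$coords[, 3] / m$sphere_radius
  y20 <- 1.5 * z^2 - 0.5 # P_2(cos theta) on the montage
  out <- surface_laplacian(matrix(y20, ncol = 1,
                                  dimnames = list(m$names, NULL)), m)
  expect_gt(cor(out[, 1], y20), 0.99)
  gain <- sum(out[, 1] * y20) / sum(y20^2)
  expect_gt(gain, 0) # sign convention: source-positive
})

test_that("the CSD operator matches a high-truncation per-sample oracle", {
  m <- reduced_montage()
  set.seed(4)
  x <- matrix(rnorm(16 * 3), 16, 3, dimnames = list(m$names, NULL))
  out <- surface_laplacian(x, m, m = 4, L = 50, lambda = 1e-5)
  ## independent evaluation of the spline formulas: doubled Legendre
  ## truncation, explicit per-sample solve of the augmented system
  legd <- function(cosm, L, mord) {
    G <- H <- matrix(0, nrow(cosm), ncol(cosm))
    Pm1 <- matrix(1, nrow(cosm), ncol(cosm)); P <- cosm
    for (l in seq_len(L)) {
      G <- G + (2 * l + 1) / (l * (l + 1))^mord * P
      H <- H + (2 * l + 1) / (l * (l + 1))^(mord - 1) * P
      Pn <- ((2 * l + 1) * cosm * P - l * Pm1) / (l + 1)
      Pm1 <- P; P <- Pn
    }
    list(G = G / (4 * pi), H = H / (4 * pi))
  }
  cosm <- tcrossprod(m$coords) / m$sphere_radius^2
  cosm[cosm > 1] <- 1; cosm[cosm < -1] <- -1
  gh <- legd(cosm, 100, 4)
  n <- 16
  K <- rbind(cbind(gh$G + diag(1e-5, n), 1), c(rep(1, n), 0))
  oracle <- sapply(seq_len(ncol(x)), function(j) {
    sol <- solve(K, c(x[, j], 0))
    (gh$H %*% sol[1:n]) / m$sphere_radius^2
  })
  expect_lt(max(abs(out - oracle)) / max(abs(oracle)), 1e-3)
})

test_that("downsampling decimates without moving spectral peaks", {
  cfg_sf <- 500
  t <- seq(0, 2.8 - 1 / cfg_sf, by = 1 / cfg_sf)
  x <- array(rep(sin(2 * pi * 20 * t), each = 2), c(1, 2, length(t)))
  ep <- new_epochs(x, cfg_sf, "stimulus", -1.2, c("a", "b"))
  expect_identical(downsample(ep, 1), ep)
  dn <- downsample(ep, 2)
  expect_equal(dim(dn$data)[3], 700)
  expect_equal(dn$sfreq, 250)
  expect_equal(dn$t0, -1.2)
  spec <- Mod(fft(dn$data[1, 1, ]))[1:350]
  peak_hz <- (which.max(spec[-1])) * 250 / 700
  expect_equal(peak_hz, 20, tolerance = 0.2)
  expect_error(downsample(ep, 1.5), "integer")
})
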