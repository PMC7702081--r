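# helper: wrap a plain curve into a tcf for fitting tests
tcf_from_curve <- function(t, v) {
  out <- tibble::tibble(lag = t, value = v, n_origins = 1L)
  class(out) <- c("tcf", class(out))
  attr(out, "window") <- max(t); attr(out, "dt") <- t[2] - t[1]
  out
}

test_that("Poisson bond breaking reproduces the analytic survival law", {
  dt <- 0.01
  h <- gen_hb_event_series(2000, k_break = 0.5, dt = dt, n_frames = 1500, seed = 2)
  S <- correlate(h, dt = dt, window = 11, kernel = "survival")
  # pointwise 3-sigma binomial envelope around exp(-k t)
  for (tl in c(1, 2, 4, 8)) {
    p <- exp(-0.5 * tl)
    got <- S$value[abs(S$lag - tl) < 1e-9]
    n <- S$n_origins[abs(S$lag - tl) < 1e-9]
    expect_lt(abs(got - p), 3 * sqrt(p * (1 - p) / 2000) + 3 / sqrt(n))
  }
  expect_equal(hb_lifetime(S), 2, tolerance = 0.05)
})

test_that("integrated HB lifetime is within 5% of 1/k across rates", {
  dt <- 0.01
  for (k in c(0.3, 0.5, 1.0)) {
    h <- gen_hb_event_series(2000, k, dt = dt, n_frames = 1500, seed = 10 + k * 10)
    S <- correlate(h, dt = dt, window = 11, kernel = "survival")
    expect_equal(hb_lifetime(S) * k, 1, tolerance = 0.05)
  }
})

test_that("hb_lifetime handles closed forms and a two-rate quadrature oracle", {
  t <- seq(0, 11, by = 0.01)
  S1 <- tcf_from_curve(t, exp(-t / 1.5))
  expect_equal(hb_lifetime(S1), 1.5, tolerance = 0.01)
  Sflat <- tcf_from_curve(t, rep(1, length(t)))
  expect_equal(hb_lifetime(Sflat, tail = "none"), 11)
  # two-rate mixture: oracle by numerical quadrature over the window
  mix <- 0.6 * exp(-t / 0.8) + 0.4 * exp(-t / 3)
  oracle <- sum(diff(t) * (mix[-1] + mix[-length(mix)]) / 2)
  expect_equal(hb_lifetime(tcf_from_curve(t, mix), tail = "none"), oracle)
})

test_that("bond-at-origin but broken in between never survives (continuity)", {
  h <- gen_hb_event_series(50, 0.8, dt = 0.05, n_frames = 100, seed = 3)
  S <- correlate(h, dt = 0.05, window = 2, kernel = "survival")
  expect_true(all(diff(S$value) <= 1e-12))  # survival is non-increasing
  expect_equal(S$value[1], 1)
})

test_that("k = 0 keeps every pair bonded and S identically 1", {
  h <- gen_hb_event_series(10, 0, dt = 0.1, n_frames = 50, seed = 1)
  S <- correlate(h, dt = 0.1, window = 3, kernel = "survival")
  expect_equal(S$value, rep(1, length(S$value)))
})

test_that("dipole vectors are unit bisectors and rotate with the molecule", {
  u <- c(0, 0, 1); p <- c(1, 0, 0)
  w <- ideal_water(c(5, 5, 5), u, p)
  traj <- make_traj(list(w), c("O", "H", "H"), c(20, 20, 20))
  topo <- build_water_topology(traj)
  mu <- dipole_vectors(frame_coords(traj, 1), topo, c(20, 20, 20))
  expect_equal(mu[1, ], c(0, 0, 1))
  # rigid rotation about x by 90 deg maps dipole z -> y
  rot <- function(v) c(v[1], -v[3], v[2])
  w2 <- t(apply(w - rep(c(5, 5, 5), each = 3), 1, rot)) + rep(c(5, 5, 5), each = 3)
  traj2 <- make_traj(list(w2), c("O", "H", "H"), c(20, 20, 20))
  mu2 <- dipole_vectors(frame_coords(traj2, 1), build_water_topology(traj2), c(20, 20, 20))
  expect_equal(mu2[1, ], rot(c(0, 0, 1)))
  expect_equal(sqrt(sum(mu2^2)), 1)
})

test_that("frozen waters give C1 = 1; scrambled orientations give C1 ~ 0", {
  set.seed(41)
  n <- 50; n_f <- 30
  u <- matrix(rnorm(n * 3), n, 3); u <- u / sqrt(rowSums(u^2))
  arr <- array(rep(u, n_f), c(n, 3, n_f))
  tc <- correlate(arr, dt = 0.1, window = 2, kernel = "dot")
  expect_equal(tc$value, rep(1, length(tc$value)))
  # independent random orientation every frame
  arr2 <- array(rnorm(n * 3 * n_f), c(n, 3, n_f))
  for (f in seq_len(n_f)) arr2[, , f] <- arr2[, , f] / sqrt(rowSums(arr2[, , f]^2))
  tc2 <- correlate(arr2, dt = 0.1, window = 2, kernel = "dot")
  # n_origins already counts origin-entity pairs
  expect_lt(max(abs(tc2$value[-1])), 4 / sqrt(tc2$n_origins[2]))
})

test_that("rotational diffusion gives C1 = exp(-2 D t) and tau_reor = 1/(2D)", {
  set.seed(1)
  D <- 0.05
  rot <- gen_rigid_rotations(500, D, 0.004, 2501)
  tc <- correlate(rot$u, dt = 0.004, window = 8, kernel = "dot")
  sel <- tc$lag %in% c(1, 2, 4)
  expect_equal(tc$value[sel], exp(-2 * D * tc$lag[sel]), tolerance = 0.03)
  fit <- fit_biexponential(tc, fit_start = 0.2)
  expect_equal(fit$tau_reor * 2 * D, 1, tolerance = 0.1)
})

test_that("bi-exponential fitting: exact arithmetic, single-exp limit, noisy recovery", {
  t <- seq(0, 16, by = 0.004)
  exact <- fit_biexponential(tcf_from_curve(t, 0.7 * exp(-t / 2) + 0.3 * exp(-t / 8)))
  expect_equal(exact$tau_reor, 3.8, tolerance = 1e-6)
  expect_false(exact$single_exponential)

  single <- fit_biexponential(tcf_from_curve(t, exp(-t / 3)))
  expect_equal(single$tau_reor, 3, tolerance = 0.01)
  expect_true(single$single_exponential)

  set.seed(5)
  noisy <- fit_biexponential(tcf_from_curve(t, 0.7 * exp(-t / 2) + 0.3 * exp(-t / 8) +
                                              rnorm(length(t), 0, 0.005)))
  expect_equal(noisy$a, 0.7, tolerance = 0.1)
  expect_equal(noisy$tau1, 2, tolerance = 0.1)
  expect_equal(noisy$b, 0.3, tolerance = 0.1)
  expect_equal(noisy$tau2, 8, tolerance = 0.1)

  td <- tidy(noisy)
  expect_setequal(td$term, c("a", "tau1", "b", "tau2", "tau_reor"))
  expect_equal(glance(noisy)$tau_reor, noisy$tau_reor)
})

test_that("VDOS locates pure tones within one frequency bin", {
  n <- 2001; dt <- 0.004
  c_cm_ps <- 2.99792458e-2
  tone <- function(wn) cos(2 * pi * wn * c_cm_ps * (0:(n - 1)) * dt)
  arr <- array(0, c(2, 3, n))
  arr[1, 1, ] <- tone(250); arr[2, 1, ] <- tone(250)
  traj <- trajectory(c("O", "O"), array(5, c(2, 3, n)), c(20, 20, 20),
                     dt = dt, velocities = arr)
  sp <- vdos(traj, window = 4, species = "O")
  res <- attr(sp, "resolution")
  expect_lt(abs(vdos_peak(sp, "O", above = 50) - 250), res + 1e-9)

  # two superposed tones -> two peaks
  arr[1, 1, ] <- tone(120) + tone(500); arr[2, 1, ] <- tone(120) + tone(500)
  traj2 <- trajectory(c("O", "O"), array(5, c(2, 3, n)), c(20, 20, 20),
                      dt = dt, velocities = arr)
  sp2 <- vdos(traj2, window = 4, species = "O")
  oxy <- sp2[sp2$species == "O" & sp2$wavenumber > 50 & sp2$wavenumber < 300, ]
  expect_lt(abs(vdos_peak(sp2, "O", above = 300) - 500), res + 1e-9)
  expect_lt(abs(oxy$wavenumber[which.max(oxy$intensity)] - 120), res + 1e-9)

  expect_error(vdos(make_traj(list(matrix(0, 2, 3)), c("O", "O"), c(9, 9, 9)),
                    window = 1), "velocities")
})

test_that("white-noise velocities give a flat spectrum", {
  set.seed(44)
  n <- 4001; dt <- 0.004
  arr <- array(rnorm(20 * 3 * n), c(20, 3, n))
  traj <- trajectory(rep("O", 20), array(5, c(20, 3, n)), c(20, 20, 20),
                     dt = dt, velocities = arr)
  sp <- vdos(traj, window = 2, species = "O", n_origins_target = 256)
  oxy <- sp$intensity[sp$species == "O"]
  # drop the DC/edge bins; remaining band should show no dominant structure
  mid <- oxy[5:(length(oxy) - 5)]
  expect_lt(max(mid) / stats::median(mid), 5)
})
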