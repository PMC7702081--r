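test_that("generators are bit-identical under the same seed", {
  spec <- synthetic_solution_spec(n_salt_units = 1, n_bulk_waters = 20,
                                  n_frames = 21, seed = 71)
  a <- gen_rotational_trajectory(spec)
  b <- gen_rotational_trajectory(spec)
  expect_identical(a$traj$positions, b$traj$positions)
  expect_identical(a$truth, b$truth)
  h1 <- gen_hb_event_series(100, 0.4, 0.01, 200, seed = 72)
  h2 <- gen_hb_event_series(100, 0.4, 0.01, 200, seed = 72)
  expect_identical(h1, h2)
  s1 <- gen_dielectric_spectrum(synthetic_spectrum_spec(noise = 0.02, seed = 73))
  s2 <- gen_dielectric_spectrum(synthetic_spectrum_spec(noise = 0.02, seed = 73))
  expect_identical(s1$eps_imag, s2$eps_imag)
})

test_that("realized frame-1 labels match the designed ground truth", {
  spec <- synthetic_solution_spec(n_salt_units = 2,
                                  class_counts = c(W_122 = 4, W_211 = 5),
                                  n_bulk_waters = 30, n_frames = 11, seed = 74)
  sol <- gen_rotational_trajectory(spec)
  labs <- label_waters(frame_coords(sol$traj, 1), sol$topology,
                       spec$cation_shells, spec$anion_shells,
                       frame_cell(sol$traj, 1))
  expect_identical(labs, sol$truth$label)
  expect_equal(sum(sol$truth$label == "W_122"), 8)   # 4 per salt unit x 2
  expect_equal(sum(sol$truth$label == "W_211"), 10)
})

test_that("labels stay fixed over time while orientations decay isotropically", {
  spec <- synthetic_solution_spec(n_salt_units = 1, class_counts = c(W_211 = 4),
                                  n_bulk_waters = 40, n_frames = 401, seed = 75)
  sol <- gen_rotational_trajectory(spec)
  for (f in c(200, 401)) {
    labs <- label_waters(frame_coords(sol$traj, f), sol$topology,
                         spec$cation_shells, spec$anion_shells,
                         frame_cell(sol$traj, f))
    expect_identical(labs, sol$truth$label)
  }
  # isotropy: time-and-molecule-averaged dipole is near zero
  mu <- dipole_array(sol$traj, sol$topology)
  avg <- apply(mu, 2, mean)
  expect_lt(sqrt(sum(avg^2)), 3 / sqrt(dim(mu)[1] * dim(mu)[3] / 100))
})

test_that("mixed hydrogen-state classes and infeasible packings are rejected", {
  expect_error(synthetic_solution_spec(class_counts = c(W_212 = 3)), "mixed hydrogen")
  # far too many waters in a first-shell band cannot be packed
  spec <- synthetic_solution_spec(n_salt_units = 1, class_counts = c(W_122 = 200),
                                  n_bulk_waters = 0, n_frames = 3, seed = 76)
  expect_error(gen_rotational_trajectory(spec), "infeasible packing")
})

test_that("rotational propagator enforces its small-step validity bound", {
  expect_error(gen_rigid_rotations(5, D = 3, dt = 0.01, n_frames = 3), "D \\* dt")
  rot <- gen_rigid_rotations(10, 0.05, 0.004, 50)
  # unit norms and u-p orthogonality preserved
  expect_equal(apply(rot$u, c(1, 3), function(v) sum(v^2)),
               matrix(1, 10, 50), tolerance = 1e-12)
  expect_lt(max(abs(sapply(1:50, function(f) rowSums(rot$u[, , f] * rot$p[, , f])))), 1e-12)
})

test_that("two designed diffusion classes give the designed tau ratio", {
  set.seed(77)
  rot_fast <- gen_rigid_rotations(300, 0.1, 0.004, 2001)
  rot_slow <- gen_rigid_rotations(300, 0.02, 0.004, 2001)
  fit_f <- fit_biexponential(correlate(rot_fast$u, dt = 0.004, window = 6, kernel = "dot"))
  fit_s <- fit_biexponential(correlate(rot_slow$u, dt = 0.004, window = 6, kernel = "dot"))
  expect_equal(fit_s$tau_reor / fit_f$tau_reor, 5, tolerance = 0.25)
})

test_that("synthetic spectra match the model plus the Ohmic term", {
  spec <- synthetic_spectrum_spec(conductivity = 3, seed = 78)
  sp <- gen_dielectric_spectrum(spec)
  eps <- double_debye_eps(sp$freq, spec$S1, spec$S2, spec$tau1, spec$tau2, spec$eps_inf)
  expect_equal(sp$eps_real, Re(eps))
  expect_equal(sp$eps_imag,
               -Im(eps) + 3 / (2 * pi * sp$freq * 1e9 * 8.8541878128e-12))
  # static value at the lowest grid point ~ S1 + S2 + eps_inf
  sp0 <- gen_dielectric_spectrum(synthetic_spectrum_spec())
  expect_equal(sp0$eps_real[1], 72 + 2.5 + 3.52, tolerance = 0.01)
})
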