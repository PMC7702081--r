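test_that("extended-XYZ round trip preserves positions, elements and cell", {
  set.seed(11)
  frames <- lapply(1:3, function(f) matrix(runif(9, 0, 12), 3, 3))
  traj <- make_traj(frames, c("O", "H", "H"), cell = c(12, 13, 14), dt = 0.5)
  path <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory(traj, path)
  back <- read_trajectory(path, dt = 0.5)
  expect_identical(back$elements, traj$elements)
  expect_equal(back$positions, traj$positions, tolerance = 1e-6)
  expect_equal(back$cell, traj$cell)
  expect_null(back$velocities)
  expect_equal(back$n_frames, 3L)
})

test_that("velocity columns survive the round trip and flag the trajectory", {
  set.seed(12)
  frames <- lapply(1:2, function(f) matrix(runif(6, 0, 9), 2, 3))
  vels <- lapply(1:2, function(f) matrix(rnorm(6), 2, 3))
  traj <- make_traj(frames, c("O", "O"), cell = c(9, 9, 9), dt = 1, velocities = vels)
  path <- withr::local_tempfile(fileext = ".xyz")
  write_trajectory(traj, path)
  back <- read_trajectory(path, dt = 1)
  expect_false(is.null(back$velocities))
  expect_equal(back$velocities, traj$velocities, tolerance = 1e-6)
})

test_that("malformed files fail with informative errors", {
  lines <- c("2", 'Lattice="9 0 0 0 9 0 0 0 9" Properties=species:S:1:pos:R:3',
             "O 0 0 0", "H 1 0 0",
             "1", 'Lattice="9 0 0 0 9 0 0 0 9" Properties=species:S:1:pos:R:3',
             "O 0 0 0")
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(lines, path)
  expect_error(read_trajectory(path, dt = 1), "frame 2.*atom count mismatch")

  no_cell <- c("1", "comment without lattice", "O 0 0 0")
  writeLines(no_cell, path)
  expect_error(read_trajectory(path, dt = 1), "missing Lattice")

  triclinic <- c("1", 'Lattice="9 1 0 0 9 0 0 0 9"', "O 0 0 0")
  writeLines(triclinic, path)
  expect_error(read_trajectory(path, dt = 1), "orthorhombic")
})

test_that("plain XYZ with a cell sidecar reads correctly", {
  path <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("2", "frame 0", "O 1 1 1", "H 1.5 1 1",
               "2", "frame 1", "O 1 1 2", "H 1.5 1 2"), path)
  writeLines("10 10 10", paste0(path, ".cell"))
  traj <- read_trajectory(path, dt = 0.25, format = "xyz")
  expect_equal(traj$n_frames, 2L)
  expect_equal(frame_cell(traj, 1), c(10, 10, 10))
  expect_equal(frame_coords(traj, 2)[1, ], c(1, 1, 2))
})

test_that("minimum-image displacement wraps into (-L/2, L/2] and matches the 27-image oracle", {
  expect_equal(minimum_image_displacement(c(0, 0, 0), c(9, 0, 0), c(10, 10, 10)),
               c(-1, 0, 0))
  expect_equal(minimum_image_displacement(c(2, 3, 4), c(2, 3, 4), c(10, 10, 10)),
               c(0, 0, 0))
  set.seed(42)
  cell <- c(8.5, 11, 14.2)
  for (i in 1:1000) {
    # in-box points: the 27-image enumeration is exhaustive only within one cell
    a <- runif(3, 0, cell); b <- runif(3, 0, cell)
    d <- minimum_image_displacement(a, b, cell)
    expect_true(all(d > -cell / 2 - 1e-12 & d <= cell / 2 + 1e-12))
    expect_equal(sqrt(sum(d^2)), oracle_min_distance(a, b, cell), tolerance = 1e-12)
  }
})

test_that("water topology pairs each oxygen with its two hydrogens and lists ions", {
  u <- c(0, 0, 1); p <- c(1, 0, 0)
  w1 <- ideal_water(c(3, 3, 3), u, p)
  w2 <- ideal_water(c(7, 7, 7), u, p)
  # scrambled atom ordering: H's of w2 before w1's O, plus one Mg
  pos <- rbind(w1[1, ], w2[2, ], w2[3, ], w1[2, ], w1[3, ], w2[1, ], c(5, 5, 5))
  traj <- make_traj(list(pos), c("O", "H", "H", "H", "H", "O", "Mg"), c(20, 20, 20))
  topo <- build_water_topology(traj)
  expect_equal(nrow(topo$molecules), 2L)
  expect_equal(ion_atoms(topo, "Mg"), 7L)
  # each O got the hydrogens built around it, regardless of file order
  m1 <- topo$molecules[topo$molecules$O == 1, ]
  expect_setequal(c(m1$H1, m1$H2), c(4L, 5L))

  # a hydrogen 1.5 A from every O is an error
  bad <- rbind(w1, c(3, 3, 3 + 1.5 + 0.9572))
  traj_bad <- make_traj(list(bad), c("O", "H", "H", "H"), c(20, 20, 20))
  expect_error(build_water_topology(traj_bad), "belong to no water")
})
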