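test_that("the cooperative model enumerates 18 labels, 15 admissible", {
  enum <- enumerate_subpopulations()
  expect_equal(nrow(enum), 18L)
  expect_equal(sum(enum$admissible), 15L)
  expect_setequal(enum$label[!enum$admissible], c("W_11B", "W_21B", "W_B1B"))
  expect_false(any(duplicated(enum$label)))
})

# build a frame with one Mg, one Cl and waters at prescribed positions
label_fixture <- function(o_pos_list, mg = c(10, 10, 10), cl = c(30, 10, 10)) {
  u <- c(0, 0, 1); p <- c(1, 0, 0)
  waters <- do.call(rbind, lapply(o_pos_list, function(o) ideal_water(o, u, p)))
  pos <- rbind(waters, mg, cl)
  elements <- c(rep(c("O", "H", "H"), length(o_pos_list)), "Mg", "Cl")
  traj <- make_traj(list(pos), elements, c(60, 60, 60))
  list(traj = traj, topo = build_water_topology(traj))
}

test_that("waters are labelled by oxygen-vs-cation and hydrogen-vs-anion shells", {
  cs <- shell_boundaries(3.0, 5.0)
  as_ <- shell_boundaries(3.0, 5.0)
  # dipoles point +z so hydrogens sit ~0.59 A above the O plane
  fx <- label_fixture(list(c(12, 10, 10),   # 2.0 from Mg, ~18 from Cl -> W_1BB
                           c(26.2, 10, 10), # ~13.8 Mg; H ~ 3.9 from Cl -> W_B22
                           c(50, 50, 50)))  # far from both -> W_BBB
  labs <- label_waters(frame_coords(fx$traj, 1), fx$topo, cs, as_, c(60, 60, 60))
  expect_equal(labs, c("W_1BB", "W_B22", "W_BBB"))
})

test_that("hydrogen states are canonicalized and no-ion systems are all bulk", {
  u <- c(0, 0, 1); p <- c(1, 0, 0)
  w <- ideal_water(c(5, 5, 5), u, p)
  traj <- make_traj(list(w), c("O", "H", "H"), c(20, 20, 20))
  topo <- build_water_topology(traj)
  labs <- label_waters(frame_coords(traj, 1), topo,
                       shell_boundaries(3, 5), shell_boundaries(3, 5), c(20, 20, 20))
  expect_equal(labs, "W_BBB")
})

test_that("label populations sum to the water count at every origin", {
  spec <- synthetic_solution_spec(n_salt_units = 1, n_bulk_waters = 30,
                                  n_frames = 51, seed = 9)
  sol <- gen_rotational_trajectory(spec)
  for (f in c(1, 25, 51)) {
    labs <- label_waters(frame_coords(sol$traj, f), sol$topology,
                         spec$cation_shells, spec$anion_shells,
                         frame_cell(sol$traj, f))
    expect_equal(length(labs), nrow(sol$topology$molecules))
    expect_true(all(grepl("^W_[12B][12B][12B]$", labs)))
  }
})

make_subpop_table <- function(label, population, tau, tau_sigma = NA_real_) {
  enum <- enumerate_subpopulations()
  out <- tibble::tibble(label = label,
                        a = substr(label, 3, 3), bc = substr(label, 4, 5),
                        population = population, tau = tau,
                        tau_sigma = tau_sigma,
                        n_samples = round(population * 100),
                        admissible = TRUE)
  class(out) <- c("subpop_table", class(out))
  out
}

test_that("retardation factors divide by the bulk reference", {
  tab <- make_subpop_table(c("W_1BB", "W_BBB"), c(6, 60), c(10, 2), c(0.5, 0.1))
  out <- retardation_factors(tab, bulk_tau = 2)
  expect_equal(out$f, c(5, 1))
  # automatic bulk reference: population-weighted mean over the seed set
  out2 <- retardation_factors(tab)
  expect_equal(attr(out2, "bulk_tau"), 2)  # only W_BBB seeds
  expect_equal(out2$f[1], 5)
})

test_that("the Empirical-Rule classifier separates slow from bulk-like", {
  set.seed(51)
  bulk_labels <- c("W_222", "W_22B", "W_B22", "W_B2B", "W_BBB")
  tab <- make_subpop_table(
    c("W_111", "W_211", bulk_labels),
    population = c(6, 9, 5, 5, 5, 5, 40),
    tau = c(10, 8, 2 + rnorm(5, 0, 0.05)),
    tau_sigma = rep(0.1, 7)
  )
  out <- classify_empirical_rule(retardation_factors(tab))
  expect_equal(out$class[out$label == "W_111"], "slow")
  expect_equal(out$class[out$label == "W_211"], "slow")
  expect_true(all(out$class[out$label %in% bulk_labels] == "bulk-like"))

  # all f ~ 1 with matching block errors -> everything bulk-like
  tab2 <- make_subpop_table(bulk_labels, rep(10, 5),
                            2 + rnorm(5, 0, 0.02), rep(0.05, 5))
  out2 <- classify_empirical_rule(retardation_factors(tab2))
  expect_true(all(out2$class == "bulk-like"))
})

test_that("null draws from the bulk distribution pass the 3-sigma window ~99.7% of the time", {
  set.seed(52)
  cover <- empirical_rule_coverage(2e5, n_sigma = 3)
  expect_equal(cover, 99.7, tolerance = 0.002)
})

test_that("hydration number sums slow populations per salt unit and is intensive", {
  tab <- make_subpop_table(c("W_122", "W_211", "W_BBB"), c(12, 18, 100),
                           c(10, 9, 2), c(0.3, 0.3, 0.1))
  out <- classify_empirical_rule(retardation_factors(tab, bulk_tau = 2))
  res <- hydration_number(out, n_salt_units = 2)
  expect_equal(res$h, 15)
  expect_equal(res$slow_first_shell, 6)
  expect_equal(res$slow_beyond, 9)
  expect_equal(res$h, res$slow_first_shell + res$slow_beyond)
  # doubling the box doubles populations and salt units; h unchanged
  tab2 <- make_subpop_table(c("W_122", "W_211", "W_BBB"), 2 * c(12, 18, 100),
                            c(10, 9, 2), c(0.3, 0.3, 0.1))
  out2 <- classify_empirical_rule(retardation_factors(tab2, bulk_tau = 2))
  expect_equal(hydration_number(out2, 4)$h, 15)
  # everything bulk-like -> h = 0
  tab3 <- make_subpop_table(c("W_222", "W_BBB"), c(10, 100), c(2.01, 2), c(0.05, 0.05))
  out3 <- classify_empirical_rule(retardation_factors(tab3, bulk_tau = 2))
  expect_equal(hydration_number(out3, 2)$h, 0)
})

test_that("per-subpopulation taus recover designed diffusion ratios", {
  spec <- synthetic_solution_spec(
    n_salt_units = 1, class_counts = c(W_122 = 8, W_211 = 10),
    n_bulk_waters = 40, D_by_class = c(W_122 = 1 / 30, W_211 = 1 / 30),
    D_bulk = 0.1, n_frames = 1251, seed = 13
  )
  sol <- gen_rotational_trajectory(spec)
  tab <- subpopulation_taus(sol$traj, sol$topology, spec$cation_shells,
                            spec$anion_shells, window = 3.2,
                            min_origin_samples = 40)
  fitted <- tab[!is.na(tab$tau), ]
  slow <- fitted$tau[fitted$label %in% c("W_122", "W_211")]
  bulk <- fitted$tau[fitted$label == "W_BBB"]
  # designed tau ratio = D_bulk / D_slow = 3
  expect_equal(mean(slow) / bulk, 3, tolerance = 0.25)
  expect_equal(tab$population[tab$label == "W_122"], 8)
  # empty admissible labels carry no tau
  expect_true(is.na(tab$tau[tab$label == "W_112"]))
})
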