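#' Rotational Brownian evolution of rigid orientations
#'
#' Evolves `n` rigid-body orientations by isotropic rotational diffusion:
#' at each step every body is rotated about a uniformly random axis by an
#' angle drawn from `Normal(0, sqrt(6 D dt))`. For a uniformly random axis
#' the expected single-step alignment is `E[u(0).u(dt)] = (1 + 2 E[cos phi])/3
#' = 1 - 2 D dt`, so the dipole TCF decays as `exp(-2 D t)` in the small-step
#' limit (the propagator requires `D dt < 0.01` and enforces it). Both the
#' dipole (bisector) axis `u` and an in-plane perpendicular axis `p` are
#' rotated, so the full rigid-body orientation is propagated.
#'
#' @param n Number of bodies.
#' @param D Rotational diffusion coefficient(s), rad^2/ps (length 1 or n).
#' @param dt Time step (ps).
#' @param n_frames Number of frames.
#' @return List of arrays `u`, `p`, each `[n, 3, n_frames]`.
#' @export
gen_rigid_rotations <- function(n, D, dt, n_frames) {
  D <- rep_len(D, n)
  if (any(D <= 0)) stop("D must be positive", call. = FALSE)
  if (any(D * dt >= 0.01)) {
    stop("small-angle propagator requires D * dt < 0.01", call. = FALSE)
  }
  u <- array(0, c(n, 3, n_frames))
  p <- array(0, c(n, 3, n_frames))
  # random initial orientations
  u0 <- unitize_rows(matrix(stats::rnorm(3 * n), n, 3))
  q <- matrix(stats::rnorm(3 * n), n, 3)
  p0 <- unitize_rows(q - u0 * rowSums(q * u0))
  u[, , 1] <- u0; p[, , 1] <- p0
  sd_phi <- sqrt(6 * D * dt)
  for (f in seq_len(n_frames - 1L)) {
    ax <- unitize_rows(matrix(stats::rnorm(3 * n), n, 3))
    phi <- stats::rnorm(n, 0, sd_phi)
    cph <- cos(phi); sph <- sin(phi)
    u0 <- rodrigues_rows(u0, ax, cph, sph)
    p0 <- rodrigues_rows(p0, ax, cph, sph)
    # re-orthonormalize against drift
    u0 <- unitize_rows(u0)
    p0 <- unitize_rows(p0 - u0 * rowSums(p0 * u0))
    u[, , f + 1L] <- u0; p[, , f + 1L] <- p0
  }
  list(u = u, p = p)
}

# row-wise Rodrigues rotation: v cos + (a x v) sin + a (a.v)(1 - cos)
rodrigues_rows <- function(v, a, cph, sph) {
  axv <- cbind(a[, 2] * v[, 3] - a[, 3] * v[, 2],
               a[, 3] * v[, 1] - a[, 1] * v[, 3],
               a[, 1] * v[, 2] - a[, 2] * v[, 1])
  adv <- rowSums(a * v)
  v * cph + axv * sph + a * (adv * (1 - cph))
}

#' Specification of a synthetic electrolyte solution
#'
#' Describes a box of rigid waters undergoing rotational Brownian motion
#' around placed ions, with designed subpopulation memberships: each entry of
#' `class_counts` places that many waters per salt unit in the geometric
#' region of the given `W_abc` label, and `D_by_class` assigns the rotational
#' diffusion coefficient per label (default `D_bulk`). Only labels whose two
#' hydrogen states are equal can be pinned geometrically under free rotation
#' (the whole hydrogen sphere must stay inside one anion shell band); mixed
#' hydrogen labels are rejected. Waters are translationally frozen, so
#' subpopulations do not exchange — this exercises the origin-membership
#' estimator cleanly.
#'
#' @param n_salt_units Number of dissolved salt units (1 cation + 2 anions).
#' @param class_counts Named integer vector: waters per salt unit per label,
#'   e.g. `c(W_122 = 6, W_211 = 9)` (6 first-cation-shell waters plus 9
#'   beyond, the second-cation-shell/first-anion-shell cooperative class).
#'   Labels must be geometrically compatible with the ion-pair distance the
#'   generator uses (about `r_min2(cation) + r_min1(anion) - 2` Angstrom):
#'   near an ion pair a first-cation-shell water always has its hydrogens
#'   inside the anion shells, so first-shell classes are `W_111`/`W_122`
#'   rather than `W_1BB`.
#' @param n_bulk_waters Waters placed beyond all shells (label `W_BBB`).
#' @param D_by_class Named numeric vector of rotational diffusion
#'   coefficients (rad^2/ps) per label.
#' @param D_bulk Diffusion coefficient of unlisted labels (default 0.1).
#' @param cation_shells,anion_shells [shell_boundaries()] defining the label
#'   geometry; defaults (3, 7.5) for cation-O and (6, 10) for anion-H. The
#'   anion bands are wider than a physical anion-hydrogen RDF would give:
#'   pinning a hydrogen state under free rotation requires the whole
#'   hydrogen sphere (O-H arm plus margin) to fit inside one band.
#' @param cation,anion Ion element symbols.
#' @param dt Time step (ps, default 0.004).
#' @param n_frames Number of frames (default 5001, i.e. 20 ps).
#' @param seed RNG seed.
#' @return Object of class `synthetic_solution_spec`.
#' @export
synthetic_solution_spec <- function(n_salt_units = 2,
                                    class_counts = c(W_122 = 6, W_211 = 9),
                                    n_bulk_waters = 100,
                                    D_by_class = c(W_122 = 0.025, W_211 = 0.025),
                                    D_bulk = 0.1,
                                    cation_shells = shell_boundaries(3.0, 7.5),
                                    anion_shells = shell_boundaries(6.0, 10.0),
                                    cation = "Mg", anion = "Cl",
                                    dt = 0.004, n_frames = 5001, seed = 1) {
  stopifnot(n_salt_units >= 1, n_bulk_waters >= 0, dt > 0, n_frames >= 2)
  if (length(class_counts) > 0) {
    bad <- !grepl("^W_[12B][12B][12B]$", names(class_counts))
    if (any(bad)) stop("class_counts names must be W_abc labels", call. = FALSE)
    mixed <- vapply(names(class_counts), function(l) {
      s <- strsplit(sub("W_", "", l), "")[[1]]
      s[2] != s[3]
    }, logical(1))
    if (any(mixed)) {
      stop("mixed hydrogen states cannot be pinned under free rotation: ",
           paste(names(class_counts)[mixed], collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(n_salt_units = n_salt_units, class_counts = class_counts,
         n_bulk_waters = n_bulk_waters, D_by_class = D_by_class,
         D_bulk = D_bulk, cation_shells = cation_shells,
         anion_shells = anion_shells, cation = cation, anion = anion,
         dt = dt, n_frames = n_frames, seed = seed),
    class = "synthetic_solution_spec"
  )
}

#' Generate a synthetic solution trajectory with ground-truth labels
#'
#' Places ions and waters according to the spec (rejection sampling inside
#' the geometric region of each designed label, with margins covering the
#' full hydrogen sphere so labels are invariant under rotation), then evolves
#' every water orientation by [gen_rigid_rotations()] with its class's
#' diffusion coefficient. Water geometry is rigid and ideal (O-H 0.9572
#' Angstrom, H-O-H 104.52 degrees); oxygens are translationally frozen. The
#' realized labels of frame 1 are verified against the design.
#'
#' @param spec A [synthetic_solution_spec()].
#' @return List of class `synthetic_solution`: `traj` (a [trajectory()]),
#'   `truth` (tibble: molecule, label, D), `spec`, and the ion coordinates.
#' @export
gen_rotational_trajectory <- function(spec) {
  stopifnot(inherits(spec, "synthetic_solution_spec"))
  set.seed(spec$seed)
  geom <- place_synthetic_system(spec)
  n_w <- nrow(geom$truth)
  D <- geom$truth$D
  rot <- gen_rigid_rotations(n_w, D, spec$dt, spec$n_frames)
  # rigid ideal water: H = O + r_oh (cos(half) u +/- sin(half) p)
  r_oh <- 0.9572
  half <- 104.52 / 2 * pi / 180
  n_ions <- nrow(geom$ion_pos)
  n_atoms <- 3L * n_w + n_ions
  pos <- array(0, c(n_atoms, 3, spec$n_frames))
  o_rows <- 3L * (seq_len(n_w) - 1L) + 1L
  for (f in seq_len(spec$n_frames)) {
    u <- rot$u[, , f]; p <- rot$p[, , f]
    h1 <- geom$o_pos + r_oh * (cos(half) * u + sin(half) * p)
    h2 <- geom$o_pos + r_oh * (cos(half) * u - sin(half) * p)
    pos[o_rows, , f] <- geom$o_pos
    pos[o_rows + 1L, , f] <- h1
    pos[o_rows + 2L, , f] <- h2
    pos[3L * n_w + seq_len(n_ions), , f] <- geom$ion_pos
  }
  elements <- c(rep(c("O", "H", "H"), n_w), geom$ion_elements)
  traj <- trajectory(elements, pos, geom$box, dt = spec$dt)
  topo <- build_water_topology(traj)
  realized <- label_waters(frame_coords(traj, 1), topo, spec$cation_shells,
                           spec$anion_shells, geom$box,
                           cation = spec$cation, anion = spec$anion)
  if (!identical(realized, geom$truth$label)) {
    bad <- which(realized != geom$truth$label)
    stop(sprintf("placement failed label verification for %d water(s), e.g. water %d: designed %s, realized %s",
                 length(bad), bad[1], geom$truth$label[bad[1]], realized[bad[1]]),
         call. = FALSE)
  }
  structure(
    list(traj = traj, truth = geom$truth, spec = spec,
         topology = topo, box = geom$box),
    class = "synthetic_solution"
  )
}

# ion + water placement honouring the label geometry; margins cover the
# hydrogen sphere (r_OH + 0.25 A) so H shell states cannot flip under rotation
place_synthetic_system <- function(spec) {
  cs <- spec$cation_shells; as_ <- spec$anion_shells
  h_margin <- 0.9572 + 0.25
  o_margin <- 0.2
  spacing <- 2 * (as_$r_min2 + h_margin) + 8
  n_grid <- ceiling(spec$n_salt_units^(1 / 3))
  # bulk waters need room beyond every shell; scale the box with the load
  box_len <- max(n_grid * spacing,
                 (3 * (spec$n_bulk_waters + 50))^(1 / 3) + 2 * (as_$r_min2 + h_margin))
  box <- rep(box_len, 3)
  # contact-ion-pair-like separation: first shells just touching, which keeps
  # both the first-cation-shell classes and the cooperative W_211 region roomy
  d_mg_cl <- cs$r_min1 + as_$r_min1
  cat_pos <- matrix(0, spec$n_salt_units, 3)
  k <- 1L
  for (i in seq_len(n_grid)) for (j in seq_len(n_grid)) for (l in seq_len(n_grid)) {
    if (k > spec$n_salt_units) break
    cat_pos[k, ] <- (c(i, j, l) - 0.5) * spacing
    k <- k + 1L
  }
  an_pos <- do.call(rbind, lapply(seq_len(spec$n_salt_units), function(k) {
    rbind(cat_pos[k, ] + c(d_mg_cl, 0, 0), cat_pos[k, ] - c(d_mg_cl, 0, 0))
  }))
  o_state_band <- function(a) switch(a,
    "1" = c(1.6, cs$r_min1 - o_margin),
    "2" = c(cs$r_min1 + o_margin, cs$r_min2 - o_margin),
    "B" = c(cs$r_min2 + o_margin, Inf))
  h_ok <- function(o, state) {
    d <- min(mi_distances(an_pos, o, box))
    switch(state,
      "1" = d + h_margin < as_$r_min1,
      "2" = d - h_margin >= as_$r_min1 && d + h_margin < as_$r_min2,
      "B" = d - h_margin >= as_$r_min2)
  }
  a_ok <- function(o, a) {
    d <- min(mi_distances(cat_pos, o, box))
    band <- o_state_band(a)
    d >= band[1] && d < band[2]
  }
  placed <- list()
  labels <- character(0)
  sample_water <- function(label, unit) {
    s <- strsplit(sub("W_", "", label), "")[[1]]
    a <- s[1]; hs <- s[2]
    for (attempt in seq_len(20000)) {
      if (a != "B") {
        band <- o_state_band(a)
        r <- stats::runif(1, band[1], band[2])
        o <- cat_pos[unit, ] + r * unitize(stats::rnorm(3))
      } else if (hs != "B") {
        an_band <- switch(hs,
          "1" = c(1.6, as_$r_min1 - h_margin),
          "2" = c(as_$r_min1 + h_margin, as_$r_min2 - h_margin))
        host <- 2L * (unit - 1L) + sample(2L, 1L)
        r <- stats::runif(1, an_band[1], an_band[2])
        o <- an_pos[host, ] + r * unitize(stats::rnorm(3))
      } else {
        o <- stats::runif(3, 0, box)
      }
      o <- o - box * floor(o / box)
      if (!a_ok(o, a) || !h_ok(o, hs)) next
      if (length(placed) > 0) {
        pm <- do.call(rbind, placed)
        # keep O-O spacing above the covalent cutoff plus an O-H arm, so a
        # neighbour's hydrogen can never be claimed by this oxygen
        if (min(mi_distances(pm, o, box)) < 2.2) next
      }
      return(o)
    }
    stop(sprintf("infeasible packing: could not place a %s water", label), call. = FALSE)
  }
  for (unit in seq_len(spec$n_salt_units)) {
    for (lab in names(spec$class_counts)) {
      for (rep_i in seq_len(spec$class_counts[[lab]])) {
        placed[[length(placed) + 1L]] <- sample_water(lab, unit)
        labels <- c(labels, lab)
      }
    }
  }
  for (i in seq_len(spec$n_bulk_waters)) {
    placed[[length(placed) + 1L]] <- sample_water("W_BBB", 1L)
    labels <- c(labels, "W_BBB")
  }
  if (length(placed) == 0) stop("spec places no waters", call. = FALSE)
  o_pos <- do.call(rbind, placed)
  D <- vapply(labels, function(l) {
    if (l %in% names(spec$D_by_class)) spec$D_by_class[[l]] else spec$D_bulk
  }, numeric(1))
  truth <- tibble::tibble(molecule = seq_along(labels), label = labels, D = unname(D))
  list(o_pos = o_pos, ion_pos = rbind(cat_pos, an_pos),
       ion_elements = c(rep(spec$cation, spec$n_salt_units),
                        rep(spec$anion, 2L * spec$n_salt_units)),
       truth = truth, box = box)
}

#' Poisson hydrogen-bond breaking event series
#'
#' Every pair starts bonded; at each step it breaks with probability
#' `1 - exp(-k_break dt)` and never reforms (the continuous-survival test
#' case). The exact survival law is `S(t) = exp(-k_break t)`.
#'
#' @param n_pairs Number of bonded pairs.
#' @param k_break Breaking rate (1/ps); 0 keeps all pairs bonded.
#' @param dt Time step (ps).
#' @param n_frames Number of frames.
#' @param seed RNG seed.
#' @return `n_pairs x n_frames` 0/1 integer matrix.
#' @export
gen_hb_event_series <- function(n_pairs, k_break, dt, n_frames, seed = 1) {
  stopifnot(n_pairs >= 1, k_break >= 0, dt > 0, n_frames >= 1)
  set.seed(seed)
  h <- matrix(0L, n_pairs, n_frames)
  if (k_break == 0) {
    h[] <- 1L
    return(h)
  }
  q <- 1 - exp(-k_break * dt)
  lifetime <- 1L + stats::rgeom(n_pairs, q)  # frames spent bonded
  lifetime <- pmin(lifetime, n_frames)
  for (p in seq_len(n_pairs)) h[p, seq_len(lifetime[p])] <- 1L
  h
}

#' Toy hydrogen-bond fixtures with known bond counts
#'
#' Single-frame configurations for detector tests: an ideal near-linear water
#' dimer (1 bond), the same dimer stretched past the O-O cutoff (0 bonds),
#' the same dimer bent past the angle cutoff (0 bonds), and a tetrahedral
#' pentamer whose central water donates twice and accepts twice (4 bonds at
#' the centre).
#'
#' @return Named list of fixtures; each holds `elements`, `pos`, `cell`,
#'   `expected_bonds` (total), and for the pentamer `central_nhb`.
#' @export
gen_toy_hb_configurations <- function() {
  r_oh <- 0.9572
  cell <- c(30, 30, 30)
  dimer <- function(d_oo, angle_deg) {
    th <- angle_deg * pi / 180
    o_d <- c(5, 5, 5)
    o_a <- o_d + c(d_oo, 0, 0)
    h1 <- o_d + r_oh * c(cos(th), sin(th), 0)       # donated H, off-axis by angle
    h2 <- o_d + r_oh * c(cos(2.1), sin(2.1), 0)     # spectator H, ~120 deg away
    # acceptor hydrogens point away from the donor
    ha1 <- o_a + r_oh * c(cos(1.0), 0, sin(1.0))
    ha2 <- o_a + r_oh * c(cos(1.0), 0, -sin(1.0))
    list(elements = c("O", "H", "H", "O", "H", "H"),
         pos = rbind(o_d, h1, h2, o_a, ha1, ha2), cell = cell)
  }
  ideal <- dimer(2.8, 5); ideal$expected_bonds <- 1L
  stretched <- dimer(3.6, 5); stretched$expected_bonds <- 0L
  bent <- dimer(2.8, 35); bent$expected_bonds <- 0L
  # tetrahedral pentamer
  t_dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  o_c <- c(15, 15, 15)
  d_oo <- 2.8
  pos <- o_c
  elements <- "O"
  pos <- rbind(pos, o_c + r_oh * t_dirs[1, ], o_c + r_oh * t_dirs[2, ])
  elements <- c(elements, "H", "H")
  for (i in 1:2) {  # acceptors of the central water's donated bonds
    o_p <- o_c + d_oo * t_dirs[i, ]
    perp <- unitize(pracma_nullvec(t_dirs[i, ]))
    pos <- rbind(pos, o_p,
                 o_p + r_oh * unitize(t_dirs[i, ] + 1.6 * perp),
                 o_p + r_oh * unitize(t_dirs[i, ] - 1.6 * perp))
    elements <- c(elements, "O", "H", "H")
  }
  for (i in 3:4) {  # donors pointing one H straight at the central oxygen
    o_p <- o_c + d_oo * t_dirs[i, ]
    perp <- unitize(pracma_nullvec(t_dirs[i, ]))
    pos <- rbind(pos, o_p,
                 o_p - r_oh * t_dirs[i, ],
                 o_p + r_oh * unitize(t_dirs[i, ] + 1.6 * perp))
    elements <- c(elements, "O", "H", "H")
  }
  pentamer <- list(elements = elements, pos = unname(pos), cell = cell,
                   expected_bonds = 4L, central_nhb = 4L)
  list(ideal_dimer = ideal, stretched_dimer = stretched,
       bent_dimer = bent, tetrahedral_pentamer = pentamer)
}

# any vector perpendicular to v
pracma_nullvec <- function(v) {
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  ref - v * sum(ref * v) / sum(v * v)
}

#' Specification of a synthetic dielectric spectrum
#'
#' @param S1,S2,tau1,tau2,eps_inf Double-Debye parameters (strengths
#'   dimensionless, times in ps).
#' @param conductivity DC conductivity added as an Ohmic loss (S/m).
#' @param noise Multiplicative Gaussian noise level (relative sd).
#' @param freq Frequency grid (GHz); default 200 log-spaced points over
#'   0.01-110 GHz, the usual coaxial-probe window.
#' @param concentration Solute molality (mol/kg).
#' @param water_concentration Water molarity (mol/L).
#' @param seed RNG seed.
#' @return Object of class `synthetic_spectrum_spec`.
#' @export
synthetic_spectrum_spec <- function(S1 = 72, S2 = 2.5, tau1 = 8.3, tau2 = 0.25,
                                    eps_inf = 3.52, conductivity = 0, noise = 0,
                                    freq = 10^seq(log10(0.01), log10(110), length.out = 200),
                                    concentration = 0,
                                    water_concentration = 55.35, seed = 1) {
  stopifnot(S1 >= 0, S2 >= 0, tau1 > 0, tau2 > 0, conductivity >= 0, noise >= 0)
  structure(
    list(S1 = S1, S2 = S2, tau1 = tau1, tau2 = tau2, eps_inf = eps_inf,
         conductivity = conductivity, noise = noise, freq = freq,
         concentration = concentration,
         water_concentration = water_concentration, seed = seed),
    class = "synthetic_spectrum_spec"
  )
}

#' Generate a synthetic dielectric spectrum
#'
#' Evaluates the double-Debye model on the grid, adds the Ohmic conductivity
#' term `sigma/(omega eps_0)` to the loss, and applies multiplicative
#' Gaussian noise to both parts.
#'
#' @param spec A [synthetic_spectrum_spec()].
#' @return A [dielectric_spectrum()].
#' @export
gen_dielectric_spectrum <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spectrum_spec"))
  set.seed(spec$seed)
  eps <- double_debye_eps(spec$freq, spec$S1, spec$S2, spec$tau1, spec$tau2,
                          spec$eps_inf)
  re <- Re(eps); im <- -Im(eps)
  if (spec$conductivity > 0) {
    im <- im + spec$conductivity / (2 * pi * spec$freq * 1e9 * .eps0)
  }
  if (spec$noise > 0) {
    re <- re * (1 + stats::rnorm(length(re), 0, spec$noise))
    im <- im * (1 + stats::rnorm(length(im), 0, spec$noise))
  }
  dielectric_spectrum(spec$freq, re, im, conductivity = spec$conductivity,
                      concentration = spec$concentration,
                      water_concentration = spec$water_concentration)
}

#' Synthetic concentration series with a designed hydration number
#'
#' Builds a pure-water reference plus one spectrum per concentration whose
#' strengths are constructed so that the depolarization chain recovers the
#' designed `N_hyd`: the static depolarization is obtained by inverting the
#' hydration-number relation, the kinetic part from the perfect-slip model at
#' the supplied conductivities, and the water molarity from a linear
#' density model for a divalent chloride salt.
#'
#' @param concentrations Molalities (mol/kg), excluding 0.
#' @param N_hyd_design Designed hydration number (waters per salt unit;
#'   length 1 or one per concentration).
#' @param conductivity Conductivities (S/m) per concentration; default
#'   `6 * c` (typical order for a strong 2:1 electrolyte).
#' @param reference A [synthetic_spectrum_spec()] for pure water.
#' @param noise Multiplicative noise applied to every spectrum.
#' @param seed RNG seed.
#' @return List with `reference` (a [dielectric_spectrum()]) and `solutions`
#'   (list of spectra), plus the design table `design`.
#' @export
gen_concentration_series <- function(concentrations, N_hyd_design = 12,
                                     conductivity = NULL,
                                     reference = synthetic_spectrum_spec(),
                                     noise = 0, seed = 1) {
  stopifnot(all(concentrations > 0))
  n_c <- length(concentrations)
  N_hyd_design <- rep_len(N_hyd_design, n_c)
  conductivity <- conductivity %||% (6 * concentrations)
  s0 <- reference$S1 + reference$S2
  eps_s0 <- s0 + reference$eps_inf
  ch2o_0 <- reference$water_concentration
  molar_mass_salt <- 0.09521  # kg/mol, MgCl2-like solute
  rows <- purrr::pmap(list(concentrations, N_hyd_design, conductivity, seq_len(n_c)),
    function(c_i, nh, sig, i) {
      density <- 0.997 + 0.075 * c_i              # kg/L, linear brine model
      ch2o_c <- 55.508 / ((1 + molar_mass_salt * c_i) / density)
      dS_static <- s0 * ((ch2o_c - nh * c_i) / ch2o_0 - 1)
      dS_kinetic <- -(2 / 3) * sig * (reference$tau1 * 1e-12) *
        (eps_s0 - reference$eps_inf) / (eps_s0 * .eps0)
      s_c <- s0 + dS_static + dS_kinetic
      if (s_c <= reference$S2) {
        stop("designed N_hyd too large for this concentration: strength exhausted",
             call. = FALSE)
      }
      list(spec = synthetic_spectrum_spec(
             S1 = s_c - reference$S2, S2 = reference$S2,
             tau1 = reference$tau1 * (1 + 0.05 * c_i), tau2 = reference$tau2,
             eps_inf = reference$eps_inf, conductivity = sig, noise = noise,
             freq = reference$freq, concentration = c_i,
             water_concentration = ch2o_c, seed = seed + i),
           design = tibble::tibble(concentration = c_i, N_hyd = nh,
                                   conductivity = sig, S_c = s_c,
                                   dS_static = dS_static,
                                   dS_kinetic = dS_kinetic,
                                   water_molarity = ch2o_c))
    })
  ref_spec <- reference
  ref_spec$noise <- noise
  ref_spec$seed <- seed
  list(
    reference = gen_dielectric_spectrum(ref_spec),
    solutions = lapply(rows, function(r) gen_dielectric_spectrum(r$spec)),
    design = dplyr::bind_rows(lapply(rows, `[[`, "design"))
  )
}
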