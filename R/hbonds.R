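#' Geometric hydrogen-bond criteria
#'
#' An HB between donor water j (providing hydrogen k) and acceptor water i
#' exists when all of: `|Oi - Oj| < r_OO_max`, `|Oj - Hk| < r_OH_cov_max`
#' (covalent attachment to the donor), `|Oi - Hk| < r_OH_hb_max`, and the
#' angle at the donor oxygen between the O->O and O->H vectors is at most
#' `theta_max` degrees. The angle vertex is configurable (`"donor"` default;
#' `"acceptor"` measures the angle at the acceptor oxygen between O->O and
#' O->H) for sensitivity checks, the two conventions differing in how bent
#' bonds are counted.
#'
#' @param r_OO_max O-O distance cutoff (Angstrom).
#' @param r_OH_cov_max Covalent O-H cutoff (Angstrom).
#' @param r_OH_hb_max Hydrogen-acceptor distance cutoff (Angstrom).
#' @param theta_max Angle cutoff (degrees).
#' @param angle_vertex `"donor"` or `"acceptor"`.
#' @return Object of class `hb_criteria`.
#' @export
hb_criteria <- function(r_OO_max = 3.5, r_OH_cov_max = 1.2, r_OH_hb_max = 2.5,
                        theta_max = 30, angle_vertex = c("donor", "acceptor")) {
  angle_vertex <- match.arg(angle_vertex)
  stopifnot(r_OO_max > 0, r_OH_cov_max > 0, r_OH_hb_max > r_OH_cov_max, theta_max > 0)
  structure(list(r_OO_max = r_OO_max, r_OH_cov_max = r_OH_cov_max,
                 r_OH_hb_max = r_OH_hb_max, theta_max = theta_max,
                 angle_vertex = angle_vertex),
            class = "hb_criteria")
}

#' Detect hydrogen bonds in one frame
#'
#' @param pos `n_atoms x 3` position matrix (Angstrom), e.g. from
#'   [frame_coords()].
#' @param topology A [build_water_topology()] result.
#' @param criteria An [hb_criteria()].
#' @param cell Box lengths (3-vector, Angstrom).
#' @return Tibble with one row per bond: `donor` (molecule index), `acceptor`
#'   (molecule index), `H` (atom index of the donated hydrogen).
#' @export
detect_hbonds <- function(pos, topology, criteria = hb_criteria(), cell) {
  stopifnot(inherits(topology, "water_topology"), inherits(criteria, "hb_criteria"))
  mol <- topology$molecules
  n_mol <- nrow(mol)
  empty <- tibble::tibble(donor = integer(0), acceptor = integer(0), H = integer(0))
  if (n_mol < 2) return(empty)
  o_pos <- pos[mol$O, , drop = FALSE]
  doo <- mi_cross_distances(o_pos, o_pos, cell)
  diag(doo) <- Inf
  cos_max <- cos(criteria$theta_max * pi / 180)
  donors <- integer(0); acceptors <- integer(0); hyds <- integer(0)
  for (j in seq_len(n_mol)) {
    cand <- which(doo[j, ] < criteria$r_OO_max)
    if (length(cand) == 0) next
    oj <- o_pos[j, ]
    for (h_atom in c(mol$H1[j], mol$H2[j])) {
      vh <- minimum_image_displacement(oj, pos[h_atom, ], cell)
      dh <- sqrt(sum(vh * vh))
      if (dh >= criteria$r_OH_cov_max) next
      for (i in cand) {
        voo <- minimum_image_displacement(oj, o_pos[i, ], cell)
        # H-acceptor distance via minimum image of (H - Oi)
        vha <- minimum_image_displacement(pos[h_atom, ], o_pos[i, ], cell)
        if (sqrt(sum(vha * vha)) >= criteria$r_OH_hb_max) next
        if (criteria$angle_vertex == "donor") {
          cosang <- sum(voo * vh) / (sqrt(sum(voo * voo)) * dh)
        } else {
          # vertex at acceptor oxygen: angle between Oi->Oj and Oi->Hk
          voj <- -voo
          vhk <- -vha
          cosang <- sum(voj * vhk) / (sqrt(sum(voj * voj)) * sqrt(sum(vhk * vhk)))
        }
        if (cosang >= cos_max) {
          donors <- c(donors, j); acceptors <- c(acceptors, i); hyds <- c(hyds, h_atom)
        }
      }
    }
  }
  tibble::tibble(donor = donors, acceptor = acceptors, H = hyds)
}

#' Hydrogen-bond statistics over a trajectory
#'
#' For each selected water molecule, the per-frame HB count is the number of
#' bonds it donates plus the number it accepts. Returns the mean count and the
#' distribution over n, averaged over frames.
#'
#' @param traj A [trajectory()].
#' @param topology A [build_water_topology()] result.
#' @param criteria An [hb_criteria()].
#' @param selection Optional `function(traj, frame)` returning the molecule
#'   indices to tally in that frame (e.g. a hydration-shell selection from
#'   [shell_selection()]); `NULL` selects all waters. Bonds to waters outside
#'   the selection still count for the selected molecule.
#' @param frames Frame indices to use (default all).
#' @return Tibble of class `hb_stats` with columns `n` (0, 1, ...) and
#'   `percent`; attributes `mean_nhb` and `n_samples`.
#' @export
hbond_statistics <- function(traj, topology, criteria = hb_criteria(),
                             selection = NULL, frames = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(frames)) frames <- seq_len(traj$n_frames)
  n_mol <- nrow(topology$molecules)
  tallies <- integer(0)
  for (f in frames) {
    sel <- if (is.null(selection)) seq_len(n_mol) else selection(traj, f)
    if (length(sel) == 0) next
    bonds <- detect_hbonds(frame_coords(traj, f), topology, criteria, frame_cell(traj, f))
    counts <- tabulate(bonds$donor, nbins = n_mol) + tabulate(bonds$acceptor, nbins = n_mol)
    tallies <- c(tallies, counts[sel])
  }
  if (length(tallies) == 0) {
    stop("selection is empty in every frame", call. = FALSE)
  }
  dist <- tibble::tibble(n = 0:max(tallies),
                         percent = 100 * tabulate(tallies + 1L, nbins = max(tallies) + 1L) /
                           length(tallies))
  class(dist) <- c("hb_stats", class(dist))
  attr(dist, "mean_nhb") <- mean(tallies)
  attr(dist, "n_samples") <- length(tallies)
  dist
}

#' Mean HB count of an `hb_stats` table
#' @param stats An [hbond_statistics()] result.
#' @return Mean number of hydrogen bonds per selected water.
#' @export
mean_nhb <- function(stats) {
  stopifnot(inherits(stats, "hb_stats"))
  attr(stats, "mean_nhb")
}

#' Hydration-shell water selection
#'
#' Builds a `function(traj, frame)` usable as the `selection` argument of
#' [hbond_statistics()], [dipole_tcf()] or [vdos()]: waters whose oxygen (or
#' either hydrogen, for anions) lies in the requested shell of any ion of a
#' species.
#'
#' @param topology A [build_water_topology()] result.
#' @param species Ion element symbol.
#' @param boundaries A [shell_boundaries()] for the ion-water pair.
#' @param shell 1 (first shell), 2 (second), or `"beyond"`.
#' @param site `"O"` to measure ion-oxygen distances, `"H"` for ion-hydrogen
#'   (nearer hydrogen decides).
#' @return A selection function.
#' @export
shell_selection <- function(topology, species, boundaries, shell = 1,
                            site = c("O", "H")) {
  site <- match.arg(site)
  stopifnot(inherits(boundaries, "shell_boundaries"))
  ions <- ion_atoms(topology, species)
  if (length(ions) == 0) stop(sprintf("no ions of species %s", species), call. = FALSE)
  mol <- topology$molecules
  function(traj, frame) {
    pos <- frame_coords(traj, frame)
    cell <- frame_cell(traj, frame)
    ion_pos <- pos[ions, , drop = FALSE]
    if (site == "O") {
      d <- mi_nearest_distances(pos[mol$O, , drop = FALSE], ion_pos, cell)
    } else {
      d <- pmin(mi_nearest_distances(pos[mol$H1, , drop = FALSE], ion_pos, cell),
                mi_nearest_distances(pos[mol$H2, , drop = FALSE], ion_pos, cell))
    }
    if (identical(shell, 1)) {
      which(d < boundaries$r_min1)
    } else if (identical(shell, 2)) {
      which(d >= boundaries$r_min1 & d < boundaries$r_min2)
    } else {
      which(d >= boundaries$r_min2)
    }
  }
}
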