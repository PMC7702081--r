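#' Classify cation-anion pairs as CIP / SSHIP / SSIP
#'
#' Per cation, the nearest anion within a counting horizon is classified by
#' its minimum-image distance d against the cation-anion shell boundaries:
#' contact ion pair (CIP) when `d < r_min1`, solvent-shared (SSHIP) when
#' `r_min1 <= d < r_min2`, solvent-separated (SSIP) when
#' `r_min2 <= d < horizon`. Cations with no anion inside the horizon are not
#' counted.
#'
#' @param pos `n_atoms x 3` position matrix for one frame.
#' @param topology A [build_water_topology()] result.
#' @param boundaries [shell_boundaries()] for the cation-anion distance.
#' @param cell Box lengths (3-vector, Angstrom).
#' @param cation,anion Ion element symbols.
#' @param horizon Counting radius for SSIP (Angstrom, default 8).
#' @return Tibble of class `speciation` with columns `species`
#'   (CIP/SSHIP/SSIP), `count`, and `percent` (summing to 100 when any pair
#'   was counted); attribute `n_pairs`.
#' @export
classify_ion_pairs <- function(pos, topology, boundaries, cell,
                               cation = "Mg", anion = "Cl", horizon = 8) {
  stopifnot(inherits(boundaries, "shell_boundaries"))
  cats <- ion_atoms(topology, cation)
  ans <- ion_atoms(topology, anion)
  if (length(cats) == 0 || length(ans) == 0) {
    stop(sprintf("need both %s and %s ions in the topology", cation, anion), call. = FALSE)
  }
  d <- mi_cross_distances(pos[cats, , drop = FALSE], pos[ans, , drop = FALSE], cell)
  nearest <- apply(d, 1, min)
  nearest <- nearest[nearest < horizon]
  counts <- c(
    CIP = sum(nearest < boundaries$r_min1),
    SSHIP = sum(nearest >= boundaries$r_min1 & nearest < boundaries$r_min2),
    SSIP = sum(nearest >= boundaries$r_min2)
  )
  n_pairs <- sum(counts)
  pct <- if (n_pairs > 0) 100 * counts / n_pairs else rep(0, 3)
  out <- tibble::tibble(species = names(counts), count = unname(counts),
                        percent = unname(pct))
  class(out) <- c("speciation", class(out))
  attr(out, "n_pairs") <- n_pairs
  out
}

#' Count water exchanges across a shell boundary (direct method)
#'
#' A water is tracked by its oxygen (for cations) or nearer hydrogen (for
#' anions). An exchange event is counted whenever the tracked atom crosses the
#' shell boundary and remains on the new side for at least `t_star`
#' continuously; shorter excursions are treated as flickers and ignored.
#'
#' @param traj A [trajectory()].
#' @param topology A [build_water_topology()] result.
#' @param ion Atom index of the ion.
#' @param boundary Shell boundary distance (Angstrom).
#' @param t_star Minimum persistence time (ps, default 0.5).
#' @param site `"O"` or `"H"`, which water atom is tracked.
#' @return Total number of exchange events (in + out) over the trajectory.
#' @export
count_water_exchanges <- function(traj, topology, ion, boundary, t_star = 0.5,
                                  site = c("O", "H")) {
  site <- match.arg(site)
  stopifnot(inherits(traj, "trajectory"), t_star >= 0)
  if ((traj$n_frames - 1) * traj$dt < t_star) {
    stop("trajectory shorter than `t_star`", call. = FALSE)
  }
  mol <- topology$molecules
  n_mol <- nrow(mol)
  inside <- matrix(FALSE, traj$n_frames, n_mol)
  for (f in seq_len(traj$n_frames)) {
    pos <- frame_coords(traj, f)
    cell <- frame_cell(traj, f)
    ion_pos <- pos[ion, ]
    if (site == "O") {
      d <- mi_distances(pos[mol$O, , drop = FALSE], ion_pos, cell)
    } else {
      d <- pmin(mi_distances(pos[mol$H1, , drop = FALSE], ion_pos, cell),
                mi_distances(pos[mol$H2, , drop = FALSE], ion_pos, cell))
    }
    inside[f, ] <- d < boundary
  }
  min_frames <- max(1L, ceiling(t_star / traj$dt))
  total <- 0L
  for (m in seq_len(n_mol)) {
    total <- total + count_persistent_crossings(inside[, m], min_frames)
  }
  total
}

# events = transitions between consecutive stable residences (runs >= min_frames)
count_persistent_crossings <- function(series, min_frames) {
  r <- rle(series)
  stable_sides <- r$values[r$lengths >= min_frames]
  if (length(stable_sides) < 2) return(0L)
  sum(stable_sides[-1] != stable_sides[-length(stable_sides)])
}
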