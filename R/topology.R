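#' Build a fixed water topology from a reference frame
#'
#' Assigns each water oxygen its two covalently bonded hydrogens by
#' minimum-image distance in one reference frame, and collects the remaining
#' (non-water) atoms as ions by species. The topology is built once and held
#' fixed for the whole trajectory: the systems targeted here show no O-H
#' dissociation, so a static connectivity is appropriate.
#'
#' @param traj A [trajectory()].
#' @param frame Reference frame used for the O-H assignment (default 1).
#' @param oh_cutoff Covalent O-H cutoff (Angstrom, default 1.2).
#' @param oxygen,hydrogen Element symbols identifying water atoms.
#' @return An object of class `water_topology`: list with
#'   `molecules` (tibble with columns `O`, `H1`, `H2` of atom indices),
#'   `ion_indices` (named list of atom index vectors per ion species),
#'   and the assignment parameters.
#' @export
build_water_topology <- function(traj, frame = 1, oh_cutoff = 1.2,
                                 oxygen = "O", hydrogen = "H") {
  stopifnot(inherits(traj, "trajectory"))
  pos <- frame_coords(traj, frame)
  cell <- frame_cell(traj, frame)
  o_idx <- which(traj$elements == oxygen)
  h_idx <- which(traj$elements == hydrogen)
  assigned_h <- integer(0)
  mol <- matrix(0L, length(o_idx), 3)
  if (length(o_idx) > 0) {
    if (length(h_idx) == 0) stop("no hydrogen atoms found", call. = FALSE)
    hd <- mi_cross_distances(pos[o_idx, , drop = FALSE], pos[h_idx, , drop = FALSE], cell)
    for (k in seq_along(o_idx)) {
      within <- which(hd[k, ] < oh_cutoff)
      if (length(within) != 2) {
        stop(sprintf(
          "oxygen atom %d has %d hydrogens within %.2f A (need exactly 2)",
          o_idx[k], length(within), oh_cutoff
        ), call. = FALSE)
      }
      mol[k, ] <- c(o_idx[k], h_idx[within])
      assigned_h <- c(assigned_h, h_idx[within])
    }
    if (anyDuplicated(assigned_h)) {
      stop("a hydrogen atom is shared by two oxygens; decrease `oh_cutoff`", call. = FALSE)
    }
  }
  unassigned_h <- setdiff(h_idx, assigned_h)
  if (length(unassigned_h) > 0) {
    stop(sprintf(
      "hydrogen atom(s) %s belong to no water molecule within %.2f A",
      paste(unassigned_h, collapse = ", "), oh_cutoff
    ), call. = FALSE)
  }
  other <- setdiff(seq_len(traj$n_atoms), c(o_idx, h_idx))
  ion_indices <- split(other, traj$elements[other])
  structure(
    list(
      molecules = tibble::tibble(O = mol[, 1], H1 = mol[, 2], H2 = mol[, 3]),
      ion_indices = lapply(ion_indices, as.integer),
      oh_cutoff = oh_cutoff,
      reference_frame = frame
    ),
    class = "water_topology"
  )
}

#' @export
print.water_topology <- function(x, ...) {
  ions <- if (length(x$ion_indices) == 0) "none" else {
    paste(sprintf("%s:%d", names(x$ion_indices), lengths(x$ion_indices)), collapse = " ")
  }
  cat(sprintf("<water_topology> %d waters; ions: %s (O-H cutoff %.2f A, frame %d)\n",
              nrow(x$molecules), ions, x$oh_cutoff, x$reference_frame))
  invisible(x)
}

#' Atom indices of the ions of one species
#' @param topology A [build_water_topology()] result.
#' @param species Element symbol, e.g. `"Mg"`.
#' @return Integer vector (possibly empty).
#' @export
ion_atoms <- function(topology, species) {
  stopifnot(inherits(topology, "water_topology"))
  idx <- topology$ion_indices[[species]]
  if (is.null(idx)) integer(0) else idx
}
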