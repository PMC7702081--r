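#' Vibrational density of states from velocity autocorrelation
#'
#' Computes the normalized velocity autocorrelation function (VACF) per
#' species over multiple time origins, applies a Hann window, and reports the
#' magnitude of the one-sided discrete Fourier transform on a wavenumber grid
#' (cm^-1). The total spectrum is the sum of the species spectra. Mass
#' weighting is off: plain velocity autocorrelations are summed.
#'
#' @param traj A [trajectory()] with velocities.
#' @param window VACF window (ps); sets the frequency resolution
#'   `1/(window c)`.
#' @param species Character vector of element symbols to resolve (default
#'   water oxygen and hydrogen).
#' @param selection Optional `function(traj, frame)` returning molecule
#'   indices (evaluated at each origin) restricting the average, e.g. the
#'   first hydration shell of a cation via [shell_selection()]; requires
#'   `topology`.
#' @param topology Needed with `selection` to map molecules to atoms.
#' @param origin_stride,n_origins_target See [correlate()].
#' @return Tibble of class `vdos_spectrum` with columns `wavenumber` (cm^-1),
#'   `species`, `intensity` (arbitrary units); the summed spectrum appears as
#'   species `"total"`.
#' @export
vdos <- function(traj, window, species = c("O", "H"), selection = NULL,
                 topology = NULL, origin_stride = NULL, n_origins_target = 1024) {
  stopifnot(inherits(traj, "trajectory"))
  if (is.null(traj$velocities)) stop("trajectory has no velocities", call. = FALSE)
  if (!is.null(selection) && is.null(topology)) {
    stop("`selection` requires `topology`", call. = FALSE)
  }
  wf <- window_frames(window, traj$dt, traj$n_frames)
  origins <- derive_origins(traj$n_frames, wf, origin_stride, n_origins_target)
  per_species <- list()
  for (sp in species) {
    atoms <- which(traj$elements == sp)
    if (length(atoms) == 0) next
    member <- NULL
    if (!is.null(selection)) {
      mol <- topology$molecules
      member <- matrix(FALSE, length(origins), length(atoms))
      for (i in seq_along(origins)) {
        sel_mol <- selection(traj, origins[i])
        sel_atoms <- c(mol$O[sel_mol], mol$H1[sel_mol], mol$H2[sel_mol])
        member[i, ] <- atoms %in% sel_atoms
      }
    }
    v <- traj$velocities[atoms, , , drop = FALSE]
    res <- cpp_tcf_dot(v, origins, wf + 1L, member)
    vacf <- res$value / res$value[1]
    per_species[[sp]] <- vacf
  }
  if (length(per_species) == 0) stop("no atoms of the requested species", call. = FALSE)
  n <- wf + 1L
  hann <- 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1)))
  c_cm_per_ps <- 2.99792458e-2  # speed of light in cm/ps
  wavenumber <- seq(0, n - 1) / (n * traj$dt * c_cm_per_ps)
  one_sided <- seq_len(floor(n / 2) + 1L)
  rows <- purrr::imap(per_species, function(vacf, sp) {
    spec <- Mod(stats::fft(vacf * hann))[one_sided]
    tibble::tibble(wavenumber = wavenumber[one_sided], species = sp, intensity = spec)
  })
  out <- dplyr::bind_rows(rows)
  total <- out |>
    dplyr::summarise(intensity = sum(.data$intensity), .by = "wavenumber") |>
    dplyr::mutate(species = "total", .after = "wavenumber")
  out <- dplyr::bind_rows(out, total)
  class(out) <- c("vdos_spectrum", class(out))
  attr(out, "resolution") <- wavenumber[2]
  attr(out, "window") <- window
  out
}

#' Peak wavenumber of a VDOS spectrum
#' @param spectrum A [vdos()] result.
#' @param species Which species trace to use (default `"total"`).
#' @param above Ignore wavenumbers below this value (cm^-1, default 0).
#' @return Wavenumber of the maximum intensity (cm^-1).
#' @export
vdos_peak <- function(spectrum, species = "total", above = 0) {
  stopifnot(inherits(spectrum, "vdos_spectrum"))
  sub <- spectrum[spectrum$species == species & spectrum$wavenumber >= above, ]
  sub$wavenumber[which.max(sub$intensity)]
}
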