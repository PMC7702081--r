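#' Radial distribution function between two species
#'
#' Computes g(r) for the pair (A, B): the probability, relative to an ideal gas
#' at the same density, of finding a B atom at distance r from an A atom.
#' Distances use the minimum-image convention; normalization divides the mean
#' per-A bin count by the exact ideal-gas shell count `rho_B * V_shell`, and
#' averages over frames.
#'
#' @param traj A [trajectory()].
#' @param pair Character 2-vector of element symbols `c(A, B)`.
#' @param r_max Histogram range (Angstrom); must not exceed half the smallest
#'   box length.
#' @param bin_width Bin width (Angstrom).
#' @param frames Frame indices to average over (default all).
#' @return A tibble of class `rdf_profile` with columns `r` (bin centers,
#'   Angstrom), `g`, and `count` (mean pair count per bin per frame), plus
#'   attributes `pair`, `density_B` (Angstrom^-3), `bin_width`, `n_frames`.
#' @export
compute_rdf <- function(traj, pair, r_max, bin_width = 0.05, frames = NULL) {
  stopifnot(inherits(traj, "trajectory"), length(pair) == 2)
  if (is.null(frames)) frames <- seq_len(traj$n_frames)
  half_min_box <- min(traj$cell[frames, ]) / 2
  if (r_max > half_min_box + 1e-9) {
    stop(sprintf("r_max = %.3f A exceeds half the smallest box length (%.3f A)",
                 r_max, half_min_box), call. = FALSE)
  }
  ia <- which(traj$elements == pair[1])
  ib <- which(traj$elements == pair[2])
  if (length(ia) == 0 || length(ib) == 0) {
    stop(sprintf("no atoms found for pair (%s, %s)", pair[1], pair[2]), call. = FALSE)
  }
  same <- identical(pair[1], pair[2])
  edges <- seq(0, r_max, by = bin_width)
  if (abs(edges[length(edges)] - r_max) > 1e-12) edges <- c(edges, r_max)
  n_bins <- length(edges) - 1
  counts <- numeric(n_bins)
  vol_sum <- 0
  for (f in frames) {
    pos <- frame_coords(traj, f)
    cell <- frame_cell(traj, f)
    d <- mi_cross_distances(pos[ia, , drop = FALSE], pos[ib, , drop = FALSE], cell)
    if (same) diag(d) <- Inf
    d <- d[d < r_max]
    if (length(d) > 0) {
      counts <- counts + tabulate(findInterval(d, edges, left.open = TRUE), nbins = n_bins)
    }
    vol_sum <- vol_sum + prod(cell)
  }
  n_f <- length(frames)
  mean_counts <- counts / n_f
  v_mean <- vol_sum / n_f
  density_b <- (length(ib) - as.integer(same)) / v_mean
  shell_vol <- 4 / 3 * pi * (edges[-1]^3 - edges[-length(edges)]^3)
  g <- mean_counts / (length(ia) * density_b * shell_vol)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  out <- tibble::tibble(r = centers, g = g, count = mean_counts)
  class(out) <- c("rdf_profile", class(out))
  attr(out, "pair") <- pair
  attr(out, "density_B") <- density_b
  attr(out, "bin_width") <- bin_width
  attr(out, "n_frames") <- n_f
  out
}

#' Coordination number by RDF integration
#'
#' Integrates `4 pi rho_B g(r) r^2` from 0 to `r_cut` by the trapezoid rule on
#' the bin centers, giving the average number of B atoms within `r_cut` of an
#' A atom.
#'
#' @param rdf An [compute_rdf()] profile.
#' @param r_cut Integration limit (Angstrom), typically a shell minimum.
#' @return Average coordination number (dimensionless).
#' @export
coordination_number <- function(rdf, r_cut) {
  stopifnot(inherits(rdf, "rdf_profile"))
  if (r_cut < 0 || r_cut > max(rdf$r) + attr(rdf, "bin_width") / 2) {
    stop("`r_cut` outside the RDF range", call. = FALSE)
  }
  rho <- attr(rdf, "density_B")
  keep <- rdf$r <= r_cut
  if (sum(keep) < 2) return(0)
  # integrate from 0 (where g r^2 vanishes) to exactly r_cut, interpolating
  # g at the cut so the last partial shell is not dropped
  r <- c(0, rdf$r[keep])
  g <- c(0, rdf$g[keep])
  if (r_cut > max(rdf$r[keep]) && any(!keep)) {
    g_cut <- stats::approx(rdf$r, rdf$g, xout = r_cut, rule = 2)$y
    r <- c(r, r_cut); g <- c(g, g_cut)
  }
  y <- 4 * pi * rho * g * r^2
  sum(diff(r) * (y[-1] + y[-length(y)]) / 2)
}

#' Shell boundaries (first and second RDF minima)
#'
#' @param r_min1 Outer edge of the first shell (Angstrom).
#' @param r_min2 Outer edge of the second shell (Angstrom).
#' @param pair Optional species pair the boundaries refer to.
#' @return Object of class `shell_boundaries`.
#' @export
shell_boundaries <- function(r_min1, r_min2, pair = NULL) {
  if (!(r_min1 > 0 && r_min2 > r_min1)) {
    stop("need 0 < r_min1 < r_min2", call. = FALSE)
  }
  structure(list(r_min1 = r_min1, r_min2 = r_min2, pair = pair),
            class = "shell_boundaries")
}

#' @export
print.shell_boundaries <- function(x, ...) {
  pr <- if (is.null(x$pair)) "" else sprintf(" [%s-%s]", x$pair[1], x$pair[2])
  cat(sprintf("<shell_boundaries>%s r_min1 = %.3f A, r_min2 = %.3f A\n",
              pr, x$r_min1, x$r_min2))
  invisible(x)
}

#' Locate the first and second RDF minima
#'
#' Smooths g(r) with a centered moving average (raw short-trajectory RDFs are
#' noisy), finds the first two local maxima above `min_peak`, and returns the
#' local minima following each. When detection fails and `fallback` boundaries
#' are supplied, those are returned instead.
#'
#' @param rdf An [compute_rdf()] profile.
#' @param smooth_window Moving-average width in bins (odd; default 5).
#' @param min_peak Minimum smoothed g value for a maximum to count as a shell
#'   peak (default 1.0).
#' @param fallback Optional [shell_boundaries()] used when detection fails.
#' @return A [shell_boundaries()].
#' @export
find_shell_minima <- function(rdf, smooth_window = 5, min_peak = 1.0, fallback = NULL) {
  stopifnot(inherits(rdf, "rdf_profile"))
  g <- rdf$g
  w <- max(1L, as.integer(smooth_window))
  if (w %% 2 == 0) w <- w + 1L
  if (w > 1) {
    k <- rep(1 / w, w)
    gs <- stats::filter(g, k, sides = 2)
    gs <- as.numeric(gs)
    half <- (w - 1L) / 2L
    gs[seq_len(half)] <- g[seq_len(half)]
    n <- length(g)
    gs[(n - half + 1L):n] <- g[(n - half + 1L):n]
  } else {
    gs <- g
  }
  detected <- detect_two_minima(rdf$r, gs, min_peak)
  if (is.null(detected)) {
    if (!is.null(fallback)) {
      stopifnot(inherits(fallback, "shell_boundaries"))
      return(fallback)
    }
    stop("could not detect two RDF peaks and no fallback boundaries given", call. = FALSE)
  }
  shell_boundaries(detected[1], detected[2], pair = attr(rdf, "pair"))
}

# first/second peak -> following minima on a smoothed profile; NULL on failure
detect_two_minima <- function(r, gs, min_peak) {
  n <- length(gs)
  if (n < 5) return(NULL)
  is_max <- c(FALSE, gs[2:(n - 1)] > gs[1:(n - 2)] & gs[2:(n - 1)] >= gs[3:n], FALSE)
  is_min <- c(FALSE, gs[2:(n - 1)] < gs[1:(n - 2)] & gs[2:(n - 1)] <= gs[3:n],
              gs[n] <= gs[n - 1])  # a decayed tail ends in a minimum
  peaks <- which(is_max & gs > min_peak)
  if (length(peaks) == 0) return(NULL)
  p1 <- peaks[1]
  m1 <- which(is_min & seq_len(n) > p1)
  if (length(m1) == 0) return(NULL)
  m1 <- m1[1]
  p2 <- peaks[peaks > m1]
  if (length(p2) == 0) return(NULL)
  p2 <- p2[1]
  m2 <- which(is_min & seq_len(n) > p2)
  if (length(m2) == 0) return(NULL)
  m2 <- m2[1]
  c(r[m1], r[m2])
}
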