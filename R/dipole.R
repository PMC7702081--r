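#' Water dipole unit vectors of one frame
#'
#' The dipole direction of each intact water is taken as the geometric
#' bisector: the unit vector from the oxygen towards the midpoint of its two
#' hydrogens, all displacements minimum-image consistent.
#'
#' @param pos `n_atoms x 3` position matrix (Angstrom).
#' @param topology A [build_water_topology()] result.
#' @param cell Box lengths (3-vector, Angstrom).
#' @return `n_waters x 3` matrix of unit vectors.
#' @export
dipole_vectors <- function(pos, topology, cell) {
  stopifnot(inherits(topology, "water_topology"))
  mol <- topology$molecules
  o <- pos[mol$O, , drop = FALSE]
  mi_rows <- function(h) {
    d <- pos[h, , drop = FALSE] - o
    d - sweep(round(sweep(d, 2, cell, "/")), 2, cell, "*")
  }
  bis <- (mi_rows(mol$H1) + mi_rows(mol$H2)) / 2
  if (any(rowSums(bis * bis) < 1e-12)) {
    stop("degenerate water geometry: hydrogens coincide with the bisector origin", call. = FALSE)
  }
  unitize_rows(bis)
}

#' Dipole unit vectors for every frame
#'
#' @param traj A [trajectory()].
#' @param topology A [build_water_topology()] result.
#' @return Array `[n_waters, 3, n_frames]` of unit vectors.
#' @export
dipole_array <- function(traj, topology) {
  stopifnot(inherits(traj, "trajectory"))
  n_mol <- nrow(topology$molecules)
  out <- array(0, dim = c(n_mol, 3, traj$n_frames))
  for (f in seq_len(traj$n_frames)) {
    out[, , f] <- dipole_vectors(frame_coords(traj, f), topology, frame_cell(traj, f))
  }
  out
}

#' First-order Legendre dipole reorientation TCF
#'
#' C1(t) = `<mu(0) . mu(t)>` over the selected waters and multiple time
#' origins, with membership evaluated at the origin (a selected water is
#' followed across the window even if it later migrates).
#'
#' @param traj A [trajectory()].
#' @param topology A [build_water_topology()] result.
#' @param window Correlation window (ps, default 16).
#' @param selection Optional `function(traj, frame)` returning molecule
#'   indices (evaluated at each origin), e.g. from [shell_selection()];
#'   `NULL` selects all waters.
#' @param origin_stride,n_origins_target See [correlate()].
#' @return A `tcf` tibble.
#' @export
dipole_tcf <- function(traj, topology, window = 16, selection = NULL,
                       origin_stride = NULL, n_origins_target = 1024) {
  mu <- dipole_array(traj, topology)
  member <- NULL
  if (!is.null(selection)) {
    wf <- window_frames(window, traj$dt, traj$n_frames)
    origins <- derive_origins(traj$n_frames, wf, origin_stride, n_origins_target)
    member <- matrix(FALSE, length(origins), nrow(topology$molecules))
    for (i in seq_along(origins)) {
      member[i, selection(traj, origins[i])] <- TRUE
    }
    if (!any(member)) stop("selection is empty at every origin", call. = FALSE)
    origin_stride <- if (length(origins) > 1) origins[2] - origins[1] else 1L
  }
  correlate(mu, dt = traj$dt, window = window, origin_stride = origin_stride,
            kernel = "dot", member = member, n_origins_target = n_origins_target)
}

#' Bi-exponential fit of a reorientation TCF
#'
#' Fits `a exp(-t/tau1) + b exp(-t/tau2)` to C(t) for `t >= fit_start` by
#' bounded Levenberg-Marquardt least squares, multi-started over log-spaced
#' time-constant pairs. The reorientation time is the amplitude-weighted mean
#' `tau_reor = (a tau1 + b tau2) / (a + b)`. The fit is done on C(t) itself
#' (not log C) to avoid amplifying tail noise; `fit_start` excludes the fast
#' librational transient. When the two components degenerate (one amplitude
#' vanishing or time constants merging), a single-exponential fit is reported
#' with `b = 0` and `tau2 = tau1`.
#'
#' @param C A `tcf` tibble.
#' @param fit_start Start of the fitted range (ps, default 0.2).
#' @param n_starts Number of multi-start initializations (default 5).
#' @param tau_max Upper bound on either time constant, as a multiple of the
#'   fitted span (default 25); prevents a vanishing-amplitude component from
#'   absorbing correlated tail noise with an unbounded time constant.
#' @param min_improvement Minimum fractional residual-sum-of-squares
#'   improvement of the bi-exponential over a single exponential required to
#'   keep the second component (default 0.9, i.e. the second component must
#'   cut the RSS about ten-fold); below it the single exponential is
#'   reported (`b = 0`, `tau2 = tau1`). Correlated noise in a TCF estimated
#'   from finitely many molecules lets a vanishing slow component soak up
#'   smooth tail deviations for a few-fold RSS gain, which would wreck the
#'   amplitude-weighted mean time, while a genuine second relaxation
#'   improves the RSS by orders of magnitude.
#' @return Object of class `biexp_fit` with fields `a`, `b`, `tau1`, `tau2`
#'   (ps), `tau_reor` (ps), `fit_start`, `residual_rms`, `single_exponential`.
#' @export
fit_biexponential <- function(C, fit_start = 0.2, n_starts = 5, tau_max = 25,
                              min_improvement = 0.9) {
  stopifnot(inherits(C, "tcf"))
  keep <- C$lag >= fit_start & !is.na(C$value)
  t <- C$lag[keep]; y <- C$value[keep]
  if (length(t) < 5) stop("too few points beyond `fit_start` to fit", call. = FALSE)
  span <- max(t) - min(t)
  tau_hi <- tau_max * span
  model <- function(p, t) p[1] * exp(-t / p[3]) + p[2] * exp(-t / p[4])
  resid_fn <- function(p) model(p, t) - y
  # crude decay-scale estimate from where C drops by 1/e of its initial value
  y0 <- y[1]
  tau_guess <- t[which(y <= y0 / exp(1))[1]] - t[1]
  if (is.na(tau_guess) || tau_guess <= 0) tau_guess <- span / 2
  tau_pairs <- exp(seq(log(tau_guess / 4), log(max(tau_guess * 4, tau_guess + 1e-3)),
                       length.out = n_starts))
  best <- NULL
  for (tp in tau_pairs) {
    p0 <- c(a = 0.6 * y0, b = 0.4 * y0, tau1 = min(tp / 2, tau_hi / 4),
            tau2 = min(tp * 2, tau_hi / 2))
    fit <- tryCatch(
      minpack.lm::nls.lm(p0, fn = resid_fn,
                         lower = c(0, 0, 1e-6, 1e-6),
                         upper = c(Inf, Inf, tau_hi, tau_hi),
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    stop("bi-exponential fit failed to converge from every start", call. = FALSE)
  }
  # reference single exponential; keep the second component only if it earns it
  r1 <- function(p) p[1] * exp(-t / p[2]) - y
  f1 <- tryCatch(
    minpack.lm::nls.lm(c(a = y0, tau = tau_guess), fn = r1,
                       lower = c(0, 1e-6), upper = c(Inf, tau_hi),
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL
  )
  rss_single <- if (is.null(f1)) Inf else sum(f1$fvec^2)
  p <- best$fit$par
  a <- p[1]; b <- p[2]; tau1 <- p[3]; tau2 <- p[4]
  # canonical order: tau1 <= tau2 (fast component first)
  if (tau1 > tau2) { tmp <- tau1; tau1 <- tau2; tau2 <- tmp; tmp <- a; a <- b; b <- tmp }
  amp <- a + b
  single <- FALSE
  # a component pinned at the tau bound is absorbing correlated tail noise,
  # not resolving a physical mode
  degenerate <- amp <= 0 || b / amp < 1e-4 || a / amp < 1e-4 ||
    abs(tau2 / tau1 - 1) < 1e-3 || tau2 >= 0.99 * tau_hi
  if (!is.null(f1) &&
      (degenerate || best$rss > (1 - min_improvement) * rss_single)) {
    a <- f1$par[1]; b <- 0; tau1 <- f1$par[2]; tau2 <- f1$par[2]
    single <- TRUE
    best$rss <- rss_single
  } else if (amp <= 0) {
    stop("degenerate fit: zero total amplitude", call. = FALSE)
  }
  tau_reor <- (a * tau1 + b * tau2) / (a + b)
  structure(
    list(a = unname(a), b = unname(b), tau1 = unname(tau1), tau2 = unname(tau2),
         tau_reor = unname(tau_reor), fit_start = fit_start,
         residual_rms = sqrt(best$rss / length(t)),
         single_exponential = single, n_points = length(t)),
    class = "biexp_fit"
  )
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat(sprintf(
    "<biexp_fit> a = %.4g (tau1 = %.4g ps), b = %.4g (tau2 = %.4g ps)%s\n  tau_reor = %.4g ps, residual rms = %.3g\n",
    x$a, x$tau1, x$b, x$tau2,
    if (x$single_exponential) " [single exponential]" else "",
    x$tau_reor, x$residual_rms
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a bi-exponential fit
#' @param x A `biexp_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter (`term`, `estimate`).
#' @method tidy biexp_fit
#' @export
tidy.biexp_fit <- function(x, ...) {
  tibble::tibble(
    term = c("a", "tau1", "b", "tau2", "tau_reor"),
    estimate = c(x$a, x$tau1, x$b, x$tau2, x$tau_reor)
  )
}

#' One-row summary of a bi-exponential fit
#' @param x A `biexp_fit`.
#' @param ... Unused.
#' @return One-row tibble.
#' @method glance biexp_fit
#' @export
glance.biexp_fit <- function(x, ...) {
  tibble::tibble(
    tau_reor = x$tau_reor, residual_rms = x$residual_rms,
    single_exponential = x$single_exponential,
    fit_start = x$fit_start, n_points = x$n_points
  )
}
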