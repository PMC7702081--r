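#' Multi-time-origin correlation engine
#'
#' Averages a time correlation function over entities and over overlapping
#' windows `[origin, origin + window]`. Two kernels are available:
#' `"dot"` computes `<u(0) . u(t)>` for per-entity vector (or scalar) series;
#' `"survival"` computes the continuous-bond survival
#' `<h(0) H(t)> / <h(0)^2>`, where `H(t) = 1` only if the bond is present at
#' every intermediate frame. Only origins with a complete window contribute,
#' so every lag averages the same set of origins.
#'
#' @param series For `kernel = "dot"`: a numeric array
#'   `[n_entities, 3, n_frames]` of vectors (or an `n_entities x n_frames`
#'   matrix of scalars). For `kernel = "survival"`: an
#'   `n_entities x n_frames` 0/1 matrix of bond indicators.
#' @param dt Frame spacing (ps).
#' @param window Correlation window length (ps).
#' @param origin_stride Frames between successive time origins; `NULL`
#'   derives the stride so that about `n_origins_target` origins are used.
#' @param kernel `"dot"` or `"survival"`.
#' @param member Optional logical `n_origins x n_entities` matrix restricting
#'   which entities contribute at each origin (membership is evaluated at the
#'   time origin; the tracked quantity follows the entity across the window).
#' @param n_origins_target Origin-count target used when deriving the stride
#'   (default 1024).
#' @return A tibble of class `tcf` with columns `lag` (ps), `value`, and
#'   `n_origins` (contributing origin-entity pairs per lag); attributes
#'   `window`, `dt`, `origins`.
#' @export
correlate <- function(series, dt, window, origin_stride = NULL,
                      kernel = c("dot", "survival"), member = NULL,
                      n_origins_target = 1024) {
  kernel <- match.arg(kernel)
  if (is.matrix(series) && kernel == "dot") {
    series <- array(t(series), dim = c(nrow(series), 1, ncol(series)))
  }
  n_frames <- if (kernel == "dot") dim(series)[3] else ncol(series)
  wf <- window_frames(window, dt, n_frames)
  origins <- derive_origins(n_frames, wf, origin_stride, n_origins_target)
  n_lags <- wf + 1L
  if (kernel == "dot") {
    res <- cpp_tcf_dot(series, origins, n_lags,
                       if (is.null(member)) NULL else member)
  } else {
    storage.mode(series) <- "integer"
    if (!is.null(member)) stop("`member` is not supported for the survival kernel", call. = FALSE)
    res <- cpp_tcf_survival(series, origins, n_lags)
    if (all(res$count == 0)) stop("no bonds present at any origin", call. = FALSE)
  }
  new_tcf(lag = (seq_len(n_lags) - 1) * dt, value = res$value,
          n_origins = res$count, window = window, dt = dt, origins = origins)
}

new_tcf <- function(lag, value, n_origins, window, dt, origins) {
  out <- tibble::tibble(lag = lag, value = value, n_origins = n_origins)
  class(out) <- c("tcf", class(out))
  attr(out, "window") <- window
  attr(out, "dt") <- dt
  attr(out, "origins") <- origins
  out
}

window_frames <- function(window, dt, n_frames) {
  wf <- as.integer(round(window / dt))
  if (wf < 1) stop("`window` must span at least one frame", call. = FALSE)
  if (wf > n_frames - 1) {
    stop(sprintf("window of %g ps exceeds the trajectory span (%g ps)",
                 window, (n_frames - 1) * dt), call. = FALSE)
  }
  wf
}

derive_origins <- function(n_frames, wf, origin_stride, n_origins_target) {
  last <- n_frames - wf
  if (is.null(origin_stride)) {
    origin_stride <- max(1L, floor((last - 1) / max(1L, n_origins_target - 1L)))
  }
  as.integer(seq.int(1L, last, by = origin_stride))
}

#' Continuous hydrogen-bond time correlation function
#'
#' Detects hydrogen bonds in every frame, then computes the probability that a
#' donor-acceptor-hydrogen triple bonded at a time origin remains continuously
#' bonded through lag t, averaged over all bonded-at-origin triples and
#' origins.
#'
#' @inheritParams hbond_statistics
#' @param window Correlation window (ps, default 11).
#' @param origin_stride,n_origins_target See [correlate()].
#' @return A `tcf` tibble (see [correlate()]).
#' @export
continuous_hb_tcf <- function(traj, topology, criteria = hb_criteria(),
                              window = 11, origin_stride = NULL,
                              n_origins_target = 1024) {
  stopifnot(inherits(traj, "trajectory"))
  # bond id = donor:acceptor:H triple; build indicator matrix over frames
  keys <- character(0)
  frames_bonds <- vector("list", traj$n_frames)
  for (f in seq_len(traj$n_frames)) {
    b <- detect_hbonds(frame_coords(traj, f), topology, criteria, frame_cell(traj, f))
    frames_bonds[[f]] <- paste(b$donor, b$acceptor, b$H, sep = ":")
    keys <- union(keys, frames_bonds[[f]])
  }
  if (length(keys) == 0) stop("no hydrogen bonds found in any frame", call. = FALSE)
  h <- matrix(0L, length(keys), traj$n_frames, dimnames = list(keys, NULL))
  for (f in seq_len(traj$n_frames)) {
    h[frames_bonds[[f]], f] <- 1L
  }
  correlate(h, dt = traj$dt, window = window, origin_stride = origin_stride,
            kernel = "survival", n_origins_target = n_origins_target)
}

#' Hydrogen-bond lifetime from the survival TCF
#'
#' Integrates S(t) over the window by the trapezoid rule. With
#' `tail = "exp_extrapolate"`, a single exponential is fitted to the last 20%
#' of the window and its analytic integral beyond the window is added,
#' correcting the truncation of slowly decaying tails.
#'
#' @param S A `tcf` from [continuous_hb_tcf()] or [correlate()].
#' @param tail `"none"` or `"exp_extrapolate"`.
#' @return Lifetime tau_HB (ps).
#' @export
hb_lifetime <- function(S, tail = c("exp_extrapolate", "none")) {
  tail <- match.arg(tail)
  stopifnot(inherits(S, "tcf"))
  ok <- !is.na(S$value)
  lag <- S$lag[ok]; v <- S$value[ok]
  base <- sum(diff(lag) * (v[-1] + v[-length(v)]) / 2)
  if (tail == "none") return(base)
  n <- length(lag)
  i0 <- max(1L, ceiling(0.8 * n))
  seg <- i0:n
  pos <- v[seg] > 0
  if (sum(pos) < 3) return(base)  # fully decayed; nothing to extrapolate
  fit <- stats::lm(log(v[seg][pos]) ~ lag[seg][pos])
  k <- -unname(stats::coef(fit)[2])
  if (!is.finite(k) || k <= 0) return(base)
  s_end <- v[n]
  base + s_end / k
}
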