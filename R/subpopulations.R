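#' Enumerate the cooperative-hydration subpopulation labels
#'
#' Each water is labelled `W_abc`: `a` is the shell state of its oxygen with
#' respect to the nearest cation and `bc` the (unordered) pair of shell states
#' of its two hydrogens with respect to the nearest anion, with states
#' 1 = first shell, 2 = second shell, B = beyond. The hydrogen pair is
#' unordered because the two hydrogens of a molecule are exchangeable, giving
#' 3 x 6 = 18 labels. Labels with exactly one hydrogen in state 1 and the
#' other beyond both shells (`W_11B`, `W_21B`, `W_B1B`) would require a
#' dissociated O-H bond and are flagged inadmissible.
#'
#' @return Tibble with columns `label`, `a`, `b`, `c`, `admissible`.
#' @export
enumerate_subpopulations <- function() {
  states <- c("1", "2", "B")
  pairs <- expand.grid(b = states, c = states, stringsAsFactors = FALSE)
  pairs <- pairs[state_rank(pairs$b) <= state_rank(pairs$c), ]
  grid <- tidyr::crossing(a = states, tibble::as_tibble(pairs))
  grid |>
    dplyr::mutate(
      label = paste0("W_", .data$a, .data$b, .data$c),
      admissible = !(.data$b == "1" & .data$c == "B")
    ) |>
    dplyr::select("label", "a", "b", "c", "admissible")
}

state_rank <- function(s) match(s, c("1", "2", "B"))

shell_state <- function(d, boundaries) {
  # half-open intervals [0, r_min1), [r_min1, r_min2), [r_min2, Inf)
  dplyr::case_when(
    d < boundaries$r_min1 ~ "1",
    d < boundaries$r_min2 ~ "2",
    .default = "B"
  )
}

#' Assign each water its subpopulation label in one frame
#'
#' The oxygen state compares the O distance to the nearest cation against the
#' cation-oxygen shell boundaries; each hydrogen state compares the H distance
#' to the nearest anion against the anion-hydrogen boundaries. Hydrogen states
#' are canonicalized to the order 1 < 2 < B. With no ions of a type present,
#' the corresponding states are B.
#'
#' @param pos `n_atoms x 3` position matrix.
#' @param topology A [build_water_topology()] result.
#' @param cation_shells,anion_shells [shell_boundaries()] for the cation-O and
#'   anion-H distances.
#' @param cell Box lengths (3-vector, Angstrom).
#' @param cation,anion Ion element symbols (defaults Mg, Cl).
#' @return Character vector of labels, one per water.
#' @export
label_waters <- function(pos, topology, cation_shells, anion_shells, cell,
                         cation = "Mg", anion = "Cl") {
  stopifnot(inherits(topology, "water_topology"))
  mol <- topology$molecules
  n <- nrow(mol)
  cats <- ion_atoms(topology, cation)
  ans <- ion_atoms(topology, anion)
  a <- rep("B", n)
  if (length(cats) > 0) {
    d_o <- mi_nearest_distances(pos[mol$O, , drop = FALSE],
                                pos[cats, , drop = FALSE], cell)
    a <- shell_state(d_o, cation_shells)
  }
  b <- rep("B", n); cc <- rep("B", n)
  if (length(ans) > 0) {
    d_h1 <- mi_nearest_distances(pos[mol$H1, , drop = FALSE],
                                 pos[ans, , drop = FALSE], cell)
    d_h2 <- mi_nearest_distances(pos[mol$H2, , drop = FALSE],
                                 pos[ans, , drop = FALSE], cell)
    b <- shell_state(d_h1, anion_shells)
    cc <- shell_state(d_h2, anion_shells)
  }
  swap <- state_rank(b) > state_rank(cc)
  tmp <- b[swap]; b[swap] <- cc[swap]; cc[swap] <- tmp
  paste0("W_", a, b, cc)
}

#' Per-subpopulation reorientation times
#'
#' Labels every water at each time origin, then computes the dipole
#' reorientation TCF of each populated admissible subpopulation with
#' origin-membership selection (a water contributes to the subpopulation it
#' belonged to at the origin and is followed across the window). Each TCF is
#' fitted with [fit_biexponential()]; uncertainties come from refitting on
#' `n_blocks` consecutive, non-overlapping origin blocks (standard error of
#' the block estimates).
#'
#' @param traj A [trajectory()].
#' @param topology A [build_water_topology()] result.
#' @param cation_shells,anion_shells [shell_boundaries()] (see
#'   [label_waters()]).
#' @param cation,anion Ion element symbols.
#' @param window TCF window (ps, default 16).
#' @param fit_start Fit range start (ps, default 0.2).
#' @param origin_stride,n_origins_target See [correlate()].
#' @param n_blocks Number of uncertainty blocks (default 4).
#' @param min_origin_samples Minimum origin-water samples for a label to be
#'   fitted (default 50).
#' @return Tibble of class `subpop_table`: `label`, `a`, `bc`, `population`
#'   (mean waters), `tau` (ps), `tau_sigma` (ps), `n_samples`, `admissible`.
#'   Attribute `curves` holds the per-label `tcf` objects.
#' @export
subpopulation_taus <- function(traj, topology, cation_shells, anion_shells,
                               cation = "Mg", anion = "Cl", window = 16,
                               fit_start = 0.2, origin_stride = NULL,
                               n_origins_target = 1024, n_blocks = 4,
                               min_origin_samples = 50) {
  stopifnot(inherits(traj, "trajectory"))
  wf <- window_frames(window, traj$dt, traj$n_frames)
  origins <- derive_origins(traj$n_frames, wf, origin_stride, n_origins_target)
  n_mol <- nrow(topology$molecules)
  labels <- matrix("", length(origins), n_mol)
  for (i in seq_along(origins)) {
    labels[i, ] <- label_waters(frame_coords(traj, origins[i]), topology,
                                cation_shells, anion_shells,
                                frame_cell(traj, origins[i]), cation, anion)
  }
  mu <- dipole_array(traj, topology)
  enum <- enumerate_subpopulations()
  curves <- list()
  rows <- purrr::pmap(enum, function(label, a, b, c, admissible) {
    member <- labels == label
    n_samples <- sum(member)
    population <- n_samples / length(origins)
    tau <- NA_real_; tau_sigma <- NA_real_
    if (admissible && n_samples >= min_origin_samples) {
      tcf <- correlate(mu, dt = traj$dt, window = window,
                       origin_stride = origins[2] - origins[1],
                       kernel = "dot", member = member)
      fit <- fit_biexponential(tcf, fit_start = fit_start)
      tau <- fit$tau_reor
      curves[[label]] <<- tcf
      block_taus <- block_tau_estimates(mu, traj$dt, window, origins, member,
                                        fit_start, n_blocks, min_origin_samples)
      if (length(block_taus) >= 2) {
        tau_sigma <- stats::sd(block_taus) / sqrt(length(block_taus))
      }
    }
    tibble::tibble(label = label, a = a, bc = paste0(b, c),
                   population = population, tau = tau, tau_sigma = tau_sigma,
                   n_samples = n_samples, admissible = admissible)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("subpop_table", class(out))
  attr(out, "curves") <- curves
  attr(out, "window") <- window
  attr(out, "n_origins") <- length(origins)
  out
}

block_tau_estimates <- function(mu, dt, window, origins, member, fit_start,
                                n_blocks, min_origin_samples) {
  blocks <- split(seq_along(origins),
                  cut(seq_along(origins), n_blocks, labels = FALSE))
  taus <- numeric(0)
  for (idx in blocks) {
    mb <- member[idx, , drop = FALSE]
    if (sum(mb) < min_origin_samples / n_blocks) next
    tcf_b <- tryCatch({
      res <- cpp_tcf_dot(mu, origins[idx], as.integer(round(window / dt)) + 1L, mb)
      new_tcf((seq_along(res$value) - 1) * dt, res$value, res$count,
              window, dt, origins[idx])
    }, error = function(e) NULL)
    if (is.null(tcf_b) || anyNA(tcf_b$value)) next
    fit <- tryCatch(fit_biexponential(tcf_b, fit_start = fit_start),
                    error = function(e) NULL)
    if (!is.null(fit)) taus <- c(taus, fit$tau_reor)
  }
  taus
}

#' Retardation factors relative to bulk water
#'
#' Divides each subpopulation reorientation time by the bulk reference time.
#' If `bulk_tau` is not supplied it is the population-weighted mean tau of the
#' seed bulk set: populated subpopulations whose oxygen is not in the first
#' cation shell and with no hydrogen in the first anion shell. (At high
#' concentration the fully bulk label can be empty, so "bulk" must be a set.)
#'
#' @param table A [subpopulation_taus()] table.
#' @param bulk_tau Optional bulk reference time (ps).
#' @return The table with columns `f` (retardation factor) and `f_sigma`
#'   added; attribute `bulk_tau` records the reference.
#' @export
retardation_factors <- function(table, bulk_tau = NULL) {
  stopifnot(inherits(table, "subpop_table"))
  if (is.null(bulk_tau)) {
    seed <- bulk_seed_rows(table)
    if (!any(seed)) stop("no populated bulk-seed subpopulation to define bulk tau", call. = FALSE)
    bulk_tau <- stats::weighted.mean(table$tau[seed], table$population[seed])
  }
  if (!(is.numeric(bulk_tau) && bulk_tau > 0)) stop("`bulk_tau` must be positive", call. = FALSE)
  out <- table |>
    dplyr::mutate(f = .data$tau / bulk_tau,
                  f_sigma = .data$tau_sigma / bulk_tau)
  class(out) <- class(table)
  attr(out, "curves") <- attr(table, "curves")
  attr(out, "bulk_tau") <- bulk_tau
  out
}

bulk_seed_rows <- function(table) {
  !is.na(table$tau) & table$a != "1" & !grepl("1", table$bc)
}

#' Window test used by the Empirical-Rule classifier
#' @param f Retardation factor(s).
#' @param center,sigma Bulk mean and standard deviation.
#' @param n_sigma Width of the window in standard deviations.
#' @return Logical vector: inside the window.
#' @export
within_sigma_window <- function(f, center, sigma, n_sigma = 3) {
  abs(f - center) <= n_sigma * sigma
}

#' Classify subpopulations as bulk-like or slow (Empirical Rule)
#'
#' Under the Empirical (68-95-99.7) Rule, bulk-like retardation factors drawn
#' from the bulk distribution fall within `n_sigma` standard deviations of the
#' bulk mean about 99.7% of the time (for `n_sigma = 3`). The classifier
#' seeds the bulk set with the subpopulations expected to be bulk-like on
#' structural grounds (oxygen not in the first cation shell, no hydrogen in
#' the first anion shell), computes the population-weighted mean and sigma of
#' f over the current bulk set, reassigns every fitted subpopulation by the
#' window test, and iterates to a fixed point. Unfitted labels with zero
#' population are classified `empty`.
#'
#' @param table A [retardation_factors()] table (must have `f`).
#' @param n_sigma Window width (default 3).
#' @param sigma_mode How the bulk sigma is estimated: `"combined"` (default)
#'   adds the population-weighted spread of f across the bulk set and the
#'   mean block error in quadrature; `"spread"` and `"block"` use one part
#'   only.
#' @param max_iter Iteration cap (default 100).
#' @return The table with a `class` column (`bulk-like` / `slow` / `empty`);
#'   attributes `bulk_mean`, `bulk_sigma`.
#' @export
classify_empirical_rule <- function(table, n_sigma = 3,
                                    sigma_mode = c("combined", "spread", "block"),
                                    max_iter = 100) {
  sigma_mode <- match.arg(sigma_mode)
  stopifnot(inherits(table, "subpop_table"))
  if (!"f" %in% names(table)) stop("run retardation_factors() first", call. = FALSE)
  fitted <- which(!is.na(table$f))
  if (length(fitted) < 2) stop("need at least two fitted subpopulations", call. = FALSE)
  bulk <- which(bulk_seed_rows(table))
  if (length(bulk) == 0) {
    message("bulk seed set empty; seeding with the smallest retardation factor")
    bulk <- fitted[which.min(table$f[fitted])]
  }
  for (it in seq_len(max_iter)) {
    w <- table$population[bulk]
    center <- stats::weighted.mean(table$f[bulk], w)
    spread <- sqrt(stats::weighted.mean((table$f[bulk] - center)^2, w))
    block <- sqrt(stats::weighted.mean(ifelse(is.na(table$f_sigma[bulk]), 0,
                                              table$f_sigma[bulk])^2, w))
    sigma <- switch(sigma_mode,
                    combined = sqrt(spread^2 + block^2),
                    spread = spread,
                    block = block)
    new_bulk <- fitted[within_sigma_window(table$f[fitted], center, sigma, n_sigma)]
    if (length(new_bulk) == 0) new_bulk <- bulk  # refuse to empty the bulk set
    if (identical(sort(new_bulk), sort(bulk))) break
    bulk <- new_bulk
  }
  cls <- rep("empty", nrow(table))
  cls[fitted] <- "slow"
  cls[bulk] <- "bulk-like"
  out <- dplyr::mutate(table, class = cls)
  class(out) <- class(table)
  attr(out, "curves") <- attr(table, "curves")
  attr(out, "bulk_tau") <- attr(table, "bulk_tau")
  attr(out, "bulk_mean") <- center
  attr(out, "bulk_sigma") <- sigma
  out
}

#' Hydration number from the classified subpopulation table
#'
#' The hydration number h is the number of water molecules per dissolved salt
#' unit whose reorientation dynamics is no longer bulk-like: the summed
#' population of the `slow` subpopulations divided by the number of salt
#' units, split into the first-cation-shell contribution (oxygen state 1) and
#' the contribution from beyond.
#'
#' @param table A [classify_empirical_rule()] table.
#' @param n_salt_units Number of dissolved salt units in the box.
#' @return Object of class `hydration_result` with fields `h`,
#'   `slow_first_shell`, `slow_beyond` (all per salt unit) and
#'   `bulk_reference_tau` (ps).
#' @export
hydration_number <- function(table, n_salt_units) {
  stopifnot(inherits(table, "subpop_table"), n_salt_units > 0)
  if (!"class" %in% names(table)) stop("run classify_empirical_rule() first", call. = FALSE)
  slow <- table$class == "slow"
  first <- slow & table$a == "1"
  res <- list(
    h = sum(table$population[slow]) / n_salt_units,
    slow_first_shell = sum(table$population[first]) / n_salt_units,
    slow_beyond = sum(table$population[slow & !first]) / n_salt_units,
    bulk_reference_tau = attr(table, "bulk_tau"),
    n_salt_units = n_salt_units
  )
  structure(res, class = "hydration_result")
}

#' @export
print.hydration_result <- function(x, ...) {
  cat(sprintf(
    "<hydration_result> h = %.2f waters per salt unit (%.2f first shell + %.2f beyond)\n",
    x$h, x$slow_first_shell, x$slow_beyond
  ))
  if (!is.null(x$bulk_reference_tau)) {
    cat(sprintf("  bulk reference tau = %.3g ps\n", x$bulk_reference_tau))
  }
  invisible(x)
}

#' One-row summary of a hydration result
#' @param x A `hydration_result`.
#' @param ... Unused.
#' @return One-row tibble.
#' @method glance hydration_result
#' @export
glance.hydration_result <- function(x, ...) {
  tibble::tibble(
    h = x$h, slow_first_shell = x$slow_first_shell, slow_beyond = x$slow_beyond,
    bulk_reference_tau = x$bulk_reference_tau %||% NA_real_,
    n_salt_units = x$n_salt_units
  )
}

#' Monte Carlo coverage of the Empirical-Rule window
#'
#' Draws retardation factors from the bulk normal distribution and reports the
#' percentage falling inside the `n_sigma` window — the null calibration of
#' the classifier (about 99.7% for three sigma).
#'
#' @param n Number of draws.
#' @param n_sigma Window width.
#' @param mean,sd Bulk distribution parameters.
#' @return Percentage of draws classified bulk-like.
#' @export
empirical_rule_coverage <- function(n = 1e6, n_sigma = 3, mean = 1, sd = 0.05) {
  f <- stats::rnorm(n, mean, sd)
  100 * base::mean(within_sigma_window(f, mean, sd, n_sigma))
}
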