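# Independent brute-force oracles. These deliberately avoid the package's
# compiled kernels and minimum-image helpers so they can certify them.

# shortest displacement by exhaustive search over the 27 periodic images
oracle_min_image <- function(a, b, cell) {
  best <- NULL
  best_d <- Inf
  for (i in -1:1) for (j in -1:1) for (k in -1:1) {
    d <- (b + c(i, j, k) * cell) - a
    dd <- sum(d * d)
    if (dd < best_d) { best_d <- dd; best <- d }
  }
  best
}

oracle_min_distance <- function(a, b, cell) sqrt(sum(oracle_min_image(a, b, cell)^2))

# O(N^2) per-frame pair-count histogram on bin edges
oracle_rdf_counts <- function(pos_a, pos_b, cell, edges, same = FALSE) {
  counts <- numeric(length(edges) - 1)
  for (i in seq_len(nrow(pos_a))) {
    for (j in seq_len(nrow(pos_b))) {
      if (same && i == j) next
      d <- oracle_min_distance(pos_a[i, ], pos_b[j, ], cell)
      if (d >= edges[length(edges)]) next
      bin <- findInterval(d, edges, left.open = TRUE)
      if (bin >= 1 && bin <= length(counts)) counts[bin] <- counts[bin] + 1
    }
  }
  counts
}

# naive multi-origin dot TCF; accumulation order matches the compiled kernel
oracle_tcf_dot <- function(arr, origins, n_lags, member = NULL) {
  n <- dim(arr)[1]; nd <- dim(arr)[2]; nf <- dim(arr)[3]
  value <- rep(NA_real_, n_lags)
  count <- integer(n_lags)
  for (k in seq_len(n_lags) - 1L) {
    acc <- 0; cnt <- 0L
    for (oi in seq_along(origins)) {
      o <- origins[oi]
      if (o + k > nf) next
      for (e in seq_len(n)) {
        if (!is.null(member) && !member[oi, e]) next
        dot <- 0
        for (d in seq_len(nd)) dot <- dot + arr[e, d, o] * arr[e, d, o + k]
        acc <- acc + dot
        cnt <- cnt + 1L
      }
    }
    if (cnt > 0) value[k + 1L] <- acc / cnt
    count[k + 1L] <- cnt
  }
  list(value = value, count = count)
}

# naive continuous survival with an explicit all() continuity check
oracle_tcf_survival <- function(h, origins, n_lags) {
  np <- nrow(h); nf <- ncol(h)
  value <- rep(NA_real_, n_lags)
  for (k in seq_len(n_lags) - 1L) {
    num <- 0L; den <- 0L
    for (o in origins) {
      if (o + k > nf) next
      for (p in seq_len(np)) {
        if (h[p, o] != 1) next
        den <- den + 1L
        if (all(h[p, o:(o + k)] == 1)) num <- num + 1L
      }
    }
    if (den > 0) value[k + 1L] <- num / den
  }
  value
}

# build a trajectory from a list of per-frame position matrices
make_traj <- function(frames, elements, cell, dt = 1, velocities = NULL) {
  pos <- array(unlist(frames), dim = c(nrow(frames[[1]]), 3, length(frames)))
  vel <- if (is.null(velocities)) NULL else {
    array(unlist(velocities), dim = dim(pos))
  }
  trajectory(elements, pos, cell, dt = dt, velocities = vel)
}

# one ideal water molecule: O at `o`, bisector along `u` (unit), in-plane `p`
ideal_water <- function(o, u, p) {
  r_oh <- 0.9572
  half <- 104.52 / 2 * pi / 180
  rbind(o,
        o + r_oh * (cos(half) * u + sin(half) * p),
        o + r_oh * (cos(half) * u - sin(half) * p))
}
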