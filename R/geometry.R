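#' Minimum-image displacement between two points in an orthorhombic cell
#'
#' Returns the displacement `b - a` wrapped into the primary image, i.e. the
#' shortest periodic vector connecting `a` to `b`. Each component of the result
#' lies in `(-L/2, L/2]` for the corresponding box length `L`.
#'
#' @param a,b Numeric 3-vectors, positions in Angstrom.
#' @param cell Numeric 3-vector of orthorhombic box lengths (Angstrom).
#' @return Numeric 3-vector, the minimum-image displacement (Angstrom).
#' @examples
#' minimum_image_displacement(c(0, 0, 0), c(9, 0, 0), cell = c(10, 10, 10))
#' @export
minimum_image_displacement <- function(a, b, cell) {
  check_cell(cell)
  d <- as.numeric(b) - as.numeric(a)
  d - cell * round(d / cell)
}

#' Minimum-image displacements of rows of a matrix from a point
#'
#' Vectorised companion of [minimum_image_displacement()]: displacement of each
#' row of `x` from the single point `origin`.
#'
#' @param x Numeric matrix (n x 3) of positions (Angstrom).
#' @param origin Numeric 3-vector (Angstrom).
#' @param cell Numeric 3-vector of box lengths (Angstrom).
#' @return n x 3 matrix of minimum-image displacements.
#' @keywords internal
mi_displacements <- function(x, origin, cell) {
  d <- sweep(x, 2, as.numeric(origin), "-")
  d - sweep(round(sweep(d, 2, cell, "/")), 2, cell, "*")
}

#' Minimum-image distances of rows of a matrix from a point
#' @inheritParams mi_displacements
#' @return Numeric vector of length `nrow(x)` (Angstrom).
#' @keywords internal
mi_distances <- function(x, origin, cell) {
  d <- mi_displacements(x, origin, cell)
  sqrt(rowSums(d * d))
}

#' All minimum-image distances between two position sets
#'
#' @param xa,xb Numeric matrices (na x 3, nb x 3) of positions.
#' @param cell Numeric 3-vector of box lengths.
#' @return na x nb matrix of pair distances.
#' @keywords internal
mi_cross_distances <- function(xa, xb, cell) {
  out <- matrix(0, nrow(xa), nrow(xb))
  for (i in seq_len(nrow(xa))) {
    out[i, ] <- mi_distances(xb, xa[i, ], cell)
  }
  out
}

#' Minimum-image distance from each row of `x` to its nearest reference point
#'
#' Vectorised over the (many) rows of `x`, looping only over the (few)
#' reference points.
#'
#' @param x Numeric matrix (n x 3).
#' @param ref Numeric matrix (m x 3) of reference points.
#' @param cell Numeric 3-vector of box lengths.
#' @return Numeric vector of length n.
#' @keywords internal
mi_nearest_distances <- function(x, ref, cell) {
  Reduce(pmin, lapply(seq_len(nrow(ref)), function(k) mi_distances(x, ref[k, ], cell)))
}

check_cell <- function(cell) {
  if (length(cell) != 3 || !is.numeric(cell) || any(!is.finite(cell)) || any(cell <= 0)) {
    stop("`cell` must be 3 positive orthorhombic box lengths", call. = FALSE)
  }
  invisible(as.numeric(cell))
}

#' Unit vector along a 3-vector
#' @keywords internal
unitize <- function(v) {
  n <- sqrt(sum(v * v))
  if (n == 0) stop("cannot normalize a zero vector", call. = FALSE)
  v / n
}

#' Row-wise unit vectors of a matrix
#' @keywords internal
unitize_rows <- function(m) {
  n <- sqrt(rowSums(m * m))
  if (any(n == 0)) stop("cannot normalize a zero vector", call. = FALSE)
  m / n
}
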