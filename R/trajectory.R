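#' Construct a trajectory object
#'
#' A `trajectory` holds frames of labelled atomic positions (and optionally
#' velocities) in an orthorhombic periodic cell, with a fixed time step.
#' Coordinates are stored unwrapped, exactly as supplied; all distance
#' computations in the package use the minimum-image convention rather than
#' rewrapping.
#'
#' @param elements Character vector of element symbols, one per atom. The atom
#'   count and ordering are identical in every frame.
#' @param positions Numeric array `[n_atoms, 3, n_frames]` in Angstrom.
#' @param cell Either a numeric 3-vector (constant cell) or a `n_frames x 3`
#'   matrix of orthorhombic box lengths in Angstrom.
#' @param dt Time step between consecutive frames (ps).
#' @param velocities Optional numeric array `[n_atoms, 3, n_frames]` in
#'   Angstrom/ps.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(elements, positions, cell, dt, velocities = NULL) {
  if (!is.array(positions) || length(dim(positions)) != 3 || dim(positions)[2] != 3) {
    stop("`positions` must be an [n_atoms, 3, n_frames] array", call. = FALSE)
  }
  n_atoms <- dim(positions)[1]
  n_frames <- dim(positions)[3]
  if (length(elements) != n_atoms) {
    stop("`elements` length must equal the atom count", call. = FALSE)
  }
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) {
    stop("`dt` must be a single positive time step in ps", call. = FALSE)
  }
  if (is.matrix(cell)) {
    if (nrow(cell) != n_frames || ncol(cell) != 3) {
      stop("per-frame `cell` must be an n_frames x 3 matrix", call. = FALSE)
    }
    apply(cell, 1, check_cell)
  } else {
    check_cell(cell)
    cell <- matrix(rep(as.numeric(cell), each = n_frames), n_frames, 3)
  }
  if (!is.null(velocities)) {
    if (!is.array(velocities) || !identical(dim(velocities), dim(positions))) {
      stop("`velocities` must match the dimensions of `positions`", call. = FALSE)
    }
  }
  structure(
    list(
      elements = as.character(elements),
      positions = positions,
      velocities = velocities,
      cell = cell,
      dt = dt,
      n_atoms = n_atoms,
      n_frames = n_frames
    ),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory> %d atoms, %d frames, dt = %g ps, cell = [%s] A%s\n",
    x$n_atoms, x$n_frames, x$dt,
    paste(signif(x$cell[1, ], 5), collapse = ", "),
    if (is.null(x$velocities)) "" else ", with velocities"
  ))
  tab <- table(x$elements)
  cat("  composition:", paste(sprintf("%s:%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}

#' Positions (or velocities) of one frame
#'
#' @param traj A [trajectory()].
#' @param frame Frame index (1-based).
#' @param what `"positions"` or `"velocities"`.
#' @return `n_atoms x 3` numeric matrix.
#' @export
frame_coords <- function(traj, frame, what = c("positions", "velocities")) {
  what <- match.arg(what)
  stopifnot(inherits(traj, "trajectory"))
  if (frame < 1 || frame > traj$n_frames) {
    stop(sprintf("frame %d out of range [1, %d]", frame, traj$n_frames), call. = FALSE)
  }
  src <- traj[[what]]
  if (is.null(src)) stop(sprintf("trajectory has no %s", what), call. = FALSE)
  m <- src[, , frame, drop = FALSE]
  dim(m) <- dim(m)[1:2]
  m
}

#' Cell lengths of one frame
#' @inheritParams frame_coords
#' @return Numeric 3-vector (Angstrom).
#' @export
frame_cell <- function(traj, frame) {
  stopifnot(inherits(traj, "trajectory"))
  traj$cell[frame, ]
}

# ---- extended-XYZ I/O --------------------------------------------------------

parse_extxyz_comment <- function(line, frame) {
  # Lattice="ax ay az bx by bz cx cy cz"; Properties=species:S:1:pos:R:3[:vel:R:3]
  lat <- regmatches(line, regexpr('Lattice="[^"]*"', line))
  if (length(lat) == 0) {
    stop(sprintf("frame %d: missing Lattice in extended-XYZ header", frame), call. = FALSE)
  }
  vals <- as.numeric(strsplit(trimws(sub('Lattice="([^"]*)"', "\\1", lat)), "\\s+")[[1]])
  if (length(vals) != 9) {
    stop(sprintf("frame %d: Lattice must have 9 components", frame), call. = FALSE)
  }
  m <- matrix(vals, 3, 3, byrow = TRUE)
  off <- m[upper.tri(m) | lower.tri(m)]
  if (any(abs(off) > 1e-8)) {
    stop(sprintf("frame %d: only orthorhombic cells are supported", frame), call. = FALSE)
  }
  props <- regmatches(line, regexpr("Properties=\\S+", line))
  has_vel <- length(props) > 0 && grepl("(vel|velo|velocities):R:3", props)
  list(cell = diag(m), has_vel = has_vel)
}

#' Read a trajectory from an extended-XYZ file
#'
#' Supports the extended-XYZ convention (`Lattice="..."` in the comment line,
#' optional velocity columns declared in `Properties=`), and plain multi-frame
#' XYZ with the cell supplied either as a one-line sidecar file or via the
#' `cell` argument. Units are taken as Angstrom and Angstrom/ps; `dt` is the
#' frame spacing in ps.
#'
#' @param path Path to the XYZ file.
#' @param dt Time step between frames (ps).
#' @param format `"extxyz"` (default) or `"xyz"` (plain, needs a cell).
#' @param cell Optional 3-vector of box lengths for plain XYZ; for
#'   `format = "xyz"` the reader otherwise looks for `<path>.cell`, a text file
#'   holding three numbers.
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, dt, format = c("extxyz", "xyz"), cell = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[!(seq_along(lines) > 1 & lines == "" & seq_along(lines) == length(lines))]
  if (format == "xyz" && is.null(cell)) {
    sidecar <- paste0(path, ".cell")
    if (!file.exists(sidecar)) {
      stop("plain XYZ needs `cell` or a one-line <path>.cell sidecar file", call. = FALSE)
    }
    cell <- as.numeric(strsplit(trimws(readLines(sidecar)[1]), "\\s+")[[1]])
  }
  pos_list <- list()
  vel_list <- list()
  cell_list <- list()
  el0 <- NULL
  i <- 1L
  frame <- 0L
  while (i <= length(lines)) {
    if (trimws(lines[i]) == "") { i <- i + 1L; next }
    frame <- frame + 1L
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop(sprintf("frame %d: expected an atom count, got '%s'", frame, lines[i]), call. = FALSE)
    if (i + 1L + n > length(lines)) {
      stop(sprintf("frame %d: truncated file (expected %d atoms)", frame, n), call. = FALSE)
    }
    comment <- lines[i + 1L]
    if (format == "extxyz") {
      hdr <- parse_extxyz_comment(comment, frame)
      cell_list[[frame]] <- hdr$cell
      has_vel <- hdr$has_vel
    } else {
      cell_list[[frame]] <- cell
      has_vel <- FALSE
    }
    body <- lines[(i + 2L):(i + 1L + n)]
    toks <- strsplit(trimws(body), "\\s+")
    ncol_body <- lengths(toks)
    if (format == "xyz") has_vel <- all(ncol_body >= 7)
    need <- if (has_vel) 7L else 4L
    if (any(ncol_body < need)) {
      stop(sprintf("frame %d: atom lines need %d columns", frame, need), call. = FALSE)
    }
    el <- vapply(toks, `[[`, character(1), 1L)
    if (is.null(el0)) {
      el0 <- el
    } else if (length(el) != length(el0)) {
      stop(sprintf("frame %d: atom count mismatch", frame), call. = FALSE)
    } else if (!identical(el, el0)) {
      stop(sprintf("frame %d: element ordering differs from frame 1", frame), call. = FALSE)
    }
    num <- vapply(toks, function(tk) as.numeric(tk[2:need]), numeric(need - 1L))
    num <- t(num)
    pos_list[[frame]] <- num[, 1:3, drop = FALSE]
    if (has_vel) vel_list[[frame]] <- num[, 4:6, drop = FALSE]
    i <- i + 2L + n
  }
  if (frame == 0L) stop("no frames found", call. = FALSE)
  n_atoms <- length(el0)
  pos <- array(unlist(pos_list), dim = c(n_atoms, 3, frame))
  vel <- NULL
  if (length(vel_list) == frame && frame > 0L && !is.null(vel_list[[1]])) {
    vel <- array(unlist(vel_list), dim = c(n_atoms, 3, frame))
  }
  cellm <- do.call(rbind, cell_list)
  trajectory(el0, pos, cellm, dt = dt, velocities = vel)
}

#' Write a trajectory to an extended-XYZ file
#'
#' @param traj A [trajectory()].
#' @param path Output path.
#' @param digits Number of significant digits for coordinates.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, digits = 10) {
  stopifnot(inherits(traj, "trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  has_vel <- !is.null(traj$velocities)
  props <- if (has_vel) "Properties=species:S:1:pos:R:3:vel:R:3" else "Properties=species:S:1:pos:R:3"
  fmt <- paste0("%.", digits, "g")
  for (f in seq_len(traj$n_frames)) {
    cl <- traj$cell[f, ]
    lattice <- sprintf('Lattice="%s 0 0 0 %s 0 0 0 %s"',
                       sprintf(fmt, cl[1]), sprintf(fmt, cl[2]), sprintf(fmt, cl[3]))
    writeLines(as.character(traj$n_atoms), con)
    writeLines(paste(lattice, props), con)
    p <- frame_coords(traj, f)
    if (has_vel) {
      v <- frame_coords(traj, f, "velocities")
      body <- sprintf(paste("%-3s", paste(rep(fmt, 6), collapse = " ")),
                      traj$elements, p[, 1], p[, 2], p[, 3], v[, 1], v[, 2], v[, 3])
    } else {
      body <- sprintf(paste("%-3s", paste(rep(fmt, 3), collapse = " ")),
                      traj$elements, p[, 1], p[, 2], p[, 3])
    }
    writeLines(body, con)
  }
  invisible(path)
}
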