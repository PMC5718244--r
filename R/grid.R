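#' Detector grid geometry for a 32x32 ionization chamber array
#'
#' Describes the physical layout of the 2D array: number of rows/columns,
#' detector pitch, which chambers are active, and the physical coordinate of
#' the first detector centre. With the default origin the grid is centred on
#' the beam axis, i.e. the centre of the array maps to (0, 0) mm.
#'
#' @param n_rows,n_cols Number of detector rows and columns (32 for the
#'   supported device).
#' @param pitch Centre-to-centre detector spacing in mm (device standard
#'   7.62 mm).
#' @param active_mask Logical matrix of dimension `n_rows x n_cols`, `TRUE`
#'   where a physical chamber exists. Defaults to all-true; use
#'   [device_active_mask()] for a device-faithful mask with clipped corners.
#' @param origin Physical (x, y) coordinate in mm of the centre of detector
#'   (row 1, column 1). Defaults to the symmetric placement
#'   `-(n - 1) / 2 * pitch` so the grid centre lies at (0, 0).
#'
#' @return An object of class `detector_grid`.
#' @export
#' @examples
#' g <- detector_grid()
#' detector_position(g, 16, 16) # (-pitch/2, -pitch/2)
detector_grid <- function(n_rows = 32L, n_cols = 32L, pitch = 7.62,
                          active_mask = NULL, origin = NULL) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  stopifnot(n_rows >= 1, n_cols >= 1, pitch > 0)
  if (is.null(origin)) {
    origin <- c(-(n_cols - 1) / 2 * pitch, -(n_rows - 1) / 2 * pitch)
  }
  if (is.null(active_mask)) {
    active_mask <- matrix(TRUE, n_rows, n_cols)
  }
  if (!is.matrix(active_mask) || !identical(dim(active_mask), c(n_rows, n_cols)))
    stop("active_mask must be a ", n_rows, "x", n_cols, " logical matrix")
  if (!any(active_mask)) stop("active_mask must have at least one active detector")
  structure(list(n_rows = n_rows, n_cols = n_cols, pitch = pitch,
                 active_mask = active_mask, origin = as.numeric(origin)),
            class = "detector_grid")
}

#' Device-faithful active-detector mask
#'
#' The physical device omits chambers in the four corners; this returns a
#' 32x32 logical mask with `n_corner` chambers clipped from each corner
#' (triangular cut). The default package grid uses an all-true mask, which is
#' the indexing convention used when deriving and applying correction factors.
#'
#' @param n_corner Number of detectors clipped along each edge of a corner.
#' @return 32x32 logical matrix.
#' @export
device_active_mask <- function(n_corner = 2L) {
  m <- matrix(TRUE, 32L, 32L)
  for (i in seq_len(n_corner)) {
    k <- n_corner - i + 1L
    idx <- seq_len(k)
    m[i, idx] <- FALSE; m[i, 33L - idx] <- FALSE
    m[33L - i, idx] <- FALSE; m[33L - i, 33L - idx] <- FALSE
  }
  m
}

#' Physical position of a detector centre
#'
#' Maps 1-based detector indices (row `i`, column `j`) to physical (x, y)
#' coordinates in mm. Columns run along x (cross-line), rows along y
#' (in-line). The mapping is antisymmetric about the grid centre:
#' `detector_position(g, i, j) == -detector_position(g, 33 - i, 33 - j)`
#' for the default 32x32 grid.
#'
#' @param grid A [detector_grid()].
#' @param i,j Row and column indices (vectorised, recycled to common length).
#' @return A two-column matrix with columns `x` and `y` (mm); a single
#'   (i, j) pair gives one row.
#' @export
detector_position <- function(grid, i, j) {
  stopifnot(inherits(grid, "detector_grid"))
  n <- max(length(i), length(j))
  i <- rep_len(as.integer(i), n); j <- rep_len(as.integer(j), n)
  if (any(i < 1L | i > grid$n_rows)) stop("row index i out of range")
  if (any(j < 1L | j > grid$n_cols)) stop("column index j out of range")
  cbind(x = grid$origin[1] + (j - 1L) * grid$pitch,
        y = grid$origin[2] + (i - 1L) * grid$pitch)
}

#' Single movie-mode dose snapshot
#'
#' A 32x32 array of non-negative doses (cGy) acquired over `duration`
#' seconds, tagged with the gantry angle reported by the angle sensor at
#' acquisition time.
#'
#' @param dose Numeric matrix of non-negative doses, dimensions matching
#'   `grid`.
#' @param gantry_angle Gantry angle in degrees, in [0, 360), or `NA` for an
#'   accumulated (angle-free) frame.
#' @param duration Frame duration in seconds (> 0); movie mode samples at
#'   0.2 s per snapshot.
#' @param grid Grid the frame belongs to (geometry check only).
#' @return An object of class `dose_frame`.
#' @export
dose_frame <- function(dose, gantry_angle = NA_real_, duration = 0.2,
                       grid = detector_grid()) {
  if (!is.matrix(dose) || !is.numeric(dose))
    stop("dose must be a numeric matrix")
  if (!identical(dim(dose), c(grid$n_rows, grid$n_cols)))
    stop("dose must be ", grid$n_rows, "x", grid$n_cols,
         " to match the detector grid")
  if (any(!is.finite(dose)) || any(dose < 0))
    stop("dose values must be finite and non-negative")
  if (!is.na(gantry_angle)) {
    if (gantry_angle < 0 || gantry_angle >= 360) {
      gantry_angle <- gantry_angle %% 360
      warning("gantry_angle normalised modulo 360 to ", gantry_angle)
    }
  }
  stopifnot(duration > 0)
  structure(list(dose = dose, gantry_angle = as.numeric(gantry_angle),
                 duration = as.numeric(duration)),
            class = "dose_frame")
}

#' Movie-mode acquisition: an ordered sequence of dose frames
#'
#' @param frames List of [dose_frame()] objects (at least one), all with the
#'   same dose dimensions.
#' @param energy Optional beam-energy label carried for bookkeeping.
#' @return An object of class `dose_movie`.
#' @export
dose_movie <- function(frames, energy = NULL) {
  if (length(frames) < 1L) stop("a dose_movie needs at least one frame")
  ok <- vapply(frames, inherits, logical(1), what = "dose_frame")
  if (!all(ok)) stop("all elements of frames must be dose_frame objects")
  d1 <- dim(frames[[1L]]$dose)
  same <- vapply(frames, function(f) identical(dim(f$dose), d1), logical(1))
  if (!all(same)) stop("all frames must have identical dose dimensions")
  structure(list(frames = frames, energy = energy), class = "dose_movie")
}

#' Accumulate a movie into a single cumulative dose frame
#'
#' Element-wise sum of all frames. The result carries no gantry angle (a
#' composite has none) and the total duration.
#'
#' @param movie A [dose_movie()].
#' @return A `dose_frame` with the cumulative dose.
#' @export
accumulate <- function(movie) {
  stopifnot(inherits(movie, "dose_movie"))
  total <- Reduce(`+`, lapply(movie$frames, `[[`, "dose"))
  dur <- sum(vapply(movie$frames, `[[`, numeric(1), "duration"))
  f <- movie$frames[[1L]]
  out <- f
  out$dose <- total
  out$gantry_angle <- NA_real_
  out$duration <- dur
  out
}

#' Mean dose of the four central detectors
#'
#' The central dose of the array is defined as the arithmetic mean of the
#' four detectors at rows 16-17, columns 16-17 (an even grid has no single
#' centre chamber).
#'
#' @param x A `dose_frame` or a bare 32x32 dose matrix.
#' @param grid Grid providing the active mask; the central 2x2 block must be
#'   active.
#' @return Scalar dose.
#' @export
central_detector_dose <- function(x, grid = detector_grid()) {
  dose <- if (inherits(x, "dose_frame")) x$dose else x
  r <- grid$n_rows %/% 2L; cc <- grid$n_cols %/% 2L
  ri <- c(r, r + 1L); ci <- c(cc, cc + 1L)
  if (!all(grid$active_mask[ri, ci]))
    stop("central detectors are not active in this grid")
  mean(dose[ri, ci])
}

#' Mean dose of the two central-row detectors in one column
#'
#' Averages detectors (row 16, j) and (row 17, j), the pair used to
#' characterise off-axis response along the cross-line direction.
#'
#' @param x A `dose_frame` or dose matrix.
#' @param j Column index, 1..32.
#' @param grid Detector grid (geometry).
#' @return Scalar dose.
#' @export
offaxis_pair_dose <- function(x, j, grid = detector_grid()) {
  dose <- if (inherits(x, "dose_frame")) x$dose else x
  j <- as.integer(j)
  if (length(j) != 1L || is.na(j) || j < 1L || j > grid$n_cols)
    stop("column index j out of range")
  r <- grid$n_rows %/% 2L
  mean(dose[c(r, r + 1L), j])
}

#' @export
print.detector_grid <- function(x, ...) {
  cat(sprintf("<detector_grid> %dx%d, pitch %.2f mm, %d active detectors\n",
              x$n_rows, x$n_cols, x$pitch, sum(x$active_mask)))
  invisible(x)
}

#' @export
print.dose_frame <- function(x, ...) {
  ang <- if (is.na(x$gantry_angle)) "no angle" else
    sprintf("gantry %.1f deg", x$gantry_angle)
  cat(sprintf("<dose_frame> %dx%d, %s, %.3g s, max %.4g cGy\n",
              nrow(x$dose), ncol(x$dose), ang, x$duration, max(x$dose)))
  invisible(x)
}

#' @export
print.dose_movie <- function(x, ...) {
  angs <- vapply(x$frames, `[[`, numeric(1), "gantry_angle")
  cat(sprintf("<dose_movie> %d frames, gantry %s\n", length(x$frames),
              if (all(is.na(angs))) "untagged" else
                sprintf("%.1f..%.1f deg", min(angs, na.rm = TRUE),
                        max(angs, na.rm = TRUE))))
  invisible(x)
}
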