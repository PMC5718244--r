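#' Derive gantry-angle-dependent correction factors
#'
#' Estimates the angular-dependence correction factors (CFs) of the array
#' from a paired calibration set: measured frames and reference ("calculated")
#' doses at the detector positions, one of each per calibration angle. For
#' every angle theta and column j the off-axis CF is
#' \deqn{CF_j(\theta) = N_j \, \bar D^{meas}_{j}(\theta) / \bar D^{ref}_{j}(\theta)}
#' where the bar denotes the mean over the two central rows (16, 17) at
#' column j, and the central CF uses the mean of the four central detectors
#' (rows 16-17, columns 16-17). The normalisation factors N are fixed so
#' every curve equals exactly 1 at theta = 0 deg. Corrected doses are later
#' obtained by *dividing* a reading by its CF.
#'
#' @param measured List of angle-tagged [dose_frame()] objects (or a
#'   [dose_movie()]), one frame per calibration angle, 0 deg included.
#' @param reference List of reference doses at the detector positions over
#'   the same angles: angle-tagged `dose_frame`s, or bare 32x32 matrices in
#'   the same order as `measured`.
#' @param energy Beam-energy label stored with the table (defaults to the
#'   movie's energy when available).
#' @param grid [detector_grid()] defining the central rows/columns.
#' @return An object of class `cf_table` with components `energy`, `angles`,
#'   `central_cf` (vector), `column_cf` (32 x n_angles matrix) and
#'   `normalization` (the N factors recorded at 0 deg).
#' @seealso [predict.cf_table()] for interpolation, [apply_correction()] and
#'   [correct_movie()] for use, [cf_difference()] for the central-vs-off-axis
#'   difference statistic.
#' @export
derive_cf <- function(measured, reference, energy = NULL,
                      grid = detector_grid()) {
  if (inherits(measured, "dose_movie")) {
    if (is.null(energy)) energy <- measured$energy
    measured <- measured$frames
  }
  stopifnot(length(measured) >= 1L,
            all(vapply(measured, inherits, logical(1), "dose_frame")))
  ang <- vapply(measured, `[[`, numeric(1), "gantry_angle")
  if (any(is.na(ang))) stop("every measured frame must carry a gantry angle")
  ref_mat <- lapply(reference, function(r) {
    if (inherits(r, "dose_frame")) r$dose
    else if (inherits(r, "dose_plane")) r$values
    else if (is.matrix(r)) r
    else stop("reference entries must be dose_frame, dose_plane or matrix")
  })
  if (length(ref_mat) != length(measured))
    stop("measured and reference must cover the same angle set")
  ref_ang <- vapply(reference, function(r)
    if (inherits(r, "dose_frame")) r$gantry_angle else NA_real_, numeric(1))
  if (!any(is.na(ref_ang))) {
    ord <- match(round(ang, 6), round(ref_ang, 6))
    if (any(is.na(ord)))
      stop("measured and reference must cover the same angle set")
    ref_mat <- ref_mat[ord]
  }
  o <- order(ang)
  ang <- ang[o]; measured <- measured[o]; ref_mat <- ref_mat[o]
  if (anyDuplicated(ang)) stop("duplicate calibration angles")
  i0 <- which(abs(ang) < 1e-9)
  if (length(i0) != 1L)
    stop("calibration set must include theta = 0 deg (normalization angle)")

  nA <- length(ang)
  col_ratio <- matrix(NA_real_, grid$n_cols, nA)
  cen_ratio <- numeric(nA)
  r16 <- grid$n_rows %/% 2L
  for (a in seq_len(nA)) {
    m <- measured[[a]]$dose; r <- ref_mat[[a]]
    if (!identical(dim(r), dim(m))) stop("reference dose shape mismatch")
    ref_rows <- r[c(r16, r16 + 1L), , drop = FALSE]
    if (any(ref_rows <= 0))
      stop("reference doses at the central rows must be positive")
    col_ratio[, a] <- colMeans(m[c(r16, r16 + 1L), , drop = FALSE]) /
      colMeans(ref_rows)
    cen_ratio[a] <- central_detector_dose(m, grid) /
      central_detector_dose(r, grid)
  }
  n_col <- 1 / col_ratio[, i0]
  n_cen <- 1 / cen_ratio[i0]
  column_cf <- col_ratio * n_col          # recycles N_j down each row
  central_cf <- cen_ratio * n_cen
  if (any(column_cf <= 0) || any(central_cf <= 0))
    stop("derived CFs must be positive")
  structure(list(energy = energy, angles = ang, central_cf = central_cf,
                 column_cf = column_cf,
                 normalization = list(angle = ang[i0], central = n_cen,
                                      column = n_col),
                 call = match.call()),
            class = "cf_table")
}

validate_cf_table <- function(table) {
  stopifnot(inherits(table, "cf_table"))
  if (is.unsorted(table$angles, strictly = TRUE))
    stop("cf_table angles must be strictly increasing")
  if (!any(abs(table$angles) < 1e-9)) stop("cf_table must include 0 deg")
  i0 <- which(abs(table$angles) < 1e-9)
  if (abs(table$central_cf[i0] - 1) > 1e-9 ||
      any(abs(table$column_cf[, i0] - 1) > 1e-9))
    stop("cf_table must be normalised to 1 at 0 deg")
  if (any(table$central_cf <= 0) || any(table$column_cf <= 0))
    stop("cf_table CFs must be positive")
  invisible(table)
}

# map an arbitrary gantry angle onto the calibration range [0, 180]:
# angles past 180 mirror onto 360 - theta (angular dependence assumed
# symmetric about the vertical axis)
fold_angle <- function(theta) {
  out_of_range <- theta < 0 | theta >= 360
  if (any(out_of_range)) {
    warning("gantry angle outside [0, 360) normalised modulo 360")
    theta <- theta %% 360
  }
  ifelse(theta > 180, 360 - theta, theta)
}

#' Interpolate correction factors at arbitrary gantry angles
#'
#' Angles beyond 180 deg are mirrored (`CF(theta) = CF(360 - theta)`), then
#' the CF is piecewise-linearly interpolated on the calibration angle grid;
#' values at grid angles are exact.
#'
#' @param object A `cf_table` from [derive_cf()] or [read_cf_table()].
#' @param angle Gantry angle(s) in degrees.
#' @param column Column index 1..32 for an off-axis CF, or `NULL` (default)
#'   for the central-detector CF.
#' @param ... Unused.
#' @return Numeric vector of CF values, recycled over `angle`.
#' @export
predict.cf_table <- function(object, angle, column = NULL, ...) {
  validate_cf_table(object)
  th <- fold_angle(angle)
  curve <- if (is.null(column)) object$central_cf else {
    column <- as.integer(column)
    if (length(column) != 1L || column < 1L || column > nrow(object$column_cf))
      stop("column index out of range")
    object$column_cf[column, ]
  }
  stats::approx(object$angles, curve, xout = th, rule = 2)$y
}

#' @rdname predict.cf_table
#' @param table A `cf_table`.
#' @param j Column index (1..32) or `NULL` for the central CF.
#' @param gantry_angle Angle(s) in degrees, [0, 360).
#' @export
cf_at <- function(table, j = NULL, gantry_angle) {
  predict(table, angle = gantry_angle, column = j)
}

#' Central vs off-axis CF difference
#'
#' The relative difference between an off-axis column's CF and the central
#' CF at a gantry angle:
#' \deqn{100 \, (CF_j(\theta) - CF_c(\theta)) / CF_c(\theta)}
#'
#' @param table A `cf_table`.
#' @param j Column index 1..32 (vectorised).
#' @param angle Gantry angle in degrees.
#' @return Difference in percent.
#' @export
cf_difference <- function(table, j, angle) {
  cen <- predict(table, angle)
  vapply(j, function(jj) {
    100 * (predict(table, angle, column = jj) - cen) / cen
  }, numeric(length(angle)))
}

#' Apply an angular-dependence correction to a dose frame
#'
#' Divides each detector reading by the correction factor interpolated at
#' the frame's gantry angle. Under the `"central"` scheme the central CF is
#' applied to every detector; under `"entire"` each column j gets its own
#' off-axis CF, broadcast over all rows of that column; `"none"` returns the
#' frame unchanged.
#'
#' @param frame An angle-tagged [dose_frame()].
#' @param table A `cf_table`. Applying a table whose energy label differs
#'   from the movie/frame energy only warns (sensitivity studies).
#' @param scheme `"entire"`, `"central"` or `"none"`.
#' @return The corrected `dose_frame` (angle and duration preserved).
#' @export
apply_correction <- function(frame, table,
                             scheme = c("entire", "central", "none")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(frame, "dose_frame"))
  if (scheme == "none") return(frame)
  validate_cf_table(table)
  if (is.na(frame$gantry_angle))
    stop("frame has no gantry angle; cannot look up correction factors")
  th <- frame$gantry_angle
  if (scheme == "central") {
    cf <- predict(table, th)
    frame$dose <- frame$dose / cf
  } else {
    cfs <- vapply(seq_len(nrow(table$column_cf)),
                  function(j) predict(table, th, column = j), numeric(1))
    if (any(cfs <= 0)) stop("correction factors must be positive")
    frame$dose <- sweep(frame$dose, 2L, cfs, `/`)
  }
  frame
}

#' Correct a movie-mode acquisition frame by frame and accumulate
#'
#' Applies [apply_correction()] to every frame using that frame's own
#' gantry-angle tag (arc deliveries thereby get per-segment CFs), then sums
#' the corrected frames into a cumulative dose.
#'
#' @param movie A [dose_movie()] whose frames all carry gantry angles.
#' @inheritParams apply_correction
#' @return Cumulative corrected `dose_frame`.
#' @export
correct_movie <- function(movie, table,
                          scheme = c("entire", "central", "none")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(movie, "dose_movie"))
  angs <- vapply(movie$frames, `[[`, numeric(1), "gantry_angle")
  if (scheme != "none" && any(is.na(angs)))
    stop("every frame needs a gantry angle for per-frame correction")
  if (!is.null(table$energy) && !is.null(movie$energy) &&
      !identical(table$energy, movie$energy))
    warning("CF table energy (", table$energy, ") differs from movie energy (",
            movie$energy, ")")
  corrected <- lapply(movie$frames, apply_correction, table = table,
                      scheme = scheme)
  accumulate(dose_movie(corrected, energy = movie$energy))
}

#' @export
print.cf_table <- function(x, ...) {
  cat(sprintf("<cf_table> %s, %d calibration angles (%.0f..%.0f deg)\n",
              x$energy %||% "unlabelled", length(x$angles),
              min(x$angles), max(x$angles)))
  key <- c(90, 92, 180)
  have <- key[key %in% x$angles]
  for (th in have)
    cat(sprintf("  central CF(%3.0f deg) = %.4f\n", th, predict(x, th)))
  invisible(x)
}

#' @export
summary.cf_table <- function(object, ...) {
  validate_cf_table(object)
  rng <- apply(object$column_cf, 2, range)
  out <- data.frame(angle = object$angles,
                    central_cf = object$central_cf,
                    column_cf_min = rng[1, ],
                    column_cf_max = rng[2, ],
                    max_diff_pct = sapply(seq_along(object$angles), function(a)
                      max(abs(100 * (object$column_cf[, a] -
                                       object$central_cf[a]) /
                                object$central_cf[a]))))
  class(out) <- c("summary.cf_table", "data.frame")
  out
}

#' @export
coef.cf_table <- function(object, ...) {
  m <- cbind(central = object$central_cf, t(object$column_cf))
  colnames(m) <- c("central", paste0("j", seq_len(nrow(object$column_cf))))
  rownames(m) <- format(object$angles)
  m
}

#' Plot CF curves against gantry angle
#'
#' Shows the central curve and the two outermost columns (the envelope of
#' the off-axis CFs).
#'
#' @param x A `cf_table`.
#' @param columns Column indices to draw alongside the central curve.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.cf_table <- function(x, columns = c(1L, 32L), ...) {
  curves <- cbind(x$central_cf, t(x$column_cf[columns, , drop = FALSE]))
  graphics::matplot(x$angles, curves, type = "l", lty = c(1, 2, 3),
                    col = c("black", "firebrick", "steelblue"),
                    xlab = "gantry angle (deg)", ylab = "correction factor",
                    main = paste("Angular dependence,", x$energy %||% ""), ...)
  graphics::abline(h = 1, col = "grey70")
  graphics::legend("bottomleft", bty = "n",
                   legend = c("central", paste0("column ", columns)),
                   lty = c(1, 2, 3),
                   col = c("black", "firebrick", "steelblue"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
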