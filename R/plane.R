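#' 2D dose plane on a regular isotropic grid
#'
#' Carrier for resampled or reference dose distributions: a matrix of
#' non-negative dose values, the isotropic pixel spacing, and the physical
#' (x, y) coordinate of the centre of pixel [1, 1]. Rows index y, columns
#' index x.
#'
#' @param values Numeric matrix of non-negative doses.
#' @param spacing Pixel spacing in mm (> 0), isotropic.
#' @param origin Length-2 numeric: (x, y) of the centre of `values[1, 1]`,
#'   in mm.
#' @return An object of class `dose_plane`.
#' @export
dose_plane <- function(values, spacing, origin = c(0, 0)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (any(!is.finite(values)) || any(values < 0))
    stop("dose values must be finite and non-negative")
  stopifnot(length(spacing) == 1L, spacing > 0, length(origin) == 2L)
  structure(list(values = values, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "dose_plane")
}

#' View a movie-mode frame as a dose plane at the detector positions
#'
#' @param frame A [dose_frame()].
#' @param grid The [detector_grid()] the frame was acquired on.
#' @return A `dose_plane` with spacing equal to the detector pitch.
#' @export
frame_to_plane <- function(frame, grid = detector_grid()) {
  stopifnot(inherits(frame, "dose_frame"))
  dose_plane(frame$dose, spacing = grid$pitch, origin = grid$origin)
}

plane_x <- function(plane) plane$origin[1] + (seq_len(ncol(plane$values)) - 1) * plane$spacing
plane_y <- function(plane) plane$origin[2] + (seq_len(nrow(plane$values)) - 1) * plane$spacing

plane_extent <- function(plane) {
  c(xmin = plane$origin[1],
    xmax = plane$origin[1] + (ncol(plane$values) - 1) * plane$spacing,
    ymin = plane$origin[2],
    ymax = plane$origin[2] + (nrow(plane$values) - 1) * plane$spacing)
}

# Bilinear interpolation of a plane at arbitrary points (vectorised).
# Points outside the plane extent give NA ("na") or an error ("error").
interp_bilinear <- function(plane, x, y, outside = c("error", "na")) {
  outside <- match.arg(outside)
  v <- plane$values
  gx <- (x - plane$origin[1]) / plane$spacing + 1
  gy <- (y - plane$origin[2]) / plane$spacing + 1
  eps <- 1e-9
  out <- gx < 1 - eps | gx > ncol(v) + eps | gy < 1 - eps | gy > nrow(v) + eps
  if (any(out) && outside == "error")
    stop("interpolation point outside plane extent")
  gx <- pmin(pmax(gx, 1), ncol(v)); gy <- pmin(pmax(gy, 1), nrow(v))
  c0 <- pmin(floor(gx), ncol(v) - 1L); r0 <- pmin(floor(gy), nrow(v) - 1L)
  if (ncol(v) == 1L) c0 <- rep_len(1L, length(gx))
  if (nrow(v) == 1L) r0 <- rep_len(1L, length(gy))
  fx <- gx - c0; fy <- gy - r0
  c1 <- pmin(c0 + 1L, ncol(v)); r1 <- pmin(r0 + 1L, nrow(v))
  nr <- nrow(v)
  idx <- function(r, c) (c - 1L) * nr + r
  res <- (1 - fx) * (1 - fy) * v[idx(r0, c0)] +
         fx       * (1 - fy) * v[idx(r0, c1)] +
         (1 - fx) * fy       * v[idx(r1, c0)] +
         fx       * fy       * v[idx(r1, c1)]
  if (any(out)) res[out] <- NA_real_
  res
}

#' Mean dose over a square region of interest
#'
#' Averages the bilinearly interpolated dose over a square ROI (default
#' 1x1 cm, matching the sensitive volume of a thimble chamber used for
#' absolute-dose cross-comparison). The ROI is sampled on a regular sub-grid
#' and the sample mean returned.
#'
#' @param plane A [dose_plane()]; a [dose_frame()] is accepted and
#'   interpreted at the detector positions of the default grid.
#' @param center Length-2 numeric (x, y) ROI centre in mm.
#' @param side ROI side length in mm (default 10).
#' @param sample_step Sub-grid sampling step in mm (default 0.5).
#' @return Scalar mean dose.
#' @export
roi_mean <- function(plane, center = c(0, 0), side = 10, sample_step = 0.5) {
  if (inherits(plane, "dose_frame")) plane <- frame_to_plane(plane)
  stopifnot(inherits(plane, "dose_plane"), side > 0, sample_step > 0)
  ext <- plane_extent(plane)
  if (center[1] - side / 2 < ext["xmin"] - 1e-9 ||
      center[1] + side / 2 > ext["xmax"] + 1e-9 ||
      center[2] - side / 2 < ext["ymin"] - 1e-9 ||
      center[2] + side / 2 > ext["ymax"] + 1e-9)
    stop("ROI extends outside the plane")
  off <- seq(-side / 2, side / 2, by = sample_step)
  pts <- expand.grid(x = center[1] + off, y = center[2] + off)
  mean(interp_bilinear(plane, pts$x, pts$y, outside = "error"))
}

#' @export
print.dose_plane <- function(x, ...) {
  ext <- plane_extent(x)
  cat(sprintf(
    "<dose_plane> %dx%d px, %.3g mm/px, x %.1f..%.1f, y %.1f..%.1f mm, max %.4g cGy\n",
    nrow(x$values), ncol(x$values), x$spacing,
    ext["xmin"], ext["xmax"], ext["ymin"], ext["ymax"], max(x$values)))
  invisible(x)
}

#' Display a dose plane as an image
#'
#' @param x A `dose_plane`.
#' @param main Plot title.
#' @param ... Passed to [graphics::image()].
#' @export
plot.dose_plane <- function(x, main = "dose plane", ...) {
  graphics::image(plane_x(x), plane_y(x), t(x$values),
                  xlab = "x (mm)", ylab = "y (mm)", main = main,
                  col = grDevices::hcl.colors(64, "viridis"),
                  useRaster = TRUE, asp = 1, ...)
  invisible(x)
}
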