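#' Gamma-evaluation criteria
#'
#' Bundles the dose-difference / distance-to-agreement (DTA) tolerances and
#' the evaluation rules: a low-dose threshold excluding reference pixels
#' below a percentage of the normalisation dose, the normalisation mode
#' (global maximum of the reference, or local reference dose), the DTA
#' search radius and the sub-sampling step used when probing the evaluated
#' distribution between pixels.
#'
#' @param dose_tol Dose tolerance in percent of the normalisation dose
#'   (e.g. 2 or 3).
#' @param dta Distance-to-agreement in mm (e.g. 2 or 3).
#' @param threshold Low-dose threshold in percent of the normalisation dose;
#'   reference pixels below it are excluded (default 5).
#' @param normalization `"global_max"` (default; the standard analysis-
#'   software behaviour) or `"local"` (experimental).
#' @param search_radius Spatial search cap in mm (default `3 * dta`).
#' @param step DTA search sub-sampling step in mm (default `dta / 10`).
#' @return An object of class `gamma_criteria`.
#' @export
gamma_criteria <- function(dose_tol = 3, dta = 3, threshold = 5,
                           normalization = c("global_max", "local"),
                           search_radius = 3 * dta, step = dta / 10) {
  normalization <- match.arg(normalization)
  stopifnot(dose_tol > 0, dta > 0, threshold >= 0, threshold < 100,
            search_radius > 0, step > 0)
  structure(list(dose_tol = dose_tol, dta = dta, threshold = threshold,
                 normalization = normalization,
                 search_radius = search_radius, step = step),
            class = "gamma_criteria")
}

#' Resample two dose distributions onto a common fine grid
#'
#' Bilinearly interpolates both distributions onto an isotropic grid
#' (default 1 mm pixels) covering the intersection of their spatial extents,
#' as required before a gamma comparison.
#'
#' @param a,b [dose_plane()] objects (a [dose_frame()] is accepted and taken
#'   at the detector positions of the default grid).
#' @param pixel Target pixel size in mm (default 1).
#' @return List with elements `a` and `b`, both `dose_plane`s on the same
#'   grid.
#' @export
resample_to_common_grid <- function(a, b, pixel = 1) {
  if (inherits(a, "dose_frame")) a <- frame_to_plane(a)
  if (inherits(b, "dose_frame")) b <- frame_to_plane(b)
  stopifnot(inherits(a, "dose_plane"), inherits(b, "dose_plane"), pixel > 0)
  ea <- plane_extent(a); eb <- plane_extent(b)
  xlo <- max(ea["xmin"], eb["xmin"]); xhi <- min(ea["xmax"], eb["xmax"])
  ylo <- max(ea["ymin"], eb["ymin"]); yhi <- min(ea["ymax"], eb["ymax"])
  if (xhi - xlo <= 0 || yhi - ylo <= 0)
    stop("dose planes have no overlapping extent")
  xs <- seq(xlo, xhi, by = pixel)
  ys <- seq(ylo, yhi, by = pixel)
  pts <- expand.grid(x = xs, y = ys)
  mk <- function(p) dose_plane(
    matrix(interp_bilinear(p, pts$x, pts$y, outside = "error"),
           nrow = length(ys), byrow = TRUE),
    spacing = pixel, origin = c(xs[1], ys[1]))
  list(a = mk(a), b = mk(b))
}

# integer-offset shift of a matrix with NA padding
int_shift <- function(v, di, dj) {
  nr <- nrow(v); nc <- ncol(v)
  out <- matrix(NA_real_, nr, nc)
  rs <- seq_len(nr) + di; cs <- seq_len(nc) + dj
  rok <- rs >= 1L & rs <= nr; cok <- cs >= 1L & cs <= nc
  out[rok, cok] <- v[rs[rok], cs[cok]]
  out
}

# values of plane matrix v sampled at (col + dcx, row + dcy) pixel offsets
# (fractional), bilinear, NA outside
frac_shift <- function(v, dcx, dcy) {
  jx <- floor(dcx); fx <- dcx - jx
  iy <- floor(dcy); fy <- dcy - iy
  if (fx == 0 && fy == 0) return(int_shift(v, iy, jx))
  s00 <- int_shift(v, iy, jx)
  s01 <- int_shift(v, iy, jx + 1)
  s10 <- int_shift(v, iy + 1, jx)
  s11 <- int_shift(v, iy + 1, jx + 1)
  (1 - fx) * (1 - fy) * s00 + fx * (1 - fy) * s01 +
    (1 - fx) * fy * s10 + fx * fy * s11
}

#' 2D gamma-index map between two dose distributions
#'
#' For every reference pixel above the low-dose threshold, searches evaluated
#' positions within `search_radius` (on a sub-grid of step `step`, bilinear
#' between pixels) for the minimum combined dose-difference / DTA metric
#' \deqn{\gamma(r) = \min_e \sqrt{ (\Delta d(r,e)/\Delta D)^2 +
#'   (|r-e|/\mathrm{dta})^2 }}
#' with \eqn{\Delta D} the dose tolerance in absolute units (percentage of
#' the global reference maximum, or of the local reference dose). The metric
#' is asymmetric: reference and evaluated roles are not interchangeable.
#' Reference pixels near the grid boundary are evaluated against the clipped
#' neighbourhood. Both planes must already be on a common grid (see
#' [resample_to_common_grid()]).
#'
#' @param reference Reference [dose_plane()] (threshold and normalisation are
#'   taken from it).
#' @param evaluated Evaluated [dose_plane()] on the identical grid.
#' @param criteria A [gamma_criteria()].
#' @return An object of class `gamma_result`: `gamma` (matrix, NA where
#'   excluded), `evaluated_mask`, `pass_rate` (percent of evaluated pixels
#'   with gamma <= 1; `NA` with `all_below_threshold = TRUE` when nothing is
#'   evaluable), `criteria`, `norm_dose`, and the grid geometry.
#' @export
gamma_map <- function(reference, evaluated, criteria = gamma_criteria()) {
  stopifnot(inherits(reference, "dose_plane"),
            inherits(evaluated, "dose_plane"),
            inherits(criteria, "gamma_criteria"))
  if (!identical(dim(reference$values), dim(evaluated$values)) ||
      abs(reference$spacing - evaluated$spacing) > 1e-9 ||
      any(abs(reference$origin - evaluated$origin) > 1e-9))
    stop("planes must share an identical grid; use resample_to_common_grid()")
  R <- reference$values
  E <- evaluated$values
  sp <- reference$spacing
  norm_dose <- max(R)
  dD <- if (criteria$normalization == "global_max")
    criteria$dose_tol / 100 * norm_dose else criteria$dose_tol / 100 * R
  mask <- if (norm_dose > 0) R >= criteria$threshold / 100 * norm_dose
    else matrix(FALSE, nrow(R), ncol(R))   # degenerate all-zero reference
  if (!any(mask)) {
    return(structure(list(gamma = matrix(NA_real_, nrow(R), ncol(R)),
                          evaluated_mask = mask, pass_rate = NA_real_,
                          all_below_threshold = TRUE, criteria = criteria,
                          norm_dose = norm_dose, spacing = sp,
                          origin = reference$origin),
                     class = "gamma_result"))
  }
  s <- criteria$step
  kmax <- floor(criteria$search_radius / s)
  offs <- expand.grid(dx = (-kmax:kmax) * s, dy = (-kmax:kmax) * s)
  offs <- offs[offs$dx^2 + offs$dy^2 <= criteria$search_radius^2 + 1e-12, ]
  # order by distance so the zero offset initialises the minimum
  offs <- offs[order(offs$dx^2 + offs$dy^2), ]
  g2 <- ((E - R) / dD)^2                      # offset (0, 0)
  dta2 <- criteria$dta^2
  for (k in seq_len(nrow(offs))[-1L]) {
    dx <- offs$dx[k]; dy <- offs$dy[k]
    dist2 <- (dx * dx + dy * dy) / dta2
    # offsets are sorted by distance: once the pure spatial penalty exceeds
    # the worst gamma^2 still in play, no later offset can lower any pixel
    if (dist2 >= max(g2[mask])) break
    Es <- frac_shift(E, dx / sp, dy / sp)
    cand <- ((Es - R) / dD)^2 + dist2
    better <- !is.na(cand) & cand < g2
    g2[better] <- cand[better]
  }
  g <- sqrt(g2)
  g[!mask] <- NA_real_
  pass <- 100 * sum(g[mask] <= 1) / sum(mask)
  structure(list(gamma = g, evaluated_mask = mask, pass_rate = pass,
                 all_below_threshold = FALSE, criteria = criteria,
                 norm_dose = norm_dose, spacing = sp,
                 origin = reference$origin),
            class = "gamma_result")
}

#' Tabulate pass rates of several gamma results
#'
#' @param results List of `gamma_result` objects (order preserved).
#' @param labels Character labels, one per result.
#' @return `data.frame` with columns `label`, `dose_tol`, `dta`, `threshold`,
#'   `n_evaluated`, `pass_rate`; ready for [utils::write.csv()].
#' @export
pass_rate_report <- function(results, labels = NULL) {
  if (inherits(results, "gamma_result")) results <- list(results)
  stopifnot(length(results) >= 1L,
            all(vapply(results, inherits, logical(1), "gamma_result")))
  if (is.null(labels)) labels <- paste0("result", seq_along(results))
  stopifnot(length(labels) == length(results))
  data.frame(
    label = as.character(labels),
    dose_tol = vapply(results, function(r) r$criteria$dose_tol, numeric(1)),
    dta = vapply(results, function(r) r$criteria$dta, numeric(1)),
    threshold = vapply(results, function(r) r$criteria$threshold, numeric(1)),
    n_evaluated = vapply(results, function(r) sum(r$evaluated_mask),
                         integer(1)),
    pass_rate = vapply(results, `[[`, numeric(1), "pass_rate"),
    stringsAsFactors = FALSE)
}

#' @export
print.gamma_result <- function(x, ...) {
  cr <- x$criteria
  if (isTRUE(x$all_below_threshold)) {
    cat(sprintf("<gamma_result> %g%%/%g mm: all pixels below the %g%% threshold\n",
                cr$dose_tol, cr$dta, cr$threshold))
  } else {
    cat(sprintf(
      "<gamma_result> %g%%/%g mm, threshold %g%%: pass rate %.1f%% (%d pixels evaluated)\n",
      cr$dose_tol, cr$dta, cr$threshold, x$pass_rate,
      sum(x$evaluated_mask)))
  }
  invisible(x)
}

#' @export
summary.gamma_result <- function(object, ...) {
  g <- object$gamma[object$evaluated_mask]
  c(pass_rate = object$pass_rate, n_evaluated = sum(object$evaluated_mask),
    mean_gamma = mean(g), max_gamma = if (length(g)) max(g) else NA_real_)
}

#' Display a gamma map
#'
#' @param x A `gamma_result`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.gamma_result <- function(x, ...) {
  nx <- ncol(x$gamma); ny <- nrow(x$gamma)
  xs <- x$origin[1] + (seq_len(nx) - 1) * x$spacing
  ys <- x$origin[2] + (seq_len(ny) - 1) * x$spacing
  graphics::image(xs, ys, t(x$gamma), xlab = "x (mm)", ylab = "y (mm)",
                  main = sprintf("gamma %g%%/%g mm (pass %.1f%%)",
                                 x$criteria$dose_tol, x$criteria$dta,
                                 x$pass_rate),
                  col = grDevices::hcl.colors(64, "inferno", rev = TRUE),
                  useRaster = TRUE, asp = 1, ...)
  invisible(x)
}
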