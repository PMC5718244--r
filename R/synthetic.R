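#' Single beam specification
#'
#' A static field at one gantry angle, or an arc. Arc direction `"cw"` means
#' increasing gantry angle (wrapping modulo 360), `"ccw"` decreasing; the
#' full-arc plan "185 to 175 deg" is `arc_start = 185, arc_stop = 175,
#' arc_direction = "cw"` (a 350 deg sweep through 0).
#'
#' @param energy Beam energy label, `"6MV"` or `"10MV"`.
#' @param field_size Length-2 numeric, field size in cm (cross-line x,
#'   in-line y); a scalar is taken as a square field.
#' @param gantry_angle Gantry angle in degrees for a static beam (`NULL` for
#'   an arc).
#' @param arc_start,arc_stop Arc end points in degrees (`NULL` for static).
#' @param arc_direction `"cw"` (increasing angle) or `"ccw"`.
#' @param weight Relative monitor units (> 0).
#' @return An object of class `beam_spec`.
#' @export
beam_spec <- function(energy = "6MV", field_size = c(10, 10),
                      gantry_angle = NULL, arc_start = NULL, arc_stop = NULL,
                      arc_direction = c("cw", "ccw"), weight = 1) {
  arc_direction <- match.arg(arc_direction)
  field_size <- rep_len(as.numeric(field_size), 2L)
  stopifnot(all(field_size > 0), weight > 0)
  is_arc <- !is.null(arc_start)
  if (is_arc) {
    stopifnot(!is.null(arc_stop))
    gantry_angle <- NULL
  } else if (is.null(gantry_angle)) {
    stop("a beam needs either gantry_angle or arc_start/arc_stop")
  }
  structure(list(energy = energy, field_size = field_size,
                 gantry_angle = if (!is_arc) as.numeric(gantry_angle) %% 360,
                 arc_start = if (is_arc) as.numeric(arc_start) %% 360,
                 arc_stop = if (is_arc) as.numeric(arc_stop) %% 360,
                 arc_direction = if (is_arc) arc_direction,
                 is_arc = is_arc, weight = as.numeric(weight)),
            class = "beam_spec")
}

#' Plan specification: an ordered list of beams
#'
#' @param beams List of [beam_spec()] objects (at least one).
#' @param frame_duration Movie-mode frame duration in seconds (default 0.2,
#'   the array's 200 ms/snap sampling).
#' @param name Optional plan label used in reports.
#' @return An object of class `plan_spec`.
#' @export
plan_spec <- function(beams, frame_duration = 0.2, name = "plan") {
  if (inherits(beams, "beam_spec")) beams <- list(beams)
  stopifnot(length(beams) >= 1L,
            all(vapply(beams, inherits, logical(1), "beam_spec")),
            frame_duration > 0)
  structure(list(beams = beams, frame_duration = as.numeric(frame_duration),
                 name = name),
            class = "plan_spec")
}

#' Six standard multi-beam verification geometries
#'
#' The simple composite plans used to validate angular correction: opposed
#' vertical, opposed lateral, four- and six-field arrangements, and a full
#' 350 deg arc (185 to 175 deg).
#'
#' @param energy Beam energy label.
#' @param field_size Field size in cm (square).
#' @return Named list of six [plan_spec()] objects.
#' @export
simple_plans <- function(energy = "6MV", field_size = 10) {
  b <- function(th) beam_spec(energy, field_size, gantry_angle = th)
  mk <- function(angles, nm) plan_spec(lapply(angles, b), name = nm)
  list(
    plan1 = mk(c(0, 180), "plan1_opposed_vertical"),
    plan2 = mk(c(90, 270), "plan2_opposed_lateral"),
    plan3 = mk(c(0, 90, 180, 270), "plan3_four_field_box"),
    plan4 = mk(c(60, 120, 240, 300), "plan4_four_field_oblique"),
    plan5 = mk(c(45, 90, 135, 225, 270, 315), "plan5_six_field"),
    plan6 = plan_spec(beam_spec(energy, field_size, arc_start = 185,
                                arc_stop = 175, arc_direction = "cw"),
                      name = "plan6_full_arc"))
}

#' Default rectangular phantom dimensions
#'
#' Solid-water slab phantom housing the array: 34 cm wide (x, cross-line),
#' 31.4 cm long (y, in-line), 22 cm high (z). The detector plane sits at
#' mid-height (z = 0).
#'
#' @return Named numeric vector (mm): `x`, `y`, `z`.
#' @export
default_phantom <- function() c(x = 340, y = 314, z = 220)

# attenuation coefficients per mm; stand-in broad-beam values, configurable
default_mu <- function(energy) {
  switch(energy, "6MV" = 0.0049, "10MV" = 0.0041,
         stop("unknown energy label: ", energy))
}

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

# error-function edge profile of a field of half-width w at off-axis t
edge_profile <- function(t, w, sigma) {
  0.5 * (erf((w - t) / (sqrt(2) * sigma)) + erf((w + t) / (sqrt(2) * sigma)))
}

# radiological depth from phantom entry surface to points (x, y, 0) along the
# ray from a source at gantry angle theta; slab (box) intersection
ray_depth <- function(x, y, theta_deg, phantom, sad) {
  th <- theta_deg * pi / 180
  s <- c(sad * sin(th), 0, sad * cos(th))
  half <- phantom / 2
  dx <- x - s[1]; dy <- y - s[2]; dz <- 0 - s[3]
  len <- sqrt(dx^2 + dy^2 + dz^2)
  t_entry <- rep(-Inf, length(x))
  for (k in 1:3) {
    sk <- s[k]
    dk <- switch(k, dx, dy, dz)
    lo <- (-half[k] - sk) / dk
    hi <- (half[k] - sk) / dk
    small <- abs(dk) < 1e-12
    tlo <- pmin(lo, hi); tlo[small] <- -Inf
    t_entry <- pmax(t_entry, tlo)
  }
  if (any(t_entry >= 1 - 1e-12) || any(!is.finite(t_entry)))
    stop("beam does not intersect the phantom at all detector positions")
  t_entry <- pmax(t_entry, 0)
  list(depth = (1 - t_entry) * len, dist = len)
}

# analytic dose at points (x, y) in the detector plane for a static field
beam_dose_points <- function(x, y, energy, field_size, theta_deg, weight,
                             phantom = default_phantom(), sad = 1000,
                             penumbra_sigma = 3, mu = NULL, dose_scale = 100) {
  if (is.null(mu)) mu <- default_mu(energy)
  th <- theta_deg * pi / 180
  # off-axis coordinates in the beam's rotated frame (detector plane z = 0)
  u <- x * cos(th)
  v <- y
  flu <- edge_profile(u, field_size[1] * 10 / 2, penumbra_sigma) *
         edge_profile(v, field_size[2] * 10 / 2, penumbra_sigma)
  rd <- ray_depth(x, y, theta_deg, phantom, sad)
  dose_scale * weight * flu * exp(-mu * rd$depth) * (sad / rd$dist)^2
}

#' Analytic ground-truth dose plane for a static beam
#'
#' Deterministic parametric dose model used as the reference ("calculated")
#' distribution in the synthetic workflow: primary fluence given by a product
#' of error-function penumbra profiles of the stated field size in the beam's
#' rotated frame, times exponential attenuation along the ray from the
#' phantom entry surface to the point, times inverse-square fall-off from a
#' point source at `sad` mm. It is a smooth, geometrically faithful test
#' harness, not a dose engine.
#'
#' @param beam A static [beam_spec()] (for arcs pass `angle` explicitly per
#'   segment or use [composite_true_dose()]).
#' @param grid [detector_grid()] defining the detector positions (used when
#'   `spacing` is `NULL`).
#' @param phantom Named phantom dimensions in mm, see [default_phantom()].
#' @param spacing If `NULL` (default), evaluate at the detector positions
#'   (pixel spacing = pitch). Otherwise evaluate on a fine grid with this
#'   spacing (mm) covering the detector extent.
#' @param angle Gantry angle override in degrees (required for arc beams,
#'   which have no single angle).
#' @param sad Source-axis distance in mm.
#' @param penumbra_sigma Gaussian penumbra width parameter in mm.
#' @param mu Linear attenuation coefficient per mm; defaults by energy
#'   (0.0049 for 6 MV, 0.0041 for 10 MV).
#' @param dose_scale Dose (cGy) per unit beam weight for unit fluence at the
#'   phantom surface on the central axis.
#' @return A [dose_plane()].
#' @export
true_dose_plane <- function(beam, grid = detector_grid(),
                            phantom = default_phantom(), spacing = NULL,
                            angle = NULL, sad = 1000, penumbra_sigma = 3,
                            mu = NULL, dose_scale = 100) {
  stopifnot(inherits(beam, "beam_spec"))
  if (is.null(angle)) {
    if (beam$is_arc)
      stop("arc beams have no single gantry angle; pass `angle` or use composite_true_dose()")
    angle <- beam$gantry_angle
  }
  if (is.null(spacing)) {
    xs <- grid$origin[1] + (seq_len(grid$n_cols) - 1) * grid$pitch
    ys <- grid$origin[2] + (seq_len(grid$n_rows) - 1) * grid$pitch
    spacing_out <- grid$pitch
  } else {
    ext <- (grid$n_cols - 1) / 2 * grid$pitch
    xs <- seq(-ext, ext, by = spacing)
    ys <- seq(-ext, ext, by = spacing)
    spacing_out <- spacing
  }
  pts <- expand.grid(x = xs, y = ys)
  d <- beam_dose_points(pts$x, pts$y, beam$energy, beam$field_size, angle,
                        beam$weight, phantom, sad, penumbra_sigma, mu,
                        dose_scale)
  dose_plane(matrix(d, nrow = length(ys), byrow = TRUE),
             spacing = spacing_out, origin = c(xs[1], ys[1]))
}

# discretise a beam into (angle, weight-fraction) segments
beam_segments <- function(beam, arc_step = 2, frames_per_beam = 5L) {
  if (!beam$is_arc) {
    n <- max(1L, as.integer(frames_per_beam))
    return(list(angles = rep(beam$gantry_angle, n), frac = rep(1 / n, n)))
  }
  span <- if (beam$arc_direction == "cw")
    (beam$arc_stop - beam$arc_start) %% 360 else
    (beam$arc_start - beam$arc_stop) %% 360
  if (span == 0) span <- 360
  n <- max(1L, round(span / arc_step))
  step <- span / n
  mids <- beam$arc_start +
    (if (beam$arc_direction == "cw") 1 else -1) * (seq_len(n) - 0.5) * step
  list(angles = mids %% 360, frac = rep(1 / n, n))
}

#' Noiseless composite ground-truth dose for a whole plan
#'
#' Sums the analytic dose over all beams, discretising arcs into angular
#' segments (default 2 deg per segment, midpoint angles) exactly as
#' [simulate_measurement()] does, so simulated and true composites share the
#' same arc discretisation.
#'
#' @inheritParams true_dose_plane
#' @param plan A [plan_spec()].
#' @param arc_step Arc discretisation step in degrees.
#' @param ... Passed to [true_dose_plane()] (`sad`, `penumbra_sigma`, `mu`,
#'   `dose_scale`).
#' @return A [dose_plane()].
#' @export
composite_true_dose <- function(plan, grid = detector_grid(),
                                phantom = default_phantom(), spacing = NULL,
                                arc_step = 2, ...) {
  stopifnot(inherits(plan, "plan_spec"))
  total <- NULL
  for (beam in plan$beams) {
    seg <- beam_segments(beam, arc_step = arc_step, frames_per_beam = 1L)
    for (k in seq_along(seg$angles)) {
      p <- true_dose_plane(beam, grid, phantom, spacing,
                           angle = seg$angles[k], ...)
      contrib <- p$values * seg$frac[k]
      total <- if (is.null(total)) contrib else total + contrib
      tmpl <- p
    }
  }
  dose_plane(total, spacing = tmpl$spacing, origin = tmpl$origin)
}

#' Calibration gantry-angle grid
#'
#' The angle grid on which correction factors are measured: 10 deg steps
#' over 0-180 deg plus 1 deg steps over the lateral range 90-110 deg
#' (37 distinct angles).
#'
#' @return Sorted numeric vector of angles in degrees.
#' @export
calibration_angles <- function() {
  sort(unique(c(seq(0, 180, by = 10), 90:110)))
}

# piecewise-linear evaluation of (angle, value) key points on a query grid
pl_interp <- function(keys_x, keys_y, x) {
  stats::approx(keys_x, keys_y, xout = x, rule = 2)$y
}

#' Packaged gantry-angle response profile of the array
#'
#' Relative detector response R_j(theta) (reading / true dose) per column on
#' the calibration angle grid, emulating the measured angular dependence of
#' the device: near-unity response at vertical incidence, a sharp
#' over-response where the beam is parallel to the detector plane (90 deg),
#' a sharp under-response just past it (92 deg), partial recovery, and a
#' smooth decline toward posterior incidence (180 deg). The central-column
#' curve hits the characterised extrema for the energy (6 MV: +6% at 90,
#' -15% at 92, -8% at 180; 10 MV: +4%, -11%, -5%); outer columns are offset
#' from the central curve so that the central-vs-off-axis CF difference
#' spans the characterised ranges near 90 deg (6 MV: -6.1% to +7.0%;
#' 10 MV: -3.7% to +6.0%) and stays within the small ranges elsewhere.
#' Between anchor angles the response is piecewise linear.
#'
#' @param energy `"6MV"` or `"10MV"`.
#' @param noise_sigma Default relative measurement noise attached to the
#'   model (used by [simulate_measurement()]).
#' @return An object of class `angular_response_model` with fields `energy`,
#'   `anchor_angles`, `column_response` (32 x n_anchor matrix) and
#'   `noise_sigma`.
#' @export
default_response_model <- function(energy = c("6MV", "10MV"),
                                   noise_sigma = 0.003) {
  energy <- match.arg(energy)
  ang <- calibration_angles()
  if (energy == "6MV") {
    ck_x <- c(0, 10, 20, 40, 60, 70, 80, 85, 89, 90, 91, 92, 93, 95,
              100, 110, 120, 140, 160, 180)
    ck_y <- c(1.000, 1.000, 0.998, 0.995, 0.990, 0.988, 0.995, 1.010, 1.040,
              1.060, 0.950, 0.850, 0.870, 0.895, 0.925, 0.945, 0.948, 0.940,
              0.930, 0.920)
    hi_x <- c(0, 20, 50, 70, 80, 90, 92, 100, 110, 120, 150, 180)
    hi_y <- c(0, 0.8, 1.8, 2.2, 3.0, 5.0, 7.0, 4.0, 3.0, 2.0, 1.5, 1.0)
    lo_x <- c(0, 20, 50, 70, 80, 90, 92, 100, 110, 120, 150, 180)
    lo_y <- c(0, -0.4, -0.8, -1.0, -2.0, -4.0, -6.1, -3.0, -2.5, -2.1,
              -1.5, -1.0)
  } else {
    ck_x <- c(0, 10, 20, 40, 60, 70, 80, 85, 89, 90, 91, 92, 93, 95,
              100, 110, 120, 140, 160, 180)
    ck_y <- c(1.000, 1.000, 0.999, 0.996, 0.993, 0.992, 0.997, 1.008, 1.028,
              1.040, 0.960, 0.890, 0.905, 0.925, 0.945, 0.958, 0.960, 0.956,
              0.953, 0.950)
    hi_x <- c(0, 20, 50, 70, 80, 90, 92, 100, 110, 120, 150, 180)
    hi_y <- c(0, 0.8, 1.9, 2.4, 3.0, 4.5, 6.0, 3.5, 2.5, 1.9, 1.4, 1.0)
    lo_x <- c(0, 20, 50, 70, 80, 90, 92, 100, 110, 120, 150, 180)
    lo_y <- c(0, -0.3, -0.8, -1.0, -1.5, -2.5, -3.7, -2.0, -1.5, -1.3,
              -1.0, -0.8)
  }
  central <- pl_interp(ck_x, ck_y, ang)
  d_hi <- pl_interp(hi_x, hi_y, ang)
  d_lo <- pl_interp(lo_x, lo_y, ang)
  # column offset profile: 0 at the two central columns (16, 17), +/-1 at
  # the outermost columns, monotone in between
  j <- 1:32
  u <- (j - 16.5) / 15.5
  uc <- 0.5 / 15.5
  u_adj <- sign(u) * (abs(u) - uc) / (1 - uc)
  colresp <- matrix(NA_real_, 32L, length(ang))
  for (a in seq_along(ang)) {
    d <- ifelse(u_adj >= 0, d_hi[a] * u_adj, -d_lo[a] * u_adj)
    colresp[, a] <- central[a] * (1 + d / 100)
  }
  stopifnot(all(colresp > 0))
  structure(list(energy = energy, anchor_angles = ang,
                 column_response = colresp, noise_sigma = noise_sigma),
            class = "angular_response_model")
}

# per-column response at an arbitrary gantry angle; angles past 180 deg are
# mirrored (response assumed symmetric about the 0-180 axis)
response_at <- function(model, theta) {
  th <- theta %% 360
  if (th > 180) th <- 360 - th
  ang <- model$anchor_angles
  k <- findInterval(th, ang, all.inside = TRUE)
  t <- (th - ang[k]) / (ang[k + 1] - ang[k])
  model$column_response[, k] * (1 - t) + model$column_response[, k + 1] * t
}

#' @export
print.angular_response_model <- function(x, ...) {
  cr <- (x$column_response[16, ] + x$column_response[17, ]) / 2
  a <- x$anchor_angles
  cat(sprintf(
    "<angular_response_model> %s, %d anchors, central response %.3f @90, %.3f @92, %.3f @180\n",
    x$energy, length(a), cr[a == 90], cr[a == 92], cr[a == 180]))
  invisible(x)
}

#' Simulate a movie-mode acquisition of a plan
#'
#' For each beam the delivery is discretised into frames (static beams into
#' `frames_per_beam` equal frames; arcs into segments of `arc_step` degrees,
#' each frame tagged with the segment midpoint angle). Each frame's dose is
#' the analytic true dose fraction, scaled column-wise by the angular
#' response R_j(theta) of `model`, with independent multiplicative Gaussian
#' noise per detector. Fully reproducible for a given `seed`.
#'
#' @inheritParams true_dose_plane
#' @param plan A [plan_spec()].
#' @param model An `angular_response_model` (see [default_response_model()]);
#'   `NULL` simulates an ideal detector (response 1 everywhere).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param noise_sigma Relative (multiplicative) noise SD per detector per
#'   frame; defaults to the model's `noise_sigma` (0 for `model = NULL`).
#' @param frames_per_beam Frames per static beam.
#' @param arc_step Arc discretisation, degrees per frame.
#' @return A [dose_movie()] tagged with the plan's energy.
#' @export
simulate_measurement <- function(plan, model = NULL, grid = detector_grid(),
                                 phantom = default_phantom(), seed = NULL,
                                 noise_sigma = NULL, frames_per_beam = 5L,
                                 arc_step = 2, ...) {
  stopifnot(inherits(plan, "plan_spec"))
  if (!is.null(model)) stopifnot(inherits(model, "angular_response_model"))
  if (is.null(noise_sigma))
    noise_sigma <- if (is.null(model)) 0 else model$noise_sigma
  if (!is.null(seed)) set.seed(as.integer(seed))
  frames <- list()
  for (beam in plan$beams) {
    seg <- beam_segments(beam, arc_step = arc_step,
                         frames_per_beam = frames_per_beam)
    static_plane <- if (!beam$is_arc)
      true_dose_plane(beam, grid, phantom, angle = beam$gantry_angle, ...)
    for (k in seq_along(seg$angles)) {
      th <- seg$angles[k]
      p <- if (!beam$is_arc) static_plane else
        true_dose_plane(beam, grid, phantom, angle = th, ...)
      d <- p$values * seg$frac[k]
      if (!is.null(model)) {
        r <- response_at(model, th)          # one factor per column j
        d <- sweep(d, 2L, r, `*`)
      }
      if (noise_sigma > 0) {
        d <- d * (1 + matrix(stats::rnorm(length(d), 0, noise_sigma),
                             nrow(d), ncol(d)))
        d[d < 0] <- 0
      }
      frames[[length(frames) + 1L]] <-
        dose_frame(d, gantry_angle = th, duration = plan$frame_duration,
                   grid = grid)
    }
  }
  dose_movie(frames, energy = plan$beams[[1]]$energy)
}

#' Reference doses at the detector positions over the calibration angles
#'
#' Evaluates the analytic dose model for the calibration field (default
#' 30x10 cm) at every calibration angle, giving the "calculated" reference
#' set that [derive_cf()] pairs with a measured set.
#'
#' @inheritParams true_dose_plane
#' @param energy Beam energy label.
#' @param angles Angle grid (default [calibration_angles()]).
#' @param field_size Calibration field size in cm.
#' @return List of angle-tagged [dose_frame()] objects, one per angle.
#' @export
reference_at_detectors <- function(energy = "6MV", grid = detector_grid(),
                                   phantom = default_phantom(),
                                   angles = calibration_angles(),
                                   field_size = c(30, 10), ...) {
  beam <- beam_spec(energy, field_size, gantry_angle = 0)
  lapply(angles, function(th) {
    p <- true_dose_plane(beam, grid, phantom, angle = th, ...)
    dose_frame(p$values, gantry_angle = th, duration = 1, grid = grid)
  })
}

#' Simulate the calibration measurement set
#'
#' One measured frame per calibration angle for the calibration field,
#' scaled by the angular response of `model`, optionally with noise. The
#' companion reference set comes from [reference_at_detectors()].
#'
#' @inheritParams reference_at_detectors
#' @param model An `angular_response_model`.
#' @param noise_sigma Relative noise SD (0 = noiseless calibration).
#' @param seed Integer seed when `noise_sigma > 0`.
#' @return List of angle-tagged [dose_frame()] objects.
#' @export
simulate_calibration <- function(model, grid = detector_grid(),
                                 phantom = default_phantom(),
                                 angles = calibration_angles(),
                                 field_size = c(30, 10), noise_sigma = 0,
                                 seed = NULL, ...) {
  stopifnot(inherits(model, "angular_response_model"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  beam <- beam_spec(model$energy, field_size, gantry_angle = 0)
  lapply(angles, function(th) {
    p <- true_dose_plane(beam, grid, phantom, angle = th, ...)
    d <- sweep(p$values, 2L, response_at(model, th), `*`)
    if (noise_sigma > 0)
      d <- pmax(d * (1 + matrix(stats::rnorm(length(d), 0, noise_sigma),
                                nrow(d), ncol(d))), 0)
    dose_frame(d, gantry_angle = th, duration = 1, grid = grid)
  })
}
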