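#' Read and write dose movies, planes, CF tables and plan specs
#'
#' All package formats are versioned JSON. Doubles are serialised at full
#' precision so every file round-trips bit-exactly through the package
#' readers. Plan specifications may also be given in YAML (same keys) when
#' the `yaml` package is available.
#'
#' @param movie,plane,table,plan Object to write.
#' @param path File path.
#' @return Readers return the package object; writers return `path`
#'   invisibly.
#' @name arrayqa_io
NULL

aq_write_json <- function(x, path) {
  # I(17) significant digits: doubles survive a write/read cycle bit-exactly
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17),
                       pretty = FALSE, null = "null")
  invisible(path)
}

aq_read_json <- function(path, format) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(x$format, format))
    stop("file ", path, " is not in the expected '", format, "' format")
  x
}

num_mat <- function(m) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  m
}

mat_rows <- function(m) lapply(seq_len(nrow(m)), function(r) unname(m[r, ]))

#' @rdname arrayqa_io
#' @export
write_dose_movie <- function(movie, path) {
  stopifnot(inherits(movie, "dose_movie"))
  aq_write_json(list(
    format = "arrayqa-movie-1",
    energy = movie$energy,
    frames = lapply(movie$frames, function(f) list(
      gantry_angle = if (!is.na(f$gantry_angle)) f$gantry_angle,
      duration = f$duration,
      dose = mat_rows(f$dose)))), path)
}

#' @rdname arrayqa_io
#' @export
read_dose_movie <- function(path) {
  x <- aq_read_json(path, "arrayqa-movie-1")
  frames <- lapply(x$frames, function(f) {
    d <- num_mat(do.call(rbind, lapply(f$dose, unlist)))
    dose_frame(d, gantry_angle = f$gantry_angle %||% NA_real_,
               duration = f$duration,
               grid = detector_grid(nrow(d), ncol(d)))
  })
  dose_movie(frames, energy = x$energy)
}

#' @rdname arrayqa_io
#' @export
write_dose_plane <- function(plane, path) {
  stopifnot(inherits(plane, "dose_plane"))
  aq_write_json(list(
    format = "arrayqa-plane-1",
    spacing = plane$spacing, origin = as.list(plane$origin),
    values = mat_rows(plane$values)), path)
}

#' @rdname arrayqa_io
#' @export
read_dose_plane <- function(path) {
  x <- aq_read_json(path, "arrayqa-plane-1")
  dose_plane(num_mat(do.call(rbind, lapply(x$values, unlist))),
             spacing = x$spacing,
             origin = unlist(x$origin))
}

#' @rdname arrayqa_io
#' @export
write_cf_table <- function(table, path) {
  validate_cf_table(table)
  aq_write_json(list(
    format = "arrayqa-cf-1",
    energy = table$energy,
    normalization_angle = table$normalization$angle,
    angles = table$angles,
    central_cf = table$central_cf,
    column_cf = mat_rows(table$column_cf),
    normalization = list(central = table$normalization$central,
                         column = table$normalization$column)), path)
}

#' @rdname arrayqa_io
#' @export
read_cf_table <- function(path) {
  x <- aq_read_json(path, "arrayqa-cf-1")
  tab <- structure(list(
    energy = x$energy,
    angles = as.numeric(unlist(x$angles)),
    central_cf = as.numeric(unlist(x$central_cf)),
    column_cf = num_mat(do.call(rbind, lapply(x$column_cf, unlist))),
    normalization = list(angle = x$normalization_angle,
                         central = x$normalization$central,
                         column = as.numeric(unlist(x$normalization$column))),
    call = NULL), class = "cf_table")
  validate_cf_table(tab)
}

#' @rdname arrayqa_io
#' @export
write_plan_spec <- function(plan, path) {
  stopifnot(inherits(plan, "plan_spec"))
  aq_write_json(list(
    format = "arrayqa-plan-1",
    name = plan$name, frame_duration = plan$frame_duration,
    beams = lapply(plan$beams, function(b) {
      out <- list(energy = b$energy, field_size = b$field_size,
                  weight = b$weight)
      if (b$is_arc) {
        out$arc_start <- b$arc_start; out$arc_stop <- b$arc_stop
        out$arc_direction <- b$arc_direction
      } else out$gantry_angle <- b$gantry_angle
      out
    })), path)
}

plan_from_list <- function(x) {
  beams <- lapply(x$beams, function(b) beam_spec(
    energy = b$energy %||% "6MV",
    field_size = unlist(b$field_size) %||% c(10, 10),
    gantry_angle = b$gantry_angle,
    arc_start = b$arc_start, arc_stop = b$arc_stop,
    arc_direction = b$arc_direction %||% "cw",
    weight = b$weight %||% 1))
  plan_spec(beams, frame_duration = x$frame_duration %||% 0.2,
            name = x$name %||% "plan")
}

#' @rdname arrayqa_io
#' @export
read_plan_spec <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML plan specs needs the 'yaml' package")
    x <- yaml::read_yaml(path)
  } else {
    x <- aq_read_json(path, "arrayqa-plan-1")
  }
  plan_from_list(x)
}
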