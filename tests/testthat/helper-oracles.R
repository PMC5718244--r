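# Shared fixtures and independent oracles, built in code at test time.

# random dose plane on an n x n grid
rand_plane <- function(n = 20, spacing = 1, origin = c(0, 0), lo = 0, hi = 100) {
  dose_plane(matrix(stats::runif(n * n, lo, hi), n, n),
             spacing = spacing, origin = origin)
}

# exhaustive all-pairs gamma oracle: for each reference pixel, minimise over
# every evaluated pixel centre with no search-radius cap. Returns the gamma
# matrix and the distance at which each minimum was attained.
brute_gamma <- function(reference, evaluated, criteria) {
  R <- reference$values; E <- evaluated$values
  sp <- reference$spacing
  norm_dose <- max(R)
  xs <- reference$origin[1] + (seq_len(ncol(R)) - 1) * sp
  ys <- reference$origin[2] + (seq_len(nrow(R)) - 1) * sp
  pts <- expand.grid(y = ys, x = xs)    # column-major matches as.vector()
  rv <- as.vector(R); ev <- as.vector(E)
  dD <- if (criteria$normalization == "global_max")
    rep(criteria$dose_tol / 100 * norm_dose, length(rv))
  else criteria$dose_tol / 100 * rv
  d2 <- outer(pts$x, pts$x, `-`)^2 + outer(pts$y, pts$y, `-`)^2
  gam <- numeric(length(rv))
  argdist <- numeric(length(rv))
  for (r in seq_along(rv)) {
    g2 <- ((ev - rv[r]) / dD[r])^2 + d2[r, ] / criteria$dta^2
    k <- which.min(g2)
    gam[r] <- sqrt(g2[k])
    argdist[r] <- sqrt(d2[r, k])
  }
  mask <- R >= criteria$threshold / 100 * norm_dose
  list(gamma = matrix(gam, nrow(R), ncol(R)),
       argdist = matrix(argdist, nrow(R), ncol(R)),
       mask = mask)
}

# hand-constructed CF table with known curves (32 columns)
make_cf_table <- function(angles, central, column = NULL, energy = "6MV") {
  if (is.null(column))
    column <- matrix(rep(central, each = 32), 32, length(angles))
  structure(list(energy = energy, angles = angles, central_cf = central,
                 column_cf = column,
                 normalization = list(angle = 0, central = 1,
                                      column = rep(1, 32)),
                 call = NULL),
            class = "cf_table")
}

# uniform-dose frame
uniform_frame <- function(value, angle = NA_real_, duration = 0.2) {
  dose_frame(matrix(value, 32, 32), gantry_angle = angle, duration = duration)
}
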