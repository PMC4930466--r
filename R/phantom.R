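#' Generate a serrated ellipsoid organ phantom
#'
#' Digitizes the surface `r(theta, phi) = r0(theta, phi) * (1 + a * s)`
#' where `r0` is the radial function of an ellipsoid with the given
#' semi-axes and `s` is a smooth, zero-mean, seeded angular field: a real
#' spherical-harmonic band at degree `serration_frequency` with standard
#' normal coefficients, max-normalised to `[-1, 1]`. Amplitude `a = 0`
#' yields the exact digitized ellipsoid; increasing `a` doses increasingly
#' serrated borders, emulating the irregular organ outlines seen in
#' abdominal MRI. A voxel is foreground iff its centre lies inside the
#' perturbed surface.
#'
#' @param base_radii positive length-3 semi-axes, mm (rows, cols, slices).
#' @param serration_amplitude `a`, fraction of local radius, `0 <= a < 1`.
#' @param serration_frequency positive integer; spherical-harmonic degree of
#'   the perturbation band (number of angular lobes).
#' @param voxel_spacing positive length-3 mm.
#' @param grid_shape length-3 integer grid; `NULL` sizes the grid to contain
#'   the perturbed ellipsoid with a 2-voxel margin.
#' @param seed integer seed for the angular field.
#' @return A [volumetric_mask()].
#' @export
generate_organ_phantom <- function(base_radii = c(30, 20, 15),
                                   serration_amplitude = 0,
                                   serration_frequency = 12L,
                                   voxel_spacing = c(1, 1, 1),
                                   grid_shape = NULL,
                                   seed = 1L) {
  stopifnot(length(base_radii) == 3, all(base_radii > 0),
            serration_amplitude >= 0, serration_amplitude < 1,
            serration_frequency >= 1,
            length(voxel_spacing) == 3, all(voxel_spacing > 0))
  a <- serration_amplitude
  rmax <- base_radii * (1 + a)
  if (is.null(grid_shape)) {
    grid_shape <- as.integer(ceiling(2 * rmax / voxel_spacing) + 4L)
  }
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1))
  half_extent <- grid_shape * voxel_spacing / 2
  if (any(rmax > half_extent - voxel_spacing))
    stop("grid_shape too small to contain the perturbed phantom", call. = FALSE)

  sfield <- if (a > 0)
    harmonic_band_field(as.integer(serration_frequency), seed) else NULL

  centre <- grid_shape * voxel_spacing / 2
  # voxel centres at (i - 0.5) * spacing; restrict work to the bounding box
  rng <- lapply(1:3, function(k) {
    i <- seq_len(grid_shape[k])
    x <- (i - 0.5) * voxel_spacing[k] - centre[k]
    i[abs(x) <= rmax[k] + voxel_spacing[k]]
  })
  vox <- array(FALSE, dim = grid_shape)
  if (any(lengths(rng) == 0)) return(volumetric_mask(vox, voxel_spacing))

  xs <- (rng[[1]] - 0.5) * voxel_spacing[1] - centre[1]
  ys <- (rng[[2]] - 0.5) * voxel_spacing[2] - centre[2]
  zs <- (rng[[3]] - 0.5) * voxel_spacing[3] - centre[3]
  nb <- c(length(xs), length(ys), length(zs))
  X <- array(xs, nb)
  Y <- aperm(array(ys, nb[c(2, 1, 3)]), c(2, 1, 3))
  Z <- aperm(array(zs, nb[c(3, 1, 2)]), c(2, 3, 1))
  r <- sqrt(X^2 + Y^2 + Z^2)
  r[r == 0] <- .Machine$double.eps
  ux <- X / r; uy <- Y / r; uz <- Z / r
  r0 <- 1 / sqrt((ux / base_radii[1])^2 + (uy / base_radii[2])^2 +
                   (uz / base_radii[3])^2)
  if (a > 0) {
    theta <- acos(pmin(1, pmax(-1, as.vector(uz))))
    phi <- atan2(as.vector(uy), as.vector(ux)) %% (2 * pi)
    s <- array(eval_field(sfield, theta, phi), dim = nb)
    surf <- r0 * (1 + a * s)
  } else {
    surf <- r0
  }
  inside <- r <= surf
  vox[rng[[1]], rng[[2]], rng[[3]]] <- inside
  volumetric_mask(vox, voxel_spacing)
}

# Precompute a band-limited real spherical-harmonic field on a
# (theta, phi) lattice; evaluated later by bilinear interpolation.
# Degrees run from the dominant frequency f up to 3f with weights (f/l),
# so the requested frequency carries the most power while higher degrees
# contribute the progressively finer detail that makes a border serrated
# rather than merely lobed. Coefficients are seeded N(0,1); the field is
# zero-mean by construction (no l = 0 term) and max-normalised to [-1, 1]
# so the amplitude knob is exact.
harmonic_band_field <- function(f, seed, n_theta = 361L, n_phi = 721L) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  theta <- seq(0, pi, length.out = n_theta)
  phi <- seq(0, 2 * pi, length.out = n_phi)
  grid <- matrix(0, n_theta, n_phi)
  degrees <- seq.int(f, 3L * f)
  for (l in degrees) {
    acoef <- stats::rnorm(l + 1)   # m = 0..l, cosine part
    bcoef <- stats::rnorm(l + 1)   # sine part (first entry unused, m = 0)
    P <- pracma::legendre(l, cos(theta))      # (l+1) x n_theta, m = 0..l
    m <- 0:l
    norm <- sqrt((2 * l + 1) / (4 * pi) *
                   exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
    w <- f / l
    for (k in seq_along(m)) {
      ang <- acoef[k] * cos(m[k] * phi)
      if (m[k] > 0) ang <- ang + bcoef[k] * sin(m[k] * phi)
      grid <- grid + w * outer(norm[k] * P[k, ], ang)
    }
  }
  grid <- grid / max(abs(grid))
  list(grid = grid, theta = theta, phi = phi)
}

# bilinear interpolation of the field at arbitrary (theta, phi)
eval_field <- function(field, theta, phi) {
  nt <- length(field$theta); np <- length(field$phi)
  ti <- theta / pi * (nt - 1) + 1
  pi_ <- (phi %% (2 * pi)) / (2 * pi) * (np - 1) + 1
  t0 <- pmin(nt - 1L, pmax(1L, floor(ti))); tf <- ti - t0
  p0 <- pmin(np - 1L, pmax(1L, floor(pi_))); pf <- pi_ - p0
  g <- field$grid
  v00 <- g[cbind(t0, p0)];     v10 <- g[cbind(t0 + 1L, p0)]
  v01 <- g[cbind(t0, p0 + 1L)]; v11 <- g[cbind(t0 + 1L, p0 + 1L)]
  v00 * (1 - tf) * (1 - pf) + v10 * tf * (1 - pf) +
    v01 * (1 - tf) * pf + v11 * tf * pf
}

#' Analytic fractal calibration fixtures
#'
#' Exact rasterizations of sets with known fractal dimension, used to
#' calibrate the box-counting estimator: a straight line (FD 1), a circle
#' boundary (FD 1), a filled square analyzed as the set itself (FD 2), and
#' the triadic Koch curve (FD log4/log3 = 1.2619).
#'
#' @param kind `"line"`, `"circle"`, `"filled_square"` or `"koch"`.
#' @param size canvas side in pixels (>= 64); for `"koch"` the canvas grows
#'   to fit the curve's base length of `3^iterations` pixels if needed.
#' @param iterations Koch iteration count, 1..6.
#' @return A [boundary_image()]; for `"koch"` the attribute `n_segments`
#'   records the `4^iterations` construction segments.
#' @export
generate_fractal_fixture <- function(kind = c("line", "circle",
                                              "filled_square", "koch"),
                                     size = 512L, iterations = 5L) {
  kind <- match.arg(kind)
  size <- as.integer(size)
  if (size < 64L) stop("`size` must be >= 64 pixels", call. = FALSE)
  px <- switch(kind,
    line = {
      m <- matrix(FALSE, size, size)
      m[size %/% 2L, ] <- TRUE
      m
    },
    circle = {
      m <- matrix(FALSE, size, size)
      R <- floor(size * 0.4)
      c0 <- (size + 1) / 2
      ang <- seq(0, 2 * pi, by = 0.25 / R)
      rr <- round(c0 + R * sin(ang)); cc <- round(c0 + R * cos(ang))
      m[cbind(rr, cc)] <- TRUE
      m
    },
    filled_square = matrix(TRUE, size, size),
    koch = {
      if (iterations < 1L || iterations > 6L)
        stop("koch iterations must lie in [1, 6]", call. = FALSE)
      koch_raster(as.integer(iterations), size)
    })
  b <- boundary_image(px, pixel_spacing = 1, source = paste0("fixture:", kind))
  if (kind == "koch")
    attr(b, "n_segments") <- as.integer(4^as.integer(iterations))
  b
}

# Triadic Koch curve via the F -> F left F right-right F left F rewriting,
# unit segments, base length 3^iter px, rasterized by dense sampling.
koch_raster <- function(iter, size) {
  headings <- koch_headings(iter)
  L <- 3^iter
  canvas <- max(size, L + 8L)
  height <- ceiling(L * sqrt(3) / 6)
  x0 <- (canvas - L) / 2
  y0 <- (canvas + height) / 2   # rows increase downward; bumps go up
  rad <- headings * pi / 180
  xs <- cumsum(c(x0, cos(rad)))
  ys <- cumsum(c(y0, -sin(rad)))
  m <- matrix(FALSE, canvas, canvas)
  # rasterize each unit segment with sub-pixel sampling
  t <- seq(0, 1, by = 0.25)
  for (k in seq_along(rad)) {
    px <- xs[k] + t * (xs[k + 1] - xs[k])
    py <- ys[k] + t * (ys[k + 1] - ys[k])
    m[cbind(pmin(canvas, pmax(1, round(py))),
            pmin(canvas, pmax(1, round(px))))] <- TRUE
  }
  m
}

koch_headings <- function(iter) {
  h <- 0
  for (i in seq_len(iter)) h <- c(h, h + 60, h - 60, h)
  h
}

#' Generate a three-point Dixon phantom with known fat fraction
#'
#' Forward model with constant total proton signal: per pixel,
#' `W = intensity * (1 - f)`, `F = intensity * f` with `f` the fat fraction,
#' and echoes `IP = (W + F)`, `OP = (W - F) * exp(i * phi)`,
#' `E3 = (W + F) * exp(2i * phi)`, where `phi` is the field-inhomogeneity
#' phase accrued per echo spacing. Seeded complex Gaussian noise of total
#' standard deviation `noise_sd` (power split equally across real and
#' imaginary channels) is added to every echo, so SNR = `intensity /
#' noise_sd`.
#'
#' @param fat_fraction_percent numeric matrix of true fat fractions in
#'   `[0, 100]` percent.
#' @param intensity total signal of a pixel, arbitrary units (> 0).
#' @param phase_error_rad phase accrued per echo spacing: a matrix matching
#'   `fat_fraction_percent` or a scalar; must satisfy `|phi| < pi/2` for the
#'   single-slice phase model to invert without unwrapping.
#' @param noise_sd complex noise standard deviation, same units as
#'   `intensity` (>= 0).
#' @param pixel_spacing positive length-2 mm.
#' @param seed integer seed for the noise.
#' @return List with `triplet` (a [dixon_triplet()]) and `truth` (a
#'   [fat_fraction_map()]).
#' @export
generate_dixon_phantom <- function(fat_fraction_percent,
                                   intensity = 100,
                                   phase_error_rad = 0,
                                   noise_sd = 0,
                                   pixel_spacing = c(1, 1),
                                   seed = 1L) {
  ff <- fat_fraction_percent
  stopifnot(is.matrix(ff), all(ff >= 0), all(ff <= 100),
            intensity > 0, noise_sd >= 0)
  if (length(phase_error_rad) == 1L)
    phase_error_rad <- matrix(phase_error_rad, nrow(ff), ncol(ff))
  stopifnot(identical(dim(phase_error_rad), dim(ff)))
  if (any(abs(phase_error_rad) >= pi / 2))
    stop("|phase_error_rad| must be < pi/2", call. = FALSE)
  f <- ff / 100
  W <- intensity * (1 - f)
  Fm <- intensity * f
  e1 <- (W + Fm) + 0i
  e2 <- (W - Fm) * exp(1i * phase_error_rad)
  e3 <- (W + Fm) * exp(2i * phase_error_rad)
  if (noise_sd > 0) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
    s <- noise_sd / sqrt(2)
    cnoise <- function() {
      matrix(complex(real = stats::rnorm(length(ff), sd = s),
                     imaginary = stats::rnorm(length(ff), sd = s)),
             nrow(ff), ncol(ff))
    }
    e1 <- e1 + cnoise(); e2 <- e2 + cnoise(); e3 <- e3 + cnoise()
  }
  list(triplet = dixon_triplet(e1, e2, e3, pixel_spacing),
       truth = fat_fraction_map(ff, pixel_spacing))
}
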