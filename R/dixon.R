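#' Three-point Dixon water-fat separation
#'
#' Under the three-echo model `IP = W + F`, `OP = (W - F) e^{i phi}`,
#' `E3 = (W + F) e^{2 i phi}`, the field-inhomogeneity phase per echo
#' spacing is `phi = arg(E3 * conj(IP)) / 2`. The opposed-phase image is
#' demodulated by `e^{-i phi}`, and the compartments recovered as
#' `W = Re(IP + OP_corr)/2`, `F = Re(IP - OP_corr)/2`. Real parts are used
#' (rather than magnitudes) so that zero-fat pixels are unbiased in noise;
#' negative compartment values arising from noise are clamped to zero and
#' counted. The fat fraction is `100 * F / (W + F)`.
#'
#' For magnitude-only inputs no phase information exists: `phi` is assumed
#' zero with a warning, which is exact only in the absence of B0
#' inhomogeneity.
#'
#' @param triplet a [dixon_triplet()].
#' @return A [fat_fraction_map()]; its `n_clamped` element counts pixels
#'   clamped into `[0, 100]`.
#' @export
dixon_separate <- function(triplet) {
  stopifnot(inherits(triplet, "dixon_triplet"))
  ip <- triplet$in_phase
  op <- triplet$opposed_phase
  if (triplet$complex_valued) {
    phi <- Arg(triplet$third_echo * Conj(ip)) / 2
    op_corr <- op * exp(-1i * phi)
    W <- Re(ip + op_corr) / 2
    Fm <- Re(ip - op_corr) / 2
  } else {
    warning("magnitude-only echoes: assuming zero phase error (phi = 0)",
            call. = FALSE)
    W <- (ip + op) / 2
    Fm <- (ip - op) / 2
  }
  ncl <- sum(W < 0) + sum(Fm < 0)
  W[W < 0] <- 0
  Fm[Fm < 0] <- 0
  tot <- W + Fm
  ff <- matrix(0, nrow(ip), ncol(ip))
  ok <- tot > 0
  ff[ok] <- 100 * Fm[ok] / tot[ok]
  fat_fraction_map(ff, triplet$pixel_spacing, n_clamped = ncl)
}

#' Circular region of interest
#'
#' @param center `(row, col)` pixel coordinates of the disc centre
#'   (0-based, may be fractional).
#' @param area_mm2 disc area in mm^2 (default 100, the conventional
#'   uniform-tissue ROI size).
#' @return Object of class `circular_roi`.
#' @export
circular_roi <- function(center, area_mm2 = 100) {
  stopifnot(length(center) == 2, is.finite(area_mm2), area_mm2 > 0)
  structure(list(center = as.numeric(center), area_mm2 = as.numeric(area_mm2)),
            class = "circular_roi")
}

# logical membership matrix: pixel centres within the disc
roi_disc_mask <- function(roi, dims, pixel_spacing) {
  r_mm <- sqrt(roi$area_mm2 / pi)
  rows <- (seq_len(dims[1]) - 1 - roi$center[1]) * pixel_spacing[1]
  cols <- (seq_len(dims[2]) - 1 - roi$center[2]) * pixel_spacing[2]
  outer(rows^2, cols^2, `+`) <= r_mm^2
}

#' Mean fat fraction over circular ROIs
#'
#' Per ROI, the mean fat fraction over pixels whose centres fall inside the
#' disc of the stated area; the returned value is the unweighted mean of
#' the per-ROI means (each sampled region counts equally, regardless of
#' pixel count).
#'
#' @param ff a [fat_fraction_map()].
#' @param rois list of [circular_roi()] (conventionally three per slice).
#' @return Single percent value; per-ROI means are attached as the
#'   attribute `"per_roi"`.
#' @export
mean_ff_in_rois <- function(ff, rois) {
  stopifnot(inherits(ff, "fat_fraction_map"), length(rois) >= 1)
  if (inherits(rois, "circular_roi")) rois <- list(rois)
  dims <- dim(ff$ff_percent)
  per_roi <- vapply(rois, function(roi) {
    stopifnot(inherits(roi, "circular_roi"))
    r_mm <- sqrt(roi$area_mm2 / pi)
    r_px <- r_mm / ff$pixel_spacing
    if (roi$center[1] - r_px[1] < -0.5 || roi$center[1] + r_px[1] > dims[1] - 0.5 ||
        roi$center[2] - r_px[2] < -0.5 || roi$center[2] + r_px[2] > dims[2] - 0.5)
      stop("ROI extends outside the image", call. = FALSE)
    disc <- roi_disc_mask(roi, dims, ff$pixel_spacing)
    if (!any(disc)) stop("ROI contains no pixel centres", call. = FALSE)
    mean(ff$ff_percent[disc])
  }, numeric(1))
  structure(mean(per_roi), per_roi = per_roi)
}

#' Per-participant pancreas fat percentage
#'
#' The published protocol samples three uniform-tissue ROIs on each of two
#' representative slices and averages: this function takes the two
#' per-slice ROI means and returns their arithmetic mean. A missing slice
#' is an error, never a silent single-slice fallback.
#'
#' @param slice_means exactly two finite per-slice mean fat fractions.
#' @return Percent pancreas fat.
#' @export
pancreas_fat_percent <- function(slice_means) {
  slice_means <- as.numeric(slice_means)
  if (length(slice_means) != 2L || any(!is.finite(slice_means)))
    stop("exactly two finite per-slice means are required", call. = FALSE)
  mean(slice_means)
}

#' Visceral fat percentage at L2-L3
#'
#' Splits a binary fat mask of an abdominal slice into the subcutaneous
#' compartment (fat pixels between the outer and inner subcutaneous
#' boundaries) and the visceral compartment (fat pixels inside the inner
#' boundary), returning `100 * visceral / (visceral + subcutaneous)`.
#'
#' @param fat_mask logical matrix of fat pixels (e.g. a thresholded fat
#'   fraction map at the L2-L3 level).
#' @param outer_polygon,inner_polygon closed vertex lists (n x 2, `(x, y)`
#'   0-based pixel coordinates) of the outer and inner subcutaneous fat
#'   boundaries; the inner region must be contained in the outer.
#' @return Percent visceral fat; compartment pixel counts attached as
#'   attribute `"counts"`.
#' @export
visceral_fat_percent <- function(fat_mask, outer_polygon, inner_polygon) {
  fat_mask <- as_pixel_matrix(fat_mask)
  dims <- dim(fat_mask)
  close_poly <- function(p) {
    p <- as.matrix(p)
    if (nrow(p) > 1L && all(p[1, ] == p[nrow(p), ]))
      p <- p[-nrow(p), , drop = FALSE]
    p
  }
  outer_polygon <- close_poly(outer_polygon)
  inner_polygon <- close_poly(inner_polygon)
  cx <- rep(seq_len(dims[2]) - 1, each = dims[1])
  cy <- rep(seq_len(dims[1]) - 1, times = dims[2])
  in_outer <- matrix(points_in_polygon(cx, cy, outer_polygon), nrow = dims[1])
  in_inner <- matrix(points_in_polygon(cx, cy, inner_polygon), nrow = dims[1])
  if (any(in_inner & !in_outer))
    stop("inner boundary is not contained in the outer boundary",
         call. = FALSE)
  visceral <- sum(fat_mask & in_inner)
  subcut <- sum(fat_mask & in_outer & !in_inner)
  if (visceral + subcut == 0L)
    stop("no fat pixels inside the outer boundary", call. = FALSE)
  structure(100 * visceral / (visceral + subcut),
            counts = c(visceral = visceral, subcutaneous = subcut))
}

#' Suggest a homogeneous-tissue ROI centre
#'
#' Convenience helper beyond the published protocol (where uniform-tissue
#' regions are selected by the observer): scans candidate disc centres on a
#' pixel grid inside an optional organ mask and returns the disc with the
#' lowest fat-fraction variance.
#'
#' @param ff a [fat_fraction_map()].
#' @param area_mm2 disc area, mm^2.
#' @param within optional logical matrix restricting candidate discs to
#'   pixels of an organ.
#' @param stride candidate-centre grid step in pixels.
#' @return A [circular_roi()] at the lowest-variance centre.
#' @export
find_uniform_roi <- function(ff, area_mm2 = 100, within = NULL, stride = 2L) {
  stopifnot(inherits(ff, "fat_fraction_map"))
  dims <- dim(ff$ff_percent)
  r_px <- ceiling(sqrt(area_mm2 / pi) / ff$pixel_spacing)
  rows <- seq(r_px[1] + 1, dims[1] - r_px[1] - 1, by = stride)
  cols <- seq(r_px[2] + 1, dims[2] - r_px[2] - 1, by = stride)
  if (!length(rows) || !length(cols))
    stop("image too small for the requested ROI area", call. = FALSE)
  best <- NULL; best_var <- Inf
  for (r in rows) for (cc in cols) {
    roi <- circular_roi(c(r, cc), area_mm2)
    disc <- roi_disc_mask(roi, dims, ff$pixel_spacing)
    if (!is.null(within) && !all(within[disc])) next
    v <- stats::var(ff$ff_percent[disc])
    if (v < best_var) { best_var <- v; best <- roi }
  }
  if (is.null(best))
    stop("no candidate disc fits inside the supplied region", call. = FALSE)
  best
}
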