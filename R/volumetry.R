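#' Slice ROI sets
#'
#' A `slice_roi_set` holds per-slice closed polygons (the manual
#' delineations of an organ outline) together with the acquisition
#' geometry. Vertices are `(x, y)` pixel coordinates, 0-based, `x` along
#' columns and `y` along rows; the centre of pixel `[r, c]` (1-based
#' storage) is at `(c - 1, r - 1)`. Polygons may be given open (the closing
#' edge back to the first vertex is implied).
#'
#' @param slices list of entries, each `list(slice_index = <int>, polygons =
#'   <list of n x 2 vertex matrices>)`; slice indices strictly increasing,
#'   inferior to superior.
#' @param pixel_spacing positive length-2 mm (row, col).
#' @param slice_thickness positive mm.
#' @return An object of class `slice_roi_set`.
#' @export
slice_roi_set <- function(slices, pixel_spacing = c(1, 1),
                          slice_thickness = 1) {
  pixel_spacing <- as.numeric(pixel_spacing)
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
  stopifnot(length(pixel_spacing) == 2, all(pixel_spacing > 0),
            length(slice_thickness) == 1, slice_thickness > 0)
  idx <- vapply(slices, function(s) as.integer(s$slice_index), 1L)
  if (is.unsorted(idx, strictly = TRUE))
    stop("slice indices must be strictly increasing", call. = FALSE)
  slices <- lapply(slices, function(s) {
    s$polygons <- lapply(s$polygons, function(p) {
      p <- as.matrix(p)
      if (ncol(p) != 2L) stop("polygon vertices must be n x 2", call. = FALSE)
      # drop an explicit closing vertex; closure is implied
      if (nrow(p) > 1L && all(p[1, ] == p[nrow(p), ]))
        p <- p[-nrow(p), , drop = FALSE]
      if (nrow(p) < 3L)
        stop("polygons need at least 3 distinct vertices", call. = FALSE)
      if (polygon_self_intersects(p))
        stop("self-intersecting polygon in ROI set", call. = FALSE)
      p
    })
    s
  })
  structure(list(slices = slices, pixel_spacing = pixel_spacing,
                 slice_thickness = slice_thickness),
            class = "slice_roi_set")
}

# proper-crossing test between all non-adjacent edge pairs (O(E^2); ROI
# polygons have few vertices)
polygon_self_intersects <- function(p) {
  n <- nrow(p)
  a <- p
  b <- p[c(2:n, 1), , drop = FALSE]
  cross <- function(ox, oy, ax, ay, bx, by)
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      d1 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], a[j, 1], a[j, 2])
      d2 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], b[j, 1], b[j, 2])
      d3 <- cross(a[j, 1], a[j, 2], b[j, 1], b[j, 2], a[i, 1], a[i, 2])
      d4 <- cross(a[j, 1], a[j, 2], b[j, 1], b[j, 2], b[i, 1], b[i, 2])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
        return(TRUE)
    }
  }
  FALSE
}

# Even-odd (crossing number) point-in-polygon, vectorized over points.
# Half-open edge rule [ymin, ymax) gives deterministic results for points
# exactly level with a vertex.
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  xs <- poly[, 1]; ys <- poly[, 2]
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((ys[i] > py) != (ys[j] > py)) &
      (px < (xs[j] - xs[i]) * (py - ys[i]) / (ys[j] - ys[i]) + xs[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize slice ROIs into a volumetric mask
#'
#' A pixel is foreground iff its centre lies inside a polygon under the
#' even-odd rule; multiple polygons on one slice are unioned. Slices
#' without ROIs stay background.
#'
#' @param rois a [slice_roi_set()].
#' @param grid_shape in-plane grid `(rows, cols)`; the slice count is taken
#'   from the largest slice index.
#' @param n_slices optional explicit slice count (>= max slice index).
#' @return A [volumetric_mask()] with spacing
#'   `c(pixel_spacing, slice_thickness)`.
#' @export
mask_from_rois <- function(rois, grid_shape, n_slices = NULL) {
  stopifnot(inherits(rois, "slice_roi_set"), length(grid_shape) == 2)
  grid_shape <- as.integer(grid_shape)
  idx <- vapply(rois$slices, function(s) as.integer(s$slice_index), 1L)
  if (length(idx) && (min(idx) < 1L))
    stop("slice indices must be >= 1", call. = FALSE)
  nz <- if (is.null(n_slices)) max(idx, 1L) else as.integer(n_slices)
  if (length(idx) && max(idx) > nz)
    stop("`n_slices` smaller than the largest slice index", call. = FALSE)
  vox <- array(FALSE, dim = c(grid_shape, nz))
  # pixel centres in the documented 0-based (x, y) geometry
  cx <- rep(seq_len(grid_shape[2]) - 1, each = grid_shape[1])
  cy <- rep(seq_len(grid_shape[1]) - 1, times = grid_shape[2])
  for (s in rois$slices) {
    plane <- rep(FALSE, grid_shape[1] * grid_shape[2])
    for (p in s$polygons) {
      if (any(p[, 1] < -0.5 | p[, 1] > grid_shape[2] - 0.5 |
              p[, 2] < -0.5 | p[, 2] > grid_shape[1] - 0.5))
        stop("polygon vertex outside the pixel grid", call. = FALSE)
      plane <- plane | points_in_polygon(cx, cy, p)
    }
    vox[, , s$slice_index] <- matrix(plane, nrow = grid_shape[1])
  }
  volumetric_mask(vox, c(rois$pixel_spacing, rois$slice_thickness))
}

#' Organ volume by slice summation
#'
#' Volume is the foreground voxel count times the physical voxel volume:
#' the sum over slices of delineated area times slice thickness, reported
#' in cubic centimetres.
#'
#' @param mask a [volumetric_mask()] with at least one foreground voxel.
#' @return Object of class `volume_result`: `volume_cm3`,
#'   `per_slice_areas_mm2` (one entry per slice), `n_slices_with_roi`.
#' @export
compute_volume <- function(mask) {
  stopifnot(inherits(mask, "volumetric_mask"))
  if (!any(mask$voxels))
    stop("empty segmentation: no foreground voxels (missing organ?)",
         call. = FALSE)
  sp <- mask$voxel_spacing
  px_area <- sp[1] * sp[2]
  areas <- apply(mask$voxels, 3, sum) * px_area
  vol_mm3 <- sum(areas) * sp[3]
  structure(list(volume_cm3 = vol_mm3 / 1000,
                 per_slice_areas_mm2 = areas,
                 n_slices_with_roi = sum(areas > 0)),
            class = "volume_result")
}

#' @export
print.volume_result <- function(x, ...) {
  cat(sprintf("<volume_result> %.3f cm^3 over %d slices with ROI\n",
              x$volume_cm3, x$n_slices_with_roi))
  invisible(x)
}

#' BMI-normalised pancreas volume index
#'
#' Organ volume divided by body mass index, in cm^3 m^2 kg^-1. Computed
#' per individual; group aggregation of per-individual indices is the
#' cohort summary's job.
#'
#' @param volume_cm3 positive organ volume, cm^3.
#' @param bmi positive body mass index, kg/m^2.
#' @return `volume_cm3 / bmi`.
#' @export
pancreas_volume_index <- function(volume_cm3, bmi) {
  if (any(!is.finite(volume_cm3)) || any(volume_cm3 <= 0))
    stop("`volume_cm3` must be strictly positive", call. = FALSE)
  if (any(!is.finite(bmi)) || any(bmi <= 0))
    stop("`bmi` must be strictly positive", call. = FALSE)
  volume_cm3 / bmi
}
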