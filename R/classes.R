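#' @title Core image containers
#' @description Light S3 containers used throughout the package. Conventions:
#'   3D masks are logical arrays indexed `[row, column, slice]`, rows running
#'   anterior to posterior, columns left to right, slices inferior to
#'   superior; `voxel_spacing` is `c(row_mm, col_mm, slice_mm)`. Pixel and
#'   voxel indices are 1-based in R storage but the documented geometry uses
#'   0-based centres: the centre of pixel `[r, c]` sits at physical
#'   coordinates `((c - 1) * col_mm, (r - 1) * row_mm)`.
#' @name pancmorph-containers
NULL

#' Construct a volumetric binary mask
#'
#' @param voxels logical (or 0/1 numeric) 3D array, `[row, col, slice]`.
#' @param voxel_spacing positive numeric length 3, mm: in-plane row and
#'   column spacing, then slice thickness.
#' @return An object of class `volumetric_mask`.
#' @export
volumetric_mask <- function(voxels, voxel_spacing = c(1, 1, 1)) {
  if (length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array", call. = FALSE)
  if (!is.logical(voxels)) {
    if (!all(voxels %in% c(0, 1)))
      stop("`voxels` must be binary (logical or 0/1)", call. = FALSE)
    voxels <- array(voxels > 0, dim = dim(voxels))
  }
  voxel_spacing <- as.numeric(voxel_spacing)
  if (length(voxel_spacing) == 1L) voxel_spacing <- rep(voxel_spacing, 3L)
  if (length(voxel_spacing) != 3L || any(!is.finite(voxel_spacing)) ||
      any(voxel_spacing <= 0))
    stop("`voxel_spacing` must be 3 strictly positive values (mm)", call. = FALSE)
  structure(list(voxels = voxels, voxel_spacing = voxel_spacing),
            class = "volumetric_mask")
}

#' @export
print.volumetric_mask <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<volumetric_mask> %d x %d x %d voxels, spacing %s mm, %d foreground\n",
              d[1], d[2], d[3],
              paste(format(x$voxel_spacing, digits = 4), collapse = " x "),
              sum(x$voxels)))
  invisible(x)
}

#' Construct a 2D silhouette image
#'
#' @param pixels logical matrix; the orthographic shadow of a mask.
#' @param pixel_spacing single positive mm value (isotropic).
#' @param axis projection axis label recorded as provenance.
#' @return Object of class `silhouette_image`.
#' @export
silhouette_image <- function(pixels, pixel_spacing = 1, axis = NA_character_) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix", call. = FALSE)
  if (!is.logical(pixels)) pixels <- matrix(pixels > 0, nrow = nrow(pixels))
  if (!is.numeric(pixel_spacing) || length(pixel_spacing) != 1L ||
      pixel_spacing <= 0)
    stop("`pixel_spacing` must be a single positive value", call. = FALSE)
  structure(list(pixels = pixels, pixel_spacing = as.numeric(pixel_spacing),
                 axis = axis),
            class = "silhouette_image")
}

#' Construct a 2D boundary (border-pixel) image
#'
#' @param pixels logical matrix of border pixels.
#' @param pixel_spacing single positive mm value.
#' @param source free-form provenance tag (projection axis, replicate id,
#'   fixture kind).
#' @return Object of class `boundary_image`.
#' @export
boundary_image <- function(pixels, pixel_spacing = 1, source = NA_character_) {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix", call. = FALSE)
  if (!is.logical(pixels)) pixels <- matrix(pixels > 0, nrow = nrow(pixels))
  structure(list(pixels = pixels, pixel_spacing = as.numeric(pixel_spacing),
                 source = source),
            class = "boundary_image")
}

#' @export
print.boundary_image <- function(x, ...) {
  cat(sprintf("<boundary_image> %d x %d px, %d border pixels (source: %s)\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels),
              if (is.na(x$source)) "unknown" else x$source))
  invisible(x)
}

#' @export
print.silhouette_image <- function(x, ...) {
  cat(sprintf("<silhouette_image> %d x %d px @ %.3g mm, %d foreground (axis: %s)\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_spacing, sum(x$pixels),
              if (is.na(x$axis)) "unknown" else x$axis))
  invisible(x)
}

#' Construct a three-point Dixon echo triplet
#'
#' Echo images may be complex (preferred) or magnitude-only matrices; all
#' three must be co-registered and share dimensions.
#'
#' @param in_phase,opposed_phase,third_echo numeric or complex matrices.
#' @param pixel_spacing positive length-2 mm (row, col).
#' @return Object of class `dixon_triplet`.
#' @export
dixon_triplet <- function(in_phase, opposed_phase, third_echo,
                          pixel_spacing = c(1, 1)) {
  echoes <- list(in_phase = in_phase, opposed_phase = opposed_phase,
                 third_echo = third_echo)
  for (nm in names(echoes)) {
    if (!is.matrix(echoes[[nm]]))
      stop(sprintf("`%s` must be a matrix", nm), call. = FALSE)
  }
  d1 <- dim(in_phase)
  if (!identical(d1, dim(opposed_phase)) || !identical(d1, dim(third_echo)))
    stop("echo images must share identical dimensions", call. = FALSE)
  pixel_spacing <- as.numeric(pixel_spacing)
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
  if (length(pixel_spacing) != 2L || any(pixel_spacing <= 0))
    stop("`pixel_spacing` must be 2 positive values (mm)", call. = FALSE)
  structure(c(echoes, list(pixel_spacing = pixel_spacing,
                           complex_valued = is.complex(in_phase) ||
                             is.complex(opposed_phase) ||
                             is.complex(third_echo))),
            class = "dixon_triplet")
}

#' Construct a fat-fraction map
#'
#' @param ff_percent numeric matrix, percent fat in `[0, 100]`.
#' @param pixel_spacing positive length-2 mm.
#' @param n_clamped number of pixels clamped into `[0, 100]` during
#'   reconstruction (0 for ground-truth maps).
#' @return Object of class `fat_fraction_map`.
#' @export
fat_fraction_map <- function(ff_percent, pixel_spacing = c(1, 1),
                             n_clamped = 0L) {
  if (!is.matrix(ff_percent)) stop("`ff_percent` must be a matrix", call. = FALSE)
  if (any(ff_percent < 0 - 1e-9 | ff_percent > 100 + 1e-9, na.rm = TRUE))
    stop("`ff_percent` values must lie in [0, 100]; clamp before construction",
         call. = FALSE)
  pixel_spacing <- as.numeric(pixel_spacing)
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
  structure(list(ff_percent = ff_percent, pixel_spacing = pixel_spacing,
                 n_clamped = as.integer(n_clamped)),
            class = "fat_fraction_map")
}

#' @export
print.fat_fraction_map <- function(x, ...) {
  cat(sprintf("<fat_fraction_map> %d x %d px, FF %.2f-%.2f%% (median %.2f%%), %d clamped\n",
              nrow(x$ff_percent), ncol(x$ff_percent),
              min(x$ff_percent), max(x$ff_percent),
              stats::median(x$ff_percent), x$n_clamped))
  invisible(x)
}

# internal: pull a logical pixel matrix out of the 2D containers
as_pixel_matrix <- function(x) {
  if (inherits(x, c("silhouette_image", "boundary_image"))) return(x$pixels)
  if (is.matrix(x)) {
    if (!is.logical(x)) x <- matrix(x > 0, nrow = nrow(x))
    return(x)
  }
  stop("expected a silhouette_image, boundary_image or logical matrix",
       call. = FALSE)
}
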