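#' Read and write volumetric masks
#'
#' NIfTI files carry voxel spacing in the header (`pixdim`); multi-page
#' TIFF does not, so spacing must be supplied when reading TIFF.
#'
#' @param mask a [volumetric_mask()].
#' @param path output/input file path (`.nii`/`.nii.gz`, or `.tif`).
#' @return `write_*` return `path` invisibly; `read_*` return a
#'   [volumetric_mask()].
#' @name mask-io
NULL

#' @rdname mask-io
#' @export
write_mask_nifti <- function(mask, path) {
  stopifnot(inherits(mask, "volumetric_mask"))
  img <- RNifti::asNifti(array(as.integer(mask$voxels),
                               dim = dim(mask$voxels)))
  RNifti::pixdim(img) <- mask$voxel_spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname mask-io
#' @export
read_mask_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)[1:3]
  volumetric_mask(array(as.array(img) > 0.5, dim = dim(img)[1:3]), sp)
}

#' @rdname mask-io
#' @param voxel_spacing spacing to attach when reading TIFF (mm).
#' @export
write_mask_tiff <- function(mask, path) {
  stopifnot(inherits(mask, "volumetric_mask"))
  pages <- lapply(seq_len(dim(mask$voxels)[3]),
                  function(k) mask$voxels[, , k] * 1)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname mask-io
#' @export
read_mask_tiff <- function(path, voxel_spacing = c(1, 1, 1)) {
  pages <- tiff::readTIFF(path, all = TRUE)
  vox <- vapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]
    p > 0.5
  }, matrix(TRUE, nrow(pages[[1]]), ncol(pages[[1]])))
  volumetric_mask(vox, voxel_spacing)
}

#' Write a binary image as PNG
#'
#' @param image a [boundary_image()], [silhouette_image()] or logical
#'   matrix.
#' @param path output path.
#' @export
write_binary_png <- function(image, path) {
  px <- as_pixel_matrix(image)
  png::writePNG(px * 1, path)
  invisible(path)
}

#' @rdname write_binary_png
#' @export
read_binary_png <- function(path) {
  p <- png::readPNG(path)
  if (length(dim(p)) == 3L) p <- p[, , 1]
  boundary_image(p > 0.5, source = basename(path))
}

#' Slice-ROI JSON schema
#'
#' ROI files are JSON objects with fields `pixel_spacing` (length 2, mm),
#' `slice_thickness` (mm) and `slices`, a list of
#' `{"slice_index": i, "polygons": [[[x, y], ...], ...]}` with 0-based
#' `(x, y)` pixel-coordinate vertices (x along columns). This plain-text
#' schema stands in for graphical ROI formats.
#'
#' @param rois a [slice_roi_set()].
#' @param path file path.
#' @return `read_rois_json` returns a [slice_roi_set()].
#' @export
write_rois_json <- function(rois, path) {
  stopifnot(inherits(rois, "slice_roi_set"))
  obj <- list(pixel_spacing = rois$pixel_spacing,
              slice_thickness = rois$slice_thickness,
              slices = lapply(rois$slices, function(s)
                list(slice_index = s$slice_index,
                     polygons = lapply(s$polygons, function(p)
                       lapply(seq_len(nrow(p)),
                              function(i) as.numeric(p[i, ]))))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rois_json
#' @export
read_rois_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  slices <- lapply(obj$slices, function(s)
    list(slice_index = as.integer(s$slice_index),
         polygons = lapply(s$polygons, function(p)
           do.call(rbind, lapply(p, as.numeric)))))
  slice_roi_set(slices,
                pixel_spacing = as.numeric(unlist(obj$pixel_spacing)),
                slice_thickness = as.numeric(obj$slice_thickness))
}

#' Read and write cohort tables
#'
#' Cohort CSVs are long-format: one row per participant-timepoint with
#' columns `id`, `group`, `timepoint` and the clinical/imaging variables.
#'
#' @param records cohort data.frame.
#' @param path CSV path.
#' @export
write_cohort_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "timepoint")
  if (!all(need %in% names(df)))
    stop("cohort CSV must have `id` and `timepoint` columns", call. = FALSE)
  df
}

#' Write complex Dixon echoes as real/imaginary NIfTI pairs
#'
#' Each echo is stored as a 3D NIfTI with two planes: real and imaginary
#' part (`dialect = "reim"`), or a single magnitude plane
#' (`dialect = "magnitude"`).
#'
#' @param triplet a [dixon_triplet()].
#' @param prefix path prefix; files `<prefix>_ip.nii.gz`,
#'   `<prefix>_op.nii.gz`, `<prefix>_e3.nii.gz` are written.
#' @param dialect `"reim"` or `"magnitude"`.
#' @return Character vector of the three paths, invisibly.
#' @export
write_dixon_nifti <- function(triplet, prefix, dialect = c("reim",
                                                           "magnitude")) {
  stopifnot(inherits(triplet, "dixon_triplet"))
  dialect <- match.arg(dialect)
  paths <- paste0(prefix, c("_ip", "_op", "_e3"), ".nii.gz")
  echoes <- list(triplet$in_phase, triplet$opposed_phase,
                 triplet$third_echo)
  for (k in 1:3) {
    e <- echoes[[k]]
    arr <- if (dialect == "reim")
      array(c(Re(e), Im(e)), dim = c(dim(e), 2)) else
        array(Mod(e), dim = c(dim(e), 1))
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- c(triplet$pixel_spacing, 1)
    RNifti::writeNifti(img, paths[k])
  }
  invisible(paths)
}

#' @rdname write_dixon_nifti
#' @export
read_dixon_nifti <- function(prefix, dialect = c("reim", "magnitude")) {
  dialect <- match.arg(dialect)
  paths <- paste0(prefix, c("_ip", "_op", "_e3"), ".nii.gz")
  read1 <- function(p) {
    a <- as.array(RNifti::readNifti(p))
    if (dialect == "reim") {
      matrix(complex(real = a[, , 1], imaginary = a[, , 2]),
             nrow = dim(a)[1])
    } else {
      # trailing singleton dimensions may be dropped by the NIfTI reader
      if (length(dim(a)) == 3L) a <- a[, , 1]
      matrix(a, nrow = dim(a)[1])
    }
  }
  sp <- RNifti::pixdim(RNifti::readNifti(paths[1]))[1:2]
  dixon_triplet(read1(paths[1]), read1(paths[2]), read1(paths[3]), sp)
}
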