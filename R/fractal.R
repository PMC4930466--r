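#' Orthographic silhouette projection of a 3D mask
#'
#' Collapses a binary mask along one anatomical axis: a silhouette pixel is
#' foreground iff any voxel along the projection ray is foreground. The
#' result is resampled (nearest neighbour) to isotropic pixels at the finer
#' of the two retained spacings, so that box counting sees square pixels.
#'
#' @param mask a [volumetric_mask()].
#' @param axis one of `"anterior_posterior"` (collapse rows),
#'   `"left_right"` (collapse columns) or `"inferior_superior"` (collapse
#'   slices). Abbreviations `"ap"`, `"lr"`, `"is"` are accepted.
#' @return A [silhouette_image()].
#' @export
project_silhouette <- function(mask, axis = c("anterior_posterior",
                                              "left_right",
                                              "inferior_superior")) {
  stopifnot(inherits(mask, "volumetric_mask"))
  axis <- normalize_axis(axis)
  if (!any(mask$voxels))
    stop("empty segmentation: mask has no foreground voxels", call. = FALSE)
  sp <- mask$voxel_spacing
  keep <- switch(axis,
                 anterior_posterior = c(2L, 3L),
                 left_right         = c(1L, 3L),
                 inferior_superior  = c(1L, 2L))
  px <- apply(mask$voxels, keep, any)
  sp2 <- sp[keep]
  iso <- min(sp2)
  if (abs(sp2[1] - sp2[2]) > 1e-12) {
    px <- resample_nn(px, sp2, iso)
  }
  silhouette_image(px, pixel_spacing = iso, axis = axis)
}

normalize_axis <- function(axis) {
  axis <- axis[1]
  full <- c(ap = "anterior_posterior", lr = "left_right",
            is = "inferior_superior")
  if (axis %in% names(full)) axis <- full[[axis]]
  match.arg(axis, unname(full))
}

# nearest-neighbour resample of a logical matrix from spacing `sp` (len 2)
# to isotropic spacing `iso`
resample_nn <- function(px, sp, iso) {
  n_new <- pmax(1L, as.integer(round(dim(px) * sp / iso)))
  ri <- pmin(nrow(px), floor(((seq_len(n_new[1]) - 0.5) * iso) / sp[1]) + 1L)
  ci <- pmin(ncol(px), floor(((seq_len(n_new[2]) - 0.5) * iso) / sp[2]) + 1L)
  px[ri, ci, drop = FALSE]
}

#' Extract the outer boundary of a silhouette
#'
#' Interior holes are filled first, so only the outer contour remains; the
#' boundary is then the foreground minus its erosion by the 3x3 structuring
#' element (the 8-connected border).
#'
#' @param silhouette a [silhouette_image()] or logical matrix.
#' @return A [boundary_image()] carrying the silhouette's pixel spacing and
#'   projection axis as provenance.
#' @export
extract_boundary <- function(silhouette) {
  px <- as_pixel_matrix(silhouette)
  if (!any(px)) stop("empty silhouette", call. = FALSE)
  filled <- EBImage::fillHull(EBImage::Image(px * 1)) > 0.5
  filled <- matrix(as.logical(filled), nrow = nrow(px))
  kern <- matrix(1, 3, 3)
  er <- EBImage::erode(EBImage::Image(filled * 1), kern) > 0.5
  er <- matrix(as.logical(er), nrow = nrow(px))
  boundary_image(filled & !er,
                 pixel_spacing = if (inherits(silhouette, "silhouette_image"))
                   silhouette$pixel_spacing else 1,
                 source = if (inherits(silhouette, "silhouette_image"))
                   paste0("projection:", silhouette$axis) else "matrix")
}

#' Default box-size ladder
#'
#' Geometric series with ratio 2, from 2 px up to
#' `min(32, floor(min_dim / 4))`. The upper cap keeps every grid cell small
#' relative to the analyzed set: when the grid origin is shifted, a set of
#' extent `A` occupies about `A/s + 1` cells per dimension, and the spurious
#' `+1` edge cell flattens the log-log slope once `s` approaches `A`;
#' capping the window at 32 px keeps that bias below ~0.05 in FD for
#' canvas-filling sets while staying well inside the unsaturated regime
#' (`s <= min_dim/4`). A fixed 2-32 px window also makes FD values
#' comparable across image sizes. At least 5 sizes are required for a
#' reliable slope, so `min_dim` must be at least 128.
#'
#' @param min_dim smaller dimension of the analyzed image, pixels.
#' @return Strictly increasing integer vector of box sizes.
#' @export
default_box_sizes <- function(min_dim) {
  smax <- min(32L, floor(min_dim / 4))
  if (smax < 2) stop("image too small for box counting", call. = FALSE)
  sizes <- 2L
  while (utils::tail(sizes, 1) * 2L <= smax)
    sizes <- c(sizes, utils::tail(sizes, 1) * 2L)
  if (length(sizes) < 5L)
    stop(sprintf(paste0("only %d box sizes available (need >= 5 for a ",
                        "reliable slope); provide an image with min ",
                        "dimension >= 128 px"), length(sizes)), call. = FALSE)
  sizes
}

#' Box counting over a grid-offset ensemble
#'
#' For each offset and box size `s`, covers the image with a grid of side
#' `s` whose origin is shifted by the offset (the image is implicitly padded
#' with background) and counts cells containing at least one foreground
#' pixel.
#'
#' @param boundary a [boundary_image()], [silhouette_image()] or logical
#'   matrix; the set being measured.
#' @param box_sizes strictly increasing integer box sides, each >= 2 and
#'   <= `floor(min_dim / 4)`; at least 5 sizes.
#' @param offsets integer matrix with columns `(dx, dy)` applied to every
#'   size (reduced modulo `s`), or a list of such matrices, one per size.
#'   Default: the zero offset.
#' @param validate enforce the FD-estimation preconditions (sizes in
#'   `[2, floor(min_dim/4)]`, at least 5 of them). Disable only for raw
#'   counting, e.g. cross-checks against enumeration; [estimate_fd()] on an
#'   unvalidated short series is not meaningful.
#' @return Object of class `boxcount_series`: `box_sizes_px`, `counts`
#'   (matrix sizes x offsets), `offsets`, `n_offsets`, `pixel_spacing`.
#' @export
box_count <- function(boundary, box_sizes, offsets = NULL, validate = TRUE) {
  px <- as_pixel_matrix(boundary)
  if (!any(px)) stop("empty image: nothing to count", call. = FALSE)
  box_sizes <- as.integer(box_sizes)
  if (is.unsorted(box_sizes, strictly = TRUE))
    stop("`box_sizes` must be strictly increasing", call. = FALSE)
  if (any(box_sizes < 1L))
    stop("box sizes must be positive", call. = FALSE)
  mind <- min(dim(px))
  if (validate) {
    if (any(box_sizes < 2L) || any(box_sizes > mind %/% 4L))
      stop("box sizes must lie in [2, floor(min_dim/4)]", call. = FALSE)
    if (length(box_sizes) < 5L)
      stop("fewer than 5 valid box sizes: slope would be unreliable",
           call. = FALSE)
  }
  if (is.null(offsets)) offsets <- matrix(0L, 1, 2)
  if (is.matrix(offsets)) offsets <- rep(list(offsets), length(box_sizes))
  if (!is.list(offsets) || length(offsets) != length(box_sizes))
    stop("`offsets` must be a 2-column matrix or a list of one per size",
         call. = FALSE)
  n_off <- nrow(offsets[[1]])
  if (any(vapply(offsets, nrow, 1L) != n_off))
    stop("all per-size offset matrices must have the same number of rows",
         call. = FALSE)
  idx <- which(px, arr.ind = TRUE) - 1L   # 0-based foreground coordinates
  counts <- matrix(NA_real_, length(box_sizes), n_off)
  for (i in seq_along(box_sizes)) {
    s <- box_sizes[i]
    om <- offsets[[i]]
    for (j in seq_len(n_off)) {
      dr <- om[j, 1] %% s
      dc <- om[j, 2] %% s
      cr <- (idx[, 1] + dr) %/% s
      cc <- (idx[, 2] + dc) %/% s
      # cells are unique (row, col) pairs; pack into one integer key
      counts[i, j] <- length(unique(cr * (max(cc) + 1) + cc))
    }
  }
  structure(list(box_sizes_px = box_sizes, counts = counts,
                 offsets = offsets, n_offsets = n_off,
                 pixel_spacing = if (inherits(boundary, "boundary_image"))
                   boundary$pixel_spacing else 1,
                 source = if (inherits(boundary, "boundary_image"))
                   boundary$source else NA_character_),
            class = "boxcount_series")
}

#' @export
print.boxcount_series <- function(x, ...) {
  cat(sprintf("<boxcount_series> %d sizes (%d..%d px) x %d offsets\n",
              length(x$box_sizes_px), min(x$box_sizes_px),
              max(x$box_sizes_px), x$n_offsets))
  print(x$counts)
  invisible(x)
}

#' Estimate fractal dimension from a box-count series
#'
#' Per grid offset, fits ordinary least squares of `log N(s)` on
#' `log(1/s)`; the reported FD is the mean of the per-offset slopes (not a
#' regression on mean counts), which also yields a dispersion estimate
#' across grid origins.
#'
#' @param series a `boxcount_series` from [box_count()].
#' @return An object of class `fd_fit`; see [fd_boxcount()] for fields.
#' @export
estimate_fd <- function(series) {
  stopifnot(inherits(series, "boxcount_series"))
  ls <- log(1 / series$box_sizes_px)
  if (stats::var(ls) == 0) stop("zero variance in log box sizes", call. = FALSE)
  n_off <- series$n_offsets
  slopes <- numeric(n_off)
  r2 <- numeric(n_off)
  for (j in seq_len(n_off)) {
    ln <- log(series$counts[, j])
    fit <- stats::lm.fit(cbind(1, ls), ln)
    slopes[j] <- fit$coefficients[2]
    r2[j] <- 1 - sum(fit$residuals^2) / sum((ln - mean(ln))^2)
  }
  fd <- mean(slopes)
  if (fd < 0.8 || fd > 2.2)
    warning(sprintf("estimated FD %.3f outside the sanity range [0.8, 2.2]",
                    fd), call. = FALSE)
  structure(list(fd = fd, per_offset_slopes = slopes, fit_r2 = r2,
                 n_sizes = length(series$box_sizes_px),
                 box_sizes_px = series$box_sizes_px,
                 counts = series$counts, n_offsets = n_off,
                 source = series$source),
            class = "fd_fit")
}

#' Box-counting fractal dimension of a binary border image
#'
#' The central estimator. Covers the image with grids of geometrically
#' decreasing cell size (ratio 2, from 2 px to `floor(min_dim/4)` by
#' default), each scanned from `n_offsets` seeded random grid origins drawn
#' uniformly in `[0, s)` per size, and fits `log N(s) ~ log(1/s)` per
#' offset. The FD estimate is the mean per-offset slope; the spread of the
#' slopes measures grid-placement sensitivity.
#'
#' @param x a [boundary_image()], [silhouette_image()] (its pixels are
#'   analyzed as given), logical matrix, or grayscale numeric matrix (Otsu
#'   thresholded with a message).
#' @param n_offsets number of random grid origins per size (default 10).
#' @param box_sizes optional explicit size ladder; default
#'   [default_box_sizes()] of the image.
#' @param seed integer seed for the offset ensemble; `NULL` uses the current
#'   RNG state.
#' @return An `fd_fit` object with elements `fd` (the estimate),
#'   `per_offset_slopes`, `fit_r2`, `n_sizes`, `box_sizes_px`, `counts`,
#'   `n_offsets`, `seed`. Methods: `print`, `summary`, `coef` (per-offset
#'   slopes), `plot` (log-log diagnostic), `residuals`.
#' @examples
#' b <- generate_fractal_fixture("koch", size = 512, iterations = 5)
#' fit <- fd_boxcount(b, n_offsets = 10, seed = 1)
#' fit$fd            # ~ log(4)/log(3) = 1.26
#' @export
fd_boxcount <- function(x, n_offsets = 10, box_sizes = NULL, seed = NULL) {
  px <- binarize_input(x)
  b <- if (inherits(x, "boundary_image")) x else
    boundary_image(px, pixel_spacing = if (inherits(x, "silhouette_image"))
      x$pixel_spacing else 1, source = "direct")
  if (is.null(box_sizes)) box_sizes <- default_box_sizes(min(dim(px)))
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  offsets <- lapply(box_sizes, function(s)
    matrix(sample.int(s, 2L * n_offsets, replace = TRUE) - 1L,
           ncol = 2L))
  series <- box_count(b, box_sizes, offsets)
  fit <- estimate_fd(series)
  fit$seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  fit
}

binarize_input <- function(x) {
  px <- if (is.matrix(x) && is.numeric(x) && !is.logical(x) &&
            any(!(x %in% c(0, 1)))) {
    thr <- EBImage::otsu(EBImage::Image(x / max(x)))
    message(sprintf("grayscale input: Otsu threshold %.4f applied", thr))
    x / max(x) > thr
  } else as_pixel_matrix(x)
  if (!any(px)) stop("empty image", call. = FALSE)
  px
}

#' @export
print.fd_fit <- function(x, ...) {
  cat(sprintf("<fd_fit> FD = %.4f (mean of %d per-offset slopes, sd %.4f)\n",
              x$fd, x$n_offsets, stats::sd(x$per_offset_slopes)))
  cat(sprintf("  %d box sizes: %s px; mean R^2 = %.4f\n", x$n_sizes,
              paste(x$box_sizes_px, collapse = ", "), mean(x$fit_r2)))
  invisible(x)
}

#' @export
summary.fd_fit <- function(object, ...) {
  out <- list(fd = object$fd,
              slope_sd = stats::sd(object$per_offset_slopes),
              slope_cv_percent = 100 * stats::sd(object$per_offset_slopes) /
                mean(object$per_offset_slopes),
              slope_range = range(object$per_offset_slopes),
              mean_r2 = mean(object$fit_r2),
              n_sizes = object$n_sizes, n_offsets = object$n_offsets,
              box_sizes_px = object$box_sizes_px)
  class(out) <- "summary.fd_fit"
  out
}

#' @export
print.summary.fd_fit <- function(x, ...) {
  cat("Box-counting fractal dimension fit\n")
  cat(sprintf("  FD estimate     : %.4f\n", x$fd))
  cat(sprintf("  slope sd (CV)   : %.4f (%.2f%%) over %d grid offsets\n",
              x$slope_sd, x$slope_cv_percent, x$n_offsets))
  cat(sprintf("  slope range     : [%.4f, %.4f]\n",
              x$slope_range[1], x$slope_range[2]))
  cat(sprintf("  mean fit R^2    : %.5f over %d sizes (%s px)\n",
              x$mean_r2, x$n_sizes, paste(x$box_sizes_px, collapse = ", ")))
  invisible(x)
}

#' @export
coef.fd_fit <- function(object, ...) object$per_offset_slopes

#' @export
residuals.fd_fit <- function(object, ...) {
  # per-offset residuals of log N about its own OLS line
  ls <- log(1 / object$box_sizes_px)
  sapply(seq_len(object$n_offsets), function(j) {
    ln <- log(object$counts[, j])
    stats::lm.fit(cbind(1, ls), ln)$residuals
  })
}

#' @export
plot.fd_fit <- function(x, ...) {
  ls <- log(1 / x$box_sizes_px)
  ln <- log(x$counts)
  graphics::matplot(ls, ln, pch = 1, col = "grey40",
                    xlab = "log(1 / box size)", ylab = "log N(s)",
                    main = sprintf("Box counting: FD = %.3f", x$fd), ...)
  graphics::abline(stats::lm(rowMeans(ln) ~ ls), col = 2, lwd = 2)
  invisible(x)
}

#' Full FD chain on a 3D mask, with replicate precision
#'
#' Runs project -> fill/boundary -> box count -> slope estimation
#' `n_replicates` times with independent seeded grid-offset ensembles on the
#' same projection, mirroring duplicate measurements of one organ. The
#' reported FD is the mean of the replicate FDs; the replicate coefficient
#' of variation quantifies estimator precision.
#'
#' @inheritParams project_silhouette
#' @param n_offsets grid origins per size within each replicate.
#' @param n_replicates number of independently re-seeded measurements.
#' @param seed root seed; per-replicate seeds are derived deterministically.
#' @param box_sizes optional explicit size ladder.
#' @return Object of class `fd_replicates`: `fd` (mean over replicates),
#'   `cv_percent` (`NA` when `n_replicates == 1`), `replicates` (list of
#'   `fd_fit`), `axis`, `seed`.
#' @export
fd_of_mask <- function(mask, axis = "anterior_posterior", n_offsets = 10,
                       n_replicates = 2, seed = 1, box_sizes = NULL) {
  stopifnot(n_replicates >= 1, n_offsets >= 1)
  sil <- project_silhouette(mask, axis)
  b <- extract_boundary(sil)
  seeds <- derive_seeds(seed, n_replicates)
  fits <- lapply(seeds, function(s)
    fd_boxcount(b, n_offsets = n_offsets, box_sizes = box_sizes, seed = s))
  fds <- vapply(fits, `[[`, numeric(1), "fd")
  structure(list(fd = mean(fds),
                 cv_percent = if (n_replicates >= 2) replicate_cv(fds)
                              else NA_real_,
                 replicate_fds = fds, replicates = fits,
                 axis = normalize_axis(axis), n_replicates = n_replicates,
                 seed = as.integer(seed)),
            class = "fd_replicates")
}

#' @export
print.fd_replicates <- function(x, ...) {
  cat(sprintf("<fd_replicates> FD = %.4f over %d replicates (axis %s)\n",
              x$fd, x$n_replicates, x$axis))
  if (!is.na(x$cv_percent))
    cat(sprintf("  replicate CV = %.3f%% (FDs: %s)\n", x$cv_percent,
                paste(sprintf("%.4f", x$replicate_fds), collapse = ", ")))
  invisible(x)
}

# deterministic substreams below 2^31 from one root seed
derive_seeds <- function(seed, n) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible()
}

#' Coefficient of variation of replicate measurements
#'
#' @param values numeric vector of at least 2 replicate values with nonzero
#'   mean.
#' @return `100 * sd(values) / mean(values)` (sample SD), in percent.
#' @export
replicate_cv <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("need at least 2 replicate values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("mean of replicates is zero; CV undefined", call. = FALSE)
  100 * stats::sd(values) / m
}
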