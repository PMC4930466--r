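test_that("silhouette projection is the orthographic shadow", {
  a <- array(FALSE, c(9, 9, 9)); a[5, 5, 5] <- TRUE
  m <- volumetric_mask(a, c(1, 1, 1))
  s <- project_silhouette(m, "inferior_superior")
  expect_identical(sum(s$pixels), 1L)
  expect_true(s$pixels[5, 5])

  # 20 x 30 x 40 mm box: shadows are the three face rectangles
  b <- array(FALSE, c(30, 40, 50)); b[1:20, 1:30, 1:40] <- TRUE
  mb <- volumetric_mask(b, c(1, 1, 1))
  expect_identical(sum(project_silhouette(mb, "anterior_posterior")$pixels),
                   30L * 40L)
  expect_identical(sum(project_silhouette(mb, "left_right")$pixels),
                   20L * 40L)
  expect_identical(sum(project_silhouette(mb, "inferior_superior")$pixels),
                   20L * 30L)
  expect_error(project_silhouette(volumetric_mask(array(FALSE, c(4, 4, 4))),
                                  "ap"), "empty")
})

test_that("sphere silhouettes are the equatorial disc along every axis", {
  m <- generate_organ_phantom(base_radii = c(15, 15, 15),
                              serration_amplitude = 0,
                              voxel_spacing = c(1, 1, 1))
  areas <- vapply(c("ap", "lr", "is"), function(ax)
    sum(project_silhouette(m, ax)$pixels), integer(1))
  expect_true(all(areas == areas[1]))
  expect_lt(abs(areas[1] - pi * 15^2) / (pi * 15^2), 0.02)
})

test_that("anisotropic masks are resampled to isotropic silhouettes", {
  a <- array(TRUE, c(10, 10, 10))
  m <- volumetric_mask(a, c(1, 1, 2))      # 2 mm slices
  s <- project_silhouette(m, "anterior_posterior")  # cols x slices
  expect_identical(s$pixel_spacing, 1)
  expect_identical(dim(s$pixels), c(10L, 20L))
})

test_that("boundary extraction keeps the outer 8-connected border only", {
  sq <- matrix(FALSE, 20, 20); sq[6:15, 6:15] <- TRUE
  b <- extract_boundary(silhouette_image(sq))
  expect_identical(sum(b$pixels), 36L)            # 4*10 - 4 ring
  one <- matrix(FALSE, 9, 9); one[5, 5] <- TRUE
  expect_identical(sum(extract_boundary(silhouette_image(one))$pixels), 1L)
  # interior holes are filled before erosion
  holed <- sq; holed[9:11, 9:11] <- FALSE
  expect_identical(extract_boundary(silhouette_image(holed))$pixels,
                   b$pixels)
})

test_that("box counts match hand counts on exact dyadic cases", {
  blk <- matrix(TRUE, 8, 8)
  s <- box_count(blk, c(1, 2, 4, 8), validate = FALSE)
  expect_identical(as.vector(s$counts), c(64, 16, 4, 1))
  ln <- matrix(FALSE, 16, 16); ln[8, ] <- TRUE
  s2 <- box_count(ln, c(1, 2, 4), validate = FALSE)
  expect_identical(as.vector(s2$counts), c(16, 8, 4))
  one <- matrix(FALSE, 32, 32); one[7, 19] <- TRUE
  s3 <- box_count(one, c(2, 3, 5, 8), offsets = rbind(c(0, 0), c(1, 2)),
                  validate = FALSE)
  expect_true(all(s3$counts == 1))
})

test_that("box counts equal a brute-force double-loop counter", {
  set.seed(101)
  for (rep in 1:5) {
    n <- sample(20:64, 1)
    px <- matrix(runif(n * n) < 0.2, n, n)
    if (!any(px)) px[1, 1] <- TRUE
    sizes <- c(2, 3, 4, 6, 9)
    off <- rbind(c(0, 0), c(1, 1), c(2, 5))
    s <- box_count(px, sizes, offsets = off, validate = FALSE)
    for (i in seq_along(sizes)) for (j in 1:3)
      expect_identical(s$counts[i, j],
                       as.numeric(brute_box_count(px, sizes[i], off[j, ])))
  }
})

test_that("count series obey the covering inequalities", {
  set.seed(77)
  for (rep in 1:5) {
    px <- matrix(runif(256 * 256) < 0.05, 256, 256)
    s <- box_count(px, c(2, 4, 8, 16, 32),
                   offsets = matrix(sample(0:7, 10, TRUE), 5, 2))
    for (j in seq_len(s$n_offsets)) {
      expect_true(all(diff(s$counts[, j]) <= 0))    # non-increasing in s
      expect_true(all(s$counts[, j] >= 1))
      # doubling the box size cannot shrink counts by more than 4x
      expect_true(all(s$counts[-1, j] >= s$counts[-5, j] / 4))
    }
  }
})

test_that("slope estimation is exact on exactly log-log-linear counts", {
  blk <- matrix(TRUE, 8, 8)
  fit <- estimate_fd(box_count(blk, c(1, 2, 4, 8), validate = FALSE))
  expect_equal(fit$fd, 2, tolerance = 1e-12)
  expect_equal(fit$fit_r2, 1, tolerance = 1e-12)
  ln <- matrix(FALSE, 16, 16); ln[8, ] <- TRUE
  fit2 <- estimate_fd(box_count(ln, c(1, 2, 4), validate = FALSE))
  expect_equal(fit2$fd, 1, tolerance = 1e-12)
})

test_that("the estimator is deterministic given the seed", {
  b <- generate_fractal_fixture("koch", iterations = 4)
  f1 <- fd_boxcount(b, seed = 3)
  f2 <- fd_boxcount(b, seed = 3)
  expect_identical(f1$fd, f2$fd)
  expect_identical(f1$counts, f2$counts)
})

test_that("fd_fit methods expose slopes, residuals and summary", {
  b <- generate_fractal_fixture("circle", size = 256)
  fit <- fd_boxcount(b, n_offsets = 8, seed = 2)
  expect_s3_class(fit, "fd_fit")
  expect_length(coef(fit), 8)
  expect_equal(mean(coef(fit)), fit$fd)
  expect_identical(dim(residuals(fit)), c(fit$n_sizes, 8L))
  s <- summary(fit)
  expect_s3_class(s, "summary.fd_fit")
  expect_output(print(fit), "FD")
})

test_that("FD is scale-equivariant under 2x nearest-neighbour upscaling", {
  # doubling the image, the box sizes and the grid offsets together maps
  # every 2s-cell of the upscaled image onto an s-cell of the original, so
  # the counts — and hence the estimate — are preserved exactly
  set.seed(19)
  for (k in c("line", "circle", "filled_square", "koch")) {
    b <- generate_fractal_fixture(k, size = 256, iterations = 4)
    up <- boundary_image(b$pixels %x% matrix(TRUE, 2, 2))
    sizes <- default_box_sizes(min(dim(b$pixels)))
    offs <- lapply(sizes, function(s)
      matrix(sample(0:(s - 1), 10, replace = TRUE), 5, 2))
    s1 <- box_count(b, sizes, offs)
    s2 <- box_count(up, 2L * sizes, lapply(offs, function(o) 2L * o))
    expect_identical(s1$counts, s2$counts)
    expect_equal(estimate_fd(s1)$fd, estimate_fd(s2)$fd, tolerance = 1e-12)
    expect_lt(abs(estimate_fd(s1)$fd - estimate_fd(s2)$fd), 0.05)
  }
})

test_that("per-offset slopes agree closely across the grid ensemble", {
  for (k in c("line", "circle", "filled_square", "koch")) {
    fit <- fd_boxcount(generate_fractal_fixture(k, size = 512,
                                                iterations = 5),
                       n_offsets = 10, seed = 4)
    cv <- 100 * sd(coef(fit)) / mean(coef(fit))
    expect_lt(cv, 5)
  }
})

test_that("full-chain FD averages replicates and reports their CV", {
  m <- make_phantom(0.25, seed = 6)
  r <- fd_of_mask(m, n_replicates = 2, seed = 11)
  expect_equal(r$fd, mean(r$replicate_fds))
  expect_length(r$replicates, 2)
  expect_equal(r$cv_percent,
               100 * sd(r$replicate_fds) / mean(r$replicate_fds))
  # same root seed reproduces the measurement exactly
  r2 <- fd_of_mask(m, n_replicates = 2, seed = 11)
  expect_identical(r$replicate_fds, r2$replicate_fds)
})

test_that("replicate CV follows its definition", {
  expect_identical(replicate_cv(c(1, 1, 1)), 0)
  expect_equal(replicate_cv(c(1.0, 1.1)), 6.734, tolerance = 1e-3)
  expect_equal(replicate_cv(c(2, 4, 4, 4, 5, 5, 7, 9)), 42.761,
               tolerance = 1e-3)
  expect_identical(replicate_cv(rep(1.2619, 10)), 0)
  expect_error(replicate_cv(1), "at least 2")
  expect_error(replicate_cv(c(-1, 1)), "mean")
})

test_that("grayscale inputs are binarized with an announced Otsu threshold", {
  g <- matrix(0.1, 256, 256)
  g[100:156, 100:156] <- 0.9
  expect_message(fit <- fd_boxcount(g, n_offsets = 3, seed = 1), "Otsu")
  expect_s3_class(fit, "fd_fit")
})
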