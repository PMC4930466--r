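test_that("unperturbed phantom digitizes the analytic ellipsoid volume", {
  m <- generate_organ_phantom(base_radii = c(30, 20, 15),
                              serration_amplitude = 0,
                              voxel_spacing = c(1, 1, 1))
  vol <- sum(m$voxels) / 1000                     # 1 mm^3 voxels
  expect_lt(abs(vol - 4 / 3 * pi * 30 * 20 * 15 / 1000) /
              (4 / 3 * pi * 30 * 20 * 15 / 1000), 0.02)
})

test_that("phantom generation is deterministic given the seed", {
  a <- generate_organ_phantom(serration_amplitude = 0.3, seed = 7,
                              voxel_spacing = c(1, 1, 1))
  b <- generate_organ_phantom(serration_amplitude = 0.3, seed = 7,
                              voxel_spacing = c(1, 1, 1))
  expect_identical(a$voxels, b$voxels)
  c <- generate_organ_phantom(serration_amplitude = 0.3, seed = 8,
                              voxel_spacing = c(1, 1, 1))
  expect_false(identical(a$voxels, c$voxels))
})

test_that("phantom validates its geometry", {
  expect_error(generate_organ_phantom(grid_shape = c(20, 20, 20)),
               "too small")
  expect_error(generate_organ_phantom(serration_amplitude = 1))
  expect_error(generate_organ_phantom(base_radii = c(-1, 10, 10)))
})

test_that("zero-mean perturbation changes volume only mildly", {
  v0 <- sum(generate_organ_phantom(serration_amplitude = 0, seed = 3,
                                   voxel_spacing = c(1, 1, 1),
                                   grid_shape = c(90, 90, 90))$voxels)
  v1 <- sum(generate_organ_phantom(serration_amplitude = 0.1, seed = 3,
                                   voxel_spacing = c(1, 1, 1),
                                   grid_shape = c(90, 90, 90))$voxels)
  expect_lt(abs(v1 - v0) / v0, 0.15)
})

test_that("line fixture is a one-pixel-wide full-width segment", {
  b <- generate_fractal_fixture("line", size = 512)
  expect_identical(sum(b$pixels), 512L)
  expect_identical(sum(rowSums(b$pixels) > 0), 1L)
})

test_that("circle fixture is a closed ring: every pixel has >= 2 neighbours", {
  b <- generate_fractal_fixture("circle", size = 256)
  px <- b$pixels
  idx <- which(px, arr.ind = TRUE)
  nbr <- vapply(seq_len(nrow(idx)), function(k) {
    r <- idx[k, 1]; cc <- idx[k, 2]
    sum(px[max(1, r - 1):min(nrow(px), r + 1),
           max(1, cc - 1):min(ncol(px), cc + 1)]) - 1L
  }, integer(1))
  expect_true(all(nbr >= 2L))
})

test_that("koch fixture has the 4^iterations construction segments and is drawn", {
  b <- generate_fractal_fixture("koch", size = 512, iterations = 5)
  expect_identical(attr(b, "n_segments"), 1024L)
  # base length 3^5 = 243 px: the drawn span matches
  cols <- range(which(colSums(b$pixels) > 0))
  expect_equal(diff(cols), 243, tolerance = 0.01)
  expect_error(generate_fractal_fixture("koch", iterations = 7), "1, 6")
  expect_error(generate_fractal_fixture("line", size = 32), ">= 64")
})

test_that("dixon phantom obeys its forward model in edge cases", {
  # zero fat, zero phase: in-phase equals opposed-phase
  ph <- generate_dixon_phantom(matrix(0, 16, 16))
  expect_equal(ph$triplet$in_phase, ph$triplet$opposed_phase)
  # 50% fat: water and fat cancel in opposed phase
  ph50 <- generate_dixon_phantom(matrix(50, 16, 16))
  expect_true(all(Mod(ph50$triplet$opposed_phase) < 1e-12))
  # truth map is returned as supplied
  expect_equal(ph50$truth$ff_percent, matrix(50, 16, 16))
  expect_error(generate_dixon_phantom(matrix(101, 4, 4)))
  expect_error(generate_dixon_phantom(matrix(5, 4, 4),
                                      phase_error_rad = 2), "pi/2")
})

test_that("dixon phantom noise is seeded and at the stated scale", {
  ff <- matrix(10, 64, 64)
  a <- generate_dixon_phantom(ff, noise_sd = 2, seed = 4)
  b <- generate_dixon_phantom(ff, noise_sd = 2, seed = 4)
  expect_identical(a$triplet$in_phase, b$triplet$in_phase)
  noise <- a$triplet$in_phase - 100
  expect_equal(sd(c(Re(noise), Im(noise))), 2 / sqrt(2), tolerance = 0.1)
})

test_that("simulated cohorts recover the generating means within 3 SEM", {
  pars <- cohort_generating_means()
  n_ok <- 0L; n_tot <- 0L
  for (s in 1:20) {
    ch <- generate_cohort(seed = s)
    gs <- summarize_group(ch)
    mm <- merge(gs$cells, pars, by = c("variable", "group", "timepoint"))
    ok <- abs(mm$mean.x - mm$generating_mean) <= 3 * mm$sem.y
    n_ok <- n_ok + sum(ok); n_tot <- n_tot + length(ok)
  }
  expect_gte(n_ok / n_tot, 0.95)
})

test_that("degenerate SD-zero cohorts reproduce the means exactly", {
  pars <- table1_parameters()
  pars$sd <- 0
  ch <- generate_cohort(2, 2, parameters = pars, seed = 1)
  for (g in c("responder", "non_responder")) {
    got <- ch$weight_kg[ch$group == g & ch$timepoint == "baseline"]
    want <- pars$mean[pars$variable == "weight_kg" & pars$group == g &
                        pars$timepoint == "baseline"]
    expect_identical(got, rep(want, 2))
  }
})

test_that("the glucose constraint holds for every generated participant", {
  for (s in 1:5) for (strat in c(TRUE, FALSE)) {
    ch <- generate_cohort(stratified = strat, seed = s)
    w8 <- ch[ch$timepoint == "week8", ]
    expect_true(all(w8$fpg_mmol_l[w8$group == "responder"] < 7))
    expect_true(all(w8$fpg_mmol_l[w8$group == "non_responder"] >= 7))
  }
})

test_that("infeasible glucose constraints error instead of looping", {
  pars <- table1_parameters()
  i <- pars$variable == "fpg_mmol_l" & pars$timepoint == "week8" &
    pars$group == "responder"
  pars$mean[i] <- 12; pars$sd[i] <- 0.01
  expect_error(generate_cohort(4, 4, parameters = pars, stratified = FALSE,
                               max_attempts = 50, seed = 1),
               "infeasible")
  pars$sd[i] <- 0
  expect_error(generate_cohort(4, 4, parameters = pars, seed = 1),
               "infeasible")
})

test_that("cohort draws are deterministic given the seed", {
  expect_identical(generate_cohort(seed = 9), generate_cohort(seed = 9))
  expect_false(identical(generate_cohort(seed = 9),
                         generate_cohort(seed = 10)))
})
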