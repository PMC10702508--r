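test_that("layout templates place the documented inserts", {
  expect_equal(nrow(make_layout("EDP_062M")$inserts), 9)
  expect_equal(nrow(make_layout("GAMMEX_467")$inserts), 7)
  expect_gt(nrow(make_layout("TORSO_M701")$inserts), 0)
  custom <- make_layout("CUSTOM")
  expect_equal(nrow(custom$inserts), 0)
  # overlapping overrides are a layout error
  bad <- data.frame(material = c("Water", "Water"), x_mm = c(0, 5),
                    y_mm = c(0, 0), radius_mm = c(10, 10))
  expect_error(make_layout("CUSTOM", overrides = list(inserts = bad)),
               "overlap")
  out <- data.frame(material = "Water", x_mm = 59, y_mm = 0, radius_mm = 10)
  expect_error(make_layout("CUSTOM", overrides = list(inserts = out)),
               "outside")
})

test_that("noiseless rendering reproduces the forward model exactly", {
  mats <- read_material_library()
  k <- spectrum_coefficients(1.5e-3, 2.5e-5)
  lay <- make_layout("EDP_062M",
                     overrides = list(grid = list(n = c(64L, 64L, 2L),
                                                  spacing_mm = c(2, 2, 2))))
  vol <- render_phantom(lay, mats, k, noise_model(0, seed = 1))
  # every insert voxel equals its material's predicted HU exactly
  for (i in seq_len(nrow(vol$truth))) {
    m <- mats[[vol$truth$material[i]]]
    want <- predicted_hu(m, k)
    expect_equal(unique(as.numeric(vol$hu[vol$labels == vol$truth$label[i]])),
                 want, tolerance = 1e-12)
  }
  # body is water at 0 HU; outside is air
  expect_equal(unique(as.numeric(vol$hu[vol$labels == 1L])), 0)
  expect_equal(unique(as.numeric(vol$hu[vol$labels == 0L])), -1000)
  # CUSTOM with zero inserts: body-only label map
  lay0 <- make_layout("CUSTOM", overrides = list(grid = lay$grid))
  vol0 <- render_phantom(lay0, mats, k, noise_model(0, seed = 1))
  expect_setequal(unique(as.integer(vol0$labels)), c(0L, 1L))
  # truth/label consistency: every labeled voxel's truth matches the library
  expect_equal(vol$truth$rho,
               vapply(vol$truth$material, function(nm) mats[[nm]]$rho,
                      numeric(1), USE.NAMES = FALSE))
  expect_error(render_phantom(make_layout("CUSTOM", overrides = list(
    body = list(semi_mm = c(60, 60), material = "Unobtainium"))), mats, k),
    "missing from the library")
})

test_that("noise statistics match the noise model", {
  mats <- read_material_library()
  k <- spectrum_coefficients(1.5e-3, 2.5e-5)
  lay <- make_layout("EDP_062M")   # default 128x128x8 grid
  vol <- render_phantom(lay, mats, k, noise_model(15, seed = 99))
  for (i in sample(nrow(vol$truth), 4)) {
    lb <- vol$truth$label[i]
    m <- mats[[vol$truth$material[i]]]
    v <- vol$hu[vol$labels == lb]
    want <- predicted_hu(m, k)
    expect_lt(abs(mean(v) - want), 3 * 15 / sqrt(length(v)))
    expect_lt(abs(sd(v) - 15) / 15, 0.10)
  }
})

test_that("rendering is deterministic and seed-separable", {
  mats <- read_material_library()
  k <- spectrum_coefficients(1.5e-3, 2.5e-5)
  lay <- make_layout("TORSO_M701",
                     overrides = list(grid = list(n = c(48L, 48L, 2L),
                                                  spacing_mm = c(2.5, 2, 2))))
  v1 <- render_phantom(lay, mats, k, noise_model(10, seed = 7))
  v2 <- render_phantom(lay, mats, k, noise_model(10, seed = 7))
  v3 <- render_phantom(lay, mats, k, noise_model(10, seed = 8))
  expect_identical(v1$hu, v2$hu)
  expect_identical(v1$labels, v3$labels)
  # changing only the seed changes only the noise realization
  v0 <- render_phantom(lay, mats, k, noise_model(0, seed = 1))
  d3 <- v3$hu - v0$hu
  d1 <- v1$hu - v0$hu
  expect_false(identical(d1, d3))
  expect_equal(mean(d1), 0, tolerance = 0.2)
  # bias field perturbs the noiseless component smoothly
  vb <- render_phantom(lay, mats, k,
                       noise_model(0, bias_amplitude = 0.05, seed = 1))
  expect_gt(max(abs(vb$hu - v0$hu)), 0)
})

test_that("train/test split schemes behave as documented", {
  vols <- list(EDP_062M = "a", TORSO_M701 = "b", TORSO_M702 = "c")
  s <- split_train_test(vols, "study")
  expect_equal(names(s$train), "EDP_062M")
  expect_setequal(names(s$test), c("TORSO_M701", "TORSO_M702"))
  expect_warning(s2 <- split_train_test(vols["EDP_062M"], "self"), "same volume")
  expect_identical(s2$train, s2$test)
  r1 <- split_train_test(vols, "random", seed = 3)
  r2 <- split_train_test(vols, "random", seed = 3)
  expect_identical(r1, r2)
  expect_error(split_train_test(vols[2:3], "study"), "at least one")
})
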