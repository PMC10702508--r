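test_that("forward HU model: water identities and frozen oracle", {
  k <- spectrum_coefficients(1.5e-3, 2.5e-5)
  # water -> 0 HU for any non-negative coefficients
  for (kk in list(k, spectrum_coefficients(0, 0),
                  spectrum_coefficients(0.01, 1e-4))) {
    expect_equal(predicted_hu(fix_water(), kk), 0, tolerance = 1e-12)
  }
  # water composition at doubled density -> exactly 1000 HU
  expect_equal(predicted_hu(fix_scaled_water(2), k), 1000, tolerance = 1e-9)
  # frozen independent formula oracle: bone-like fixture at (1e-3, 1e-5)
  expect_equal(predicted_hu(fix_bonelike(), spectrum_coefficients(1e-3, 1e-5)),
               593.19314678, tolerance = 1e-6)
  expect_error(spectrum_coefficients(-1e-3, 0), "non-negative")
})

test_that("spectrum coefficient fit recovers generating values exactly", {
  lib <- filter_material_library(read_material_library(), "cirs_062m")
  k_true <- spectrum_coefficients(2e-3, 5e-5)
  hu <- predicted_hu(lib, k_true)
  fit <- fit_spectrum_coefficients(unclass(lib), hu)
  expect_equal(fit$k1, k_true$k1, tolerance = 1e-6)
  expect_equal(fit$k2, k_true$k2, tolerance = 1e-6)
  expect_lt(attr(fit, "fit")$residual_norm, 1e-5)
  # round trip: refitted coefficients reproduce the HU values
  expect_equal(predicted_hu(lib, fit), hu, tolerance = 1e-6)
})

test_that("degenerate and undersized designs are rejected", {
  expect_error(fit_spectrum_coefficients(list(fix_water()), 0), "at least 2")
  # all water-like compositions: unidentifiable
  mats <- list(fix_water(), fix_scaled_water(1.2), fix_scaled_water(0.5))
  expect_error(fit_spectrum_coefficients(mats, c(0, 200, -500)),
               "unidentifiable")
})

test_that("Bethe RSP: identities, frozen oracle, monotone in I", {
  expect_equal(bethe_rsp(1, 75), 1.0)
  expect_equal(bethe_rsp(1.1, 75), 1.1)        # I terms cancel, linear in rho_e
  expect_equal(bethe_rsp(1, 100), 0.9641533751, tolerance = 1e-9)
  # strictly decreasing in I_m on a grid
  grid <- seq(20, 400, length.out = 50)
  vals <- bethe_rsp(rep(1, 50), grid)
  expect_true(all(diff(vals) < 0))
  expect_error(bethe_rsp(1, 1e9), "argument")
})

test_that("calibration curve construction and node-by-node consistency", {
  lib <- read_material_library()
  cirs <- filter_material_library(lib, "cirs_062m")
  k <- spectrum_coefficients(1.5e-3, 2.5e-5)
  curve <- build_calibration_curve(c(lib["Water"], unclass(cirs)), k)
  expect_equal(nrow(curve$nodes), 10)
  expect_true(all(diff(curve$nodes$hu) > 0))
  expect_true(all(diff(curve$nodes$rho) >= 0))
  # node-by-node: each node equals a per-material single evaluation
  constants <- physics_constants()
  for (i in seq_len(nrow(curve$nodes))) {
    m <- lib[[curve$nodes$material[i]]]
    expect_equal(curve$nodes$hu[i], predicted_hu(m, k))
    expect_equal(curve$nodes$rho[i], m$rho)
    expect_equal(curve$nodes$rsp[i],
                 bethe_rsp(relative_electron_density(m),
                           mean_excitation_energy(m), constants))
  }
})

test_that("single-node and two-node curves interpolate as specified", {
  k <- spectrum_coefficients(1e-3, 1e-5)
  wcurve <- build_calibration_curve(list(fix_water()), k)
  expect_equal(apply_curve(wcurve, c(-500, 0, 1000)), rep(1, 3))
  # two nodes at HU 0 and 1000 with rho 1.0 and 1.5: midpoint maps to 1.25
  two <- structure(list(nodes = data.frame(
    hu = c(0, 1000), rho = c(1, 1.5), rsp = c(1, 1.4),
    material = c("a", "b"))), class = "calibration_curve")
  expect_equal(apply_curve(two, 500), 1.25)
  expect_equal(apply_curve(two, c(-100, 2000)), c(1, 1.5))  # flat extrapolation
})

test_that("duplicate HU nodes keep the denser material with a warning", {
  m1 <- ct_material("lite", 1.0, c(H = 0.111894, O = 0.888106))
  m2 <- ct_material("dense", 1.0 + 1e-12, c(H = 0.111894, O = 0.888106))
  expect_warning(curve <- build_calibration_curve(list(m1, m2),
                                                  spectrum_coefficients(1e-3, 1e-5)),
                 "denser")
  expect_equal(nrow(curve$nodes), 1)
  expect_equal(curve$nodes$material, "dense")
})

test_that("apply_curve matches a per-voxel interpolation oracle", {
  lib <- read_material_library()
  curve <- build_calibration_curve(
    c(lib["Water"], unclass(filter_material_library(lib, "cirs_062m"))),
    spectrum_coefficients(1.5e-3, 2.5e-5))
  set.seed(11)
  hu <- array(runif(1000, -900, 1400), dim = c(10, 10, 10))
  got <- apply_curve(curve, hu, "rsp")
  nodes <- curve$nodes
  oracle <- vapply(as.numeric(hu), function(h) {
    if (h <= nodes$hu[1]) return(nodes$rsp[1])
    if (h >= nodes$hu[nrow(nodes)]) return(nodes$rsp[nrow(nodes)])
    i <- findInterval(h, nodes$hu)
    t <- (h - nodes$hu[i]) / (nodes$hu[i + 1] - nodes$hu[i])
    (1 - t) * nodes$rsp[i] + t * nodes$rsp[i + 1]
  }, numeric(1))
  expect_equal(as.numeric(got), oracle, tolerance = 1e-12)
  # monotone inputs give monotone density outputs
  ramp <- sort(runif(200, -900, 1400))
  expect_true(!is.unsorted(apply_curve(curve, ramp, "rho")))
})

test_that("NaN HU voxels propagate as NA with a message", {
  two <- structure(list(nodes = data.frame(
    hu = c(0, 1000), rho = c(1, 1.5), rsp = c(1, 1.4),
    material = c("a", "b"))), class = "calibration_curve")
  expect_message(out <- apply_curve(two, c(0, NaN, 1000)), "non-finite")
  expect_equal(out, c(1, NA, 1.5))
})

test_that("curve CSV round trip preserves nodes", {
  lib <- read_material_library()
  curve <- build_calibration_curve(
    c(lib["Water"], unclass(filter_material_library(lib, "gammex_467"))),
    spectrum_coefficients(1.2e-3, 3e-5))
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_calibration_curve(curve, tmp)
  curve2 <- read_calibration_curve(tmp)
  expect_equal(curve2$nodes$hu, curve$nodes$hu)
  expect_equal(curve2$nodes$rho, curve$nodes$rho)
  expect_equal(curve2$nodes$rsp, curve$nodes$rsp)
})

test_that("noisy coefficient recovery is unbiased at the declared scale", {
  lib <- filter_material_library(read_material_library(), "cirs_062m")
  k_true <- spectrum_coefficients(2e-3, 5e-5)
  hu0 <- predicted_hu(lib, k_true)
  set.seed(123)
  k1s <- k2s <- numeric(50)
  for (r in 1:50) {
    fit <- fit_spectrum_coefficients(unclass(lib), hu0 + rnorm(9, 0, 5))
    k1s[r] <- fit$k1
    k2s[r] <- fit$k2
  }
  expect_lt(abs(median(k1s) - k_true$k1) / k_true$k1, 0.10)
  expect_lt(abs(median(k2s) - k_true$k2) / k_true$k2, 0.10)
})
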