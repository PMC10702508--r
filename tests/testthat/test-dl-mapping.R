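test_that("model specs encode the published architectures", {
  ann <- build_model(model_spec("ANN", "DENSITY"), seed = 1)
  # exactly one hidden layer of 30 tanh units between scalar input and output
  expect_length(ann$net$layers, 2)
  expect_equal(dim(ann$net$layers[[1]]$W), c(1, 30))
  expect_equal(ann$net$layers[[1]]$act, "tanh")
  expect_equal(dim(ann$net$layers[[2]]$W), c(30, 1))
  expect_equal(n_parameters(ann), 1 * 30 + 30 + 30 * 1 + 1)
  expect_error(model_spec("ANN", input_length = 5), "per-voxel")

  fcnn <- build_model(model_spec("FCNN", "RSP", input_length = 16), seed = 1)
  # seven hidden weight layers: 3 conv + 4 dense
  types <- vapply(fcnn$net$layers, `[[`, character(1), "type")
  expect_equal(types, c("conv", "conv", "conv", "flatten",
                        "dense", "dense", "dense", "dense"))
  expect_equal(vapply(fcnn$net$layers[5:8],
                      function(l) ncol(l$W), numeric(1)), c(256, 128, 64, 1))

  rn <- build_model(model_spec("RESNET", "DENSITY", input_length = 32), seed = 1)
  types <- vapply(rn$net$layers, `[[`, character(1), "type")
  expect_equal(types, c("conv", rep("residual", 5), "gap", "dense"))
  # stem + per-block channel sequence 64, 64, 128, 256, 512, 1024
  chans <- c(rn$net$layers[[1]]$out_ch,
             vapply(rn$net$layers[2:6], function(b) b$main[[1]]$out_ch,
                    integer(1)))
  expect_equal(chans, c(64L, 64L, 128L, 256L, 512L, 1024L))
  # shortcut stride equals the product of the block's main-path strides
  for (b in rn$net$layers[2:6]) {
    expect_equal(b$shortcut$stride,
                 b$main[[1]]$stride * b$main[[2]]$stride)
  }
  expect_error(model_spec("RESNET", input_length = 8), ">= 16")
})

test_that("builds are deterministic in the seed", {
  s <- model_spec("FCNN", "DENSITY", input_length = 16)
  m1 <- build_model(s, seed = 7)
  m2 <- build_model(s, seed = 7)
  m3 <- build_model(s, seed = 8)
  expect_identical(parameter_checksum(m1), parameter_checksum(m2))
  expect_false(identical(parameter_checksum(m1), parameter_checksum(m3)))
})

test_that("training-pair extraction: counts, windows, edge replication", {
  vol <- fix_toy_volume()
  ds <- extract_training_pairs(vol, input_length = 1, target = "DENSITY")
  expect_equal(nrow(ds$features), sum(vol$labels > 0))
  expect_equal(ncol(ds$features), 1)
  expect_setequal(unique(ds$targets), c(1, 1.5))
  # all-background volume: empty dataset with a warning
  vol0 <- vol
  vol0$labels[] <- 0L
  expect_warning(ds0 <- extract_training_pairs(vol0), "no labeled")
  expect_equal(length(ds0$targets), 0)
  # hand-constructed 3-voxel row: windows with edge replication
  hu <- array(c(10, 20, 30), dim = c(3, 1, 1))
  labels <- array(c(1L, 1L, 1L), dim = c(3, 1, 1))
  v <- phantom_volume(hu, labels, c(1, 1, 1),
                      data.frame(label = 1L, material = "m", rho = 1,
                                 rsp = 1, rho_e = 1, zeff = 7))
  ds3 <- extract_training_pairs(v, input_length = 3)
  expect_equal(ds3$features[1, ], c(10, 10, 20))  # center voxel a -> (a,a,b)
  expect_equal(ds3$features[2, ], c(10, 20, 30))  # center voxel b -> (a,b,c)
  expect_equal(ds3$features[3, ], c(20, 30, 30))
  # label without material mapping
  vbad <- v
  vbad$truth <- data.frame(label = 1L, material = "m", rho = NA_real_,
                           rsp = 1, rho_e = 1, zeff = 7)
  expect_error(extract_training_pairs(vbad, target = "DENSITY"), "label")
})

test_that("constant-target training converges and is seed-reproducible", {
  set.seed(31)
  hu <- array(rnorm(400, 100, 30), dim = c(20, 20, 1))
  labels <- array(1L, dim = dim(hu))
  vol <- phantom_volume(hu, labels, c(1, 1, 1),
                        data.frame(label = 1L, material = "m", rho = 1,
                                   rsp = 1, rho_e = 1, zeff = 7))
  ds <- extract_training_pairs(vol, 1, "DENSITY")
  cfg <- training_config(batch_size = 50, learning_rate = 2e-2, epochs = 150,
                         seed = 5, patience = Inf)
  m <- train_mapper(build_model(model_spec("ANN", "DENSITY"), seed = 5), ds, cfg)
  pred <- predict_map(m, vol)
  expect_true(all(abs(pred - 1) < 1e-3))
  # identical loss curves on a re-run with the same seed
  m2 <- train_mapper(build_model(model_spec("ANN", "DENSITY"), seed = 5), ds, cfg)
  expect_identical(m$history, m2$history)
  expect_identical(parameter_checksum(m), parameter_checksum(m2))
})

test_that("ANN learns an exact linear HU->density rule to sub-0.5% MAPE", {
  # ground truth rho = 1 + 4e-4 * HU; closed-form least squares is exact,
  # the network must approach it on held-out data
  set.seed(32)
  hu_tr <- runif(1500, -200, 1200)
  rho_tr <- 1 + 4e-4 * hu_tr
  ds <- structure(list(features = matrix(hu_tr, ncol = 1), targets = rho_tr,
                       provenance = data.frame(voxel = seq_along(hu_tr),
                                               label = 1L)),
                  class = "voxel_dataset")
  cfg <- training_config(batch_size = 100, learning_rate = 5e-3, epochs = 400,
                         seed = 6, patience = 60)
  m <- train_mapper(build_model(model_spec("ANN", "DENSITY"), seed = 6), ds, cfg)
  hu_te <- seq(-150, 1150, by = 25)
  pred <- as.numeric(predict_map(m, array(hu_te, dim = c(length(hu_te), 1, 1))))
  oracle <- 1 + 4e-4 * hu_te   # = closed-form regression on noiseless data
  mape <- mean(abs(pred - oracle) / oracle) * 100
  expect_lt(mape, 0.5)
  # training loss non-increasing over a trailing window on separable data
  tl <- m$history$train_loss
  expect_lt(mean(tail(tl, 5)), mean(head(tl, 5)))
})

test_that("prediction is congruent, batch-invariant, and window-consistent", {
  set.seed(33)
  spec <- model_spec("FCNN", "DENSITY", input_length = 8)
  m <- build_model(spec, seed = 2)
  m$trained <- TRUE   # random weights suffice for invariance checks
  hu <- array(rnorm(6 * 5 * 2, 0, 100), dim = c(6, 5, 2))
  p1 <- predict_map(m, hu, batch_size = 7L)
  p2 <- predict_map(m, hu, batch_size = 60L)
  expect_equal(dim(p1), dim(hu))
  expect_equal(p1, p2, tolerance = 1e-12)
  # constant volume: every edge-replicated window is identical, so the whole
  # output is constant
  huc <- array(50, dim = c(12, 3, 1))
  pc <- predict_map(m, huc)
  expect_equal(max(abs(pc - pc[1])), 0, tolerance = 1e-12)
  # masked prediction only fills the mask
  pm <- predict_map(m, hu, mask = c(1L, 10L))
  expect_equal(sum(!is.na(pm)), 2)
  expect_equal(pm[1], p1[1])
})

test_that("separate density and RSP networks never share weights", {
  ds_rho <- model_spec("ANN", "DENSITY")
  ds_rsp <- model_spec("ANN", "RSP")
  m_rho <- build_model(ds_rho, seed = 3)
  m_rsp <- build_model(ds_rsp, seed = 4)
  expect_false(identical(parameter_checksum(m_rho), parameter_checksum(m_rsp)))
})

test_that("training aborts with diagnostics on divergent loss", {
  set.seed(34)
  ds <- structure(list(features = matrix(c(0, 1), ncol = 1),
                       targets = c(NaN, 1),
                       provenance = data.frame(voxel = 1:2, label = 1L)),
                  class = "voxel_dataset")
  cfg <- training_config(batch_size = 2, learning_rate = 1, epochs = 5,
                         seed = 1, validation_fraction = 0)
  expect_error(train_mapper(build_model(model_spec("ANN", "DENSITY"), 1), ds, cfg),
               "non-finite loss")
})
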