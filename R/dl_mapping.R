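#' Specify a voxel-regressor architecture
#'
#' Three supervised architectures map a CT-number input to a scalar tissue
#' property (mass density or RSP):
#' \describe{
#'   \item{ANN}{a single voxel's HU through one hidden layer of 30 tanh
#'     units (input length fixed at 1).}
#'   \item{FCNN}{a 1D fully convolutional network over an along-row HU
#'     window: three kernel-3 convolutions followed by fully connected
#'     layers of widths 256, 128 and 64 and a linear output — seven hidden
#'     weight layers.}
#'   \item{RESNET}{a 1D residual network: a stride-2 kernel-7 stem
#'     convolution, five residual blocks with channels
#'     64, 128, 256, 512, 1024 (each a pair of convolutions plus a 1x1
#'     projection shortcut), global average pooling and a linear output.}
#' }
#'
#' @param architecture One of `"ANN"`, `"FCNN"`, `"RESNET"`.
#' @param target `"DENSITY"` or `"RSP"` (bookkeeping; the network itself is
#'   target-agnostic).
#' @param input_length HU window length (voxels). Forced to 1 for ANN;
#'   default 64 for the convolutional architectures. ResNet requires at
#'   least 16 for its downsampling chain to be non-degenerate.
#' @param fcnn_channels Convolution channel widths of the FCNN stem.
#' @return An object of class `model_spec`.
#' @export
#' @examples
#' model_spec("ANN", "DENSITY")
model_spec <- function(architecture = c("ANN", "FCNN", "RESNET"),
                       target = c("DENSITY", "RSP"),
                       input_length = NULL,
                       fcnn_channels = c(8, 16, 16)) {
  architecture <- match.arg(architecture)
  target <- match.arg(target)
  if (architecture == "ANN") {
    if (!is.null(input_length) && input_length != 1) {
      stop("ANN is a per-voxel model; input_length must be 1")
    }
    input_length <- 1L
  } else if (is.null(input_length)) {
    input_length <- 64L
  }
  input_length <- as.integer(input_length)
  stopifnot(input_length >= 1)
  if (architecture == "RESNET" && input_length < 16) {
    stop("ResNet downsampling chain requires input_length >= 16 (got ",
         input_length, ")")
  }
  structure(list(architecture = architecture, target = target,
                 input_length = input_length,
                 fcnn_channels = as.integer(fcnn_channels)),
            class = "model_spec")
}

# Table-defined ResNet channel schedule (stem + five blocks)
.RESNET_CHANNELS <- c(64L, 64L, 128L, 256L, 512L, 1024L)

.build_layers <- function(spec) {
  L <- spec$input_length
  if (spec$architecture == "ANN") {
    return(list(input = "matrix",
                layers = list(.layer_dense(1, 30, "tanh"),
                              .layer_dense(30, 1, "linear"))))
  }
  if (spec$architecture == "FCNN") {
    ch <- spec$fcnn_channels
    layers <- list(
      .layer_conv1d(1, ch[1], 3, 1, "relu"),
      .layer_conv1d(ch[1], ch[2], 3, 1, "relu"),
      .layer_conv1d(ch[2], ch[3], 3, 1, "relu"),
      .layer_flatten(),
      .layer_dense(ch[3] * L, 256, "relu"),
      .layer_dense(256, 128, "relu"),
      .layer_dense(128, 64, "relu"),
      .layer_dense(64, 1, "linear"))
    return(list(input = "conv", layers = layers))
  }
  # RESNET: stem + blocks (channels, kernel, first-conv stride per block)
  blocks <- list(
    list(ch = 64L,  k = 3L, s1 = 1L, s2 = 1L),
    list(ch = 128L, k = 3L, s1 = 2L, s2 = 1L),
    list(ch = 256L, k = 3L, s1 = 2L, s2 = 1L),
    list(ch = 512L, k = 2L, s1 = 2L, s2 = 1L),
    list(ch = 1024L, k = 3L, s1 = 2L, s2 = 2L))
  layers <- list(.layer_conv1d(1, 64, 7, 2, "relu"))
  in_ch <- 64L
  for (b in blocks) {
    main <- list(.layer_conv1d(in_ch, b$ch, b$k, b$s1, "relu"),
                 .layer_conv1d(b$ch, b$ch, b$k, b$s2, "linear"))
    shortcut <- .layer_conv1d(in_ch, b$ch, 1, b$s1 * b$s2, "linear")
    layers <- c(layers, list(.layer_residual(main, shortcut)))
    in_ch <- b$ch
  }
  head <- .layer_dense(in_ch, 1, "linear")
  # zero-init output head: the global-average-pooled 1024-channel features
  # otherwise give the untrained net a huge output variance and Adam wastes
  # its budget on the transient
  head$W[] <- 0
  layers <- c(layers, list(.layer_gap(), head))
  list(input = "conv", layers = layers)
}

#' Build an (untrained) voxel mapper
#'
#' Parameter shapes are a pure function of the spec; all weight
#' initialization derives from `seed`, so two builds with the same seed are
#' weight-identical.
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `voxel_mapper`.
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  net <- .build_layers(spec)
  net$input_length <- spec$input_length
  structure(list(spec = spec, net = net, seed = as.integer(seed),
                 trained = FALSE, history = NULL, config = NULL),
            class = "voxel_mapper")
}

#' @export
print.voxel_mapper <- function(x, ...) {
  cat(sprintf("<voxel_mapper> %s -> %s, input length %d, %s parameters, %s\n",
              x$spec$architecture, x$spec$target, x$spec$input_length,
              format(n_parameters(x), big.mark = ","),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' Number of trainable parameters of a mapper
#' @param mapper A `voxel_mapper`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(mapper) .n_params(mapper$net$layers)

#' Deterministic checksum of a mapper's parameters
#'
#' Order-sensitive weighted sum over every weight and bias, printed to 12
#' significant digits; identical builds/trainings give identical checksums.
#'
#' @param mapper A `voxel_mapper`.
#' @return Character checksum.
#' @export
parameter_checksum <- function(mapper) .param_checksum(mapper$net$layers)

#' Extract (HU window, target) training pairs from a labeled volume
#'
#' One sample per labeled voxel.  For `input_length > 1` the feature is the
#' along-row (x-direction) HU neighborhood centered on the voxel,
#' edge-padded by replicating the first/last voxel of the row; for even
#' window lengths the extra voxel sits on the right.  Unlabeled (label 0)
#' voxels are excluded.
#'
#' @param volume A [phantom_volume()].
#' @param input_length Window length in voxels.
#' @param target `"DENSITY"` or `"RSP"`; looked up per label in the volume's
#'   truth table.
#' @return A `voxel_dataset`: list with `features` (N x input_length
#'   matrix), `targets` (length N), and `provenance` (data frame with voxel
#'   index and label).
#' @export
extract_training_pairs <- function(volume, input_length = 1L,
                                   target = c("DENSITY", "RSP")) {
  target <- match.arg(target)
  stopifnot(inherits(volume, "phantom_volume"))
  input_length <- as.integer(input_length)
  labs <- volume$labels
  idx <- which(labs > 0)
  if (length(idx) == 0) {
    warning("volume has no labeled voxels; returning an empty dataset")
    return(structure(list(features = matrix(numeric(0), 0, input_length),
                          targets = numeric(0),
                          provenance = data.frame(voxel = integer(0),
                                                  label = integer(0))),
                     class = "voxel_dataset"))
  }
  truth <- volume$truth
  col <- if (target == "DENSITY") "rho" else "rsp"
  present <- sort(unique(labs[idx]))
  unknown <- setdiff(present, truth$label)
  if (length(unknown) > 0) {
    stop("labels without material mapping: ", paste(unknown, collapse = ", "))
  }
  lut <- rep(NA_real_, max(truth$label))
  lut[truth$label] <- truth[[col]]
  targets <- lut[labs[idx]]
  if (anyNA(targets)) {
    bad <- sort(unique(labs[idx][is.na(targets)]))
    stop("labels without a defined ", tolower(target), " value: ",
         paste(bad, collapse = ", "))
  }
  features <- .hu_windows(volume$hu, idx, input_length)
  structure(list(features = features, targets = targets,
                 provenance = data.frame(voxel = idx, label = labs[idx])),
            class = "voxel_dataset")
}

# windows along x (first, fastest-varying axis), edge replication
.hu_windows <- function(hu, idx, input_length) {
  d <- dim(hu)
  nx <- d[1]
  if (input_length == 1L) return(matrix(hu[idx], ncol = 1))
  half_l <- (input_length - 1L) %/% 2L
  ix <- ((idx - 1L) %% nx) + 1L          # x index of each voxel
  row0 <- idx - ix                       # linear index of (0, y, z)
  offs <- seq.int(-half_l, length.out = input_length)
  feat <- matrix(0, length(idx), input_length)
  for (j in seq_along(offs)) {
    xj <- pmin(pmax(ix + offs[j], 1L), nx)
    feat[, j] <- hu[row0 + xj]
  }
  feat
}

#' Training configuration for voxel mappers
#'
#' Defaults follow the published protocol: batch size 100 and Adam with
#' learning rate 1e-5.  The epoch budget, early-stopping patience and
#' validation fraction are package choices (the protocol does not state
#' them).  All randomness (shuffling, validation split) derives from `seed`.
#'
#' @param batch_size Minibatch size (>= 1).
#' @param learning_rate Adam learning rate (> 0).
#' @param epochs Maximum number of epochs.
#' @param seed Integer seed for shuffling/splitting.
#' @param loss `"mse"` (default) or `"l1"` per-voxel discrepancy.
#' @param validation_fraction Fraction of samples held out for validation
#'   (stratified by label when provenance is available).
#' @param patience Early-stopping patience in epochs on the validation loss
#'   (`Inf` disables early stopping).
#' @return An object of class `training_config`.
#' @export
training_config <- function(batch_size = 100L, learning_rate = 1e-5,
                            epochs = 100L, seed = 1L, loss = c("mse", "l1"),
                            validation_fraction = 0.1, patience = Inf) {
  loss <- match.arg(loss)
  stopifnot(batch_size >= 1, learning_rate > 0, epochs >= 1,
            validation_fraction >= 0, validation_fraction < 1)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 seed = as.integer(seed), loss = loss,
                 validation_fraction = validation_fraction,
                 patience = patience),
            class = "training_config")
}

# HU standardization before the networks: keeps tanh/ReLU units in range
.HU_SCALE <- 1000

#' Train a voxel mapper
#'
#' Minibatch Adam on the per-voxel loss (mean squared error by default)
#' between predicted and true property values.  HU inputs are scaled by
#' 1/1000 before the network; targets are used unscaled.  A stratified
#' validation split (by label) monitors generalization; training aborts
#' with diagnostics if the loss becomes non-finite.  With a fixed
#' `config$seed` the entire run is deterministic.
#'
#' @param mapper An untrained (or trained) `voxel_mapper`.
#' @param dataset A `voxel_dataset` from [extract_training_pairs()].
#' @param config A [training_config()].
#' @param verbose Print per-epoch losses.
#' @return The trained `voxel_mapper`, with `history` (data frame of
#'   per-epoch training/validation loss) and the config attached.
#' @export
train_mapper <- function(mapper, dataset, config = training_config(),
                         verbose = FALSE) {
  stopifnot(inherits(mapper, "voxel_mapper"),
            inherits(dataset, "voxel_dataset"))
  n <- length(dataset$targets)
  if (n == 0) stop("dataset is empty")
  if (ncol(dataset$features) != mapper$spec$input_length) {
    stop("dataset window length ", ncol(dataset$features),
         " does not match the model input length ", mapper$spec$input_length)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  X <- dataset$features / .HU_SCALE
  y <- dataset$targets

  # stratified validation split by label
  val_idx <- integer(0)
  if (config$validation_fraction > 0 && n >= 10) {
    labs <- dataset$provenance$label
    for (lb in unique(labs)) {
      i <- which(labs == lb)
      k <- max(1L, round(length(i) * config$validation_fraction))
      val_idx <- c(val_idx, sample(i, k))
    }
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  if (length(tr_idx) == 0) stop("no training samples left after validation split")

  net <- mapper$net
  state <- .adam_init(net$layers)
  step <- 0L
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  best_val <- Inf
  best_layers <- net$layers
  wait <- 0L
  n_batches <- ceiling(length(tr_idx) / config$batch_size)

  for (epoch in seq_len(config$epochs)) {
    perm <- sample(tr_idx)
    ep_loss <- 0
    for (bi in seq_len(n_batches)) {
      rows <- perm[(((bi - 1L) * config$batch_size + 1L):
                      min(bi * config$batch_size, length(perm)))]
      fw <- .net_forward(net, X[rows, , drop = FALSE], want_cache = TRUE)
      pred <- as.numeric(fw$out)
      lval <- .loss_value(pred, y[rows], config$loss)
      if (!is.finite(lval)) {
        stop(sprintf(paste0("training aborted: non-finite loss at epoch %d, ",
                            "batch %d (lr %.3g, loss %s)"),
                     epoch, bi, config$learning_rate, config$loss))
      }
      ep_loss <- ep_loss + lval * length(rows)
      dY <- matrix(.loss_grad(pred, y[rows], config$loss), ncol = 1)
      grads <- .net_backward(net, dY, fw$caches)
      step <- step + 1L
      r <- .adam_update(net$layers, grads, state, config$learning_rate, step)
      net$layers <- r$layers
      state <- r$state
    }
    ep_loss <- ep_loss / length(tr_idx)
    vl <- if (length(val_idx) > 0) {
      vp <- as.numeric(.net_forward(net, X[val_idx, , drop = FALSE])$out)
      .loss_value(vp, y[val_idx], config$loss)
    } else NA_real_
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = ep_loss,
                                   val_loss = vl))
    if (verbose) {
      message(sprintf("epoch %3d  train %.6g  val %.6g", epoch, ep_loss, vl))
    }
    monitor <- if (is.na(vl)) ep_loss else vl
    if (monitor < best_val - 1e-12) {
      best_val <- monitor
      best_layers <- net$layers
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }
  net$layers <- best_layers
  mapper$net <- net
  mapper$trained <- TRUE
  mapper$history <- hist
  mapper$config <- config
  mapper
}

#' Predict a property map from a CT volume
#'
#' Applies a trained mapper voxel-by-voxel: every voxel (labeled or not)
#' receives a prediction from its along-row HU window (edge replication at
#' row ends).  Batch decomposition does not change the result.
#'
#' @param mapper A trained `voxel_mapper`.
#' @param volume A [phantom_volume()] (or bare numeric array of HU).
#' @param mask Optional logical/index mask: only these voxels are predicted
#'   (others return NA).  Useful when only contoured regions are needed.
#' @param batch_size Voxels per forward batch.
#' @return Numeric array congruent with the input volume.
#' @export
predict_map <- function(mapper, volume, mask = NULL, batch_size = 4096L) {
  stopifnot(inherits(mapper, "voxel_mapper"))
  if (!mapper$trained) warning("mapper is untrained; predictions are from random weights")
  hu <- if (inherits(volume, "phantom_volume")) volume$hu else volume
  d <- dim(hu)
  idx <- if (is.null(mask)) seq_along(hu) else which(.as_mask(mask, hu))
  out <- array(NA_real_, dim = d)
  L <- mapper$spec$input_length
  for (b in split(idx, ceiling(seq_along(idx) / batch_size))) {
    feats <- .hu_windows(hu, b, L) / .HU_SCALE
    out[b] <- as.numeric(.net_forward(mapper$net, feats)$out)
  }
  out
}

.as_mask <- function(mask, hu) {
  if (is.logical(mask)) {
    stopifnot(length(mask) == length(hu))
    mask
  } else {
    m <- logical(length(hu))
    m[mask] <- TRUE
    m
  }
}

#' Save / load a voxel-mapper checkpoint
#'
#' Checkpoints embed the architecture spec, training config, seed and
#' trained weights; the training history can be exported separately as CSV.
#'
#' @param mapper A `voxel_mapper`.
#' @param path Checkpoint path (`.rds`).
#' @return `save_mapper` returns `path` invisibly; `load_mapper` returns
#'   the `voxel_mapper`.
#' @export
save_mapper <- function(mapper, path) {
  saveRDS(mapper, path)
  invisible(path)
}

#' @rdname save_mapper
#' @export
load_mapper <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "voxel_mapper"))
  m
}
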