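# Minimal feed-forward / 1D-convolutional network engine.
#
# No deep-learning framework for R is available in the deployment
# environment, and the voxel regressors are the core of this package, so a
# small deterministic engine is implemented here: dense and 1D convolution
# layers (im2col + BLAS gemm), residual blocks with projection shortcuts,
# global average pooling, tanh/ReLU activations, MSE/L1 losses and Adam.
# All tensors are base-R arrays; convolution activations use dim
# (channels, length, batch) so that im2col reduces to one gemm per layer.

.act_fwd <- function(z, act) {
  switch(act, linear = z, tanh = tanh(z), relu = pmax(z, 0),
         stop("unknown activation: ", act))
}

# gradient wrt pre-activation, expressed through the activation output a
.act_bwd <- function(da, a, act) {
  switch(act, linear = da, tanh = da * (1 - a * a), relu = da * (a > 0),
         stop("unknown activation: ", act))
}

.layer_dense <- function(in_dim, out_dim, act = "linear") {
  # Glorot uniform
  lim <- sqrt(6 / (in_dim + out_dim))
  list(type = "dense", act = act,
       W = matrix(stats::runif(in_dim * out_dim, -lim, lim), in_dim, out_dim),
       b = numeric(out_dim))
}

.layer_conv1d <- function(in_ch, out_ch, kernel, stride, act = "linear") {
  # He normal; weight matrix rows = output channels, cols = in_ch * kernel
  kernel <- as.integer(kernel)[[1]]
  stride <- as.integer(stride)[[1]]
  sd <- sqrt(2 / (in_ch * kernel))
  list(type = "conv", act = act, in_ch = in_ch, out_ch = out_ch,
       kernel = kernel, stride = stride,
       W = matrix(stats::rnorm(out_ch * in_ch * kernel, 0, sd),
                  out_ch, in_ch * kernel),
       b = numeric(out_ch))
}

# residual block: main path of convs (ReLU between, linear on the last),
# 1x1 projection shortcut whose stride is the product of main-path strides,
# ReLU after the addition.  "Same"-style padding keeps every conv output
# length at ceiling(L / stride), which makes main and shortcut lengths agree.
.layer_residual <- function(main, shortcut) {
  list(type = "residual", main = main, shortcut = shortcut)
}

.layer_flatten <- function() list(type = "flatten")
.layer_gap <- function() list(type = "gap")

# ---- conv primitives -------------------------------------------------------

.conv_fwd <- function(X, ly) {
  d <- dim(X)
  C <- d[1]; L <- d[2]; N <- d[3]
  k <- ly$kernel; s <- ly$stride
  Lout <- as.integer(ceiling(L / s))
  pad_total <- max((Lout - 1L) * s + k - L, 0L)
  pl <- pad_total %/% 2L
  Lp <- L + pad_total
  Xp <- array(0, dim = c(C, Lp, N))
  Xp[, (pl + 1L):(pl + L), ] <- X
  starts <- (seq_len(Lout) - 1L) * s                      # 0-based window starts
  taps <- rep(seq_len(k) - 1L, each = C)
  chan <- rep(seq_len(C), k)
  idx <- outer(chan + taps * C, starts * C, "+")          # (C*k) x Lout
  big <- as.vector(outer(as.vector(idx), (seq_len(N) - 1L) * (C * Lp), "+"))
  Xcol <- matrix(Xp[big], nrow = C * k)                   # (C*k) x (Lout*N)
  Z <- ly$W %*% Xcol + ly$b
  A <- .act_fwd(Z, ly$act)
  list(out = array(A, dim = c(ly$out_ch, Lout, N)),
       cache = list(Xcol = Xcol, A = A, C = C, L = L, N = N, Lp = Lp,
                    pl = pl, Lout = Lout, starts = starts))
}

.conv_bwd <- function(dY, ly, cache) {
  dY_mat <- matrix(dY, nrow = ly$out_ch)
  dZ <- .act_bwd(dY_mat, cache$A, ly$act)
  dW <- tcrossprod(dZ, cache$Xcol)                        # (Cout) x (C*k)
  db <- rowSums(dZ)
  dXcol <- crossprod(ly$W, dZ)                            # (C*k) x (Lout*N)
  C <- cache$C; k <- ly$kernel
  dXp <- array(0, dim = c(C, cache$Lp, cache$N))
  for (t in seq_len(k)) {
    rows <- ((t - 1L) * C + 1L):(t * C)
    pos <- cache$starts + t                               # distinct for fixed t
    dXp[, pos, ] <- dXp[, pos, , drop = FALSE] +
      array(dXcol[rows, , drop = FALSE], dim = c(C, cache$Lout, cache$N))
  }
  dX <- dXp[, (cache$pl + 1L):(cache$pl + cache$L), , drop = FALSE]
  list(dX = dX, dW = dW, db = db)
}

# ---- layer dispatch --------------------------------------------------------

.layer_fwd <- function(ly, X) {
  switch(ly$type,
    dense = {
      Z <- X %*% ly$W
      Z <- Z + rep(ly$b, each = nrow(X))
      A <- .act_fwd(Z, ly$act)
      list(out = A, cache = list(X = X, A = A))
    },
    conv = .conv_fwd(X, ly),
    flatten = {
      d <- dim(X)
      list(out = t(matrix(X, d[1] * d[2], d[3])), cache = list(d = d))
    },
    gap = {
      d <- dim(X)
      s <- colSums(aperm(X, c(2, 1, 3)))                  # (C, N)
      list(out = t(s) / d[2], cache = list(d = d))
    },
    residual = {
      caches_m <- vector("list", length(ly$main))
      h <- X
      for (i in seq_along(ly$main)) {
        r <- .layer_fwd(ly$main[[i]], h)
        caches_m[[i]] <- r$cache
        h <- r$out
      }
      rs <- .layer_fwd(ly$shortcut, X)
      A <- .act_fwd(h + rs$out, "relu")
      list(out = A, cache = list(main = caches_m, shortcut = rs$cache, A = A))
    },
    stop("unknown layer type: ", ly$type))
}

.layer_bwd <- function(ly, dY, cache) {
  switch(ly$type,
    dense = {
      dZ <- .act_bwd(dY, cache$A, ly$act)
      list(dX = tcrossprod(dZ, ly$W),
           grads = list(W = crossprod(cache$X, dZ), b = colSums(dZ)))
    },
    conv = {
      r <- .conv_bwd(dY, ly, cache)
      list(dX = r$dX, grads = list(W = r$dW, b = r$db))
    },
    flatten = list(dX = array(t(dY), dim = cache$d), grads = NULL),
    gap = {
      d <- cache$d
      dXc <- t(dY) / d[2]                                 # (C, N)
      list(dX = aperm(array(dXc, dim = c(d[1], d[3], d[2])), c(1, 3, 2)),
           grads = NULL)
    },
    residual = {
      dS <- .act_bwd(dY, cache$A, "relu")
      rs <- .layer_bwd(ly$shortcut, dS, cache$shortcut)
      gm <- vector("list", length(ly$main))
      d <- dS
      for (i in rev(seq_along(ly$main))) {
        r <- .layer_bwd(ly$main[[i]], d, cache$main[[i]])
        gm[i] <- list(r$grads)
        d <- r$dX
      }
      list(dX = d + rs$dX, grads = list(main = gm, shortcut = rs$grads))
    },
    stop("unknown layer type: ", ly$type))
}

# ---- network ---------------------------------------------------------------

# net: list(layers = list(...), input = "matrix" | "conv", input_length = L)
.net_forward <- function(net, X, want_cache = FALSE) {
  if (net$input == "conv") {
    # X arrives as an (N x L) matrix of windows
    X <- array(t(X), dim = c(1L, ncol(X), nrow(X)))
  }
  caches <- if (want_cache) vector("list", length(net$layers)) else NULL
  for (i in seq_along(net$layers)) {
    r <- .layer_fwd(net$layers[[i]], X)
    if (want_cache) caches[[i]] <- r$cache
    X <- r$out
  }
  list(out = X, caches = caches)
}

.net_backward <- function(net, dY, caches) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    r <- .layer_bwd(net$layers[[i]], dY, caches[[i]])
    grads[i] <- list(r$grads)   # [[<- would drop NULL entries
    dY <- r$dX
  }
  grads
}

.n_params <- function(layers) {
  n <- 0
  for (ly in layers) {
    if (ly$type == "residual") {
      n <- n + .n_params(ly$main) + .n_params(list(ly$shortcut))
    } else if (!is.null(ly$W)) n <- n + length(ly$W) + length(ly$b)
  }
  n
}

# deterministic checksum over all parameters (order-sensitive)
.param_checksum <- function(layers) {
  acc <- 0
  i <- 0
  walk <- function(ls) {
    for (ly in ls) {
      if (ly$type == "residual") {
        walk(ly$main); walk(list(ly$shortcut))
      } else if (!is.null(ly$W)) {
        i <<- i + 1
        v <- c(as.numeric(ly$W), ly$b)
        acc <<- acc + sum(v * seq_along(v)) * i
      }
    }
  }
  walk(layers)
  sprintf("%.12e", acc)
}

# ---- Adam ------------------------------------------------------------------

.adam_init <- function(layers) {
  lapply(layers, function(ly) {
    if (ly$type == "residual") {
      list(main = .adam_init(ly$main), shortcut = .adam_init(list(ly$shortcut))[[1]])
    } else if (!is.null(ly$W)) {
      list(mW = ly$W * 0, vW = ly$W * 0, mb = ly$b * 0, vb = ly$b * 0)
    } else NULL
  })
}

.adam_update <- function(layers, grads, state, lr, t,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  upd <- function(ly, g, st) {
    st$mW <- beta1 * st$mW + (1 - beta1) * g$W
    st$vW <- beta2 * st$vW + (1 - beta2) * g$W * g$W
    ly$W <- ly$W - lr * (st$mW / bc1) / (sqrt(st$vW / bc2) + eps)
    st$mb <- beta1 * st$mb + (1 - beta1) * g$b
    st$vb <- beta2 * st$vb + (1 - beta2) * g$b * g$b
    ly$b <- ly$b - lr * (st$mb / bc1) / (sqrt(st$vb / bc2) + eps)
    list(ly = ly, st = st)
  }
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "residual") {
      r <- .adam_update(ly$main, grads[[i]]$main, state[[i]]$main,
                        lr, t, beta1, beta2, eps)
      ly$main <- r$layers
      state[[i]]$main <- r$state
      rs <- upd(ly$shortcut, grads[[i]]$shortcut, state[[i]]$shortcut)
      ly$shortcut <- rs$ly
      state[[i]]$shortcut <- rs$st
      layers[[i]] <- ly
    } else if (!is.null(ly$W)) {
      r <- upd(ly, grads[[i]], state[[i]])
      layers[[i]] <- r$ly
      state[[i]] <- r$st
    }
  }
  list(layers = layers, state = state)
}

# ---- losses ----------------------------------------------------------------

.loss_value <- function(pred, y, loss) {
  switch(loss,
         mse = mean((pred - y)^2),
         l1 = mean(abs(pred - y)),
         stop("unknown loss: ", loss))
}

.loss_grad <- function(pred, y, loss) {
  n <- length(pred)
  switch(loss,
         mse = 2 * (pred - y) / n,
         l1 = sign(pred - y) / n,
         stop("unknown loss: ", loss))
}
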