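# Engine-level checks: analytic gradients against finite differences, and
# shape/determinism contracts of the three architectures.

# enumerate parameter paths: each is a list of keys ending in a linear index.
# The same path indexes both the layer tree (net$layers) and the gradient
# tree returned by the backward pass, whose shapes mirror each other.
param_paths <- function(layers, prefix = list()) {
  paths <- list()
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "residual") {
      paths <- c(paths, param_paths(ly$main, c(prefix, list(i, "main"))))
      for (nm in c("W", "b")) {
        for (j in seq_along(ly$shortcut[[nm]])) {
          paths <- c(paths, list(c(prefix, list(i, "shortcut", nm, j))))
        }
      }
    } else if (!is.null(ly$W)) {
      for (nm in c("W", "b")) {
        for (j in seq_along(ly[[nm]])) {
          paths <- c(paths, list(c(prefix, list(i, nm, j))))
        }
      }
    }
  }
  paths
}

get_path <- function(x, keys) Reduce(function(a, k) a[[k]], keys, x)

set_path <- function(x, keys, value) {
  if (length(keys) == 1) {
    x[[keys[[1]]]] <- value
    return(x)
  }
  x[[keys[[1]]]] <- set_path(x[[keys[[1]]]], keys[-1], value)
  x
}

# numerical MSE-loss gradient for each parameter path
num_grad <- function(net, X, y, paths, eps = 1e-6) {
  loss_at <- function(layers) {
    n2 <- net
    n2$layers <- layers
    pred <- as.numeric(sectmap:::.net_forward(n2, X)$out)
    mean((pred - y)^2)
  }
  vapply(paths, function(p) {
    v <- get_path(net$layers, p)
    (loss_at(set_path(net$layers, p, v + eps)) -
       loss_at(set_path(net$layers, p, v - eps))) / (2 * eps)
  }, numeric(1))
}

analytic_grads <- function(net, X, y) {
  fw <- sectmap:::.net_forward(net, X, want_cache = TRUE)
  pred <- as.numeric(fw$out)
  dY <- matrix(2 * (pred - y) / length(y), ncol = 1)
  sectmap:::.net_backward(net, dY, fw$caches)
}

expect_grads_match <- function(net, X, y, tol = 1e-5) {
  paths <- param_paths(net$layers)
  ng <- num_grad(net, X, y, paths)
  grads <- analytic_grads(net, X, y)
  ag <- vapply(paths, function(p) as.numeric(get_path(grads, p)), numeric(1))
  expect_equal(ag, ng, tolerance = tol)
}

test_that("dense-network gradients match finite differences", {
  set.seed(21)
  net <- list(input = "matrix",
              layers = list(sectmap:::.layer_dense(2, 4, "tanh"),
                            sectmap:::.layer_dense(4, 1, "linear")))
  X <- matrix(rnorm(10), 5, 2)
  y <- rnorm(5)
  expect_grads_match(net, X, y)
})

test_that("conv/flatten network gradients match finite differences", {
  set.seed(22)
  net <- list(input = "conv",
              layers = list(sectmap:::.layer_conv1d(1, 3, 3, 1, "relu"),
                            sectmap:::.layer_conv1d(3, 2, 3, 2, "tanh"),
                            sectmap:::.layer_flatten(),
                            sectmap:::.layer_dense(2 * 4, 1, "linear")))
  X <- matrix(rnorm(8 * 6), 6, 8)   # 6 samples, length-8 windows
  y <- rnorm(6)
  expect_grads_match(net, X, y)
})

test_that("residual block + GAP gradients match finite differences", {
  set.seed(23)
  main <- list(sectmap:::.layer_conv1d(2, 3, 3, 2, "relu"),
               sectmap:::.layer_conv1d(3, 3, 3, 1, "linear"))
  shortcut <- sectmap:::.layer_conv1d(2, 3, 1, 2, "linear")
  net <- list(input = "conv",
              layers = list(sectmap:::.layer_conv1d(1, 2, 3, 1, "relu"),
                            sectmap:::.layer_residual(main, shortcut),
                            sectmap:::.layer_gap(),
                            sectmap:::.layer_dense(3, 1, "linear")))
  X <- matrix(rnorm(8 * 4), 4, 8)
  y <- rnorm(4)
  expect_grads_match(net, X, y)
})

test_that("conv layer output lengths follow the ceil(L/stride) rule", {
  set.seed(24)
  for (cse in list(c(k = 7, s = 2, L = 32, want = 16),
                   c(k = 3, s = 1, L = 16, want = 16),
                   c(k = 3, s = 2, L = 16, want = 8),
                   c(k = 2, s = 2, L = 5, want = 3),
                   c(k = 2, s = 1, L = 4, want = 4),
                   c(k = 1, s = 4, L = 2, want = 1))) {
    ly <- sectmap:::.layer_conv1d(1, 2, cse["k"], cse["s"])
    X <- array(rnorm(cse["L"] * 3), dim = c(1, unname(cse["L"]), 3))
    out <- sectmap:::.conv_fwd(X, ly)$out
    expect_equal(unname(dim(out)), c(2, unname(cse["want"]), 3))
  }
})

test_that("stride-1 kernel-3 convolution matches a direct loop oracle", {
  set.seed(25)
  ly <- sectmap:::.layer_conv1d(2, 3, 3, 1, "linear")
  L <- 7; N <- 2
  X <- array(rnorm(2 * L * N), dim = c(2, L, N))
  out <- sectmap:::.conv_fwd(X, ly)$out
  # zero-padded direct convolution
  Xp <- array(0, dim = c(2, L + 2, N))
  Xp[, 2:(L + 1), ] <- X
  for (n in 1:N) for (j in 1:L) for (co in 1:3) {
    window <- as.numeric(Xp[, j:(j + 2), n])   # channel-fastest flattening
    expect_equal(out[co, j, n],
                 sum(ly$W[co, ] * window) + ly$b[co], tolerance = 1e-12)
  }
})
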