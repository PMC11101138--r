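# Minimal 3D-CNN engine.
#
# Volumetric activations are stored as dense matrices with one column per
# channel and V*B rows (B sample blocks of V voxels, column-major voxel
# order); fully connected activations are (B x features) matrices. Each layer
# is a mutable environment holding its parameters, their gradients, the
# Adadelta accumulators and the forward cache. Convolutions are evaluated as
# im2col patch-matrix GEMMs so the heavy lifting stays in BLAS.

.idx_cache <- new.env(parent = emptyenv())

cache_get <- function(key, maker) {
  if (is.null(.idx_cache[[key]])) .idx_cache[[key]] <- maker()
  .idx_cache[[key]]
}

# 27 neighbour linear indices per voxel (pad 1); out-of-bounds -> V+1 (zero row)
conv_nbr <- function(D) cache_get(sprintf("nbr%d", D), function() {
  V <- D^3
  coords <- arrayInd(seq_len(V), c(D, D, D))
  nbr <- matrix(V + 1L, V, 27L)
  t <- 0L
  for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
    t <- t + 1L
    x <- coords[, 1] + dx; y <- coords[, 2] + dy; z <- coords[, 3] + dz
    ok <- x >= 1L & x <= D & y >= 1L & y <= D & z >= 1L & z <= D
    idx <- rep.int(V + 1L, V)
    idx[ok] <- (z[ok] - 1L) * D * D + (y[ok] - 1L) * D + x[ok]
    nbr[, t] <- idx
  }
  nbr
})

# batched neighbour indices into the padded ((V+1)*B row) activation matrix
conv_nbrB <- function(D, B) cache_get(sprintf("nbrB%d_%d", D, B), function() {
  V <- D^3
  conv_nbr(D)[rep(seq_len(V), B), , drop = FALSE] +
    rep((seq_len(B) - 1L) * (V + 1L), each = V)
})

# positions of the real rows inside the padded matrix
pad_rows <- function(V, B) cache_get(sprintf("pad%d_%d", V, B), function() {
  rep(seq_len(V), B) + rep((seq_len(B) - 1L) * (V + 1L), each = V)
})

# 8 child linear indices per coarse voxel of the half-resolution grid
pool_children <- function(D) cache_get(sprintf("pool%d", D), function() {
  Dh <- D %/% 2L
  Vh <- Dh^3
  coords <- arrayInd(seq_len(Vh), c(Dh, Dh, Dh))
  ch <- matrix(0L, Vh, 8L)
  s <- 0L
  for (oz in 0:1) for (oy in 0:1) for (ox in 0:1) {
    s <- s + 1L
    x <- 2L * coords[, 1] - 1L + ox
    y <- 2L * coords[, 2] - 1L + oy
    z <- 2L * coords[, 3] - 1L + oz
    ch[, s] <- (z - 1L) * D * D + (y - 1L) * D + x
  }
  ch
})

pool_childrenB <- function(D, B) cache_get(sprintf("poolB%d_%d", D, B), function() {
  V <- D^3
  Vh <- (D %/% 2L)^3
  pool_children(D)[rep(seq_len(Vh), B), , drop = FALSE] +
    rep((seq_len(B) - 1L) * V, each = Vh)
})

# children of each parent voxel inside the doubled grid (for upsampling)
up_childrenB <- function(D, B) cache_get(sprintf("upB%d_%d", D, B), function() {
  V <- D^3
  D2 <- 2L * D
  V2 <- D2^3
  coords <- arrayInd(seq_len(V), c(D, D, D))
  ch <- matrix(0L, V, 8L)
  s <- 0L
  for (oz in 0:1) for (oy in 0:1) for (ox in 0:1) {
    s <- s + 1L
    x <- 2L * (coords[, 1] - 1L) + 1L + ox
    y <- 2L * (coords[, 2] - 1L) + 1L + oy
    z <- 2L * (coords[, 3] - 1L) + 1L + oz
    ch[, s] <- (z - 1L) * D2 * D2 + (y - 1L) * D2 + x
  }
  ch[rep(seq_len(V), B), , drop = FALSE] + rep((seq_len(B) - 1L) * V2, each = V)
})

new_layer <- function(type, params = list(), extra = list()) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$params <- params
  e$grads <- lapply(params, function(p) array(0, dim(p) %||% length(p)))
  e$opt <- NULL
  for (n in names(extra)) assign(n, extra[[n]], envir = e)
  class(e) <- "nn_layer"
  e
}

glorot <- function(nrow, ncol) {
  lim <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

# biases start slightly positive so the ReLU chains are born active
nn_conv3d <- function(c_in, c_out, kernel = 3L) {
  K <- if (kernel == 3L) 27L else 1L
  new_layer("conv3d",
            params = list(W = glorot(K * c_in, c_out), b = rep(0.01, c_out)),
            extra = list(c_in = c_in, c_out = c_out, K = K))
}

nn_fc <- function(n_in, n_out) {
  new_layer("fc", params = list(W = glorot(n_in, n_out), b = rep(0.01, n_out)))
}

nn_batchnorm <- function(c, momentum = 0.9, eps = 1e-5) {
  new_layer("batchnorm",
            params = list(gamma = rep(1, c), beta = numeric(c)),
            extra = list(momentum = momentum, eps = eps,
                         run_mean = numeric(c), run_var = rep(1, c)))
}

nn_relu <- function() new_layer("relu")
nn_brelu <- function() new_layer("brelu")
nn_maxpool <- function() new_layer("maxpool")
nn_upsample <- function() new_layer("upsample")
nn_flatten <- function() new_layer("flatten")
nn_unflatten <- function() new_layer("unflatten")

#' Bounded rectified linear unit
#'
#' `min(1, max(0, x))` elementwise: the decoder's output activation, keeping
#' reconstructions inside the min-max-scaled field range \[0, 1\].
#'
#' @param x numeric scalar or array.
#' @return Same shape as `x`.
#' @export
bounded_relu <- function(x) {
  x[] <- pmin(1, pmax(0, x))
  x
}

nn_forward <- function(layer, x, B, training = TRUE) {
  switch(layer$type,
    conv3d = {
      V <- nrow(x) %/% B
      if (layer$K == 1L) {
        layer$cache <- list(x = x)
        sweep(x %*% layer$params$W, 2L, layer$params$b, "+")
      } else {
        D <- round(V^(1 / 3))
        nbrB <- conv_nbrB(D, B)
        Xp <- matrix(0, (V + 1L) * B, ncol(x))
        Xp[pad_rows(V, B), ] <- x
        Ci <- ncol(x)
        patches <- matrix(0, V * B, 27L * Ci)
        for (t in 1:27)
          patches[, ((t - 1L) * Ci + 1L):(t * Ci)] <- Xp[nbrB[, t], , drop = FALSE]
        layer$cache <- list(patches = patches, D = D, Ci = Ci)
        sweep(patches %*% layer$params$W, 2L, layer$params$b, "+")
      }
    },
    fc = {
      layer$cache <- list(x = x)
      sweep(x %*% layer$params$W, 2L, layer$params$b, "+")
    },
    batchnorm = {
      if (training) {
        mu <- colMeans(x)
        xc <- sweep(x, 2L, mu)
        v <- colMeans(xc^2)
        inv <- 1 / sqrt(v + layer$eps)
        xhat <- sweep(xc, 2L, inv, "*")
        mm <- layer$momentum
        layer$run_mean <- mm * layer$run_mean + (1 - mm) * mu
        layer$run_var <- mm * layer$run_var + (1 - mm) * v
        layer$cache <- list(xhat = xhat, inv = inv)
        sweep(sweep(xhat, 2L, layer$params$gamma, "*"), 2L, layer$params$beta, "+")
      } else {
        xhat <- sweep(sweep(x, 2L, layer$run_mean), 2L,
                      1 / sqrt(layer$run_var + layer$eps), "*")
        sweep(sweep(xhat, 2L, layer$params$gamma, "*"), 2L, layer$params$beta, "+")
      }
    },
    relu = {
      layer$cache <- list(pos = x > 0)
      x * layer$cache$pos
    },
    brelu = {
      out <- x
      out[] <- pmin(1, pmax(0, x)) # keep dims: pmax(0, x) would drop them
      # leaky backward slope through the saturated zones: with sparse masked
      # targets the all-zero output is a dead attractor of the exact
      # subgradient, so a small slope is propagated where the unit saturates
      layer$cache <- list(slope = ifelse(x > 0 & x < 1, 1, 0.01))
      out
    },
    maxpool = {
      V <- nrow(x) %/% B
      D <- round(V^(1 / 3))
      chB <- pool_childrenB(D, B)
      m <- x[chB[, 1], , drop = FALSE]
      arg <- matrix(1L, nrow(m), ncol(m))
      for (s in 2:8) {
        v <- x[chB[, s], , drop = FALSE]
        upd <- v > m
        m[upd] <- v[upd]
        arg[upd] <- s
      }
      layer$cache <- list(arg = arg, D = D, C = ncol(x))
      m
    },
    upsample = {
      V <- nrow(x) %/% B
      D <- round(V^(1 / 3))
      chB <- up_childrenB(D, B)
      out <- matrix(0, 8L * V * B, ncol(x))
      for (s in 1:8) out[chB[, s], ] <- x
      layer$cache <- list(D = D)
      out
    },
    flatten = {
      V <- nrow(x) %/% B
      layer$cache <- list(V = V)
      t(matrix(x, V, B))
    },
    unflatten = {
      layer$cache <- list(F = ncol(x))
      matrix(t(x), ncol = 1L)
    },
    stop_mf("unknown layer type '%s'", layer$type)
  )
}

nn_backward <- function(layer, dout, B) {
  switch(layer$type,
    conv3d = {
      layer$grads$b <- colSums(dout)
      if (layer$K == 1L) {
        layer$grads$W <- crossprod(layer$cache$x, dout)
        tcrossprod(dout, layer$params$W)
      } else {
        patches <- layer$cache$patches
        D <- layer$cache$D
        Ci <- layer$cache$Ci
        Co <- layer$c_out
        V <- D^3
        layer$grads$W <- crossprod(patches, dout)
        # input gradient as a transposed convolution: im2col of the output
        # gradient times the spatially flipped kernel (gathers + one GEMM,
        # no scatter-add)
        nbrB <- conv_nbrB(D, B)
        doutP <- matrix(0, (V + 1L) * B, Co)
        doutP[pad_rows(V, B), ] <- dout
        gp <- matrix(0, V * B, 27L * Co)
        for (t in 1:27)
          gp[, ((t - 1L) * Co + 1L):(t * Co)] <- doutP[nbrB[, 28L - t], , drop = FALSE]
        # the mirrored gather already flips the stencil; only the channel
        # axes of the kernel are transposed
        Warr <- array(layer$params$W, c(Ci, 27L, Co))
        Wt <- matrix(aperm(Warr, c(3, 2, 1)), 27L * Co, Ci)
        gp %*% Wt
      }
    },
    fc = {
      layer$grads$W <- crossprod(layer$cache$x, dout)
      layer$grads$b <- colSums(dout)
      tcrossprod(dout, layer$params$W)
    },
    batchnorm = {
      xhat <- layer$cache$xhat
      inv <- layer$cache$inv
      n <- nrow(dout)
      layer$grads$gamma <- colSums(dout * xhat)
      layer$grads$beta <- colSums(dout)
      dxhat <- sweep(dout, 2L, layer$params$gamma, "*")
      term <- sweep(dxhat, 2L, colMeans(dxhat)) -
        sweep(xhat, 2L, colMeans(dxhat * xhat), "*")
      sweep(term, 2L, inv, "*")
    },
    relu = dout * layer$cache$pos,
    brelu = dout * layer$cache$slope,
    maxpool = {
      D <- layer$cache$D
      V <- D^3
      chB <- pool_childrenB(D, B)
      dx <- matrix(0, V * B, layer$cache$C)
      arg <- layer$cache$arg
      for (s in 1:8) {
        sel <- arg == s
        if (any(sel)) {
          g <- dout
          g[!sel] <- 0
          dx[chB[, s], ] <- g # children partition the input: plain assignment
        }
      }
      dx
    },
    upsample = {
      D <- layer$cache$D
      chB <- up_childrenB(D, B)
      dx <- dout[chB[, 1], , drop = FALSE]
      for (s in 2:8) dx <- dx + dout[chB[, s], , drop = FALSE]
      dx
    },
    flatten = matrix(t(dout), ncol = 1L),
    unflatten = t(matrix(dout, layer$cache$F, nrow(dout) %/% layer$cache$F)),
    stop_mf("unknown layer type '%s'", layer$type)
  )
}

chain_forward <- function(layers, x, B, training = TRUE) {
  for (l in layers) x <- nn_forward(l, x, B, training)
  x
}

chain_backward <- function(layers, dout, B) {
  for (l in rev(layers)) dout <- nn_backward(l, dout, B)
  dout
}

#' Reparameterized Gaussian sample
#'
#' `z = mu + exp(logvar / 2) * eps`, `eps ~ N(0, I)`: the standard pathwise
#' sampler for a diagonal-Gaussian surrogate posterior, differentiable in
#' `mu` and `logvar`.
#'
#' @param mu,logvar numeric vectors or matrices of equal shape.
#' @return A draw of the same shape (uses the current RNG stream).
#' @export
reparameterize <- function(mu, logvar) {
  eps <- if (is.matrix(mu)) matrix(stats::rnorm(length(mu)), nrow(mu)) else
    stats::rnorm(length(mu))
  mu + exp(0.5 * logvar) * eps
}

# --- parameter bookkeeping ----------------------------------------------

layer_param_count <- function(layers)
  sum(vapply(layers, function(l) sum(vapply(l$params, length, numeric(1))),
             numeric(1)))

# deterministic fingerprint of all parameters of a set of layers
layers_checksum <- function(layers) {
  v <- unlist(lapply(layers, function(l) lapply(l$params, as.numeric)),
              use.names = FALSE)
  if (is.null(v) || length(v) == 0L) return(c(sum = 0, sumsq = 0, n = 0))
  c(sum = sum(v), sumsq = sum(v^2), n = length(v))
}

adadelta_step <- function(layer, lr, rho = 0.95, eps = 1e-7) {
  if (is.null(layer$opt))
    layer$opt <- list(ag = lapply(layer$params, function(p) p * 0),
                      ad = lapply(layer$params, function(p) p * 0))
  for (nm in names(layer$params)) {
    g <- layer$grads[[nm]]
    layer$opt$ag[[nm]] <- rho * layer$opt$ag[[nm]] + (1 - rho) * g^2
    delta <- -sqrt(layer$opt$ad[[nm]] + eps) / sqrt(layer$opt$ag[[nm]] + eps) * g
    layer$opt$ad[[nm]] <- rho * layer$opt$ad[[nm]] + (1 - rho) * delta^2
    layer$params[[nm]] <- layer$params[[nm]] + lr * delta
  }
}
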