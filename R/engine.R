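# Internal tensor engine for the residual 1-D convolutional models.
#
# Activations are 3-d arrays (L positions, n sequences, c channels). Two
# zero-copy matrix views of the same memory drive the BLAS kernels:
# dim (L*n, c) for channel-wise GEMMs and dim (L, n*c) for position shifts.
# A same-length convolution with kernel width k is computed as k
# shift-and-GEMM accumulations, avoiding any im2col buffer; its backward
# pass mirrors the shifts. Everything is double precision and deterministic
# given the R RNG state.

# a: (L, n, cin) -> z: (L*n, cout) pre-activation matrix (compiled kernel)
conv_forward <- function(a, W, bvec, k) {
  cpp_conv_forward(a, W, bvec, k)
}

# backward of conv_forward: dz (L*n, cout), a the cached layer input
conv_backward <- function(dz, a, W, k) {
  cpp_conv_backward(dz, a, W, k)
}

# channel count feeding the skip of the residual block ending at layer r
skip_channels <- function(config, r) {
  if (r <= 2L) config$input_channels else config$conv_channels[r - 2L]
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# column-broadcast helpers (x is (m, c), v length c)
col_mul <- function(x, v) x * rep(v, each = nrow(x))
col_add <- function(x, v) x + rep(v, each = nrow(x))
col_sub <- function(x, v) x - rep(v, each = nrow(x))

nn_bn_forward <- function(x, gamma, beta, state_mean, state_var, train) {
  if (train) {
    r <- cpp_bn_train(x, gamma, beta)
    new_mean <- (1 - BN_MOMENTUM) * state_mean + BN_MOMENTUM * as.numeric(r$mu)
    # running variance uses the unbiased batch estimate, as is conventional
    new_var <- (1 - BN_MOMENTUM) * state_var + BN_MOMENTUM * as.numeric(r$var_unbiased)
  } else {
    r <- cpp_bn_eval(x, gamma, beta, state_mean, state_var)
    new_mean <- state_mean
    new_var <- state_var
  }
  list(y = r$y, xhat = r$xhat, istd = as.numeric(r$istd), train = train,
       new_mean = new_mean, new_var = new_var)
}

nn_bn_backward <- function(dy, bncache, gamma) {
  r <- cpp_bn_backward(dy, bncache$xhat, bncache$istd, gamma, bncache$train)
  list(dx = r$dx, dgamma = as.numeric(r$dgamma), dbeta = as.numeric(r$dbeta))
}

# Forward pass. x: array (L, n, cin). Returns list(pred, cache, new_state).
# cache is populated only when keep_cache = TRUE (training / attribution).
nn_forward <- function(model, x, train = FALSE, keep_cache = FALSE) {
  cfg <- model$config
  par <- model$par
  st <- model$state
  L <- dim(x)[1L]; n <- dim(x)[2L]
  if (dim(x)[3L] != cfg$input_channels) {
    stop(sprintf("batch has %d channels but the model expects %d",
                 dim(x)[3L], cfg$input_channels), call. = FALSE)
  }
  if (L != cfg$input_len) {
    stop(sprintf("batch has length %d but the model expects %d", L,
                 cfg$input_len), call. = FALSE)
  }
  if (n == 0L) return(list(pred = numeric(0), cache = NULL, new_state = st))

  ncv <- length(cfg$conv_channels)
  acts <- vector("list", ncv + 1L)
  acts[[1L]] <- x # acts[[i + 1]] holds the activation after conv block i
  cache <- if (keep_cache) {
    list(conv = vector("list", ncv), fc = NULL, pool = NULL, n = n)
  } else NULL
  new_state <- st

  a <- x
  for (i in seq_len(ncv)) {
    cout <- cfg$conv_channels[i]
    z <- conv_forward(a, par[[paste0("conv", i, ".W")]],
                      par[[paste0("conv", i, ".b")]], cfg$kernel_sizes[i])
    bncache <- NULL
    if (cfg$batchnorm) {
      bncache <- nn_bn_forward(z, par[[paste0("conv", i, ".gamma")]],
                               par[[paste0("conv", i, ".beta")]],
                               st[[paste0("conv", i, ".rmean")]],
                               st[[paste0("conv", i, ".rvar")]], train)
      z <- bncache$y
      if (train) {
        new_state[[paste0("conv", i, ".rmean")]] <- bncache$new_mean
        new_state[[paste0("conv", i, ".rvar")]] <- bncache$new_var
      }
    }
    proj_xmat <- NULL
    if (i %in% cfg$residual_after) {
      s <- acts[[i - 1L]] # activation two conv layers back (input when i = 2)
      cs <- skip_channels(cfg, i)
      smat <- s; dim(smat) <- c(L * n, cs)
      pkey <- paste0("proj", i, ".W")
      if (!is.null(par[[pkey]])) {
        z <- z + col_add(smat %*% par[[pkey]], par[[paste0("proj", i, ".b")]])
        proj_xmat <- smat
      } else {
        z <- z + smat
      }
    }
    mask <- z > 0
    aout <- z * mask
    dim(aout) <- c(L, n, cout)
    acts[[i + 1L]] <- aout
    if (keep_cache) {
      cache$conv[[i]] <- list(mask = mask, bn = bncache, proj_x = proj_xmat)
    }
    a <- aout
  }

  # penultimate max pooling along the position axis, then flatten
  clast <- cfg$conv_channels[ncv]
  if (isTRUE(cfg$maxpool) && cfg$pool_width > 1L) {
    pw <- cfg$pool_width
    nwin <- L %/% pw
    crop <- a[seq_len(nwin * pw), , , drop = FALSE]
    m <- crop; dim(m) <- c(pw, nwin * n * clast)
    maxv <- m[1L, ]
    argm <- rep(1L, ncol(m))
    if (pw > 1L) {
      for (r in 2:pw) {
        upd <- m[r, ] > maxv
        maxv[upd] <- m[r, upd]
        argm[upd] <- r
      }
    }
    pooled <- array(maxv, c(nwin, n, clast))
    if (keep_cache) cache$pool <- list(argm = argm, nwin = nwin, pw = pw)
    h <- nwin
  } else {
    pooled <- a
    h <- L
  }
  pa <- aperm(pooled, c(1L, 3L, 2L)) # (h, c, n)
  d <- h * clast
  dim(pa) <- c(d, n)
  fmat <- t(pa) # n x d, positions fastest within each channel

  # fully connected stack
  nfc <- length(cfg$fc_dims)
  fccache <- if (keep_cache) vector("list", nfc) else NULL
  hcur <- fmat
  for (j in seq_len(nfc)) {
    zj <- col_add(hcur %*% par[[paste0("fc", j, ".W")]],
                  par[[paste0("fc", j, ".b")]])
    maskj <- zj > 0
    aj <- zj * maskj
    dropmask <- NULL
    rate <- cfg$dropout[j]
    if (train && rate > 0) {
      dropmask <- matrix(stats::runif(length(aj)) >= rate, nrow(aj), ncol(aj))
      aj <- aj * dropmask / (1 - rate)
    }
    if (keep_cache) {
      fccache[[j]] <- list(input = hcur, mask = maskj, dropmask = dropmask,
                           rate = rate)
    }
    hcur <- aj
  }
  pred <- as.numeric(hcur %*% par[["out.W"]]) + as.numeric(par[["out.b"]])

  if (keep_cache) {
    cache$fc <- fccache
    cache$out_input <- hcur
    cache$acts <- acts
    cache$h <- h
    cache$train <- train
  }
  list(pred = pred, cache = cache, new_state = new_state)
}

# Backward pass from d(loss)/d(pred). Returns parameter gradients and the
# accumulated gradient of the scalar outputs w.r.t. each conv block
# activation (used by Grad-CAM).
nn_backward <- function(model, cache, dpred) {
  cfg <- model$config
  par <- model$par
  n <- cache$n
  L <- cfg$input_len
  ncv <- length(cfg$conv_channels)
  grads <- list()

  dh <- matrix(dpred, n, 1L)
  grads[["out.W"]] <- crossprod(cache$out_input, dh)
  grads[["out.b"]] <- sum(dh)
  dcur <- dh %*% t(par[["out.W"]])

  for (j in rev(seq_along(cfg$fc_dims))) {
    fc <- cache$fc[[j]]
    if (!is.null(fc$dropmask)) dcur <- dcur * fc$dropmask / (1 - fc$rate)
    dcur <- dcur * fc$mask
    grads[[paste0("fc", j, ".W")]] <- crossprod(fc$input, dcur)
    grads[[paste0("fc", j, ".b")]] <- colSums(dcur)
    dcur <- dcur %*% t(par[[paste0("fc", j, ".W")]])
  }

  # unflatten to (h, n, clast), undo pooling
  clast <- cfg$conv_channels[ncv]
  h <- cache$h
  dpa <- t(dcur)
  dim(dpa) <- c(h, clast, n)
  dpooled <- aperm(dpa, c(1L, 3L, 2L))
  if (!is.null(cache$pool)) {
    pw <- cache$pool$pw
    nwin <- cache$pool$nwin
    dm <- matrix(0, pw, nwin * n * clast)
    dflat <- dpooled; dim(dflat) <- NULL
    dm[cbind(cache$pool$argm, seq_len(nwin * n * clast))] <- dflat
    da_last <- array(0, c(L, n, clast))
    tmp <- dm; dim(tmp) <- c(nwin * pw, n, clast)
    da_last[seq_len(nwin * pw), , ] <- tmp
  } else {
    da_last <- dpooled
  }

  dact <- vector("list", ncv + 1L) # gradient w.r.t. acts[[i]]
  dact[[ncv + 1L]] <- da_last
  for (i in rev(seq_len(ncv))) {
    cc <- cache$conv[[i]]
    cout <- cfg$conv_channels[i]
    dz <- dact[[i + 1L]]
    dim(dz) <- c(L * n, cout)
    dz <- dz * cc$mask
    if (i %in% cfg$residual_after) {
      cs <- skip_channels(cfg, i)
      pkey <- paste0("proj", i, ".W")
      if (!is.null(par[[pkey]])) {
        grads[[pkey]] <- crossprod(cc$proj_x, dz)
        grads[[paste0("proj", i, ".b")]] <- colSums(dz)
        dskip <- dz %*% t(par[[pkey]])
      } else {
        dskip <- dz
      }
      dim(dskip) <- c(L, n, cs)
      prev <- dact[[i - 1L]]
      dact[[i - 1L]] <- if (is.null(prev)) dskip else prev + dskip
    }
    if (cfg$batchnorm) {
      bb <- nn_bn_backward(dz, cc$bn, par[[paste0("conv", i, ".gamma")]])
      grads[[paste0("conv", i, ".gamma")]] <- bb$dgamma
      grads[[paste0("conv", i, ".beta")]] <- bb$dbeta
      dz <- bb$dx
    }
    cb <- conv_backward(dz, cache$acts[[i]], par[[paste0("conv", i, ".W")]],
                        cfg$kernel_sizes[i])
    grads[[paste0("conv", i, ".W")]] <- cb$dW
    grads[[paste0("conv", i, ".b")]] <- cb$db
    prev <- dact[[i]]
    dact[[i]] <- if (is.null(prev)) cb$dx else prev + cb$dx
  }
  list(grads = grads, dact = dact)
}

# ---- optimizers -----------------------------------------------------------

opt_init <- function(par, optimizer) {
  zeros <- lapply(par, function(p) p * 0) # shape-preserving zeros
  switch(optimizer,
         AdamW = list(m = zeros, v = zeros, t = 0L),
         Lion = list(m = zeros),
         stop(sprintf("unknown optimizer '%s'", optimizer), call. = FALSE))
}

# decoupled weight decay applies to weight matrices only, never to biases or
# batch-norm scales
decayed <- function(name) grepl("\\.W$", name)

opt_step <- function(par, grads, state, lr, weight_decay, optimizer, trainable) {
  if (optimizer == "AdamW") {
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    state$t <- state$t + 1L
    bc1 <- 1 - b1^state$t
    bc2 <- 1 - b2^state$t
    for (nm in names(par)) {
      if (!isTRUE(trainable[[nm]])) next
      g <- grads[[nm]]
      if (is.null(g)) next
      state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
      state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
      upd <- (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
      if (decayed(nm)) upd <- upd + weight_decay * par[[nm]]
      par[[nm]] <- par[[nm]] - lr * upd
    }
  } else { # Lion
    b1 <- 0.9; b2 <- 0.99
    for (nm in names(par)) {
      if (!isTRUE(trainable[[nm]])) next
      g <- grads[[nm]]
      if (is.null(g)) next
      upd <- sign(b1 * state$m[[nm]] + (1 - b1) * g)
      if (decayed(nm)) upd <- upd + weight_decay * par[[nm]]
      par[[nm]] <- par[[nm]] - lr * upd
      state$m[[nm]] <- b2 * state$m[[nm]] + (1 - b2) * g
    }
  }
  list(par = par, state = state)
}

# ---- losses ---------------------------------------------------------------

loss_value <- function(pred, y, loss, delta = 1) {
  r <- pred - y
  switch(loss,
         L1 = mean(abs(r)),
         MSE = mean(r * r),
         Huber = mean(ifelse(abs(r) <= delta, 0.5 * r * r,
                             delta * (abs(r) - 0.5 * delta))))
}

loss_grad <- function(pred, y, loss, delta = 1) {
  n <- length(y)
  r <- pred - y
  switch(loss,
         L1 = sign(r) / n,
         MSE = 2 * r / n,
         Huber = ifelse(abs(r) <= delta, r, delta * sign(r)) / n)
}

# batched eval-mode prediction on an encoded (L, n, c) array
nn_predict <- function(model, x, batch_size = 512L) {
  n <- dim(x)[2L]
  if (n == 0L) return(numeric(0))
  out <- numeric(n)
  starts <- seq(1L, n, by = batch_size)
  for (s in starts) {
    e <- min(s + batch_size - 1L, n)
    out[s:e] <- nn_forward(model, x[, s:e, , drop = FALSE])$pred
  }
  out
}

# encoded_batch (n, L, 1, c) -> engine layout (L, n, c)
batch_to_engine <- function(batch) {
  stopifnot(inherits(batch, "encoded_batch"))
  v <- batch$values
  d <- dim(v)
  dim(v) <- c(d[1L], d[2L], d[4L])
  aperm(v, c(2L, 1L, 3L))
}
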