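# Minimal reverse-mode neural network engine.
#
# Conventions:
#  * dense activations are (features x N) matrices;
#  * convolutional activations are (C, H, W, N) arrays, channel-first;
#  * modules are plain lists tagged with a `type`; parameters live in
#    `$params` as named numeric arrays, sub-modules in `$mods`;
#  * nn_forward() returns list(mod, out, cache) — `mod` is returned because
#    batch-norm updates its running statistics during training;
#  * nn_backward() returns list(dx, grads) with `grads` mirroring the flat
#    parameter naming of nn_params().
#
# Only what the architectures here require is implemented: linear, 2-d
# convolution (im2col/col2im in C++), batch normalization, ReLU, dropout,
# global average pooling, sequential containers and pre-activation-sum
# residual blocks.

kaiming_sd <- function(fan_in) sqrt(2 / fan_in)

nn_linear <- function(d_in, d_out, init_sd = NULL) {
  if (is.null(init_sd)) init_sd <- kaiming_sd(d_in)
  list(type = "linear",
       params = list(W = matrix(stats::rnorm(d_out * d_in, sd = init_sd), d_out, d_in),
                     b = numeric(d_out)))
}

nn_conv <- function(c_in, c_out, k, stride = 1, pad = (k - 1) %/% 2) {
  list(type = "conv", k = k, stride = stride, pad = pad, c_in = c_in,
       params = list(W = matrix(stats::rnorm(c_out * c_in * k * k,
                                             sd = kaiming_sd(c_in * k * k)),
                                c_out, c_in * k * k)))
}

nn_bn <- function(channels, gamma_init = 1, momentum = 0.1, eps = 1e-5) {
  list(type = "bn", momentum = momentum, eps = eps,
       params = list(gamma = rep(gamma_init, channels), beta = numeric(channels)),
       state = list(mean = numeric(channels), var = rep(1, channels)))
}

nn_relu <- function() list(type = "relu")
nn_dropout <- function(p) list(type = "dropout", p = p)
nn_gap <- function() list(type = "gap")

nn_seq <- function(...) list(type = "seq", mods = list(...))

# Residual block: branch conv-bn-relu-conv-bn with the final bn scale
# zero-initialized so the block is the identity (plus shortcut) at init;
# projection shortcut (1x1 conv + bn) when the shape changes.
nn_resblock <- function(c_in, c_out, stride = 1) {
  branch <- nn_seq(nn_conv(c_in, c_out, 3, stride), nn_bn(c_out), nn_relu(),
                   nn_conv(c_out, c_out, 3, 1), nn_bn(c_out, gamma_init = 0))
  shortcut <- NULL
  if (stride != 1 || c_in != c_out) {
    shortcut <- nn_seq(nn_conv(c_in, c_out, 1, stride, pad = 0), nn_bn(c_out))
  }
  list(type = "resblock", mods = list(branch = branch, shortcut = shortcut))
}

# ---- forward ---------------------------------------------------------------

nn_forward <- function(mod, x, training = FALSE) {
  switch(mod$type,
    linear = {
      out <- mod$params$W %*% x + mod$params$b
      list(mod = mod, out = out, cache = x)
    },
    conv = {
      d <- dim(x)  # (C, H, W, N)
      oH <- (d[2] + 2 * mod$pad - mod$k) %/% mod$stride + 1
      oW <- (d[3] + 2 * mod$pad - mod$k) %/% mod$stride + 1
      if (oH < 1 || oW < 1) {
        stop(sprintf("conv: input %dx%d too small for kernel %d stride %d",
                     d[2], d[3], mod$k, mod$stride), call. = FALSE)
      }
      cols <- im2col_cpp(as.numeric(x), d[1], d[2], d[3], d[4],
                         mod$k, mod$stride, mod$pad)
      out <- mod$params$W %*% cols
      dim(out) <- c(nrow(mod$params$W), oH, oW, d[4])
      list(mod = mod, out = out, cache = list(cols = cols, in_dim = d))
    },
    bn = {
      conv_in <- length(dim(x)) == 4
      Cc <- length(mod$params$gamma)
      xm <- if (conv_in) matrix(x, nrow = Cc) else x
      if (training) {
        mu <- rowMeans(xm)
        v <- rowMeans(xm^2) - mu^2
        mod$state$mean <- (1 - mod$momentum) * mod$state$mean + mod$momentum * mu
        mod$state$var <- (1 - mod$momentum) * mod$state$var + mod$momentum * v
      } else {
        mu <- mod$state$mean
        v <- mod$state$var
      }
      inv_std <- 1 / sqrt(v + mod$eps)
      xhat <- (xm - mu) * inv_std
      out <- mod$params$gamma * xhat + mod$params$beta
      if (conv_in) dim(out) <- dim(x)
      list(mod = mod, out = out,
           cache = list(xhat = xhat, inv_std = inv_std, dims = dim(x),
                        training = training))
    },
    relu = {
      out <- x * (x > 0)
      list(mod = mod, out = out, cache = x > 0)
    },
    dropout = {
      if (!training || mod$p == 0) {
        list(mod = mod, out = x, cache = NULL)
      } else {
        mask <- (stats::runif(length(x)) >= mod$p) / (1 - mod$p)
        dim(mask) <- dim(x)
        list(mod = mod, out = x * mask, cache = mask)
      }
    },
    gap = {
      d <- dim(x)  # (C, H, W, N)
      out <- matrix(0, d[1], d[4])
      xr <- array(x, c(d[1], d[2] * d[3], d[4]))
      for (n in seq_len(d[4])) out[, n] <- rowMeans(xr[, , n, drop = FALSE], dims = 1)
      list(mod = mod, out = out, cache = d)
    },
    seq = {
      caches <- vector("list", length(mod$mods))
      for (i in seq_along(mod$mods)) {
        f <- nn_forward(mod$mods[[i]], x, training)
        mod$mods[[i]] <- f$mod
        caches[[i]] <- f$cache
        x <- f$out
      }
      list(mod = mod, out = x, cache = caches)
    },
    resblock = {
      fb <- nn_forward(mod$mods$branch, x, training)
      mod$mods$branch <- fb$mod
      if (is.null(mod$mods$shortcut)) {
        sc <- x; sc_cache <- NULL
      } else {
        fs <- nn_forward(mod$mods$shortcut, x, training)
        mod$mods$shortcut <- fs$mod
        sc <- fs$out; sc_cache <- fs$cache
      }
      pre <- fb$out + sc
      out <- pre * (pre > 0)
      list(mod = mod, out = out,
           cache = list(branch = fb$cache, shortcut = sc_cache, mask = pre > 0))
    },
    stop("unknown module type: ", mod$type))
}

# ---- backward --------------------------------------------------------------

nn_backward <- function(mod, cache, dout) {
  switch(mod$type,
    linear = {
      list(dx = crossprod(mod$params$W, dout),
           grads = list(W = tcrossprod(dout, cache), b = rowSums(dout)))
    },
    conv = {
      d <- cache$in_dim
      od <- dim(dout)
      dmat <- matrix(dout, nrow = od[1])
      dW <- tcrossprod(dmat, cache$cols)
      dcols <- crossprod(mod$params$W, dmat)
      dx <- col2im_cpp(dcols, d[1], d[2], d[3], d[4], mod$k, mod$stride, mod$pad)
      dim(dx) <- d
      list(dx = dx, grads = list(W = dW))
    },
    bn = {
      dims <- cache$dims
      conv_in <- length(dims) == 4
      Cc <- length(mod$params$gamma)
      dm <- if (conv_in) matrix(dout, nrow = Cc) else dout
      xhat <- cache$xhat
      dgamma <- rowSums(dm * xhat)
      dbeta <- rowSums(dm)
      if (cache$training) {
        m <- ncol(dm)
        dx <- (mod$params$gamma * cache$inv_std / m) *
          (m * dm - dbeta - xhat * dgamma)
      } else {
        dx <- mod$params$gamma * cache$inv_std * dm
      }
      if (conv_in) dim(dx) <- dims
      list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
    },
    relu = list(dx = dout * cache, grads = NULL),
    dropout = {
      if (is.null(cache)) list(dx = dout, grads = NULL)
      else list(dx = dout * cache, grads = NULL)
    },
    gap = {
      d <- cache
      hw <- d[2] * d[3]
      dx <- array(0, d)
      dxr <- array(dx, c(d[1], hw, d[4]))
      for (n in seq_len(d[4])) dxr[, , n] <- dout[, n] / hw
      dim(dxr) <- d
      list(dx = dxr, grads = NULL)
    },
    seq = {
      grads <- vector("list", length(mod$mods))
      names(grads) <- as.character(seq_along(mod$mods))
      for (i in rev(seq_along(mod$mods))) {
        b <- nn_backward(mod$mods[[i]], cache[[i]], dout)
        grads[i] <- list(b$grads)  # plain [[<-]] would drop NULL entries
        dout <- b$dx
      }
      list(dx = dout, grads = grads)
    },
    resblock = {
      dpre <- dout * cache$mask
      bb <- nn_backward(mod$mods$branch, cache$branch, dpre)
      if (is.null(mod$mods$shortcut)) {
        dx <- bb$dx + dpre
        sgrads <- NULL
      } else {
        bs <- nn_backward(mod$mods$shortcut, cache$shortcut, dpre)
        dx <- bb$dx + bs$dx
        sgrads <- bs$grads
      }
      list(dx = dx, grads = list(branch = bb$grads, shortcut = sgrads))
    },
    stop("unknown module type: ", mod$type))
}

# ---- parameter flattening --------------------------------------------------

nn_params <- function(mod, prefix = "") {
  out <- list()
  if (!is.null(mod$params)) {
    for (nm in names(mod$params)) out[[paste0(prefix, nm)]] <- mod$params[[nm]]
  }
  if (!is.null(mod$mods)) {
    keys <- names(mod$mods)
    if (is.null(keys)) keys <- as.character(seq_along(mod$mods))
    for (i in seq_along(mod$mods)) {
      if (is.null(mod$mods[[i]])) next
      key <- if (nzchar(keys[i])) keys[i] else as.character(i)
      out <- c(out, nn_params(mod$mods[[i]], paste0(prefix, key, ".")))
    }
  }
  out
}

nn_set_params <- function(mod, flat, prefix = "") {
  if (!is.null(mod$params)) {
    for (nm in names(mod$params)) {
      key <- paste0(prefix, nm)
      if (!is.null(flat[[key]])) {
        p <- flat[[key]]
        dim(p) <- dim(mod$params[[nm]])
        mod$params[[nm]] <- p
      }
    }
  }
  if (!is.null(mod$mods)) {
    keys <- names(mod$mods)
    if (is.null(keys)) keys <- as.character(seq_along(mod$mods))
    for (i in seq_along(mod$mods)) {
      if (is.null(mod$mods[[i]])) next
      key <- if (nzchar(keys[i])) keys[i] else as.character(i)
      mod$mods[[i]] <- nn_set_params(mod$mods[[i]], flat, paste0(prefix, key, "."))
    }
  }
  mod
}

# Flatten the nested grads structure returned by nn_backward into the same
# naming scheme as nn_params.
nn_flatten_grads <- function(mod, grads, prefix = "") {
  out <- list()
  if (!is.null(mod$params) && !is.null(grads)) {
    for (nm in names(mod$params)) {
      if (!is.null(grads[[nm]])) out[[paste0(prefix, nm)]] <- grads[[nm]]
    }
  }
  if (!is.null(mod$mods)) {
    keys <- names(mod$mods)
    if (is.null(keys)) keys <- as.character(seq_along(mod$mods))
    for (i in seq_along(mod$mods)) {
      if (is.null(mod$mods[[i]])) next
      key <- if (nzchar(keys[i])) keys[i] else as.character(i)
      g <- if (is.null(grads)) NULL else grads[[i]]
      if (!is.null(names(grads)) && keys[i] %in% names(grads)) g <- grads[[keys[i]]]
      out <- c(out, nn_flatten_grads(mod$mods[[i]], g, paste0(prefix, key, ".")))
    }
  }
  out
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(param_names) {
  list(m = stats::setNames(vector("list", length(param_names)), param_names),
       v = stats::setNames(vector("list", length(param_names)), param_names),
       t = 0)
}

adam_step <- function(state, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(grads)) {
    g <- as.numeric(grads[[nm]])
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- numeric(length(g))
      state$v[[nm]] <- numeric(length(g))
    }
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    p <- params[[nm]]
    pd <- dim(p)
    p <- as.numeric(p) - lr * mhat / (sqrt(vhat) + eps)
    dim(p) <- pd
    params[[nm]] <- p
  }
  list(state = state, params = params)
}
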