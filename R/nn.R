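# Minimal 1D neural-network engine: convolution, batch normalization,
# GELU, max pooling, global average pooling and a dense head, with manual
# reverse-mode gradients and an Adam optimizer. Written directly on BLAS
# matrix products.
#
# Activations are carried as a matrix of shape (N * L, C): rows are time
# points grouped by sample (sample 1 rows first), columns are channels.
# Strided convolutions are computed as a sum over kernel offsets of
# row-gathered matrix products, which avoids materializing an im2col
# buffer larger than the activation itself.
#
# Layers are environments: parameters, gradients and optimizer moments are
# updated in place by the training loop.

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  for (nm in names(list(...))) assign(nm, list(...)[[nm]], envir = e)
  e
}

# He-normal initialized convolution; W stored as a list of k (Cin x Cout)
# matrices, one per kernel offset.
layer_conv <- function(k, cin, cout, stride = 1L, pad = (k - 1L) %/% 2L) {
  W <- lapply(seq_len(k), function(j)
    matrix(stats::rnorm(cin * cout, 0, sqrt(2 / (k * cin))), cin, cout))
  new_layer("conv", k = as.integer(k), cin = cin, cout = cout,
            stride = as.integer(stride), pad = as.integer(pad),
            W = W, b = numeric(cout))
}

layer_bn <- function(c, momentum = 0.1, eps = 1e-5) {
  new_layer("bn", c = c, gamma = rep(1, c), beta = numeric(c),
            rmean = numeric(c), rvar = rep(1, c),
            momentum = momentum, eps = eps)
}

layer_gelu <- function() new_layer("gelu")

layer_maxpool <- function(k = 3L, stride = 2L, pad = 1L)
  new_layer("maxpool", k = as.integer(k), stride = as.integer(stride),
            pad = as.integer(pad))

layer_gap <- function() new_layer("gap")

# Head initialized at zero so an untrained network outputs probability 0.5
# for every input.
layer_dense <- function(cin, cout = 1L)
  new_layer("dense", w = matrix(0, cin, cout), b = numeric(cout))

conv_out_len <- function(L, k, stride, pad) (L + 2L * pad - k) %/% stride + 1L

# Row indices of the padded activation matrix contributing to kernel
# offset j = 1 are base + 1, offset j -> base + j.
conv_base_idx <- function(N, Lp, Lout, stride) {
  rep((seq_len(N) - 1L) * Lp, each = Lout) +
    rep(seq.int(0L, by = stride, length.out = Lout), N)
}

pad_rows_idx <- function(N, L, pad) {
  rep((seq_len(N) - 1L) * (L + 2L * pad), each = L) + pad + seq_len(L)
}

conv_fwd <- function(ly, X, N, L) {
  Lp <- L + 2L * ly$pad
  if (ly$pad > 0L) {
    Xp <- matrix(0, N * Lp, ly$cin)
    Xp[pad_rows_idx(N, L, ly$pad), ] <- X
  } else Xp <- X
  Lout <- conv_out_len(L, ly$k, ly$stride, ly$pad)
  if (Lout < 1L) stop("configuration error: convolution reduces length below 1",
                      call. = FALSE)
  base <- conv_base_idx(N, Lp, Lout, ly$stride)
  Y <- matrix(ly$b, N * Lout, ly$cout, byrow = TRUE)
  for (j in seq_len(ly$k))
    Y <- Y + Xp[base + j, , drop = FALSE] %*% ly$W[[j]]
  list(Y = Y, L = Lout, cache = list(Xp = Xp, base = base, N = N, Lin = L))
}

conv_bwd <- function(ly, dY, cache) {
  k <- ly$k
  dXp <- matrix(0, nrow(cache$Xp), ly$cin)
  gW <- vector("list", k)
  for (j in seq_len(k)) {
    idx <- cache$base + j
    gW[[j]] <- crossprod(cache$Xp[idx, , drop = FALSE], dY)
    dXp[idx, ] <- dXp[idx, , drop = FALSE] + dY %*% t(ly$W[[j]])
  }
  ly$gW <- gW
  ly$gb <- colSums(dY)
  if (ly$pad > 0L)
    dXp[pad_rows_idx(cache$N, cache$Lin, ly$pad), , drop = FALSE]
  else dXp
}

bn_fwd <- function(ly, X, training) {
  if (training) {
    m <- colMeans(X)
    v <- colMeans(X * X) - m * m
    v[v < 0] <- 0
    ly$rmean <- (1 - ly$momentum) * ly$rmean + ly$momentum * m
    ly$rvar <- (1 - ly$momentum) * ly$rvar + ly$momentum * v
  } else {
    m <- ly$rmean
    v <- ly$rvar
  }
  invstd <- 1 / sqrt(v + ly$eps)
  xhat <- sweep(X, 2, m, "-")
  xhat <- sweep(xhat, 2, invstd, "*")
  Y <- sweep(xhat, 2, ly$gamma, "*")
  Y <- sweep(Y, 2, ly$beta, "+")
  list(Y = Y, cache = list(xhat = xhat, invstd = invstd))
}

bn_bwd <- function(ly, dY, cache) {
  R <- nrow(dY)
  dxhat <- sweep(dY, 2, ly$gamma, "*")
  ly$ggamma <- colSums(dY * cache$xhat)
  ly$gbeta <- colSums(dY)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dX <- R * dxhat
  dX <- sweep(dX, 2, s1, "-")
  dX <- dX - sweep(cache$xhat, 2, s2, "*")
  sweep(dX, 2, cache$invstd / R, "*")
}

gelu_fwd <- function(X) {
  Phi <- stats::pnorm(X)
  list(Y = X * Phi, cache = list(X = X, Phi = Phi))
}

gelu_bwd <- function(dY, cache)
  dY * (cache$Phi + cache$X * stats::dnorm(cache$X))

maxpool_fwd <- function(ly, X, N, L) {
  C <- ncol(X)
  Lp <- L + 2L * ly$pad
  Xp <- matrix(-Inf, N * Lp, C)
  Xp[pad_rows_idx(N, L, ly$pad), ] <- X
  Lout <- conv_out_len(L, ly$k, ly$stride, ly$pad)
  base <- conv_base_idx(N, Lp, Lout, ly$stride)
  Y <- Xp[base + 1L, , drop = FALSE]
  amax <- matrix(1L, nrow(Y), C)
  for (j in 2:ly$k) {
    Z <- Xp[base + j, , drop = FALSE]
    upd <- Z > Y
    Y[upd] <- Z[upd]
    amax[upd] <- j
  }
  list(Y = Y, L = Lout,
       cache = list(base = base, amax = amax, N = N, Lin = L, Lp = Lp))
}

maxpool_bwd <- function(ly, dY, cache) {
  C <- ncol(dY)
  dXp <- matrix(0, cache$N * cache$Lp, C)
  for (j in seq_len(ly$k)) {
    sel <- cache$amax == j
    if (!any(sel)) next
    idx <- cache$base + j
    blk <- dXp[idx, , drop = FALSE]
    blk[sel] <- blk[sel] + dY[sel]
    dXp[idx, ] <- blk
  }
  dXp[pad_rows_idx(cache$N, cache$Lin, ly$pad), , drop = FALSE]
}

gap_fwd <- function(X, N, L) {
  Y <- rowsum(X, rep(seq_len(N), each = L), reorder = FALSE) / L
  list(Y = Y, cache = list(N = N, L = L))
}

gap_bwd <- function(dY, cache)
  dY[rep(seq_len(cache$N), each = cache$L), , drop = FALSE] / cache$L

dense_fwd <- function(ly, X) list(Y = X %*% ly$w + ly$b[1], cache = list(X = X))

dense_bwd <- function(ly, dY, cache) {
  ly$gw <- crossprod(cache$X, dY)
  ly$gb <- colSums(dY)
  dY %*% t(ly$w)
}

# ---- graph traversal -------------------------------------------------------
# `layers` is a nested list: plain layer environments, or residual blocks
# represented as list(type = "block", main = <layers>, shortcut = <conv>).

seq_forward <- function(layers, X, N, L, training) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (is.list(ly) && identical(ly$type, "block")) {
      mn <- seq_forward(ly$main, X, N, L, training)
      sc <- conv_fwd(ly$shortcut, X, N, L)
      stopifnot(mn$L == sc$L, ncol(mn$Y) == ncol(sc$Y))
      X <- mn$Y + sc$Y
      L <- mn$L
      caches[[i]] <- list(main = mn$caches, shortcut = sc$cache)
    } else {
      r <- switch(ly$type,
        conv = conv_fwd(ly, X, N, L),
        bn = bn_fwd(ly, X, training),
        gelu = gelu_fwd(X),
        maxpool = maxpool_fwd(ly, X, N, L),
        gap = gap_fwd(X, N, L),
        dense = dense_fwd(ly, X),
        stop("unknown layer type ", ly$type))
      X <- r$Y
      if (!is.null(r$L)) L <- r$L
      if (identical(ly$type, "gap")) L <- 1L
      caches[[i]] <- r$cache
    }
  }
  list(Y = X, L = L, caches = caches)
}

seq_backward <- function(layers, dY, caches) {
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    if (is.list(ly) && identical(ly$type, "block")) {
      d_main <- seq_backward(ly$main, dY, caches[[i]]$main)
      d_sc <- conv_bwd(ly$shortcut, dY, caches[[i]]$shortcut)
      dY <- d_main + d_sc
    } else {
      dY <- switch(ly$type,
        conv = conv_bwd(ly, dY, caches[[i]]),
        bn = bn_bwd(ly, dY, caches[[i]]),
        gelu = gelu_bwd(dY, caches[[i]]),
        maxpool = maxpool_bwd(ly, dY, caches[[i]]),
        gap = gap_bwd(dY, caches[[i]]),
        dense = dense_bwd(ly, dY, caches[[i]]))
    }
  }
  invisible(dY)
}

# Flatten the nested layer structure into the list of parameterized layer
# environments (execution order; blocks contribute main then shortcut).
param_layers <- function(layers) {
  out <- list()
  for (ly in layers) {
    if (is.list(ly) && identical(ly$type, "block")) {
      out <- c(out, param_layers(ly$main), list(ly$shortcut))
    } else if (ly$type %in% c("conv", "bn", "dense")) {
      out <- c(out, list(ly))
    }
  }
  out
}

layer_param_names <- function(ly) switch(ly$type,
  conv = c("W", "b"), bn = c("gamma", "beta"), dense = c("w", "b"))

layer_grad_names <- function(ly) switch(ly$type,
  conv = c("gW", "gb"), bn = c("ggamma", "gbeta"), dense = c("gw", "gb"))

snapshot_params <- function(layers)
  lapply(param_layers(layers), function(ly)
    mget(c(layer_param_names(ly), if (ly$type == "bn") c("rmean", "rvar")),
         envir = ly))

restore_params <- function(layers, snap) {
  pls <- param_layers(layers)
  for (i in seq_along(pls))
    for (nm in names(snap[[i]])) assign(nm, snap[[i]][[nm]], envir = pls[[i]])
  invisible(NULL)
}

n_params <- function(layers)
  sum(vapply(param_layers(layers), function(ly)
    sum(vapply(mget(layer_param_names(ly), envir = ly),
               function(p) length(unlist(p)), 0)), 0))

# ---- Adam ------------------------------------------------------------------

adam_init <- function(layers) {
  for (ly in param_layers(layers)) {
    pn <- layer_param_names(ly)
    ly$m <- lapply(mget(pn, envir = ly), function(p)
      if (is.list(p)) lapply(p, function(q) q * 0) else p * 0)
    ly$v <- ly$m
    names(ly$m) <- pn
    names(ly$v) <- pn
  }
  invisible(NULL)
}

adam_step <- function(layers, lr, t, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  for (ly in param_layers(layers)) {
    pn <- layer_param_names(ly)
    gn <- layer_grad_names(ly)
    for (i in seq_along(pn)) {
      p <- get(pn[i], envir = ly)
      g <- get(gn[i], envir = ly)
      if (is.list(p)) {
        for (j in seq_along(p)) {
          r <- upd(p[[j]], g[[j]], ly$m[[pn[i]]][[j]], ly$v[[pn[i]]][[j]])
          p[[j]] <- r$p
          ly$m[[pn[i]]][[j]] <- r$m
          ly$v[[pn[i]]][[j]] <- r$v
        }
      } else {
        r <- upd(p, g, ly$m[[pn[i]]], ly$v[[pn[i]]])
        p <- r$p
        ly$m[[pn[i]]] <- r$m
        ly$v[[pn[i]]] <- r$v
      }
      assign(pn[i], p, envir = ly)
    }
  }
  invisible(NULL)
}
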