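# Modified 1D ResNet34 binary classifier for fixed-length RRI inputs.
#
# Architecture: a convolutional stem (single 1D convolution, batch
# normalization, GELU, max pooling), four stages of residual blocks with
# ResNet34 stage depths 3-4-6-3 by default, global average pooling and a
# single-logit head. Each residual block holds three 1D convolutions and
# two batch normalizations (conv3-BN-GELU-conv3-BN-GELU-conv1), with an
# additional kernel-size-1 convolution as the shortcut connection in every
# block; GELU replaces ReLU throughout and batch normalization precedes
# each activation. Note this three-convolution block is deliberately not
# the canonical two-convolution ResNet34 basic block.

#' Architecture specification for the 1D residual network
#'
#' @param input_len input length: 1200 (5-min segment at 4 Hz) or 240
#'   (1-min epoch). Other positive lengths are permitted for
#'   experimentation as long as the strides keep the temporal length >= 1.
#' @param stem list with `kernel`, `channels`, `stride`, `pool`
#'   (pool kernel), `pool_stride`.
#' @param stages list of `c(n_blocks, channels, stride)` triples; the
#'   stage's first block applies the stride and the channel change.
#'   Defaults to the ResNet34 stage plan (3,64,1), (4,128,2), (6,256,2),
#'   (3,512,2) — 16 residual blocks.
#' @return An object of class `resnet_spec`.
#' @examples
#' spec <- resnet_spec(input_len = 240)
#' sum(vapply(spec$stages, `[`, 0, 1)) # 16 blocks
#' @export
resnet_spec <- function(input_len = 1200,
                        stem = list(kernel = 7, channels = 64, stride = 2,
                                    pool = 3, pool_stride = 2),
                        stages = list(c(3, 64, 1), c(4, 128, 2),
                                      c(6, 256, 2), c(3, 512, 2))) {
  stopifnot(input_len >= 1, length(stages) >= 1)
  for (st in stages)
    if (length(st) != 3 || any(st < 1))
      stop("configuration error: each stage must be c(n_blocks, channels, stride)",
           call. = FALSE)
  # dry-run the temporal lengths so impossible stride plans fail at spec time
  L <- conv_out_len(as.integer(input_len), stem$kernel, stem$stride,
                    (stem$kernel - 1L) %/% 2L)
  L <- conv_out_len(L, stem$pool, stem$pool_stride, 1L)
  for (st in stages) L <- conv_out_len(L, 3L, as.integer(st[3]), 1L)
  if (L < 1)
    stop("configuration error: stage/stride plan reduces temporal length below 1",
         call. = FALSE)
  structure(list(input_len = as.integer(input_len), stem = stem,
                 stages = stages),
            class = "resnet_spec")
}

#' A reduced residual-network specification for quick experiments
#'
#' Same block structure as [resnet_spec()] but fewer, narrower stages —
#' suitable for desk-scale simulations and tests where the full 16-block
#' network is unnecessarily large.
#'
#' @param input_len input length (default 240).
#' @param width base channel width (doubled per stage).
#' @param blocks number of stages, one block each.
#' @return A `resnet_spec`.
#' @export
resnet_spec_small <- function(input_len = 240, width = 8, blocks = 3) {
  stages <- lapply(seq_len(blocks), function(i)
    c(1, width * 2^(i - 1), if (i == 1) 1 else 2))
  resnet_spec(input_len = input_len,
              stem = list(kernel = 7, channels = width, stride = 2,
                          pool = 3, pool_stride = 2),
              stages = stages)
}

residual_block <- function(cin, cout, stride) {
  list(type = "block",
       main = list(layer_conv(3L, cin, cout, stride = stride),
                   layer_bn(cout),
                   layer_gelu(),
                   layer_conv(3L, cout, cout),
                   layer_bn(cout),
                   layer_gelu(),
                   layer_conv(1L, cout, cout, pad = 0L)),
       shortcut = layer_conv(1L, cin, cout, stride = stride, pad = 0L))
}

#' Build a 1D residual network
#'
#' Instantiates the network described by a [resnet_spec()]: He-normal
#' convolution weights, unit-gamma batch norms, and a zero-initialized
#' single-logit head (so the untrained model outputs probability 0.5 for
#' any input). Deterministic given `seed`.
#'
#' @param spec a [resnet_spec()].
#' @param seed integer seed for weight initialization.
#' @return An object of class `resnet1d` with elements `spec`, `layers`,
#'   `n_blocks`, `n_params`.
#' @examples
#' m <- build_model(resnet_spec_small(240), seed = 1)
#' p <- predict(m, matrix(0, 4, 240))
#' all(p == 0.5)
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "resnet_spec"))
  with_seed(seed, {
    layers <- list()
    st <- spec$stem
    layers <- c(layers, list(
      layer_conv(as.integer(st$kernel), 1L, st$channels,
                 stride = as.integer(st$stride)),
      layer_bn(st$channels),
      layer_gelu(),
      layer_maxpool(as.integer(st$pool), as.integer(st$pool_stride), 1L)))
    cin <- st$channels
    n_blocks <- 0L
    for (stage in spec$stages) {
      nb <- stage[1]; cout <- stage[2]; stride <- stage[3]
      for (b in seq_len(nb)) {
        layers <- c(layers, list(residual_block(
          cin, cout, if (b == 1) as.integer(stride) else 1L)))
        cin <- cout
        n_blocks <- n_blocks + 1L
      }
    }
    layers <- c(layers, list(layer_gap(), layer_dense(cin)))
    structure(list(spec = spec, layers = layers, n_blocks = n_blocks,
                   n_params = n_params(layers)),
              class = "resnet1d")
  })
}

#' @export
print.resnet1d <- function(x, ...) {
  cat(sprintf("1D residual network: input length %d, %d residual blocks, %s parameters\n",
              x$spec$input_len, x$n_blocks,
              format(x$n_params, big.mark = ",")))
  widths <- vapply(x$spec$stages, `[`, 0, 2)
  cat("  stages (blocks x channels): ",
      paste(sprintf("%dx%d", vapply(x$spec$stages, `[`, 0, 1), widths),
            collapse = ", "), "\n", sep = "")
  if (!is.null(x$history))
    cat(sprintf("  trained: %d epochs, best validation loss %.4f\n",
                nrow(x$history), min(x$history$val_loss)))
  invisible(x)
}

# Forward pass over a segment matrix (rows = segments). Returns logits.
model_logits <- function(model, x, training = FALSE) {
  N <- nrow(x)
  L <- ncol(x)
  if (L != model$spec$input_len)
    stop(sprintf("input error: segments have length %d, model expects %d",
                 L, model$spec$input_len), call. = FALSE)
  X <- matrix(as.vector(t(x)), N * L, 1L) # (N*L, 1), time within sample
  r <- seq_forward(model$layers, X, N, L, training)
  list(logits = as.vector(r$Y), caches = r$caches, L = r$L)
}

#' Predict stress probabilities for a batch of segments
#'
#' @param object a trained or untrained `resnet1d`.
#' @param x matrix of segments, one row each, `ncol == input_len`.
#' @param batch_size forward-pass batch size.
#' @param ... unused.
#' @return Numeric vector of probabilities in (0, 1), one per row of `x`,
#'   order-preserving and deterministic given the weights.
#' @export
predict.resnet1d <- function(object, x, batch_size = 256L, ...) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  n <- nrow(x)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    z <- model_logits(object, x[i:j, , drop = FALSE], training = FALSE)$logits
    out[i:j] <- 1 / (1 + exp(-z))
    i <- j + 1L
  }
  out
}

#' Training configuration for the residual network
#'
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param epochs maximal number of epochs (>= 1).
#' @param patience early-stopping patience on the validation loss
#'   (must be < `epochs`).
#' @param seed seed for weight initialization fallback and minibatch
#'   shuffling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr = 1e-3, batch_size = 32L, epochs = 100L,
                         patience = 10L, seed = 1L) {
  stopifnot(epochs >= 1, patience < epochs, lr > 0, batch_size >= 1)
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = as.integer(patience),
                 seed = as.integer(seed)),
            class = "train_config")
}

bce_loss <- function(p, y) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Train a residual network with binary cross-entropy and early stopping
#'
#' Minibatch Adam on the training segments; after each epoch the
#' validation loss is computed (inference mode, running batch-norm
#' statistics) and the best-so-far weights are retained. Training stops
#' when the validation loss has not improved for `cfg$patience` epochs;
#' the returned model carries the best weights and a per-epoch loss
#' history. Training and validation sets must come from disjoint
#' participants (enforced by the cross-validation machinery upstream).
#'
#' @param model a `resnet1d` from [build_model()].
#' @param x,y training segments (matrix) and 0/1 labels.
#' @param val_x,val_y validation segments and labels.
#' @param cfg a [train_config()].
#' @param verbose print per-epoch losses.
#' @return The trained model with `history` (data.frame epoch,
#'   train_loss, val_loss) attached. The model's layer environments are
#'   updated in place.
#' @export
train_model <- function(model, x, y, val_x, val_y, cfg = train_config(),
                        verbose = FALSE) {
  stopifnot(inherits(model, "resnet1d"), inherits(cfg, "train_config"),
            nrow(x) == length(y), nrow(val_x) == length(val_y))
  adam_init(model$layers)
  n <- nrow(x)
  best_val <- Inf
  best_snap <- NULL
  wait <- 0L
  hist <- list()
  t_adam <- 0L
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      tr_loss <- 0
      nb <- 0L
      i <- 1L
      while (i <= n) {
        j <- min(i + cfg$batch_size - 1L, n)
        idx <- ord[i:j]
        fw <- model_logits(model, x[idx, , drop = FALSE], training = TRUE)
        p <- 1 / (1 + exp(-fw$logits))
        tr_loss <- tr_loss + bce_loss(p, y[idx])
        nb <- nb + 1L
        dz <- matrix((p - y[idx]) / length(idx), ncol = 1)
        seq_backward(model$layers, dz, fw$caches)
        t_adam <- t_adam + 1L
        adam_step(model$layers, cfg$lr, t_adam)
        i <- j + 1L
      }
      vp <- predict(model, val_x)
      v_loss <- bce_loss(vp, val_y)
      if (!is.finite(v_loss))
        stop("training aborted: validation loss is not finite", call. = FALSE)
      hist[[epoch]] <- data.frame(epoch = epoch, train_loss = tr_loss / nb,
                                  val_loss = v_loss)
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f", epoch,
                        tr_loss / nb, v_loss))
      if (v_loss < best_val - 1e-6) {
        best_val <- v_loss
        best_snap <- snapshot_params(model$layers)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
  })
  if (!is.null(best_snap)) restore_params(model$layers, best_snap)
  model$history <- do.call(rbind, hist)
  model
}
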