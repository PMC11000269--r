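# One-dimensional residual convolutional network for beat classification.
#
# The network maps a standardised beat segment (length input_len, one lead)
# to class probabilities over {N, PSVC, PVC}. Architecture: n_blocks residual
# blocks, each
#   conv(kernel_len, stride 1, same padding) -> batch norm -> ReLU ->
#   conv(kernel_len, stride 1, same padding) -> batch norm
# added to a 1x1-convolution projection of the block input; ReLU between
# blocks (and before pooling); then global average pooling over time and one
# fully connected layer to the class logits, softmax-normalised.
#
# Everything is implemented directly on BLAS matrix products: the time axis
# of a batch is unrolled into rows ((segment, t) pairs), a length-k
# convolution is an im2col gather followed by one matrix multiplication, and
# a 1x1 convolution is a plain matrix multiplication. Convolution biases are
# folded into the batch-norm shift.

#' Residual-network architecture specification
#'
#' @param input_len segment length in samples.
#' @param n_blocks number of residual blocks.
#' @param kernel_len convolution kernel length along time (odd).
#' @param stride convolution stride; only 1 is supported (stride 1 with same
#'   padding preserves the temporal length, which the residual addition
#'   requires).
#' @param channels channel width, constant across blocks.
#' @param n_classes number of output classes.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(input_len, n_blocks = 8, kernel_len = 3, stride = 1,
                       channels = 32, n_classes = 3) {
  if (n_blocks < 1) stop_config("n_blocks", "must be >= 1")
  if (kernel_len < 1 || kernel_len %% 2 != 1) stop_config("kernel_len", "must be odd and >= 1")
  if (stride != 1) stop_config("stride", "must be 1 (length-preserving blocks)")
  if (n_classes < 2) stop_config("n_classes", "must be >= 2")
  if (input_len < kernel_len) stop_config("input_len", "must be >= kernel_len")
  structure(list(input_len = as.integer(input_len), n_blocks = as.integer(n_blocks),
                 kernel_len = as.integer(kernel_len), stride = 1L,
                 channels = as.integer(channels), n_classes = as.integer(n_classes)),
            class = "model_spec")
}

he_init <- function(nr, nc, fan_in) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)

#' Build an untrained residual network
#'
#' @param spec a [model_spec()].
#' @param seed RNG seed for weight initialisation.
#' @return an object of class `resnet1d` (untrained).
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  with_seed(seed, {
    C <- spec$channels; k <- spec$kernel_len
    blocks <- vector("list", spec$n_blocks)
    for (i in seq_len(spec$n_blocks)) {
      cin <- if (i == 1) 1L else C
      # identity projection shortcut (where shapes allow): the batch-normed
      # residual branch adds unit variance per block, so activations grow
      # linearly with depth instead of exponentially, keeping the softmax
      # unsaturated at init
      Wsc <- if (cin == C) diag(C) else he_init(cin, C, cin)
      blocks[[i]] <- list(
        W1 = he_init(k * cin, C, k * cin), g1 = rep(1, C), b1 = rep(0, C),
        rm1 = rep(0, C), rv1 = rep(1, C),
        W2 = he_init(k * C, C, k * C), g2 = rep(1, C), b2 = rep(0, C),
        rm2 = rep(0, C), rv2 = rep(1, C),
        Wsc = Wsc)
    }
    structure(list(spec = spec,
                   params = list(blocks = blocks,
                                 Wfc = 0.1 * he_init(C, spec$n_classes, C),
                                 bfc = rep(0, spec$n_classes)),
                   trained = FALSE),
              class = "resnet1d")
  })
}

#' Enumerate the layers of a residual network
#'
#' Programmatic layer walk used to audit the architecture: for each block,
#' the five in-path layers (conv, batch norm, ReLU, conv, batch norm) plus
#' the 1x1 shortcut convolution, the inter-block ReLU, and the global average
#' pooling / fully connected head.
#'
#' @param model a `resnet1d`.
#' @return data frame with columns `block` (NA for head layers), `layer`,
#'   `type`, `kernel_len`, `in_channels`, `out_channels`.
#' @export
model_layers <- function(model) {
  stopifnot(inherits(model, "resnet1d"))
  s <- model$spec
  rows <- list()
  for (i in seq_len(s$n_blocks)) {
    cin <- if (i == 1) 1L else s$channels
    rows[[length(rows) + 1]] <- data.frame(
      block = i,
      layer = c("conv1", "bn1", "relu", "conv2", "bn2", "shortcut"),
      type = c("conv", "batch_norm", "relu", "conv", "batch_norm", "conv"),
      kernel_len = c(s$kernel_len, NA, NA, s$kernel_len, NA, 1L),
      in_channels = c(cin, s$channels, s$channels, s$channels, s$channels, cin),
      out_channels = rep(s$channels, 6))
    if (i < s$n_blocks) {
      rows[[length(rows) + 1]] <- data.frame(
        block = i, layer = "inter_block_relu", type = "relu",
        kernel_len = NA, in_channels = s$channels, out_channels = s$channels)
    }
  }
  rows[[length(rows) + 1]] <- data.frame(
    block = NA, layer = c("pre_pool_relu", "global_average_pooling", "fully_connected", "softmax"),
    type = c("relu", "gap", "dense", "softmax"),
    kernel_len = NA,
    in_channels = s$channels,
    out_channels = c(s$channels, s$channels, s$n_classes, s$n_classes))
  do.call(rbind, rows)
}

# fast column-major broadcast of a per-channel vector over R rows
brep <- function(v, R) rep.int(v, rep.int(R, length(v)))

# Per-batch row layout: rows of the unrolled (N*L) x C activations are
# grouped by segment. A same-padded convolution shifts rows within each
# segment; in column-major storage that is a shift of the whole data vector
# by `off`, provided the entries whose source falls outside the segment (the
# first/last `off` rows of every segment, in every channel column) are
# zeroed. Those fix-up positions are precomputed here.
make_layout <- function(N, L, k, C) {
  half <- (k - 1L) %/% 2L
  R <- N * L
  pos <- rep.int(seq_len(L), N)
  colbase <- (seq_len(C) - 1L) * R
  lay <- list(R = R, N = N, L = L, C = C, half = half,
              inv_lo = vector("list", max(half, 1)),
              inv_hi = vector("list", max(half, 1)))
  for (off in seq_len(half)) {
    rows_lo <- which(pos <= off)            # source row r-off leaves the segment
    rows_hi <- which(pos > L - off)         # source row r+off leaves the segment
    lay$inv_lo[[off]] <- as.integer(outer(rows_lo, colbase, "+"))
    lay$inv_hi[[off]] <- as.integer(outer(rows_hi, colbase, "+"))
  }
  lay
}

w_block <- function(W, cin, j) W[((j - 1L) * cin + 1L):(j * cin), , drop = FALSE]

# stacked ((k*cin) x C) weights -> wide (cin x (k*C)), optionally folding a
# per-output-channel scale (inference batch norm)
widen_weights <- function(W, cin, C, k, scale = NULL) {
  Ww <- do.call(cbind, lapply(seq_len(k), function(j) w_block(W, cin, j)))
  if (!is.null(scale)) Ww <- Ww * rep.int(brep(scale, cin), k)
  Ww
}

# length-k same-padded convolution along time: one wide matmul plus a fused
# compiled tap combination; optional per-output-channel affine (folded
# batch norm) and fused ReLU
conv1d_fwd <- function(H, W, cin, C, k, lay, bias = NULL, scale = NULL,
                       relu = FALSE) {
  M <- H %*% widen_weights(W, cin, C, k, scale)
  conv_combine(M, C, lay$L, bias, relu)
}

# adjoint: gradients w.r.t. the stacked weights and the conv input.
# D_j = dZ shifted by -o_j (zeroed outside segments); dW_j = H^T D_j;
# dH = sum_j D_j W_j^T.
conv1d_bwd <- function(H, dZ, W, cin, C, k, lay) {
  half <- lay$half
  dW <- matrix(0, k * cin, C)
  ctr <- half * cin
  dW[(ctr + 1L):(ctr + cin), ] <- crossprod(H, dZ)
  dH <- dZ %*% t(w_block(W, cin, half + 1L))
  for (off in seq_len(half)) {
    Da <- shift_zero_cpp(dZ, -off, lay$inv_hi[[off]])  # tap -off: D[r] = dZ[r+off]
    a <- (half - off) * cin
    dW[(a + 1L):(a + cin), ] <- crossprod(H, Da)
    add_inplace(dH, Da %*% t(w_block(W, cin, half + 1L - off)), FALSE)
    Db <- shift_zero_cpp(dZ, off, lay$inv_lo[[off]])   # tap +off: D[r] = dZ[r-off]
    b <- (half + off) * cin
    dW[(b + 1L):(b + cin), ] <- crossprod(H, Db)
    add_inplace(dH, Db %*% t(w_block(W, cin, half + 1L + off)), FALSE)
  }
  list(dW = dW, dH = dH)
}

bn_forward <- function(Z, gamma, beta, rm, rv, training, eps = 1e-5) {
  R <- nrow(Z)
  if (training) {
    m <- .colMeans(Z, R, ncol(Z))
    v <- .colMeans(Z * Z, R, ncol(Z)) - m^2
    v[v < 0] <- 0
  } else {
    m <- rm; v <- rv
  }
  ivar <- 1 / sqrt(v + eps)
  ba <- bn_apply(Z, m, ivar, gamma, beta)
  list(out = ba$out, xhat = ba$xhat, ivar = ivar, m = m, v = v)
}

# With dxhat = dY * gamma, the batch-statistic terms reduce to
# mean(dxhat) = gamma * dbeta / R and mean(dxhat * xhat) = gamma * dgamma / R,
# so the standard batch-norm backward needs only the two weight reductions.
bn_backward <- function(dY, xhat, ivar, gamma) {
  R <- nrow(dY)
  C <- ncol(dY)
  dgamma <- .colSums(dY * xhat, R, C)
  dbeta <- .colSums(dY, R, C)
  dZ <- col_affine(dY, gamma * ivar, -(gamma * dbeta * ivar) / R)
  add_inplace(dZ, col_affine(xhat, -(gamma * dgamma * ivar) / R, numeric(C)), FALSE)
  list(dZ = dZ, dgamma = dgamma, dbeta = dbeta)
}

softmax <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Forward pass. X: N x input_len matrix of standardised segments.
# Returns probs (N x n_classes); with cache = TRUE also everything the
# backward pass needs; training = TRUE uses batch statistics and returns
# updated running moments.
rn_forward <- function(model, X, training = FALSE, cache = FALSE, momentum = 0.1) {
  s <- model$spec
  N <- nrow(X); L <- s$input_len; k <- s$kernel_len; C <- s$channels
  stopifnot(ncol(X) == L)
  H <- matrix(as.vector(t(X)), ncol = 1)   # (N*L) x 1, time-major per segment
  lay <- make_layout(N, L, k, C)
  caches <- if (cache) vector("list", s$n_blocks) else NULL
  new_stats <- if (training) vector("list", s$n_blocks) else NULL
  eps <- 1e-5
  for (i in seq_len(s$n_blocks)) {
    p <- model$params$blocks[[i]]
    cin <- if (i == 1) 1L else C
    Hin <- H
    if (!training && !cache) {
      # inference fast path: fold batch norm (running moments) into the conv
      sc1 <- p$g1 / sqrt(p$rv1 + eps); bi1 <- p$b1 - p$rm1 * sc1
      sc2 <- p$g2 / sqrt(p$rv2 + eps); bi2 <- p$b2 - p$rm2 * sc2
      A1 <- conv1d_fwd(Hin, p$W1, cin, C, k, lay, bias = bi1, scale = sc1,
                       relu = TRUE)
      pre <- conv1d_fwd(A1, p$W2, C, C, k, lay, bias = bi2, scale = sc2)
      add_inplace(pre, Hin %*% p$Wsc, TRUE)
      H <- pre
    } else {
      Z1 <- conv1d_fwd(Hin, p$W1, cin, C, k, lay)
      bn1 <- bn_forward(Z1, p$g1, p$b1, p$rm1, p$rv1, training)
      A1 <- bn1$out
      bias_relu_inplace(A1, NULL, TRUE)
      Z2 <- conv1d_fwd(A1, p$W2, C, C, k, lay)
      bn2 <- bn_forward(Z2, p$g2, p$b2, p$rm2, p$rv2, training)
      pre <- bn2$out
      add_inplace(pre, Hin %*% p$Wsc, TRUE)     # residual join + ReLU
      H <- pre
      if (cache) {
        caches[[i]] <- list(Hin = Hin, xhat1 = bn1$xhat, ivar1 = bn1$ivar,
                            A1 = A1, xhat2 = bn2$xhat, ivar2 = bn2$ivar)
      }
      if (training) {
        new_stats[[i]] <- list(
          rm1 = (1 - momentum) * p$rm1 + momentum * bn1$m,
          rv1 = (1 - momentum) * p$rv1 + momentum * bn1$v,
          rm2 = (1 - momentum) * p$rm2 + momentum * bn2$m,
          rv2 = (1 - momentum) * p$rv2 + momentum * bn2$v)
      }
    }
  }
  seg_id <- rep(seq_len(N), each = L)
  G <- rowsum(H, seg_id, reorder = FALSE) / L
  logits <- G %*% model$params$Wfc + brep(model$params$bfc, N)
  probs <- softmax(logits)
  res <- list(probs = probs, feature_len = L, layout = lay)
  if (cache) { res$caches <- caches; res$G <- G; res$Hlast <- H }
  if (training) res$new_stats <- new_stats
  res
}

# Backward pass: gradients of mean cross-entropy w.r.t. all parameters.
# y_onehot: N x n_classes.
rn_backward <- function(model, fw, y_onehot) {
  s <- model$spec
  N <- nrow(y_onehot); L <- s$input_len; k <- s$kernel_len; C <- s$channels
  dlogits <- (fw$probs - y_onehot) / N
  grads <- list(blocks = vector("list", s$n_blocks),
                Wfc = crossprod(fw$G, dlogits),
                bfc = colSums(dlogits))
  dG <- dlogits %*% t(model$params$Wfc)
  seg_id <- rep(seq_len(N), each = L)
  dH <- dG[seg_id, , drop = FALSE] / L
  lay <- fw$layout
  for (i in rev(seq_len(s$n_blocks))) {
    p <- model$params$blocks[[i]]
    cin <- if (i == 1) 1L else C
    cc <- fw$caches[[i]]
    Hout <- if (i == s$n_blocks) fw$Hlast else fw$caches[[i + 1]]$Hin
    dpre <- relu_bwd(dH, Hout)
    bb2 <- bn_backward(dpre, cc$xhat2, cc$ivar2, p$g2)
    cv2 <- conv1d_bwd(cc$A1, bb2$dZ, p$W2, C, C, k, lay)
    dBN1 <- relu_bwd(cv2$dH, cc$A1)
    bb1 <- bn_backward(dBN1, cc$xhat1, cc$ivar1, p$g1)
    cv1 <- conv1d_bwd(cc$Hin, bb1$dZ, p$W1, cin, C, k, lay)
    dWsc <- crossprod(cc$Hin, dpre)
    grads$blocks[[i]] <- list(W1 = cv1$dW, g1 = bb1$dgamma, b1 = bb1$dbeta,
                              W2 = cv2$dW, g2 = bb2$dgamma, b2 = bb2$dbeta,
                              Wsc = dWsc)
    if (i > 1) {
      dH <- cv1$dH + dpre %*% t(p$Wsc)
    }
  }
  grads
}

trainable_names <- c("W1", "g1", "b1", "W2", "g2", "b2", "Wsc")

adam_init <- function(params) {
  zero_like <- function(x) if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else rep(0, length(x))
  list(blocks = lapply(params$blocks, function(b) lapply(b[trainable_names], zero_like)),
       Wfc = zero_like(params$Wfc), bfc = zero_like(params$bfc))
}

adam_step <- function(params, grads, m, v, t, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  upd <- function(p, g, mm, vv) {
    mm <- beta1 * mm + (1 - beta1) * g
    vv <- beta2 * vv + (1 - beta2) * g * g
    mh <- mm / (1 - beta1^t)
    vh <- vv / (1 - beta2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = mm, v = vv)
  }
  for (i in seq_along(params$blocks)) {
    for (nm in trainable_names) {
      u <- upd(params$blocks[[i]][[nm]], grads$blocks[[i]][[nm]],
               m$blocks[[i]][[nm]], v$blocks[[i]][[nm]])
      params$blocks[[i]][[nm]] <- u$p
      m$blocks[[i]][[nm]] <- u$m
      v$blocks[[i]][[nm]] <- u$v
    }
  }
  u <- upd(params$Wfc, grads$Wfc, m$Wfc, v$Wfc)
  params$Wfc <- u$p; m$Wfc <- u$m; v$Wfc <- u$v
  u <- upd(params$bfc, grads$bfc, m$bfc, v$bfc)
  params$bfc <- u$p; m$bfc <- u$m; v$bfc <- u$v
  list(params = params, m = m, v = v)
}

#' Patient-disjoint dataset split
#'
#' Splits patients (not beats) into train/validation/test sets in the given
#' ratio; no patient appears in more than one split. Deterministic under
#' `seed`.
#'
#' @param patients vector of patient identifiers (one per beat, or unique).
#' @param ratio length-3 positive weights, default `c(8, 1, 1)`.
#' @param seed RNG seed.
#' @return list with character vectors `train`, `val`, `test` of patient ids.
#' @export
split_by_patient <- function(patients, ratio = c(8, 1, 1), seed = 1L) {
  ids <- unique(as.character(patients))
  n <- length(ids)
  if (n < 3) stop("split_by_patient: need at least 3 patients")
  stopifnot(length(ratio) == 3, all(ratio > 0))
  w <- ratio / sum(ratio)
  n_val <- max(1L, round(n * w[2]))
  n_test <- max(1L, round(n * w[3]))
  if (n - n_val - n_test < 1) stop("split_by_patient: ratio leaves no training patients")
  perm <- with_seed(seed, sample(ids))
  list(train = sort(perm[seq_len(n - n_val - n_test)]),
       val = sort(perm[(n - n_val - n_test + 1):(n - n_test)]),
       test = sort(perm[(n - n_test + 1):n]))
}

eval_loss_acc <- function(model, X, y_idx, chunk = 512) {
  n <- nrow(X)
  loss <- 0; correct <- 0
  for (a in seq(1, n, by = chunk)) {
    b <- min(n, a + chunk - 1)
    fw <- rn_forward(model, X[a:b, , drop = FALSE], training = FALSE)
    p <- fw$probs
    pi <- p[cbind(seq_len(nrow(p)), y_idx[a:b])]
    loss <- loss + sum(-log(pmax(pi, 1e-12)))
    correct <- correct + sum(max.col(p, ties.method = "first") == y_idx[a:b])
  }
  c(loss = loss / n, acc = correct / n)
}

#' Fit the residual-network beat classifier
#'
#' Trains the residual convolutional network on labelled beat segments with
#' the Adam optimiser and categorical cross-entropy. When `patient` is
#' supplied, patients are split 8:1:1 (train/validation/test) with no patient
#' overlap, per-epoch validation loss is tracked, and the parameters with the
#' best validation loss are retained; without `patient`, all beats are used
#' for training and validation is computed on the training set.
#'
#' @param x a [segment_beats()] result or a numeric matrix (one standardised
#'   segment per row).
#' @param labels beat labels, one per segment, from
#'   `c("N", "PSVC", "PVC")` (or any label set matching `spec$n_classes`;
#'   `"N"` is always ordered first so probability ties resolve to it).
#' @param patient optional patient identifier per segment for the
#'   patient-disjoint split.
#' @param spec a [model_spec()]; default: 8 blocks, kernel 3, 32 channels.
#' @param split_ratio train/val/test weights when `patient` is given.
#' @param epochs,batch_size,learning_rate optimiser settings.
#' @param seed RNG seed (initialisation and batch shuffling).
#' @param verbose print per-epoch progress.
#' @return an object of class `beat_classifier` with elements `spec`,
#'   `params`, `class_order`, `history` (per-epoch losses/accuracies),
#'   `split` (patient ids per split, if any).
#' @export
beat_classifier <- function(x, labels, patient = NULL, spec = NULL,
                            split_ratio = c(8, 1, 1), epochs = 20,
                            batch_size = 128, learning_rate = 1e-3,
                            seed = 1L, verbose = FALSE) {
  X <- if (inherits(x, "beat_segments")) x$segments else as.matrix(x)
  labels <- as.character(labels)
  stopifnot(nrow(X) == length(labels))
  lvl <- unique(labels)
  class_order <- c(intersect("N", lvl), sort(setdiff(lvl, "N")))
  if (is.null(spec)) spec <- model_spec(input_len = ncol(X), n_classes = length(class_order))
  if (spec$n_classes != length(class_order)) {
    stop(sprintf("beat_classifier: spec has %d classes but data has %d",
                 spec$n_classes, length(class_order)))
  }
  if (ncol(X) != spec$input_len) {
    stop(sprintf("beat_classifier: segment length %d != spec$input_len %d",
                 ncol(X), spec$input_len))
  }
  y_idx <- match(labels, class_order)

  split <- NULL
  tr <- seq_len(nrow(X)); va <- tr
  if (!is.null(patient)) {
    stopifnot(length(patient) == length(labels))
    split <- split_by_patient(patient, split_ratio, seed = seed)
    tr <- which(patient %in% split$train)
    va <- which(patient %in% split$val)
    stopifnot(length(intersect(split$train, split$val)) == 0,
              length(intersect(split$train, split$test)) == 0,
              length(intersect(split$val, split$test)) == 0)
  }
  missing_cls <- setdiff(class_order, labels[tr])
  if (length(missing_cls)) {
    stop("beat_classifier: class(es) absent from training set: ",
         paste(missing_cls, collapse = ", "))
  }

  model <- build_model(spec, seed = seed)
  m <- adam_init(model$params); v <- adam_init(model$params)
  step <- 0L
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0), train_acc = numeric(0),
                     val_acc = numeric(0))
  best <- list(loss = Inf, params = model$params)
  with_seed(sub_seed(seed, 271L), {
    for (ep in seq_len(epochs)) {
      ord <- sample(tr)
      for (a in seq(1, length(ord), by = batch_size)) {
        b <- min(length(ord), a + batch_size - 1)
        if (b - a < 1) next               # BN needs >= 2 rows
        bi <- ord[a:b]
        fw <- rn_forward(model, X[bi, , drop = FALSE], training = TRUE, cache = TRUE)
        Y <- matrix(0, length(bi), spec$n_classes)
        Y[cbind(seq_along(bi), y_idx[bi])] <- 1
        grads <- rn_backward(model, fw, Y)
        step <- step + 1L
        st <- adam_step(model$params, grads, m, v, step, learning_rate)
        model$params <- st$params; m <- st$m; v <- st$v
        for (i in seq_len(spec$n_blocks)) {
          model$params$blocks[[i]][c("rm1", "rv1", "rm2", "rv2")] <- fw$new_stats[[i]]
        }
      }
      trm <- eval_loss_acc(model, X[tr, , drop = FALSE], y_idx[tr])
      vam <- eval_loss_acc(model, X[va, , drop = FALSE], y_idx[va])
      hist[ep, ] <- list(ep, trm["loss"], vam["loss"], trm["acc"], vam["acc"])
      if (vam["loss"] < best$loss) best <- list(loss = vam["loss"], params = model$params)
      if (verbose) {
        message(sprintf("epoch %3d  train loss %.4f acc %.4f | val loss %.4f acc %.4f",
                        ep, trm["loss"], trm["acc"], vam["loss"], vam["acc"]))
      }
    }
  })
  model$params <- best$params
  structure(list(spec = spec, params = model$params, class_order = class_order,
                 history = hist, split = split, trained = TRUE,
                 best_val_loss = best$loss,
                 control = list(epochs = epochs, batch_size = batch_size,
                                learning_rate = learning_rate, seed = seed)),
            class = c("beat_classifier", "resnet1d"))
}

#' Classify beat segments
#'
#' @param object a fitted [beat_classifier()].
#' @param newdata a [segment_beats()] result or segment matrix; segment
#'   length must equal `object$spec$input_len`.
#' @param type `"class"` for argmax labels (probability ties resolve to
#'   `"N"`), `"prob"` for the probability matrix.
#' @param ... unused.
#' @return character vector of labels, or an `n x n_classes` probability
#'   matrix with one row per segment (rows sum to 1).
#' @export
predict.beat_classifier <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "beat_segments")) newdata$segments else as.matrix(newdata)
  if (nrow(X) == 0) {
    if (type == "prob") {
      return(matrix(numeric(0), 0, object$spec$n_classes,
                    dimnames = list(NULL, object$class_order)))
    }
    return(character(0))
  }
  if (ncol(X) != object$spec$input_len) {
    stop(sprintf("predict: segment length %d != model input_len %d",
                 ncol(X), object$spec$input_len))
  }
  n <- nrow(X)
  chunk <- max(1L, 45000L %/% object$spec$input_len)
  P <- matrix(NA_real_, n, object$spec$n_classes,
              dimnames = list(NULL, object$class_order))
  for (a in seq(1, n, by = chunk)) {
    b <- min(n, a + chunk - 1)
    P[a:b, ] <- rn_forward(object, X[a:b, , drop = FALSE], training = FALSE)$probs
  }
  if (type == "prob") return(P)
  object$class_order[max.col(P, ties.method = "first")]
}

#' @rdname predict.beat_classifier
#' @param model a fitted [beat_classifier()].
#' @param segments segments to classify.
#' @return `classify_beats()` returns a list with `prob` (probability
#'   matrix) and `label` (argmax labels, ties to `"N"`).
#' @export
classify_beats <- function(model, segments) {
  P <- predict(model, segments, type = "prob")
  lab <- if (nrow(P)) model$class_order[max.col(P, ties.method = "first")] else character(0)
  list(prob = P, label = lab)
}

#' @export
print.beat_classifier <- function(x, ...) {
  s <- x$spec
  cat(sprintf("Residual CNN beat classifier: %d block(s), kernel %d, %d channels, %d classes\n",
              s$n_blocks, s$kernel_len, s$channels, s$n_classes))
  cat(sprintf("Input length: %d samples; classes: %s\n",
              s$input_len, paste(x$class_order, collapse = ", ")))
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("Trained %d epoch(s); final train acc %.3f, val acc %.3f (best val loss %.4f)\n",
                nrow(x$history), last$train_acc, last$val_acc, x$best_val_loss))
  }
  invisible(x)
}

#' @export
summary.beat_classifier <- function(object, ...) {
  print(object)
  lay <- model_layers(object)
  n_par <- sum(vapply(object$params$blocks, function(b) {
    sum(vapply(b[trainable_names], length, numeric(1)))
  }, numeric(1))) + length(object$params$Wfc) + length(object$params$bfc)
  cat(sprintf("Layers: %d (%d conv, %d batch-norm); trainable parameters: %d\n",
              nrow(lay), sum(lay$type == "conv"), sum(lay$type == "batch_norm"),
              as.integer(n_par)))
  invisible(lay)
}

#' @export
plot.beat_classifier <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) stop("no training history to plot")
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("black", "firebrick"),
                    xlab = "epoch", ylab = "cross-entropy loss", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("black", "firebrick"), bty = "n")
  invisible(x)
}

#' @export
coef.beat_classifier <- function(object, ...) object$params
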