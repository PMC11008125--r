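# 17-layer convolutional network for two-class (nonsickled/sickled) cell
# patch classification. Layer order: C1 P2 C3 P4 D5 C6 P7 D8 C9 P10 D11
# C12 P13 D14 F15 FC16 D17, softmax output. Convolutions are 3x3 stride 1
# same-padded; pooling is 2x2 max; dropout probability 0.001; ReLU
# activations; categorical cross-entropy loss; Adam optimizer.
#
# Implemented directly on BLAS GEMM with compiled im2col/col2im gathers.
# Activations are arrays (H, W, C, N); the im2col row order is sample-major,
# then column, then row.

#' Architecture description of the 17-layer classifier
#'
#' @param filters number of kernels in each of the 5 convolutional layers
#'   (unspecified in the assay description; the default widens monotonically
#'   and keeps the model CPU-trainable).
#' @param dropout dropout probability (default 0.001).
#' @param n_classes number of output classes.
#' @return list of class `cnn_architecture`.
#' @export
cnn_architecture <- function(filters = c(16, 32, 64, 128, 128),
                             dropout = 0.001, n_classes = 2) {
  if (length(filters) != 5) stopf("exactly 5 convolutional layers are required")
  structure(list(filters = as.integer(filters), kernel = c(3L, 3L),
                 pool = c(2L, 2L), dropout = dropout,
                 n_classes = as.integer(n_classes)),
            class = "cnn_architecture")
}

#' Build the 17-layer CNN
#'
#' @param arch a [cnn_architecture()].
#' @param input_size input patch side in pixels; must be divisible by 32
#'   (the five 2x2 poolings).
#' @param n_fused number of scalar shape factors concatenated to the
#'   flattened features before the fully connected layer (0 = image-only
#'   model; 4 for the shape-factor fusion variant).
#' @param seed weight initialization seed (He initialization).
#' @return object of class `sickle_cnn`.
#' @export
build_cnn <- function(arch = cnn_architecture(), input_size = 64,
                      n_fused = 0L, seed = 1L) {
  if (input_size %% 32 != 0)
    stopf("input_size must be divisible by 2^5 = 32 (got %d)", input_size)
  f <- arch$filters
  cin <- c(1L, f[-5])
  sp <- input_size / 32
  d_flat <- as.integer(sp * sp * f[5])
  with_seed(seed, {
    conv <- lapply(1:5, function(l) {
      fan_in <- 9 * cin[l]
      list(W = matrix(rnorm(9 * cin[l] * f[l], 0, sqrt(2 / fan_in)),
                      9 * cin[l], f[l]),
           b = rep(0, f[l]))
    })
    fc <- list(W = matrix(rnorm((d_flat + n_fused) * arch$n_classes, 0,
                                sqrt(2 / (d_flat + n_fused))),
                          d_flat + n_fused, arch$n_classes),
               b = rep(0, arch$n_classes))
  })
  structure(list(arch = arch, input_size = as.integer(input_size),
                 conv = conv, fc = fc, n_fused = as.integer(n_fused),
                 d_flat = d_flat, factor_center = rep(0, n_fused),
                 factor_scale = rep(1, n_fused)),
            class = "sickle_cnn")
}

#' Layer-kind sequence of the model
#'
#' Introspection of the 17-layer order (dropout sits after the second
#' through fifth pooling layers, after the fully connected output, and
#' nowhere else).
#'
#' @param model a `sickle_cnn`.
#' @return character vector of length 17.
#' @export
layer_kinds <- function(model) {
  c("conv", "pool",
    "conv", "pool", "dropout",
    "conv", "pool", "dropout",
    "conv", "pool", "dropout",
    "conv", "pool", "dropout",
    "flatten", "fc", "dropout")
}

#' @rdname layer_kinds
#' @export
fc_input_length <- function(model) nrow(model$fc$W)

#' @export
print.sickle_cnn <- function(x, ...) {
  cat("17-layer CNN, input", x$input_size, "x", x$input_size,
      "| filters:", paste(x$arch$filters, collapse = "/"),
      "| flattened:", x$d_flat,
      if (x$n_fused > 0) sprintf("+ %d fused factors", x$n_fused) else "", "\n")
  invisible(x)
}

scale_factors <- function(model, factors) {
  if (model$n_fused == 0L) return(NULL)
  if (is.null(factors)) stopf("this model requires %d fused shape factors", model$n_fused)
  factors <- as.matrix(factors)
  if (ncol(factors) != model$n_fused || any(!is.finite(factors)))
    stopf("fused factors must be a finite matrix with %d columns", model$n_fused)
  sweep(sweep(factors, 2, model$factor_center), 2, model$factor_scale, "/")
}

cnn_forward <- function(model, X, train = FALSE, factors = NULL,
                        keep_cache = FALSE) {
  d <- dim(X)
  N <- d[length(d)]
  h <- d[1]; w <- d[2]
  M <- matrix(as.vector(X), h * w * N, 1)   # (i, j, n)-ordered rows
  p <- model$arch$dropout
  caches <- if (keep_cache) vector("list", 5) else NULL
  cin <- 1L
  for (l in 1:5) {
    co <- model$arch$filters[l]
    P <- im2col_pad(M, h, w, cin, N)
    Z <- P %*% model$conv[[l]]$W
    bias_relu_inplace(Z, model$conv[[l]]$b)
    pl <- maxpool_m(Z, h, w, co, N)
    M <- pl$A
    dm <- NULL
    if (l >= 2 && train) {                 # dropout after pools 2..5
      dm <- matrix((runif(length(M)) >= p) / (1 - p), nrow(M))
      M <- M * dm
    }
    if (keep_cache)
      caches[[l]] <- list(P = P, Z = Z, win = pl$win, h = h, w = w,
                          cin = cin, drop = dm)
    h <- h %/% 2L; w <- w %/% 2L
    cin <- co
  }
  A <- array(M, c(h, w, N, cin))
  Fm <- t(matrix(aperm(A, c(1, 2, 4, 3)), h * w * cin, N))
  if (model$n_fused > 0L) Fm <- cbind(Fm, scale_factors(model, factors))
  Z <- Fm %*% model$fc$W
  Z <- Z + rep(model$fc$b, each = N)
  dm17 <- NULL
  if (train) {
    dm17 <- matrix((runif(length(Z)) >= p) / (1 - p), N)
    Z <- Z * dm17
  }
  Zs <- Z - apply(Z, 1, max)
  E <- exp(Zs)
  probs <- E / rowSums(E)
  list(probs = probs, Fm = if (keep_cache) Fm else NULL,
       caches = caches, dm17 = dm17, d5 = c(h, w, cin, N))
}

cnn_backward <- function(model, fwd, y_onehot) {
  N <- nrow(fwd$probs)
  grads <- list()
  dZ <- (fwd$probs - y_onehot) / N
  if (!is.null(fwd$dm17)) dZ <- dZ * fwd$dm17
  grads$fc <- list(dW = crossprod(fwd$Fm, dZ), db = colSums(dZ))
  dF <- tcrossprod(dZ, model$fc$W)
  if (model$n_fused > 0L) dF <- dF[, seq_len(model$d_flat), drop = FALSE]
  d5 <- fwd$d5
  dM <- aperm(array(t(dF), c(d5[1], d5[2], d5[3], N)), c(1, 2, 4, 3))
  dim(dM) <- c(d5[1] * d5[2] * N, d5[3])
  grads$conv <- vector("list", 5)
  for (l in 5:1) {
    cc <- fwd$caches[[l]]
    co <- model$arch$filters[l]
    if (!is.null(cc$drop)) dM <- dM * cc$drop
    dZc <- maxpool_m_bwd(dM, cc$win, cc$h, cc$w, co, N)
    relu_bwd_inplace(dZc, cc$Z)
    grads$conv[[l]] <- list(dW = crossprod(cc$P, dZc), db = colSums(dZc))
    if (l > 1L)
      dM <- col2im_pad(tcrossprod(dZc, model$conv[[l]]$W),
                       cc$h, cc$w, cc$cin, N)
  }
  grads
}

adam_init <- function(model) {
  z <- function(x) list(m = array(0, dim(as.array(x))), v = array(0, dim(as.array(x))))
  list(t = 0,
       conv = lapply(model$conv, function(l) list(W = z(l$W), b = list(m = 0 * l$b, v = 0 * l$b))),
       fc = list(W = z(model$fc$W), b = list(m = 0 * model$fc$b, v = 0 * model$fc$b)))
}

adam_step <- function(par, grad, st, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  st$m <- b1 * st$m + (1 - b1) * grad
  st$v <- b2 * st$v + (1 - b2) * grad^2
  mh <- st$m / (1 - b1^t)
  vh <- st$v / (1 - b2^t)
  list(par = par - lr * mh / (sqrt(vh) + eps), st = st)
}

adam_update <- function(model, grads, opt, lr) {
  opt$t <- opt$t + 1
  for (l in 1:5) {
    u <- adam_step(model$conv[[l]]$W, grads$conv[[l]]$dW, opt$conv[[l]]$W, lr, opt$t)
    model$conv[[l]]$W <- u$par; opt$conv[[l]]$W <- u$st
    u <- adam_step(model$conv[[l]]$b, grads$conv[[l]]$db, opt$conv[[l]]$b, lr, opt$t)
    model$conv[[l]]$b <- u$par; opt$conv[[l]]$b <- u$st
  }
  u <- adam_step(model$fc$W, grads$fc$dW, opt$fc$W, lr, opt$t)
  model$fc$W <- u$par; opt$fc$W <- u$st
  u <- adam_step(model$fc$b, grads$fc$db, opt$fc$b, lr, opt$t)
  model$fc$b <- u$par; opt$fc$b <- u$st
  list(model = model, opt = opt)
}

#' Training configuration
#'
#' Defaults follow the assay's training protocol (Adam, learning rate 0.001,
#' 80/20 stratified split, width-only 10% shift plus horizontal and vertical
#' flips on the training set) at a desk-scale epoch count; `epochs = 500` on
#' 256 x 256 inputs reproduces the full-scale configuration.
#'
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param val_fraction held-out validation fraction (stratified by class).
#' @param augment apply augmentation to the training set.
#' @param width_shift maximum horizontal shift as a fraction of patch width.
#' @param flip_h,flip_v random flips.
#' @param seed seed for split, shuffling, augmentation and dropout.
#' @param verbose print per-epoch progress.
#' @return list of class `train_config`.
#' @export
train_config <- function(epochs = 12, batch_size = 32, lr = 0.001,
                         val_fraction = 0.2, augment = TRUE,
                         width_shift = 0.10, flip_h = TRUE, flip_v = TRUE,
                         seed = 1L, verbose = FALSE) {
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, val_fraction = val_fraction, augment = augment,
                 width_shift = width_shift, flip_h = flip_h, flip_v = flip_v,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "train_config")
}

augment_patch <- function(m, width_shift, flip_h, flip_v) {
  P <- nrow(m)
  dx <- sample.int(2L * as.integer(P * width_shift) + 1L, 1L) -
    as.integer(P * width_shift) - 1L
  if (dx != 0) m <- m[clamp(seq_len(P) - dx, 1L, P), , drop = FALSE]
  if (flip_h && runif(1) < 0.5) m <- m[P:1, , drop = FALSE]
  if (flip_v && runif(1) < 0.5) m <- m[, P:1, drop = FALSE]
  m
}

stratified_split <- function(y, val_fraction) {
  val <- integer(0)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    n_val <- max(1L, round(length(idx) * val_fraction))
    val <- c(val, sample(idx, n_val))
  }
  sort(val)
}

#' Train the 17-layer CNN
#'
#' Stratified 80/20 split (configurable), per-epoch shuffling, augmentation
#' of the training set only, Adam updates with categorical cross-entropy,
#' per-epoch history of train/validation accuracy and loss, and retention of
#' the best-validation-accuracy checkpoint. Fully seeded: a repeated run
#' with the same seed reproduces the history.
#'
#' @param model a `sickle_cnn` from [build_cnn()].
#' @param x array `(P, P, n)` of patches in `[0, 1]` at the model's input
#'   size.
#' @param y integer labels (0 = nonsickled, 1 = sickled); both classes must
#'   be present.
#' @param factors optional `n x n_fused` matrix of shape factors for the
#'   fusion variant; standardized with training-set statistics stored in the
#'   model.
#' @param config a [train_config()].
#' @return list of class `cnn_fit`: `model` (best checkpoint), `final_model`,
#'   `history` (data frame `epoch, train_loss, train_acc, val_loss, val_acc`),
#'   `val_idx`, `config`.
#' @export
train_cnn <- function(model, x, y, factors = NULL, config = train_config()) {
  y <- as.integer(y)
  if (length(unique(y)) < 2) stopf("training data must contain both classes")
  n <- dim(x)[3]
  if (length(y) != n) stopf("labels do not match the number of patches")
  if (dim(x)[1] != model$input_size)
    stopf("patches are %d px but the model expects %d", dim(x)[1], model$input_size)
  if (model$n_fused > 0L) {
    factors <- as.matrix(factors)
    if (is.null(factors) || nrow(factors) != n || any(!is.finite(factors)))
      stopf("fused training requires a finite %d x %d factor matrix", n, model$n_fused)
  }
  with_seed(config$seed, {
    val_idx <- stratified_split(y, config$val_fraction)
    tr_idx <- setdiff(seq_len(n), val_idx)
    if (model$n_fused > 0L) {
      model$factor_center <- colMeans(factors[tr_idx, , drop = FALSE])
      model$factor_scale <- pmax(apply(factors[tr_idx, , drop = FALSE], 2, sd), 1e-8)
    }
    x_val <- x[, , val_idx, drop = FALSE]
    y_val <- y[val_idx]
    f_val <- if (model$n_fused > 0L) factors[val_idx, , drop = FALSE] else NULL
    opt <- adam_init(model)
    best <- list(acc = -1, model = model)
    hist <- vector("list", config$epochs)
    P <- model$input_size
    for (ep in seq_len(config$epochs)) {
      ord <- sample(tr_idx)
      tl <- 0; tn <- 0; tc <- 0
      for (bs in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
        nb <- length(bs)
        Xb <- array(0, c(P, P, 1, nb))
        for (k in seq_len(nb)) {
          m <- x[, , bs[k]]
          if (config$augment)
            m <- augment_patch(m, config$width_shift, config$flip_h, config$flip_v)
          Xb[, , 1, k] <- m
        }
        fb <- if (model$n_fused > 0L) factors[bs, , drop = FALSE] else NULL
        fwd <- cnn_forward(model, Xb, train = TRUE, factors = fb, keep_cache = TRUE)
        yb <- y[bs]
        onehot <- matrix(0, nb, 2); onehot[cbind(seq_len(nb), yb + 1L)] <- 1
        tl <- tl + -sum(log(pmax(fwd$probs[cbind(seq_len(nb), yb + 1L)], 1e-12)))
        tc <- tc + sum(max.col(fwd$probs) - 1L == yb)
        tn <- tn + nb
        grads <- cnn_backward(model, fwd, onehot)
        st <- adam_update(model, grads, opt, config$lr)
        model <- st$model; opt <- st$opt
      }
      ev <- eval_loss_acc(model, x_val, y_val, f_val)
      hist[[ep]] <- data.frame(epoch = ep, train_loss = tl / tn,
                               train_acc = tc / tn, val_loss = ev$loss,
                               val_acc = ev$acc)
      if (ev$acc > best$acc) best <- list(acc = ev$acc, model = model)
      if (config$verbose)
        message(sprintf("epoch %3d  train %.4f/%.3f  val %.4f/%.3f",
                        ep, tl / tn, tc / tn, ev$loss, ev$acc))
    }
    structure(list(model = best$model, final_model = model,
                   history = do.call(rbind, hist), val_idx = val_idx,
                   config = config),
              class = "cnn_fit")
  })
}

eval_loss_acc <- function(model, x, y, factors = NULL, batch = 256L) {
  n <- dim(x)[3]
  loss <- 0; correct <- 0
  for (bs in split(seq_len(n), ceiling(seq_len(n) / batch))) {
    f <- if (model$n_fused > 0L) factors[bs, , drop = FALSE] else NULL
    pr <- cnn_forward(model, x[, , bs, drop = FALSE], factors = f)$probs
    loss <- loss + -sum(log(pmax(pr[cbind(seq_along(bs), y[bs] + 1L)], 1e-12)))
    correct <- correct + sum(max.col(pr) - 1L == y[bs])
  }
  list(loss = loss / n, acc = correct / n)
}

#' Predict class probabilities for patches
#'
#' Deterministic inference (no dropout).
#'
#' @param model a `sickle_cnn`.
#' @param x array `(P, P, n)`; resized to the model input if needed.
#' @param factors optional factor matrix for fused models.
#' @param batch inference batch size.
#' @return matrix `n x 2` with columns `p_nonsickled, p_sickled`.
#' @export
predict_cnn <- function(model, x, factors = NULL, batch = 256L) {
  if (length(dim(x)) == 2L) dim(x) <- c(dim(x), 1L)
  if (dim(x)[1] != model$input_size || dim(x)[2] != model$input_size) {
    n <- dim(x)[3]
    xr <- array(0, c(model$input_size, model$input_size, n))
    for (k in seq_len(n))
      xr[, , k] <- EBImage::imageData(EBImage::resize(
        EBImage::Image(x[, , k]), w = model$input_size, h = model$input_size))
    x <- xr
  }
  n <- dim(x)[3]
  out <- matrix(0, n, 2, dimnames = list(NULL, c("p_nonsickled", "p_sickled")))
  for (bs in split(seq_len(n), ceiling(seq_len(n) / batch))) {
    f <- if (model$n_fused > 0L) factors[bs, , drop = FALSE] else NULL
    out[bs, ] <- cnn_forward(model, x[, , bs, drop = FALSE], factors = f)$probs
  }
  out
}

#' Confusion matrix and performance metrics
#'
#' Positive class = sickled. `Accuracy = (TP+TN)/(TP+TN+FP+FN)`,
#' `Precision = TP/(TP+FP)`, `Recall = TP/(TP+FN)`,
#' `F1 = 2 Precision Recall / (Precision + Recall)`. Ratios with a zero
#' denominator are reported as `NA`, not 0.
#'
#' @param tp,tn,fp,fn confusion counts.
#' @return named list `accuracy, precision, recall, f1`.
#' @export
classification_metrics <- function(tp, tn, fp, fn) {
  tot <- tp + tn + fp + fn
  acc <- if (tot > 0) (tp + tn) / tot else NA_real_
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
    2 * prec * rec / (prec + rec) else NA_real_
  list(accuracy = acc, precision = prec, recall = rec, f1 = f1)
}

#' Evaluate a model on a labeled set
#'
#' @inheritParams predict_cnn
#' @param y integer labels (0/1).
#' @return list with `confusion` (named counts `tp, tn, fp, fn`) and
#'   `metrics` (from [classification_metrics()]).
#' @export
evaluate_cnn <- function(model, x, y, factors = NULL) {
  if (!dim(x)[3]) stopf("validation set is empty")
  pr <- predict_cnn(model, x, factors)
  pred <- max.col(pr) - 1L
  y <- as.integer(y)
  conf <- c(tp = sum(pred == 1L & y == 1L), tn = sum(pred == 0L & y == 0L),
            fp = sum(pred == 1L & y == 0L), fn = sum(pred == 0L & y == 1L))
  list(confusion = conf,
       metrics = classification_metrics(conf["tp"], conf["tn"],
                                        conf["fp"], conf["fn"]),
       predicted = pred)
}

#' Classify segmented cell records
#'
#' One prediction per non-discarded record; patches are resized to the model
#' input on the fly. Inference is deterministic.
#'
#' @param model a `sickle_cnn`.
#' @param records list of `cell_record` objects.
#' @param factors optional matrix of fused shape factors aligned with
#'   `records`.
#' @return data frame `cell_label, frame, t, p_nonsickled, p_sickled, label`
#'   (label is `"sickled"` or `"nonsickled"`).
#' @export
predict_cells <- function(model, records, factors = NULL) {
  keep <- !vapply(records, function(r) isTRUE(r$discarded), logical(1))
  records <- records[keep]
  if (!length(records))
    return(data.frame(cell_label = integer(), frame = integer(), t = numeric(),
                      p_nonsickled = numeric(), p_sickled = numeric(),
                      label = character()))
  P <- nrow(records[[1]]$patch)
  x <- array(0, c(P, P, length(records)))
  for (k in seq_along(records)) x[, , k] <- records[[k]]$patch
  f <- if (!is.null(factors)) as.matrix(factors)[keep, , drop = FALSE] else NULL
  pr <- predict_cnn(model, x, f)
  data.frame(cell_label = vapply(records, `[[`, integer(1), "cell_label"),
             frame = vapply(records, `[[`, integer(1), "frame_index"),
             t = vapply(records, `[[`, numeric(1), "t"),
             p_nonsickled = pr[, 1], p_sickled = pr[, 2],
             label = ifelse(pr[, 2] >= pr[, 1], "sickled", "nonsickled"))
}

#' Train the shape-factor fusion variant
#'
#' Concatenates four shape factors (CSF, ESF, Convexity, Compactness by
#' convention) to the flattened convolutional features before the fully
#' connected layer; the training contract is identical to [train_cnn()].
#'
#' @param x,y,config as in [train_cnn()].
#' @param factors `n x 4` matrix of shape factors (finite).
#' @param arch a [cnn_architecture()].
#' @param input_size model input side.
#' @param seed weight initialization seed.
#' @return a `cnn_fit`.
#' @export
fuse_shape_factors <- function(x, y, factors, config = train_config(),
                               arch = cnn_architecture(), input_size = 64,
                               seed = 1L) {
  if (is.null(factors)) stopf("fused training requires shape factors")
  model <- build_cnn(arch, input_size, n_fused = ncol(as.matrix(factors)),
                     seed = seed)
  train_cnn(model, x, y, factors = factors, config = config)
}

#' Save / load a trained model
#'
#' @param model a `sickle_cnn` (or `cnn_fit`).
#' @param path file path (RDS).
#' @return `path` / the loaded object.
#' @export
save_cnn <- function(model, path) { saveRDS(model, path); invisible(path) }

#' @rdname save_cnn
#' @export
load_cnn <- function(path) readRDS(path)
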