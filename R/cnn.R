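# A small residual convolutional network, implemented in base R.
#
# No deep-learning backend is assumed: convolutions are im2col matrix
# products, so the whole network runs on one CPU in minutes for the image
# sizes used here. The architecture is the smallest genuinely residual
# design: stem 3x3 convolution, two residual blocks (two 3x3 convolutions
# with an identity shortcut each) separated by 2x2 max-pools, a 4x4
# average-pool, and a flattened softmax head. (A fully global average pool
# was tried first and discarded: the class signal of rank-1 correlation
# maps lives in the spatial sign pattern, which channel means cannot
# represent.) Everything (initialisation, batch shuffling) is driven by
# one seed, so training is bitwise reproducible.
#
# Activations are arrays (H, W, C, B); convolution weights are matrices
# (9*C_in, C_out) with rows ordered offset-fastest within channel.

conv_indices <- function(H, W) {
  # linear indices into the zero-padded (H+2) x (W+2) plane for each of the
  # 9 kernel offsets, per output position (row-major over H then W)
  Hp <- H + 2
  base <- outer(seq_len(H), seq_len(W), function(i, j) (j - 1) * Hp + i)
  idx <- matrix(0L, H * W, 9)
  k <- 0
  for (dj in 0:2) for (di in 0:2) {
    k <- k + 1
    idx[, k] <- as.integer(base + di + dj * Hp)
  }
  idx
}

conv_forward <- function(A, Wf, b, idx) {
  d <- dim(A); H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  Hp <- H + 2; Wp <- W + 2
  P <- array(0, c(Hp, Wp, C, B))
  P[2:(H + 1), 2:(W + 1), , ] <- A
  dim(P) <- c(Hp * Wp, C, B)
  M <- array(0, c(H * W, 9, C, B))
  for (k in 1:9) M[, k, , ] <- P[idx[, k], , ]
  Mp <- aperm(M, c(1, 4, 2, 3))            # (HW, B, 9, C)
  dim(Mp) <- c(H * W * B, 9 * C)
  OutM <- Mp %*% Wf
  OutM <- sweep(OutM, 2, b, "+")
  Fc <- ncol(Wf)
  dim(OutM) <- c(H * W, B, Fc)
  Out <- aperm(OutM, c(1, 3, 2))
  dim(Out) <- c(H, W, Fc, B)
  list(out = Out, M = Mp, dims = d)
}

conv_backward <- function(dOut, cache, Wf, idx) {
  d <- cache$dims; H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  Fc <- ncol(Wf)
  dim(dOut) <- c(H * W, Fc, B)
  dOutM <- aperm(dOut, c(1, 3, 2))
  dim(dOutM) <- c(H * W * B, Fc)
  dW <- crossprod(cache$M, dOutM)
  db <- colSums(dOutM)
  dM <- tcrossprod(dOutM, Wf)              # (HW*B, 9*C)
  dim(dM) <- c(H * W, B, 9, C)
  dM <- aperm(dM, c(1, 3, 4, 2))           # (HW, 9, C, B)
  Hp <- H + 2; Wp <- W + 2
  dP <- array(0, c(Hp * Wp, C, B))
  for (k in 1:9) dP[idx[, k], , ] <- dP[idx[, k], , ] + dM[, k, , ]
  dim(dP) <- c(Hp, Wp, C, B)
  dA <- dP[2:(H + 1), 2:(W + 1), , , drop = FALSE]
  dim(dA) <- d
  list(dA = dA, dW = dW, db = db)
}

maxpool_forward <- function(A) {
  d <- dim(A); H <- d[1]; W <- d[2]
  io <- seq(1, H, 2); jo <- seq(1, W, 2)
  s1 <- A[io, jo, , , drop = FALSE]; s2 <- A[io + 1, jo, , , drop = FALSE]
  s3 <- A[io, jo + 1, , , drop = FALSE]; s4 <- A[io + 1, jo + 1, , , drop = FALSE]
  m12 <- pmax(s1, s2); m34 <- pmax(s3, s4)
  out <- pmax(m12, m34)
  arg <- ifelse(m12 >= m34, ifelse(s1 >= s2, 1L, 2L), ifelse(s3 >= s4, 3L, 4L))
  list(out = out, arg = arg, dims = d)
}

# Non-overlapping average pool with block size b: (H, W, C, B) -> (H/b,
# H/b, C, B), implemented through the separable bin-average weights.
avgpool_forward <- function(A, b) {
  d <- dim(A)
  Ho <- d[1] / b; Wo <- d[2] / b
  grp_i <- rep(seq_len(Ho), each = b)
  out <- array(0, c(Ho, Wo, d[3], d[4]))
  for (ii in seq_len(Ho)) for (jj in seq_len(Wo)) {
    blk <- A[(ii - 1) * b + seq_len(b), (jj - 1) * b + seq_len(b), , ,
             drop = FALSE]
    out[ii, jj, , ] <- apply(blk, c(3, 4), mean)
  }
  list(out = out, dims = d, b = b)
}

avgpool_backward <- function(dOut, cache) {
  d <- cache$dims; b <- cache$b
  dA <- array(0, d)
  Ho <- d[1] / b; Wo <- d[2] / b
  for (ii in seq_len(Ho)) for (jj in seq_len(Wo)) {
    g <- dOut[ii, jj, , ] / b^2
    dA[(ii - 1) * b + seq_len(b), (jj - 1) * b + seq_len(b), , ] <-
      aperm(array(g, c(d[3], d[4], b, b)), c(3, 4, 1, 2))
  }
  dA
}

maxpool_backward <- function(dOut, cache) {
  d <- cache$dims
  dA <- array(0, d)
  io <- seq(1, d[1], 2); jo <- seq(1, d[2], 2)
  a <- cache$arg
  dA[io, jo, , ] <- dOut * (a == 1L)
  dA[io + 1, jo, , ] <- dA[io + 1, jo, , , drop = FALSE] + dOut * (a == 2L)
  dA[io, jo + 1, , ] <- dA[io, jo + 1, , , drop = FALSE] + dOut * (a == 3L)
  dA[io + 1, jo + 1, , ] <- dA[io + 1, jo + 1, , , drop = FALSE] + dOut * (a == 4L)
  dA
}

#' Build the small residual CNN
#'
#' @param image_size input raster side; must be divisible by 16 (two 2x2
#'   max-pools plus the final 4x4 average-pool).
#' @param n_classes output classes (>= 2).
#' @param channels feature channels throughout (default 32).
#' @param seed integer seed; initialization is deterministic given it.
#' @return a `resnet_model`: parameter list plus architecture metadata and
#'   the total parameter count.
#' @export
build_resnet <- function(image_size, n_classes, channels = 32, seed = 1L) {
  if (n_classes < 2) stop("n_classes must be >= 2")
  if (image_size < 16 || image_size %% 16 != 0)
    stop("image_size must be >= 16 and divisible by 16")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(stage_seed(seed, "cnn_init"))
  he <- function(fan_in, nr, nc)
    matrix(rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
  C <- channels
  params <- list(
    stem_W = he(9 * 3, 9 * 3, C), stem_b = numeric(C),
    r1a_W = he(9 * C, 9 * C, C), r1a_b = numeric(C),
    r1b_W = he(9 * C, 9 * C, C), r1b_b = numeric(C),
    r2a_W = he(9 * C, 9 * C, C), r2a_b = numeric(C),
    r2b_W = he(9 * C, 9 * C, C), r2b_b = numeric(C),
    head_W = matrix(rnorm(16 * C * n_classes, 0, sqrt(1 / (16 * C))),
                    16 * C, n_classes),
    head_b = numeric(n_classes))
  n_par <- sum(vapply(params, length, integer(1)))
  structure(list(params = params, image_size = image_size,
                 n_classes = n_classes, channels = C,
                 idx1 = conv_indices(image_size, image_size),
                 idx2 = conv_indices(image_size / 2, image_size / 2),
                 idx3 = conv_indices(image_size / 4, image_size / 4),
                 n_parameters = n_par),
            class = "resnet_model")
}

#' @export
print.resnet_model <- function(x, ...) {
  cat(sprintf("<resnet_model> %dx%dx3 -> %d classes, %d channels, %d parameters\n",
              x$image_size, x$image_size, x$n_classes, x$channels,
              x$n_parameters))
  invisible(x)
}

resnet_forward <- function(model, Xb) {
  p <- model$params
  Xb <- Xb - 0.5   # images are RGB in [0, 1]; center for conditioning
  cache <- list()
  c1 <- conv_forward(Xb, p$stem_W, p$stem_b, model$idx1)
  a1 <- pmax(c1$out, 0)
  mp1 <- maxpool_forward(a1)
  # residual block 1
  cb1a <- conv_forward(mp1$out, p$r1a_W, p$r1a_b, model$idx2)
  ab1a <- pmax(cb1a$out, 0)
  cb1b <- conv_forward(ab1a, p$r1b_W, p$r1b_b, model$idx2)
  s1 <- cb1b$out + mp1$out
  as1 <- pmax(s1, 0)
  mp2 <- maxpool_forward(as1)
  # residual block 2
  cb2a <- conv_forward(mp2$out, p$r2a_W, p$r2a_b, model$idx3)
  ab2a <- pmax(cb2a$out, 0)
  cb2b <- conv_forward(ab2a, p$r2b_W, p$r2b_b, model$idx3)
  s2 <- cb2b$out + mp2$out
  as2 <- pmax(s2, 0)
  ap <- avgpool_forward(as2, dim(as2)[1] / 4)        # (4, 4, C, B)
  B <- dim(as2)[4]
  feat <- matrix(ap$out, ncol = B)                   # (16*C, B)
  logits <- sweep(crossprod(feat, p$head_W), 2, p$head_b, "+")  # (B, K)
  list(logits = logits,
       cache = list(Xb = Xb, c1 = c1, a1 = a1, mp1 = mp1, cb1a = cb1a,
                    ab1a = ab1a, cb1b = cb1b, s1 = s1, as1 = as1, mp2 = mp2,
                    cb2a = cb2a, ab2a = ab2a, cb2b = cb2b, s2 = s2,
                    as2 = as2, ap = ap, feat = feat))
}

softmax <- function(logits) {
  z <- exp(logits - apply(logits, 1, max))
  z / rowSums(z)
}

resnet_backward <- function(model, cache, dlogits) {
  p <- model$params
  g <- list()
  g$head_W <- cache$feat %*% dlogits                 # (16C, K)
  g$head_b <- colSums(dlogits)
  dfeat <- p$head_W %*% t(dlogits)                   # (16C, B)
  dap <- array(dfeat, dim(cache$ap$out))
  das2 <- avgpool_backward(dap, cache$ap)
  ds2 <- das2 * (cache$s2 > 0)
  bb <- conv_backward(ds2, cache$cb2b, p$r2b_W, model$idx3)
  g$r2b_W <- bb$dW; g$r2b_b <- bb$db
  dab2a <- bb$dA * (cache$cb2a$out > 0)
  ba <- conv_backward(dab2a, cache$cb2a, p$r2a_W, model$idx3)
  g$r2a_W <- ba$dW; g$r2a_b <- ba$db
  dmp2 <- ba$dA + ds2                                # shortcut path
  das1 <- maxpool_backward(dmp2, cache$mp2)
  ds1 <- das1 * (cache$s1 > 0)
  bb1 <- conv_backward(ds1, cache$cb1b, p$r1b_W, model$idx2)
  g$r1b_W <- bb1$dW; g$r1b_b <- bb1$db
  dab1a <- bb1$dA * (cache$cb1a$out > 0)
  ba1 <- conv_backward(dab1a, cache$cb1a, p$r1a_W, model$idx2)
  g$r1a_W <- ba1$dW; g$r1a_b <- ba1$db
  dmp1 <- ba1$dA + ds1
  da1 <- maxpool_backward(dmp1, cache$mp1)
  dc1 <- da1 * (cache$c1$out > 0)
  bs <- conv_backward(dc1, cache$c1, p$stem_W, model$idx1)
  g$stem_W <- bs$dW; g$stem_b <- bs$db
  g
}

# Cross-entropy loss and gradient from logits and integer class targets.
ce_loss_grad <- function(logits, y) {
  pr <- softmax(logits)
  B <- nrow(logits)
  loss <- -mean(log(pmax(pr[cbind(seq_len(B), y)], 1e-12)))
  dlogits <- pr
  dlogits[cbind(seq_len(B), y)] <- dlogits[cbind(seq_len(B), y)] - 1
  list(loss = loss, dlogits = dlogits / B)
}

batch_array <- function(images, idx) {
  aperm(images[idx, , , , drop = FALSE], c(2, 3, 4, 1))
}

#' Predict classes with a (trained) residual CNN
#'
#' @param object a `resnet_model`.
#' @param images array `n x S x S x 3`.
#' @param batch_size forward-pass batch size.
#' @param ... unused.
#' @return integer class indices (1-based).
#' @export
predict.resnet_model <- function(object, images, batch_size = 32, ...) {
  n <- dim(images)[1]
  out <- integer(n)
  for (s in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    lg <- resnet_forward(object, batch_array(images, s))$logits
    out[s] <- max.col(lg, ties.method = "first")
  }
  out
}

#' Train the residual CNN
#'
#' Adam on softmax cross-entropy over the `train` partition only; test
#' accuracy is logged each epoch and the `external` partition is never
#' touched during training. Fully seeded: identical seeds give identical
#' histories and final weights.
#'
#' @param model a `resnet_model`.
#' @param images array `n x S x S x 3`.
#' @param labels factor/character labels, length n.
#' @param split a `split_indices` with partitions named `train`, `test` (and
#'   optionally `external`).
#' @param epochs training epochs (default 30; 0 returns the model
#'   untrained with an empty history).
#' @param batch_size minibatch size (default 8; with 60 training
#'   images that is 8 optimisation steps per epoch).
#' @param lr Adam learning rate (default 2e-3).
#' @param seed integer seed for shuffling.
#' @return list: `model` (trained), `history` (data.frame epoch, loss,
#'   train/test accuracy), `levels` (class level order).
#' @export
cnn_train <- function(model, images, labels, split, epochs = 30,
                      batch_size = 8, lr = 2e-3, seed = 1L) {
  if (!all(c("train", "test") %in% names(split)))
    stop("split must have partitions named train and test")
  labels <- droplevels(as.factor(labels))
  y <- as.integer(labels)
  tr <- split[["train"]]; te <- split[["test"]]
  if (length(tr) == 0 || length(te) == 0) stop("empty partition")
  hist <- data.frame(epoch = integer(), loss = numeric(),
                     train_accuracy = numeric(), test_accuracy = numeric())
  if (epochs == 0)
    return(list(model = model, history = hist, levels = levels(labels)))
  p <- model$params
  mom <- lapply(p, function(x) x * 0)
  vel <- lapply(p, function(x) x * 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(stage_seed(seed, "cnn_shuffle"))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0
  for (ep in seq_len(epochs)) {
    ord <- sample(tr)
    ep_loss <- 0; nb <- 0
    for (bi in split(ord, ceiling(seq_along(ord) / batch_size))) {
      fw <- resnet_forward(model, batch_array(images, bi))
      lg <- ce_loss_grad(fw$logits, y[bi])
      g <- resnet_backward(model, fw$cache, lg$dlogits)
      t <- t + 1
      for (nm in names(p)) {
        mom[[nm]] <- b1 * mom[[nm]] + (1 - b1) * g[[nm]]
        vel[[nm]] <- b2 * vel[[nm]] + (1 - b2) * g[[nm]]^2
        mhat <- mom[[nm]] / (1 - b1^t)
        vhat <- vel[[nm]] / (1 - b2^t)
        p[[nm]] <- p[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
      model$params <- p
      ep_loss <- ep_loss + lg$loss; nb <- nb + 1
    }
    acc_tr <- mean(predict(model, images[tr, , , , drop = FALSE]) == y[tr])
    acc_te <- mean(predict(model, images[te, , , , drop = FALSE]) == y[te])
    hist <- rbind(hist, data.frame(epoch = ep, loss = ep_loss / nb,
                                   train_accuracy = acc_tr,
                                   test_accuracy = acc_te))
  }
  list(model = model, history = hist, levels = levels(labels))
}

#' Evaluate a CNN: per-class one-vs-rest confusion counts
#'
#' @param model a trained `resnet_model`.
#' @param images array `n x S x S x 3`.
#' @param labels true labels.
#' @param levels class level order used in training.
#' @return list: `counts` (data.frame class, TP, TN, FP, FN), `accuracy`,
#'   `predicted`.
#' @export
cnn_evaluate <- function(model, images, labels, levels = NULL) {
  labels <- as.factor(labels)
  if (is.null(levels)) levels <- base::levels(labels)
  y <- match(as.character(labels), levels)
  pred <- predict(model, images)
  counts <- confusion_counts(y, pred, length(levels))
  counts$class <- levels
  list(counts = counts[, c("class", "TP", "TN", "FP", "FN")],
       accuracy = mean(pred == y),
       predicted = factor(levels[pred], levels = levels))
}

#' One-vs-rest confusion counts
#'
#' @param truth,pred integer class indices (1-based).
#' @param k number of classes.
#' @return data.frame with TP/TN/FP/FN per class; rows sum to
#'   `length(truth)`.
#' @export
confusion_counts <- function(truth, pred, k = max(truth, pred)) {
  out <- data.frame(TP = integer(k), TN = integer(k), FP = integer(k),
                    FN = integer(k))
  for (c in seq_len(k)) {
    out$TP[c] <- sum(truth == c & pred == c)
    out$TN[c] <- sum(truth != c & pred != c)
    out$FP[c] <- sum(truth != c & pred == c)
    out$FN[c] <- sum(truth == c & pred != c)
  }
  out
}

#' Sensitivity, specificity and efficiency from confusion counts
#'
#' `SEN = TP / (TP + FN)`, `SPE = TN / (TN + FP)`, and `EFF = SEN * SPE`
#' (the product form; `variant = "geometric"` gives `sqrt(SEN * SPE)`, a
#' common alternative — both equal 1 for a perfect classifier). A zero
#' denominator yields `NA` with the `undefined` flag set rather than
#' silently propagating NaN.
#'
#' @param counts data.frame with columns TP, TN, FP, FN (e.g. from
#'   [confusion_counts()] or [cnn_evaluate()]).
#' @param variant `"product"` (default) or `"geometric"`.
#' @return data.frame with SEN, SPE, EFF and `undefined` per class.
#' @export
classification_metrics <- function(counts, variant = c("product", "geometric")) {
  variant <- match.arg(variant)
  sen_d <- counts$TP + counts$FN
  spe_d <- counts$TN + counts$FP
  sen <- ifelse(sen_d > 0, counts$TP / sen_d, NA_real_)
  spe <- ifelse(spe_d > 0, counts$TN / spe_d, NA_real_)
  eff <- if (variant == "product") sen * spe else sqrt(sen * spe)
  out <- data.frame(SEN = sen, SPE = spe, EFF = eff,
                    undefined = sen_d == 0 | spe_d == 0)
  if ("class" %in% names(counts)) out <- cbind(class = counts$class, out)
  out
}
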