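# Distinct block-pattern images per class: a cheap separable image task.
toy_images <- function(n_per_class, k = 3, size = 16, noise = 0.05,
                       seed = 99) {
  set.seed(seed)
  n <- n_per_class * k
  imgs <- array(0, c(n, size, size, 3))
  lab <- rep(seq_len(k), each = n_per_class)
  for (i in seq_len(n)) {
    base <- array(runif(size * size * 3, 0, noise), c(size, size, 3))
    q <- lab[i]
    rows <- ((q - 1) * floor(size / k) + 1):(q * floor(size / k))
    base[rows, , q %% 3 + 1] <- base[rows, , q %% 3 + 1] + 0.8
    imgs[i, , , ] <- base
  }
  list(images = imgs, labels = factor(letters[lab]))
}

test_that("model construction is deterministic and shaped by its inputs", {
  m1 <- build_resnet(32, 5, seed = 7)
  m2 <- build_resnet(32, 5, seed = 7)
  expect_identical(m1$params, m2$params)
  m3 <- build_resnet(32, 5, seed = 8)
  expect_false(identical(m1$params, m3$params))
  expect_equal(ncol(m1$params$head_W), 5)
  expect_gt(m1$n_parameters, 0)
  expect_error(build_resnet(32, 1), "n_classes")
  expect_error(build_resnet(30, 3), "divisible")
  # forward pass on a zero image gives finite logits
  z <- array(0, c(16, 16, 3, 1))
  lg <- dryspec:::resnet_forward(build_resnet(16, 4, seed = 1), z)$logits
  expect_true(all(is.finite(lg)))
  expect_equal(dim(lg), c(1, 4))
})

test_that("analytic gradients match finite differences", {
  set.seed(51)
  model <- build_resnet(16, 3, channels = 3, seed = 4)
  imgs <- array(rnorm(3 * 16 * 16 * 3), c(3, 16, 16, 3))
  y <- c(1L, 2L, 3L)
  Xb <- aperm(imgs, c(2, 3, 4, 1))
  fw <- dryspec:::resnet_forward(model, Xb)
  lg <- dryspec:::ce_loss_grad(fw$logits, y)
  g <- dryspec:::resnet_backward(model, fw$cache, lg$dlogits)
  loss_at <- function(m)
    dryspec:::ce_loss_grad(dryspec:::resnet_forward(m, Xb)$logits, y)$loss
  eps <- 1e-6
  for (nm in c("stem_W", "r1b_W", "r2a_b", "head_W")) {
    P <- model$params[[nm]]
    ii <- sample(length(P), min(4, length(P)))
    num <- sapply(ii, function(i) {
      m1 <- model; m1$params[[nm]][i] <- P[i] + eps
      m2 <- model; m2$params[[nm]][i] <- P[i] - eps
      (loss_at(m1) - loss_at(m2)) / (2 * eps)
    })
    expect_equal(num, g[[nm]][ii], tolerance = 1e-4)
  }
})

test_that("training learns a separable toy task and is seed-reproducible", {
  toy <- toy_images(8, k = 3, size = 16)
  split <- structure(list(train = c(1:6, 9:14, 17:22),
                          test = c(7:8, 15:16, 23:24)),
                     class = "split_indices")
  model <- build_resnet(16, 3, channels = 8, seed = 2)
  tr <- cnn_train(model, toy$images, toy$labels, split, epochs = 15,
                  batch_size = 6, lr = 2e-3, seed = 2)
  expect_equal(nrow(tr$history), 15)
  expect_equal(tail(tr$history$train_accuracy, 1), 1)
  expect_equal(tail(tr$history$test_accuracy, 1), 1)
  tr2 <- cnn_train(model, toy$images, toy$labels, split, epochs = 15,
                   batch_size = 6, lr = 2e-3, seed = 2)
  expect_identical(tr$history, tr2$history)
  expect_identical(tr$model$params, tr2$model$params)
})

test_that("zero epochs returns the untrained model with empty history", {
  toy <- toy_images(2, k = 2, size = 16)
  split <- structure(list(train = c(1, 2, 3), test = 4L),
                     class = "split_indices")
  model <- build_resnet(16, 2, channels = 2, seed = 1)
  tr <- cnn_train(model, toy$images, toy$labels, split, epochs = 0)
  expect_equal(nrow(tr$history), 0)
  expect_identical(tr$model$params, model$params)
  expect_error(cnn_train(model, toy$images, toy$labels,
                         structure(list(train = integer(), test = 1L),
                                   class = "split_indices")),
               "empty partition")
})

test_that("confusion counts match a hand tally", {
  truth <- c(1, 1, 1, 2, 2, 3, 3, 3, 3, 2)
  pred  <- c(1, 2, 1, 2, 2, 3, 1, 3, 3, 3)
  cc <- confusion_counts(truth, pred, 3)
  expect_equal(cc$TP, c(2, 2, 3))
  expect_equal(cc$FN, c(1, 1, 1))
  expect_equal(cc$FP, c(1, 1, 1))
  expect_equal(cc$TN, c(6, 6, 5))
  expect_true(all(rowSums(cc) == 10))
})

test_that("classification metrics follow their definitions", {
  cc <- data.frame(TP = 9, TN = 8, FP = 2, FN = 1)
  m <- classification_metrics(cc)
  expect_equal(m$SEN, 0.9)
  expect_equal(m$SPE, 0.8)
  expect_equal(m$EFF, 0.72)
  g <- classification_metrics(cc, variant = "geometric")
  expect_equal(g$EFF, sqrt(0.72))
  # perfect classifier: all three are 1 under either variant
  perf <- classification_metrics(data.frame(TP = 5, TN = 20, FP = 0, FN = 0))
  expect_equal(c(perf$SEN, perf$SPE, perf$EFF), c(1, 1, 1))
  # zero denominator flags rather than NaN
  z <- classification_metrics(data.frame(TP = 0, TN = 5, FP = 0, FN = 0))
  expect_true(z$undefined)
  expect_true(is.na(z$SEN))
  # EFF bounded by each factor
  set.seed(52)
  for (rep in 1:20) {
    cc <- data.frame(TP = sample(0:9, 1) + 1, TN = sample(0:9, 1) + 1,
                     FP = sample(0:9, 1), FN = sample(0:9, 1))
    m <- classification_metrics(cc)
    expect_lte(m$EFF, m$SEN + 1e-12)
    expect_lte(m$EFF, m$SPE + 1e-12)
  }
})

test_that("degenerate one-sided predictions give SEN 1 / SPE 0", {
  truth <- rep(c(1, 2), each = 5)
  pred <- rep(1, 10)
  m <- classification_metrics(confusion_counts(truth, pred, 2))
  expect_equal(m$SEN[1], 1)
  expect_equal(m$SPE[1], 0)
})
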