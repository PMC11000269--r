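# Residual network: architecture contract, splits, training, classification.

test_that("the architecture walk matches the specified block composition", {
  m <- build_model(model_spec(input_len = 175, n_blocks = 8))
  lay <- model_layers(m)
  for (b in 1:8) {
    blk <- lay[!is.na(lay$block) & lay$block == b & lay$layer != "inter_block_relu", ]
    expect_equal(blk$type, c("conv", "batch_norm", "relu", "conv", "batch_norm", "conv"))
    convs <- blk[blk$type == "conv", ]
    expect_equal(convs$kernel_len, c(3, 3, 1))        # two length-3 taps + 1x1 shortcut
    expect_equal(sum(blk$type == "batch_norm"), 2)
  }
  head_l <- lay[is.na(lay$block), ]
  expect_equal(head_l$type, c("relu", "gap", "dense", "softmax"))
  expect_equal(m$spec$stride, 1L)
  # parameter shapes: stacked conv weights are (kernel * in_channels) x channels
  expect_equal(dim(m$params$blocks[[2]]$W1), c(3 * 32, 32))
  expect_equal(dim(m$params$blocks[[1]]$W1), c(3 * 1, 32))
  expect_equal(dim(m$params$blocks[[1]]$Wsc), c(1, 32))
})

test_that("stride-1 same-padded blocks preserve the temporal length into pooling", {
  ns <- asNamespace("holterscan")
  m <- build_model(model_spec(input_len = 50, n_blocks = 3, channels = 6), seed = 2)
  X <- matrix(rnorm(4 * 50), 4, 50)
  fw <- ns$rn_forward(m, X, training = FALSE, cache = TRUE)
  expect_equal(nrow(fw$Hlast), 4 * 50)               # (segments x input_len) rows
  expect_equal(fw$feature_len, 50)
})

test_that("forward output is a probability simplex for arbitrary inputs", {
  m <- build_model(model_spec(input_len = 40, n_blocks = 2, channels = 4), seed = 3)
  m <- structure(c(m, list(class_order = c("N", "PSVC", "PVC"), trained = TRUE)),
                 class = c("beat_classifier", "resnet1d"))
  for (X in list(matrix(0, 3, 40), matrix(rnorm(30 * 40), 30, 40),
                 matrix(1e3 * rnorm(5 * 40), 5, 40))) {
    p <- predict(m, X, type = "prob")
    expect_true(all(is.finite(p)) && all(p >= 0 & p <= 1))
    expect_equal(rowSums(p), rep(1, nrow(X)), tolerance = 1e-6)
  }
  expect_equal(predict(m, matrix(numeric(0), 0, 40), "class"), character(0))
  expect_error(predict(m, matrix(0, 2, 39)), "input_len")
})

test_that("analytic gradients agree with finite differences", {
  ns <- asNamespace("holterscan")
  set.seed(4)
  m <- build_model(model_spec(input_len = 16, n_blocks = 2, channels = 4), seed = 2)
  X <- matrix(rnorm(5 * 16), 5, 16)
  Y <- diag(3)[sample(1:3, 5, TRUE), ]
  fw <- ns$rn_forward(m, X, training = TRUE, cache = TRUE)
  gr <- ns$rn_backward(m, fw, Y)
  loss <- function(mm) {
    f <- ns$rn_forward(mm, X, training = TRUE)
    -mean(log(rowSums(f$probs * Y)))
  }
  eps <- 1e-5
  for (bi in 1:2) for (nm in c("W1", "W2", "Wsc", "g1", "b2")) {
    g <- gr$blocks[[bi]][[nm]]
    for (j in sample(length(g), 3)) {
      m1 <- m; m1$params$blocks[[bi]][[nm]][j] <- m1$params$blocks[[bi]][[nm]][j] + eps
      m2 <- m; m2$params$blocks[[bi]][[nm]][j] <- m2$params$blocks[[bi]][[nm]][j] - eps
      num <- (loss(m1) - loss(m2)) / (2 * eps)
      expect_equal(g[j], num, tolerance = 1e-5)
    }
  }
})

test_that("patient splits are disjoint, proportional and deterministic", {
  sp <- split_by_patient(sprintf("P%02d", 1:10), seed = 3)
  expect_length(sp$train, 8); expect_length(sp$val, 1); expect_length(sp$test, 1)
  expect_identical(sp, split_by_patient(sprintf("P%02d", 1:10), seed = 3))
  expect_error(split_by_patient(c("a", "b")), "at least 3")
  # property sweep: disjoint and exhaustive for many random cohort sizes
  set.seed(99)
  for (i in 1:1000) {
    n <- sample(3:40, 1)
    ids <- paste0("x", sample(1e6, n))
    s <- split_by_patient(ids, seed = i)
    expect_length(intersect(s$train, s$val), 0)
    expect_length(intersect(s$train, s$test), 0)
    expect_length(intersect(s$val, s$test), 0)
    expect_setequal(c(s$train, s$val, s$test), ids)
  }
})

test_that("training overfits a tiny separable set and reduces the loss", {
  set.seed(8)
  # three synthetic bump classes, 20 beats each
  mk <- function(center, width, n) {
    t(vapply(seq_len(n), function(i) {
      x <- exp(-(seq_len(64) - center)^2 / (2 * width^2)) + rnorm(64, 0, 0.05)
      (x - mean(x)) / sd(x)
    }, numeric(64)))
  }
  X <- rbind(mk(20, 2, 20), mk(32, 6, 20), mk(45, 3, 20))
  y <- rep(c("N", "PSVC", "PVC"), each = 20)
  fit <- beat_classifier(X, y, spec = model_spec(64, n_blocks = 2, channels = 8),
                         epochs = 200, batch_size = 32, seed = 1)
  h <- fit$history
  expect_equal(max(h$train_acc), 1.0)
  expect_lt(h$train_loss[nrow(h)], h$train_loss[1])
  expect_identical(fit$class_order, c("N", "PSVC", "PVC"))
})

test_that("training errors when a class is missing from the training patients", {
  set.seed(2)
  X <- matrix(rnorm(30 * 20), 30, 20)
  y <- rep(c("N", "PVC", "PSVC"), each = 10)
  expect_error(
    beat_classifier(X[y != "PSVC", ], y[y != "PSVC"],
                    spec = model_spec(20, n_blocks = 1, channels = 2, n_classes = 3)),
    "classes")
  # with patient splitting, a class present only in the held-out patient fails
  pat <- c(rep("A", 10), rep("B", 10), rep("C", 10))
  expect_error(suppressWarnings(
    beat_classifier(X, y, patient = pat, spec = model_spec(20, 1, channels = 2))),
    "absent from training")
})

test_that("label-shuffled training yields chance-level validation accuracy", {
  set.seed(31)
  X <- matrix(rnorm(90 * 32), 90, 32)
  accs <- vapply(1:10, function(s) {
    y <- sample(rep(c("N", "PSVC", "PVC"), each = 30))
    fit <- beat_classifier(X, y, spec = model_spec(32, n_blocks = 1, channels = 4),
                           epochs = 3, batch_size = 32, seed = s)
    tail(fit$history$val_acc, 1)
  }, numeric(1))
  # null control: mean accuracy within 3 SE of 1/3 (SE over the 10 runs)
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 1 / 3), 3 * max(se, 0.02))
})

test_that("the trained classifier recovers held-out beat labels on synthetic data", {
  fit <- fixture_trained_model()
  d <- fixture_beat_dataset()
  expect_gt(length(unique(d$patient)), 5)
  expect_gt(nrow(d$x), 2000)
  test_rows <- d$patient %in% fit$split$test
  pred <- predict(fit, d$x[test_rows, ], type = "class")
  expect_gte(mean(pred == d$labels[test_rows]), 0.95)
  # probability output matches the argmax labels with ties toward N
  cb <- classify_beats(fit, d$x[test_rows, ][1:20, ])
  expect_equal(cb$label, pred[1:20])
  expect_equal(rowSums(cb$prob), rep(1, 20), tolerance = 1e-6)
})

test_that("training is reproducible under a fixed seed", {
  set.seed(77)
  X <- matrix(rnorm(60 * 24), 60, 24)
  y <- rep(c("N", "PVC"), each = 30)
  f1 <- beat_classifier(X, y, spec = model_spec(24, 1, channels = 3, n_classes = 2),
                        epochs = 3, seed = 12)
  f2 <- beat_classifier(X, y, spec = model_spec(24, 1, channels = 3, n_classes = 2),
                        epochs = 3, seed = 12)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
})
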