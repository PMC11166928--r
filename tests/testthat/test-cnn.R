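make_image_set <- function(n_per_class, H, W, classes = 2L, noise = 0.5,
                           seed = 1) {
  set.seed(seed)
  n <- n_per_class * classes
  x <- array(runif(n * H * W) < noise, c(n, H, W)) * 1
  labels <- rep(seq_len(classes), each = n_per_class)
  for (i in seq_len(n)) if (labels[i] == 2) x[i, , ] <- 1 - x[i, , ]
  structure(list(x = x, labels = labels), class = "image_set")
}

test_that("the classifier architecture matches its specification", {
  clf <- build_classifier(c(20, 30), 12, seed = 1)
  expect_equal(clf$spec$n_models, 12L)
  expect_equal(ncol(clf$params$Wo), 12L) # output layer width = model count
  expect_equal(dim(clf$params$W1)[1], 3L) # 3x1 kernels throughout
  expect_equal(dim(clf$params$W2)[1], 3L)
  expect_equal(ncol(clf$params$Wd1), 100L)
  expect_equal(ncol(clf$params$Wd2), 40L)
  expect_equal(clf$spec$batch_size, 100L)
  expect_equal(clf$spec$epochs, 10L)
  expect_error(build_classifier(c(10, 30), 3), "minimal admissible")
})

test_that("softmax outputs are probabilities even untrained", {
  clf <- build_classifier(c(18, 25), 5, n_filters = c(3L, 4L), seed = 2)
  x <- array(runif(4 * 18 * 25), c(4, 18, 25))
  p <- landcnn:::cnn_forward(clf$params, x)$probs
  expect_equal(dim(p), c(4L, 5L)) # one vector per image
  expect_equal(rowSums(p), rep(1, 4), tolerance = 1e-6)
  expect_true(all(p >= 0))
})

test_that("backpropagation matches finite-difference gradients", {
  set.seed(7)
  clf <- build_classifier(c(20, 6), 3, n_filters = c(3L, 4L),
                          dense_units = c(10L, 8L), seed = 5)
  N <- 5
  x <- array(runif(N * 20 * 6), c(N, 20, 6))
  y <- matrix(0, N, 3)
  y[cbind(seq_len(N), sample(1:3, N, TRUE))] <- 1
  fwd <- landcnn:::cnn_forward(clf$params, x, keep = TRUE)
  g <- landcnn:::cnn_backward(clf$params, fwd, y)
  loss_at <- function(params) {
    p <- landcnn:::cnn_forward(params, x)$probs
    -sum(log(p[y == 1]))
  }
  eps <- 1e-5
  for (nm in names(g)) {
    expect_gt(max(abs(g[[nm]])), 0) # no dead layers in this configuration
    idx <- order(-abs(g[[nm]]))[1:3]
    for (i in idx) {
      up <- clf$params
      up[[nm]][i] <- up[[nm]][i] + eps
      dn <- clf$params
      dn[[nm]][i] <- dn[[nm]][i] - eps
      num <- (loss_at(up) - loss_at(dn)) / (2 * eps)
      expect_equal(g[[nm]][i], num, tolerance = 1e-5)
    }
  }
})

test_that("training separates trivially separable classes", {
  train <- structure(list(x = array(0, c(100, 20, 12)),
                          labels = rep(1:2, each = 50)),
                     class = "image_set")
  train$x[51:100, , ] <- 1 # all-zero vs all-one images
  clf <- build_classifier(c(20, 12), 2, n_filters = c(4L, 6L), seed = 1)
  clf <- train_classifier(clf, train, seed = 1)
  expect_length(clf$history$loss, 10L) # exactly ten epochs
  expect_lt(clf$history$loss[10], clf$history$loss[1])
  expect_equal(evaluate_classifier(clf, train)$overall_accuracy, 100)
})

test_that("training is deterministic under a seed", {
  train <- make_image_set(30, 18, 10, seed = 11)
  clf0 <- build_classifier(c(18, 10), 2, n_filters = c(2L, 3L), seed = 4)
  a <- train_classifier(clf0, train, seed = 9, epochs = 3, batch_size = 20)
  b <- train_classifier(clf0, train, seed = 9, epochs = 3, batch_size = 20)
  expect_identical(a$history$loss, b$history$loss)
  expect_identical(a$params, b$params)
})

test_that("degenerate training sets are rejected", {
  train <- make_image_set(20, 18, 10, seed = 12)
  clf <- build_classifier(c(18, 10), 2, n_filters = c(2L, 3L), seed = 4)
  single <- structure(list(x = train$x[train$labels == 1, , , drop = FALSE],
                           labels = rep(1L, 20)), class = "image_set")
  expect_error(train_classifier(clf, single, seed = 1), "label-coverage")
  clf3 <- build_classifier(c(18, 10), 3, n_filters = c(2L, 3L), seed = 4)
  expect_error(train_classifier(clf3, train, seed = 1), "2 classes")
})

test_that("evaluation reports follow the count formulas", {
  # perfect predictor: identity confusion, accuracy 100, precision=recall=1
  truth <- rep(1:3, each = 10)
  perfect <- evaluation_report(truth, truth)
  expect_equal(unname(diag(perfect$confusion)), rep(100, 3))
  expect_equal(perfect$overall_accuracy, 100)
  expect_equal(unname(perfect$precision), rep(1, 3))
  expect_equal(unname(perfect$recall), rep(1, 3))
  expect_equal(unname(rowSums(perfect$confusion)), rep(100, 3))

  # two-class toy with TP=40, FP=10, FN=20 for class "A"
  true <- c(rep("A", 60), rep("B", 40))
  pred <- c(rep("A", 40), rep("B", 20), rep("A", 10), rep("B", 30))
  rep2 <- evaluation_report(true, pred, classes = c("A", "B"))
  expect_equal(unname(rep2$precision["A"]), 40 / (40 + 10))
  expect_equal(unname(rep2$recall["A"]), 40 / (40 + 20), tolerance = 1e-12)
  expect_equal(rep2$overall_accuracy, 70)
  expect_equal(unname(rowSums(rep2$confusion)), c(100, 100))
})

test_that("label permutation drives accuracy to chance", {
  train <- make_image_set(40, 18, 12, classes = 2L, seed = 13)
  test <- make_image_set(40, 18, 12, classes = 2L, seed = 14)
  set.seed(15)
  train$labels <- sample(train$labels)
  clf <- build_classifier(c(18, 12), 2, n_filters = c(2L, 3L), seed = 5)
  clf <- train_classifier(clf, train, seed = 5, epochs = 5, batch_size = 20)
  acc <- evaluate_classifier(clf, test)$overall_accuracy / 100
  n <- length(test$labels)
  band <- stats::qbinom(c(0.025, 0.975), n, 0.5) / n
  expect_gte(acc, band[1])
  expect_lte(acc, band[2])
})

test_that("calibration bins partition predictions as specified", {
  # an always-confident, always-right predictor
  rep1 <- calibration_bins(rep(1, 50), rep(TRUE, 50))
  expect_equal(nrow(rep1), 5L)
  expect_equal(rep1$count, c(0L, 0L, 0L, 0L, 50L))
  expect_equal(rep1$accuracy[5], 1)
  expect_true(all(is.na(rep1$accuracy[1:4]))) # empty bins flagged undefined
  expect_equal(sum(rep1$count), 50L)

  # softmax of uniform random 12-class logits never exceeds confidence 0.4
  set.seed(16)
  p <- exp(matrix(runif(2000 * 12), 2000))
  p <- p / rowSums(p)
  top <- apply(p, 1, max)
  rep2 <- calibration_bins(top, rep(TRUE, 2000))
  expect_equal(sum(rep2$count[1:2]), 2000L)
  expect_equal(sum(rep2$count[3:5]), 0L)
})

test_that("synthetic calibrated predictions land inside their bins", {
  set.seed(17)
  n <- 2000
  conf <- runif(n, 0.025, 0.975)
  correct <- runif(n) < conf # confidence equals correctness probability
  rep3 <- calibration_bins(conf, correct)
  inside <- rep3$accuracy >= rep3$lower & rep3$accuracy <= rep3$upper
  expect_gte(sum(inside, na.rm = TRUE), 4)
})

test_that("stratified splits are exact, disjoint and exhaustive", {
  imgs <- structure(list(x = array(runif(20 * 18 * 9), c(20, 18, 9)),
                         labels = rep(1:2, each = 10)), class = "image_set")
  parts <- split_dataset(imgs, train_fraction = 0.8, seed = 2)
  expect_equal(dim(parts$train$x)[1], 16L)
  expect_equal(dim(parts$test$x)[1], 4L)
  expect_equal(as.integer(table(parts$train$labels)), c(8L, 8L))
  parts2 <- split_dataset(imgs, train_fraction = 0.8, seed = 2)
  expect_identical(parts$train$labels, parts2$train$labels)
  expect_identical(parts$train$x, parts2$train$x)
  bad <- imgs
  bad$labels[1] <- 2L
  expect_error(split_dataset(bad), "stratification error")
})

test_that("empirical prediction returns a probability vector over models", {
  train <- make_image_set(30, 18, 10, seed = 18)
  clf <- build_classifier(c(18, 10), 2, n_filters = c(2L, 3L), seed = 6)
  clf <- train_classifier(clf, train, seed = 6, epochs = 3, batch_size = 20)
  img <- structure(list(pixels = matrix(as.integer(runif(180) < 0.5), 18, 10),
                        row_manifest = NULL, label = NA_integer_),
                   class = "snp_image")
  pred <- predict_empirical(clf, img)
  expect_equal(sum(pred$probabilities), 1, tolerance = 1e-6)
  expect_true(pred$selected %in% clf$classes)
  wrong <- img
  wrong$pixels <- wrong$pixels[, 1:5]
  expect_error(predict_empirical(clf, wrong), "re-encode")
})
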