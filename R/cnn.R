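#' Convolutional classifier over landscape models
#'
#' A small fixed-architecture CNN operating on binary SNP images
#' (sequences x SNPs): convolution (3x1 kernel, i.e. 3 sequence rows by 1
#' SNP column, stride 1, no padding) -> 3x1 max-pool -> convolution (3x1)
#' -> 3x1 max-pool -> flatten -> dense 100 -> dense 40 -> softmax output
#' with one unit per candidate model. Hidden activations are ReLU. Training
#' uses Adam (lr 0.001, beta1 0.9, beta2 0.999), categorical cross-entropy,
#' mini-batches of 100 and 10 epochs by default. The implementation is
#' self-contained (BLAS matrix products), so runs are reproducible under a
#' seed on a single thread.
#'
#' @param input_shape integer length-2: image height (sequences) and width
#'   (SNPs). Two valid 3x1 conv+pool stages require a height of at least 17.
#' @param n_models number of output classes.
#' @param n_filters filters in the two convolution layers (default 8, 16).
#' @param dense_units units in the two dense layers (default 100, 40).
#' @param seed optional seed for weight initialization.
#' @return an untrained `landcnn_classifier`.
#' @export
build_classifier <- function(input_shape, n_models, n_filters = c(8L, 16L),
                             dense_units = c(100L, 40L), seed = NULL) {
  H <- input_shape[1]; W <- input_shape[2]
  shapes <- tryCatch(conv_shapes(H), error = function(e) e)
  if (inherits(shapes, "error"))
    stop(sprintf(paste0("input height %d too small for two 3x1 conv+pool ",
                        "stages; minimal admissible shape is 17 x 1"), H))
  if (!is.null(seed)) set.seed(seed)
  f1 <- n_filters[1]; f2 <- n_filters[2]
  flat <- shapes$hp2 * W * f2
  he <- function(fan_in, n) rnorm(n, sd = sqrt(2 / fan_in))
  params <- list(
    W1 = array(he(3, 3 * 1 * f1), c(3, 1, f1)), b1 = numeric(f1),
    W2 = array(he(3 * f1, 3 * f1 * f2), c(3, f1, f2)), b2 = numeric(f2),
    Wd1 = matrix(he(flat, flat * dense_units[1]), flat, dense_units[1]),
    bd1 = numeric(dense_units[1]),
    Wd2 = matrix(he(dense_units[1], prod(dense_units)), dense_units[1],
                 dense_units[2]),
    bd2 = numeric(dense_units[2]),
    Wo = matrix(he(dense_units[2], dense_units[2] * n_models),
                dense_units[2], n_models),
    bo = numeric(n_models))
  structure(list(
    spec = list(input_shape = c(H, W), n_models = as.integer(n_models),
                n_filters = c(f1, f2), dense_units = dense_units,
                kernel = c(3L, 1L), pool = c(3L, 1L), optimizer = "adam",
                loss = "categorical_crossentropy", batch_size = 100L,
                epochs = 10L, shapes = shapes),
    params = params, classes = NULL, history = NULL),
    class = "landcnn_classifier")
}

conv_shapes <- function(H) {
  h1 <- H - 2L
  hp1 <- h1 %/% 3L
  if (hp1 < 3L) stop("too small")
  h2 <- hp1 - 2L
  hp2 <- h2 %/% 3L
  if (hp2 < 1L) stop("too small")
  list(h1 = h1, hp1 = hp1, h2 = h2, hp2 = hp2)
}

#' @export
print.landcnn_classifier <- function(x, ...) {
  s <- x$spec
  cat(sprintf(paste0("landcnn_classifier: input %d x %d -> conv3x1(%d) -> ",
                     "pool3x1 -> conv3x1(%d) -> pool3x1 -> dense %d -> ",
                     "dense %d -> softmax(%d)%s\n"),
              s$input_shape[1], s$input_shape[2], s$n_filters[1],
              s$n_filters[2], s$dense_units[1], s$dense_units[2], s$n_models,
              if (is.null(x$classes)) " [untrained]" else " [trained]"))
  invisible(x)
}

relu <- function(x) { x[x < 0] <- 0; x }

# Thin wrappers over the compiled 3x1 kernels (ties in the pool go to the
# first row of the window; see src/convnet.cpp).
conv_forward <- function(x, W, b) .conv3_forward(x, dim(x), W, b)

conv_backward <- function(x, W, dY) .conv3_backward(x, dim(x), W, dY)

pool_forward <- function(x) .pool3_forward(x, dim(x))

pool_backward <- function(p, dY) .pool3_backward(p$which, dY, p$H)

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Forward pass; x is (N, H, W). Returns probabilities and, if keep = TRUE,
# the activations needed for backprop.
cnn_forward <- function(params, x, keep = FALSE) {
  d <- dim(x)
  x4 <- x
  dim(x4) <- c(d[1], d[2], d[3], 1L)
  z1 <- conv_forward(x4, params$W1, params$b1)
  a1 <- relu(z1)
  p1 <- pool_forward(a1)
  z2 <- conv_forward(p1$out, params$W2, params$b2)
  a2 <- relu(z2)
  p2 <- pool_forward(a2)
  flat <- p2$out
  dim(flat) <- c(d[1], prod(dim(p2$out)[2:4]))
  h1 <- relu(flat %*% params$Wd1 + rep(params$bd1, each = d[1]))
  h2 <- relu(h1 %*% params$Wd2 + rep(params$bd2, each = d[1]))
  logits <- h2 %*% params$Wo + rep(params$bo, each = d[1])
  probs <- softmax_rows(logits)
  if (!keep) return(list(probs = probs))
  list(probs = probs, x4 = x4, z1 = z1, p1 = p1, z2 = z2, p2 = p2,
       flat = flat, h1 = h1, h2 = h2)
}

# Gradients of the summed cross-entropy over the chunk (divide by batch
# size outside). y is the one-hot matrix.
cnn_backward <- function(params, cache, y) {
  dlogit <- cache$probs - y
  dWo <- crossprod(cache$h2, dlogit)
  dbo <- colSums(dlogit)
  dh2 <- tcrossprod(dlogit, params$Wo) * (cache$h2 > 0)
  dWd2 <- crossprod(cache$h1, dh2)
  dbd2 <- colSums(dh2)
  dh1 <- tcrossprod(dh2, params$Wd2) * (cache$h1 > 0)
  dWd1 <- crossprod(cache$flat, dh1)
  dbd1 <- colSums(dh1)
  dflat <- tcrossprod(dh1, params$Wd1)
  dp2 <- dflat
  dim(dp2) <- dim(cache$p2$out)
  da2 <- pool_backward(cache$p2, dp2)
  dz2 <- da2 * (cache$z2 > 0)
  g2 <- conv_backward(cache$p1$out, params$W2, dz2)
  da1 <- pool_backward(cache$p1, g2$dx)
  dz1 <- da1 * (cache$z1 > 0)
  g1 <- conv_backward(cache$x4, params$W1, dz1)
  list(W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db,
       Wd1 = dWd1, bd1 = dbd1, Wd2 = dWd2, bd2 = dbd2, Wo = dWo, bo = dbo)
}

#' Train the classifier
#'
#' Mini-batch Adam on categorical cross-entropy for a fixed number of
#' epochs (a trailing partial batch is allowed). The per-epoch mean training
#' loss is recorded in the returned classifier's `history`.
#'
#' @param clf an untrained (or previously trained) `landcnn_classifier`.
#' @param train an `image_set` with labels covering at least two classes;
#'   the number of distinct labels must equal the classifier's output width.
#' @param seed integer seed controlling batch shuffling.
#' @param epochs,batch_size,lr training hyperparameters (defaults 10, 100,
#'   0.001).
#' @param chunk_size internal forward/backward chunk (gradients are exact
#'   for the full mini-batch regardless; smaller chunks only bound memory).
#' @param verbose print the per-epoch loss.
#' @return the trained classifier, with `classes` (sorted label values) and
#'   `history$loss` (length `epochs`) filled in.
#' @export
train_classifier <- function(clf, train, seed = 1, epochs = 10L,
                             batch_size = 100L, lr = 0.001,
                             chunk_size = 32L, verbose = FALSE) {
  stopifnot(inherits(clf, "landcnn_classifier"), inherits(train, "image_set"))
  labels <- train$labels
  if (any(is.na(labels))) stop("training set must be fully labeled")
  classes <- sort(unique(labels))
  if (length(classes) < 2)
    stop("label-coverage error: training set holds a single class")
  if (length(classes) != clf$spec$n_models)
    stop(sprintf("classifier has %d outputs but training set has %d classes",
                 clf$spec$n_models, length(classes)))
  n <- dim(train$x)[1]
  y_idx <- match(labels, classes)
  onehot <- matrix(0, n, length(classes))
  onehot[cbind(seq_len(n), y_idx)] <- 1

  set.seed(seed)
  adam <- list(m = lapply(clf$params, function(p) p * 0),
               v = lapply(clf$params, function(p) p * 0), t = 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  loss_trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    starts <- seq(1L, n, by = batch_size)
    for (bs in starts) {
      batch <- ord[bs:min(bs + batch_size - 1L, n)]
      nb <- length(batch)
      grads <- NULL
      bloss <- 0
      for (cs in seq(1L, nb, by = chunk_size)) {
        rows <- batch[cs:min(cs + chunk_size - 1L, nb)]
        cache <- cnn_forward(clf$params, train$x[rows, , , drop = FALSE],
                             keep = TRUE)
        yb <- onehot[rows, , drop = FALSE]
        bloss <- bloss - sum(log(pmax(cache$probs[yb == 1], 1e-12)))
        g <- cnn_backward(clf$params, cache, yb)
        grads <- if (is.null(grads)) g
                 else Map(`+`, grads, g)
      }
      grads <- lapply(grads, `/`, nb)
      adam$t <- adam$t + 1
      c1 <- 1 - beta1^adam$t
      c2 <- 1 - beta2^adam$t
      for (nm in names(clf$params)) {
        adam$m[[nm]] <- beta1 * adam$m[[nm]] + (1 - beta1) * grads[[nm]]
        adam$v[[nm]] <- beta2 * adam$v[[nm]] + (1 - beta2) * grads[[nm]]^2
        clf$params[[nm]] <- clf$params[[nm]] -
          lr * (adam$m[[nm]] / c1) / (sqrt(adam$v[[nm]] / c2) + eps)
      }
      ep_loss <- ep_loss + bloss
    }
    loss_trace[ep] <- ep_loss / n
    if (verbose) message(sprintf("epoch %d/%d: loss %.4f", ep, epochs,
                                 loss_trace[ep]))
  }
  clf$classes <- classes
  clf$history <- list(loss = loss_trace)
  clf
}

#' Predict class probabilities for a set of images
#'
#' @param clf a trained `landcnn_classifier`.
#' @param x an `image_set` or numeric array (N, height, width).
#' @param chunk_size forward-pass chunk.
#' @return matrix (N x n_models) of softmax probabilities, columns named by
#'   class label.
#' @export
predict_proba <- function(clf, x, chunk_size = 64L) {
  if (inherits(x, "image_set")) x <- x$x
  d <- dim(x)
  if (!all(d[2:3] == clf$spec$input_shape))
    stop(sprintf(paste0("image shape %d x %d differs from the training ",
                        "shape %d x %d; re-encode with the training design"),
                 d[2], d[3], clf$spec$input_shape[1], clf$spec$input_shape[2]))
  out <- matrix(0, d[1], clf$spec$n_models)
  for (cs in seq(1L, d[1], by = chunk_size)) {
    rows <- cs:min(cs + chunk_size - 1L, d[1])
    out[rows, ] <- cnn_forward(clf$params, x[rows, , , drop = FALSE])$probs
  }
  if (!is.null(clf$classes)) colnames(out) <- clf$classes
  out
}

#' Evaluate a trained classifier on a labeled test set
#'
#' Argmax predictions against the true labels: confusion matrix as row
#' percentages (rows = true model, columns = predicted), overall accuracy in
#' percent (the count-weighted trace), and per-model precision
#' TP / (TP + FP) and recall TP / (TP + FN).
#'
#' @param clf a trained `landcnn_classifier`.
#' @param test a labeled `image_set`.
#' @return an `evaluation_report`.
#' @export
evaluate_classifier <- function(clf, test) {
  probs <- predict_proba(clf, test)
  pred <- clf$classes[max.col(probs, ties.method = "first")]
  evaluation_report(test$labels, pred, clf$classes)
}

#' @rdname evaluate_classifier
#' @param true,pred vectors of true and predicted labels.
#' @param classes class levels fixing the confusion-matrix order.
#' @export
evaluation_report <- function(true, pred, classes = sort(unique(true))) {
  counts <- table(factor(true, classes), factor(pred, classes))
  counts <- matrix(counts, length(classes), length(classes),
                   dimnames = list(true = classes, predicted = classes))
  pct <- 100 * counts / pmax(rowSums(counts), 1)
  tp <- diag(counts)
  structure(list(
    confusion_counts = counts, confusion = pct,
    overall_accuracy = 100 * sum(tp) / sum(counts),
    precision = ifelse(colSums(counts) > 0, tp / colSums(counts), NA_real_),
    recall = ifelse(rowSums(counts) > 0, tp / rowSums(counts), NA_real_),
    n_test = sum(counts)),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report: overall accuracy %.1f%% on %d test images\n",
              x$overall_accuracy, x$n_test))
  cat("confusion (row %):\n")
  print(round(x$confusion, 1))
  invisible(x)
}

#' Softmax calibration report
#'
#' Bins each test prediction's top softmax probability into five confidence
#' classes (0-20, 20-40, 40-60, 60-80, 80-100%) and reports the count and
#' the empirical accuracy per bin; a well-calibrated classifier has per-bin
#' accuracy inside the bin's confidence interval. Empty bins are reported
#' with count 0 and accuracy NA.
#'
#' @param clf a trained `landcnn_classifier`.
#' @param test a labeled `image_set`.
#' @return a `calibration_report` data frame: `bin`, `lower`, `upper`,
#'   `count`, `accuracy`.
#' @export
calibration_report <- function(clf, test) {
  probs <- predict_proba(clf, test)
  top <- max.col(probs, ties.method = "first")
  conf <- probs[cbind(seq_len(nrow(probs)), top)]
  correct <- clf$classes[top] == test$labels
  calibration_bins(conf, correct)
}

#' @rdname calibration_report
#' @param confidence vector of top softmax probabilities in \[0, 1\].
#' @param correct logical vector: was the argmax prediction right?
#' @export
calibration_bins <- function(confidence, correct) {
  breaks <- c(0, 0.2, 0.4, 0.6, 0.8, 1)
  bin <- cut(confidence, breaks, include.lowest = TRUE)
  out <- data.frame(
    bin = levels(bin),
    lower = breaks[-6], upper = breaks[-1],
    count = as.integer(table(bin)),
    accuracy = as.numeric(tapply(correct, bin, mean)[levels(bin)]))
  rownames(out) <- NULL
  class(out) <- c("calibration_report", "data.frame")
  out
}

#' Predict the landscape model for an empirical image
#'
#' @param clf a trained `landcnn_classifier`.
#' @param image a `snp_image` encoded with the same encoder and design as
#'   the training images.
#' @return list with `probabilities` (named over models, summing to 1) and
#'   `selected` (the argmax model id).
#' @export
predict_empirical <- function(clf, image) {
  stopifnot(inherits(image, "snp_image"))
  x <- array(0, c(1L, nrow(image$pixels), ncol(image$pixels)))
  x[1, , ] <- image$pixels
  p <- predict_proba(clf, x)[1, ]
  list(probabilities = p, selected = clf$classes[which.max(p)])
}

#' Stratified train/test split
#'
#' Splits a labeled image set by label: per model,
#' `round(train_fraction * n)` images go to training and the rest to test;
#' the split is disjoint and exhaustive and requires equal example counts
#' per label.
#'
#' @param images a labeled `image_set`.
#' @param train_fraction fraction per label assigned to training
#'   (default 0.8).
#' @param seed integer seed for the within-label shuffle.
#' @return list with `train` and `test` image sets.
#' @export
split_dataset <- function(images, train_fraction = 0.8, seed = 1) {
  stopifnot(inherits(images, "image_set"))
  labels <- images$labels
  if (any(is.na(labels))) stop("split requires a fully labeled set")
  tab <- table(labels)
  if (length(unique(as.integer(tab))) != 1)
    stop("stratification error: unequal example counts per label")
  set.seed(seed)
  train_idx <- integer(0)
  for (lv in names(tab)) {
    idx <- which(labels == as.integer(lv))
    n_train <- round(train_fraction * length(idx))
    train_idx <- c(train_idx, sample(idx, n_train))
  }
  list(train = subset_image_set(images, sort(train_idx)),
       test = subset_image_set(images, sort(setdiff(seq_along(labels),
                                                    train_idx))))
}
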