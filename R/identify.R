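#' Configuration of the 1D convolutional spectrum classifier
#'
#' Hyperparameters of the five-layer network (convolution, ReLU, fully
#' connected, ReLU, fully connected; softmax output over the three classes
#' interference / BZD / EBZD) and of its training schedule: adaptive moment
#' estimation (Adam) starting at `lr_init = 1e-4` with cosine annealing to
#' `lr_min = 1e-5` over a period of 10 epochs (warm restarts each period), and
#' a stratified 7:3 train/validation split.
#'
#' @param input_length Channels per spectrum (default 308).
#' @param conv_channels,kernel_size,stride Convolution layer shape
#'   (defaults 8 filters, kernel 7, stride 1).
#' @param hidden_units Width of the first fully connected layer (default 64).
#' @param n_classes Fixed at 3.
#' @param lr_init,lr_min Initial and minimum learning rates (1e-4, 1e-5).
#' @param cosine_period_epochs Annealing period (default 10).
#' @param warm_restarts Restart the cosine each period (default `TRUE`); if
#'   `FALSE` the rate stays at `lr_min` after one period.
#' @param epochs,batch_size Training length (100) and minibatch size (8).
#' @param split_ratio Train fraction of the stratified split (0.7).
#' @param seed RNG seed for weight initialization and shuffling (default 42).
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(input_length = 308L, conv_channels = 8L,
                              kernel_size = 7L, stride = 1L,
                              hidden_units = 64L, n_classes = 3L,
                              lr_init = 1e-4, lr_min = 1e-5,
                              cosine_period_epochs = 10L,
                              warm_restarts = TRUE,
                              epochs = 100L, batch_size = 8L,
                              split_ratio = 0.7, seed = 42L) {
  if (n_classes != 3L) stop("the classifier is fixed at 3 classes", call. = FALSE)
  if (!(lr_min < lr_init)) stop("lr_min must be below lr_init", call. = FALSE)
  if (split_ratio <= 0 || split_ratio >= 1)
    stop("split_ratio must be in (0, 1)", call. = FALSE)
  if (stride < 1L) stop("stride must be >= 1", call. = FALSE)
  structure(list(input_length = as.integer(input_length),
                 conv_channels = as.integer(conv_channels),
                 kernel_size = as.integer(kernel_size),
                 stride = as.integer(stride),
                 hidden_units = as.integer(hidden_units),
                 n_classes = 3L, lr_init = lr_init, lr_min = lr_min,
                 cosine_period_epochs = as.integer(cosine_period_epochs),
                 warm_restarts = isTRUE(warm_restarts),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 split_ratio = split_ratio, seed = as.integer(seed)),
            class = "classifier_config")
}

#' Build (initialize) the 1D CNN classifier
#'
#' Layer sequence: 1D convolution -> ReLU -> fully connected -> ReLU -> fully
#' connected -> softmax. Weights use seeded He-normal initialization, so the
#' model is deterministic given `config$seed`.
#'
#' @param config A [classifier_config()].
#' @return An object of class `sers_cnn` holding the weight matrices, the
#'   config and `n_parameters`.
#' @export
build_classifier <- function(config = classifier_config()) {
  stopifnot(inherits(config, "classifier_config"))
  L <- config$input_length; K <- config$kernel_size; s <- config$stride
  if (K > L)
    stop(sprintf("kernel size %d exceeds input length %d", K, L), call. = FALSE)
  L_out <- (L - K) %/% s + 1L
  C <- config$conv_channels; Hn <- config$hidden_units
  set.seed(config$seed)
  he <- function(nr, nc, fan_in) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
  w <- list(Wc = he(C, K, K), bc = numeric(C),
            W1 = he(Hn, C * L_out, C * L_out), b1 = numeric(Hn),
            W2 = he(3L, Hn, Hn), b2 = numeric(3L))
  n_par <- sum(vapply(w, length, integer(1)))
  structure(list(weights = w, config = config, L_out = L_out,
                 n_parameters = n_par),
            class = "sers_cnn")
}

#' @export
print.sers_cnn <- function(x, ...) {
  cat(sprintf("<sers_cnn> conv(%d x k%d) -> ReLU -> FC(%d) -> ReLU -> FC(3) -> softmax; %d parameters\n",
              x$config$conv_channels, x$config$kernel_size,
              x$config$hidden_units, x$n_parameters))
  invisible(x)
}

#' Cosine-annealing learning-rate schedule
#'
#' `eta(t) = lr_min + (lr_init - lr_min) * (1 + cos(pi * (t mod T) / T)) / 2`
#' with period `T = cosine_period_epochs`; with warm restarts the schedule
#' repeats every period (epoch 0 and epoch T both give `lr_init`), otherwise
#' `t` is capped at `T`.
#'
#' @param epoch Integer epoch index, >= 0 (vector allowed).
#' @param config A [classifier_config()].
#' @return Learning rate(s).
#' @export
lr_schedule <- function(epoch, config = classifier_config()) {
  T <- config$cosine_period_epochs
  t <- if (config$warm_restarts) epoch %% T else pmin(epoch, T)
  config$lr_min + (config$lr_init - config$lr_min) * (1 + cos(pi * t / T)) / 2
}

#' Stratified train/validation split
#'
#' Shuffles within each label and sends `round(ratio * n_label)` spectra per
#' label to the training set, the remainder to validation — a deterministic
#' partition given `seed`. Labels with fewer than 2 spectra go entirely to the
#' training set with a warning.
#'
#' @param dataset A [labeled_spectrum_dataset()].
#' @param ratio Train fraction (default 0.7).
#' @param seed RNG seed (default 42).
#' @return List with elements `train` and `valid`.
#' @export
split_dataset <- function(dataset, ratio = 0.7, seed = 42L) {
  stopifnot(inherits(dataset, "labeled_spectrum_dataset"))
  if (nrow(dataset$spectra) == 0L) stop("dataset is empty", call. = FALSE)
  set.seed(seed)
  train_idx <- integer(0)
  for (lab in sort(unique(dataset$labels))) {
    idx <- which(dataset$labels == lab)
    if (length(idx) < 2L) {
      warning(sprintf("label %d has < 2 spectra; all sent to train", lab))
      train_idx <- c(train_idx, idx)
      next
    }
    idx <- sample(idx)
    train_idx <- c(train_idx, idx[seq_len(round(ratio * length(idx)))])
  }
  valid_idx <- setdiff(seq_along(dataset$labels), train_idx)
  list(train = labeled_spectrum_dataset(
         dataset$spectra[train_idx, , drop = FALSE],
         dataset$labels[train_idx], split_tag = "train"),
       valid = labeled_spectrum_dataset(
         dataset$spectra[valid_idx, , drop = FALSE],
         dataset$labels[valid_idx], split_tag = "valid"))
}

# per-spectrum max-normalization used at every entry point to the network
normalize_spectra <- function(X) {
  mx <- apply(X, 1L, max)
  mx[mx <= 0] <- 1
  X / mx
}

# forward pass for one normalized spectrum; returns activations for backprop
cnn_forward <- function(w, x, idx) {
  Xw <- matrix(x[idx], nrow(idx), ncol(idx))       # L_out x K windows
  Z1 <- Xw %*% t(w$Wc) + rep(w$bc, each = nrow(Xw)) # L_out x C
  A1 <- pmax(Z1, 0)
  a1 <- as.vector(A1)
  z2 <- as.vector(w$W1 %*% a1 + w$b1)
  a2 <- pmax(z2, 0)
  z3 <- as.vector(w$W2 %*% a2 + w$b2)
  p <- exp(z3 - max(z3)); p <- p / sum(p)
  list(Xw = Xw, Z1 = Z1, a1 = a1, z2 = z2, a2 = a2, p = p)
}

#' Train the 1D CNN spectrum classifier
#'
#' Minimizes cross-entropy with Adam under the cosine-annealing
#' [lr_schedule()]. Every spectrum is max-normalized on entry. Minibatches are
#' reshuffled each epoch; weight initialization, shuffling and therefore the
#' final model are deterministic given `config$seed`.
#'
#' @param train,valid [labeled_spectrum_dataset()] splits (e.g. from
#'   [split_dataset()]); `valid` may be `NULL`.
#' @param config A [classifier_config()].
#' @return List with `model` (class `sers_cnn`, trained weights) and `report`
#'   (class `classifier_report`): per-epoch `loss_curves` (train, valid) and
#'   per-epoch training accuracy.
#' @export
train_classifier <- function(train, valid = NULL,
                             config = classifier_config()) {
  stopifnot(inherits(train, "labeled_spectrum_dataset"))
  if (!all(train$labels %in% 0:2)) stop("labels must be in {0,1,2}", call. = FALSE)
  model <- build_classifier(config)   # seeds the RNG; shuffles continue the stream
  w <- model$weights
  s <- config$stride
  idx <- outer(1L + (seq_len(model$L_out) - 1L) * s,
               0:(config$kernel_size - 1L), "+")
  Xtr <- pad_spectra(train$spectra, config$input_length)
  Xtr <- normalize_spectra(Xtr)
  ytr <- train$labels + 1L
  Xva <- NULL
  if (!is.null(valid) && nrow(valid$spectra) > 0L) {
    Xva <- normalize_spectra(pad_spectra(valid$spectra, config$input_length))
    yva <- valid$labels + 1L
  }

  adam_m <- lapply(w, function(p) p * 0)
  adam_v <- lapply(w, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  n <- nrow(Xtr)
  tr_loss <- va_loss <- tr_acc <- rep(NA_real_, config$epochs)

  mean_loss <- function(X, y) {
    tot <- 0
    for (i in seq_len(nrow(X))) {
      fw <- cnn_forward(w, X[i, ], idx)
      tot <- tot - log(max(fw$p[y[i]], 1e-12))
    }
    tot / nrow(X)
  }

  for (epoch in seq_len(config$epochs)) {
    lr <- lr_schedule(epoch - 1L, config)
    ord <- sample.int(n)
    correct <- 0L; ep_loss <- 0
    for (b0 in seq(1L, n, by = config$batch_size)) {
      batch <- ord[b0:min(b0 + config$batch_size - 1L, n)]
      grads <- lapply(w, function(p) p * 0)
      for (i in batch) {
        fw <- cnn_forward(w, Xtr[i, ], idx)
        ep_loss <- ep_loss - log(max(fw$p[ytr[i]], 1e-12))
        if (which.max(fw$p) == ytr[i]) correct <- correct + 1L
        dz3 <- fw$p; dz3[ytr[i]] <- dz3[ytr[i]] - 1
        grads$W2 <- grads$W2 + dz3 %o% fw$a2
        grads$b2 <- grads$b2 + dz3
        dz2 <- as.vector(crossprod(w$W2, dz3)) * (fw$z2 > 0)
        grads$W1 <- grads$W1 + dz2 %o% fw$a1
        grads$b1 <- grads$b1 + dz2
        dA1 <- matrix(as.vector(crossprod(w$W1, dz2)), nrow(idx),
                      config$conv_channels)
        dZ1 <- dA1 * (fw$Z1 > 0)
        grads$Wc <- grads$Wc + t(dZ1) %*% fw$Xw
        grads$bc <- grads$bc + colSums(dZ1)
      }
      step <- step + 1L
      bn <- length(batch)
      for (nm in names(w)) {
        gr <- grads[[nm]] / bn
        adam_m[[nm]] <- beta1 * adam_m[[nm]] + (1 - beta1) * gr
        adam_v[[nm]] <- beta2 * adam_v[[nm]] + (1 - beta2) * gr^2
        mhat <- adam_m[[nm]] / (1 - beta1^step)
        vhat <- adam_v[[nm]] / (1 - beta2^step)
        w[[nm]] <- w[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    tr_loss[epoch] <- ep_loss / n
    tr_acc[epoch] <- correct / n
    if (!is.null(Xva)) va_loss[epoch] <- mean_loss(Xva, yva)
    if (!is.finite(tr_loss[epoch]))
      stop("training loss became non-finite at epoch ", epoch, call. = FALSE)
  }

  model$weights <- w
  report <- structure(
    list(loss_curves = data.frame(epoch = seq_len(config$epochs),
                                  train = tr_loss, valid = va_loss),
         train_accuracy = tr_acc),
    class = "classifier_report")
  list(model = model, report = report)
}

pad_spectra <- function(X, to) {
  if (ncol(X) == to - 1L) X <- cbind(X, X[, ncol(X)])
  if (ncol(X) != to)
    stop(sprintf("spectra have %d channels; classifier expects %d (or %d, padded)",
                 ncol(X), to, to - 1L), call. = FALSE)
  X
}

#' Predict class labels for spectra
#'
#' Spectra are max-normalized (and right-padded by one channel if needed)
#' before the forward pass; the label is the argmax of the softmax output,
#' ties resolved toward the lower class index. Spectra carrying no signal at
#' all (maximum <= 0) are interference by definition and get label 0 without
#' a forward pass.
#'
#' @param model A trained `sers_cnn`.
#' @param spectra Numeric matrix, one spectrum per row, or a
#'   [labeled_spectrum_dataset()].
#' @return Integer labels in `{0, 1, 2}`; softmax probabilities in attribute
#'   `"probabilities"`.
#' @export
predict_labels <- function(model, spectra) {
  stopifnot(inherits(model, "sers_cnn"))
  if (inherits(spectra, "labeled_spectrum_dataset")) spectra <- spectra$spectra
  X <- normalize_spectra(pad_spectra(as.matrix(spectra),
                                     model$config$input_length))
  s <- model$config$stride
  idx <- outer(1L + (seq_len(model$L_out) - 1L) * s,
               0:(model$config$kernel_size - 1L), "+")
  no_signal <- apply(X, 1L, max) <= 0
  probs <- t(vapply(seq_len(nrow(X)),
                    function(i) cnn_forward(model$weights, X[i, ], idx)$p,
                    numeric(3)))
  probs[no_signal, ] <- rep(c(1, 0, 0), each = sum(no_signal))
  labels <- max.col(probs, ties.method = "first") - 1L
  attr(labels, "probabilities") <- probs
  labels
}

#' Confusion matrix and accuracy on a labeled test set
#'
#' @param model A trained `sers_cnn`.
#' @param test A [labeled_spectrum_dataset()], non-empty.
#' @return An object of class `classifier_report` with `confusion` (3x3
#'   integer matrix, rows = true, cols = predicted), `accuracy`
#'   (trace / total) and the predicted labels.
#' @export
evaluate_classifier <- function(model, test) {
  stopifnot(inherits(test, "labeled_spectrum_dataset"))
  if (nrow(test$spectra) == 0L) stop("test set is empty", call. = FALSE)
  pred <- predict_labels(model, test)
  confusion <- table(factor(test$labels, levels = 0:2),
                     factor(pred, levels = 0:2))
  confusion <- matrix(as.integer(confusion), 3, 3,
                      dimnames = list(true = 0:2, predicted = 0:2))
  structure(list(confusion = confusion,
                 accuracy = sum(diag(confusion)) / sum(confusion),
                 predicted = as.integer(pred)),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  if (!is.null(x$confusion)) {
    cat(sprintf("<classifier_report> accuracy %.4f\n", x$accuracy))
    print(x$confusion)
  } else {
    lc <- x$loss_curves
    cat(sprintf("<classifier_report> %d epochs, final train loss %.4g\n",
                nrow(lc), lc$train[nrow(lc)]))
  }
  invisible(x)
}

#' Label NMF components with the trained classifier
#'
#' Runs each feature spectrum (row of `H`) through the trained network and
#' returns its class: 0 interference, 1 BZD, 2 EBZD.
#'
#' @param H Feature matrix or `unmixing_result`.
#' @param model A trained `sers_cnn`.
#' @return Integer labels, one per component (probabilities attached).
#' @export
predict_component_labels <- function(H, model) {
  if (inherits(H, "unmixing_result")) H <- H$H
  predict_labels(model, as.matrix(H))
}
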