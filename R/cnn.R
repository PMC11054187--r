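# 2D CNN for contact-map images, implemented directly on matrix algebra.
#
# Architecture (fixed form, sizes configurable):
#   input N x N (1 channel)
#   conv 1x1, 16 filters -> 2x2 max-pool -> ReLU
#   conv 1x1, 32 filters -> 2x2 max-pool -> ReLU
#   flatten -> FC 512 (ReLU, dropout 0.5) -> FC 128 (ReLU, dropout 0.5)
#   -> FC K, softmax
#
# A 1x1 convolution is a per-pixel linear map across channels, so every
# layer reduces to dense matrix products on (image, pixel)-major
# activation matrices; max-pooling is a gather + pmax with recorded
# argmax routes for backprop. Cross-entropy loss, Adam optimizer.

#' Specification of the contact-map CNN classifier
#'
#' @param n_input image side N (square N x N grayscale input, N >= 8 so
#'   that two 2x2 pools are possible).
#' @param n_classes number of classes K (>= 2).
#' @param conv_filters filter counts of the two 1x1 convolution layers.
#' @param fc sizes of the two hidden fully connected layers.
#' @param dropout dropout rate applied after each hidden FC layer during
#'   training.
#' @param epochs default training epochs (30).
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param seed seed for weight initialization and shuffling.
#' @return object of class `cnn_spec`; fields `pool1`, `pool2` and
#'   `flatten` carry the derived shape arithmetic
#'   (flatten = floor(floor(N/2)/2)^2 * conv_filters[2]).
#' @export
cnn_spec <- function(n_input, n_classes, conv_filters = c(16, 32),
                     fc = c(512, 128), dropout = 0.5, epochs = 30,
                     lr = 1e-3, batch_size = 64, seed = 1) {
  if (n_input < 8) stopf("input size %d too small for two 2x2 pools", n_input)
  if (n_classes < 2) stopf("classification needs K >= 2 classes")
  p1 <- n_input %/% 2
  p2 <- p1 %/% 2
  structure(list(n_input = as.integer(n_input),
                 n_classes = as.integer(n_classes),
                 conv_filters = as.integer(conv_filters),
                 fc = as.integer(fc), dropout = dropout,
                 epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 pool1 = p1, pool2 = p2,
                 flatten = p2 * p2 * conv_filters[2]),
            class = "cnn_spec")
}

# 2x2 max-pool source indices: m^2 x 4 matrix of linear pixel indices
# (column-major) feeding each pooled cell; non-overlapping, stride 2.
pool_sources <- function(n) {
  m <- n %/% 2
  q <- expand.grid(a = seq_len(m), b = seq_len(m))
  cbind((2 * q$a - 1) + (2 * q$b - 2) * n,
        (2 * q$a) + (2 * q$b - 2) * n,
        (2 * q$a - 1) + (2 * q$b - 1) * n,
        (2 * q$a) + (2 * q$b - 1) * n)
}

#' Build (initialize) the CNN classifier
#'
#' He-initialized weights, zero biases, deterministic under the spec
#' seed.
#'
#' @param spec a `cnn_spec`.
#' @return object of class `cnn_classifier` (untrained).
#' @export
build_model <- function(spec) {
  stopifnot(inherits(spec, "cnn_spec"))
  with_seed(spec$seed, {
    he <- function(nin, nout) {
      matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
    }
    w <- list(
      w1 = he(1, spec$conv_filters[1]), b1 = rep(0, spec$conv_filters[1]),
      W2 = he(spec$conv_filters[1], spec$conv_filters[2]),
      b2 = rep(0, spec$conv_filters[2]),
      W3 = he(spec$flatten, spec$fc[1]), b3 = rep(0, spec$fc[1]),
      W4 = he(spec$fc[1], spec$fc[2]), b4 = rep(0, spec$fc[2]),
      W5 = he(spec$fc[2], spec$n_classes), b5 = rep(0, spec$n_classes)
    )
    structure(list(spec = spec, weights = w, trained = FALSE,
                   src1 = pool_sources(spec$n_input),
                   src2 = pool_sources(spec$pool1)),
              class = "cnn_classifier")
  })
}

#' @export
print.cnn_classifier <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "<cnn_classifier> %dx%d -> conv1x1(%d) -> pool -> conv1x1(%d) -> pool -> flatten(%d) -> FC(%d, %d) -> %d classes%s\n",
    s$n_input, s$n_input, s$conv_filters[1], s$conv_filters[2], s$flatten,
    s$fc[1], s$fc[2], s$n_classes, if (x$trained) " [trained]" else ""))
  invisible(x)
}

# gather rows for pooling: activations A ((B*P) x C, pixel-major per
# image) -> pooled ((B*m2) x C) plus argmax route masks
pool_forward <- function(A, src, P, B) {
  m2 <- nrow(src)
  offs <- rep((seq_len(B) - 1L) * P, each = m2)
  M <- lapply(1:4, function(k) A[offs + src[, k], , drop = FALSE])
  pooled <- pmax(M[[1]], M[[2]], M[[3]], M[[4]])
  taken <- matrix(FALSE, nrow(pooled), ncol(pooled))
  route <- vector("list", 4)
  for (k in 1:4) {
    sel <- (M[[k]] >= pooled) & !taken
    route[[k]] <- sel
    taken <- taken | sel
  }
  list(pooled = pooled, route = route, offs = offs)
}

pool_backward <- function(dpooled, fwd, src, P, B, C) {
  dA <- matrix(0, B * P, C)
  for (k in 1:4) {
    rows <- fwd$offs + src[, k]
    dA[rows, ] <- dpooled * fwd$route[[k]]
  }
  dA
}

# flatten (B*m2) x C  ->  B x (m2*C), channel-major blocks
flatten_act <- function(A, m2, B) {
  do.call(cbind, lapply(seq_len(ncol(A)), function(c) {
    t(matrix(A[, c], m2, B))
  }))
}

unflatten_act <- function(Fl, m2, B, C) {
  A <- matrix(0, B * m2, C)
  for (c in seq_len(C)) {
    A[, c] <- as.vector(t(Fl[, (c - 1) * m2 + seq_len(m2), drop = FALSE]))
  }
  A
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# full forward pass; X is B x N^2. Returns activations needed for
# backprop. Dropout masks are applied only when `drop` masks are given.
cnn_forward <- function(model, X, drop = NULL) {
  s <- model$spec; w <- model$weights
  B <- nrow(X); P <- s$n_input^2
  p1sq <- s$pool1^2; p2sq <- s$pool2^2
  add_bias <- function(M, b) M + rep(b, each = nrow(M))
  Xcol <- matrix(as.vector(t(X)), ncol = 1)          # (B*P) x 1, pixel-major
  Z1 <- add_bias(Xcol %*% w$w1, w$b1)
  pf1 <- pool_forward(Z1, model$src1, P, B)
  R1 <- pmax(pf1$pooled, 0)
  Z2 <- add_bias(R1 %*% w$W2, w$b2)
  pf2 <- pool_forward(Z2, model$src2, p1sq, B)
  R2 <- pmax(pf2$pooled, 0)
  Fl <- flatten_act(R2, p2sq, B)
  H1 <- pmax(sweep(Fl %*% w$W3, 2, w$b3, "+"), 0)
  H1d <- if (!is.null(drop)) H1 * drop$D1 else H1
  H2 <- pmax(sweep(H1d %*% w$W4, 2, w$b4, "+"), 0)
  H2d <- if (!is.null(drop)) H2 * drop$D2 else H2
  logits <- sweep(H2d %*% w$W5, 2, w$b5, "+")
  list(Xcol = Xcol, pf1 = pf1, R1 = R1, pf2 = pf2, R2 = R2, Fl = Fl,
       H1 = H1, H1d = H1d, H2 = H2, H2d = H2d, logits = logits,
       probs = softmax_rows(logits), B = B)
}

# backward pass from dlogits; returns weight gradients and, when
# `want_input` is TRUE, the gradient with respect to the input pixels.
cnn_backward <- function(model, fwd, dlogits, drop = NULL,
                         want_input = FALSE) {
  s <- model$spec; w <- model$weights
  B <- fwd$B; P <- s$n_input^2
  p1sq <- s$pool1^2; p2sq <- s$pool2^2
  g <- list()
  g$W5 <- crossprod(fwd$H2d, dlogits); g$b5 <- colSums(dlogits)
  dH2d <- dlogits %*% t(w$W5)
  if (!is.null(drop)) dH2d <- dH2d * drop$D2
  dH2 <- dH2d * (fwd$H2 > 0)
  g$W4 <- crossprod(fwd$H1d, dH2); g$b4 <- colSums(dH2)
  dH1d <- dH2 %*% t(w$W4)
  if (!is.null(drop)) dH1d <- dH1d * drop$D1
  dH1 <- dH1d * (fwd$H1 > 0)
  g$W3 <- crossprod(fwd$Fl, dH1); g$b3 <- colSums(dH1)
  dFl <- dH1 %*% t(w$W3)
  dR2 <- unflatten_act(dFl, p2sq, B, s$conv_filters[2])
  dP2 <- dR2 * (fwd$pf2$pooled > 0)
  dZ2 <- pool_backward(dP2, fwd$pf2, model$src2, p1sq, B, s$conv_filters[2])
  g$W2 <- crossprod(fwd$R1, dZ2); g$b2 <- colSums(dZ2)
  dR1 <- dZ2 %*% t(w$W2)
  dP1 <- dR1 * (fwd$pf1$pooled > 0)
  dZ1 <- pool_backward(dP1, fwd$pf1, model$src1, P, B, s$conv_filters[1])
  g$w1 <- crossprod(fwd$Xcol, dZ1); g$b1 <- colSums(dZ1)
  if (want_input) {
    g$input <- matrix(as.vector(dZ1 %*% t(w$w1)), B, P, byrow = TRUE)
  }
  g
}

#' Class probabilities for a batch of images
#'
#' @param object a `cnn_classifier`.
#' @param pixels B x N^2 matrix (or an `image_dataset`).
#' @param ... unused.
#' @return B x K matrix of softmax probabilities.
#' @export
predict.cnn_classifier <- function(object, pixels, ...) {
  if (inherits(pixels, "image_dataset")) pixels <- pixels$pixels
  if (is.null(dim(pixels))) pixels <- matrix(pixels, nrow = 1)
  chunks <- split(seq_len(nrow(pixels)),
                  ceiling(seq_len(nrow(pixels)) / 256))
  do.call(rbind, lapply(chunks, function(id) {
    cnn_forward(object, pixels[id, , drop = FALSE])$probs
  }))
}

#' Train the CNN on a split image dataset
#'
#' Minibatch Adam on the cross-entropy loss with per-epoch bookkeeping.
#' Deterministic given the seed and a fixed thread count.
#'
#' @param model a `cnn_classifier` from [build_model()].
#' @param ds an `image_dataset` with labels and a train/val split.
#' @param epochs training epochs (default: from the spec).
#' @param seed shuffling/dropout seed (default: spec seed + 1).
#' @param verbose print per-epoch metrics.
#' @return list of class `train_result`: the trained `model`, `history`
#'   (per-epoch train/val loss and accuracy), final `confusion`
#'   (K x K counts, rows = true class), `accuracy` (percent) and `loss`
#'   on the validation split.
#' @export
train_classifier <- function(model, ds, epochs = NULL, seed = NULL,
                             verbose = FALSE) {
  s <- model$spec
  if (is.null(ds$split)) stopf("dataset has no train/val split")
  epochs <- epochs %||% s$epochs
  seed <- seed %||% (s$seed + 1L)
  tr <- which(ds$split == "train"); va <- which(ds$split == "val")
  if (length(tr) == 0 || length(va) == 0) stopf("empty split")
  Xtr <- ds$pixels[tr, , drop = FALSE]; ytr <- ds$labels[tr]
  K <- s$n_classes
  w <- model$weights
  adam <- list(m = lapply(w, function(x) x * 0),
               v = lapply(w, function(x) x * 0), t = 0)
  hist_rows <- vector("list", epochs)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample(length(tr))
      batches <- split(ord, ceiling(seq_along(ord) / s$batch_size))
      ep_loss <- 0; ep_correct <- 0
      for (bt in batches) {
        X <- Xtr[bt, , drop = FALSE]
        y <- ytr[bt]
        B <- length(bt)
        keep <- 1 - s$dropout
        drop <- list(
          D1 = matrix(stats::rbinom(B * s$fc[1], 1, keep) / keep, B, s$fc[1]),
          D2 = matrix(stats::rbinom(B * s$fc[2], 1, keep) / keep, B, s$fc[2])
        )
        model$weights <- w
        fwd <- cnn_forward(model, X, drop)
        Y <- matrix(0, B, K); Y[cbind(seq_len(B), y)] <- 1
        eps <- 1e-12
        loss <- -mean(log(fwd$probs[cbind(seq_len(B), y)] + eps))
        if (!is.finite(loss)) {
          stopf("training diverged (non-finite loss) at epoch %d", ep)
        }
        ep_loss <- ep_loss + loss * B
        ep_correct <- ep_correct + sum(max.col(fwd$probs) == y)
        dlogits <- (fwd$probs - Y) / B
        g <- cnn_backward(model, fwd, dlogits, drop)
        adam$t <- adam$t + 1
        b1 <- 0.9; b2 <- 0.999; aeps <- 1e-8
        # bias corrections absorbed into the step size
        step <- s$lr * sqrt(1 - b2^adam$t) / (1 - b1^adam$t)
        for (nm in names(w)) {
          adam$m[[nm]] <- b1 * adam$m[[nm]] + (1 - b1) * g[[nm]]
          adam$v[[nm]] <- b2 * adam$v[[nm]] + (1 - b2) * g[[nm]]^2
          w[[nm]] <- w[[nm]] - step * adam$m[[nm]] /
            (sqrt(adam$v[[nm]]) + aeps)
        }
      }
      model$weights <- w
      ev <- evaluate_classifier(model, ds, split = "val")
      hist_rows[[ep]] <- data.frame(
        epoch = ep,
        train_loss = ep_loss / length(tr),
        train_accuracy = 100 * ep_correct / length(tr),
        val_loss = ev$loss, val_accuracy = ev$accuracy)
      if (verbose) {
        message(sprintf("epoch %2d  train acc %.2f%%  val acc %.2f%%",
                        ep, hist_rows[[ep]]$train_accuracy, ev$accuracy))
      }
    }
  })
  model$trained <- TRUE
  ev <- evaluate_classifier(model, ds, split = "val")
  structure(list(model = model, history = do.call(rbind, hist_rows),
                 confusion = ev$confusion, accuracy = ev$accuracy,
                 loss = ev$loss),
            class = "train_result")
}

#' @export
print.train_result <- function(x, ...) {
  cat(sprintf("<train_result> %d epochs, validation accuracy %.2f%%, loss %.4f\n",
              nrow(x$history), x$accuracy, x$loss))
  invisible(x)
}

#' Confusion matrix, accuracy and loss on a dataset split
#'
#' @param model a `cnn_classifier`.
#' @param ds a labelled, split `image_dataset`.
#' @param split which split to evaluate ("val" or "train").
#' @return list with `confusion` (K x K counts, rows = true class,
#'   columns = predicted; each row sums to that class's count in the
#'   split), `accuracy` (percent, trace/total) and `loss` (mean
#'   cross-entropy).
#' @export
evaluate_classifier <- function(model, ds, split = "val") {
  idx <- if (is.null(ds$split)) seq_len(nrow(ds$pixels))
  else which(ds$split == split)
  if (length(idx) == 0) stopf("split '%s' is empty", split)
  probs <- predict(model, ds$pixels[idx, , drop = FALSE])
  y <- ds$labels[idx]
  K <- model$spec$n_classes
  pred <- max.col(probs)
  confusion <- matrix(0L, K, K,
                      dimnames = list(true = seq_len(K), pred = seq_len(K)))
  for (i in seq_along(y)) {
    confusion[y[i], pred[i]] <- confusion[y[i], pred[i]] + 1L
  }
  list(confusion = confusion,
       accuracy = 100 * sum(diag(confusion)) / length(y),
       loss = -mean(log(probs[cbind(seq_along(y), y)] + 1e-12)))
}

#' Vanilla-gradient saliency map of one image
#'
#' Absolute gradient of the pre-softmax class score with respect to every
#' input pixel, symmetrized as (M + t(M))/2 since contact matrices are
#' symmetric.
#'
#' @param model a trained `cnn_classifier`.
#' @param image N x N matrix (or length-N^2 pixel vector).
#' @param class target class index.
#' @return list of class `saliency_result` with `raw` (N x N
#'   non-negative matrix), `class`, and empty `masked` / `domain_table`
#'   slots filled by [mask_and_aggregate()].
#' @export
vanilla_gradient_saliency <- function(model, image, class) {
  if (!model$trained) stopf("classifier is not trained")
  n <- model$spec$n_input
  X <- matrix(as.numeric(image), nrow = 1)
  if (ncol(X) != n * n) stopf("image size mismatch")
  fwd <- cnn_forward(model, X)
  dlogits <- matrix(0, 1, model$spec$n_classes)
  dlogits[1, class] <- 1
  g <- cnn_backward(model, fwd, dlogits, want_input = TRUE)
  M <- abs(matrix(g$input[1, ], n, n))
  M <- (M + t(M)) / 2
  structure(list(raw = M, class = class, masked = NULL, domain_table = NULL),
            class = "saliency_result")
}
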