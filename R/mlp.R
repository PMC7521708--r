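# Cost-sensitive multilayer perceptron for essentiality classification.
# Hand-implemented dense network: ReLU hidden layers with inverted dropout,
# sigmoid output head (2 independent units against one-hot targets by
# default, or a single unit), class-weighted binary cross-entropy, Adam,
# minibatch training with validation-based early stopping.

relu <- function(x) pmax(x, 0)
sigmoid <- function(x) 1 / (1 + exp(-x))

clip_prob <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

#' Class-weighted binary cross-entropy
#'
#' Mean over samples of `w(class) * BCE(sample)`; for a multi-unit target
#' the per-sample BCE is the mean over output units. Predictions are
#' clipped to `[1e-7, 1 - 1e-7]` before taking logs. With all weights 1
#' this is the standard binary cross-entropy.
#'
#' @param y_true 0/1 vector (1 = essential) or one-hot matrix.
#' @param y_pred Predicted probabilities, same shape as `y_true`.
#' @param class_weight Named weights, `c(nonessential = , essential = )`;
#'   applied per sample according to the sample's true class.
#' @return Scalar loss.
#' @examples
#' weighted_bce(c(1, 0), c(0.5, 0.5), c(nonessential = 1, essential = 4))
#' @export
weighted_bce <- function(y_true, y_pred,
                         class_weight = c(nonessential = 1, essential = 4)) {
  y_true <- as.matrix(y_true)
  y_pred <- clip_prob(as.matrix(y_pred))
  if (!all(dim(y_true) == dim(y_pred))) stopf("shape mismatch")
  if (any(class_weight <= 0)) stopf("class weights must be positive")
  # the sample's class: essential iff its (first) essential indicator is 1;
  # for one-hot (nonessential, essential) targets use the last column
  is_ess <- y_true[, ncol(y_true)] > 0.5
  w <- ifelse(is_ess, class_weight[["essential"]],
              class_weight[["nonessential"]])
  bce <- -rowMeans(y_true * log(y_pred) + (1 - y_true) * log(1 - y_pred))
  mean(w * bce)
}

#' Parameter count of a dense network
#'
#' `sum((fan_in + 1) * fan_out)` over consecutive layer pairs.
#'
#' @param input_dim Input width.
#' @param hidden Hidden layer widths.
#' @param output_units Output width.
#' @return Integer parameter count.
#' @export
mlp_parameter_count <- function(input_dim, hidden = c(128, 256, 512),
                                output_units = 2) {
  sizes <- c(input_dim, hidden, output_units)
  sum((sizes[-length(sizes)] + 1) * sizes[-1])
}

mlp_init <- function(input_dim, hidden, output_units, seed) {
  sizes <- c(input_dim, hidden, output_units)
  with_seed_(seed, {
    W <- vector("list", length(sizes) - 1L)
    b <- vector("list", length(sizes) - 1L)
    for (l in seq_along(W)) {
      fan_in <- sizes[l]
      limit <- sqrt(6 / fan_in)  # fan-in-scaled uniform, suits ReLU stacks
      W[[l]] <- matrix(stats::runif(fan_in * sizes[l + 1], -limit, limit),
                       fan_in, sizes[l + 1])
      b[[l]] <- numeric(sizes[l + 1])
    }
    list(W = W, b = b)
  })
}

# Forward pass. Returns output probabilities plus the per-layer activations
# and pre-activation sign masks needed for backprop. `masks` (dropout) are
# applied post-activation (inverted dropout: scaled by 1/keep at train time).
mlp_forward <- function(pars, X, dropout = 0, masks = NULL) {
  L <- length(pars$W)
  A <- vector("list", L + 1L)
  A[[1]] <- X
  relu_mask <- vector("list", L)
  for (l in seq_len(L)) {
    Z <- sweep(A[[l]] %*% pars$W[[l]], 2, pars$b[[l]], "+")
    if (l < L) {
      relu_mask[[l]] <- Z > 0
      H <- relu(Z)
      if (!is.null(masks)) H <- H * masks[[l]] / (1 - dropout)
      A[[l + 1]] <- H
    } else {
      A[[l + 1]] <- sigmoid(Z)
    }
  }
  list(A = A, relu_mask = relu_mask, P = A[[L + 1]])
}

# Loss and analytic gradients on one batch (used by the trainer and by the
# finite-difference gradient tests).
mlp_loss_grad <- function(pars, X, Tm, w, dropout = 0, masks = NULL) {
  L <- length(pars$W)
  fwd <- mlp_forward(pars, X, dropout, masks)
  P <- fwd$P
  n <- nrow(X); U <- ncol(Tm)
  Pc <- clip_prob(P)
  loss <- mean((w / U) * rowSums(-(Tm * log(Pc) + (1 - Tm) * log(1 - Pc))))
  gW <- vector("list", L); gb <- vector("list", L)
  dZ <- (P - Tm) * (w / (n * U))  # sigmoid + BCE shortcut
  for (l in L:1) {
    gW[[l]] <- crossprod(fwd$A[[l]], dZ)
    gb[[l]] <- colSums(dZ)
    if (l > 1) {
      dH <- dZ %*% t(pars$W[[l]])
      if (!is.null(masks)) dH <- dH * masks[[l - 1]] / (1 - dropout)
      dZ <- dH * fwd$relu_mask[[l - 1]]
    }
  }
  list(loss = loss, gW = gW, gb = gb)
}

one_hot_targets <- function(y, output_units) {
  if (output_units == 2L) cbind(nonessential = 1 - y, essential = y)
  else matrix(y, ncol = 1, dimnames = list(NULL, "essential"))
}

#' Fit a cost-sensitive multilayer perceptron
#'
#' The package's central model: a dense ReLU network with dropout after
#' each hidden layer and a sigmoid output head, trained by Adam on
#' class-weighted binary cross-entropy with minibatches, seeded shuffling
#' and validation-based early stopping (best-weight restoration). The
#' default architecture is three hidden layers of 128/256/512 units with
#' dropout 0.2, batch size 32, learning rate 0.001, at most 100 epochs, and
#' class weight 4 on the essential (minority) class.
#'
#' @param x Numeric feature matrix (standardize first; see
#'   [fit_standardizer()]).
#' @param y Labels: `essential`/`nonessential` (factor or character) or 0/1
#'   with 1 = essential.
#' @param hidden Hidden layer widths.
#' @param dropout Dropout probability per hidden layer, in `[0, 1)`.
#' @param output_units 2 (independent sigmoid units against one-hot
#'   targets; the essential unit is the score) or 1 (single sigmoid unit,
#'   the conventional equivalent).
#' @param class_weight Named positive weights for the two classes.
#' @param learning_rate,batch_size,max_epochs Adam step size, minibatch
#'   size and epoch cap.
#' @param patience Early stopping: stop after this many consecutive epochs
#'   without validation-loss improvement; best weights are restored.
#' @param validation Either `NULL` (carve `val_fraction` off `x`
#'   stratified), a list `list(x =, y =)`, or `FALSE` to disable early
#'   stopping.
#' @param val_fraction Fraction held out for validation when
#'   `validation = NULL`.
#' @param seed Seed for initialization, shuffling and dropout.
#' @param verbose Print per-epoch losses.
#' @return Object of class `essnet_mlp` with `weights`, `biases`,
#'   `history` (per-epoch train/validation loss), `best_epoch` and the
#'   configuration; supports [predict()], [print()], [summary()],
#'   [coef()], [plot()], [residuals()] and [fitted()].
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200), ncol = 2)
#' y <- as.integer(x[, 1] + x[, 2] > 0)
#' fit <- essnet_mlp(x, y, hidden = c(8), max_epochs = 20, seed = 1)
#' mean((predict(fit, x) > 0.5) == y)
#' @export
essnet_mlp <- function(x, y, hidden = c(128, 256, 512), dropout = 0.2,
                       output_units = 2L,
                       class_weight = c(nonessential = 1, essential = 4),
                       learning_rate = 1e-3, batch_size = 32L,
                       max_epochs = 100L, patience = 10L,
                       validation = NULL, val_fraction = 0.1,
                       seed = 1L, verbose = FALSE) {
  x <- as.matrix(x)
  if (!length(hidden) || any(hidden < 1)) stopf("`hidden` must be nonempty positive widths")
  if (dropout < 0 || dropout >= 1) stopf("`dropout` must be in [0, 1)")
  if (any(class_weight <= 0)) stopf("class weights must be positive")
  output_units <- as.integer(output_units)
  if (!output_units %in% c(1L, 2L)) stopf("`output_units` must be 1 or 2")
  lab <- canonical_labels(y)
  y1 <- as.integer(lab == "essential")
  if (nrow(x) != length(y1)) stopf("nrow(x) != length(y)")

  use_val <- !identical(validation, FALSE)
  if (use_val && is.null(validation)) {
    idx_val <- with_seed_(derive_seed(seed, 21L), {
      pos <- which(y1 == 1); neg <- which(y1 == 0)
      c(sample(pos, round(length(pos) * val_fraction)),
        sample(neg, round(length(neg) * val_fraction)))
    })
    if (!length(idx_val)) { use_val <- FALSE }
    else {
      validation <- list(x = x[idx_val, , drop = FALSE], y = y1[idx_val])
      x <- x[-idx_val, , drop = FALSE]; y1 <- y1[-idx_val]
    }
  }
  if (use_val) {
    xv <- as.matrix(validation$x)
    yv <- as.integer(canonical_labels(validation$y) == "essential")
    Tv <- one_hot_targets(yv, output_units)
    wv <- ifelse(yv == 1, class_weight[["essential"]],
                 class_weight[["nonessential"]])
  }

  Tm <- one_hot_targets(y1, output_units)
  w <- ifelse(y1 == 1, class_weight[["essential"]],
              class_weight[["nonessential"]])
  pars <- mlp_init(ncol(x), hidden, output_units, derive_seed(seed, 22L))

  # Adam state
  zeros_like <- function(p) lapply(p, function(m) m * 0)
  mW <- zeros_like(pars$W); vW <- zeros_like(pars$W)
  mb <- zeros_like(pars$b); vb <- zeros_like(pars$b)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; tstep <- 0L

  n <- nrow(x)
  hist_epoch <- integer(0); hist_train <- numeric(0); hist_val <- numeric(0)
  best_val <- Inf; best_pars <- pars; best_epoch <- 0L; bad <- 0L

  with_seed_(derive_seed(seed, 23L), {
    for (epoch in seq_len(max_epochs)) {
      ord <- sample.int(n)
      batch_losses <- numeric(0)
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        Xb <- x[idx, , drop = FALSE]
        masks <- if (dropout > 0) {
          lapply(hidden, function(h)
            matrix(stats::runif(length(idx) * h) >= dropout,
                   length(idx), h))
        } else NULL
        g <- mlp_loss_grad(pars, Xb, Tm[idx, , drop = FALSE], w[idx],
                           dropout, masks)
        batch_losses <- c(batch_losses, g$loss)
        tstep <- tstep + 1L
        corr <- sqrt(1 - b2^tstep) / (1 - b1^tstep)
        for (l in seq_along(pars$W)) {
          mW[[l]] <- b1 * mW[[l]] + (1 - b1) * g$gW[[l]]
          vW[[l]] <- b2 * vW[[l]] + (1 - b2) * g$gW[[l]]^2
          pars$W[[l]] <- pars$W[[l]] -
            learning_rate * corr * mW[[l]] / (sqrt(vW[[l]]) + eps)
          mb[[l]] <- b1 * mb[[l]] + (1 - b1) * g$gb[[l]]
          vb[[l]] <- b2 * vb[[l]] + (1 - b2) * g$gb[[l]]^2
          pars$b[[l]] <- pars$b[[l]] -
            learning_rate * corr * mb[[l]] / (sqrt(vb[[l]]) + eps)
        }
      }
      train_loss <- mean(batch_losses)
      val_loss <- NA_real_
      if (use_val) {
        Pv <- mlp_forward(pars, xv)$P
        val_loss <- mean((wv / ncol(Tv)) *
                           rowSums(-(Tv * log(clip_prob(Pv)) +
                                       (1 - Tv) * log(1 - clip_prob(Pv)))))
      }
      hist_epoch <- c(hist_epoch, epoch)
      hist_train <- c(hist_train, train_loss)
      hist_val <- c(hist_val, val_loss)
      if (verbose)
        message(sprintf("epoch %3d  train %.5f  val %s", epoch, train_loss,
                        ifelse(is.na(val_loss), "-", sprintf("%.5f", val_loss))))
      if (use_val) {
        if (val_loss < best_val) {
          best_val <- val_loss; best_pars <- pars; best_epoch <- epoch
          bad <- 0L
        } else {
          bad <- bad + 1L
          if (bad > patience) break
        }
      }
      if (!is.finite(train_loss)) {
        stop(structure(class = c("essnet_divergence", "error", "condition"),
                       list(message = "training diverged (non-finite loss)",
                            call = sys.call(-1),
                            history = data.frame(epoch = hist_epoch,
                                                 train_loss = hist_train,
                                                 val_loss = hist_val))))
      }
    }
  })

  if (use_val) pars <- best_pars else best_epoch <- length(hist_epoch)
  structure(list(
    weights = pars$W, biases = pars$b,
    hidden = hidden, dropout = dropout, output_units = output_units,
    class_weight = class_weight, input_dim = ncol(x),
    levels = c("nonessential", "essential"),
    history = data.frame(epoch = hist_epoch, train_loss = hist_train,
                         val_loss = hist_val),
    best_epoch = best_epoch,
    train_x = x, train_y = y1,
    call = match.call()
  ), class = "essnet_mlp")
}

#' Predict essentiality scores
#'
#' Dropout is disabled at prediction time; the score is the essential-class
#' sigmoid output.
#'
#' @param object A fitted [essnet_mlp()].
#' @param newdata Feature matrix with `input_dim` columns (defaults to the
#'   training matrix).
#' @param type `"score"` for probabilities in \[0, 1\], `"class"` for the
#'   thresholded label (score >= `threshold` is essential).
#' @param threshold Decision threshold for `type = "class"`.
#' @param ... Unused.
#' @return Numeric scores or a character label vector.
#' @export
predict.essnet_mlp <- function(object, newdata = NULL,
                               type = c("score", "class"),
                               threshold = 0.5, ...) {
  type <- match.arg(type)
  x <- if (is.null(newdata)) object$train_x else as.matrix(newdata)
  if (ncol(x) != object$input_dim)
    stopf("feature width %d does not match input_dim %d", ncol(x),
          object$input_dim)
  P <- mlp_forward(list(W = object$weights, b = object$biases), x)$P
  score <- P[, ncol(P)]
  names(score) <- rownames(x)
  if (type == "score") score
  else ifelse(score >= threshold, "essential", "nonessential")
}

#' @export
print.essnet_mlp <- function(x, ...) {
  cat(sprintf("Cost-sensitive MLP: %d -> %s -> %d (ReLU, dropout %.2g, sigmoid out)\n",
              x$input_dim, paste(x$hidden, collapse = " -> "),
              x$output_units, x$dropout))
  cat(sprintf("  %s parameters; class weights %s\n",
              format(mlp_parameter_count(x$input_dim, x$hidden, x$output_units),
                     big.mark = ","),
              paste(sprintf("%s=%g", names(x$class_weight), x$class_weight),
                    collapse = ", ")))
  nh <- nrow(x$history)
  if (nh) cat(sprintf("  trained %d epochs (best at %d), final train loss %.4f\n",
                      nh, x$best_epoch, x$history$train_loss[nh]))
  invisible(x)
}

#' @export
summary.essnet_mlp <- function(object, ...) {
  print(object)
  h <- object$history
  if (nrow(h)) {
    cat("  validation loss: ",
        if (all(is.na(h$val_loss))) "not monitored"
        else sprintf("best %.4f at epoch %d", min(h$val_loss, na.rm = TRUE),
                     object$best_epoch), "\n", sep = "")
    sc <- predict(object)
    cat(sprintf("  training score range: [%.3f, %.3f]\n", min(sc), max(sc)))
  }
  invisible(object)
}

#' @export
coef.essnet_mlp <- function(object, ...) {
  list(weights = object$weights, biases = object$biases)
}

#' @export
residuals.essnet_mlp <- function(object, ...) {
  object$train_y - predict(object)
}

#' @export
fitted.essnet_mlp <- function(object, ...) predict(object)

#' Plot training history
#'
#' @param x A fitted [essnet_mlp()].
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.essnet_mlp <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("black", "red3"),
                    xlab = "epoch", ylab = "weighted BCE loss", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("black", "red3"), bty = "n")
  invisible(x)
}
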