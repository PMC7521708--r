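# The cost-sensitive MLP: architecture arithmetic, loss, gradients,
# training behavior and prediction contracts.

test_that("parameter count follows sum((fan_in + 1) * fan_out)", {
  sizes <- c(153, 128, 256, 512, 2)
  by_hand <- sum((sizes[-length(sizes)] + 1) * sizes[-1])
  expect_equal(mlp_parameter_count(153, c(128, 256, 512), 2), by_hand)
  expect_equal(by_hand, 185346)
  expect_equal(mlp_parameter_count(2, c(3), 1), 3 * 3 + 4 * 1)
})

test_that("a zero-parameter network outputs 0.5 everywhere", {
  pars <- list(W = list(matrix(0, 4, 3), matrix(0, 3, 2)),
               b = list(numeric(3), numeric(2)))
  P <- essnet:::mlp_forward(pars, matrix(rnorm(20), 5, 4))$P
  expect_true(all(P == 0.5))
})

test_that("weighted binary cross-entropy matches hand evaluation", {
  # all weights 1: standard BCE
  y <- c(1, 0, 1); p <- c(0.8, 0.3, 0.6)
  by_hand <- -mean(y * log(p) + (1 - y) * log(1 - p))
  expect_equal(weighted_bce(y, p, c(nonessential = 1, essential = 1)),
               by_hand, tolerance = 1e-12)
  # confident correct prediction: loss near zero
  expect_lt(weighted_bce(1, 1 - 1e-9, c(nonessential = 1, essential = 1)),
            1e-6)
  # one positive (w=4) and one negative (w=1), both at 0.5:
  # (4 + 1)/2 * ln 2 = 1.7329
  expect_equal(weighted_bce(c(1, 0), c(0.5, 0.5),
                            c(nonessential = 1, essential = 4)),
               2.5 * log(2), tolerance = 1e-9)
  expect_equal(round(2.5 * log(2), 4), 1.7329)
  # weights apply identically to one-hot two-unit targets
  Y <- cbind(nonessential = c(0, 1), essential = c(1, 0))
  P <- cbind(c(0.5, 0.5), c(0.5, 0.5))
  expect_equal(weighted_bce(Y, P, c(nonessential = 1, essential = 4)),
               2.5 * log(2), tolerance = 1e-9)
  expect_error(weighted_bce(c(1, 0), c(0.5, 0.5),
                            c(nonessential = 0, essential = 4)), "positive")
})

test_that("analytic gradients match central finite differences", {
  set.seed(33)
  X <- matrix(rnorm(12), 4, 3)
  Tm <- cbind(nonessential = c(1, 0, 1, 0), essential = c(0, 1, 0, 1))
  w <- c(1, 4, 1, 4)
  pars <- essnet:::mlp_init(3, c(2), 2, seed = 1)
  g <- essnet:::mlp_loss_grad(pars, X, Tm, w)
  eps <- 1e-6
  for (l in seq_along(pars$W)) {
    for (i in seq_along(pars$W[[l]])) {
      up <- pars; up$W[[l]][i] <- up$W[[l]][i] + eps
      dn <- pars; dn$W[[l]][i] <- dn$W[[l]][i] - eps
      fd <- (essnet:::mlp_loss_grad(up, X, Tm, w)$loss -
               essnet:::mlp_loss_grad(dn, X, Tm, w)$loss) / (2 * eps)
      expect_lt(abs(g$gW[[l]][i] - fd), 1e-5 * max(1, abs(fd)))
    }
    for (i in seq_along(pars$b[[l]])) {
      up <- pars; up$b[[l]][i] <- up$b[[l]][i] + eps
      dn <- pars; dn$b[[l]][i] <- dn$b[[l]][i] - eps
      fd <- (essnet:::mlp_loss_grad(up, X, Tm, w)$loss -
               essnet:::mlp_loss_grad(dn, X, Tm, w)$loss) / (2 * eps)
      expect_lt(abs(g$gb[[l]][i] - fd), 1e-5 * max(1, abs(fd)))
    }
  }
})

test_that("class weight 4 equals duplicating positives fourfold", {
  y <- c(1, 0, 0)
  p <- c(0.7, 0.4, 0.2)
  w4 <- weighted_bce(y, p, c(nonessential = 1, essential = 4))
  y_dup <- c(rep(1, 4), 0, 0)
  p_dup <- c(rep(0.7, 4), 0.4, 0.2)
  w1 <- weighted_bce(y_dup, p_dup, c(nonessential = 1, essential = 1))
  # identical total loss once the differing sample counts are undone
  expect_equal(w4 * length(y), w1 * length(y_dup), tolerance = 1e-12)
})

test_that("the network fits a separable toy problem to 100% accuracy", {
  set.seed(2)
  x <- matrix(c(runif(20, -3, -1), runif(20, 1, 3)), ncol = 1)
  y <- rep(c(0, 1), each = 20)
  fit <- essnet_mlp(x, y, hidden = c(8), dropout = 0, validation = FALSE,
                    class_weight = c(nonessential = 1, essential = 1),
                    max_epochs = 100, batch_size = 8, seed = 1)
  acc <- mean((predict(fit, x) >= 0.5) == y)
  expect_equal(acc, 1.0)
})

test_that("early stopping obeys the patience contract and restores best weights", {
  set.seed(4)
  x <- matrix(c(rnorm(30, -1.5), rnorm(30, 1.5)), ncol = 1)
  y <- rep(c(0, 1), each = 30)
  # validation labels flipped: validation loss worsens as the model learns
  fit <- essnet_mlp(x, y, hidden = c(8), dropout = 0,
                    validation = list(x = x, y = 1 - y),
                    patience = 0, max_epochs = 50, seed = 1)
  expect_lt(nrow(fit$history), 50)
  expect_equal(nrow(fit$history), fit$best_epoch + 1)  # one bad epoch allowed
  # restored weights are the best-epoch weights: recomputing the validation
  # loss on the returned model matches the stored minimum
  Tv <- cbind(nonessential = y, essential = 1 - y)
  P <- essnet:::mlp_forward(list(W = fit$weights, b = fit$biases), x)$P
  vloss <- weighted_bce(Tv, P, fit$class_weight)
  expect_equal(vloss, min(fit$history$val_loss), tolerance = 1e-9)
})

test_that("training is deterministic given the seed", {
  set.seed(5)
  x <- matrix(rnorm(120), ncol = 3)
  y <- as.integer(x[, 1] > 0)
  f1 <- essnet_mlp(x, y, hidden = c(6), max_epochs = 10, seed = 7)
  f2 <- essnet_mlp(x, y, hidden = c(6), max_epochs = 10, seed = 7)
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$history, f2$history)
  f3 <- essnet_mlp(x, y, hidden = c(6), max_epochs = 10, seed = 8)
  expect_false(identical(f1$weights, f3$weights))
})

test_that("prediction is stateless, bounded and width-checked", {
  set.seed(6)
  x <- matrix(rnorm(60), ncol = 2)
  y <- as.integer(x[, 1] + x[, 2] > 0)
  fit <- essnet_mlp(x, y, hidden = c(5), max_epochs = 5, seed = 1,
                    validation = FALSE)
  s <- predict(fit, x)
  expect_true(all(s >= 0 & s <= 1))
  one_by_one <- vapply(seq_len(nrow(x)), function(i)
    predict(fit, x[i, , drop = FALSE]), numeric(1))
  expect_equal(unname(s), one_by_one, tolerance = 1e-12)
  expect_error(predict(fit, x[, 1, drop = FALSE]), "width")
  cls <- predict(fit, x, type = "class")
  expect_setequal(unique(cls), c("essential", "nonessential"))
})

test_that("scores increase with the feature on a monotone problem", {
  set.seed(9)
  x <- matrix(c(runif(40, 0, 0.9), runif(40, 1.1, 2)), ncol = 1)
  y <- rep(c(0, 1), each = 40)
  fit <- essnet_mlp(x, y, hidden = c(8), dropout = 0, validation = FALSE,
                    class_weight = c(nonessential = 1, essential = 1),
                    learning_rate = 0.01, max_epochs = 150, seed = 2)
  grid <- matrix(seq(0, 2, length.out = 50), ncol = 1)
  s <- predict(fit, grid)
  expect_true(all(diff(s) >= -1e-6))
})

test_that("model methods expose history, coefficients and residuals", {
  set.seed(10)
  x <- matrix(rnorm(80), ncol = 2)
  y <- as.integer(x[, 1] > 0)
  fit <- essnet_mlp(x, y, hidden = c(4), max_epochs = 8, seed = 1)
  expect_s3_class(fit, "essnet_mlp")
  expect_output(print(fit), "Cost-sensitive MLP")
  expect_output(summary(fit), "validation loss")
  cf <- coef(fit)
  expect_length(cf$weights, 2)   # one hidden layer + output
  r <- residuals(fit)
  expect_equal(length(r), nrow(fit$train_x))
  expect_true(all(abs(r) <= 1))
  expect_equal(unname(fitted(fit) + r), fit$train_y)
})
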