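# small labeled dataset + network shared across model tests
model_fixture <- function(m = 24, n = 30, k = 3, seed = 5) {
  d <- generate_synthetic(synthetic_spec(m = m, n = n, n_classes = k,
                                         signature_genes = floor(n / (2 * k)),
                                         seed = seed))
  net <- build_network(d$x, theta = 0.3)
  list(x = d$x, y = d$y, codes = as.integer(d$y), net = net)
}

test_that("parameter initialization is seeded, shaped, and Glorot-bounded", {
  p1 <- init_parameters(100, 64, 4, seed = 11)
  p2 <- init_parameters(100, 64, 4, seed = 11)
  expect_identical(p1, p2)
  expect_identical(dim(p1$W1), c(100L, 64L))
  expect_identical(dim(p1$skip_weight), c(100L, 64L))
  expect_identical(length(p1$skip_bias), 64L)
  expect_identical(dim(p1$W2), c(64L, 4L))
  expect_true(all(p1$skip_bias == 0))
  expect_true(all(abs(p1$W1) <= sqrt(6 / (100 + 64))))
  expect_true(all(abs(p1$W2) <= sqrt(6 / (64 + 4))))
  expect_false(identical(p1$W1, init_parameters(100, 64, 4, seed = 12)$W1))
})

test_that("gcn_layer is the plain triple product S H W", {
  h <- matrix(rnorm(12), 4, 3)
  expect_equal(gcn_layer(diag(4), h, diag(3)), h)
  s <- matrix(0.5, 2, 2)
  expect_equal(gcn_layer(s, matrix(c(2, 0), 2, 1), matrix(1)), matrix(1, 2, 1))
  withr::local_seed(2)
  s <- oracle_normalize(threshold_adjacency(correlation_matrix(
    matrix(rnorm(5 * 8), 5, 8)), 0.3))
  h <- matrix(rnorm(5 * 4), 5, 4)
  w <- matrix(rnorm(4 * 2), 4, 2)
  expect_lt(max(abs(gcn_layer(s, h, w) - s %*% h %*% w)), 1e-12)
  expect_error(gcn_layer(s, h, matrix(rnorm(6), 3, 2)), "conformable")
})

test_that("forward pass yields valid softmax rows and honors the variant contracts", {
  fx <- model_fixture()
  par <- init_parameters(ncol(fx$x), 8, 3, seed = 0)
  S <- fx$net$snorm
  fwd <- ergcn:::ergcn_forward(fx$x, S %*% fx$x, S, par, "ergcn")
  expect_equal(unname(rowSums(fwd$P)), rep(1, nrow(fx$x)), tolerance = 1e-6)
  expect_true(all(fwd$P >= 0 & fwd$P <= 1))
  # zero skip map: ergcn forward collapses exactly onto the gcn variant
  par0 <- par
  par0$skip_weight[] <- 0
  par0$skip_bias[] <- 0
  fwd0 <- ergcn:::ergcn_forward(fx$x, S %*% fx$x, S, par0, "ergcn")
  fwd_g <- ergcn:::ergcn_forward(fx$x, S %*% fx$x, S, par, "gcn")
  expect_identical(fwd0$P, fwd_g$P)
  expect_identical(fwd0$Hp, fwd_g$Hp)
  # inference is deterministic
  fwd2 <- ergcn:::ergcn_forward(fx$x, S %*% fx$x, S, par, "ergcn")
  expect_identical(fwd$P, fwd2$P)
  # the mlp never touches the graph
  fwd_m1 <- ergcn:::ergcn_forward(fx$x, fx$x, S, par, "mlp")
  fwd_m2 <- ergcn:::ergcn_forward(fx$x, fx$x, diag(nrow(fx$x)), par, "mlp")
  expect_identical(fwd_m1$P, fwd_m2$P)
})

test_that("masked cross-entropy follows the summed negative log-likelihood", {
  # exactly one-hot and correct: zero loss
  prob <- diag(3)
  expect_equal(masked_cross_entropy(prob, 1:3, rep(TRUE, 3)), 0)
  # uniform over F=4 on 3 masked rows: 3 ln 4
  prob <- matrix(0.25, 5, 4)
  mask <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  expect_equal(masked_cross_entropy(prob, c(1, 2, 3, 4, 4), mask), 3 * log(4),
               tolerance = 1e-12)
  # unmasked rows never matter
  prob2 <- prob
  prob2[4:5, ] <- matrix(c(0.97, 0.01, 0.01, 0.01), 2, 4, byrow = TRUE)
  expect_identical(masked_cross_entropy(prob, c(1, 2, 3, 4, 4), mask),
                   masked_cross_entropy(prob2, c(1, 2, 3, 4, 4), mask))
  expect_error(masked_cross_entropy(prob, c(1, 2, 3, 4, 4), rep(FALSE, 5)),
               "empty")
  expect_gte(masked_cross_entropy(matrix(c(1e-20, 1 - 1e-20), 1, 2), 1, TRUE), 0)
})

test_that("analytic gradients match central finite differences", {
  # tiny instance: m=6, n=5, h=3, F=2
  withr::local_seed(31)
  x <- matrix(rnorm(6 * 5), 6, 5)
  a <- threshold_adjacency(correlation_matrix(x), 0.2)
  S <- normalize_adjacency(a)
  y_codes <- c(1L, 2L, 1L, 2L, 1L, 2L)
  mask <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  for (variant in c("ergcn", "gcn", "mlp")) {
    par <- init_parameters(5, 3, 2, seed = 17)
    prop_x <- if (variant == "mlp") x else S %*% x
    bw <- ergcn:::ergcn_backward(x, prop_x, S, par, variant, y_codes, mask)
    blocks <- if (variant == "ergcn") {
      c("W1", "skip_weight", "skip_bias", "W2")
    } else {
      c("W1", "W2")
    }
    for (b in blocks) {
      fd <- fd_gradient(x, S, par, variant, y_codes, mask, b)
      denom <- max(abs(fd), 1e-8)
      expect_lt(max(abs(bw$grads[[b]] - fd)) / denom, 1e-4,
                label = sprintf("gradient of %s (%s)", b, variant))
    }
  }
})

test_that("training is deterministic, loss decreases, and separable data is learned", {
  fx <- model_fixture(m = 30, n = 60, k = 3, seed = 8)
  mask <- rep(c(TRUE, TRUE, FALSE), 10)
  fit1 <- ergcn(fx$x, fx$y, theta = 0.3, network = fx$net <- build_network(fx$x, 0.3),
                hidden = 16, epochs = 120, train_mask = mask, seed = 4)
  fit2 <- ergcn(fx$x, fx$y, theta = 0.3, network = fx$net,
                hidden = 16, epochs = 120, train_mask = mask, seed = 4)
  expect_equal(fit1$history, fit2$history, tolerance = 1e-10)
  expect_identical(fit1$fitted_labels, fit2$fitted_labels)
  expect_true(all(is.finite(fit1$history)))
  expect_lt(fit1$history[length(fit1$history)], fit1$history[1])
  # held-out accuracy on well-separated synthetic data
  acc <- mean(fit1$fitted_labels[!mask] == fx$y[!mask])
  expect_gte(acc, 0.9)
  # probabilities are a valid stochastic matrix and labels are the argmax
  expect_equal(unname(rowSums(fit1$probabilities)), rep(1, 30),
               tolerance = 1e-6)
  expect_identical(as.integer(fit1$fitted_labels),
                   max.col(fit1$probabilities, ties.method = "first"))
})

test_that("all three variants fit and produce valid probability rows", {
  fx <- model_fixture(m = 24, n = 30, k = 3, seed = 5)
  for (v in c("ergcn", "gcn", "mlp")) {
    fit <- ergcn(fx$x, fx$y, theta = 0.3, variant = v, hidden = 8,
                 epochs = 30, seed = 2)
    expect_equal(unname(rowSums(fit$probabilities)), rep(1, 24),
                 tolerance = 1e-6)
    expect_s3_class(fit$fitted_labels, "factor")
  }
})

test_that("prediction for a new sample uses augmentation, not retraining", {
  d <- generate_synthetic(synthetic_spec(m = 31, n = 60, n_classes = 3,
                                         signature_genes = 12, seed = 14))
  fit <- ergcn(d$x[1:30, ], d$y[1:30], theta = 0.4, hidden = 16,
               epochs = 120, seed = 6)
  p_class <- predict(fit, newdata = d$x[31, , drop = FALSE])
  expect_identical(as.character(p_class), as.character(d$y[31]))
  p_prob <- predict(fit, newdata = d$x[31, , drop = FALSE], type = "prob")
  expect_equal(unname(rowSums(p_prob)), 1, tolerance = 1e-6)
  # fitted values are unchanged by predicting new data
  expect_identical(fitted(fit), predict(fit))
})

test_that("degenerate configurations are rejected", {
  fx <- model_fixture()
  expect_error(ergcn(fx$x, fx$y[-1]), "missing|length")
  expect_error(ergcn(fx$x, unname(as.character(fx$y))[-1]), "length")
  expect_error(ergcn(fx$x, fx$y, dropout = 1), "dropout")
  expect_error(ergcn(fx$x, fx$y, learning_rate = -1), "learning_rate")
  expect_error(ergcn(fx$x, fx$y, train_mask = rep(FALSE, nrow(fx$x))),
               "no samples")
  expect_warning(
    ergcn(fx$x, fx$y, theta = 0.3, epochs = 5, hidden = 4,
          train_mask = fx$y != levels(fx$y)[1], seed = 1),
    "no training samples")
})
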