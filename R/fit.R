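#' Fit a residual graph convolutional network for subtype classification
#'
#' Trains ERGCN: a two-layer graph convolutional network (GCN) on the patient
#' similarity network, with a residual skip connection that adds a
#' ReLU-transformed affine map of the raw expression profiles to the first
#' layer's output. The skip connection re-injects the original features
#' between the two graph convolutions, counteracting the over-smoothing that
#' makes stacked GCN layers blur node representations together.
#'
#' The forward pass is
#' \deqn{H^{(1)} = \mathrm{ReLU}(S X W_1), \quad
#'       H^{(p)} = H^{(1)} + \mathrm{ReLU}(X W_s + b_s), \quad
#'       Z = S H^{(p)} W_2, \quad P = \mathrm{softmax}(Z)}
#' with \eqn{S = D^{-1/2} A D^{-1/2}} the symmetric-normalized adjacency of
#' the thresholded-correlation network. The GCN layers carry no bias; the
#' skip map is affine. Dropout (training only) is applied to \eqn{H^{(p)}}.
#' Training is transductive and full-batch: the network spans all samples,
#' and the summed cross-entropy loss counts only samples selected by
#' `train_mask`. Held-out samples contribute graph structure but never loss.
#' Optimization uses Adam; the whole run is reproducible from `seed`.
#'
#' @param x samples-x-genes numeric expression matrix with sample ids as
#'   rownames. Values are used as provided (no internal normalization).
#' @param y subtype labels: a factor (or character/integer vector) of length
#'   `nrow(x)`, or named and matched to `rownames(x)`.
#' @param theta correlation threshold in (0, 1) for the similarity network.
#' @param network optionally, a pre-built [build_network()] object for `x`
#'   at `theta` (saves recomputation across folds).
#' @param hidden hidden dimension of the first layer (default 64).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param epochs full-batch training epochs (default 200).
#' @param dropout dropout rate in \[0, 1) applied to the residual sum during
#'   training (default 0.5).
#' @param variant `"ergcn"` (default), `"gcn"` (no skip connection), or
#'   `"mlp"` (two-layer perceptron, graph unused) — the ablation variants.
#' @param train_mask logical vector marking which samples enter the loss;
#'   default all. Test samples stay in the graph but out of the loss.
#' @param seed integer seed controlling initialization and dropout.
#' @param verbose print loss every 50 epochs.
#' @return an object of class `"ergcn"`; see Details. Use [predict.ergcn()]
#'   for new samples, `fitted()` for in-graph predictions, `plot()` for the
#'   loss curve.
#' @details The returned object carries `parameters` (W1, skip_weight,
#'   skip_bias, W2), `history` (per-epoch training loss), `probabilities`
#'   (m x F), `fitted_labels`, `embeddings` (the residual-sum features
#'   \eqn{H^{(p)}} at inference), the `network`, and the call configuration.
#' @examples
#' bench <- default_benchmark()
#' fit <- ergcn(bench$x, bench$y, theta = 0.5, epochs = 50, seed = 1)
#' fit
#' mean(fitted(fit) == bench$y)
#' @export
ergcn <- function(x, y, theta = 0.5, network = NULL, hidden = 64L,
                  learning_rate = 0.001, epochs = 200L, dropout = 0.5,
                  variant = c("ergcn", "gcn", "mlp"), train_mask = NULL,
                  seed = 0L, verbose = FALSE) {
  variant <- match.arg(variant)
  check_matrix(x, "x")
  m <- nrow(x)
  n <- ncol(x)
  if (!is.null(names(y)) && !is.null(rownames(x))) {
    if (!all(rownames(x) %in% names(y))) {
      stop_ergcn("labels missing for some samples; use align_samples() first")
    }
    y <- y[rownames(x)]
  }
  if (length(y) != m) stop_ergcn("length(y) must equal nrow(x)")
  cls <- as_class_codes(y)
  n_class <- length(cls$class_names)
  if (n_class < 2L) stop_ergcn("need at least 2 subtypes")
  if (is.null(train_mask)) train_mask <- rep(TRUE, m)
  if (!is.logical(train_mask) || length(train_mask) != m) {
    stop_ergcn("train_mask must be a logical vector of length nrow(x)")
  }
  if (!any(train_mask)) stop_ergcn("train_mask selects no samples")
  missing_cls <- setdiff(seq_len(n_class), unique(cls$codes[train_mask]))
  if (length(missing_cls) > 0L) {
    warning("no training samples for subtype(s): ",
            paste(cls$class_names[missing_cls], collapse = ", "))
  }
  if (!is_scalar_number(dropout) || dropout < 0 || dropout >= 1) {
    stop_ergcn("dropout must be in [0, 1)")
  }
  if (!is_scalar_number(learning_rate) || learning_rate <= 0) {
    stop_ergcn("learning_rate must be positive")
  }
  epochs <- as.integer(epochs)
  hidden <- as.integer(hidden)
  if (epochs < 1L || hidden < 1L) stop_ergcn("epochs and hidden must be positive")

  if (variant == "mlp") {
    S <- NULL
    prop_x <- x               # the MLP never touches the graph
  } else {
    if (is.null(network)) network <- build_network(x, theta, verbose = verbose)
    if (!inherits(network, "similarity_network") ||
        nrow(network$adjacency) != m) {
      stop_ergcn("network does not match x")
    }
    S <- network$snorm
    prop_x <- S %*% x         # fixed across epochs: X never changes
  }

  res <- withr::with_seed(seed, {
    par <- init_parameters(n, hidden, n_class, seed = NULL)
    opt <- adam_state(par)
    history <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      dropmask <- NULL
      if (dropout > 0) {
        keep <- matrix(stats::runif(m * hidden) >= dropout, m, hidden)
        dropmask <- keep / (1 - dropout)
      }
      bw <- ergcn_backward(x, prop_x, S, par, variant, cls$codes, train_mask,
                           dropmask)
      history[ep] <- bw$loss
      if (!is.finite(bw$loss)) {
        stop_ergcn("training loss diverged (NaN/Inf) at epoch ", ep,
                   "; try a lower learning_rate")
      }
      upd <- adam_update(par, bw$grads, opt, learning_rate)
      par <- upd$par
      opt <- upd$opt
      if (verbose && ep %% 50L == 0L) {
        message(sprintf("epoch %4d  loss %.4f", ep, bw$loss))
      }
    }
    list(par = par, history = history)
  })

  fwd <- ergcn_forward(x, prop_x, S, res$par, variant, dropmask = NULL)
  pred_idx <- max.col(fwd$P, ties.method = "first")
  fitted_labels <- factor(cls$class_names[pred_idx], levels = cls$class_names)
  names(fitted_labels) <- rownames(x)

  structure(list(
    parameters = res$par,
    history = res$history,
    probabilities = structure(fwd$P, dimnames = list(rownames(x), cls$class_names)),
    fitted_labels = fitted_labels,
    embeddings = fwd$Hp,
    network = network,
    x = x,
    y = factor(cls$class_names[cls$codes], levels = cls$class_names),
    train_mask = train_mask,
    class_names = cls$class_names,
    config = list(theta = theta, hidden = hidden,
                  learning_rate = learning_rate, epochs = epochs,
                  dropout = dropout, variant = variant, seed = seed)
  ), class = "ergcn")
}

#' Initialize ERGCN parameters
#'
#' Glorot-uniform weights for both GCN layers and the skip map, zero skip
#' bias. Fully determined by `seed` (pass `NULL` to draw from the current
#' RNG state).
#'
#' @param n input dimension (number of genes).
#' @param hidden hidden dimension.
#' @param n_class number of subtypes F.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return list with `W1` (n x hidden), `skip_weight` (n x hidden),
#'   `skip_bias` (hidden), `W2` (hidden x n_class).
#' @export
init_parameters <- function(n, hidden, n_class, seed = 0L) {
  stopifnot(n >= 1L, hidden >= 1L, n_class >= 2L)
  draw <- function() {
    b1 <- sqrt(6 / (n + hidden))
    b2 <- sqrt(6 / (hidden + n_class))
    list(W1 = matrix(stats::runif(n * hidden, -b1, b1), n, hidden),
         skip_weight = matrix(stats::runif(n * hidden, -b1, b1), n, hidden),
         skip_bias = numeric(hidden),
         W2 = matrix(stats::runif(hidden * n_class, -b2, b2), hidden, n_class))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' One graph-convolution layer, pre-activation
#'
#' Returns \eqn{S H W}: the degree-normalized neighborhood aggregation
#' followed by the linear map. The caller applies the activation.
#'
#' @param s normalized adjacency (m x m).
#' @param h input features (m x d_in).
#' @param w weight matrix (d_in x d_out).
#' @return m x d_out matrix.
#' @export
gcn_layer <- function(s, h, w) {
  if (ncol(s) != nrow(h) || ncol(h) != nrow(w)) {
    stop_ergcn("non-conformable shapes in gcn_layer")
  }
  s %*% h %*% w
}

#' Masked cross-entropy loss
#'
#' The summed negative log-likelihood of the true subtype over the training
#' samples only: \eqn{L = -\sum_{d \in T} \ln P_{d, y_d}}. Probabilities are
#' clipped at 1e-12 before the log. Rows outside the mask never contribute.
#'
#' @param prob m x F matrix of predicted probabilities (rows sum to 1).
#' @param y_codes integer class codes in 1..F.
#' @param mask logical length-m training mask.
#' @return the loss (non-negative scalar).
#' @export
masked_cross_entropy <- function(prob, y_codes, mask) {
  if (length(y_codes) != nrow(prob) || length(mask) != nrow(prob)) {
    stop_ergcn("prob, y_codes and mask disagree in length")
  }
  if (!any(mask)) stop_ergcn("empty training mask")
  p_true <- prob[cbind(which(mask), y_codes[mask])]
  -sum(log(pmax(p_true, 1e-12)))
}

# forward pass shared by all variants; prop_x is S %*% x for graph variants
# and x itself for the mlp. dropmask (inverted-dropout scaling included) is
# NULL at inference.
ergcn_forward <- function(x, prop_x, S, par, variant, dropmask = NULL) {
  pre1 <- prop_x %*% par$W1
  H1 <- relu(pre1)
  if (variant == "ergcn") {
    preR <- sweep(x %*% par$skip_weight, 2L, par$skip_bias, "+")
    Hp <- H1 + relu(preR)
  } else {
    preR <- NULL
    Hp <- H1
  }
  Hp_drop <- if (is.null(dropmask)) Hp else Hp * dropmask
  logits <- if (variant == "mlp") Hp_drop %*% par$W2 else S %*% Hp_drop %*% par$W2
  if (any(!is.finite(logits))) {
    stop_ergcn("non-finite values in layer 'logits'")
  }
  P <- softmax_rows(logits)
  list(pre1 = pre1, preR = preR, Hp = Hp, Hp_drop = Hp_drop,
       logits = logits, P = P)
}

# analytic gradients of the masked summed cross-entropy wrt all parameter
# blocks. Derivation: with one-hot targets Y on masked rows,
# dL/dZ = P - Y (masked rows, else 0); logits Z = S Hp' W2 (Hp' after
# dropout), so dW2 = (S Hp')^T dZ and dHp' = S dZ W2^T (S symmetric);
# dropout backprops as elementwise mask; ReLU as indicator of positive
# pre-activation; dW1 = (S X)^T dH1, dWs = X^T dR, dbs = colSums(dR).
ergcn_backward <- function(x, prop_x, S, par, variant, y_codes, mask,
                           dropmask = NULL) {
  fwd <- ergcn_forward(x, prop_x, S, par, variant, dropmask)
  loss <- masked_cross_entropy(fwd$P, y_codes, mask)
  m <- nrow(x)
  dZ <- fwd$P
  dZ[cbind(which(mask), y_codes[mask])] <-
    dZ[cbind(which(mask), y_codes[mask])] - 1
  dZ[!mask, ] <- 0
  if (variant == "mlp") {
    dW2 <- crossprod(fwd$Hp_drop, dZ)
    dHp_drop <- tcrossprod(dZ, par$W2)
  } else {
    SHp <- S %*% fwd$Hp_drop
    dW2 <- crossprod(SHp, dZ)
    dHp_drop <- (S %*% dZ) %*% t(par$W2)
  }
  dHp <- if (is.null(dropmask)) dHp_drop else dHp_drop * dropmask
  dH1 <- dHp * (fwd$pre1 > 0)
  dW1 <- crossprod(prop_x, dH1)
  grads <- list(W1 = dW1, skip_weight = NULL, skip_bias = NULL, W2 = dW2)
  if (variant == "ergcn") {
    dR <- dHp * (fwd$preR > 0)
    grads$skip_weight <- crossprod(x, dR)
    grads$skip_bias <- colSums(dR)
  }
  list(loss = loss, grads = grads, forward = fwd)
}

# Adam optimizer state and update (beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
adam_state <- function(par) {
  list(t = 0L,
       m = lapply(par, function(p) p * 0),
       v = lapply(par, function(p) p * 0))
}

adam_update <- function(par, grads, opt, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  for (k in names(par)) {
    g <- grads[[k]]
    if (is.null(g)) next
    opt$m[[k]] <- beta1 * opt$m[[k]] + (1 - beta1) * g
    opt$v[[k]] <- beta2 * opt$v[[k]] + (1 - beta2) * g^2
    mhat <- opt$m[[k]] / (1 - beta1^opt$t)
    vhat <- opt$v[[k]] / (1 - beta2^opt$t)
    par[[k]] <- par[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, opt = opt)
}

#' @export
print.ergcn <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("ERGCN fit (variant '%s'): %d samples, %d genes, %d subtypes\n",
              cfg$variant, nrow(x$x), ncol(x$x), length(x$class_names)))
  cat(sprintf("  theta = %g, hidden = %d, lr = %g, epochs = %d, dropout = %g, seed = %d\n",
              cfg$theta, cfg$hidden, cfg$learning_rate, cfg$epochs,
              cfg$dropout, cfg$seed))
  cat(sprintf("  training loss: %.4f -> %.4f\n",
              x$history[1L], x$history[length(x$history)]))
  acc <- mean(x$fitted_labels[x$train_mask] == x$y[x$train_mask])
  cat(sprintf("  training-set accuracy: %.4f (%d labeled samples)\n",
              acc, sum(x$train_mask)))
  invisible(x)
}

#' @export
summary.ergcn <- function(object, ...) {
  held <- !object$train_mask
  out <- list(config = object$config,
              class_names = object$class_names,
              n_train = sum(object$train_mask),
              n_test = sum(held),
              train_metrics = external_metrics(
                object$y[object$train_mask],
                object$fitted_labels[object$train_mask]),
              test_metrics = if (any(held)) {
                external_metrics(object$y[held], object$fitted_labels[held])
              } else NULL,
              confusion = table(true = object$y, predicted = object$fitted_labels))
  class(out) <- "summary.ergcn"
  out
}

#' @export
print.summary.ergcn <- function(x, ...) {
  cat("ERGCN fit summary\n")
  cat(sprintf("  %d training / %d held-out samples, subtypes: %s\n",
              x$n_train, x$n_test, paste(x$class_names, collapse = ", ")))
  cat("  training-set metrics:\n")
  print(round(unlist(x$train_metrics), 4))
  if (!is.null(x$test_metrics)) {
    cat("  held-out metrics:\n")
    print(round(unlist(x$test_metrics), 4))
  }
  cat("  confusion (all samples):\n")
  print(x$confusion)
  invisible(x)
}

#' @export
coef.ergcn <- function(object, ...) object$parameters

#' @export
fitted.ergcn <- function(object, type = c("class", "prob", "embedding"), ...) {
  type <- match.arg(type)
  switch(type,
         class = object$fitted_labels,
         prob = object$probabilities,
         embedding = object$embeddings)
}

#' Predict subtypes for fitted or new samples
#'
#' With `newdata = NULL`, returns the transductive predictions for the
#' samples the model was fitted on. With `newdata`, each new sample is
#' classified by the new-sample augmentation protocol: its correlations to
#' the training samples are computed, thresholded at the fitted `theta`, the
#' normalized operator is rebuilt on the m+1 node graph, and one forward
#' pass of the already-trained weights yields the prediction at the new
#' node. Each new sample is augmented individually; the model is not
#' retrained.
#'
#' @param object an `"ergcn"` fit.
#' @param newdata optional matrix of new samples (columns must match the
#'   training genes), or a single profile vector.
#' @param type `"class"` (factor), `"prob"` (matrix), or `"embedding"`.
#' @param ... unused.
#' @export
predict.ergcn <- function(object, newdata = NULL,
                          type = c("class", "prob", "embedding"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) return(fitted(object, type = type))
  if (is.vector(newdata) && is.numeric(newdata)) {
    newdata <- matrix(newdata, nrow = 1L,
                      dimnames = list("new_sample", names(newdata)))
  }
  if (ncol(newdata) != ncol(object$x)) {
    stop_ergcn("newdata has ", ncol(newdata), " genes; expected ",
               ncol(object$x))
  }
  variant <- object$config$variant
  par <- object$parameters
  n_new <- nrow(newdata)
  probs <- matrix(NA_real_, n_new, length(object$class_names),
                  dimnames = list(rownames(newdata), object$class_names))
  embs <- matrix(NA_real_, n_new, object$config$hidden,
                 dimnames = list(rownames(newdata), NULL))
  if (variant == "mlp") {
    fwd <- ergcn_forward(newdata, newdata, NULL, par, variant)
    probs[] <- fwd$P
    embs[] <- fwd$Hp
  } else {
    for (i in seq_len(n_new)) {
      net <- augment_network(object$x, newdata[i, ], object$config$theta)
      xa <- rbind(object$x, newdata[i, , drop = FALSE])
      fwd <- ergcn_forward(xa, net$snorm %*% xa, net$snorm, par, variant)
      probs[i, ] <- fwd$P[nrow(xa), ]
      embs[i, ] <- fwd$Hp[nrow(xa), ]
    }
  }
  switch(type,
         prob = probs,
         embedding = embs,
         class = {
           lab <- factor(object$class_names[max.col(probs, ties.method = "first")],
                         levels = object$class_names)
           names(lab) <- rownames(newdata)
           lab
         })
}

#' Plot the training loss curve of an ERGCN fit
#' @param x an `"ergcn"` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ergcn <- function(x, ...) {
  graphics::plot(seq_along(x$history), x$history, type = "l",
                 xlab = "epoch", ylab = "training cross-entropy",
                 main = sprintf("ERGCN training loss (variant '%s')",
                                x$config$variant), ...)
  invisible(x)
}
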