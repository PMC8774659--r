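# Independent brute-force / definitional oracles used to cross-check the
# package implementations. These deliberately use naive loops and the
# textbook formulas, never the package's own code paths.

# Pearson correlation from its definitional sum form
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2))
  num / den
}

# pairwise-loop correlation matrix
oracle_correlation_matrix <- function(x) {
  m <- nrow(x)
  r <- matrix(NA_real_, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      r[i, j] <- oracle_pearson(x[i, ], x[j, ])
    }
  }
  r
}

# dense D^{-1/2} A D^{-1/2} product
oracle_normalize <- function(a) {
  d_inv_sqrt <- diag(1 / sqrt(rowSums(a)))
  d_inv_sqrt %*% a %*% d_inv_sqrt
}

# exhaustive pair enumeration for the pair-counting partition comparison
oracle_pair_counts <- function(y_true, y_pred) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  m <- length(y_true)
  tp <- fp <- fn <- tn <- 0L
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      st <- y_true[i] == y_true[j]
      sp <- y_pred[i] == y_pred[j]
      if (st && sp) tp <- tp + 1L
      else if (!st && sp) fp <- fp + 1L
      else if (st && !sp) fn <- fn + 1L
      else tn <- tn + 1L
    }
  }
  list(TP = tp, FP = fp, FN = fn, TN = tn)
}

# per-class one-vs-rest external metrics, macro averaged, from first principles
oracle_external <- function(y_true, y_pred) {
  y_true <- as.character(y_true)
  y_pred <- as.character(y_pred)
  classes <- sort(unique(c(y_true, y_pred)))
  m <- length(y_true)
  prec <- rec <- f1 <- numeric(length(classes))
  for (k in seq_along(classes)) {
    cl <- classes[k]
    tp <- sum(y_true == cl & y_pred == cl)
    fp <- sum(y_true != cl & y_pred == cl)
    fn <- sum(y_true == cl & y_pred != cl)
    prec[k] <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec[k] <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1[k] <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }
  # multiclass MCC via the covariance form on the contingency table
  cm <- table(factor(y_true, classes), factor(y_pred, classes))
  s <- sum(cm)
  c_ <- sum(diag(cm))
  t_k <- rowSums(cm)
  p_k <- colSums(cm)
  den <- sqrt(s^2 - sum(p_k^2)) * sqrt(s^2 - sum(t_k^2))
  mcc <- if (den == 0) 0 else (c_ * s - sum(t_k * p_k)) / den
  list(accuracy = mean(y_true == y_pred),
       precision = mean(prec), recall = mean(rec), f1 = mean(f1), mcc = mcc)
}

# binary MCC from the literal 2x2 formula
oracle_mcc_binary <- function(tp, tn, fp, fn) {
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) 0 else (tp * tn - fp * fn) / den
}

# per-sample silhouette by direct loops
oracle_silhouette <- function(feat, labels) {
  labels <- as.character(labels)
  m <- nrow(feat)
  dmat <- as.matrix(dist(feat))
  s <- numeric(m)
  for (i in seq_len(m)) {
    own <- which(labels == labels[i] & seq_len(m) != i)
    if (length(own) == 0L) { s[i] <- 0; next }
    a <- mean(dmat[i, own])
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i])) {
      b <- min(b, mean(dmat[i, labels == cl]))
    }
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Davies-Bouldin by direct loops
oracle_dbi <- function(feat, labels) {
  labels <- as.character(labels)
  classes <- unique(labels)
  k <- length(classes)
  cent <- matrix(NA_real_, k, ncol(feat))
  avg <- numeric(k)
  for (g in seq_len(k)) {
    mem <- feat[labels == classes[g], , drop = FALSE]
    cent[g, ] <- colMeans(mem)
    avg[g] <- mean(apply(mem, 1L, function(v) sqrt(sum((v - cent[g, ])^2))))
  }
  total <- 0
  for (i in seq_len(k)) {
    worst <- -Inf
    for (j in seq_len(k)) {
      if (i == j) next
      dij <- sqrt(sum((cent[i, ] - cent[j, ])^2))
      worst <- max(worst, (avg[i] + avg[j]) / dij)
    }
    total <- total + worst
  }
  total / k
}

# central finite differences of the masked cross-entropy wrt one parameter
# block of an ERGCN-family model
fd_gradient <- function(x, S, par, variant, y_codes, mask, block, eps = 1e-6) {
  prop_x <- if (variant == "mlp") x else S %*% x
  loss_at <- function(p) {
    fwd <- ergcn:::ergcn_forward(x, prop_x, S, p, variant, dropmask = NULL)
    masked_cross_entropy(fwd$P, y_codes, mask)
  }
  g <- par[[block]] * 0
  for (i in seq_along(g)) {
    pp <- par; pp[[block]][i] <- pp[[block]][i] + eps
    pm <- par; pm[[block]][i] <- pm[[block]][i] - eps
    g[i] <- (loss_at(pp) - loss_at(pm)) / (2 * eps)
  }
  g
}

# small random labeled dataset for metric fuzzing
random_labels <- function(m, k) sample.int(k, m, replace = TRUE)
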