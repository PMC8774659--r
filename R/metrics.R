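# ---- external (label-comparison) metrics -----------------------------------

# put two label vectors on one shared 1..F coding
harmonize_labels <- function(y_true, y_pred, n_class = NULL) {
  if (length(y_true) != length(y_pred)) {
    stop_ergcn("y_true and y_pred differ in length")
  }
  if (is.factor(y_true) || is.factor(y_pred) ||
      is.character(y_true) || is.character(y_pred)) {
    lev <- sort(unique(c(as.character(y_true), as.character(y_pred))))
    list(true = match(as.character(y_true), lev),
         pred = match(as.character(y_pred), lev),
         n_class = length(lev), class_names = lev)
  } else {
    lev <- sort(unique(c(as.integer(y_true), as.integer(y_pred))))
    if (!is.null(n_class)) lev <- sort(unique(c(lev, seq_len(n_class) - 1L)))
    list(true = match(as.integer(y_true), lev),
         pred = match(as.integer(y_pred), lev),
         n_class = length(lev), class_names = as.character(lev))
  }
}

#' Confusion matrix with one-vs-rest counts
#'
#' Cross-tabulates true against predicted subtypes, and for every class f
#' collapses the table to the one-vs-rest counts TP (class-f samples
#' predicted f), FP (other samples predicted f), FN (class-f samples
#' predicted otherwise) and TN (the rest).
#'
#' @param y_true,y_pred label vectors of equal length (factors, characters,
#'   or integer codes).
#' @param n_class optional number of classes (for integer codes whose range
#'   exceeds the observed labels).
#' @return list with `matrix` (F x F counts, rows = true) and `per_class`
#'   (F x 4 matrix of TP/FP/FN/TN).
#' @export
confusion_counts <- function(y_true, y_pred, n_class = NULL) {
  h <- harmonize_labels(y_true, y_pred, n_class)
  f <- h$n_class
  cm <- matrix(0L, f, f, dimnames = list(true = h$class_names,
                                         predicted = h$class_names))
  for (i in seq_along(h$true)) {
    cm[h$true[i], h$pred[i]] <- cm[h$true[i], h$pred[i]] + 1L
  }
  m <- length(h$true)
  per_class <- t(vapply(seq_len(f), function(k) {
    tp <- cm[k, k]
    fp <- sum(cm[-k, k])
    fn <- sum(cm[k, -k])
    c(TP = tp, FP = fp, FN = fn, TN = m - tp - fp - fn)
  }, numeric(4L)))
  rownames(per_class) <- h$class_names
  list(matrix = cm, per_class = per_class)
}

#' External classification metrics
#'
#' Accuracy, macro-averaged one-vs-rest precision, recall and F1, the
#' multiclass Matthews correlation coefficient, and the pair-counting
#' adjusted Rand index, comparing predicted against true subtypes.
#'
#' Precision, recall and F1 are computed per class (one-vs-rest) and
#' averaged without weights (macro); a class with a zero denominator
#' contributes 0. The MCC is the full-confusion-matrix multiclass
#' generalization, which reduces exactly to the familiar binary formula
#' \eqn{(TP\,TN - FP\,FN)/\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}} when F = 2;
#' a degenerate denominator yields 0.
#'
#' @inheritParams confusion_counts
#' @param average `"macro"` (default) or `"micro"` for precision/recall/F1.
#' @return named list: `precision`, `recall`, `f1`, `accuracy`, `ari`,
#'   `mcc`.
#' @export
external_metrics <- function(y_true, y_pred, n_class = NULL,
                             average = c("macro", "micro")) {
  average <- match.arg(average)
  cc <- confusion_counts(y_true, y_pred, n_class)
  cm <- cc$matrix
  m <- sum(cm)
  accuracy <- sum(diag(cm)) / m
  pc <- cc$per_class
  safe_div <- function(num, den) ifelse(den == 0, 0, num / den)
  if (average == "macro") {
    prec_k <- safe_div(pc[, "TP"], pc[, "TP"] + pc[, "FP"])
    rec_k <- safe_div(pc[, "TP"], pc[, "TP"] + pc[, "FN"])
    f1_k <- safe_div(2 * pc[, "TP"], 2 * pc[, "TP"] + pc[, "FP"] + pc[, "FN"])
    precision <- mean(prec_k)
    recall <- mean(rec_k)
    f1 <- mean(f1_k)
  } else {
    precision <- recall <- f1 <- accuracy
  }
  # multiclass MCC from the full confusion matrix
  c_ <- sum(diag(cm))
  t_k <- rowSums(cm)
  p_k <- colSums(cm)
  num <- c_ * m - sum(t_k * p_k)
  den <- sqrt(m^2 - sum(p_k^2)) * sqrt(m^2 - sum(t_k^2))
  mcc <- if (den == 0) {
    warning("degenerate MCC denominator; returning 0")
    0
  } else num / den
  list(precision = precision, recall = recall, f1 = f1,
       accuracy = accuracy,
       ari = adjusted_rand(y_true, y_pred),
       mcc = mcc)
}

#' Pair-agreement counts between two partitions
#'
#' Classifies each of the m(m-1)/2 unordered sample pairs: TP (same true
#' class, same predicted class), FP (different true, same predicted), FN
#' (same true, different predicted), TN (different in both). These counts
#' feed the pair-counting adjusted Rand index.
#'
#' @inheritParams confusion_counts
#' @return object of class `pair_counts`: list with integers `TP`, `FP`,
#'   `FN`, `TN` and `total`.
#' @export
pair_counts <- function(y_true, y_pred) {
  h <- harmonize_labels(y_true, y_pred)
  m <- length(h$true)
  if (m < 2L) stop_ergcn("need at least 2 samples")
  same_t <- outer(h$true, h$true, "==")
  same_p <- outer(h$pred, h$pred, "==")
  up <- upper.tri(same_t)
  tp <- sum(same_t[up] & same_p[up])
  fp <- sum(!same_t[up] & same_p[up])
  fn <- sum(same_t[up] & !same_p[up])
  tn <- sum(!same_t[up] & !same_p[up])
  structure(list(TP = tp, FP = fp, FN = fn, TN = tn,
                 total = m * (m - 1) / 2),
            class = "pair_counts")
}

#' Adjusted Rand index (pair-counting)
#'
#' Chance-corrected pairwise agreement between two partitions of the same
#' samples. The default `"standard"` formula is the Hubert–Arabie ARI in its
#' pair-count form,
#' \deqn{ARI = \frac{2(TP \cdot TN - FP \cdot FN)}
#'   {(TP+FP)(FP+TN) + (TP+FN)(FN+TN)},}
#' which equals 1 for identical partitions and has expectation 0 under
#' independent random partitions. `formula = "eq10"` instead evaluates the
#' literal textbook chain \eqn{(RI - E(RI)) / (\max(RI) - E(RI))} with
#' \eqn{RI = (TP+TN)/N}, \eqn{E(RI) = (TP+TN)(TP+FP)/N},
#' \eqn{\max(RI) = ((TP+TN)+(TP+FP))/2}; it also returns 1 for identical
#' partitions but can go strongly negative on mild disagreements, and is
#' kept only as a documented alternative.
#'
#' @param y_true true labels, or a [pair_counts()] object.
#' @param y_pred predicted labels (ignored when `y_true` is a `pair_counts`).
#' @param formula `"standard"` (default) or `"eq10"`.
#' @return the index (at most 1).
#' @export
adjusted_rand <- function(y_true, y_pred = NULL,
                          formula = c("standard", "eq10")) {
  formula <- match.arg(formula)
  pc <- if (inherits(y_true, "pair_counts")) y_true else pair_counts(y_true, y_pred)
  tp <- pc$TP; fp <- pc$FP; fn <- pc$FN; tn <- pc$TN
  # perfect pair agreement is 1 under either formula; the literal textbook
  # chain does not evaluate to 1 there on its own, so the convention is fixed
  # here before the arithmetic
  if (fp == 0 && fn == 0) return(1)
  if (formula == "standard") {
    den <- (tp + fp) * (fp + tn) + (tp + fn) * (fn + tn)
    if (den == 0) {
      if (fp == 0 && fn == 0) return(1)  # identical partitions
      warning("degenerate ARI denominator; returning 0")
      return(0)
    }
    2 * (tp * tn - fp * fn) / den
  } else {
    total <- tp + fp + fn + tn
    ri <- (tp + tn) / total
    e_ri <- (tp + tn) * (tp + fp) / total
    max_ri <- ((tp + tn) + (tp + fp)) / 2
    den <- max_ri - e_ri
    if (den == 0) {
      if (fp == 0 && fn == 0) return(1)
      warning("degenerate ARI denominator; returning 0")
      return(0)
    }
    (ri - e_ri) / den
  }
}

# ---- internal (clustering-validity) metrics --------------------------------

#' Mean silhouette width
#'
#' For each sample i, \eqn{s(i) = (b(i) - a(i)) / \max(a(i), b(i))} with
#' a(i) the mean Euclidean distance to the other members of its own cluster
#' and b(i) the smallest mean distance to the members of any other cluster.
#' Samples in singleton clusters score 0 by convention. Returns the mean
#' over all samples, in \[-1, 1\].
#'
#' @param features m x d numeric matrix (rows are samples).
#' @param labels cluster/subtype assignment of each row.
#' @return mean silhouette width.
#' @export
silhouette_width <- function(features, labels) {
  features <- as.matrix(features)
  if (nrow(features) != length(labels)) stop_ergcn("features/labels mismatch")
  lab <- as.integer(factor(labels))
  k <- max(lab)
  if (k < 2L) stop_ergcn("silhouette needs at least 2 clusters")
  d <- as.matrix(stats::dist(features))
  m <- nrow(features)
  sizes <- tabulate(lab, k)
  # mean distance from each sample to each cluster
  cl_sum <- vapply(seq_len(k), function(g) rowSums(d[, lab == g, drop = FALSE]),
                   numeric(m))
  s <- numeric(m)
  for (i in seq_len(m)) {
    g <- lab[i]
    if (sizes[g] == 1L) { s[i] <- 0; next }
    a <- cl_sum[i, g] / (sizes[g] - 1L)
    b <- min(cl_sum[i, -g] / sizes[-g])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Davies–Bouldin index
#'
#' \deqn{DBI = \frac{1}{N}\sum_i \max_{j \ne i}
#'   \frac{avg(C_i) + avg(C_j)}{dis(C_i, C_j)}}
#' where avg(C) is the mean Euclidean distance of the members of cluster C
#' to its centroid and dis the distance between the two centroids. Zero is
#' the lower limit (ideally compact, well-separated clusters); smaller is
#' better. Coincident centroids make the ratio undefined and raise an error.
#'
#' @inheritParams silhouette_width
#' @return the index (non-negative).
#' @export
davies_bouldin <- function(features, labels) {
  features <- as.matrix(features)
  if (nrow(features) != length(labels)) stop_ergcn("features/labels mismatch")
  lab <- as.integer(factor(labels))
  k <- max(lab)
  if (k < 2L) stop_ergcn("Davies-Bouldin needs at least 2 clusters")
  centroids <- t(vapply(seq_len(k), function(g)
    colMeans(features[lab == g, , drop = FALSE]), numeric(ncol(features))))
  avg <- vapply(seq_len(k), function(g) {
    mem <- features[lab == g, , drop = FALSE]
    mean(sqrt(rowSums(sweep(mem, 2L, centroids[g, ])^2)))
  }, numeric(1L))
  cd <- as.matrix(stats::dist(centroids))
  if (any(cd[upper.tri(cd)] == 0)) {
    stop_ergcn("coincident cluster centroids: Davies-Bouldin undefined")
  }
  ratios <- vapply(seq_len(k), function(i)
    max((avg[i] + avg[-i]) / cd[i, -i]), numeric(1L))
  mean(ratios)
}

#' Full metrics report for one evaluation
#'
#' Bundles the external metrics (predicted vs true labels) with the internal
#' clustering-validity metrics computed on a feature space under the
#' PREDICTED labels — by default the learned embeddings, optionally the raw
#' expression features. Internal metrics that are undefined for the run
#' (e.g., all samples predicted into one subtype) are reported as `NA` with
#' a warning rather than aborting the evaluation.
#'
#' @param y_true true subtype labels of the evaluated samples.
#' @param y_pred predicted labels.
#' @param features optional m x d feature matrix (embeddings or raw
#'   expression) for the internal metrics; `NULL` skips them.
#' @param metadata named list of run descriptors (theta, seed, fold...)
#'   stored alongside the metric values.
#' @return object of class `metrics_report`: named list of `precision`,
#'   `recall`, `f1`, `accuracy`, `ari`, `mcc`, `silhouette`, `dbi`, plus
#'   `metadata`.
#' @export
evaluate_predictions <- function(y_true, y_pred, features = NULL,
                                 metadata = list()) {
  ext <- external_metrics(y_true, y_pred)
  sil <- dbi <- NA_real_
  if (!is.null(features)) {
    sil <- tryCatch(silhouette_width(features, y_pred),
                    error = function(e) {
                      warning("silhouette undefined: ", conditionMessage(e))
                      NA_real_
                    })
    dbi <- tryCatch(davies_bouldin(features, y_pred),
                    error = function(e) {
                      warning("Davies-Bouldin undefined: ", conditionMessage(e))
                      NA_real_
                    })
  }
  structure(c(ext, list(silhouette = sil, dbi = dbi, metadata = metadata)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  vals <- unlist(x[c("precision", "recall", "f1", "accuracy", "ari", "mcc",
                     "silhouette", "dbi")])
  print(round(vals, 4))
  invisible(x)
}

# flatten a metrics_report (or plain metric list) to a one-row data frame
report_row <- function(rep) {
  flds <- c("precision", "recall", "f1", "accuracy", "ari", "mcc",
            "silhouette", "dbi")
  vals <- lapply(flds, function(f) if (is.null(rep[[f]])) NA_real_ else rep[[f]])
  names(vals) <- flds
  meta <- rep$metadata
  if (length(meta)) vals <- c(vals, meta)
  as.data.frame(vals, stringsAsFactors = FALSE)
}
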