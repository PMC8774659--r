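#' Build a repeated stratified cross-validation plan
#'
#' Partitions the samples into `folds` disjoint folds, `repeats` independent
#' times. Stratification (default) balances every subtype across folds so
#' that per-stratum fold sizes differ by at most one — with cohorts under a
#' couple hundred samples and four subtypes, unstratified folds frequently
#' lose a class entirely. Fully reproducible from `seed`.
#'
#' @param y subtype labels (factor or vector).
#' @param folds number of folds (default 5).
#' @param repeats number of repeats (default 10).
#' @param seed integer seed.
#' @param stratified balance classes across folds (default `TRUE`).
#' @return object of class `cv_plan`: list with `assignments` (one integer
#'   vector of fold ids per repeat), `folds`, `repeats`, `seed`,
#'   `stratified`.
#' @export
make_cv_plan <- function(y, folds = 5L, repeats = 10L, seed = 0L,
                         stratified = TRUE) {
  m <- length(y)
  folds <- as.integer(folds)
  repeats <- as.integer(repeats)
  stopifnot(folds >= 2L, repeats >= 1L, m >= folds)
  cls <- as.integer(factor(y))
  assignments <- withr::with_seed(seed, {
    lapply(seq_len(repeats), function(r) {
      fold_id <- integer(m)
      if (stratified) {
        for (k in unique(cls)) {
          idx <- sample(which(cls == k))
          off <- sample.int(folds, 1L)
          fold_id[idx] <- ((seq_along(idx) + off - 2L) %% folds) + 1L
        }
      } else {
        fold_id <- sample(rep(seq_len(folds), length.out = m))
      }
      fold_id
    })
  })
  structure(list(assignments = assignments, folds = folds, repeats = repeats,
                 seed = as.integer(seed), stratified = stratified),
            class = "cv_plan")
}

#' Repeated k-fold transductive cross-validation of ERGCN
#'
#' The evaluation protocol of the classifier: the similarity network is
#' built ONCE from all samples at `theta`; in each of the
#' `folds * repeats` runs the model is trained with the loss masked to the
#' training folds, while the held-out fold's samples stay in the graph with
#' their labels hidden (transductive evaluation — test profiles shape the
#' propagation operator but never the loss). External metrics are computed
#' on the held-out fold, internal metrics on the held-out samples in the
#' chosen feature space under predicted labels, and all runs are averaged.
#'
#' @param x samples-x-genes expression matrix.
#' @param y subtype labels.
#' @param theta correlation threshold.
#' @param plan a [make_cv_plan()]; built from `folds`/`repeats`/`seed` when
#'   `NULL`.
#' @param folds,repeats,seed used when `plan` is `NULL`; `seed` also drives
#'   the per-run training seeds.
#' @param feature_space `"embeddings"` (default: the learned residual-sum
#'   features) or `"raw"` (expression profiles) for the internal metrics.
#' @param variant model variant, see [ergcn()].
#' @param ... further arguments to [ergcn()] (hidden, learning_rate,
#'   epochs, dropout...).
#' @return object of class `ergcn_cv`: `results` (one row per fold-run),
#'   `mean` and `sd` (aggregates over runs), `plan`, `theta`, `variant`.
#' @examples
#' \donttest{
#' bench <- default_benchmark()
#' cv <- cross_validate(bench$x, bench$y, theta = 0.5, repeats = 2, seed = 1)
#' cv
#' }
#' @export
cross_validate <- function(x, y, theta = 0.5, plan = NULL, folds = 5L,
                           repeats = 10L, seed = 0L,
                           feature_space = c("embeddings", "raw"),
                           variant = "ergcn", ...) {
  feature_space <- match.arg(feature_space)
  al <- if (!is.null(names(y))) align_samples(x, y) else list(x = x, y = y)
  x <- al$x; y <- al$y
  if (is.null(plan)) plan <- make_cv_plan(y, folds, repeats, seed = seed)
  net <- if (variant == "mlp") NULL else build_network(x, theta)
  rows <- vector("list", plan$repeats * plan$folds)
  run <- 0L
  for (r in seq_len(plan$repeats)) {
    fold_id <- plan$assignments[[r]]
    for (f in seq_len(plan$folds)) {
      run <- run + 1L
      mask <- fold_id != f
      run_seed <- (seed + 104729L * run) %% 2147483647L
      fit <- suppressWarnings(
        ergcn(x, y, theta = theta, network = net, variant = variant,
              train_mask = mask, seed = run_seed, ...))
      held <- which(!mask)
      stopifnot(!any(fit$train_mask[held]))  # held-out rows never enter loss
      feats <- if (feature_space == "embeddings") {
        fit$embeddings[held, , drop = FALSE]
      } else {
        x[held, , drop = FALSE]
      }
      rep_i <- suppressWarnings(evaluate_predictions(
        y[held], fit$fitted_labels[held], features = feats,
        metadata = list(rep = r, fold = f, theta = theta, seed = run_seed)))
      rows[[run]] <- report_row(rep_i)
    }
  }
  results <- do.call(rbind, rows)
  metric_cols <- c("precision", "recall", "f1", "accuracy", "ari", "mcc",
                   "silhouette", "dbi")
  agg_mean <- colMeans(results[metric_cols], na.rm = TRUE)
  agg_sd <- vapply(results[metric_cols], stats::sd, numeric(1L), na.rm = TRUE)
  structure(list(results = results, mean = agg_mean, sd = agg_sd,
                 plan = plan, theta = theta, variant = variant,
                 feature_space = feature_space,
                 n_edges = if (is.null(net)) NA_integer_ else net$n_edges),
            class = "ergcn_cv")
}

#' @export
print.ergcn_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation x %d repeats (variant '%s', theta = %g)\n",
              x$plan$folds, x$plan$repeats, x$variant, x$theta))
  cat(sprintf("  %d fold-runs; internal metrics on %s\n",
              nrow(x$results), x$feature_space))
  tab <- rbind(mean = x$mean, sd = x$sd)
  print(round(tab, 4))
  invisible(x)
}

#' Sweep the correlation threshold
#'
#' Runs [cross_validate()] at every threshold of `grid` with the SAME fold
#' plan, recording the mean/sd of each metric and the network edge count per
#' threshold. Very high thresholds leaving the graph edgeless are allowed
#' (the propagation operator degenerates to the identity) and flagged in
#' the result.
#'
#' @inheritParams cross_validate
#' @param grid thresholds in (0, 1); default 0.1 to 0.9 in steps of 0.05.
#' @return object of class `ergcn_sweep`: data frame `results` with one row
#'   per threshold (metric means, sds, edge count), plus the plan.
#' @export
threshold_sweep <- function(x, y, grid = seq(0.1, 0.9, by = 0.05),
                            plan = NULL, folds = 5L, repeats = 10L,
                            seed = 0L, variant = "ergcn", ...) {
  stopifnot(all(grid > 0 & grid < 1))
  al <- if (!is.null(names(y))) align_samples(x, y) else list(x = x, y = y)
  x <- al$x; y <- al$y
  if (is.null(plan)) plan <- make_cv_plan(y, folds, repeats, seed = seed)
  rows <- lapply(grid, function(th) {
    cv <- cross_validate(x, y, theta = th, plan = plan, seed = seed,
                         variant = variant, ...)
    data.frame(theta = th, n_edges = cv$n_edges,
               t(cv$mean),
               t(stats::setNames(cv$sd, paste0(names(cv$sd), "_sd"))))
  })
  results <- do.call(rbind, rows)
  structure(list(results = results, plan = plan, variant = variant),
            class = "ergcn_sweep")
}

#' @export
print.ergcn_sweep <- function(x, ...) {
  cat(sprintf("Threshold sweep (%d thresholds, variant '%s')\n",
              nrow(x$results), x$variant))
  cols <- c("theta", "n_edges", "accuracy", "f1", "mcc", "silhouette")
  print(round(x$results[cols], 4), row.names = FALSE)
  invisible(x)
}

#' Plot a threshold sweep
#' @param x an `ergcn_sweep`.
#' @param metric which mean metric to plot against theta.
#' @param ... passed to [graphics::plot()].
#' @export
plot.ergcn_sweep <- function(x, metric = "accuracy", ...) {
  graphics::plot(x$results$theta, x$results[[metric]], type = "b",
                 xlab = expression(theta), ylab = paste("mean", metric), ...)
  invisible(x)
}

#' Leave-one-out evaluation of new samples via network augmentation
#'
#' The clinical-deployment protocol: each sample in turn is held out
#' entirely; the similarity network is rebuilt and the model trained on the
#' remaining m-1 samples only; the held-out profile is then attached to the
#' trained model's network by its correlations to the training samples
#' (see [augment_network()]) and classified with a single forward pass — no
#' retraining. The m single-sample predictions are pooled and scored
#' together with the external metrics.
#'
#' @inheritParams cross_validate
#' @param ... further arguments to [ergcn()].
#' @return object of class `ergcn_loo`: `predictions` (data frame of
#'   sample, true, predicted), `metrics` (pooled external metrics).
#' @export
new_sample_eval <- function(x, y, theta = 0.5, seed = 0L, variant = "ergcn",
                            ...) {
  al <- if (!is.null(names(y))) align_samples(x, y) else list(x = x, y = y)
  x <- al$x; y <- al$y
  m <- nrow(x)
  stopifnot(m >= 3L)
  preds <- character(m)
  for (i in seq_len(m)) {
    run_seed <- (seed + 104729L * i) %% 2147483647L
    fit <- suppressWarnings(
      ergcn(x[-i, , drop = FALSE], y[-i], theta = theta, variant = variant,
            seed = run_seed, ...))
    preds[i] <- as.character(
      predict(fit, newdata = x[i, , drop = FALSE], type = "class"))
  }
  preds <- factor(preds, levels = levels(y))
  metrics <- external_metrics(y, preds)
  structure(list(predictions = data.frame(sample_id = rownames(x),
                                          true = y, predicted = preds,
                                          stringsAsFactors = FALSE),
                 metrics = metrics, theta = theta, variant = variant),
            class = "ergcn_loo")
}

#' @export
print.ergcn_loo <- function(x, ...) {
  cat(sprintf("New-sample (leave-one-out, augmented network) evaluation: %d samples, theta = %g\n",
              nrow(x$predictions), x$theta))
  print(round(unlist(x$metrics), 4))
  invisible(x)
}

#' Ablation study: MLP vs plain GCN vs ERGCN
#'
#' Cross-validates the three model variants with an identical fold plan and
#' identical per-run seeds, isolating the contribution of the graph
#' (mlp vs gcn) and of the residual skip connection (gcn vs ergcn). All
#' other settings are shared across variants.
#'
#' @inheritParams cross_validate
#' @param variants which variants to run (default all three).
#' @return object of class `ergcn_ablation`: `table` (one row per variant,
#'   mean external metrics), `cv` (the full `ergcn_cv` per variant).
#' @export
ablation <- function(x, y, theta = 0.5, plan = NULL, folds = 5L,
                     repeats = 10L, seed = 0L,
                     variants = c("mlp", "gcn", "ergcn"), ...) {
  al <- if (!is.null(names(y))) align_samples(x, y) else list(x = x, y = y)
  x <- al$x; y <- al$y
  if (is.null(plan)) plan <- make_cv_plan(y, folds, repeats, seed = seed)
  cvs <- lapply(variants, function(v)
    cross_validate(x, y, theta = theta, plan = plan, seed = seed,
                   variant = v, ...))
  names(cvs) <- variants
  ext <- c("precision", "recall", "f1", "accuracy", "ari", "mcc")
  tab <- do.call(rbind, lapply(variants, function(v)
    data.frame(variant = v, t(cvs[[v]]$mean[ext]), stringsAsFactors = FALSE)))
  structure(list(table = tab, cv = cvs, theta = theta),
            class = "ergcn_ablation")
}

#' @export
print.ergcn_ablation <- function(x, ...) {
  cat(sprintf("Ablation (theta = %g): mean external metrics over %d fold-runs\n",
              x$theta, nrow(x$cv[[1L]]$results)))
  tab <- x$table
  tab[-1L] <- round(tab[-1L], 4)
  print(tab, row.names = FALSE)
  invisible(x)
}
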