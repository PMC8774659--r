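#' Specify a synthetic expression dataset with subtype structure
#'
#' The generator emulates the correlation structure the classifier relies
#' on: each of `n_classes` subtypes owns a disjoint block of
#' `signature_genes` whose mean is shifted upward by `effect_size` (in units
#' of the noise SD) in samples of that subtype. Shared per-gene baselines of
#' SD `baseline_sd` induce a common correlation floor between all samples;
#' the signature shifts push within-subtype Pearson correlation above
#' between-subtype correlation, which is what the thresholded similarity
#' network picks up.
#'
#' The generative model for sample i of class k at gene j is
#' \deqn{x_{ij} = b_j + \delta\,[j \in sig(k)] + \epsilon_{ij}, \quad
#'       b_j \sim N(0, \tau^2),\ \epsilon_{ij} \sim N(0, \sigma^2).}
#'
#' @param m number of samples.
#' @param n number of genes.
#' @param n_classes number of subtypes F (>= 2).
#' @param proportions length-F class proportions (default equal); class
#'   sizes follow largest-remainder rounding.
#' @param signature_genes signature genes per class g (F * g <= n).
#' @param effect_size mean shift delta of signature genes, in noise-SD
#'   units (>= 0; 0 means the labels carry no signal).
#' @param noise_sd per-entry noise SD sigma (> 0).
#' @param baseline_sd shared gene-baseline SD tau (>= 0).
#' @param seed integer seed; the dataset is a deterministic function of the
#'   spec.
#' @return object of class `synthetic_spec` (a named list).
#' @export
synthetic_spec <- function(m = 120L, n = 400L, n_classes = 4L,
                           proportions = NULL, signature_genes = 40L,
                           effect_size = 3, noise_sd = 1, baseline_sd = 1,
                           seed = 0L) {
  if (is.null(proportions)) proportions <- rep(1 / n_classes, n_classes)
  stopifnot(m >= 2L, n >= 2L, n_classes >= 2L,
            length(proportions) == n_classes,
            abs(sum(proportions) - 1) < 1e-8,
            n_classes * signature_genes <= n,
            effect_size >= 0, noise_sd > 0, baseline_sd >= 0)
  structure(list(m = as.integer(m), n = as.integer(n),
                 n_classes = as.integer(n_classes),
                 proportions = proportions,
                 signature_genes = as.integer(signature_genes),
                 effect_size = effect_size, noise_sd = noise_sd,
                 baseline_sd = baseline_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# largest-remainder apportionment of m samples to the class proportions
apportion <- function(m, proportions) {
  raw <- m * proportions
  sizes <- floor(raw)
  short <- m - sum(sizes)
  if (short > 0L) {
    extra <- order(raw - sizes, decreasing = TRUE)[seq_len(short)]
    sizes[extra] <- sizes[extra] + 1L
  }
  as.integer(sizes)
}

#' Generate a synthetic expression dataset
#'
#' Draws a dataset from a [synthetic_spec()]: a samples-x-genes matrix plus
#' ground-truth subtype labels and the signature-gene index per class.
#' Deterministic given the spec (including its seed).
#'
#' @param spec a `synthetic_spec`; omit it and pass [synthetic_spec()]
#'   arguments directly instead.
#' @param ... arguments forwarded to [synthetic_spec()] when `spec` is
#'   omitted.
#' @return object of class `synthetic_dataset`: list with `x` (expression
#'   matrix, dimnames set), `y` (named factor of subtypes `class1..classF`),
#'   `spec`, and `signature_index` (list of gene-index vectors per class).
#' @examples
#' d <- generate_synthetic(synthetic_spec(m = 30, n = 50, n_classes = 3,
#'                                        signature_genes = 10, seed = 1))
#' table(d$y)
#' @export
generate_synthetic <- function(spec = NULL, ...) {
  if (is.null(spec)) {
    spec <- synthetic_spec(...)
  } else if (!inherits(spec, "synthetic_spec")) {
    stop_ergcn("'spec' must be a synthetic_spec (or omitted)")
  } else if (length(list(...)) > 0L) {
    stop_ergcn("pass either a spec or synthetic_spec() arguments, not both")
  }
  sizes <- apportion(spec$m, spec$proportions)
  classes <- rep(seq_len(spec$n_classes), sizes)
  sig <- lapply(seq_len(spec$n_classes), function(k) {
    ((k - 1L) * spec$signature_genes + 1L):(k * spec$signature_genes)
  })
  x <- withr::with_seed(spec$seed, {
    baseline <- stats::rnorm(spec$n, 0, spec$baseline_sd)
    noise <- matrix(stats::rnorm(spec$m * spec$n, 0, spec$noise_sd),
                    spec$m, spec$n)
    shift <- matrix(0, spec$m, spec$n)
    for (k in seq_len(spec$n_classes)) {
      shift[classes == k, sig[[k]]] <- spec$effect_size * spec$noise_sd
    }
    sweep(noise + shift, 2L, baseline, "+")
  })
  sample_ids <- sprintf("sample%03d", seq_len(spec$m))
  gene_ids <- sprintf("gene%04d", seq_len(spec$n))
  dimnames(x) <- list(sample_ids, gene_ids)
  y <- factor(paste0("class", classes),
              levels = paste0("class", seq_len(spec$n_classes)))
  names(y) <- sample_ids
  names(sig) <- levels(y)
  structure(list(x = x, y = y, spec = spec, signature_index = sig),
            class = "synthetic_dataset")
}

#' The canonical synthetic benchmark dataset
#'
#' 120 samples, 400 genes, 4 equally sized subtypes, 40 signature genes per
#' subtype shifted by 3 noise SDs, unit noise and baseline SDs — dimensioned
#' like the small TCGA subtype cohorts (tens to a couple hundred samples)
#' this classifier targets.
#'
#' @param seed seed for the draw (default 0).
#' @param effect_size mean shift of signature genes (default 3); set 0 for a
#'   no-signal null dataset of the same shape.
#' @return a `synthetic_dataset`.
#' @export
default_benchmark <- function(seed = 0L, effect_size = 3) {
  generate_synthetic(synthetic_spec(m = 120L, n = 400L, n_classes = 4L,
                                    signature_genes = 40L,
                                    effect_size = effect_size,
                                    noise_sd = 1, baseline_sd = 1,
                                    seed = seed))
}

#' Diagnostic summary of a synthetic dataset
#'
#' Reports the mean within- and between-subtype Pearson correlation, class
#' sizes, and the recovery of the planted signature genes by a naive
#' mean-difference ranking (genes ranked by the largest absolute difference
#' between any two class means; recovery is the fraction of planted
#' signature genes in the top F*g of that ranking).
#'
#' @param data a `synthetic_dataset`.
#' @return named list: `within_pcc`, `between_pcc`, `class_sizes`,
#'   `signature_recovery`.
#' @export
structure_report <- function(data) {
  stopifnot(inherits(data, "synthetic_dataset"))
  r <- correlation_matrix(data$x)
  same <- outer(data$y, data$y, "==")
  up <- upper.tri(r)
  within <- mean(r[up & same])
  between <- mean(r[up & !same])
  cm <- vapply(levels(data$y), function(k)
    colMeans(data$x[data$y == k, , drop = FALSE]), numeric(ncol(data$x)))
  spread <- apply(cm, 1L, function(v) max(v) - min(v))
  n_sig <- length(unlist(data$signature_index))
  top <- order(spread, decreasing = TRUE)[seq_len(n_sig)]
  recovery <- mean(unlist(data$signature_index) %in% top)
  list(within_pcc = within, between_pcc = between,
       class_sizes = as.integer(table(data$y)),
       signature_recovery = recovery)
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  s <- x$spec
  cat(sprintf("Synthetic expression dataset: %d samples x %d genes, %d subtypes\n",
              s$m, s$n, s$n_classes))
  cat(sprintf("  %d signature genes/subtype, effect size %g SD, noise SD %g, baseline SD %g, seed %d\n",
              s$signature_genes, s$effect_size, s$noise_sd, s$baseline_sd,
              s$seed))
  invisible(x)
}
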