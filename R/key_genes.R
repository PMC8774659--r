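#' Rank genes driving a subtype partition by Gini importance
#'
#' Fits a random-forest classifier to the expression matrix against a
#' subtype labeling — typically the labels PREDICTED by a trained ERGCN
#' model, so the ranking explains the partition the network actually
#' produces — and ranks genes by mean decrease in Gini impurity across the
#' forest's splits. Ties are broken by gene identifier so the ranking is
#' fully deterministic given the seed.
#'
#' @param x samples-x-genes expression matrix.
#' @param labels subtype assignment per sample (factor or vector; at least
#'   two classes).
#' @param n_trees number of trees (default 500).
#' @param seed integer seed for the forest.
#' @return object of class `gene_ranking`: data frame `ranking` with
#'   `gene_id` and `importance` sorted by descending importance, plus
#'   `n_trees` and `seed`.
#' @examples
#' \donttest{
#' bench <- default_benchmark()
#' rk <- rank_genes(bench$x, bench$y, n_trees = 100, seed = 1)
#' head(top_k(rk, 10))
#' }
#' @export
rank_genes <- function(x, labels, n_trees = 500L, seed = 0L) {
  check_matrix(x, "x")
  if (length(labels) != nrow(x)) stop_ergcn("labels must match rows of x")
  lab <- droplevels(factor(labels))
  if (nlevels(lab) < 2L) stop_ergcn("gene ranking needs at least 2 classes")
  if (n_trees < 50L) stop_ergcn("use at least 50 trees for a stable ranking")
  gene_ids <- colnames(x) %||% sprintf("gene%04d", seq_len(ncol(x)))
  feat <- x
  colnames(feat) <- make.names(gene_ids)  # randomForest needs syntactic names
  rf <- withr::with_seed(seed, {
    randomForest::randomForest(feat, lab, ntree = as.integer(n_trees))
  })
  imp <- rf$importance[, "MeanDecreaseGini"]
  ord <- order(-imp, gene_ids)
  ranking <- data.frame(gene_id = gene_ids[ord],
                        importance = unname(imp[ord]),
                        stringsAsFactors = FALSE)
  structure(list(ranking = ranking, n_trees = as.integer(n_trees),
                 seed = as.integer(seed)),
            class = "gene_ranking")
}

#' Top-k genes of a ranking
#'
#' The first `k` gene identifiers of a [rank_genes()] ranking — the "key
#' genes" of the partition. `top_k(r, k)` is always a prefix of
#' `top_k(r, k + 1)`.
#'
#' @param ranking a `gene_ranking`.
#' @param k number of genes (default 50).
#' @return character vector of `k` gene identifiers.
#' @export
top_k <- function(ranking, k = 50L) {
  stopifnot(inherits(ranking, "gene_ranking"))
  n <- nrow(ranking$ranking)
  if (k < 1L || k > n) stop_ergcn("k must be between 1 and ", n)
  ranking$ranking$gene_id[seq_len(k)]
}

#' @export
print.gene_ranking <- function(x, ...) {
  cat(sprintf("Gini-importance gene ranking (%d genes, %d trees, seed %d)\n",
              nrow(x$ranking), x$n_trees, x$seed))
  print(utils::head(x$ranking, 10L), row.names = FALSE)
  if (nrow(x$ranking) > 10L) cat("  ...\n")
  invisible(x)
}
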