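#' Read a sample-by-gene expression table
#'
#' Reads a delimited expression table whose header row holds gene identifiers
#' and whose first column holds sample identifiers. The delimiter is sniffed
#' from the file extension (`.csv` gives comma, anything else tab) unless
#' given explicitly. No normalization of any kind is applied to the values:
#' profiles are used exactly as provided, so users wanting log-transformed or
#' standardized input must pre-process before writing the file.
#'
#' @param path path to the table.
#' @param delimiter field delimiter; `NULL` (default) sniffs from the
#'   extension.
#' @param transpose set `TRUE` for files with genes as rows and samples as
#'   columns; the returned matrix is always samples x genes.
#' @return a numeric matrix with sample identifiers as `rownames` and gene
#'   identifiers as `colnames`.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write_expression(matrix(rnorm(12), 3, 4,
#'   dimnames = list(paste0("s", 1:3), paste0("g", 1:4))), tf)
#' x <- read_expression(tf)
#' dim(x)
#' @export
read_expression <- function(path, delimiter = NULL, transpose = FALSE) {
  if (!file.exists(path)) stop_ergcn("file not found: ", path)
  sep <- delimiter %||% sniff_delimiter(path)
  raw <- utils::read.table(path, sep = sep, header = TRUE, row.names = NULL,
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE, comment.char = "")
  if (ncol(raw) < 2L) stop_ergcn("expression table needs at least one gene column")
  sample_ids <- raw[[1L]]
  gene_ids <- colnames(raw)[-1L]
  vals <- suppressWarnings(
    vapply(raw[-1L], as.numeric, numeric(nrow(raw)))
  )
  vals <- matrix(as.numeric(vals), nrow = nrow(raw), ncol = length(gene_ids))
  bad <- which(is.na(vals) | !is.finite(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop_ergcn(sprintf(
      "non-numeric or missing expression value at sample '%s', gene '%s'",
      sample_ids[bad[1L, 1L]], gene_ids[bad[1L, 2L]]))
  }
  dimnames(vals) <- list(sample_ids, gene_ids)
  if (transpose) vals <- t(vals)
  validate_expression(vals)
  vals
}

#' Write an expression matrix
#'
#' Inverse of [read_expression()]: header row of gene ids, first column of
#' sample ids. Values are written at full double precision so that a
#' write/read round trip is lossless.
#'
#' @param x samples-x-genes numeric matrix with dimnames.
#' @param path output path; extension picks the delimiter unless `delimiter`
#'   is given.
#' @param delimiter optional explicit field delimiter.
#' @export
write_expression <- function(x, path, delimiter = NULL) {
  validate_expression(x)
  sep <- delimiter %||% sniff_delimiter(path)
  df <- data.frame(sample_id = rownames(x),
                   format(x, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("sample_id", colnames(x))
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_expression <- function(x) {
  check_matrix(x, "expression matrix")
  if (nrow(x) < 2L || ncol(x) < 2L) {
    stop_ergcn("expression matrix needs at least 2 samples and 2 genes")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop_ergcn("expression matrix needs sample ids (rownames) and gene ids (colnames)")
  }
  if (anyDuplicated(rownames(x))) stop_ergcn("duplicate sample identifiers")
  if (anyDuplicated(colnames(x))) stop_ergcn("duplicate gene identifiers")
  invisible(x)
}

#' Read a sample-to-subtype label table
#'
#' Expects a two-column delimited table (`sample_id`, `subtype`), with a
#' header row. Subtype names are mapped to a factor whose levels are the
#' sorted distinct names.
#'
#' @param path path to the table.
#' @param delimiter field delimiter; `NULL` sniffs from the extension.
#' @return a named factor of subtypes, names are sample ids.
#' @export
read_labels <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop_ergcn("file not found: ", path)
  sep <- delimiter %||% sniff_delimiter(path)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = "character", stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop_ergcn("empty label file: ", path)
  if (ncol(df) < 2L) stop_ergcn("label table needs two columns (sample_id, subtype)")
  if (anyDuplicated(df[[1L]])) stop_ergcn("duplicate sample identifiers in label file")
  lev <- sort(unique(df[[2L]]))
  if (length(lev) < 2L) stop_ergcn("at least 2 distinct subtypes are required")
  y <- factor(df[[2L]], levels = lev)
  names(y) <- df[[1L]]
  y
}

#' Write a label table
#' @param y named factor (or character vector) of subtype labels.
#' @param path output path.
#' @param delimiter optional explicit field delimiter.
#' @export
write_labels <- function(y, path, delimiter = NULL) {
  sep <- delimiter %||% sniff_delimiter(path)
  df <- data.frame(sample_id = names(y), subtype = as.character(y),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align an expression matrix with a label table
#'
#' Restricts both inputs to the samples present in each, keeping the
#' expression-file order as the canonical order. Aligning already-aligned
#' inputs is a no-op.
#'
#' @param x samples-x-genes expression matrix.
#' @param y named factor of subtype labels.
#' @return list with elements `x` and `y`, restricted to the common samples.
#' @export
align_samples <- function(x, y) {
  validate_expression(x)
  if (is.null(names(y))) stop_ergcn("labels must carry sample ids as names")
  common <- intersect(rownames(x), names(y))
  if (length(common) == 0L) {
    stop_ergcn("no samples in common between expression matrix and labels")
  }
  keep <- rownames(x)[rownames(x) %in% common]
  y2 <- y[keep]
  y2 <- droplevels(y2)
  if (nlevels(y2) < 2L) stop_ergcn("aligned labels contain fewer than 2 subtypes")
  list(x = x[keep, , drop = FALSE], y = y2)
}

#' Write metric reports to disk
#'
#' One record per run, as JSON lines (default) or a delimited table. All
#' numeric fields are written at full precision so round trips are lossless.
#'
#' @param reports a single metrics report (named list / one-row data frame) or
#'   a data frame with one row per run.
#' @param path output path.
#' @param format `"jsonl"` or `"tsv"`; `NULL` sniffs from the extension
#'   (`.jsonl`/`.json` gives JSON lines).
#' @export
write_metrics <- function(reports, path, format = NULL) {
  fmt <- format %||%
    (if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl" else "tsv")
  df <- as.data.frame(reports, stringsAsFactors = FALSE)
  if (fmt == "jsonl") {
    lines <- vapply(seq_len(nrow(df)), function(i) {
      as.character(jsonlite::toJSON(as.list(df[i, , drop = FALSE]),
                                    auto_unbox = TRUE, digits = NA, na = "null"))
    }, character(1L))
    writeLines(lines, path)
  } else if (fmt == "tsv") {
    num <- vapply(df, is.numeric, logical(1L))
    out <- df
    out[num] <- lapply(df[num], function(v)
      format(v, digits = 17, trim = TRUE, scientific = TRUE))
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    stop_ergcn("unknown metrics format: ", fmt)
  }
  invisible(path)
}

#' Read metric reports written by [write_metrics()]
#' @param path input path.
#' @param format `"jsonl"`, `"tsv"`, or `NULL` to sniff from the extension.
#' @return data frame with one row per record.
#' @export
read_metrics <- function(path, format = NULL) {
  fmt <- format %||%
    (if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl" else "tsv")
  if (fmt == "jsonl") {
    recs <- lapply(readLines(path), jsonlite::fromJSON)
    do.call(rbind, lapply(recs, function(r)
      as.data.frame(lapply(r, function(v) if (is.null(v)) NA else v),
                    stringsAsFactors = FALSE)))
  } else {
    utils::read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  }
}

#' Export network edges as a three-column edge list
#'
#' Writes one row per undirected off-diagonal edge
#' (`sample_id_a`, `sample_id_b`, `weight`), weight 1 for the binary
#' adjacency.
#'
#' @param net a `similarity_network` from [build_network()].
#' @param path output path.
#' @export
write_edges <- function(net, path) {
  stopifnot(inherits(net, "similarity_network"))
  a <- net$adjacency
  idx <- which(upper.tri(a) & a == 1, arr.ind = TRUE)
  df <- data.frame(sample_id_a = net$sample_ids[idx[, 1L]],
                   sample_id_b = net$sample_ids[idx[, 2L]],
                   weight = rep(1L, nrow(idx)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

sniff_delimiter <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

`%||%` <- function(a, b) if (is.null(a)) b else a
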