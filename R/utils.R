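# internal numerical helpers

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# row-wise softmax with max-subtraction for numerical stability
softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

stop_ergcn <- function(..., call. = FALSE) {
  stop(..., call. = call.)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

check_matrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_ergcn(sprintf("'%s' must be a numeric matrix", name))
  }
  if (anyNA(x) || any(!is.finite(x))) {
    stop_ergcn(sprintf("'%s' contains missing or non-finite values", name))
  }
  invisible(x)
}

# coerce a label vector (factor, character, or integer) to 1-based integer
# codes plus class names; F >= 2 enforced by callers that need it
as_class_codes <- function(y, class_names = NULL) {
  if (is.factor(y)) {
    list(codes = as.integer(y), class_names = levels(y))
  } else if (is.character(y)) {
    lev <- sort(unique(y))
    list(codes = match(y, lev), class_names = lev)
  } else if (is.numeric(y)) {
    if (!is.null(class_names)) {
      list(codes = as.integer(y), class_names = class_names)
    } else {
      lev <- sort(unique(as.integer(y)))
      list(codes = match(as.integer(y), lev), class_names = as.character(lev))
    }
  } else {
    stop_ergcn("labels must be a factor, character, or integer vector")
  }
}
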