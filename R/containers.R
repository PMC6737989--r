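#' Normalized expression matrix
#'
#' Light-weight container holding a non-negative abundance matrix
#' (features x samples) together with its normalization method and, for
#' RPKM, the feature lengths used.
#'
#' @param values numeric matrix, features in rows, samples in columns.
#' @param method normalization tag, `"RPKM"` or `"TPM"`.
#' @param lengths named vector of feature lengths in nt (RPKM only).
#' @return an object of class `normalized_matrix`.
#' @export
normalized_matrix <- function(values, method = c("RPKM", "TPM"),
                              lengths = NULL) {
  method <- match.arg(method)
  values <- as.matrix(values)
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("normalized values must be finite and non-negative", call. = FALSE)
  }
  structure(list(values = values, method = method, lengths = lengths),
            class = "normalized_matrix")
}

#' Extract the numeric matrix from an expression container
#'
#' Accepts either a plain matrix/data.frame or a `normalized_matrix`.
#'
#' @param x expression object.
#' @return numeric matrix.
#' @export
expr_values <- function(x) {
  if (inherits(x, "normalized_matrix")) {
    x$values
  } else {
    as.matrix(x)
  }
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat(sprintf("<normalized_matrix> %s, %d features x %d samples\n",
              x$method, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.normalized_matrix <- function(x) dim(x$values)
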