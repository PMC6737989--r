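#' Reads per kilobase per million mapped reads (RPKM)
#'
#' `RPKM[g, s] = counts[g, s] * 1e9 / (colsum[s] * length[g])`. A
#' zero-depth sample column yields all-zero RPKM rather than NaN. RPKM is
#' invariant to uniform scaling of a sample's counts.
#'
#' @param counts non-negative count matrix (genes x samples).
#' @param lengths named numeric vector of gene lengths in nt; every counted
#'   gene must have a positive length.
#' @return a `normalized_matrix` with method `"RPKM"`.
#' @export
compute_rpkm <- function(counts, lengths) {
  counts <- expr_values(counts)
  if (is.null(names(lengths))) {
    if (length(lengths) != nrow(counts)) {
      stop("unnamed 'lengths' must match the number of genes", call. = FALSE)
    }
    names(lengths) <- rownames(counts)
  }
  missing <- setdiff(rownames(counts), names(lengths))
  if (length(missing) > 0L) {
    stop("missing length for counted gene(s): ",
         paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  len <- lengths[rownames(counts)]
  if (any(!is.finite(len)) || any(len <= 0)) {
    stop("gene lengths must be positive and finite", call. = FALSE)
  }
  depth <- colSums(counts)
  denom <- ifelse(depth > 0, depth, Inf)   # zero-depth column -> all zeros
  vals <- sweep(counts, 2L, denom, "/")
  vals <- sweep(vals, 1L, len, "/") * 1e9
  normalized_matrix(vals, "RPKM", lengths = len)
}

#' Reads per million mapped reads (small-RNA TPM)
#'
#' Depth normalization without a length term, the standard practice for
#' ~22 nt mature miRNAs: `TPM[m, s] = counts[m, s] * 1e6 / colsum[s]`.
#' Every output column of a sample with non-zero depth sums to 1e6. If
#' `lengths` is supplied, the classical length-normalized TPM
#' (rate = counts/length, rescaled to 1e6 per sample) is computed instead.
#'
#' @param counts non-negative count matrix (miRNAs x samples).
#' @param lengths optional named lengths enabling length-normalized TPM.
#' @return a `normalized_matrix` with method `"TPM"`.
#' @export
compute_tpm <- function(counts, lengths = NULL) {
  counts <- expr_values(counts)
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be finite and non-negative", call. = FALSE)
  }
  if (is.null(lengths)) {
    depth <- colSums(counts)
    denom <- ifelse(depth > 0, depth, Inf)
    vals <- sweep(counts, 2L, denom, "/") * 1e6
  } else {
    len <- lengths[rownames(counts)]
    if (any(is.na(len)) || any(len <= 0)) {
      stop("missing or non-positive length for a counted feature",
           call. = FALSE)
    }
    rate <- sweep(counts, 1L, len, "/")
    depth <- colSums(rate)
    denom <- ifelse(depth > 0, depth, Inf)
    vals <- sweep(rate, 2L, denom, "/") * 1e6
  }
  normalized_matrix(vals, "TPM")
}

#' Flag expressed features
#'
#' A feature/sample cell is expressed when its abundance strictly exceeds
#' the threshold; a feature is expressed overall when it is expressed in at
#' least one sample.
#'
#' @param norm a `normalized_matrix` or numeric matrix.
#' @param threshold strictly positive abundance threshold (default 0.1).
#' @return list with `per_sample` (logical matrix) and `per_feature`
#'   (named logical vector, the OR over samples).
#' @export
flag_expressed <- function(norm, threshold = 0.1) {
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  v <- expr_values(norm)
  per_sample <- v > threshold
  per_feature <- rowSums(per_sample) > 0L
  list(per_sample = per_sample, per_feature = per_feature)
}

#' Tissue similarity structure
#'
#' Pearson correlations between sample columns of `log2(value + 1)` and
#' average-linkage hierarchical clustering on distance `1 - r`. Sample
#' columns that are constant after the log transform have undefined
#' correlations; they are reported as NA and excluded from clustering with
#' a warning.
#'
#' @param norm a `normalized_matrix` or numeric matrix with >= 2 samples.
#' @param linkage agglomeration method passed to [stats::hclust()].
#' @return list with `correlation` (symmetric matrix, unit diagonal, NA for
#'   excluded samples), `hclust` (or NULL when < 2 usable samples), and
#'   `excluded` (character vector of excluded sample names).
#' @export
tissue_similarity <- function(norm, linkage = "average") {
  v <- expr_values(norm)
  if (ncol(v) < 2L) stop("tissue_similarity needs >= 2 samples", call. = FALSE)
  lv <- log2(v + 1)
  sds <- apply(lv, 2L, stats::sd)
  ok <- sds > 0
  r <- matrix(NA_real_, ncol(v), ncol(v),
              dimnames = list(colnames(v), colnames(v)))
  if (any(ok)) {
    r[ok, ok] <- stats::cor(lv[, ok, drop = FALSE])
  }
  diag(r) <- 1
  excluded <- colnames(v)[!ok]
  if (length(excluded) > 0L) {
    warning("excluded constant sample column(s) from clustering: ",
            paste(excluded, collapse = ", "), call. = FALSE)
  }
  hc <- NULL
  if (sum(ok) >= 2L) {
    d <- stats::as.dist(1 - r[ok, ok, drop = FALSE])
    hc <- stats::hclust(d, method = linkage)
  }
  list(correlation = r, hclust = hc, excluded = excluded)
}
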