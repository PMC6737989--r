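#' Universally expressed mRNAs
#'
#' Tissue-conserved genes whose abundance strictly exceeds `min_value`
#' (default 10 RPKM) in every tissue column of the supplied panel.
#'
#' @param rpkm `normalized_matrix` or matrix restricted to the tissue panel
#'   (one column per tissue).
#' @param min_value abundance floor (strict `>`).
#' @return character vector of universal feature IDs.
#' @export
find_universal_mrna <- function(rpkm, min_value = 10) {
  v <- expr_values(rpkm)
  rownames(v)[apply(v > min_value, 1L, all)]
}

#' Universally expressed miRNAs
#'
#' A miRNA is universal when (1) its abundance strictly exceeds `min_value`
#' (default 1 TPM) in every tissue and (2) its coefficient of variation
#' across tissues (sample sd with n-1 denominator, divided by the mean) is
#' strictly below `cv_max` (default 0.5).
#'
#' @param tpm `normalized_matrix` or matrix restricted to the tissue panel
#'   (>= 2 columns).
#' @param min_value TPM floor (strict `>`).
#' @param cv_max coefficient-of-variation ceiling (strict `<`).
#' @return character vector of universal miRNA IDs.
#' @export
find_universal_mirna <- function(tpm, min_value = 1, cv_max = 0.5) {
  v <- expr_values(tpm)
  if (ncol(v) < 2L) stop("need >= 2 tissue columns", call. = FALSE)
  mins <- apply(v, 1L, min)
  mus <- rowMeans(v)
  sds <- apply(v, 1L, stats::sd)
  cv <- ifelse(mus > 0, sds / mus, Inf)
  rownames(v)[mins > min_value & cv < cv_max]
}

#' Tissue-associated features
#'
#' Per feature, `z_t = (x_t - mean) / sd` across tissues (n-1 sd). A
#' feature is associated with tissue `t` when `z_t >= z_min` and
#' `x_t >= expr_min` (both inclusive). Zero-variance features are never
#' associated.
#'
#' @param expr `normalized_matrix` or matrix restricted to the tissue panel
#'   (>= 3 columns).
#' @param z_min z-score cutoff (default 1.5).
#' @param expr_min abundance floor (default 1).
#' @param log_scale compute z-scores on `log2(x + 1)` instead of the linear
#'   scale (the abundance floor is always applied on the linear scale).
#' @return named list, one data.frame per tissue with columns `feature_id`,
#'   `z`, `value`.
#' @export
find_tissue_associated <- function(expr, z_min = 1.5, expr_min = 1,
                                   log_scale = FALSE) {
  v <- expr_values(expr)
  if (ncol(v) < 3L) stop("need >= 3 tissue columns", call. = FALSE)
  zin <- if (log_scale) log2(v + 1) else v
  mus <- rowMeans(zin)
  sds <- apply(zin, 1L, stats::sd)
  z <- (zin - mus) / ifelse(sds > 0, sds, Inf)
  hits <- z >= z_min & v >= expr_min
  out <- lapply(colnames(v), function(tis) {
    idx <- which(hits[, tis])
    data.frame(feature_id = rownames(v)[idx], z = z[idx, tis],
               value = v[idx, tis], row.names = NULL,
               stringsAsFactors = FALSE)
  })
  names(out) <- colnames(v)
  out
}

#' Tissue-specific features
#'
#' A feature is specific to tissue `t` when `x_t >= expr_min` (default 10)
#' and `x_t > fold * mean(x over all other tissues)` (default 10-fold over
#' the leave-one-out mean). When the leave-one-out mean is zero the fold
#' condition is vacuously satisfied, so any feature at or above the
#' abundance floor is specific. With fold = 10 and at most 11 tissues no
#' feature can be specific to two tissues.
#'
#' @param expr `normalized_matrix` or matrix restricted to the tissue panel
#'   (>= 2 columns).
#' @param fold fold-excess over the leave-one-out mean (strict `>`).
#' @param expr_min abundance floor (inclusive `>=`).
#' @return named list, one data.frame per tissue with columns `feature_id`,
#'   `fold` (observed `x_t / loo_mean`, Inf when the loo mean is 0) and
#'   `value`.
#' @export
find_tissue_specific <- function(expr, fold = 10, expr_min = 10) {
  v <- expr_values(expr)
  nt <- ncol(v)
  if (nt < 2L) stop("need >= 2 tissue columns", call. = FALSE)
  tot <- rowSums(v)
  out <- lapply(colnames(v), function(tis) {
    x <- v[, tis]
    loo <- (tot - x) / (nt - 1L)
    pass <- x >= expr_min & x > fold * loo
    idx <- which(pass)
    data.frame(feature_id = rownames(v)[idx],
               fold = ifelse(loo[idx] > 0, x[idx] / loo[idx], Inf),
               value = x[idx], row.names = NULL, stringsAsFactors = FALSE)
  })
  names(out) <- colnames(v)
  out
}

#' Select the tissue panel from atlas sample columns
#'
#' Atlas matrices carry one column per non-muscle tissue plus three muscle
#' developmental stage columns (`muscle_D0`, `muscle_D30`, `muscle_D240`).
#' Classification uses one muscle column -- the adult stage -- alongside
#' the other tissues; the earlier stages are reserved for the
#' developmental analyses.
#'
#' @param mat matrix or `normalized_matrix` with atlas sample columns.
#' @param muscle_stage name of the muscle column representing the muscle
#'   tissue in the panel.
#' @return matrix restricted to the panel, with the muscle stage column
#'   renamed `"muscle"`.
#' @export
tissue_panel <- function(mat, muscle_stage = "muscle_D240") {
  v <- expr_values(mat)
  stage_cols <- grep("^muscle_D", colnames(v), value = TRUE)
  keep <- c(setdiff(colnames(v), stage_cols), muscle_stage)
  if (!muscle_stage %in% colnames(v)) {
    stop("muscle stage column '", muscle_stage, "' not found", call. = FALSE)
  }
  panel <- v[, keep, drop = FALSE]
  colnames(panel)[colnames(panel) == muscle_stage] <- "muscle"
  panel[, sort(colnames(panel)), drop = FALSE]
}

#' Classify an atlas into universal / associated / specific sets
#'
#' Convenience wrapper applying the three classification rules to a
#' tissue-panel matrix with the cutoffs in `config`.
#'
#' @param panel tissue-panel matrix (one column per tissue).
#' @param config an [atlas_config()].
#' @param kind `"mrna"` (RPKM rules) or `"mirna"` (TPM rules, universal set
#'   additionally constrained by the CV ceiling).
#' @return list with elements `universal`, `associated`, `specific` and
#'   `parameters`.
#' @export
classify_atlas <- function(panel, config = atlas_config(),
                           kind = c("mrna", "mirna")) {
  kind <- match.arg(kind)
  universal <- if (kind == "mrna") {
    find_universal_mrna(panel, config$universal_mrna_min)
  } else {
    find_universal_mirna(panel, config$universal_mirna_min,
                         config$universal_mirna_cv_max)
  }
  list(
    universal = universal,
    associated = find_tissue_associated(panel, config$associated_z_min,
                                        config$associated_expr_min),
    specific = find_tissue_specific(panel, config$specific_fold,
                                    config$specific_expr_min),
    parameters = config
  )
}
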