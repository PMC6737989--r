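#' Median-of-ratios library size factors
#'
#' For each sample, the size factor is the median across features of the
#' ratio between its count and the feature's geometric mean over all
#' samples, computed over features with all-positive counts. When no
#' feature is positive in every sample the function falls back to
#' column-sum factors (scaled to geometric mean 1) with a warning.
#'
#' @param counts non-negative count matrix.
#' @return named numeric vector of positive size factors.
#' @export
normalize_library <- function(counts) {
  counts <- expr_values(counts)
  allpos <- rowSums(counts > 0) == ncol(counts)
  if (!any(allpos)) {
    warning("no feature with all-positive counts; ",
            "falling back to column-sum size factors", call. = FALSE)
    cs <- colSums(counts)
    if (any(cs == 0)) stop("cannot normalize all-zero sample", call. = FALSE)
    sf <- cs / exp(mean(log(cs)))
    return(sf)
  }
  sub <- counts[allpos, , drop = FALSE]
  logg <- rowMeans(log(sub))
  sf <- apply(sub, 2L, function(col) exp(stats::median(log(col) - logg)))
  sf
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with monotonicity enforcement; output order
#' matches input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in the input order.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Negative-binomial Wald test between two sample groups
#'
#' A deliberately simple two-group test for designs where a full
#' regression framework is not warranted: counts are normalized by
#' median-of-ratios size factors, the fold change is
#' `log2((mean_B + pc) / (mean_A + pc))` with pseudocount `pc = 0.5`, and
#' the p-value comes from a Wald statistic on the log fold with the
#' delta-method standard error under a negative-binomial variance
#' `v = m + dispersion * m^2`. The dispersion is either supplied or
#' estimated by pooled method-of-moments across features; single-replicate
#' designs must supply a dispersion (no estimate is possible).
#'
#' @param counts non-negative count matrix covering both groups.
#' @param cols_a,cols_b column names or indices of the two conditions.
#' @param dispersion positive number, or `"estimate"` (requires >= 2
#'   replicates in at least one group).
#' @param lfc_min,fdr_max call cutoffs (defaults 1 and 0.05).
#' @param pseudocount added to normalized means in the fold change.
#' @return data.frame with `feature_id`, `base_mean_a`, `base_mean_b`,
#'   `log2fc`, `p`, `fdr`, `call` (`up` / `down` / `ns`).
#' @export
de_test <- function(counts, cols_a, cols_b, dispersion = "estimate",
                    lfc_min = 1, fdr_max = 0.05, pseudocount = 0.5) {
  counts <- expr_values(counts)
  a <- counts[, cols_a, drop = FALSE]
  b <- counts[, cols_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  sf <- normalize_library(cbind(a, b))
  a <- sweep(a, 2L, sf[seq_len(na)], "/")
  b <- sweep(b, 2L, sf[na + seq_len(nb)], "/")
  ma <- rowMeans(a)
  mb <- rowMeans(b)
  if (identical(dispersion, "estimate")) {
    if (na < 2L && nb < 2L) {
      stop("single-replicate design: dispersion cannot be estimated; ",
           "supply a fixed dispersion value", call. = FALSE)
    }
    alphas <- c()
    for (grp in list(a, b)) {
      if (ncol(grp) < 2L) next
      m <- rowMeans(grp)
      v <- apply(grp, 1L, stats::var)
      ok <- m > 0
      alphas <- c(alphas, (v[ok] - m[ok]) / m[ok]^2)
    }
    dispersion <- max(stats::median(alphas, na.rm = TRUE), 1e-8)
  }
  if (!is.numeric(dispersion) || dispersion <= 0) {
    stop("dispersion must be a positive number or \"estimate\"",
         call. = FALSE)
  }
  pc <- pseudocount
  lfc <- log2((mb + pc) / (ma + pc))
  va <- (ma + dispersion * ma^2) / na
  vb <- (mb + dispersion * mb^2) / nb
  se <- sqrt(va / (ma + pc)^2 + vb / (mb + pc)^2)
  z <- ifelse(se > 0, log((mb + pc) / (ma + pc)) / se, 0)
  p <- ifelse(ma == 0 & mb == 0, 1, 2 * stats::pnorm(-abs(z)))
  fdr <- bh_fdr(p)
  call <- rep("ns", length(p))
  call[lfc >= lfc_min & fdr < fdr_max] <- "up"
  call[lfc <= -lfc_min & fdr < fdr_max] <- "down"
  data.frame(feature_id = rownames(counts), base_mean_a = ma,
             base_mean_b = mb, log2fc = lfc, p = p, fdr = fdr,
             call = call, row.names = NULL, stringsAsFactors = FALSE)
}

#' Partition DE calls from two consecutive comparisons into patterns
#'
#' Crosses the up/down calls of two stage-wise comparisons (e.g. D0 vs D30
#' and D30 vs D240) into the four dynamic classes `up_up`, `up_down`,
#' `down_up`, `down_down`; features significant in only one comparison are
#' reported separately. The monotone classes (`up_up`, `down_down`) are the
#' features changing in the same direction throughout the time course.
#'
#' @param de_1,de_2 DE tables from [de_test()] computed with identical
#'   cutoffs, sharing the feature universe.
#' @return an object of class `pattern_partition`: named list of character
#'   vectors `up_up`, `up_down`, `down_up`, `down_down`, `up_only_1`,
#'   `down_only_1`, `up_only_2`, `down_only_2`.
#' @export
overlap_patterns <- function(de_1, de_2) {
  call1 <- stats::setNames(de_1$call, de_1$feature_id)
  call2 <- stats::setNames(de_2$call, de_2$feature_id)
  ids <- union(de_1$feature_id, de_2$feature_id)
  c1 <- call1[ids]; c1[is.na(c1)] <- "ns"
  c2 <- call2[ids]; c2[is.na(c2)] <- "ns"
  pick <- function(x, y) ids[c1 == x & c2 == y]
  out <- list(
    up_up = pick("up", "up"),
    up_down = pick("up", "down"),
    down_up = pick("down", "up"),
    down_down = pick("down", "down"),
    up_only_1 = pick("up", "ns"),
    down_only_1 = pick("down", "ns"),
    up_only_2 = pick("ns", "up"),
    down_only_2 = pick("ns", "down")
  )
  structure(out, class = c("pattern_partition", "list"))
}
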