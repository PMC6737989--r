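#' Pipeline configuration
#'
#' Collects every numeric cutoff used by the atlas pipeline. The defaults
#' reproduce the standard published thresholds for this kind of multi-tissue
#' atlas analysis: features are called expressed above 0.1 RPKM/TPM in at
#' least one sample; universally expressed mRNAs exceed 10 RPKM in every
#' tissue while universal miRNAs exceed 1 TPM everywhere with a coefficient
#' of variation below 0.5; tissue association requires a z-score of at least
#' 1.5 at 1 RPKM; tissue specificity requires an abundance of at least 10
#' plus more than a 10-fold excess over the mean of the remaining tissues;
#' co-expression edges require Pearson r >= 0.90 and are clustered at MCL
#' inflation 2.2; intragenic host pairs require expression in at least five
#' tissues and a correlation with p < 0.05 and r > 0.6; interaction screening
#' keeps pairs with r < -0.5; differential expression requires |log2 FC| >= 1
#' at FDR < 0.05.
#'
#' @param expressed_threshold abundance above which a feature counts as
#'   expressed (strict inequality for the expressed flag, inclusive for the
#'   host-pair breadth filter).
#' @param universal_mrna_min RPKM floor for universally expressed mRNAs.
#' @param universal_mirna_min TPM floor for universally expressed miRNAs.
#' @param universal_mirna_cv_max coefficient-of-variation ceiling for
#'   universal miRNAs.
#' @param associated_z_min z-score cutoff for tissue association.
#' @param associated_expr_min abundance floor for tissue association.
#' @param specific_fold fold-excess over the leave-one-out tissue mean
#'   required for tissue specificity.
#' @param specific_expr_min abundance floor for tissue specificity.
#' @param network_r_min Pearson threshold for co-expression edges.
#' @param mcl_inflation MCL inflation exponent.
#' @param host_min_tissues minimum number of tissues in which both members of
#'   an intragenic miRNA/host-gene pair must be expressed.
#' @param host_p_max p-value ceiling for host-pair correlation.
#' @param host_r_min correlation floor for host-pair correlation.
#' @param interact_r_max correlation ceiling (negative) for the
#'   miRNA-target screen.
#' @param de_lfc_min |log2 fold-change| cutoff for differential expression.
#' @param de_fdr_max Benjamini-Hochberg FDR cutoff.
#' @param de_dispersion negative-binomial dispersion used when the design has
#'   no replicates (single pooled library per stage).
#' @param mfe_max duplex minimum-free-energy ceiling (kcal/mol) applied when
#'   `mfe_filter` is enabled.
#' @param mfe_filter logical; require `best_mfe <= mfe_max` in addition to a
#'   seed site? Off by default: a canonical seed site suffices.
#' @param rng_seed integer seed recorded with every run.
#'
#' @return an object of class `atlas_config` (a validated named list).
#' @export
atlas_config <- function(expressed_threshold = 0.1,
                         universal_mrna_min = 10,
                         universal_mirna_min = 1,
                         universal_mirna_cv_max = 0.5,
                         associated_z_min = 1.5,
                         associated_expr_min = 1,
                         specific_fold = 10,
                         specific_expr_min = 10,
                         network_r_min = 0.90,
                         mcl_inflation = 2.2,
                         host_min_tissues = 5,
                         host_p_max = 0.05,
                         host_r_min = 0.6,
                         interact_r_max = -0.5,
                         de_lfc_min = 1,
                         de_fdr_max = 0.05,
                         de_dispersion = 0.1,
                         mfe_max = -15,
                         mfe_filter = FALSE,
                         rng_seed = 1L) {
  cfg <- list(
    expressed_threshold = expressed_threshold,
    universal_mrna_min = universal_mrna_min,
    universal_mirna_min = universal_mirna_min,
    universal_mirna_cv_max = universal_mirna_cv_max,
    associated_z_min = associated_z_min,
    associated_expr_min = associated_expr_min,
    specific_fold = specific_fold,
    specific_expr_min = specific_expr_min,
    network_r_min = network_r_min,
    mcl_inflation = mcl_inflation,
    host_min_tissues = host_min_tissues,
    host_p_max = host_p_max,
    host_r_min = host_r_min,
    interact_r_max = interact_r_max,
    de_lfc_min = de_lfc_min,
    de_fdr_max = de_fdr_max,
    de_dispersion = de_dispersion,
    mfe_max = mfe_max,
    mfe_filter = isTRUE(mfe_filter),
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "atlas_config"
  validate_config(cfg)
}

#' Validate an atlas configuration
#'
#' Checks range invariants: probabilities in (0, 1], correlations in
#' \[-1, 1\], fold/threshold fields strictly positive.
#'
#' @param cfg an `atlas_config` object or compatible named list.
#' @return the validated config, invisibly classed as `atlas_config`.
#' @export
validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  num1 <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("config field '", field, "' must be a single finite number",
           call. = FALSE)
    }
    v
  }
  for (f in c("host_p_max", "de_fdr_max")) {
    v <- num1(f)
    if (v <= 0 || v > 1) {
      stop("config field '", f, "' must lie in (0, 1]", call. = FALSE)
    }
  }
  for (f in c("network_r_min", "host_r_min", "interact_r_max")) {
    v <- num1(f)
    if (v < -1 || v > 1) {
      stop("config field '", f, "' must lie in [-1, 1]", call. = FALSE)
    }
  }
  positive <- c("expressed_threshold", "universal_mrna_min",
                "universal_mirna_min", "universal_mirna_cv_max",
                "associated_z_min", "associated_expr_min", "specific_fold",
                "specific_expr_min", "mcl_inflation", "host_min_tissues",
                "de_lfc_min", "de_dispersion")
  for (f in positive) {
    if (num1(f) <= 0) {
      stop("config field '", f, "' must be > 0", call. = FALSE)
    }
  }
  num1("mfe_max")
  class(cfg) <- "atlas_config"
  cfg
}

#' @export
print.atlas_config <- function(x, ...) {
  cat("<atlas_config>\n")
  for (f in names(x)) {
    cat(sprintf("  %-24s %s\n", f, format(x[[f]])))
  }
  invisible(x)
}
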