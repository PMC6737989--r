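#' Intragenic miRNA / host-gene candidates
#'
#' A miRNA locus is an intragenic candidate for a gene when its interval is
#' entirely contained within the gene span on the same chromosome and both
#' are transcribed from the same strand. Intervals are 0-based half-open as
#' produced by [read_annotation()].
#'
#' @param mirnas `feature_annotation` rows of type `miRNA` (other types are
#'   dropped).
#' @param genes `feature_annotation` rows of type `gene`.
#' @return data.frame with columns `mirna_id`, `gene_id`, `containment`,
#'   `same_strand`, `copy_count`, restricted to containment AND same-strand
#'   candidates.
#' @export
find_intragenic_candidates <- function(mirnas, genes) {
  tab <- host_pair_overlaps(mirnas, genes)
  tab[tab$containment & tab$same_strand,
      c("mirna_id", "gene_id", "containment", "same_strand", "copy_count")]
}

# All same-chromosome overlapping (miRNA locus, gene) pairs with the
# positional criterion flags. One row per (mirna_id, gene_id) pair; when a
# multi-copy miRNA overlaps the same gene through several loci the most
# favourable locus is kept (copy count fails such pairs anyway).
host_pair_overlaps <- function(mirnas, genes) {
  mirnas <- as.data.frame(mirnas)[as.data.frame(mirnas)$type == "miRNA", ,
                                  drop = FALSE]
  genes <- as.data.frame(genes)[as.data.frame(genes)$type == "gene", ,
                                drop = FALSE]
  out <- list()
  for (chr in intersect(unique(mirnas$chrom), unique(genes$chrom))) {
    m <- mirnas[mirnas$chrom == chr, , drop = FALSE]
    g <- genes[genes$chrom == chr, , drop = FALSE]
    if (nrow(m) == 0L || nrow(g) == 0L) next
    mi <- rep(seq_len(nrow(m)), each = nrow(g))
    gi <- rep(seq_len(nrow(g)), times = nrow(m))
    overlap <- m$start[mi] < g$end[gi] & g$start[gi] < m$end[mi]
    mi <- mi[overlap]; gi <- gi[overlap]
    if (length(mi) == 0L) next
    out[[chr]] <- data.frame(
      mirna_id = m$feature_id[mi],
      gene_id = g$feature_id[gi],
      containment = m$start[mi] >= g$start[gi] & m$end[mi] <= g$end[gi],
      same_strand = m$strand[mi] == g$strand[gi],
      copy_count = m$copy_count[mi],
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0L) {
    return(data.frame(mirna_id = character(0), gene_id = character(0),
                      containment = logical(0), same_strand = logical(0),
                      copy_count = integer(0), stringsAsFactors = FALSE))
  }
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  # collapse duplicate (mirna, gene) pairs, keeping the best locus
  key <- paste(tab$mirna_id, tab$gene_id, sep = "\r")
  ord <- order(key, -(tab$containment & tab$same_strand))
  tab <- tab[ord, , drop = FALSE]
  tab <- tab[!duplicated(key[ord]), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Drop candidates whose miRNA has extra genomic copies
#'
#' Retains candidates whose miRNA name maps to exactly one genomic locus.
#'
#' @param candidates data.frame with a `mirna_id` column.
#' @param mirnas `feature_annotation` used to (re)compute copy counts.
#' @return the filtered candidate data.frame.
#' @export
filter_single_copy <- function(candidates, mirnas) {
  mirnas <- as.data.frame(mirnas)
  mirnas <- mirnas[mirnas$type == "miRNA", , drop = FALSE]
  copies <- table(mirnas$feature_id)
  keep <- as.integer(copies[candidates$mirna_id]) == 1L
  keep[is.na(keep)] <- FALSE
  candidates[keep, , drop = FALSE]
}

#' Keep candidates expressed broadly enough
#'
#' Both the miRNA and the host gene must reach `threshold` (inclusive
#' `>=`, default 0.1) in at least `min_tissues` sample columns.
#'
#' @param candidates data.frame with `mirna_id` and `gene_id`.
#' @param mirna_tpm,mrna_rpkm expression matrices covering all candidates;
#'   a missing feature is a hard error naming it.
#' @param min_tissues minimum breadth (default 5).
#' @param threshold abundance threshold (default 0.1).
#' @return the filtered candidate data.frame.
#' @export
filter_expression_breadth <- function(candidates, mirna_tpm, mrna_rpkm,
                                      min_tissues = 5, threshold = 0.1) {
  tpm <- expr_values(mirna_tpm)
  rpkm <- expr_values(mrna_rpkm)
  miss_m <- setdiff(candidates$mirna_id, rownames(tpm))
  miss_g <- setdiff(candidates$gene_id, rownames(rpkm))
  if (length(miss_m) + length(miss_g) > 0L) {
    stop("candidate feature(s) absent from expression matrix: ",
         paste(c(miss_m, miss_g), collapse = ", "), call. = FALSE)
  }
  if (nrow(candidates) == 0L) return(candidates)
  bm <- rowSums(tpm[candidates$mirna_id, , drop = FALSE] >= threshold)
  bg <- rowSums(rpkm[candidates$gene_id, , drop = FALSE] >= threshold)
  candidates[bm >= min_tissues & bg >= min_tissues, , drop = FALSE]
}

#' Correlation test for host-pair candidates
#'
#' Pearson correlation between the miRNA and host-gene profiles over the
#' shared sample columns; two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` with n-2 degrees of freedom. A pair
#' passes when \code{p < p_max} and \code{r > r_min}. Zero-variance profiles yield an
#' undefined correlation (NA) and fail.
#'
#' @param candidates data.frame with `mirna_id` and `gene_id`.
#' @param mirna_tpm,mrna_rpkm expression matrices with >= 3 shared samples.
#' @param r_min correlation floor (strict `>`, default 0.6).
#' @param p_max p-value ceiling (strict `<`, default 0.05).
#' @return the candidates with added columns `r`, `p`, `corr_pass`,
#'   restricted to passing pairs.
#' @export
test_host_correlation <- function(candidates, mirna_tpm, mrna_rpkm,
                                  r_min = 0.6, p_max = 0.05) {
  scored <- score_host_correlation(candidates, mirna_tpm, mrna_rpkm,
                                   r_min, p_max)
  scored[scored$corr_pass, , drop = FALSE]
}

score_host_correlation <- function(candidates, mirna_tpm, mrna_rpkm,
                                   r_min = 0.6, p_max = 0.05) {
  tpm <- expr_values(mirna_tpm)
  rpkm <- expr_values(mrna_rpkm)
  shared <- intersect(colnames(tpm), colnames(rpkm))
  if (length(shared) < 3L) {
    stop("host-pair correlation needs >= 3 shared samples", call. = FALSE)
  }
  n <- length(shared)
  r <- p <- rep(NA_real_, nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    x <- tpm[candidates$mirna_id[i], shared]
    y <- rpkm[candidates$gene_id[i], shared]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    ri <- stats::cor(x, y)
    r[i] <- ri
    tt <- ri * sqrt((n - 2) / max(1 - ri^2, .Machine$double.eps))
    p[i] <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  candidates$r <- r
  candidates$p <- p
  candidates$corr_pass <- !is.na(r) & p < p_max & r > r_min
  candidates
}

#' Full five-criterion host-pair evaluation
#'
#' Evaluates every same-chromosome overlapping (miRNA, gene) pair against
#' the five criteria -- full containment, same strand, single genomic copy,
#' expression breadth of both members, and significant positive correlation
#' -- and records one flag per criterion. The criteria are independent
#' per-pair predicates, so filtering by them commutes.
#'
#' @param mirnas,genes `feature_annotation` tables.
#' @param mirna_tpm,mrna_rpkm expression matrices (features absent from a
#'   matrix fail the breadth criterion and carry NA correlation).
#' @param config an [atlas_config()] supplying the cutoffs.
#' @return data.frame with columns `mirna_id`, `gene_id`, `containment`,
#'   `same_strand`, `single_copy`, `breadth_mirna`, `breadth_gene`,
#'   `breadth_pass`, `r`, `p`, `corr_pass`, `passed`.
#' @export
find_host_pairs <- function(mirnas, genes, mirna_tpm, mrna_rpkm,
                            config = atlas_config()) {
  tab <- host_pair_overlaps(mirnas, genes)
  tab$single_copy <- tab$copy_count == 1L
  tpm <- expr_values(mirna_tpm)
  rpkm <- expr_values(mrna_rpkm)
  thr <- config$expressed_threshold
  bm <- rep(0L, nrow(tab))
  bg <- rep(0L, nrow(tab))
  known_m <- tab$mirna_id %in% rownames(tpm)
  known_g <- tab$gene_id %in% rownames(rpkm)
  bm[known_m] <- rowSums(tpm[tab$mirna_id[known_m], , drop = FALSE] >= thr)
  bg[known_g] <- rowSums(rpkm[tab$gene_id[known_g], , drop = FALSE] >= thr)
  tab$breadth_mirna <- bm
  tab$breadth_gene <- bg
  tab$breadth_pass <- bm >= config$host_min_tissues &
    bg >= config$host_min_tissues
  tab$r <- NA_real_
  tab$p <- NA_real_
  tab$corr_pass <- FALSE
  ok <- known_m & known_g
  if (any(ok)) {
    scored <- score_host_correlation(tab[ok, c("mirna_id", "gene_id")],
                                     mirna_tpm, mrna_rpkm,
                                     config$host_r_min, config$host_p_max)
    tab$r[ok] <- scored$r
    tab$p[ok] <- scored$p
    tab$corr_pass[ok] <- scored$corr_pass
  }
  tab$passed <- tab$containment & tab$same_strand & tab$single_copy &
    tab$breadth_pass & tab$corr_pass
  tab
}
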