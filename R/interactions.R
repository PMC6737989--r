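#' Screening predicate for negatively correlated pairs
#'
#' A pair passes the screen when its Pearson correlation is strictly below
#' `r_max` (default -0.5). Undefined correlations never pass.
#'
#' @param r numeric vector of correlations.
#' @param r_max correlation ceiling (strict `<`).
#' @return logical vector.
#' @export
passes_screen <- function(r, r_max = -0.5) {
  !is.na(r) & r < r_max
}

#' Screen all miRNA-mRNA pairs for negative expression correlation
#'
#' Computes the Pearson correlation of every (miRNA, gene) profile pair
#' over the selected sample columns and keeps pairs with \code{r < r_max}.
#' Zero-variance profiles are excluded with a message.
#'
#' @param mirna_expr,mrna_expr expression matrices sharing sample columns.
#' @param r_max correlation ceiling (default -0.5, strict `<`).
#' @param samples optional character vector selecting the screening sample
#'   columns (default: all shared columns); at least 3 are required.
#' @return data.frame with `mirna_id`, `gene_id`, `r`, sorted by `r`
#'   ascending with ties broken by (miRNA, gene) lexicographic order.
#' @export
screen_negative_correlation <- function(mirna_expr, mrna_expr,
                                        r_max = -0.5, samples = NULL) {
  a <- expr_values(mirna_expr)
  b <- expr_values(mrna_expr)
  shared <- intersect(colnames(a), colnames(b))
  if (!is.null(samples)) shared <- intersect(samples, shared)
  if (length(shared) < 3L) {
    stop("screening needs >= 3 shared samples", call. = FALSE)
  }
  a <- a[, shared, drop = FALSE]
  b <- b[, shared, drop = FALSE]
  va <- apply(a, 1L, stats::sd) > 0
  vb <- apply(b, 1L, stats::sd) > 0
  dropped <- sum(!va) + sum(!vb)
  if (dropped > 0L) {
    message("excluding ", dropped, " zero-variance profile(s) from screen")
  }
  a <- a[va, , drop = FALSE]
  b <- b[vb, , drop = FALSE]
  r <- stats::cor(t(a), t(b))
  idx <- which(r < r_max, arr.ind = TRUE)
  out <- data.frame(mirna_id = rownames(a)[idx[, 1L]],
                    gene_id = rownames(b)[idx[, 2L]],
                    r = r[idx], stringsAsFactors = FALSE)
  out[order(out$r, out$mirna_id, out$gene_id), , drop = FALSE]
}

#' Assemble miRNA-mRNA interaction records
#'
#' For each screened pair: confirms canonical 3'UTR seed sites, computes
#' the correlation over the developmental-stage columns, and (for the
#' persistent subset, or for all site-passing pairs when the energy filter
#' is enabled) annotates the best duplex minimum free energy over the
#' sites. The final reported set requires a passed screen and at least one
#' seed site; the persistent subset additionally requires the stage
#' correlation to pass the same screen threshold.
#'
#' @param screened data.frame from [screen_negative_correlation()].
#' @param mirna_seqs,utr_seqs named sequence vectors (pairs with a missing
#'   sequence are dropped with a message).
#' @param mirna_stage_expr,mrna_stage_expr expression matrices restricted
#'   to the developmental-stage columns (>= 3 columns); pass `NULL` to skip
#'   the persistence correlation.
#' @param config an [atlas_config()].
#' @param detail_sites which pairs get an explicit seed-site table and MFE
#'   annotation: `"persistent"` (default), `"all"` site-passing pairs, or
#'   `"none"`.
#' @param mfe_flank nt of UTR context added on each side of a seed site for
#'   the duplex energy computation.
#' @return list with `records` (one row per retained pair: `mirna_id`,
#'   `gene_id`, `r`, `r_stages`, `n_sites`, `best_mfe`, `passed_screen`,
#'   `passed_sites`, `passed_persistence`, `final`, `persistent`; sorted by
#'   `r` ascending) and `sites` (seed-site rows for the detailed subset).
#' @export
assemble_interactions <- function(screened, mirna_seqs, utr_seqs,
                                  mirna_stage_expr = NULL,
                                  mrna_stage_expr = NULL,
                                  config = atlas_config(),
                                  detail_sites = c("persistent", "all",
                                                   "none"),
                                  mfe_flank = 15L) {
  detail_sites <- match.arg(detail_sites)
  rec <- screened
  have <- rec$mirna_id %in% names(mirna_seqs) &
    rec$gene_id %in% names(utr_seqs)
  if (any(!have)) {
    message("dropping ", sum(!have), " pair(s) with missing sequences")
    rec <- rec[have, , drop = FALSE]
  }
  # fast site presence: a canonical site exists iff the 7mer-m8 string or
  # the 6mer+A string occurs in the UTR (8mers contain both)
  rec$n_sites <- 0L
  rec$has_site <- FALSE
  for (mid in unique(rec$mirna_id)) {
    rows <- which(rec$mirna_id == mid)
    sites <- seed_site_strings(mirna_seqs[[mid]])
    utrs <- utr_seqs[rec$gene_id[rows]]
    rec$has_site[rows] <- grepl(sites[["site7m8"]], utrs, fixed = TRUE) |
      grepl(sites[["site7a1"]], utrs, fixed = TRUE)
  }
  # persistence over developmental stages
  rec$r_stages <- NA_real_
  if (!is.null(mirna_stage_expr) && nrow(rec) > 0L) {
    sa <- expr_values(mirna_stage_expr)
    sb <- expr_values(mrna_stage_expr)
    shared <- intersect(colnames(sa), colnames(sb))
    if (length(shared) < 3L) {
      stop("persistence correlation needs >= 3 stage columns",
           call. = FALSE)
    }
    for (i in seq_len(nrow(rec))) {
      x <- sa[rec$mirna_id[i], shared]
      y <- sb[rec$gene_id[i], shared]
      if (stats::sd(x) > 0 && stats::sd(y) > 0) {
        rec$r_stages[i] <- stats::cor(x, y)
      }
    }
  }
  rec$passed_screen <- passes_screen(rec$r, config$interact_r_max)
  rec$passed_persistence <- passes_screen(rec$r_stages,
                                          config$interact_r_max)
  rec$best_mfe <- NA_real_
  rec$passed_sites <- rec$has_site
  # detailed seed-site table + duplex energies
  detail_rows <- switch(detail_sites,
    none = integer(0),
    all = which(rec$has_site),
    persistent = which(rec$has_site & rec$passed_screen &
                         rec$passed_persistence)
  )
  if (config$mfe_filter) detail_rows <- which(rec$has_site)
  site_tabs <- list()
  for (i in detail_rows) {
    utr <- utr_seqs[[rec$gene_id[i]]]
    st <- find_seed_sites(mirna_seqs[[rec$mirna_id[i]]], utr)
    if (nrow(st) == 0L) next
    mfes <- vapply(seq_len(nrow(st)), function(k) {
      from <- max(1L, st$span_start[k] + 1L - mfe_flank)
      to <- min(nchar(utr), st$span_end[k] + mfe_flank)
      duplex_mfe(mirna_seqs[[rec$mirna_id[i]]],
                 substr(utr, from, to))$mfe
    }, numeric(1L))
    rec$best_mfe[i] <- min(mfes)
    rec$n_sites[i] <- nrow(st)
    st$mirna_id <- rec$mirna_id[i]
    st$gene_id <- rec$gene_id[i]
    st$mfe <- mfes
    site_tabs[[length(site_tabs) + 1L]] <- st
  }
  if (config$mfe_filter) {
    rec$passed_sites <- rec$has_site & !is.na(rec$best_mfe) &
      rec$best_mfe <= config$mfe_max
  }
  rec$final <- rec$passed_screen & rec$passed_sites
  rec$persistent <- rec$final & rec$passed_persistence
  rec <- rec[order(rec$r, rec$mirna_id, rec$gene_id), , drop = FALSE]
  rownames(rec) <- NULL
  sites <- if (length(site_tabs) > 0L) {
    do.call(rbind, site_tabs)
  } else {
    data.frame(utr_position = integer(0), site_type = character(0),
               span_start = integer(0), span_end = integer(0),
               mirna_id = character(0), gene_id = character(0),
               mfe = numeric(0), stringsAsFactors = FALSE)
  }
  cols <- c("mirna_id", "gene_id", "r", "r_stages", "n_sites", "best_mfe",
            "passed_screen", "passed_sites", "passed_persistence",
            "final", "persistent")
  list(records = rec[, cols], sites = sites)
}
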