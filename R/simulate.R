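#' Simulation design for a synthetic multi-tissue atlas
#'
#' Describes the study layout the generator emulates: nine tissues plus
#' three skeletal-muscle developmental stages (one pooled library each, the
#' adult stage doubling as the muscle column of the tissue panel),
#' negative-binomial counts, planted universally expressed genes, planted
#' tissue-specific genes at a controlled fold-change, intragenic same-strand
#' single-copy miRNAs co-expressed with their host genes, and planted
#' repressor miRNA-target pairs that are anti-correlated across samples and
#' carry genuine canonical seed sites in the target 3'UTR (plus decoy pairs
#' that are anti-correlated but carry only a scrambled site).
#'
#' Because RPKM/TPM depend only on relative library composition, a small
#' class of very highly expressed "sink" features absorbs the bulk of each
#' library so that the absolute abundance cutoffs (10 RPKM universal floor,
#' 0.1 expressed threshold) sit in the same place they do in real, highly
#' skewed transcriptomes. Sink features satisfy the universal rule by
#' construction and are listed in the truth bundle's universal set.
#'
#' @param tissue_names nine tissue names; must contain `"muscle"`.
#' @param stage_names muscle developmental stage sample names.
#' @param n_genes,n_mirnas feature counts.
#' @param frac_universal fraction of genes planted as dedicated universal
#'   (housekeeping-like) genes.
#' @param n_specific_per_tissue planted tissue-specific genes per tissue.
#' @param specific_fold_planted planted on/off expression ratio; must
#'   exceed the 10-fold specificity cutoff so recovery is well-posed.
#' @param frac_intragenic_mirna fraction of miRNAs planted inside host
#'   genes (same strand, single copy, co-expressed).
#' @param n_repressor_pairs,n_decoy_pairs planted interaction pairs.
#' @param n_host_violations planted host-pair violations per type
#'   (antisense, multi-copy, narrow expression breadth).
#' @param nb_dispersion negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); 0 gives Poisson counts.
#' @param library_depth,mirna_depth expected mapped reads per library.
#' @param gene_length_range nt interval for gene lengths.
#' @param utr_length simulated 3'UTR length (nt).
#' @param mirna_length mature miRNA length (nt).
#' @param n_sink_genes,n_sink_mirnas high-abundance mass-sink features.
#' @param seed RNG seed.
#' @return validated `simulation_design` list.
#' @export
simulation_design <- function(tissue_names = c("fat", "heart", "kidney",
                                               "liver", "lung", "muscle",
                                               "ovary", "spleen", "testis"),
                              stage_names = c("muscle_D0", "muscle_D30",
                                              "muscle_D240"),
                              n_genes = 5000L,
                              n_mirnas = 400L,
                              frac_universal = 0.006,
                              n_specific_per_tissue = 20L,
                              specific_fold_planted = 50,
                              frac_intragenic_mirna = 0.1,
                              n_repressor_pairs = 20L,
                              n_decoy_pairs = 10L,
                              n_host_violations = 3L,
                              nb_dispersion = 0.1,
                              library_depth = 2e6,
                              mirna_depth = 2e6,
                              gene_length_range = c(500L, 5000L),
                              utr_length = 500L,
                              mirna_length = 22L,
                              n_sink_genes = 50L,
                              n_sink_mirnas = 10L,
                              seed = 1L) {
  d <- list(tissue_names = tissue_names, stage_names = stage_names,
            n_genes = as.integer(n_genes), n_mirnas = as.integer(n_mirnas),
            frac_universal = frac_universal,
            n_specific_per_tissue = as.integer(n_specific_per_tissue),
            specific_fold_planted = specific_fold_planted,
            frac_intragenic_mirna = frac_intragenic_mirna,
            n_repressor_pairs = as.integer(n_repressor_pairs),
            n_decoy_pairs = as.integer(n_decoy_pairs),
            n_host_violations = as.integer(n_host_violations),
            nb_dispersion = nb_dispersion,
            library_depth = library_depth, mirna_depth = mirna_depth,
            gene_length_range = as.integer(gene_length_range),
            utr_length = as.integer(utr_length),
            mirna_length = as.integer(mirna_length),
            n_sink_genes = as.integer(n_sink_genes),
            n_sink_mirnas = as.integer(n_sink_mirnas),
            seed = as.integer(seed))
  if (!"muscle" %in% d$tissue_names) {
    stop("tissue_names must contain 'muscle'", call. = FALSE)
  }
  if (d$frac_universal < 0 || d$frac_universal > 1 ||
      d$frac_intragenic_mirna < 0 || d$frac_intragenic_mirna > 1) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (d$n_genes <= 0 || d$n_mirnas <= 0 || d$library_depth <= 0 ||
      d$mirna_depth <= 0 || d$utr_length < 20L || d$mirna_length < 8L) {
    stop("counts and depths must be positive", call. = FALSE)
  }
  if (d$nb_dispersion < 0) stop("nb_dispersion must be >= 0", call. = FALSE)
  if (d$specific_fold_planted <= 10) {
    stop("specific_fold_planted must exceed the 10-fold specificity ",
         "cutoff so that recovery is well-posed", call. = FALSE)
  }
  if (diff(d$gene_length_range) < 0 || d$gene_length_range[1L] < 100L) {
    stop("gene_length_range must be an increasing interval >= 100 nt",
         call. = FALSE)
  }
  class(d) <- "simulation_design"
  d
}

# run code with a locally seeded RNG, restoring the caller's RNG state
with_local_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Negative-binomial count draws at given means
#'
#' Mean/dispersion parameterization (`var = mu + dispersion * mu^2`);
#' dispersion 0 gives Poisson draws. Used by [simulate_atlas()] for every
#' count matrix it emits.
#'
#' @param mu matrix (or vector) of expected counts.
#' @param dispersion non-negative dispersion.
#' @return integer-valued matrix shaped like `mu`.
#' @export
draw_nb_counts <- function(mu, dispersion) {
  n <- length(mu)
  counts <- if (dispersion == 0) {
    stats::rpois(n, lambda = as.numeric(mu))
  } else {
    stats::rnbinom(n, size = 1 / dispersion, mu = as.numeric(mu))
  }
  if (is.matrix(mu)) {
    matrix(counts, nrow = nrow(mu), dimnames = dimnames(mu))
  } else {
    stats::setNames(counts, names(mu))
  }
}

random_rna <- function(n_seq, len) {
  chars <- sample(c("A", "C", "G", "U"), n_seq * len, replace = TRUE)
  apply(matrix(chars, nrow = n_seq), 1L, paste, collapse = "")
}

# linear abundance ramp across samples; stages sit at the extremes and the
# midpoint so pair profiles are monotone over development as well
ramp_profile <- function(low, high, pos, n_pos = 11L) {
  low + (high - low) * (pos - 1) / (n_pos - 1)
}

#' Simulate a complete synthetic atlas with planted truth
#'
#' Draws mRNA and miRNA count matrices over the design's samples (eight
#' non-muscle tissues plus three muscle stages), a GTF-style annotation, a
#' mature-miRNA and a 3'UTR sequence set, and a truth bundle recording
#' every planted structure. Counts are negative-binomial with per-feature
#' mean equal to the planted relative abundance times feature length times
#' sample depth (mRNA; miRNA means carry no length term). Intragenic
#' miRNA means are proportional to their host gene's realized abundance,
#' emulating co-transcription.
#'
#' @param design a [simulation_design()].
#' @return list with `mrna_counts`, `mirna_counts`, `annotation`,
#'   `sequences` (list `mirna`, `utr`), `truth`, `mrna_mu`, `mirna_mu`,
#'   `gene_lengths`, `design`.
#' @export
simulate_atlas <- function(design = simulation_design()) {
  stopifnot(inherits(design, "simulation_design"))
  with_local_seed(design$seed, simulate_atlas_impl(design))
}

simulate_atlas_impl <- function(d) {
  tissues <- d$tissue_names
  samples <- sort(c(setdiff(tissues, "muscle"), d$stage_names))
  ns <- length(samples)
  nt <- length(tissues)
  # sample column corresponding to each tissue in the panel
  panel_col <- stats::setNames(ifelse(tissues == "muscle",
                                      d$stage_names[length(d$stage_names)],
                                      tissues), tissues)

  ## ---- gene classes ------------------------------------------------
  n_univ <- round(d$frac_universal * d$n_genes)
  n_spec <- d$n_specific_per_tissue * nt
  n_intra <- round(d$frac_intragenic_mirna * d$n_mirnas)
  n_viol <- 3L * d$n_host_violations
  n_hosts <- n_intra + n_viol
  n_rep <- d$n_repressor_pairs
  n_dec <- d$n_decoy_pairs
  n_fixed <- d$n_sink_genes + n_univ + n_spec + n_hosts + n_rep + n_dec
  if (n_fixed >= d$n_genes) {
    stop("design infeasible: planted gene classes (", n_fixed,
         ") exceed n_genes", call. = FALSE)
  }
  gene_ids <- sprintf("gene%05d", seq_len(d$n_genes))
  idx <- seq_len(d$n_genes)
  take <- function(n) {
    out <- idx[seq_len(n)]
    idx <<- idx[-seq_len(n)]
    out
  }
  sink_g <- take(d$n_sink_genes)
  univ_g <- take(n_univ)
  spec_g <- matrix(take(n_spec), ncol = nt,
                   dimnames = list(NULL, tissues))
  host_g <- take(n_hosts)
  rep_g <- take(n_rep)
  dec_g <- take(n_dec)
  bg_g <- idx

  gene_len <- as.integer(round(stats::runif(d$n_genes,
                                            d$gene_length_range[1L],
                                            d$gene_length_range[2L])))
  gene_len[sink_g] <- 2000L
  names(gene_len) <- gene_ids

  ## ---- planted expected RPKM profiles ------------------------------
  R <- matrix(0, d$n_genes, ns, dimnames = list(gene_ids, samples))
  nbg <- length(bg_g)
  R[bg_g, ] <- stats::rlnorm(nbg, log(1), 0.8) *
    matrix(stats::rlnorm(nbg * ns, 0, 0.5), nbg, ns)
  if (n_univ > 0L) {
    R[univ_g, ] <- stats::runif(n_univ, 80, 300) *
      matrix(stats::rlnorm(n_univ * ns, 0, 0.1), n_univ, ns)
  }
  for (tis in tissues) {
    g <- spec_g[, tis]
    off <- stats::runif(length(g), 3, 6)
    R[g, ] <- off * matrix(stats::rlnorm(length(g) * ns, 0, 0.2),
                           length(g), ns)
    on_cols <- if (tis == "muscle") d$stage_names else tis
    R[g, on_cols] <- off * d$specific_fold_planted
  }
  if (n_hosts > 0L) {
    R[host_g, ] <- stats::runif(n_hosts, 5, 20) *
      matrix(stats::rlnorm(n_hosts * ns, 0, 1.2), n_hosts, ns)
  }
  # anti-correlated pairs: linear abundance ramps over a fixed sample
  # ordering (population Pearson r = -1 between a ramp and its reverse)
  ramp_pos <- stats::setNames(rep(NA_real_, ns), samples)
  ramp_pos[d$stage_names] <- c(1, (1 + ns) / 2, ns)
  ramp_pos[is.na(ramp_pos)] <- setdiff(seq_len(ns), ramp_pos[d$stage_names])
  plant_ramp <- function(gidx) {
    dirs <- rep_len(c(1L, -1L), length(gidx))
    for (k in seq_along(gidx)) {
      low <- stats::runif(1L, 2, 6)
      pos <- if (dirs[k] == 1L) ramp_pos else (ns + 1 - ramp_pos)
      R[gidx[k], ] <<- ramp_profile(low, 16 * low, pos, ns)
    }
    dirs
  }
  rep_dir <- plant_ramp(rep_g)
  dec_dir <- plant_ramp(dec_g)
  # sinks absorb the remaining library mass so absolute RPKM is meaningful
  other_mass <- colSums(R * gene_len)
  sink_tot <- 1e9 - other_mass
  if (any(sink_tot <= 0)) {
    stop("design infeasible: planted abundances exceed the library mass",
         call. = FALSE)
  }
  R[sink_g, ] <- matrix(rep(sink_tot / (d$n_sink_genes * 2000L),
                            each = d$n_sink_genes), d$n_sink_genes, ns)

  mrna_mu <- R * gene_len * d$library_depth / 1e9
  mrna_counts <- draw_nb_counts(mrna_mu, d$nb_dispersion)
  depth_real <- colSums(mrna_counts)
  rpkm_real <- sweep(sweep(mrna_counts, 2L, ifelse(depth_real > 0,
                                                  depth_real, Inf), "/"),
                     1L, gene_len, "/") * 1e9

  ## ---- miRNA classes -----------------------------------------------
  n_muniv <- 15L
  m_fixed <- d$n_sink_mirnas + n_muniv + n_intra + n_viol + n_rep + n_dec
  if (m_fixed >= d$n_mirnas) {
    stop("design infeasible: planted miRNA classes (", m_fixed,
         ") exceed n_mirnas", call. = FALSE)
  }
  mir_ids <- sprintf("mir%04d", seq_len(d$n_mirnas))
  midx <- seq_len(d$n_mirnas)
  mtake <- function(n) {
    out <- midx[seq_len(n)]
    midx <<- midx[-seq_len(n)]
    out
  }
  sink_m <- mtake(d$n_sink_mirnas)
  univ_m <- mtake(n_muniv)
  intra_m <- mtake(n_intra)
  anti_m <- mtake(d$n_host_violations)
  multi_m <- mtake(d$n_host_violations)
  narrow_m <- mtake(d$n_host_violations)
  rep_m <- mtake(n_rep)
  dec_m <- mtake(n_dec)
  bg_m <- midx

  host_of <- stats::setNames(host_g, mir_ids[c(intra_m, anti_m, multi_m,
                                               narrow_m)])

  TPM <- matrix(0, d$n_mirnas, ns, dimnames = list(mir_ids, samples))
  nbm <- length(bg_m)
  TPM[bg_m, ] <- stats::rlnorm(nbm, log(20), 1) *
    matrix(stats::rlnorm(nbm * ns, 0, 0.8), nbm, ns)
  TPM[univ_m, ] <- stats::runif(n_muniv, 100, 500) *
    matrix(stats::rlnorm(n_muniv * ns, 0, 0.1), n_muniv, ns)
  # co-transcribed miRNAs track their host's realized abundance
  for (mi in c(intra_m, anti_m, multi_m, narrow_m)) {
    TPM[mi, ] <- 10 * rpkm_real[host_of[[mir_ids[mi]]], ]
  }
  narrow_cols <- samples[seq_len(3L)]
  TPM[narrow_m, setdiff(samples, narrow_cols)] <- 0
  for (k in seq_along(rep_m)) {
    low <- stats::runif(1L, 5, 15)
    pos <- if (rep_dir[k] == 1L) (ns + 1 - ramp_pos) else ramp_pos
    TPM[rep_m[k], ] <- ramp_profile(low, 16 * low, pos, ns)
  }
  for (k in seq_along(dec_m)) {
    low <- stats::runif(1L, 5, 15)
    pos <- if (dec_dir[k] == 1L) (ns + 1 - ramp_pos) else ramp_pos
    TPM[dec_m[k], ] <- ramp_profile(low, 16 * low, pos, ns)
  }
  m_other <- colSums(TPM)
  m_sink_tot <- 1e6 - m_other
  if (any(m_sink_tot <= 0)) {
    stop("design infeasible: planted miRNA abundances exceed 1e6 TPM",
         call. = FALSE)
  }
  TPM[sink_m, ] <- matrix(rep(m_sink_tot / d$n_sink_mirnas,
                              each = d$n_sink_mirnas),
                          d$n_sink_mirnas, ns)
  mirna_mu <- TPM * d$mirna_depth / 1e6
  mirna_counts <- draw_nb_counts(mirna_mu, d$nb_dispersion)

  ## ---- annotation ---------------------------------------------------
  n_chr <- 18L
  chroms <- sprintf("chr%d", seq_len(n_chr))
  gene_chr <- chroms[(seq_len(d$n_genes) - 1L) %% n_chr + 1L]
  gene_start <- integer(d$n_genes)
  cursor <- stats::setNames(rep(0L, n_chr), chroms)
  for (g in seq_len(d$n_genes)) {
    gene_start[g] <- cursor[[gene_chr[g]]]
    cursor[[gene_chr[g]]] <- gene_start[g] + gene_len[g] + 2000L
  }
  gene_strand <- sample(c("+", "-"), d$n_genes, replace = TRUE)
  gene_ann <- data.frame(feature_id = gene_ids, type = "gene",
                         chrom = gene_chr, start = gene_start,
                         end = gene_start + gene_len,
                         strand = gene_strand, stringsAsFactors = FALSE)

  mir_rows <- list()
  place_inside <- function(mid, flip_strand = FALSE) {
    host <- host_of[[mir_ids[mid]]]
    len_h <- gene_len[host]
    off <- sample.int(len_h - d$mirna_length, 1L) - 1L
    strand <- gene_strand[host]
    if (flip_strand) strand <- if (strand == "+") "-" else "+"
    data.frame(feature_id = mir_ids[mid], type = "miRNA",
               chrom = gene_chr[host],
               start = gene_start[host] + off,
               end = gene_start[host] + off + d$mirna_length,
               strand = strand, stringsAsFactors = FALSE)
  }
  for (mid in c(intra_m, multi_m, narrow_m)) {
    mir_rows[[length(mir_rows) + 1L]] <- place_inside(mid)
  }
  for (mid in anti_m) {
    mir_rows[[length(mir_rows) + 1L]] <- place_inside(mid, flip_strand = TRUE)
  }
  # intergenic loci sit beyond every gene on their chromosome
  inter_counter <- 0L
  place_intergenic <- function(mid, avoid_chrom = NULL) {
    inter_counter <<- inter_counter + 1L
    chr <- chroms[(inter_counter - 1L) %% n_chr + 1L]
    if (!is.null(avoid_chrom) && chr == avoid_chrom) {
      inter_counter <<- inter_counter + 1L
      chr <- chroms[(inter_counter - 1L) %% n_chr + 1L]
    }
    start <- cursor[[chr]] + 5000L + 200L * inter_counter
    data.frame(feature_id = mir_ids[mid], type = "miRNA", chrom = chr,
               start = start, end = start + d$mirna_length, strand = "+",
               stringsAsFactors = FALSE)
  }
  for (mid in multi_m) {  # the extra genomic copy
    host <- host_of[[mir_ids[mid]]]
    mir_rows[[length(mir_rows) + 1L]] <-
      place_intergenic(mid, avoid_chrom = gene_chr[host])
  }
  for (mid in c(sink_m, univ_m, rep_m, dec_m, bg_m)) {
    mir_rows[[length(mir_rows) + 1L]] <- place_intergenic(mid)
  }
  ann <- rbind(gene_ann, do.call(rbind, mir_rows))
  rownames(ann) <- NULL
  ann$copy_count <- 1L
  is_mir <- ann$type == "miRNA"
  tab <- table(ann$feature_id[is_mir])
  ann$copy_count[is_mir] <- as.integer(tab[ann$feature_id[is_mir]])
  class(ann) <- c("feature_annotation", "data.frame")

  ## ---- sequences ----------------------------------------------------
  mirna_seq <- stats::setNames(random_rna(d$n_mirnas, d$mirna_length),
                               mir_ids)
  utr_seq <- stats::setNames(random_rna(d$n_genes, d$utr_length), gene_ids)
  site_types <- c("8mer", "7mer-m8", "7mer-A1")
  insert_at <- function(utr, piece, pos0) {
    paste0(substr(utr, 1L, pos0),
           piece,
           substr(utr, pos0 + nchar(piece) + 1L, nchar(utr)))
  }
  has_any_site <- function(mirna, utr) {
    s <- seed_site_strings(mirna)
    grepl(s[["site7m8"]], utr, fixed = TRUE) ||
      grepl(s[["site7a1"]], utr, fixed = TRUE)
  }
  rep_site_pos <- integer(n_rep)
  rep_site_type <- character(n_rep)
  for (k in seq_len(n_rep)) {
    m <- mirna_seq[[mir_ids[rep_m[k]]]]
    type <- sample(site_types, 1L)
    s <- seed_site_strings(m)
    piece <- switch(type, `8mer` = s[["site8"]],
                    `7mer-m8` = s[["site7m8"]], `7mer-A1` = s[["site7a1"]])
    pos0 <- sample.int(d$utr_length - 8L, 1L) - 1L
    utr <- insert_at(utr_seq[[gene_ids[rep_g[k]]]], piece, pos0)
    if (type == "7mer-m8" && substr(utr, pos0 + 8L, pos0 + 8L) == "A") {
      # an A after the match would upgrade the site to an 8mer
      substr(utr, pos0 + 8L, pos0 + 8L) <- sample(c("C", "G", "U"), 1L)
    }
    utr_seq[[gene_ids[rep_g[k]]]] <- utr
    rep_site_pos[k] <- pos0
    # record the realized tier at the planted position
    w8 <- substr(utr, pos0 + 1L, pos0 + 8L)
    w7 <- substr(utr, pos0 + 1L, pos0 + 7L)
    rep_site_type[k] <- if (w8 == s[["site8"]]) "8mer"
      else if (w7 == s[["site7m8"]]) "7mer-m8" else "7mer-A1"
  }
  for (k in seq_len(n_dec)) {
    m <- mirna_seq[[mir_ids[dec_m[k]]]]
    s <- seed_site_strings(m)
    gid <- gene_ids[dec_g[k]]
    for (attempt in seq_len(50L)) {
      base <- if (attempt == 1L) utr_seq[[gid]] else {
        random_rna(1L, d$utr_length)   # chance site in the backbone: redraw
      }
      scramble <- paste(sample(strsplit(s[["site8"]], "")[[1L]]),
                        collapse = "")
      pos0 <- sample.int(d$utr_length - 8L, 1L) - 1L
      cand <- insert_at(base, scramble, pos0)
      if (!has_any_site(m, cand)) {
        utr_seq[[gid]] <- cand
        break
      }
      if (attempt == 50L) {
        stop("failed to plant a site-free decoy UTR", call. = FALSE)
      }
    }
  }

  ## ---- truth bundle --------------------------------------------------
  spec_sets <- lapply(tissues, function(tis) gene_ids[spec_g[, tis]])
  names(spec_sets) <- tissues
  truth <- list(
    universal_ids = gene_ids[c(univ_g, sink_g)],
    specific_ids = spec_sets,
    associated_ids = spec_sets,
    host_pairs = data.frame(mirna_id = mir_ids[intra_m],
                            gene_id = gene_ids[host_g[seq_len(n_intra)]],
                            stringsAsFactors = FALSE),
    host_violations = data.frame(
      mirna_id = mir_ids[c(anti_m, multi_m, narrow_m)],
      gene_id = gene_ids[host_g[n_intra + seq_len(n_viol)]],
      type = rep(c("antisense", "multi_copy", "narrow_breadth"),
                 each = d$n_host_violations),
      stringsAsFactors = FALSE),
    repressor_pairs = data.frame(mirna_id = mir_ids[rep_m],
                                 gene_id = gene_ids[rep_g],
                                 utr_site_position = rep_site_pos,
                                 site_type = rep_site_type,
                                 stringsAsFactors = FALSE),
    decoy_pairs = data.frame(mirna_id = mir_ids[dec_m],
                             gene_id = gene_ids[dec_g],
                             stringsAsFactors = FALSE),
    sink_gene_ids = gene_ids[sink_g],
    sink_mirna_ids = mir_ids[sink_m],
    panel_columns = panel_col
  )
  class(truth) <- c("truth_bundle", "list")

  list(mrna_counts = mrna_counts, mirna_counts = mirna_counts,
       annotation = ann,
       sequences = list(mirna = mirna_seq, utr = utr_seq),
       truth = truth, mrna_mu = mrna_mu, mirna_mu = mirna_mu,
       gene_lengths = gene_len, design = d)
}

# ordering of host genes inside simulate_atlas_impl: the first n_intra
# hosts pair with intragenic miRNAs, the rest with the planted violations
# (antisense, then multi-copy, then narrow-breadth), d$n_host_violations
# of each.

#' Write a simulated atlas as a fixture bundle
#'
#' Emits the annotation (GTF), the two count matrices (TSV), the two
#' sequence sets (FASTA) and the truth bundle (JSON) into `outdir`.
#' Re-reading the files with the package readers reproduces the in-memory
#' objects.
#'
#' @param sim result of [simulate_atlas()].
#' @param outdir output directory (created if needed; a hard error if it
#'   cannot be created or written).
#' @return named character vector of the written paths, invisibly.
#' @export
write_fixture_bundle <- function(sim, outdir) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory ", outdir, call. = FALSE)
  }
  if (file.access(outdir, 2L) != 0L) {
    stop("output directory ", outdir, " is not writable", call. = FALSE)
  }
  paths <- c(
    mrna_counts = file.path(outdir, "mrna_counts.tsv"),
    mirna_counts = file.path(outdir, "mirna_counts.tsv"),
    annotation = file.path(outdir, "annotation.gtf"),
    mirna_fasta = file.path(outdir, "mirna_mature.fa"),
    utr_fasta = file.path(outdir, "utr3.fa"),
    truth = file.path(outdir, "truth.json")
  )
  write_count_matrix(sim$mrna_counts, paths[["mrna_counts"]], "gene_id")
  write_count_matrix(sim$mirna_counts, paths[["mirna_counts"]], "mirna_id")
  write_annotation(sim$annotation, paths[["annotation"]])
  write_sequences(sim$sequences$mirna, paths[["mirna_fasta"]])
  write_sequences(sim$sequences$utr, paths[["utr_fasta"]])
  jsonlite::write_json(unclass(sim$truth), paths[["truth"]],
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(paths)
}
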