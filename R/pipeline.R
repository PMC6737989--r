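#' Run the full atlas pipeline
#'
#' Chains the pipeline stages -- quantify, classify, network, host pairs,
#' differential expression, patterns, interactions -- over a set of input
#' files, writing one TSV per result table plus a JSON run summary
#' (package version, seed, cutoffs, per-stage counts). Reruns with
#' identical inputs, config and seed produce byte-identical outputs. Any
#' stage failure aborts with the stage name and cause.
#'
#' @param mrna_counts_path,mirna_counts_path TSV count matrices.
#' @param annotation_path GTF with `gene` and `miRNA` rows; gene spans
#'   provide the RPKM lengths.
#' @param mirna_fasta_path,utr_fasta_path mature miRNA and 3'UTR FASTA.
#' @param outdir output directory.
#' @param config an [atlas_config()]; validated before any stage runs.
#' @param stage_columns sample columns holding the muscle developmental
#'   stages, in temporal order.
#' @return invisibly, the run summary list.
#' @export
run_pipeline <- function(mrna_counts_path, mirna_counts_path,
                         annotation_path, mirna_fasta_path, utr_fasta_path,
                         outdir, config = atlas_config(),
                         stage_columns = c("muscle_D0", "muscle_D30",
                                           "muscle_D240")) {
  config <- validate_config(config)
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory ", outdir, call. = FALSE)
  }
  set.seed(config$rng_seed)
  stages <- character(0)
  counts_log <- list()
  run_stage <- function(name, fn) {
    message("[", name, "] running")
    out <- tryCatch(fn(), error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    stages <<- c(stages, name)
    out
  }

  mrna_counts <- read_count_matrix(mrna_counts_path)
  mirna_counts <- read_count_matrix(mirna_counts_path)
  ann <- read_annotation(annotation_path)
  mirna_seqs <- read_sequences(mirna_fasta_path)
  utr_seqs <- read_sequences(utr_fasta_path)
  genes_ann <- ann[ann$type == "gene", , drop = FALSE]
  lengths <- stats::setNames(genes_ann$end - genes_ann$start,
                             genes_ann$feature_id)

  q <- run_stage("quantify", function() {
    rpkm <- compute_rpkm(mrna_counts, lengths)
    tpm <- compute_tpm(mirna_counts)
    expr_mrna <- flag_expressed(rpkm, config$expressed_threshold)
    expr_mirna <- flag_expressed(tpm, config$expressed_threshold)
    sim <- tissue_similarity(rpkm)
    write_count_matrix(rpkm$values, file.path(outdir, "rpkm.tsv"), "gene_id")
    write_count_matrix(tpm$values, file.path(outdir, "tpm.tsv"), "mirna_id")
    write_count_matrix(sim$correlation,
                       file.path(outdir, "tissue_similarity.tsv"), "sample")
    list(rpkm = rpkm, tpm = tpm, expr_mrna = expr_mrna,
         expr_mirna = expr_mirna)
  })
  counts_log$expressed_mrna <- sum(q$expr_mrna$per_feature)
  counts_log$expressed_mirna <- sum(q$expr_mirna$per_feature)

  cls <- run_stage("classify", function() {
    panel_m <- tissue_panel(q$rpkm)
    panel_mi <- tissue_panel(q$tpm)
    cm <- classify_atlas(panel_m, config, "mrna")
    cmi <- classify_atlas(panel_mi, config, "mirna")
    flatten <- function(lst, stat) {
      do.call(rbind, lapply(names(lst), function(tis) {
        df <- lst[[tis]]
        if (nrow(df) == 0L) return(NULL)
        data.frame(feature_id = df$feature_id, tissue = tis,
                   statistic = df[[stat]], value = df$value,
                   stringsAsFactors = FALSE)
      }))
    }
    write_result_table(data.frame(feature_id = c(cm$universal,
                                                 cmi$universal)),
                       file.path(outdir, "universal.tsv"))
    for (nm in c("associated", "specific")) {
      tab <- rbind(flatten(cm[[nm]], if (nm == "associated") "z" else "fold"),
                   flatten(cmi[[nm]], if (nm == "associated") "z" else "fold"))
      if (is.null(tab)) {
        tab <- data.frame(feature_id = character(0), tissue = character(0),
                          statistic = numeric(0), value = numeric(0))
      }
      write_result_table(tab, file.path(outdir, paste0(nm, ".tsv")))
    }
    list(mrna = cm, mirna = cmi, panel_m = panel_m, panel_mi = panel_mi)
  })
  counts_log$universal_mrna <- length(cls$mrna$universal)
  counts_log$universal_mirna <- length(cls$mirna$universal)
  counts_log$specific_mrna <- sum(vapply(cls$mrna$specific, nrow,
                                         integer(1L)))
  counts_log$specific_mirna <- sum(vapply(cls$mirna$specific, nrow,
                                          integer(1L)))

  net <- run_stage("network", function() {
    expressed <- q$rpkm$values[q$expr_mrna$per_feature, , drop = FALSE]
    g <- build_correlation_graph(expressed, config$network_r_min)
    cl <- mcl_cluster(g, inflation = config$mcl_inflation)
    cl <- label_clusters(cl, expressed)
    write_result_table(g$edges, file.path(outdir, "network_edges.tsv"))
    memb <- data.frame(
      feature_id = unlist(cl$clusters, use.names = FALSE),
      cluster = rep(seq_along(cl$clusters),
                    vapply(cl$clusters, length, integer(1L))),
      label = rep(cl$labels, vapply(cl$clusters, length, integer(1L))),
      stringsAsFactors = FALSE
    )
    write_result_table(memb, file.path(outdir, "clusters.tsv"))
    cl
  })
  counts_log$network_clusters <- length(net$clusters)

  hp <- run_stage("hostpairs", function() {
    tab <- find_host_pairs(ann, ann, q$tpm, q$rpkm, config)
    write_result_table(tab, file.path(outdir, "host_pairs.tsv"))
    tab
  })
  counts_log$host_pairs_passed <- sum(hp$passed)

  de <- run_stage("de", function() {
    out <- list()
    for (k in 1:2) {
      a <- stage_columns[k]; b <- stage_columns[k + 1L]
      res_m <- de_test(mrna_counts, a, b, dispersion = config$de_dispersion,
                       lfc_min = config$de_lfc_min,
                       fdr_max = config$de_fdr_max)
      res_mi <- de_test(mirna_counts, a, b,
                        dispersion = config$de_dispersion,
                        lfc_min = config$de_lfc_min,
                        fdr_max = config$de_fdr_max)
      tag <- paste0(sub("^muscle_", "", a), "_vs_", sub("^muscle_", "", b))
      write_result_table(res_m, file.path(outdir,
                                          paste0("de_mrna_", tag, ".tsv")))
      write_result_table(res_mi, file.path(outdir,
                                           paste0("de_mirna_", tag, ".tsv")))
      out[[k]] <- list(mrna = res_m, mirna = res_mi)
    }
    out
  })

  pat <- run_stage("patterns", function() {
    pp <- overlap_patterns(de[[1L]]$mrna, de[[2L]]$mrna)
    tab <- do.call(rbind, lapply(names(pp), function(nm) {
      if (length(pp[[nm]]) == 0L) return(NULL)
      data.frame(feature_id = pp[[nm]], pattern = nm,
                 stringsAsFactors = FALSE)
    }))
    if (is.null(tab)) {
      tab <- data.frame(feature_id = character(0), pattern = character(0))
    }
    write_result_table(tab[order(tab$pattern, tab$feature_id), ,
                           drop = FALSE],
                       file.path(outdir, "patterns.tsv"))
    pp
  })
  counts_log$pattern_up_down <- length(pat$up_down)

  inter <- run_stage("interactions", function() {
    screened <- screen_negative_correlation(q$tpm, q$rpkm,
                                            config$interact_r_max)
    res <- assemble_interactions(
      screened, mirna_seqs, utr_seqs,
      mirna_stage_expr = q$tpm$values[, stage_columns, drop = FALSE],
      mrna_stage_expr = q$rpkm$values[, stage_columns, drop = FALSE],
      config = config
    )
    write_result_table(res$records[res$records$final, , drop = FALSE],
                       file.path(outdir, "interactions.tsv"))
    write_result_table(res$sites, file.path(outdir,
                                            "interaction_sites.tsv"))
    res
  })
  counts_log$interactions_final <- sum(inter$records$final)
  counts_log$interactions_persistent <- sum(inter$records$persistent)

  summary <- list(
    package = "miratlas",
    version = as.character(utils::packageVersion("miratlas")),
    seed = config$rng_seed,
    config = unclass(config),
    stages_completed = stages,
    counts = counts_log
  )
  jsonlite::write_json(summary, file.path(outdir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
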