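# shared fixture builders and independent oracles

rna_bases <- c("A", "C", "G", "U")

random_rna_str <- function(len) {
  paste(sample(rna_bases, len, replace = TRUE), collapse = "")
}

write_tsv_text <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

write_gtf_text <- function(lines) {
  path <- tempfile(fileext = ".gtf")
  writeLines(lines, path)
  path
}

gtf_line <- function(chrom, type, start1, end1, strand, id) {
  sprintf("%s\ttest\t%s\t%d\t%d\t.\t%s\t.\tgene_id \"%s\";",
          chrom, type, start1, end1, strand, id)
}

# annotation data.frame in the package's internal convention
make_annotation <- function(feature_id, type, chrom, start, end, strand) {
  ann <- data.frame(feature_id = feature_id, type = type, chrom = chrom,
                    start = start, end = end, strand = strand,
                    stringsAsFactors = FALSE)
  ann$copy_count <- 1L
  is_mir <- ann$type == "miRNA"
  if (any(is_mir)) {
    tab <- table(ann$feature_id[is_mir])
    ann$copy_count[is_mir] <- as.integer(tab[ann$feature_id[is_mir]])
  }
  class(ann) <- c("feature_annotation", "data.frame")
  ann
}

# a coexpression_graph from an explicit edge list
make_graph <- function(nodes, edge_a, edge_b, r = NULL) {
  if (is.null(r)) r <- rep(1, length(edge_a))
  structure(list(nodes = nodes,
                 edges = data.frame(a = edge_a, b = edge_b, r = r,
                                    stringsAsFactors = FALSE),
                 r_min = 0.9),
            class = "coexpression_graph")
}

clique_edges <- function(members) {
  cmb <- t(utils::combn(members, 2L))
  list(a = cmb[, 1L], b = cmb[, 2L])
}

# partition comparison: Rand index from scratch
rand_index <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b))
  n <- length(labels_a)
  agree <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      same_a <- labels_a[i] == labels_a[j]
      same_b <- labels_b[i] == labels_b[j]
      if (same_a == same_b) agree <- agree + 1
    }
  }
  agree / (n * (n - 1) / 2)
}

cluster_labels <- function(cluster_set, nodes) {
  lab <- stats::setNames(rep(0L, length(nodes)), nodes)
  for (k in seq_along(cluster_set$clusters)) {
    lab[cluster_set$clusters[[k]]] <- k
  }
  singles <- intersect(cluster_set$singletons, nodes)
  lab[singles] <- length(cluster_set$clusters) + seq_along(singles)
  lab
}

# exhaustive window-by-window seed-site oracle, independent of the scanner
oracle_seed_sites <- function(mirna, utr) {
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  rc <- function(x) {
    paste(rev(comp[strsplit(x, "")[[1L]]]), collapse = "")
  }
  m7 <- rc(substr(mirna, 2L, 8L))
  m6 <- rc(substr(mirna, 2L, 7L))
  L <- nchar(utr)
  hits <- list()
  for (p in seq_len(max(L - 6L, 0L))) {
    w7 <- substr(utr, p, p + 6L)
    w8 <- if (p + 7L <= L) substr(utr, p, p + 7L) else ""
    type <- NULL
    if (w8 == paste0(m7, "A")) type <- "8mer"
    else if (w7 == m7) type <- "7mer-m8"
    else if (w7 == paste0(m6, "A")) type <- "7mer-A1"
    if (!is.null(type)) {
      hits[[length(hits) + 1L]] <- data.frame(
        utr_position = p - 1L, site_type = type, stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(utr_position = integer(0), site_type = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}

# exhaustive duplex oracle: enumerate every monotone chain of admissible
# pairs, scoring each chain directly from the energy model definition
oracle_duplex_mfe <- function(a, b) {
  par <- duplex_energy_params()
  A <- strsplit(a, "")[[1L]]
  B <- rev(strsplit(b, "")[[1L]])
  n <- length(A); m <- length(B)
  strength <- function(i, j) par$pair_strength[paste0(A[i], B[j])]
  adm <- outer(seq_len(n), seq_len(m),
               function(i, j) !is.na(par$pair_strength[paste0(A[i], B[j])]))
  best <- 0
  extend_cost <- function(pi, pj, i, j) {
    if (i == pi + 1L && j == pj + 1L) {
      -(strength(pi, pj) + strength(i, j)) / 2
    } else {
      par$loop_open + par$loop_ext * ((i - pi - 1L) + (j - pj - 1L))
    }
  }
  recurse <- function(i, j, e) {
    if (e < best) best <<- e
    if (i >= n || j >= m) return()
    for (i2 in (i + 1L):n) {
      for (j2 in (j + 1L):m) {
        if (adm[i2, j2]) recurse(i2, j2, e + extend_cost(i, j, i2, j2))
      }
    }
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      if (adm[i, j]) recurse(i, j, par$init)
    }
  }
  unname(best)
}

# brute-force Benjamini-Hochberg step-up, straight from the definition
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  adj[ord] <- p[ord] * m / seq_len(m)
  # step-up monotonicity: running minimum from the largest p downwards
  if (m >= 2L) {
    for (k in (m - 1L):1L) {
      adj[ord[k]] <- min(adj[ord[k]], adj[ord[k + 1L]])
    }
  }
  pmin(adj, 1)
}

# constructed host-pair fixture: one genuine intragenic pair plus one
# violation of each positional / copy / breadth criterion
host_fixture <- function() {
  ann <- make_annotation(
    feature_id = c("gHost", "gOther",
                   "mirTrue", "mirAnti", "mirPart", "mirMulti", "mirMulti",
                   "mirNarrow"),
    type = c("gene", "gene", rep("miRNA", 6L)),
    chrom = c("chr1", "chr2", "chr1", "chr1", "chr1", "chr1", "chr5",
              "chr1"),
    start = c(100L, 0L, 150L, 300L, 90L, 500L, 900L, 700L),
    end = c(5000L, 1000L, 172L, 322L, 112L, 522L, 922L, 722L),
    strand = c("+", "+", "+", "-", "+", "+", "+", "+")
  )
  samples <- sprintf("s%02d", 1:11)
  gene_prof <- 2^seq(0, 5, length.out = 11)
  rpkm <- expr_mat(rep(gene_prof, 2), c("gHost", "gOther"), samples)
  mir <- rbind(mirTrue = 10 * gene_prof,
               mirAnti = 10 * gene_prof,
               mirPart = 10 * gene_prof,
               mirMulti = 10 * gene_prof,
               mirNarrow = c(10 * gene_prof[1:4], rep(0, 7)))
  colnames(mir) <- samples
  list(ann = ann, rpkm = rpkm, tpm = mir)
}

# all permutations of 1:n as a list of index vectors
combinat_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (sub in combinat_perms(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos - 1L)
    }
  }
  out
}

# small expression matrix with named dims
expr_mat <- function(values, features, samples) {
  matrix(values, nrow = length(features), byrow = TRUE,
         dimnames = list(features, samples))
}

# compact simulation design for fast tests; ... overrides the defaults
small_design <- function(seed, ...) {
  args <- list(n_genes = 800L, n_mirnas = 120L, frac_universal = 0.02,
               n_specific_per_tissue = 5L, n_repressor_pairs = 8L,
               n_decoy_pairs = 4L, n_host_violations = 2L,
               library_depth = 5e5, mirna_depth = 5e5, seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(simulation_design, args)
}
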