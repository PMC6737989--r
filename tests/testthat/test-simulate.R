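test_that("the same seed reproduces the atlas exactly", {
  s1 <- simulate_atlas(small_design(seed = 5))
  s2 <- simulate_atlas(small_design(seed = 5))
  expect_identical(s1$mrna_counts, s2$mrna_counts)
  expect_identical(s1$mirna_counts, s2$mirna_counts)
  expect_identical(s1$sequences, s2$sequences)
  s3 <- simulate_atlas(small_design(seed = 6))
  expect_false(identical(s1$mrna_counts, s3$mrna_counts))
})

test_that("count draws converge to their design means", {
  set.seed(91)
  mu <- matrix(c(20, 80, 250, 600, 50, 1500), 2, 3)
  total <- matrix(0, 2, 3)
  for (k in 1:1000) total <- total + draw_nb_counts(mu, 0.1)
  expect_true(all(abs(total / 1000 - mu) / mu < 0.05))
})

test_that("in the noise-free limit universal genes clear 10 RPKM everywhere", {
  sim <- simulate_atlas(small_design(seed = 9, nb_dispersion = 0))
  rpkm <- compute_rpkm(sim$mrna_counts, sim$gene_lengths)
  uni <- sim$truth$universal_ids
  expect_true(all(rpkm$values[uni, ] > 10))
})

test_that("every planted repressor site is found by an exhaustive scan", {
  sim <- simulate_atlas(small_design(seed = 10, n_repressor_pairs = 5L))
  tr <- sim$truth$repressor_pairs
  expect_identical(nrow(tr), 5L)
  for (k in seq_len(nrow(tr))) {
    hits <- oracle_seed_sites(sim$sequences$mirna[[tr$mirna_id[k]]],
                              sim$sequences$utr[[tr$gene_id[k]]])
    match <- hits[hits$utr_position == tr$utr_site_position[k], ]
    expect_identical(nrow(match), 1L)
    expect_identical(match$site_type, tr$site_type[k])
  }
  # the package scanner rediscovers 100% of planted sites
  for (k in seq_len(nrow(tr))) {
    got <- find_seed_sites(sim$sequences$mirna[[tr$mirna_id[k]]],
                           sim$sequences$utr[[tr$gene_id[k]]])
    expect_true(tr$utr_site_position[k] %in% got$utr_position)
  }
})

test_that("decoy and repressor pair sets are disjoint; truth is complete", {
  sim <- simulate_atlas(small_design(seed = 11))
  tr <- sim$truth
  key <- function(df) paste(df$mirna_id, df$gene_id)
  expect_length(intersect(key(tr$repressor_pairs), key(tr$decoy_pairs)), 0L)
  expect_gt(length(tr$universal_ids), 0L)
  expect_true(all(vapply(tr$specific_ids, length, integer(1)) > 0L))
  expect_gt(nrow(tr$host_pairs), 0L)
  # every planted specific gene belongs to exactly one tissue
  all_spec <- unlist(tr$specific_ids, use.names = FALSE)
  expect_identical(anyDuplicated(all_spec), 0L)
})

test_that("infeasible designs are rejected up front", {
  expect_error(simulation_design(specific_fold_planted = 5),
               "well-posed")
  expect_error(simulation_design(n_genes = 0), "positive")
  expect_error(simulate_atlas(small_design(seed = 1, n_genes = 100L)),
               "infeasible")
})

test_that("the fixture bundle round-trips through the package readers", {
  sim <- simulate_atlas(small_design(seed = 12))
  outdir <- file.path(tempdir(), "bundle-test")
  paths <- write_fixture_bundle(sim, outdir)
  expect_true(all(file.exists(paths)))
  m <- read_count_matrix(paths[["mrna_counts"]])
  expect_equal(m, sim$mrna_counts)
  ann <- read_annotation(paths[["annotation"]])
  orig <- sim$annotation
  ord <- function(a) a[order(a$feature_id, a$chrom, a$start), ]
  a1 <- ord(as.data.frame(ann)); a2 <- ord(as.data.frame(orig))
  rownames(a1) <- rownames(a2) <- NULL
  expect_identical(a1, a2)
  seqs <- read_sequences(paths[["utr_fasta"]])
  expect_identical(seqs[names(sim$sequences$utr)], sim$sequences$utr)
  truth <- jsonlite::read_json(paths[["truth"]], simplifyVector = TRUE)
  expect_setequal(truth$universal_ids, sim$truth$universal_ids)
  # intragenic miRNA loci are contained in their host gene intervals
  mir <- ann[ann$type == "miRNA", ]
  gen <- ann[ann$type == "gene", ]
  for (k in seq_len(nrow(sim$truth$host_pairs))) {
    mrow <- mir[mir$feature_id == sim$truth$host_pairs$mirna_id[k], ]
    grow <- gen[gen$feature_id == sim$truth$host_pairs$gene_id[k], ]
    expect_identical(mrow$chrom, grow$chrom)
    expect_true(mrow$start >= grow$start && mrow$end <= grow$end)
    expect_identical(mrow$strand, grow$strand)
  }
})
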