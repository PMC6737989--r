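stage_cols <- c("muscle_D0", "muscle_D30", "muscle_D240")

test_that("the screening predicate implements a strict r < -0.5 rule", {
  expect_true(passes_screen(-0.5390881))
  expect_true(passes_screen(-0.9999364))
  expect_false(passes_screen(-0.5))
  expect_false(passes_screen(-0.4999))
  expect_false(passes_screen(NA_real_))
  expect_identical(passes_screen(c(-0.6, -0.2), r_max = -0.5),
                   c(TRUE, FALSE))
})

test_that("screening finds exactly the anti-correlated pairs", {
  samples <- sprintf("s%d", 1:5)
  mir <- expr_mat(c(5, 4, 3, 2, 1,
                    1, 1, 1, 2, 1), c("mDown", "mFlat"), samples)
  gene <- expr_mat(c(1, 2, 3, 4, 5,
                     5, 5, 5, 5, 5), c("gUp", "gConst"), samples)
  expect_message(scr <- screen_negative_correlation(mir, gene),
                 "zero-variance")
  expect_identical(nrow(scr), 1L)
  expect_identical(scr$mirna_id, "mDown")
  expect_identical(scr$gene_id, "gUp")
  expect_equal(scr$r, -1)
  expect_error(screen_negative_correlation(mir[, 1:2], gene[, 1:2]),
               ">= 3")
  # tightening the threshold shrinks the screened set monotonically
  set.seed(95)
  a <- matrix(rlnorm(20 * 6), 20, 6,
              dimnames = list(sprintf("m%02d", 1:20), sprintf("s%d", 1:6)))
  b <- matrix(rlnorm(30 * 6), 30, 6,
              dimnames = list(sprintf("g%02d", 1:30), sprintf("s%d", 1:6)))
  loose <- screen_negative_correlation(a, b, r_max = -0.3)
  tight <- screen_negative_correlation(a, b, r_max = -0.7)
  expect_true(all(paste(tight$mirna_id, tight$gene_id) %in%
                    paste(loose$mirna_id, loose$gene_id)))
})

test_that("tissue-wide but stage-flat pairs reach the final set only", {
  samples <- c("fat", "heart", "kidney", stage_cols)
  # anti-correlated across tissues, constant across muscle stages
  mir <- expr_mat(c(9, 6, 3, 5, 5, 5), "m1", samples)
  gene <- expr_mat(c(1, 4, 7, 5, 5, 5), "g1", samples)
  mirna_seqs <- c(m1 = random_rna_str(22))
  site <- seed_site_strings(mirna_seqs[["m1"]])[["site8"]]
  utr_seqs <- c(g1 = paste0(random_rna_str(30), site, random_rna_str(30)))
  scr <- screen_negative_correlation(mir, gene)
  expect_identical(nrow(scr), 1L)
  res <- assemble_interactions(scr, mirna_seqs, utr_seqs,
                               mir[, stage_cols, drop = FALSE],
                               gene[, stage_cols, drop = FALSE],
                               detail_sites = "all")
  expect_true(res$records$final)
  expect_false(res$records$persistent)
  # the planted 8mer is reported (its 3' sub-site also matches as 7mer-A1)
  expect_true("8mer" %in% res$sites$site_type)
  expect_gte(res$records$n_sites, 1L)
})

test_that("pairs without sequences are dropped with a message", {
  scr <- data.frame(mirna_id = c("m1", "m2"), gene_id = c("g1", "g2"),
                    r = c(-0.8, -0.9), stringsAsFactors = FALSE)
  expect_message(
    res <- assemble_interactions(scr, c(m1 = random_rna_str(22)),
                                 c(g1 = random_rna_str(50))),
    "missing sequences")
  expect_identical(nrow(res$records), 1L)
})

test_that("planted repressors are recovered and decoys fail the site filter", {
  sim <- simulate_atlas(small_design(seed = 14))
  rpkm <- compute_rpkm(sim$mrna_counts, sim$gene_lengths)
  tpm <- compute_tpm(sim$mirna_counts)
  scr <- suppressMessages(screen_negative_correlation(tpm, rpkm))
  res <- assemble_interactions(scr, sim$sequences$mirna, sim$sequences$utr,
                               tpm$values[, stage_cols],
                               rpkm$values[, stage_cols],
                               detail_sites = "none")
  rec <- res$records
  key <- function(df) paste(df$mirna_id, df$gene_id)
  truth <- sim$truth
  pers <- key(rec[rec$persistent, ])
  expect_gte(mean(key(truth$repressor_pairs) %in% pers), 0.85)
  dec <- rec[key(rec) %in% key(truth$decoy_pairs), ]
  expect_gt(nrow(dec), 0L)               # decoys do pass the screen
  expect_false(any(dec$passed_sites))    # but never the site filter
  # records are sorted by ascending correlation
  expect_true(!is.unsorted(rec$r))
})

test_that("enabling the energy filter never enlarges the final set", {
  sim <- simulate_atlas(small_design(seed = 15))
  rpkm <- compute_rpkm(sim$mrna_counts, sim$gene_lengths)
  tpm <- compute_tpm(sim$mirna_counts)
  scr <- suppressMessages(screen_negative_correlation(tpm, rpkm))
  scr <- scr[1:500, ]   # a slice is enough to exercise the filter
  base <- assemble_interactions(scr, sim$sequences$mirna,
                                sim$sequences$utr,
                                detail_sites = "none")
  strict <- assemble_interactions(scr, sim$sequences$mirna,
                                  sim$sequences$utr,
                                  config = atlas_config(mfe_filter = TRUE,
                                                        mfe_max = -10))
  key <- function(df) paste(df$mirna_id, df$gene_id)
  expect_true(all(key(strict$records[strict$records$final, ]) %in%
                    key(base$records[base$records$final, ])))
})
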