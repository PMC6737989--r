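nine <- sprintf("t%d", 1:9)

test_that("universal mRNA rule is strict in every tissue", {
  m <- expr_mat(c(rep(11, 9),
                  c(10, rep(100, 8)),
                  rep(10.001, 9)), c("hi", "edge", "just"), nine)
  uni <- find_universal_mrna(m, 10)
  expect_true("hi" %in% uni)
  expect_false("edge" %in% uni)   # 10.0 in one tissue: excluded (strict >)
  expect_true("just" %in% uni)
})

test_that("universal miRNA rule combines floor and CV ceiling", {
  m <- expr_mat(c(rep(5, 3),
                  1.5, 1.5, 15,
                  0.5, 40, 40), c("const", "spiky", "low"),
                c("t1", "t2", "t3"))
  uni <- find_universal_mirna(m, 1, 0.5)
  expect_true("const" %in% uni)       # CV 0
  # hand computation with n-1 sd: sd = 7.794, mean = 6, CV = 1.299
  expect_equal(sd(c(1.5, 1.5, 15)) / 6, 1.299038, tolerance = 1e-6)
  expect_false("spiky" %in% uni)
  expect_false("low" %in% uni)        # floor rule regardless of CV
})

test_that("tissue association uses n-1 z-scores with an abundance floor", {
  prof <- c(10, rep(1, 8))
  m <- expr_mat(c(prof, rep(7, 9)), c("assoc", "flat"), nine)
  res <- find_tissue_associated(m, 1.5, 1)
  # hand z-score: mean 2, sd 3 -> z = 8/3
  expect_equal(res$t1$z[res$t1$feature_id == "assoc"], 8 / 3)
  expect_false("flat" %in% unlist(lapply(res, `[[`, "feature_id")))
  # a feature can be associated with two tissues; verify both z-scores by
  # direct computation
  m2 <- expr_mat(c(9, 9, rep(1, 7)), "dual", nine)
  z <- (m2[1, ] - mean(m2[1, ])) / sd(m2[1, ])
  expect_true(all(z[1:2] >= 1.5))
  res2 <- find_tissue_associated(m2, 1.5, 1)
  expect_true("dual" %in% res2$t1$feature_id)
  expect_true("dual" %in% res2$t2$feature_id)
})

test_that("tissue specificity uses the leave-one-out mean", {
  m <- expr_mat(c(100, rep(1, 8),
                  100, 100, rep(0, 7),
                  50, rep(0, 8)),
                c("clean", "double", "vacuous"), nine)
  res <- find_tissue_specific(m, 10, 10)
  all_ids <- unlist(lapply(res, `[[`, "feature_id"))
  expect_true("clean" %in% res$t1$feature_id)
  expect_equal(res$t1$fold[res$t1$feature_id == "clean"], 100)
  # leave-one-out mean for "double" at t1 is 100/8 = 12.5; 100 <= 125
  expect_false("double" %in% all_ids)
  # zero loo mean with abundance >= floor: vacuously specific
  expect_true("vacuous" %in% res$t1$feature_id)
  expect_identical(res$t1$fold[res$t1$feature_id == "vacuous"], Inf)
})

test_that("raising cutoffs never enlarges classified sets", {
  set.seed(31)
  for (rep in 1:20) {
    m <- matrix(rlnorm(45 * 9, 1, 1.5), 45, 9,
                dimnames = list(sprintf("g%02d", 1:45), nine))
    ids <- function(x) sort(unlist(lapply(x, `[[`, "feature_id")))
    s1 <- ids(find_tissue_specific(m, 5, 5))
    s2 <- ids(find_tissue_specific(m, 10, 5))
    s3 <- ids(find_tissue_specific(m, 5, 20))
    expect_true(all(s2 %in% s1))
    expect_true(all(s3 %in% s1))
    a1 <- ids(find_tissue_associated(m, 1.0, 1))
    a2 <- ids(find_tissue_associated(m, 2.0, 1))
    expect_true(all(a2 %in% a1))
  }
})

test_that("planted classes are recovered exactly on a low-noise atlas", {
  sim <- simulate_atlas(small_design(seed = 101, nb_dispersion = 0.01,
                                     frac_intragenic_mirna = 0,
                                     n_host_violations = 0L,
                                     n_repressor_pairs = 0L,
                                     n_decoy_pairs = 0L))
  rpkm <- compute_rpkm(sim$mrna_counts, sim$gene_lengths)
  panel <- tissue_panel(rpkm)
  truth <- sim$truth
  expect_setequal(find_universal_mrna(panel), truth$universal_ids)
  spec <- find_tissue_specific(panel)
  for (tis in names(truth$specific_ids)) {
    expect_setequal(spec[[tis]]$feature_id, truth$specific_ids[[tis]])
  }
})

test_that("classify_atlas applies the configured cutoffs", {
  set.seed(33)
  m <- matrix(rlnorm(90, 2, 1), 10, 9,
              dimnames = list(sprintf("g%02d", 1:10), nine))
  res <- classify_atlas(m, atlas_config(), "mrna")
  expect_setequal(res$universal, find_universal_mrna(m, 10))
  expect_identical(res$parameters$specific_fold, 10)
})
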