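test_that("intragenic candidacy needs full containment on the same strand", {
  fx <- host_fixture()
  cand <- find_intragenic_candidates(fx$ann, fx$ann)
  got <- paste(cand$mirna_id, cand$gene_id)
  expect_true("mirTrue gHost" %in% got)
  expect_false("mirPart gHost" %in% got)   # [90,112) vs [100,5000)
  expect_false("mirAnti gHost" %in% got)   # contained but antisense
  expect_true("mirMulti gHost" %in% got)   # copy rule is a later filter
})

test_that("multi-copy miRNAs are removed wherever they appear", {
  fx <- host_fixture()
  cand <- data.frame(mirna_id = c("mirTrue", "mirMulti", "mirMulti"),
                     gene_id = c("gHost", "gHost", "gOther"),
                     stringsAsFactors = FALSE)
  kept <- filter_single_copy(cand, fx$ann)
  expect_identical(kept$mirna_id, "mirTrue")
})

test_that("expression breadth is inclusive and applies to both members", {
  fx <- host_fixture()
  cand <- data.frame(mirna_id = c("mirTrue", "mirNarrow"),
                     gene_id = c("gHost", "gHost"),
                     stringsAsFactors = FALSE)
  kept <- filter_expression_breadth(cand, fx$tpm, fx$rpkm, 5, 0.1)
  expect_identical(kept$mirna_id, "mirTrue")
  # a value of exactly 0.1 in the fifth tissue counts (inclusive >=)
  tpm <- expr_mat(c(rep(0.1, 5), rep(0, 6)), "mirEdge",
                  colnames(fx$tpm))
  cand2 <- data.frame(mirna_id = "mirEdge", gene_id = "gHost",
                      stringsAsFactors = FALSE)
  expect_identical(
    nrow(filter_expression_breadth(cand2, tpm, fx$rpkm, 5, 0.1)), 1L)
  expect_error(
    filter_expression_breadth(data.frame(mirna_id = "ghost",
                                         gene_id = "gHost"),
                              fx$tpm, fx$rpkm),
    "ghost")
})

test_that("correlation test matches the closed-form t transform", {
  fx <- host_fixture()
  cand <- data.frame(mirna_id = "mirTrue", gene_id = "gHost",
                     stringsAsFactors = FALSE)
  res <- test_host_correlation(cand, fx$tpm, fx$rpkm)
  expect_equal(res$r, 1)
  # perfectly anti-ordered profiles fail the r > 0.6 rule
  anti <- expr_mat(rev(fx$rpkm["gHost", ]), "mirFlip", colnames(fx$tpm))
  res2 <- test_host_correlation(data.frame(mirna_id = "mirFlip",
                                           gene_id = "gHost"),
                                anti, fx$rpkm)
  expect_identical(nrow(res2), 0L)
  # independent oracle on random pairs: cor.test implements the same
  # t transform
  set.seed(51)
  for (k in 1:20) {
    x <- rlnorm(11); y <- rlnorm(11)
    tpm <- expr_mat(x, "m", sprintf("s%02d", 1:11))
    rpkm <- expr_mat(y, "g", sprintf("s%02d", 1:11))
    scored <- miratlas:::score_host_correlation(
      data.frame(mirna_id = "m", gene_id = "g"), tpm, rpkm)
    ct <- cor.test(x, y)
    expect_equal(scored$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(scored$p, ct$p.value, tolerance = 1e-12)
  }
})

test_that("exactly the true pair passes; each violation fails its flag", {
  fx <- host_fixture()
  tab <- find_host_pairs(fx$ann, fx$ann, fx$tpm, fx$rpkm)
  tab$key <- paste(tab$mirna_id, tab$gene_id)
  expect_identical(tab$key[tab$passed], "mirTrue gHost")
  row <- function(id) tab[tab$mirna_id == id & tab$gene_id == "gHost", ]
  expect_false(row("mirAnti")$same_strand)
  expect_false(row("mirPart")$containment)
  expect_false(row("mirMulti")$single_copy)
  expect_false(row("mirNarrow")$breadth_pass)
  expect_true(row("mirNarrow")$containment)
  expect_true(row("mirMulti")$containment && row("mirMulti")$same_strand)
})

test_that("the five filters commute over all 120 orderings", {
  fx <- host_fixture()
  tab <- find_host_pairs(fx$ann, fx$ann, fx$tpm, fx$rpkm)
  flags <- c("containment", "same_strand", "single_copy", "breadth_pass",
             "corr_pass")
  perms <- combinat_perms(5L)
  key <- function(t) sort(paste(t$mirna_id, t$gene_id))
  want <- key(tab[tab$passed, ])
  for (p in perms) {
    cur <- tab
    for (f in flags[p]) cur <- cur[cur[[f]], , drop = FALSE]
    expect_identical(key(cur), want)
  }
})
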