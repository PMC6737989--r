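test_that("size factors recover scale and match hand median-of-ratios", {
  m <- expr_mat(c(10, 10,
                  20, 20,
                  5, 5), c("a", "b", "c"), c("s1", "s2"))
  sf <- normalize_library(m)
  expect_equal(sf[["s1"]], sf[["s2"]])       # identical columns
  m2 <- cbind(m, s3 = 2 * m[, 1])
  sf2 <- normalize_library(m2)
  expect_equal(sf2[["s3"]] / sf2[["s1"]], 2, tolerance = 1e-9)
  # hand computation on a 5x3 toy matrix
  toy <- expr_mat(c(2, 4, 8,
                    10, 10, 10,
                    1, 2, 1,
                    6, 3, 12,
                    5, 5, 20), sprintf("g%d", 1:5), c("x", "y", "z"))
  geo <- exp(rowMeans(log(toy)))
  want <- apply(toy / geo, 2L, median)
  expect_equal(normalize_library(toy), want)
  # all-zero-containing features force the fallback
  z <- expr_mat(c(0, 5, 3, 0), c("a", "b"), c("s1", "s2"))
  expect_warning(sfz <- normalize_library(z), "column-sum")
  expect_true(all(sfz > 0))
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.123), 0.123)                 # m = 1
  set.seed(61)
  p <- runif(10000)
  adj <- bh_fdr(p)
  expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
  expect_true(all(adj >= p) && all(adj <= 1))
  # order-equivariance
  ord <- sample(length(p))
  expect_equal(bh_fdr(p[ord]), adj[ord])
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("identical condition columns give zero fold change everywhere", {
  set.seed(62)
  cts <- matrix(rpois(40, 50), 20, 2,
                dimnames = list(sprintf("g%02d", 1:20), c("a", "b")))
  cts[, 2] <- cts[, 1]
  res <- de_test(cts, "a", "b", dispersion = 0.1)
  expect_true(all(res$log2fc == 0))
  expect_true(all(res$call == "ns"))
})

test_that("replicate-free designs must supply a dispersion", {
  cts <- expr_mat(c(5, 9, 100, 80), c("g1", "g2"), c("a", "b"))
  expect_error(de_test(cts, "a", "b"), "dispersion")
  expect_silent(de_test(cts, "a", "b", dispersion = 0.1))
})

test_that("planted folds are recovered and nulls are controlled", {
  set.seed(63)
  n <- 520L
  mu <- exp(runif(n, log(500), log(2000)))
  mu_b <- mu
  mu_b[1:20] <- mu[1:20] * 8   # planted 8-fold features
  a <- matrix(rnbinom(n * 6L, size = 1 / 0.005, mu = rep(mu, 6L)), n, 6L)
  b <- matrix(rnbinom(n * 6L, size = 1 / 0.005, mu = rep(mu_b, 6L)), n, 6L)
  cts <- cbind(a, b)
  dimnames(cts) <- list(sprintf("g%03d", 1:n), sprintf("s%02d", 1:12))
  res <- de_test(cts, 1:6, 7:12, dispersion = 0.005)
  expect_true(all(abs(res$log2fc[1:20] - 3) <= 0.3))
  expect_true(all(res$fdr[1:20] < 0.05))
  # null features stay quiet
  expect_lte(mean(res$fdr[-(1:20)] < 0.05), 0.05)
  # method-of-moments dispersion estimation lands near the truth
  set.seed(64)
  cts2 <- matrix(rnbinom(2000 * 8L, size = 1 / 0.1,
                         mu = rep(exp(runif(2000, 4, 6)), 8L)), 2000, 8L)
  dimnames(cts2) <- list(sprintf("g%04d", 1:2000), sprintf("s%d", 1:8))
  res2 <- de_test(cts2, 1:4, 5:8)   # dispersion = "estimate"
  expect_lte(mean(res2$fdr < 0.05), 0.05)
})

test_that("null p-values are approximately uniform", {
  set.seed(65)
  n <- 2000L
  mu <- exp(runif(n, log(100), log(1000)))
  cts <- matrix(rnbinom(n * 20L, size = 1 / 0.05, mu = rep(mu, 20L)),
                n, 20L,
                dimnames = list(sprintf("g%04d", 1:n), sprintf("s%02d", 1:20)))
  res <- de_test(cts, 1:10, 11:20, dispersion = 0.05)
  expect_gt(suppressWarnings(ks.test(res$p, "punif")$p.value), 0.01)
})

test_that("pattern partition matches exhaustive enumeration of calls", {
  calls <- c("up", "down", "ns")
  grid <- expand.grid(c1 = calls, c2 = calls, stringsAsFactors = FALSE)
  ids <- sprintf("f%d", seq_len(nrow(grid)))
  mk <- function(col) data.frame(feature_id = ids, call = grid[[col]],
                                 stringsAsFactors = FALSE)
  pp <- overlap_patterns(mk("c1"), mk("c2"))
  pick <- function(a, b) ids[grid$c1 == a & grid$c2 == b]
  expect_identical(pp$up_up, pick("up", "up"))
  expect_identical(pp$up_down, pick("up", "down"))
  expect_identical(pp$down_up, pick("down", "up"))
  expect_identical(pp$down_down, pick("down", "down"))
  expect_identical(pp$up_only_1, pick("up", "ns"))
  expect_identical(pp$down_only_2, pick("ns", "down"))
  # the eight classes tile the union of all DE calls without overlap
  all_sets <- unlist(pp, use.names = FALSE)
  expect_identical(anyDuplicated(all_sets), 0L)
  expect_setequal(all_sets, ids[grid$c1 != "ns" | grid$c2 != "ns"])
})
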