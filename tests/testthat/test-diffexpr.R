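# Normalization, the Audic-Claverie test, BH, and response classification.

test_that("median-of-ratios size factors match the hand-computed example", {
  m <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2,
              dimnames = list(c("g1", "g2", "g3"), c("A", "B")))
  sf <- size_factors(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-6)

  same <- matrix(rep(c(5, 9, 13), 3), ncol = 3,
                 dimnames = list(c("a", "b", "c"), c("s1", "s2", "s3")))
  expect_equal(unname(size_factors(same)), c(1, 1, 1))

  single <- matrix(1:3, ncol = 1, dimnames = list(letters[1:3], "s1"))
  expect_equal(unname(size_factors(single)), 1)

  zeros <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(size_factors(zeros), "pseudo-reference")
})

test_that("size factors agree with the reference median-of-ratios code", {
  skip_if_not_installed("DESeq2")
  set.seed(31)
  m <- matrix(rpois(400, lambda = rep(exp(rnorm(100, 5, 1)), 4)), ncol = 4)
  m <- m + 1L  # all-positive so both definitions share the gene set
  rownames(m) <- sprintf("g%03d", 1:100); colnames(m) <- sprintf("s%d", 1:4)
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-8)
})

test_that("scaling one sample rescales its factor, not normalized ratios", {
  set.seed(32)
  m <- matrix(rpois(300, 100) + 1L, ncol = 3,
              dimnames = list(sprintf("g%d", 1:100), c("s1", "s2", "s3")))
  sf0 <- size_factors(m)
  m2 <- m; m2[, 2] <- m2[, 2] * 4L
  sf1 <- size_factors(m2)
  # between-sample factor ratios absorb the full 4x depth change ...
  expect_equal(unname(sf1[2] / sf1[1]), unname(4 * sf0[2] / sf0[1]),
               tolerance = 1e-9)
  # ... so normalized counts are unchanged up to one global constant
  n0 <- sweep(m, 2, sf0, "/")
  n1 <- sweep(m2, 2, sf1, "/")
  expect_equal(n1 / n0, matrix(mean(n1 / n0), 100, 3, dimnames = dimnames(m)),
               tolerance = 1e-9)
})

test_that("Audic-Claverie p-values match the stated exact cases", {
  expect_equal(audic_claverie_p(0, 0, 1e6, 1e6), 1.0)
  expect_equal(audic_claverie_p(5, 0, 1e6, 1e6), 0.03125)
  # equal-size reduction: lower tail of (5,0) is 1/64, doubled
  expect_equal(audic_claverie_p(5, 0, 1e6, 1e6, sided = "less"), 1 / 64)
})

test_that("swapping libraries and counts gives complementary lower tails", {
  # P(X <= x | y; n2, n1) = P(Y > y | x; n1, n2): the swapped lower tails
  # sum exactly to one; the inclusive two-sided values then agree up to
  # the shared boundary-point mass
  set.seed(41)
  for (i in 1:100) {
    x <- sample(0:80, 1); y <- sample(0:80, 1)
    n1 <- runif(1, 1e5, 1e7); n2 <- runif(1, 1e5, 1e7)
    expect_equal(audic_claverie_p(x, y, n1, n2, sided = "less") +
                   audic_claverie_p(y, x, n2, n1, sided = "less"),
                 1, tolerance = 1e-10)
    p_xy <- audic_claverie_p(x, y, n1, n2)
    p_yx <- audic_claverie_p(y, x, n2, n1)
    boundary <- 2 * max(exp(tfcobind:::ac_log_pmf(y, x, n2 / n1)),
                        exp(tfcobind:::ac_log_pmf(x, y, n1 / n2)))
    expect_lte(abs(p_xy - p_yx), boundary + 1e-10)
  }
})

test_that("the conditional posterior sums to one", {
  set.seed(42)
  for (i in 1:20) {
    x <- sample(0:200, 1)
    r <- runif(1, 0.2, 5)
    k <- 0:(20 * (x + 10))
    total <- sum(exp(tfcobind:::ac_log_pmf(k, x, r)))
    expect_equal(total, 1, tolerance = 1e-9)
  }
})

test_that("the normal approximation tracks the exact tail at the switch-over", {
  # same inputs through both code paths
  for (y in c(4800, 5000, 5200)) {
    exact <- audic_claverie_p(5000, y, 1e6, 1e6, exact_limit = 1e6)
    approx <- audic_claverie_p(5000, y, 1e6, 1e6, exact_limit = 1)
    expect_equal(approx, exact, tolerance = 0.05)
  }
})

test_that("BH adjustment reproduces the step-up example and validates input", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  perm <- c(3, 1, 4, 2)
  p <- c(0.001, 0.03, 0.2, 0.9)
  expect_equal(bh_adjust(p)[perm], bh_adjust(p[perm]))
  expect_error(bh_adjust(c(0.1, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.1, 1.5)), "\\(0, 1\\]")
})

test_that("contrast applies the 1.5-fold and FDR gates on normalized means", {
  set.seed(51)
  n <- 200
  base <- rpois(n, 5000) + 1000L
  counts <- cbind(
    matrix(rep(base, 3), ncol = 3) + matrix(rpois(3 * n, 20), ncol = 3),
    matrix(rep(base, 3), ncol = 3) + matrix(rpois(3 * n, 20), ncol = 3)
  )
  counts[1, 4:6] <- as.integer(base[1] * 1.6)  # clear up at FC 1.6
  counts[2, 4:6] <- as.integer(base[2] * 1.4)  # below the 1.5 gate
  counts[3, 4:6] <- as.integer(base[3] / 1.6)  # clear down
  storage.mode(counts) <- "integer"
  rownames(counts) <- sprintf("g%03d", 1:n)
  colnames(counts) <- sprintf("s%d", 1:6)
  cm <- mk_cm(counts, rep("control", 6), rep(c("untreated", "tnf"), each = 3))
  de <- contrast(cm, list(treatment = "untreated"), list(treatment = "tnf"))
  expect_equal(de$direction[1], "up")
  expect_equal(de$direction[2], "unchanged")
  expect_equal(de$direction[3], "down")
  expect_true(all(de$q >= de$p - 1e-12 | de$q == de$q))  # q in (0,1]
  expect_true(all(de$q > 0 & de$q <= 1))
  expect_error(contrast(cm, list(treatment = "untreated"), list(treatment = "none")),
               "empty")
  expect_error(contrast(cm, 1:3, 3:6), "disjoint")
})

test_that("zero pooled counts take the flagged pseudocount ratio", {
  counts <- matrix(c(0L, 50L, 100L, 60L), 2,
                   dimnames = list(c("gz", "gn"), c("s1", "s2")))
  cm <- mk_cm(counts, c("control", "control"), c("untreated", "tnf"))
  de <- contrast(cm, list(treatment = "untreated"), list(treatment = "tnf"))
  expect_true(de$pseudocount[de$gene_id == "gz"])
  expect_false(de$pseudocount[de$gene_id == "gn"])
  expect_true(is.finite(de$fold_change[1]))
})

test_that("response/dependence classification follows the truth table", {
  mk_de <- function(dirs) data.frame(gene_id = sprintf("g%d", seq_along(dirs)),
                                     direction = dirs, stringsAsFactors = FALSE)
  ctl <- mk_de(c("up", "up", "up", "down", "unchanged"))
  ko <- mk_de(c("unchanged", "down", "up", "down", "up"))
  lab <- classify_response(ctl, ko)
  expect_equal(lab$tnf_response, c("up", "up", "up", "down", "none"))
  expect_equal(lab$soxc_dependence,
               c("dependent_unchanged", "dependent_reversed", "independent",
                 "independent", "not_applicable"))
  expect_equal(attr(lab, "dependent_fraction"), 0.5)
  expect_error(classify_response(ctl, mk_de(c("up", "up"))), "universes")
})

test_that("planted responsive genes are recovered from NB counts", {
  cfg <- sim_config(seed = 3, counts = list(n_genes = 600, n_responsive = 60,
                                            nb_dispersion = 0.02,
                                            depth_per_sample = 3e5))
  sim <- simulate_counts(cfg)
  de <- contrast(sim$cm, list(genotype = "control", treatment = "untreated"),
                 list(genotype = "control", treatment = "tnf"))
  truth <- sim$truth
  called <- de$direction[match(truth$gene_id, de$gene_id)]
  resp <- truth$response != "none"
  expect_gte(mean(called[resp] == truth$response[resp]), 0.9)
  # false-call rate on null genes stays low
  expect_lte(mean(called[!resp] != "unchanged"), 0.05)
})
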