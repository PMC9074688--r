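# Summit-based feature classification and peak-to-gene assignment.

test_that("summits classify by position relative to gene structure", {
  genes <- mk_genes(
    mk_gene("gA", "chr1", 100000, 110000, "+",
            exons = cbind(c(100000L, 104000L, 108000L),
                          c(101000L, 105000L, 110000L)),
            cds = c(100300, 109000), utr3 = c(109000, 110000))
  )
  # 10 kb 5' of the + strand TSS: upstream, signed distance -10 kb
  up <- classify_peak(mk_peaks("chr1", 90000), genes)
  expect_equal(up$category, "upstream")
  expect_equal(up$genes, "gA")
  expect_equal(up$tss_distance, -10000L)
  # inside the second intron
  expect_equal(classify_peak(mk_peaks("chr1", 102500), genes)$category, "intron")
  # exonic positions: CDS, 5' UTR, 3' UTR
  expect_equal(classify_peak(mk_peaks("chr1", 104500), genes)$category, "cds")
  expect_equal(classify_peak(mk_peaks("chr1", 100100), genes)$category, "five_utr")
  expect_equal(classify_peak(mk_peaks("chr1", 109500), genes)$category, "three_utr")
  # 60 kb from the TSS, outside every window: intergenic with no gene
  far <- classify_peak(mk_peaks("chr1", 40000), genes)
  expect_equal(far$category, "intergenic")
  expect_length(far$genes, 0)
})

test_that("every peak gets exactly one category and counts partition", {
  set.seed(11)
  genes <- mk_genes(
    mk_gene("g1", "chr1", 200000, 210000, "+"),
    mk_gene("g2", "chr1", 500000, 520000, "-"),
    mk_gene("g3", "chr2", 100000, 105000, "+")
  )
  peaks <- mk_peaks(sample(c("chr1", "chr2"), 300, TRUE),
                    sample.int(8e5, 300))
  ann <- annotate_peaks(peaks, genes)
  expect_equal(nrow(ann), 300)
  expect_true(all(ann$category %in% tfcobind:::PEAK_CATEGORIES))
  expect_equal(sum(table(ann$category)), 300)
  # intergenic <=> no genes
  expect_identical(ann$category == "intergenic", ann$genes == "")
})

test_that("feature distribution sums to 100 and matches direct tallies", {
  ann <- data.frame(category = rep(c("upstream", "intron", "intergenic"),
                                   c(6, 2, 2)))
  d <- feature_distribution(ann)
  expect_equal(unname(d["upstream"]), 60)
  expect_equal(unname(d["intron"]), 20)
  expect_equal(unname(d["intergenic"]), 20)
  expect_equal(sum(d), 100, tolerance = 1e-9)
  expect_equal(sum(feature_distribution(data.frame(category = rep("cds", 5)))), 100)
  expect_error(feature_distribution(data.frame(category = character())), "empty")
})

test_that("planted category proportions are recovered from placed summits", {
  # one + strand gene with known structure; summits planted per category
  genes <- mk_gene("g", "chr1", 1000000, 1010000, "+",
                   exons = cbind(c(1000000L, 1008000L),
                                 c(1002000L, 1010000L)),
                   cds = c(1000200, 1009500), utr3 = c(1009500, 1010000))
  probs <- c(upstream = 0.55, intron = 0.20, three_utr = 0.05, intergenic = 0.20)
  set.seed(99)
  n <- 2000
  planted <- sample(names(probs), n, TRUE, prob = probs)
  pos <- vapply(planted, function(cat) switch(cat,
    upstream = 1000000L - sample.int(49000L, 1L),
    intron = 1002000L + sample.int(5999L, 1L),
    three_utr = 1009500L + sample.int(499L, 1L),
    intergenic = 1000000L - 50000L - sample.int(100000L, 1L)), 1L)
  ann <- annotate_peaks(mk_peaks("chr1", pos), genes)
  got <- feature_distribution(ann)
  want <- 100 * table(factor(planted, levels = tfcobind:::PEAK_CATEGORIES)) / n
  expect_equal(as.numeric(got), as.numeric(want))  # exact: same tally
  # and the tally itself sits within binomial range of the planted rates
  expect_lt(max(abs(got[names(probs)] - 100 * probs)), 2)
})

test_that("peak-to-gene assignment matches a brute-force window scan", {
  set.seed(7)
  pad <- 50000L
  for (rep in 1:10) {
    n_genes <- sample(5:30, 1)
    starts <- sort(sample.int(3e6, n_genes))
    genes <- do.call(rbind, lapply(seq_len(n_genes), function(i) {
      mk_gene(sprintf("g%02d", i), "chr1", starts[i], starts[i] + 5000,
              sample(c("+", "-"), 1))
    }))
    peaks <- mk_peaks("chr1", sample.int(3.2e6, 150))
    map <- assign_peaks_to_genes(peaks, genes)
    # oracle: all-pairs scan (assignment window is body +/- pad)
    for (i in seq_len(n_genes)) {
      want <- which(peaks$summit >= genes$start[i] - pad &
                      peaks$summit < genes$end[i] + pad)
      got <- map[[genes$gene_id[i]]]
      expect_equal(sort(if (is.null(got)) integer() else got), want)
    }
  }
})

test_that("a shared upstream window assigns one peak to both divergent genes", {
  genes <- mk_genes(
    mk_gene("left", "chr1", 100000, 110000, "-"),   # TSS at 110000
    mk_gene("right", "chr1", 140000, 150000, "+")   # TSS at 140000
  )
  map <- assign_peaks_to_genes(mk_peaks("chr1", 125000), genes)
  expect_setequal(names(map), c("left", "right"))
  # intronic peak only in its gene; intergenic peak absent
  map2 <- assign_peaks_to_genes(mk_peaks("chr1", c(105000, 3000000)), genes)
  expect_equal(map2, list(left = 1L, right = 1L))
})

test_that("widening the upstream pad never loses upstream assignments", {
  set.seed(21)
  genes <- do.call(rbind, lapply(1:10, function(i) {
    mk_gene(sprintf("g%d", i), "chr1", i * 3e5, i * 3e5 + 8000,
            sample(c("+", "-"), 1))
  }))
  peaks <- mk_peaks("chr1", sample.int(3.3e6, 400))
  n_up <- vapply(c(10000L, 30000L, 50000L, 80000L), function(pad) {
    ann <- annotate_peaks(peaks, genes, annotation_params(upstream_pad = pad))
    sum(ann$category == "upstream")
  }, 1L)
  expect_true(all(diff(n_up) >= 0))
})

test_that("condition comparison counts gained/lost/persistent peaks", {
  a <- mk_peaks("chr1", seq(10000, by = 10000, length.out = 100))
  b <- mk_peaks("chr1", seq(5000, by = 5000, length.out = 300))
  cmp <- compare_conditions(a, b)
  expect_equal(cmp$fold_change, 3.0)

  same <- compare_conditions(a, a)
  expect_equal(same$fold_change, 1.0)
  expect_length(same$gained, 0)
  expect_length(same$lost, 0)

  # 1 bp overlap at the boundary counts as persistent
  x <- mk_intervals("chr1", 100, 200); x$summit <- 150L; x$name <- "a"
  y <- mk_intervals("chr1", 199, 300); y$summit <- 250L; y$name <- "b"
  cmp2 <- compare_conditions(x, y)
  expect_equal(nrow(cmp2$persistent), 1)
  y2 <- mk_intervals("chr1", 200, 300); y2$summit <- 250L; y2$name <- "b"
  expect_equal(nrow(compare_conditions(x, y2)$persistent), 0)

  expect_message(cmp0 <- compare_conditions(a[0, ], b), "undefined")
  expect_true(is.na(cmp0$fold_change))
})
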