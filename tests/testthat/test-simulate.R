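# Generator determinism, invariants, and planted-truth consistency.

test_that("the generator is deterministic under the seed and varies across seeds", {
  cfg <- sim_config(seed = 11, n_genes = 40, n_peaks_induced = 60,
                    counts = list(n_genes = 100, n_responsive = 20))
  g1 <- simulate_gene_models(cfg)
  g2 <- simulate_gene_models(cfg)
  expect_identical(g1, g2)
  p1 <- simulate_peak_sets(cfg, g1)
  p2 <- simulate_peak_sets(cfg, g1)
  expect_identical(p1, p2)
  c1 <- simulate_counts(cfg)
  c2 <- simulate_counts(cfg)
  expect_identical(c1$cm$counts, c2$cm$counts)

  cfg2 <- sim_config(seed = 12, n_genes = 40, n_peaks_induced = 60,
                     counts = list(n_genes = 100, n_responsive = 20))
  expect_false(identical(simulate_gene_models(cfg2), g1))
  expect_false(identical(simulate_counts(cfg2)$cm$counts, c1$cm$counts))
})

test_that("simulated gene models satisfy the model invariants", {
  genes <- simulate_gene_models(sim_config(seed = 2, n_genes = 80))
  expect_equal(nrow(genes), 80)
  expect_equal(sum(genes$autoregulated), 2)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    ex <- g$exons[[1]]
    expect_true(all(ex[, 1] >= g$start & ex[, 2] <= g$end))
    expect_true(all(ex[, 1] < ex[, 2]))
    if (nrow(ex) > 1) expect_true(all(ex[-1, 1] >= ex[-nrow(ex), 2]))
    expect_equal(g$tss, if (g$strand == "+") g$start else g$end)
    expect_true(g$utr3_start >= g$start && g$utr3_end <= g$end)
    # the 3' UTR sits on the strand-appropriate terminal side of the CDS
    if (g$strand == "+") expect_gte(g$utr3_start, g$cds_end)
    else expect_lte(g$utr3_end, g$cds_start)
  }
  expect_equal(nrow(simulate_gene_models(sim_config(seed = 2, n_genes = 0))), 0)
  expect_error(simulate_gene_models(sim_config(seed = 1, chrom_length = 1e6)),
               "too small")
})

test_that("peak sets realize the planted grouping, fold and switch structure", {
  cfg <- sim_config(seed = 7)
  genes <- simulate_gene_models(cfg)
  ps <- simulate_peak_sets(cfg, genes)
  grp <- group_summits(ps$peaks$SOX4$tnf, ps$peaks$RELA$tnf)
  man <- ps$manifest
  expect_equal(grp$summary$n_group1, man$n_cobound_planted)
  expect_equal(grp$summary$fraction_a_cobound,
               man$n_cobound_planted / man$n_a_induced)
  # per-peak recovery matches the manifest exactly (jitter-free default)
  asn <- grp$assignments
  got <- asn$group[asn$set == "a"] == "group1_cobound"
  expect_identical(got, man$a_induced_groups$group == "cobound")

  for (fac in c("SOX4", "RELA")) {
    cmp <- compare_conditions(ps$peaks[[fac]]$untreated, ps$peaks[[fac]]$tnf)
    expect_equal(cmp$fold_change, cfg$induced_fold, tolerance = 0.01)
  }

  calls <- detect_switch(ps$peaks$RELA, ps$peaks$SOX4)
  expect_equal(nrow(calls), cfg$n_switch_loci)
  ann <- annotate_switches(calls, genes)
  expect_setequal(ann$gene_id, man$switch_loci$gene_id)
  expect_true(all(ann$in_utr3))
})

test_that("planted fold changes are recovered in the deep low-noise limit", {
  cfg <- sim_config(seed = 5, counts = list(n_genes = 200, n_responsive = 40,
                                            nb_dispersion = 0,
                                            baseline_sdlog = 0.5,
                                            depth_per_sample = 1e8))
  sim <- simulate_counts(cfg)
  de <- contrast(sim$cm, list(genotype = "control", treatment = "untreated"),
                 list(genotype = "control", treatment = "tnf"))
  truth <- sim$truth
  resp <- which(truth$response != "none")
  planted <- ifelse(truth$response[resp] == "down",
                    1 / truth$fc[resp], truth$fc[resp])
  got <- de$fold_change[match(truth$gene_id[resp], de$gene_id)]
  expect_lt(max(abs(got / planted - 1)), 0.01)
})

test_that("full dependence planting drives the response labels", {
  cfg <- sim_config(seed = 6, counts = list(n_genes = 400, n_responsive = 80,
                                            fraction_dependent = 1,
                                            fraction_reversed = 0,
                                            nb_dispersion = 0.005))
  sim <- simulate_counts(cfg)
  ctl <- contrast(sim$cm, list(genotype = "control", treatment = "untreated"),
                  list(genotype = "control", treatment = "tnf"))
  ko <- contrast(sim$cm, list(genotype = "soxc_ko", treatment = "untreated"),
                 list(genotype = "soxc_ko", treatment = "tnf"))
  lab <- classify_response(ctl, ko)
  resp <- lab$tnf_response != "none"
  expect_gte(dependent_fraction(lab), 0.95)
})

test_that("peak sequences carry the planted motif instances at recorded offsets", {
  cfg <- sim_config(seed = 9, n_genes = 40, n_peaks_induced = 40)
  genes <- simulate_gene_models(cfg)
  ps <- simulate_peak_sets(cfg, genes)
  a <- ps$peaks$SOX4$tnf
  sq <- simulate_peak_sequences(cfg, a, ps$manifest$a_induced_groups$group)
  m <- motif_model("planted", consensus = cfg$motif$consensus)
  w <- nchar(cfg$motif$consensus)
  planted <- which(sq$truth$planted)
  expect_equal(sq$truth$name[planted],
               ps$manifest$a_induced_groups$name[
                 ps$manifest$a_induced_groups$group == "cobound"])
  for (i in planted) {
    hits <- scan_consensus(sq$seqs[[i]], m)
    key <- paste(hits$offset, hits$strand)
    expect_true(paste(sq$truth$offset[i], sq$truth$strand[i]) %in% key)
  }
})

test_that("a study round-trips through disk as plain-text inputs", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(seed = 13, n_genes = 60, n_peaks_induced = 80,
                    counts = list(nb_dispersion = 0.01),
                    classes = list(c1 = 3, c2 = 3, c3 = 5, n_independent = 5))
  st <- simulate_study(cfg)
  write_study(st, dir)
  res <- run_pipeline(
    file.path(dir, "SOX4_untreated.narrowPeak"),
    file.path(dir, "SOX4_tnf.narrowPeak"),
    file.path(dir, "RELA_untreated.narrowPeak"),
    file.path(dir, "RELA_tnf.narrowPeak"),
    file.path(dir, "genes.bed12"),
    file.path(dir, "counts.tsv"), file.path(dir, "samples.tsv")
  )
  expect_s3_class(res$report, "integration_report")
  # reading back the peak files reproduces the in-memory sets
  back <- read_peaks(file.path(dir, "SOX4_tnf.narrowPeak"), "narrowPeak",
                     "SOX4", "tnf")
  expect_equal(back$summit, st$peaks$SOX4$tnf$summit)
  expect_equal(back$start, st$peaks$SOX4$tnf$start)
  genes_back <- read_gene_models(file.path(dir, "genes.bed12"), "bed12")
  expect_equal(genes_back$tss, st$genes$tss)
  expect_equal(genes_back$utr3_start, st$genes$utr3_start)
  expect_error(run_pipeline("nope.narrowPeak",
                            file.path(dir, "SOX4_tnf.narrowPeak"),
                            file.path(dir, "RELA_untreated.narrowPeak"),
                            file.path(dir, "RELA_tnf.narrowPeak"),
                            file.path(dir, "genes.bed12"),
                            file.path(dir, "counts.tsv"),
                            file.path(dir, "samples.tsv")),
               "missing input")
})
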