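# End-to-end orchestration: grouping -> annotation -> switch detection
# -> differential expression -> class assignment -> report.

#' Run the full integration on in-memory objects
#'
#' Factor A is the perspective of the co-binding fraction (the factor
#' whose summits are asked to lie near factor B's); the binding switch
#' is scanned in the opposite direction (factor B bound at baseline,
#' factor A gaining upon induction), matching an autoregulatory
#' switch from a constitutive factor to the induced one.
#'
#' @param peaks Nested list `factor -> condition -> peak table`.
#' @param genes Gene model table.
#' @param cm A `count_matrix` covering genotypes control/soxc_ko and
#'   treatments untreated/tnf.
#' @param factor_a,factor_b Names of the two factors in `peaks`
#'   (defaults `"SOX4"`, `"RELA"`).
#' @param basal,induced Condition labels (defaults `"untreated"`,
#'   `"tnf"`).
#' @param cobind [cobind_params()].
#' @param annotation [annotation_params()].
#' @param de [de_params()].
#' @return List with `report` (see [build_report()]) and every
#'   intermediate stage: `cobinding`, `comparisons`, `annotations`,
#'   `switches`, `de_control`, `de_ko`, `response`, `classes`.
#' @export
run_integration <- function(peaks, genes, cm,
                            factor_a = "SOX4", factor_b = "RELA",
                            basal = "untreated", induced = "tnf",
                            cobind = cobind_params(),
                            annotation = annotation_params(),
                            de = de_params()) {
  for (fac in c(factor_a, factor_b)) {
    for (cond in c(basal, induced)) {
      if (is.null(peaks[[fac]][[cond]])) {
        stop(sprintf("missing peak set: factor '%s', condition '%s'", fac, cond))
      }
    }
  }
  a1 <- peaks[[factor_a]][[induced]]
  b1 <- peaks[[factor_b]][[induced]]
  grouping <- group_summits(a1, b1, cobind)
  comparisons <- setNames(list(
    compare_conditions(peaks[[factor_a]][[basal]], a1),
    compare_conditions(peaks[[factor_b]][[basal]], b1)
  ), c(factor_a, factor_b))

  # combined induced peak table: A rows first, then B rows
  combined <- rbind(a1, b1)
  asn <- grouping$assignments
  a_groups <- asn$group[asn$set == "a"][order(asn$idx[asn$set == "a"])]
  b_groups <- rep("cobound_partner", nrow(b1))
  b_groups[asn$idx[asn$set == "b"]] <- "group3_b_only"
  peak_groups <- c(a_groups, b_groups)
  gene_peak_map <- assign_peaks_to_genes(combined, genes, annotation)
  annotations <- annotate_peaks(combined, genes, annotation)

  switches <- detect_switch(peaks[[factor_b]], peaks[[factor_a]],
                            basal = basal, induced = induced)
  switches <- annotate_switches(switches, genes, annotation)

  de_control <- contrast(cm,
                         list(genotype = "control", treatment = "untreated"),
                         list(genotype = "control", treatment = "tnf"), de)
  de_ko <- contrast(cm,
                    list(genotype = "soxc_ko", treatment = "untreated"),
                    list(genotype = "soxc_ko", treatment = "tnf"), de)
  response <- classify_response(de_control, de_ko, de)

  classes <- assign_reg_classes(response, gene_peak_map, peak_groups,
                                switch_genes = switches$gene_id[!is.na(switches$gene_id)])
  report <- build_report(grouping$summary, classes, response, cm,
                         comparisons = comparisons, switches = switches)
  list(report = report, cobinding = grouping, comparisons = comparisons,
       annotations = annotations, switches = switches,
       de_control = de_control, de_ko = de_ko, response = response,
       classes = classes)
}

#' Run the pipeline from files on disk
#'
#' Thin wrapper over [run_integration()] reading the standard formats:
#' four narrowPeak files (two factors x two conditions), a BED12 gene
#' annotation, and count/metadata TSVs. Results are written to
#' `out_dir` when given.
#'
#' @param peaks_a_basal,peaks_a_induced,peaks_b_basal,peaks_b_induced
#'   narrowPeak paths for factors A and B.
#' @param genes_path BED12 gene models.
#' @param counts_path,samples_path Count matrix and sample sheet TSVs.
#' @param out_dir Optional output directory for [write_report()].
#' @param ... Passed to [run_integration()] (factor/condition labels and
#'   parameter objects).
#' @return The [run_integration()] result list.
#' @export
run_pipeline <- function(peaks_a_basal, peaks_a_induced,
                         peaks_b_basal, peaks_b_induced,
                         genes_path, counts_path, samples_path,
                         out_dir = NULL,
                         factor_a = "SOX4", factor_b = "RELA",
                         basal = "untreated", induced = "tnf", ...) {
  paths <- c(peaks_a_basal, peaks_a_induced, peaks_b_basal, peaks_b_induced,
             genes_path, counts_path, samples_path)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("missing input file(s): ", paste(missing, collapse = ", "))
  }
  peaks <- list()
  peaks[[factor_a]] <- setNames(list(
    read_peaks(peaks_a_basal, "narrowPeak", factor_a, basal),
    read_peaks(peaks_a_induced, "narrowPeak", factor_a, induced)
  ), c(basal, induced))
  peaks[[factor_b]] <- setNames(list(
    read_peaks(peaks_b_basal, "narrowPeak", factor_b, basal),
    read_peaks(peaks_b_induced, "narrowPeak", factor_b, induced)
  ), c(basal, induced))
  genes <- read_gene_models(genes_path, "bed12")
  cm <- read_count_matrix(counts_path, samples_path)
  res <- run_integration(peaks, genes, cm, factor_a = factor_a,
                         factor_b = factor_b, basal = basal,
                         induced = induced, ...)
  if (!is.null(out_dir)) write_report(res$report, res$classes, out_dir)
  res
}
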