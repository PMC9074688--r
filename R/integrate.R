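# Join ChIP grouping, switch calls and DE labels into the Class 1-4
# regulatory-mode assignment and the summary report.
#
# Class 1: co-bound direct targets (>= 1 co-bound peak assigned, and a
#   genotype-dependent treatment response).
# Class 2: factor-B-only direct targets (>= 1 B-only peak, no co-bound
#   peak, dependent response).
# Class 3: indirect targets (dependent response, no assigned peak of
#   either factor).
# Class 4: binding-switch genes; a switch call alone suffices - switch
#   genes typically keep flat expression (the switch maintains, rather
#   than changes, their output), so class 4 is exempt from the
#   dependence filter and takes precedence.

REG_CLASSES <- c("class1_cobound_direct", "class2_rela_only",
                 "class3_indirect", "class4_switch", "unclassified")

#' Regulatory-mode call for one gene
#'
#' @param gene_id Gene identifier.
#' @param peak_idx Integer indices (into the combined peak table) of
#'   peaks assigned to the gene.
#' @param peak_groups Character vector parallel to the combined peak
#'   table: `"group1_cobound"`, `"group2_a_only"`, `"group3_b_only"` or
#'   `"cobound_partner"` (a factor-B peak that partners a co-bound A
#'   peak).
#' @param switch_genes Character vector of gene ids carrying a switch
#'   call.
#' @param response One-row slice of [classify_response()] output for the
#'   gene.
#' @return List with `gene_id`, `reg_class`, `reason` and evidence
#'   counts.
#' @export
assign_reg_class <- function(gene_id, peak_idx, peak_groups, switch_genes,
                             response) {
  if (NROW(response) != 1L) {
    stop(sprintf("gene '%s' missing from response labels", gene_id))
  }
  g <- peak_groups[peak_idx]
  n_cobound <- sum(g == "group1_cobound")
  n_a_only <- sum(g == "group2_a_only")
  n_b_only <- sum(g == "group3_b_only")
  dependent <- response$soxc_dependence %in%
    c("dependent_unchanged", "dependent_reversed")
  has_switch <- gene_id %in% switch_genes
  if (has_switch) {
    cls <- "class4_switch"; reason <- "binding switch at locus"
  } else if (!dependent) {
    cls <- "unclassified"
    reason <- if (response$tnf_response == "none") "not treatment-responsive"
              else "treatment response is genotype-independent"
  } else if (n_cobound > 0) {
    cls <- "class1_cobound_direct"; reason <- "co-bound peak assigned"
  } else if (n_b_only > 0) {
    cls <- "class2_rela_only"; reason <- "factor-B-only peak assigned"
  } else if (length(peak_idx) == 0L) {
    cls <- "class3_indirect"; reason <- "dependent with no assigned peak"
  } else {
    cls <- "unclassified"
    reason <- "dependent with only factor-A-only peaks"
  }
  list(gene_id = gene_id, reg_class = cls, reason = reason,
       n_cobound_peaks = n_cobound, n_a_only_peaks = n_a_only,
       n_b_only_peaks = n_b_only, n_assigned_peaks = length(peak_idx),
       has_switch = has_switch,
       tnf_response = response$tnf_response,
       soxc_dependence = response$soxc_dependence)
}

#' Regulatory-mode calls for a gene universe
#'
#' @param response Output of [classify_response()] (defines the gene
#'   universe).
#' @param gene_peak_map Named list gene_id -> indices into the combined
#'   peak table (see [assign_peaks_to_genes()]).
#' @param peak_groups Group label per combined peak (see
#'   [assign_reg_class()]).
#' @param switch_genes Gene ids with annotated switch calls.
#' @return `data.frame`, one row per gene, with class, reason and
#'   evidence counts.
#' @export
assign_reg_classes <- function(response, gene_peak_map, peak_groups,
                               switch_genes = character()) {
  rows <- lapply(seq_len(nrow(response)), function(i) {
    gid <- response$gene_id[i]
    idx <- gene_peak_map[[gid]]
    if (is.null(idx)) idx <- integer()
    as.data.frame(assign_reg_class(gid, idx, peak_groups, switch_genes,
                                   response[i, ]),
                  stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Build the integration report
#'
#' Deterministic summary of a full run: co-binding Venn counts, response
#' and dependence tallies, class counts with per-class gene lists, and a
#' matrix of group-mean normalized expression per genotype x treatment
#' for the classified genes.
#'
#' @param cobind_summary `summary` element of [group_summits()].
#' @param classes Output of [assign_reg_classes()].
#' @param response Output of [classify_response()].
#' @param cm The `count_matrix` used for the contrasts.
#' @param comparisons Optional named list of [compare_conditions()]
#'   results (per factor).
#' @param switches Optional annotated switch-call table.
#' @return An `integration_report` list.
#' @export
build_report <- function(cobind_summary, classes, response, cm,
                         comparisons = NULL, switches = NULL) {
  if (!setequal(classes$gene_id, response$gene_id)) {
    stop("gene universes differ between class calls and response labels: ",
         paste(head(c(setdiff(classes$gene_id, response$gene_id),
                      setdiff(response$gene_id, classes$gene_id))),
               collapse = ", "))
  }
  class_counts <- table(factor(classes$reg_class, levels = REG_CLASSES))
  class_genes <- lapply(setNames(REG_CLASSES, REG_CLASSES), function(cl) {
    sort(classes$gene_id[classes$reg_class == cl])
  })
  classified <- unlist(class_genes[setdiff(REG_CLASSES, "unclassified")],
                       use.names = FALSE)
  sf <- size_factors(cm)
  norm <- sweep(cm$counts, 2, sf, "/")
  grp <- interaction(cm$samples$genotype, cm$samples$treatment, sep = ".")
  expr <- if (length(classified)) {
    t(apply(norm[classified, , drop = FALSE], 1,
            function(v) tapply(v, grp, mean)))
  } else {
    matrix(numeric(), 0, nlevels(grp), dimnames = list(NULL, levels(grp)))
  }
  structure(list(
    venn_counts = list(group1 = cobind_summary$n_group1,
                       group2 = cobind_summary$n_group2,
                       group3 = cobind_summary$n_group3),
    fraction_a_cobound = cobind_summary$fraction_a_cobound,
    fraction_b_cobound = cobind_summary$fraction_b_cobound,
    n_tnf_responsive = sum(response$tnf_response != "none"),
    n_soxc_dependent = sum(response$soxc_dependence %in%
                             c("dependent_unchanged", "dependent_reversed")),
    dependent_fraction = dependent_fraction(response),
    n_switch_calls = if (is.null(switches)) 0L else nrow(switches),
    peak_fold_changes = if (is.null(comparisons)) NULL else
      lapply(comparisons, `[[`, "fold_change"),
    class_counts = as.list(class_counts),
    class_genes = class_genes,
    expression_matrix = expr
  ), class = "integration_report")
}

#' @export
print.integration_report <- function(x, ...) {
  cat("integration_report\n")
  cat(sprintf("  co-binding: %d co-bound / %d A-only / %d B-only (fraction A co-bound %.3f)\n",
              x$venn_counts$group1, x$venn_counts$group2, x$venn_counts$group3,
              x$fraction_a_cobound))
  cat(sprintf("  responsive genes: %d; dependent: %d (fraction %.3f)\n",
              x$n_tnf_responsive, x$n_soxc_dependent, x$dependent_fraction))
  cat("  class counts:",
      paste(sprintf("%s=%d", names(x$class_counts), unlist(x$class_counts)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Write an integration report to disk
#'
#' Emits `report.json` (everything except the expression matrix, which
#' goes to `expression.tsv`), `classes.tsv` and `venn.tsv`. Output is
#' byte-identical across reruns on identical inputs.
#'
#' @param report An `integration_report`.
#' @param classes The class table from [assign_reg_classes()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, classes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json_part <- report[setdiff(names(report), "expression_matrix")]
  jsonlite::write_json(json_part, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  write.table(classes, file.path(dir, "classes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  venn <- data.frame(group = names(report$venn_counts),
                     n = unlist(report$venn_counts))
  write.table(venn, file.path(dir, "venn.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  em <- report$expression_matrix
  write.table(data.frame(gene_id = rownames(em), em, check.names = FALSE),
              file.path(dir, "expression.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(dir)
}
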