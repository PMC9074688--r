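# Peak-to-gene annotation with an upstream padding window, genomic
# feature classification of peak summits, and condition comparison.

#' Annotation parameters
#'
#' @param upstream_pad Width in bp of the strand-aware padding window
#'   around gene bodies used both for the `upstream`/`downstream`
#'   categories and for peak-to-gene assignment. Default 50000 bp.
#' @param feature_priority Order in which feature categories win when a
#'   summit falls in features of several genes. More specific (exonic)
#'   features outrank positional ones.
#' @param merge_downstream If TRUE, report `downstream` summits as
#'   `intergenic` (some annotation schemes do not use a downstream
#'   category).
#' @export
annotation_params <- function(upstream_pad = 50000L,
                              feature_priority = c("five_utr", "cds", "three_utr",
                                                   "intron", "upstream",
                                                   "downstream", "intergenic"),
                              merge_downstream = FALSE) {
  stopifnot(upstream_pad > 0)
  structure(list(upstream_pad = as.integer(upstream_pad),
                 feature_priority = feature_priority,
                 merge_downstream = isTRUE(merge_downstream)),
            class = "annotation_params")
}

PEAK_CATEGORIES <- c("upstream", "five_utr", "cds", "intron", "three_utr",
                     "downstream", "intergenic")

# Feature of a summit relative to one gene, or NA when outside the
# gene body and both padding windows. Strand-aware throughout.
feature_for_gene <- function(summit, gene, pad) {
  s <- summit
  if (s >= gene$start && s < gene$end) {
    if (!is.na(gene$utr3_start) && s >= gene$utr3_start && s < gene$utr3_end) {
      return("three_utr")
    }
    ex <- gene$exons[[1]]
    in_exon <- any(s >= ex[, 1] & s < ex[, 2])
    if (!in_exon) return("intron")
    if (!is.na(gene$cds_start)) {
      if (s >= gene$cds_start && s < gene$cds_end) return("cds")
      five_side <- if (gene$strand == "+") s < gene$cds_start else s >= gene$cds_end
      return(if (five_side) "five_utr" else "three_utr")
    }
    return("five_utr")  # non-coding exon: counted with the 5' UTR class
  }
  before <- s < gene$start && s >= gene$start - pad
  after <- s >= gene$end && s < gene$end + pad
  if (gene$strand == "+") {
    if (before) return("upstream")
    if (after) return("downstream")
  } else {
    if (after) return("upstream")
    if (before) return("downstream")
  }
  NA_character_
}

tss_distance_for <- function(summit, gene) {
  if (gene$strand == "+") summit - gene$tss else gene$tss - summit
}

#' Classify one peak against the gene annotation
#'
#' The summit (not the whole interval) decides the category. Summits in a
#' gene body are labeled `five_utr` / `cds` / `three_utr` / `intron`;
#' summits outside every body are `upstream` or `downstream` when within
#' `upstream_pad` of a TSS / gene end on the strand-appropriate side,
#' else `intergenic`. When several genes contribute features,
#' `feature_priority` picks the category and the genes reported are those
#' providing it; `tss_distance` is to the nearest such gene's TSS
#' (negative = upstream of the TSS, strand-aware).
#'
#' @param peak One-row peak table (see [read_peaks()]).
#' @param genes Gene models (see [read_gene_models()]).
#' @param params [annotation_params()].
#' @return A list with `category`, `genes` (character vector, empty for
#'   intergenic) and `tss_distance` (NA for intergenic).
#' @export
classify_peak <- function(peak, genes, params = annotation_params()) {
  ann <- annotate_peaks(peak, genes, params)
  list(category = ann$category[1],
       genes = if (nzchar(ann$genes[1])) strsplit(ann$genes[1], ",")[[1]] else character(),
       tss_distance = ann$tss_distance[1])
}

#' Annotate a peak table
#'
#' Vectorized form of [classify_peak()]; one row per peak.
#'
#' @inheritParams classify_peak
#' @param peaks Peak table.
#' @return `data.frame` with `name`, `category`, `genes` (comma-joined),
#'   `tss_distance`.
#' @export
annotate_peaks <- function(peaks, genes, params = annotation_params()) {
  stopifnot(nrow(genes) > 0)
  pad <- params$upstream_pad
  unknown <- setdiff(unique(peaks$chrom), unique(genes$chrom))
  if (length(unknown)) {
    warning("chromosome(s) absent from gene annotation, peaks there set intergenic: ",
            paste(unknown, collapse = ", "))
  }
  # candidate gene windows: body +/- pad on both sides (strand decides later)
  win <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(genes$start - pad, 0L) + 1L, genes$end + pad)
  )
  hits <- GenomicRanges::findOverlaps(summits_gr(peaks), win)
  cand <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))

  category <- character(nrow(peaks))
  gene_str <- character(nrow(peaks))
  tssd <- rep(NA_integer_, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    gi <- cand[[as.character(i)]]
    if (is.null(gi)) {
      category[i] <- "intergenic"
      next
    }
    feats <- vapply(gi, function(g) feature_for_gene(peaks$summit[i], genes[g, ], pad),
                    NA_character_)
    keep <- !is.na(feats)
    gi <- gi[keep]; feats <- feats[keep]
    if (params$merge_downstream) {
      drop <- feats == "downstream"
      gi <- gi[!drop]; feats <- feats[!drop]
    }
    if (length(gi) == 0L) {
      category[i] <- "intergenic"
      next
    }
    ranks <- match(feats, params$feature_priority)
    best <- min(ranks)
    sel <- gi[ranks == best]
    category[i] <- params$feature_priority[best]
    gene_str[i] <- paste(genes$gene_id[sel], collapse = ",")
    d <- vapply(sel, function(g) tss_distance_for(peaks$summit[i], genes[g, ]), 1L)
    tssd[i] <- d[which.min(abs(d))]
  }
  data.frame(
    name = if (is.null(peaks$name)) sprintf("peak_%d", seq_len(nrow(peaks))) else peaks$name,
    category = category, genes = gene_str, tss_distance = tssd,
    stringsAsFactors = FALSE
  )
}

#' Genome-wide feature distribution of a peak set
#'
#' @param annotations Output of [annotate_peaks()].
#' @return Named numeric vector of percentages over all categories;
#'   sums to 100.
#' @export
feature_distribution <- function(annotations) {
  if (NROW(annotations) == 0L) stop("empty annotation set")
  tab <- table(factor(annotations$category, levels = PEAK_CATEGORIES))
  100 * as.vector(tab) / sum(tab) -> pct
  setNames(pct, PEAK_CATEGORIES)
}

#' Assign peaks to genes through the padding window
#'
#' A peak is assigned to every gene whose body or strand-aware padding
#' window (upstream always; downstream unless `merge_downstream`)
#' contains the peak summit; divergent promoters can therefore claim the
#' same peak for two genes. Genes with no peak are absent from the map.
#'
#' @inheritParams annotate_peaks
#' @return Named list mapping `gene_id` to integer indices into `peaks`.
#' @export
assign_peaks_to_genes <- function(peaks, genes, params = annotation_params()) {
  pad <- params$upstream_pad
  if (nrow(peaks) == 0L) return(structure(list(), names = character()))
  win <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(genes$start - pad, 0L) + 1L, genes$end + pad)
  )
  hits <- GenomicRanges::findOverlaps(summits_gr(peaks), win)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  keep <- vapply(seq_along(q), function(k) {
    !is.na(feature_for_gene(peaks$summit[q[k]], genes[s[k], ], pad))
  }, TRUE)
  if (params$merge_downstream) {
    keep <- keep & vapply(seq_along(q), function(k) {
      !identical(feature_for_gene(peaks$summit[q[k]], genes[s[k], ], pad), "downstream")
    }, TRUE)
  }
  q <- q[keep]; s <- s[keep]
  split(q, genes$gene_id[s])
}

#' Compare a factor's peak sets between two conditions
#'
#' @param peaks_a Peaks in the reference condition (e.g. untreated).
#' @param peaks_b Peaks in the comparison condition (e.g. treated).
#' @param min_overlap Minimum interval overlap in bp for a peak to count
#'   as persistent between conditions (default 1).
#' @return A `condition_comparison` list: `n_a`, `n_b`, `fold_change`
#'   (`n_b / n_a`, NA when `n_a == 0`), `gained` / `lost` (row indices in
#'   b / a), `persistent` (data.frame of index pairs).
#' @export
compare_conditions <- function(peaks_a, peaks_b, min_overlap = 1L) {
  hits <- GenomicRanges::findOverlaps(peaks_gr(peaks_a), peaks_gr(peaks_b),
                                      minoverlap = min_overlap)
  a_hit <- unique(S4Vectors::queryHits(hits))
  b_hit <- unique(S4Vectors::subjectHits(hits))
  fold <- if (nrow(peaks_a) > 0) nrow(peaks_b) / nrow(peaks_a) else NA_real_
  if (is.na(fold)) message("reference condition has no peaks; fold change undefined")
  structure(list(
    n_a = nrow(peaks_a), n_b = nrow(peaks_b), fold_change = fold,
    gained = setdiff(seq_len(nrow(peaks_b)), b_hit),
    lost = setdiff(seq_len(nrow(peaks_a)), a_hit),
    persistent = data.frame(a = S4Vectors::queryHits(hits),
                            b = S4Vectors::subjectHits(hits))
  ), class = "condition_comparison")
}
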