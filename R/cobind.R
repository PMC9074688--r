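# Summit-proximity co-binding classification and binding-switch detection.
#
# Group 1: factor-A peaks whose summit lies within max_summit_distance of
# a factor-B summit (inclusive, same chromosome); Group 2: the remaining
# A peaks; Group 3: B peaks with no A summit within the distance.

#' Co-binding parameters
#'
#' @param max_summit_distance Maximum |summit_a - summit_b| in bp for two
#'   summits to count as co-bound; the threshold is inclusive (a 50 bp
#'   separation is co-bound at the default of 50).
#' @param tie_break Partner choice when two B summits are equidistant:
#'   `"lower_coordinate"` (default) or `"first_listed"` (input order).
#' @export
cobind_params <- function(max_summit_distance = 50L,
                          tie_break = c("lower_coordinate", "first_listed")) {
  stopifnot(max_summit_distance >= 0)
  structure(list(max_summit_distance = as.integer(max_summit_distance),
                 tie_break = match.arg(tie_break)),
            class = "cobind_params")
}

#' Group two factors' peaks by summit proximity
#'
#' Each A peak with at least one B summit within `max_summit_distance`
#' (inclusive, same chromosome) is Group 1, with the nearest B summit as
#' its partner; remaining A peaks are Group 2; B peaks with no A summit
#' within the distance are Group 3. Matching is many-to-one: two A
#' summits may share a B partner. Run with the arguments swapped to get
#' the B-perspective co-bound count (the two fractions need not agree).
#'
#' @param peaks_a,peaks_b Peak tables for the two factors, one condition
#'   each, with summits set.
#' @param params [cobind_params()].
#' @return A list with `assignments` (data.frame: `set` ("a"/"b"),
#'   `idx` (row in the input table), `group`, `partner` (row in the other
#'   table or NA), `distance`) and `summary` (counts,
#'   `fraction_a_cobound = n_group1 / n_a`, and the symmetric
#'   `fraction_b_cobound`).
#' @export
group_summits <- function(peaks_a, peaks_b, params = cobind_params()) {
  if (anyNA(peaks_a$summit) || anyNA(peaks_b$summit)) {
    stop("every peak must carry a summit")
  }
  d <- params$max_summit_distance
  near <- nearest_summit(peaks_a, peaks_b, params$tie_break)
  cobound <- !is.na(near$distance) & near$distance <= d
  a_df <- data.frame(
    set = rep("a", nrow(peaks_a)), idx = seq_len(nrow(peaks_a)),
    group = ifelse(cobound, "group1_cobound", "group2_a_only"),
    partner = ifelse(cobound, near$partner, NA_integer_),
    distance = ifelse(cobound, near$distance, NA_integer_),
    stringsAsFactors = FALSE
  )
  near_b <- nearest_summit(peaks_b, peaks_a, params$tie_break)
  b_only <- is.na(near_b$distance) | near_b$distance > d
  b_df <- data.frame(
    set = rep("b", sum(b_only)), idx = which(b_only),
    group = rep("group3_b_only", sum(b_only)),
    partner = rep(NA_integer_, sum(b_only)),
    distance = rep(NA_integer_, sum(b_only)),
    stringsAsFactors = FALSE
  )
  n_a <- nrow(peaks_a); n_b <- nrow(peaks_b)
  summary <- list(
    n_a = n_a, n_b = n_b,
    n_group1 = sum(cobound), n_group2 = sum(!cobound), n_group3 = sum(b_only),
    fraction_a_cobound = if (n_a > 0) sum(cobound) / n_a else NA_real_,
    fraction_b_cobound = if (n_b > 0) sum(!b_only) / n_b else NA_real_,
    max_summit_distance = d
  )
  list(assignments = rbind(a_df, b_df), summary = summary)
}

# Nearest partner summit per query peak (same chromosome), O(n log n).
# Returns partner row index in `ref` and the absolute distance (NA when
# the chromosome has no ref summit).
nearest_summit <- function(query, ref, tie_break = "lower_coordinate") {
  partner <- rep(NA_integer_, nrow(query))
  distance <- rep(NA_integer_, nrow(query))
  for (chr in unique(query$chrom)) {
    qi <- which(query$chrom == chr)
    ri <- which(ref$chrom == chr)
    if (length(ri) == 0L) next
    ord <- order(ref$summit[ri], ri)  # stable on input order at equal coords
    rs <- ref$summit[ri][ord]
    rid <- ri[ord]
    pos <- query$summit[qi]
    left <- findInterval(pos, rs)
    for (k in seq_along(qi)) {
      lo <- left[k]; hi <- lo + 1L
      d_lo <- if (lo >= 1L) pos[k] - rs[lo] else NA_integer_
      d_hi <- if (hi <= length(rs)) rs[hi] - pos[k] else NA_integer_
      if (is.na(d_hi) || (!is.na(d_lo) && d_lo < d_hi)) {
        pick <- lo; dd <- d_lo
      } else if (is.na(d_lo) || d_hi < d_lo) {
        pick <- hi; dd <- d_hi
      } else {  # tie: lower coordinate is the left candidate
        dd <- d_lo
        pick <- if (tie_break == "lower_coordinate") lo else {
          if (rid[lo] <= rid[hi]) lo else hi
        }
      }
      partner[qi[k]] <- rid[pick]
      distance[qi[k]] <- dd
    }
  }
  list(partner = partner, distance = distance)
}

#' Planted co-binding fraction recovery harness
#'
#' Generates `n` A summits; a planted share receives a B summit within
#' the co-binding threshold (uniform offset in `[0, max_summit_distance]`)
#' and the rest a B summit at least ten thresholds away, then the
#' grouping is re-run. In this noise-free construction the recovered
#' fraction equals `round(planted_fraction * n) / n` exactly.
#'
#' @param n Number of A summits (> 0).
#' @param planted_fraction Share of A summits given a nearby B partner.
#' @param seed Integer seed.
#' @param params [cobind_params()].
#' @return List with `planted` and `recovered` fractions and the
#'   `group_summits()` summary.
#' @export
cobind_fraction_recovery <- function(n, planted_fraction, seed = 1L,
                                     params = cobind_params()) {
  if (n <= 0) stop("n must be positive")
  stopifnot(planted_fraction >= 0, planted_fraction <= 1)
  set.seed(seed)
  d <- params$max_summit_distance
  spacing <- max(1000L, 40L * (d + 1L))
  a_pos <- spacing * seq_len(n)
  k <- round(planted_fraction * n)
  planted <- rep(FALSE, n)
  planted[sample.int(n, k)] <- TRUE
  b_off <- rep(10L * (d + 1L), n)
  b_off[planted] <- sample.int(d + 1L, k, replace = TRUE) - 1L
  mk <- function(pos) data.frame(
    chrom = "chrS", start = pos - 100L, end = pos + 100L,
    name = sprintf("p%d", seq_along(pos)), score = 0, strand = ".",
    summit = pos, factor = NA_character_, condition = NA_character_,
    stringsAsFactors = FALSE
  )
  grp <- group_summits(mk(a_pos), mk(a_pos + b_off), params)
  list(planted = k / n,
       recovered = grp$summary$fraction_a_cobound,
       summary = grp$summary)
}

#' Detect condition-induced binding switches
#'
#' A switch locus is a basal-condition peak of factor A where, upon
#' induction, factor A's binding disappears and factor B's appears at
#' the same genomic region. Presence/absence is interval overlap
#' (>= `min_overlap` bp), not summit distance. For every basal A peak P a
#' call is emitted iff (i) no induced A peak overlaps P, (ii) no basal B
#' peak overlaps P, and (iii) at least one induced B peak overlaps P; the
#' induced B peak with the greatest overlap is recorded.
#'
#' @param factor_a_peaks,factor_b_peaks Named lists of peak tables keyed
#'   by condition label; both must contain `basal` and `induced` keys.
#' @param basal,induced The two condition labels.
#' @param min_overlap Minimum overlap in bp (default 1).
#' @return `data.frame` of switch calls: locus coordinates (the basal A
#'   peak), `basal_a_idx`, `gained_b_idx`, `overlap_bp`, summit of the
#'   basal A peak, and the four evidence booleans.
#' @export
detect_switch <- function(factor_a_peaks, factor_b_peaks,
                          basal = "untreated", induced = "tnf",
                          min_overlap = 1L) {
  for (nm in c(basal, induced)) {
    if (is.null(factor_a_peaks[[nm]]) || is.null(factor_b_peaks[[nm]])) {
      stop(sprintf("missing condition '%s' in peak lists", nm))
    }
  }
  a0 <- factor_a_peaks[[basal]]
  a1 <- factor_a_peaks[[induced]]
  b0 <- factor_b_peaks[[basal]]
  b1 <- factor_b_peaks[[induced]]
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      summit = integer(), basal_a_idx = integer(),
                      gained_b_idx = integer(), overlap_bp = integer(),
                      a_induced_absent = logical(), b_basal_absent = logical(),
                      b_induced_present = logical(), a_basal_present = logical(),
                      stringsAsFactors = FALSE)
  if (nrow(a0) == 0L) return(empty)
  # shared seqlevels so cross-set overlap queries are well defined even
  # when a condition's peaks sit on disjoint chromosomes
  lev <- unique(c(a0$chrom, a1$chrom, b0$chrom, b1$chrom))
  gr <- function(p) GenomicRanges::GRanges(
    factor(p$chrom, levels = lev), IRanges::IRanges(p$start + 1L, p$end))
  g0 <- gr(a0)
  keep_i <- GenomicRanges::countOverlaps(g0, gr(a1), minoverlap = min_overlap) == 0L
  keep_ii <- GenomicRanges::countOverlaps(g0, gr(b0), minoverlap = min_overlap) == 0L
  hits <- GenomicRanges::findOverlaps(g0, gr(b1), minoverlap = min_overlap)
  calls <- empty
  for (i in which(keep_i & keep_ii)) {
    bj <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]
    if (length(bj) == 0L) next
    ow <- pmin(a0$end[i], b1$end[bj]) - pmax(a0$start[i], b1$start[bj])
    best <- bj[which.max(ow)]
    calls <- rbind(calls, data.frame(
      chrom = a0$chrom[i], start = a0$start[i], end = a0$end[i],
      summit = a0$summit[i], basal_a_idx = i, gained_b_idx = best,
      overlap_bp = max(ow),
      a_induced_absent = TRUE, b_basal_absent = TRUE,
      b_induced_present = TRUE, a_basal_present = TRUE,
      stringsAsFactors = FALSE
    ))
  }
  rownames(calls) <- NULL
  calls
}

#' Annotate switch calls with genes and 3' UTR overlap
#'
#' Assigns each switch locus to a gene with the same summit-based rules
#' as [annotate_peaks()] and flags loci whose interval overlaps the
#' assigned gene's 3' UTR (the hallmark of an autoregulatory switch).
#'
#' @param calls Output of [detect_switch()].
#' @param genes Gene models.
#' @param params [annotation_params()].
#' @return `calls` with added columns `gene_id` (NA when intergenic) and
#'   `in_utr3`.
#' @export
annotate_switches <- function(calls, genes, params = annotation_params()) {
  calls$gene_id <- NA_character_
  calls$in_utr3 <- FALSE
  if (nrow(calls) == 0L) return(calls)
  ann <- annotate_peaks(calls, genes, params)
  for (i in seq_len(nrow(calls))) {
    if (!nzchar(ann$genes[i])) next
    gid <- strsplit(ann$genes[i], ",")[[1]][1]
    calls$gene_id[i] <- gid
    g <- genes[genes$gene_id == gid, ]
    if (!is.na(g$utr3_start)) {
      calls$in_utr3[i] <- calls$start[i] < g$utr3_end && calls$end[i] > g$utr3_start
    }
  }
  calls
}
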