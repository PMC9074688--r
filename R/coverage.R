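# TSS-centered read-density matrices and per-peak normalized read counts.
# Reads are supplied as plain intervals (BED-style data.frame), keeping
# the package free of alignment-file dependencies.

#' TSS-centered coverage profile matrix
#'
#' Bins a +/- `window` region around each anchor into `bin_width` bins;
#' every read interval contributes 1 to each bin it overlaps, and rows of
#' minus-strand anchors are flipped so that bins always run 5' to 3'.
#' Values are scaled to reads per million by `1e6 / library_size`.
#'
#' @param read_intervals `data.frame` with `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param anchors `data.frame` with `anchor_id`, `chrom`, `pos` (0-based
#'   point, e.g. a TSS) and `strand` (`+`/`-`).
#' @param window Half-window in bp (default 2000).
#' @param bin_width Bin width in bp (default 50); must divide
#'   `2 * window`.
#' @param library_size Total reads in the library (> 0).
#' @return A `profile_matrix` list: `values` (anchors x bins, RPM),
#'   `window`, `bin_width`, `library_size`. Column names are bin centers
#'   relative to the anchor.
#' @export
tss_profile <- function(read_intervals, anchors, window = 2000L,
                        bin_width = 50L, library_size) {
  stopifnot(library_size > 0)
  if ((2L * window) %% bin_width != 0L) {
    stop("bin_width must divide 2 * window")
  }
  n_bins <- as.integer(2L * window / bin_width)
  n_anchor <- nrow(anchors)
  starts <- rep(anchors$pos - window, each = n_bins) +
    rep.int(bin_width * (seq_len(n_bins) - 1L), n_anchor)
  bins <- GenomicRanges::GRanges(
    rep(anchors$chrom, each = n_bins),
    IRanges::IRanges(starts + 1L, starts + bin_width)
  )
  counts <- GenomicRanges::countOverlaps(bins, intervals_gr(read_intervals))
  values <- matrix(counts, nrow = n_anchor, ncol = n_bins, byrow = TRUE)
  flip <- anchors$strand == "-"
  values[flip, ] <- values[flip, n_bins:1, drop = FALSE]
  values <- values * 1e6 / library_size
  rownames(values) <- anchors$anchor_id
  colnames(values) <- seq(-window + bin_width / 2, window - bin_width / 2,
                          by = bin_width)
  structure(list(values = values, window = window, bin_width = bin_width,
                 library_size = library_size),
            class = "profile_matrix")
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("profile_matrix: %d anchors x %d bins (+/- %d bp, %d bp bins)\n",
              nrow(x$values), ncol(x$values), x$window, x$bin_width))
  invisible(x)
}

#' Normalized read counts per peak
#'
#' @param read_intervals Read intervals (see [tss_profile()]).
#' @param peaks Peak table.
#' @param library_size Total reads in the library (> 0).
#' @return Numeric vector (reads per million overlapping each peak
#'   interval), named by peak name.
#' @export
peak_read_counts <- function(read_intervals, peaks, library_size) {
  stopifnot(library_size > 0)
  n <- GenomicRanges::countOverlaps(peaks_gr(peaks), intervals_gr(read_intervals))
  setNames(n * 1e6 / library_size,
           if (is.null(peaks$name)) sprintf("peak_%d", seq_len(nrow(peaks))) else peaks$name)
}

#' Tukey box-plot summary
#'
#' Quartiles use linear interpolation (R quantile type 7); whiskers reach
#' the most extreme observations within 1.5 IQR of the quartiles, and
#' points beyond them are reported as outliers.
#'
#' @param values Non-empty numeric vector.
#' @return List with `median`, `q1`, `q3`, `whisker_low`, `whisker_high`,
#'   `outliers`.
#' @export
boxplot_summary <- function(values) {
  if (length(values) == 0L) stop("empty value vector")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  list(median = q[2], q1 = q[1], q3 = q[3],
       whisker_low = min(values[inside]),
       whisker_high = max(values[inside]),
       outliers = values[!inside])
}

#' Pairwise tests on per-peak normalized counts
#'
#' Welch t-tests between every pair of groups of per-peak normalized
#' read counts, BH-adjusted - the standard annotation for box-plot
#' comparisons of ChIP signal between conditions.
#'
#' @param groups Named list of numeric vectors.
#' @return `data.frame` with `group_a`, `group_b`, `p`, `q`.
#' @export
peak_signal_tests <- function(groups) {
  stopifnot(length(groups) >= 2, !is.null(names(groups)))
  pairs <- utils::combn(names(groups), 2)
  p <- apply(pairs, 2, function(g) {
    t.test(groups[[g[1]]], groups[[g[2]]])$p.value
  })
  data.frame(group_a = pairs[1, ], group_b = pairs[2, ],
             p = p, q = p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE)
}
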