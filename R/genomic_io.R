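# Readers and writers for the plain-text formats the pipeline touches.
# Everything downstream assumes 0-based half-open intervals (BED convention).

#' Read ChIP-seq peaks from narrowPeak or BED6
#'
#' Parses an ENCODE narrowPeak (10 column) or BED6 file into the peak table
#' used throughout the package. The summit is stored as an absolute 0-based
#' coordinate: for narrowPeak it is `start + offset` (column 10) when the
#' offset is non-negative, otherwise the interval midpoint
#' (`floor((start + end) / 2)`, the convention also used for BED6 input,
#' which carries no summit).
#'
#' @param path Path to a tab-separated peak file.
#' @param format `"narrowPeak"` or `"bed6"`.
#' @param factor Factor label attached to every peak (e.g. `"SOX4"`).
#' @param condition Condition label attached to every peak (e.g. `"tnf"`).
#' @param normalize_chr `"none"` (default, chromosome names compared as
#'   exact strings), `"strip"` (remove a leading `"chr"`), or `"add"`
#'   (prepend `"chr"` where missing).
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`, `summit`, `factor`, `condition`.
#' @export
read_peaks <- function(path, format = c("narrowPeak", "bed6"),
                       factor = NA_character_, condition = NA_character_,
                       normalize_chr = c("none", "strip", "add")) {
  format <- match.arg(format)
  normalize_chr <- match.arg(normalize_chr)
  stopifnot(file.exists(path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0L) {
    return(empty_peaks(factor, condition))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  need <- if (format == "narrowPeak") 10L else 6L
  nf <- lengths(fields)
  if (any(nf < need)) {
    stop(sprintf("line %d: expected %d tab-separated columns, found %d",
                 which(nf < need)[1], need, nf[which(nf < need)[1]]))
  }
  m <- do.call(rbind, lapply(fields, `[`, seq_len(need)))
  start <- parse_coord(m[, 2], "start")
  end <- parse_coord(m[, 3], "end")
  bad <- which(start >= end)
  if (length(bad)) {
    stop(sprintf("line %d: start (%d) >= end (%d)", bad[1], start[bad[1]], end[bad[1]]))
  }
  if (format == "narrowPeak") {
    off <- parse_coord(m[, 10], "summit offset", allow_negative = TRUE)
    summit <- ifelse(off >= 0, start + off, (start + end) %/% 2L)
    if (any(summit < start | summit >= end)) {
      stop(sprintf("line %d: summit outside its peak interval",
                   which(summit < start | summit >= end)[1]))
    }
  } else {
    summit <- (start + end) %/% 2L
  }
  chrom <- normalize_chrom(m[, 1], normalize_chr)
  data.frame(
    chrom = chrom, start = start, end = end,
    name = m[, 4], score = suppressWarnings(as.numeric(m[, 5])),
    strand = m[, 6], summit = as.integer(summit),
    factor = factor, condition = condition,
    stringsAsFactors = FALSE
  )
}

empty_peaks <- function(factor = NA_character_, condition = NA_character_) {
  data.frame(chrom = character(), start = integer(), end = integer(),
             name = character(), score = numeric(), strand = character(),
             summit = integer(),
             factor = character(), condition = character(),
             stringsAsFactors = FALSE)
}

parse_coord <- function(x, what, allow_negative = FALSE) {
  pat <- if (allow_negative) "^-?[0-9]+$" else "^[0-9]+$"
  bad <- which(!grepl(pat, x))
  if (length(bad)) {
    stop(sprintf("line %d: non-integer %s '%s'", bad[1], what, x[bad[1]]))
  }
  as.integer(x)
}

normalize_chrom <- function(chrom, mode) {
  switch(mode,
    none = chrom,
    strip = sub("^chr", "", chrom),
    add = ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom))
  )
}

#' Write peaks as narrowPeak
#'
#' Inverse of [read_peaks()]: coordinates and summits round-trip
#' bit-exactly (`summit` is emitted as the column-10 offset
#' `summit - start`).
#'
#' @param peaks Peak table as returned by [read_peaks()].
#' @param path Output path.
#' @export
write_peaks <- function(peaks, path) {
  stopifnot(all(c("chrom", "start", "end", "summit") %in% names(peaks)))
  out <- data.frame(
    peaks$chrom, peaks$start, peaks$end,
    if (is.null(peaks$name)) sprintf("peak_%d", seq_len(nrow(peaks))) else peaks$name,
    if (is.null(peaks$score)) 0 else peaks$score,
    if (is.null(peaks$strand)) "." else peaks$strand,
    0, -1, -1, peaks$summit - peaks$start
  )
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene models from BED12 or a GTF subset
#'
#' Builds the strand-aware gene table used for peak annotation and switch
#' calling. The TSS is `start` for `+` genes and `end` for `-` genes
#' (0-based half-open throughout; GTF's 1-based inclusive coordinates are
#' converted at parse time). For BED12, the CDS span is taken from
#' thickStart/thickEnd and the 3' UTR is the terminal region beyond the
#' CDS on the strand-appropriate side. For GTF input, `gene`, `exon` and
#' `three_prime_utr` features are honored.
#'
#' @param path Path to the annotation file.
#' @param format `"bed12"` or `"gtf_lite"`.
#' @return A `data.frame` with one row per gene: `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `tss`, `cds_start`, `cds_end`,
#'   `utr3_start`, `utr3_end` (NA where absent) and a list column `exons`
#'   of two-column matrices (start, end).
#' @export
read_gene_models <- function(path, format = c("bed12", "gtf_lite")) {
  format <- match.arg(format)
  stopifnot(file.exists(path))
  if (format == "bed12") read_bed12(path) else read_gtf_lite(path)
}

read_bed12 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^(track|browser|#)", lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 12L)) {
    stop(sprintf("line %d: BED12 requires 12 columns", which(lengths(fields) < 12L)[1]))
  }
  rows <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    start <- parse_coord(f[2], "start"); end <- parse_coord(f[3], "end")
    strand <- f[6]
    if (!strand %in% c("+", "-")) {
      stop(sprintf("line %d: strand '%s' invalid; gene models require + or - (TSS is strand-derived)",
                   i, strand))
    }
    thick_start <- parse_coord(f[7], "thickStart")
    thick_end <- parse_coord(f[8], "thickEnd")
    n_blocks <- parse_coord(f[10], "blockCount")
    sizes <- as.integer(strsplit(f[11], ",")[[1]])[seq_len(n_blocks)]
    offs <- as.integer(strsplit(f[12], ",")[[1]])[seq_len(n_blocks)]
    ex <- cbind(start + offs, start + offs + sizes)
    if (is.unsorted(ex[, 1]) || any(ex[-1, 1] < ex[-n_blocks, 2])) {
      stop(sprintf("line %d: exon blocks overlap or are unsorted", i))
    }
    has_cds <- thick_start < thick_end
    if (has_cds) {
      if (strand == "+") {
        utr3 <- if (thick_end < end) c(thick_end, end) else c(NA, NA)
      } else {
        utr3 <- if (start < thick_start) c(start, thick_start) else c(NA, NA)
      }
    } else {
      utr3 <- c(NA, NA)
    }
    list(gene_id = f[4], chrom = f[1], start = start, end = end,
         strand = strand, tss = if (strand == "+") start else end,
         cds_start = if (has_cds) thick_start else NA_integer_,
         cds_end = if (has_cds) thick_end else NA_integer_,
         utr3_start = utr3[1], utr3_end = utr3[2], exons = ex)
  })
  gene_rows_to_df(rows)
}

read_gtf_lite <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 9L)) {
    stop(sprintf("line %d: GTF requires 9 columns", which(lengths(fields) < 9L)[1]))
  }
  feat <- vapply(fields, `[`, "", 3)
  keep <- feat %in% c("gene", "exon", "three_prime_utr")
  fields <- fields[keep]; feat <- feat[keep]
  gid <- vapply(fields, function(f) {
    m <- regmatches(f[9], regexec('gene_id "([^"]+)"', f[9]))[[1]]
    if (length(m) < 2) stop("GTF record without gene_id attribute")
    m[2]
  }, "")
  # GTF is 1-based inclusive: convert to 0-based half-open
  start <- vapply(fields, function(f) parse_coord(f[4], "start"), 1L) - 1L
  end <- vapply(fields, function(f) parse_coord(f[5], "end"), 1L)
  chrom <- vapply(fields, `[`, "", 1)
  strand <- vapply(fields, `[`, "", 7)
  rows <- lapply(unique(gid), function(g) {
    sel <- gid == g
    gi <- which(sel & feat == "gene")
    if (length(gi) != 1L) stop(sprintf("gene '%s': expected exactly one gene record", g))
    st <- strand[gi]
    if (!st %in% c("+", "-")) {
      stop(sprintf("gene '%s': strand '%s' invalid; + or - required", g, st))
    }
    ei <- which(sel & feat == "exon")
    ex <- cbind(start[ei], end[ei])[order(start[ei]), , drop = FALSE]
    if (nrow(ex) == 0L) ex <- cbind(start[gi], end[gi])
    if (nrow(ex) > 1L && any(ex[-1, 1] < ex[-nrow(ex), 2])) {
      stop(sprintf("gene '%s': overlapping exon records", g))
    }
    ui <- which(sel & feat == "three_prime_utr")
    list(gene_id = g, chrom = chrom[gi], start = start[gi], end = end[gi],
         strand = st, tss = if (st == "+") start[gi] else end[gi],
         cds_start = NA_integer_, cds_end = NA_integer_,
         utr3_start = if (length(ui)) min(start[ui]) else NA_integer_,
         utr3_end = if (length(ui)) max(end[ui]) else NA_integer_,
         exons = ex)
  })
  gene_rows_to_df(rows)
}

gene_rows_to_df <- function(rows) {
  df <- data.frame(
    gene_id = vapply(rows, `[[`, "", "gene_id"),
    chrom = vapply(rows, `[[`, "", "chrom"),
    start = vapply(rows, function(r) as.integer(r$start), 1L),
    end = vapply(rows, function(r) as.integer(r$end), 1L),
    strand = vapply(rows, `[[`, "", "strand"),
    tss = vapply(rows, function(r) as.integer(r$tss), 1L),
    cds_start = vapply(rows, function(r) as.integer(r$cds_start), 1L),
    cds_end = vapply(rows, function(r) as.integer(r$cds_end), 1L),
    utr3_start = vapply(rows, function(r) as.integer(r$utr3_start), 1L),
    utr3_end = vapply(rows, function(r) as.integer(r$utr3_end), 1L),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in annotation")
  df$exons <- I(lapply(rows, `[[`, "exons"))
  df
}

#' Read an RNA-seq count matrix with sample metadata
#'
#' @param path TSV with gene ids in the first column and one column of
#'   non-negative integer counts per sample.
#' @param metadata TSV sample sheet with columns `sample_id`, `genotype`
#'   (`control`/`soxc_ko`), `treatment` (`tnf`/`untreated`) and
#'   `replicate`; every sample in the count header must be present.
#' @return An object of class `count_matrix`: a list with `counts`
#'   (integer matrix, genes x samples) and `samples` (the metadata
#'   data.frame, ordered as the count columns).
#' @export
read_count_matrix <- function(path, metadata) {
  stopifnot(file.exists(path), file.exists(metadata))
  tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- read.delim(metadata, stringsAsFactors = FALSE)
  gene_ids <- as.character(tab[[1]])
  counts <- as.matrix(tab[, -1, drop = FALSE])
  if (any(is.na(suppressWarnings(as.numeric(counts)))) ||
      any(as.numeric(counts) < 0) ||
      any(as.numeric(counts) != floor(as.numeric(counts)))) {
    stop("counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  rownames(counts) <- gene_ids
  missing <- setdiff(colnames(counts), meta$sample_id)
  if (length(missing)) {
    stop(sprintf("sample(s) in count header missing from metadata: %s",
                 paste(missing, collapse = ", ")))
  }
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  count_matrix(counts, meta)
}

#' Construct a count_matrix object
#'
#' @param counts Integer matrix, genes x samples, with gene ids as
#'   rownames.
#' @param samples Data frame with `sample_id`, `genotype`, `treatment`,
#'   `replicate`; one row per count column, in order.
#' @export
count_matrix <- function(counts, samples) {
  stopifnot(is.matrix(counts), nrow(samples) == ncol(counts))
  if (is.null(rownames(counts))) stop("counts needs gene ids as rownames")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids")
  if (any(counts < 0)) stop("counts must be non-negative")
  req <- c("sample_id", "genotype", "treatment", "replicate")
  if (!all(req %in% names(samples))) {
    stop("sample metadata needs columns: ", paste(req, collapse = ", "))
  }
  if (!all(samples$genotype %in% c("control", "soxc_ko"))) {
    stop("genotype must be 'control' or 'soxc_ko'")
  }
  if (!all(samples$treatment %in% c("tnf", "untreated"))) {
    stop("treatment must be 'tnf' or 'untreated'")
  }
  if (anyDuplicated(samples[, c("genotype", "treatment", "replicate")])) {
    stop("(genotype, treatment, replicate) must be unique")
  }
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  print(x$samples)
  invisible(x)
}

# --- internal GRanges bridges (0-based half-open -> 1-based closed) ------

peaks_gr <- function(p) {
  GenomicRanges::GRanges(p$chrom, IRanges::IRanges(p$start + 1L, p$end))
}

summits_gr <- function(p) {
  GenomicRanges::GRanges(p$chrom, IRanges::IRanges(p$summit + 1L, width = 1L))
}

intervals_gr <- function(d) {
  GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$start + 1L, d$end))
}
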