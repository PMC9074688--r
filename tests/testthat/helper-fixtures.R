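# Shared builders for small in-code fixtures.

mk_peaks <- function(chrom, summit, width = 200L,
                     factor = NA_character_, condition = NA_character_,
                     name = NULL) {
  summit <- as.integer(summit)
  n <- length(summit)
  half <- as.integer(width) %/% 2L
  data.frame(
    chrom = rep_len(chrom, n),
    start = summit - half, end = summit + half,
    name = if (is.null(name)) sprintf("p%d", seq_len(n)) else rep_len(name, n),
    score = rep_len(0, n), strand = rep_len(".", n),
    summit = summit, factor = rep_len(factor, n),
    condition = rep_len(condition, n),
    stringsAsFactors = FALSE
  )
}

mk_intervals <- function(chrom, start, end) {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             stringsAsFactors = FALSE)
}

# single-row gene; exons default to the whole span
mk_gene <- function(gene_id, chrom, start, end, strand,
                    exons = NULL, cds = c(NA, NA), utr3 = c(NA, NA)) {
  row <- list(gene_id = gene_id, chrom = chrom,
              start = as.integer(start), end = as.integer(end),
              strand = strand,
              tss = if (strand == "+") as.integer(start) else as.integer(end),
              cds_start = as.integer(cds[1]), cds_end = as.integer(cds[2]),
              utr3_start = as.integer(utr3[1]), utr3_end = as.integer(utr3[2]),
              exons = if (is.null(exons)) cbind(as.integer(start), as.integer(end))
                      else exons)
  tfcobind:::gene_rows_to_df(list(row))
}

mk_genes <- function(...) do.call(rbind, list(...))

# count_matrix for one genotype x two treatments (or both genotypes)
mk_cm <- function(counts, genotype, treatment) {
  samples <- data.frame(
    sample_id = colnames(counts), genotype = genotype, treatment = treatment,
    replicate = stats::ave(seq_along(genotype),
                           paste(genotype, treatment), FUN = seq_along),
    stringsAsFactors = FALSE
  )
  count_matrix(counts, samples)
}

# memoized small planted study shared between integration tests
get_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_study(sim_config(seed = 7,
                                          counts = list(nb_dispersion = 0.01)))
    }
    cache
  }
})

get_study_result <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      st <- get_study()
      cache <<- run_integration(st$peaks, st$genes, st$cm)
    }
    cache
  }
})

count_dinucs <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  if (length(ch) < 2) return(table(character()))
  table(paste0(ch[-length(ch)], ch[-1]))
}
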