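# Seeded synthetic-data generator with a truth manifest.
#
# The generator emulates the study design the pipeline is built for: two
# factors (an inducible partner "SOX4" and a constitutive "RELA") x two
# conditions (untreated / tnf), a stimulus that multiplies the peak count
# by induced_fold, a planted share of co-bound summits, binding switches
# in the 3' UTRs of designated autoregulated genes, and a genotype x
# treatment negative-binomial count matrix with planted fold changes
# whose knockout behavior encodes dependence. Every planted fact is
# recorded in a manifest so recovery tests never guess.
#
# Genes live on a grid of private "slots" (one gene centered per slot).
# Planted peaks are confined to narrow zones around slot centers so that
# a peak can never fall inside the 50 kb assignment window of a
# neighboring slot's gene; this is what makes exact planted-class
# recovery possible. With the default 50 kb pad this requires the
# 2 x 20 Mb default genome.

#' Synthetic study configuration
#'
#' Defaults describe the emulated study: a treatment that triples the
#' peak count per factor, 70.4% of induced factor-A summits within 50 bp
#' of a factor-B summit, two autoregulatory switch loci, and triplicate
#' negative-binomial RNA-seq for two genotypes x two treatments.
#'
#' @param seed Integer master seed; every stage derives its stream from
#'   it.
#' @param n_chroms,chrom_length Genome shape (default 2 x 20 Mb - sized
#'   so each gene's 50 kb assignment window fits in a private slot).
#' @param n_genes Number of gene models (default 300).
#' @param n_peaks_induced Induced-condition peaks per factor (default
#'   600).
#' @param induced_fold Peak-count ratio induced/basal (default 3).
#' @param cobind_fraction Share of induced factor-A summits planted
#'   within the co-binding distance of a factor-B summit (default
#'   0.704).
#' @param max_summit_distance Co-binding distance used for planting
#'   (default 50 bp).
#' @param summit_jitter_sd Gaussian jitter (bp) added to planted
#'   co-bound offsets; 0 (default) gives the exact noise-free
#'   construction.
#' @param n_switch_loci Number of switch loci planted in autoregulated
#'   genes' 3' UTRs (default 2).
#' @param peak_width Range of peak interval widths in bp.
#' @param counts Count-simulation settings: `n_genes` (standalone runs),
#'   `n_responsive`, `fraction_dependent`, `fraction_reversed` (share of
#'   dependent genes whose knockout response flips sign),
#'   `true_fc_range` (linear), `nb_dispersion`, `depth_per_sample`,
#'   `n_replicates`, `baseline_meanlog`, `baseline_sdlog`.
#' @param motif Peak-sequence settings: IUPAC `consensus` planted in
#'   co-bound peaks and the `planting_rate`.
#' @param classes Planted regulatory classes for [simulate_study()]:
#'   `c1` co-bound direct, `c2` B-only direct, `c3` indirect, `c4`
#'   switch (tied to `n_switch_loci`), and `n_independent`
#'   responsive-but-independent genes.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 7L,
                       n_chroms = 2L, chrom_length = 2e7,
                       n_genes = 300L,
                       n_peaks_induced = 600L, induced_fold = 3,
                       cobind_fraction = 0.704,
                       max_summit_distance = 50L,
                       summit_jitter_sd = 0,
                       n_switch_loci = 2L,
                       peak_width = c(200L, 600L),
                       counts = list(),
                       motif = list(),
                       classes = list()) {
  counts_def <- list(n_genes = 2000L, n_responsive = 200L,
                     fraction_dependent = 0.6, fraction_reversed = 0.25,
                     true_fc_range = c(3, 3), nb_dispersion = 0.02,
                     depth_per_sample = 1e6, n_replicates = 3L,
                     baseline_meanlog = log(200), baseline_sdlog = 1)
  motif_def <- list(consensus = "WWCAAW", planting_rate = 1.0)
  classes_def <- list(c1 = 20L, c2 = 30L, c3 = 100L, c4 = n_switch_loci,
                      n_independent = 100L)
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = chrom_length, n_genes = as.integer(n_genes),
              n_peaks_induced = as.integer(n_peaks_induced),
              induced_fold = induced_fold,
              cobind_fraction = cobind_fraction,
              max_summit_distance = as.integer(max_summit_distance),
              summit_jitter_sd = summit_jitter_sd,
              n_switch_loci = as.integer(n_switch_loci),
              peak_width = peak_width,
              counts = utils::modifyList(counts_def, counts),
              motif = utils::modifyList(motif_def, motif),
              classes = utils::modifyList(classes_def, classes))
  stopifnot(cfg$cobind_fraction >= 0, cfg$cobind_fraction <= 1,
            cfg$induced_fold > 0,
            cfg$counts$fraction_dependent >= 0, cfg$counts$fraction_dependent <= 1,
            cfg$counts$fraction_reversed >= 0, cfg$counts$fraction_reversed <= 1)
  structure(cfg, class = "sim_config")
}

sim_chrom_names <- function(config) sprintf("chr%d", seq_len(config$n_chroms))

# gene slot geometry: each gene owns slot_len bp on its chromosome
slot_layout <- function(config) {
  per_chrom <- ceiling(config$n_genes / config$n_chroms)
  slot_len <- floor(config$chrom_length / per_chrom)
  if (slot_len < 40000) {
    stop("genome too small: each gene needs a private slot of >= 40 kb ",
         "(increase chrom_length or reduce n_genes)")
  }
  chrom <- rep(sim_chrom_names(config), each = per_chrom)[seq_len(config$n_genes)]
  idx_in_chrom <- unlist(lapply(table(factor(chrom, levels = sim_chrom_names(config))),
                                seq_len), use.names = FALSE)
  data.frame(chrom = chrom,
             slot_start = (idx_in_chrom - 1L) * slot_len,
             slot_end = idx_in_chrom * slot_len,
             stringsAsFactors = FALSE)
}

#' Simulate non-overlapping gene models
#'
#' One gene per slot, random strand, 2-8 exons, an explicit CDS span and
#' a strand-appropriate 3' UTR. `n_switch_loci` random genes are flagged
#' `autoregulated` (switch-planting targets).
#'
#' @param config A [sim_config()].
#' @return Gene model table (see [read_gene_models()]) with extra
#'   columns `slot_start`, `slot_end`, `autoregulated`.
#' @export
simulate_gene_models <- function(config = sim_config()) {
  if (config$n_genes == 0L) {
    g <- gene_rows_to_df(list())
    g$slot_start <- integer(); g$slot_end <- integer(); g$autoregulated <- logical()
    return(g)
  }
  set.seed(config$seed)
  slots <- slot_layout(config)
  rows <- lapply(seq_len(config$n_genes), function(i) {
    slot_mid <- (slots$slot_start[i] + slots$slot_end[i]) %/% 2L
    glen <- sample(3000:12000, 1L)
    start <- as.integer(slot_mid - glen %/% 2L)
    end <- start + glen
    strand <- sample(c("+", "-"), 1L)
    n_ex <- sample(2:8, 1L)
    # alternate exon/intron segments spanning the gene; every segment
    # keeps a 60 bp floor and the leftover is split proportionally
    k <- 2L * n_ex - 1L
    w <- runif(k, 1, 4)
    seg <- 60L + as.integer(floor((glen - 60L * k) * w / sum(w)))
    seg[k] <- glen - sum(seg[-k])
    bounds <- cumsum(c(0L, seg))
    ex_idx <- seq(1L, 2L * n_ex - 1L, by = 2L)
    ex <- cbind(start + bounds[ex_idx], start + bounds[ex_idx + 1L])
    margin5 <- sample(150:400, 1L)
    margin3 <- sample(200:500, 1L)
    cds_start <- min(ex[1, 1] + margin5, ex[1, 2] - 1L)
    cds_end <- max(ex[n_ex, 2] - margin3, ex[n_ex, 1] + 1L)
    if (strand == "+") {
      utr3 <- c(cds_end, end)
    } else {
      utr3 <- c(start, cds_start)
    }
    list(gene_id = sprintf("gene_%04d", i), chrom = slots$chrom[i],
         start = start, end = end, strand = strand,
         tss = if (strand == "+") start else end,
         cds_start = cds_start, cds_end = cds_end,
         utr3_start = utr3[1], utr3_end = utr3[2], exons = ex)
  })
  genes <- gene_rows_to_df(rows)
  genes$slot_start <- as.integer(slots$slot_start)
  genes$slot_end <- as.integer(slots$slot_end)
  genes$autoregulated <- FALSE
  if (config$n_switch_loci > 0L) {
    genes$autoregulated[sample.int(config$n_genes, config$n_switch_loci)] <- TRUE
  }
  genes
}

new_peak_row <- function(chrom, summit, width, name, factor, condition) {
  half <- width %/% 2L
  data.frame(chrom = chrom, start = as.integer(max(summit - half, 0L)),
             end = as.integer(summit + half),
             name = name, score = round(runif(1, 5, 100), 2), strand = ".",
             summit = as.integer(summit), factor = factor,
             condition = condition, stringsAsFactors = FALSE)
}

rbind_peaks <- function(lst) {
  if (length(lst) == 0L) return(empty_peaks())
  do.call(rbind, lst)
}

# Build the factor x condition peak sets around a site plan.
# `site_plan`: data.frame with chrom, pos, unit ("pair"/"a_only"/"b_only")
# `switch_genes`: rows of the gene table to receive switch loci
build_peak_sets <- function(config, site_plan, switch_genes,
                            factor_a = "SOX4", factor_b = "RELA",
                            basal = "untreated", induced = "tnf") {
  d <- config$max_summit_distance
  wrange <- config$peak_width
  a_ind <- list(); b_ind <- list()
  a_groups <- character(); b_groups <- character()
  for (i in seq_len(nrow(site_plan))) {
    pos <- site_plan$pos[i]; chr <- site_plan$chrom[i]
    unit <- site_plan$unit[i]
    w_a <- sample(wrange[1]:wrange[2], 1L)
    w_b <- sample(wrange[1]:wrange[2], 1L)
    if (unit %in% c("pair", "a_only")) {
      off <- if (unit == "pair") {
        o <- sample.int(d + 1L, 1L) - 1L
        if (config$summit_jitter_sd > 0) {
          o <- o + as.integer(round(rnorm(1, 0, config$summit_jitter_sd)))
        }
        o
      } else 0L
      a_ind[[length(a_ind) + 1L]] <- new_peak_row(
        chr, pos + off, w_a, sprintf("%s_%s_%d", factor_a, induced, length(a_ind) + 1L),
        factor_a, induced)
      a_groups <- c(a_groups, if (unit == "pair") "cobound" else "a_only")
    }
    if (unit %in% c("pair", "b_only")) {
      b_ind[[length(b_ind) + 1L]] <- new_peak_row(
        chr, pos, w_b, sprintf("%s_%s_%d", factor_b, induced, length(b_ind) + 1L),
        factor_b, induced)
      b_groups <- c(b_groups, if (unit == "pair") "cobound" else "b_only")
    }
  }
  # switch loci: factor-B bound at the 3' UTR only in basal, factor A
  # gains the same region only when induced
  b_bas_switch <- list(); a_ind_switch <- list()
  switch_truth <- list()
  for (k in seq_len(NROW(switch_genes))) {
    g <- switch_genes[k, ]
    center <- (g$utr3_start + g$utr3_end) %/% 2L
    w <- 400L
    b_bas_switch[[k]] <- new_peak_row(
      g$chrom, center, w, sprintf("%s_%s_switch_%d", factor_b, basal, k),
      factor_b, basal)
    a_ind_switch[[k]] <- new_peak_row(
      g$chrom, center + 50L, w, sprintf("%s_%s_switchgain_%d", factor_a, induced, k),
      factor_a, induced)
    switch_truth[[k]] <- data.frame(
      gene_id = g$gene_id, chrom = g$chrom,
      start = b_bas_switch[[k]]$start, end = b_bas_switch[[k]]$end,
      stringsAsFactors = FALSE)
  }
  a_induced <- rbind_peaks(c(a_ind, a_ind_switch))
  a_groups <- c(a_groups, rep("switch_gain", length(a_ind_switch)))
  b_induced <- rbind_peaks(b_ind)
  # basal sets: persistent subsets of the induced peaks (plus the planted
  # switch peaks for factor B); switch-gain peaks are never basal
  n_basal <- round(config$n_peaks_induced / config$induced_fold)
  a_eligible <- which(a_groups != "switch_gain")
  a_bas_idx <- sort(sample(a_eligible, min(n_basal, length(a_eligible))))
  a_basal <- a_induced[a_bas_idx, , drop = FALSE]
  n_b_extra <- max(n_basal - length(b_bas_switch), 0L)
  b_bas_idx <- sort(sample.int(nrow(b_induced), min(n_b_extra, nrow(b_induced))))
  b_basal <- rbind_peaks(c(list(b_induced[b_bas_idx, , drop = FALSE]), b_bas_switch))
  a_basal$condition <- basal
  b_basal$condition <- basal
  a_basal$name <- sub(induced, basal, a_basal$name, fixed = TRUE)
  rownames(a_basal) <- rownames(b_basal) <- NULL
  peaks <- list()
  peaks[[factor_a]] <- setNames(list(a_basal, a_induced), c(basal, induced))
  peaks[[factor_b]] <- setNames(list(b_basal, b_induced), c(basal, induced))
  list(peaks = peaks,
       manifest = list(
         a_induced_groups = data.frame(name = a_induced$name, group = a_groups,
                                       stringsAsFactors = FALSE),
         b_induced_groups = data.frame(name = b_induced$name, group = b_groups,
                                       stringsAsFactors = FALSE),
         switch_loci = if (length(switch_truth)) do.call(rbind, switch_truth)
                       else data.frame(gene_id = character(), chrom = character(),
                                       start = integer(), end = integer()),
         n_cobound_planted = sum(a_groups == "cobound"),
         n_a_induced = nrow(a_induced), n_b_induced = nrow(b_induced)))
}

# sites spaced 2 kb within +/- zone_half of each eligible slot center
background_sites <- function(genes, eligible, zone_half = 12000L, spacing = 2000L) {
  sites <- lapply(which(eligible), function(i) {
    mid <- (genes$slot_start[i] + genes$slot_end[i]) %/% 2L
    pos <- seq(mid - zone_half, mid + zone_half, by = spacing)
    data.frame(chrom = genes$chrom[i], pos = as.integer(pos),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, sites)
}

#' Simulate factor x condition ChIP-seq peak sets
#'
#' Induced factor-B summits are placed first; a `cobind_fraction` share
#' of induced factor-A summits is planted within the co-binding distance
#' of one of them and the rest at least 500 bp from any factor-B summit.
#' Basal peak sets are persistent subsets of the induced sets with
#' `n_peaks_induced / induced_fold` peaks, and `n_switch_loci` switch
#' loci (B basal present, B induced absent, A basal absent, A induced
#' present) are planted in the 3' UTRs of the flagged genes.
#'
#' @param config A [sim_config()].
#' @param genes Gene models from [simulate_gene_models()].
#' @return List with `peaks` (factor -> condition -> peak table) and
#'   `manifest` (planted groups, switch loci, counts).
#' @export
simulate_peak_sets <- function(config = sim_config(), genes) {
  set.seed(config$seed + 1L)
  n_i <- config$n_peaks_induced
  n_cobound <- round(config$cobind_fraction * n_i)
  n_switch <- sum(genes$autoregulated)
  n_a_only <- n_i - n_cobound - n_switch
  if (n_a_only < 0) stop("n_switch_loci exceeds the non-cobound peak budget")
  n_b_only <- n_i - n_cobound
  sites <- background_sites(genes, !genes$autoregulated)
  n_units <- n_cobound + n_a_only + n_b_only
  if (nrow(sites) < n_units) {
    stop("genome too small to place the requested peaks without forced overlap")
  }
  chosen <- sites[sample.int(nrow(sites), n_units), ]
  chosen$unit <- rep(c("pair", "a_only", "b_only"),
                     c(n_cobound, n_a_only, n_b_only))
  build_peak_sets(config, chosen, genes[genes$autoregulated, , drop = FALSE])
}

#' Simulate the RNA-seq count matrix with planted responses
#'
#' Baseline expression is log-normal; treated samples of responsive
#' genes change by a planted linear fold change, which in the knockout
#' genotype is nulled (`dependent_unchanged`), sign-flipped
#' (`dependent_reversed`) or kept (`independent`). Counts are negative
#' binomial at `nb_dispersion` (Poisson when 0) with per-sample depths
#' jittered +/- 10%.
#'
#' @param config A [sim_config()].
#' @param genes Optional gene models; their ids become the count rows
#'   (otherwise `counts$n_genes` synthetic ids).
#' @param response_plan Optional pre-built plan (`gene_id`, `response`,
#'   `dependence`, `fc`); when NULL one is drawn from the `counts`
#'   settings.
#' @return List with `cm` (a `count_matrix`) and `truth` (the plan).
#' @export
simulate_counts <- function(config = sim_config(), genes = NULL,
                            response_plan = NULL) {
  set.seed(config$seed + 2L)
  cc <- config$counts
  gene_ids <- if (!is.null(genes)) genes$gene_id else
    sprintf("gene_%04d", seq_len(cc$n_genes))
  n <- length(gene_ids)
  if (is.null(response_plan)) {
    response_plan <- data.frame(gene_id = gene_ids, response = "none",
                                dependence = "not_applicable", fc = 1,
                                stringsAsFactors = FALSE)
    n_resp <- min(cc$n_responsive, n)
    resp <- sample.int(n, n_resp)
    response_plan$response[resp] <- sample(c("up", "down"), n_resp, replace = TRUE)
    n_dep <- round(cc$fraction_dependent * n_resp)
    dep <- sample(resp, n_dep)
    n_rev <- round(cc$fraction_reversed * n_dep)
    rev_ <- if (n_rev > 0) sample(dep, n_rev) else integer()
    response_plan$dependence[resp] <- "independent"
    response_plan$dependence[dep] <- "dependent_unchanged"
    response_plan$dependence[rev_] <- "dependent_reversed"
    response_plan$fc[resp] <- runif(n_resp, cc$true_fc_range[1], cc$true_fc_range[2])
  }
  stopifnot(identical(response_plan$gene_id, gene_ids))
  base <- rlnorm(n, cc$baseline_meanlog, cc$baseline_sdlog)
  fc_lin <- ifelse(response_plan$response == "down",
                   1 / response_plan$fc, response_plan$fc)
  fc_lin[response_plan$response == "none"] <- 1
  ko_fc <- ifelse(response_plan$dependence == "dependent_unchanged", 1,
           ifelse(response_plan$dependence == "dependent_reversed", 1 / fc_lin,
                  fc_lin))
  ko_fc[response_plan$response == "none"] <- 1
  samples <- expand.grid(replicate = seq_len(cc$n_replicates),
                         treatment = c("untreated", "tnf"),
                         genotype = c("control", "soxc_ko"),
                         stringsAsFactors = FALSE)
  samples$sample_id <- sprintf("%s_%s_r%d", samples$genotype,
                               samples$treatment, samples$replicate)
  samples <- samples[, c("sample_id", "genotype", "treatment", "replicate")]
  counts <- matrix(0L, n, nrow(samples),
                   dimnames = list(gene_ids, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    eff <- if (samples$treatment[j] == "untreated") rep(1, n)
           else if (samples$genotype[j] == "control") fc_lin else ko_fc
    expr <- base * eff
    depth_j <- cc$depth_per_sample * runif(1, 0.9, 1.1)
    mu <- depth_j * expr / sum(expr)
    counts[, j] <- if (cc$nb_dispersion > 0) {
      rnbinom(n, mu = mu, size = 1 / cc$nb_dispersion)
    } else {
      rpois(n, mu)
    }
  }
  list(cm = count_matrix(counts, samples), truth = response_plan)
}

#' Simulate peak sequences with planted motif instances
#'
#' Each peak receives a random sequence of its interval length; a
#' `planting_rate` share of the peaks flagged as co-bound receives one
#' concrete instance of the configured consensus at a recorded offset
#' and strand.
#'
#' @param config A [sim_config()].
#' @param peaks Peak table (typically induced factor-A peaks).
#' @param groups Planted group per peak (from the peak-set manifest);
#'   `"cobound"` entries are planting candidates.
#' @return List with `seqs` (named character vector) and `truth`
#'   (`name`, `planted`, `offset`, `strand`).
#' @export
simulate_peak_sequences <- function(config = sim_config(), peaks,
                                    groups = rep("cobound", nrow(peaks))) {
  set.seed(config$seed + 3L)
  consensus <- toupper(config$motif$consensus)
  w <- nchar(consensus)
  codes <- strsplit(consensus, "")[[1]]
  instantiate <- function() {
    paste(vapply(codes, function(cd) {
      opts <- IUPAC_SETS[[cd]]
      opts[sample.int(length(opts), 1L)]
    }, ""), collapse = "")
  }
  n <- nrow(peaks)
  seqs <- character(n)
  truth <- data.frame(name = peaks$name, planted = FALSE,
                      offset = NA_integer_, strand = NA_character_,
                      stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    len <- max(peaks$end[i] - peaks$start[i], w + 2L)
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    if (groups[i] == "cobound" && runif(1) < config$motif$planting_rate) {
      off <- sample.int(len - w + 1L, 1L) - 1L
      strand <- sample(c("+", "-"), 1L)
      inst <- instantiate()
      if (strand == "-") inst <- reverse_complement(inst)
      s <- paste0(substr(s, 1, off), inst, substr(s, off + w + 1L, len))
      truth$planted[i] <- TRUE
      truth$offset[i] <- off
      truth$strand[i] <- strand
    }
    seqs[i] <- s
  }
  names(seqs) <- peaks$name
  list(seqs = seqs, truth = truth)
}

#' Simulate read intervals around peak summits
#'
#' Gaussian spread of single-end reads around each summit, for coverage
#' profile tests.
#'
#' @param peaks Peak table.
#' @param reads_per_peak Reads sampled per peak.
#' @param spread Gaussian SD of read start positions around the summit.
#' @param read_length Read length in bp.
#' @param seed Integer seed.
#' @return `data.frame` of read intervals (`chrom`, `start`, `end`).
#' @export
simulate_reads <- function(peaks, reads_per_peak = 20L, spread = 60,
                           read_length = 50L, seed = 1L) {
  set.seed(seed)
  centers <- rep(peaks$summit, each = reads_per_peak) +
    as.integer(round(rnorm(nrow(peaks) * reads_per_peak, 0, spread)))
  start <- pmax(centers - read_length %/% 2L, 0L)
  data.frame(chrom = rep(peaks$chrom, each = reads_per_peak),
             start = as.integer(start),
             end = as.integer(start + read_length),
             stringsAsFactors = FALSE)
}

#' Simulate a complete planted study
#'
#' Builds every pipeline input with planted regulatory classes: `c1`
#' genes get a co-bound peak pair in their upstream window, `c2` genes a
#' factor-B-only peak, `c3` genes no peak at all, `c4` (autoregulated)
#' genes a 3' UTR binding switch with flat expression; `n_independent`
#' further genes respond to treatment independently of genotype.
#' Background peaks fill the configured totals while staying out of the
#' assignment windows of class genes.
#'
#' @param config A [sim_config()].
#' @return List with `genes`, `peaks`, `cm`, `seqs` and `manifest` (all
#'   planted truths plus the config).
#' @export
simulate_study <- function(config = sim_config()) {
  cl <- config$classes
  stopifnot(cl$c4 == config$n_switch_loci)
  genes <- simulate_gene_models(config)
  set.seed(config$seed + 4L)
  n <- nrow(genes)
  class4 <- which(genes$autoregulated)
  pool <- setdiff(seq_len(n), class4)
  pick <- sample(pool, cl$c1 + cl$c2 + cl$c3 + cl$n_independent)
  class1 <- pick[seq_len(cl$c1)]
  class2 <- pick[cl$c1 + seq_len(cl$c2)]
  class3 <- pick[cl$c1 + cl$c2 + seq_len(cl$c3)]
  indep <- pick[cl$c1 + cl$c2 + cl$c3 + seq_len(cl$n_independent)]
  planted_class <- rep("none", n)
  planted_class[class1] <- "class1"; planted_class[class2] <- "class2"
  planted_class[class3] <- "class3"; planted_class[class4] <- "class4"
  planted_class[indep] <- "independent"

  # planted sites near class gene TSSs (strand-aware upstream)
  upstream_site <- function(i) {
    offset <- sample(2000:20000, 1L)
    pos <- if (genes$strand[i] == "+") genes$tss[i] - offset
           else genes$tss[i] + offset
    data.frame(chrom = genes$chrom[i], pos = as.integer(pos),
               stringsAsFactors = FALSE)
  }
  c1_sites <- do.call(rbind, lapply(class1, upstream_site))
  c2_sites <- do.call(rbind, lapply(class2, upstream_site))
  c1_sites$unit <- "pair"; c2_sites$unit <- "b_only"

  n_i <- config$n_peaks_induced
  n_switch <- cl$c4
  n_cobound <- round(config$cobind_fraction * n_i)
  n_bg_pair <- n_cobound - cl$c1
  n_a_only <- n_i - n_cobound - n_switch
  n_bg_b_only <- (n_i - n_cobound) - cl$c2
  if (n_bg_pair < 0 || n_a_only < 0 || n_bg_b_only < 0) {
    stop("class counts exceed the configured peak budget")
  }
  eligible <- planted_class %in% c("none", "independent")
  sites <- background_sites(genes, eligible)
  n_units <- n_bg_pair + n_a_only + n_bg_b_only
  if (nrow(sites) < n_units) stop("genome too small for the requested peak counts")
  bg <- sites[sample.int(nrow(sites), n_units), ]
  bg$unit <- rep(c("pair", "a_only", "b_only"), c(n_bg_pair, n_a_only, n_bg_b_only))
  site_plan <- rbind(c1_sites, c2_sites, bg)
  ps <- build_peak_sets(config, site_plan, genes[class4, , drop = FALSE])

  # response plan from the class structure
  plan <- data.frame(gene_id = genes$gene_id, response = "none",
                     dependence = "not_applicable", fc = 1,
                     stringsAsFactors = FALSE)
  dep_idx <- c(class1, class2, class3)
  n_rev <- round(config$counts$fraction_reversed * length(dep_idx))
  rev_idx <- if (n_rev > 0) sample(dep_idx, n_rev) else integer()
  responsive <- c(dep_idx, indep)
  plan$response[responsive] <- sample(c("up", "down"), length(responsive),
                                      replace = TRUE)
  plan$dependence[dep_idx] <- "dependent_unchanged"
  plan$dependence[rev_idx] <- "dependent_reversed"
  plan$dependence[indep] <- "independent"
  plan$fc[responsive] <- runif(length(responsive),
                               config$counts$true_fc_range[1],
                               config$counts$true_fc_range[2])
  sim <- simulate_counts(config, genes, response_plan = plan)

  a_induced <- ps$peaks$SOX4$tnf
  seqs <- simulate_peak_sequences(config, a_induced,
                                  ps$manifest$a_induced_groups$group)
  manifest <- c(ps$manifest, list(
    planted_class = data.frame(gene_id = genes$gene_id, class = planted_class,
                               stringsAsFactors = FALSE),
    response_plan = plan,
    motif_truth = seqs$truth,
    config = unclass(config)
  ))
  list(genes = genes, peaks = ps$peaks, cm = sim$cm, seqs = seqs$seqs,
       manifest = manifest)
}

#' Write a simulated study to disk as plain-text pipeline inputs
#'
#' Emits narrowPeak files per factor x condition, a BED12 gene file, the
#' count/metadata TSVs, peak sequences as FASTA and the manifest as
#' JSON.
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (fac in names(study$peaks)) {
    for (cond in names(study$peaks[[fac]])) {
      write_peaks(study$peaks[[fac]][[cond]],
                  file.path(dir, sprintf("%s_%s.narrowPeak", fac, cond)))
    }
  }
  write_bed12(study$genes, file.path(dir, "genes.bed12"))
  counts <- data.frame(gene_id = rownames(study$cm$counts), study$cm$counts,
                       check.names = FALSE)
  write.table(counts, file.path(dir, "counts.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(study$cm$samples, file.path(dir, "samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_fasta_seqs(study$seqs, file.path(dir, "peak_sequences.fa"))
  jsonlite::write_json(study$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Write gene models as BED12
#'
#' @param genes Gene model table.
#' @param path Output path.
#' @export
write_bed12 <- function(genes, path) {
  rows <- vapply(seq_len(nrow(genes)), function(i) {
    ex <- genes$exons[[i]]
    paste(c(genes$chrom[i], genes$start[i], genes$end[i], genes$gene_id[i],
            0, genes$strand[i],
            ifelse(is.na(genes$cds_start[i]), genes$start[i], genes$cds_start[i]),
            ifelse(is.na(genes$cds_end[i]), genes$start[i], genes$cds_end[i]),
            "0", nrow(ex),
            paste0(paste(ex[, 2] - ex[, 1], collapse = ","), ","),
            paste0(paste(ex[, 1] - genes$start[i], collapse = ","), ",")),
          collapse = "\t")
  }, "")
  writeLines(rows, path)
  invisible(path)
}
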