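# Differential expression: median-of-ratios normalization, the
# Audic-Claverie exact two-library count test, BH correction, and the
# responsiveness / genotype-dependence classification.
#
# The Audic-Claverie posterior for the count y in library 2 given x in
# library 1 is
#   P(y | x) = (n2/n1)^y * (x+y)! / (x! y! (1 + n2/n1)^(x+y+1)),
# i.e. a negative-binomial pmf in y with size x+1 and success probability
# n1/(n1+n2). Tail probabilities are accumulated in log space; above
# `exact_limit` total counts a normal approximation with continuity
# correction is used.

#' Median-of-ratios size factors
#'
#' The classic count-normalization scheme: for each sample, the factor is
#' the median over genes of the ratio of that sample's count to the
#' gene's geometric mean across samples, using only genes with nonzero
#' counts in every sample.
#'
#' @param counts Integer matrix (genes x samples) or a `count_matrix`.
#' @return Numeric vector of per-sample size factors.
#' @export
size_factors <- function(counts) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  stopifnot(is.matrix(counts))
  if (ncol(counts) == 1L) return(setNames(1, colnames(counts)))
  log_geo <- rowMeans(log(counts))
  use <- is.finite(log_geo)
  if (!any(use)) {
    stop("no gene has nonzero counts in all samples; ",
         "consider a pseudo-reference (e.g. add a pseudocount)")
  }
  sf <- apply(counts, 2, function(col) {
    exp(median(log(col[use]) - log_geo[use]))
  })
  setNames(sf, colnames(counts))
}

#' Audic-Claverie p-value for a two-library count comparison
#'
#' Exact conditional test for whether a tag/read count differs between
#' two sequencing libraries of sizes `n1` and `n2`. The two-sided p-value
#' is `min(1, 2 * min(P(Y <= y | x), P(Y >= y | x)))`.
#'
#' @param x,y Observed counts in libraries 1 and 2 (vectors recycle).
#' @param n1,n2 Library sizes (> 0; only their ratio matters).
#' @param sided `"two"` (default), `"greater"` (P(Y >= y | x)) or
#'   `"less"` (P(Y <= y | x)).
#' @param exact_limit Total count `x + y` above which the normal
#'   approximation replaces exact log-space summation (default 10000).
#' @return Numeric vector of p-values in (0, 1].
#' @export
audic_claverie_p <- function(x, y, n1, n2, sided = c("two", "greater", "less"),
                             exact_limit = 10000L) {
  sided <- match.arg(sided)
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  if (any(n1 <= 0) || any(n2 <= 0)) stop("library sizes must be positive")
  n <- max(length(x), length(y), length(n1), length(n2))
  x <- rep_len(x, n); y <- rep_len(y, n)
  n1 <- rep_len(n1, n); n2 <- rep_len(n2, n)
  vapply(seq_len(n), function(i) {
    ac_p_one(x[i], y[i], n2[i] / n1[i], sided, exact_limit)
  }, 1.0)
}

ac_log_pmf <- function(k, x, r) {
  lchoose(x + k, k) + k * log(r) - (x + k + 1) * log1p(r)
}

log_sum_exp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

ac_p_one <- function(x, y, r, sided, exact_limit) {
  if (x + y <= exact_limit) {
    lower <- min(1, exp(log_sum_exp(ac_log_pmf(0:y, x, r))))
    # upper tail summed directly; past the mean the pmf decays at least
    # geometrically with ratio q = r/(1+r), so run the sum far enough
    # beyond both the mean and y for ~1e-12 truncation error
    mu <- (x + 1) * r
    sd_ <- sqrt((x + 1) * r * (1 + r))
    log_q <- log(r) - log1p(r)
    n_geo <- min(ceiling(-30 * log(10) / log_q) + 10, 1e5)
    kmax <- max(ceiling(mu + 20 * sd_ + 20), y + n_geo)
    upper <- min(1, exp(log_sum_exp(ac_log_pmf(y:kmax, x, r))))
  } else {
    mu <- (x + 1) * r
    sd_ <- sqrt((x + 1) * r * (1 + r))
    lower <- pnorm(y + 0.5, mu, sd_)
    upper <- pnorm(y - 0.5, mu, sd_, lower.tail = FALSE)
  }
  p <- switch(sided,
    two = min(1, 2 * min(lower, upper)),
    greater = upper,
    less = lower
  )
  max(p, .Machine$double.xmin)
}

#' Benjamini-Hochberg adjustment
#'
#' Validated step-up FDR adjustment (wraps `stats::p.adjust`): ranks are
#' computed on the sorted p-values, each adjusted value is the running
#' minimum of `p * m / rank` from the largest rank down, capped at 1, and
#' the original order is restored.
#'
#' @param pvals Numeric vector of p-values, all in (0, 1].
#' @return Adjusted q-values in the input order.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  p.adjust(pvals, method = "BH")
}

#' Differential-expression parameters
#'
#' @param fc_threshold Linear fold-change threshold for calling a gene
#'   responsive (default 1.5; applies symmetrically as `>= fc` or
#'   `<= 1/fc`).
#' @param alpha BH FDR cutoff (default 0.05).
#' @param fc_only If TRUE, direction calls use the fold threshold alone
#'   (no FDR gate) - the threshold-only reading of a >= 1.5-fold rule.
#' @export
de_params <- function(fc_threshold = 1.5, alpha = 0.05, fc_only = FALSE) {
  stopifnot(fc_threshold >= 1, alpha > 0, alpha < 1)
  structure(list(fc_threshold = fc_threshold, alpha = alpha,
                 fc_only = isTRUE(fc_only)),
            class = "de_params")
}

resolve_samples <- function(samples, filter) {
  if (is.logical(filter)) return(which(filter))
  if (is.numeric(filter)) return(as.integer(filter))
  if (is.list(filter)) {
    keep <- rep(TRUE, nrow(samples))
    for (nm in names(filter)) keep <- keep & samples[[nm]] %in% filter[[nm]]
    return(which(keep))
  }
  stop("group filter must be logical, indices, or a named list of metadata values")
}

#' Two-group contrast with the Audic-Claverie test
#'
#' Replicates are pooled by summation within each group (the test is
#' defined for two libraries); library sizes are the summed per-sample
#' effective sizes (size factor x mean total count). Fold change is the
#' ratio of normalized pooled means, with a +1 pseudocount applied to
#' both pooled counts only when either is zero (flagged). A gene is `up`
#' (`down`) when its fold change passes the threshold and, unless
#' `fc_only`, its BH q-value is below `alpha`.
#'
#' @param cm A `count_matrix`.
#' @param group_a,group_b Sample filters: logical vector, indices, or a
#'   named list matched against the sample metadata, e.g.
#'   `list(genotype = "control", treatment = "untreated")`.
#' @param params [de_params()].
#' @return `data.frame` with one row per gene: `gene_id`, pooled
#'   `count_a`/`count_b`, effective library sizes `n_a`/`n_b`,
#'   `fold_change`, `pseudocount` flag, `p`, `q`, `direction`.
#' @export
contrast <- function(cm, group_a, group_b, params = de_params()) {
  stopifnot(inherits(cm, "count_matrix"))
  ia <- resolve_samples(cm$samples, group_a)
  ib <- resolve_samples(cm$samples, group_b)
  if (length(ia) == 0L || length(ib) == 0L) stop("empty sample group")
  if (length(intersect(ia, ib))) stop("groups must be disjoint")
  counts <- cm$counts
  sf <- size_factors(counts)
  scale_unit <- mean(colSums(counts))
  count_a <- as.numeric(rowSums(counts[, ia, drop = FALSE]))
  count_b <- as.numeric(rowSums(counts[, ib, drop = FALSE]))
  n_a <- sum(sf[ia]) * scale_unit
  n_b <- sum(sf[ib]) * scale_unit
  pseudo <- count_a == 0 | count_b == 0
  fa <- ifelse(pseudo, count_a + 1, count_a) / n_a
  fb <- ifelse(pseudo, count_b + 1, count_b) / n_b
  fc <- fb / fa
  p <- audic_claverie_p(count_a, count_b, n_a, n_b)
  q <- bh_adjust(p)
  thr <- params$fc_threshold
  sig <- if (params$fc_only) rep(TRUE, length(p)) else q < params$alpha
  direction <- ifelse(sig & fc >= thr, "up",
                      ifelse(sig & fc <= 1 / thr, "down", "unchanged"))
  data.frame(gene_id = rownames(counts),
             count_a = count_a, count_b = count_b,
             n_a = n_a, n_b = n_b,
             fold_change = fc, pseudocount = pseudo,
             p = p, q = q, direction = direction,
             stringsAsFactors = FALSE)
}

#' Classify treatment response and genotype dependence
#'
#' The treatment response of each gene comes from the control-genotype
#' contrast; for responsive genes the knockout contrast decides
#' dependence: `dependent_unchanged` when the response disappears in the
#' knockout, `dependent_reversed` when it flips sign, `independent` when
#' it persists. Non-responsive genes are `not_applicable`.
#'
#' @param de_control Contrast (treated vs untreated) in the control
#'   genotype; see [contrast()].
#' @param de_ko Same contrast in the knockout genotype, identical gene
#'   universe.
#' @param params [de_params()] (reserved for future thresholds).
#' @return `data.frame` with `gene_id`, `tnf_response` (`up`/`down`/
#'   `none`), `soxc_dependence`; attribute `dependent_fraction` holds the
#'   share of responsive genes that are dependent.
#' @export
classify_response <- function(de_control, de_ko, params = de_params()) {
  if (!setequal(de_control$gene_id, de_ko$gene_id)) {
    stop("contrasts cover different gene universes")
  }
  ko <- de_ko[match(de_control$gene_id, de_ko$gene_id), ]
  resp <- ifelse(de_control$direction == "unchanged", "none", de_control$direction)
  dep <- rep("not_applicable", length(resp))
  r <- resp != "none"
  dep[r & ko$direction == "unchanged"] <- "dependent_unchanged"
  dep[r & ko$direction != "unchanged" & ko$direction != resp] <- "dependent_reversed"
  dep[r & ko$direction == resp] <- "independent"
  out <- data.frame(gene_id = de_control$gene_id,
                    tnf_response = resp, soxc_dependence = dep,
                    stringsAsFactors = FALSE)
  attr(out, "dependent_fraction") <- dependent_fraction(out)
  out
}

#' Share of responsive genes that are genotype-dependent
#'
#' @param labels Output of [classify_response()].
#' @return Fraction of responsive genes labeled `dependent_unchanged` or
#'   `dependent_reversed` (NA when no gene is responsive).
#' @export
dependent_fraction <- function(labels) {
  r <- labels$tnf_response != "none"
  if (!any(r)) return(NA_real_)
  mean(labels$soxc_dependence[r] %in%
         c("dependent_unchanged", "dependent_reversed"))
}
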