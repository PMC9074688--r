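# Consensus / PWM motif scanning over peak sequences, edit-and-rescan
# for binding-site mutation checks, and shuffled-background enrichment.
#
# The IUPAC matcher is written out explicitly because the package needs
# one precise degeneracy rule everywhere: an N in the *sequence* is
# treated as unknown and matches only the motif code N, while a motif
# code's degeneracy set applies to concrete sequence letters.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A",
                      R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                      B = "V", V = "B", D = "H", H = "D", N = "N")

#' Reverse complement of a DNA / IUPAC string
#'
#' @param seq Character string over the IUPAC alphabet.
#' @return Reverse-complemented string.
#' @export
reverse_complement <- function(seq) {
  chars <- rev(strsplit(toupper(seq), "")[[1]])
  bad <- setdiff(unique(chars), names(IUPAC_COMPLEMENT))
  if (length(bad)) stop("invalid character(s): ", paste(bad, collapse = ", "))
  paste(IUPAC_COMPLEMENT[chars], collapse = "")
}

#' Motif model (IUPAC consensus or count PWM)
#'
#' @param name Motif name.
#' @param consensus IUPAC consensus string (optional).
#' @param counts 4 x width count matrix with rows A, C, G, T (optional;
#'   at least one of `consensus`/`counts` is required).
#' @param pseudocount Laplace pseudocount alpha added per cell; column
#'   probabilities are `(count + alpha) / (N + 4 alpha)` for a uniform
#'   background (background-weighted for non-uniform backgrounds).
#' @param background Base frequency vector (A, C, G, T), default uniform.
#' @param score_threshold Minimum log-odds score in bits for a PWM hit
#'   (default 0).
#' @export
motif_model <- function(name, consensus = NULL, counts = NULL,
                        pseudocount = 1, background = rep(0.25, 4),
                        score_threshold = 0) {
  if (is.null(consensus) && is.null(counts)) {
    stop("provide a consensus and/or a count matrix")
  }
  if (!is.null(consensus)) {
    consensus <- toupper(consensus)
    bad <- setdiff(strsplit(consensus, "")[[1]], names(IUPAC_SETS))
    if (length(bad)) stop("consensus uses non-IUPAC code(s): ", paste(bad, collapse = ", "))
  }
  stopifnot(length(background) == 4, abs(sum(background) - 1) < 1e-9)
  probs <- NULL
  if (!is.null(counts)) {
    stopifnot(is.matrix(counts), nrow(counts) == 4)
    rownames(counts) <- c("A", "C", "G", "T")
    n <- colSums(counts)
    probs <- sweep(counts + pseudocount * 4 * background,
                   2, n + 4 * pseudocount, "/")
  }
  structure(list(name = name, consensus = consensus, counts = counts,
                 probs = probs, pseudocount = pseudocount,
                 background = background, score_threshold = score_threshold),
            class = "motif_model")
}

check_dna <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  bad <- setdiff(unique(chars), c("A", "C", "G", "T", "N"))
  if (length(bad)) stop("invalid sequence character(s): ", paste(bad, collapse = ", "))
  chars
}

# offsets (0-based) where the IUPAC pattern matches; sequence N matches
# only pattern code N
iupac_match_offsets <- function(seq_chars, pattern) {
  pat <- strsplit(pattern, "")[[1]]
  w <- length(pat)
  L <- length(seq_chars)
  if (w > L) return(integer())
  ok <- rep(TRUE, L - w + 1L)
  for (j in seq_len(w)) {
    sub <- seq_chars[j:(j + L - w)]
    allowed <- sub %in% IUPAC_SETS[[pat[j]]] & sub != "N"
    if (pat[j] == "N") allowed <- allowed | sub == "N"
    ok <- ok & allowed
  }
  which(ok) - 1L
}

#' Scan a sequence for an IUPAC consensus
#'
#' Both strands are scanned; minus-strand hits are reported at their
#' offset on the forward sequence.
#'
#' @param seq DNA string over A/C/G/T/N.
#' @param motif A [motif_model()] with a consensus.
#' @return `data.frame` of hits: `offset` (0-based), `strand`, `matched`
#'   (forward-strand substring), `score` (1 for exact consensus hits).
#' @export
scan_consensus <- function(seq, motif) {
  stopifnot(inherits(motif, "motif_model"), !is.null(motif$consensus))
  chars <- check_dna(seq)
  w <- nchar(motif$consensus)
  fwd <- iupac_match_offsets(chars, motif$consensus)
  rev_ <- iupac_match_offsets(chars, reverse_complement(motif$consensus))
  hit_df(c(fwd, rev_),
         c(rep("+", length(fwd)), rep("-", length(rev_))),
         chars, w,
         rep(1, length(fwd) + length(rev_)))
}

hit_df <- function(offsets, strands, chars, w, scores) {
  ord <- order(offsets, strands)
  data.frame(
    offset = offsets[ord],
    strand = strands[ord],
    matched = vapply(offsets[ord], function(o) {
      paste(chars[(o + 1):(o + w)], collapse = "")
    }, ""),
    score = scores[ord],
    stringsAsFactors = FALSE
  )
}

#' Scan a sequence with a PWM
#'
#' Log-odds score in bits against the background, summed over columns;
#' windows containing N score `-Inf`. Hits are windows with score at or
#' above `score_threshold`, on either strand (minus-strand windows are
#' scored on their reverse complement and reported at the forward
#' offset).
#'
#' @inheritParams scan_consensus
#' @param motif A [motif_model()] with a count matrix.
#' @return `data.frame` of hits with bit scores.
#' @export
scan_pwm <- function(seq, motif) {
  stopifnot(inherits(motif, "motif_model"), !is.null(motif$probs))
  chars <- check_dna(seq)
  w <- ncol(motif$probs)
  L <- length(chars)
  if (w > L) return(hit_df(integer(), character(), chars, w, numeric()))
  lod <- log2(sweep(motif$probs, 1, motif$background, "/"))
  score_at <- function(window) {
    if (any(window == "N")) return(-Inf)
    sum(lod[cbind(match(window, c("A", "C", "G", "T")), seq_len(w))])
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  offs <- integer(); strands <- character(); scores <- numeric()
  for (o in 0:(L - w)) {
    win <- chars[(o + 1):(o + w)]
    s_f <- score_at(win)
    if (s_f >= motif$score_threshold) {
      offs <- c(offs, o); strands <- c(strands, "+"); scores <- c(scores, s_f)
    }
    s_r <- score_at(rev(comp[win]))
    if (s_r >= motif$score_threshold) {
      offs <- c(offs, o); strands <- c(strands, "-"); scores <- c(scores, s_r)
    }
  }
  hit_df(offs, strands, chars, w, scores)
}

scan_motif <- function(seq, motif) {
  if (!is.null(motif$probs)) scan_pwm(seq, motif) else scan_consensus(seq, motif)
}

#' Apply sequence edits and rescan for motif hits
#'
#' Edits are given against the *original* sequence (1-based positions);
#' each `old` string must match the sequence at its position, otherwise
#' an error reports expected vs found (this guards against coordinate
#' convention slips). Replacements may change length; downstream
#' coordinates shift accordingly. Hits are matched before/after through
#' the induced coordinate map.
#'
#' @param seq DNA string.
#' @param edits List of `list(pos =, old =, new =)` edits (or a
#'   data.frame with those columns); `pos` is 1-based.
#' @param motif [motif_model()]; scanned with the PWM when present, else
#'   the consensus.
#' @return List with `hits_before`, `hits_after` (hit tables),
#'   `destroyed`, `created` (counts), and `seq_after`.
#' @export
mutate_and_rescan <- function(seq, edits, motif) {
  seq <- toupper(seq)
  if (is.data.frame(edits)) {
    edits <- lapply(seq_len(nrow(edits)), function(i) as.list(edits[i, ]))
  }
  for (e in edits) {
    found <- substr(seq, e$pos, e$pos + nchar(e$old) - 1)
    if (!identical(found, toupper(e$old))) {
      stop(sprintf("edit at position %d: expected '%s', found '%s'",
                   e$pos, e$old, found))
    }
  }
  hits_before <- scan_motif(seq, motif)
  # apply right-to-left so earlier positions stay valid
  ord <- order(vapply(edits, `[[`, 1, "pos"), decreasing = TRUE)
  seq_after <- seq
  for (e in edits[ord]) {
    seq_after <- paste0(substr(seq_after, 1, e$pos - 1), toupper(e$new),
                        substr(seq_after, e$pos + nchar(e$old), nchar(seq_after)))
  }
  hits_after <- scan_motif(seq_after, motif)
  # map a 0-based original offset to the edited sequence
  shift_for <- function(off) {
    s <- 0L
    for (e in edits) {
      if (e$pos - 1 + nchar(e$old) <= off) s <- s + nchar(e$new) - nchar(e$old)
    }
    off + s
  }
  before_keys <- paste(vapply(hits_before$offset, shift_for, 1L), hits_before$strand)
  after_keys <- paste(hits_after$offset, hits_after$strand)
  list(hits_before = hits_before, hits_after = hits_after,
       destroyed = sum(!before_keys %in% after_keys),
       created = sum(!after_keys %in% before_keys),
       seq_after = seq_after)
}

# Altschul-Erickson dinucleotide-preserving shuffle (Euler-path based):
# the shuffled sequence keeps the exact dinucleotide multiset.
dinuc_shuffle <- function(seq) {
  chars <- check_dna(seq)
  n <- length(chars)
  if (n < 3L) return(seq)
  verts <- unique(chars)
  last <- chars[n]
  out_edges <- split(chars[-1], chars[-n])  # targets per source vertex
  repeat {
    last_edge <- vapply(verts, function(v) {
      if (v == last || is.null(out_edges[[v]])) return(NA_character_)
      targets <- out_edges[[v]]
      targets[sample.int(length(targets), 1L)]
    }, "")
    # the chosen last-edges must lead every vertex to the terminal vertex
    ok <- TRUE
    for (v in verts) {
      if (v == last || is.null(out_edges[[v]])) next
      cur <- v; steps <- 0L
      while (cur != last && steps <= length(verts)) {
        cur <- last_edge[[cur]]
        if (is.na(cur)) break
        steps <- steps + 1L
      }
      if (is.na(cur) || cur != last) { ok <- FALSE; break }
    }
    if (ok) break
  }
  shuffled <- lapply(verts, function(v) {
    targets <- out_edges[[v]]
    if (is.null(targets)) return(character())
    if (v == last) return(sample(targets))
    drop_idx <- match(last_edge[[v]], targets)
    rest <- targets[-drop_idx]
    c(if (length(rest)) sample(rest) else character(), last_edge[[v]])
  })
  names(shuffled) <- verts
  used <- setNames(integer(length(verts)), verts)
  res <- character(n)
  res[1] <- chars[1]
  cur <- chars[1]
  for (i in 2:n) {
    used[cur] <- used[cur] + 1L
    nxt <- shuffled[[cur]][used[cur]]
    res[i] <- nxt
    cur <- nxt
  }
  paste(res, collapse = "")
}

#' Motif enrichment against dinucleotide-shuffled backgrounds
#'
#' Counts motif hits (both strands, overlapping hits all counted) in the
#' observed sequences and in `n_shuffles` rounds of per-sequence
#' dinucleotide-preserving shuffles. The empirical p-value is
#' `(1 + #null >= observed) / (n_shuffles + 1)` and is therefore bounded
#' below by `1 / (n_shuffles + 1)`.
#'
#' @param seqs Character vector of DNA sequences.
#' @param motif [motif_model()].
#' @param n_shuffles Number of shuffle rounds (>= 1, default 100).
#' @param seed Optional integer seed for the shuffles.
#' @return List with `observed`, `null_mean`, `null_sd`, `z`,
#'   `empirical_p`, `n_shuffles`.
#' @export
motif_enrichment <- function(seqs, motif, n_shuffles = 100L, seed = NULL) {
  stopifnot(n_shuffles >= 1)
  if (!is.null(seed)) set.seed(seed)
  w <- if (!is.null(motif$probs)) ncol(motif$probs) else nchar(motif$consensus)
  short <- nchar(seqs) < w
  if (any(short)) {
    warning(sum(short), " sequence(s) shorter than the motif contribute zero counts")
  }
  count_hits <- function(ss) {
    sum(vapply(ss, function(s) {
      if (nchar(s) < w) 0L else nrow(scan_motif(s, motif))
    }, 1L))
  }
  observed <- count_hits(seqs)
  null_counts <- vapply(seq_len(n_shuffles), function(i) {
    count_hits(vapply(seqs, dinuc_shuffle, ""))
  }, 1L)
  null_sd <- sd(null_counts)
  list(observed = observed,
       null_mean = mean(null_counts),
       null_sd = null_sd,
       z = if (isTRUE(null_sd > 0)) (observed - mean(null_counts)) / null_sd else NA_real_,
       empirical_p = (1 + sum(null_counts >= observed)) / (n_shuffles + 1),
       n_shuffles = n_shuffles)
}

#' Read sequences from FASTA
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta_seqs <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @export
write_fasta_seqs <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
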