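#' @keywords internal
AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", `*` = "Ter")

get_contig_seq <- function(genome, contig) {
  if (methods::is(genome, "DNAStringSet")) {
    if (!contig %in% names(genome)) stop("missing contig sequence: ", contig)
    return(as.character(genome[[contig]]))
  }
  if (is.character(genome)) {
    if (!contig %in% names(genome)) stop("missing contig sequence: ", contig)
    return(genome[[contig]])
  }
  stop("genome must be a named character vector or a DNAStringSet")
}

# spliced sequence of genomic intervals, 5'->3' in transcript orientation
extract_spliced <- function(intervals, contig_seq, strand) {
  s <- paste(substring(contig_seq, intervals$start + 1, intervals$end),
             collapse = "")
  if (strand == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  s
}

# 0-based genomic position -> 0-based transcript coordinate (NA if not exonic)
genomic_to_tx <- function(pos, exons, strand) {
  lens <- exons$end - exons$start
  offs <- cumsum(c(0L, lens))
  i <- which(pos >= exons$start & pos < exons$end)
  if (length(i) == 0) return(NA_integer_)
  t_plus <- offs[i] + (pos - exons$start[i])
  if (strand == "-") sum(lens) - 1L - t_plus else t_plus
}

# translate from position 1 to first stop; returns 1-letter residues and
# whether a stop codon was reached
translate_to_stop <- function(seq) {
  n <- 3L * (nchar(seq) %/% 3L)
  if (n == 0) return(list(peptide = character(0), stopped = FALSE))
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(seq, 1, n)), no.init.codon = TRUE))
  chars <- strsplit(aa, "")[[1]]
  stop_at <- match("*", chars)
  if (is.na(stop_at)) {
    list(peptide = chars, stopped = FALSE)
  } else {
    list(peptide = chars[seq_len(stop_at - 1)], stopped = TRUE)
  }
}

#' Predict the protein-level consequence of a splicing change
#'
#' Splices the candidate transcript's exonic sequence, locates the canonical
#' start codon on the genome within the candidate, and translates both the
#' canonical CDS and the candidate reading frame to their first stop codons.
#' The two peptides are then compared:
#'
#' * identical: `synonymous_structure`, `p.(=)`;
#' * a contiguous residue run deleted with frame and flanks preserved:
#'   `in_frame_deletion`, `p.<Xxx><i>_<Yyy><j>del` (single-residue deletions
#'   as `p.<Xxx><i>del`); the deletion is placed as far C-terminal as the
#'   flanking repeats allow (HGVS 3' rule, applied at the residue level);
#' * first divergent residue at position p with a new downstream frame:
#'   `frameshift`, `p.<Ref><p><New>fs*<n>` where n is the 1-based position of
#'   the new stop counting the divergent residue as 1 (`fs*?` when no stop is
#'   reached before the transcript ends);
#' * start codon absent from the candidate's exons: `start_lost`, `p.Met1?`;
#' * other patterns are kind `other`: frame-preserving but codon-misaligned
#'   deletions, whose splice joint forms one hybrid codon
#'   (`p.<X><i>_<Y><j>delins<Z>`), single-residue substitutions, clean
#'   insertions, C-terminal extensions, and immediate nonsense
#'   (`p.<X><p>Ter`).
#'
#' @param canonical a [transcript_model] with a CDS.
#' @param candidate a [transcript_model] on the same contig/strand.
#' @param genome named character vector (or `DNAStringSet`) of contig
#'   sequences covering all exons.
#' @return list with `hgvs_p`, `kind`, plus `canonical_peptide` and
#'   `candidate_peptide` (1-letter strings) for inspection.
#' @export
predict_protein_consequence <- function(canonical, candidate, genome) {
  stopifnot(inherits(canonical, "transcript_model"),
            inherits(candidate, "transcript_model"))
  if (is.null(canonical$cds)) stop("canonical model has no CDS")
  if (candidate$contig != canonical$contig ||
      candidate$strand != canonical$strand) {
    stop("candidate and canonical must share contig and strand")
  }
  contig_seq <- get_contig_seq(genome, canonical$contig)
  strand <- canonical$strand

  can_cds_seq <- extract_spliced(canonical$cds, contig_seq, strand)
  can_tr <- translate_to_stop(can_cds_seq)
  if (!can_tr$stopped) {
    # tolerated: CDS annotations often exclude the stop codon — extend the
    # reading frame through the 3' UTR of the canonical transcript
    tx_seq <- extract_spliced(canonical$exons, contig_seq, strand)
    start_pos0 <- if (strand == "+") min(canonical$cds$start) else
      max(canonical$cds$end) - 1L
    t0 <- genomic_to_tx(start_pos0, canonical$exons, strand)
    can_tr <- translate_to_stop(substr(tx_seq, t0 + 1, nchar(tx_seq)))
  }
  can_pep <- can_tr$peptide

  # genomic position of the first base of the start codon
  start_pos0 <- if (strand == "+") min(canonical$cds$start) else
    max(canonical$cds$end) - 1L
  t0 <- genomic_to_tx(start_pos0, candidate$exons, strand)
  if (is.na(t0)) {
    return(list(hgvs_p = "p.Met1?", kind = "start_lost",
                canonical_peptide = paste(can_pep, collapse = ""),
                candidate_peptide = NA_character_))
  }
  cand_tx <- extract_spliced(candidate$exons, contig_seq, strand)
  cand_tr <- translate_to_stop(substr(cand_tx, t0 + 1, nchar(cand_tx)))
  cand_pep <- cand_tr$peptide

  out <- compare_peptides(can_pep, cand_pep, cand_tr$stopped)
  out$canonical_peptide <- paste(can_pep, collapse = "")
  out$candidate_peptide <- paste(cand_pep, collapse = "")
  out
}

# decision procedure shared by documentation and tests; peptides are
# character vectors of 1-letter residues, without the stop
compare_peptides <- function(can, cand, cand_stopped) {
  n_can <- length(can)
  n_cand <- length(cand)
  if (n_can == n_cand && all(can == cand) && cand_stopped) {
    return(list(hgvs_p = "p.(=)", kind = "synonymous_structure"))
  }
  # longest common prefix
  lim <- min(n_can, n_cand)
  lcp <- 0L
  while (lcp < lim && can[lcp + 1] == cand[lcp + 1]) lcp <- lcp + 1L
  if (cand_stopped && n_cand < n_can) {
    d <- n_can - n_cand
    # clean deletion, pushed 3' by maximal common prefix
    if (lcp + d <= n_can &&
        (lcp == n_cand || all(can[(lcp + d + 1):n_can] == cand[(lcp + 1):n_cand]))) {
      i <- lcp + 1L
      j <- lcp + d
      hgvs <- if (d == 1) {
        sprintf("p.%s%ddel", AA3[[can[i]]], i)
      } else {
        sprintf("p.%s%d_%s%ddel", AA3[[can[i]]], i, AA3[[can[j]]], j)
      }
      return(list(hgvs_p = hgvs, kind = "in_frame_deletion"))
    }
    # frame-preserving deletion that is not codon-aligned: the splice joint
    # forms one hybrid codon, so a run of d + 1 canonical residues is
    # replaced by a single new residue (delins)
    if (lcp + 1L <= n_cand &&
        identical(if (lcp + d + 2L <= n_can) can[(lcp + d + 2L):n_can] else character(0),
                  if (lcp + 2L <= n_cand) cand[(lcp + 2L):n_cand] else character(0))) {
      i <- lcp + 1L
      j <- lcp + d + 1L
      return(list(hgvs_p = sprintf("p.%s%d_%s%ddelins%s", AA3[[can[i]]], i,
                                   AA3[[can[j]]], j, AA3[[cand[i]]]),
                  kind = "other"))
    }
  }
  if (cand_stopped && n_cand > n_can) {
    d <- n_cand - n_can
    if (lcp == n_can || all(cand[(lcp + d + 1):n_cand] == can[(lcp + 1):n_can])) {
      return(list(hgvs_p = "p.?", kind = "other"))  # clean in-frame insertion
    }
  }
  if (cand_stopped && n_cand == n_can && lcp < n_can &&
      identical(if (lcp + 2L <= n_can) can[(lcp + 2L):n_can] else character(0),
                if (lcp + 2L <= n_cand) cand[(lcp + 2L):n_cand] else character(0))) {
    # single-residue substitution with frame and flanks preserved
    p <- lcp + 1L
    return(list(hgvs_p = sprintf("p.%s%d%s", AA3[[can[p]]], p,
                                 AA3[[cand[p]]]),
                kind = "other"))
  }
  p <- lcp + 1L
  if (p > n_cand) {
    # candidate is a strict prefix: premature stop in the canonical frame
    if (cand_stopped && p <= n_can) {
      return(list(hgvs_p = sprintf("p.%s%dTer", AA3[[can[p]]], p),
                  kind = "other"))
    }
    return(list(hgvs_p = "p.?", kind = "other"))
  }
  if (p > n_can) {
    # canonical is a prefix of candidate: C-terminal extension
    return(list(hgvs_p = "p.?", kind = "other"))
  }
  n_str <- if (cand_stopped) sprintf("%d", n_cand - p + 2L) else "?"
  list(hgvs_p = sprintf("p.%s%d%sfs*%s", AA3[[can[p]]], p, AA3[[cand[p]]],
                        n_str),
       kind = "frameshift")
}
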