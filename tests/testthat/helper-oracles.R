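# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths (and Biostrings) so that agreement is a
# real cross-check, not a tautology.

# --- percent-spliced oracle: rescan all junctions for interval overlap ------
brute_force_ps <- function(tab) {
  j <- tab$junctions
  n <- nrow(j)
  ps <- matrix(NA_real_, n, ncol(tab$counts), dimnames = dimnames(tab$counts))
  for (i in seq_len(n)) {
    excl <- integer(0)
    for (k in seq_len(n)) {
      if (k == i) next
      if (j$contig[k] != j$contig[i]) next
      if (j$strand[i] != "*" && j$strand[k] != "*" &&
          j$strand[i] != j$strand[k]) next
      if (max(j$start[i], j$start[k]) < min(j$end[i], j$end[k])) {
        excl <- c(excl, k)
      }
    }
    for (s in seq_len(ncol(tab$counts))) {
      denom <- tab$counts[i, s] + sum(tab$counts[excl, s])
      if (denom > 0) ps[i, s] <- tab$counts[i, s] / denom
    }
  }
  ps
}

random_junction_table <- function(n_junctions, n_samples) {
  repeat {
    contig <- sample(c("chr1", "chr2"), n_junctions, replace = TRUE)
    start <- sample(0:5000, n_junctions, replace = TRUE)
    len <- sample(50:2000, n_junctions, replace = TRUE)
    strand <- sample(c("+", "-", "*"), n_junctions, replace = TRUE)
    j <- data.frame(contig = contig, start = start, end = start + len,
                    strand = strand)
    if (!anyDuplicated(paste(j$contig, j$start, j$end, j$strand))) break
  }
  counts <- matrix(stats::rpois(n_junctions * n_samples, 20), n_junctions,
                   dimnames = list(NULL, paste0("s", seq_len(n_samples))))
  counts[sample(length(counts), length(counts) %/% 4)] <- 0L
  junction_counts(j, counts)
}

# --- independent translator and consequence oracle --------------------------
ORACLE_CODONS <- local({
  bases <- c("T", "C", "A", "G")
  # standard genetic code in TCAG order, third base fastest
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W", "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR", "VVVVAAAADDEEGGGG"), "")[[1]]
  stats::setNames(aas, sapply(0:63, function(i) {
    paste0(bases[i %/% 16 + 1], bases[(i %/% 4) %% 4 + 1], bases[i %% 4 + 1])
  }))
})

oracle_translate <- function(seq) {
  n <- nchar(seq) %/% 3L
  pep <- character(0)
  stopped <- FALSE
  for (i in seq_len(n)) {
    aa <- ORACLE_CODONS[[substr(seq, 3 * i - 2, 3 * i)]]
    if (aa == "*") { stopped <- TRUE; break }
    pep <- c(pep, aa)
  }
  list(peptide = pep, stopped = stopped)
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTU", "TGCAA", toupper(s)), "")[[1]]),
        collapse = "")
}

oracle_spliced <- function(intervals, contig_seq, strand) {
  s <- paste(substring(contig_seq, intervals$start + 1, intervals$end),
             collapse = "")
  if (strand == "-") oracle_revcomp(s) else s
}

AA3_ORACLE <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
                Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
                L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
                S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val")

# consequence of skipping internal exons (transcription-order ordinals) of a
# canonical model, computed from first principles on character vectors
oracle_skip_consequence <- function(gene, ordinals) {
  canonical <- gene$canonical
  contig_seq <- gene$genome[[1]]
  strand <- canonical$strand
  n <- nrow(canonical$exons)
  genomic_idx <- if (strand == "-") n + 1L - ordinals else ordinals

  can_pep <- oracle_translate(oracle_spliced(canonical$cds, contig_seq,
                                             strand))$peptide

  cand_exons <- canonical$exons[-genomic_idx, , drop = FALSE]
  cand_tx <- oracle_spliced(cand_exons, contig_seq, strand)
  # transcript offset of the start codon in the candidate
  start_pos0 <- if (strand == "+") min(canonical$cds$start) else
    max(canonical$cds$end) - 1L
  ex_order <- if (strand == "-") rev(seq_len(nrow(cand_exons))) else
    seq_len(nrow(cand_exons))
  t0 <- NA_integer_
  off <- 0L
  for (i in ex_order) {
    if (start_pos0 >= cand_exons$start[i] && start_pos0 < cand_exons$end[i]) {
      within <- if (strand == "+") start_pos0 - cand_exons$start[i] else
        cand_exons$end[i] - 1L - start_pos0
      t0 <- off + within
      break
    }
    off <- off + cand_exons$end[i] - cand_exons$start[i]
  }
  if (is.na(t0)) return(list(hgvs_p = "p.Met1?", kind = "start_lost"))
  cand_tr <- oracle_translate(substr(cand_tx, t0 + 1, nchar(cand_tx)))
  cand_pep <- cand_tr$peptide

  # decision procedure, re-derived: identity, clean indel, else frameshift
  if (length(can_pep) == length(cand_pep) && all(can_pep == cand_pep) &&
      cand_tr$stopped) {
    return(list(hgvs_p = "p.(=)", kind = "synonymous_structure"))
  }
  lcp <- 0L
  while (lcp < min(length(can_pep), length(cand_pep)) &&
         can_pep[lcp + 1] == cand_pep[lcp + 1]) lcp <- lcp + 1L
  d <- length(can_pep) - length(cand_pep)
  seg <- function(v, from) if (from <= length(v)) v[from:length(v)] else
    character(0)
  if (cand_tr$stopped && d > 0) {
    tail_can <- seg(can_pep, lcp + d + 1L)
    tail_cand <- seg(cand_pep, lcp + 1L)
    if (length(tail_can) == length(tail_cand) && all(tail_can == tail_cand)) {
      i <- lcp + 1L
      j <- lcp + d
      hg <- if (d == 1) sprintf("p.%s%ddel", AA3_ORACLE[[can_pep[i]]], i) else
        sprintf("p.%s%d_%s%ddel", AA3_ORACLE[[can_pep[i]]], i,
                AA3_ORACLE[[can_pep[j]]], j)
      return(list(hgvs_p = hg, kind = "in_frame_deletion"))
    }
    # codon-misaligned in-frame deletion: d + 1 residues collapse to the one
    # hybrid-codon residue
    if (lcp + 1L <= length(cand_pep) &&
        identical(seg(can_pep, lcp + d + 2L), seg(cand_pep, lcp + 2L))) {
      i <- lcp + 1L
      j <- lcp + d + 1L
      return(list(hgvs_p = sprintf("p.%s%d_%s%ddelins%s",
                                   AA3_ORACLE[[can_pep[i]]], i,
                                   AA3_ORACLE[[can_pep[j]]], j,
                                   AA3_ORACLE[[cand_pep[i]]]),
                  kind = "other"))
    }
  }
  if (cand_tr$stopped && d == 0 && lcp < length(can_pep) &&
      identical(seg(can_pep, lcp + 2L), seg(cand_pep, lcp + 2L))) {
    p <- lcp + 1L
    return(list(hgvs_p = sprintf("p.%s%d%s", AA3_ORACLE[[can_pep[p]]], p,
                                 AA3_ORACLE[[cand_pep[p]]]),
                kind = "other"))
  }
  if (cand_tr$stopped && d < 0) {
    tail_can <- if (lcp < length(can_pep)) can_pep[(lcp + 1):length(can_pep)]
      else character(0)
    tail_cand <- if (lcp - d < length(cand_pep)) {
      cand_pep[(lcp - d + 1):length(cand_pep)]
    } else character(0)
    if (length(tail_can) == length(tail_cand) && all(tail_can == tail_cand)) {
      return(list(hgvs_p = "p.?", kind = "other"))
    }
  }
  p <- lcp + 1L
  if (p > length(cand_pep)) {
    if (cand_tr$stopped && p <= length(can_pep)) {
      return(list(hgvs_p = sprintf("p.%s%dTer", AA3_ORACLE[[can_pep[p]]], p),
                  kind = "other"))
    }
    return(list(hgvs_p = "p.?", kind = "other"))
  }
  if (p > length(can_pep)) return(list(hgvs_p = "p.?", kind = "other"))
  n_str <- if (cand_tr$stopped) sprintf("%d", length(cand_pep) - p + 2L) else "?"
  list(hgvs_p = sprintf("p.%s%d%sfs*%s", AA3_ORACLE[[can_pep[p]]], p,
                        AA3_ORACLE[[cand_pep[p]]], n_str),
       kind = "frameshift")
}
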