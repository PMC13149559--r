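#' Per-gene isoform fractions from TPM
#'
#' The fraction of a gene's expression carried by each isoform is its TPM
#' divided by the gene's summed TPM. Genes whose isoforms sum to zero TPM get
#' `NA` fractions (undefined, reported rather than dropped).
#'
#' @param abundances data.frame with columns `transcript_id`, `gene_id`,
#'   `tpm` (all TPM values must be non-negative).
#' @return The input with a `fraction` column appended; within each gene the
#'   non-NA fractions sum to 1 (tolerance 1e-9).
#' @export
isoform_fractions <- function(abundances) {
  required <- c("transcript_id", "gene_id", "tpm")
  if (!all(required %in% names(abundances))) {
    stop("abundance table needs columns: ", paste(required, collapse = ", "))
  }
  if (any(abundances$tpm < 0)) stop("negative TPM")
  totals <- tapply(abundances$tpm, abundances$gene_id, sum)
  denom <- as.numeric(totals[as.character(abundances$gene_id)])
  abundances$fraction <- ifelse(denom > 0, abundances$tpm / denom, NA_real_)
  abundances
}

#' Read an isoform abundance TSV (transcript_id, gene_id, TPM)
#'
#' @param path TSV path with header; the TPM column may be named `tpm` or
#'   `TPM`.
#' @return data.frame with `transcript_id`, `gene_id`, `tpm`.
#' @export
read_abundance_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  names(df)[names(df) == "TPM"] <- "tpm"
  required <- c("transcript_id", "gene_id", "tpm")
  if (!all(required %in% names(df))) {
    stop("abundance TSV needs columns transcript_id, gene_id, TPM")
  }
  df[, required]
}

#' Classify an isoform's structure against the canonical transcript
#'
#' Comparison is by intron chain (the set of splice junctions), not exon
#' endpoints, so terminal-exon length differences do not change the category:
#' * identical intron chains: `canonical_match`;
#' * the candidate chain equals the canonical chain with one or more runs of
#'   consecutive canonical introns merged across whole skipped exon(s):
#'   `exon_skipping`, with the skipped exon ordinals (1-based, in
#'   transcription order) in `detail`;
#' * same number of introns, identical except exactly one intron with exactly
#'   one boundary moved: `altered_splice_site`, with the shifted genomic
#'   coordinate in `detail`;
#' * anything else: `other`.
#'
#' @param candidate,canonical [transcript_model] objects on the same contig
#'   and strand.
#' @return list with `transcript_id`, `category`, `detail`
#'   (`skipped_exons` integer vector for exon skipping; `new_coordinate` and
#'   `side` for an altered splice site; NULL otherwise).
#' @export
classify_isoform <- function(candidate, canonical) {
  stopifnot(inherits(candidate, "transcript_model"),
            inherits(canonical, "transcript_model"))
  if (candidate$contig != canonical$contig ||
      candidate$strand != canonical$strand) {
    stop("candidate and canonical must share contig and strand")
  }
  can_in <- intron_chain(canonical)
  cand_in <- intron_chain(candidate)
  res <- function(category, detail = NULL) {
    list(transcript_id = candidate$transcript_id, category = category,
         detail = detail)
  }
  if (nrow(can_in) == nrow(cand_in) &&
      all(can_in$start == cand_in$start) && all(can_in$end == cand_in$end)) {
    return(res("canonical_match"))
  }

  # exon skipping: every candidate intron is either a canonical intron or a
  # merge [start of canonical intron i, end of canonical intron j], i < j,
  # skipping canonical exons i+1 .. j; all canonical introns are accounted for
  if (nrow(cand_in) > 0 && nrow(can_in) > 1) {
    skipped <- integer(0)
    covered <- logical(nrow(can_in))
    ok <- TRUE
    for (r in seq_len(nrow(cand_in))) {
      i <- match(cand_in$start[r], can_in$start)
      j <- match(cand_in$end[r], can_in$end)
      if (is.na(i) || is.na(j) || j < i) { ok <- FALSE; break }
      if (any(covered[i:j])) { ok <- FALSE; break }
      covered[i:j] <- TRUE
      if (j > i) skipped <- c(skipped, (i + 1):j)  # genomic exon indices
    }
    if (ok && all(covered) && length(skipped) > 0) {
      n_exons <- nrow(canonical$exons)
      ordinals <- if (canonical$strand == "-") n_exons + 1L - skipped else skipped
      return(res("exon_skipping",
                 list(skipped_exons = sort(as.integer(ordinals)))))
    }
  }

  # altered splice site: same chain length, exactly one intron differs, in
  # exactly one boundary
  if (nrow(cand_in) == nrow(can_in) && nrow(can_in) > 0) {
    diff_start <- cand_in$start != can_in$start
    diff_end <- cand_in$end != can_in$end
    changed <- which(diff_start | diff_end)
    if (length(changed) == 1) {
      k <- changed
      if (xor(diff_start[k], diff_end[k])) {
        if (diff_start[k]) {
          # intron start moved: the upstream exon's 3' (genomic-right) edge
          new_coord <- cand_in$start[k]
          side <- if (canonical$strand == "+") "donor" else "acceptor"
        } else {
          new_coord <- cand_in$end[k]
          side <- if (canonical$strand == "+") "acceptor" else "donor"
        }
        return(res("altered_splice_site",
                   list(new_coordinate = new_coord, side = side,
                        intron_index = k)))
      }
    }
  }
  res("other")
}
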