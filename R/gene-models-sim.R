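#' Simulate a toy multi-exon gene with genome sequence and CDS
#'
#' Builds a deterministic (seeded) single-gene world for exercising the
#' isoform classification and protein-consequence machinery: a random contig
#' sequence, a canonical multi-exon transcript whose CDS starts in the first
#' exon and ends in the last, translates cleanly (ATG start, no internal
#' stops, terminal stop codon), and optional exon lengths/strand. The CDS
#' length is always a multiple of 3.
#'
#' @param seed integer seed.
#' @param n_exons number of exons (>= 2; default 3).
#' @param exon_lengths optional integer vector of exon lengths; random in
#'   60..180 nt otherwise.
#' @param strand `"+"` or `"-"` (default `"+"`).
#' @return list with `genome` (named character vector, one contig),
#'   `canonical` (a [transcript_model] with CDS), and `exon_lengths`.
#' @export
simulate_gene_models <- function(seed = 1L, n_exons = 3, exon_lengths = NULL,
                                 strand = "+") {
  stopifnot(n_exons >= 2, strand %in% c("+", "-"))
  set.seed(seed)
  if (is.null(exon_lengths)) {
    exon_lengths <- sample(60:180, n_exons, replace = TRUE)
  }
  stopifnot(length(exon_lengths) == n_exons, all(exon_lengths >= 30))
  intron_lengths <- sample(80:300, n_exons - 1, replace = TRUE)

  starts <- integer(n_exons)
  starts[1] <- 100L
  for (i in seq_len(n_exons - 1)) {
    starts[i + 1] <- starts[i] + exon_lengths[i] + intron_lengths[i]
  }
  ends <- starts + exon_lengths
  contig_len <- ends[n_exons] + 100L

  # CDS: from an offset inside the 5' terminal exon to inside the 3' one
  # (in transcription order); trimmed to a multiple of 3
  utr5 <- 15L
  utr3 <- 10L
  cds_len <- sum(exon_lengths) - utr5 - utr3
  cds_len <- cds_len - cds_len %% 3L
  utr3 <- sum(exon_lengths) - utr5 - cds_len

  # coding sequence: ATG + non-stop codons + stop
  codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                              c("A", "C", "G", "T")), 1, paste, collapse = "")
  sense <- setdiff(codons, c("TAA", "TAG", "TGA"))
  n_codons <- cds_len %/% 3L
  coding <- paste0("ATG",
                   paste(sample(sense, n_codons - 2, replace = TRUE),
                         collapse = ""),
                   "TAA")

  # transcript (mRNA) sequence with UTRs
  mrna <- paste0(paste(sample(c("A", "C", "G", "T"), utr5, replace = TRUE),
                       collapse = ""),
                 coding,
                 paste(sample(c("A", "C", "G", "T"), utr3, replace = TRUE),
                       collapse = ""))

  # lay the transcript down on the contig exon by exon (transcription order)
  contig <- sample(c("A", "C", "G", "T"), contig_len, replace = TRUE)
  tx_order <- if (strand == "+") seq_len(n_exons) else rev(seq_len(n_exons))
  mrna_chars <- strsplit(mrna, "")[[1]]
  pos <- 0L
  for (i in tx_order) {
    piece <- mrna_chars[(pos + 1):(pos + exon_lengths[i])]
    if (strand == "-") {
      piece <- rev(chartr("ACGT", "TGCA", piece))
    }
    contig[(starts[i] + 1):ends[i]] <- piece
    pos <- pos + exon_lengths[i]
  }
  genome <- stats::setNames(paste(contig, collapse = ""), "chrS")

  # CDS genomic intervals: drop utr5 from the 5' end, utr3 from the 3' end
  exons <- data.frame(start = starts, end = ends)
  cds <- exons
  if (strand == "+") {
    cds$start[1] <- cds$start[1] + utr5
    cds$end[n_exons] <- cds$end[n_exons] - utr3
  } else {
    cds$end[n_exons] <- cds$end[n_exons] - utr5
    cds$start[1] <- cds$start[1] + utr3
  }
  canonical <- transcript_model("TX_CANON", "GENE1", "chrS", strand, exons,
                                cds = cds)
  list(genome = genome, canonical = canonical, exon_lengths = exon_lengths)
}

#' Derive an exon-skipping candidate from a canonical model
#'
#' Removes the given internal exons (1-based ordinals in transcription
#' order), merging the flanking introns — the structural signature of exon
#' skipping. The CDS is dropped from the candidate (it is a novel isoform
#' whose coding potential is what [predict_protein_consequence()] infers).
#'
#' @param model a [transcript_model].
#' @param ordinals internal exon ordinals to skip (transcription order).
#' @return a new [transcript_model] without those exons.
#' @export
skip_exons <- function(model, ordinals) {
  n <- nrow(model$exons)
  genomic <- if (model$strand == "-") n + 1L - ordinals else ordinals
  if (any(genomic <= 1 | genomic >= n)) {
    stop("only internal exons can be skipped")
  }
  transcript_model(paste0(model$transcript_id, "_skip",
                          paste(ordinals, collapse = "_")),
                   model$gene_id, model$contig, model$strand,
                   model$exons[-genomic, , drop = FALSE])
}
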