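#' Reverse complement of a nucleotide sequence, in the DNA alphabet
#'
#' RNA input is accepted (U pairs like T); the result is always DNA, since
#' antisense oligonucleotides are synthesized as modified DNA. N is preserved.
#'
#' @param seq character scalar over A/C/G/T/U/N (case-insensitive).
#' @return reverse-complement DNA string, upper case.
#' @export
reverse_complement <- function(seq) {
  s <- toupper(seq)
  s <- chartr("U", "T", s)
  if (!grepl("^[ACGTN]*$", s)) stop("sequence alphabet must be A/C/G/T/U/N")
  if (nchar(s) == 0) return("")
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Design a tiled antisense-oligonucleotide (ASO) walk
#'
#' Slides a k-nt window along the target pre-mRNA region at a fixed stride
#' and emits, for each window, the reverse-complement DNA oligo together with
#' its chemistry annotation. Defaults follow common splice-modulation
#' practice: 18-mers with a 2'-O-methoxyethyl (2'MOE) sugar at every position
#' and a full phosphorothioate backbone for nuclease resistance. Windows
#' containing N are emitted but flagged.
#'
#' @param target nucleotide sequence (DNA or RNA alphabet, N allowed).
#' @param k oligo length in nt (default 18).
#' @param step stride between consecutive window starts (default 1, a dense
#'   walk; thin afterwards as needed).
#' @param sugar_chemistry,backbone chemistry labels recorded per design.
#' @return data.frame, one row per ASO: `aso_id`, `start_offset` (0-based
#'   window start on the target), `length`, `sequence` (reverse-complement
#'   DNA), `sugar_chemistry`, `backbone`, `contains_n`.
#' @export
design_walk <- function(target, k = 18, step = 1,
                        sugar_chemistry = "2'MOE", backbone = "phosphorothioate") {
  if (k <= 0 || step <= 0) stop("k and step must be positive")
  s <- toupper(target)
  s <- chartr("U", "T", s)
  if (!grepl("^[ACGTN]+$", s)) stop("sequence alphabet must be A/C/G/T/U/N")
  L <- nchar(s)
  if (L < k) stop("target shorter than k")
  offsets <- seq(0L, L - k, by = step)
  windows <- substring(s, offsets + 1, offsets + k)
  seqs <- vapply(windows, reverse_complement, character(1), USE.NAMES = FALSE)
  has_n <- grepl("N", windows, fixed = TRUE)
  if (any(has_n)) {
    warning(sum(has_n), " window(s) contain N and are flagged")
  }
  data.frame(aso_id = sprintf("ASO_%03d", seq_along(offsets)),
             start_offset = offsets,
             length = k,
             sequence = seqs,
             sugar_chemistry = sugar_chemistry,
             backbone = backbone,
             contains_n = has_n)
}

#' Read a single-sequence FASTA target
#'
#' @param path FASTA path; the first record is used.
#' @return character scalar sequence.
#' @export
read_fasta_target <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0) stop("no sequences in ", path)
  as.character(set[[1]])
}

#' Write an ASO walk as TSV
#'
#' @param designs data.frame from [design_walk()].
#' @param path output path.
#' @export
write_aso_tsv <- function(designs, path) {
  utils::write.table(designs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
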