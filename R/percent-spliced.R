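#' Build mutually-exclusive (exclusion) junction sets
#'
#' For each junction, the exclusion set collects every other junction whose
#' intron interval overlaps it: reads supporting such a junction represent an
#' alternative splicing outcome over the same genomic interval, so they enter
#' the percent-spliced denominator. Overlap is intersection of nonzero length
#' under half-open semantics — two introns sharing only a boundary coordinate
#' do not overlap. Junctions on explicitly opposite strands never exclude each
#' other; unknown strand (`"*"`) matches both.
#'
#' @param junctions data.frame of junctions (`contig`, `start`, `end`,
#'   `strand`; 0-based half-open), e.g. the `$junctions` slot of a
#'   [junction_counts] table.
#' @return A list, one element per junction (in input order), each an integer
#'   vector of row indices of the overlapping junctions. The relation is
#'   symmetric and irreflexive.
#' @export
build_exclusion_sets <- function(junctions) {
  n <- nrow(junctions)
  if (n == 0) return(list())
  # half-open [start, end) -> 1-based closed [start+1, end]; nonzero-length
  # intersection of half-open intervals == closed-interval overlap here
  gr <- GenomicRanges::GRanges(
    seqnames = junctions$contig,
    ranges = IRanges::IRanges(start = junctions$start + 1L,
                              end = junctions$end),
    strand = junctions$strand)
  hits <- GenomicRanges::findOverlaps(gr, gr, ignore.strand = FALSE)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  keep <- q != s
  out <- split(s[keep], factor(q[keep], levels = seq_len(n)))
  out <- lapply(out, function(v) sort(unname(v)))
  names(out) <- junction_key(junctions)
  out
}

#' Percent-spliced (PS) quantification
#'
#' For junction j and sample s,
#' `PS(j, s) = count(j, s) / (count(j, s) + sum of counts of j's exclusion
#' junctions in s)`. The value is `NA` when the denominator is zero (the
#' junction and all its competitors are unobserved in that sample). A junction
#' with an empty exclusion set has PS 1 wherever it has any reads.
#'
#' @param table a [junction_counts] object.
#' @param exclusion exclusion sets from [build_exclusion_sets()] over the same
#'   junctions; computed internally if omitted.
#' @return A `ps_matrix` object: list with `junctions` (data.frame) and `ps`
#'   (junction-by-sample numeric matrix in `[0, 1]`, `NA` where undefined).
#' @export
percent_spliced <- function(table, exclusion = NULL) {
  stopifnot(inherits(table, "junction_counts"))
  if (is.null(exclusion)) exclusion <- build_exclusion_sets(table$junctions)
  n <- nrow(table$junctions)
  if (length(exclusion) != n) {
    stop("exclusion sets do not match the table's junctions")
  }
  counts <- table$counts
  ps <- matrix(NA_real_, nrow = n, ncol = ncol(counts),
               dimnames = dimnames(counts))
  for (i in seq_len(n)) {
    excl <- exclusion[[i]]
    denom <- counts[i, ] + if (length(excl) > 0) {
      colSums(counts[excl, , drop = FALSE])
    } else 0
    ok <- denom > 0
    ps[i, ok] <- counts[i, ok] / denom[ok]
  }
  structure(list(junctions = table$junctions, ps = ps), class = "ps_matrix")
}

#' @export
print.ps_matrix <- function(x, ...) {
  cat(sprintf("ps_matrix: %d junctions x %d samples (%d missing values)\n",
              nrow(x$ps), ncol(x$ps), sum(is.na(x$ps))))
  invisible(x)
}

#' Write a PS matrix as TSV
#'
#' One row per junction (contig, start, end, strand, then one column per
#' sample); missing PS written as NA.
#'
#' @param psm a `ps_matrix` from [percent_spliced()].
#' @param path output path.
#' @export
write_ps_tsv <- function(psm, path) {
  stopifnot(inherits(psm, "ps_matrix"))
  out <- cbind(psm$junctions, as.data.frame(psm$ps, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a PS matrix written by [write_ps_tsv()]
#'
#' @param path input TSV path.
#' @return A `ps_matrix` object.
#' @export
read_ps_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  jcols <- c("contig", "start", "end", "strand")
  if (!all(jcols %in% names(df))) stop("not a PS matrix TSV")
  ps <- as.matrix(df[, setdiff(names(df), jcols), drop = FALSE])
  junctions <- df[, jcols]
  rownames(ps) <- junction_key(junctions)
  structure(list(junctions = junctions, ps = ps), class = "ps_matrix")
}
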