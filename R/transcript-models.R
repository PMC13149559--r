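#' Construct a transcript model
#'
#' A transcript model is an exon chain on a genome: ordered, disjoint exon
#' intervals stored 0-based half-open, plus an optional CDS (also as genomic
#' intervals, a subset of the exons). All interval arithmetic in the package
#' stays genomic; strand only matters when sequence is extracted.
#'
#' @param transcript_id,gene_id identifiers.
#' @param contig contig/chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons data.frame with `start`, `end` (0-based half-open), any order;
#'   sorted and validated here.
#' @param cds optional data.frame with `start`, `end` for the coding region.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, contig, strand, exons,
                             cds = NULL) {
  stopifnot(strand %in% c("+", "-"))
  exons <- as.data.frame(exons)[, c("start", "end")]
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (any(exons$start >= exons$end)) stop("exon start must be < end")
  if (nrow(exons) > 1 && any(exons$start[-1] < exons$end[-nrow(exons)])) {
    stop("exons overlap in transcript ", transcript_id)
  }
  if (!is.null(cds)) {
    cds <- as.data.frame(cds)[, c("start", "end")]
    cds <- cds[order(cds$start), , drop = FALSE]
    rownames(cds) <- NULL
    # every CDS chunk must lie within some exon
    inside <- vapply(seq_len(nrow(cds)), function(i) {
      any(cds$start[i] >= exons$start & cds$end[i] <= exons$end)
    }, logical(1))
    if (!all(inside)) stop("CDS intervals must be contained in exons")
  }
  structure(list(transcript_id = transcript_id, gene_id = gene_id,
                 contig = contig, strand = strand, exons = exons, cds = cds),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript_model %s (%s) %s:%s, %d exon(s)%s\n",
              x$transcript_id, x$gene_id, x$contig, x$strand, nrow(x$exons),
              if (is.null(x$cds)) "" else sprintf(", CDS %d segment(s)",
                                                  nrow(x$cds))))
  invisible(x)
}

#' Intron chain of a transcript model
#'
#' @param model a [transcript_model].
#' @return data.frame of intron intervals (`start`, `end`, 0-based half-open)
#'   in genomic order; zero rows for a single-exon transcript.
#' @export
intron_chain <- function(model) {
  ex <- model$exons
  n <- nrow(ex)
  if (n < 2) return(data.frame(start = integer(), end = integer()))
  data.frame(start = ex$end[-n], end = ex$start[-1])
}

#' Read transcript models from a GTF file
#'
#' Uses the standard GTF 2.2 conventions: `exon` (and optionally `CDS`)
#' features carrying `gene_id` and `transcript_id` attributes, 1-based
#' inclusive coordinates (converted to 0-based half-open internally).
#'
#' @param path GTF file path.
#' @return Named list of [transcript_model] objects, keyed by transcript id.
#' @export
parse_gtf_transcripts <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  md <- S4Vectors::mcols(gr)
  keep <- md$type %in% c("exon", "CDS")
  gr <- gr[keep]
  md <- S4Vectors::mcols(gr)
  if (length(gr) == 0) return(list())
  if (is.null(md$transcript_id) || anyNA(md$transcript_id)) {
    stop("GTF exon/CDS feature missing transcript_id attribute in ", path)
  }
  if (is.null(md$gene_id) || anyNA(md$gene_id)) {
    stop("GTF exon/CDS feature missing gene_id attribute in ", path)
  }
  df <- data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,  # 1-based inclusive -> 0-based
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(md$type),
    transcript_id = md$transcript_id,
    gene_id = md$gene_id)
  models <- lapply(split(df, df$transcript_id), function(d) {
    ex <- d[d$type == "exon", c("start", "end")]
    if (nrow(ex) == 0) stop("transcript without exon features: ",
                            d$transcript_id[1])
    cds <- d[d$type == "CDS", c("start", "end")]
    transcript_model(d$transcript_id[1], d$gene_id[1], d$contig[1],
                     d$strand[1], ex,
                     cds = if (nrow(cds) > 0) cds else NULL)
  })
  models[order(names(models))]
}

#' Write transcript models as GTF
#'
#' Emits `exon` (and `CDS`, where present) features in GTF 2.2 with 1-based
#' inclusive coordinates; inverse of [parse_gtf_transcripts()].
#'
#' @param models list of [transcript_model] objects.
#' @param path output path.
#' @export
write_gtf_transcripts <- function(models, path) {
  lines <- character(0)
  for (m in models) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";', m$gene_id,
                     m$transcript_id)
    lines <- c(lines, sprintf("%s\tvusplice\texon\t%d\t%d\t.\t%s\t.\t%s",
                              m$contig, m$exons$start + 1L, m$exons$end,
                              m$strand, attrs))
    if (!is.null(m$cds)) {
      lines <- c(lines, sprintf("%s\tvusplice\tCDS\t%d\t%d\t.\t%s\t0\t%s",
                                m$contig, m$cds$start + 1L, m$cds$end,
                                m$strand, attrs))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
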