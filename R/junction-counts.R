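#' Construct a junction count table
#'
#' A junction count table holds a set of splice junctions (intron intervals)
#' together with a junction-by-sample matrix of read counts. It is the
#' substrate of percent-spliced (PS) quantification: each row is one intron,
#' stored 0-based half-open on the genome, and each column one sample.
#'
#' @param junctions data.frame with columns `contig` (character),
#'   `start` (0-based inclusive first intron base), `end` (0-based exclusive,
#'   i.e. one past the last intron base) and `strand` (`"+"`, `"-"` or `"*"`
#'   for unknown).
#' @param counts numeric matrix of non-negative integers, one row per
#'   junction, one column per sample; column names are sample ids.
#' @return An object of class `junction_counts`.
#' @export
junction_counts <- function(junctions, counts) {
  junctions <- as.data.frame(junctions)
  required <- c("contig", "start", "end", "strand")
  missing_cols <- setdiff(required, names(junctions))
  if (length(missing_cols) > 0) {
    stop("junctions is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  junctions$contig <- as.character(junctions$contig)
  junctions$strand <- as.character(junctions$strand)
  if (any(!nzchar(junctions$contig))) stop("contig names must be non-empty")
  if (!all(junctions$strand %in% c("+", "-", "*"))) {
    stop("strand must be one of '+', '-', '*'")
  }
  if (any(junctions$start >= junctions$end)) {
    stop("intron start must be < intron end (0-based half-open)")
  }
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(junctions)) {
    stop("counts must have one row per junction")
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("sample", seq_len(ncol(counts)))
  }
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (any(counts < 0)) stop("counts must be non-negative")
  keys <- junction_key(junctions)
  if (anyDuplicated(keys)) stop("duplicate junctions")
  if (nrow(counts) > 0) rownames(counts) <- keys
  rownames(junctions) <- NULL
  structure(list(junctions = junctions, counts = counts),
            class = "junction_counts")
}

junction_key <- function(junctions) {
  paste0(junctions$contig, ":", junctions$start, "-", junctions$end,
         ":", junctions$strand)
}

#' @export
print.junction_counts <- function(x, ...) {
  cat(sprintf("junction_counts: %d junctions x %d samples\n",
              nrow(x$junctions), ncol(x$counts)))
  invisible(x)
}

#' @export
dim.junction_counts <- function(x) dim(x$counts)

#' Read a STAR splice-junction file (SJ.out.tab dialect)
#'
#' Parses the 9-column tab-separated junction output written by the STAR
#' aligner. STAR reports introns 1-based inclusive; they are converted to the
#' 0-based half-open convention used internally (`start = col2 - 1`,
#' `end = col3`). The strand code (0/1/2) maps to unknown/plus/minus. By
#' default only the uniquely-mapping read count (column 7) is used;
#' multi-mapping reads (column 8) can be added with `multimappers = TRUE`.
#'
#' @param path path to an SJ.out.tab-style file.
#' @param sample_id sample id for the resulting single-sample table; defaults
#'   to the file name without extension.
#' @param multimappers if `TRUE`, add the multi-mapping read count to the
#'   unique count. Default `FALSE` (conservative).
#' @return A single-sample [junction_counts] object.
#' @export
parse_star_sj <- function(path, sample_id = NULL, multimappers = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sample_id)) {
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(junction_counts(
      data.frame(contig = character(), start = integer(), end = integer(),
                 strand = character()),
      matrix(integer(), nrow = 0, ncol = 1,
             dimnames = list(NULL, sample_id))))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 9L)
  if (length(bad) > 0) {
    stop(sprintf("malformed SJ line %d: expected 9 tab-separated columns, got %d",
                 bad[1], nf[bad[1]]))
  }
  m <- do.call(rbind, fields)
  start1 <- suppressWarnings(as.integer(m[, 2]))
  end1 <- suppressWarnings(as.integer(m[, 3]))
  strand_code <- suppressWarnings(as.integer(m[, 4]))
  uniq <- suppressWarnings(as.integer(m[, 7]))
  multi <- suppressWarnings(as.integer(m[, 8]))
  bad <- which(is.na(start1) | is.na(end1) | is.na(strand_code) |
                 is.na(uniq) | is.na(multi))
  if (length(bad) > 0) {
    stop(sprintf("malformed SJ line %d: non-numeric coordinate or count field",
                 bad[1]))
  }
  if (any(strand_code < 0 | strand_code > 2)) {
    stop("strand code outside 0/1/2 at line ",
         which(strand_code < 0 | strand_code > 2)[1])
  }
  counts <- if (multimappers) uniq + multi else uniq
  junction_counts(
    data.frame(contig = m[, 1],
               start = start1 - 1L,
               end = end1,
               strand = c("*", "+", "-")[strand_code + 1L]),
    matrix(counts, ncol = 1, dimnames = list(NULL, sample_id)))
}

#' Write a junction table in STAR SJ.out.tab format
#'
#' Inverse of [parse_star_sj()] for a single-sample table: coordinates are
#' converted back to STAR's 1-based inclusive intron convention and the count
#' is written to the unique-reads column. Intron motif, annotation and
#' overhang columns are written as 0.
#'
#' @param table a single-sample [junction_counts] object.
#' @param path output path.
#' @export
write_star_sj <- function(table, path) {
  stopifnot(inherits(table, "junction_counts"))
  if (ncol(table$counts) != 1) stop("write_star_sj expects a single-sample table")
  j <- table$junctions
  strand_code <- match(j$strand, c("*", "+", "-")) - 1L
  lines <- sprintf("%s\t%d\t%d\t%d\t0\t0\t%d\t0\t0",
                   j$contig, j$start + 1L, j$end, strand_code,
                   as.integer(table$counts[, 1]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a generic long-format junction TSV
#'
#' Columns: contig, start (0-based), end (0-based exclusive), strand,
#' sample, count. Useful for cohort-scale tables not tied to the STAR dialect.
#'
#' @param path input TSV path (with header).
#' @return A [junction_counts] object, possibly multi-sample.
#' @export
parse_junction_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  required <- c("contig", "start", "end", "strand", "sample", "count")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("junction TSV missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  jdf <- unique(df[, c("contig", "start", "end", "strand")])
  keys <- junction_key(jdf)
  samples <- unique(df$sample)
  counts <- matrix(0L, nrow = nrow(jdf), ncol = length(samples),
                   dimnames = list(keys, samples))
  ridx <- match(junction_key(df), keys)
  cidx <- match(df$sample, samples)
  counts[cbind(ridx, cidx)] <- as.integer(df$count)
  junction_counts(jdf, counts)
}

#' Write a junction table as a generic long-format TSV
#'
#' @param table a [junction_counts] object.
#' @param path output path.
#' @param drop_zero omit zero-count (junction, sample) pairs. Default `TRUE`.
#' @export
write_junction_tsv <- function(table, path, drop_zero = TRUE) {
  stopifnot(inherits(table, "junction_counts"))
  j <- table$junctions
  long <- data.frame(
    contig = rep(j$contig, times = ncol(table$counts)),
    start = rep(j$start, times = ncol(table$counts)),
    end = rep(j$end, times = ncol(table$counts)),
    strand = rep(j$strand, times = ncol(table$counts)),
    sample = rep(colnames(table$counts), each = nrow(j)),
    count = as.vector(table$counts))
  if (drop_zero) long <- long[long$count > 0, , drop = FALSE]
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Merge single-sample junction tables into a cohort table
#'
#' Takes the union of junctions across samples; a junction absent from a
#' sample gets count 0 there. Sample ids must be distinct.
#'
#' @param tables list of [junction_counts] objects (typically single-sample).
#' @return A multi-sample [junction_counts] object.
#' @export
merge_samples <- function(tables) {
  stopifnot(length(tables) >= 1)
  lapply(tables, function(t) stopifnot(inherits(t, "junction_counts")))
  sample_ids <- unlist(lapply(tables, function(t) colnames(t$counts)))
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample id: ", sample_ids[duplicated(sample_ids)][1])
  }
  all_j <- unique(do.call(rbind, lapply(tables, `[[`, "junctions")))
  keys <- junction_key(all_j)
  counts <- matrix(0L, nrow = nrow(all_j), ncol = length(sample_ids),
                   dimnames = list(keys, sample_ids))
  for (t in tables) {
    ridx <- match(junction_key(t$junctions), keys)
    counts[ridx, colnames(t$counts)] <- t$counts
  }
  junction_counts(all_j, counts)
}
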