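#' Per-junction background distributions with Tukey fences
#'
#' Summarizes each junction's PS values across a reference cohort: quartiles
#' Q1 and Q3, their difference IQR, and the Tukey fences
#' `Q1 - 1.5 * IQR` and `Q3 + 1.5 * IQR` that define outlier splicing.
#' Missing PS values (zero-denominator samples) are dropped, not imputed; a
#' junction observed in fewer than `min_samples` samples is flagged
#' `not_evaluable` and gets NA quartiles.
#'
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7, the common scientific-computing default) unless
#' another `type` is requested.
#'
#' @param cohort a `ps_matrix` of the background cohort.
#' @param min_samples minimum number of non-missing background values needed
#'   to evaluate a junction (default 20).
#' @param type quantile algorithm passed to [stats::quantile()] (default 7,
#'   linear interpolation; 2 gives nearest-rank-style averaging).
#' @return data.frame with one row per junction: contig, start, end, strand,
#'   n_used, q1, q3, iqr, lower_fence, upper_fence, evaluable.
#' @export
build_background <- function(cohort, min_samples = 20, type = 7) {
  stopifnot(inherits(cohort, "ps_matrix"))
  if (ncol(cohort$ps) == 0) stop("empty cohort")
  if (ncol(cohort$ps) < min_samples) {
    stop(sprintf("cohort has %d samples but min_samples = %d",
                 ncol(cohort$ps), min_samples))
  }
  n <- nrow(cohort$ps)
  out <- cohort$junctions
  out$n_used <- integer(n)
  out$q1 <- out$q3 <- out$iqr <- NA_real_
  out$lower_fence <- out$upper_fence <- NA_real_
  out$evaluable <- FALSE
  for (i in seq_len(n)) {
    v <- cohort$ps[i, ]
    v <- v[!is.na(v)]
    out$n_used[i] <- length(v)
    if (length(v) < min_samples) next
    qs <- unname(stats::quantile(v, c(0.25, 0.75), type = type))
    iqr <- qs[2] - qs[1]
    out$q1[i] <- qs[1]
    out$q3[i] <- qs[2]
    out$iqr[i] <- iqr
    out$lower_fence[i] <- qs[1] - 1.5 * iqr
    out$upper_fence[i] <- qs[2] + 1.5 * iqr
    out$evaluable[i] <- TRUE
  }
  out
}

#' Call splicing outliers in a query sample against a background
#'
#' A junction is an up-outlier when its PS in the query lies strictly above
#' the background's upper Tukey fence, a down-outlier when strictly below the
#' lower fence. Values exactly on a fence are not outliers. Junctions with a
#' missing query PS, or whose background is not evaluable, are reported
#' `not_evaluable`. Junctions present in only one of query and background are
#' reported (direction `not_evaluable`), never silently dropped.
#'
#' @param query_ps a `ps_matrix` containing the query sample, or a named
#'   numeric vector of PS values keyed like the background rows.
#' @param background background table from [build_background()].
#' @param sample id of the query column when `query_ps` is a `ps_matrix`
#'   with several samples; defaults to its only column.
#' @return data.frame: junction coordinates, ps, fences, and
#'   `direction` in `{"up", "down", "none", "not_evaluable"}`.
#' @export
call_outliers <- function(query_ps, background, sample = NULL) {
  if (inherits(query_ps, "ps_matrix")) {
    if (is.null(sample)) {
      if (ncol(query_ps$ps) != 1) {
        stop("query has several samples; pass `sample`")
      }
      sample <- colnames(query_ps$ps)[1]
    }
    if (!sample %in% colnames(query_ps$ps)) {
      stop("sample not found in query PS matrix: ", sample)
    }
    v <- query_ps$ps[, sample]
    names(v) <- junction_key(query_ps$junctions)
    qjunc <- query_ps$junctions
  } else {
    v <- query_ps
    if (is.null(names(v))) stop("query vector must be named by junction key")
    qjunc <- NULL
    if (is.null(sample)) sample <- "query"
  }
  bkeys <- junction_key(background)
  all_keys <- union(bkeys, names(v))
  out <- data.frame(junction = all_keys, sample = sample,
                    ps = v[match(all_keys, names(v))],
                    stringsAsFactors = FALSE, row.names = NULL)
  bidx <- match(all_keys, bkeys)
  out$lower_fence <- background$lower_fence[bidx]
  out$upper_fence <- background$upper_fence[bidx]
  evaluable <- !is.na(bidx) & background$evaluable[bidx] & !is.na(out$ps)
  out$direction <- "not_evaluable"
  out$direction[evaluable] <- "none"
  out$direction[evaluable & out$ps > out$upper_fence] <- "up"
  out$direction[evaluable & out$ps < out$lower_fence] <- "down"
  out
}

#' Cohort usage summary for one junction
#'
#' Reports what fraction of cohort samples use a junction at all (PS strictly
#' greater than zero; a missing PS counts as not using) and the maximum
#' non-missing PS observed. Used to contextualize a novel junction: e.g. a
#' junction may be touched by under half the background cohort and never
#' exceed a small share of usage there, yet dominate in a patient.
#'
#' @param cohort a `ps_matrix`.
#' @param junction junction key string (`contig:start-end:strand`) or row index.
#' @return list with `fraction_samples_using` and `max_ps` (NA when the
#'   junction has no non-missing PS anywhere).
#' @export
cohort_usage_summary <- function(cohort, junction) {
  stopifnot(inherits(cohort, "ps_matrix"))
  keys <- junction_key(cohort$junctions)
  i <- if (is.character(junction)) match(junction, keys) else as.integer(junction)
  if (is.na(i) || i < 1 || i > length(keys)) {
    stop("junction not found: ", junction)
  }
  v <- cohort$ps[i, ]
  using <- !is.na(v) & v > 0
  list(fraction_samples_using = mean(using),
       max_ps = if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
}
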