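#' Assign fragment-analysis peaks to reporter isoforms
#'
#' Each peak in a replicate is assigned to the nearest expected amplicon size
#' (exon-included or exon-skipped isoform) if it falls within
#' `tolerance_nt`; signals of co-assigned peaks are summed. Peaks outside
#' both windows are returned unassigned, never silently dropped. The two
#' expected sizes must be separated by more than `2 * tolerance_nt` so the
#' windows cannot overlap.
#'
#' @param peaks data.frame with columns `size_nt` (> 0) and `signal` (>= 0)
#'   for one replicate.
#' @param included_size,skipped_size expected amplicon sizes in nt.
#' @param tolerance_nt half-width of the assignment window (default 5;
#'   fragment analyzers drift by a few nt).
#' @return list with `included_signal`, `skipped_signal`, and `unassigned`
#'   (data.frame of unassignable peaks).
#' @export
assign_peaks <- function(peaks, included_size, skipped_size,
                         tolerance_nt = 5) {
  if (abs(included_size - skipped_size) <= 2 * tolerance_nt) {
    stop("expected sizes must differ by more than 2 * tolerance_nt")
  }
  if (nrow(peaks) > 0 && any(peaks$size_nt <= 0)) stop("peak sizes must be > 0")
  if (nrow(peaks) > 0 && any(peaks$signal < 0)) stop("peak signals must be >= 0")
  d_inc <- abs(peaks$size_nt - included_size)
  d_skp <- abs(peaks$size_nt - skipped_size)
  to_inc <- d_inc <= tolerance_nt & d_inc <= d_skp
  to_skp <- d_skp <= tolerance_nt & !to_inc
  list(included_signal = sum(peaks$signal[to_inc]),
       skipped_signal = sum(peaks$signal[to_skp]),
       unassigned = peaks[!(to_inc | to_skp), , drop = FALSE])
}

#' Percent spliced in (PSI) from isoform signals
#'
#' `PSI = 100 * included / (included + skipped)`, the percentage of reporter
#' mRNA molecules that include the exon of interest. Undefined (NA) when both
#' signals are zero.
#'
#' @param included_signal,skipped_signal non-negative summed peak signals.
#' @return PSI on the 0-100 scale, or NA.
#' @export
compute_psi <- function(included_signal, skipped_signal) {
  total <- included_signal + skipped_signal
  ifelse(total > 0, 100 * included_signal / total, NA_real_)
}

#' Read a fragment-analysis peak table
#'
#' @param path CSV with header columns `condition`, `replicate`, `size_nt`,
#'   `signal`.
#' @return data.frame in long format, one row per peak.
#' @export
read_peaks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("condition", "replicate", "size_nt", "signal")
  if (!all(required %in% names(df))) {
    stop("peak CSV needs columns: ", paste(required, collapse = ", "))
  }
  df
}

#' Per-replicate PSI across all conditions of a peak table
#'
#' Applies [assign_peaks()] and [compute_psi()] to each (condition,
#' replicate) in a long-format peak table.
#'
#' @param peaks long-format peak data.frame (see [read_peaks_csv()]).
#' @param included_size,skipped_size expected amplicon sizes (nt).
#' @param tolerance_nt assignment window half-width (default 5).
#' @return data.frame: condition, replicate, included_signal, skipped_signal,
#'   n_unassigned, psi (percent).
#' @export
psi_by_replicate <- function(peaks, included_size, skipped_size,
                             tolerance_nt = 5) {
  key <- interaction(peaks$condition, peaks$replicate, drop = TRUE)
  rows <- lapply(split(peaks, key), function(d) {
    a <- assign_peaks(d, included_size, skipped_size, tolerance_nt)
    data.frame(condition = d$condition[1], replicate = d$replicate[1],
               included_signal = a$included_signal,
               skipped_signal = a$skipped_signal,
               n_unassigned = nrow(a$unassigned),
               psi = compute_psi(a$included_signal, a$skipped_signal))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$condition, out$replicate), , drop = FALSE]
}

#' One-way fixed-effects analysis of variance
#'
#' Classical one-way ANOVA F statistic with its p-value from the F
#' distribution. When both the between-group and within-group sums of squares
#' are zero (all values identical) the data are degenerate: p is reported as
#' 1 with `degenerate = TRUE`.
#'
#' @param groups named list of numeric vectors (>= 2 groups, each >= 2
#'   values).
#' @return list with `F`, `p`, `df_between`, `df_within`, `degenerate`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(lengths(groups) < 2)) stop("each group needs at least 2 values")
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(names(groups), lengths(groups)))
  ss_total <- sum((values - mean(values))^2)
  group_means <- tapply(values, labels, mean)
  ss_between <- sum(lengths(groups) * (group_means[names(groups)] - mean(values))^2)
  ss_within <- ss_total - ss_between
  df_b <- length(groups) - 1
  df_w <- length(values) - length(groups)
  if (ss_within <= 0 && ss_between <= 1e-12 * max(1, ss_total)) {
    return(list(F = 0, p = 1, df_between = df_b, df_within = df_w,
                degenerate = TRUE))
  }
  fit <- stats::anova(stats::lm(values ~ labels))
  list(F = fit$`F value`[1], p = fit$`Pr(>F)`[1],
       df_between = fit$Df[1], df_within = fit$Df[2], degenerate = FALSE)
}

#' Dunnett's many-to-one comparisons with Monte-Carlo adjustment
#'
#' Compares each treatment group's mean against a shared control using t
#' statistics on the pooled within-group variance, and controls the
#' family-wise error rate with Dunnett's max-|t| adjustment. Rather than
#' table lookup, the null distribution of the maximum absolute statistic is
#' estimated by seeded Monte-Carlo simulation of the joint t statistics
#' (correlated through the shared control mean and pooled variance), which
#' extends naturally to unbalanced designs. Adjusted p-values use the
#' add-one estimator `(r + 1) / (mc_reps + 1)`.
#'
#' @param groups named list of numeric vectors of per-replicate responses.
#' @param control name of the control group (must have >= 2 values).
#' @param mc_reps Monte-Carlo replicates for the max-|t| null (default 1e5;
#'   below 1e4 a warning is issued).
#' @param seed integer seed for the Monte-Carlo draw (recorded in the
#'   output).
#' @return data.frame, one row per treatment group: comparison, mean_diff,
#'   t, p_unadjusted (two-sided pooled t), p_adjusted (family-wise),
#'   plus attributes `F`, `anova_p`, `mc_reps`, `seed`.
#' @export
dunnett_test <- function(groups, control, mc_reps = 1e5, seed = 1L) {
  if (!control %in% names(groups)) stop("control group not found: ", control)
  if (length(groups[[control]]) < 2) stop("control group needs >= 2 values")
  if (length(groups) < 2) stop("need at least one treatment group")
  if (any(lengths(groups) < 2)) stop("each group needs at least 2 values")
  if (mc_reps < 1e4) warning("mc_reps < 10^4: adjusted p-values will be coarse")
  treatments <- setdiff(names(groups), control)

  n <- lengths(groups)
  N <- sum(n)
  k <- length(groups)
  df <- N - k
  group_means <- vapply(groups, mean, numeric(1))
  ss_within <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  s2 <- ss_within / df
  if (s2 <= 0) stop("zero pooled within-group variance; t statistics undefined")

  se <- sqrt(s2 * (1 / n[treatments] + 1 / n[control]))
  mean_diff <- group_means[treatments] - group_means[control]
  t_obs <- mean_diff / se
  p_unadj <- 2 * stats::pt(-abs(t_obs), df)

  # null of max |t|: group means ~ N(0, s2/n_i), pooled s2 ~ s2 * chi2_df / df
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  z_ctrl <- stats::rnorm(mc_reps, sd = sqrt(1 / n[control]))
  s_fac <- sqrt(stats::rchisq(mc_reps, df) / df)
  max_t <- rep(0, mc_reps)
  for (g in treatments) {
    z_g <- stats::rnorm(mc_reps, sd = sqrt(1 / n[g]))
    t_g <- abs(z_g - z_ctrl) / (s_fac * sqrt(1 / n[g] + 1 / n[control]))
    max_t <- pmax(max_t, t_g)
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())

  p_adj <- vapply(abs(t_obs), function(ta) {
    (sum(max_t >= ta) + 1) / (mc_reps + 1)
  }, numeric(1))
  # a family-wise p can never undercut its own per-comparison p
  p_adj <- pmax(p_adj, p_unadj)

  omnibus <- one_way_anova(groups)
  out <- data.frame(comparison = paste(treatments, "vs", control),
                    group = treatments,
                    mean_diff = unname(mean_diff), t = unname(t_obs),
                    df = df,
                    p_unadjusted = unname(p_unadj),
                    p_adjusted = unname(p_adj),
                    row.names = NULL)
  attr(out, "F") <- omnibus$F
  attr(out, "anova_p") <- omnibus$p
  attr(out, "mc_reps") <- mc_reps
  attr(out, "seed") <- seed
  out
}

#' Summarize per-replicate PSI by condition
#'
#' @param psi data.frame from [psi_by_replicate()].
#' @return data.frame: condition, n, mean_psi, sd_psi (NA for n = 1).
#' @export
summarize_psi <- function(psi) {
  rows <- lapply(split(psi, psi$condition), function(d) {
    v <- d$psi[!is.na(d$psi)]
    data.frame(condition = d$condition[1], n = length(v),
               mean_psi = if (length(v) > 0) mean(v) else NA_real_,
               sd_psi = if (length(v) > 1) stats::sd(v) else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
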