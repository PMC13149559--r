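#' Read a lipid panel CSV
#'
#' Long format, one row per technical replicate measurement:
#' `sample`, `group` (proband/control), `class` (DHCer or Cer), `chain`
#' (e.g. "C24:1"), `replicate`, `concentration`.
#'
#' @param path CSV path with header.
#' @return data.frame validated as a lipid panel.
#' @export
read_lipid_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_lipid_panel(df)
}

validate_lipid_panel <- function(df) {
  required <- c("sample", "group", "class", "chain", "replicate",
                "concentration")
  if (!all(required %in% names(df))) {
    stop("lipid panel needs columns: ", paste(required, collapse = ", "))
  }
  if (!all(df$class %in% c("DHCer", "Cer"))) {
    stop("lipid class must be DHCer or Cer")
  }
  if (!all(grepl("^C[0-9]+:[0-9]+$", df$chain))) {
    stop("acyl chain labels must match C<carbons>:<double bonds>, e.g. C24:1")
  }
  if (any(df$concentration < 0)) stop("concentrations must be >= 0")
  df
}

#' Per-sample DHCer/Cer ratios
#'
#' Technical replicates are averaged within each (sample, class, chain)
#' before any ratio is formed (so replicate noise does not leak into
#' between-group statistics as pseudo-replication). The ratio for a sample
#' and chain is mean(DHCer) / mean(Cer); it is NA and flagged when the Cer
#' mean is zero or either class is missing for that chain. This ratio is a
#' direct readout of DES1 desaturase activity: substrate over product.
#'
#' @param panel lipid panel data.frame (see [read_lipid_csv()]).
#' @return data.frame: sample, group, chain, dhcer_mean, cer_mean, ratio,
#'   flag ("" | "missing_class" | "zero_cer").
#' @export
dhcer_cer_ratios <- function(panel) {
  panel <- validate_lipid_panel(panel)
  agg <- stats::aggregate(concentration ~ sample + group + chain + class,
                          data = panel, FUN = mean)
  samples <- unique(agg[, c("sample", "group")])
  chains <- unique(agg$chain)
  grid <- merge(samples, data.frame(chain = chains))
  idx <- function(class) {
    m <- agg[agg$class == class, ]
    m$concentration[match(paste(grid$sample, grid$chain),
                          paste(m$sample, m$chain))]
  }
  grid$dhcer_mean <- idx("DHCer")
  grid$cer_mean <- idx("Cer")
  grid$ratio <- NA_real_
  grid$flag <- ""
  missing_class <- is.na(grid$dhcer_mean) | is.na(grid$cer_mean)
  grid$flag[missing_class] <- "missing_class"
  zero_cer <- !missing_class & grid$cer_mean == 0
  grid$flag[zero_cer] <- "zero_cer"
  ok <- !missing_class & !zero_cer
  grid$ratio[ok] <- grid$dhcer_mean[ok] / grid$cer_mean[ok]
  grid[order(grid$chain, grid$group, grid$sample), , drop = FALSE]
}

#' Fold elevation of DHCer/Cer ratios over the control mean
#'
#' Each proband's per-chain ratio is divided by the mean of the control
#' samples' ratios for that chain, so the control group sits at 1 by
#' construction. Undefined when the control mean ratio is zero or no control
#' ratio is defined.
#'
#' @param ratios output of [dhcer_cer_ratios()].
#' @param control_group group label of the controls (default "control").
#' @return data.frame: sample, group, chain, ratio, control_mean_ratio, fold.
#' @export
fold_over_control <- function(ratios, control_group = "control") {
  if (!any(ratios$group == control_group)) {
    stop("no samples in control group '", control_group, "'")
  }
  ctrl <- ratios[ratios$group == control_group & !is.na(ratios$ratio), ]
  ctrl_mean <- tapply(ctrl$ratio, ctrl$chain, mean)
  out <- ratios[, c("sample", "group", "chain", "ratio")]
  out$control_mean_ratio <- as.numeric(ctrl_mean[out$chain])
  out$fold <- ifelse(!is.na(out$ratio) & !is.na(out$control_mean_ratio) &
                       out$control_mean_ratio > 0,
                     out$ratio / out$control_mean_ratio, NA_real_)
  out
}

#' Two-tailed Student's t test (pooled variance)
#'
#' Classical two-sample t with pooled variance and `df = n_a + n_b - 2`.
#' When the pooled variance is zero and the means are equal the test is
#' degenerate and p is reported as 1 with a flag. Welch's unequal-variance
#' variant is available with `welch = TRUE`.
#'
#' @param a,b numeric vectors (each >= 2 finite values).
#' @param welch use Welch's unequal-variance t instead of the pooled test.
#' @return list with `t`, `df`, `p`, `degenerate`.
#' @export
student_t_two_tailed <- function(a, b, welch = FALSE) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 finite values")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = length(a) + length(b) - 2, p = 1,
                  degenerate = TRUE))
    }
    return(list(t = if (mean(a) > mean(b)) Inf else -Inf,
                df = length(a) + length(b) - 2, p = 0, degenerate = TRUE))
  }
  ht <- stats::t.test(a, b, var.equal = !welch)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, degenerate = FALSE)
}

#' Panel-wide summary report
#'
#' One row per (chain, class, group): mean, SD and n of the
#' replicate-averaged concentrations, plus the per-chain proband folds and
#' the two-tailed Student's t test of proband vs control. The test can be
#' run on the DHCer/Cer ratios (default, `on = "ratio"`) or on raw
#' concentrations per class (`on = "concentration"`); each row is labelled
#' with the quantity tested. No multiple-testing correction is applied
#' across lipid species.
#'
#' Rows are ordered deterministically by class, carbon count, then
#' unsaturation.
#'
#' @param panel lipid panel data.frame.
#' @param control_group,proband_group group labels.
#' @param on quantity for the significance test: "ratio" or "concentration".
#' @param alpha significance cutoff (default 0.05).
#' @return data.frame report; see Details.
#' @export
summarize_panel <- function(panel, control_group = "control",
                            proband_group = "proband", on = c("ratio", "concentration"),
                            alpha = 0.05) {
  on <- match.arg(on)
  panel <- validate_lipid_panel(panel)
  ratios <- dhcer_cer_ratios(panel)
  folds <- fold_over_control(ratios, control_group)

  persample <- stats::aggregate(concentration ~ sample + group + chain + class,
                                data = panel, FUN = mean)
  grp_stat <- function(v) {
    c(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else NA_real_,
      n = length(v))
  }
  key <- interaction(persample$chain, persample$class, persample$group,
                     drop = TRUE)
  rows <- lapply(split(persample, key), function(d) {
    s <- grp_stat(d$concentration)
    data.frame(chain = d$chain[1], class = d$class[1], group = d$group[1],
               mean = s["mean"], sd = s["sd"], n = as.integer(s["n"]),
               row.names = NULL)
  })
  out <- do.call(rbind, rows)

  # per-chain test and fold summary
  chains <- unique(out$chain)
  tst <- lapply(chains, function(ch) {
    if (on == "ratio") {
      rc <- ratios[ratios$chain == ch, ]
      a <- rc$ratio[rc$group == proband_group]
      b <- rc$ratio[rc$group == control_group]
    } else {
      pc <- persample[persample$chain == ch & persample$class == "DHCer", ]
      a <- pc$concentration[pc$group == proband_group]
      b <- pc$concentration[pc$group == control_group]
    }
    a <- a[is.finite(a)]; b <- b[is.finite(b)]
    if (length(a) >= 2 && length(b) >= 2) {
      r <- student_t_two_tailed(a, b)
      data.frame(chain = ch, tested_on = on, t = r$t, df = r$df, p = r$p,
                 significant = is.finite(r$p) && r$p < alpha)
    } else {
      data.frame(chain = ch, tested_on = on, t = NA_real_, df = NA_real_,
                 p = NA_real_, significant = NA)
    }
  })
  tests <- do.call(rbind, tst)
  fold_by_chain <- folds[folds$group == proband_group,
                         c("sample", "chain", "fold")]

  out <- merge(out, tests, by = "chain", all.x = TRUE)
  carbons <- as.integer(sub("^C([0-9]+):.*$", "\\1", out$chain))
  unsat <- as.integer(sub("^C[0-9]+:([0-9]+)$", "\\1", out$chain))
  out <- out[order(out$class, carbons, unsat, out$group), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "proband_folds") <- fold_by_chain
  attr(out, "note") <- "no multiple-testing correction across lipid species"
  out
}
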