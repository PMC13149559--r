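#' Multiplicative log-normal noise factors with unit mean
#'
#' Parameterized by coefficient of variation; cv = 0 returns exact 1s, so
#' every simulator reproduces its configured truth in the no-noise limit.
#' @keywords internal
rlnorm_cv <- function(n, cv) {
  if (cv < 0) stop("cv must be >= 0")
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Configuration for the synthetic junction cohort
#'
#' Describes a cohort of background (healthy) samples plus one patient
#' sample over a single multi-exon gene, emulating the structure of a
#' GTEx-scale whole-blood background (670 samples by default) against which
#' a dominant exon-skipping junction is an outlier. Per sample, total
#' junction-spanning depth is negative-binomial; the exon-skip fraction psi
#' is Beta-distributed around `background_skip_mean` in the background and
#' fixed at `patient_skip` (default 0.56, the patient effect size emulated)
#' for the patient.
#'
#' Depth and dispersion defaults are placeholders (typical bulk RNA-seq
#' junction depth), not calibrated to any cohort.
#'
#' @param seed integer seed; all randomness flows from it.
#' @param n_background number of background samples (default 670).
#' @param n_exons exons in the gene model (default 3; the skip junction
#'   always joins exons 1 and 3).
#' @param depth_mean expected junction-spanning reads per sample (> 0).
#' @param depth_dispersion negative-binomial dispersion (0 = Poisson).
#' @param background_skip_mean mean skip fraction in healthy samples.
#' @param background_skip_concentration Beta concentration (larger =
#'   tighter around the mean).
#' @param patient_skip true skip fraction of the patient sample.
#' @return validated config list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(seed = 1L, n_background = 670, n_exons = 3,
                              depth_mean = 2000, depth_dispersion = 0.1,
                              background_skip_mean = 0.02,
                              background_skip_concentration = 100,
                              patient_skip = 0.56) {
  cfg <- list(seed = as.integer(seed), n_background = n_background,
              n_exons = n_exons, depth_mean = depth_mean,
              depth_dispersion = depth_dispersion,
              background_skip_mean = background_skip_mean,
              background_skip_concentration = background_skip_concentration,
              patient_skip = patient_skip)
  if (any(!vapply(cfg, is.finite, logical(1)))) {
    stop("all config values must be finite")
  }
  if (n_background < 1 || n_exons < 3) stop("n_background >= 1, n_exons >= 3")
  if (depth_mean <= 0) stop("depth_mean must be > 0")
  if (depth_dispersion < 0) stop("depth_dispersion must be >= 0")
  for (p in c("background_skip_mean", "patient_skip")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must be in [0, 1]")
  }
  if (background_skip_concentration <= 0) {
    stop("background_skip_concentration must be > 0")
  }
  structure(cfg, class = "cohort_sim_config")
}

# gene model used by the cohort simulator: exon i = [1000*i, 1000*i + 200)
sim_gene_junctions <- function(n_exons) {
  exon_start <- function(i) 1000L * i
  exon_end <- function(i) 1000L * i + 200L
  inc <- data.frame(contig = "chr1",
                    start = exon_end(seq_len(n_exons - 1)),
                    end = exon_start(seq_len(n_exons - 1) + 1L),
                    strand = "+")
  skip <- data.frame(contig = "chr1", start = exon_end(1L),
                     end = exon_start(3L), strand = "+")
  list(inclusion = inc, skip = skip)
}

#' Simulate a junction-count cohort with one exon-skipping patient
#'
#' Generates single-gene junction count tables for `n_background` healthy
#' samples and one patient. Per sample: total depth
#' `N ~ NegBin(depth_mean, dispersion)`; skip fraction
#' `psi ~ Beta(mean, concentration)` (background) or fixed `patient_skip`
#' (patient); skip-junction count `~ Binomial(N, psi)`; the remaining reads
#' are split uniformly across the consecutive-exon inclusion junctions
#' (for the default 3-exon gene, `Binomial(., 1/2)` between e1-e2 and
#' e2-e3). In expectation the skip junction's PS equals psi, because the
#' skip competes against all inclusion reads.
#'
#' @param config a [cohort_sim_config()].
#' @return list with `background` and `patient`, both [junction_counts]
#'   (rows: inclusion junctions e1-e2 ... then the e1-e3 skip junction).
#' @export
simulate_junction_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  set.seed(config$seed)
  gj <- sim_gene_junctions(config$n_exons)
  junctions <- rbind(gj$inclusion, gj$skip)
  n_inc <- nrow(gj$inclusion)

  draw_sample <- function(psi) {
    N <- if (config$depth_dispersion == 0) {
      stats::rpois(1, config$depth_mean)
    } else {
      stats::rnbinom(1, mu = config$depth_mean,
                     size = 1 / config$depth_dispersion)
    }
    skip <- stats::rbinom(1, N, psi)
    inc <- as.vector(stats::rmultinom(1, N - skip, rep(1 / n_inc, n_inc)))
    c(inc, skip)
  }

  m <- config$background_skip_mean
  c0 <- config$background_skip_concentration
  psi_bg <- if (m %in% c(0, 1)) rep(m, config$n_background) else
    stats::rbeta(config$n_background, m * c0, (1 - m) * c0)
  bg_counts <- vapply(psi_bg, draw_sample, numeric(n_inc + 1))
  colnames(bg_counts) <- sprintf("bg%03d", seq_len(config$n_background))
  pt_counts <- matrix(draw_sample(config$patient_skip), ncol = 1,
                      dimnames = list(NULL, "patient1"))
  list(background = junction_counts(junctions, bg_counts),
       patient = junction_counts(junctions, pt_counts))
}

#' Simulate an isoform abundance (TPM) table
#'
#' `TPM_i = total_tpm * fraction_i * lognormal(cv)`; at cv = 0 the
#' configured fractions are recovered exactly. The default profile mirrors
#' a patient in whom the canonical transcript is a small minority (6%) and
#' an exon-skipping transcript dominates (69%), with a cryptic-splice-site
#' isoform (12%) and remainder (13%).
#'
#' @param fractions named numeric vector of isoform fractions summing to 1
#'   (tolerance 1e-9).
#' @param total_tpm total gene expression in TPM (>= 0).
#' @param noise_cv coefficient of variation of the multiplicative noise.
#' @param seed integer seed.
#' @param gene_id gene id written to the table.
#' @return data.frame: transcript_id, gene_id, tpm.
#' @export
simulate_abundance_table <- function(fractions = c(canonical = 0.06,
                                                   exon2_skip = 0.69,
                                                   cryptic = 0.12,
                                                   other = 0.13),
                                     total_tpm = 100, noise_cv = 0,
                                     seed = 1L, gene_id = "GENE1") {
  if (total_tpm < 0) stop("total_tpm must be >= 0")
  if (abs(sum(fractions) - 1) > 1e-9) stop("fractions must sum to 1")
  if (is.null(names(fractions))) {
    names(fractions) <- paste0("isoform", seq_along(fractions))
  }
  set.seed(seed)
  tpm <- total_tpm * fractions * rlnorm_cv(length(fractions), noise_cv)
  data.frame(transcript_id = names(fractions), gene_id = gene_id,
             tpm = unname(tpm))
}

#' Configuration for splicing-reporter simulations
#'
#' One condition of a fragment-analysis reporter experiment: `n_replicates`
#' biological replicates (default 9), each yielding an exon-included and an
#' exon-skipped amplicon peak whose signals are proportional to `psi_true`
#' and `1 - psi_true`, perturbed by unit-mean log-normal noise.
#'
#' @param seed integer seed.
#' @param n_replicates number of replicates (>= 2; default 9).
#' @param psi_true true inclusion fraction in [0, 1].
#' @param total_signal_mean expected total peak signal (arbitrary units).
#' @param noise_cv coefficient of variation of the per-peak signal noise.
#' @param included_size_nt,skipped_size_nt amplicon sizes (must differ).
#' @return validated config list of class `reporter_sim_config`.
#' @export
reporter_sim_config <- function(seed = 1L, n_replicates = 9, psi_true = 0.9,
                                total_signal_mean = 10000, noise_cv = 0.1,
                                included_size_nt = 412, skipped_size_nt = 269) {
  cfg <- list(seed = as.integer(seed), n_replicates = n_replicates,
              psi_true = psi_true, total_signal_mean = total_signal_mean,
              noise_cv = noise_cv, included_size_nt = included_size_nt,
              skipped_size_nt = skipped_size_nt)
  if (any(!vapply(cfg, is.finite, logical(1)))) {
    stop("all config values must be finite")
  }
  if (n_replicates < 2) stop("n_replicates must be >= 2")
  if (psi_true < 0 || psi_true > 1) stop("psi_true must be in [0, 1]")
  if (total_signal_mean <= 0) stop("total_signal_mean must be > 0")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  if (included_size_nt == skipped_size_nt) stop("amplicon sizes must differ")
  structure(cfg, class = "reporter_sim_config")
}

#' Simulate one splicing-reporter condition
#'
#' @param config a [reporter_sim_config()].
#' @param condition condition label written to the peak table.
#' @return long-format peak data.frame (condition, replicate, size_nt,
#'   signal); peaks with zero expected signal (psi_true of exactly 0 or 1)
#'   are omitted.
#' @export
simulate_reporter_run <- function(config, condition = "reporter") {
  stopifnot(inherits(config, "reporter_sim_config"))
  set.seed(config$seed)
  rows <- lapply(seq_len(config$n_replicates), function(r) {
    sizes <- c(config$included_size_nt, config$skipped_size_nt)
    expected <- config$total_signal_mean * c(config$psi_true,
                                             1 - config$psi_true)
    keep <- expected > 0
    data.frame(condition = condition, replicate = r,
               size_nt = sizes[keep],
               signal = expected[keep] * rlnorm_cv(sum(keep), config$noise_cv))
  })
  do.call(rbind, rows)
}

#' Configuration for the synthetic lipid panel
#'
#' Emulates a plasma sphingolipid panel: `n_controls` healthy samples
#' (default 9) and `n_probands` patients (default 2), each species measured
#' in `n_technical_replicates` technical replicates (default 3).
#' `fold_effect` is the configured DHCer/Cer ratio fold in probands over the
#' control mean; it is realized symmetrically (DHCer multiplied and Cer
#' divided by sqrt(fold)), matching the loss-of-desaturase signature of
#' substrate accumulation plus product depletion. Default fold 42 is the
#' low end of the effect range this panel emulates.
#'
#' @param seed integer seed.
#' @param n_controls,n_probands sample counts.
#' @param chains acyl chain labels (default the seven-chain panel
#'   C14:0 ... C26:0).
#' @param control_mean_dhcer,control_mean_cer control concentration means
#'   per class; scalar or named by chain (> 0).
#' @param cv coefficient of variation of measurement noise (>= 0).
#' @param fold_effect ratio fold in probands; scalar or named by chain
#'   (> 0). Names outside `chains` are an error.
#' @param n_technical_replicates replicates per measurement.
#' @return validated config list of class `lipid_sim_config`.
#' @export
lipid_sim_config <- function(seed = 1L, n_controls = 9, n_probands = 2,
                             chains = c("C14:0", "C16:0", "C20:0", "C22:0",
                                        "C24:0", "C24:1", "C26:0"),
                             control_mean_dhcer = 0.1, control_mean_cer = 1,
                             cv = 0.1, fold_effect = 42,
                             n_technical_replicates = 3) {
  expand <- function(x, what) {
    if (length(x) == 1 && is.null(names(x))) {
      x <- stats::setNames(rep(x, length(chains)), chains)
    }
    if (!all(names(x) %in% chains)) {
      stop("unknown species in ", what, ": ",
           paste(setdiff(names(x), chains), collapse = ", "))
    }
    full <- stats::setNames(rep(NA_real_, length(chains)), chains)
    full[names(x)] <- x
    if (anyNA(full)) stop(what, " must cover every chain")
    full
  }
  if (!all(grepl("^C[0-9]+:[0-9]+$", chains))) {
    stop("chains must match C<carbons>:<double bonds>")
  }
  fold_effect <- expand(fold_effect, "fold_effect")
  control_mean_dhcer <- expand(control_mean_dhcer, "control_mean_dhcer")
  control_mean_cer <- expand(control_mean_cer, "control_mean_cer")
  if (any(control_mean_dhcer <= 0) || any(control_mean_cer <= 0)) {
    stop("control means must be > 0")
  }
  if (any(fold_effect <= 0)) stop("fold_effect must be > 0")
  if (cv < 0) stop("cv must be >= 0")
  if (n_controls < 2 || n_probands < 1) stop("n_controls >= 2, n_probands >= 1")
  if (n_technical_replicates < 1) stop("n_technical_replicates >= 1")
  structure(list(seed = as.integer(seed), n_controls = n_controls,
                 n_probands = n_probands, chains = chains,
                 control_mean_dhcer = control_mean_dhcer,
                 control_mean_cer = control_mean_cer, cv = cv,
                 fold_effect = fold_effect,
                 n_technical_replicates = n_technical_replicates),
            class = "lipid_sim_config")
}

#' Simulate a lipid panel
#'
#' Every technical replicate is an independent unit-mean log-normal draw
#' around the group mean for its (sample group, class, chain); at cv = 0 the
#' configured group means, and hence the configured ratio folds, are
#' recovered exactly.
#'
#' @param config a [lipid_sim_config()].
#' @return long-format lipid panel data.frame (sample, group, class, chain,
#'   replicate, concentration).
#' @export
simulate_lipid_panel <- function(config) {
  stopifnot(inherits(config, "lipid_sim_config"))
  set.seed(config$seed)
  samples <- data.frame(
    sample = c(sprintf("control%02d", seq_len(config$n_controls)),
               sprintf("proband%d", seq_len(config$n_probands))),
    group = rep(c("control", "proband"),
                c(config$n_controls, config$n_probands)))
  grid <- expand.grid(sample = samples$sample, class = c("DHCer", "Cer"),
                      chain = config$chains,
                      replicate = seq_len(config$n_technical_replicates),
                      stringsAsFactors = FALSE)
  grid$group <- samples$group[match(grid$sample, samples$sample)]
  sqrt_fold <- sqrt(config$fold_effect[grid$chain])
  base <- ifelse(grid$class == "DHCer",
                 config$control_mean_dhcer[grid$chain],
                 config$control_mean_cer[grid$chain])
  mu <- ifelse(grid$group == "proband",
               ifelse(grid$class == "DHCer", base * sqrt_fold,
                      base / sqrt_fold),
               base)
  grid$concentration <- mu * rlnorm_cv(nrow(grid), config$cv)
  out <- grid[, c("sample", "group", "class", "chain", "replicate",
                  "concentration")]
  out <- out[order(out$sample, out$class, out$chain, out$replicate), ]
  rownames(out) <- NULL
  out
}

#' Write simulator outputs in their downstream input formats
#'
#' @param df table to write.
#' @param path output path.
#' @name synthetic-writers
NULL

#' @rdname synthetic-writers
#' @export
write_abundance_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname synthetic-writers
#' @export
write_peaks_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname synthetic-writers
#' @export
write_lipid_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
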