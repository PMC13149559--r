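pipeline_defaults <- function() {
  list(
    seed = 1L,
    outdir = "vusplice_run",
    stages = c("simulate", "ps", "outliers", "isoforms", "reporter",
               "lipids", "aso"),
    # cohort / outlier stage
    n_background = 670, n_exons = 3, depth_mean = 2000,
    depth_dispersion = 0.1, background_skip_mean = 0.02,
    background_skip_concentration = 100, patient_skip = 0.56,
    min_samples = 20, quantile_type = 7,
    # isoform stage
    fractions = c(canonical = 0.06, exon2_skip = 0.69, cryptic = 0.12,
                  other = 0.13),
    total_tpm = 100, abundance_noise_cv = 0,
    # reporter stage
    n_replicates = 9, reference_psi = 0.9, variant_psi = 0,
    reporter_noise_cv = 0.1, total_signal_mean = 10000,
    included_size_nt = 412, skipped_size_nt = 269, tolerance_nt = 5,
    mc_reps = 1e5,
    # lipid stage
    n_controls = 9, n_probands = 2, lipid_cv = 0.1, fold_effect = 42,
    n_technical_replicates = 3,
    # ASO stage
    aso_k = 18, aso_step = 1
  )
}

#' Validate a pipeline configuration
#'
#' Accepts a JSON file path or a plain list, fills in defaults, rejects
#' unknown keys (with a nearest-key suggestion), and range-checks every
#' parameter. Errors are aggregated so a bad config reports all its problems
#' at once.
#'
#' @param config path to a JSON config file, or a named list of overrides;
#'   `NULL` or an empty list yields the defaults.
#' @return validated config list of class `pipeline_config`, echoing every
#'   default alongside the overrides.
#' @export
validate_config <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config)) config <- list()
  defaults <- pipeline_defaults()
  errors <- character(0)

  unknown <- setdiff(names(config), names(defaults))
  for (key in unknown) {
    near <- agrep(key, names(defaults), max.distance = 0.3, value = TRUE)
    hint <- if (length(near) > 0) {
      sprintf(" (did you mean '%s'?)", near[1])
    } else ""
    errors <- c(errors, sprintf("unknown key '%s'%s", key, hint))
  }
  cfg <- defaults
  for (key in intersect(names(config), names(defaults))) {
    cfg[[key]] <- config[[key]]
  }
  if (!is.null(names(cfg$fractions)) || length(cfg$fractions) > 0) {
    cfg$fractions <- unlist(cfg$fractions)
  }

  chk <- function(cond, msg) if (!isTRUE(cond)) errors <<- c(errors, msg)
  chk(length(cfg$seed) == 1 && is.finite(cfg$seed), "seed must be a finite integer")
  chk(all(cfg$stages %in% defaults$stages),
      paste0("stages must be a subset of: ",
             paste(defaults$stages, collapse = ", ")))
  chk(cfg$min_samples >= 2, "min_samples must be >= 2")
  chk(cfg$quantile_type %in% 1:9, "quantile_type must be in 1..9")
  chk(cfg$n_background >= 1, "n_background must be >= 1")
  chk(cfg$n_exons >= 3, "n_exons must be >= 3")
  chk(cfg$depth_mean > 0, "depth_mean must be > 0")
  chk(cfg$depth_dispersion >= 0, "depth_dispersion must be >= 0")
  for (p in c("background_skip_mean", "patient_skip", "reference_psi",
              "variant_psi")) {
    chk(cfg[[p]] >= 0 && cfg[[p]] <= 1, paste(p, "must be in [0, 1]"))
  }
  chk(cfg$background_skip_concentration > 0,
      "background_skip_concentration must be > 0")
  chk(abs(sum(cfg$fractions) - 1) <= 1e-9, "fractions must sum to 1")
  chk(cfg$total_tpm >= 0, "total_tpm must be >= 0")
  for (p in c("abundance_noise_cv", "reporter_noise_cv", "lipid_cv")) {
    chk(cfg[[p]] >= 0, paste(p, "must be >= 0"))
  }
  chk(cfg$n_replicates >= 2, "n_replicates must be >= 2")
  chk(cfg$total_signal_mean > 0, "total_signal_mean must be > 0")
  chk(abs(cfg$included_size_nt - cfg$skipped_size_nt) > 2 * cfg$tolerance_nt,
      "amplicon sizes must differ by more than 2 * tolerance_nt")
  chk(cfg$mc_reps >= 100, "mc_reps must be >= 100")
  chk(cfg$n_controls >= 2, "n_controls must be >= 2")
  chk(cfg$n_probands >= 1, "n_probands must be >= 1")
  chk(all(cfg$fold_effect > 0), "fold_effect must be > 0")
  chk(cfg$n_technical_replicates >= 1, "n_technical_replicates must be >= 1")
  chk(cfg$aso_k > 0 && cfg$aso_step > 0, "aso_k and aso_step must be positive")

  if (length(errors) > 0) {
    stop("invalid pipeline config:\n  - ", paste(errors, collapse = "\n  - "),
         call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

#' Run the whole analysis pipeline on synthetic data
#'
#' Executes the enabled stages in dependency order — simulate, percent-
#' spliced quantification, outlier calling, isoform analysis, reporter
#' statistics, lipid analysis, ASO design — writing every stage's tabular
#' output plus a consolidated machine-readable JSON report under
#' `config$outdir`. All randomness flows from `config$seed` (each stage gets
#' a fixed offset of it), so a rerun with the same config produces an
#' identical report payload.
#'
#' @param config a `pipeline_config` from [validate_config()] (or anything
#'   that function accepts).
#' @return The run report (list, class `run_report`), invisibly; also
#'   written to `<outdir>/report.json`.
#' @export
run_pipeline <- function(config = NULL) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  fixture_dir <- file.path(config$outdir, "fixtures")
  dir.create(fixture_dir, showWarnings = FALSE)
  report <- list(package_version = as.character(utils::packageVersion("vusplice")),
                 config = unclass(config), stages = list(), warnings = list())
  run_stage <- function(name, fn) {
    if (!name %in% config$stages) return(invisible(NULL))
    res <- tryCatch(fn(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    report$stages[[name]] <<- res
    invisible(res)
  }

  cohort <- NULL
  run_stage("simulate", function() {
    ccfg <- cohort_sim_config(
      seed = config$seed, n_background = config$n_background,
      n_exons = config$n_exons, depth_mean = config$depth_mean,
      depth_dispersion = config$depth_dispersion,
      background_skip_mean = config$background_skip_mean,
      background_skip_concentration = config$background_skip_concentration,
      patient_skip = config$patient_skip)
    cohort <<- simulate_junction_cohort(ccfg)
    write_star_sj(cohort$patient, file.path(fixture_dir, "patient1.SJ.out.tab"))
    write_junction_tsv(merge_samples(list(cohort$background)),
                       file.path(fixture_dir, "background_junctions.tsv"))
    ab <- simulate_abundance_table(config$fractions, config$total_tpm,
                                   config$abundance_noise_cv,
                                   seed = config$seed + 1L)
    write_abundance_tsv(ab, file.path(fixture_dir, "abundance.tsv"))
    ref_peaks <- simulate_reporter_run(
      reporter_sim_config(seed = config$seed + 2L,
                          n_replicates = config$n_replicates,
                          psi_true = config$reference_psi,
                          total_signal_mean = config$total_signal_mean,
                          noise_cv = config$reporter_noise_cv,
                          included_size_nt = config$included_size_nt,
                          skipped_size_nt = config$skipped_size_nt),
      condition = "reference")
    var_peaks <- simulate_reporter_run(
      reporter_sim_config(seed = config$seed + 3L,
                          n_replicates = config$n_replicates,
                          psi_true = config$variant_psi,
                          total_signal_mean = config$total_signal_mean,
                          noise_cv = config$reporter_noise_cv,
                          included_size_nt = config$included_size_nt,
                          skipped_size_nt = config$skipped_size_nt),
      condition = "variant")
    write_peaks_csv(rbind(ref_peaks, var_peaks),
                    file.path(fixture_dir, "reporter_peaks.csv"))
    lcfg <- lipid_sim_config(seed = config$seed + 4L,
                             n_controls = config$n_controls,
                             n_probands = config$n_probands,
                             cv = config$lipid_cv,
                             fold_effect = config$fold_effect,
                             n_technical_replicates = config$n_technical_replicates)
    write_lipid_csv(simulate_lipid_panel(lcfg),
                    file.path(fixture_dir, "lipid_panel.csv"))
    list(n_background = config$n_background,
         fixtures = sort(list.files(fixture_dir)))
  })

  ps_out <- NULL
  run_stage("ps", function() {
    if (is.null(cohort)) stop("the 'ps' stage needs the 'simulate' stage")
    patient <- parse_star_sj(file.path(fixture_dir, "patient1.SJ.out.tab"),
                             sample_id = "patient1")
    background <- parse_junction_tsv(
      file.path(fixture_dir, "background_junctions.tsv"))
    merged <- merge_samples(list(background, patient))
    psm <- percent_spliced(merged)
    write_ps_tsv(psm, file.path(config$outdir, "ps_matrix.tsv"))
    ps_out <<- psm
    skip_key <- junction_key(psm$junctions)[nrow(psm$junctions)]
    list(n_junctions = nrow(psm$junctions), n_samples = ncol(psm$ps),
         patient_skip_ps = unname(psm$ps[skip_key, "patient1"]))
  })

  run_stage("outliers", function() {
    if (is.null(ps_out)) stop("the 'outliers' stage needs the 'ps' stage")
    bg_cols <- setdiff(colnames(ps_out$ps), "patient1")
    bg_ps <- structure(list(junctions = ps_out$junctions,
                            ps = ps_out$ps[, bg_cols, drop = FALSE]),
                       class = "ps_matrix")
    background <- build_background(bg_ps, min_samples = config$min_samples,
                                   type = config$quantile_type)
    utils::write.table(background,
                       file.path(config$outdir, "background_fences.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    calls <- call_outliers(ps_out, background, sample = "patient1")
    utils::write.table(calls, file.path(config$outdir, "outlier_calls.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    skip_key <- junction_key(ps_out$junctions)[nrow(ps_out$junctions)]
    skip_summary <- cohort_usage_summary(bg_ps, skip_key)
    list(calls = stats::setNames(as.list(calls$direction), calls$junction),
         skip_junction = skip_key,
         background_fraction_using_skip = skip_summary$fraction_samples_using,
         background_max_skip_ps = skip_summary$max_ps)
  })

  run_stage("isoforms", function() {
    ab <- read_abundance_tsv(file.path(fixture_dir, "abundance.tsv"))
    fr <- isoform_fractions(ab)
    utils::write.table(fr, file.path(config$outdir, "isoform_fractions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    gene <- simulate_gene_models(seed = config$seed + 5L)
    gtf <- file.path(fixture_dir, "gene_models.gtf")
    skip <- skip_exons(gene$canonical, 2L)
    write_gtf_transcripts(list(gene$canonical, skip), gtf)
    models <- parse_gtf_transcripts(gtf)
    canonical <- models[["TX_CANON"]]
    canonical$cds <- gene$canonical$cds  # CDS carried by the generator
    cls <- classify_isoform(models[[skip$transcript_id]], canonical)
    cons <- predict_protein_consequence(canonical,
                                        models[[skip$transcript_id]],
                                        gene$genome)
    dominant <- fr$transcript_id[which.max(fr$fraction)]
    list(fractions = stats::setNames(as.list(round(fr$fraction, 9)),
                                     fr$transcript_id),
         dominant_isoform = dominant,
         dominant_is_noncanonical = dominant != "canonical",
         skip_classification = cls$category,
         skipped_exons = cls$detail$skipped_exons,
         skip_consequence = cons$hgvs_p,
         consequence_kind = cons$kind)
  })

  run_stage("reporter", function() {
    peaks <- read_peaks_csv(file.path(fixture_dir, "reporter_peaks.csv"))
    psi <- psi_by_replicate(peaks, config$included_size_nt,
                            config$skipped_size_nt, config$tolerance_nt)
    utils::write.table(psi, file.path(config$outdir, "reporter_psi.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    groups <- split(psi$psi, psi$condition)
    dt <- dunnett_test(groups, control = "reference",
                       mc_reps = config$mc_reps, seed = config$seed + 6L)
    utils::write.table(dt, file.path(config$outdir, "reporter_stats.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summ <- summarize_psi(psi)
    list(mean_psi = stats::setNames(as.list(summ$mean_psi), summ$condition),
         anova_F = attr(dt, "F"), anova_p = attr(dt, "anova_p"),
         dunnett_p_adjusted = stats::setNames(as.list(dt$p_adjusted),
                                              dt$group),
         mc_reps = attr(dt, "mc_reps"), mc_seed = attr(dt, "seed"))
  })

  run_stage("lipids", function() {
    panel <- read_lipid_csv(file.path(fixture_dir, "lipid_panel.csv"))
    rep_tab <- summarize_panel(panel)
    utils::write.table(rep_tab, file.path(config$outdir, "lipid_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    folds <- attr(rep_tab, "proband_folds")
    med_fold <- tapply(folds$fold, folds$chain, stats::median)
    sig <- unique(rep_tab[, c("chain", "significant")])
    list(median_proband_fold = as.list(med_fold),
         significant = stats::setNames(as.list(sig$significant), sig$chain))
  })

  run_stage("aso", function() {
    gene <- simulate_gene_models(seed = config$seed + 5L)
    ex2 <- gene$canonical$exons[2, ]
    target <- substring(gene$genome[[1]], ex2$start + 1 - 30, ex2$end + 30)
    designs <- design_walk(target, k = config$aso_k, step = config$aso_step)
    write_aso_tsv(designs, file.path(config$outdir, "aso_walk.tsv"))
    list(n_designs = nrow(designs), k = config$aso_k, step = config$aso_step,
         chemistry = "2'MOE / phosphorothioate")
  })

  class(report) <- "run_report"
  jsonlite::write_json(unclass(report),
                       file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(report)
}

#' @export
print.run_report <- function(x, ...) {
  cat("vusplice run report; stages:", paste(names(x$stages), collapse = ", "),
      "\n")
  invisible(x)
}
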