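toy_panel <- function() {
  # two controls, one proband, two chains, duplicate technical replicates
  expand <- expand.grid(sample = c("c1", "c2", "p1"),
                        class = c("DHCer", "Cer"),
                        chain = c("C16:0", "C24:1"), replicate = 1:2,
                        stringsAsFactors = FALSE)
  expand$group <- ifelse(grepl("^c", expand$sample), "control", "proband")
  base <- ifelse(expand$class == "DHCer", 0.5, 2)
  mult <- ifelse(expand$group == "proband" & expand$class == "DHCer", 4, 1)
  mult <- mult * ifelse(expand$group == "proband" & expand$class == "Cer",
                        0.5, 1)
  expand$concentration <- base * mult
  expand[, c("sample", "group", "class", "chain", "replicate",
             "concentration")]
}

test_that("ratios average technical replicates before dividing", {
  p <- toy_panel()
  r <- dhcer_cer_ratios(p)
  expect_equal(r$ratio[r$sample == "c1" & r$chain == "C16:0"], 0.25)
  expect_equal(r$ratio[r$sample == "p1" & r$chain == "C16:0"], 2)

  # perturb replicates keeping the mean: ratio unchanged
  p2 <- p
  i <- which(p2$sample == "c1" & p2$class == "DHCer" & p2$chain == "C16:0")
  p2$concentration[i] <- c(0.2, 0.8)
  r2 <- dhcer_cer_ratios(p2)
  expect_equal(r2$ratio[r2$sample == "c1" & r2$chain == "C16:0"], 0.25)
})

test_that("triplicate averaging equals a brute-force mean on random panels", {
  set.seed(61)
  for (i in 1:20) {
    p <- toy_panel()
    p$concentration <- stats::runif(nrow(p), 0.1, 5)
    r <- dhcer_cer_ratios(p)
    for (k in seq_len(nrow(r))) {
      num <- mean(p$concentration[p$sample == r$sample[k] &
                                    p$class == "DHCer" &
                                    p$chain == r$chain[k]])
      den <- mean(p$concentration[p$sample == r$sample[k] &
                                    p$class == "Cer" &
                                    p$chain == r$chain[k]])
      expect_equal(r$ratio[k], num / den)
    }
  }
})

test_that("zero or missing Cer is flagged, not silently dropped", {
  p <- toy_panel()
  p$concentration[p$sample == "c1" & p$class == "Cer" &
                    p$chain == "C16:0"] <- 0
  r <- dhcer_cer_ratios(p)
  row <- r[r$sample == "c1" & r$chain == "C16:0", ]
  expect_true(is.na(row$ratio))
  expect_equal(row$flag, "zero_cer")

  p2 <- p[!(p$class == "Cer" & p$chain == "C24:1"), ]
  r2 <- dhcer_cer_ratios(p2)
  expect_true(all(r2$flag[r2$chain == "C24:1"] == "missing_class"))
})

test_that("fold over control mean: construction, null case, scale invariance", {
  ratios <- data.frame(sample = c("c1", "c2", "c3", "p1"),
                       group = c("control", "control", "control", "proband"),
                       chain = "C16:0", ratio = c(0.2, 0.2, 0.2, 8.4))
  f <- fold_over_control(ratios)
  expect_equal(f$fold[f$sample == "p1"], 42)
  expect_equal(f$fold[f$group == "control"], c(1, 1, 1))

  ratios$ratio[4] <- 0.2
  expect_equal(fold_over_control(ratios)$fold[4], 1)

  # rescaling all concentrations leaves folds unchanged
  p <- toy_panel()
  f1 <- fold_over_control(dhcer_cer_ratios(p))
  p$concentration <- p$concentration * 37.5
  f2 <- fold_over_control(dhcer_cer_ratios(p))
  expect_equal(f1$fold, f2$fold)
})

test_that("pooled Student's t: identity, degenerate flags, permutation oracle", {
  res <- student_t_two_tailed(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)

  deg <- student_t_two_tailed(c(2, 2, 2), c(2, 2, 2))
  expect_true(deg$degenerate)
  expect_equal(deg$p, 1)

  a <- c(4.1, 5.2, 6.3, 4.8, 5.5)
  b <- c(7.9, 8.4, 7.1, 9)
  res2 <- student_t_two_tailed(a, b)
  expect_equal(res2$df, 7)
  # exhaustive permutation of group labels
  pool <- c(a, b)
  idx <- utils::combn(9, 5)
  t_perm <- apply(idx, 2, function(ia) {
    x <- pool[ia]; y <- pool[-ia]
    sp <- sqrt(((length(x) - 1) * stats::var(x) +
                  (length(y) - 1) * stats::var(y)) / 7)
    (mean(x) - mean(y)) / (sp * sqrt(1 / 5 + 1 / 4))
  })
  p_perm <- mean(abs(t_perm) >= abs(res2$t) - 1e-12)
  expect_lt(abs(res2$p - p_perm), 0.1)
})

test_that("probands separate from controls at realistic noise", {
  hits <- vapply(1:50, function(s) {
    cfg <- lipid_sim_config(seed = s, chains = "C16:0", fold_effect = 42,
                            cv = 0.1)
    panel <- simulate_lipid_panel(cfg)
    r <- dhcer_cer_ratios(panel)
    res <- student_t_two_tailed(r$ratio[r$group == "proband"],
                                r$ratio[r$group == "control"])
    res$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("panel report has deterministic shape and brute-force SDs", {
  p <- toy_panel()
  rep_tab <- summarize_panel(p)
  # chains x classes x groups rows
  expect_equal(nrow(rep_tab), 2 * 2 * 2)
  expect_equal(rep_tab$chain[1:4], rep(c("C16:0", "C24:1"), each = 2))

  set.seed(71)
  p$concentration <- stats::runif(nrow(p), 0.5, 3)
  rep_tab <- summarize_panel(p)
  persample <- stats::aggregate(concentration ~ sample + class + chain,
                                data = p, FUN = mean)
  for (k in which(rep_tab$group == "control")) {
    v <- persample$concentration[persample$class == rep_tab$class[k] &
                                   persample$chain == rep_tab$chain[k] &
                                   grepl("^c", persample$sample)]
    m <- sum(v) / length(v)
    expect_equal(rep_tab$mean[k], m)
    expect_equal(rep_tab$sd[k], sqrt(sum((v - m)^2) / (length(v) - 1)))
  }
})

test_that("a single measurement reports sd as missing with n = 1", {
  p <- toy_panel()
  p <- p[!(p$group == "proband" & p$replicate == 2), ]
  r <- summarize_panel(p)
  expect_true(all(r$n[r$group == "proband"] == 1))
  expect_true(all(is.na(r$sd[r$group == "proband"])))
})

test_that("configured fold is recovered exactly at cv = 0", {
  cfg <- lipid_sim_config(seed = 1, cv = 0, fold_effect = 42)
  panel <- simulate_lipid_panel(cfg)
  f <- fold_over_control(dhcer_cer_ratios(panel))
  expect_equal(f$fold[f$group == "proband"],
               rep(42, sum(f$group == "proband")))
})
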