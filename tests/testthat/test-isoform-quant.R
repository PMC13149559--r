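test_that("isoform fractions reproduce the patient and control profiles", {
  # patient-like: canonical is a 6% minority, exon-skip isoform dominates
  ab <- data.frame(transcript_id = c("canonical", "skip", "cryptic", "other"),
                   gene_id = "DEGS1", tpm = c(6, 69, 12, 13))
  fr <- isoform_fractions(ab)
  expect_equal(fr$fraction, c(0.06, 0.69, 0.12, 0.13))
  expect_equal(sum(fr$fraction), 1, tolerance = 1e-9)

  # control-like: canonical dominates
  ab2 <- data.frame(transcript_id = c("canonical", "rest"), gene_id = "G",
                    tpm = c(90, 10))
  expect_equal(isoform_fractions(ab2)$fraction[1], 0.9)

  ab3 <- data.frame(transcript_id = "only", gene_id = "G", tpm = 5)
  expect_equal(isoform_fractions(ab3)$fraction, 1)
})

test_that("zero-TPM genes get undefined fractions; negative TPM errors", {
  ab <- data.frame(transcript_id = c("a", "b", "c"),
                   gene_id = c("G1", "G1", "G2"), tpm = c(0, 0, 4))
  fr <- isoform_fractions(ab)
  expect_true(all(is.na(fr$fraction[fr$gene_id == "G1"])))
  expect_equal(fr$fraction[fr$gene_id == "G2"], 1)
  ab$tpm[1] <- -1
  expect_error(isoform_fractions(ab), "negative")
})

test_that("GTF parsing sorts exons and round-trips transcript models", {
  tf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'chrS\tsrc\texon\t501\t600\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    'chrS\tsrc\texon\t101\t220\t.\t+\t.\tgene_id "G1"; transcript_id "T1";',
    'chrS\tsrc\texon\t801\t950\t.\t+\t.\tgene_id "G1"; transcript_id "T1";'),
    tf)
  models <- parse_gtf_transcripts(tf)
  expect_length(models, 1)
  m <- models[["T1"]]
  expect_equal(m$exons$start, c(100L, 500L, 800L))  # sorted, 0-based
  expect_equal(m$exons$end, c(220L, 600L, 950L))

  gene <- simulate_gene_models(seed = 4, n_exons = 4)
  tf2 <- withr::local_tempfile(fileext = ".gtf")
  write_gtf_transcripts(list(gene$canonical, skip_exons(gene$canonical, 2)),
                        tf2)
  back <- parse_gtf_transcripts(tf2)
  expect_equal(back[["TX_CANON"]]$exons, gene$canonical$exons)
  expect_equal(back[["TX_CANON"]]$cds, gene$canonical$cds)
  expect_equal(back[["TX_CANON_skip2"]]$exons,
               skip_exons(gene$canonical, 2)$exons)
})

test_that("classification by intron chain covers the spec'd categories", {
  gene <- simulate_gene_models(seed = 8, n_exons = 3)
  canonical <- gene$canonical

  expect_equal(classify_isoform(canonical, canonical)$category,
               "canonical_match")

  skip <- skip_exons(canonical, 2)
  cls <- classify_isoform(skip, canonical)
  expect_equal(cls$category, "exon_skipping")
  expect_equal(cls$detail$skipped_exons, 2L)

  # cryptic acceptor: exon-3 start moved 30 nt into the exon
  ex <- canonical$exons
  ex$start[3] <- ex$start[3] + 30L
  cryptic <- transcript_model("T_cryp", "GENE1", canonical$contig, "+", ex)
  cls2 <- classify_isoform(cryptic, canonical)
  expect_equal(cls2$category, "altered_splice_site")
  expect_equal(cls2$detail$new_coordinate, ex$start[3])
  expect_equal(cls2$detail$side, "acceptor")

  # terminal-exon length change leaves the intron chain intact
  ex2 <- canonical$exons
  ex2$end[3] <- ex2$end[3] + 40L
  longer <- transcript_model("T_long", "GENE1", canonical$contig, "+", ex2)
  expect_equal(classify_isoform(longer, canonical)$category,
               "canonical_match")

  # unrelated chain
  alt <- transcript_model("T_alt", "GENE1", canonical$contig, "+",
                          data.frame(start = c(ex$start[1], ex$start[1] + 2000L),
                                     end = c(ex$start[1] + 50L,
                                             ex$start[1] + 2100L)))
  expect_equal(classify_isoform(alt, canonical)$category, "other")
  expect_error(classify_isoform(
    transcript_model("T", "G", "chrOther", "+", canonical$exons), canonical),
    "contig")
})

test_that("constructed skips are recovered with exactly their ordinals", {
  set.seed(31)
  for (i in 1:60) {
    n_ex <- sample(4:7, 1)
    strand <- sample(c("+", "-"), 1)
    gene <- simulate_gene_models(seed = sample.int(1e6, 1), n_exons = n_ex,
                                 strand = strand)
    internal <- 2:(n_ex - 1)
    k <- sample(1:length(internal), 1)
    ords <- sort(internal[sample.int(length(internal), k)])
    cand <- skip_exons(gene$canonical, ords)
    cls <- classify_isoform(cand, gene$canonical)
    expect_equal(cls$category, "exon_skipping")
    expect_equal(cls$detail$skipped_exons, as.integer(ords))
  }
})

test_that("protein consequences: identity and clean in-frame deletion", {
  # exon 1 carries 15 nt of 5' UTR, so a 99-nt exon 1 leaves the exon 1/2
  # boundary on a codon boundary; exon 2 of 90 nt then deletes 30 residues
  gene <- simulate_gene_models(seed = 2, n_exons = 3,
                               exon_lengths = c(99L, 90L, 120L))
  canonical <- gene$canonical
  same <- transcript_model("T_id", "GENE1", canonical$contig,
                           canonical$strand, canonical$exons)
  res <- predict_protein_consequence(canonical, same, gene$genome)
  expect_equal(res$hgvs_p, "p.(=)")
  expect_equal(res$kind, "synonymous_structure")

  # exon 2 length 90 (0 mod 3): skipping deletes 30 residues in frame
  skip <- skip_exons(canonical, 2)
  res2 <- predict_protein_consequence(canonical, skip, gene$genome)
  expect_equal(res2$kind, "in_frame_deletion")
  expect_match(res2$hgvs_p, "^p\\.[A-Z][a-z]{2}[0-9]+_[A-Z][a-z]{2}[0-9]+del$")
  expect_equal(nchar(res2$candidate_peptide),
               nchar(res2$canonical_peptide) - 30)
})

test_that("a frame-breaking skip yields an fs* string with the right index", {
  gene <- simulate_gene_models(seed = 14, n_exons = 3,
                               exon_lengths = c(100L, 91L, 120L))
  skip <- skip_exons(gene$canonical, 2)
  res <- predict_protein_consequence(gene$canonical, skip, gene$genome)
  expect_equal(res$kind, "frameshift")
  expect_match(res$hgvs_p, "^p\\.[A-Z][a-z]{2}[0-9]+[A-Z][a-z]{2}fs\\*[0-9]+$")
  expect_identical(res, c(oracle_skip_consequence(gene, 2),
                          list(canonical_peptide = res$canonical_peptide,
                               candidate_peptide = res$candidate_peptide)))
})

test_that("removing the start-codon exon is reported as start loss", {
  # put the start codon in exon 2 by trimming the CDS
  gene <- simulate_gene_models(seed = 9, n_exons = 4)
  canonical <- gene$canonical
  cds <- canonical$cds[-1, , drop = FALSE]  # CDS now begins in exon 2
  canonical2 <- transcript_model(canonical$transcript_id, canonical$gene_id,
                                 canonical$contig, canonical$strand,
                                 canonical$exons, cds = cds)
  skip <- skip_exons(canonical2, 2)
  res <- predict_protein_consequence(canonical2, skip, gene$genome)
  expect_equal(res$kind, "start_lost")
  expect_equal(res$hgvs_p, "p.Met1?")
})

test_that("consequence prediction agrees with the brute-force oracle", {
  set.seed(77)
  for (i in 1:150) {
    n_ex <- sample(3:6, 1)
    strand <- sample(c("+", "-"), 1)
    gene <- simulate_gene_models(seed = sample.int(1e6, 1), n_exons = n_ex,
                                 strand = strand)
    internal <- 2:(n_ex - 1)
    k <- sample(1:length(internal), 1)
    ords <- sort(internal[sample.int(length(internal), k)])
    cand <- skip_exons(gene$canonical, ords)
    got <- predict_protein_consequence(gene$canonical, cand, gene$genome)
    want <- oracle_skip_consequence(gene, ords)
    expect_equal(got$hgvs_p, want$hgvs_p)
    expect_equal(got$kind, want$kind)
  }
})
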