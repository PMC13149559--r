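# Three-exon toy gene used throughout: introns e1-e2 [1200,2000),
# e2-e3 [2200,3000), and the exon-2-skipping intron e1-e3 [1200,3000).
three_exon_junctions <- function() {
  data.frame(contig = "chr1",
             start = c(1200L, 2200L, 1200L),
             end = c(2000L, 3000L, 3000L),
             strand = "+")
}

test_that("parse_star_sj converts STAR's 1-based inclusive introns", {
  tf <- withr::local_tempfile()
  writeLines("chr1\t1000\t1200\t1\t1\t1\t25\t3\t40", tf)
  tab <- parse_star_sj(tf, sample_id = "s1")
  expect_equal(tab$junctions$start, 999L)
  expect_equal(tab$junctions$end, 1200L)
  expect_equal(tab$junctions$strand, "+")
  expect_equal(unname(tab$counts[1, "s1"]), 25L)
  # multi-mapper column ignored by default, added on request
  tab2 <- parse_star_sj(tf, sample_id = "s1", multimappers = TRUE)
  expect_equal(unname(tab2$counts[1, "s1"]), 28L)
})

test_that("parse_star_sj handles empty files and flags malformed lines", {
  tf <- withr::local_tempfile()
  writeLines(character(0), tf)
  expect_equal(nrow(parse_star_sj(tf, "s1")$junctions), 0)

  writeLines("chr1\t1000\t1200\t1", tf)
  expect_error(parse_star_sj(tf, "s1"), "line 1")
  writeLines(c("chr1\t1000\t1200\t1\t1\t1\t25\t3\t40",
               "chr1\tXXX\t1300\t1\t1\t1\t5\t0\t40"), tf)
  expect_error(parse_star_sj(tf, "s1"), "line 2")
})

test_that("STAR writer/parser round-trips a table", {
  set.seed(11)
  tab <- random_junction_table(20, 1)
  tf <- withr::local_tempfile()
  write_star_sj(tab, tf)
  back <- parse_star_sj(tf, sample_id = colnames(tab$counts))
  expect_equal(back$junctions, tab$junctions)
  expect_equal(unname(back$counts), unname(tab$counts))
})

test_that("generic junction TSV round-trips including zero counts", {
  set.seed(12)
  tab <- random_junction_table(15, 4)
  tf <- withr::local_tempfile()
  write_junction_tsv(tab, tf, drop_zero = FALSE)
  back <- parse_junction_tsv(tf)
  expect_equal(back$junctions, tab$junctions)
  expect_equal(back$counts[rownames(tab$counts), colnames(tab$counts)],
               tab$counts)
})

test_that("merge_samples unions junctions, zero-fills, rejects duplicates", {
  j1 <- data.frame(contig = "chr1", start = 100L, end = 200L, strand = "+")
  j2 <- data.frame(contig = "chr1", start = c(100L, 400L),
                   end = c(200L, 600L), strand = "+")
  t1 <- junction_counts(j1, matrix(5L, 1, 1, dimnames = list(NULL, "a")))
  t2 <- junction_counts(j2, matrix(c(3L, 7L), 2, 1,
                                   dimnames = list(NULL, "b")))
  m <- merge_samples(list(t1, t2))
  expect_equal(dim(m$counts), c(2L, 2L))
  expect_equal(unname(m$counts[, "a"]), c(5L, 0L))
  expect_equal(unname(m$counts[, "b"]), c(3L, 7L))
  expect_error(merge_samples(list(t1, t1)), "duplicate sample id")
})

test_that("merging preserves per-sample column sums", {
  set.seed(13)
  singles <- lapply(1:5, function(i) {
    tab <- random_junction_table(10, 1)
    colnames(tab$counts) <- paste0("s", i)
    rownames(tab$counts) <- junction_key(tab$junctions)
    tab
  })
  m <- merge_samples(singles)
  for (i in seq_along(singles)) {
    expect_equal(sum(m$counts[, paste0("s", i)]), sum(singles[[i]]$counts))
  }
})

test_that("exclusion sets use half-open overlap and are symmetric", {
  # introns sharing only a boundary do not overlap
  j <- data.frame(contig = "chr1", start = c(100L, 200L),
                  end = c(200L, 300L), strand = "+")
  expect_equal(unname(lengths(build_exclusion_sets(j))), c(0L, 0L))

  j3 <- three_exon_junctions()
  ex <- build_exclusion_sets(j3)
  expect_equal(ex[[1]], 3L)            # e1-e2 excluded only by the skip
  expect_equal(ex[[2]], 3L)
  expect_equal(ex[[3]], c(1L, 2L))     # skip excluded by both inclusions
  # never self-excluding
  for (i in seq_along(ex)) expect_false(i %in% ex[[i]])
})

test_that("opposite strands never exclude; unknown strand matches both", {
  j <- data.frame(contig = "chr1", start = c(100L, 150L, 150L),
                  end = c(300L, 400L, 350L), strand = c("+", "-", "*"))
  ex <- build_exclusion_sets(j)
  expect_equal(ex[[1]], 3L)
  expect_equal(ex[[2]], 3L)
  expect_equal(ex[[3]], c(1L, 2L))
})

test_that("percent_spliced reproduces the patient skip-junction share", {
  tab <- junction_counts(three_exon_junctions(),
                         matrix(c(24L, 20L, 56L), ncol = 1,
                                dimnames = list(NULL, "patient")))
  ps <- percent_spliced(tab)$ps
  expect_equal(unname(ps[3, 1]), 0.56)          # skip dominates
  expect_equal(unname(ps[1, 1]), 24 / 80)
  expect_equal(unname(ps[2, 1]), 20 / 76)
})

test_that("PS formula edge cases: no competition, exclusive pair, zeros", {
  j <- data.frame(contig = c("chr1", "chr2", "chr2"),
                  start = c(100L, 100L, 150L), end = c(200L, 300L, 400L),
                  strand = "+")
  tab <- junction_counts(j, matrix(c(7L, 30L, 10L, 0L, 0L, 0L), ncol = 2,
                                   dimnames = list(NULL, c("a", "b"))))
  ps <- percent_spliced(tab)$ps
  expect_equal(unname(ps[, "a"]), c(1, 0.75, 0.25))
  expect_true(all(is.na(ps[, "b"])))    # zero denominator -> missing
})

test_that("percent_spliced matches the brute-force oracle on random tables", {
  set.seed(42)
  for (rep in 1:25) {
    tab <- random_junction_table(sample(2:50, 1), sample(1:4, 1))
    expect_equal(percent_spliced(tab)$ps, brute_force_ps(tab))
  }
})

test_that("PS is invariant to junction order up to row permutation", {
  set.seed(99)
  tab <- random_junction_table(30, 3)
  perm <- sample(nrow(tab$junctions))
  tab_p <- junction_counts(tab$junctions[perm, ],
                           tab$counts[perm, , drop = FALSE])
  ps <- percent_spliced(tab)$ps
  ps_p <- percent_spliced(tab_p)$ps
  expect_equal(ps_p[rownames(ps), ], ps)
})
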