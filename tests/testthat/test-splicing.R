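test_that("junctions are the gaps between consecutive exons, collapsed across isoforms", {
  exons <- data.frame(
    transcript_id = c("t1", "t1", "t2", "t2"),
    chrom = "chr1",
    start = c(1L, 201L, 1L, 201L),
    end = c(100L, 300L, 100L, 300L),
    strand = "+"
  )
  jn <- extract_junction_annotations(exons)
  expect_equal(nrow(jn), 1L)  # two transcripts share one intron
  expect_equal(jn$intron_start, 101L)
  expect_equal(jn$intron_end, 200L)
})

test_that("transcripts with overlapping exons are rejected with a message", {
  exons <- data.frame(
    transcript_id = c("ok", "ok", "bad", "bad"),
    chrom = "chr1",
    start = c(1L, 201L, 1L, 50L),
    end = c(100L, 300L, 100L, 150L),
    strand = "+"
  )
  expect_warning(jn <- extract_junction_annotations(exons), "overlapping")
  expect_equal(nrow(jn), 1L)  # only the well-formed transcript contributes
})

test_that("junction extraction equals per-transcript enumeration on random models", {
  for (seed in c(21, 22, 23)) {
    exons <- random_gene_models(seed, n_genes = 6)
    got <- extract_junction_annotations(exons)
    want <- oracle_junctions(exons)
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("a three-exon gene with a skip isoform yields exactly one cassette event", {
  exons <- data.frame(
    transcript_id = c(rep("incl", 3), rep("skip", 2)),
    chrom = "chr1",
    start = c(1L, 201L, 401L, 1L, 401L),
    end = c(100L, 300L, 500L, 100L, 500L),
    strand = "+"
  )
  jn <- extract_junction_annotations(exons)
  ev <- find_cassette_exons(jn, exons)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$skip_start, 101L)
  expect_equal(ev$skip_end, 400L)
  expect_equal(c(ev$exon_start, ev$exon_end), c(201L, 300L))
  expect_equal(c(ev$incl5_start, ev$incl5_end), c(101L, 200L))
  expect_equal(c(ev$incl3_start, ev$incl3_end), c(301L, 400L))
})

test_that("junctions enclosing two exons are not cassette events", {
  # five-exon gene with a transcript skipping exons 2 and 3 together
  starts <- c(1L, 201L, 401L, 601L, 801L)
  ends <- starts + 99L
  exons <- rbind(
    data.frame(transcript_id = "full", chrom = "chr1", start = starts,
               end = ends, strand = "+"),
    data.frame(transcript_id = "dskip", chrom = "chr1",
               start = starts[c(1, 4, 5)], end = ends[c(1, 4, 5)], strand = "+")
  )
  jn <- extract_junction_annotations(exons)
  ev <- find_cassette_exons(jn, exons)
  # the double-skip junction (101,600) contains 2 exons: rejected; the
  # single-exon containments (e.g. around exon 2) lack the two-intron
  # structure unless a single-skip isoform exists
  expect_false(any(ev$skip_start == 101L & ev$skip_end == 600L))
})

test_that("enclosed introns must share a boundary with the skip junction", {
  # skip-like junction (101,400) enclosing one exon and two introns that
  # share neither end with it (alternative donor/acceptor decoy)
  jn <- data.frame(
    chrom = "chr1",
    intron_start = c(101L, 121L, 301L),
    intron_end = c(400L, 200L, 380L),
    strand = "+"
  )
  exons <- data.frame(transcript_id = "t", chrom = "chr1",
                      start = 201L, end = 300L, strand = "+")
  ev <- find_cassette_exons(jn, exons)
  expect_equal(nrow(ev), 0L)
})

test_that("cassette detection equals the brute-force oracle on random models", {
  for (seed in 31:35) {
    exons <- random_gene_models(seed, n_genes = 6)
    jn <- extract_junction_annotations(exons)
    got <- find_cassette_exons(jn, exons)
    want <- oracle_cassette(jn, exons)
    expect_equal(got, want, ignore_attr = TRUE)
  }
})

test_that("percent spliced out applies the formula and its evidence thresholds", {
  expect_equal(percent_spliced_out(20, 90, 90), 10.0)
  expect_true(is.na(percent_spliced_out(1, 500, 500)))    # skip below 2
  expect_true(is.na(percent_spliced_out(50, 40, 50)))     # flank sum 90 < 100
  expect_equal(percent_spliced_out(2, 50, 50), 100 * 2 / 102)  # both boundaries met
  # monotone: more skip reads, higher PSO; more inclusion reads, lower PSO
  expect_gt(percent_spliced_out(30, 90, 90), percent_spliced_out(20, 90, 90))
  expect_lt(percent_spliced_out(20, 120, 90), percent_spliced_out(20, 90, 90))
})

test_that("intron overlap counting honors the minimum overlap and matches brute force", {
  intron <- data.frame(chrom = "chr1", start = 1001L, end = 1450L)
  reads <- data.frame(
    chrom = "chr1",
    start = c(960L, 959L, 1100L, 1442L, 1441L),
    end = c(1009L, 1008L, 1149L, 1491L, 1490L)
  )
  # overlaps: 9, 8, 50, 9, 10
  got <- count_intron_reads(reads, intron, min_overlap = 10)
  expect_equal(got, 2L)
  expect_equal(count_intron_reads(reads, intron, min_overlap = 9), 4L)

  set.seed(55)
  r <- data.frame(chrom = "chr1", start = sample(900:1500, 300, TRUE))
  r$end <- r$start + 49L
  introns <- data.frame(chrom = "chr1", start = c(1001L, 1200L), end = c(1450L, 1300L))
  expect_equal(count_intron_reads(r, introns, 10),
               oracle_overlap_count(r, introns, 10))
})

test_that("intron PSI follows the length-normalized formula and its limits", {
  expect_equal(intron_psi(200, 80, 450, 50), 20.0)
  expect_equal(intron_psi(0, 80, 450, 50), 0)
  expect_equal(intron_psi(200, 0, 450, 50), 100)
  expect_true(is.na(intron_psi(0, 0, 450, 50)))
  # invariant under joint scaling of the two counts
  expect_equal(intron_psi(200, 80, 450, 50), intron_psi(2000, 800, 450, 50))
  # bounded
  expect_true(all(intron_psi(c(1, 10, 1e6), c(1e6, 10, 1), 450, 50) >= 0))
  expect_true(all(intron_psi(c(1, 10, 1e6), c(1e6, 10, 1), 450, 50) <= 100))
})

test_that("retention quantification suppresses introns below the read floor", {
  introns <- data.frame(chrom = "chr1", intron_start = c(1001L, 5001L),
                        intron_end = c(1450L, 5450L))
  mk_reads <- function(n, s) {
    data.frame(chrom = "chr1", start = seq(s, s + n - 1), end = seq(s, s + n - 1) + 49L)
  }
  reads <- rbind(mk_reads(99, 1001L), mk_reads(100, 5001L))
  jc <- data.frame(chrom = "chr1", intron_start = c(1001L, 5001L),
                   intron_end = c(1450L, 5450L), unique_reads = c(80L, 80L))
  out <- quantify_intron_retention(introns, reads, jc, read_length = 50)
  expect_equal(out$pass, c(FALSE, TRUE))   # 99 vs 100 qualifying reads
  expect_true(is.na(out$psi[1]))
  expect_false(is.na(out$psi[2]))
  expect_equal(out$normalized_intron_reads[2], 100 * 50 / (450 + 50))
})

test_that("junction tables in both dialects parse to the same columns", {
  tmp9 <- withr::local_tempfile(fileext = ".tab")
  writeLines("chr1\t101\t200\t1\t1\t1\t42\t7\t38", tmp9)
  j9 <- read_junction_table(tmp9)
  expect_equal(j9$unique_reads, 42L)
  expect_equal(j9$strand, "+")

  tmp4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("chr1\t101\t200\t42", tmp4)
  j4 <- read_junction_table(tmp4)
  expect_equal(j4$unique_reads, 42L)
  expect_equal(j4[, c("chrom", "intron_start", "intron_end", "unique_reads")],
               j9[, c("chrom", "intron_start", "intron_end", "unique_reads")])
})
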