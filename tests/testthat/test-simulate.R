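test_that("the simulator is a pure function of config and seed", {
  cfg <- sim_config(seed = 9, n_genes = 10, n_nontargeting_pairs = 4,
                    collision_rate = 0.01, near_dup_rate = 0.02)
  a <- simulate_library(cfg)
  b <- simulate_library(cfg)
  expect_identical(a$library, b$library)
  expect_identical(a$barcodes, b$barcodes)
  expect_identical(simulate_linkage_reads(a), simulate_linkage_reads(b))
  expect_identical(simulate_fitness_screen(a)$reads,
                   simulate_fitness_screen(b)$reads)

  other <- simulate_library(sim_config(seed = 10, n_genes = 10,
                                       n_nontargeting_pairs = 4))
  expect_false(identical(a$library$protospacer_a, other$library$protospacer_a))
})

test_that("clean configurations emit all-unique, unambiguous barcodes", {
  cfg <- sim_config(seed = 13, n_genes = 15, collision_rate = 0,
                    near_dup_rate = 0)
  sl <- simulate_library(cfg)
  expect_false(any(duplicated(sl$barcodes$barcode)))
  expect_false(any(sl$barcodes$ambiguous))
  expect_equal(nrow(sl$linkage_truth), nrow(sl$barcodes))
})

test_that("collision injection matches its closed-form expectation", {
  cfg <- sim_config(seed = 14, n_genes = 320, collision_rate = 0.01)
  sl <- simulate_library(cfg)
  n_bc <- sum(is.na(sl$barcodes$near_dup_of) & !duplicated(sl$barcodes$barcode))
  n_ambig <- length(unique(sl$barcodes$barcode[sl$barcodes$ambiguous]))
  # ~1% of roughly 10k barcodes; binomial-scale tolerance
  expect_gt(n_ambig, 0.005 * n_bc)
  expect_lt(n_ambig, 0.02 * n_bc)
})

test_that("barcodes per sgRNA follow the truncated dispersion model", {
  cfg <- sim_config(seed = 15, n_genes = 200)
  sl <- simulate_library(cfg)
  per_sg <- table(sl$barcodes$sgrna_id)
  expect_true(all(per_sg >= 1))
  expect_equal(unname(median(per_sg)), 8, tolerance = 0.15)
})

test_that("fitness truth follows the exponential depletion closed form", {
  cfg <- sim_config(seed = 16, n_genes = 10, frac_essential = 0.2,
                    essential_fitness = -0.5)
  sl <- simulate_library(cfg)
  scr <- simulate_fitness_screen(sl, days = c(1, 13))
  eff <- scr$truth$gene_effects
  expect_equal(eff$expected_log2_depletion_gdna[eff$fitness == -0.5],
               rep(-0.5 * 12, 2))
  expect_equal(eff$expected_log2_depletion_gdna[eff$fitness == 0],
               rep(0, sum(eff$fitness == 0)))
})

test_that("a null screen produces centered ratios scattered around zero", {
  cfg <- sim_config(seed = 17, n_genes = 20, frac_essential = 0,
                    error_rate = 0, mean_umis_per_barcode = 80)
  sl <- simulate_library(cfg)
  scr <- simulate_fitness_screen(sl, days = c(1, 21))
  parsed <- parse_screen_reads(scr$reads, reporter_whitelist = scr$reporters)
  counts <- count_umis(parsed, sl$linkage_truth)
  rt <- log2_ratio_centered(counts, contrast("null", "mrna_day21", "mrna_day1"))
  gene_lfc <- aggregate_gene(aggregate_gene(rt), "sgrna_to_gene")
  expect_lt(max(abs(gene_lfc$log2_ratio)), 0.5)
})

test_that("dual-barcode stabilization shifts the centered ratio by its log2", {
  cfg <- sim_config(seed = 18, n_genes = 40, frac_essential = 0,
                    error_rate = 0, mean_umis_per_barcode = 120)
  sl <- simulate_library(cfg)
  scr <- simulate_dual_barcode_screen(sl, stabilization = 4, n_affected = 4)
  expect_equal(
    sort(unique(scr$truth$gene_effects$expected_log2_shift)), c(0, 2))
  parsed <- parse_screen_reads(scr$reads, reporter_whitelist = scr$reporters)
  counts <- count_umis(parsed, sl$linkage_truth)
  cent <- dual_barcode_stats(counts, "pool", "ptc", "mcherry")
  gene_lfc <- aggregate_gene(aggregate_gene(cent), "sgrna_to_gene")
  aff <- scr$truth$gene_effects$gene[scr$truth$gene_effects$affected]
  expect_equal(mean(gene_lfc$log2_ratio[gene_lfc$gene %in% aff]), 2,
               tolerance = 0.15)
  expect_equal(median(gene_lfc$log2_ratio[!gene_lfc$gene %in% aff]), 0,
               tolerance = 0.1)
})

test_that("polysome redistribution shifts H/M ratios as prescribed", {
  cfg <- sim_config(seed = 19, n_genes = 40, frac_essential = 0,
                    error_rate = 0, mean_umis_per_barcode = 120)
  sl <- simulate_library(cfg)
  scr <- simulate_polysome_screen(sl, n_affected = 4)
  parsed <- parse_screen_reads(scr$reads, reporter_whitelist = scr$reporters)
  counts <- count_umis(parsed, sl$linkage_truth)
  rt <- log2_ratio_centered(counts, contrast("HM", "heavy", "mono",
                                             modality = "polysome_HM"))
  gene_lfc <- aggregate_gene(aggregate_gene(rt), "sgrna_to_gene")
  eff <- scr$truth$gene_effects
  aff <- eff$gene[eff$affected]
  want <- unique(eff$expected_log2_HM_shift[eff$affected])
  expect_equal(mean(gene_lfc$log2_ratio[gene_lfc$gene %in% aff]), want,
               tolerance = abs(want) * 0.15)
})

test_that("junction simulation converges to its molecular skip fraction", {
  sim <- simulate_junction_data(n_cassette = 1, n_retention = 0,
                                skip_fraction = 0.1, depth = 1e5, seed = 71)
  ev <- find_cassette_exons(extract_junction_annotations(sim$exons), sim$exons)
  q <- quantify_cassette_exons(ev, sim$junction_counts)
  expect_equal(q$pso, 10, tolerance = 0.05)

  sim0 <- simulate_junction_data(n_cassette = 1, n_retention = 0,
                                 skip_fraction = 0, depth = 1e4, seed = 72)
  ev0 <- find_cassette_exons(extract_junction_annotations(sim0$exons), sim0$exons)
  q0 <- quantify_cassette_exons(ev0, sim0$junction_counts)
  expect_true(is.na(q0$pso) || q0$pso == 0)
})

test_that("intron retention simulation recovers the retention fraction", {
  sim <- simulate_junction_data(n_cassette = 0, n_retention = 5,
                                retention = 0.2, coverage = 20, seed = 73)
  raw <- sim$raw_intron_counts
  psi <- intron_psi(raw$raw_intron_reads, raw$junction_reads, 450,
                    sim$read_length)
  expect_equal(mean(psi), 20, tolerance = 1.5)
})

test_that("screen reads round-trip through FASTQ", {
  cfg <- sim_config(seed = 20, n_genes = 3, mean_umis_per_barcode = 10)
  sl <- simulate_library(cfg)
  scr <- simulate_fitness_screen(sl, days = c(1, 5))
  dir <- withr::local_tempdir()
  paths <- write_screen_fastq(scr$reads, dir)
  back <- read_screen_fastq(paths)
  orig <- scr$reads[order(scr$reads$sample_id, scr$reads$seq), ]
  back <- back[order(back$sample_id, back$seq), ]
  expect_equal(back$seq, orig$seq)
  expect_equal(back$sample_id, orig$sample_id)
})
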