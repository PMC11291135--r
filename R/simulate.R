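#' Simulation configuration for a synthetic ReLiC screen
#'
#' Defaults mirror the study design this workflow targets: 2,190 targeted
#' genes with 4 dual-sgRNA pairs per gene, a median of ~8 barcodes per sgRNA
#' pair (drawn from a truncated negative binomial), 20-nt barcodes and 7-nt
#' UMIs, plus non-targeting sgRNA pairs grouped into pseudo-genes as negative
#' controls. Essential genes deplete exponentially at a fixed log2-per-day
#' fitness cost; sequencing realism comes from PCR duplication (reads per
#' molecule), per-base substitution errors, and optional barcode collisions
#' and near-duplicate (1-edit) barcodes to exercise the linkage filters.
#'
#' @param seed RNG seed; mandatory — every simulated dataset is a pure
#'   function of (config, seed).
#' @param n_genes targeted genes.
#' @param sgrnas_per_gene dual-sgRNA pairs per gene.
#' @param barcodes_per_sgrna target barcodes per sgRNA pair (negative
#'   binomial mean, truncated at 1).
#' @param barcode_dispersion negative binomial size parameter.
#' @param n_nontargeting_pairs non-targeting control sgRNA pairs, grouped
#'   into pseudo-genes of `sgrnas_per_gene`.
#' @param frac_essential fraction of targeted genes given a fitness cost.
#' @param essential_fitness fitness effect of essential genes in log2 units
#'   per day (negative = depletion).
#' @param mrna_amplification multiplier on the fitness effect in mRNA
#'   relative to genomic DNA (slower-growing cells carry less RNA; 1 =
#'   no amplification).
#' @param collision_rate fraction of barcodes also assigned to a second,
#'   different sgRNA insert (ambiguous barcodes).
#' @param near_dup_rate fraction of barcodes that spawn a 1-edit variant
#'   linked to the same insert (sequencing-error-derived duplicates).
#' @param error_rate per-base substitution error rate in emitted reads.
#' @param mean_reads_per_molecule mean sequencing reads per molecule (PCR
#'   duplication); 1 = no duplication.
#' @param mean_umis_per_barcode sequencing depth: expected molecules per
#'   barcode per sample.
#' @param umi_length,barcode_length field lengths in nt.
#' @param unique_umis force collision-free UMIs (distinct molecules always
#'   get distinct UMIs); default FALSE draws UMIs uniformly with
#'   replacement from the 4^umi_length space.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_genes = 2190,
                       sgrnas_per_gene = 4,
                       barcodes_per_sgrna = 8,
                       barcode_dispersion = 5,
                       n_nontargeting_pairs = 100,
                       frac_essential = 0.1,
                       essential_fitness = -0.5,
                       mrna_amplification = 1,
                       collision_rate = 0,
                       near_dup_rate = 0,
                       error_rate = 0.001,
                       mean_reads_per_molecule = 1.5,
                       mean_umis_per_barcode = 100,
                       umi_length = 7L,
                       barcode_length = 20L,
                       unique_umis = FALSE) {
  if (missing(seed) || is.null(seed)) stop("sim_config requires a seed")
  cfg <- list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    sgrnas_per_gene = as.integer(sgrnas_per_gene),
    barcodes_per_sgrna = barcodes_per_sgrna,
    barcode_dispersion = barcode_dispersion,
    n_nontargeting_pairs = as.integer(n_nontargeting_pairs),
    frac_essential = frac_essential,
    essential_fitness = essential_fitness,
    mrna_amplification = mrna_amplification,
    collision_rate = collision_rate,
    near_dup_rate = near_dup_rate,
    error_rate = error_rate,
    mean_reads_per_molecule = mean_reads_per_molecule,
    mean_umis_per_barcode = mean_umis_per_barcode,
    umi_length = as.integer(umi_length),
    barcode_length = as.integer(barcode_length),
    unique_umis = isTRUE(unique_umis)
  )
  stopifnot(cfg$n_genes >= 1, cfg$sgrnas_per_gene >= 1,
            cfg$barcodes_per_sgrna >= 1,
            cfg$frac_essential >= 0, cfg$frac_essential <= 1,
            cfg$collision_rate >= 0, cfg$near_dup_rate >= 0,
            cfg$error_rate >= 0, cfg$mean_reads_per_molecule >= 1,
            cfg$mean_umis_per_barcode > 0)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a designed library and its true barcode linkage
#'
#' Generates random protospacers per sgRNA pair, draws the number of
#' barcodes per pair from a truncated negative binomial, and assigns unique
#' random barcodes. The first `round(frac_essential * n_genes)` targeted
#' genes carry the essential fitness effect. Barcode collisions (same
#' barcode linked to two inserts) and 1-edit near-duplicate barcodes are
#' injected at the configured rates so the linkage filters have something to
#' remove; both are flagged in the truth table.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_library`:
#' \describe{
#'   \item{library}{designed library `(sgrna_id, gene, protospacer_a,
#'     protospacer_b, category)`}
#'   \item{barcodes}{all emitted barcode/insert links with `ambiguous` and
#'     `near_dup_of` flags}
#'   \item{linkage_truth}{the clean truth: unambiguous, non-error barcodes
#'     only `(barcode, sgrna_id, gene)`}
#'   \item{gene_effects}{`(gene, category, fitness)`}
#'   \item{config}{the input config}
#' }
#' @export
simulate_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)

  n_t <- config$n_genes
  genes_t <- sprintf("GENE%04d", seq_len(n_t))
  n_ntc_genes <- ceiling(config$n_nontargeting_pairs / config$sgrnas_per_gene)
  genes_ntc <- if (n_ntc_genes > 0) sprintf("NTC%03d", seq_len(n_ntc_genes)) else character()

  lib <- data.frame(
    gene = c(rep(genes_t, each = config$sgrnas_per_gene),
             rep(genes_ntc, each = config$sgrnas_per_gene)[seq_len(config$n_nontargeting_pairs)]),
    stringsAsFactors = FALSE
  )
  lib$sgrna_id <- sprintf("sg%05d", seq_len(nrow(lib)))
  lib$category <- ifelse(startsWith(lib$gene, "NTC"),
                         "nontargeting_control", "targeting")
  protos <- random_dna(2L * nrow(lib), 20L)
  lib$protospacer_a <- protos[seq_len(nrow(lib))]
  lib$protospacer_b <- protos[nrow(lib) + seq_len(nrow(lib))]
  lib <- lib[, c("sgrna_id", "gene", "protospacer_a", "protospacer_b", "category")]
  lib <- validate_sgrna_library(lib)

  n_ess <- round(config$frac_essential * n_t)
  gene_effects <- data.frame(
    gene = c(genes_t, genes_ntc),
    category = c(rep("targeting", n_t), rep("nontargeting_control", length(genes_ntc))),
    fitness = c(rep(config$essential_fitness, n_ess), rep(0, n_t - n_ess),
                rep(0, length(genes_ntc))),
    stringsAsFactors = FALSE
  )

  n_bc <- pmax(1L, rnbinom(nrow(lib), size = config$barcode_dispersion,
                           mu = config$barcodes_per_sgrna))
  if (sum(n_bc) > 4^config$barcode_length / 100) {
    stop("barcode space too small for the requested library")
  }
  barcodes <- data.frame(
    barcode = random_dna(sum(n_bc), config$barcode_length),
    sgrna_id = rep(lib$sgrna_id, times = n_bc),
    stringsAsFactors = FALSE
  )
  barcodes$gene <- lib$gene[match(barcodes$sgrna_id, lib$sgrna_id)]
  barcodes$ambiguous <- FALSE
  barcodes$near_dup_of <- NA_character_

  # inject ambiguous barcodes: an existing barcode is also cloned in front
  # of a second, different insert
  n_coll <- round(config$collision_rate * nrow(barcodes))
  if (n_coll > 0) {
    victim <- sample.int(nrow(barcodes), n_coll)
    other <- vapply(victim, function(i) {
      sample(setdiff(lib$sgrna_id, barcodes$sgrna_id[i]), 1)
    }, character(1))
    extra <- data.frame(
      barcode = barcodes$barcode[victim], sgrna_id = other,
      gene = lib$gene[match(other, lib$sgrna_id)],
      ambiguous = TRUE, near_dup_of = NA_character_,
      stringsAsFactors = FALSE
    )
    barcodes$ambiguous[victim] <- TRUE
    barcodes <- rbind(barcodes, extra)
  }

  # inject near-duplicate (1-edit) barcodes linked to the same insert
  n_dup <- round(config$near_dup_rate * nrow(barcodes))
  if (n_dup > 0) {
    parent <- sample(which(!barcodes$ambiguous), min(n_dup, sum(!barcodes$ambiguous)))
    dups <- lapply(parent, function(i) {
      repeat {
        v <- mutate_one_base(barcodes$barcode[i])
        if (!v %in% barcodes$barcode) return(v)
      }
    })
    extra <- data.frame(
      barcode = unlist(dups), sgrna_id = barcodes$sgrna_id[parent],
      gene = barcodes$gene[parent], ambiguous = FALSE,
      near_dup_of = barcodes$barcode[parent],
      stringsAsFactors = FALSE
    )
    barcodes <- rbind(barcodes, extra)
  }

  clean <- barcodes[!barcodes$ambiguous & is.na(barcodes$near_dup_of), ]
  clean <- clean[!clean$barcode %in% barcodes$barcode[barcodes$ambiguous], ]
  structure(list(
    library = lib,
    barcodes = barcodes,
    linkage_truth = clean[, c("barcode", "sgrna_id", "gene")],
    gene_effects = gene_effects,
    config = config
  ), class = "sim_library")
}

# substitute one random base of a DNA string
mutate_one_base <- function(x) {
  p <- sample.int(nchar(x), 1)
  base <- substr(x, p, p)
  substr(x, p, p) <- sample(setdiff(DNA_BASES, base), 1)
  x
}

#' Simulate linkage sequencing reads
#'
#' One read per sequenced plasmid: the insert (concatenated protospacers)
#' followed by the barcode. Primary barcodes draw deep Poisson read support;
#' injected near-duplicate barcodes draw shallow support (they arise from
#' sequencing errors, so they are rare). Per-base substitution errors are
#' applied at the configured rate to both fields.
#'
#' @param sim_lib a [simulate_library()] result.
#' @param mean_reads mean reads per true insert-barcode pair (default 30).
#' @param near_dup_mean mean reads per injected near-duplicate (default 2).
#' @return data.frame `(insert_seq, barcode_seq)`, one row per read.
#' @export
simulate_linkage_reads <- function(sim_lib, mean_reads = 30, near_dup_mean = 2) {
  stopifnot(inherits(sim_lib, "sim_library"))
  cfg <- sim_lib$config
  set.seed(cfg$seed + 1L)
  bc <- sim_lib$barcodes
  lib <- sim_lib$library
  is_dup <- !is.na(bc$near_dup_of)
  n_reads <- integer(nrow(bc))
  n_reads[!is_dup] <- rpois(sum(!is_dup), mean_reads)
  n_reads[is_dup] <- 1L + rpois(sum(is_dup), max(near_dup_mean - 1, 0))

  insert <- paste0(lib$protospacer_a, lib$protospacer_b)[match(bc$sgrna_id, lib$sgrna_id)]
  reads <- data.frame(
    insert_seq = rep(insert, times = n_reads),
    barcode_seq = rep(bc$barcode, times = n_reads),
    stringsAsFactors = FALSE
  )
  reads$insert_seq <- mutate_dna(reads$insert_seq, cfg$error_rate)
  reads$barcode_seq <- mutate_dna(reads$barcode_seq, cfg$error_rate)
  reads[sample.int(nrow(reads)), , drop = FALSE]
}

# integer index (1-based) -> DNA string of given length
int_to_dna <- function(idx, len) {
  idx0 <- idx - 1
  parts <- vector("list", len)
  for (p in seq_len(len)) {
    parts[[p]] <- DNA_BASES[idx0 %% 4 + 1]
    idx0 <- idx0 %/% 4
  }
  do.call(paste0, parts)
}

# Core read emitter: molecules per (sample, reporter, barcode) are drawn
# multinomially at the configured depth from relative abundance weights;
# each molecule gets a UMI; PCR duplication expands molecules to reads;
# substitution errors are applied per base. Returns one row per read.
emit_screen_reads <- function(weights, config, reporters) {
  dt <- as.data.table(weights)
  space <- 4^config$umi_length
  groups <- split(seq_len(nrow(dt)), list(dt$sample_id, dt$reporter_id), drop = TRUE)
  mols <- vector("list", length(groups))
  truth_mol <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    g <- dt[groups[[gi]]]
    total <- round(config$mean_umis_per_barcode * nrow(g))
    m <- as.vector(rmultinom(1, total, g$weight))
    truth_mol[[gi]] <- data.table(
      sample_id = g$sample_id, reporter_id = g$reporter_id,
      barcode = g$barcode, molecules = m
    )
    keep <- m > 0
    g <- g[keep]; m <- m[keep]
    if (config$unique_umis) {
      if (any(m > space)) stop("UMI space exhausted under unique_umis")
      umi_idx <- unlist(lapply(m, function(k) sample.int(space, k)))
    } else {
      umi_idx <- sample.int(space, sum(m), replace = TRUE)
    }
    mols[[gi]] <- data.table(
      sample_id = rep(g$sample_id, m),
      reporter_id = rep(g$reporter_id, m),
      barcode = rep(g$barcode, m),
      umi = int_to_dna(umi_idx, config$umi_length)
    )
  }
  mol <- rbindlist(mols)
  n_reads <- 1L + rpois(nrow(mol), config$mean_reads_per_molecule - 1)
  reads <- mol[rep(seq_len(nrow(mol)), times = n_reads)]
  reads[, barcode := mutate_dna(barcode, config$error_rate)]
  reads[, umi := mutate_dna(umi, config$error_rate)]
  reads[, seq := paste0(barcode, umi,
                        mutate_dna(unname(reporters[reporter_id]), config$error_rate))]
  out <- as.data.frame(reads[, .(sample_id, seq)])
  attr(out, "molecules") <- as.data.frame(rbindlist(truth_mol))
  out
}

# baseline (pre-selection) abundance per barcode: lognormal representation
# differences from cloning and integration
baseline_abundance <- function(truth, sdlog = 0.5) {
  stats::rlnorm(nrow(truth), meanlog = 0, sdlog = sdlog)
}

#' Simulate a fitness (depletion) screen
#'
#' Cell abundances evolve deterministically as
#' `abundance0 * 2^(fitness * day)`; genomic DNA weights follow abundance,
#' mRNA weights additionally amplify the fitness effect by
#' `mrna_amplification`. Samples are named `gdna_day<d>` / `mrna_day<d>`.
#'
#' @param sim_lib a [simulate_library()] result.
#' @param days timepoints after Cas9 induction (default `c(1, 13)`).
#' @param reporters named reporter whitelist; default one reporter,
#'   `c(globin = "ACGTAC")`.
#' @return list of class `sim_screen`: `reads` (`sample_id, seq`),
#'   `reporters`, and `truth` (linkage truth, gene effects, per-sample
#'   molecule counts, expected uncentered log2 depletion per gene).
#' @export
simulate_fitness_screen <- function(sim_lib, days = c(1, 13),
                                    reporters = c(globin = "ACGTAC")) {
  stopifnot(inherits(sim_lib, "sim_library"))
  cfg <- sim_lib$config
  set.seed(cfg$seed + 2L)
  truth <- sim_lib$linkage_truth
  fitness <- sim_lib$gene_effects$fitness[match(truth$gene, sim_lib$gene_effects$gene)]
  a0 <- baseline_abundance(truth)

  weights <- rbindlist(lapply(days, function(d) {
    rbindlist(list(
      data.table(sample_id = sprintf("gdna_day%d", d),
                 reporter_id = names(reporters)[1L],
                 barcode = truth$barcode,
                 weight = a0 * 2^(fitness * d)),
      data.table(sample_id = sprintf("mrna_day%d", d),
                 reporter_id = names(reporters)[1L],
                 barcode = truth$barcode,
                 weight = a0 * 2^(fitness * d * cfg$mrna_amplification))
    ))
  }))
  reads <- emit_screen_reads(weights, cfg, reporters)
  span <- max(days) - min(days)
  expected <- data.frame(
    gene = sim_lib$gene_effects$gene,
    fitness = sim_lib$gene_effects$fitness,
    expected_log2_depletion_gdna = sim_lib$gene_effects$fitness * span,
    expected_log2_depletion_mrna = sim_lib$gene_effects$fitness * span * cfg$mrna_amplification,
    stringsAsFactors = FALSE
  )
  structure(list(
    reads = reads, reporters = reporters,
    truth = list(linkage = truth, gene_effects = expected,
                 molecules = attr(reads, "molecules"), days = days)
  ), class = "sim_screen")
}

#' Simulate a polysome fractionation screen
#'
#' Each cell's reporter mRNA pool is partitioned across monosome (M), light
#' (L) and heavy (H) polysome fractions. Unaffected genes follow
#' `base_fractions`; `n_affected` genes redistribute to
#' `affected_fractions` (default: a shift from polysomes toward the
#' monosome, i.e. reduced ribosome occupancy). Cas9 has been induced for
#' `days` days, so fitness effects also deplete abundances. Samples are
#' `mono`, `light`, `heavy`.
#'
#' @param sim_lib a [simulate_library()] result.
#' @param base_fractions M/L/H fractions for unaffected genes; must sum
#'   to 1.
#' @param affected_fractions M/L/H fractions for affected genes.
#' @param n_affected number of targeted genes (taken from the end of the
#'   gene list, so they do not overlap the essential set) with redistributed
#'   fractions.
#' @param days days of Cas9 induction feeding fitness depletion (default 7).
#' @param reporters named reporter whitelist.
#' @return a `sim_screen` list; truth includes each gene's fraction vector
#'   and expected uncentered log2 H/M and L/M shifts.
#' @export
simulate_polysome_screen <- function(sim_lib,
                                     base_fractions = c(M = 0.20, L = 0.35, H = 0.45),
                                     affected_fractions = c(M = 0.60, L = 0.25, H = 0.15),
                                     n_affected = 0,
                                     days = 7,
                                     reporters = c(globin = "ACGTAC")) {
  stopifnot(inherits(sim_lib, "sim_library"),
            abs(sum(base_fractions) - 1) < 1e-8,
            abs(sum(affected_fractions) - 1) < 1e-8)
  cfg <- sim_lib$config
  set.seed(cfg$seed + 3L)
  truth <- sim_lib$linkage_truth
  eff <- sim_lib$gene_effects
  targeting <- eff$gene[eff$category == "targeting"]
  affected <- if (n_affected > 0) utils::tail(targeting, n_affected) else character()

  fitness <- eff$fitness[match(truth$gene, eff$gene)]
  a0 <- baseline_abundance(truth) * 2^(fitness * days)
  is_aff <- truth$gene %in% affected
  frac <- function(name) {
    ifelse(is_aff, affected_fractions[[name]], base_fractions[[name]])
  }
  sample_names <- c(M = "mono", L = "light", H = "heavy")
  weights <- rbindlist(lapply(names(sample_names), function(f) {
    data.table(sample_id = sample_names[[f]], reporter_id = names(reporters)[1L],
               barcode = truth$barcode, weight = a0 * frac(f))
  }))
  reads <- emit_screen_reads(weights, cfg, reporters)

  shift <- function(name) {
    log2((affected_fractions[[name]] / affected_fractions[["M"]]) /
         (base_fractions[[name]] / base_fractions[["M"]]))
  }
  gene_truth <- data.frame(
    gene = eff$gene,
    affected = eff$gene %in% affected,
    expected_log2_HM_shift = ifelse(eff$gene %in% affected, shift("H"), 0),
    expected_log2_LM_shift = ifelse(eff$gene %in% affected, shift("L"), 0),
    stringsAsFactors = FALSE
  )
  structure(list(
    reads = reads, reporters = reporters,
    truth = list(linkage = truth, gene_effects = gene_truth,
                 molecules = attr(reads, "molecules"),
                 base_fractions = base_fractions,
                 affected_fractions = affected_fractions)
  ), class = "sim_screen")
}

#' Simulate an isoform-selective amplicon screen
#'
#' The reporter pre-mRNA yields a canonical spliced species plus three
#' aberrant isoforms — intron 1 retained (`i12`), intron 2 retained
#' (`i23`), and exon 2 skipped (`e13`) — each amplified selectively into its
#' own sample alongside a `total` sample. Unaffected genes follow
#' `base_isoforms`; `n_affected` genes follow `affected_isoforms`.
#'
#' @param sim_lib a [simulate_library()] result.
#' @param base_isoforms,affected_isoforms fractions over
#'   `c(canonical, i12, i23, e13)`, summing to 1.
#' @param n_affected genes (from the end of the targeting list) with shifted
#'   isoform usage.
#' @param days days of Cas9 induction (default 7).
#' @param reporters named reporter whitelist.
#' @return a `sim_screen`; truth records each gene's isoform fractions and
#'   expected uncentered log2 isoform/total shifts.
#' @export
simulate_isoform_screen <- function(sim_lib,
                                    base_isoforms = c(canonical = 0.97, i12 = 0.01,
                                                      i23 = 0.01, e13 = 0.01),
                                    affected_isoforms = c(canonical = 0.77, i12 = 0.21,
                                                          i23 = 0.01, e13 = 0.01),
                                    n_affected = 0,
                                    days = 7,
                                    reporters = c(globin = "ACGTAC")) {
  stopifnot(inherits(sim_lib, "sim_library"),
            abs(sum(base_isoforms) - 1) < 1e-8,
            abs(sum(affected_isoforms) - 1) < 1e-8)
  cfg <- sim_lib$config
  set.seed(cfg$seed + 4L)
  truth <- sim_lib$linkage_truth
  eff <- sim_lib$gene_effects
  targeting <- eff$gene[eff$category == "targeting"]
  affected <- if (n_affected > 0) utils::tail(targeting, n_affected) else character()

  fitness <- eff$fitness[match(truth$gene, eff$gene)]
  a0 <- baseline_abundance(truth) * 2^(fitness * days)
  is_aff <- truth$gene %in% affected
  iso_frac <- function(name) {
    ifelse(is_aff, affected_isoforms[[name]], base_isoforms[[name]])
  }
  weights <- rbindlist(c(
    list(data.table(sample_id = "total", reporter_id = names(reporters)[1L],
                    barcode = truth$barcode, weight = a0)),
    lapply(c("i12", "i23", "e13"), function(iso) {
      data.table(sample_id = iso, reporter_id = names(reporters)[1L],
                 barcode = truth$barcode, weight = a0 * iso_frac(iso))
    })
  ))
  reads <- emit_screen_reads(weights, cfg, reporters)
  shift <- function(name) log2(affected_isoforms[[name]] / base_isoforms[[name]])
  gene_truth <- data.frame(
    gene = eff$gene,
    affected = eff$gene %in% affected,
    expected_log2_i12_shift = ifelse(eff$gene %in% affected, shift("i12"), 0),
    expected_log2_i23_shift = ifelse(eff$gene %in% affected, shift("i23"), 0),
    expected_log2_e13_shift = ifelse(eff$gene %in% affected, shift("e13"), 0),
    stringsAsFactors = FALSE
  )
  structure(list(
    reads = reads, reporters = reporters,
    truth = list(linkage = truth, gene_effects = gene_truth,
                 molecules = attr(reads, "molecules"))
  ), class = "sim_screen")
}

#' Simulate a dual-barcode reporter-level screen
#'
#' Each integrant carries the same barcode in a reporter of interest (e.g. a
#' premature-termination-codon reporter degraded by NMD) and in a control
#' reporter. Knockouts that stabilize the reporter multiply its mRNA level
#' by `stabilization` without touching the control, so the
#' reporter/control ratio isolates reporter regulation from cell abundance.
#'
#' @param sim_lib a [simulate_library()] result.
#' @param stabilization fold-stabilization of the reporter in affected
#'   genes (default 4).
#' @param n_affected genes (from the end of the targeting list) whose
#'   knockout stabilizes the reporter.
#' @param days days of Cas9 induction (default 7).
#' @param reporters length-2 named whitelist: reporter of interest first,
#'   control second.
#' @return a `sim_screen` with one sample `pool`; truth records the
#'   expected uncentered log2 reporter/control shift per gene.
#' @export
simulate_dual_barcode_screen <- function(sim_lib, stabilization = 4,
                                         n_affected = 0, days = 7,
                                         reporters = c(ptc = "ACGTAC",
                                                       mcherry = "TTGGCC")) {
  stopifnot(inherits(sim_lib, "sim_library"), length(reporters) == 2L)
  cfg <- sim_lib$config
  set.seed(cfg$seed + 5L)
  truth <- sim_lib$linkage_truth
  eff <- sim_lib$gene_effects
  targeting <- eff$gene[eff$category == "targeting"]
  affected <- if (n_affected > 0) utils::tail(targeting, n_affected) else character()

  fitness <- eff$fitness[match(truth$gene, eff$gene)]
  a0 <- baseline_abundance(truth) * 2^(fitness * days)
  stab <- ifelse(truth$gene %in% affected, stabilization, 1)
  weights <- rbindlist(list(
    data.table(sample_id = "pool", reporter_id = names(reporters)[1L],
               barcode = truth$barcode, weight = a0 * stab),
    data.table(sample_id = "pool", reporter_id = names(reporters)[2L],
               barcode = truth$barcode, weight = a0)
  ))
  reads <- emit_screen_reads(weights, cfg, reporters)
  gene_truth <- data.frame(
    gene = eff$gene,
    affected = eff$gene %in% affected,
    expected_log2_shift = ifelse(eff$gene %in% affected, log2(stabilization), 0),
    stringsAsFactors = FALSE
  )
  structure(list(
    reads = reads, reporters = reporters,
    truth = list(linkage = truth, gene_effects = gene_truth,
                 molecules = attr(reads, "molecules"))
  ), class = "sim_screen")
}

#' Simulate junction and intron-read tables for the splicing metrics
#'
#' Builds a toy annotation on one synthetic chromosome: `n_cassette`
#' three-exon genes with an annotated exon-skipping isoform, and
#' `n_retention` two-exon genes with a retainable intron. Junction reads are
#' drawn per molecule: an included molecule contributes a read to one of its
#' two flanking junctions with equal probability, a skipped molecule to the
#' skip junction, so percent spliced out estimates the molecular skip
#' fraction. Retention genes draw junction reads from spliced molecules and
#' intron-overlapping reads from retained molecules at rates such that the
#' length-normalized percent spliced in estimates the retention fraction.
#'
#' @param n_cassette,n_retention gene counts per event type.
#' @param skip_fraction per-gene molecular skip fractions (recycled).
#' @param retention per-gene intron retention fractions (recycled).
#' @param depth molecules per cassette gene (junction reads total).
#' @param coverage read-start rate per nt for retention genes.
#' @param read_length nominal read length (default 50).
#' @param intron_length intron length of retention genes (default 450).
#' @param seed RNG seed.
#' @return list: `exons` (annotation table), `junction_counts`,
#'   `intron_reads` (alignment intervals), `raw_intron_counts`
#'   (full-window Poisson counts per retention intron), `truth`,
#'   `read_length`.
#' @export
simulate_junction_data <- function(n_cassette = 10, n_retention = 10,
                                   skip_fraction = 0.1, retention = 0.2,
                                   depth = 2000, coverage = 4,
                                   read_length = 50, intron_length = 450,
                                   seed) {
  if (missing(seed)) stop("simulate_junction_data requires a seed")
  set.seed(seed)
  skip_fraction <- rep_len(skip_fraction, n_cassette)
  retention <- rep_len(retention, n_retention)
  chrom <- "chrS"
  gene_span <- 10000L

  exons <- list(); jc <- list(); intron_reads <- list()
  raw_counts <- list(); truth <- list()

  for (g in seq_len(n_cassette)) {
    off <- (g - 1L) * gene_span
    e1 <- c(off + 1L, off + 200L)
    e2 <- c(off + 651L, off + 750L)
    e3 <- c(off + 1201L, off + 1400L)
    gid <- sprintf("cass%03d", g)
    exons[[length(exons) + 1L]] <- data.frame(
      transcript_id = c(rep(paste0(gid, "_incl"), 3), rep(paste0(gid, "_skip"), 2)),
      chrom = chrom,
      start = c(e1[1], e2[1], e3[1], e1[1], e3[1]),
      end = c(e1[2], e2[2], e3[2], e1[2], e3[2]),
      strand = "+", stringsAsFactors = FALSE
    )
    f <- skip_fraction[g]
    n <- as.vector(rmultinom(1, depth, c(f, (1 - f) / 2, (1 - f) / 2)))
    jc[[length(jc) + 1L]] <- data.frame(
      chrom = chrom,
      intron_start = c(e1[2] + 1L, e1[2] + 1L, e2[2] + 1L),
      intron_end = c(e3[1] - 1L, e2[1] - 1L, e3[1] - 1L),
      unique_reads = c(n[1], n[2], n[3])
    )
    truth[[length(truth) + 1L]] <- data.frame(
      gene = gid, type = "cassette", skip_fraction = f, retention = NA_real_,
      chrom = chrom, intron_start = e1[2] + 1L, intron_end = e3[1] - 1L,
      stringsAsFactors = FALSE
    )
  }

  for (g in seq_len(n_retention)) {
    off <- (n_cassette + g - 1L) * gene_span
    e1 <- c(off + 1L, off + 200L)
    i1 <- c(e1[2] + 1L, e1[2] + intron_length)
    e2 <- c(i1[2] + 1L, i1[2] + 200L)
    gid <- sprintf("ret%03d", g)
    exons[[length(exons) + 1L]] <- data.frame(
      transcript_id = paste0(gid, "_spliced"), chrom = chrom,
      start = c(e1[1], e2[1]), end = c(e1[2], e2[2]),
      strand = "+", stringsAsFactors = FALSE
    )
    rho <- retention[g]
    jn <- rpois(1, coverage * read_length * (1 - rho))
    raw <- rpois(1, coverage * (intron_length + read_length) * rho)
    jc[[length(jc) + 1L]] <- data.frame(
      chrom = chrom, intron_start = i1[1], intron_end = i1[2], unique_reads = jn
    )
    starts <- i1[1] - read_length + 1L +
      floor(runif(raw) * (intron_length + read_length))
    intron_reads[[length(intron_reads) + 1L]] <- data.frame(
      chrom = chrom, start = starts, end = starts + read_length - 1L
    )
    raw_counts[[length(raw_counts) + 1L]] <- data.frame(
      gene = gid, chrom = chrom, intron_start = i1[1], intron_end = i1[2],
      raw_intron_reads = raw, junction_reads = jn, stringsAsFactors = FALSE
    )
    truth[[length(truth) + 1L]] <- data.frame(
      gene = gid, type = "retention", skip_fraction = NA_real_, retention = rho,
      chrom = chrom, intron_start = i1[1], intron_end = i1[2],
      stringsAsFactors = FALSE
    )
  }

  list(
    exons = do.call(rbind, exons),
    junction_counts = do.call(rbind, jc),
    intron_reads = if (length(intron_reads)) do.call(rbind, intron_reads) else
      data.frame(chrom = character(), start = integer(), end = integer()),
    raw_intron_counts = if (length(raw_counts)) do.call(rbind, raw_counts) else NULL,
    truth = do.call(rbind, truth),
    read_length = read_length
  )
}

#' Simulate transcript-space ribosome-profiling alignments
#'
#' Footprints of length 27-33 nt whose P-sites mix a point mass at the start
#' codon (initiation peak) with a uniform elongation distribution over the
#' CDS; a configurable fraction of junk reads outside the accepted length
#' range exercises the length filter.
#'
#' @param n_transcripts transcripts, each with a 100-nt 5' UTR and a CDS of
#'   `cds_length` nt.
#' @param reads_per_transcript footprints per transcript.
#' @param start_fraction fraction of footprints initiating (P-site exactly
#'   at the start codon).
#' @param cds_length CDS length in nt.
#' @param junk_fraction fraction of extra reads with out-of-range lengths.
#' @param seed RNG seed.
#' @return list: `alignments` (`transcript_id, five_prime_pos,
#'   read_length`), `start_codons` (named vector), `truth`.
#' @export
simulate_ribo_data <- function(n_transcripts = 20, reads_per_transcript = 200,
                               start_fraction = 0.3, cds_length = 600,
                               junk_fraction = 0.05, seed) {
  if (missing(seed)) stop("simulate_ribo_data requires a seed")
  set.seed(seed)
  utr5 <- 100L
  tx <- sprintf("TX%03d", seq_len(n_transcripts))
  start_codons <- setNames(rep(utr5, n_transcripts), tx)

  n_total <- n_transcripts * reads_per_transcript
  tx_id <- rep(tx, each = reads_per_transcript)
  at_start <- runif(n_total) < start_fraction
  psite <- ifelse(at_start, utr5,
                  utr5 + 3L * floor(runif(n_total) * (cds_length / 3)))
  len <- sample(27:33, n_total, replace = TRUE)
  aln <- data.frame(
    transcript_id = tx_id,
    five_prime_pos = as.integer(psite - 13L),
    read_length = len,
    stringsAsFactors = FALSE
  )
  n_junk <- round(junk_fraction * n_total)
  if (n_junk > 0) {
    junk <- data.frame(
      transcript_id = sample(tx, n_junk, replace = TRUE),
      five_prime_pos = as.integer(utr5 + floor(runif(n_junk) * cds_length) - 13L),
      read_length = sample(c(21:26, 34:40), n_junk, replace = TRUE),
      stringsAsFactors = FALSE
    )
    aln <- rbind(aln, junk)
  }
  aln <- aln[sample.int(nrow(aln)), , drop = FALSE]
  rownames(aln) <- NULL
  list(
    alignments = aln,
    start_codons = start_codons,
    truth = list(start_fraction = start_fraction, utr5 = utr5,
                 cds_length = cds_length, n_in_range = n_total)
  )
}

#' Write screen reads as FASTQ
#'
#' One record per read, sequence `barcode + UMI + reporter identifier`,
#' constant quality `I` (qualities are unused downstream).
#'
#' @param reads data.frame `(sample_id, seq)` (a `sim_screen$reads`).
#' @param dir output directory; one `<sample_id>.fastq` per sample.
#' @return invisibly, the written paths.
#' @export
write_screen_fastq <- function(reads, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()
  for (s in unique(reads$sample_id)) {
    seqs <- reads$seq[reads$sample_id == s]
    path <- file.path(dir, paste0(s, ".fastq"))
    qual <- strrep("I", nchar(seqs))
    writeLines(paste0("@", s, ":", seq_along(seqs), "\n", seqs, "\n+\n", qual), path)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Read screen FASTQ files back into a read table
#'
#' @param paths FASTQ paths; the sample id is the file name without
#'   extension.
#' @return data.frame `(sample_id, seq)`.
#' @export
read_screen_fastq <- function(paths) {
  out <- lapply(paths, function(p) {
    lines <- readLines(p)
    data.frame(
      sample_id = sub("\\.fastq$", "", basename(p)),
      seq = lines[seq(2L, length(lines), by = 4L)],
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
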