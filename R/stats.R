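#' Define a screen contrast
#'
#' A contrast names the two count sets whose per-barcode ratio is the screen
#' readout: genomic DNA or mRNA at two timepoints (fitness), heavy or light
#' polysomes over monosomes (ribosome occupancy), an isoform-selective
#' amplicon over the total reporter (splicing), or treatment over control
#' (modifier screens). The optional reporter fields restrict each side to one
#' reporter's counts.
#'
#' @param name label for outputs.
#' @param numerator_sample,denominator_sample sample ids in the count table.
#' @param numerator_reporter,denominator_reporter optional reporter ids; NULL
#'   sums across reporters within the sample.
#' @param modality free-form tag (e.g. `"fitness_rna"`, `"polysome_HM"`,
#'   `"isoform_i12"`, `"dual_barcode"`, `"modifier"`).
#' @return a `screen_contrast` list.
#' @export
contrast <- function(name, numerator_sample, denominator_sample,
                     numerator_reporter = NULL, denominator_reporter = NULL,
                     modality = "fitness_rna") {
  structure(list(
    name = name,
    numerator_sample = numerator_sample,
    denominator_sample = denominator_sample,
    numerator_reporter = numerator_reporter,
    denominator_reporter = denominator_reporter,
    modality = modality
  ), class = "screen_contrast")
}

#' Floor a pair of count vectors at the detection threshold
#'
#' Units detected (at or above the floor) in at least one sample of a
#' contrast are kept; a count below the floor in either sample is replaced by
#' the floor, so weakly sampled denominators cannot produce explosive ratios.
#' Units below the floor in both samples are undetected and excluded.
#'
#' @param num,den equal-length non-negative count vectors (absent = 0).
#' @param floor detection floor (default 20).
#' @return list with floored `num`, `den` and logical `kept` marking which
#'   input positions survive.
#' @export
floor_counts <- function(num, den, floor = 20) {
  stopifnot(length(num) == length(den))
  kept <- num >= floor | den >= floor
  list(num = pmax(num[kept], floor), den = pmax(den[kept], floor), kept = kept)
}

#' Per-barcode median-centered log2 ratios for a contrast
#'
#' For every barcode detected in the contrast, computes
#' `log2(numerator / denominator)` after flooring ([floor_counts()]) and
#' library-size scaling (each side divided by its total over the analysis
#' set), then subtracts the library-wide median so the typical perturbation
#' is defined as no effect. Median-centering makes the result invariant to
#' any global scale factor between the two samples.
#'
#' @param counts a `umi_count_table`.
#' @param contrast a [contrast()].
#' @param floor detection floor passed to [floor_counts()].
#' @return data.frame of class `centered_ratio_table` with columns
#'   `unit_id` (barcode), `sgrna_id`, `gene`, `log2_ratio`, and attribute
#'   `contrast`.
#' @export
log2_ratio_centered <- function(counts, contrast, floor = 20) {
  stopifnot(inherits(contrast, "screen_contrast"))
  num <- side_counts(counts, contrast$numerator_sample, contrast$numerator_reporter)
  den <- side_counts(counts, contrast$denominator_sample, contrast$denominator_reporter)
  if (nrow(num) == 0L || nrow(den) == 0L) {
    stop("contrast '", contrast$name, "': no counts for one side")
  }
  merged <- merge(num, den, by = c("barcode", "sgrna_id", "gene"),
                  all = TRUE, suffixes = c("_num", "_den"))
  merged$umi_count_num[is.na(merged$umi_count_num)] <- 0
  merged$umi_count_den[is.na(merged$umi_count_den)] <- 0

  fl <- floor_counts(merged$umi_count_num, merged$umi_count_den, floor)
  if (!any(fl$kept)) stop("contrast '", contrast$name, "': no unit detected in either sample")
  merged <- merged[fl$kept, , drop = FALSE]

  scaled_num <- fl$num / sum(fl$num)
  scaled_den <- fl$den / sum(fl$den)
  lr <- log2(scaled_num / scaled_den)
  out <- data.frame(
    unit_id = merged$barcode,
    sgrna_id = merged$sgrna_id,
    gene = merged$gene,
    log2_ratio = lr - median(lr),
    stringsAsFactors = FALSE
  )
  class(out) <- unique(c("centered_ratio_table", class(out)))
  attr(out, "contrast") <- contrast
  out
}

# One side of a contrast: per-barcode UMI counts for a sample, optionally a
# single reporter; multiple reporters sum.
side_counts <- function(counts, sample, reporter = NULL) {
  dt <- as.data.table(as.data.frame(counts))[sample_id == sample]
  if (!is.null(reporter)) dt <- dt[reporter_id == reporter]
  out <- dt[, .(umi_count = sum(umi_count)), by = .(barcode, sgrna_id, gene)]
  as.data.frame(out)
}

#' Median-center pre-computed per-unit log2 values
#'
#' Used for readouts that arrive as a ratio already (e.g. dual-barcode
#' reporter/control ratios within one sample).
#'
#' @param values data.frame with columns `unit_id, sgrna_id, gene, log2_ratio`.
#' @return a `centered_ratio_table` with the library median subtracted.
#' @export
center_log2_values <- function(values) {
  values <- as.data.frame(values)
  values$log2_ratio <- values$log2_ratio - median(values$log2_ratio)
  class(values) <- unique(c("centered_ratio_table", class(values)))
  values
}

#' Aggregate per-unit ratios by median
#'
#' Barcode-level values aggregate to sgRNAs, and sgRNA-level values to genes,
#' by the median across detected members.
#'
#' @param ratios a `centered_ratio_table` (or sgRNA-level data.frame).
#' @param level `"barcode_to_sgrna"` or `"sgrna_to_gene"`.
#' @return data.frame with `unit_id` (sgRNA or gene), `gene`, `log2_ratio`
#'   (member median) and `n_units` (member count).
#' @export
aggregate_gene <- function(ratios, level = c("barcode_to_sgrna", "sgrna_to_gene")) {
  level <- match.arg(level)
  dt <- as.data.table(as.data.frame(ratios))
  if (level == "barcode_to_sgrna") {
    out <- dt[, .(log2_ratio = median(log2_ratio), n_units = .N),
              by = .(unit_id = sgrna_id, gene)]
  } else {
    out <- dt[, .(log2_ratio = median(log2_ratio), n_units = .N),
              by = .(unit_id = gene, gene)]
  }
  out <- as.data.frame(out)
  class(out) <- unique(c("centered_ratio_table", class(out)))
  out
}

#' Robust rank aggregation score for one gene's sgRNA ranks
#'
#' Given a gene's sgRNA ranks normalized to (0, 1] among all sgRNAs in the
#' screen, the score is the smallest beta quantile probability
#' `pbeta(r_(i), i, k - i + 1)` over the gene's "good" sgRNAs — those inside
#' the top `alpha_frac` tail. Small scores mean the gene's sgRNAs sit
#' improbably high in the ranking. Genes with no sgRNA in the tail score 1.
#'
#' @param ranks normalized ranks in (0, 1] for one gene's sgRNAs.
#' @param alpha_frac fraction of the ranking treated as the "good" tail.
#' @return the rho score in (0, 1].
#' @export
rra_rho <- function(ranks, alpha_frac = 0.25) {
  r <- sort(ranks)
  k <- length(r)
  good <- which(r <= alpha_frac)
  if (length(good) == 0L) return(1)
  min(pbeta(r[good], good, k - good + 1))
}

# Vectorized rho over a matrix of rank sets (rows = permutations).
rra_rho_matrix <- function(m, alpha_frac) {
  k <- ncol(m)
  ms <- matrix(m[order(row(m), m)], nrow = nrow(m), ncol = k, byrow = TRUE)
  i <- matrix(rep(seq_len(k), each = nrow(m)), nrow = nrow(m))
  pb <- pbeta(ms, i, k - i + 1)
  pb[ms > alpha_frac] <- Inf
  rho <- do.call(pmin, as.data.frame(pb))
  rho[is.infinite(rho)] <- 1
  rho
}

#' Gene-level hit test by permutation-calibrated robust rank aggregation
#'
#' Ranks all sgRNAs by their centered log2 ratio (ascending for depletion,
#' descending for enrichment), scores each gene by [rra_rho()] over its
#' sgRNAs' normalized ranks, and calibrates the score against a null built by
#' permuting gene labels over the observed ranks (`n_perm` draws per gene
#' size). Benjamini-Hochberg FDR is computed per direction; each gene reports
#' the direction with the smaller permutation p-value. `n_good_sgrnas` counts
#' the gene's sgRNAs inside the directional `alpha_frac` tail; hits
#' additionally require at least `min_good` of them (see [call_hits()]).
#'
#' @param ratios a `centered_ratio_table`. Barcode-level tables (with
#'   `sgrna_id` distinct from `unit_id`) are first aggregated to sgRNAs by
#'   median when `aggregate = "sgrna"`; pass `aggregate = "none"` to rank the
#'   units as-is.
#' @param n_perm permutation draws per gene size (>= 1000 recommended).
#' @param alpha_frac tail fraction defining "good" sgRNAs (default 0.25).
#' @param seed RNG seed for the permutation null; required for reproducible
#'   p-values.
#' @param fdr_threshold,min_good hit criteria, see [call_hits()].
#' @param aggregate `"sgrna"` (default) or `"none"`.
#' @return data.frame of class `gene_result` with columns `gene, n_sgrnas,
#'   median_lfc, p_neg, p_pos, fdr_neg, fdr_pos, direction, p, fdr,
#'   n_good_sgrnas, is_hit`.
#' @export
rra_gene_test <- function(ratios, n_perm = 1000, alpha_frac = 0.25, seed = NULL,
                          fdr_threshold = 0.05, min_good = 3,
                          aggregate = c("sgrna", "none")) {
  aggregate <- match.arg(aggregate)
  stopifnot(n_perm >= 1)
  if (!is.null(seed)) set.seed(seed)

  units <- as.data.frame(ratios)
  if (aggregate == "sgrna" && !identical(units$unit_id, units$sgrna_id) &&
      "sgrna_id" %in% names(units)) {
    units <- aggregate_gene(units, "barcode_to_sgrna")
  }
  units <- units[!is.na(units$gene), , drop = FALSE]
  n <- nrow(units)
  if (n == 0L) stop("no units with a gene label")

  r_neg <- rank(units$log2_ratio, ties.method = "average") / n
  r_pos <- rank(-units$log2_ratio, ties.method = "average") / n

  genes <- split(seq_len(n), units$gene)
  sizes <- lengths(genes)

  rho_obs <- function(rnorm) {
    vapply(genes, function(ix) rra_rho(rnorm[ix], alpha_frac), numeric(1))
  }
  rho_neg <- rho_obs(r_neg)
  rho_pos <- rho_obs(r_pos)

  # Null per gene size: permute gene labels = draw k ranks without
  # replacement from the pooled normalized ranks. The pooled rank grid is
  # identical for both directions, so one null serves both.
  pool <- r_neg
  null_by_k <- lapply(sort(unique(sizes)), function(k) {
    m <- matrix(0, nrow = n_perm, ncol = k)
    for (b in seq_len(n_perm)) m[b, ] <- pool[sample.int(n, k)]
    sort(rra_rho_matrix(m, alpha_frac))
  })
  names(null_by_k) <- as.character(sort(unique(sizes)))

  perm_p <- function(rho, k) {
    null <- null_by_k[[as.character(k)]]
    (1 + findInterval(rho + 1e-12, null)) / (n_perm + 1)
  }
  p_neg <- mapply(perm_p, rho_neg, sizes)
  p_pos <- mapply(perm_p, rho_pos, sizes)

  dt <- as.data.table(units)
  gstat <- dt[, .(median_lfc = median(log2_ratio), n_sgrnas = .N), by = gene]
  data.table::setkeyv(gstat, "gene")
  gstat <- gstat[names(genes)]

  n_good_neg <- vapply(genes, function(ix) sum(r_neg[ix] <= alpha_frac), integer(1))
  n_good_pos <- vapply(genes, function(ix) sum(r_pos[ix] <= alpha_frac), integer(1))

  fdr_neg <- p.adjust(p_neg, "BH")
  fdr_pos <- p.adjust(p_pos, "BH")
  down <- p_neg <= p_pos

  res <- data.frame(
    gene = names(genes),
    n_sgrnas = as.integer(gstat$n_sgrnas),
    median_lfc = gstat$median_lfc,
    p_neg = p_neg,
    p_pos = p_pos,
    fdr_neg = fdr_neg,
    fdr_pos = fdr_pos,
    direction = ifelse(down, "down", "up"),
    p = ifelse(down, p_neg, p_pos),
    fdr = ifelse(down, fdr_neg, fdr_pos),
    n_good_sgrnas = as.integer(ifelse(down, n_good_neg, n_good_pos)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  res <- call_hits(res, fdr_threshold = fdr_threshold, min_good = min_good)
  class(res) <- unique(c("gene_result", class(res)))
  res
}

#' Flag gene-level hits
#'
#' A gene is a hit when its FDR is strictly below the threshold and at least
#' `min_good` of its sgRNAs show consistent effects in the reported
#' direction (membership in the directional rank tail).
#'
#' @param results a `gene_result` data.frame (needs `fdr` and
#'   `n_good_sgrnas`).
#' @param fdr_threshold strict upper bound on FDR (default 0.05).
#' @param min_good minimum consistent sgRNAs (default 3).
#' @return `results` with `is_hit` recomputed.
#' @export
call_hits <- function(results, fdr_threshold = 0.05, min_good = 3) {
  results$is_hit <- results$fdr < fdr_threshold & results$n_good_sgrnas >= min_good
  results
}

#' Dual-barcode normalization: reporter counts over co-integrated control
#'
#' In dual-barcode designs each integrant carries the same 20-nt barcode in
#' both the reporter of interest and a control reporter. Dividing the
#' reporter's UMI count by the control's within the same sample cancels
#' cell-abundance and integration effects, isolating reporter mRNA level.
#' Barcodes whose control count is below the floor are excluded; reporter
#' counts below the floor are raised to it.
#'
#' @param counts a `umi_count_table`.
#' @param sample sample id to normalize within.
#' @param reporter_id,control_id reporter identifiers of the reporter of
#'   interest and the control.
#' @param floor detection floor (default 20).
#' @return data.frame `(unit_id, sgrna_id, gene, reporter_count,
#'   control_count, ratio)` per barcode.
#' @export
dual_barcode_normalize <- function(counts, sample, reporter_id, control_id,
                                   floor = 20) {
  rep_side <- side_counts(counts, sample, reporter_id)
  ctl_side <- side_counts(counts, sample, control_id)
  merged <- merge(rep_side, ctl_side, by = c("barcode", "sgrna_id", "gene"),
                  suffixes = c("_rep", "_ctl"))
  merged <- merged[merged$umi_count_ctl >= floor, , drop = FALSE]
  if (nrow(merged) == 0L) stop("no barcode with control counts above the floor")
  rep_n <- pmax(merged$umi_count_rep, floor)
  data.frame(
    unit_id = merged$barcode,
    sgrna_id = merged$sgrna_id,
    gene = merged$gene,
    reporter_count = rep_n,
    control_count = merged$umi_count_ctl,
    ratio = rep_n / merged$umi_count_ctl,
    stringsAsFactors = FALSE
  )
}

#' Centered log2 reporter levels from a dual-barcode sample
#'
#' Convenience wrapper: [dual_barcode_normalize()] followed by log2 and
#' median-centering across the library ([center_log2_values()]).
#'
#' @inheritParams dual_barcode_normalize
#' @return a `centered_ratio_table` at barcode level.
#' @export
dual_barcode_stats <- function(counts, sample, reporter_id, control_id,
                               floor = 20) {
  norm <- dual_barcode_normalize(counts, sample, reporter_id, control_id, floor)
  center_log2_values(data.frame(
    unit_id = norm$unit_id,
    sgrna_id = norm$sgrna_id,
    gene = norm$gene,
    log2_ratio = log2(norm$ratio),
    stringsAsFactors = FALSE
  ))
}

#' Write gene results as CSV
#' @param x a `gene_result` data.frame.
#' @param path output CSV path.
#' @export
write_gene_results <- function(x, path) {
  data.table::fwrite(as.data.frame(x), path)
  invisible(path)
}
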