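# Independent brute-force oracles and fixture builders. Everything here is
# deliberately written with plain loops and its own arithmetic so it shares
# no code path with the package implementation.

# Levenshtein distance between one string and many, by textbook DP
# (vectorized across the many strings, looped over positions).
dp_edit_dist <- function(a, bs) {
  la <- nchar(a)
  lb <- nchar(bs[1L])
  A <- strsplit(a, "")[[1L]]
  B <- do.call(rbind, strsplit(bs, ""))
  n <- length(bs)
  prev <- matrix(rep(0:lb, each = n), nrow = n)
  for (i in seq_len(la)) {
    cur <- matrix(0L, n, lb + 1L)
    cur[, 1L] <- i
    for (j in seq_len(lb)) {
      cost <- as.integer(B[, j] != A[i])
      cur[, j + 1L] <- pmin(prev[, j + 1L] + 1L, cur[, j] + 1L, prev[, j] + cost)
    }
    prev <- cur
  }
  prev[, lb + 1L]
}

# Exhaustive application of the two linkage filtering rules.
oracle_cluster_barcodes <- function(df, threshold) {
  links <- unique(df[, c("barcode", "sgrna_id")])
  tab <- table(links$barcode)
  ambig <- names(tab[tab > 1L])
  df <- df[!df$barcode %in% ambig, , drop = FALSE]
  out <- list()
  for (sg in unique(df$sgrna_id)) {
    sub <- df[df$sgrna_id == sg, , drop = FALSE]
    sub <- sub[order(-sub$read_count, sub$barcode), , drop = FALSE]
    kept <- integer()
    for (i in seq_len(nrow(sub))) {
      if (length(kept) == 0L) {
        kept <- i
      } else if (all(dp_edit_dist(sub$barcode[i], sub$barcode[kept]) > threshold)) {
        kept <- c(kept, i)
      }
    }
    out[[sg]] <- sub[kept, , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Full linkage oracle: exact insert matching, manual aggregation, both
# filtering rules, min-read threshold.
oracle_linkage <- function(reads, library, min_reads, threshold) {
  key <- paste0(library$protospacer_a, library$protospacer_b)
  sg <- library$sgrna_id[match(reads$insert_seq, key)]
  ok <- !is.na(sg) & grepl("^[ACGT]{20}$", reads$barcode_seq)
  agg <- aggregate(
    list(read_count = rep(1L, sum(ok))),
    by = list(barcode = reads$barcode_seq[ok], sgrna_id = sg[ok]),
    FUN = sum
  )
  res <- oracle_cluster_barcodes(agg, threshold)
  res <- res[res$read_count >= min_reads, , drop = FALSE]
  rownames(res) <- NULL
  res
}

# A random linkage problem with injected ambiguous barcodes and 1-edit
# duplicates, returned both as a read table and as the designed library.
random_linkage_instance <- function(seed, n_barcodes = 200, n_sgrnas = 30,
                                    n_collisions = 5, n_near_dups = 12) {
  set.seed(seed)
  mk_dna <- function(n, w) {
    out <- unique(vapply(seq_len(2L * n), function(i) {
      paste(sample(c("A", "C", "G", "T"), w, replace = TRUE), collapse = "")
    }, character(1)))
    out[seq_len(n)]
  }
  lib <- data.frame(
    sgrna_id = sprintf("sg%03d", seq_len(n_sgrnas)),
    gene = sprintf("G%03d", rep(seq_len(ceiling(n_sgrnas / 4)), each = 4)[seq_len(n_sgrnas)]),
    protospacer_a = mk_dna(n_sgrnas, 20),
    protospacer_b = mk_dna(n_sgrnas, 20),
    category = "targeting",
    stringsAsFactors = FALSE
  )
  df <- data.frame(
    barcode = mk_dna(n_barcodes, 20),
    sgrna_id = sample(lib$sgrna_id, n_barcodes, replace = TRUE),
    read_count = sample(1:30, n_barcodes, replace = TRUE),
    stringsAsFactors = FALSE
  )
  if (n_collisions > 0) {
    victims <- sample.int(n_barcodes, n_collisions)
    extra <- data.frame(
      barcode = df$barcode[victims],
      sgrna_id = vapply(victims, function(i) {
        sample(setdiff(lib$sgrna_id, df$sgrna_id[i]), 1)
      }, character(1)),
      read_count = sample(1:30, n_collisions, replace = TRUE),
      stringsAsFactors = FALSE
    )
    df <- rbind(df, extra)
  }
  if (n_near_dups > 0) {
    parents <- sample.int(n_barcodes, n_near_dups)
    dup <- df[parents, , drop = FALSE]
    dup$barcode <- vapply(dup$barcode, function(b) {
      p <- sample.int(20, 1)
      substr(b, p, p) <- sample(setdiff(c("A", "C", "G", "T"), substr(b, p, p)), 1)
      b
    }, character(1))
    dup$read_count <- sample(1:30, n_near_dups, replace = TRUE)
    df <- rbind(df, dup)
    df <- df[!duplicated(df[, c("barcode", "sgrna_id")]), , drop = FALSE]
  }
  insert <- paste0(lib$protospacer_a, lib$protospacer_b)[match(df$sgrna_id, lib$sgrna_id)]
  reads <- data.frame(
    insert_seq = rep(insert, times = df$read_count),
    barcode_seq = rep(df$barcode, times = df$read_count),
    stringsAsFactors = FALSE
  )
  reads <- reads[sample.int(nrow(reads)), , drop = FALSE]
  list(reads = reads, library = lib, agg = df)
}

# Per-transcript enumeration of spliced-out introns.
oracle_junctions <- function(exons) {
  out <- list()
  for (tx in unique(exons$transcript_id)) {
    e <- exons[exons$transcript_id == tx, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    if (nrow(e) < 2L) next
    for (i in seq_len(nrow(e) - 1L)) {
      out[[length(out) + 1L]] <- data.frame(
        chrom = e$chrom[i], intron_start = e$end[i] + 1L,
        intron_end = e$start[i + 1L] - 1L, strand = e$strand[i],
        stringsAsFactors = FALSE
      )
    }
  }
  res <- unique(do.call(rbind, out))
  res <- res[order(res$chrom, res$intron_start, res$intron_end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Triple-loop cassette-exon enumeration: for every junction, count exons
# strictly inside and proper sub-introns, then apply the shared-end rule.
oracle_cassette <- function(junctions, exons) {
  ex <- unique(exons[, c("chrom", "start", "end", "strand")])
  out <- list()
  for (j in seq_len(nrow(junctions))) {
    J <- junctions[j, ]
    ex_in <- integer()
    for (i in seq_len(nrow(ex))) {
      if (ex$chrom[i] == J$chrom && ex$strand[i] == J$strand &&
          ex$start[i] > J$intron_start && ex$end[i] < J$intron_end) {
        ex_in <- c(ex_in, i)
      }
    }
    if (length(ex_in) != 1L) next
    in_introns <- integer()
    for (k in seq_len(nrow(junctions))) {
      K <- junctions[k, ]
      if (k != j && K$chrom == J$chrom && K$strand == J$strand &&
          K$intron_start >= J$intron_start && K$intron_end <= J$intron_end &&
          !(K$intron_start == J$intron_start && K$intron_end == J$intron_end)) {
        in_introns <- c(in_introns, k)
      }
    }
    if (length(in_introns) != 2L) next
    s5 <- junctions$intron_start[in_introns] == J$intron_start
    s3 <- junctions$intron_end[in_introns] == J$intron_end
    if (!all(xor(s5, s3))) next
    if (sum(s5) != 1L || sum(s3) != 1L) next
    i5 <- in_introns[s5]
    i3 <- in_introns[s3]
    out[[length(out) + 1L]] <- data.frame(
      chrom = J$chrom, strand = J$strand,
      skip_start = J$intron_start, skip_end = J$intron_end,
      exon_start = ex$start[ex_in], exon_end = ex$end[ex_in],
      incl5_start = junctions$intron_start[i5], incl5_end = junctions$intron_end[i5],
      incl3_start = junctions$intron_start[i3], incl3_end = junctions$intron_end[i3],
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) {
    return(data.frame(
      chrom = character(), strand = character(), skip_start = integer(),
      skip_end = integer(), exon_start = integer(), exon_end = integer(),
      incl5_start = integer(), incl5_end = integer(),
      incl3_start = integer(), incl3_end = integer()
    ))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$skip_start, res$skip_end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Random multi-isoform gene models: a full transcript per gene plus
# exon-skipping variants, alternative-donor decoys, and double-skip decoys.
random_gene_models <- function(seed, n_genes = 8) {
  set.seed(seed)
  exons <- list()
  for (g in seq_len(n_genes)) {
    off <- (g - 1L) * 100000L
    n_ex <- sample(3:6, 1)
    bounds <- off + sort(sample(seq(1L, 30000L, by = 13L), 2L * n_ex))
    starts <- bounds[seq(1L, 2L * n_ex, 2L)]
    ends <- bounds[seq(2L, 2L * n_ex, 2L)]
    strand <- sample(c("+", "-"), 1)
    gid <- sprintf("g%02d", g)
    exons[[length(exons) + 1L]] <- data.frame(
      transcript_id = paste0(gid, "_full"), chrom = "chrT",
      start = starts, end = ends, strand = strand, stringsAsFactors = FALSE
    )
    for (i in seq(2L, n_ex - 1L)) {
      if (runif(1) < 0.6) {
        keep <- setdiff(seq_len(n_ex), i)
        exons[[length(exons) + 1L]] <- data.frame(
          transcript_id = sprintf("%s_skip%d", gid, i), chrom = "chrT",
          start = starts[keep], end = ends[keep], strand = strand,
          stringsAsFactors = FALSE
        )
      }
    }
    if (n_ex >= 4L && runif(1) < 0.4) {
      keep <- setdiff(seq_len(n_ex), c(2L, 3L))
      exons[[length(exons) + 1L]] <- data.frame(
        transcript_id = paste0(gid, "_dskip"), chrom = "chrT",
        start = starts[keep], end = ends[keep], strand = strand,
        stringsAsFactors = FALSE
      )
    }
    if (runif(1) < 0.4) {
      alt_ends <- ends
      alt_ends[1L] <- ends[1L] + 6L
      exons[[length(exons) + 1L]] <- data.frame(
        transcript_id = paste0(gid, "_altd"), chrom = "chrT",
        start = starts, end = alt_ends, strand = strand,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, exons)
}

# Naive O(n*m) interval-overlap counter.
oracle_overlap_count <- function(reads, introns, min_overlap) {
  out <- integer(nrow(introns))
  for (i in seq_len(nrow(introns))) {
    n <- 0L
    for (r in seq_len(nrow(reads))) {
      if (reads$chrom[r] != introns$chrom[i]) next
      ov <- min(reads$end[r], introns$end[i]) - max(reads$start[r], introns$start[i]) + 1L
      if (ov >= min_overlap) n <- n + 1L
    }
    out[i] <- n
  }
  out
}

# Plain histogram recount of a metagene profile.
oracle_metagene <- function(psites, start_codons, window) {
  offsets <- seq.int(window[1L], window[2L])
  counts <- integer(length(offsets))
  for (i in seq_len(nrow(psites))) {
    rel <- psites$psite_pos[i] - start_codons[[psites$transcript_id[i]]]
    if (rel >= window[1L] && rel <= window[2L]) {
      k <- rel - window[1L] + 1L
      counts[k] <- counts[k] + 1L
    }
  }
  counts
}

# Deterministic toy library: seeded random protospacers, unique by draw.
toy_library <- function(n_sgrnas = 4, genes = NULL, seed = 4242) {
  set.seed(seed)
  mk_dna <- function(n, w) {
    out <- unique(vapply(seq_len(2L * n + 4L), function(i) {
      paste(sample(c("A", "C", "G", "T"), w, replace = TRUE), collapse = "")
    }, character(1)))
    out[seq_len(n)]
  }
  protos <- mk_dna(2L * n_sgrnas, 20)
  data.frame(
    sgrna_id = sprintf("sg%04d", seq_len(n_sgrnas)),
    gene = genes %||% sprintf("GENE%02d", ceiling(seq_len(n_sgrnas) / 2)),
    protospacer_a = protos[seq_len(n_sgrnas)],
    protospacer_b = protos[n_sgrnas + seq_len(n_sgrnas)],
    category = "targeting",
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build a umi_count_table directly (bypassing reads) for statistics tests.
toy_count_table <- function(sample_id, umi_counts, reporter_id = "globin",
                            barcodes = NULL, sgrna_per_barcode = 1L) {
  n <- length(umi_counts)
  barcodes <- barcodes %||% sprintf("BC%04d", seq_len(n))
  sg <- sprintf("sg%04d", ceiling(seq_len(n) / sgrna_per_barcode))
  structure(data.frame(
    sample_id = sample_id, reporter_id = reporter_id, barcode = barcodes,
    sgrna_id = sg, gene = sprintf("GENE%03d", ceiling(seq_len(n) / (4L * sgrna_per_barcode))),
    umi_count = umi_counts, stringsAsFactors = FALSE
  ), class = c("umi_count_table", "data.frame"))
}
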