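#' Read exon coordinates from a GTF annotation
#'
#' Thin wrapper over `rtracklayer::import()` extracting exon records with
#' their transcript ids into the plain exon table the splicing functions
#' consume. Coordinates stay 1-based inclusive throughout.
#'
#' @param path GTF file (transcript structure via `transcript_id` attribute).
#' @return data.frame `(transcript_id, chrom, start, end, strand)`.
#' @export
read_gtf_exons <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading GTF requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  data.frame(
    transcript_id = as.character(gr$transcript_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

#' Extract annotated splice junctions (spliced-out introns) from exon models
#'
#' Each pair of consecutive exons in a transcript defines one spliced-out
#' intron; the junction is keyed by the first and last intronic base
#' (1-based inclusive). Junctions shared by several transcripts collapse to
#' one record. Transcripts with overlapping exons are malformed and are
#' dropped with a warning.
#'
#' @param exons data.frame `(transcript_id, chrom, start, end, strand)`, or a
#'   GTF path (delegated to [read_gtf_exons()]).
#' @return data.frame `(chrom, intron_start, intron_end, strand)`, unique.
#' @export
extract_junction_annotations <- function(exons) {
  if (is.character(exons) && length(exons) == 1L) {
    exons <- read_gtf_exons(exons)
  }
  dt <- as.data.table(exons)
  need <- c("transcript_id", "chrom", "start", "end", "strand")
  if (!all(need %in% names(dt))) {
    stop("exon table needs columns: ", paste(need, collapse = ", "))
  }
  data.table::setorderv(dt, c("transcript_id", "start"))

  bad_tx <- dt[, .(bad = .N > 1L && any(start[-1L] <= cummax(end)[-.N])),
               by = transcript_id][bad == TRUE, transcript_id]
  if (length(bad_tx)) {
    warning("dropping ", length(bad_tx),
            " transcript(s) with overlapping exons: ",
            paste(head(bad_tx, 5), collapse = ", "))
    dt <- dt[!transcript_id %in% bad_tx]
  }

  jn <- dt[, if (.N > 1L) .(
    chrom = chrom[-.N],
    intron_start = end[-.N] + 1L,
    intron_end = start[-1L] - 1L,
    strand = strand[-.N]
  ), by = transcript_id]
  if (nrow(jn) == 0L) {
    return(data.frame(chrom = character(), intron_start = integer(),
                      intron_end = integer(), strand = character()))
  }
  jn <- unique(jn[, .(chrom, intron_start, intron_end, strand)])
  data.table::setorderv(jn, c("chrom", "intron_start", "intron_end"))
  as.data.frame(jn)
}

#' Detect annotated cassette exons from junctions and exon models
#'
#' A junction is the skip junction of a cassette-exon event when its intron
#' interval contains exactly one annotated exon strictly inside it and
#' exactly two annotated introns, each sharing exactly one boundary (its
#' first or last intronic base) with the skip junction — one the 5'
#' boundary, one the 3' boundary. The two enclosed introns are the flanking
#' inclusion junctions of the skipped exon.
#'
#' @param junctions junction table from [extract_junction_annotations()].
#' @param exons exon table `(transcript_id, chrom, start, end, strand)` from
#'   the same annotation.
#' @return data.frame with one row per event: skip junction, enclosed exon,
#'   and the two inclusion junctions (`incl5` shares the skip junction's
#'   start, `incl3` its end; coordinate orientation, not transcript
#'   orientation).
#' @export
find_cassette_exons <- function(junctions, exons) {
  jn <- as.data.table(junctions)
  ex <- unique(as.data.table(exons)[, .(chrom, start, end, strand)])
  empty <- data.frame(
    chrom = character(), strand = character(),
    skip_start = integer(), skip_end = integer(),
    exon_start = integer(), exon_end = integer(),
    incl5_start = integer(), incl5_end = integer(),
    incl3_start = integer(), incl3_end = integer()
  )
  if (nrow(jn) == 0L || nrow(ex) == 0L) return(empty)

  events <- vector("list", nrow(jn))
  groups <- split(seq_len(nrow(jn)), paste(jn$chrom, jn$strand))
  for (ix in groups) {
    g <- jn[ix]
    exg <- ex[chrom == g$chrom[1L] & strand == g$strand[1L]]
    jr <- IRanges::IRanges(g$intron_start, g$intron_end)
    # candidate enclosed exons: strictly inside the open interval
    if (nrow(exg)) {
      er <- IRanges::IRanges(exg$start, exg$end)
      ov <- IRanges::findOverlaps(er, jr, type = "within")
      q <- S4Vectors::queryHits(ov); s <- S4Vectors::subjectHits(ov)
      strict <- exg$start[q] > g$intron_start[s] & exg$end[q] < g$intron_end[s]
      q <- q[strict]; s <- s[strict]
    } else {
      q <- s <- integer()
    }
    n_exon <- tabulate(s, nbins = nrow(g))
    # enclosed introns: proper subintervals of the skip junction
    ovi <- IRanges::findOverlaps(jr, jr, type = "within")
    qi <- S4Vectors::queryHits(ovi); si <- S4Vectors::subjectHits(ovi)
    proper <- qi != si &
      !(g$intron_start[qi] == g$intron_start[si] & g$intron_end[qi] == g$intron_end[si])
    qi <- qi[proper]; si <- si[proper]
    n_intron <- tabulate(si, nbins = nrow(g))

    share5 <- g$intron_start[qi] == g$intron_start[si]
    share3 <- g$intron_end[qi] == g$intron_end[si]
    one_end <- xor(share5, share3)

    for (j in which(n_exon == 1L & n_intron == 2L)) {
      inc <- which(si == j)
      if (!all(one_end[inc])) next
      i5 <- inc[share5[inc]]
      i3 <- inc[share3[inc]]
      if (length(i5) != 1L || length(i3) != 1L) next
      eix <- q[which(s == j)]
      events[[ix[j]]] <- data.frame(
        chrom = g$chrom[1L], strand = g$strand[1L],
        skip_start = g$intron_start[j], skip_end = g$intron_end[j],
        exon_start = exg$start[eix], exon_end = exg$end[eix],
        incl5_start = g$intron_start[qi[i5]], incl5_end = g$intron_end[qi[i5]],
        incl3_start = g$intron_start[qi[i3]], incl3_end = g$intron_end[qi[i3]],
        stringsAsFactors = FALSE
      )
    }
  }
  events <- events[!vapply(events, is.null, logical(1))]
  if (!length(events)) return(empty)
  out <- do.call(rbind, events)
  out[order(out$chrom, out$skip_start, out$skip_end), , drop = FALSE]
}

#' Percent spliced out for a cassette-exon event
#'
#' Reads on the skip junction as a percentage of skip plus both flanking
#' inclusion junction reads. Undefined (NA) below the evidence thresholds:
#' fewer than `min_skip` skip reads, or fewer than `min_incl_sum` reads
#' summed over the two flanking junctions.
#'
#' @param skip_reads,incl5_reads,incl3_reads non-negative junction read
#'   counts (vectorized).
#' @param min_skip minimum skip-junction reads (default 2).
#' @param min_incl_sum minimum summed flanking reads (default 100).
#' @return percent in \[0, 100\], or NA where undefined.
#' @export
percent_spliced_out <- function(skip_reads, incl5_reads, incl3_reads,
                                min_skip = 2, min_incl_sum = 100) {
  stopifnot(all(skip_reads >= 0), all(incl5_reads >= 0), all(incl3_reads >= 0))
  pso <- 100 * skip_reads / (skip_reads + incl5_reads + incl3_reads)
  pso[skip_reads < min_skip | (incl5_reads + incl3_reads) < min_incl_sum] <- NA_real_
  pso
}

#' Count reads overlapping an intron by at least a minimum overlap
#'
#' Overlap counting delegates to `GenomicRanges::countOverlaps()` with
#' `minoverlap` — reads overlapping fewer than `min_overlap` intronic bases
#' do not count.
#'
#' @param reads data.frame `(chrom, start, end)` of alignment intervals
#'   (1-based inclusive), or a GRanges.
#' @param introns data.frame `(chrom, start, end)` of introns, or a GRanges.
#' @param min_overlap minimum overlap in nt (default 10).
#' @return integer vector of qualifying read counts, one per intron.
#' @export
count_intron_reads <- function(reads, introns, min_overlap = 10) {
  as_gr <- function(x) {
    if (methods::is(x, "GRanges")) return(x)
    x <- as.data.frame(x)
    GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start, x$end))
  }
  GenomicRanges::countOverlaps(as_gr(introns), as_gr(reads),
                               minoverlap = min_overlap, ignore.strand = TRUE)
}

#' Percent spliced in for a retained intron
#'
#' Intron-overlapping read counts are length-normalized by
#' `read_length / (intron_length + read_length)` — the factor that converts
#' an interval count into a per-splice-event equivalent, since a read can
#' start anywhere in `intron_length + read_length` nt and still overlap the
#' intron — and then compared against reads on the intron's splice-out
#' junction: `psi = 100 * n / (n + junction_reads)`.
#'
#' @param raw_intron_reads reads overlapping the intron (vectorized).
#' @param junction_reads reads on the splice-out junction.
#' @param intron_length intron length in nt (> 0).
#' @param read_length nominal sequencing read length in nt (> 0), a single
#'   configuration scalar.
#' @return percent in \[0, 100\]; NA where both counts are zero.
#' @export
intron_psi <- function(raw_intron_reads, junction_reads, intron_length,
                       read_length) {
  stopifnot(all(intron_length > 0), read_length > 0)
  n <- raw_intron_reads * read_length / (intron_length + read_length)
  psi <- 100 * n / (n + junction_reads)
  psi[raw_intron_reads == 0 & junction_reads == 0] <- NA_real_
  psi[raw_intron_reads == 0 & junction_reads > 0] <- 0
  psi
}

#' Read a junction count table
#'
#' Accepts the 9-column tab-delimited junction dialect (chrom, intron start,
#' intron end, strand code 0/1/2, motif, annotated, unique reads,
#' multi-mapping reads, max overhang) or a minimal 4-column TSV (chrom,
#' intron_start, intron_end, unique_reads). Only uniquely mapping reads are
#' used.
#'
#' @param path junction table path.
#' @return data.frame `(chrom, intron_start, intron_end, strand,
#'   unique_reads)`; strand is NA in the 4-column dialect.
#' @export
read_junction_table <- function(path) {
  dt <- data.table::fread(path, header = FALSE)
  if (ncol(dt) == 9L) {
    out <- data.frame(
      chrom = as.character(dt[[1L]]),
      intron_start = as.integer(dt[[2L]]),
      intron_end = as.integer(dt[[3L]]),
      strand = c("*", "+", "-")[as.integer(dt[[4L]]) + 1L],
      unique_reads = as.integer(dt[[7L]])
    )
  } else if (ncol(dt) == 4L) {
    out <- data.frame(
      chrom = as.character(dt[[1L]]),
      intron_start = as.integer(dt[[2L]]),
      intron_end = as.integer(dt[[3L]]),
      strand = NA_character_,
      unique_reads = as.integer(dt[[4L]])
    )
  } else {
    stop("junction table must have 9 or 4 columns, got ", ncol(dt))
  }
  out
}

#' Quantify cassette-exon skipping across annotated events
#'
#' Joins junction counts onto detected events and computes
#' [percent_spliced_out()]. Events whose skip junction is absent from the
#' count table get zero skip reads; only annotation-derived events are
#' quantified.
#'
#' @param events output of [find_cassette_exons()].
#' @param junction_counts data.frame `(chrom, intron_start, intron_end,
#'   unique_reads)` (see [read_junction_table()]).
#' @param min_skip,min_incl_sum thresholds for [percent_spliced_out()].
#' @return `events` with `skip_reads, incl5_reads, incl3_reads, pso,
#'   pass` columns appended.
#' @export
quantify_cassette_exons <- function(events, junction_counts,
                                    min_skip = 2, min_incl_sum = 100) {
  jc <- as.data.frame(junction_counts)
  key <- function(chrom, s, e) paste(chrom, s, e, sep = ":")
  jkey <- key(jc$chrom, jc$intron_start, jc$intron_end)
  grab <- function(chrom, s, e) {
    n <- jc$unique_reads[match(key(chrom, s, e), jkey)]
    ifelse(is.na(n), 0L, n)
  }
  events$skip_reads <- grab(events$chrom, events$skip_start, events$skip_end)
  events$incl5_reads <- grab(events$chrom, events$incl5_start, events$incl5_end)
  events$incl3_reads <- grab(events$chrom, events$incl3_start, events$incl3_end)
  events$pso <- percent_spliced_out(events$skip_reads, events$incl5_reads,
                                    events$incl3_reads, min_skip, min_incl_sum)
  events$pass <- !is.na(events$pso)
  events
}

#' Quantify intron retention across annotated introns
#'
#' Counts qualifying intron-overlapping reads ([count_intron_reads()]),
#' suppresses introns below the read floor, and computes the
#' length-normalized [intron_psi()] against the splice-out junction counts.
#'
#' @param introns data.frame `(chrom, intron_start, intron_end)` of introns
#'   to quantify (typically the junction annotation).
#' @param reads alignment intervals for [count_intron_reads()].
#' @param junction_counts junction read counts as in
#'   [quantify_cassette_exons()].
#' @param read_length nominal read length (config scalar).
#' @param min_overlap minimum read/intron overlap in nt (default 10).
#' @param min_intron_reads minimum qualifying intron reads for a usable
#'   record (default 100); failing records keep their counts but have
#'   `pass = FALSE` and NA psi.
#' @return data.frame with intron coordinates, `intron_length,
#'   raw_intron_reads, normalized_intron_reads, junction_reads, psi, pass`.
#' @export
quantify_intron_retention <- function(introns, reads, junction_counts,
                                      read_length, min_overlap = 10,
                                      min_intron_reads = 100) {
  introns <- as.data.frame(introns)
  jc <- as.data.frame(junction_counts)
  raw <- count_intron_reads(
    reads,
    data.frame(chrom = introns$chrom, start = introns$intron_start,
               end = introns$intron_end),
    min_overlap = min_overlap
  )
  len <- introns$intron_end - introns$intron_start + 1L
  jkey <- paste(jc$chrom, jc$intron_start, jc$intron_end, sep = ":")
  jn <- jc$unique_reads[match(
    paste(introns$chrom, introns$intron_start, introns$intron_end, sep = ":"), jkey)]
  jn[is.na(jn)] <- 0L

  out <- introns
  out$intron_length <- len
  out$raw_intron_reads <- raw
  out$normalized_intron_reads <- raw * read_length / (len + read_length)
  out$junction_reads <- jn
  out$psi <- intron_psi(raw, jn, len, read_length)
  out$pass <- raw >= min_intron_reads
  out$psi[!out$pass] <- NA_real_
  out
}
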