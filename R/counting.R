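#' Default screen read layout
#'
#' Screen sequencing reads carry, in fixed positions, a 20-nt barcode, a 7-nt
#' UMI added at reverse transcription, and a 6-nt constant reporter
#' identifier. The layout gives 1-based start and length for each field.
#'
#' @param barcode,umi,reporter integer `c(start, length)` pairs.
#' @return a named list of field coordinates.
#' @export
screen_layout <- function(barcode = c(1L, 20L), umi = c(21L, 7L),
                          reporter = c(28L, 6L)) {
  lay <- list(barcode = as.integer(barcode), umi = as.integer(umi),
              reporter = as.integer(reporter))
  for (f in names(lay)) {
    if (length(lay[[f]]) != 2L || any(lay[[f]] < 1L)) {
      stop("layout field '", f, "' must be c(start, length) with start >= 1")
    }
  }
  lay
}

#' Parse raw screen reads into barcode / UMI / reporter fields
#'
#' Extracts the three fields verbatim from each read sequence and maps the
#' 6-nt reporter identifier against a whitelist. Matching is exact
#' everywhere: reads whose barcode or UMI contain non-ACGT characters
#' (including N), whose sequence is too short for the layout, or whose
#' reporter identifier is not in the whitelist are discarded with a reason.
#'
#' @param reads data.frame with columns `sample_id, seq`, or a character
#'   vector of sequences (then `sample_id` must be given).
#' @param layout a [screen_layout()].
#' @param reporter_whitelist named character vector mapping reporter name ->
#'   6-nt identifier sequence.
#' @param sample_id sample label used when `reads` is a bare vector.
#' @return data.frame `(sample_id, barcode, umi, reporter_id)` of parsed
#'   reads, with attribute `log` counting discards by reason.
#' @export
parse_screen_reads <- function(reads, layout = screen_layout(),
                               reporter_whitelist, sample_id = NULL) {
  if (is.character(reads)) {
    if (is.null(sample_id)) stop("sample_id required when reads is a vector")
    reads <- data.frame(sample_id = sample_id, seq = reads)
  }
  dt <- as.data.table(reads)
  if (!all(c("sample_id", "seq") %in% names(dt))) {
    stop("screen reads need columns sample_id and seq")
  }
  if (is.null(names(reporter_whitelist)) || any(names(reporter_whitelist) == "")) {
    stop("reporter_whitelist must be a named vector: name -> 6-nt identifier")
  }
  if (!all(is_dna(reporter_whitelist, layout$reporter[2L]))) {
    stop("reporter identifiers must be ", layout$reporter[2L], "-nt DNA strings")
  }
  n_in <- nrow(dt)
  need_len <- max(vapply(layout, function(f) f[1L] + f[2L] - 1L, integer(1)))

  too_short <- nchar(dt$seq) < need_len
  n_short <- sum(too_short)
  dt <- dt[!too_short]

  cut <- function(field) {
    substr(dt$seq, layout[[field]][1L],
           layout[[field]][1L] + layout[[field]][2L] - 1L)
  }
  dt[, barcode := cut("barcode")]
  dt[, umi := cut("umi")]
  dt[, reporter_seq := cut("reporter")]

  bad_bc <- !is_dna(dt$barcode, layout$barcode[2L])
  bad_umi <- !is_dna(dt$umi, layout$umi[2L])
  bad_field <- bad_bc | bad_umi
  n_bad_field <- sum(bad_field)
  dt <- dt[!bad_field]

  dt[, reporter_id := names(reporter_whitelist)[match(reporter_seq, reporter_whitelist)]]
  n_bad_reporter <- sum(is.na(dt$reporter_id))
  dt <- dt[!is.na(reporter_id)]

  out <- as.data.frame(dt[, .(sample_id, barcode, umi, reporter_id)])
  attr(out, "log") <- list(
    reads_in = n_in,
    reads_too_short = n_short,
    reads_bad_barcode_or_umi = n_bad_field,
    reads_unknown_reporter = n_bad_reporter,
    reads_out = nrow(out)
  )
  out
}

#' Count distinct UMIs per sample, reporter and barcode
#'
#' Collapses reads to molecules: within each (sample, reporter, barcode),
#' duplicate (barcode, UMI) combinations — PCR and sequencing duplicates of
#' the same reverse-transcribed molecule — count once. Only barcodes present
#' in the validated linkage table are retained; everything else (sequencing
#' errors, ambient barcodes) contributes nothing. Distinct literal UMIs count
#' separately: no UMI error correction is attempted.
#'
#' @param reads parsed reads: data.frame `(sample_id, barcode, umi,
#'   reporter_id)` (see [parse_screen_reads()]).
#' @param linkage a `linkage_table` (with `gene` column) restricting and
#'   annotating the barcodes.
#' @return data.frame of class `umi_count_table` with columns `sample_id,
#'   reporter_id, barcode, sgrna_id, gene, umi_count`; attribute `log`
#'   records read and barcode accounting.
#' @export
count_umis <- function(reads, linkage) {
  linkage <- as.data.frame(linkage)
  if (nrow(linkage) == 0L) stop("linkage table is empty")
  dt <- as.data.table(reads)
  need <- c("sample_id", "barcode", "umi", "reporter_id")
  if (!all(need %in% names(dt))) {
    stop("reads need columns: ", paste(need, collapse = ", "))
  }
  n_in <- nrow(dt)
  dt <- dt[barcode %in% linkage$barcode]
  n_linked <- nrow(dt)

  mol <- unique(dt, by = c("sample_id", "reporter_id", "barcode", "umi"))
  counts <- mol[, .(umi_count = .N), by = .(sample_id, reporter_id, barcode)]

  idx <- match(counts$barcode, linkage$barcode)
  counts[, sgrna_id := linkage$sgrna_id[idx]]
  counts[, gene := if ("gene" %in% names(linkage)) linkage$gene[idx] else NA_character_]
  data.table::setorderv(counts, c("sample_id", "reporter_id", "barcode"))

  out <- as.data.frame(counts[, .(sample_id, reporter_id, barcode, sgrna_id, gene, umi_count)])
  class(out) <- unique(c("umi_count_table", class(out)))
  attr(out, "log") <- list(
    reads_in = n_in,
    reads_barcode_not_in_linkage = n_in - n_linked,
    reads_retained = n_linked,
    distinct_molecules = nrow(mol),
    records_out = nrow(out)
  )
  out
}

#' Flag records below the minimum UMI detection floor
#'
#' A barcode needs a minimum number of distinct UMIs in a sample to be
#' considered detected (default 20). Records below the floor are retained in
#' the table but flagged `pass_floor = FALSE`; downstream analysis sets use
#' [detected_counts()] to keep only passing records.
#'
#' @param counts a `umi_count_table`.
#' @param min_umis detection floor (default 20); 0 flags everything as
#'   passing.
#' @return `counts` with a logical `pass_floor` column added.
#' @export
apply_umi_floor <- function(counts, min_umis = 20) {
  stopifnot(min_umis >= 0)
  counts$pass_floor <- counts$umi_count >= min_umis
  counts
}

#' @rdname apply_umi_floor
#' @export
detected_counts <- function(counts, min_umis = 20) {
  counts <- apply_umi_floor(counts, min_umis)
  counts[counts$pass_floor, , drop = FALSE]
}

#' Write / read a UMI count table as CSV
#'
#' @param x a `umi_count_table`.
#' @param path output CSV path.
#' @export
write_counts <- function(x, path) {
  data.table::fwrite(as.data.frame(x), path)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  x <- as.data.frame(data.table::fread(path))
  for (col in c("sample_id", "reporter_id", "barcode", "sgrna_id", "gene")) {
    if (col %in% names(x)) x[[col]] <- as.character(x[[col]])
  }
  class(x) <- unique(c("umi_count_table", class(x)))
  x
}
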