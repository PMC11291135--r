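#' Read a designed sgRNA library
#'
#' The designed library lists every dual-sgRNA cassette that was cloned:
#' one row per sgRNA pair with its target gene, the two 20-nt protospacers,
#' and a category distinguishing gene-targeting pairs from essential-gene
#' positive controls and non-targeting negative controls.
#'
#' @param path CSV with columns `sgrna_id, gene, protospacer_a, protospacer_b,
#'   category`.
#' @return A validated `data.frame` of class `sgrna_library`.
#' @export
read_sgrna_library <- function(path) {
  lib <- as.data.frame(data.table::fread(path, colClasses = "character"))
  validate_sgrna_library(lib)
}

#' Validate a designed sgRNA library table
#'
#' @param lib data.frame with columns `sgrna_id, gene, protospacer_a,
#'   protospacer_b, category`.
#' @return `lib`, with class `sgrna_library` prepended.
#' @export
validate_sgrna_library <- function(lib) {
  need <- c("sgrna_id", "gene", "protospacer_a", "protospacer_b", "category")
  missing <- setdiff(need, names(lib))
  if (length(missing)) {
    stop("sgRNA library is missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(lib$sgrna_id)) {
    stop("sgrna_id values must be unique within a designed library")
  }
  if (!all(is_dna(lib$protospacer_a, 20)) || !all(is_dna(lib$protospacer_b, 20))) {
    stop("protospacers must be 20-nt strings over {A,C,G,T}")
  }
  ok_cat <- c("targeting", "essential_control", "nontargeting_control")
  if (!all(lib$category %in% ok_cat)) {
    stop("category must be one of: ", paste(ok_cat, collapse = ", "))
  }
  class(lib) <- unique(c("sgrna_library", class(lib)))
  lib
}

#' Match observed sgRNA inserts against the designed library
#'
#' A linkage read pairs an observed insert (the concatenated protospacers of a
#' dual-sgRNA cassette) with a barcode. Matching is exact: an insert carrying
#' even a single substitution relative to every designed cassette is treated
#' as absent from the library and dropped, so sequencing errors in the insert
#' cannot mis-assign a barcode.
#'
#' @param insert_seq character vector of observed insert sequences.
#' @param library an `sgrna_library`.
#' @return character vector of `sgrna_id`s, `NA` where no exact match exists.
#' @export
match_insert <- function(insert_seq, library) {
  library <- validate_sgrna_library(as.data.frame(library))
  key <- paste0(library$protospacer_a, library$protospacer_b)
  library$sgrna_id[match(insert_seq, key)]
}

#' Filter barcode-to-insert assignments for ambiguity and sequencing errors
#'
#' Two rules, applied in order:
#' 1. A barcode observed with more than one distinct sgRNA insert is removed
#'    entirely (it cannot be attributed to a single perturbation).
#' 2. Among barcodes linked to the same insert, any pair within
#'    `edit_threshold` global edit distance is presumed to differ only by
#'    sequencing error: the lower-count member is discarded and the survivor
#'    keeps its own count (no merging). Count ties discard the
#'    lexicographically larger barcode.
#'
#' Rule 2 is resolved greedily from the highest-count barcode down, so the
#' surviving set contains no pair within the threshold.
#'
#' @param barcode_counts data.frame with columns `barcode, sgrna_id,
#'   read_count` (one row per observed barcode/insert combination).
#' @param edit_threshold maximum edit distance at which two same-insert
#'   barcodes are considered error-derived duplicates (default 2).
#' @return the filtered data.frame, with a `discards` attribute recording
#'   removed rows and the reason (`ambiguous_insert` or `similar_barcode`).
#' @export
cluster_barcodes <- function(barcode_counts, edit_threshold = 2) {
  dt <- as.data.table(barcode_counts)[, .(barcode, sgrna_id, read_count)]
  discards <- list()

  # Rule 1: ambiguous barcodes out first
  ambig <- dt[, .(n_sgrna = data.table::uniqueN(sgrna_id)), by = barcode][n_sgrna > 1L, barcode]
  if (length(ambig)) {
    drop <- dt[barcode %in% ambig]
    drop[, reason := "ambiguous_insert"]
    discards[[length(discards) + 1L]] <- drop
    dt <- dt[!barcode %in% ambig]
  }

  # Rule 2: same-insert similarity collapse, high count (ties: lex order) first
  if (nrow(dt) && edit_threshold > 0) {
    data.table::setorderv(dt, c("sgrna_id", "read_count", "barcode"),
                          order = c(1L, -1L, 1L))
    dt[, keep := similarity_survivors(barcode, edit_threshold), by = sgrna_id]
    if (any(!dt$keep)) {
      drop <- dt[keep == FALSE, .(barcode, sgrna_id, read_count)]
      drop[, reason := "similar_barcode"]
      discards[[length(discards) + 1L]] <- drop
    }
    dt <- dt[keep == TRUE][, keep := NULL]
  }

  out <- as.data.frame(dt)
  attr(out, "discards") <- if (length(discards)) {
    as.data.frame(rbindlist(discards))
  } else {
    data.frame(barcode = character(), sgrna_id = character(),
               read_count = integer(), reason = character())
  }
  out
}

# Greedy survivor scan over barcodes pre-sorted by priority: a barcode
# survives iff it is beyond `threshold` edits from every prior survivor.
similarity_survivors <- function(barcodes, threshold) {
  n <- length(barcodes)
  keep <- logical(n)
  if (n == 0L) return(keep)
  keep[1L] <- TRUE
  if (n == 1L) return(keep)
  d <- adist(barcodes)
  for (i in 2:n) {
    keep[i] <- all(d[i, keep, drop = TRUE] > threshold)
  }
  keep
}

#' Build a barcode-to-sgRNA linkage table from linkage sequencing reads
#'
#' Pipeline: exact insert matching against the designed library, aggregation
#' of reads per (barcode, insert), ambiguity/similarity filtering via
#' [cluster_barcodes()], and a minimum read support threshold. The result is
#' the whitelist every downstream barcode count is restricted to.
#'
#' Reads with a malformed barcode (wrong length, or characters outside
#' A/C/G/T, including N) are discarded and logged, as are reads whose insert
#' is not in the designed library.
#'
#' @param reads data.frame with columns `insert_seq, barcode_seq`, or a path
#'   to a 2-column TSV with those columns.
#' @param library an `sgrna_library` (or path to its CSV).
#' @param min_reads minimum read support for a retained pair (default 5).
#' @param edit_threshold see [cluster_barcodes()].
#' @return data.frame of class `linkage_table` with columns `barcode,
#'   sgrna_id, gene, read_count`; attributes `discards` (barcode-level) and
#'   `log` (read/barcode accounting used by the run manifest).
#' @export
build_linkage_table <- function(reads, library, min_reads = 5, edit_threshold = 2) {
  stopifnot(min_reads >= 1)
  if (is.character(library) && length(library) == 1L) {
    library <- read_sgrna_library(library)
  } else {
    library <- validate_sgrna_library(as.data.frame(library))
  }
  if (is.character(reads) && length(reads) == 1L) {
    reads <- as.data.frame(data.table::fread(reads, colClasses = "character"))
  }
  reads <- as.data.table(reads)
  if (!all(c("insert_seq", "barcode_seq") %in% names(reads))) {
    stop("linkage reads need columns insert_seq and barcode_seq")
  }
  n_in <- nrow(reads)
  if (n_in == 0L) {
    warning("empty linkage read stream; returning empty table")
  }

  bad <- !is_dna(reads$barcode_seq, 20)
  n_malformed <- sum(bad)
  reads <- reads[!bad]

  reads[, sgrna_id := match_insert(insert_seq, library)]
  n_unmatched <- sum(is.na(reads$sgrna_id))
  reads <- reads[!is.na(sgrna_id)]

  agg <- reads[, .(read_count = .N), by = .(barcode = barcode_seq, sgrna_id)]
  n_barcodes_raw <- nrow(agg)

  filtered <- cluster_barcodes(agg, edit_threshold = edit_threshold)
  discards <- attr(filtered, "discards")

  filtered <- as.data.table(filtered)
  low <- filtered[read_count < min_reads]
  if (nrow(low)) {
    low[, reason := "below_min_reads"]
    discards <- rbind(discards, as.data.frame(low))
  }
  filtered <- filtered[read_count >= min_reads]

  filtered[, gene := library$gene[match(sgrna_id, library$sgrna_id)]]
  out <- as.data.frame(filtered[, .(barcode, sgrna_id, gene, read_count)])
  class(out) <- unique(c("linkage_table", class(out)))
  attr(out, "discards") <- discards
  attr(out, "log") <- list(
    reads_in = n_in,
    reads_malformed = n_malformed,
    reads_insert_not_in_library = n_unmatched,
    reads_matched = n_in - n_malformed - n_unmatched,
    barcodes_raw = n_barcodes_raw,
    barcodes_ambiguous = sum(discards$reason == "ambiguous_insert"),
    barcodes_similar_discarded = sum(discards$reason == "similar_barcode"),
    barcodes_below_min_reads = sum(discards$reason == "below_min_reads"),
    barcodes_out = nrow(out)
  )
  out
}

#' Write / read a linkage table as CSV
#'
#' The canonical hand-off format between linkage sequencing and barcode
#' counting: one row per validated barcode.
#'
#' @param x a `linkage_table`.
#' @param path output CSV path.
#' @export
write_linkage <- function(x, path) {
  data.table::fwrite(as.data.frame(x), path)
  invisible(path)
}

#' @rdname write_linkage
#' @export
read_linkage <- function(path) {
  x <- as.data.frame(data.table::fread(path))
  x$barcode <- as.character(x$barcode)
  x$sgrna_id <- as.character(x$sgrna_id)
  class(x) <- unique(c("linkage_table", class(x)))
  x
}
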