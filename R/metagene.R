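#' Assign ribosome P-sites from transcript-space footprint alignments
#'
#' Ribosome footprints of canonical length (27-33 nt) position their P-site
#' at a fixed 13-nt offset from the read's 5' end. Reads outside the length
#' range are dropped; reads whose resulting P-site would fall before the
#' transcript start are dropped with a warning.
#'
#' @param alignments data.frame `(transcript_id, five_prime_pos,
#'   read_length)`; positions are 0-based transcript coordinates of the
#'   read's 5' end.
#' @param min_length,max_length accepted footprint lengths (defaults 27, 33).
#' @param p_offset 5' end to P-site offset in nt (default 13).
#' @return data.frame `(transcript_id, psite_pos, read_length)` with
#'   attribute `log` counting drops.
#' @export
assign_psites <- function(alignments, min_length = 27, max_length = 33,
                          p_offset = 13) {
  aln <- as.data.frame(alignments)
  need <- c("transcript_id", "five_prime_pos", "read_length")
  if (!all(need %in% names(aln))) {
    stop("alignments need columns: ", paste(need, collapse = ", "))
  }
  n_in <- nrow(aln)
  keep_len <- aln$read_length >= min_length & aln$read_length <= max_length
  aln <- aln[keep_len, , drop = FALSE]

  psite <- aln$five_prime_pos + p_offset
  neg <- psite < 0
  if (any(neg)) {
    warning(sum(neg), " P-site position(s) before transcript start; dropped")
  }
  out <- data.frame(
    transcript_id = aln$transcript_id[!neg],
    psite_pos = psite[!neg],
    read_length = aln$read_length[!neg],
    stringsAsFactors = FALSE
  )
  attr(out, "log") <- list(
    reads_in = n_in,
    reads_length_filtered = n_in - sum(keep_len),
    reads_negative_psite = sum(neg),
    reads_out = nrow(out)
  )
  out
}

#' Metagene P-site profile around start codons
#'
#' P-site counts are summed per position relative to each transcript's
#' annotated start codon (offset 0 = first nucleotide of the AUG), across
#' all transcripts, then divided by the maximum count over the window so
#' profiles from different libraries are comparable.
#'
#' @param psites output of [assign_psites()].
#' @param start_codons named integer vector (transcript_id ->
#'   start codon position, 0-based) or data.frame `(transcript_id,
#'   start_codon_pos)`.
#' @param window integer `c(upstream, downstream)` offsets, inclusive
#'   (default `c(-100, 500)`).
#' @return data.frame `(offset, count, normalized)` covering every offset in
#'   the window; `normalized` peaks at 1 when any count is positive, and is
#'   all zero otherwise.
#' @export
metagene_profile <- function(psites, start_codons, window = c(-100L, 500L)) {
  stopifnot(length(window) == 2L, window[1L] <= window[2L])
  if (is.data.frame(start_codons)) {
    start_codons <- setNames(start_codons$start_codon_pos,
                             start_codons$transcript_id)
  }
  psites <- as.data.frame(psites)
  offsets <- seq.int(window[1L], window[2L])
  counts <- integer(length(offsets))

  if (nrow(psites) > 0L) {
    start <- start_codons[psites$transcript_id]
    if (anyNA(start)) {
      stop("missing start codon annotation for: ",
           paste(unique(psites$transcript_id[is.na(start)]), collapse = ", "))
    }
    rel <- psites$psite_pos - unname(start)
    rel <- rel[rel >= window[1L] & rel <= window[2L]]
    counts <- tabulate(rel - window[1L] + 1L, nbins = length(offsets))
  }
  normalized <- if (any(counts > 0L)) counts / max(counts) else as.numeric(counts)
  data.frame(offset = offsets, count = counts, normalized = normalized)
}

#' Per-transcript P-site profile
#'
#' The metagene computation restricted to a single transcript: summing over
#' one transcript reduces to its own profile.
#'
#' @inheritParams metagene_profile
#' @param transcript_id transcript to profile.
#' @return see [metagene_profile()].
#' @export
transcript_profile <- function(psites, start_codons, transcript_id,
                               window = c(-100L, 500L)) {
  psites <- as.data.frame(psites)
  metagene_profile(psites[psites$transcript_id == transcript_id, , drop = FALSE],
                   start_codons, window)
}
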