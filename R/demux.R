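#' Assign reads to wells by exact barcode prefix match
#'
#' A read is assigned to a well if and only if its 5' prefix exactly
#' matches that well's barcode, either in the read as given or in its
#' reverse complement; reads matched via the reverse complement are
#' re-oriented to the template strand (sequence reverse-complemented,
#' quality string reversed) before being returned. Exact matching only —
#' no mismatch rescue — mirroring prefix demultiplexers of the Sabre
#' family; barcodes generated by [generate_barcodes()] are separated
#' enough that this is unambiguous. Each read is assigned to at most one
#' well and read counts are conserved.
#'
#' @param reads A list as returned by [read_fastq()], or a character
#'   vector of sequences (then `quals` may be supplied separately).
#' @param barcodes A data.frame with columns `well_id` and `barcode`
#'   (one plate); all barcodes must have equal width and be unique.
#' @param quals Optional character vector of quality strings.
#' @return A list with `reads` (data.frame: well_id, seq, qual,
#'   reverse_matched), `n_assigned`, `n_unassigned`, `n_total`.
#' @export
demultiplex <- function(reads, barcodes, quals = NULL) {
  if (is.list(reads) && !is.null(reads$seq)) {
    quals <- reads$qual
    reads <- reads$seq
  }
  if (nrow(barcodes) == 0) stop("empty barcode table")
  if (anyDuplicated(barcodes$barcode))
    stop("duplicate barcodes in table: demultiplexing would be ambiguous")
  w <- unique(nchar(barcodes$barcode))
  if (length(w) != 1) stop("barcodes must have equal width")
  if (is.null(quals)) quals <- strrep(" ", nchar(reads))

  n <- length(reads)
  hit <- match(substr(reads, 1, w), barcodes$barcode)
  need_rc <- is.na(hit) & nchar(reads) >= w
  rc_seq <- character(n)
  if (any(need_rc)) {
    rc_seq[need_rc] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(reads[need_rc])))
    hit_rc <- match(substr(rc_seq[need_rc], 1, w), barcodes$barcode)
    reoriented <- which(need_rc)[!is.na(hit_rc)]
    hit[reoriented] <- hit_rc[!is.na(hit_rc)]
    reads[reoriented] <- rc_seq[reoriented]
    quals[reoriented] <- as.character(
      Biostrings::reverse(Biostrings::BStringSet(quals[reoriented])))
    rev_flag <- logical(n)
    rev_flag[reoriented] <- TRUE
  } else {
    rev_flag <- logical(n)
  }

  keep <- !is.na(hit)
  out <- data.frame(well_id = barcodes$well_id[hit[keep]],
                    seq = reads[keep], qual = quals[keep],
                    reverse_matched = rev_flag[keep])
  list(reads = out, n_assigned = sum(keep), n_unassigned = sum(!keep),
       n_total = n)
}

#' Count reference and variant bases at the target site
#'
#' For reads already oriented to the template strand, reads the base at
#' the target offset (counted within the template, after the barcode) and
#' tallies A as reference and G as variant. Bases with Phred quality below
#' `min_base_quality`, non-A/G bases, and reads too short to cover the
#' site are tallied as discarded. The per-base Phred cutoff (default 28)
#' is this pipeline's rendering of a caller-level mean-quality filter: at
#' a single interrogated position the conservative reading is to require
#' the cutoff of every counted base.
#'
#' @param seqs Character vector of oriented read sequences.
#' @param quals Character vector of Phred+33 quality strings.
#' @param target_offset 0-based offset of the site within the template.
#' @param barcode_width Width of the barcode preceding the template.
#' @param min_base_quality Minimum Phred score for a base to be counted.
#' @return A one-row data.frame: `ref_count`, `alt_count`, `depth`
#'   (= ref + alt), `n_discarded_low_quality`.
#' @export
count_alleles <- function(seqs, quals, target_offset, barcode_width = 0,
                          min_base_quality = 28) {
  pos <- barcode_width + target_offset + 1
  n <- length(seqs)
  covered <- nchar(seqs) >= pos & nchar(quals) >= pos
  base <- rep(NA_character_, n)
  phred <- rep(-1L, n)
  if (any(covered)) {
    base[covered] <- substr(seqs[covered], pos, pos)
    qc <- substr(quals[covered], pos, pos)
    phred[covered] <- as.integer(charToRaw(paste(qc, collapse = ""))) - 33L
  }
  ok <- covered & phred >= min_base_quality
  ref <- sum(ok & base == "A")
  alt <- sum(ok & base == "G")
  data.frame(ref_count = ref, alt_count = alt, depth = ref + alt,
             n_discarded_low_quality = n - ref - alt)
}

#' Per-well allele counts for a demultiplexed plate
#'
#' Applies [count_alleles()] to every well of a [demultiplex()] result,
#' including wells that received no reads (zero counts).
#'
#' @param demux Result of [demultiplex()].
#' @param barcodes The plate's barcode table (defines the well universe).
#' @inheritParams count_alleles
#' @return A data.frame with one row per well: `well_id`, `ref_count`,
#'   `alt_count`, `depth`, `n_discarded_low_quality`.
#' @export
count_plate <- function(demux, barcodes, target_offset, barcode_width,
                        min_base_quality = 28) {
  res <- lapply(barcodes$well_id, function(wid) {
    sel <- demux$reads$well_id == wid
    count_alleles(demux$reads$seq[sel], demux$reads$qual[sel],
                  target_offset, barcode_width, min_base_quality)
  })
  cbind(well_id = barcodes$well_id, do.call(rbind, res))
}

#' Variant allele fraction from allele counts
#'
#' The per-cell heteroplasmy estimate: the fraction of counted reads
#' carrying the variant base, `alt / (ref + alt)`.
#'
#' @param ref_count,alt_count Non-negative integer vectors.
#' @return Numeric vector of VAFs in \[0,1\].
#' @export
heteroplasmy <- function(ref_count, alt_count) {
  if (any(ref_count < 0) || any(alt_count < 0)) stop("negative counts")
  depth <- ref_count + alt_count
  if (any(depth == 0))
    stop("VAF undefined at zero depth; exclude these cells upstream")
  alt_count / depth
}
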