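#' Emit synthetic barcoded amplicon reads as FASTQ
#'
#' Writes one FASTQ file per plate. Each read is the well barcode followed
#' by the amplicon template carrying the reference (A) or variant (G) base
#' at the target offset; the number of A and G reads per well equals the
#' planted `ref_count`/`alt_count` exactly. Reads are emitted in
#' reverse-complement orientation with probability `spec$reverse_prob`.
#' Per-base miscalls at `spec$error_rate` are applied to template flanks
#' only — never to the barcode or the target base — so planted counts are
#' recoverable by exact-prefix demultiplexing and target-base counting.
#' Read names record provenance as `plate:well:index:allele`.
#'
#' @param plates Output of [build_plates()] (uses its `truth` table).
#' @param template Amplicon template sequence (character, A/C/G/T) whose
#'   base at `target_offset` must be `"A"` (the reference allele).
#' @param target_offset 0-based offset of the interrogated site within the
#'   template.
#' @param spec A [sequencing_spec()].
#' @param dir Output directory (created if needed).
#' @param seed Optional integer seed.
#' @return Invisibly, a character vector of FASTQ paths (one per plate),
#'   named by plate id.
#' @export
emit_fastq <- function(plates, template, target_offset,
                       spec = sequencing_spec(), dir, seed = NULL) {
  truth <- if (is.list(plates) && !is.null(plates$truth)) plates$truth else plates
  template <- toupper(template)
  L <- nchar(template)
  if (target_offset < 0 || target_offset >= L)
    stop("target_offset outside template")
  if (substr(template, target_offset + 1, target_offset + 1) != "A")
    stop("template must carry the reference base A at target_offset")
  if (!is.null(seed)) set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  pre <- substr(template, 1, target_offset)
  post <- substring(template, target_offset + 2)
  paths <- character(0)
  for (pid in unique(truth$plate_id)) {
    tw <- truth[truth$plate_id == pid & truth$depth > 0, , drop = FALSE]
    n_reads <- sum(tw$depth)
    if (n_reads == 0) {
      path <- file.path(dir, paste0(pid, ".fastq"))
      writeLines(character(0), path)
      paths[pid] <- path
      next
    }
    widx <- rep(seq_len(nrow(tw)), times = tw$depth)
    allele <- rep(rep(c("G", "A"), nrow(tw)),
                  times = as.vector(rbind(tw$alt_count, tw$ref_count)))
    core <- paste0(pre, allele, post)
    if (spec$error_rate > 0 && L > 1)
      core <- mutate_flanks(core, target_offset, spec$error_rate)
    seqs <- paste0(tw$barcode[widx], core)

    q <- switch(spec$base_quality_law$type,
      fixed = rep(spec$base_quality_law$q, n_reads),
      discrete = sample(spec$base_quality_law$q, n_reads, replace = TRUE,
                        prob = spec$base_quality_law$prob))
    read_len <- nchar(seqs[1])
    qchars <- vapply(sort(unique(q)),
                     function(qq) strrep(intToUtf8(qq + 33L), read_len), "")
    quals <- qchars[match(q, sort(unique(q)))]

    rc <- runif(n_reads) < spec$reverse_prob
    if (any(rc)) {
      seqs[rc] <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[rc])))
    }
    ids <- paste(pid, tw$well_id[widx], sequence(tw$depth), allele, sep = ":")
    path <- file.path(dir, paste0(pid, ".fastq"))
    write_fastq(seqs, quals, ids, path)
    paths[pid] <- path
  }
  invisible(paths)
}

# Apply iid per-base miscalls to every template position except the target.
mutate_flanks <- function(core, target_offset, e) {
  L <- nchar(core[1])
  flank_pos <- setdiff(seq_len(L), target_offset + 1)
  n_err <- rbinom(length(core), length(flank_pos), e)
  hit <- which(n_err > 0)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    pos <- sample(flank_pos, n_err[i])
    for (p in pos) {
      cur <- substr(core[i], p, p)
      substr(core[i], p, p) <- sample(setdiff(bases, cur), 1)
    }
  }
  core
}

#' Read and write FASTQ files
#'
#' Thin wrappers over Biostrings' FASTQ support returning plain character
#' vectors, which is what the exact-match demultiplexer works on.
#'
#' @param path FASTQ file path.
#' @param seqs,quals,ids Character vectors of sequences, Phred+33 quality
#'   strings and read names.
#' @return `read_fastq()`: a list with `seq`, `qual` and `id` character
#'   vectors.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  list(seq = as.character(x),
       qual = as.character(S4Vectors::mcols(x)$qualities),
       id = names(x))
}

#' @rdname read_fastq
#' @export
write_fastq <- function(seqs, quals, ids, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(quals))
  invisible(path)
}
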