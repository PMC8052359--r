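#' Read and write the package's plain-text interchange formats
#'
#' Transcriptomes travel as FASTA (transcript-orientation sequences) plus
#' BED6 (0-based half-open intervals, strand in column 6); pileups and call
#' sets as TSV. All writers accept an optional leading comment line so that
#' pipeline outputs record version, seed and parameters; readers skip `#`
#' comments.
#'
#' @param tx Transcript tibble (id, chrom, start, end, strand, sequence).
#' @param fasta,bed File paths.
#' @return `read_transcriptome()` returns the transcript tibble; writers
#'   return their input invisibly.
#' @name transcriptome_io
NULL

#' @rdname transcriptome_io
#' @export
write_transcriptome <- function(tx, fasta, bed) {
  seqs <- Biostrings::DNAStringSet(setNames(tx$sequence, tx$id))
  Biostrings::writeXStringSet(seqs, fasta)
  bed6 <- tibble::tibble(
    chrom = tx$chrom,
    start = tx$start - 1L,      # BED is 0-based half-open
    end = tx$end,
    name = tx$id,
    score = 0L,
    strand = tx$strand
  )
  readr::write_tsv(bed6, bed, col_names = FALSE, progress = FALSE)
  invisible(tx)
}

#' @rdname transcriptome_io
#' @export
read_transcriptome <- function(fasta, bed) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  bed6 <- readr::read_tsv(
    bed, col_names = c("chrom", "start", "end", "name", "score", "strand"),
    col_types = "ciicic", comment = "#", progress = FALSE)
  idx <- match(bed6$name, names(seqs))
  if (anyNA(idx)) abort("BED names missing from FASTA")
  tibble::tibble(
    id = bed6$name,
    chrom = bed6$chrom,
    start = bed6$start + 1L,
    end = bed6$end,
    strand = bed6$strand,
    sequence = as.character(seqs[idx])
  )
}

write_table_with_header <- function(df, path, header = NULL) {
  if (!is.null(header)) {
    readr::write_lines(header, path)
    readr::write_tsv(df, path, append = TRUE, col_names = TRUE, progress = FALSE)
  } else {
    readr::write_tsv(df, path, progress = FALSE)
  }
  invisible(df)
}

#' Pileup table IO
#'
#' The pileup TSV schema is `chrom, pos (1-based), ref, depth, countA,
#' countC, countG, countT`. Counts are assumed to be quality-filtered
#' upstream (e.g. bam-readcount with mapping quality >= 20 and base quality
#' >= 30); the package never re-applies per-read quality filters.
#'
#' @param pileup Pileup tibble.
#' @param path File path.
#' @param header Optional `#`-prefixed comment line written first.
#' @return The pileup tibble.
#' @export
write_pileup <- function(pileup, path, header = NULL) {
  write_table_with_header(pileup, path, header)
}

#' @rdname write_pileup
#' @export
read_pileup <- function(path) {
  df <- readr::read_tsv(path, comment = "#", col_types = "ciciiiii",
                        progress = FALSE)
  need <- c("chrom", "pos", "ref", "depth", "countA", "countC", "countG", "countT")
  if (!all(need %in% names(df))) {
    abort(paste("pileup file missing columns:",
                paste(setdiff(need, names(df)), collapse = ", ")))
  }
  bad <- with(df, depth != countA + countC + countG + countT)
  if (any(bad)) abort(sprintf("pileup depth != sum of counts at %d rows", sum(bad)))
  df
}

#' Call-set table IO
#'
#' @param calls An edit-call tibble (see [call_edits()]).
#' @param path File path.
#' @param header Optional comment line.
#' @return The call set.
#' @export
write_callset <- function(calls, path, header = NULL) {
  write_table_with_header(as_tibble_calls(calls), path, header)
}

#' @rdname write_callset
#' @export
read_callset <- function(path) {
  df <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
    chrom = "c", pos = "i", transcript_id = "c", strand = "c", ref = "c",
    alt = "c", efficiency = "d", depth = "i", alt_reads = "i",
    sample_id = "c"), progress = FALSE)
  new_edit_calls(df, sample_id = df$sample_id[1] %||% NA_character_)
}

#' FASTQ IO for amplicon reads
#'
#' Reads are written with constant Q30 qualities (Sanger Phred+33); base
#' qualities play no further role because quality filtering is modelled as
#' applied upstream.
#'
#' @param reads Tibble with `read_id`, `sequence`.
#' @param path FASTQ path.
#' @return The reads tibble.
#' @export
write_fastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
  quals <- Biostrings::BStringSet(vapply(nchar(reads$sequence), function(n) {
    strrep("?", n)  # '?' = Phred 30 in Sanger encoding
  }, character(1)))
  Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = quals)
  invisible(reads)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble::tibble(read_id = names(seqs),
                 sequence = unname(as.character(seqs)))
}

#' Write a motif matrix as a TSV of per-position base probabilities and IC
#'
#' @param motif A [build_motif()] result.
#' @param path File path.
#' @param header Optional comment line.
#' @return The motif object, invisibly.
#' @export
write_motif <- function(motif, path, header = NULL) {
  write_table_with_header(tidy(motif), path, header)
  invisible(motif)
}
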