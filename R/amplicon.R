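#' Define an amplicon target with its protospacer
#'
#' An amplicon target is the PCR reference sequence plus the 20-nt
#' protospacer interval inside it. Protospacer positions are numbered
#' PAM-distally: position 1 is the most PAM-distal nucleotide, position 20
#' the PAM-proximal one. For a plus-strand protospacer (PAM on the 3' side
#' of the interval) position 1 is `protospacer_start`; for a minus-strand
#' protospacer the spacer sequence is the reverse complement of the
#' amplicon slice and position 1 maps to `protospacer_end`.
#'
#' @param sequence Amplicon reference sequence (A/C/G/T).
#' @param protospacer_start,protospacer_end 1-based inclusive interval of
#'   the protospacer within the amplicon; must span exactly 20 nt.
#' @param strand Protospacer strand relative to the amplicon.
#' @param name Target label.
#' @return An `amplicon_target` object.
#' @export
#' @examples
#' amp <- amplicon_target(paste0(strrep("C", 30), "GATTAAAGAATCAGCAATGC",
#'                               strrep("C", 30)), 31, 50)
#' protospacer_sequence(amp)
amplicon_target <- function(sequence, protospacer_start, protospacer_end,
                            strand = c("+", "-"), name = "target") {
  strand <- match.arg(strand)
  sequence <- toupper(sequence)
  s <- as.integer(protospacer_start); e <- as.integer(protospacer_end)
  if (!grepl("^[ACGT]+$", sequence)) abort("amplicon sequence must be over A/C/G/T")
  if (is.na(s) || is.na(e) || s < 1L || e > nchar(sequence) || s > e) {
    abort("protospacer interval must lie within the amplicon")
  }
  if (e - s + 1L != 20L) abort("protospacer must be exactly 20 nt")
  structure(list(sequence = sequence, protospacer_start = s,
                 protospacer_end = e, strand = strand, name = name),
            class = "amplicon_target")
}

#' @export
print.amplicon_target <- function(x, ...) {
  cat(sprintf("<amplicon_target> %s: %d nt, protospacer %d-%d (%s)\n",
              x$name, nchar(x$sequence), x$protospacer_start,
              x$protospacer_end, x$strand))
  invisible(x)
}

#' Map PAM-distal protospacer positions to amplicon coordinates
#'
#' @param target An [amplicon_target()].
#' @param positions Protospacer positions (1-20, PAM-distal numbering).
#' @return Integer vector of 1-based amplicon coordinates.
#' @export
protospacer_to_amplicon <- function(target, positions) {
  positions <- as.integer(positions)
  if (any(is.na(positions) | positions < 1L | positions > 20L)) {
    abort("protospacer positions must lie in 1-20")
  }
  if (target$strand == "+") target$protospacer_start + positions - 1L
  else target$protospacer_end - positions + 1L
}

#' Protospacer sequence in PAM-distal orientation
#'
#' @param target An [amplicon_target()].
#' @return 20-nt character scalar, position 1 first.
#' @export
protospacer_sequence <- function(target) {
  slice <- substr(target$sequence, target$protospacer_start,
                  target$protospacer_end)
  if (target$strand == "+") slice else revcomp(slice)
}

#' Alignment scoring scheme
#'
#' Linear-gap global alignment scores. The defaults (match +2, mismatch -3,
#' gap -5) tolerate the point substitutions base editing creates while
#' penalising spurious gaps.
#'
#' @param match Positive match score.
#' @param mismatch Negative mismatch score.
#' @param gap Negative per-base gap score (linear).
#' @return An `align_scoring` list.
#' @export
align_scoring <- function(match = 2, mismatch = -3, gap = -5) {
  if (match <= 0 || mismatch >= 0 || gap >= 0) {
    abort("require match > 0, mismatch < 0, gap < 0")
  }
  structure(list(match = as.numeric(match), mismatch = as.numeric(mismatch),
                 gap = as.numeric(gap)), class = "align_scoring")
}

#' Optimal global alignment of a read against a reference
#'
#' Needleman-Wunsch alignment with linear gap penalty. Tie-breaking during
#' traceback is deterministic: on equal score a match/mismatch step is
#' preferred over a deletion (gap in the read), which is preferred over an
#' insertion (extra read base).
#'
#' @param read,ref Sequences over A/C/G/T/N.
#' @param scoring An [align_scoring()] scheme.
#' @return A `read_alignment`: list with `score`, `cigar` (runs of M/I/D),
#'   `ref_row` (aligned read base per reference position, `-` at deletions),
#'   `read`, `ref`.
#' @export
#' @examples
#' align_global("ACGT", "ACGT")$score
#' align_global("ACGT", "AGT")$cigar
align_global <- function(read, ref, scoring = align_scoring()) {
  stopifnot(inherits(scoring, "align_scoring"))
  if (!nzchar(read) || !nzchar(ref)) abort("sequences must be nonempty")
  r <- nw_batch_cpp(read, ref, scoring$match, scoring$mismatch, scoring$gap)
  structure(list(score = r$score[1], cigar = as.character(r$cigar[1]),
                 ref_row = as.character(r$ref_row[1]),
                 read = read, ref = ref, scoring = scoring),
            class = "read_alignment")
}

#' @export
print.read_alignment <- function(x, ...) {
  cat(sprintf("<read_alignment> score %g, cigar %s\n", x$score, x$cigar))
  invisible(x)
}

.reads_as_vector <- function(reads) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- read_fastq(reads)
  }
  if (is.data.frame(reads)) reads$sequence else as.character(reads)
}

#' Quantify per-position editing from amplicon reads
#'
#' Globally aligns every read to the amplicon reference, discards reads
#' scoring below `min_score_fraction` of the reference self-alignment score
#' as unmapped, classifies a read as indel-containing when its alignment
#' places at least one inserted or deleted base inside the protospacer, and
#' tabulates substitution rates per protospacer position from the
#' indel-free reads (alignment columns are ill-defined across indels).
#' Indel frequency is indel-containing reads over total mapped reads.
#' Positions and base identities are reported in PAM-distal protospacer
#' orientation; a minus-strand protospacer is handled by complementing
#' reference and read bases.
#'
#' @param reads FASTQ path, reads tibble from [simulate_amplicon_reads()],
#'   or character vector of sequences.
#' @param target An [amplicon_target()].
#' @param scoring An [align_scoring()] scheme.
#' @param min_score_fraction Mapping threshold as a fraction of the
#'   reference self-alignment score.
#' @return A `position_edit_table` tibble with one row per protospacer
#'   position: ref_base, n_obs, base counts, rate_ag, rate_ac, rate_at,
#'   rate_non_g (A-to-C + A-to-T), rate_other (non-A reference positions).
#'   Attributes: `n_total`, `n_mapped`, `n_indel`, `indel_frequency`,
#'   `mean_non_g`, `target`.
#' @export
quantify_amplicon <- function(reads, target, scoring = align_scoring(),
                              min_score_fraction = 0.6) {
  stopifnot(inherits(target, "amplicon_target"),
            inherits(scoring, "align_scoring"))
  seqs <- .reads_as_vector(reads)
  n_total <- length(seqs)
  aln <- nw_batch_cpp(seqs, target$sequence, scoring$match, scoring$mismatch,
                      scoring$gap, target$protospacer_start,
                      target$protospacer_end)
  self_score <- scoring$match * nchar(target$sequence)
  mapped <- aln$score >= min_score_fraction * self_score
  if (!any(mapped)) {
    abort("no reads aligned above min_score_fraction; cannot quantify")
  }
  n_mapped <- sum(mapped)
  indel <- aln$indel & mapped
  n_indel <- sum(indel)

  # substitution matrix from mapped, protospacer-indel-free reads
  clean <- mapped & !aln$indel
  ps_cols <- protospacer_to_amplicon(target, 1:20)
  ref_chars <- strsplit(target$sequence, "")[[1]][ps_cols]
  if (target$strand == "-") ref_chars <- complement_base(ref_chars)

  base_counts <- matrix(0L, nrow = 20L, ncol = 4L,
                        dimnames = list(NULL, DNA_BASES))
  n_obs <- integer(20L)
  if (any(clean)) {
    rows <- strsplit(as.character(aln$ref_row[clean]), "")
    m <- matrix(unlist(rows, use.names = FALSE), nrow = sum(clean),
                byrow = TRUE)[, ps_cols, drop = FALSE]
    if (target$strand == "-") {
      m[] <- chartr("ACGTN", "TGCAN", m)
    }
    for (k in 1:20) {
      col <- m[, k]
      counts <- table(factor(col, levels = DNA_BASES))  # '-' and N dropped
      base_counts[k, ] <- as.integer(counts)
      n_obs[k] <- sum(counts)
    }
  }

  rate <- function(b) ifelse(n_obs > 0, base_counts[, b] / n_obs, NA_real_)
  is_a <- ref_chars == "A"
  tbl <- tibble::tibble(
    position = 1:20,
    ref_base = ref_chars,
    n_obs = n_obs,
    n_a = base_counts[, "A"], n_c = base_counts[, "C"],
    n_g = base_counts[, "G"], n_t = base_counts[, "T"],
    rate_ag = ifelse(is_a, rate("G"), NA_real_),
    rate_ac = ifelse(is_a, rate("C"), NA_real_),
    rate_at = ifelse(is_a, rate("T"), NA_real_),
    rate_non_g = ifelse(is_a, rate("C") + rate("T"), NA_real_),
    rate_other = ifelse(is_a, NA_real_,
                        ifelse(n_obs > 0,
                               1 - base_counts[cbind(1:20, match(ref_chars, DNA_BASES))] / n_obs,
                               NA_real_))
  )
  structure(
    tbl,
    n_total = n_total, n_mapped = n_mapped, n_indel = n_indel,
    indel_frequency = n_indel / n_mapped,
    mean_non_g = mean(tbl$rate_non_g[is_a], na.rm = TRUE),
    target = target,
    class = c("position_edit_table", class(tibble::tibble()))
  )
}

#' @export
glance.position_edit_table <- function(x, ...) {
  tibble::tibble(
    n_total = attr(x, "n_total"),
    n_mapped = attr(x, "n_mapped"),
    n_indel = attr(x, "n_indel"),
    indel_frequency = attr(x, "indel_frequency"),
    mean_non_g = attr(x, "mean_non_g"),
    max_rate_ag = suppressWarnings(max(x$rate_ag, na.rm = TRUE))
  )
}

#' Conventional editing windows
#'
#' @return Named list of inclusive protospacer position ranges: `report`
#'   (4-8), the window used when reporting the most highly edited adenine,
#'   and `heatmap` (2-9), the wider window used for per-position heat maps.
#' @export
editing_windows <- function() {
  list(report = c(4L, 8L), heatmap = c(2L, 9L))
}

#' Most highly edited adenine within an editing window
#'
#' Scans the reference adenines at protospacer positions
#' `window[1]:window[2]` and returns the maximum A-to-G rate; ties break
#' towards the smaller (more PAM-distal) position. A window with no
#' reference adenine yields a zero-row result flagged via the `flagged`
#' attribute and a warning.
#'
#' @param table A `position_edit_table`.
#' @param window Inclusive position pair, e.g. `editing_windows()$report`.
#' @return One-row tibble (`position`, `rate_ag`), or zero rows if the
#'   window holds no adenine.
#' @export
window_summary <- function(table, window = editing_windows()$report) {
  window <- as.integer(window)
  if (length(window) != 2L || any(is.na(window)) ||
      window[1] < 1L || window[2] > 20L || window[1] > window[2]) {
    abort("window must be an increasing pair within 1-20")
  }
  cand <- table |>
    dplyr::filter(.data$position >= window[1], .data$position <= window[2],
                  .data$ref_base == "A", !is.na(.data$rate_ag))
  if (nrow(cand) == 0L) {
    warn("no adenine in the requested editing window")
    out <- tibble::tibble(position = integer(), rate_ag = numeric())
    attr(out, "flagged") <- TRUE
    return(out)
  }
  out <- cand |>
    dplyr::arrange(dplyr::desc(.data$rate_ag), .data$position) |>
    dplyr::slice(1L) |>
    dplyr::select("position", "rate_ag")
  attr(out, "flagged") <- FALSE
  out
}

#' Per-position log2 fold change between a variant and a reference editor
#'
#' Computes `log2((variant + pc) / (reference + pc))` at matched protospacer
#' positions, the transform used to display variant editing efficiencies
#' normalised to the reference editor in heat maps. The pseudocount guards
#' against division by zero at unedited positions; identical rates give 0.
#'
#' @param variant,reference `position_edit_table`s or tibbles with
#'   `position` and `rate_ag` columns.
#' @param pseudocount Small positive rate added to both sides.
#' @return Tibble: position, variant_rate, reference_rate, log2fc.
#' @export
log2fc_table <- function(variant, reference, pseudocount = 0.01) {
  v <- dplyr::select(tibble::as_tibble(variant), "position", variant_rate = "rate_ag")
  r <- dplyr::select(tibble::as_tibble(reference), "position", reference_rate = "rate_ag")
  j <- dplyr::inner_join(v, r, by = "position")
  if (nrow(j) != nrow(v) || nrow(j) != nrow(r)) {
    abort("variant and reference tables must cover the same positions")
  }
  j <- dplyr::filter(j, !is.na(.data$variant_rate), !is.na(.data$reference_rate))
  if (any(j$variant_rate < 0 | j$reference_rate < 0)) {
    abort("rates must be non-negative")
  }
  dplyr::mutate(j, log2fc = log2((.data$variant_rate + pseudocount) /
                                   (.data$reference_rate + pseudocount)))
}

#' Bar plot of per-position A-to-G and byproduct rates
#'
#' @param object A `position_edit_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.position_edit_table <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::filter(.data$ref_base == "A") |>
    dplyr::select("position", "rate_ag", "rate_non_g") |>
    tidyr::pivot_longer(-"position", names_to = "outcome", values_to = "rate")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$position), y = .data$rate,
                                   fill = .data$outcome)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "protospacer position (PAM-distal numbering)",
                  y = "rate") +
    ggplot2::theme_minimal()
}
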