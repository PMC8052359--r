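#' Extract transcript-strand sequence contexts around called edits
#'
#' For every call, reads the `2*flank + 1` nt window centred on the edited
#' adenine from the transcript-orientation sequence (so minus-strand genes
#' are implicitly reverse-complemented). Edits closer than `flank` to a
#' transcript end cannot provide a full window and are dropped with a
#' message; the number dropped is recorded in the `n_dropped` attribute. A
#' non-A centre base signals an upstream strand-handling bug and raises an
#' error.
#'
#' @param calls An `edit_calls` tibble (must carry `transcript_id`).
#' @param tx Transcript tibble with transcript-orientation sequences.
#' @param flank Context half-width in nt; the default 4 gives the 9-nt
#'   window conventional for deaminase-motif logos.
#' @return Tibble with chrom, pos, transcript_id, efficiency, context.
#' @export
#' @examples
#' tx <- tibble::tibble(id = "t1", chrom = "chr1", start = 1, end = 9,
#'                      strand = "+", sequence = "TTTTATTTT")
#' calls <- tibble::tibble(chrom = "chr1", pos = 5L, transcript_id = "t1",
#'                         strand = "+", efficiency = 0.5)
#' extract_contexts(calls, tx)$context
extract_contexts <- function(calls, tx, flank = 4L) {
  flank <- as.integer(flank)
  df <- as_tibble_calls(calls)
  if (nrow(df) == 0L) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          transcript_id = character(), efficiency = numeric(),
                          context = character()))
  }
  j <- dplyr::inner_join(
    df,
    dplyr::select(tx, transcript_id = "id", tx_start = "start",
                  tx_end = "end", tx_strand = "strand", "sequence"),
    by = "transcript_id")
  if (nrow(j) < nrow(df)) abort("calls reference transcripts missing from tx")
  j <- j |>
    dplyr::mutate(
      tx_pos = ifelse(.data$tx_strand == "+",
                      .data$pos - .data$tx_start + 1L,
                      .data$tx_end - .data$pos + 1L),
      tx_len = .data$tx_end - .data$tx_start + 1L
    )
  full <- j$tx_pos - flank >= 1L & j$tx_pos + flank <= j$tx_len
  if (any(!full)) {
    inform(sprintf("%d edits within %d nt of a transcript end dropped from motif analysis",
                   sum(!full), flank))
  }
  j <- j[full, ]
  ctx <- substr(j$sequence, j$tx_pos - flank, j$tx_pos + flank)
  centre <- substr(ctx, flank + 1L, flank + 1L)
  if (any(centre != "A")) {
    abort(sprintf(
      "context centre is not A at %d sites; transcript strand handling is inconsistent",
      sum(centre != "A")))
  }
  out <- tibble::tibble(chrom = j$chrom, pos = j$pos,
                        transcript_id = j$transcript_id,
                        efficiency = j$efficiency, context = ctx)
  attr(out, "n_dropped") <- sum(!full)
  out
}

#' Build an efficiency-stratified position frequency matrix and IC profile
#'
#' Keeps contexts whose edit efficiency strictly exceeds
#' `efficiency_threshold` (strict inequality, matching the ">40%, >20%"
#' stratification convention), tabulates per-position base frequencies, and
#' computes the information content of each column as `IC = 2 - H` where `H`
#' is the Shannon entropy in bits. No small-sample correction or pseudocount
#' is applied. Bases outside A/C/G/T are excluded per column with
#' renormalisation. An empty stratum yields an `n = 0` result with `NA`
#' frequencies rather than an error.
#'
#' @param contexts Tibble from [extract_contexts()] (columns `context`,
#'   `efficiency`).
#' @param efficiency_threshold Strict lower bound on efficiency; 0 keeps
#'   every context ("all" stratum).
#' @return A `motif_matrix`: list with `pfm` (4 x width probability matrix),
#'   `ic` (per-position bits, in `[0, 2]`), `n` and `threshold`.
#' @export
build_motif <- function(contexts, efficiency_threshold = 0) {
  keep <- contexts$efficiency > efficiency_threshold
  ctx <- contexts$context[keep]
  width <- if (length(ctx)) nchar(ctx[1]) else 9L
  if (length(ctx) && any(nchar(ctx) != width)) {
    abort("contexts must share a common width")
  }
  if (length(ctx) == 0L) {
    pfm <- matrix(NA_real_, 4, width, dimnames = list(DNA_BASES, NULL))
    return(structure(list(pfm = pfm, ic = rep(NA_real_, width), n = 0L,
                          threshold = efficiency_threshold),
                     class = "motif_matrix"))
  }
  m <- matrix(unlist(strsplit(ctx, ""), use.names = FALSE),
              nrow = length(ctx), byrow = TRUE)
  pfm <- apply(m, 2L, function(col) {
    counts <- table(factor(col, levels = DNA_BASES))  # drops N et al.
    tot <- sum(counts)
    if (tot == 0L) rep(NA_real_, 4L) else as.numeric(counts) / tot
  })
  dimnames(pfm) <- list(DNA_BASES, NULL)
  ic <- apply(pfm, 2L, function(p) {
    if (anyNA(p)) return(NA_real_)
    nz <- p[p > 0]
    2 + sum(nz * log2(nz))
  })
  structure(list(pfm = pfm, ic = ic, n = length(ctx),
                 threshold = efficiency_threshold),
            class = "motif_matrix")
}

#' Build the conventional efficiency strata in one call
#'
#' @param contexts Tibble from [extract_contexts()].
#' @param thresholds Strict lower bounds; defaults give the "all", ">20%"
#'   and ">40%" strata.
#' @return Named list of `motif_matrix` objects.
#' @export
motif_strata <- function(contexts, thresholds = c(all = 0, gt20 = 0.2, gt40 = 0.4)) {
  lapply(thresholds, function(t) build_motif(contexts, t))
}

# positions labelled relative to the edited adenine: -flank .. 0 .. +flank
.motif_positions <- function(width) seq_len(width) - (width + 1L) %/% 2L

#' Per-position total-variation distance between two motif matrices
#'
#' Symmetric, zero exactly when the two position frequency matrices are
#' identical; `0.75` for an indicator column against the uniform column.
#' Useful for quantifying where an editor variant's context preference
#' diverges from the reference editor's.
#'
#' @param m1,m2 `motif_matrix` objects of equal width.
#' @return Tibble with `position` (centre = 0) and `total_variation`.
#' @export
motif_similarity <- function(m1, m2) {
  stopifnot(inherits(m1, "motif_matrix"), inherits(m2, "motif_matrix"))
  if (ncol(m1$pfm) != ncol(m2$pfm)) abort("motif matrices differ in width")
  tv <- colSums(abs(m1$pfm - m2$pfm)) / 2
  tibble::tibble(position = .motif_positions(ncol(m1$pfm)),
                 total_variation = as.numeric(tv))
}

#' @export
tidy.motif_matrix <- function(x, ...) {
  width <- ncol(x$pfm)
  pos <- .motif_positions(width)
  tibble::tibble(
    position = rep(pos, each = 4L),
    base = rep(DNA_BASES, width),
    prob = as.numeric(x$pfm),
    ic = rep(x$ic, each = 4L)
  )
}

#' @export
glance.motif_matrix <- function(x, ...) {
  tibble::tibble(
    n_sequences = x$n,
    threshold = x$threshold,
    total_ic = if (x$n) sum(x$ic) else NA_real_,
    centre_ic = if (x$n) x$ic[(ncol(x$pfm) + 1L) %/% 2L] else NA_real_
  )
}

#' @export
print.motif_matrix <- function(x, ...) {
  cat(sprintf("<motif_matrix> %d sequences, efficiency > %g\n", x$n, x$threshold))
  if (x$n) {
    cat("IC (bits):", paste(sprintf("%.2f", x$ic), collapse = " "), "\n")
  }
  invisible(x)
}

#' Sequence-logo style plot of a motif matrix
#'
#' Letter heights are the base frequencies scaled by the column information
#' content, the standard information-content logo layout, rendered as
#' stacked text glyphs.
#'
#' @param object A `motif_matrix`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.motif_matrix <- function(object, ...) {
  if (object$n == 0L) abort("cannot plot an empty motif stratum")
  df <- tidy(object) |>
    dplyr::mutate(height = .data$prob * .data$ic) |>
    dplyr::arrange(.data$position, .data$prob) |>
    dplyr::group_by(.data$position) |>
    dplyr::mutate(ymax = cumsum(.data$height),
                  ymid = .data$ymax - .data$height / 2) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$height > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$ymid)) +
    ggplot2::geom_text(ggplot2::aes(label = .data$base, size = .data$height,
                                    colour = .data$base),
                       fontface = "bold", show.legend = FALSE) +
    ggplot2::scale_size(range = c(1, 10)) +
    ggplot2::scale_x_continuous(breaks = .motif_positions(ncol(object$pfm))) +
    ggplot2::labs(x = "position relative to edited A", y = "bits") +
    ggplot2::theme_minimal()
}
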