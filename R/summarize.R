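#' Summarise a call set: counts, mean frequency, efficiency histogram
#'
#' Produces the per-sample summary surface: number of edits, mean editing
#' frequency (arithmetic mean of per-edit efficiencies over *called* edits,
#' not over all covered adenines), counts in the strict `>20%` and `>40%`
#' strata, and a histogram of efficiencies in bins of width 10% over
#' (0, 1]. Histogram counts always sum to the number of edits.
#'
#' @param calls An `edit_calls` tibble.
#' @return A `callset_summary`: list with one-row `stats` tibble and a
#'   10-bin `histogram` tibble.
#' @export
#' @examples
#' calls <- tibble::tibble(chrom = "chr1", pos = 1:3,
#'                         efficiency = c(0.05, 0.25, 0.45))
#' glance(summarize_callset(calls))
summarize_callset <- function(calls) {
  df <- tibble::as_tibble(calls)
  eff <- df$efficiency
  if (length(eff) && any(eff <= 0 | eff > 1)) {
    abort("efficiencies must lie in (0, 1]")
  }
  breaks <- seq(0, 1, by = 0.1)
  counts <- if (length(eff)) {
    as.integer(table(cut(eff, breaks = breaks, include.lowest = FALSE)))
  } else {
    integer(10L)
  }
  stats <- tibble::tibble(
    sample_id = attr(calls, "sample_id") %||% NA_character_,
    editor_label = attr(calls, "editor_label") %||% NA_character_,
    n_edits = length(eff),
    mean_frequency = if (length(eff)) mean(eff) else NA_real_,
    n_gt20 = sum(eff > 0.2),
    n_gt40 = sum(eff > 0.4)
  )
  histogram <- tibble::tibble(
    bin_lo = breaks[-11], bin_hi = breaks[-1], count = counts
  )
  structure(list(stats = stats, histogram = histogram),
            class = "callset_summary")
}

#' @export
glance.callset_summary <- function(x, ...) x$stats

#' @export
tidy.callset_summary <- function(x, ...) x$histogram

#' @export
print.callset_summary <- function(x, ...) {
  s <- x$stats
  cat(sprintf("<callset_summary> %d edits, mean frequency %.3f, >20%%: %d, >40%%: %d\n",
              s$n_edits, s$mean_frequency, s$n_gt20, s$n_gt40))
  invisible(x)
}

#' Efficiency histogram plot for a call-set summary
#'
#' @param object A `callset_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.callset_summary <- function(object, ...) {
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = (.data$bin_lo + .data$bin_hi) / 2,
                               y = .data$count)) +
    ggplot2::geom_col(width = 0.09) +
    ggplot2::labs(x = "editing efficiency", y = "edits") +
    ggplot2::theme_minimal()
}

#' Lay out edits on a cumulative genome coordinate for Manhattan plots
#'
#' Orders chromosomes (natural sort by default), offsets each chromosome by
#' the cumulative length of its predecessors, and returns one row per edit
#' sorted by cumulative coordinate.
#'
#' @param calls An `edit_calls` tibble.
#' @param chrom_lengths Named numeric vector of chromosome lengths covering
#'   every chromosome present in `calls`.
#' @param chrom_order Optional explicit chromosome ordering; defaults to a
#'   natural sort of `names(chrom_lengths)`.
#' @return Tibble: chrom, pos, cum_pos, efficiency, sorted by `cum_pos`.
#' @export
manhattan_table <- function(calls, chrom_lengths, chrom_order = NULL) {
  df <- tibble::as_tibble(calls)
  if (is.null(chrom_order)) {
    chrom_order <- stringr::str_sort(names(chrom_lengths), numeric = TRUE)
  }
  unknown <- setdiff(unique(df$chrom), chrom_order)
  if (length(unknown)) {
    abort(paste("calls on chromosomes missing from chrom_lengths:",
                paste(unknown, collapse = ", ")))
  }
  offsets <- setNames(
    cumsum(c(0, as.numeric(chrom_lengths[chrom_order])))[seq_along(chrom_order)],
    chrom_order)
  df |>
    dplyr::transmute(
      chrom = .data$chrom, pos = .data$pos,
      cum_pos = unname(offsets[.data$chrom]) + .data$pos,
      efficiency = .data$efficiency
    ) |>
    dplyr::arrange(.data$cum_pos)
}

#' Manhattan-style plot of edit efficiencies across the genome
#'
#' @param tbl A [manhattan_table()] result.
#' @return A ggplot object.
#' @export
plot_manhattan <- function(tbl) {
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$cum_pos, y = .data$efficiency,
                                    colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::labs(x = "cumulative genomic coordinate",
                  y = "editing efficiency") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Compare editor variants against a reference editor
#'
#' Joins per-editor summaries into one table and normalises edit counts and
#' strata to a designated reference editor (ratio columns), the comparison
#' used to rank engineered editor variants by residual RNA off-target load.
#'
#' @param summaries Named list of [summarize_callset()] results (names are
#'   editor labels).
#' @param reference Name of the reference editor; must appear in
#'   `summaries`.
#' @return Tibble with one row per editor: n_edits, mean_frequency, n_gt20,
#'   n_gt40, and ratios of each count to the reference editor.
#' @export
compare_variants <- function(summaries, reference) {
  if (length(summaries) < 2L) abort("need summaries for at least two editors")
  if (is.null(names(summaries)) || any(!nzchar(names(summaries)))) {
    abort("summaries must be a named list (editor labels)")
  }
  if (!reference %in% names(summaries)) {
    abort(sprintf("reference editor '%s' absent from summaries", reference))
  }
  tbl <- purrr::imap(summaries, function(s, nm) {
    st <- if (inherits(s, "callset_summary")) s$stats else tibble::as_tibble(s)
    dplyr::mutate(st, editor = nm, .before = 1L)
  }) |>
    purrr::list_rbind() |>
    dplyr::select("editor", "n_edits", "mean_frequency", "n_gt20", "n_gt40")
  ref <- dplyr::filter(tbl, .data$editor == reference)
  safe_ratio <- function(x, r) if (r > 0) x / r else NA_real_
  tbl |>
    dplyr::mutate(
      ratio_n_edits = vapply(.data$n_edits, safe_ratio, 0, r = ref$n_edits),
      ratio_gt20 = vapply(.data$n_gt20, safe_ratio, 0, r = ref$n_gt20),
      ratio_gt40 = vapply(.data$n_gt40, safe_ratio, 0, r = ref$n_gt40)
    )
}
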