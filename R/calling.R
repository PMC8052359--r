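#' Filter parameters for RNA A-to-I edit calling
#'
#' Encodes the pileup-level filters used to call ABE-induced RNA edits from a
#' treated/control sample pair: a site must be covered at least `min_depth`
#' times in both samples, the control must support the reference allele in at
#' least `control_ref_fraction` of its reads, only transcript-orientation
#' A-to-G changes are considered, and a small alt-read floor keeps sequencing
#' error from flooding the call set. `germline_like` mode additionally floors
#' the callable efficiency at `germline_min_efficiency`, emulating the
#' behaviour of germline-oriented variant callers that effectively cannot
#' recover edits below ~10% allele fraction; `somatic_like` mode has no such
#' floor.
#'
#' @param min_depth Minimum quality-filtered depth in both samples.
#' @param control_ref_fraction Minimum fraction of control reads supporting
#'   the reference allele.
#' @param min_alt_reads Minimum edited (alt) reads in the treated sample.
#' @param min_alt_fraction Minimum edited-read fraction in the treated sample.
#' @param mode `"somatic_like"` (sensitive) or `"germline_like"`
#'   (efficiency-floored emulation).
#' @param germline_min_efficiency Efficiency floor applied in
#'   `germline_like` mode only.
#' @return A validated list of class `filter_params`.
#' @export
#' @examples
#' filter_params()
#' filter_params(mode = "germline_like")
filter_params <- function(min_depth = 10L,
                          control_ref_fraction = 0.99,
                          min_alt_reads = 2L,
                          min_alt_fraction = 0.01,
                          mode = c("somatic_like", "germline_like"),
                          germline_min_efficiency = 0.10) {
  mode <- match.arg(mode)
  p <- list(
    min_depth = as.integer(min_depth),
    control_ref_fraction = as.numeric(control_ref_fraction),
    min_alt_reads = as.integer(min_alt_reads),
    min_alt_fraction = as.numeric(min_alt_fraction),
    mode = mode,
    germline_min_efficiency = as.numeric(germline_min_efficiency)
  )
  if (is.na(p$min_depth) || p$min_depth < 1L) abort("min_depth must be >= 1")
  fr <- c(p$control_ref_fraction, p$min_alt_fraction, p$germline_min_efficiency)
  if (any(is.na(fr)) || any(fr < 0 | fr > 1)) {
    abort("fractions must lie in [0, 1]")
  }
  if (is.na(p$min_alt_reads) || p$min_alt_reads < 0L) {
    abort("min_alt_reads must be >= 0")
  }
  structure(p, class = "filter_params")
}

new_edit_calls <- function(df, sample_id = NA_character_,
                           editor_label = NA_character_) {
  stopifnot(is.data.frame(df))
  structure(
    tibble::as_tibble(df),
    sample_id = sample_id,
    editor_label = editor_label,
    class = c("edit_calls", class(tibble::tibble()))
  )
}

as_tibble_calls <- function(calls) {
  out <- tibble::as_tibble(calls)
  class(out) <- class(tibble::tibble())
  out
}

empty_calls <- function(sample_id = NA_character_,
                        editor_label = NA_character_) {
  new_edit_calls(
    tibble::tibble(chrom = character(), pos = integer(),
                   transcript_id = character(), strand = character(),
                   ref = character(), alt = character(),
                   efficiency = numeric(), depth = integer(),
                   alt_reads = integer(), sample_id = character()),
    sample_id, editor_label
  )
}

# annotate plus-strand pileup rows with their (unique) host transcript;
# rows outside any transcript are dropped, rows inside transcripts on both
# strands are ambiguous and dropped with a message. Non-overlapping
# annotations (the common case) take an O(n log T) findInterval path; a
# general interval join handles overlapping transcripts.
.annotate_sites <- function(pileup, tx) {
  if (nrow(pileup) == 0L || nrow(tx) == 0L) {
    return(dplyr::mutate(pileup[0, ], transcript_id = character(),
                         strand_tx = character()))
  }
  if (!any(unique(pileup$chrom) %in% unique(tx$chrom))) {
    abort("pileup and annotation share no chromosome names")
  }
  txs <- tx[order(tx$chrom, tx$start), ]
  overlapping <- any(unlist(tapply(seq_len(nrow(txs)), txs$chrom, function(i) {
    if (length(i) < 2L) return(FALSE)
    txs$start[i][-1] <= cummax(txs$end[i])[-length(i)]
  })))
  if (!overlapping) {
    idx <- rep(NA_integer_, nrow(pileup))
    for (ch in intersect(unique(pileup$chrom), txs$chrom)) {
      rows <- which(pileup$chrom == ch)
      anni <- which(txs$chrom == ch)
      k <- findInterval(pileup$pos[rows], txs$start[anni])
      ok <- k >= 1L & pileup$pos[rows] <= txs$end[anni][pmax(k, 1L)]
      idx[rows[ok]] <- anni[k[ok]]
    }
    hits <- pileup[!is.na(idx), ]
    hits$transcript_id <- txs$id[idx[!is.na(idx)]]
    hits$strand_tx <- txs$strand[idx[!is.na(idx)]]
    return(hits)
  }
  ann <- tibble::tibble(transcript_id = txs$id, chrom = txs$chrom,
                        start = txs$start, end = txs$end,
                        strand_tx = txs$strand)
  hits <- dplyr::inner_join(
    pileup, ann,
    by = dplyr::join_by("chrom", between(x$pos, y$start, y$end)),
    relationship = "many-to-many")
  dup <- hits |>
    dplyr::summarise(n_tx = dplyr::n_distinct(.data$strand_tx),
                     .by = c("chrom", "pos")) |>
    dplyr::filter(.data$n_tx > 1L)
  if (nrow(dup)) {
    inform(sprintf(
      "%d sites overlap transcripts on both strands; excluded as ambiguous",
      nrow(dup)))
    hits <- dplyr::anti_join(hits, dup, by = c("chrom", "pos"))
  }
  hits |> dplyr::select(-"start", -"end")
}

#' Call RNA A-to-I edits from treated and control pileups
#'
#' A site is called when all of the following hold: it lies inside an
#' annotated transcript; the transcript-orientation reference base is A (a
#' plus-strand A, or a plus-strand T for minus-strand genes); treated depth
#' and edited-read count/fraction clear the thresholds in `params`; the
#' control sample reaches `min_depth` and supports the reference allele in
#' at least `control_ref_fraction` of reads; and, in `germline_like` mode,
#' the efficiency clears `germline_min_efficiency`. Efficiency is the edited
#' read fraction `alt_reads / depth` in the treated sample. Sites covered by
#' transcripts on both strands are excluded as ambiguous.
#'
#' @param treated,control Pileup tibbles (see [read_pileup()] for schema).
#' @param tx Stranded transcript annotation tibble
#'   (id, chrom, start, end, strand, ...).
#' @param params A [filter_params()] object.
#' @param sample_id,editor_label Labels carried on the result.
#' @return An `edit_calls` tibble: chrom, pos, transcript_id, strand, ref
#'   (always "A", transcript orientation), alt (always "G"), efficiency,
#'   depth, alt_reads, sample_id.
#' @export
#' @examples
#' p <- sim_params(n_transcripts = 50, motif_site_count = 5,
#'                 background_site_count = 10, endogenous_site_count = 0,
#'                 seed = 7)
#' sim <- simulate_transcriptome(p)
#' piles <- simulate_pileups(sim$transcripts, sim$truth, p)
#' calls <- call_edits(piles$treated, piles$control, sim$transcripts)
#' nrow(calls)
call_edits <- function(treated, control, tx, params = filter_params(),
                       sample_id = "treated", editor_label = NA_character_) {
  stopifnot(inherits(params, "filter_params"))
  if (nrow(treated) == 0L) return(empty_calls(sample_id, editor_label))
  ann <- .annotate_sites(treated, tx)
  if (nrow(ann) == 0L) return(empty_calls(sample_id, editor_label))

  ann <- ann |>
    dplyr::mutate(
      tx_ref = ifelse(.data$strand_tx == "+", .data$ref,
                      complement_base(.data$ref)),
      alt_reads = ifelse(.data$strand_tx == "+", .data$countG, .data$countC)
    ) |>
    dplyr::filter(.data$tx_ref == "A")
  if (nrow(ann) == 0L) return(empty_calls(sample_id, editor_label))

  # treated-side thresholds first so the control join touches few sites
  ann <- dplyr::filter(
    ann,
    .data$depth >= params$min_depth,
    .data$alt_reads >= params$min_alt_reads,
    .data$alt_reads / .data$depth >= params$min_alt_fraction)
  if (nrow(ann) == 0L) return(empty_calls(sample_id, editor_label))

  ctrl <- tibble::tibble(
    chrom = control$chrom, pos = control$pos,
    depth_ctrl = control$depth,
    ref_reads_ctrl = .pick_base_count(control, control$ref)
  )
  joined <- dplyr::left_join(ann, ctrl, by = c("chrom", "pos"))
  keep <- joined |>
    dplyr::filter(
      !is.na(.data$depth_ctrl),
      .data$depth_ctrl >= params$min_depth,
      .data$ref_reads_ctrl / .data$depth_ctrl >= params$control_ref_fraction
    ) |>
    dplyr::mutate(efficiency = .data$alt_reads / .data$depth)
  if (params$mode == "germline_like") {
    keep <- dplyr::filter(keep,
                          .data$efficiency >= params$germline_min_efficiency)
  }
  out <- keep |>
    dplyr::transmute(
      chrom = .data$chrom, pos = .data$pos,
      transcript_id = .data$transcript_id, strand = .data$strand_tx,
      ref = "A", alt = "G",
      efficiency = .data$efficiency, depth = .data$depth,
      alt_reads = as.integer(.data$alt_reads), sample_id = sample_id
    ) |>
    dplyr::arrange(.data$chrom, .data$pos)
  new_edit_calls(out, sample_id, editor_label)
}

# count supporting the reference base, rowwise over the four count columns
.pick_base_count <- function(pileup, base) {
  m <- cbind(pileup$countA, pileup$countC, pileup$countG, pileup$countT)
  m[cbind(seq_len(nrow(pileup)), match(base, DNA_BASES))]
}

#' Detect endogenous A-to-I editing from the control sample alone
#'
#' Endogenous (e.g. ADAR-driven) editing is present without any base editor,
#' so it shows up as transcript-orientation A-to-G signal in the control
#' pileup. Sites whose control alt fraction and alt count clear permissive
#' thresholds are returned as an endogenous call set suitable for
#' [subtract_endogenous()]. Detection is deliberately truth-blind: it uses
#' only the control pileup and the annotation.
#'
#' @param control Control pileup tibble.
#' @param tx Transcript annotation tibble.
#' @param min_depth,min_alt_reads,min_alt_fraction Permissive thresholds.
#' @return An `edit_calls` tibble labelled `sample_id = "endogenous"`.
#' @export
detect_endogenous <- function(control, tx, min_depth = 10L,
                              min_alt_reads = 2L, min_alt_fraction = 0.01) {
  if (nrow(control) == 0L) return(empty_calls("endogenous"))
  ann <- .annotate_sites(control, tx)
  if (nrow(ann) == 0L) return(empty_calls("endogenous"))
  out <- ann |>
    dplyr::mutate(
      tx_ref = ifelse(.data$strand_tx == "+", .data$ref,
                      complement_base(.data$ref)),
      alt_reads = ifelse(.data$strand_tx == "+", .data$countG, .data$countC)
    ) |>
    dplyr::filter(
      .data$tx_ref == "A",
      .data$depth >= min_depth,
      .data$alt_reads >= min_alt_reads,
      .data$alt_reads / .data$depth >= min_alt_fraction
    ) |>
    dplyr::transmute(
      chrom = .data$chrom, pos = .data$pos,
      transcript_id = .data$transcript_id, strand = .data$strand_tx,
      ref = "A", alt = "G",
      efficiency = .data$alt_reads / .data$depth, depth = .data$depth,
      alt_reads = as.integer(.data$alt_reads), sample_id = "endogenous"
    ) |>
    dplyr::arrange(.data$chrom, .data$pos)
  new_edit_calls(out, "endogenous")
}

#' Remove calls overlapping endogenous A-to-I edits
#'
#' Drops every call whose (chrom, pos) key appears in the endogenous call
#' set, mirroring the exclusion of endogenous editing detected in
#' untransfected cells.
#'
#' @param calls,endogenous `edit_calls` tibbles.
#' @return The filtered `edit_calls` tibble.
#' @export
subtract_endogenous <- function(calls, endogenous) {
  out <- dplyr::anti_join(as_tibble_calls(calls), as_tibble_calls(endogenous),
                          by = c("chrom", "pos"))
  new_edit_calls(out, attr(calls, "sample_id"), attr(calls, "editor_label"))
}

#' Call-set algebra: overlap, caller-specific and merged sets
#'
#' Intersects and merges two call sets keyed on (chrom, pos), the operation
#' used to compare edits recovered by different variant callers on the same
#' sample. The identity `|merged| = |a| + |b| - |overlapped|` holds by
#' construction; overlapped records keep the annotation of set `a`.
#'
#' @param a,b `edit_calls` tibbles.
#' @return A list with `edit_calls` elements `overlapped`, `a_specific`,
#'   `b_specific`, `merged`.
#' @export
overlap_callsets <- function(a, b) {
  ta <- as_tibble_calls(a); tb <- as_tibble_calls(b)
  key <- c("chrom", "pos")
  overlapped <- dplyr::semi_join(ta, tb, by = key)
  a_specific <- dplyr::anti_join(ta, tb, by = key)
  b_specific <- dplyr::anti_join(tb, ta, by = key)
  merged <- dplyr::bind_rows(ta, b_specific) |>
    dplyr::arrange(.data$chrom, .data$pos)
  lab <- function(x) new_edit_calls(x, attr(a, "sample_id"),
                                    attr(a, "editor_label"))
  list(overlapped = lab(overlapped), a_specific = lab(a_specific),
       b_specific = new_edit_calls(b_specific, attr(b, "sample_id"),
                                   attr(b, "editor_label")),
       merged = lab(merged))
}

#' Read an external caller's VCF into a call set
#'
#' Ingests a single-sample VCF 4.x, keeps SNV records that are A-to-G in
#' plus-strand genes or T-to-C in minus-strand genes (i.e. transcript
#' orientation A-to-G) inside the annotation, and takes the efficiency from
#' the `AF` FORMAT field when present, else from `AD` (alt / (ref + alt)),
#' else leaves it `NA`.
#'
#' @param path VCF path (uncompressed or bgzipped).
#' @param tx Transcript annotation tibble.
#' @param sample_id Label for the resulting call set.
#' @return An `edit_calls` tibble.
#' @export
read_callset_vcf <- function(path, tx, sample_id = NA_character_) {
  lines <- readr::read_lines(path, progress = FALSE)
  body <- which(!startsWith(lines, "#"))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf < 8L)) {
    abort(sprintf("malformed VCF: fewer than 8 fields at line %d",
                  body[which(nf < 8L)[1]]))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v),
                                         stringsAsFactors = FALSE))
  if (nrow(fix) == 0L) return(empty_calls(sample_id))
  fix$POS <- suppressWarnings(as.integer(fix$POS))
  if (anyNA(fix$POS)) abort("malformed VCF: non-integer POS")
  snv <- fix$REF %in% DNA_BASES & fix$ALT %in% DNA_BASES

  eff <- rep(NA_real_, nrow(fix))
  if (ncol(v@gt) >= 2L) {
    af <- try(vcfR::extract.gt(v, element = "AF", as.numeric = TRUE),
              silent = TRUE)
    if (!inherits(af, "try-error") && !is.null(af)) eff <- as.numeric(af[, 1])
    need_ad <- is.na(eff)
    if (any(need_ad)) {
      ad <- try(vcfR::extract.gt(v, element = "AD"), silent = TRUE)
      if (!inherits(ad, "try-error") && !is.null(ad)) {
        parts <- strsplit(ad[, 1], ",", fixed = TRUE)
        ad_eff <- vapply(parts, function(x) {
          x <- suppressWarnings(as.numeric(x))
          if (length(x) < 2L || anyNA(x[1:2]) || sum(x[1:2]) == 0) NA_real_
          else x[2] / (x[1] + x[2])
        }, numeric(1))
        eff[need_ad] <- ad_eff[need_ad]
      }
    }
  }

  df <- tibble::tibble(chrom = fix$CHROM, pos = fix$POS, ref_vcf = fix$REF,
                       alt_vcf = fix$ALT, efficiency = eff)[snv, ]
  ann <- tibble::tibble(transcript_id = tx$id, chrom = tx$chrom,
                        start = tx$start, end = tx$end, strand = tx$strand)
  hits <- dplyr::inner_join(
    df, ann, by = dplyr::join_by("chrom", between(x$pos, y$start, y$end)))
  keep <- hits |>
    dplyr::filter(
      (.data$strand == "+" & .data$ref_vcf == "A" & .data$alt_vcf == "G") |
      (.data$strand == "-" & .data$ref_vcf == "T" & .data$alt_vcf == "C")
    ) |>
    dplyr::transmute(
      chrom = .data$chrom, pos = .data$pos,
      transcript_id = .data$transcript_id, strand = .data$strand,
      ref = "A", alt = "G", efficiency = .data$efficiency,
      depth = NA_integer_, alt_reads = NA_integer_, sample_id = sample_id
    ) |>
    dplyr::arrange(.data$chrom, .data$pos)
  new_edit_calls(keep, sample_id)
}

#' Sensitivity fold between somatic-like and germline-like calling
#'
#' Runs [call_edits()] twice on the same input, once per mode, and reports
#' the ratio of call counts. Because the germline-like filters are a strict
#' superset of the somatic-like ones, the germline-like call set is nested
#' inside the somatic-like set and the fold is >= 1 whenever it is defined.
#' An empty germline-like set yields a flagged result with `fold = NA`
#' rather than an error.
#'
#' @inheritParams call_edits
#' @return A one-row tibble: n_somatic, n_germline, fold, flagged.
#' @export
sensitivity_fold <- function(treated, control, tx, params = filter_params()) {
  p_som <- params; p_som$mode <- "somatic_like"
  p_ger <- params; p_ger$mode <- "germline_like"
  n_som <- nrow(call_edits(treated, control, tx, p_som))
  n_ger <- nrow(call_edits(treated, control, tx, p_ger))
  tibble::tibble(
    n_somatic = n_som,
    n_germline = n_ger,
    fold = if (n_ger > 0L) n_som / n_ger else NA_real_,
    flagged = n_ger == 0L
  )
}

#' @export
glance.edit_calls <- function(x, ...) {
  tibble::tibble(
    sample_id = attr(x, "sample_id"),
    editor_label = attr(x, "editor_label"),
    n_edits = nrow(x),
    mean_frequency = if (nrow(x)) mean(x$efficiency) else NA_real_,
    n_gt20 = sum(x$efficiency > 0.2),
    n_gt40 = sum(x$efficiency > 0.4)
  )
}
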