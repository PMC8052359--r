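#' Build and validate a pipeline configuration
#'
#' A pipeline configuration bundles the seed, simulator parameters, caller
#' filters, amplicon scenario and motif strata for an end-to-end synthetic
#' run. `validate_config()` accepts a YAML file path or a plain named list,
#' reports *all* problems at once (unknown keys, out-of-range values), fills
#' documented defaults, and returns a normalized `pipeline_config`.
#' Configurations serialize losslessly: `validate_config(read_config(p))`
#' after `write_config()` reproduces the original object.
#'
#' @param x YAML path or named list.
#' @return A `pipeline_config` list: `seed`, `sim` ([sim_params()]),
#'   `filter` ([filter_params()]), `amplicon` (profile, n_reads, nong_rate,
#'   indel_rate, error_rate, min_score_fraction), `motif_thresholds`.
#' @export
#' @examples
#' cfg <- validate_config(list(seed = 7, sim = list(n_transcripts = 100)))
#' cfg$sim$n_transcripts
validate_config <- function(x = list()) {
  if (is.character(x) && length(x) == 1L) x <- read_config(x)
  if (!is.list(x)) abort("config must be a list or a YAML file path")
  errs <- character()
  note <- function(msg) errs <<- c(errs, msg)

  known_top <- c("seed", "sim", "filter", "amplicon", "motif_thresholds")
  unknown <- setdiff(names(x), known_top)
  if (length(unknown)) {
    note(paste("unknown config keys:", paste(unknown, collapse = ", ")))
  }

  seed <- x$seed %||% 1L
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != trunc(seed) || abs(seed) > 2^31 - 100) {
    note("seed must be a single integer below 2^31")
    seed <- 1L
  }

  sim_in <- x$sim %||% list()
  sim_known <- setdiff(names(formals(sim_params)), "seed")
  bad <- setdiff(names(sim_in), sim_known)
  if (length(bad)) note(paste("unknown sim keys:", paste(bad, collapse = ", ")))
  sim <- tryCatch(
    do.call(sim_params, c(sim_in[intersect(names(sim_in), sim_known)],
                          list(seed = seed))),
    error = function(e) { note(paste("sim:", conditionMessage(e))); sim_params(seed = seed) })

  fil_in <- x$filter %||% list()
  fil_known <- names(formals(filter_params))
  bad <- setdiff(names(fil_in), fil_known)
  if (length(bad)) note(paste("unknown filter keys:", paste(bad, collapse = ", ")))
  fil <- tryCatch(
    do.call(filter_params, fil_in[intersect(names(fil_in), fil_known)]),
    error = function(e) { note(paste("filter:", conditionMessage(e))); filter_params() })

  amp_defaults <- list(
    profile = list(`5` = 0.6, `7` = 0.3),
    n_reads = 10000L, nong_rate = 0.01, indel_rate = 0.05,
    error_rate = 1e-3, min_score_fraction = 0.6
  )
  amp_in <- x$amplicon %||% list()
  bad <- setdiff(names(amp_in), names(amp_defaults))
  if (length(bad)) note(paste("unknown amplicon keys:", paste(bad, collapse = ", ")))
  amp <- modifyList(amp_defaults, amp_in[intersect(names(amp_in), names(amp_defaults))])
  amp$n_reads <- as.integer(amp$n_reads)
  if (is.na(amp$n_reads) || amp$n_reads < 0L) note("amplicon: n_reads must be >= 0")
  for (f in c("nong_rate", "indel_rate", "error_rate", "min_score_fraction")) {
    v <- amp[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      note(sprintf("amplicon: %s must lie in [0, 1]", f))
    }
  }
  prof <- unlist(amp$profile)
  if (length(prof)) {
    pp <- suppressWarnings(as.integer(names(prof)))
    if (anyNA(pp) || any(pp < 1L | pp > 20L)) {
      note("amplicon: profile names must be protospacer positions 1-20")
    }
    if (any(prof < 0 | prof > 1)) note("amplicon: profile probabilities must lie in [0, 1]")
  }

  thr <- x$motif_thresholds %||% c(all = 0, gt20 = 0.2, gt40 = 0.4)
  thr <- unlist(thr)
  if (any(thr < 0 | thr >= 1)) note("motif_thresholds must lie in [0, 1)")
  if (is.null(names(thr)) || any(!nzchar(names(thr)))) {
    names(thr) <- paste0("gt", round(100 * thr))
  }

  if (length(errs)) {
    abort(paste0("invalid pipeline config:\n  ",
                 paste(errs, collapse = "\n  ")))
  }
  structure(list(seed = as.integer(seed), sim = sim, filter = fil,
                 amplicon = amp, motif_thresholds = thr),
            class = "pipeline_config")
}

#' @rdname validate_config
#' @param config A `pipeline_config` (or raw list) to serialize.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  raw <- list(
    seed = config$seed,
    sim = unclass(config$sim)[setdiff(names(config$sim), "seed")],
    filter = unclass(config$filter),
    amplicon = config$amplicon,
    motif_thresholds = as.list(config$motif_thresholds)
  )
  yaml::write_yaml(raw, path)
  invisible(config)
}

#' @rdname validate_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  yaml::read_yaml(path)
}

# fixed protospacer with adenines spread over the editing window; flanks are
# seeded random sequence
.default_amplicon <- function(seed) {
  spacer <- "GATTAAAGAATCAGCAATGC"
  withr::with_seed(seed + 2L, {
    left <- paste(sample(DNA_BASES, 30, replace = TRUE), collapse = "")
    right <- paste(sample(DNA_BASES, 30, replace = TRUE), collapse = "")
    amplicon_target(paste0(left, spacer, right), 31L, 50L,
                    strand = "+", name = "synthetic_site")
  })
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the full synthetic pipeline end to end
#'
#' Simulates a transcriptome with planted ground truth, simulates treated
#' and control pileups and amplicon reads, calls edits in both caller
#' modes, detects and subtracts endogenous editing (truth-blind), builds
#' efficiency-stratified motifs, quantifies the amplicon, summarises the
#' final call set, and writes a recovery report juxtaposing truth against
#' estimates (sensitivity, false-call rate, efficiency RMSE, motif
#' recovery, caller-mode fold). Every output file starts with a header line
#' recording package version, seed and key parameters; no timestamps are
#' written, so a fixed seed reproduces every file byte for byte.
#'
#' @param config A `pipeline_config` from [validate_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list with the in-memory results (`sim`, `pileups`,
#'   `calls`, `motifs`, `amplicon`, `summary`, `report`) and the output
#'   `paths`.
#' @export
run_pipeline <- function(config = validate_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  hdr <- pkg_header(seed = seed)
  path <- function(f) file.path(out_dir, f)

  sim <- .stage("simulate", simulate_transcriptome(config$sim, dir = out_dir))
  piles <- .stage("pileups", {
    p <- simulate_pileups(sim$transcripts, sim$truth, config$sim)
    write_pileup(p$treated, path("pileup_treated.tsv"), hdr)
    write_pileup(p$control, path("pileup_control.tsv"), hdr)
    p
  })

  calls <- .stage("call", {
    p_som <- config$filter; p_som$mode <- "somatic_like"
    p_ger <- config$filter; p_ger$mode <- "germline_like"
    somatic <- call_edits(piles$treated, piles$control, sim$transcripts,
                          p_som, sample_id = "treated")
    germline <- call_edits(piles$treated, piles$control, sim$transcripts,
                           p_ger, sample_id = "treated")
    endogenous <- detect_endogenous(piles$control, sim$transcripts)
    final <- subtract_endogenous(somatic, endogenous)
    write_callset(somatic, path("calls_somatic.tsv"), hdr)
    write_callset(germline, path("calls_germline.tsv"), hdr)
    write_callset(endogenous, path("calls_endogenous.tsv"), hdr)
    write_callset(final, path("calls_final.tsv"), hdr)
    list(somatic = somatic, germline = germline, endogenous = endogenous,
         final = final)
  })

  motifs <- .stage("motif", {
    ctx <- extract_contexts(calls$final, sim$transcripts)
    strata <- motif_strata(ctx, config$motif_thresholds)
    for (nm in names(strata)) {
      if (strata[[nm]]$n > 0L) {
        write_motif(strata[[nm]], path(sprintf("motif_%s.tsv", nm)), hdr)
      }
    }
    list(contexts = ctx, strata = strata)
  })

  amp <- .stage("amplicon", {
    target <- .default_amplicon(seed)
    profile <- unlist(config$amplicon$profile)
    reads <- simulate_amplicon_reads(
      target, profile,
      nong_rate = config$amplicon$nong_rate,
      indel_rate = config$amplicon$indel_rate,
      error_rate = config$amplicon$error_rate,
      n_reads = config$amplicon$n_reads,
      seed = seed + 3L,
      path = path("amplicon_reads.fastq"))
    tbl <- quantify_amplicon(reads, target,
                             min_score_fraction = config$amplicon$min_score_fraction)
    write_table_with_header(tibble::as_tibble(tbl), path("amplicon_table.tsv"), hdr)
    ws <- window_summary(tbl)
    write_table_with_header(ws, path("window_summary.tsv"), hdr)
    list(target = target, profile = profile, table = tbl, window = ws)
  })

  summ <- .stage("summarize", {
    s <- summarize_callset(calls$final)
    write_table_with_header(glance(s), path("summary.tsv"), hdr)
    write_table_with_header(tidy(s), path("histogram.tsv"), hdr)
    chrom_lengths <- tapply(sim$transcripts$end, sim$transcripts$chrom, max) + 100
    mh <- manhattan_table(calls$final, chrom_lengths)
    write_table_with_header(mh, path("manhattan.tsv"), hdr)
    list(summary = s, manhattan = mh)
  })

  report <- .stage("report", {
    rep <- recovery_report(sim$truth, calls, motifs$strata, amp)
    jsonlite::write_json(rep, path("recovery_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    rep
  })

  invisible(list(
    sim = sim, pileups = piles, calls = calls, motifs = motifs,
    amplicon = amp, summary = summ, report = report,
    paths = list(dir = out_dir, files = sort(list.files(out_dir)))
  ))
}

#' Juxtapose planted truth against pipeline estimates
#'
#' Computes the recovery statistics reported by [run_pipeline()]:
#' sensitivity of the final call set for planted non-endogenous edits
#' (overall and for true efficiency >= 0.05), false-call rate (called sites
#' that were never planted), RMSE of efficiency estimates and the fraction
#' within three binomial standard deviations of truth, endogenous leakage,
#' the somatic-like/germline-like fold, motif recovery in the >20% stratum,
#' and amplicon profile/indel errors.
#'
#' @param truth Ground-truth tibble.
#' @param calls List with `somatic`, `germline`, `final` call sets.
#' @param strata Named list of `motif_matrix` objects (needs `gt20`).
#' @param amp Amplicon stage list (`profile`, planted rates; `table`,
#'   estimates), or `NULL` to skip amplicon statistics.
#' @return Named list of scalar statistics.
#' @export
recovery_report <- function(truth, calls, strata = NULL, amp = NULL) {
  planted <- dplyr::filter(truth, !.data$endogenous)
  final <- tibble::as_tibble(calls$final)
  key <- function(d) paste(d$chrom, d$pos)
  hit <- key(planted) %in% key(final)
  ge05 <- planted$true_efficiency >= 0.05

  matched <- dplyr::inner_join(
    final, dplyr::select(planted, "chrom", "pos", "true_efficiency"),
    by = c("chrom", "pos"))
  sd3 <- 3 * sqrt(matched$true_efficiency * (1 - matched$true_efficiency) /
                    matched$depth)
  within3 <- abs(matched$efficiency - matched$true_efficiency) <= sd3

  endo_leak <- sum(key(dplyr::filter(truth, .data$endogenous)) %in% key(final))
  false_calls <- sum(!key(final) %in% key(truth))
  n_som <- nrow(calls$somatic); n_ger <- nrow(calls$germline)

  rep <- list(
    n_planted = nrow(planted),
    n_called_final = nrow(final),
    sensitivity_all = if (nrow(planted)) mean(hit) else NA_real_,
    sensitivity_ge05 = if (any(ge05)) mean(hit[ge05]) else NA_real_,
    n_ge05 = sum(ge05),
    false_call_rate = if (nrow(final)) false_calls / nrow(final) else 0,
    efficiency_rmse = if (nrow(matched)) {
      sqrt(mean((matched$efficiency - matched$true_efficiency)^2))
    } else NA_real_,
    frac_within_3sd = if (nrow(matched)) mean(within3) else NA_real_,
    endogenous_in_final = endo_leak,
    n_somatic = n_som,
    n_germline = n_ger,
    caller_mode_fold = if (n_ger > 0) n_som / n_ger else NA_real_
  )
  if (!is.null(strata) && !is.null(strata$gt20) && strata$gt20$n > 0L) {
    m <- strata$gt20
    posn <- .motif_positions(ncol(m$pfm))
    upstream <- match(-4:-1, posn)
    argmax <- rownames(m$pfm)[apply(m$pfm[, upstream, drop = FALSE], 2L, which.max)]
    rep$motif_upstream_recovered <- sum(argmax == c("T", "A", "C", "G"))
    rep$motif_centre_ic <- m$ic[match(0L, posn)]
  }
  if (!is.null(amp)) {
    est <- tibble::as_tibble(amp$table)
    prof_pos <- as.integer(names(amp$profile))
    est_rates <- est$rate_ag[match(prof_pos, est$position)]
    rep$amplicon_profile_max_abs_error <- max(abs(est_rates - as.numeric(amp$profile)))
    rep$amplicon_indel_frequency <- attr(amp$table, "indel_frequency")
  }
  rep
}
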