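#' Simulation parameters for the synthetic ABE experiment
#'
#' Bundles every knob of the synthetic-data generator. The defaults describe
#' the package's reference study condition: a toy transcriptome of 2,000
#' transcripts carrying 500 planted ABE-induced edits (100 inside the
#' TACGA/UACGA deaminase motif, 400 at unconstrained background adenines) and
#' 50 endogenous A-to-I sites that are edited in the control sample too.
#' Editing efficiencies are Beta-distributed: background edits are strongly
#' concentrated near zero (most off-target RNA edits have <10% efficiency),
#' motif edits are shifted towards high efficiency, and endogenous sites are
#' drawn above 10% (an endogenous edit is, by definition, detectable in the
#' control). Sequencing depth per site is negative binomial truncated at 1,
#' and base-calling noise is a symmetric substitution error applied to
#' already quality-filtered counts.
#'
#' @param n_transcripts Number of transcripts in the toy transcriptome.
#' @param transcript_length Length range (min, max) in nt, drawn uniformly.
#' @param motif_site_count Planted edits with 5' context TACG (edited A last).
#' @param background_site_count Planted edits at unconstrained adenines.
#' @param endogenous_site_count Planted endogenous A-to-I sites (edited in
#'   both samples and excluded from the editor-specific truth).
#' @param motif_eff_shape,background_eff_shape,endogenous_eff_shape Beta
#'   shape pairs (alpha, beta) for per-class true editing efficiencies.
#' @param endogenous_min_efficiency Lower truncation for endogenous
#'   efficiencies.
#' @param mean_depth,depth_dispersion Negative-binomial depth model
#'   (`mu`, `size`), truncated at depth >= 1.
#' @param fixed_depth If non-`NULL`, use this constant depth at every site
#'   instead of the negative binomial (useful for controlled experiments).
#' @param per_base_error_rate Probability that a read base is miscalled;
#'   the error is distributed evenly over the three non-reference bases.
#' @param seed Integer seed; fixes all generator output bit-for-bit.
#' @return A validated list of class `sim_params`.
#' @export
#' @examples
#' p <- sim_params(n_transcripts = 20, motif_site_count = 5,
#'                 background_site_count = 10, endogenous_site_count = 2)
#' sim <- simulate_transcriptome(p)
#' nrow(sim$truth)
sim_params <- function(n_transcripts = 2000,
                       transcript_length = c(200, 500),
                       motif_site_count = 100,
                       background_site_count = 400,
                       endogenous_site_count = 50,
                       motif_eff_shape = c(2, 2),
                       background_eff_shape = c(0.05, 4),
                       endogenous_eff_shape = c(2, 3),
                       endogenous_min_efficiency = 0.10,
                       mean_depth = 50,
                       depth_dispersion = 20,
                       fixed_depth = NULL,
                       per_base_error_rate = 1e-4,
                       seed = 1L) {
  p <- list(
    n_transcripts = as.integer(n_transcripts),
    transcript_length = as.integer(transcript_length),
    motif_site_count = as.integer(motif_site_count),
    background_site_count = as.integer(background_site_count),
    endogenous_site_count = as.integer(endogenous_site_count),
    motif_eff_shape = as.numeric(motif_eff_shape),
    background_eff_shape = as.numeric(background_eff_shape),
    endogenous_eff_shape = as.numeric(endogenous_eff_shape),
    endogenous_min_efficiency = as.numeric(endogenous_min_efficiency),
    mean_depth = as.numeric(mean_depth),
    depth_dispersion = as.numeric(depth_dispersion),
    fixed_depth = if (is.null(fixed_depth)) NULL else as.integer(fixed_depth),
    per_base_error_rate = as.numeric(per_base_error_rate),
    seed = as.integer(seed)
  )
  counts <- c(p$n_transcripts, p$motif_site_count, p$background_site_count,
              p$endogenous_site_count)
  if (any(is.na(counts)) || any(counts < 0)) {
    abort("n_transcripts and site counts must be non-negative integers")
  }
  if (length(p$transcript_length) != 2L || any(p$transcript_length < 1L) ||
      p$transcript_length[1] > p$transcript_length[2]) {
    abort("transcript_length must be an increasing (min, max) pair of positive lengths")
  }
  if (p$per_base_error_rate < 0 || p$per_base_error_rate > 1) {
    abort("per_base_error_rate must lie in [0, 1]")
  }
  if (p$endogenous_min_efficiency < 0 || p$endogenous_min_efficiency > 1) {
    abort("endogenous_min_efficiency must lie in [0, 1]")
  }
  if (p$mean_depth <= 0 || p$depth_dispersion <= 0) {
    abort("mean_depth and depth_dispersion must be positive")
  }
  if (is.na(p$seed)) abort("seed must be an integer")
  structure(p, class = "sim_params")
}

# minimum spacing between planted sites; keeps 9-nt context windows disjoint
.SITE_SPACING <- 9L

#' Simulate a toy transcriptome with planted ground-truth edits
#'
#' Generates random transcript sequences laid out without overlap on a small
#' set of chromosomes (roughly half on the minus strand), then plants edit
#' sites: motif sites receive the DNA context `TACGA` (edited A as the final
#' base, transcript orientation), background and endogenous sites are forced
#' to A with an unconstrained context. True efficiencies are drawn from the
#' class-specific Beta distributions in `params`. Planted sites are spaced at
#' least 9 nt apart so context windows never collide, and a background site
#' whose 5' context happens to spell TACG is perturbed so that
#' `motif_site == TRUE` identifies exactly the planted motif sites.
#'
#' @param params A [sim_params()] object.
#' @param dir Optional directory; when given, writes `transcripts.fasta`,
#'   `transcripts.bed` and `truth.tsv` there.
#' @return A list with two tibbles: `transcripts` (id, chrom, start, end,
#'   strand, sequence in transcript orientation) and `truth` (chrom, pos,
#'   transcript_id, strand, tx_pos, true_efficiency, motif_site, endogenous,
#'   class).
#' @export
simulate_transcriptome <- function(params = sim_params(), dir = NULL) {
  stopifnot(inherits(params, "sim_params"))
  withr::with_seed(params$seed, .simulate_transcriptome(params, dir))
}

.simulate_transcriptome <- function(params, dir) {
  n <- params$n_transcripts
  n_sites <- params$motif_site_count + params$background_site_count +
    params$endogenous_site_count
  if (n == 0L) {
    tx <- tibble::tibble(id = character(), chrom = character(),
                         start = integer(), end = integer(),
                         strand = character(), sequence = character())
    truth <- .empty_truth()
    if (n_sites > 0L) abort("cannot place planted sites in an empty transcriptome")
    out <- list(transcripts = tx, truth = truth)
    if (!is.null(dir)) .write_sim(out, dir, params)
    return(out)
  }

  lens <- sample(params$transcript_length[1]:params$transcript_length[2],
                 n, replace = TRUE)
  # capacity check: each planted site needs a 4-nt flank on both sides and
  # 9-nt spacing from its neighbours
  capacity <- sum(pmax(0L, (lens - 2L * 4L) %/% .SITE_SPACING))
  if (n_sites > capacity) {
    abort(sprintf(
      "transcripts too short to host %d planted sites (capacity %d); increase lengths or transcript count",
      n_sites, capacity))
  }

  n_chrom <- min(5L, n)
  chrom_of <- sprintf("chr%d", rep_len(seq_len(n_chrom), n))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  seqs <- vapply(lens, function(L) {
    paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
  }, character(1))

  # sequential layout with a 100-nt intergenic gap per chromosome
  tx <- tibble::tibble(
    id = sprintf("tx%04d", seq_len(n)),
    chrom = chrom_of, len = lens, strand = strand, sequence = seqs
  ) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(
      start = cumsum(dplyr::lag(.data$len + 100L, default = 1L)),
      end = .data$start + .data$len - 1L
    ) |>
    dplyr::ungroup()

  truth <- .plant_sites(tx, params)
  tx$sequence <- truth$sequences
  out <- list(
    transcripts = dplyr::select(tx, "id", "chrom", "start", "end", "strand",
                                "sequence"),
    truth = truth$truth
  )
  if (!is.null(dir)) .write_sim(out, dir, params)
  out
}

.empty_truth <- function() {
  tibble::tibble(chrom = character(), pos = integer(),
                 transcript_id = character(), strand = character(),
                 tx_pos = integer(), true_efficiency = numeric(),
                 motif_site = logical(), endogenous = logical(),
                 class = character())
}

.plant_sites <- function(tx, params) {
  classes <- c(rep("motif", params$motif_site_count),
               rep("background", params$background_site_count),
               rep("endogenous", params$endogenous_site_count))
  n_sites <- length(classes)
  seq_chars <- strsplit(tx$sequence, "")
  if (n_sites == 0L) {
    return(list(truth = .empty_truth(),
                sequences = vapply(seq_chars, paste, character(1), collapse = "")))
  }

  taken <- vector("list", nrow(tx))  # planted tx positions per transcript
  picked_tx <- integer(n_sites)
  picked_pos <- integer(n_sites)
  w <- pmax(0, tx$end - tx$start + 1L - 8L)
  filled <- 0L
  guard <- 0L
  while (filled < n_sites) {
    guard <- guard + 1L
    if (guard > 200L) abort("failed to place planted sites; transcriptome too crowded")
    need <- n_sites - filled
    cand_tx <- sample.int(nrow(tx), 3L * need, replace = TRUE, prob = w)
    L <- tx$end[cand_tx] - tx$start[cand_tx] + 1L
    cand_pos <- 5L + floor(runif(length(cand_tx)) * (L - 8L))
    for (k in seq_along(cand_tx)) {
      i <- cand_tx[k]; p <- cand_pos[k]
      if (length(taken[[i]]) && any(abs(taken[[i]] - p) < .SITE_SPACING)) next
      taken[[i]] <- c(taken[[i]], p)
      filled <- filled + 1L
      picked_tx[filled] <- i
      picked_pos[filled] <- p
      if (filled == n_sites) break
    }
  }

  # plant contexts into the transcript-orientation sequences
  for (k in seq_len(n_sites)) {
    i <- picked_tx[k]; p <- picked_pos[k]
    if (classes[k] == "motif") {
      seq_chars[[i]][(p - 4L):p] <- c("T", "A", "C", "G", "A")
    } else {
      seq_chars[[i]][p] <- "A"
      ctx <- paste(seq_chars[[i]][(p - 4L):(p - 1L)], collapse = "")
      if (ctx == "TACG") seq_chars[[i]][p - 1L] <- "T"  # break accidental motif
    }
  }

  eff <- numeric(n_sites)
  m <- classes == "motif"
  b <- classes == "background"
  e <- classes == "endogenous"
  eff[m] <- rbeta(sum(m), params$motif_eff_shape[1], params$motif_eff_shape[2])
  eff[b] <- rbeta(sum(b), params$background_eff_shape[1], params$background_eff_shape[2])
  # endogenous efficiencies truncated from below via inverse-CDF sampling
  lo <- stats::pbeta(params$endogenous_min_efficiency,
                     params$endogenous_eff_shape[1], params$endogenous_eff_shape[2])
  eff[e] <- stats::qbeta(lo + runif(sum(e)) * (1 - lo),
                         params$endogenous_eff_shape[1], params$endogenous_eff_shape[2])

  strand <- tx$strand[picked_tx]
  pos <- ifelse(strand == "+",
                tx$start[picked_tx] + picked_pos - 1L,
                tx$end[picked_tx] - picked_pos + 1L)
  truth <- tibble::tibble(
    chrom = tx$chrom[picked_tx],
    pos = as.integer(pos),
    transcript_id = tx$id[picked_tx],
    strand = strand,
    tx_pos = picked_pos,
    true_efficiency = eff,
    motif_site = m,
    endogenous = e,
    class = classes
  ) |>
    dplyr::arrange(.data$chrom, .data$pos)
  list(truth = truth,
       sequences = vapply(seq_chars, paste, character(1), collapse = ""))
}

.write_sim <- function(sim, dir, params) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_transcriptome(sim$transcripts,
                      fasta = file.path(dir, "transcripts.fasta"),
                      bed = file.path(dir, "transcripts.bed"))
  write_table_with_header(sim$truth, file.path(dir, "truth.tsv"),
                          pkg_header(seed = params$seed))
  invisible(sim)
}

#' Simulate treated and control pileup tables
#'
#' Produces per-position quality-filtered base counts on the reference plus
#' strand for every transcript position. At a planted site with true
#' efficiency `e`, edited reads are Binomial(depth, e); every unedited read
#' can be miscalled to each non-reference base at `per_base_error_rate / 3`.
#' Endogenous sites are edited in both samples (same true efficiency);
#' editor-specific sites only in the treated sample. Edits in minus-strand
#' genes appear on the plus strand as T-to-C.
#'
#' @param tx Transcript tibble from [simulate_transcriptome()].
#' @param truth Ground-truth tibble from [simulate_transcriptome()].
#' @param params A [sim_params()] object (depth, error and seed are used).
#' @return A list with tibbles `treated` and `control`, each with columns
#'   chrom, pos, ref, depth, countA, countC, countG, countT.
#' @export
simulate_pileups <- function(tx, truth, params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  if (nrow(truth)) {
    bad <- dplyr::anti_join(
      truth, tx, by = dplyr::join_by("transcript_id" == "id"))
    if (nrow(bad)) abort("truth sites reference unknown transcripts")
  }
  withr::with_seed(params$seed + 1L, {
    base <- .pileup_frame(tx)
    eff_treated <- .site_efficiency(base, truth, endogenous_only = FALSE)
    eff_control <- .site_efficiency(base, truth, endogenous_only = TRUE)
    list(
      treated = .draw_counts(base, eff_treated, params),
      control = .draw_counts(base, eff_control, params)
    )
  })
}

# one row per transcript position, reference plus-strand ref base
.pileup_frame <- function(tx) {
  if (nrow(tx) == 0L) {
    return(tibble::tibble(chrom = character(), pos = integer(),
                          ref = character(), strand = character()))
  }
  chars <- strsplit(tx$sequence, "")
  plus <- Map(function(ch, s) {
    if (s == "+") ch else rev(chartr("ACGT", "TGCA", ch))
  }, chars, tx$strand)
  lens <- lengths(plus)
  tibble::tibble(
    chrom = rep(tx$chrom, lens),
    pos = as.integer(unlist(Map(seq.int, tx$start, tx$end))),
    ref = unlist(plus),
    strand = rep(tx$strand, lens)
  )
}

.site_efficiency <- function(base, truth, endogenous_only) {
  eff <- numeric(nrow(base))
  if (!nrow(truth)) return(eff)
  t2 <- if (endogenous_only) truth[truth$endogenous, ] else truth
  if (!nrow(t2)) return(eff)
  key <- paste(base$chrom, base$pos)
  idx <- match(paste(t2$chrom, t2$pos), key)
  eff[idx] <- t2$true_efficiency
  eff
}

.draw_counts <- function(base, eff, params) {
  n <- nrow(base)
  out <- tibble::tibble(chrom = base$chrom, pos = base$pos, ref = base$ref)
  if (n == 0L) {
    out$depth <- integer()
    out[c("countA", "countC", "countG", "countT")] <- integer()
    return(out)
  }
  if (!is.null(params$fixed_depth)) {
    depth <- rep(params$fixed_depth, n)
  } else {
    # zero-truncated negative binomial via inverse CDF
    p0 <- pnbinom(0, mu = params$mean_depth, size = params$depth_dispersion)
    depth <- qnbinom(p0 + runif(n) * (1 - p0),
                     mu = params$mean_depth, size = params$depth_dispersion)
    depth <- pmax(depth, 1L)
  }
  err <- params$per_base_error_rate
  n_edit <- rbinom(n, depth, eff)
  n_err <- rbinom(n, depth - n_edit, err)
  e1 <- rbinom(n, n_err, 1 / 3)
  e2 <- rbinom(n, n_err - e1, 1 / 2)
  e3 <- n_err - e1 - e2

  counts <- matrix(0L, nrow = n, ncol = 4L, dimnames = list(NULL, DNA_BASES))
  ref_idx <- match(base$ref, DNA_BASES)
  counts[cbind(seq_len(n), ref_idx)] <- depth - n_edit - n_err
  # edited base: G in transcript orientation = G (+) / C (-) on plus strand
  alt_idx <- ifelse(base$strand == "+", 3L, 2L)
  has_edit <- n_edit > 0L
  if (any(has_edit)) {
    i <- which(has_edit)
    counts[cbind(i, alt_idx[i])] <- counts[cbind(i, alt_idx[i])] + n_edit[i]
  }
  # distribute errors over the three non-reference channels
  nonref_table <- rbind(c(2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 4L), c(1L, 2L, 3L))
  nonref <- nonref_table[ref_idx, , drop = FALSE]
  counts[cbind(seq_len(n), nonref[, 1])] <- counts[cbind(seq_len(n), nonref[, 1])] + e1
  counts[cbind(seq_len(n), nonref[, 2])] <- counts[cbind(seq_len(n), nonref[, 2])] + e2
  counts[cbind(seq_len(n), nonref[, 3])] <- counts[cbind(seq_len(n), nonref[, 3])] + e3

  out$depth <- as.integer(depth)
  out$countA <- counts[, "A"]
  out$countC <- counts[, "C"]
  out$countG <- counts[, "G"]
  out$countT <- counts[, "T"]
  out
}

#' Simulate amplicon deep-sequencing reads with a planted editing profile
#'
#' Each read derives from the amplicon reference. At every profiled
#' protospacer adenine the read independently carries G with the profiled
#' probability, or an A-to-nonG byproduct (C or T, equally likely) with
#' probability `nong_rate`. A fraction `indel_rate` of reads receives one
#' insertion or deletion of 1-3 nt at a uniform position inside the
#' protospacer; sequencing error substitutes any base at `error_rate`.
#' Positions use PAM-distal numbering (position 1 = most PAM-distal
#' nucleotide) and are mapped through the protospacer strand.
#'
#' @param target An [amplicon_target()].
#' @param profile Named numeric vector: names are protospacer positions
#'   (1-20, PAM-distal numbering), values are A-to-G probabilities. Profiled
#'   positions must be adenines in protospacer orientation.
#' @param nong_rate,indel_rate,error_rate Per-read/-base rates in `[0, 1]`.
#' @param n_reads Number of reads.
#' @param seed Integer seed.
#' @param path Optional FASTQ path (Sanger Phred+33, constant Q30).
#' @return Tibble with columns `read_id`, `sequence`; attribute
#'   `indel_reads` marks the reads that carry a planted protospacer indel.
#' @export
simulate_amplicon_reads <- function(target, profile, nong_rate = 0,
                                    indel_rate = 0, error_rate = 0,
                                    n_reads, seed = 1L, path = NULL) {
  stopifnot(inherits(target, "amplicon_target"))
  prof <- .check_profile(target, profile)
  rates <- c(nong_rate, indel_rate, error_rate)
  if (any(rates < 0 | rates > 1)) abort("rates must lie in [0, 1]")
  reads <- withr::with_seed(as.integer(seed), {
    .sim_reads(target, prof, nong_rate, indel_rate, error_rate, as.integer(n_reads))
  })
  if (!is.null(path)) write_fastq(reads, path)
  reads
}

.check_profile <- function(target, profile) {
  if (length(profile) == 0L) {
    return(tibble::tibble(position = integer(), prob = numeric(),
                          amp_pos = integer()))
  }
  pos <- as.integer(names(profile))
  if (anyNA(pos) || any(pos < 1L | pos > 20L)) {
    abort("profile names must be protospacer positions 1-20")
  }
  if (any(profile < 0 | profile > 1)) abort("profile probabilities must lie in [0, 1]")
  amp_pos <- protospacer_to_amplicon(target, pos)
  ref <- strsplit(target$sequence, "")[[1]][amp_pos]
  ps_ref <- if (target$strand == "+") ref else complement_base(ref)
  if (any(ps_ref != "A")) {
    abort("profiled protospacer positions must be adenines in protospacer orientation")
  }
  tibble::tibble(position = pos, prob = as.numeric(profile), amp_pos = amp_pos)
}

.sim_reads <- function(target, prof, nong_rate, indel_rate, error_rate, n_reads) {
  tmpl <- strsplit(target$sequence, "")[[1]]
  L <- length(tmpl)
  if (n_reads == 0L) {
    return(tibble::tibble(read_id = character(), sequence = character()))
  }
  mat <- matrix(rep(tmpl, each = n_reads), nrow = n_reads)
  minus <- target$strand == "-"
  for (k in seq_len(nrow(prof))) {
    u <- runif(n_reads)
    p <- prof$prob[k]
    j <- prof$amp_pos[k]
    conv_g <- u < p
    conv_non <- !conv_g & u < p + nong_rate
    # A->G reads as G on the protospacer strand; on the amplicon sequence a
    # minus-strand protospacer shows the complement
    if (any(conv_g)) mat[conv_g, j] <- if (minus) "C" else "G"
    if (any(conv_non)) {
      nb <- sample(c("C", "T"), sum(conv_non), replace = TRUE)
      mat[conv_non, j] <- if (minus) complement_base(nb) else nb
    }
  }
  if (error_rate > 0) {
    hit <- which(runif(n_reads * L) < error_rate)
    if (length(hit)) {
      cur <- mat[hit]
      sub <- vapply(cur, function(b) sample(setdiff(DNA_BASES, b), 1L), character(1))
      mat[hit] <- sub
    }
  }
  seqs <- apply(mat, 1L, paste, collapse = "")

  has_indel <- runif(n_reads) < indel_rate
  ps <- c(target$protospacer_start, target$protospacer_end)
  for (i in which(has_indel)) {
    len <- sample(1:3, 1L)
    if (runif(1) < 0.5 && ps[2] - ps[1] + 1L > len) {       # deletion
      s <- sample(ps[1]:(ps[2] - len + 1L), 1L)
      seqs[i] <- paste0(substr(seqs[i], 1L, s - 1L),
                        substr(seqs[i], s + len, L))
    } else {                                                 # insertion
      s <- sample(ps[1]:(ps[2] - 1L), 1L)  # insert after position s
      ins <- paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
      seqs[i] <- paste0(substr(seqs[i], 1L, s), ins, substr(seqs[i], s + 1L, L))
    }
  }
  out <- tibble::tibble(
    read_id = sprintf("read%06d", seq_len(n_reads)),
    sequence = seqs
  )
  attr(out, "indel_reads") <- which(has_indel)
  out
}
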