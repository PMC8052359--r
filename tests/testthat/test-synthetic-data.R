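test_that("transcriptome generator is deterministic, handles the empty case, and plants motifs verifiably", {
  p <- sim_params(n_transcripts = 0, motif_site_count = 0,
                  background_site_count = 0, endogenous_site_count = 0)
  empty <- simulate_transcriptome(p)
  expect_identical(nrow(empty$transcripts), 0L)
  expect_identical(nrow(empty$truth), 0L)
  d <- withr::local_tempdir()
  simulate_transcriptome(p, dir = d)  # valid empty FASTA/BED
  expect_true(file.exists(file.path(d, "transcripts.fasta")))
  expect_identical(nrow(read_transcriptome(file.path(d, "transcripts.fasta"),
                                           file.path(d, "transcripts.bed"))), 0L)

  p <- sim_params(n_transcripts = 60, motif_site_count = 10,
                  background_site_count = 20, endogenous_site_count = 5,
                  seed = 13)
  s1 <- simulate_transcriptome(p)
  s2 <- simulate_transcriptome(p)
  expect_identical(s1, s2)

  # structural invariants
  tx <- s1$transcripts
  expect_identical(nchar(tx$sequence), tx$end - tx$start + 1L)
  expect_false(any(duplicated(tx$id)))
  by_chrom <- split(tx[order(tx$start), ], tx$chrom[order(tx$start)])
  for (g in by_chrom) {
    if (nrow(g) > 1L) expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  }
  expect_gt(mean(tx$strand == "-"), 0.25)
  expect_lt(mean(tx$strand == "-"), 0.75)

  # independent string search: exactly the planted motif sites carry TACGA
  truth <- s1$truth
  expect_identical(sum(truth$motif_site), 10L)
  ctx5 <- vapply(seq_len(nrow(truth)), function(i) {
    s <- tx$sequence[tx$id == truth$transcript_id[i]]
    substr(s, truth$tx_pos[i] - 4L, truth$tx_pos[i])
  }, character(1))
  expect_identical(ctx5 == "TACGA", truth$motif_site)
  expect_true(all(substr(ctx5, 5, 5) == "A"))
  expect_true(all(truth$true_efficiency >= 0 & truth$true_efficiency <= 1))

  # sizing error when transcripts cannot host the requested sites
  expect_error(
    simulate_transcriptome(sim_params(n_transcripts = 2,
                                      transcript_length = c(10, 12),
                                      motif_site_count = 50,
                                      background_site_count = 0,
                                      endogenous_site_count = 0)),
    "too short")
})

test_that("pileups respect depth sums, strand convention and endogenous sharing", {
  p <- sim_params(n_transcripts = 40, motif_site_count = 5,
                  background_site_count = 10, endogenous_site_count = 5,
                  seed = 21)
  sim <- simulate_transcriptome(p)
  piles <- simulate_pileups(sim$transcripts, sim$truth, p)
  for (tab in piles) {
    expect_true(all(tab$depth ==
                      tab$countA + tab$countC + tab$countG + tab$countT))
    expect_true(all(tab$depth >= 1L))
  }
  expect_identical(piles$treated[c("chrom", "pos", "ref")],
                   piles$control[c("chrom", "pos", "ref")])

  # minus-strand-gene edits appear as T ref / C alt on the plus strand
  minus <- dplyr::semi_join(
    piles$treated,
    dplyr::filter(sim$truth, strand == "-", true_efficiency > 0.3),
    by = c("chrom", "pos"))
  expect_true(all(minus$ref == "T"))
  expect_true(all(minus$countC > 0))

  # endogenous sites carry signal in both samples; editor-specific sites
  # carry at most sequencing error in the control
  endo <- dplyr::filter(sim$truth, endogenous, true_efficiency > 0.2)
  alt_of <- function(tab, sites) {
    j <- dplyr::semi_join(tab, sites, by = c("chrom", "pos"))
    j <- j[order(j$chrom, j$pos), ]
    ifelse(j$ref == "A", j$countG, j$countC)
  }
  expect_true(all(alt_of(piles$treated, endo) > 0))
  expect_true(all(alt_of(piles$control, endo) > 0))
  spec <- dplyr::filter(sim$truth, !endogenous, true_efficiency > 0.2)
  expect_true(all(alt_of(piles$control, spec) <= 2))

  # zero efficiency and zero error: every read supports the reference
  p0 <- sim_params(n_transcripts = 10, motif_site_count = 0,
                   background_site_count = 0, endogenous_site_count = 0,
                   per_base_error_rate = 0, seed = 5)
  sim0 <- simulate_transcriptome(p0)
  piles0 <- simulate_pileups(sim0$transcripts, sim0$truth, p0)
  ref_count <- with(piles0$treated,
                    cbind(countA, countC, countG, countT)[
                      cbind(seq_len(nrow(piles0$treated)),
                            match(ref, c("A", "C", "G", "T")))])
  expect_identical(as.integer(ref_count), piles0$treated$depth)
})

test_that("planted efficiency is recovered within binomial tolerance at high depth", {
  # one plus-strand site, e = 0.5, depth forced to 10,000, no error
  tx <- tibble::tibble(id = "t1", chrom = "chr1", start = 1L, end = 50L,
                       strand = "+",
                       sequence = paste(rep("A", 50), collapse = ""))
  truth <- tibble::tibble(chrom = "chr1", pos = 25L, transcript_id = "t1",
                          strand = "+", tx_pos = 25L, true_efficiency = 0.5,
                          motif_site = FALSE, endogenous = FALSE,
                          class = "background")
  p <- sim_params(n_transcripts = 1, motif_site_count = 0,
                  background_site_count = 1, endogenous_site_count = 0,
                  fixed_depth = 10000L, per_base_error_rate = 0, seed = 77)
  piles <- simulate_pileups(tx, truth, p)
  site <- piles$treated[piles$treated$pos == 25L, ]
  expect_identical(site$depth, 10000L)
  tol <- 3 * sqrt(0.5 * 0.5 / 10000)
  expect_lt(abs(site$countG / site$depth - 0.5), tol)

  # empirical mean of the alt count over replicate draws matches Binomial
  p100 <- sim_params(n_transcripts = 1, motif_site_count = 0,
                     background_site_count = 1, endogenous_site_count = 0,
                     fixed_depth = 100L, per_base_error_rate = 0, seed = 1)
  alts <- vapply(1:300, function(s) {
    p100$seed <- s
    pp <- simulate_pileups(tx, truth, p100)
    pp$treated$countG[pp$treated$pos == 25L]
  }, integer(1))
  expect_true(all(alts >= 0 & alts <= 100))
  se <- sqrt(100 * 0.25) / sqrt(300)
  expect_lt(abs(mean(alts) - 50), 3 * se)
})

test_that("amplicon read generator honours planted conversion, indel and empty cases", {
  amp <- amplicon_target(
    paste0(strrep("C", 20), "GATTAAAGAATCAGCAATGC", strrep("G", 20)), 21, 40)

  empty <- simulate_amplicon_reads(amp, c(`5` = 0.5), n_reads = 0, seed = 1)
  expect_identical(nrow(empty), 0L)
  f <- withr::local_tempfile(fileext = ".fastq")
  simulate_amplicon_reads(amp, c(`5` = 0.5), n_reads = 0, seed = 1, path = f)
  expect_identical(nrow(read_fastq(f)), 0L)

  # indel_rate = 1: every read changes length (insertions and deletions of
  # 1-3 nt never cancel within one read)
  ind <- simulate_amplicon_reads(amp, c(`5` = 0), indel_rate = 1,
                                 n_reads = 200, seed = 2)
  expect_true(all(nchar(ind$sequence) != nchar(amp$sequence)))

  # planted A->G probability recovered by direct string counting
  rd <- simulate_amplicon_reads(amp, c(`5` = 0.6), n_reads = 10000, seed = 3)
  j <- protospacer_to_amplicon(amp, 5L)
  frac_g <- mean(substr(rd$sequence, j, j) == "G")
  expect_lt(abs(frac_g - 0.6), 3 * sqrt(0.6 * 0.4 / 10000))

  # determinism and FASTQ round trip
  r1 <- simulate_amplicon_reads(amp, c(`5` = 0.6), indel_rate = 0.1,
                                error_rate = 1e-3, n_reads = 100, seed = 9)
  r2 <- simulate_amplicon_reads(amp, c(`5` = 0.6), indel_rate = 0.1,
                                error_rate = 1e-3, n_reads = 100, seed = 9)
  expect_identical(r1, r2)
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(r1, f2)
  expect_identical(read_fastq(f2)$sequence, r1$sequence)

  # profiled positions must be adenines; rates must be probabilities
  expect_error(simulate_amplicon_reads(amp, c(`1` = 0.5), n_reads = 1),
               "adenines")
  expect_error(simulate_amplicon_reads(amp, c(`5` = 1.5), n_reads = 1),
               "\\[0, 1\\]")
})
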