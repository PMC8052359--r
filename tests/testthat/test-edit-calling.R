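test_that("calling filters enforce depth, control purity and transcript-strand A-to-G", {
  tx <- tiny_tx()
  ok_ctl <- pileup_row("chr1", 150, "A", a = 100)

  expect_identical(nrow(call_edits(pileup_row("chr1", 1, "A")[0, ],
                                   ok_ctl[0, ], tx)), 0L)

  # depth 9 with 9 alt reads: below the 10x depth floor
  tr <- pileup_row("chr1", 150, "A", g = 9)
  expect_identical(nrow(call_edits(tr, ok_ctl, tx)), 0L)

  # fully edited treated site, but control only 98% reference: excluded
  tr <- pileup_row("chr1", 150, "A", g = 100)
  ctl_98 <- pileup_row("chr1", 150, "A", a = 98, g = 2)
  expect_identical(nrow(call_edits(tr, ctl_98, tx)), 0L)
  ctl_99 <- pileup_row("chr1", 150, "A", a = 99, g = 1)
  called <- call_edits(tr, ctl_99, tx)
  expect_identical(nrow(called), 1L)
  expect_identical(called$efficiency, 1)
  expect_identical(called$strand, "+")

  # minus-strand gene: T ref / C alt on the plus strand becomes an A-to-G call
  tr_m <- pileup_row("chr1", 350, "T", t = 40, c = 10)
  ctl_m <- pileup_row("chr1", 350, "T", t = 50)
  called_m <- call_edits(tr_m, ctl_m, tx)
  expect_identical(nrow(called_m), 1L)
  expect_identical(called_m$strand, "-")
  expect_identical(called_m$ref, "A")
  expect_equal(called_m$efficiency, 0.2)
  # the same pattern with G alts (wrong strand) is not an edit
  tr_g <- pileup_row("chr1", 350, "T", t = 40, g = 10)
  expect_identical(nrow(call_edits(tr_g, ctl_m, tx)), 0L)

  # positions outside every transcript are skipped, not errors
  tr_out <- pileup_row("chr1", 50, "A", g = 50, a = 50)
  expect_identical(nrow(call_edits(tr_out, pileup_row("chr1", 50, "A", a = 100), tx)), 0L)
  # disjoint chromosome names are an error
  expect_error(call_edits(pileup_row("chrX", 150, "A", g = 50),
                          ok_ctl, tx), "chromosome")
})

test_that("call_edits matches a brute-force re-filter on randomized tables", {
  tx <- tiny_tx()
  withr::local_seed(421)
  for (mode in c("somatic_like", "germline_like")) {
    pos <- c(sample(101:200, 30), sample(301:400, 20))
    ref <- ifelse(pos <= 200, sample(c("A", "C", "G"), 50, replace = TRUE),
                  sample(c("T", "C", "G"), 50, replace = TRUE))
    mk <- function() {
      n <- length(pos)
      counts <- matrix(rpois(4 * n, 8), ncol = 4)
      tibble::tibble(chrom = "chr1", pos = as.integer(pos), ref = ref,
                     depth = as.integer(rowSums(counts)),
                     countA = counts[, 1], countC = counts[, 2],
                     countG = counts[, 3], countT = counts[, 4])
    }
    treated <- mk(); control <- mk()
    # make some control sites clean so calls can survive
    clean <- sample(50, 25)
    for (b in c("countA", "countC", "countG", "countT")) control[[b]][clean] <- 0L
    ref_col <- paste0("count", control$ref[clean])
    for (k in seq_along(clean)) control[[ref_col[k]]][clean[k]] <- 40L
    control$depth <- control$countA + control$countC + control$countG + control$countT

    params <- filter_params(mode = mode)
    got <- call_edits(treated, control, tx, params)
    expect_identical(sort(paste(got$chrom, got$pos)),
                     refilter_oracle(treated, control, tx, params))
  }
})

test_that("endogenous subtraction removes exactly the overlapping keys", {
  a <- random_callset(30)
  expect_identical(as.data.frame(subtract_endogenous(a, a[0, ])),
                   as.data.frame(a))
  expect_identical(nrow(subtract_endogenous(a, a)), 0L)
  sub <- a[1:10, ]
  left <- subtract_endogenous(a, sub)
  expect_identical(nrow(left), 20L)
  expect_false(any(paste(left$chrom, left$pos) %in% paste(sub$chrom, sub$pos)))
})

test_that("planted endogenous edits never survive into the final call set", {
  p <- sim_params(n_transcripts = 150, motif_site_count = 10,
                  background_site_count = 20, endogenous_site_count = 15,
                  seed = 31)
  sim <- simulate_transcriptome(p)
  piles <- simulate_pileups(sim$transcripts, sim$truth, p)
  somatic <- call_edits(piles$treated, piles$control, sim$transcripts)
  final <- subtract_endogenous(
    somatic, detect_endogenous(piles$control, sim$transcripts))
  endo_keys <- with(dplyr::filter(sim$truth, endogenous), paste(chrom, pos))
  expect_identical(sum(paste(final$chrom, final$pos) %in% endo_keys), 0L)
})

test_that("call-set algebra satisfies the inclusion-exclusion identity", {
  a <- random_callset(40)
  same <- overlap_callsets(a, a)
  expect_identical(nrow(same$overlapped), nrow(a))
  expect_identical(nrow(same$a_specific), 0L)
  expect_identical(nrow(same$b_specific), 0L)

  b <- a; b$pos <- b$pos + 1000L
  disj <- overlap_callsets(a, b)
  expect_identical(nrow(disj$overlapped), 0L)
  expect_identical(nrow(disj$merged), nrow(a) + nrow(b))

  withr::local_seed(7)
  for (i in 1:25) {
    x <- random_callset(sample(5:200, 1))
    y <- random_callset(sample(5:200, 1))
    o <- overlap_callsets(x, y)
    expect_identical(nrow(o$merged), nrow(x) + nrow(y) - nrow(o$overlapped))
    keys <- function(d) paste(d$chrom, d$pos)
    expect_true(all(keys(o$overlapped) %in% keys(x)))
    expect_true(all(keys(o$overlapped) %in% keys(y)))
    expect_false(any(duplicated(keys(o$merged))))
  }
})

test_that("raising any threshold never increases the number of calls", {
  p <- sim_params(n_transcripts = 80, motif_site_count = 10,
                  background_site_count = 30, endogenous_site_count = 5,
                  seed = 55)
  sim <- simulate_transcriptome(p)
  piles <- simulate_pileups(sim$transcripts, sim$truth, p)
  n_calls <- function(...) {
    nrow(call_edits(piles$treated, piles$control, sim$transcripts,
                    filter_params(...)))
  }
  for (field in list(
    list(min_depth = c(1L, 10L, 30L, 60L)),
    list(min_alt_reads = c(0L, 2L, 5L, 10L)),
    list(min_alt_fraction = c(0, 0.01, 0.05, 0.2)),
    list(control_ref_fraction = c(0.9, 0.95, 0.99, 1))
  )) {
    ns <- vapply(field[[1]], function(v) {
      do.call(n_calls, setNames(list(v), names(field)))
    }, integer(1))
    expect_true(all(diff(ns) <= 0))
  }
  # germline-like calls are nested in somatic-like calls
  som <- call_edits(piles$treated, piles$control, sim$transcripts,
                    filter_params(mode = "somatic_like"))
  ger <- call_edits(piles$treated, piles$control, sim$transcripts,
                    filter_params(mode = "germline_like"))
  expect_true(all(paste(ger$chrom, ger$pos) %in% paste(som$chrom, som$pos)))
})

test_that("VCF ingestion keeps transcript-orientation A-to-G SNVs only", {
  tx <- tiny_tx()
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Depths\">",
           "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"Fraction\">",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "s1", sep = "\t"))
  rec <- function(chrom, pos, ref, alt, fmt = "GT:AF", val = "0/1:0.25") {
    paste(chrom, pos, ".", ref, alt, "50", "PASS", ".", fmt, val, sep = "\t")
  }
  recs <- c(
    rec("chr1", 110, "A", "G"),            # + gene, kept (AF 0.25)
    rec("chr1", 120, "C", "T"),            # wrong change, dropped
    rec("chr1", 130, "T", "C"),            # T>C in + gene, dropped
    rec("chr1", 310, "T", "C", "GT:AD", "0/1:30,10"),  # - gene, kept (AD)
    rec("chr1", 320, "A", "G"),            # A>G in - gene, dropped
    rec("chr1", 330, "G", "A"),            # dropped
    rec("chr1", 50, "A", "G"),             # outside transcripts, dropped
    rec("chr1", 150, "A", "AG"),           # indel, dropped
    rec("chr1", 340, "TA", "T"),           # indel, dropped
    rec("chr1", 160, "A", "G", "GT", "0/1")  # kept, efficiency NA
  )
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(hdr, recs), f)
  cs <- read_callset_vcf(f, tx, sample_id = "mutect")
  expect_identical(cs$pos, c(110L, 160L, 310L))
  expect_identical(cs$strand, c("+", "+", "-"))
  expect_equal(cs$efficiency, c(0.25, NA, 0.25))
  expect_identical(unique(cs$ref), "A")

  bad <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(hdr, recs[1], "chr1\t10\tbroken"), bad)
  expect_error(read_callset_vcf(bad, tx), "line 7")
})

test_that("sensitivity fold reflects the efficiency floor of germline-like calling", {
  tx <- tiny_tx()
  # every edit at 50% efficiency: both modes call everything, fold == 1
  pos <- as.integer(101:120)
  tr <- do.call(rbind, lapply(pos, function(p) pileup_row("chr1", p, "A",
                                                          a = 50, g = 50)))
  ctl <- do.call(rbind, lapply(pos, function(p) pileup_row("chr1", p, "A",
                                                           a = 100)))
  r <- sensitivity_fold(tr, ctl, tx)
  expect_identical(r$fold, 1)
  expect_false(r$flagged)
  expect_identical(r$n_somatic, 20L)

  # every edit at 5% efficiency: germline-like finds nothing, flagged result
  tr_low <- do.call(rbind, lapply(pos, function(p) pileup_row("chr1", p, "A",
                                                              a = 95, g = 5)))
  r_low <- sensitivity_fold(tr_low, ctl, tx)
  expect_true(r_low$flagged)
  expect_identical(r_low$n_germline, 0L)
  expect_true(is.na(r_low$fold))
  expect_identical(r_low$n_somatic, 20L)
})
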