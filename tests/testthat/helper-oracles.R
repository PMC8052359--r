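# Independent oracles and fixture builders shared across test files.

# Exhaustive brute-force global alignment score: enumerates every alignment
# as a sequence of diagonal / gap-in-read / gap-in-ref steps. Exponential;
# only for very short sequences.
nw_enumerate <- function(a, b, match = 2, mismatch = -3, gap = -5) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(0)
    best <- -Inf
    if (i > 0 && j > 0) {
      best <- max(best, rec(i - 1, j - 1) +
                    if (A[i] == B[j]) match else mismatch)
    }
    if (j > 0) best <- max(best, rec(i, j - 1) + gap)
    if (i > 0) best <- max(best, rec(i - 1, j) + gap)
    best
  }
  rec(length(A), length(B))
}

# Memoized top-down optimal-score recursion; same optimum as exhaustive
# enumeration but tractable for the ~10^4-pair acceptance sweep. Written
# top-down over suffix moves, independent of the bottom-up C++ matrix fill.
nw_memo <- function(a, b, match = 2, mismatch = -3, gap = -5) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  memo <- matrix(NA_real_, length(A) + 1L, length(B) + 1L)
  rec <- function(i, j) {
    v <- memo[i + 1L, j + 1L]
    if (!is.na(v)) return(v)
    if (i == 0L && j == 0L) {
      v <- 0
    } else {
      v <- -Inf
      if (i > 0L && j > 0L) {
        v <- max(v, rec(i - 1L, j - 1L) +
                   if (A[i] == B[j]) match else mismatch)
      }
      if (j > 0L) v <- max(v, rec(i, j - 1L) + gap)
      if (i > 0L) v <- max(v, rec(i - 1L, j) + gap)
    }
    memo[i + 1L, j + 1L] <<- v
    v
  }
  rec(length(A), length(B))
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

revcomp_chr <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

revcomp_chr_vec <- function(x) vapply(x, revcomp_chr, character(1),
                                      USE.NAMES = FALSE)

# A two-transcript annotation (one per strand) used by hand-built pileup
# fixtures. Sequences are transcript orientation.
tiny_tx <- function() {
  tibble::tibble(
    id = c("txP", "txM"),
    chrom = c("chr1", "chr1"),
    start = c(101L, 301L),
    end = c(200L, 400L),
    strand = c("+", "-"),
    sequence = c(strrep("A", 100), strrep("A", 100))  # all-A in tx orientation
  )
}

# Pileup row builder on the reference plus strand.
pileup_row <- function(chrom, pos, ref, a = 0, c = 0, g = 0, t = 0) {
  tibble::tibble(chrom = chrom, pos = as.integer(pos), ref = ref,
                 depth = as.integer(a + c + g + t),
                 countA = as.integer(a), countC = as.integer(c),
                 countG = as.integer(g), countT = as.integer(t))
}

# Plain-loop re-implementation of the calling filters, used as the
# brute-force oracle for call_edits on hand-built tables. Assumes the
# tiny_tx() annotation (non-overlapping, one transcript per strand).
refilter_oracle <- function(treated, control, tx, params) {
  hits <- character()
  for (r in seq_len(nrow(treated))) {
    row <- treated[r, ]
    tx_hit <- tx[tx$chrom == row$chrom & tx$start <= row$pos & tx$end >= row$pos, ]
    if (nrow(tx_hit) != 1L) next
    ref_tx <- if (tx_hit$strand == "+") row$ref else chartr("ACGT", "TGCA", row$ref)
    if (ref_tx != "A") next
    alt <- if (tx_hit$strand == "+") row$countG else row$countC
    if (row$depth < params$min_depth) next
    if (alt < params$min_alt_reads) next
    if (alt / row$depth < params$min_alt_fraction) next
    ctl <- control[control$chrom == row$chrom & control$pos == row$pos, ]
    if (nrow(ctl) != 1L) next
    if (ctl$depth < params$min_depth) next
    ref_count <- ctl[[paste0("count", ctl$ref)]]
    if (ref_count / ctl$depth < params$control_ref_fraction) next
    if (params$mode == "germline_like" &&
        alt / row$depth < params$germline_min_efficiency) next
    hits <- c(hits, paste(row$chrom, row$pos))
  }
  sort(hits)
}

# Random call-set tibble over a small key space (collisions intended).
random_callset <- function(n, key_space = 400L) {
  pos <- sample.int(key_space, n, replace = FALSE)
  tibble::tibble(
    chrom = "chr1", pos = as.integer(pos),
    transcript_id = "txP", strand = "+", ref = "A", alt = "G",
    efficiency = runif(n, 0.01, 1), depth = 50L,
    alt_reads = 5L, sample_id = "s"
  )
}
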