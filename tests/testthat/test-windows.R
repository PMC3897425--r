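test_that("mappability census matches brute-force substring enumeration", {
  seqs <- list(chrA = "ACGTACGTAC")
  ref <- Biostrings::DNAStringSet(unlist(seqs))
  mapp <- simulate_mappability(ref, read_length = 4, step = 1)
  oracle <- enum_unique_positions(seqs, 4)
  expect_identical(mapp$positions$chrA, oracle[[1]])
  # ACGT occurs twice (and is its own reverse complement): excluded
  expect_false(0L %in% mapp$positions$chrA)
  expect_false(4L %in% mapp$positions$chrA)
  expect_equal(mapp$U_sim, sum(lengths(oracle)))

  # random small genomes, including a two-chromosome case
  set.seed(91)
  for (rep in 1:5) {
    seqs <- list(c1 = paste(sample(c("A", "C", "G", "T"), 60, TRUE),
                            collapse = ""),
                 c2 = paste(sample(c("A", "C", "G", "T"), 40, TRUE),
                            collapse = ""))
    ref <- Biostrings::DNAStringSet(unlist(seqs))
    mapp <- simulate_mappability(ref, read_length = 8, step = 2)
    oracle <- enum_unique_positions(seqs, 8, step = 2)
    expect_identical(mapp$positions$c1, oracle[[1]])
    expect_identical(mapp$positions$c2, oracle[[2]])
  }
})

test_that("fully repetitive and strand-disjoint sequences behave as expected", {
  # every 3-mer of AAAAAA is identical: nothing is unique
  mapp <- simulate_mappability(Biostrings::DNAStringSet(c(chr = "AAAAAA")),
                               read_length = 3)
  expect_equal(mapp$U_sim, 0L)

  # A/C-only de Bruijn-style sequence: all 3-mers distinct, and their
  # reverse complements (G/T-only) never occur, so every position is unique
  s <- "AAACACCCAA"   # de Bruijn sequence: all 8 A/C 3-mers exactly once
  mapp <- simulate_mappability(Biostrings::DNAStringSet(c(chr = s)),
                               read_length = 3)
  expect_identical(mapp$positions$chr, 0:7)
  expect_equal(mapp$U_sim, nchar(s) - 3L + 1L)

  # read longer than every sequence: empty track with a warning
  expect_warning(
    m2 <- simulate_mappability(Biostrings::DNAStringSet(c(chr = "ACGT")),
                               read_length = 10),
    "read_length")
  expect_equal(m2$U_sim, 0L)
})

test_that("window sizing follows the expected-read-count principle", {
  # U_sim = 1000 uniform positions, expected RC 10 at 100 sample reads:
  # n_w = ceiling(10 * 1000 / 100) = 100, ten windows
  mapp <- structure(list(positions = list(chr1 = as.integer(0:999)),
                         read_length = 36L, step = 1L,
                         seqlengths = c(chr1 = 1000L), U_sim = 1000L),
                    class = "pscc_mappability")
  w <- build_windows(mapp, expected_rc = 10, sample_total_reads = 100)
  expect_equal(attr(w, "n_w"), 100L)
  expect_equal(nrow(w), 10L)
  expect_false(any(w$partial))
  # uniform positions force near-equal widths
  widths <- w$end - w$start
  expect_lte(max(widths) / min(widths), 1.02)
  # partition: windows tile the chromosome
  expect_equal(w$start[1], 0L)
  expect_equal(w$end[nrow(w)], 1000L)
  expect_true(all(w$start[-1] == head(w$end, -1)))

  # degenerate: one window holding every position
  w1 <- build_windows(mapp, expected_rc = 1000, sample_total_reads = 1000)
  expect_equal(nrow(w1), 1L)

  # trailing remainder becomes a partial window
  w2 <- build_windows(mapp, expected_rc = 15, sample_total_reads = 100)
  expect_equal(attr(w2, "n_w"), 150L)
  expect_equal(nrow(w2), 7L)
  expect_true(w2$partial[7])
  expect_equal(w2$n_sim[7], 1000L - 6L * 150L)
})

test_that("read counting assigns by leftmost base with half-open windows", {
  mapp <- structure(list(positions = list(chr1 = as.integer(0:19)),
                         read_length = 5L, step = 1L,
                         seqlengths = c(chr1 = 20L), U_sim = 20L),
                    class = "pscc_mappability")
  w <- build_windows(mapp, expected_rc = 5, sample_total_reads = 10)
  expect_equal(nrow(w), 2L)
  expect_equal(w$end[1], 10L)
  # reads at 0-based 5, 9, 15 (SAM POS 6, 10, 16); boundary read at 0-based
  # 10 (SAM POS 11) belongs to the second window under half-open convention
  reads <- data.frame(chrom = "chr1", pos1 = c(6L, 10L, 16L, 11L),
                      seq = c("ACGTA", "GGGGG", "CCCCC", "ATATA"))
  bam <- write_toy_bam(reads, c(chr1 = 20L))
  tr <- count_reads(bam, w)
  expect_equal(tr$count, c(2L, 2L))
  expect_equal(sum(tr$count), nrow(reads))  # conservation
  # per-window GC = mean of read GC fractions
  expect_equal(tr$gc, c(mean(c(2/5, 1)), mean(c(1, 0))))
})

test_that("filters drop low-MAPQ and secondary reads; empty BAMs give zero tracks", {
  mapp <- structure(list(positions = list(chr1 = as.integer(0:19)),
                         read_length = 5L, step = 1L,
                         seqlengths = c(chr1 = 20L), U_sim = 20L),
                    class = "pscc_mappability")
  w <- build_windows(mapp, expected_rc = 10, sample_total_reads = 10)
  reads <- data.frame(chrom = "chr1", pos1 = c(2L, 5L, 8L),
                      seq = c("ACGTA", "ACGTA", "ACGTA"),
                      mapq = c(60L, 0L, 60L),
                      flag = c(0L, 0L, 256L))
  bam <- write_toy_bam(reads, c(chr1 = 20L))
  tr <- count_reads(bam, w, mapq_min = 1)
  expect_equal(sum(tr$count), 1L)   # only the primary, MAPQ-60 read

  ref <- Biostrings::DNAStringSet(c(chr1 = "GGGGGGGGGGAAAAAAAAAA"))
  empty <- write_toy_bam(reads[0, ], c(chr1 = 20L))
  tr0 <- count_reads(empty, w, reference = ref)
  expect_true(all(tr0$count == 0L))
  expect_equal(tr0$gc, 0.5)   # reference fallback GC

  # contig mismatch is a configuration error naming the contig
  reads2 <- data.frame(chrom = "chrZ", pos1 = 3L, seq = "ACGTA")
  bam2 <- write_toy_bam(reads2, c(chrZ = 20L))
  expect_error(count_reads(bam2, w), "chrZ")
})

test_that("paired fragments are counted once via the plus-strand proper read", {
  mapp <- structure(list(positions = list(chr1 = as.integer(0:39)),
                         read_length = 5L, step = 1L,
                         seqlengths = c(chr1 = 40L), U_sim = 40L),
                    class = "pscc_mappability")
  w <- build_windows(mapp, expected_rc = 40, sample_total_reads = 40)
  # one proper pair: flags 99 (plus, first) and 147 (minus, second)
  reads <- data.frame(chrom = "chr1", pos1 = c(3L, 20L),
                      seq = c("ACGTA", "ACGTA"),
                      flag = c(99L, 147L))
  bam <- write_toy_bam(reads, c(chr1 = 40L))
  tr <- count_reads(bam, w)
  expect_equal(sum(tr$count), 1L)
})

test_that("empirical window means converge to the expected read count", {
  set.seed(103)
  # uniformly mappable chromosome, windows sized for expected RC 20
  U <- 60000L
  mapp <- structure(list(positions = list(chr1 = as.integer(seq_len(U) - 1L)),
                         read_length = 36L, step = 1L,
                         seqlengths = c(chr1 = U), U_sim = U),
                    class = "pscc_mappability")
  total_reads <- 120000L
  w <- build_windows(mapp, expected_rc = 20, sample_total_reads = total_reads)
  # draw reads uniformly over mappable starts and count per window
  pos <- sample.int(U, total_reads, replace = TRUE) - 1L
  counts <- tabulate(findInterval(pos, w$start), nbins = nrow(w))
  full <- !w$partial
  se <- sd(counts[full]) / sqrt(sum(full))
  expect_lt(abs(mean(counts[full]) - 20), 3 * se + 1e-9)
})
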