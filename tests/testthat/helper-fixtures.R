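# Shared fixture builders. Everything is generated in code at test time.

# small simulated experiment + corrected panel, reused across tests
tiny_setup <- function(n_chrom = 6, windows_per_chrom = 400, depth = 2,
                       n_controls = 20, seed = 101, gc_bias = TRUE,
                       multiplex_sd = 0.1, overdispersion = 1.2) {
  cfg <- sim_config(n_chrom = n_chrom, windows_per_chrom = windows_per_chrom,
                    depth = depth, n_controls = n_controls, seed = seed,
                    gc_bias = gc_bias, multiplex_sd = multiplex_sd,
                    overdispersion = overdispersion)
  xp <- sim_experiment(cfg)
  ctrl <- lapply(generate_panel_tracks(xp), gc_correct, min_bin = 20)
  panel <- build_panel(ctrl)
  list(cfg = cfg, xp = xp, ctrl = ctrl, panel = panel,
       params = pscc_params(gc_min_bin = 20))
}

# hand-rolled counts track on explicit values
toy_track <- function(counts, gc, chrom = "chr1", width = 1000L,
                      usable = TRUE, sample_id = "toy") {
  n <- length(counts)
  start <- width * (seq_len(n) - 1L)
  out <- data.frame(window = seq_len(n), chrom = chrom, start = start,
                    end = start + width, count = counts, gc = gc,
                    usable = rep(usable, length.out = n),
                    stringsAsFactors = FALSE)
  attr(out, "sample_id") <- sample_id
  class(out) <- c("pscc_counts", "data.frame")
  out
}

# brute-force null pmf of the two-sample run count (independent oracle)
enum_runs_pmf <- function(n1, n2) {
  n <- n1 + n2
  idx <- utils::combn(n, n1)
  runs <- apply(idx, 2, function(s) {
    lab <- rep(2L, n)
    lab[s] <- 1L
    1L + sum(diff(lab) != 0L)
  })
  tabulate(runs, n) / ncol(idx)
}

# two-sided p from a pmf with the double-the-smaller-tail convention
pmf_two_sided <- function(pmf, r) {
  n <- length(pmf)
  min(1, 2 * min(sum(pmf[1:r]), sum(pmf[r:n])))
}

# write a tiny SAM and convert it to BAM; reads is a data.frame with
# chrom, pos1 (1-based), seq, and optional mapq/flag
write_toy_bam <- function(reads, seqlengths, dir = NULL) {
  if (is.null(dir)) {
    dir <- tempfile("bamdir")
    dir.create(dir)
  }
  sam <- file.path(dir, "toy.sam")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                   as.integer(seqlengths)))
  if (nrow(reads)) {
    reads <- reads[order(match(reads$chrom, names(seqlengths)), reads$pos1), ]
    mapq <- if ("mapq" %in% names(reads)) reads$mapq else 60L
    flag <- if ("flag" %in% names(reads)) reads$flag else 0L
    rows <- sprintf("r%03d\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*",
                    seq_len(nrow(reads)), flag, reads$chrom, reads$pos1,
                    mapq, nchar(reads$seq), reads$seq)
  } else rows <- character(0)
  writeLines(c(hdr, rows), sam)
  Rsamtools::asBam(sam, file.path(dir, "toy"), overwrite = TRUE,
                   indexDestination = FALSE)
}

# brute-force unique-occurrence census for simulate_mappability oracle
enum_unique_positions <- function(seqs, k, step = 1) {
  rc1 <- function(s) {
    comp <- chartr("ACGT", "TGCA", s)
    paste(rev(strsplit(comp, "")[[1]]), collapse = "")
  }
  all_canon <- unlist(lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    km <- substring(s, 1:(L - k + 1), k:L)
    vapply(km, function(x) min(x, rc1(x)), "", USE.NAMES = FALSE)
  }))
  tab <- table(all_canon)
  lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(integer(0))
    starts <- seq(1, L - k + 1, by = step)
    km <- substring(s, starts, starts + k - 1)
    canon <- vapply(km, function(x) min(x, rc1(x)), "", USE.NAMES = FALSE)
    ok <- !grepl("[^ACGT]", km) & as.vector(tab[canon]) == 1
    as.integer(starts[ok] - 1L)
  })
}
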