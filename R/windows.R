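## Observation-window construction.
##
## Windows are sized so that every window holds the same number of uniquely
## mappable simulated read starts, hence the same *expected* read count for a
## sample sequenced to a given depth. All coordinates are 0-based half-open.

#' Simulated-read mappability of a reference
#'
#' Slides simulated reads of length `read_length` across the reference
#' (every `step` bases) and retains the start coordinates of those whose
#' sequence occurs exactly once in the genome, counting occurrences on both
#' strands. This is an exact-occurrence census: no mismatches are modelled,
#' and reads containing non-ACGT bases are treated as unmappable.
#'
#' @param reference Path to a FASTA file, or a [Biostrings::DNAStringSet].
#' @param read_length Simulated read length in bp (>= 20).
#' @param step Distance between consecutive simulated read starts (bp).
#' @return An object of class `"pscc_mappability"`: a list with `positions`
#'   (named list per chromosome of 0-based start coordinates), `read_length`,
#'   `step`, `seqlengths`, and `U_sim`, the genome-wide count of uniquely
#'   mappable simulated reads.
#' @export
simulate_mappability <- function(reference, read_length = 36L, step = 1L) {
  if (is.character(reference)) {
    if (!file.exists(reference)) stop("reference FASTA not found: ", reference)
    reference <- Biostrings::readDNAStringSet(reference)
  }
  stopifnot(methods::is(reference, "DNAStringSet"))
  if (length(reference) == 0L) stop("reference contains no sequences")
  read_length <- as.integer(read_length)
  step <- as.integer(step)
  stopifnot(read_length >= 2L, step >= 1L)
  # short names (drop FASTA description)
  names(reference) <- sub("\\s.*$", "", names(reference))
  seqlen <- Biostrings::width(reference)
  names(seqlen) <- names(reference)

  if (all(seqlen < read_length)) {
    warning("read_length exceeds every sequence length; empty mappability track")
    return(structure(list(positions = stats::setNames(list(), character(0)),
                          read_length = read_length, step = step,
                          seqlengths = seqlen, U_sim = 0L),
                     class = "pscc_mappability"))
  }

  # census of every read_length-mer (step 1) in canonical (strand-collapsed) form
  all_kmers <- list()
  cand <- list()
  for (ch in names(reference)) {
    L <- seqlen[[ch]]
    if (L < read_length) next
    s <- as.character(reference[[ch]])
    starts <- seq.int(1L, L - read_length + 1L)
    km <- substring(s, starts, starts + read_length - 1L)
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(km)))
    canon <- ifelse(km <= rc, km, rc)
    valid <- !grepl("[^ACGT]", km)
    all_kmers[[ch]] <- list(canon = canon, valid = valid)
  }
  tab <- table(unlist(lapply(all_kmers, function(z) z$canon[z$valid]),
                      use.names = FALSE))
  for (ch in names(all_kmers)) {
    z <- all_kmers[[ch]]
    idx <- seq.int(1L, length(z$canon), by = step)
    keep <- idx[z$valid[idx] & as.vector(tab[z$canon[idx]]) == 1L]
    cand[[ch]] <- as.integer(sort(keep) - 1L)   # 0-based
  }
  structure(list(positions = cand, read_length = read_length, step = step,
                 seqlengths = seqlen,
                 U_sim = sum(lengths(cand))),
            class = "pscc_mappability")
}

#' Build equal-expected-count observation windows
#'
#' Tiles each chromosome into consecutive windows holding `n_w` uniquely
#' mappable simulated read starts each, where
#' `n_w = ceiling(expected_rc * U_sim / sample_total_reads)`. With a sample
#' of `sample_total_reads` retained reads falling uniformly over the `U_sim`
#' mappable starts, every full window then has the same expected read count
#' `expected_rc`. Window boundaries are placed at the midpoint between the
#' last simulated start of one window and the first of the next; chromosome
#' ends close the terminal windows. A trailing remainder with fewer than
#' `n_w` starts becomes a final window flagged `partial`.
#'
#' @param mapp A `"pscc_mappability"` object from [simulate_mappability()].
#' @param expected_rc Target expected read count per window.
#' @param sample_total_reads Total retained reads of the sample whose depth
#'   calibrates the windows.
#' @return A `data.frame` of class `"pscc_windows"` with columns `chrom`,
#'   `start`, `end` (0-based half-open), `n_sim`, `partial`, and attributes
#'   `expected_rc`, `n_w`, `read_length`, `U_sim`.
#' @export
build_windows <- function(mapp, expected_rc = 150, sample_total_reads) {
  stopifnot(inherits(mapp, "pscc_mappability"),
            expected_rc >= 1, sample_total_reads >= expected_rc)
  U <- mapp$U_sim
  if (U < 1L) stop("mappability track is empty")
  n_w <- as.integer(ceiling(expected_rc * U / sample_total_reads))
  if (n_w < 1L) stop("computed simulated reads per window is below 1")
  out <- list()
  for (ch in names(mapp$positions)) {
    pos <- mapp$positions[[ch]]
    L <- mapp$seqlengths[[ch]]
    if (length(pos) == 0L) next
    if (length(pos) < n_w)
      warning("chromosome ", ch, " has fewer than ", n_w,
              " mappable positions; single partial window")
    grp <- ceiling(seq_along(pos) / n_w)
    first <- tapply(pos, grp, function(p) p[1L])
    last <- tapply(pos, grp, function(p) p[length(p)])
    cnt <- as.integer(tapply(pos, grp, length))
    k <- length(cnt)
    starts <- integer(k)
    starts[1L] <- 0L
    if (k > 1L)
      starts[2:k] <- (last[1:(k - 1L)] + first[2:k]) %/% 2L + 1L
    ends <- c(starts[-1L], as.integer(L))
    out[[ch]] <- data.frame(chrom = ch, start = as.integer(starts),
                            end = as.integer(ends), n_sim = cnt,
                            partial = cnt < n_w,
                            stringsAsFactors = FALSE)
  }
  w <- do.call(rbind, out)
  rownames(w) <- NULL
  w$window <- seq_len(nrow(w))
  w <- w[, c("window", "chrom", "start", "end", "n_sim", "partial")]
  attr(w, "expected_rc") <- expected_rc
  attr(w, "n_w") <- n_w
  attr(w, "read_length") <- mapp$read_length
  attr(w, "U_sim") <- U
  class(w) <- c("pscc_windows", "data.frame")
  w
}

#' Count retained reads per observation window
#'
#' Scans a BAM file and assigns each retained read to the window containing
#' its leftmost mapped base (0-based half-open). Retained reads are primary,
#' mapped alignments with mapping quality at least `mapq_min`; for paired
#' data, each properly paired fragment is counted once through its
#' plus-strand (leftmost) read. Per-window GC is the mean GC fraction of the
#' retained reads' sequences, falling back to the reference GC of the window
#' where a window has no reads and a reference is supplied.
#'
#' @param bam Path to a BAM file (whole file is streamed; no index needed).
#' @param windows A `"pscc_windows"` object.
#' @param mapq_min Minimum mapping quality (default 1, i.e. uniquely mapped).
#' @param reference Optional FASTA path or `DNAStringSet` for the GC
#'   fallback of read-free windows.
#' @param sample_id Sample identifier stored on the track.
#' @return A `data.frame` of class `"pscc_counts"` with columns `window`,
#'   `chrom`, `start`, `end`, `count`, `gc`, `usable`.
#' @export
count_reads <- function(bam, windows, mapq_min = 1L, reference = NULL,
                        sample_id = basename(bam)) {
  stopifnot(inherits(windows, "pscc_windows"))
  if (!file.exists(bam)) stop("BAM file not found: ", bam)
  p <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "mapq", "flag", "seq"))
  b <- Rsamtools::scanBam(bam, param = p)[[1L]]
  flag <- b$flag
  keep <- !is.na(b$pos) &
    bitwAnd(flag, 4L) == 0L &      # mapped
    bitwAnd(flag, 256L) == 0L &    # primary
    bitwAnd(flag, 2048L) == 0L &   # not supplementary
    !is.na(b$mapq) & b$mapq >= mapq_min
  paired <- bitwAnd(flag, 1L) != 0L
  # one count per properly paired fragment, via its plus-strand read
  keep <- keep & (!paired | (bitwAnd(flag, 2L) != 0L & bitwAnd(flag, 16L) == 0L))
  rname <- as.character(b$rname[keep])
  pos0 <- b$pos[keep] - 1L
  seqs <- b$seq[keep]
  bad <- setdiff(unique(rname), unique(windows$chrom))
  if (length(bad))
    stop("alignment contigs absent from windows: ", paste(bad, collapse = ", "))
  gcr <- as.vector(
    Biostrings::letterFrequency(seqs, "GC", as.prob = TRUE))

  n <- nrow(windows)
  count <- integer(n)
  gcsum <- numeric(n)
  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    ri <- which(rname == ch)
    if (!length(ri)) next
    idx <- findInterval(pos0[ri], windows$start[wi])
    ok <- idx >= 1L & pos0[ri] < windows$end[wi][pmax(idx, 1L)]
    idx <- idx[ok]; g <- gcr[ri][ok]
    tc <- tabulate(idx, nbins = length(wi))
    count[wi] <- count[wi] + tc
    gcsum[wi] <- gcsum[wi] + as.vector(tapply(g, factor(idx, levels = seq_along(wi)),
                                              sum, default = 0))
  }
  gc <- ifelse(count > 0L, gcsum / count, NA_real_)
  if (any(count == 0L) && !is.null(reference)) {
    if (is.character(reference))
      reference <- Biostrings::readDNAStringSet(reference)
    names(reference) <- sub("\\s.*$", "", names(reference))
    z <- which(count == 0L)
    for (i in z) {
      sq <- Biostrings::subseq(reference[[windows$chrom[i]]],
                               windows$start[i] + 1L, windows$end[i])
      gc[i] <- sum(Biostrings::letterFrequency(sq, "GC")) / length(sq)
    }
  }
  out <- data.frame(window = windows$window, chrom = windows$chrom,
                    start = windows$start, end = windows$end,
                    count = count, gc = gc,
                    usable = !windows$partial & !is.na(gc),
                    stringsAsFactors = FALSE)
  attr(out, "sample_id") <- sample_id
  class(out) <- c("pscc_counts", "data.frame")
  out
}
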