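## Binary segmentation on the RCR track.
##
## Candidate breakpoints are positions where the distributions of RCR values
## in the flanking blocks differ by a two-sample Wald-Wolfowitz runs test;
## candidates are then pruned iteratively against full inter-breakpoint
## flanks until every survivor clears a genome-wide significance threshold.
## Segmentation operates per chromosome on usable windows only and is fully
## deterministic.

#' Two-sample Wald-Wolfowitz runs test
#'
#' Pools the two blocks, sorts ascending, labels each value by block of
#' origin and counts runs of consecutive equal labels. Few runs indicate
#' separated distributions. Returns a two-sided p-value (double the smaller
#' tail of the run count), from the exact run-count null distribution when
#' the pooled size is at most `exact_limit` and from the normal
#' approximation with continuity correction otherwise. Ties spanning the two
#' blocks are laid out alternately in sorted order, a deterministic and
#' conservative convention. Blocks with fewer than 5 finite values, or
#' all-identical pooled values, return the sentinel p = 1.
#'
#' @param left,right Numeric vectors of RCR values.
#' @param exact_limit Pooled-size cutoff for the exact null distribution.
#' @return A p-value between 0 and 1.
#' @export
#' @examples
#' runs_test(rep(1, 5), rep(2, 5))   # complete separation, 2 runs
runs_test <- function(left, right, exact_limit = 40) {
  left <- left[is.finite(left)]
  right <- right[is.finite(right)]
  if (length(left) < 5L || length(right) < 5L) return(1)
  .runs_p_cpp(left, right, as.integer(exact_limit))
}

#' Null distribution of the two-sample run count
#'
#' Exact probability mass function of the number of runs when `n1` values
#' from one block and `n2` from another are pooled under exchangeability.
#'
#' @param n1,n2 Block sizes.
#' @return Numeric vector whose element r is the probability of observing
#'   exactly r runs, for r = 1..n1+n2.
#' @export
runs_null_pmf <- function(n1, n2) {
  stopifnot(n1 >= 1, n2 >= 1)
  .runs_null_pmf_cpp(as.integer(n1), as.integer(n2))[-1L]
}

#' Scan a chromosome's RCR values for candidate breakpoints
#'
#' Computes the runs-test p-value at every interior position (the `block`
#' values left of the boundary against the `block` values right of it) and
#' retains local minima of the p curve at or below `p_enter` as ordered
#' candidate breakpoints. A breakpoint index `b` means a new segment starts
#' at position `b` of the supplied vector.
#'
#' @param x Numeric vector of usable-window RCR values (one chromosome).
#' @param block Flank size in windows.
#' @param p_enter Candidate-entry threshold.
#' @param exact_limit Passed to the runs test.
#' @return Integer vector of candidate breakpoint positions (possibly
#'   empty), with the scan p-values as attribute `p`.
#' @export
initial_breakpoints <- function(x, block = 10, p_enter = 0.01,
                                exact_limit = 40) {
  n <- length(x)
  block <- as.integer(block)
  if (n < 2L * block) return(integer(0))
  p <- .scan_runs_cpp(x, block, as.integer(exact_limit))  # p[b]: boundary after b
  ok <- which(!is.na(p) & p <= p_enter)
  if (!length(ok)) return(integer(0))
  # local minima (non-strict, so plateaus of the minimal p all enter;
  # pruning removes the redundant ones)
  pm <- c(Inf, p, Inf)
  pm[is.na(pm)] <- Inf
  loc <- ok[pm[ok + 1L] <= pm[ok] & pm[ok + 1L] <= pm[ok + 2L]]
  bp <- loc + 1L  # segment starts at b+1
  attr(bp, "p") <- p
  bp
}

# p-value of breakpoint bps[i] given its surviving neighbours, using the
# full flanks (capped at max_flank windows each side)
prune_p_one <- function(x, bps, i, max_flank, exact_limit) {
  b <- bps[i]
  lo <- if (i > 1L) bps[i - 1L] else 1L
  hi <- if (i < length(bps)) bps[i + 1L] - 1L else length(x)
  left <- x[max(lo, b - max_flank):(b - 1L)]
  right <- x[b:min(hi, b + max_flank - 1L)]
  runs_test(left, right, exact_limit)
}

#' Prune candidate breakpoints to a genome-wide-significant set
#'
#' Iteratively re-tests every surviving breakpoint against its full flanking
#' segments (from the previous surviving breakpoint to the next, capped at
#' `max_flank` windows per side) and removes the least significant one
#' (largest p-value; ties remove the highest position first) while it
#' exceeds `p_genome`. Stops when all survivors are at or below `p_genome`.
#'
#' @param x Numeric vector of usable-window RCR values (one chromosome).
#' @param candidates Ordered candidate positions from
#'   [initial_breakpoints()].
#' @param p_genome Genome-wide significance threshold.
#' @param max_flank Flank cap in windows.
#' @param exact_limit Passed to the runs test.
#' @param scan_p Optional scan p-values of the candidates (from
#'   [initial_breakpoints()]); among equally insignificant breakpoints the
#'   one with the weakest scan evidence is removed first, which protects a
#'   true boundary from being evicted by plateau neighbours whose pruning
#'   flanks are still crowded.
#' @return Integer vector of surviving breakpoint positions with final
#'   p-values as attribute `p`.
#' @export
prune_breakpoints <- function(x, candidates, p_genome, max_flank = 200,
                              exact_limit = 40, scan_p = NULL) {
  ord <- order(as.integer(candidates))
  bps <- as.integer(candidates)[ord]
  sp <- if (is.null(scan_p)) rep(0, length(bps)) else scan_p[ord]
  keep <- !duplicated(bps)
  bps <- bps[keep]; sp <- sp[keep]
  max_flank <- as.integer(max_flank)
  if (!length(bps)) return(structure(integer(0), p = numeric(0)))
  p <- vapply(seq_along(bps), function(i)
    prune_p_one(x, bps, i, max_flank, exact_limit), 0)
  while (length(bps)) {
    worst <- max(p)
    if (worst <= p_genome) break
    # ties: weakest scan evidence first, then highest position
    cand_drop <- which(p == worst)
    cand_drop <- cand_drop[sp[cand_drop] == max(sp[cand_drop])]
    drop <- max(cand_drop)
    bps <- bps[-drop]
    p <- p[-drop]
    sp <- sp[-drop]
    # only the neighbours of the removed breakpoint change flanks
    for (i in c(drop - 1L, drop)) {
      if (i >= 1L && i <= length(bps))
        p[i] <- prune_p_one(x, bps, i, max_flank, exact_limit)
    }
  }
  structure(bps, p = p)
}

#' Cut a chromosome into segments at final breakpoints
#'
#' Consecutive breakpoints (plus the chromosome ends) delimit segments over
#' the usable-window positions. Segments shorter than `min_windows` are
#' merged into the neighbour whose mean is closer, and means are refreshed
#' after each merge.
#'
#' @param x Numeric vector of usable-window RCR values (one chromosome).
#' @param breakpoints Sorted positions where new segments start.
#' @param min_windows Minimum segment length in usable windows.
#' @return A `data.frame` with columns `start`, `end` (positions in `x`,
#'   inclusive), `n`, `mean`.
#' @export
segments_from_breakpoints <- function(x, breakpoints, min_windows = 3) {
  n <- length(x)
  bps <- sort(unique(as.integer(breakpoints)))
  bps <- bps[bps > 1L & bps <= n]
  starts <- c(1L, bps)
  ends <- c(bps - 1L, n)
  seg <- data.frame(start = starts, end = ends)
  seg$n <- seg$end - seg$start + 1L
  seg$mean <- vapply(seq_len(nrow(seg)),
                     function(i) mean(x[seg$start[i]:seg$end[i]]), 0)
  while (nrow(seg) > 1L && any(seg$n < min_windows)) {
    i <- which(seg$n < min_windows)[1L]
    nb <- if (i == 1L) 2L
          else if (i == nrow(seg)) i - 1L
          else if (abs(seg$mean[i - 1L] - seg$mean[i]) <=
                   abs(seg$mean[i + 1L] - seg$mean[i])) i - 1L
          else i + 1L
    j <- min(i, nb); k <- max(i, nb)
    seg$end[j] <- seg$end[k]
    seg$n[j] <- seg$end[j] - seg$start[j] + 1L
    seg$mean[j] <- mean(x[seg$start[j]:seg$end[j]])
    seg <- seg[-k, , drop = FALSE]
    rownames(seg) <- NULL
  }
  seg
}

#' Segment an RCR track
#'
#' Runs the scan, prune, and cut steps per chromosome over usable windows,
#' and maps segments back to window indices and genomic coordinates. The
#' default genome-wide threshold is Bonferroni: 0.05 divided by the total
#' number of scan positions tested across the genome.
#'
#' @param rcr A `"pscc_rcr"` track.
#' @param params A [pscc_params()] list.
#' @return A `data.frame` with one row per segment: `chrom`, `start`, `end`
#'   (genomic, 0-based half-open), `first_window`, `last_window` (window
#'   indices), `n_windows` (usable windows), `mean_rcr`.
#' @export
segment_rcr <- function(rcr, params = pscc_params()) {
  stopifnot(inherits(rcr, "pscc_rcr"))
  chroms <- unique(rcr$chrom)
  n_tested <- 0L
  per_chrom <- list()
  for (ch in chroms) {
    idx <- which(rcr$chrom == ch & rcr$usable)
    x <- rcr$rcr[idx]
    n_tested <- n_tested + max(0L, length(x) - 2L * params$block + 1L)
    per_chrom[[ch]] <- list(idx = idx, x = x)
  }
  p_genome <- if (is.null(params$p_genome)) 0.05 / max(1L, n_tested)
              else params$p_genome
  out <- list()
  for (ch in chroms) {
    idx <- per_chrom[[ch]]$idx
    x <- per_chrom[[ch]]$x
    if (length(x) == 0L) next
    cand <- initial_breakpoints(x, params$block, params$p_enter,
                                params$exact_limit)
    fin <- prune_breakpoints(x, cand, p_genome, params$max_flank,
                             params$exact_limit,
                             scan_p = attr(cand, "p")[cand - 1L])
    seg <- segments_from_breakpoints(x, fin, params$min_seg_windows)
    out[[ch]] <- data.frame(
      chrom = ch,
      start = rcr$start[idx[seg$start]],
      end = rcr$end[idx[seg$end]],
      first_window = rcr$window[idx[seg$start]],
      last_window = rcr$window[idx[seg$end]],
      n_windows = seg$n,
      mean_rcr = seg$mean,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "p_genome") <- p_genome
  res
}
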