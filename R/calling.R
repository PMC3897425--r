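## Segment genotyping: combined self-test / parallelism-test scheme.
##
## ST (self-test): two-sided Mann-Whitney U test of the segment's window
## RCRs against all other usable windows of the same sample. PT
## (parallelism-test): z test of the segment mean against the standard
## error implied by the control panel's per-window relative SDs; regions
## the panel itself shows to be unstable get a large SE and fail PT, which
## is the unstable-region filter. The 2x2 significance grid maps to four
## categories: normal, cnv, unstable_region, sample_quality.

#' Self-test of a segment against the rest of the genome
#'
#' Two-sided Mann-Whitney U test of the segment's usable-window RCR values
#' against the sample's remaining usable-window RCR values.
#'
#' @param segment_values RCR values of the segment's usable windows.
#' @param background_values RCR values of all other usable windows.
#' @return A p-value. If the background is empty (segment spans the whole
#'   genome) returns 1 with a warning.
#' @export
self_test <- function(segment_values, background_values) {
  segment_values <- segment_values[is.finite(segment_values)]
  background_values <- background_values[is.finite(background_values)]
  if (length(background_values) == 0L) {
    warning("segment spans all usable windows; self-test undefined")
    return(1)
  }
  if (length(segment_values) == 0L) return(1)
  suppressWarnings(
    stats::wilcox.test(segment_values, background_values,
                       alternative = "two.sided", exact = FALSE)$p.value)
}

#' Parallelism-test of a segment against the control panel
#'
#' Tests the segment mean RCR against 1 using the standard error implied by
#' the panel's per-window relative standard deviations:
#' `SE = sqrt(sum((sigma_i/mu_i)^2)) / n` over the segment's usable
#' windows, `z = (mean - 1) / SE`, two-sided normal p-value. Windows with
#' undefined relative SD are dropped with a warning; if all are dropped the
#' segment is untestable and p = 1 is returned (unstable region).
#'
#' @param mean_rcr Segment mean RCR.
#' @param rel_sd Vector `sigma_i / mu_i` over the segment's usable windows.
#' @return A list with elements `stat` (the z statistic) and `p`.
#' @export
parallelism_test <- function(mean_rcr, rel_sd) {
  ok <- is.finite(rel_sd)
  if (!all(ok)) {
    warning(sum(!ok), " windows with undefined panel SD dropped from PT")
    rel_sd <- rel_sd[ok]
  }
  n <- length(rel_sd)
  if (n == 0L) return(list(stat = NA_real_, p = 1))
  se <- sqrt(sum(rel_sd^2)) / n
  if (se == 0) return(list(stat = if (mean_rcr == 1) 0 else Inf * sign(mean_rcr - 1),
                           p = if (mean_rcr == 1) 1 else 0))
  z <- (mean_rcr - 1) / se
  list(stat = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Classify a segment from its two test p-values
#'
#' The four-situation decision grid: both tests insignificant means the
#' segment is consistent with the control set (`normal`); both significant
#' is a high-credibility deletion/duplication (`cnv`); ST significant alone
#' is a false signal from sequence instability or shared bias
#' (`unstable_region`); PT significant alone indicates inappropriate
#' sequence quality of the sample (`sample_quality`).
#'
#' @param st_p,pt_p Self-test and parallelism-test p-values.
#' @param alpha_st,alpha_pt Significance levels (defaults 0.001).
#' @return One of `"normal"`, `"cnv"`, `"unstable_region"`,
#'   `"sample_quality"`.
#' @export
classify <- function(st_p, pt_p, alpha_st = 0.001, alpha_pt = 0.001) {
  stopifnot(is.finite(st_p), is.finite(pt_p),
            st_p >= 0, st_p <= 1, pt_p >= 0, pt_p <= 1)
  st <- st_p <= alpha_st
  pt <- pt_p <= alpha_pt
  if (st && pt) "cnv"
  else if (!st && !pt) "normal"
  else if (st) "unstable_region"
  else "sample_quality"
}

seg_usable_idx <- function(rcr, first_window, last_window) {
  which(rcr$window >= first_window & rcr$window <= last_window & rcr$usable)
}

#' Genotype segments and emit CNV calls
#'
#' End-to-end calling on a normalized track: segment the genome, run the
#' self-test and parallelism-test on every segment, classify, and emit the
#' `cnv`-category segments whose integer copy number differs from 2 and
#' whose genomic size reaches `min_size`. Adjacent same-state calls
#' separated only by unusable windows are merged (and re-tested). Copy
#' number is `round(2 * mean RCR)` (half away from zero), clipped at 0.
#'
#' @param rcr A `"pscc_rcr"` track normalized against `panel`.
#' @param panel The `"pscc_panel"` used for normalization.
#' @param params A [pscc_params()] list.
#' @param sample_id Sample identifier carried onto the calls.
#' @return A list with `segments` (all segments with `st_p`, `pt_p`,
#'   `pt_stat`, `category`, `copy_number`) and `calls` (the reportable CNV
#'   calls: `chrom`, `start`, `end`, `state`, `copy_number`, `mean_rcr`,
#'   `n_windows`, `st_p`, `pt_p`, `sample`).
#' @export
call_cnvs <- function(rcr, panel, params = pscc_params(),
                      sample_id = attr(rcr, "sample_id") %||% "sample") {
  stopifnot(inherits(rcr, "pscc_rcr"), inherits(panel, "pscc_panel"),
            nrow(rcr) == nrow(panel))
  seg <- segment_rcr(rcr, params)
  rel_sd_all <- ifelse(panel$usable & panel$mu > 0,
                       panel$sigma / panel$mu, NA_real_)
  all_usable <- rcr$rcr[rcr$usable]
  test_one <- function(first_window, last_window, mean_rcr) {
    idx <- seg_usable_idx(rcr, first_window, last_window)
    sv <- rcr$rcr[idx]
    bg <- rcr$rcr[rcr$usable &
                    !(rcr$window >= first_window & rcr$window <= last_window)]
    st <- self_test(sv, bg)
    pt <- parallelism_test(mean_rcr, rel_sd_all[idx])
    list(st = st, pt = pt$p, stat = pt$stat)
  }
  res <- lapply(seq_len(nrow(seg)), function(i)
    test_one(seg$first_window[i], seg$last_window[i], seg$mean_rcr[i]))
  seg$st_p <- vapply(res, `[[`, 0, "st")
  seg$pt_p <- vapply(res, `[[`, 0, "pt")
  seg$pt_stat <- vapply(res, `[[`, 0, "stat")
  seg$category <- vapply(seq_len(nrow(seg)), function(i)
    classify(seg$st_p[i], seg$pt_p[i], params$alpha_st, params$alpha_pt), "")
  seg$copy_number <- pmax(0, floor(2 * seg$mean_rcr + 0.5))

  is_call <- seg$category == "cnv" & seg$copy_number != 2L
  calls <- seg[is_call, , drop = FALSE]
  if (nrow(calls)) {
    calls$state <- ifelse(calls$mean_rcr < 1, "deletion", "duplication")
    # merge adjacent same-state calls separated only by unusable windows
    calls <- calls[order(match(calls$chrom, unique(rcr$chrom)), calls$start), ]
    merged <- list()
    cur <- calls[1L, ]
    for (i in seq_len(nrow(calls))[-1L]) {
      nx <- calls[i, ]
      gap_usable <- sum(rcr$usable & rcr$chrom == cur$chrom &
                          rcr$window > cur$last_window &
                          rcr$window < nx$first_window)
      if (nx$chrom == cur$chrom && nx$state == cur$state && gap_usable == 0L) {
        idx <- seg_usable_idx(rcr, cur$first_window, nx$last_window)
        cur$end <- nx$end
        cur$last_window <- nx$last_window
        cur$n_windows <- length(idx)
        cur$mean_rcr <- mean(rcr$rcr[idx])
        t <- test_one(cur$first_window, cur$last_window, cur$mean_rcr)
        cur$st_p <- t$st; cur$pt_p <- t$pt; cur$pt_stat <- t$stat
        cur$copy_number <- max(0, floor(2 * cur$mean_rcr + 0.5))
      } else {
        merged[[length(merged) + 1L]] <- cur
        cur <- nx
      }
    }
    merged[[length(merged) + 1L]] <- cur
    calls <- do.call(rbind, merged)
    calls <- calls[calls$end - calls$start >= params$min_size, , drop = FALSE]
    calls$sample <- sample_id
    calls <- calls[, c("chrom", "start", "end", "state", "copy_number",
                       "mean_rcr", "n_windows", "st_p", "pt_p", "sample")]
    rownames(calls) <- NULL
  } else {
    calls <- data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), state = character(0),
                        copy_number = integer(0), mean_rcr = numeric(0),
                        n_windows = integer(0), st_p = numeric(0),
                        pt_p = numeric(0), sample = character(0),
                        stringsAsFactors = FALSE)
  }
  list(segments = seg, calls = calls,
       p_genome = attr(seg, "p_genome"))
}

#' Per-sample quality summary
#'
#' Counts segments in the `sample_quality` category (parallelism-test
#' significant while the self-test is not) and flags the sample for
#' replication when their fraction strictly exceeds `quality_frac`.
#'
#' @param segments The `segments` table from [call_cnvs()].
#' @param quality_frac Flagging threshold on the fraction of segments.
#' @return A list with `n_segments`, `n_sample_quality`, `fraction`,
#'   `flagged`.
#' @export
report_sample_quality <- function(segments, quality_frac = 0.01) {
  n <- nrow(segments)
  k <- sum(segments$category == "sample_quality")
  frac <- if (n > 0) k / n else 0
  list(n_segments = n, n_sample_quality = k, fraction = frac,
       flagged = frac > quality_frac)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
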