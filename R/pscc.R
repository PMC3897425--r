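#' Fit the population-scale CNV caller to one sample
#'
#' The top-level interface: takes a raw per-window read-count track for a
#' test sample and a control panel, applies the two-step correction
#' (within-sample GC median rescaling, then normalization by the panel's
#' per-window means), segments the resulting relative copy ratio (RCR)
#' track by runs-test binary segmentation, genotypes every segment with the
#' combined self-test / parallelism-test scheme, and collects the
#' reportable CNV calls.
#'
#' @param counts A raw `"pscc_counts"` track (from [count_reads()], the
#'   simulator, or [read_counts_tsv()]).
#' @param panel A `"pscc_panel"` built from GC-corrected control tracks
#'   with [build_panel()].
#' @param params A [pscc_params()] parameter list.
#' @param sample_id Sample identifier.
#' @return An object of class `"pscc"`: a list with components `rcr` (the
#'   normalized track), `segments` (all segments with test results and
#'   categories), `calls` (reportable CNV calls), `quality` (the
#'   [report_sample_quality()] summary), `params`, `p_genome` (the
#'   genome-wide threshold used) and `sample_id`. Methods: `print`,
#'   `summary`, `plot`.
#' @seealso [call_cnvs()] for the stage-level interface.
#' @export
#' @examples
#' cfg <- sim_config(n_chrom = 4, windows_per_chrom = 400, n_controls = 10,
#'                   seed = 7)
#' xp <- sim_experiment(cfg)
#' ctrl <- lapply(generate_panel_tracks(xp), gc_correct, min_bin = 20)
#' panel <- build_panel(ctrl)
#' truth <- sim_truth(xp, 2, c(3e5, 8e5))
#' fit <- pscc(sim_case(xp, truth), panel,
#'             params = pscc_params(gc_min_bin = 20))
#' fit
pscc <- function(counts, panel, params = pscc_params(),
                 sample_id = attr(counts, "sample_id") %||% "sample") {
  stopifnot(inherits(panel, "pscc_panel"))
  corrected <- gc_correct(counts, params$gc_bin_width, params$gc_min_bin)
  rcr <- normalize_rcr(corrected, panel)
  attr(rcr, "sample_id") <- sample_id
  res <- call_cnvs(rcr, panel, params, sample_id)
  structure(list(rcr = rcr,
                 segments = res$segments,
                 calls = res$calls,
                 quality = report_sample_quality(res$segments,
                                                 params$quality_frac),
                 params = params,
                 p_genome = res$p_genome,
                 sample_id = sample_id),
            class = "pscc")
}

#' @export
print.pscc <- function(x, ...) {
  cat("Population-scale CNV fit -- sample", x$sample_id, "\n")
  cat(sprintf("  %d windows (%d usable), %d segments, genome-wide p <= %.3g\n",
              nrow(x$rcr), sum(x$rcr$usable), nrow(x$segments), x$p_genome))
  tab <- table(factor(x$segments$category,
                      levels = c("normal", "cnv", "unstable_region",
                                 "sample_quality")))
  cat("  segment categories:",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  cat(sprintf("  %d CNV call(s) >= %.0f kb%s\n", nrow(x$calls),
              x$params$min_size / 1e3,
              if (x$quality$flagged) " [sample flagged for replication]" else ""))
  if (nrow(x$calls)) {
    df <- x$calls[, c("chrom", "start", "end", "state", "copy_number",
                      "mean_rcr")]
    df$mean_rcr <- round(df$mean_rcr, 3)
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' @rdname pscc
#' @param object,... Method arguments.
#' @method summary pscc
#' @export
summary.pscc <- function(object, ...) {
  out <- list(sample_id = object$sample_id,
              n_windows = nrow(object$rcr),
              n_usable = sum(object$rcr$usable),
              median_rcr = stats::median(object$rcr$rcr[object$rcr$usable]),
              n_segments = nrow(object$segments),
              categories = table(object$segments$category),
              calls = object$calls,
              quality = object$quality)
  class(out) <- "summary.pscc"
  out
}

#' @export
print.summary.pscc <- function(x, ...) {
  cat("Sample:", x$sample_id, "\n")
  cat(sprintf("Windows: %d (%d usable); median RCR %.4f\n",
              x$n_windows, x$n_usable, x$median_rcr))
  cat("Segments:", x$n_segments, "\n")
  print(x$categories)
  cat("Calls:\n")
  if (nrow(x$calls)) print(x$calls, row.names = FALSE) else cat("  none\n")
  cat(sprintf("Sample-quality segments: %d/%d (flagged: %s)\n",
              x$quality$n_sample_quality, x$quality$n_segments,
              x$quality$flagged))
  invisible(x)
}

#' Plot an RCR track with its segmentation
#'
#' Base-graphics genome plot: usable-window RCR values in window order,
#' chromosomes in alternating shades, segment means drawn as horizontal
#' red lines, and reportable calls shaded.
#'
#' @param x A `"pscc"` fit.
#' @param chrom Optional chromosome subset.
#' @param ... Passed to [graphics::plot()].
#' @method plot pscc
#' @export
plot.pscc <- function(x, chrom = NULL, ...) {
  rcr <- x$rcr
  if (!is.null(chrom)) rcr <- rcr[rcr$chrom %in% chrom, , drop = FALSE]
  u <- which(rcr$usable)
  pos <- seq_along(u)
  chf <- factor(rcr$chrom[u], levels = unique(rcr$chrom))
  cols <- c("grey40", "grey70")[1 + (as.integer(chf) %% 2L)]
  plot(pos, rcr$rcr[u], pch = 16, cex = 0.3, col = cols,
       xlab = "usable window", ylab = "relative copy ratio", ...)
  abline(h = 1, col = "steelblue", lty = 2)
  seg <- x$segments
  if (!is.null(chrom)) seg <- seg[seg$chrom %in% chrom, , drop = FALSE]
  for (i in seq_len(nrow(seg))) {
    j <- which(rcr$window[u] >= seg$first_window[i] &
                 rcr$window[u] <= seg$last_window[i])
    if (length(j))
      segments(min(j), seg$mean_rcr[i], max(j), seg$mean_rcr[i],
               col = "red", lwd = 2)
  }
  invisible(x)
}
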