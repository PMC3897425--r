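## Two-step bias correction.
##
## Step 1 rescales each window's raw count by the ratio of the sample's
## overall median count to the median count of windows sharing its GC bin
## (per-GC-percentage median correction). Step 2 divides the GC-corrected
## count by the per-window mean of a panel of GC-corrected control samples,
## yielding the relative copy ratio (RCR), with expectation 1 at copy
## number 2. The panel's per-window standard deviation is kept: it drives
## the parallelism-test used to filter unstable regions downstream.

gc_bin_index <- function(gc, width) as.integer(floor(gc / width + 1e-9))

#' Within-sample GC-content correction
#'
#' Corrects each window's raw read count as
#' `count * M_overall / M_gc`, where `M_overall` is the median count over
#' all usable windows of the sample and `M_gc` the median count over usable
#' windows in the same GC bin (default bins of 1% GC). Bins holding fewer
#' than `min_bin` usable windows borrow the median of the nearest populated
#' bin. Windows whose populated bin has a zero median cannot be rescaled and
#' are flagged unusable.
#'
#' @param track A `"pscc_counts"` track (raw counts).
#' @param gc_bin_width GC bin width as a fraction (default 0.01).
#' @param min_bin Minimum usable windows per self-supporting bin.
#' @return The track with `count` replaced by the corrected count and
#'   `usable` updated; attribute `gc_corrected` set to `TRUE`.
#' @export
gc_correct <- function(track, gc_bin_width = 0.01, min_bin = 50) {
  stopifnot(is.data.frame(track), all(c("count", "gc", "usable") %in% names(track)),
            gc_bin_width > 0, gc_bin_width <= 0.1)
  usable <- track$usable & is.finite(track$gc)
  m <- track$count
  if (!any(usable) || all(m[usable] == 0))
    stop("track has no usable windows with nonzero counts")
  M_overall <- stats::median(m[usable])
  bin <- gc_bin_index(track$gc, gc_bin_width)
  ub <- sort(unique(bin[usable]))
  med <- vapply(ub, function(b) stats::median(m[usable & bin == b]), 0)
  cnt <- vapply(ub, function(b) sum(usable & bin == b), 0L)
  pop <- cnt >= min_bin
  if (!any(pop)) pop[which.max(cnt)] <- TRUE  # degenerate tiny tracks
  # sparse bins borrow the nearest populated bin's median (ties: lower bin)
  popb <- ub[pop]
  popm <- med[pop]
  M_gc_bin <- vapply(seq_along(ub), function(i) {
    if (pop[i]) return(med[i])
    d <- abs(popb - ub[i])
    popm[which.min(d)]
  }, 0)
  M_gc <- M_gc_bin[match(bin, ub)]
  bad <- usable & (is.na(M_gc) | M_gc == 0)
  corrected <- ifelse(usable & !bad, m * M_overall / M_gc, m)
  out <- track
  out$count <- corrected
  out$usable <- usable & !bad
  attr(out, "sample_id") <- attr(track, "sample_id")
  attr(out, "gc_corrected") <- TRUE
  class(out) <- class(track)
  out
}

#' Build a control panel from GC-corrected tracks
#'
#' Rescales every control to a common overall median (so controls sequenced
#' at different depths are comparable), then records the per-window mean and
#' standard deviation (denominator n - 1) of the rescaled corrected counts.
#' Windows unusable in any control, or whose mean falls below
#' `mu_floor_frac` times the panel-wide median mean, are flagged unusable.
#'
#' @param tracks A list of at least two GC-corrected `"pscc_counts"` tracks
#'   on identical windows.
#' @param mu_floor_frac Unusable-window floor on the panel mean, as a
#'   fraction of the panel-wide median mean.
#' @return A `data.frame` of class `"pscc_panel"` with columns `window`,
#'   `chrom`, `start`, `end`, `mu`, `sigma`, `usable`; attributes
#'   `n_controls` and `target_median` (the common overall median).
#' @export
build_panel <- function(tracks, mu_floor_frac = 0.1) {
  stopifnot(is.list(tracks), length(tracks) >= 2)
  n <- nrow(tracks[[1L]])
  for (t in tracks) {
    if (nrow(t) != n || any(t$window != tracks[[1L]]$window) ||
        any(t$chrom != tracks[[1L]]$chrom))
      stop("control tracks are not on identical windows")
  }
  usable <- Reduce(`&`, lapply(tracks, function(t) t$usable))
  meds <- vapply(tracks, function(t) stats::median(t$count[t$usable]), 0)
  target <- stats::median(meds)
  mat <- vapply(seq_along(tracks),
                function(j) tracks[[j]]$count * (target / meds[j]),
                numeric(n))
  mu <- rowMeans(mat)
  sigma <- sqrt(rowSums((mat - mu)^2) / (ncol(mat) - 1L))
  floor_mu <- mu_floor_frac * stats::median(mu[usable])
  usable <- usable & mu >= floor_mu
  out <- data.frame(window = tracks[[1L]]$window, chrom = tracks[[1L]]$chrom,
                    start = tracks[[1L]]$start, end = tracks[[1L]]$end,
                    mu = mu, sigma = sigma, usable = usable,
                    stringsAsFactors = FALSE)
  attr(out, "n_controls") <- length(tracks)
  attr(out, "target_median") <- target
  class(out) <- c("pscc_panel", "data.frame")
  out
}

#' Normalize a corrected track against a control panel
#'
#' Rescales the GC-corrected case track to the panel's common overall
#' median, then divides each window's corrected count by the panel mean,
#' yielding the relative copy ratio (RCR) track. Windows unusable in either
#' the track or the panel propagate as unusable.
#'
#' @param track A GC-corrected `"pscc_counts"` track.
#' @param panel A `"pscc_panel"` from [build_panel()].
#' @return A `data.frame` of class `"pscc_rcr"` with columns `window`,
#'   `chrom`, `start`, `end`, `rcr`, `usable`.
#' @export
normalize_rcr <- function(track, panel) {
  stopifnot(inherits(panel, "pscc_panel"), nrow(track) == nrow(panel))
  if (!isTRUE(attr(track, "gc_corrected")))
    warning("track does not look GC-corrected; normalizing anyway")
  usable <- track$usable & panel$usable
  if (any(usable & panel$mu == 0))
    stop("internal error: zero panel mean on a usable window")
  s <- attr(panel, "target_median") / stats::median(track$count[track$usable])
  rcr <- ifelse(usable, s * track$count / panel$mu, NA_real_)
  out <- data.frame(window = track$window, chrom = track$chrom,
                    start = track$start, end = track$end,
                    rcr = rcr, usable = usable, stringsAsFactors = FALSE)
  attr(out, "sample_id") <- attr(track, "sample_id")
  class(out) <- c("pscc_rcr", "data.frame")
  out
}

#' Coefficient-of-variation profile by GC bin
#'
#' Diagnostic for the correction steps: within each GC bin, the coefficient
#' of variation (SD/mean) of a per-window statistic across the bin's usable
#' windows, one row per sample and bin. Computed on raw counts, corrected
#' counts, or RCR values, it shows how much window-to-window variability
#' each correction step removes per GC stratum.
#'
#' @param tracks A single track or list of tracks (`"pscc_counts"` or
#'   `"pscc_rcr"`), all on the same windows.
#' @param gc A vector of per-window GC fractions (taken from the first track
#'   if it has a `gc` column).
#' @param gc_bin_width GC bin width (default 0.01).
#' @return A `data.frame` with columns `sample`, `gc_bin` (bin lower edge),
#'   `n`, `cv`. Empty bins are omitted.
#' @export
cv_profile <- function(tracks, gc = NULL, gc_bin_width = 0.01) {
  if (is.data.frame(tracks)) tracks <- list(tracks)
  if (is.null(gc)) {
    if (!"gc" %in% names(tracks[[1L]]))
      stop("supply per-window GC via `gc` for tracks without a gc column")
    gc <- tracks[[1L]]$gc
  }
  out <- list()
  for (j in seq_along(tracks)) {
    t <- tracks[[j]]
    val <- if ("rcr" %in% names(t)) t$rcr else t$count
    ok <- t$usable & is.finite(val) & is.finite(gc)
    bin <- gc_bin_index(gc, gc_bin_width)
    for (b in sort(unique(bin[ok]))) {
      v <- val[ok & bin == b]
      if (length(v) < 2 || mean(v) == 0) next
      out[[length(out) + 1L]] <- data.frame(
        sample = j, gc_bin = b * gc_bin_width, n = length(v),
        cv = stats::sd(v) / mean(v))
    }
  }
  do.call(rbind, out)
}
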