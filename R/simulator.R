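## Window-level simulator.
##
## Emulates the per-window read-count generating process of low-coverage
## WGS: Poisson counts whose rate is the product of the expected read count,
## a unimodal GC-dependent efficiency curve (suppressing GC-poor and GC-rich
## windows), a window-specific multiplicative bias shared by every sample of
## the experiment (the "multiplex-related" bias: genome structure and
## mappability effects), and a small independent lognormal over-dispersion.
## Depth is realized through the window-sizing rule: windows are rebuilt per
## depth at constant expected read count, so the bp width of a window scales
## inversely with depth and event sizes in bp map to depth-dependent window
## counts.

#' Simulator configuration
#'
#' @param n_chrom Number of synthetic chromosomes.
#' @param windows_per_chrom Windows per chromosome.
#' @param depth Depth factor relative to the 1x calibration (0.2-20).
#' @param expected_rc Expected read count per window (constant across depth;
#'   windows are rebuilt per depth).
#' @param read_length Read length in bp used to convert depth to window
#'   width: `width = expected_rc * read_length / depth`.
#' @param gc_shape1,gc_shape2 Beta parameters of the per-window GC fractions
#'   (defaults give mean 0.41, SD 0.063, a human-like autosomal profile).
#' @param gc_bias Logical; apply the GC efficiency curve.
#' @param multiplex_sd SD (log scale) of the shared lognormal per-window
#'   bias.
#' @param overdispersion Target ratio of the per-window relative SD to the
#'   Poisson floor `1/sqrt(expected_rc)` (1 = pure Poisson; default 1.2
#'   adds a 20% margin emulating residual real-data noise).
#' @param n_controls Number of control samples in the panel.
#' @param seed Integer seed for the experiment's shared structure.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_chrom = 12, windows_per_chrom = 4500, depth = 2,
                       expected_rc = 150, read_length = 36,
                       gc_shape1 = 24, gc_shape2 = 35,
                       gc_bias = TRUE, multiplex_sd = 0.1,
                       overdispersion = 1.2, n_controls = 90, seed = 1L) {
  stopifnot(n_chrom >= 1, windows_per_chrom >= 1, depth > 0,
            expected_rc >= 1, read_length >= 1,
            gc_shape1 > 0, gc_shape2 > 0, multiplex_sd >= 0,
            overdispersion >= 1, n_controls >= 2)
  structure(as.list(environment()), class = "sim_config")
}

#' GC efficiency curve
#'
#' Unimodal multiplicative rate curve: 1 on the plateau GC in
#' 0.35-0.50, decaying as a half-Gaussian outside so that efficiency
#' halves 0.10 GC beyond either edge (e.g. 2-fold suppression at GC 0.60).
#'
#' @param gc Vector of GC fractions.
#' @return Multiplicative efficiencies in `(0, 1]`.
#' @export
gc_bias_curve <- function(gc) {
  lo <- pmax(0, 0.35 - gc) / 0.10
  hi <- pmax(0, gc - 0.50) / 0.10
  2^-(lo^2) * 2^-(hi^2)
}

#' Set up a simulated experiment's shared structure
#'
#' Draws the window grid, the per-window GC fractions, and the shared
#' multiplex bias, all from `cfg$seed`. Controls and cases generated from
#' the returned object share the same windows, GC profile and bias, as the
#' population-normalization model assumes.
#'
#' @param cfg A [sim_config()].
#' @return A list of class `"sim_experiment"` with `windows`
#'   (`"pscc_windows"`-like data frame), `gc`, `bias`, `rate` (per-window
#'   Poisson rate at copy number 2), `sd_extra` (lognormal sdlog of the
#'   over-dispersion term) and `cfg`.
#' @export
sim_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  width <- max(1L, as.integer(round(cfg$expected_rc * cfg$read_length / cfg$depth)))
  n <- cfg$n_chrom * cfg$windows_per_chrom
  chrom <- rep(sprintf("sim%02d", seq_len(cfg$n_chrom)),
               each = cfg$windows_per_chrom)
  start <- rep.int(width * (seq_len(cfg$windows_per_chrom) - 1L), cfg$n_chrom)
  windows <- data.frame(window = seq_len(n), chrom = chrom,
                        start = start, end = start + width,
                        n_sim = NA_integer_, partial = FALSE,
                        stringsAsFactors = FALSE)
  attr(windows, "expected_rc") <- cfg$expected_rc
  class(windows) <- c("pscc_windows", "data.frame")
  gc <- stats::rbeta(n, cfg$gc_shape1, cfg$gc_shape2)
  g <- if (cfg$gc_bias) gc_bias_curve(gc) else rep(1, n)
  bias <- if (cfg$multiplex_sd > 0)
    stats::rlnorm(n, -cfg$multiplex_sd^2 / 2, cfg$multiplex_sd) else rep(1, n)
  # independent over-dispersion: total relative variance od^2/E
  extra_var <- max(0, (cfg$overdispersion^2 - 1) / cfg$expected_rc)
  sd_extra <- sqrt(log1p(extra_var))
  structure(list(windows = windows, gc = gc, bias = bias,
                 rate = cfg$expected_rc * g * bias,
                 sd_extra = sd_extra, cfg = cfg, window_width = width),
            class = "sim_experiment")
}

sim_draw_counts <- function(xp, cn_factor = 1, sample_id = "sim") {
  n <- nrow(xp$windows)
  u <- if (xp$sd_extra > 0)
    stats::rlnorm(n, -xp$sd_extra^2 / 2, xp$sd_extra) else 1
  counts <- stats::rpois(n, xp$rate * cn_factor * u)
  out <- data.frame(window = xp$windows$window, chrom = xp$windows$chrom,
                    start = xp$windows$start, end = xp$windows$end,
                    count = counts, gc = xp$gc,
                    usable = TRUE, stringsAsFactors = FALSE)
  attr(out, "sample_id") <- sample_id
  class(out) <- c("pscc_counts", "data.frame")
  out
}

#' Generate the control samples of an experiment
#'
#' Each control's window counts are Poisson with the experiment's shared
#' rate (expected count x GC curve x shared bias), times an independent
#' lognormal over-dispersion factor.
#'
#' @param xp A [sim_experiment()].
#' @return A list of `"pscc_counts"` tracks of length `cfg$n_controls`.
#' @export
generate_panel_tracks <- function(xp) {
  stopifnot(inherits(xp, "sim_experiment"))
  lapply(seq_len(xp$cfg$n_controls), function(j)
    sim_draw_counts(xp, 1, sprintf("control%02d", j)))
}

#' Draw a truth set of spiked CNV events
#'
#' Places one event per chromosome on randomly chosen distinct chromosomes
#' (so events never overlap), with sizes drawn log-uniformly from
#' `size_range` (bp) and converted to whole windows, and types split evenly
#' between heterozygous deletions (copy number 1) and duplications (copy
#' number 3) unless specified. A margin of `margin` windows is kept clear
#' of chromosome ends.
#'
#' @param xp A [sim_experiment()].
#' @param n_events Number of events (at most `n_chrom`).
#' @param size_range Length-2 vector, event size range in bp.
#' @param types Event types, recycled to `n_events`; default alternates.
#' @param margin Clear margin at chromosome ends, in windows.
#' @return A `data.frame` of class `"sim_truth"`: `chrom`, `start`, `end`
#'   (bp), `first_window`, `last_window`, `n_windows`, `type`, `cn`,
#'   `size`.
#' @export
sim_truth <- function(xp, n_events = 10, size_range = c(3e5, 1e7),
                      types = NULL, margin = 30) {
  cfg <- xp$cfg
  stopifnot(n_events <= cfg$n_chrom)
  width <- xp$window_width
  if (is.null(types))
    types <- rep(c("deletion", "duplication"), length.out = n_events)
  types <- rep(types, length.out = n_events)
  sizes <- exp(stats::runif(n_events, log(size_range[1]), log(size_range[2])))
  nwin <- pmax(1L, as.integer(round(sizes / width)))
  maxw <- cfg$windows_per_chrom - 2L * margin
  if (any(nwin > maxw))
    stop("event larger than a chromosome minus margins; enlarge chromosomes")
  chroms <- sample(sprintf("sim%02d", seq_len(cfg$n_chrom)), n_events)
  first <- vapply(nwin, function(k)
    as.integer(margin + sample.int(maxw - k + 1L, 1L)), 0L)
  wpc <- cfg$windows_per_chrom
  chrom_index <- match(chroms, sprintf("sim%02d", seq_len(cfg$n_chrom)))
  fw <- (chrom_index - 1L) * wpc + first
  lw <- fw + nwin - 1L
  out <- data.frame(chrom = chroms,
                    start = xp$windows$start[fw],
                    end = xp$windows$end[lw],
                    first_window = fw, last_window = lw, n_windows = nwin,
                    type = types,
                    cn = ifelse(types == "deletion", 1L, 3L),
                    stringsAsFactors = FALSE)
  out$size <- out$end - out$start
  class(out) <- c("sim_truth", "data.frame")
  out
}

#' Generate a case sample carrying spiked events
#'
#' The case is generated like a control, except the Poisson rate is
#' multiplied by `cn / 2` inside each truth event's window span.
#'
#' @param xp A [sim_experiment()].
#' @param truth A [sim_truth()] table (may have zero rows for a diploid
#'   null sample).
#' @param sample_id Sample identifier.
#' @return A `"pscc_counts"` track.
#' @export
sim_case <- function(xp, truth = NULL, sample_id = "case") {
  cn_factor <- rep(1, nrow(xp$windows))
  if (!is.null(truth) && nrow(truth)) {
    for (i in seq_len(nrow(truth)))
      cn_factor[truth$first_window[i]:truth$last_window[i]] <- truth$cn[i] / 2
  }
  sim_draw_counts(xp, cn_factor, sample_id)
}
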