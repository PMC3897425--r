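## Call-level evaluation and power studies.

#' Score calls against a truth set at call level
#'
#' A truth event counts as detected when some call of the same state
#' reciprocally overlaps it by at least `criterion` (overlap at least
#' `criterion` times the call length AND at least `criterion` times the
#' truth length; the boundary is inclusive). A call is false when it matches
#' no truth event under the same rule. Specificity is reported as
#' `1 - false calls / total calls`.
#'
#' @param calls A calls table from [call_cnvs()] (columns `chrom`, `start`,
#'   `end`, `state`).
#' @param truth A [sim_truth()] table (columns `chrom`, `start`, `end`,
#'   `type`).
#' @param criterion Reciprocal-overlap fraction (default 0.5).
#' @return A list: `truth` (with logical `detected`), `calls` (with logical
#'   `matched`), and `summary` (`n_truth`, `n_detected`, `sensitivity`,
#'   `n_calls`, `n_false`, `specificity`).
#' @export
evaluate_calls <- function(calls, truth, criterion = 0.5) {
  nt <- nrow(truth); nc <- nrow(calls)
  detected <- logical(nt)
  matched <- logical(nc)
  if (nt && nc) {
    for (i in seq_len(nt)) {
      cand <- which(calls$chrom == truth$chrom[i] &
                      calls$state == truth$type[i])
      for (j in cand) {
        ov <- min(calls$end[j], truth$end[i]) - max(calls$start[j], truth$start[i])
        if (ov <= 0) next
        if (ov >= criterion * (calls$end[j] - calls$start[j]) &&
            ov >= criterion * (truth$end[i] - truth$start[i])) {
          detected[i] <- TRUE
          matched[j] <- TRUE
        }
      }
    }
  }
  truth$detected <- detected
  calls$matched <- matched
  list(truth = truth, calls = calls,
       summary = list(n_truth = nt, n_detected = sum(detected),
                      sensitivity = if (nt) sum(detected) / nt else NA_real_,
                      n_calls = nc, n_false = sum(!matched),
                      specificity = if (nc) 1 - sum(!matched) / nc else NA_real_))
}

#' Run one simulation cell of a power study
#'
#' Builds one experiment (shared windows, GC profile and multiplex bias),
#' generates and corrects the control panel, then for each case sample
#' spikes a fresh truth set, runs the full pipeline (GC correction, panel
#' normalization, segmentation, combined tests) and scores the calls at
#' call level. Deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @param n_cases Number of case samples.
#' @param events_per_case Spiked events per case (half deletions, half
#'   duplications).
#' @param size_range Event size range in bp (log-uniform draw).
#' @param params A [pscc_params()] list.
#' @param criterion Reciprocal-overlap detection criterion.
#' @return A list with pooled `truth` and `calls` tables (each carrying
#'   `sample`, sizes and match flags) and the experiment's window width.
#' @export
power_cell <- function(cfg, n_cases = 50, events_per_case = 10,
                       size_range = c(3e5, 1e7), params = pscc_params(),
                       criterion = 0.5) {
  xp <- sim_experiment(cfg)
  ctrl <- generate_panel_tracks(xp)
  ctrl <- lapply(ctrl, gc_correct,
                 gc_bin_width = params$gc_bin_width,
                 min_bin = params$gc_min_bin)
  panel <- build_panel(ctrl, mu_floor_frac = params$mu_floor_frac)
  truth_all <- list()
  calls_all <- list()
  half <- floor(events_per_case / 2)
  types <- rep(c("deletion", "duplication"), length.out = events_per_case)
  for (s in seq_len(n_cases)) {
    id <- sprintf("case%03d", s)
    truth <- sim_truth(xp, events_per_case, size_range, types = sample(types))
    case <- sim_case(xp, truth, id)
    case <- gc_correct(case, params$gc_bin_width, params$gc_min_bin)
    rcr <- normalize_rcr(case, panel)
    res <- call_cnvs(rcr, panel, params, id)
    ev <- evaluate_calls(res$calls, truth, criterion)
    ev$truth$sample <- rep(id, nrow(ev$truth))
    truth_all[[s]] <- ev$truth
    calls_all[[s]] <- ev$calls
  }
  truth <- do.call(rbind, truth_all)
  calls <- do.call(rbind, calls_all)
  list(truth = truth, calls = calls, window_width = xp$window_width,
       cfg = cfg)
}

#' Summarize a power cell above a size threshold
#'
#' @param cell A [power_cell()] result.
#' @param min_size Count only truth events (and calls) strictly larger than
#'   this many bp.
#' @param type Optionally restrict truth events to `"deletion"` or
#'   `"duplication"`.
#' @return A list with `sensitivity`, `specificity` (both in percent),
#'   `n_truth`, `n_calls`, `n_false`.
#' @export
power_summary <- function(cell, min_size = 3e5, type = NULL) {
  tr <- cell$truth[cell$truth$size > min_size, , drop = FALSE]
  if (!is.null(type)) tr <- tr[tr$type == type, , drop = FALSE]
  ca <- cell$calls
  if (nrow(ca)) ca <- ca[(ca$end - ca$start) > min_size, , drop = FALSE]
  list(sensitivity = 100 * mean(tr$detected),
       specificity = if (nrow(ca)) 100 * (1 - sum(!ca$matched) / nrow(ca))
                     else NA_real_,
       n_truth = nrow(tr), n_calls = nrow(ca), n_false = sum(!ca$matched))
}

#' Sensitivity/specificity grid across event sizes and depths
#'
#' Runs [power_cell()] for every combination of the depth and size-bin
#' grids and tabulates call-level sensitivity and specificity per cell,
#' the usual way detection power of read-depth callers is reported.
#'
#' @param depths Vector of depth factors.
#' @param size_bins Two-column matrix (or list of length-2 vectors) of size
#'   ranges in bp.
#' @param cfg Base [sim_config()]; its `depth` and `seed` are overridden
#'   per cell (seed offset by cell index for independence, derived from
#'   `cfg$seed`).
#' @param n_cases,events_per_case,params,criterion Passed to
#'   [power_cell()].
#' @return A `data.frame` with one row per cell: `depth`, `size_min`,
#'   `size_max`, `sensitivity`, `specificity`, `n_truth`, `n_calls`.
#' @export
power_study <- function(depths = c(0.2, 2),
                        size_bins = list(c(1e5, 1e6), c(1e6, 1e7)),
                        cfg = sim_config(), n_cases = 10,
                        events_per_case = 10, params = pscc_params(),
                        criterion = 0.5) {
  if (is.matrix(size_bins))
    size_bins <- lapply(seq_len(nrow(size_bins)), function(i) size_bins[i, ])
  rows <- list()
  k <- 0L
  for (d in depths) for (sb in size_bins) {
    k <- k + 1L
    cfg_cell <- cfg
    cfg_cell$depth <- d
    cfg_cell$seed <- cfg$seed + 1000L * k
    cell <- power_cell(cfg_cell, n_cases, events_per_case, sb, params,
                       criterion)
    s <- power_summary(cell, min_size = 0)
    rows[[k]] <- data.frame(depth = d, size_min = sb[1], size_max = sb[2],
                            sensitivity = s$sensitivity,
                            specificity = s$specificity,
                            n_truth = s$n_truth, n_calls = s$n_calls)
  }
  do.call(rbind, rows)
}
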