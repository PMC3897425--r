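#' Pipeline parameters
#'
#' Collects the tunable parameters of the caller in one validated list.
#' Defaults correspond to the settings used for low-coverage (~2x) calling
#' with 150 expected reads per observation window.
#'
#' @param expected_rc Target expected read count per observation window.
#' @param gc_bin_width Width of the GC-content bins used for the
#'   within-sample median correction (fraction of GC; default 0.01 = 1%).
#' @param gc_min_bin Minimum number of usable windows a GC bin must hold to
#'   contribute its own median; sparser bins borrow the nearest populated
#'   bin's median.
#' @param mu_floor_frac Windows whose panel mean falls below this fraction of
#'   the panel-wide median mean are flagged unusable (guards divisions in
#'   unmappable regions).
#' @param block Number of windows on each side of a position used by the
#'   scanning runs test when proposing candidate breakpoints.
#' @param p_enter Candidate-entry p-value threshold for the scanning runs
#'   test (local minima of the p curve at or below this enter pruning).
#' @param p_genome Genome-wide significance threshold for surviving
#'   breakpoints. `NULL` (default) means Bonferroni: 0.05 divided by the
#'   number of tested positions.
#' @param max_flank Cap, in windows, on the flank length used when a
#'   breakpoint is re-tested against its neighbouring segments during
#'   pruning.
#' @param min_seg_windows Segments with fewer usable windows than this are
#'   merged into the neighbour with the closer mean.
#' @param exact_limit Pooled sample size at or below which the runs-test
#'   p-value uses the exact run-count null distribution; larger pools use
#'   the normal approximation with continuity correction.
#' @param alpha_st Significance level of the self-test (rank test of a
#'   segment against the rest of the genome).
#' @param alpha_pt Significance level of the parallelism-test (z test of the
#'   segment mean against the panel-implied standard error).
#' @param min_size Minimum reportable call size in base pairs.
#' @param quality_frac A sample is flagged for re-sequencing when more than
#'   this fraction of its segments land in the `sample_quality` category.
#'
#' @return A list of class `"pscc_params"`.
#' @export
#' @examples
#' p <- pscc_params(block = 12)
#' p$block
pscc_params <- function(expected_rc = 150,
                        gc_bin_width = 0.01,
                        gc_min_bin = 50,
                        mu_floor_frac = 0.1,
                        block = 10,
                        p_enter = 0.01,
                        p_genome = NULL,
                        max_flank = 200,
                        min_seg_windows = 3,
                        exact_limit = 40,
                        alpha_st = 0.001,
                        alpha_pt = 0.001,
                        min_size = 1e5,
                        quality_frac = 0.01) {
  stopifnot(expected_rc >= 1,
            gc_bin_width > 0, gc_bin_width <= 0.1,
            gc_min_bin >= 1,
            mu_floor_frac >= 0, mu_floor_frac < 1,
            block >= 5,
            p_enter > 0, p_enter <= 1,
            is.null(p_genome) || (p_genome > 0 && p_genome <= 1),
            max_flank >= block,
            min_seg_windows >= 1,
            exact_limit >= 0,
            alpha_st > 0, alpha_st < 1,
            alpha_pt > 0, alpha_pt < 1,
            min_size >= 0,
            quality_frac >= 0, quality_frac <= 1)
  structure(list(expected_rc = expected_rc,
                 gc_bin_width = gc_bin_width,
                 gc_min_bin = gc_min_bin,
                 mu_floor_frac = mu_floor_frac,
                 block = as.integer(block),
                 p_enter = p_enter,
                 p_genome = p_genome,
                 max_flank = as.integer(max_flank),
                 min_seg_windows = as.integer(min_seg_windows),
                 exact_limit = as.integer(exact_limit),
                 alpha_st = alpha_st,
                 alpha_pt = alpha_pt,
                 min_size = min_size,
                 quality_frac = quality_frac),
            class = "pscc_params")
}
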