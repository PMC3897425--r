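test_that("unbiased simulator counts are Poisson at the expected rate", {
  cfg <- sim_config(n_chrom = 2, windows_per_chrom = 5000, gc_bias = FALSE,
                    multiplex_sd = 0, overdispersion = 1, n_controls = 2,
                    seed = 3)
  xp <- sim_experiment(cfg)
  tr <- pscc:::sim_draw_counts(xp)
  n <- nrow(tr)
  se <- sqrt(150 / n)
  expect_lt(abs(mean(tr$count) - 150), 3 * se)
  expect_equal(var(tr$count), 150, tolerance = 0.1)
})

test_that("window width encodes depth at constant expected read count", {
  w2 <- sim_experiment(sim_config(n_chrom = 1, windows_per_chrom = 10,
                                  depth = 2, n_controls = 2))$window_width
  w02 <- sim_experiment(sim_config(n_chrom = 1, windows_per_chrom = 10,
                                   depth = 0.2, n_controls = 2))$window_width
  expect_equal(w2, 2700L)     # 150 reads * 36 bp / 2x
  expect_equal(w02, 27000L)   # ten-fold wider at a tenth the depth
})

test_that("the multiplex bias is shared across samples of one experiment", {
  cfg <- sim_config(n_chrom = 1, windows_per_chrom = 2000, n_controls = 2,
                    seed = 17)
  xp1 <- sim_experiment(cfg)
  xp2 <- sim_experiment(cfg)
  expect_identical(xp1$bias, xp2$bias)   # same seed, same shared structure
  expect_identical(xp1$gc, xp2$gc)
  t1 <- pscc:::sim_draw_counts(xp1)
  t2 <- pscc:::sim_draw_counts(xp1)
  expect_gt(sum(t1$count != t2$count), 0)  # counts remain independent draws
})

test_that("the GC curve suppresses GC-poor and GC-rich windows as designed", {
  expect_equal(gc_bias_curve(0.40), 1)
  expect_equal(gc_bias_curve(0.35), 1)
  expect_equal(gc_bias_curve(0.50), 1)
  expect_equal(gc_bias_curve(0.60), 0.5)   # 2-fold suppression
  expect_equal(gc_bias_curve(0.25), 0.5)
  expect_true(all(diff(gc_bias_curve(seq(0, 0.35, 0.01))) >= 0))
  expect_true(all(diff(gc_bias_curve(seq(0.50, 1, 0.01))) <= 0))
})

test_that("spiked events multiply the rate by half the copy number", {
  cfg <- sim_config(n_chrom = 2, windows_per_chrom = 2000, gc_bias = FALSE,
                    multiplex_sd = 0, overdispersion = 1, n_controls = 2,
                    seed = 19)
  xp <- sim_experiment(cfg)
  truth <- data.frame(chrom = c("sim01", "sim02"),
                      start = c(xp$windows$start[101], xp$windows$start[2101]),
                      end = c(xp$windows$end[1100], xp$windows$end[3100]),
                      first_window = c(101L, 2101L),
                      last_window = c(1100L, 3100L), n_windows = 1000L,
                      type = c("deletion", "duplication"), cn = c(1L, 3L))
  case <- sim_case(xp, truth)
  expect_equal(mean(case$count[101:1100]), 75, tolerance = 0.03)
  expect_equal(mean(case$count[2101:3100]), 225, tolerance = 0.03)
  expect_equal(mean(case$count[1101:2100]), 150, tolerance = 0.03)

  # CN = 2 events leave the distribution unchanged
  truth2 <- truth[1, ]; truth2$cn <- 2L
  set.seed(5); a <- sim_case(xp, truth2)
  set.seed(5); b <- sim_case(xp, NULL)
  expect_identical(a$count, b$count)
})

test_that("truth sets respect bounds, types and non-overlap", {
  cfg <- sim_config(n_chrom = 12, windows_per_chrom = 500, depth = 0.2,
                    n_controls = 2, seed = 23)
  xp <- sim_experiment(cfg)
  set.seed(29)
  for (rep in 1:10) {
    tr <- sim_truth(xp, 10, c(3e5, 1e7))
    expect_equal(sum(tr$type == "deletion"), 5L)
    expect_lte(max(table(tr$chrom)), 1L)  # one event per chromosome
    expect_true(all(tr$last_window <= nrow(xp$windows)))
    expect_true(all(tr$n_windows >= 1L))
    expect_true(all(tr$end > tr$start))
  }
})

test_that("call-level scoring implements inclusive reciprocal overlap", {
  truth <- data.frame(chrom = "sim01", start = 0L, end = 1000L,
                      type = "deletion", stringsAsFactors = FALSE)
  perfect <- data.frame(chrom = "sim01", start = 0L, end = 1000L,
                        state = "deletion", stringsAsFactors = FALSE)
  ev <- evaluate_calls(perfect, truth)
  expect_equal(ev$summary$sensitivity, 1)
  expect_equal(ev$summary$n_false, 0L)

  none <- perfect[0, ]
  ev0 <- evaluate_calls(none, truth)
  expect_equal(ev0$summary$sensitivity, 0)
  expect_true(is.na(ev0$summary$specificity))

  # call covering exactly half the event: 50% reciprocal overlap counts
  half <- data.frame(chrom = "sim01", start = 0L, end = 500L,
                     state = "deletion", stringsAsFactors = FALSE)
  expect_true(evaluate_calls(half, truth, criterion = 0.5)$truth$detected)
  expect_false(evaluate_calls(half, truth, criterion = 0.51)$truth$detected)

  # state mismatch never matches
  dup <- data.frame(chrom = "sim01", start = 0L, end = 1000L,
                    state = "duplication", stringsAsFactors = FALSE)
  evd <- evaluate_calls(dup, truth)
  expect_false(evd$truth$detected)
  expect_equal(evd$summary$n_false, 1L)
})

test_that("power cells are reproducible and summarize by size and type", {
  cfg <- sim_config(n_chrom = 6, windows_per_chrom = 400, depth = 0.2,
                    n_controls = 10, seed = 31)
  pars <- pscc_params(gc_min_bin = 20)
  c1 <- power_cell(cfg, n_cases = 2, events_per_case = 4,
                   size_range = c(5e5, 5e6), params = pars)
  c2 <- power_cell(cfg, n_cases = 2, events_per_case = 4,
                   size_range = c(5e5, 5e6), params = pars)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$calls, c2$calls)
  s <- power_summary(c1, min_size = 3e5)
  expect_true(s$n_truth <= 8 && s$n_truth >= 1)
  sd_ <- power_summary(c1, min_size = 3e5, type = "deletion")
  su <- power_summary(c1, min_size = 3e5, type = "duplication")
  expect_equal(sd_$n_truth + su$n_truth, s$n_truth)
})

test_that("sensitivity grows with event size and depth (unbiased model)", {
  cfg <- sim_config(n_chrom = 6, windows_per_chrom = 600, gc_bias = FALSE,
                    multiplex_sd = 0, n_controls = 10, seed = 37)
  pars <- pscc_params(gc_min_bin = 20)
  tab <- power_study(depths = c(0.2, 2),
                     size_bins = list(c(5e4, 2e5), c(8e5, 1.2e6)),
                     cfg = cfg, n_cases = 4, events_per_case = 6,
                     params = pars)
  for (d in unique(tab$depth)) {
    sub <- tab[tab$depth == d, ]
    expect_true(all(diff(sub[order(sub$size_min), "sensitivity"]) >= 0))
  }
  small <- tab[tab$size_min == 5e4, ]
  expect_true(all(diff(small[order(small$depth), "sensitivity"]) >= 0))
})
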