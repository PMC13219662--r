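test_that("the ROH age and Ne closed forms are exact", {
  expect_equal(roh_age(1, 2.8), 100 / (2 * 2.8 * 1))
  expect_equal(roh_age(1, 2.8), 17.857, tolerance = 1e-4)
  expect_equal(roh_age(5, 2.8), 3.571, tolerance = 1e-3)
  # doubling L halves g
  set.seed(2)
  l <- stats::runif(20, 0.5, 60)
  expect_equal(roh_age(2 * l), roh_age(l) / 2)
  expect_error(roh_age(0), "positive")
  expect_error(roh_age(1, -1), "positive")

  expect_equal(ne_from_froh(0.5, 1), 1)
  expect_equal(ne_from_froh(0.75, 2), 1)
  expect_warning(expect_equal(ne_from_froh(1, 1), 0.5), "boundary")
  expect_warning(expect_true(is.infinite(ne_from_froh(0, 5))), "boundary")
  expect_error(ne_from_froh(-0.1, 1), "0, 1")

  # forward/inverse round trip over a parameter grid
  for (ne in c(2, 10, 100, 1e4)) {
    for (t in c(1, 10, 100)) {
      f <- froh_expected(ne, t)
      expect_equal(ne_from_froh(f, t, complement = froh_survival(ne, t)),
                   ne, tolerance = 1e-9)
      expect_equal(ne_from_froh(f, t), ne, tolerance = 1e-5)
    }
  }
})

test_that("froh applies length and posterior cutoffs over merged intervals", {
  cfg <- roh_config(genome_length = 1e8)
  one <- tibble::tibble(sample = "S1", chrom = "chr1",
                        start = 0, end = 5e7, p_roh = 1)
  expect_equal(froh(one, cfg)$froh, 0.5)

  short <- tibble::tibble(sample = "S1", chrom = "chr1",
                          start = c(0, 1e6), end = c(5e5, 1.5e6),
                          p_roh = 1)
  expect_equal(froh(short, cfg)$froh, 0)  # all below the 1 Mb cutoff

  lowp <- dplyr::mutate(one, p_roh = 0.8)
  expect_equal(froh(lowp, cfg)$froh, 0)   # posterior below 0.9

  # overlapping intervals merge before measuring
  over <- tibble::tibble(sample = "S1", chrom = "chr1",
                         start = c(0, 1e6), end = c(2e6, 4e6), p_roh = 1)
  expect_equal(froh(over, cfg)$froh, 0.04)

  expect_error(froh(tibble::tibble(sample = "S1", chrom = "chr1",
                                   start = 0, end = 2e8, p_roh = 1), cfg),
               "coordinate mismatch")

  # monotone non-increasing in the minimum length
  set.seed(4)
  iv <- tibble::tibble(sample = "S1", chrom = "chr1",
                       start = seq(0, 9e7, by = 1e7),
                       end = seq(0, 9e7, by = 1e7) +
                         stats::runif(10, 2e5, 8e6),
                       p_roh = 1)
  fs <- vapply(c(0, 5e5, 1e6, 2e6, 4e6, 8e6), function(m) {
    froh(iv, roh_config(min_roh_length = m, genome_length = 1e8))$froh
  }, 1)
  expect_true(all(diff(fs) <= 0))
})

test_that("the window caller handles degenerate inputs and recovers planted tracts", {
  cl <- c(chr1 = 1e7)
  none <- tibble::tibble(sample = character(), chrom = character(),
                         pos = integer())
  iv <- call_roh_windows(none, cl, window_bp = 1e6, samples = "S1")
  expect_equal(nrow(iv), 1L)
  expect_equal(iv$end - iv$start, 1e7)   # zero het: one ROH, whole chromosome

  dense <- tibble::tibble(sample = "S1", chrom = "chr1",
                          pos = seq(5e5, 1e7, by = 1e6))
  expect_equal(nrow(call_roh_windows(dense, cl, window_bp = 1e6)), 0L)

  expect_error(call_roh_windows(dense, cl, window_bp = 0), "positive")

  # planted tracts recovered with boundary error <= one window
  set.seed(12)
  cl2 <- c(chr1 = 5e7)
  win <- 2e4
  sim <- simulate_planted_roh(0.4, cl2, het_rate_outside = 1e-3,
                              mean_tract = 4e6, min_tract = 1.5e6)
  called <- call_roh_windows(sim$het_positions, cl2, window_bp = win,
                             max_het_per_window = 0)
  truth <- sim$truth
  for (i in seq_len(nrow(truth))) {
    ovl <- called[called$end > truth$start[i] &
                    called$start < truth$end[i], ]
    expect_gte(nrow(ovl), 1)
    expect_lte(abs(min(ovl$start) - truth$start[i]), win)
    expect_lte(abs(max(ovl$end) - truth$end[i]), win)
  }
})

test_that("interval merging is idempotent and order-insensitive", {
  set.seed(8)
  iv <- tibble::tibble(
    sample = "S1",
    chrom = sample(c("chr1", "chr2"), 30, replace = TRUE),
    start = sample.int(1e6, 30))
  iv$end <- iv$start + sample.int(2e5, 30)
  iv$p_roh <- 1
  m1 <- loadscape:::merge_roh(iv)
  m2 <- loadscape:::merge_roh(m1)
  expect_equal(m1, m2)
  shuffled <- iv[sample.int(nrow(iv)), ]
  m3 <- loadscape:::merge_roh(shuffled)
  expect_equal(sum(m3$end - m3$start), sum(m1$end - m1$start))
})

test_that("ne_trajectory composes roh_age and ne_from_froh exactly", {
  cfg <- roh_config(genome_length = 1e8,
                    length_bins = list(c(16, 64)))
  iv <- tibble::tibble(sample = "S1", chrom = "chr1",
                       start = 0, end = 5e7, p_roh = 1)
  tr <- ne_trajectory(iv, cfg)
  l_rep <- sqrt(16 * 64)
  t_rep <- roh_age(l_rep, cfg$recombination_rate)
  expect_equal(tr$f_bin, 0.5)
  expect_equal(tr$length_mb, l_rep)
  expect_equal(tr$age_generations, t_rep)
  expect_equal(tr$age_years, t_rep * 2)
  expect_equal(tr$ne, ne_from_froh(0.5, t_rep))

  # midpoint alternative
  cfg_mid <- roh_config(genome_length = 1e8,
                        length_bins = list(c(16, 64)),
                        bin_representative = "midpoint")
  expect_equal(ne_trajectory(iv, cfg_mid)$length_mb, 40)

  # no ROH: bins undetermined
  tr0 <- ne_trajectory(iv[0, ], roh_config(genome_length = 1e8))
  expect_true(all(is.na(tr0$ne)))
  expect_error(
    ne_trajectory(iv, roh_config(genome_length = 1e8,
                                 length_bins = list())),
    "non-empty")
})
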