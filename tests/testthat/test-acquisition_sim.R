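test_that("acquisition simulation is seeded and unbiased", {
  base <- sinusoid_trace(2.5e6, n = 2048)
  s0 <- simulate_acquisitions(base, noise_sigma = 0, n = 5, seed = 1)
  for (i in 1:5) expect_equal(s0$traces[i, ], base$pressure)
  a <- simulate_acquisitions(base, noise_sigma = 0.5, n = 50, seed = 3)
  b <- simulate_acquisitions(base, noise_sigma = 0.5, n = 50, seed = 3)
  expect_identical(a$traces, b$traces)
  d <- simulate_acquisitions(base, noise_sigma = 0.5, n = 50, seed = 4)
  expect_false(identical(a$traces, d$traces))
  # CLT: the mean of n acquisitions approaches the base trace
  big <- simulate_acquisitions(base, noise_sigma = 1, n = 3000, seed = 7)
  m <- colMeans(big$traces)
  bound <- 3 * 1 / sqrt(3000)
  expect_lt(stats::quantile(abs(m - base$pressure), 0.99), 1.5 * bound)
  expect_lt(max(abs(m - base$pressure)), 5 * 1 / sqrt(3000))
})

test_that("grouped statistics partition 3000 acquisitions into 30 x 100", {
  base <- sinusoid_trace(2.5e6, n = 512)
  set <- simulate_acquisitions(base, noise_sigma = 0.2, n = 3000, seed = 2)
  gs <- grouped_stats(set, function(tr) max(tr$pressure))
  expect_equal(gs$n_groups, 30)
  expect_equal(gs$group_size, 100)
  expect_length(gs$values, 30)
  expect_gte(gs$ci_half_width, 0)
  # zero noise: all groups identical, zero half-width
  set0 <- simulate_acquisitions(base, noise_sigma = 0, n = 300, seed = 2)
  gs0 <- grouped_stats(set0, function(tr) max(tr$pressure), n_groups = 3)
  expect_equal(gs0$ci_half_width, 0)
  expect_error(grouped_stats(set0, max, n_groups = 4, group_size = 100),
               "insufficient")
})

test_that("group statistics are invariant to within-group reordering", {
  base <- sinusoid_trace(1e6, n = 256)
  set <- simulate_acquisitions(base, noise_sigma = 0.3, n = 120, seed = 9)
  gs1 <- grouped_stats(set, function(tr) mean(tr$pressure^2), n_groups = 4)
  set2 <- set
  # permute acquisitions inside each group of 30
  for (g in 1:4) {
    rows <- ((g - 1) * 30 + 1):(g * 30)
    set2$traces[rows, ] <- set2$traces[sample(rows), ]
  }
  gs2 <- grouped_stats(set2, function(tr) mean(tr$pressure^2), n_groups = 4)
  expect_equal(gs2$values, gs1$values, tolerance = 1e-12)
})

test_that("99% confidence intervals achieve nominal coverage", {
  # known Gaussian noise on a sinusoid; amplitude statistic at f0
  f0 <- fs_acq / 16
  n_samp <- 1024
  base <- sinusoid_trace(f0, n = n_samp, amp = 2)
  win <- c(0, n_samp / fs_acq)
  stat <- function(tr) amplitude_at_frequency(tr, f0, window = win,
                                              df = fs_acq / 4096)$amplitude
  # truth: amplitude of the noiseless base trace
  truth <- stat(base)
  n_rep <- 400
  cover <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    set <- simulate_acquisitions(base, noise_sigma = 1.5, n = 240, seed = r)
    gs <- grouped_stats(set, stat, n_groups = 12, group_size = 20)
    cover[r] <- abs(gs$mean - truth) <= gs$ci_half_width
  }
  cov <- mean(cover)
  # binomial noise on 400 replicates: ~99% +- ~1.5%
  expect_gte(cov, 0.965)
})

test_that("confidence half-width shrinks like 1/sqrt(group size)", {
  base <- sinusoid_trace(2e6, n = 512)
  hw <- vapply(c(10, 40, 160), function(gsz) {
    hws <- vapply(1:12, function(s) {
      set <- simulate_acquisitions(base, noise_sigma = 1, n = 10 * gsz,
                                   seed = 100 + s)
      grouped_stats(set, function(tr) mean(tr$pressure),
                    n_groups = 10, group_size = gsz)$ci_half_width
    }, numeric(1))
    mean(hws)
  }, numeric(1))
  expect_equal(hw[1] / hw[2], 2, tolerance = 0.3)
  expect_equal(hw[2] / hw[3], 2, tolerance = 0.3)
})

test_that("measurement sets round-trip through CSV", {
  base <- sinusoid_trace(1e6, n = 64)
  set <- simulate_acquisitions(base, noise_sigma = 0.1, n = 5, seed = 1)
  f <- tempfile(fileext = ".csv")
  measurement_set_write(set, f)
  set2 <- measurement_set_read(f)
  expect_equal(set2$traces, set$traces, tolerance = 1e-12,
               ignore_attr = TRUE)
  unlink(f)
})
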