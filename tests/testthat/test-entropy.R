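# Interaction-entropy estimator, outlier filter, window planning and
# aggregation.

test_that("outlier filter keeps order, drops spikes, tolerates ties", {
  expect_equal(filter_outliers(rep(2, 50)), rep(2, 50))
  x <- gaussian_energy_series(0, 1, 1000, seed = 2)
  spike <- c(x, mean(x) + 10 * stats::sd(x))
  kept <- filter_outliers(spike, 3)
  expect_length(kept, 1000L)
  expect_equal(kept, spike[seq_len(1000)]) # order preserved
  expect_equal(filter_outliers(c(1, 5)), c(1, 5))
  expect_error(filter_outliers(numeric(0)), "empty")
})

test_that("IE of constant, Gaussian, and two-point series match closed forms", {
  expect_equal(interaction_entropy(rep(-7, 100))$minus_t_ds, 0)
  # translation invariance
  x <- gaussian_energy_series(0, 0.8, 5000, seed = 3)
  e1 <- interaction_entropy(x)$minus_t_ds
  e2 <- interaction_entropy(x + 123.4)$minus_t_ds
  expect_num_eq(e1, e2, 1e-9)
  # Gaussian closed form sigma^2 / (2 kT) at N = 1e6
  g <- gaussian_energy_series(-10, 1, 1e6, seed = 42)
  kt <- KB * 300
  expect_equal(interaction_entropy(g, 300)$minus_t_ds, 1 / (2 * kt),
               tolerance = 0.012)
  # alternating +/- 1: kT ln cosh(1/kT)
  alt <- rep(c(1, -1), 500)
  expect_equal(interaction_entropy(alt, 300)$minus_t_ds,
               kt * log(cosh(1 / kt)), tolerance = 1e-10)
})

test_that("IE is non-negative and monotone in spread", {
  set.seed(77)
  for (i in 1:10) {
    x <- rnorm(200, sd = runif(1, 0.1, 2))
    v1 <- interaction_entropy(x)$minus_t_ds
    v2 <- interaction_entropy(1.5 * (x - mean(x)) + mean(x))$minus_t_ds
    expect_gte(v1, 0)
    expect_gte(v2, v1 - 1e-12)
  }
})

test_that("log-sum-exp path agrees with naive exponentiation", {
  x <- gaussian_energy_series(0, 2, 2000, seed = 5)
  kt <- KB * 300
  naive <- kt * log(mean(exp((x - mean(x)) / kt)))
  expect_num_eq(interaction_entropy(x)$minus_t_ds, naive, 1e-10)
  # large fluctuations overflow the naive path but not the estimator
  big <- c(rep(0, 10), 5000)
  expect_true(is.finite(interaction_entropy(big)$minus_t_ds))
})

test_that("IE records filtering counts", {
  x <- c(gaussian_energy_series(0, 1, 500, seed = 9), 50)
  r <- interaction_entropy(x, filter_sd = 3)
  expect_equal(r$n_frames_used + r$n_frames_filtered, 501L)
  expect_gte(r$n_frames_filtered, 1L)
})

test_that("window planner honors protocol arithmetic and stability", {
  # 100 ns at 1 ps -> 5 windows x 5000 frames
  flat <- rep(1, 100000)
  w <- plan_windows(flat, 1, 5000, 5)
  expect_equal(nrow(w), 5L)
  expect_equal(w$end - w$start + 1L, rep(5000L, 5))
  # flat series: earliest non-overlapping windows win ties
  expect_equal(w$start, c(1L, 5001L, 10001L, 15001L, 20001L))
  # noisy segment is avoided
  st <- rep(0.5, 40000)
  st[20001:30000] <- st[20001:30000] + rep(c(0, 4), 5000)
  w2 <- plan_windows(st, 1, 5000, 5)
  overlaps <- w2$start <= 30000 & w2$end >= 20001
  expect_false(any(overlaps))
  expect_error(plan_windows(rep(1, 100), 1, 5000, 5), "short")
})

test_that("window aggregation uses the sample SD", {
  a <- aggregate_windows(c(1, 1, 1))
  expect_equal(a$mean, 1)
  expect_equal(a$sd, 0)
  b <- aggregate_windows(c(0, 2))
  expect_equal(b$mean, 1)
  expect_equal(b$sd, sqrt(2))
  expect_equal(aggregate_windows(rep(3.2, 15))$sd, 0)
  expect_error(aggregate_windows(1), "windows")
})
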