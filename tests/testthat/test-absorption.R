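# The mono-only meal has the closed-form (bi-exponential) solution
#   rate(t) = k_abs * k_e * M * (exp(-k_e t) - exp(-k_abs t)) / (k_abs - k_e)
# which serves as the independent oracle for the integrator.
mono_closed_form <- function(t, mass, k_e, k_abs) {
  k_abs * k_e * mass * (exp(-k_e * t) - exp(-k_abs * t)) / (k_abs - k_e)
}

trapz <- function(t, r) {
  n <- length(t)
  sum(diff(t) * (r[-n] + r[-1]) / 2)
}

random_meal <- function(i) {
  meal_record("P", paste0("m", i), "2021-03-01T08:00:00",
              monosaccharide_g = runif(1, 5, 40),
              starch_g = runif(1, 10, 100),
              protein_g = runif(1, 0, 30),
              lipid_g = runif(1, 0, 30),
              fiber_g = runif(1, 0, 12),
              glycemic_index = runif(1, 50, 110))
}

test_that("zero-carbohydrate meals yield the flagged empty curve", {
  m <- meal_record("P", "m0", "2021-03-01T08:00:00", 0, 0, 20, 10, 3, 70)
  cv <- simulate_absorption(m)
  expect_true(cv$empty)
  expect_identical(cv$times_min, 0)
  expect_identical(cv$rates_g_per_min, 0)
})

test_that("negative masses and malformed meals are rejected", {
  expect_error(meal_record("P", "m", "2021-03-01T08:00:00", -1, 10),
               "masses")
  m <- meal_record("P", "m", "2021-03-01T08:00:00", 10, 0)
  m$starch_g <- -5
  expect_error(simulate_absorption(m), ">= 0")
  m$starch_g <- NULL
  expect_error(simulate_absorption(m), "starch_g")
})

test_that("mono-only meals match the bi-exponential closed form", {
  p <- absorption_params()
  m <- meal_record("P", "m1", "2021-03-01T08:00:00", 10, 0, 0, 0, 0, 70)
  cv <- simulate_absorption(m, p)
  expect_false(cv$empty)
  analytic <- mono_closed_form(cv$times_min, 10, p$k_empty0, p$k_abs)
  expect_lt(max(abs(cv$rates_g_per_min - analytic)), 1e-3)
  # peak within one grid step of the closed-form peak time
  t_peak_exact <- log(p$k_abs / p$k_empty0) / (p$k_abs - p$k_empty0)
  i_peak <- which.max(cv$rates_g_per_min)
  expect_lte(abs(cv$times_min[i_peak] - t_peak_exact), p$step_min)
})

test_that("protein, lipid and fiber delay and flatten the curve", {
  base <- meal_record("P", "a", "2021-03-01T08:00:00", 10, 0, 0, 0, 0, 70)
  fib <- meal_record("P", "b", "2021-03-01T08:00:00", 10, 0, 0, 0, 20, 70)
  fine <- absorption_params(step_min = 0.125)
  for (prm in list(absorption_params(), fine)) {
    cv0 <- simulate_absorption(base, prm)
    cv1 <- simulate_absorption(fib, prm)
    expect_lt(max(cv1$rates_g_per_min), max(cv0$rates_g_per_min))
    expect_gt(cv1$times_min[which.max(cv1$rates_g_per_min)],
              cv0$times_min[which.max(cv0$rates_g_per_min)])
  }
})

test_that("the returned curve conserves digestible carbohydrate mass", {
  set.seed(101)
  for (i in 1:25) {
    m <- random_meal(i)
    cv <- simulate_absorption(m)
    ch <- total_ch_g(m)
    area <- trapz(cv$times_min, cv$rates_g_per_min)
    expect_lt(max(cv$times_min), absorption_params()$t_max_min)
    expect_gte(area, 0.995 * ch)
    expect_lte(area, ch * (1 + 1e-9))
    expect_true(all(cv$rates_g_per_min >= 0))
  }
})

test_that("rates are linear in the carbohydrate pools at fixed inhibitors", {
  m1 <- meal_record("P", "a", "2021-03-01T08:00:00", 8, 30, 15, 10, 4, 80)
  m3 <- m1
  m3$monosaccharide_g <- 3 * m1$monosaccharide_g
  m3$starch_g <- 3 * m1$starch_g
  p <- absorption_params(completeness = 0.9999, t_max_min = 2000)
  cv1 <- simulate_absorption(m1, p)
  cv3 <- simulate_absorption(m3, p)
  n <- min(length(cv1$rates_g_per_min), length(cv3$rates_g_per_min))
  expect_equal(cv3$rates_g_per_min[1:n], 3 * cv1$rates_g_per_min[1:n],
               tolerance = 1e-12)
})

test_that("halving the integration step barely changes the curve", {
  m <- meal_record("P", "a", "2021-03-01T08:00:00", 20, 100, 20, 15, 8, 60)
  cv1 <- simulate_absorption(m, absorption_params(step_min = 1))
  cv2 <- simulate_absorption(m, absorption_params(step_min = 0.5))
  shared <- seq(1, by = 2, length.out = length(cv1$rates_g_per_min))
  shared <- shared[shared <= length(cv2$rates_g_per_min)]
  expect_lt(max(abs(cv2$rates_g_per_min[shared] -
                      cv1$rates_g_per_min[seq_along(shared)])), 1e-6)
})

test_that("parameters validate and round-trip through YAML", {
  expect_error(absorption_params(k_abs = -1), "positive")
  expect_error(absorption_params(completeness = 1), "completeness")
  path <- tempfile(fileext = ".yaml")
  writeLines(c("k_empty0: 0.05", "alpha_fiber: 0.08", "step_min: 2"), path)
  p <- read_absorption_params(path)
  expect_equal(p$k_empty0, 0.05)
  expect_equal(p$alpha_fiber, 0.08)
  expect_equal(p$step_min, 2)
  expect_equal(p$k_abs, 0.056)  # untouched default
  writeLines("nonsense_key: 1", path)
  expect_error(read_absorption_params(path), "unknown keys")
})

test_that("curve export writes the documented CSV layout", {
  m <- meal_record("P", "a", "2021-03-01T08:00:00", 10, 0)
  cv <- simulate_absorption(m)
  path <- tempfile(fileext = ".csv")
  write_absorption_curve(cv, path)
  back <- read.csv(path)
  expect_identical(names(back), c("t_min", "rate_g_per_min"))
  expect_equal(back$rate_g_per_min, cv$rates_g_per_min, tolerance = 1e-12)
})
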