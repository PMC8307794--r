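make_curve <- function(times, rates) {
  structure(list(times_min = times, rates_g_per_min = rates, empty = FALSE),
            class = "absorption_curve")
}

make_episode <- function(bolus_pmol = 6000, sbgl = 6.2, dfb = 300) {
  structure(list(meal = list(meal_id = "m1", patient_id = "P"),
                 patient_id = "P",
                 sbgl_mmol_l = sbgl, bolus_dose_pmol = bolus_pmol,
                 dfb_min = dfb, targets = list()),
            class = "meal_episode")
}

tri_params <- function() {
  # triangle rising 0 -> 2 g/min over 60 min, back to 0 at 180 min
  t <- 0:180
  r <- ifelse(t <= 60, t / 30, 2 * (180 - t) / 120)
  curve_parameters(make_curve(t, r))
}

test_that("curve parameters recover the geometry of a triangular curve", {
  cp <- tri_params()
  expect_equal(cp$t_peak_min, 60)
  expect_equal(cp$t_50_min, 30)
  expect_equal(cp$max_rate_g_min, 2)
  expect_equal(cp$area_g, 180)
})

test_that("scaling a curve scales MaxCH and AuC but not the times", {
  t <- 0:180
  r <- ifelse(t <= 60, t / 30, 2 * (180 - t) / 120)
  cp1 <- curve_parameters(make_curve(t, r))
  cp3 <- curve_parameters(make_curve(t, 3 * r))
  expect_equal(cp3$max_rate_g_min, 3 * cp1$max_rate_g_min)
  expect_equal(cp3$area_g, 3 * cp1$area_g)
  expect_equal(cp3$t_peak_min, cp1$t_peak_min)
  expect_equal(cp3$t_50_min, cp1$t_50_min)
})

test_that("T50 is the rising-edge crossing and peak ties go to the earliest time", {
  # plateau at the maximum: earliest time wins
  cp <- curve_parameters(make_curve(0:4, c(0, 1, 2, 2, 0)))
  expect_equal(cp$t_peak_min, 2)
  # rising edge crosses 1 (half of 2) between t=0 and t=1 -> interpolated
  expect_equal(cp$t_50_min, 1)
  cp2 <- curve_parameters(make_curve(0:3, c(0, 0.5, 2, 0))) # cross at 1+1/3
  expect_equal(cp2$t_50_min, 1 + 1 / 3)
})

test_that("TPeak of the mono-only meal matches the closed form within a step", {
  p <- absorption_params()
  cv <- simulate_absorption(
    meal_record("P", "m", "2021-03-01T08:00:00", 10, 0), p)
  cp <- curve_parameters(cv)
  t_exact <- log(p$k_abs / p$k_empty0) / (p$k_abs - p$k_empty0)
  expect_lte(abs(cp$t_peak_min - t_exact), p$step_min)
  expect_lte(cp$t_50_min, cp$t_peak_min)
})

test_that("appending trailing zeros leaves the parameters unchanged", {
  t <- 0:180
  r <- ifelse(t <= 60, t / 30, pmax(2 * (180 - t) / 120, 0))
  cp <- curve_parameters(make_curve(t, r))
  cp_pad <- curve_parameters(make_curve(0:300, c(r, rep(0, 120))))
  expect_equal(cp_pad$t_peak_min, cp$t_peak_min)
  expect_equal(cp_pad$t_50_min, cp$t_50_min)
  expect_equal(cp_pad$max_rate_g_min, cp$max_rate_g_min)
  expect_lt(abs(cp_pad$area_g - cp$area_g), 1e-9)
})

test_that("T50 never exceeds TPeak on simulated meals", {
  set.seed(7)
  for (i in 1:20) {
    m <- meal_record("P", paste0("m", i), "2021-03-01T08:00:00",
                     runif(1, 1, 30), runif(1, 0, 90), runif(1, 0, 30),
                     runif(1, 0, 25), runif(1, 0, 10), runif(1, 40, 110))
    cp <- curve_parameters(simulate_absorption(m))
    expect_lte(cp$t_50_min, cp$t_peak_min)
  }
})

test_that("empty curves have no defined parameters", {
  m <- meal_record("P", "m", "2021-03-01T08:00:00", 0, 0)
  expect_error(curve_parameters(simulate_absorption(m)), "empty")
})

test_that("the four strategies carry their documented input orderings", {
  expect_identical(strategy("ABS")$input_names,
                   c("BI", "SBGL", "MaxCH", "TPeak", "T50"))
  expect_identical(strategy("AUC")$input_names,
                   c("BI", "SBGL", "MaxCH", "AuC", "TPeak"))
  expect_identical(strategy("DFB")$input_names,
                   c("BI", "SBGL", "MaxCH", "TPeak", "DfB"))
  expect_identical(strategy("AUC_DFB")$input_names,
                   c("BI", "SBGL", "MaxCH", "AuC", "DfB"))
  expect_error(strategy("XYZ"))
})

test_that("feature vectors scale BI by 1/1000 and DfB by 1/100", {
  cp <- tri_params()
  ep <- make_episode(bolus_pmol = 6000, sbgl = 6.2, dfb = 300)
  fv <- build_features(ep, cp, "AUC_DFB")
  expect_length(fv$values, 5L)
  expect_equal(unname(fv$values),
               c(6.0, 6.2, 2, 180, 3.0))
  fv_abs <- build_features(ep, cp, "ABS")
  expect_equal(unname(fv_abs$values), c(6.0, 6.2, 2, 60, 30))
})

test_that("every strategy produces a 5-vector in its documented order", {
  cp <- tri_params()
  ep <- make_episode()
  pool <- c(BI = 6, SBGL = 6.2, MaxCH = 2, AuC = 180, TPeak = 60,
            T50 = 30, DfB = 3)
  for (nm in c("ABS", "AUC", "DFB", "AUC_DFB")) {
    fv <- build_features(ep, cp, nm)
    expect_length(fv$values, 5L)
    expect_identical(names(fv$values), strategy(nm)$input_names)
    expect_equal(unname(fv$values), unname(pool[strategy(nm)$input_names]))
  }
})

test_that("strategies needing DfB refuse episodes without a basal delay", {
  cp <- tri_params()
  ep <- make_episode(dfb = NA)
  expect_error(build_features(ep, cp, "DFB"), "DfB")
  expect_error(build_features(ep, cp, "AUC_DFB"), "DfB")
  expect_silent(build_features(ep, cp, "ABS"))
})

test_that("the feature table leaves unused inputs empty", {
  eps <- small_patient_episodes()[1:3]
  path <- tempfile(fileext = ".csv")
  tab <- feature_table(eps, "ABS", path = path)
  expect_identical(names(tab),
                   c("meal_id", "strategy", "BI", "SBGL", "MaxCH", "AuC",
                     "TPeak", "T50", "DfB"))
  expect_true(all(is.na(tab$AuC)))
  expect_true(all(is.na(tab$DfB)))
  expect_true(all(is.finite(tab$TPeak)))
  raw <- readLines(path)
  expect_match(raw[1], "meal_id")
  expect_false(any(grepl("NA", raw)))
})
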