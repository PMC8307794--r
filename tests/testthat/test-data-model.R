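test_that("header-only files load as empty collections", {
  logs <- write_and_load_logs(empty_meals_df(), empty_insulin_df(),
                              empty_bgl_df(), empty_bgl_df())
  expect_s3_class(logs, "patient_logs")
  expect_identical(nrow(logs$meals), 0L)
  expect_identical(nrow(logs$insulin), 0L)
  expect_length(logs$cgm, 0L)
  expect_identical(logs$patients, character(0))
})

test_that("total carbohydrate is the monosaccharide + starch sum", {
  meals <- data.frame(patient_id = "P01", meal_id = "m1",
                      timestamp = "2021-03-01T08:00:00",
                      monosaccharide_g = 10, starch_g = 30, protein_g = 1,
                      lipid_g = 2, fiber_g = 3, glycemic_index = 70)
  logs <- write_and_load_logs(meals, empty_insulin_df(), empty_bgl_df(),
                              empty_bgl_df())
  expect_equal(total_ch_g(logs$meals[1, ]), 40)
})

test_that("a written synthetic cohort re-reads record-for-record", {
  dir <- tempfile("cohort_rt_")
  coh <- generate_cohort(2, 3, seed = 5, out_dir = dir)
  logs <- load_logs(file.path(dir, "meals.csv"),
                    file.path(dir, "insulin.csv"),
                    file.path(dir, "cgm.csv"),
                    file.path(dir, "fingertip.csv"))
  expect_equal(logs$meals$meal_id, coh$logs$meals$meal_id)
  expect_equal(logs$meals$starch_g, coh$logs$meals$starch_g)
  expect_equal(logs$insulin$dose_pmol, coh$logs$insulin$dose_pmol)
  expect_equal(logs$fingertip$bgl_mmol_l, coh$logs$fingertip$bgl_mmol_l,
               tolerance = 1e-12)
  for (pid in names(coh$logs$cgm)) {
    expect_equal(logs$cgm[[pid]]$values, coh$logs$cgm[[pid]]$values,
                 tolerance = 1e-12)
    expect_equal(logs$cgm[[pid]]$start, coh$logs$cgm[[pid]]$start)
  }
})

test_that("malformed rows are reported with file and line", {
  meals <- data.frame(patient_id = "P01", meal_id = "m1",
                      timestamp = "2021-03-01T08:00:00",
                      monosaccharide_g = "oops", starch_g = 30,
                      protein_g = 1, lipid_g = 2, fiber_g = 3,
                      glycemic_index = 70)
  expect_error(write_and_load_logs(meals, empty_insulin_df(),
                                   empty_bgl_df(), empty_bgl_df()),
               "line 2.*oops")
  meals$monosaccharide_g <- 10
  meals$timestamp <- "not-a-time"
  expect_error(write_and_load_logs(meals, empty_insulin_df(),
                                   empty_bgl_df(), empty_bgl_df()),
               "line 2.*not-a-time")
  ins <- data.frame(patient_id = "P01", timestamp = "2021-03-01T08:00:00",
                    kind = "sideways", dose_pmol = 100)
  expect_error(write_and_load_logs(empty_meals_df(), ins, empty_bgl_df(),
                                   empty_bgl_df()),
               "basal.*bolus")
})

test_that("an off-grid CGM timestamp is a schema error, a missing one a gap", {
  cgm <- flat_cgm("P01", "2021-03-01 08:00:00", 10)
  cgm$timestamp[4] <- "2021-03-01T08:07:00"  # 7 min offset: off the grid
  expect_error(write_and_load_logs(empty_meals_df(), empty_insulin_df(),
                                   cgm, empty_bgl_df()),
               "non-uniform")
  cgm2 <- flat_cgm("P01", "2021-03-01 08:00:00", 10)[-4, ]
  logs <- write_and_load_logs(empty_meals_df(), empty_insulin_df(), cgm2,
                              empty_bgl_df())
  expect_length(logs$cgm[["P01"]]$values, 10L)
  expect_true(is.na(logs$cgm[["P01"]]$values[4]))
  expect_identical(sum(is.na(logs$cgm[["P01"]]$values)), 1L)
})

# A hand-built two-day log exercising every exclusion reason.
filter_fixture <- function() {
  ts <- function(x) paste0("2021-03-01T", x)
  meals <- rbind(
    data.frame(patient_id = "P01", meal_id = "ok1", timestamp = ts("08:00:00"),
               monosaccharide_g = 10, starch_g = 30, protein_g = 5,
               lipid_g = 5, fiber_g = 2, glycemic_index = 70),
    data.frame(patient_id = "P01", meal_id = "lowch", timestamp = ts("10:30:00"),
               monosaccharide_g = 2, starch_g = 2.9, protein_g = 5,
               lipid_g = 5, fiber_g = 2, glycemic_index = 70),
    data.frame(patient_id = "P01", meal_id = "early", timestamp = ts("13:00:00"),
               monosaccharide_g = 10, starch_g = 30, protein_g = 5,
               lipid_g = 5, fiber_g = 2, glycemic_index = 70),
    data.frame(patient_id = "P01", meal_id = "ok2", timestamp = ts("13:45:00"),
               monosaccharide_g = 10, starch_g = 30, protein_g = 5,
               lipid_g = 5, fiber_g = 2, glycemic_index = 70),
    data.frame(patient_id = "P01", meal_id = "nobolus", timestamp = ts("17:00:00"),
               monosaccharide_g = 10, starch_g = 30, protein_g = 5,
               lipid_g = 5, fiber_g = 2, glycemic_index = 70))
  insulin <- rbind(
    data.frame(patient_id = "P01", timestamp = ts("06:30:00"), kind = "basal",
               dose_pmol = 2400),
    data.frame(patient_id = "P01", timestamp = ts("07:50:00"), kind = "bolus",
               dose_pmol = 3000),
    data.frame(patient_id = "P01", timestamp = ts("10:20:00"), kind = "bolus",
               dose_pmol = 500),
    data.frame(patient_id = "P01", timestamp = ts("12:55:00"), kind = "bolus",
               dose_pmol = 3200),
    data.frame(patient_id = "P01", timestamp = ts("13:30:00"), kind = "bolus",
               dose_pmol = 3100))
  cgm <- flat_cgm("P01", "2021-03-01 06:00:00", 420, bgl = 6.5)
  fingertip <- data.frame(patient_id = "P01",
                          timestamp = ts("07:45:00"), bgl_mmol_l = 5.9)
  write_and_load_logs(meals, insulin, cgm, fingertip)
}

test_that("the exclusion filters drop the documented meals", {
  eps <- clean_meals(filter_fixture())
  kept <- vapply(eps$episodes, function(e) e$meal$meal_id, character(1))
  expect_setequal(kept, c("ok1", "ok2"))
  expect_identical(unname(eps$exclusions["low_ch"]), 1L)       # 4.9 g < 5 g
  expect_identical(unname(eps$exclusions["close_successor"]), 1L) # 45 min gap
  expect_identical(unname(eps$exclusions["no_bolus"]), 1L)
  expect_identical(sum(eps$exclusions),
                   eps$n_input - length(eps$episodes))
})

test_that("episode fields are assembled from the matched records", {
  eps <- clean_meals(filter_fixture())
  ep <- eps$episodes[[1]]  # ok1 at 08:00
  expect_equal(ep$sbgl_mmol_l, 5.9)        # fingertip 15 min before
  expect_equal(ep$bolus_dose_pmol, 3000)
  expect_equal(ep$dfb_min, 90)             # basal 06:30 -> meal 08:00
  ep2 <- eps$episodes[[2]] # ok2, no fingertip within 60 min -> CGM fallback
  expect_equal(ep2$sbgl_mmol_l, 6.5)
  for (h in c(60, 90, 120, 180))
    expect_length(ep$targets[[as.character(h)]], h / 2)
})

test_that("a CGM gap inside a horizon window drops the episode", {
  logs <- filter_fixture()
  # remove the CGM samples 100 min after ok2 (13:45 -> gap at ~15:25)
  series <- logs$cgm[["P01"]]
  gap_at <- glucopred:::cgm_index_at(series, as.POSIXct("2021-03-01 15:25:00",
                                                        tz = "UTC"))
  series$values[gap_at + 1L] <- NA
  logs$cgm[["P01"]] <- series
  eps <- clean_meals(logs)
  kept <- vapply(eps$episodes, function(e) e$meal$meal_id, character(1))
  expect_setequal(kept, "ok1")
  expect_identical(unname(eps$exclusions["cgm_gap"]), 1L)
  # shorter horizons that end before the gap keep the episode
  eps2 <- clean_meals(logs, horizons = c(60, 90))
  expect_setequal(vapply(eps2$episodes, function(e) e$meal$meal_id,
                         character(1)), c("ok1", "ok2"))
})

test_that("meals with no preceding basal injection are excluded and counted", {
  logs <- filter_fixture()
  logs$insulin <- logs$insulin[logs$insulin$kind != "basal", , drop = FALSE]
  eps <- clean_meals(logs)
  expect_length(eps$episodes, 0L)
  expect_identical(unname(eps$exclusions["no_basal"]), 2L)
  expect_identical(sum(eps$exclusions), eps$n_input)
})

test_that("filtering is idempotent on the surviving meals", {
  coh <- small_cohort()
  eps1 <- clean_meals(coh$logs)
  kept <- vapply(eps1$episodes, function(e) e$meal$meal_id, character(1))
  logs2 <- coh$logs
  logs2$meals <- logs2$meals[logs2$meals$meal_id %in% kept, , drop = FALSE]
  eps2 <- clean_meals(logs2)
  kept2 <- vapply(eps2$episodes, function(e) e$meal$meal_id, character(1))
  expect_identical(kept2, kept)
  expect_identical(sum(eps2$exclusions), 0L)
})

test_that("the generated cohort passes cleaning with the intended meal count", {
  coh <- default_cohort()
  eps <- default_episodes()
  expect_identical(length(eps$episodes), length(coh$intended_meal_ids))
  expect_setequal(vapply(eps$episodes, function(e) e$meal$meal_id,
                         character(1)), coh$intended_meal_ids)
  expect_identical(unname(eps$exclusions["no_basal"]), 0L)
  expect_identical(unname(eps$exclusions["cgm_gap"]), 0L)
  expect_identical(sum(eps$exclusions), eps$n_input - length(eps$episodes))
})
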