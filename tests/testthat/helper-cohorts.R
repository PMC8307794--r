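# Shared fixtures, generated once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Default study cohort: 5 patients x 12 days, sigma = 0.4 mmol/L, seed 42.
default_cohort <- function() {
  cached("default_cohort", generate_cohort(5, 12, seed = 42))
}

default_episodes <- function() {
  cached("default_episodes", clean_meals(default_cohort()$logs))
}

# One small quiet patient for fast training tests.
small_cohort <- function() {
  cached("small_cohort", generate_cohort(1, 10, seed = 11))
}

small_patient_episodes <- function() {
  cached("small_eps", {
    eps <- clean_meals(small_cohort()$logs)
    episodes_by_patient(eps)[[1]]
  })
}

# Fabricated minimal episodes: enough structure for split/subsample logic.
fake_episodes <- function(n, patient_id = "P01") {
  t0 <- as.POSIXct("2021-03-01 08:00:00", tz = "UTC")
  lapply(seq_len(n), function(i) {
    structure(list(meal = list(patient_id = patient_id,
                               meal_id = sprintf("m%03d", i),
                               timestamp = t0 + i * 3600,
                               monosaccharide_g = 10, starch_g = 30,
                               protein_g = 5, lipid_g = 5, fiber_g = 2,
                               glycemic_index = 70),
                   patient_id = patient_id,
                   timestamp = t0 + i * 3600,
                   sbgl_mmol_l = 6, bolus_dose_pmol = 3000,
                   dfb_min = 60 + i,
                   targets = list()),
              class = "meal_episode")
  })
}

# Write a hand-built log set to CSVs and load it back.
write_and_load_logs <- function(meals, insulin, cgm, fingertip,
                                dir = tempfile("logs_")) {
  dir.create(dir)
  utils::write.csv(meals, file.path(dir, "meals.csv"), row.names = FALSE)
  utils::write.csv(insulin, file.path(dir, "insulin.csv"), row.names = FALSE)
  utils::write.csv(cgm, file.path(dir, "cgm.csv"), row.names = FALSE)
  utils::write.csv(fingertip, file.path(dir, "fingertip.csv"),
                   row.names = FALSE)
  load_logs(file.path(dir, "meals.csv"), file.path(dir, "insulin.csv"),
            file.path(dir, "cgm.csv"), file.path(dir, "fingertip.csv"))
}

# A regular 2-min CGM table at constant BGL.
flat_cgm <- function(patient_id, start, n, bgl = 6) {
  t0 <- as.POSIXct(start, tz = "UTC")
  data.frame(patient_id = patient_id,
             timestamp = format(t0 + 120 * (seq_len(n) - 1L),
                                "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
             bgl_mmol_l = bgl)
}

empty_meals_df <- function() {
  data.frame(patient_id = character(), meal_id = character(),
             timestamp = character(), monosaccharide_g = numeric(),
             starch_g = numeric(), protein_g = numeric(),
             lipid_g = numeric(), fiber_g = numeric(),
             glycemic_index = numeric())
}

empty_insulin_df <- function() {
  data.frame(patient_id = character(), timestamp = character(),
             kind = character(), dose_pmol = numeric())
}

empty_bgl_df <- function() {
  data.frame(patient_id = character(), timestamp = character(),
             bgl_mmol_l = numeric())
}
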