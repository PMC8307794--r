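#' Virtual patient parameters
#'
#' The simulator generates lifestyle logs (meals, basal/bolus insulin,
#' fingertip baselines) and 2-min CGM traces whose post-meal excursions are
#' driven by the absorption model, a gamma-shaped bolus action profile and a
#' slowly varying basal insulin effect with a gradual rise, a plateau and a
#' gradual decay.  Noiseless BGL evolves as
#' `dB/dt = carb_gain*g(t) - insulin_sensitivity*(bolus_action(t) +
#' basal_effect(t)) - glucose_restitution_rate*(B - target_bgl)` where `g` is
#' the summed glucose absorption rate of all meals (g/min), `bolus_action`
#' the summed dose-weighted action profile (1000 pmol/min units) and
#' `basal_effect` the basal profile scaled to `basal_amplitude`.
#'
#' @param carb_gain BGL rise per absorbed gram of glucose, mmol/L per g.
#' @param insulin_sensitivity BGL drop per 1000 pmol of effective insulin,
#'   mmol/L.
#' @param glucose_restitution_rate First-order pull toward `target_bgl`,
#'   1/min.
#' @param bolus_tau_min Time constant of the gamma-shaped bolus action
#'   profile (peak effect at `bolus_tau_min` after injection), minutes.
#' @param basal_rise_min Midpoint of the logistic rise of the basal effect
#'   after injection, minutes.
#' @param basal_plateau_min,basal_decay_min The decaying logistic ramp is
#'   centred at `basal_plateau_min + basal_decay_min` after injection.
#' @param basal_amplitude Peak basal effect, 1000 pmol/min equivalents.
#' @param basal_dose_pmol Logged basal dose, pmol.
#' @param target_bgl_mmol_l Restitution target, mmol/L.
#' @param noise_sigma_mmol_l Standard deviation of the iid Gaussian CGM and
#'   fingertip measurement noise, mmol/L.
#' @param bolus_per_g_ch_pmol Bolus dose per gram of meal carbohydrate, pmol.
#' @param basal_clock_min Daily basal injection clock time, minutes after
#'   midnight.
#' @param snack_probability Probability of a fourth, un-bolused snack per
#'   day.
#' @param meal_jitter_min Half-width of the uniform jitter applied to the
#'   scheduled meal times, minutes (applied in 2-min quanta so that meal
#'   times stay on the CGM grid).
#' @param ch_scale Multiplier applied to every meal's monosaccharide and
#'   starch mass after the composition draw, with bolus doses still computed
#'   from the unscaled carbohydrate content.  A dose-response experimentation
#'   hook: two runs with the same seed and different `ch_scale` share the
#'   identical schedule and insulin stream.
#' @return An object of class `virtual_patient_params`.
#' @export
virtual_patient_params <- function(carb_gain = 0.25,
                                   insulin_sensitivity = 1.6,
                                   glucose_restitution_rate = 0.008,
                                   bolus_tau_min = 55,
                                   basal_rise_min = 120,
                                   basal_plateau_min = 600,
                                   basal_decay_min = 240,
                                   basal_amplitude = 0.008,
                                   basal_dose_pmol = 2400,
                                   target_bgl_mmol_l = 7.5,
                                   noise_sigma_mmol_l = 0.4,
                                   bolus_per_g_ch_pmol = 90,
                                   basal_clock_min = 7 * 60,
                                   snack_probability = 0.35,
                                   meal_jitter_min = 24,
                                   ch_scale = 1) {
  p <- as.list(environment())
  pos <- c("carb_gain", "insulin_sensitivity", "glucose_restitution_rate",
           "bolus_tau_min", "basal_rise_min", "basal_plateau_min",
           "basal_decay_min", "basal_amplitude", "basal_dose_pmol",
           "target_bgl_mmol_l", "bolus_per_g_ch_pmol", "ch_scale")
  for (nm in pos)
    if (!is.numeric(p[[nm]]) || p[[nm]] <= 0)
      stop("virtual_patient_params: '", nm, "' must be > 0")
  if (p$noise_sigma_mmol_l < 0)
    stop("virtual_patient_params: noise_sigma_mmol_l must be >= 0")
  structure(p, class = "virtual_patient_params")
}

#' @export
print.virtual_patient_params <- function(x, ...) {
  cat("Virtual patient parameters\n")
  cat(sprintf("  carb gain %g mmol/L/g, insulin sensitivity %g mmol/L per 1000 pmol\n",
              x$carb_gain, x$insulin_sensitivity))
  cat(sprintf("  restitution %g /min toward %g mmol/L, CGM noise sd %g mmol/L\n",
              x$glucose_restitution_rate, x$target_bgl_mmol_l,
              x$noise_sigma_mmol_l))
  cat(sprintf("  basal: amplitude %g, rise %g min, plateau %g min, decay %g min\n",
              x$basal_amplitude, x$basal_rise_min, x$basal_plateau_min,
              x$basal_decay_min))
  invisible(x)
}

# basal effect profile at u minutes after injection, peak-normalized to 1.
# Difference of two logistic ramps: rise centred at basal_rise_min, fall at
# basal_plateau_min + basal_decay_min.  Anchored to zero at u = 0 so the
# effect starts continuously at the injection.
basal_profile <- function(u, p) {
  rise_scale <- pmax(p$basal_rise_min / 4, 1)
  fall_mid <- p$basal_plateau_min + p$basal_decay_min
  fall_scale <- pmax(p$basal_decay_min / 4, 1)
  raw <- function(t) stats::plogis((t - p$basal_rise_min) / rise_scale) -
    stats::plogis((t - fall_mid) / fall_scale)
  r0 <- raw(0)
  peak <- max(raw(seq(0, fall_mid, by = 1))) - r0
  out <- pmax(raw(u) - r0, 0) / peak
  out[u < 0] <- 0
  out
}

# bolus action at u minutes after injection per 1000 pmol: gamma-shaped
# profile (u/tau^2) exp(-u/tau), unit integral, peak at tau.
bolus_profile <- function(u, tau) {
  out <- u / tau^2 * exp(-u / tau)
  out[u < 0] <- 0
  out
}

meal_composition <- function(kind) {
  r <- function(a, b) stats::runif(1, a, b)
  switch(kind,
         breakfast = list(mono = r(8, 20), starch = r(25, 50),
                          protein = r(8, 20), lipid = r(5, 18),
                          fiber = r(2, 7), gi = r(55, 85)),
         lunch = list(mono = r(5, 15), starch = r(35, 65),
                      protein = r(15, 35), lipid = r(10, 28),
                      fiber = r(3, 10), gi = r(45, 80)),
         dinner = list(mono = r(5, 18), starch = r(25, 55),
                       protein = r(12, 30), lipid = r(8, 25),
                       fiber = r(2, 8), gi = r(50, 85)),
         snack = list(mono = r(8, 20), starch = r(0, 10),
                      protein = r(0, 5), lipid = r(0, 8),
                      fiber = r(0, 3), gi = r(60, 95)))
}

#' Generate a synthetic cohort with known ground truth
#'
#' Per patient and day: one basal injection at the fixed clock time, three
#' bolused main meals (and occasionally an un-bolused snack) with jittered
#' times and randomized compositions, a bolus 0-15 min before each main meal
#' with dose proportional to the meal's carbohydrate content, a fingertip
#' baseline at each meal time, and a continuous 2-min CGM trace.  Noiseless
#' BGL is integrated with fixed-step RK4 (1 min) from the summed absorption,
#' bolus-action and basal-effect forcings; CGM adds iid Gaussian noise and
#' clamps to (2, 30) mmol/L.  The run is fully determined by
#' `(params, seed)`.
#'
#' @param n_patients Number of virtual patients.
#' @param days_per_patient Diary length, days.
#' @param params A single [virtual_patient_params()] or a list of one per
#'   patient.
#' @param seed Integer seed.
#' @param out_dir Optional directory; when given, `meals.csv`,
#'   `insulin.csv`, `cgm.csv`, `fingertip.csv` and `ground_truth.json` are
#'   written there.
#' @param absorption An [absorption_params()] object used for the true
#'   absorption dynamics.
#' @return An object of class `synthetic_cohort`: list with `logs` (a
#'   `patient_logs`), `truth` (ground truth: per-patient noiseless BGL grid,
#'   per-meal true absorption curves, all parameters and the seed) and
#'   `intended_meal_ids` (bolused main meals, i.e. the meals the cleaning
#'   filters are expected to retain).
#' @export
generate_cohort <- function(n_patients, days_per_patient,
                            params = virtual_patient_params(),
                            seed = 42, out_dir = NULL,
                            absorption = absorption_params()) {
  stopifnot(n_patients >= 1, days_per_patient >= 1)
  if (inherits(params, "virtual_patient_params"))
    params <- rep(list(params), n_patients)
  stopifnot(length(params) == n_patients)

  origin <- as.POSIXct("2021-03-01T00:00:00", format = .ts_format, tz = "UTC")
  tail_min <- 240  # simulate past the last day so late dinners keep targets
  total_min <- days_per_patient * 1440 + tail_min

  meals <- list(); insulin <- list(); fingertip <- list(); cgm <- list()
  truth_patients <- list()
  intended <- character()

  with_local_seed(seed, {
    for (ip in seq_len(n_patients)) {
      p <- params[[ip]]
      pid <- sprintf("VP%02d", ip)

      # --- schedule ----------------------------------------------------
      # even-minute schedule anchors so every meal lands on the 2-min CGM grid
      sched <- list(breakfast = 450, lunch = 764, dinner = 1110, snack = 944)
      pm <- list(); pins <- list(); pft <- list()
      for (day in seq_len(days_per_patient) - 1L) {
        day0 <- day * 1440
        pins[[length(pins) + 1L]] <- list(t = day0 + p$basal_clock_min,
                                          kind = "basal",
                                          dose = p$basal_dose_pmol)
        kinds <- c("breakfast", "lunch", "dinner")
        if (stats::runif(1) < p$snack_probability) kinds <- c(kinds, "snack")
        for (kind in kinds) {
          jit <- 2 * sample.int(p$meal_jitter_min + 1L, 1L) - 2L -
            p$meal_jitter_min  # even-minute jitter keeps meals on CGM grid
          t_meal <- day0 + sched[[kind]] + jit
          comp <- meal_composition(kind)
          raw_ch <- comp$mono + comp$starch
          comp$mono <- comp$mono * p$ch_scale
          comp$starch <- comp$starch * p$ch_scale
          mid <- sprintf("%s_d%02d_%s", pid, day + 1L, kind)
          pm[[length(pm) + 1L]] <- list(id = mid, t = t_meal, kind = kind,
                                        comp = comp)
          if (kind != "snack") {
            # whole-minute lead keeps the bolus-action kink on the RK4 grid
            lead <- sample.int(16L, 1L) - 1L
            dose <- p$bolus_per_g_ch_pmol * raw_ch * stats::runif(1, 0.9, 1.1)
            pins[[length(pins) + 1L]] <- list(t = t_meal - lead,
                                              kind = "bolus", dose = dose)
            intended <- c(intended, mid)
          }
        }
      }

      # --- forcings on a quarter-minute grid --------------------------
      # (fine enough that the 1-min RK4 below and a half-step refinement
      # read the same forcing samples)
      fine_grid <- seq(0, total_min, by = 0.25)
      g_tot <- numeric(length(fine_grid))
      abs_fine <- absorption
      abs_fine$step_min <- 0.25
      # run the true curves essentially to exhaustion: the residual rate at
      # the truncation point must be negligible for the BGL integration
      abs_fine$completeness <- max(abs_fine$completeness, 0.999999)
      abs_fine$t_max_min <- max(abs_fine$t_max_min, 3000)
      meal_curves <- list()
      for (m in pm) {
        mr <- c(list(patient_id = pid, meal_id = m$id),
                list(monosaccharide_g = m$comp$mono, starch_g = m$comp$starch,
                     protein_g = m$comp$protein, lipid_g = m$comp$lipid,
                     fiber_g = m$comp$fiber, glycemic_index = m$comp$gi))
        curve <- simulate_absorption(mr, abs_fine)
        # trim to a whole minute so the cut sits on every integrator's grid
        len4 <- ((length(curve$rates_g_per_min) - 1L) %/% 4L) * 4L + 1L
        curve$times_min <- curve$times_min[seq_len(len4)]
        curve$rates_g_per_min <- curve$rates_g_per_min[seq_len(len4)]
        meal_curves[[m$id]] <- curve
        i0 <- as.integer(round(m$t / 0.25)) + 1L
        idx <- i0 + seq_along(curve$rates_g_per_min) - 1L
        keep <- idx <= length(g_tot)
        g_tot[idx[keep]] <- g_tot[idx[keep]] + curve$rates_g_per_min[keep]
      }
      ins_tot <- numeric(length(fine_grid))
      for (ev in pins) {
        u <- fine_grid - ev$t
        if (ev$kind == "bolus") {
          ins_tot <- ins_tot + (ev$dose / 1000) * bolus_profile(u, p$bolus_tau_min)
        } else {
          ins_tot <- ins_tot + p$basal_amplitude * basal_profile(u, p)
        }
      }

      # --- RK4 on the 1-min grid --------------------------------------
      drive <- p$carb_gain * g_tot - p$insulin_sensitivity * ins_tot
      n_steps <- total_min
      bgl <- numeric(n_steps + 1L)
      bgl[1L] <- p$target_bgl_mmol_l
      kr <- p$glucose_restitution_rate
      tb <- p$target_bgl_mmol_l
      for (i in seq_len(n_steps)) {
        j <- 4L * i - 3L  # index of t = i-1 on the quarter grid
        d0 <- drive[j]; dh <- drive[j + 2L]; d1 <- drive[j + 4L]
        B <- bgl[i]
        k1 <- d0 - kr * (B - tb)
        k2 <- dh - kr * (B + 0.5 * k1 - tb)
        k3 <- dh - kr * (B + 0.5 * k2 - tb)
        k4 <- d1 - kr * (B + k3 - tb)
        bgl[i + 1L] <- B + (k1 + 2 * k2 + 2 * k3 + k4) / 6
      }

      # --- observation model ------------------------------------------
      cgm_idx <- seq(1L, n_steps + 1L, by = 2L)  # every 2 min
      noiseless <- bgl[cgm_idx]
      noise <- if (p$noise_sigma_mmol_l > 0)
        stats::rnorm(length(cgm_idx), 0, p$noise_sigma_mmol_l) else 0
      observed <- pmin(pmax(noiseless + noise, 2), 30)
      frac_clamped <- mean(noiseless + noise != observed)
      if (frac_clamped > 0.2)
        warning(sprintf(paste("generate_cohort: %s: %.0f%% of CGM samples fell",
                              "outside (2, 30) mmol/L; the parameter set is",
                              "physiologically implausible - regenerate with",
                              "gentler gains"), pid, 100 * frac_clamped))

      for (m in pm) {
        ft_noise <- if (p$noise_sigma_mmol_l > 0)
          stats::rnorm(1, 0, p$noise_sigma_mmol_l) else 0
        pft[[length(pft) + 1L]] <-
          list(t = m$t, bgl = pmin(pmax(bgl[m$t + 1L] + ft_noise, 2), 30))
      }

      ts_of <- function(mins) origin + mins * 60
      meals[[pid]] <- do.call(rbind, lapply(pm, function(m)
        data.frame(patient_id = pid, meal_id = m$id,
                   timestamp = format_ts(ts_of(m$t)),
                   monosaccharide_g = round(m$comp$mono, 3),
                   starch_g = round(m$comp$starch, 3),
                   protein_g = round(m$comp$protein, 3),
                   lipid_g = round(m$comp$lipid, 3),
                   fiber_g = round(m$comp$fiber, 3),
                   glycemic_index = round(m$comp$gi, 1))))
      insulin[[pid]] <- do.call(rbind, lapply(pins, function(ev)
        data.frame(patient_id = pid, timestamp = format_ts(ts_of(ev$t)),
                   kind = ev$kind, dose_pmol = round(ev$dose, 1))))
      fingertip[[pid]] <- do.call(rbind, lapply(pft, function(ev)
        data.frame(patient_id = pid, timestamp = format_ts(ts_of(ev$t)),
                   bgl_mmol_l = ev$bgl)))
      cgm[[pid]] <- data.frame(patient_id = pid,
                               timestamp = format_ts(ts_of((cgm_idx - 1L) * 1)),
                               bgl_mmol_l = observed)

      truth_patients[[pid]] <- list(
        params = unclass(p),
        start = format_ts(origin),
        interval_min = 2,
        noiseless_bgl = noiseless,
        meal_times_min = stats::setNames(vapply(pm, `[[`, numeric(1), "t"),
                                         vapply(pm, `[[`, character(1), "id")),
        meal_comps = stats::setNames(lapply(pm, `[[`, "comp"),
                                     vapply(pm, `[[`, character(1), "id")),
        events = data.frame(
          t = vapply(pins, `[[`, numeric(1), "t"),
          kind = vapply(pins, `[[`, character(1), "kind"),
          dose = vapply(pins, `[[`, numeric(1), "dose")),
        drive = drive,  # net forcing, quarter-minute grid
        meal_curves = meal_curves)
    }
  })

  bind <- function(lst) {
    out <- do.call(rbind, lst)
    rownames(out) <- NULL
    out
  }
  files <- list(meals = bind(meals), insulin = bind(insulin),
                cgm = bind(cgm), fingertip = bind(fingertip))

  truth <- structure(list(seed = seed, patients = truth_patients,
                          origin = format_ts(origin)),
                     class = "cohort_truth")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(files))
      utils::write.csv(files[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE, quote = FALSE)
    truth_json <- list(seed = seed, origin = truth$origin,
                       patients = lapply(truth$patients, function(tp)
                         list(params = tp$params, start = tp$start,
                              interval_min = tp$interval_min,
                              noiseless_bgl = tp$noiseless_bgl,
                              meal_times_min = as.list(tp$meal_times_min))))
    jsonlite::write_json(truth_json, file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  logs <- logs_from_tables(files)
  structure(list(logs = logs, truth = truth,
                 intended_meal_ids = intended, tables = files),
            class = "synthetic_cohort")
}

# build a patient_logs object from in-memory tables (same validation path as
# load_logs, via a temporary on-disk round trip kept out of hot loops)
logs_from_tables <- function(tables) {
  td <- tempfile("cohort_")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  for (nm in names(tables))
    utils::write.csv(tables[[nm]], file.path(td, paste0(nm, ".csv")),
                     row.names = FALSE, quote = FALSE)
  load_logs(file.path(td, "meals.csv"), file.path(td, "insulin.csv"),
            file.path(td, "cgm.csv"), file.path(td, "fingertip.csv"))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d patient(s), %d logged meals (%d bolused), seed %s\n",
              length(x$truth$patients), nrow(x$logs$meals),
              length(x$intended_meal_ids), format(x$truth$seed)))
  invisible(x)
}

#' Noiseless ground-truth BGL trajectory after a meal
#'
#' Returns the generator's exact noiseless BGL at the 2-min grid points
#' following the meal (first value at t = 2 min after the meal), for use as
#' an oracle against trained predictors.
#'
#' @param truth The `truth` component of a [generate_cohort()] result.
#' @param meal_id Meal identifier.
#' @param horizon_min Horizon in minutes; the result has `horizon_min / 2`
#'   values.
#' @param include_t0 Prepend the meal-time BGL (making the result one value
#'   longer).
#' @return Numeric vector of noiseless BGL, mmol/L.
#' @export
truth_trajectory <- function(truth, meal_id, horizon_min,
                             include_t0 = FALSE) {
  stopifnot(inherits(truth, "cohort_truth"))
  hit <- NULL
  for (tp in truth$patients)
    if (meal_id %in% names(tp$meal_times_min)) { hit <- tp; break }
  if (is.null(hit)) stop("truth_trajectory: unknown meal id: ", meal_id)
  t_meal <- hit$meal_times_min[[meal_id]]
  i0 <- as.integer(round(t_meal / 2))  # 2-min grid index of the meal time
  want <- i0 + seq_len(horizon_min / 2) + 1L
  if (max(want) > length(hit$noiseless_bgl))
    stop("truth_trajectory: horizon extends past the simulated window")
  out <- hit$noiseless_bgl[want]
  if (include_t0) out <- c(hit$noiseless_bgl[i0 + 1L], out)
  out
}
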