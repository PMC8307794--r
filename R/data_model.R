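#' @useDynLib glucopred, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Timestamps are timezone-naive local clock times; internally they are stored
# as POSIXct in UTC so arithmetic never crosses DST.
.ts_format <- "%Y-%m-%dT%H:%M:%S"

format_ts <- function(x) format(x, .ts_format, tz = "UTC")

parse_ts <- function(x, file = "<input>", line = NULL) {
  out <- as.POSIXct(x, format = .ts_format, tz = "UTC")
  alt <- is.na(out) & !is.na(x)
  if (any(alt))
    out[alt] <- as.POSIXct(x[alt], format = "%Y-%m-%d %H:%M:%S", tz = "UTC")
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad)) {
    ln <- if (is.null(line)) bad[1L] + 1L else line[bad[1L]]
    stop(sprintf("%s: line %d: unparseable timestamp '%s'", file, ln, x[bad[1L]]))
  }
  out
}

#' Construct a single meal record
#'
#' Convenience constructor used mostly in examples and tests; bulk data come
#' in through [load_logs()].  The total carbohydrate content is always
#' derived as `monosaccharide_g + starch_g`, never stored.
#'
#' @param patient_id,meal_id Identifiers.
#' @param timestamp Meal time (POSIXct or ISO 8601 string).
#' @param monosaccharide_g,starch_g,protein_g,lipid_g,fiber_g Nutrient
#'   masses, g.  Sugars other than pure monosaccharide map onto the
#'   monosaccharide pool.
#' @param glycemic_index Dimensionless, 0-110.
#' @return A list of class `meal_record`.
#' @export
meal_record <- function(patient_id, meal_id, timestamp,
                        monosaccharide_g, starch_g, protein_g = 0,
                        lipid_g = 0, fiber_g = 0, glycemic_index = 70) {
  masses <- c(monosaccharide_g, starch_g, protein_g, lipid_g, fiber_g)
  if (any(!is.finite(masses)) || any(masses < 0))
    stop("meal_record: nutrient masses must be finite and >= 0")
  if (!is.finite(glycemic_index) || glycemic_index < 0 || glycemic_index > 110)
    stop("meal_record: glycemic_index must lie in [0, 110]")
  if (is.character(timestamp)) timestamp <- parse_ts(timestamp)
  structure(list(patient_id = as.character(patient_id),
                 meal_id = as.character(meal_id),
                 timestamp = timestamp,
                 monosaccharide_g = monosaccharide_g, starch_g = starch_g,
                 protein_g = protein_g, lipid_g = lipid_g, fiber_g = fiber_g,
                 glycemic_index = glycemic_index),
            class = "meal_record")
}

#' Total carbohydrate content of a meal
#'
#' @param meal A meal record (list or data frame row).
#' @return `monosaccharide_g + starch_g`, g.
#' @export
total_ch_g <- function(meal) meal$monosaccharide_g + meal$starch_g

read_schema_csv <- function(path, columns, numeric_cols) {
  if (!file.exists(path)) stop("load_logs: file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing <- setdiff(columns, names(df))
  if (length(missing))
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing, collapse = ", ")))
  df <- df[columns]
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & nzchar(trimws(df[[col]])))
    if (length(bad))
      stop(sprintf("%s: line %d: malformed numeric value '%s' in column '%s'",
                   path, bad[1L] + 1L, df[[col]][bad[1L]], col))
    blank <- which(!nzchar(trimws(df[[col]])))
    if (length(blank))
      stop(sprintf("%s: line %d: empty value in column '%s'",
                   path, blank[1L] + 1L, col))
    df[[col]] <- v
  }
  df
}

build_cgm_series <- function(df, path) {
  split_rows <- split(df, df$patient_id)
  out <- lapply(names(split_rows), function(pid) {
    d <- split_rows[[pid]]
    d <- d[order(d$timestamp), , drop = FALSE]
    if (any(d$bgl_mmol_l <= 0 | d$bgl_mmol_l >= 35))
      stop(sprintf("%s: CGM value out of (0, 35) for patient %s", path, pid))
    start <- d$timestamp[1L]
    off_min <- as.numeric(difftime(d$timestamp, start, units = "mins"))
    idx <- off_min / 2
    if (any(abs(idx - round(idx)) > 1e-6))
      stop(sprintf("%s: non-uniform CGM interval for patient %s (expected a strict 2-min grid)",
                   path, pid))
    idx <- as.integer(round(idx))
    if (anyDuplicated(idx))
      stop(sprintf("%s: duplicate CGM timestamp for patient %s", path, pid))
    values <- rep(NA_real_, max(idx) + 1L)  # NA marks a gap in the 2-min grid
    values[idx + 1L] <- d$bgl_mmol_l
    structure(list(patient_id = pid, start = start, interval_min = 2,
                   values = values),
              class = "cgm_series")
  })
  stats::setNames(out, names(split_rows))
}

#' @export
print.cgm_series <- function(x, ...) {
  cat(sprintf("CGM series %s: %d samples every %g min from %s (%d gaps)\n",
              x$patient_id, length(x$values), x$interval_min,
              format_ts(x$start), sum(is.na(x$values))))
  invisible(x)
}

#' Load lifestyle logs and CGM data from the four CSV schemas
#'
#' Schemas (headers required):
#' * `meals.csv`: `patient_id,meal_id,timestamp,monosaccharide_g,starch_g,protein_g,lipid_g,fiber_g,glycemic_index`
#' * `insulin.csv`: `patient_id,timestamp,kind,dose_pmol` with `kind` in `basal|bolus`
#' * `cgm.csv`: `patient_id,timestamp,bgl_mmol_l` on a strict 2-min cadence per patient
#' * `fingertip.csv`: `patient_id,timestamp,bgl_mmol_l`
#'
#' Timestamps are ISO 8601 (`YYYY-MM-DDTHH:MM:SS`; a space separator is also
#' accepted).  Records come back grouped by patient and time-sorted; missing
#' CGM samples inside a patient's observation window become explicit `NA` gap
#' markers.
#'
#' @param meals_path,insulin_path,cgm_path,fingertip_path CSV file paths.
#' @return An object of class `patient_logs`: list with `meals`, `insulin`,
#'   `fingertip` (data frames), `cgm` (named list of `cgm_series`) and
#'   `patients` (character vector).
#' @export
load_logs <- function(meals_path, insulin_path, cgm_path, fingertip_path) {
  meals <- read_schema_csv(meals_path,
                           c("patient_id", "meal_id", "timestamp",
                             "monosaccharide_g", "starch_g", "protein_g",
                             "lipid_g", "fiber_g", "glycemic_index"),
                           c("monosaccharide_g", "starch_g", "protein_g",
                             "lipid_g", "fiber_g", "glycemic_index"))
  if (nrow(meals)) {
    meals$timestamp <- parse_ts(meals$timestamp, meals_path)
    masses <- as.matrix(meals[c("monosaccharide_g", "starch_g", "protein_g",
                                "lipid_g", "fiber_g")])
    if (any(masses < 0) || any(meals$glycemic_index < 0))
      stop(meals_path, ": negative nutrient mass or glycemic index")
  }

  insulin <- read_schema_csv(insulin_path,
                             c("patient_id", "timestamp", "kind", "dose_pmol"),
                             "dose_pmol")
  if (nrow(insulin)) {
    insulin$timestamp <- parse_ts(insulin$timestamp, insulin_path)
    bad <- which(!insulin$kind %in% c("basal", "bolus"))
    if (length(bad))
      stop(sprintf("%s: line %d: kind must be 'basal' or 'bolus' (got '%s')",
                   insulin_path, bad[1L] + 1L, insulin$kind[bad[1L]]))
    if (any(insulin$dose_pmol <= 0))
      stop(insulin_path, ": dose_pmol must be > 0")
  }

  cgm_raw <- read_schema_csv(cgm_path,
                             c("patient_id", "timestamp", "bgl_mmol_l"),
                             "bgl_mmol_l")
  if (nrow(cgm_raw)) cgm_raw$timestamp <- parse_ts(cgm_raw$timestamp, cgm_path)

  fingertip <- read_schema_csv(fingertip_path,
                               c("patient_id", "timestamp", "bgl_mmol_l"),
                               "bgl_mmol_l")
  if (nrow(fingertip)) {
    fingertip$timestamp <- parse_ts(fingertip$timestamp, fingertip_path)
    if (any(fingertip$bgl_mmol_l <= 0 | fingertip$bgl_mmol_l >= 35))
      stop(fingertip_path, ": fingertip BGL out of (0, 35)")
  }

  ord <- function(df) df[order(df$patient_id, df$timestamp), , drop = FALSE]
  structure(list(meals = ord(meals), insulin = ord(insulin),
                 cgm = if (nrow(cgm_raw)) build_cgm_series(cgm_raw, cgm_path)
                       else stats::setNames(list(), character()),
                 fingertip = ord(fingertip),
                 patients = sort(unique(c(meals$patient_id,
                                          insulin$patient_id,
                                          cgm_raw$patient_id,
                                          fingertip$patient_id)))),
            class = "patient_logs")
}

#' @export
print.patient_logs <- function(x, ...) {
  cat(sprintf("Patient logs: %d patient(s), %d meals, %d insulin events, %d fingertip readings\n",
              length(x$patients), nrow(x$meals), nrow(x$insulin),
              nrow(x$fingertip)))
  invisible(x)
}

cgm_index_at <- function(series, time, tol_min = 1) {
  off <- as.numeric(difftime(time, series$start, units = "mins"))
  idx <- round(off / 2)
  if (abs(off - 2 * idx) > tol_min + 1e-9) return(NA_integer_)
  as.integer(idx)
}

#' Clean raw meal logs into analyzable meal episodes
#'
#' Applies the meal exclusion filters and assembles, for each surviving meal,
#' the quantities the prediction pipeline needs.  A meal is excluded when
#' (in this order of accounting; each excluded meal is counted once):
#' * `no_bolus` - no bolus insulin event within `bolus_window_min` minutes
#'   before (up to and including) the meal time;
#' * `low_ch` - total carbohydrate (monosaccharide + starch) below
#'   `min_ch_g` g;
#' * `close_successor` - another logged meal of the same patient follows
#'   within `min_gap_min` minutes;
#' * `no_basal` - no basal injection anywhere before the meal in the log;
#' * `cgm_gap` - the CGM series misses samples inside a requested horizon
#'   window (or provides no usable baseline fallback).
#'
#' For survivors, the startup BGL (SBGL) is the latest fingertip reading at
#' most `sbgl_window_min` minutes before the meal, falling back to the CGM
#' sample at meal time; the bolus dose is the matched bolus; `dfb_min` is the
#' delay since the latest preceding basal injection; targets are the raw CGM
#' values at 2-min steps after the meal for every requested horizon (the
#' sample at t = 2 min is target index 1; meal timestamps are snapped to the
#' nearest CGM grid point, tolerating up to 1 min of skew).
#'
#' @param logs A `patient_logs` object from [load_logs()].
#' @param min_ch_g Minimum total carbohydrate, g.
#' @param min_gap_min Minimum gap to the next meal, minutes.
#' @param bolus_window_min Width of the pre-meal bolus matching window,
#'   minutes.
#' @param sbgl_window_min Maximum age of a fingertip baseline, minutes.
#' @param horizons Prediction horizons, minutes; each episode carries one
#'   target trajectory of length `H/2` per horizon.
#' @return An object of class `meal_episodes`: list with `episodes` (list of
#'   `meal_episode`), `exclusions` (named counts by reason), `dropped`
#'   (data frame of meal_id/reason) and `n_input`.
#' @export
clean_meals <- function(logs, min_ch_g = 5, min_gap_min = 60,
                        bolus_window_min = 30, sbgl_window_min = 60,
                        horizons = c(60, 90, 120, 180)) {
  stopifnot(inherits(logs, "patient_logs"))
  stopifnot(all(horizons %% 2 == 0), all(horizons > 0))
  reasons <- c("no_bolus", "low_ch", "close_successor", "no_basal", "cgm_gap")
  counts <- stats::setNames(integer(length(reasons)), reasons)
  dropped <- list()
  episodes <- list()

  meals <- logs$meals
  for (k in seq_len(nrow(meals))) {
    m <- as.list(meals[k, , drop = FALSE])
    t_meal <- m$timestamp
    pid <- m$patient_id
    reason <- NULL

    ins <- logs$insulin[logs$insulin$patient_id == pid, , drop = FALSE]
    boli <- ins[ins$kind == "bolus" &
                  ins$timestamp <= t_meal &
                  ins$timestamp >= t_meal - bolus_window_min * 60, ,
                drop = FALSE]
    if (nrow(boli) == 0L) reason <- "no_bolus"

    if (is.null(reason) && total_ch_g(m) < min_ch_g) reason <- "low_ch"

    if (is.null(reason)) {
      others <- meals[meals$patient_id == pid & meals$meal_id != m$meal_id, ,
                      drop = FALSE]
      dt <- as.numeric(difftime(others$timestamp, t_meal, units = "mins"))
      if (any(dt > 0 & dt <= min_gap_min)) reason <- "close_successor"
    }

    dfb <- NA_real_
    if (is.null(reason)) {
      basal <- ins[ins$kind == "basal" & ins$timestamp <= t_meal, ,
                   drop = FALSE]
      if (nrow(basal) == 0L) {
        reason <- "no_basal"
      } else {
        dfb <- as.numeric(difftime(t_meal, max(basal$timestamp),
                                   units = "mins"))
      }
    }

    if (is.null(reason)) {
      series <- logs$cgm[[pid]]
      i0 <- if (is.null(series)) NA_integer_ else cgm_index_at(series, t_meal)
      targets <- NULL
      if (is.na(i0) || i0 < 0L) {
        reason <- "cgm_gap"
      } else {
        targets <- stats::setNames(vector("list", length(horizons)),
                                   as.character(horizons))
        for (h in horizons) {
          want <- i0 + seq_len(h / 2)
          vals <- if (max(want) + 1L > length(series$values)) NA_real_
                  else series$values[want + 1L]
          if (anyNA(vals)) { reason <- "cgm_gap"; break }
          targets[[as.character(h)]] <- vals
        }
      }

      if (is.null(reason)) {
        ft <- logs$fingertip[logs$fingertip$patient_id == pid, , drop = FALSE]
        ft <- ft[ft$timestamp <= t_meal &
                   ft$timestamp >= t_meal - sbgl_window_min * 60, ,
                 drop = FALSE]
        sbgl <- if (nrow(ft)) ft$bgl_mmol_l[which.max(as.numeric(ft$timestamp))]
                else series$values[i0 + 1L]
        if (is.na(sbgl) || sbgl <= 0) {
          reason <- "cgm_gap"
        } else {
          episodes[[length(episodes) + 1L]] <- structure(
            list(meal = m, patient_id = pid, timestamp = t_meal,
                 sbgl_mmol_l = sbgl,
                 bolus_dose_pmol = boli$dose_pmol[which.max(as.numeric(boli$timestamp))],
                 dfb_min = dfb, targets = targets),
            class = "meal_episode")
        }
      }
    }

    if (!is.null(reason)) {
      counts[reason] <- counts[reason] + 1L
      dropped[[length(dropped) + 1L]] <- data.frame(meal_id = m$meal_id,
                                                    patient_id = pid,
                                                    reason = reason)
    }
  }

  structure(list(episodes = episodes, exclusions = counts,
                 dropped = if (length(dropped)) do.call(rbind, dropped)
                           else data.frame(meal_id = character(),
                                           patient_id = character(),
                                           reason = character()),
                 n_input = nrow(meals)),
            class = "meal_episodes")
}

#' @export
print.meal_episodes <- function(x, ...) {
  cat(sprintf("Meal episodes: %d retained of %d logged meals\n",
              length(x$episodes), x$n_input))
  if (sum(x$exclusions) > 0) {
    cat("  exclusions:",
        paste(sprintf("%s=%d", names(x$exclusions), x$exclusions),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.meal_episode <- function(x, ...) {
  cat(sprintf("Meal episode %s (%s, %s): CH %.1f g, SBGL %.2f mmol/L, bolus %.0f pmol, DfB %.0f min\n",
              x$meal$meal_id, x$patient_id, format_ts(x$timestamp),
              total_ch_g(x$meal), x$sbgl_mmol_l, x$bolus_dose_pmol, x$dfb_min))
  invisible(x)
}

episode_timestamps <- function(episodes)
  do.call(c, lapply(episodes, `[[`, "timestamp"))

sort_episodes <- function(episodes)
  episodes[order(as.numeric(episode_timestamps(episodes)))]
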