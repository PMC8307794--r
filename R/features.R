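#' Dynamics parameters of an absorption curve
#'
#' Reduces a glucose absorption rate curve to the four dynamics parameters
#' used as network inputs: `t_peak_min` (TPeak, earliest grid time attaining
#' the maximum rate), `t_50_min` (T50, earliest time at which the rate
#' reaches half the maximum, linearly interpolated between grid points on the
#' rising edge), `max_rate_g_min` (MaxCH, the maximum rate) and `area_g`
#' (AuC, the trapezoid integral of the whole curve).
#'
#' @param curve An `absorption_curve` from [simulate_absorption()].
#' @return An object of class `curve_parameters`: a list with fields
#'   `t_peak_min`, `t_50_min`, `max_rate_g_min`, `area_g`.
#' @export
curve_parameters <- function(curve) {
  stopifnot(inherits(curve, "absorption_curve"))
  if (isTRUE(curve$empty) || all(curve$rates_g_per_min == 0))
    stop("curve_parameters: undefined for an empty or all-zero curve")
  t <- curve$times_min
  r <- curve$rates_g_per_min
  max_rate <- max(r)
  i_peak <- which(r == max_rate)[1L]
  t_peak <- t[i_peak]

  half <- max_rate / 2
  i_cross <- which(r >= half)[1L]
  if (i_cross == 1L) {
    t_50 <- t[1L]
  } else {
    r0 <- r[i_cross - 1L]; r1 <- r[i_cross]
    t_50 <- t[i_cross - 1L] + (half - r0) / (r1 - r0) * (t[i_cross] - t[i_cross - 1L])
  }

  n <- length(t)
  area <- sum(diff(t) * (r[-n] + r[-1L]) / 2)

  structure(list(t_peak_min = t_peak, t_50_min = t_50,
                 max_rate_g_min = max_rate, area_g = area),
            class = "curve_parameters")
}

#' @export
print.curve_parameters <- function(x, ...) {
  cat(sprintf("Absorption dynamics: TPeak %.4g min, T50 %.4g min, MaxCH %.4g g/min, AuC %.4g g\n",
              x$t_peak_min, x$t_50_min, x$max_rate_g_min, x$area_g))
  invisible(x)
}

# Ordered input sets of the four training strategies.  BI is the bolus dose
# in pmol/1000, DfB the minutes since the last basal injection /100; the
# remaining inputs are unscaled (SBGL mmol/L, MaxCH g/min, AuC g, TPeak and
# T50 min).
.strategy_inputs <- list(
  ABS     = c("BI", "SBGL", "MaxCH", "TPeak", "T50"),
  AUC     = c("BI", "SBGL", "MaxCH", "AuC",   "TPeak"),
  DFB     = c("BI", "SBGL", "MaxCH", "TPeak", "DfB"),
  AUC_DFB = c("BI", "SBGL", "MaxCH", "AuC",   "DfB")
)

#' Training strategies and their input sets
#'
#' Each strategy names an ordered 5-tuple of network inputs.  `ABS` is the
#' short-term absorption-dynamics set; `AUC` swaps T50 for the area under the
#' absorption curve; `DFB` swaps T50 for the delay from the last basal
#' injection; `AUC_DFB` uses both longer-term parameters (dropping TPeak and
#' T50 except through MaxCH) and is the proposed mid-term set.
#'
#' @param name One of `"ABS"`, `"AUC"`, `"DFB"`, `"AUC_DFB"`.
#' @return An object of class `strategy` with fields `name` and
#'   `input_names` (ordered character 5-vector).
#' @export
strategy <- function(name = c("ABS", "AUC", "DFB", "AUC_DFB")) {
  name <- match.arg(name)
  structure(list(name = name, input_names = .strategy_inputs[[name]]),
            class = "strategy")
}

as_strategy <- function(x) {
  if (inherits(x, "strategy")) x else strategy(x)
}

#' @export
print.strategy <- function(x, ...) {
  cat(sprintf("Strategy %s: (%s)\n", x$name, paste(x$input_names, collapse = ", ")))
  invisible(x)
}

#' Assemble the scaled 5-input feature vector for one meal episode
#'
#' Values are placed in the strategy's input order.  Scaling: BI is the bolus
#' dose divided by 1000, DfB the basal delay in minutes divided by 100; SBGL,
#' MaxCH, AuC, TPeak and T50 stay in their natural units.
#'
#' @param episode A `meal_episode` from [clean_meals()].
#' @param params A `curve_parameters` object for the episode's meal.
#' @param strategy A [strategy()] object or its name.
#' @return An object of class `feature_vector`: list with `strategy`,
#'   `values` (named numeric 5-vector) and `meal_id`.
#' @export
build_features <- function(episode, params, strategy) {
  strategy <- as_strategy(strategy)
  stopifnot(inherits(params, "curve_parameters"))
  pool <- c(BI    = episode$bolus_dose_pmol / 1000,
            SBGL  = episode$sbgl_mmol_l,
            MaxCH = params$max_rate_g_min,
            AuC   = params$area_g,
            TPeak = params$t_peak_min,
            T50   = params$t_50_min,
            DfB   = if (is.null(episode$dfb_min) || is.na(episode$dfb_min))
              NA_real_ else episode$dfb_min / 100)
  vals <- pool[strategy$input_names]
  if (anyNA(vals) || any(!is.finite(vals)))
    stop("build_features: missing or non-finite input(s) for strategy ",
         strategy$name, ": ",
         paste(strategy$input_names[!is.finite(vals)], collapse = ", "))
  structure(list(strategy = strategy, values = vals,
                 meal_id = episode$meal$meal_id),
            class = "feature_vector")
}

#' Export a feature table for a set of episodes
#'
#' One row per episode with columns
#' `meal_id,strategy,BI,SBGL,MaxCH,AuC,TPeak,T50,DfB`; inputs not used by the
#' strategy are left empty.
#'
#' @param episodes A list of `meal_episode` objects.
#' @param strategy Strategy object or name.
#' @param params An [absorption_params()] object used to simulate each meal.
#' @param path Optional CSV output path.
#' @return The feature table as a data frame (invisibly written to `path`
#'   when given).
#' @export
feature_table <- function(episodes, strategy, params = absorption_params(),
                          path = NULL) {
  strategy <- as_strategy(strategy)
  cols <- c("BI", "SBGL", "MaxCH", "AuC", "TPeak", "T50", "DfB")
  rows <- lapply(episodes, function(ep) {
    cp <- curve_parameters(simulate_absorption(ep$meal, params))
    fv <- build_features(ep, cp, strategy)
    out <- stats::setNames(rep(NA_real_, length(cols)), cols)
    out[names(fv$values)] <- fv$values
    data.frame(meal_id = ep$meal$meal_id, strategy = strategy$name,
               as.list(out), check.names = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (!is.null(path))
    utils::write.csv(tab, path, row.names = FALSE, na = "")
  tab
}
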