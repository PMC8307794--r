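#' Parameters of the two-compartment glucose absorption model
#'
#' The absorption model converts a meal's nutrient composition into an
#' estimated glucose infusion rate ("absorption") curve.  It is a deliberately
#' small two-compartment stomach-to-gut system: gastric emptying moves the
#' monosaccharide and starch pools from the stomach into the gut at a common
#' rate that is slowed by the protein, lipid and fiber content of the meal;
#' starch in the gut is digested into glucose at a rate proportional to the
#' meal's glycemic index; gut glucose is absorbed into the blood at a fixed
#' rate, and that absorption flux is the returned curve.
#'
#' @param k_empty0 Baseline gastric emptying rate, 1/min.
#' @param alpha_protein,alpha_lipid,alpha_fiber Emptying-inhibition
#'   coefficients, 1/g.  The effective emptying rate for a meal with P g
#'   protein, L g lipid and F g fiber is
#'   `k_empty0 / (1 + alpha_protein*P + alpha_lipid*L + alpha_fiber*F)`.
#' @param k_abs Gut-to-blood absorption rate, 1/min.
#' @param k_digest_ref Starch digestion rate at the reference glycemic index,
#'   1/min.  A meal with glycemic index GI digests starch at
#'   `k_digest_ref * GI / gi_ref`.
#' @param gi_ref Reference glycemic index (dimensionless).
#' @param step_min Fixed integration step, minutes.
#' @param t_max_min Hard cap on the simulated duration, minutes.
#' @param completeness Fraction of the digestible carbohydrate mass whose
#'   absorption terminates the integration early.
#' @return An object of class `absorption_params`.
#' @export
absorption_params <- function(k_empty0 = 0.046,
                              alpha_protein = 0.02,
                              alpha_lipid = 0.035,
                              alpha_fiber = 0.06,
                              k_abs = 0.056,
                              k_digest_ref = 0.023,
                              gi_ref = 100,
                              step_min = 1,
                              t_max_min = 600,
                              completeness = 0.995) {
  p <- list(k_empty0 = k_empty0, alpha_protein = alpha_protein,
            alpha_lipid = alpha_lipid, alpha_fiber = alpha_fiber,
            k_abs = k_abs, k_digest_ref = k_digest_ref, gi_ref = gi_ref,
            step_min = step_min, t_max_min = t_max_min,
            completeness = completeness)
  rates <- c("k_empty0", "alpha_protein", "alpha_lipid", "alpha_fiber",
             "k_abs", "k_digest_ref", "gi_ref", "step_min", "t_max_min")
  for (nm in rates) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]) ||
        p[[nm]] <= 0)
      stop("absorption_params: '", nm, "' must be a single positive number")
  }
  if (!is.numeric(completeness) || completeness <= 0 || completeness >= 1)
    stop("absorption_params: 'completeness' must lie strictly in (0, 1)")
  structure(p, class = "absorption_params")
}

#' Read absorption model parameters from a YAML file
#'
#' The file holds a flat mapping whose keys mirror [absorption_params()]
#' argument names; absent keys keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return An `absorption_params` object.
#' @export
read_absorption_params <- function(path) {
  stopifnot(file.exists(path))
  vals <- yaml::read_yaml(path)
  known <- names(formals(absorption_params))
  extra <- setdiff(names(vals), known)
  if (length(extra))
    stop("read_absorption_params: unknown keys: ", paste(extra, collapse = ", "))
  do.call(absorption_params, vals)
}

#' @export
print.absorption_params <- function(x, ...) {
  cat("Two-compartment absorption model parameters\n")
  cat(sprintf("  gastric emptying  k_empty0 = %g /min (inhibition /g: protein %g, lipid %g, fiber %g)\n",
              x$k_empty0, x$alpha_protein, x$alpha_lipid, x$alpha_fiber))
  cat(sprintf("  starch digestion  k_digest_ref = %g /min at GI %g\n",
              x$k_digest_ref, x$gi_ref))
  cat(sprintf("  gut absorption    k_abs = %g /min\n", x$k_abs))
  cat(sprintf("  integration       step %g min, cap %g min, completeness %g\n",
              x$step_min, x$t_max_min, x$completeness))
  invisible(x)
}

new_absorption_curve <- function(times_min, rates_g_per_min, empty = FALSE) {
  structure(list(times_min = times_min,
                 rates_g_per_min = rates_g_per_min,
                 empty = empty),
            class = "absorption_curve")
}

#' @export
print.absorption_curve <- function(x, ...) {
  if (x$empty) {
    cat("Absorption curve: empty (zero-carbohydrate meal)\n")
  } else {
    cat(sprintf("Absorption curve: %d points over %g min, peak %.4g g/min\n",
                length(x$times_min), max(x$times_min), max(x$rates_g_per_min)))
  }
  invisible(x)
}

#' Simulate the glucose absorption curve of a meal
#'
#' Integrates the two-compartment system with the classical fixed-step
#' 4th-order Runge-Kutta scheme on the grid `0, step_min, 2*step_min, ...`.
#' State: stomach monosaccharide `S_m`, stomach starch `S_s`, gut starch
#' `Q_s`, gut glucose `Q`, plus the cumulative absorbed mass used for the
#' completeness stop.  The returned rate is `k_abs * Q(t)`.  Integration stops
#' as soon as the cumulative absorbed mass reaches
#' `completeness * (monosaccharide_g + starch_g)` or at `t_max_min`.
#'
#' @param meal A meal record (list or one-row data frame) with numeric fields
#'   `monosaccharide_g`, `starch_g`, `protein_g`, `lipid_g`, `fiber_g`,
#'   `glycemic_index`.
#' @param params An [absorption_params()] object.
#' @return An `absorption_curve` with fields `times_min`, `rates_g_per_min`
#'   and the flag `empty` (`TRUE` for a zero-carbohydrate meal, in which case
#'   the curve is the single point (0, 0)).
#' @export
simulate_absorption <- function(meal, params = absorption_params()) {
  stopifnot(inherits(params, "absorption_params"))
  need <- c("monosaccharide_g", "starch_g", "protein_g", "lipid_g",
            "fiber_g", "glycemic_index")
  m <- lapply(need, function(nm) {
    v <- meal[[nm]]
    if (is.null(v) || !is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("simulate_absorption: meal field '", nm, "' must be a finite number")
    as.numeric(v)
  })
  names(m) <- need
  if (any(unlist(m[c(need[1:5])]) < 0) || m$glycemic_index < 0)
    stop("simulate_absorption: meal masses and glycemic index must be >= 0")

  ch <- m$monosaccharide_g + m$starch_g
  if (ch == 0)
    return(new_absorption_curve(0, 0, empty = TRUE))

  k_e <- params$k_empty0 /
    (1 + params$alpha_protein * m$protein_g +
       params$alpha_lipid * m$lipid_g +
       params$alpha_fiber * m$fiber_g)
  k_d <- params$k_digest_ref * m$glycemic_index / params$gi_ref
  k_a <- params$k_abs
  h <- params$step_min
  n_steps <- ceiling(params$t_max_min / h)
  target <- params$completeness * ch

  # The completeness stop watches the running trapezoid integral of the
  # emitted rate grid, so the returned curve's own area satisfies the
  # conservation contract.
  rates <- absorption_rk4_cpp(m$monosaccharide_g, m$starch_g,
                              k_e, k_d, k_a, h, n_steps, target)
  new_absorption_curve(times_min = (seq_along(rates) - 1L) * h,
                       rates_g_per_min = rates)
}

#' Write an absorption curve to CSV
#'
#' Columns `t_min,rate_g_per_min`.
#'
#' @param curve An `absorption_curve`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_absorption_curve <- function(curve, path) {
  stopifnot(inherits(curve, "absorption_curve"))
  utils::write.csv(data.frame(t_min = curve$times_min,
                              rate_g_per_min = curve$rates_g_per_min),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
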