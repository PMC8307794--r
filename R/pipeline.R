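#' Chronological train/validation split
#'
#' The first `floor(n * train_fraction)` episodes (by meal date and time)
#' form the training set; the remainder validate.  No shuffling: with the
#' default two-thirds fraction, 43 episodes split 28/15 and 26 split 17/9.
#'
#' @param episodes List of `meal_episode` objects (any order; they are
#'   sorted by meal timestamp first).
#' @param train_fraction Fraction of episodes used for training.
#' @return List with `train` and `validation` episode lists.
#' @export
chronological_split <- function(episodes, train_fraction = 2 / 3) {
  n <- length(episodes)
  if (n < 3L) stop("chronological_split: need at least 3 episodes, got ", n)
  episodes <- sort_episodes(episodes)
  n_train <- floor(n * train_fraction + 1e-9)
  list(train = episodes[seq_len(n_train)],
       validation = episodes[seq(n_train + 1L, n)])
}

episode_matrices <- function(episodes, strategy, horizon_min,
                             absorption = absorption_params()) {
  strategy <- as_strategy(strategy)
  hkey <- as.character(horizon_min)
  X <- matrix(NA_real_, length(episodes), 5L)
  Y <- matrix(NA_real_, length(episodes), horizon_min / 2)
  for (i in seq_along(episodes)) {
    ep <- episodes[[i]]
    cp <- curve_parameters(simulate_absorption(ep$meal, absorption))
    X[i, ] <- build_features(ep, cp, strategy)$values
    tgt <- ep$targets[[hkey]]
    if (is.null(tgt))
      stop("episode ", ep$meal$meal_id, " carries no ", horizon_min,
           "-min target trajectory")
    Y[i, ] <- tgt
  }
  colnames(X) <- strategy$input_names
  list(X = X, Y = Y)
}

#' Train a per-patient model for one strategy and horizon
#'
#' Builds the strategy's scaled feature vectors and the horizon's CGM target
#' trajectories for every episode, splits chronologically, initializes the
#' network from `config$seed` and trains on the training split only.
#'
#' @param episodes Episodes of a single patient (at least 3 after cleaning).
#' @param strategy [strategy()] object or name.
#' @param horizon_min Prediction horizon, minutes (60, 90, 120, 180).
#' @param config A [training_config()].
#' @param absorption An [absorption_params()] object.
#' @param train_fraction Passed to [chronological_split()].
#' @return An object of class `patient_model` with the trained network, the
#'   training history and the episode ids of both splits.
#' @export
train_patient <- function(episodes, strategy, horizon_min,
                          config = training_config(),
                          absorption = absorption_params(),
                          train_fraction = 2 / 3) {
  strategy <- as_strategy(strategy)
  if (length(episodes) < 3L)
    stop("train_patient: need at least 3 episodes")
  pid <- unique(vapply(episodes, `[[`, character(1), "patient_id"))
  if (length(pid) != 1L)
    stop("train_patient: episodes span several patients; models are per-patient")
  split <- chronological_split(episodes, train_fraction)
  mats <- episode_matrices(split$train, strategy, horizon_min, absorption)
  net <- init_network(network_layout(horizon_min), config$seed)
  fit <- train_network(net, mats$X, mats$Y, config)
  ids <- function(eps) vapply(eps, function(e) e$meal$meal_id, character(1))
  structure(list(patient_id = pid, strategy = strategy,
                 horizon_min = horizon_min, network = fit$network,
                 config = config, history = fit$history,
                 final_mse = fit$final_mse,
                 train_ids = ids(split$train),
                 validation_ids = ids(split$validation)),
            class = "patient_model")
}

#' @export
print.patient_model <- function(x, ...) {
  cat(sprintf("Patient model %s: strategy %s, horizon %d min, %d train / %d validation episodes\n",
              x$patient_id, x$strategy$name, x$horizon_min,
              length(x$train_ids), length(x$validation_ids)))
  if (!is.null(x$final_mse))
    cat(sprintf("  final training MSE %.4g (mmol/L)^2\n", x$final_mse))
  invisible(x)
}

#' Predict the post-meal BGL trajectory for one episode
#'
#' @param model A `patient_model`.
#' @param episode A `meal_episode`.
#' @param absorption An [absorption_params()] object (must match the one
#'   used in training).
#' @return Numeric vector of `horizon_min / 2` BGL values at 2-min steps.
#' @export
predict_episode <- function(model, episode,
                            absorption = absorption_params()) {
  stopifnot(inherits(model, "patient_model"))
  cp <- curve_parameters(simulate_absorption(episode$meal, absorption))
  fv <- build_features(episode, cp, model$strategy)
  forward(model$network, fv$values)
}

#' Build a hybrid short/mid-term predictor
#'
#' Combines a 60-min model trained with the short-term `ABS` input set and a
#' mid-term (90 min or longer) model trained with `AUC_DFB`: the first
#' 60 minutes of the prediction window come from the short model, the rest
#' from the mid model, with no smoothing at the seam.
#'
#' @param short_model A `patient_model` (strategy ABS, 60 min horizon).
#' @param mid_model A `patient_model` (strategy AUC_DFB, horizon >= 90 min),
#'   same patient.
#' @return An object of class `hybrid_model`.
#' @export
hybrid_model <- function(short_model, mid_model) {
  stopifnot(inherits(short_model, "patient_model"),
            inherits(mid_model, "patient_model"))
  if (short_model$patient_id != mid_model$patient_id)
    stop("hybrid_model: models belong to different patients")
  if (short_model$horizon_min != 60)
    stop("hybrid_model: the short model must have a 60-min horizon")
  if (mid_model$horizon_min <= 60)
    stop("hybrid_model: the mid model horizon must exceed 60 min")
  structure(list(short_model = short_model, mid_model = mid_model),
            class = "hybrid_model")
}

#' @export
print.hybrid_model <- function(x, ...) {
  cat(sprintf("Hybrid model %s: %s (<= 60 min) + %s (%d min)\n",
              x$short_model$patient_id, x$short_model$strategy$name,
              x$mid_model$strategy$name, x$mid_model$horizon_min))
  invisible(x)
}

#' Predict with the hybrid model
#'
#' Outputs 1..30 (t <= 60 min) are copied from the short model's
#' prediction, outputs 31..n from the mid model's.
#'
#' @param h A [hybrid_model()].
#' @param episode A `meal_episode`.
#' @param absorption An [absorption_params()] object.
#' @return Numeric vector to the mid model's horizon.
#' @export
hybrid_predict <- function(h, episode, absorption = absorption_params()) {
  stopifnot(inherits(h, "hybrid_model"))
  short <- predict_episode(h$short_model, episode, absorption)
  mid <- predict_episode(h$mid_model, episode, absorption)
  c(short[1:30], mid[31:length(mid)])
}

#' Pooled RMSE/MAE over a set of predicted trajectories
#'
#' Errors (predicted minus measured BGL) are pooled over all sample points
#' of all episodes in scope; `RMSE = sqrt(mean(e^2))`, `MAE = mean(|e|)`.
#' With a window `(lo, hi]` (minutes), only trajectory indices `i` with
#' `lo < 2*i <= hi` contribute: window `c(60, 120)` uses indices 31..60,
#' `c(120, 180)` indices 61..90.
#'
#' @param predictions List of predicted trajectories.
#' @param targets List of measured trajectories, same lengths.
#' @param window Optional `c(lo, hi)` window in minutes, half-open on the
#'   left.
#' @param scope Label for the metrics (patient id or `"all datasets"`).
#' @return An object of class `metrics`: list with `rmse_mmol_l`,
#'   `mae_mmol_l`, `n_points`, `window`, `scope`.
#' @export
evaluate <- function(predictions, targets, window = NULL,
                     scope = "all datasets") {
  stopifnot(length(predictions) == length(targets))
  errs <- numeric(0)
  for (i in seq_along(predictions)) {
    p <- predictions[[i]]; y <- targets[[i]]
    if (length(p) != length(y))
      stop("evaluate: prediction and target lengths differ for episode ", i)
    e <- p - y
    if (!is.null(window)) {
      idx <- which(window[1L] < 2 * seq_along(e) &
                     2 * seq_along(e) <= window[2L])
      e <- e[idx]
    }
    errs <- c(errs, e)
  }
  if (length(errs) == 0L)
    stop("evaluate: no error points in scope (empty pool)")
  structure(list(rmse_mmol_l = sqrt(mean(errs^2)),
                 mae_mmol_l = mean(abs(errs)),
                 n_points = length(errs),
                 window = window, scope = scope),
            class = "metrics")
}

#' @export
print.metrics <- function(x, ...) {
  win <- if (is.null(x$window)) "full horizon"
         else sprintf("(%g, %g] min", x$window[1L], x$window[2L])
  cat(sprintf("%s: RMSE %.3f mmol/L, MAE %.3f mmol/L (%s, %d points)\n",
              x$scope, x$rmse_mmol_l, x$mae_mmol_l, win, x$n_points))
  invisible(x)
}

#' Evaluate a patient model on its validation episodes
#'
#' @param model A `patient_model`.
#' @param episodes The patient's full episode list (validation episodes are
#'   selected by the ids recorded at training time), or any episode list
#'   when `use_validation_ids = FALSE`.
#' @param window Optional evaluation window, see [evaluate()].
#' @param absorption An [absorption_params()] object.
#' @param use_validation_ids Restrict to the model's recorded validation
#'   split.
#' @return A `metrics` object.
#' @export
evaluate_model <- function(model, episodes, window = NULL,
                           absorption = absorption_params(),
                           use_validation_ids = TRUE) {
  eps <- episodes
  if (use_validation_ids) {
    ids <- vapply(episodes, function(e) e$meal$meal_id, character(1))
    eps <- episodes[ids %in% model$validation_ids]
  }
  preds <- lapply(eps, predict_episode, model = model,
                  absorption = absorption)
  targs <- lapply(eps, function(e) e$targets[[as.character(model$horizon_min)]])
  evaluate(preds, targs, window = window, scope = model$patient_id)
}

#' Per-episode RMSE values (the paired t-test unit)
#'
#' @inheritParams evaluate_model
#' @return Named numeric vector, one pooled RMSE per validation episode.
#' @export
per_episode_rmse <- function(model, episodes, window = NULL,
                             absorption = absorption_params()) {
  ids <- vapply(episodes, function(e) e$meal$meal_id, character(1))
  eps <- episodes[ids %in% model$validation_ids]
  out <- vapply(eps, function(e) {
    evaluate(list(predict_episode(model, e, absorption)),
             list(e$targets[[as.character(model$horizon_min)]]),
             window = window, scope = model$patient_id)$rmse_mmol_l
  }, numeric(1))
  stats::setNames(out, vapply(eps, function(e) e$meal$meal_id, character(1)))
}

#' Threefold chronological cross-validation
#'
#' Episodes are cut into three contiguous chronological blocks whose sizes
#' differ by at most one; each fold validates on one block and trains on the
#' other two.
#'
#' @param episodes A single patient's episodes (n >= 6).
#' @param strategy,horizon_min,config,absorption As in [train_patient()].
#' @return List of three elements, each with `metrics` (a [evaluate()]
#'   result pooled over the fold's validation block), `model` and
#'   `validation_ids`.
#' @export
crossval3 <- function(episodes, strategy, horizon_min,
                      config = training_config(),
                      absorption = absorption_params()) {
  n <- length(episodes)
  if (n < 6L) stop("crossval3: need at least 6 episodes, got ", n)
  episodes <- sort_episodes(episodes)
  fold_of <- rep(1:3, times = diff(floor(n * (0:3) / 3)))
  lapply(1:3, function(k) {
    train_eps <- episodes[fold_of != k]
    val_eps <- episodes[fold_of == k]
    mats <- episode_matrices(train_eps, strategy, horizon_min, absorption)
    net <- init_network(network_layout(horizon_min), config$seed)
    fit <- train_network(net, mats$X, mats$Y, config)
    model <- structure(list(patient_id = val_eps[[1L]]$patient_id,
                            strategy = as_strategy(strategy),
                            horizon_min = horizon_min,
                            network = fit$network, config = config,
                            history = fit$history,
                            final_mse = fit$final_mse,
                            train_ids = vapply(train_eps, function(e)
                              e$meal$meal_id, character(1)),
                            validation_ids = vapply(val_eps, function(e)
                              e$meal$meal_id, character(1))),
                       class = "patient_model")
    preds <- lapply(val_eps, predict_episode, model = model,
                    absorption = absorption)
    targs <- lapply(val_eps, function(e)
      e$targets[[as.character(horizon_min)]])
    list(metrics = evaluate(preds, targs,
                            scope = sprintf("%s fold %d",
                                            model$patient_id, k)),
         model = model,
         validation_ids = model$validation_ids)
  })
}

#' Random subsample of episodes, re-sorted chronologically
#'
#' Used to equalize training set sizes across patients (default 26 meals,
#' which then split 17/9 chronologically).
#'
#' @param episodes Episode list.
#' @param n Subsample size.
#' @param seed Integer seed; the draw is uniform without replacement and
#'   deterministic per seed.
#' @return Episode list of length `n` in chronological order.
#' @export
limited_subsample <- function(episodes, n = 26, seed = 1L) {
  if (length(episodes) < n)
    stop("limited_subsample: only ", length(episodes),
         " episodes available, need ", n)
  keep <- with_local_seed(seed, sample.int(length(episodes), n))
  sort_episodes(episodes[keep])
}

#' Paired sample t-test on per-episode errors
#'
#' Classical paired t: `t = mean(d) / (sd(d) / sqrt(n))` with the sample
#' standard deviation (n-1 denominator) and a two-tailed p-value from the t
#' distribution with n-1 degrees of freedom.  Pairs are per-validation-
#' episode RMSE values of two models on the same episodes.
#'
#' @param errors_a,errors_b Equal-length numeric vectors (n >= 2), paired by
#'   episode.
#' @return An object of class `t_test_result`: list with `t_statistic`,
#'   `p_value` (two-tailed), `n`.
#' @export
paired_t_test <- function(errors_a, errors_b) {
  stopifnot(is.numeric(errors_a), is.numeric(errors_b))
  if (length(errors_a) != length(errors_b))
    stop("paired_t_test: sequences must have equal length")
  n <- length(errors_a)
  if (n < 2L) stop("paired_t_test: need at least 2 pairs")
  d <- errors_a - errors_b
  if (stats::sd(d) == 0)
    stop("paired_t_test: degenerate (zero-variance) differences")
  ht <- stats::t.test(errors_a, errors_b, paired = TRUE)
  structure(list(t_statistic = unname(ht$statistic),
                 p_value = unname(ht$p.value), n = n),
            class = "t_test_result")
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("Paired t-test: t = %.4f, two-tailed p = %.4g (n = %d pairs)\n",
              x$t_statistic, x$p_value, x$n))
  invisible(x)
}

#' Write an evaluation report row to CSV
#'
#' Columns `scope,strategy,horizon,window,rmse_mmol_l,mae_mmol_l,n_points`.
#'
#' @param metrics_list List of `metrics` objects.
#' @param strategy_name,horizon_min Report annotations.
#' @param path Output CSV path.
#' @return The report data frame, invisibly written to `path`.
#' @export
write_report <- function(metrics_list, strategy_name, horizon_min, path) {
  rows <- lapply(metrics_list, function(m)
    data.frame(scope = m$scope, strategy = strategy_name,
               horizon = horizon_min,
               window = if (is.null(m$window)) ""
                        else sprintf("%g:%g", m$window[1L], m$window[2L]),
               rmse_mmol_l = m$rmse_mmol_l, mae_mmol_l = m$mae_mmol_l,
               n_points = m$n_points))
  report <- do.call(rbind, rows)
  utils::write.csv(report, path, row.names = FALSE, quote = FALSE)
  invisible(report)
}

#' Split episodes by patient
#'
#' @param episodes A `meal_episodes` object or plain episode list.
#' @return Named list of per-patient episode lists, chronologically sorted.
#' @export
episodes_by_patient <- function(episodes) {
  if (inherits(episodes, "meal_episodes")) episodes <- episodes$episodes
  pids <- vapply(episodes, `[[`, character(1), "patient_id")
  lapply(split(episodes, pids), sort_episodes)
}
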