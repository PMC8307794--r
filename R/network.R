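#' Network layout for a prediction horizon
#'
#' The trajectory regressor is a fully connected feed-forward network with
#' five inputs, two tanh hidden layers of 20 and 60 neurons, and a linear
#' output layer with one output per 2-min step of the horizon (30 outputs
#' for 60 min, 45 for 90, 60 for 120, 90 for 180).  Hidden sizes and input
#' width are exposed for small diagnostic networks but default to the study
#' configuration.
#'
#' @param horizon_min Prediction horizon in minutes (60, 90, 120 or 180).
#'   Ignored when `n_out` is given directly.
#' @param n_out Number of output neurons; defaults to `horizon_min / 2`.
#' @param hidden Hidden layer sizes.
#' @param n_in Input width.
#' @return An object of class `network_layout` with field `layer_sizes`.
#' @export
network_layout <- function(horizon_min = NULL, n_out = NULL,
                           hidden = c(20, 60), n_in = 5) {
  if (is.null(n_out)) {
    if (is.null(horizon_min))
      stop("network_layout: give either horizon_min or n_out")
    if (!horizon_min %in% c(60, 90, 120, 180))
      stop("network_layout: horizon_min must be one of 60, 90, 120, 180")
    n_out <- horizon_min / 2
  }
  sizes <- as.integer(c(n_in, hidden, n_out))
  if (any(sizes < 1L)) stop("network_layout: all layer sizes must be >= 1")
  structure(list(layer_sizes = sizes,
                 hidden_activation = "tanh",
                 output_activation = "linear"),
            class = "network_layout")
}

#' @export
print.network_layout <- function(x, ...) {
  cat(sprintf("FNN layout: %s (tanh hidden, linear output)\n",
              paste(x$layer_sizes, collapse = " -> ")))
  invisible(x)
}

n_weights <- function(layout) {
  s <- layout$layer_sizes
  sum(s[-length(s)] * s[-1L] + s[-1L])
}

with_local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Initialize a network with seeded symmetric weights
#'
#' Weights and biases of each layer are drawn uniformly from
#' `[-1/sqrt(fan_in), 1/sqrt(fan_in)]`; the draw is fully determined by
#' `seed`.
#'
#' @param layout A [network_layout()].
#' @param seed Integer seed.
#' @return An object of class `fnn`: list with `layout`, `weights` (list of
#'   `W` matrices and `b` vectors per layer) and `seed`.
#' @export
init_network <- function(layout, seed) {
  stopifnot(inherits(layout, "network_layout"), is.numeric(seed))
  s <- layout$layer_sizes
  weights <- with_local_seed(seed, {
    lapply(seq_len(length(s) - 1L), function(l) {
      r <- 1 / sqrt(s[l])
      list(W = matrix(stats::runif(s[l] * s[l + 1L], -r, r), s[l], s[l + 1L]),
           b = stats::runif(s[l + 1L], -r, r))
    })
  })
  structure(list(layout = layout, weights = weights, seed = seed),
            class = "fnn")
}

#' @export
print.fnn <- function(x, ...) {
  cat(sprintf("Feed-forward network %s, %d parameters (seed %s)\n",
              paste(x$layout$layer_sizes, collapse = " -> "),
              n_weights(x$layout), format(x$seed)))
  invisible(x)
}

flatten_weights <- function(net) {
  unlist(lapply(net$weights, function(l) c(as.numeric(l$W), l$b)),
         use.names = FALSE)
}

unflatten_weights <- function(flat, layout) {
  s <- layout$layer_sizes
  pos <- 0L
  lapply(seq_len(length(s) - 1L), function(l) {
    nw <- s[l] * s[l + 1L]
    W <- matrix(flat[pos + seq_len(nw)], s[l], s[l + 1L])
    pos <<- pos + nw
    b <- flat[pos + seq_len(s[l + 1L])]
    pos <<- pos + s[l + 1L]
    list(W = W, b = b)
  })
}

#' Forward pass through the network
#'
#' @param net An `fnn`.
#' @param input A numeric vector of length `n_in`, or a matrix with one
#'   sample per row.
#' @return The output vector (or matrix, one row per input row).
#' @export
forward <- function(net, input) {
  stopifnot(inherits(net, "fnn"))
  vec_in <- is.null(dim(input))
  A <- if (vec_in) matrix(input, nrow = 1L) else as.matrix(input)
  if (ncol(A) != net$layout$layer_sizes[1L])
    stop("forward: input width must be ", net$layout$layer_sizes[1L])
  if (any(!is.finite(A))) stop("forward: input must be finite")
  L <- length(net$weights)
  for (l in seq_len(L)) {
    A <- A %*% net$weights[[l]]$W +
      matrix(net$weights[[l]]$b, nrow(A), length(net$weights[[l]]$b),
             byrow = TRUE)
    if (l < L) A <- tanh(A)
  }
  if (vec_in) drop(A) else A
}

#' Training configuration
#'
#' Defaults follow the study configuration: quasi-Newton (BFGS) training
#' with a Brent-style scalar line search of tolerance `1e-6`, at most 118
#' iteration cycles, and an error goal of `1e-15` (10 x 10^-16) that stops
#' training early.
#'
#' @param max_iterations Maximum number of iteration cycles.
#' @param line_search_tolerance Brent line search tolerance.
#' @param error_goal Training MSE below which training stops.
#' @param seed Integer seed used for weight initialization bookkeeping.
#' @param mode `"batch"` (BFGS over the whole training set; default) or
#'   `"sequential"` (samples visited chronologically, each optimized from
#'   the previous sample's final weights).
#' @return An object of class `training_config`.
#' @export
training_config <- function(max_iterations = 118,
                            line_search_tolerance = 1e-6,
                            error_goal = 1e-15,
                            seed = 1L,
                            mode = c("batch", "sequential")) {
  mode <- match.arg(mode)
  stopifnot(max_iterations >= 1, line_search_tolerance > 0, error_goal > 0)
  structure(list(max_iterations = as.integer(max_iterations),
                 line_search_tolerance = line_search_tolerance,
                 error_goal = error_goal, seed = as.integer(seed),
                 mode = mode),
            class = "training_config")
}

#' Train the network on a set of samples
#'
#' Batch mode minimizes the mean squared error over all samples and output
#' positions by BFGS with a Brent line search (bracket `[0, 10]`), resetting
#' the inverse-Hessian approximation whenever the curvature condition fails.
#' Sequential mode follows the literal one-sample-at-a-time narrative:
#' samples are visited in order, each optimized for up to `max_iterations`
#' starting from the previous sample's final weights; its recorded history
#' is the full-set MSE after each sample and is not guaranteed to be
#' monotone.
#'
#' @param net An initialized `fnn`.
#' @param X Input matrix, one sample per row (`n x n_in`).
#' @param Y Target matrix (`n x n_out`), BGL in mmol/L at 2-min steps.
#' @param config A [training_config()].
#' @return A list with `network` (trained `fnn`), `history` (per-iteration
#'   training MSE), `initial_mse`, `final_mse`.
#' @export
train_network <- function(net, X, Y, config = training_config()) {
  stopifnot(inherits(net, "fnn"), inherits(config, "training_config"))
  X <- as.matrix(X); Y <- as.matrix(Y)
  s <- net$layout$layer_sizes
  if (nrow(X) < 1L) stop("train_network: need at least one sample")
  if (nrow(X) != nrow(Y))
    stop("train_network: X and Y must have the same number of rows")
  if (ncol(X) != s[1L] || ncol(Y) != s[length(s)])
    stop("train_network: sample dimensions do not match the layout")
  if (any(!is.finite(X)) || any(!is.finite(Y)))
    stop("train_network: non-finite training data")

  w0 <- flatten_weights(net)
  if (config$mode == "batch") {
    fit <- fnn_train_bfgs(w0, s, X, Y, config$max_iterations,
                          config$line_search_tolerance, config$error_goal)
    w <- fit$weights
    history <- fit$history
    initial <- fit$initial_mse
  } else {
    w <- w0
    initial <- fnn_mse_cpp(w, s, X, Y)
    history <- numeric(0)
    for (i in seq_len(nrow(X))) {
      fit <- fnn_train_bfgs(w, s, X[i, , drop = FALSE], Y[i, , drop = FALSE],
                            config$max_iterations,
                            config$line_search_tolerance, config$error_goal)
      w <- fit$weights
      history <- c(history, fnn_mse_cpp(w, s, X, Y))
    }
  }
  net$weights <- unflatten_weights(w, net$layout)
  list(network = net, history = history, initial_mse = initial,
       final_mse = fnn_mse_cpp(w, s, X, Y), config = config)
}

#' Save a trained network as versioned JSON
#'
#' The file round-trips bit-exactly through [load_model()].
#'
#' @param model A `patient_model` from [train_patient()] or a bare `fnn`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  if (inherits(model, "fnn")) {
    payload <- list(format = "glucopred-fnn", version = 1L,
                    kind = "fnn",
                    layer_sizes = model$layout$layer_sizes,
                    seed = model$seed,
                    weights = flatten_weights(model))
  } else if (inherits(model, "patient_model")) {
    payload <- list(format = "glucopred-fnn", version = 1L,
                    kind = "patient_model",
                    patient_id = model$patient_id,
                    strategy = model$strategy$name,
                    horizon_min = model$horizon_min,
                    layer_sizes = model$network$layout$layer_sizes,
                    seed = model$network$seed,
                    config = unclass(model$config),
                    train_ids = model$train_ids,
                    validation_ids = model$validation_ids,
                    weights = flatten_weights(model$network))
  } else stop("save_model: unsupported object")
  # I(17) significant digits: decimal round-trips to the identical double
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Load a network or patient model saved by [save_model()]
#'
#' @param path JSON model file.
#' @return An `fnn` or `patient_model`.
#' @export
load_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "glucopred-fnn"))
    stop("load_model: not a glucopred model file: ", path)
  sizes <- as.integer(p$layer_sizes)
  layout <- network_layout(n_out = sizes[length(sizes)],
                           hidden = sizes[-c(1L, length(sizes))],
                           n_in = sizes[1L])
  net <- structure(list(layout = layout,
                        weights = unflatten_weights(as.numeric(p$weights),
                                                    layout),
                        seed = p$seed),
                   class = "fnn")
  if (identical(p$kind, "patient_model")) {
    cfg <- do.call(training_config, p$config[c("max_iterations",
                                               "line_search_tolerance",
                                               "error_goal", "seed", "mode")])
    structure(list(patient_id = p$patient_id,
                   strategy = strategy(p$strategy),
                   horizon_min = p$horizon_min,
                   network = net, config = cfg,
                   train_ids = as.character(p$train_ids),
                   validation_ids = as.character(p$validation_ids),
                   history = NULL),
              class = "patient_model")
  } else net
}
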