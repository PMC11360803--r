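#' Training configuration for the SHO-trained network
#'
#' The Sea Horse Optimization metaheuristic searches the network's flat
#' weight-and-bias vector inside the box
#' \code{[-weight_bound, +weight_bound]^N}, minimizing the squared-error
#' cost (or the training error rate) on the training batch. The default
#' weight bound of 5 reflects that sigmoidal units saturate beyond |z| of
#' about 5, so wider boxes waste population budget.
#'
#' Two hybrid ingredients are on by default because the full training recipe
#' uses them: offspring mutation in the breeding phase (the recipe generates
#' offspring by combining \emph{and mutating} the selected parents; pure
#' convex recombination alone leaves the population rank-deficient around
#' the elite and the search stalls at constant predictors), and full-batch
#' gradient-descent refinement of the returned optimum (the network's
#' gradient-descent update is fully specified as its training rule and is
#' the natural local polish of the global population search). Set
#' \code{refine_with_gd = FALSE} and \code{sho = list(mutation_p = 0)} for
#' the bare population search.
#'
#' @param hidden_layers number of hidden layers (each of
#'   \code{hidden_neurons} units).
#' @param hidden_neurons units per hidden layer (default 10).
#' @param hidden_activation,output_activation passed to [network_spec()].
#' @param weight_bound half-width of the search box for every parameter.
#' @param pop_size,max_iter SHO population size and iteration budget.
#' @param fitness \code{"mse_cost"} (squared-error cost, default) or
#'   \code{"error_rate"} (1 - training accuracy).
#' @param refine_with_gd logical; polish the SHO optimum with full-batch
#'   gradient descent.
#' @param eta,epochs gradient-descent refinement parameters.
#' @param seed integer seed for the whole training run.
#' @param sho named list of overrides forwarded to [sho_params()]
#'   (e.g. \code{levy_lambda}).
#' @return an object of class \code{"training_config"}.
#' @export
training_config <- function(hidden_layers = 1L, hidden_neurons = 10L,
                            hidden_activation = "radial_basis",
                            output_activation = "sigmoid",
                            weight_bound = 5,
                            pop_size = 30L, max_iter = 100L,
                            fitness = c("mse_cost", "error_rate"),
                            refine_with_gd = TRUE, eta = 0.5,
                            epochs = 300L,
                            seed = 1L,
                            sho = list(mutation_p = 0.2, mutation_sd = 0.5)) {
  fitness <- match.arg(fitness)
  if (weight_bound <= 0) stop("`weight_bound` must be positive")
  if (hidden_layers < 1L) stop("need at least one hidden layer")
  structure(list(hidden_layers = as.integer(hidden_layers),
                 hidden_neurons = as.integer(hidden_neurons),
                 hidden_activation = hidden_activation,
                 output_activation = output_activation,
                 weight_bound = weight_bound,
                 pop_size = as.integer(pop_size),
                 max_iter = as.integer(max_iter),
                 fitness = fitness,
                 refine_with_gd = isTRUE(refine_with_gd),
                 eta = eta, epochs = as.integer(epochs),
                 seed = as.integer(seed), sho = sho),
            class = "training_config")
}

# encode labels for the network: binary -> one 0/1 column (second level is
# the positive class), multi-class -> one-hot
.encode_targets <- function(y) {
  y <- droplevels(as.factor(y))
  lev <- levels(y)
  if (length(lev) < 2L) stop("need at least two classes to train")
  if (length(lev) == 2L) {
    targets <- matrix(as.numeric(y == lev[2]), ncol = 1L)
  } else {
    targets <- matrix(0, length(y), length(lev))
    targets[cbind(seq_along(y), as.integer(y))] <- 1
  }
  list(targets = targets, levels = lev)
}

.net_for <- function(config, input_size, output_size) {
  network_spec(c(input_size, rep(config$hidden_neurons, config$hidden_layers),
                 output_size),
               hidden_activation = config$hidden_activation,
               output_activation = config$output_activation)
}

#' Training objective over flat parameter vectors
#'
#' Returns the function the optimizer minimizes: the squared-error cost of
#' the network on the (already normalized) training batch, or the training
#' error rate when the config selects it.
#'
#' @param config a [training_config()].
#' @param spec the [network_spec()] being trained.
#' @param x normalized input matrix.
#' @param targets encoded target matrix.
#' @return function mapping a flat parameter vector to a scalar fitness.
#' @export
shodnn_fitness <- function(config, spec, x, targets) {
  if (config$fitness == "mse_cost") {
    function(theta) nn_cost(spec, theta, x, targets)
  } else {
    function(theta) {
      y <- nn_forward(spec, theta, x)$output
      pred <- if (ncol(targets) == 1L) as.integer(y[, 1] >= 0.5)
              else max.col(y, ties.method = "first") - 1L
      truth <- if (ncol(targets) == 1L) targets[, 1]
               else max.col(targets, ties.method = "first") - 1L
      mean(pred != truth)
    }
  }
}

#' Train the network with Sea Horse Optimization
#'
#' The swarm-trained classifier: every candidate solution is a flat
#' weight-and-bias vector; SHO evolves the population through movement,
#' predation, breeding and elitist selection, evaluating each candidate's
#' cost on the training batch; the best-so-far vector becomes the model.
#' Inputs should already be z-score normalized (see [fit_zscore()]).
#'
#' @param config a [training_config()].
#' @param x a labeled [feature_table()], or a numeric input matrix.
#' @param y labels (ignored when \code{x} is a labeled feature table).
#' @return an object of class \code{"shodnn_model"}: \code{spec},
#'   \code{theta}, \code{levels}, \code{history} (best-so-far fitness
#'   trace), \code{training_accuracy}, \code{config}.
#' @export
shodnn_train <- function(config, x, y = NULL) {
  if (inherits(x, "feature_table")) {
    y <- x$y
    x <- x$X
  }
  x <- as.matrix(x)
  if (is.null(y)) stop("training needs labels")
  if (nrow(x) != length(y)) stop("inputs and labels disagree in length")
  enc <- .encode_targets(y)
  spec <- .net_for(config, ncol(x), ncol(enc$targets))
  n_par <- param_count(spec)
  objective <- shodnn_fitness(config, spec, x, enc$targets)
  params <- do.call(sho_params, c(list(
    dim = n_par, lower = -config$weight_bound, upper = config$weight_bound,
    pop_size = config$pop_size, max_iter = config$max_iter), config$sho))
  res <- sho_minimize(objective, params, seed = config$seed)
  theta <- res$best_position
  refinement <- NULL
  if (config$refine_with_gd) {
    refinement <- nn_gd_refine(spec, theta, x, enc$targets,
                               eta = config$eta, epochs = config$epochs)
    theta <- refinement$theta
  }
  model <- structure(list(spec = spec, theta = theta, levels = enc$levels,
                          history = res$history,
                          evaluations = res$evaluations,
                          refinement = refinement,
                          config = config),
                     class = "shodnn_model")
  model$training_accuracy <- mean(predict(model, x) == as.character(y))
  model
}

#' @export
print.shodnn_model <- function(x, ...) {
  cat("SHO-trained network\n")
  cat("  layers:", paste(x$spec$layer_sizes, collapse = " -> "), "\n")
  cat("  classes:", paste(x$levels, collapse = ", "), "\n")
  cat(sprintf("  final training fitness: %.6g (%d evaluations)\n",
              x$history[length(x$history)], x$evaluations))
  cat(sprintf("  training accuracy: %.4f\n", x$training_accuracy))
  invisible(x)
}

#' Predict classes or scores from a trained model
#'
#' Binary models threshold the single output at 0.5 (a score of exactly 0.5
#' predicts the positive, i.e. second, class); multi-class models take the
#' arg-max over per-class scores with ties broken toward the lowest class
#' index. Inputs must be normalized with the same z-score model as the
#' training data.
#'
#' @param object a \code{"shodnn_model"}.
#' @param x input matrix or [feature_table()].
#' @param type \code{"class"} (default) or \code{"score"}.
#' @param ... unused.
#' @return character vector of class labels, or the score matrix.
#' @export
predict.shodnn_model <- function(object, x, type = c("class", "score"), ...) {
  type <- match.arg(type)
  if (inherits(x, "feature_table")) x <- x$X
  x <- as.matrix(x)
  if (ncol(x) != object$spec$layer_sizes[1])
    stop("input has ", ncol(x), " features but the model expects ",
         object$spec$layer_sizes[1])
  scores <- nn_forward(object$spec, object$theta, x)$output
  if (type == "score") return(scores)
  if (length(object$levels) == 2L) {
    object$levels[1L + (scores[, 1] >= 0.5)]
  } else {
    object$levels[max.col(scores, ties.method = "first")]
  }
}

#' Random-search baseline with the same evaluation budget
#'
#' Evaluates the same number of uniformly drawn parameter vectors as a full
#' SHO run (\code{pop_size} initial + \code{1.5 * pop_size} per iteration)
#' and keeps the best: the null the optimizer must beat.
#'
#' @inheritParams shodnn_train
#' @return list with \code{best_fitness}, \code{best_position},
#'   \code{evaluations}.
#' @export
random_search_baseline <- function(config, x, y = NULL) {
  if (inherits(x, "feature_table")) {
    y <- x$y
    x <- x$X
  }
  x <- as.matrix(x)
  enc <- .encode_targets(y)
  spec <- .net_for(config, ncol(x), ncol(enc$targets))
  n_par <- param_count(spec)
  objective <- shodnn_fitness(config, spec, x, enc$targets)
  budget <- config$pop_size +
    config$max_iter * (config$pop_size + config$pop_size %/% 2L)
  set.seed(config$seed)
  best <- Inf; best_pos <- NULL
  # draw in chunks to bound memory
  left <- budget
  while (left > 0L) {
    m <- min(left, 500L)
    cand <- matrix(stats::runif(m * n_par, -config$weight_bound,
                                config$weight_bound), m, n_par)
    f <- .eval_rows(objective, cand)
    i <- which.min(f)
    if (f[i] < best) { best <- f[i]; best_pos <- cand[i, ] }
    left <- left - m
  }
  list(best_fitness = best, best_position = best_pos, evaluations = budget)
}

#' Select the hidden-layer count by validation fitness
#'
#' Trains one model per candidate depth (each hidden layer holding
#' \code{hidden_neurons} units) on a stratified internal split and returns
#' the model whose held-out fitness is lowest. The depth search is an outer
#' loop rather than an extra optimizer dimension, since the population
#' updates are real-vector arithmetic.
#'
#' @param config a [training_config()] (its \code{hidden_layers} field is
#'   overridden per candidate).
#' @param x labeled [feature_table()] or input matrix.
#' @param y labels when \code{x} is a matrix.
#' @param candidate_depths integer vector of hidden-layer counts, each >= 1.
#' @param val_fraction fraction held out for depth selection.
#' @return list with \code{model} (the winner), \code{report} (data frame of
#'   depth and validation fitness) and \code{depth}.
#' @export
optimize_architecture <- function(config, x, y = NULL,
                                  candidate_depths = c(1L, 2L, 3L),
                                  val_fraction = 0.2) {
  if (!length(candidate_depths) || any(candidate_depths < 1L))
    stop("`candidate_depths` must be a non-empty set of counts >= 1")
  if (inherits(x, "feature_table")) {
    y <- x$y
    x <- x$X
  }
  x <- as.matrix(x)
  split <- holdout_split(y, train_fraction = 1 - val_fraction,
                         seed = config$seed)
  xtr <- x[split$train, , drop = FALSE]; ytr <- y[split$train]
  xva <- x[split$test, , drop = FALSE]; yva <- y[split$test]
  best <- NULL; best_fit <- Inf
  report <- data.frame(depth = integer(0), val_fitness = numeric(0))
  for (d in candidate_depths) {
    cfg <- config
    cfg$hidden_layers <- as.integer(d)
    model <- shodnn_train(cfg, xtr, ytr)
    # one-hot the validation labels against the model's class set (no level
    # dropping: a fold may lack a class)
    yva_f <- factor(as.character(yva), levels = model$levels)
    if (length(model$levels) == 2L) {
      tva <- matrix(as.numeric(yva_f == model$levels[2]), ncol = 1L)
    } else {
      tva <- matrix(0, length(yva_f), length(model$levels))
      tva[cbind(seq_along(yva_f), as.integer(yva_f))] <- 1
    }
    fit <- nn_cost(model$spec, model$theta, xva, tva)
    report <- rbind(report, data.frame(depth = d, val_fitness = fit))
    if (fit < best_fit) { best_fit <- fit; best <- model }
  }
  list(model = best, report = report, depth = best$config$hidden_layers)
}

#' Teacher-student recovery experiment
#'
#' A fixed "teacher" network labels random Gaussian inputs; a "student" of
#' identical architecture is trained on those labels by the SHO hybrid and
#' its held-out label agreement with the teacher is measured. Weights are
#' not identifiable (hidden units permute), so agreement is measured on
#' labels, not parameters. The teacher's weights are drawn Uniform(-1, 1)
#' and re-drawn until its positive rate on a probe sample lies in
#' [0.3, 0.7], so the task is non-degenerate.
#'
#' @param seed integer seed driving the teacher, the data and the training.
#' @param layer_sizes architecture shared by teacher and student.
#' @param n_train,n_test sample sizes.
#' @param config optional [training_config()]; the default uses a logistic
#'   hidden layer and a long gradient-descent polish.
#' @return list with \code{agreement} (held-out), \code{train_agreement}
#'   and the student \code{model}.
#' @export
teacher_student_experiment <- function(seed, layer_sizes = c(3, 5, 1),
                                       n_train = 2000, n_test = 300,
                                       config = NULL) {
  if (is.null(config))
    config <- training_config(pop_size = 30L, max_iter = 100L,
                              hidden_activation = "logistic",
                              eta = 0.5, epochs = 5000L, seed = seed)
  set.seed(seed)
  spec <- network_spec(layer_sizes, hidden_activation = config$hidden_activation)
  d <- layer_sizes[1]
  repeat {
    theta <- stats::runif(param_count(spec), -1, 1)
    probe <- matrix(stats::rnorm(200 * d), 200, d)
    p <- mean(nn_forward(spec, theta, probe)$output[, 1] >= 0.5)
    if (p > 0.3 && p < 0.7) break
  }
  lab <- function(x)
    factor(ifelse(nn_forward(spec, theta, x)$output[, 1] >= 0.5, "P", "N"),
           levels = c("N", "P"))
  xtr <- matrix(stats::rnorm(n_train * d), n_train, d)
  xte <- matrix(stats::rnorm(n_test * d), n_test, d)
  model <- shodnn_train(config, xtr, lab(xtr))
  list(agreement = mean(predict(model, xte) == as.character(lab(xte))),
       train_agreement = model$training_accuracy,
       model = model)
}

#' Save / load a trained model
#'
#' Round-trips through the plain-text network model file, storing the class
#' labels alongside the parameters.
#'
#' @param model a \code{"shodnn_model"}.
#' @param path file path.
#' @return the path, invisibly ([save_shodnn_model()]); a reconstructed
#'   model without training history ([load_shodnn_model()]).
#' @export
save_shodnn_model <- function(model, path) {
  write_nn_model(model$spec, model$theta, path, levels = model$levels)
}

#' @rdname save_shodnn_model
#' @export
load_shodnn_model <- function(path) {
  raw <- read_nn_model(path)
  structure(list(spec = raw$spec, theta = raw$theta, levels = raw$levels,
                 history = NULL, config = NULL),
            class = "shodnn_model")
}
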