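#' Describe a small fully connected network
#'
#' @param layer_sizes integer vector, input layer first, output layer last;
#'   at least two layers, every size >= 1.
#' @param hidden_activation activation of every hidden layer. The default
#'   \code{"radial_basis"} is the Gaussian bump \code{exp(-z^2)} applied to
#'   the usual affine pre-activation; alternatives are \code{"logistic"},
#'   \code{"tanh"} and \code{"relu"}.
#' @param output_activation \code{"sigmoid"} (per-class logistic, the
#'   default, paired with one-hot targets and squared error) or
#'   \code{"softmax"}.
#' @return an object of class \code{"network_spec"}.
#' @export
network_spec <- function(layer_sizes,
                         hidden_activation = c("radial_basis", "logistic",
                                               "tanh", "relu"),
                         output_activation = c("sigmoid", "softmax")) {
  hidden_activation <- match.arg(hidden_activation)
  output_activation <- match.arg(output_activation)
  layer_sizes <- as.integer(layer_sizes)
  if (length(layer_sizes) < 2L) stop("need at least input and output layers")
  if (any(layer_sizes < 1L)) stop("every layer size must be >= 1")
  structure(list(layer_sizes = layer_sizes,
                 hidden_activation = hidden_activation,
                 output_activation = output_activation),
            class = "network_spec")
}

#' Number of trainable parameters of a network
#'
#' Every layer transition contributes an \code{n_out x n_in} weight block and
#' an \code{n_out} bias block, so the total is
#' \code{sum(n_out * (n_in + 1))} over transitions. This flat length is the
#' dimension of the optimizer's search space.
#'
#' @param spec a [network_spec()] (or bare integer vector of layer sizes).
#' @return integer parameter count.
#' @examples
#' param_count(c(13, 10, 1))  # 151
#' @export
param_count <- function(spec) {
  sizes <- if (inherits(spec, "network_spec")) spec$layer_sizes
           else as.integer(spec)
  m <- length(sizes)
  sum(sizes[-1] * (sizes[-m] + 1L))
}

#' Reference network presets
#'
#' Two published hyperparameter readings ship side by side: a single hidden
#' layer of 10 neurons over 13 inputs (\code{"151_params"}; exactly 151
#' weights and biases) and three hidden layers of 10 neurons
#' (\code{"three_hidden"}, input size supplied by the caller). The two are
#' mutually inconsistent in the source hyperparameter table, so neither is
#' asserted as canonical.
#'
#' @param preset which preset to build.
#' @param input_size input dimension for \code{"three_hidden"}.
#' @param output_size output dimension (default 1, binary).
#' @return a [network_spec()].
#' @export
network_presets <- function(preset = c("151_params", "three_hidden"),
                            input_size = 13L, output_size = 1L) {
  preset <- match.arg(preset)
  sizes <- switch(preset,
    "151_params" = c(13L, 10L, 1L),
    "three_hidden" = c(as.integer(input_size), 10L, 10L, 10L,
                       as.integer(output_size)))
  network_spec(sizes)
}

# numerically safe activations; pre-activations clipped at +/- 500 before
# exponentiation
.act <- function(z, kind) {
  z <- pmin(pmax(z, -500), 500)
  switch(kind,
    logistic = ifelse(z >= 0, 1 / (1 + exp(-z)), exp(z) / (1 + exp(z))),
    sigmoid  = ifelse(z >= 0, 1 / (1 + exp(-z)), exp(z) / (1 + exp(z))),
    tanh = tanh(z),
    relu = pmax(z, 0),  # scalar second: keeps matrix dims
    radial_basis = exp(-z^2),
    stop("unknown activation: ", kind))
}

# derivative wrt z given activation value a and pre-activation z
.act_deriv <- function(a, z, kind) {
  switch(kind,
    logistic = a * (1 - a),
    sigmoid  = a * (1 - a),
    tanh = 1 - a^2,
    relu = (z > 0) * 1,
    radial_basis = -2 * z * a,
    stop("unknown activation: ", kind))
}

#' Evaluate an activation function
#'
#' @param kind one of \code{"logistic"}, \code{"tanh"}, \code{"relu"},
#'   \code{"radial_basis"}.
#' @param z numeric pre-activation(s).
#' @return numeric of the same shape.
#' @export
nn_activation <- function(kind, z) .act(z, kind)

#' Unpack a flat parameter vector into weight matrices and bias vectors
#'
#' Layout, per layer transition in order: the weight block flattened row by
#' row (one row per destination unit), then the bias block. [nn_encode()] is
#' the exact inverse.
#'
#' @param spec a [network_spec()].
#' @param theta numeric vector of length \code{param_count(spec)}.
#' @return list with \code{W} (list of n_out x n_in matrices) and \code{b}
#'   (list of bias vectors).
#' @export
nn_decode <- function(spec, theta) {
  sizes <- spec$layer_sizes
  if (length(theta) != param_count(spec))
    stop("parameter vector has length ", length(theta),
         " but the network needs ", param_count(spec))
  W <- list(); b <- list()
  pos <- 0L
  for (m in seq_len(length(sizes) - 1L)) {
    n_in <- sizes[m]; n_out <- sizes[m + 1L]
    W[[m]] <- matrix(theta[pos + seq_len(n_in * n_out)],
                     nrow = n_out, ncol = n_in, byrow = TRUE)
    pos <- pos + n_in * n_out
    b[[m]] <- theta[pos + seq_len(n_out)]
    pos <- pos + n_out
  }
  list(W = W, b = b)
}

#' Pack weight matrices and bias vectors into a flat parameter vector
#'
#' @param spec a [network_spec()].
#' @param wb list with \code{W} and \code{b} as produced by [nn_decode()].
#' @return numeric vector of length \code{param_count(spec)}.
#' @export
nn_encode <- function(spec, wb) {
  out <- numeric(0)
  for (m in seq_along(wb$W))
    out <- c(out, as.numeric(t(wb$W[[m]])), wb$b[[m]])
  if (length(out) != param_count(spec))
    stop("encoded length does not match the network spec")
  out
}

#' Forward pass through the network
#'
#' \code{a^1 = x}; for every later layer
#' \code{a^m = act(W a^(m-1) + b)}; hidden layers use the spec's hidden
#' activation, the final layer its output activation.
#'
#' @param spec a [network_spec()].
#' @param theta flat parameter vector.
#' @param x numeric matrix (n x input size) or vector (one sample).
#' @return list with \code{output} (n x output size), and cached
#'   \code{activations} and \code{preactivations} per layer (for
#'   backpropagation).
#' @export
nn_forward <- function(spec, theta, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  sizes <- spec$layer_sizes
  if (ncol(x) != sizes[1])
    stop("input has ", ncol(x), " columns but the network expects ", sizes[1])
  wb <- nn_decode(spec, theta)
  n_trans <- length(sizes) - 1L
  A <- vector("list", length(sizes))
  Z <- vector("list", length(sizes))
  A[[1]] <- x
  for (m in seq_len(n_trans)) {
    z <- A[[m]] %*% t(wb$W[[m]]) +
      matrix(wb$b[[m]], nrow(x), sizes[m + 1L], byrow = TRUE)
    Z[[m + 1L]] <- z
    if (m < n_trans) {
      A[[m + 1L]] <- .act(z, spec$hidden_activation)
    } else if (spec$output_activation == "softmax") {
      zs <- z - apply(z, 1L, max)
      e <- exp(zs)
      A[[m + 1L]] <- e / rowSums(e)
    } else {
      A[[m + 1L]] <- .act(z, "sigmoid")
    }
  }
  list(output = A[[length(sizes)]], activations = A, preactivations = Z)
}

#' Mean squared-error cost
#'
#' \deqn{C = \frac{1}{k}\sum_{k}\sum_i (t_i - y_i)^2} with \code{k} the
#' number of samples: the per-sample squared errors are summed over output
#' dimensions and averaged over the batch.
#'
#' @param spec a [network_spec()].
#' @param theta flat parameter vector.
#' @param x inputs (n x input size).
#' @param targets matrix (n x output size): one-hot rows for multi-class,
#'   a 0/1 column for binary.
#' @return non-negative scalar; 0 iff the fit is exact.
#' @export
nn_cost <- function(spec, theta, x, targets) {
  y <- nn_forward(spec, theta, x)$output
  targets <- as.matrix(targets)
  if (!all(dim(targets) == dim(y)))
    stop("target dimensions do not match the network output")
  sum((targets - y)^2) / nrow(y)
}

#' Analytic gradient of the cost by backpropagation
#'
#' Returns the flat gradient vector, same layout and length as \code{theta}.
#' The output-layer error is propagated backwards through the cached
#' activations; the relu subgradient at 0 is taken as 0.
#'
#' @inheritParams nn_cost
#' @return numeric vector of length \code{param_count(spec)}.
#' @export
nn_gradient <- function(spec, theta, x, targets) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  targets <- as.matrix(targets)
  fw <- nn_forward(spec, theta, x)
  wb <- nn_decode(spec, theta)
  sizes <- spec$layer_sizes
  n_trans <- length(sizes) - 1L
  n <- nrow(x)
  y <- fw$output
  dY <- -(2 / n) * (targets - y)
  # output layer: chain through the output nonlinearity
  if (spec$output_activation == "softmax") {
    delta <- y * (dY - rowSums(dY * y))
  } else {
    delta <- dY * y * (1 - y)
  }
  gW <- vector("list", n_trans)
  gb <- vector("list", n_trans)
  for (m in rev(seq_len(n_trans))) {
    gW[[m]] <- t(delta) %*% fw$activations[[m]]
    gb[[m]] <- colSums(delta)
    if (m > 1L) {
      back <- delta %*% wb$W[[m]]
      a_prev <- fw$activations[[m]]
      z_prev <- fw$preactivations[[m]]
      delta <- back * .act_deriv(a_prev, z_prev, spec$hidden_activation)
    }
  }
  nn_encode(spec, list(W = gW, b = gb))
}

#' One gradient-descent step
#'
#' \code{theta - eta * gradient}: descends the cost (the update is a
#' subtraction even though some sources typeset it with a plus sign, which
#' would ascend).
#'
#' @param theta flat parameter vector.
#' @param gradient flat gradient of the same length.
#' @param eta positive learning rate.
#' @return updated parameter vector.
#' @export
nn_gd_step <- function(theta, gradient, eta) {
  if (eta <= 0) stop("`eta` must be positive")
  theta - eta * gradient
}

#' Full-batch gradient-descent refinement
#'
#' Repeated [nn_gd_step()]s on a fixed batch; returns the lowest-cost
#' parameters seen, so the refined cost never exceeds the starting cost.
#'
#' @inheritParams nn_cost
#' @param eta learning rate.
#' @param epochs number of full-batch steps.
#' @return list with \code{theta}, \code{cost}, \code{cost_history}.
#' @export
nn_gd_refine <- function(spec, theta, x, targets, eta = 0.1, epochs = 100L) {
  best <- theta
  best_cost <- nn_cost(spec, theta, x, targets)
  hist <- numeric(epochs + 1L)
  hist[1] <- best_cost
  cur <- theta
  for (e in seq_len(epochs)) {
    cur <- nn_gd_step(cur, nn_gradient(spec, cur, x, targets), eta)
    cc <- nn_cost(spec, cur, x, targets)
    hist[e + 1L] <- cc
    if (cc < best_cost) { best <- cur; best_cost <- cc }
  }
  list(theta = best, cost = best_cost, cost_history = hist)
}

#' Write a network and its parameters to a plain-text model file
#'
#' Versioned text format: a header with the layer sizes, activations and an
#' optional class-level line, then one full-precision parameter value per
#' line. [read_nn_model()] restores it exactly.
#'
#' @param spec a [network_spec()].
#' @param theta flat parameter vector.
#' @param path output file path.
#' @param levels optional character vector of class labels to store.
#' @return the path, invisibly.
#' @export
write_nn_model <- function(spec, theta, path, levels = NULL) {
  if (length(theta) != param_count(spec))
    stop("parameter vector does not match the network spec")
  lines <- c(
    "shodnn-model v1",
    paste("layer_sizes:", paste(spec$layer_sizes, collapse = " ")),
    paste("hidden_activation:", spec$hidden_activation),
    paste("output_activation:", spec$output_activation),
    if (!is.null(levels)) paste("levels:", paste(levels, collapse = " ")),
    "params:",
    sprintf("%.17g", theta)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a plain-text model file
#'
#' @param path file written by [write_nn_model()].
#' @return list with \code{spec}, \code{theta} and \code{levels} (possibly
#'   \code{NULL}).
#' @export
read_nn_model <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 6L || lines[1] != "shodnn-model v1")
    stop("not a shodnn model file: ", path)
  field <- function(key) {
    hit <- grep(paste0("^", key, ":"), lines, value = TRUE)
    if (!length(hit)) return(NULL)
    strsplit(sub(paste0("^", key, ": ?"), "", hit[1]), " ")[[1]]
  }
  sizes <- as.integer(field("layer_sizes"))
  spec <- network_spec(sizes,
                       hidden_activation = field("hidden_activation"),
                       output_activation = field("output_activation"))
  levels <- field("levels")
  start <- which(lines == "params:")[1]
  theta <- as.numeric(lines[(start + 1L):length(lines)])
  if (length(theta) != param_count(spec))
    stop("model file holds ", length(theta), " parameters but the spec needs ",
         param_count(spec))
  list(spec = spec, theta = theta, levels = levels)
}
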