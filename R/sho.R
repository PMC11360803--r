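#' Sea Horse Optimization parameters
#'
#' Collects and validates the configuration of the Sea Horse Optimization
#' (SHO) metaheuristic: a swarm optimizer whose population update mimics the
#' movement (spiral exploitation vs. Brownian exploration), predation and
#' breeding behaviour of sea horses.
#'
#' @param dim problem dimension (length of a candidate solution).
#' @param lower,upper box bounds; scalars are recycled to \code{dim}.
#' @param pop_size population size \code{pp}; must be even and at least 4
#'   (breeding pairs the fitness-sorted halves).
#' @param max_iter maximum number of iterations \code{T}.
#' @param u,v logarithmic-spiral constants of the spiral movement
#'   (default 0.05 each).
#' @param levy_lambda Levy-flight exponent \eqn{\lambda} in (0, 2]
#'   (default 1.5).
#' @param levy_scale Levy-flight scale constant \code{s} (default 0.01).
#' @param brownian_l constant step coefficient \code{l} of the Brownian
#'   movement (default 0.05).
#' @param predation_threshold probability cutoff separating successful from
#'   failed predation (default 0.1: predation succeeds when a uniform draw
#'   exceeds it, i.e. with probability 0.9).
#' @param levy_normal if \code{TRUE}, draw the Levy numerator/denominator
#'   variates from standard normals (the classical Mantegna scheme); the
#'   default \code{FALSE} draws them Uniform(0, 1), re-drawing exact zeros in
#'   the denominator.
#' @param theta_range range of the spiral rotation angle \eqn{\theta};
#'   default \code{c(0, 2*pi)}.
#' @param mutation_p,mutation_sd optional offspring mutation: after the
#'   convex recombination of breeding, each offspring coordinate is
#'   perturbed with probability \code{mutation_p} by Gaussian noise of SD
#'   \code{mutation_sd} (then clipped to the box). The default 0 keeps the
#'   pure convex breeding; the hybrid network trainer switches it on, since
#'   its recipe generates offspring by combining \emph{and mutating} the
#'   selected parents.
#'
#' @return an object of class \code{"sho_params"}.
#' @seealso [sho_minimize()]
#' @export
sho_params <- function(dim, lower, upper, pop_size = 30L, max_iter = 100L,
                       u = 0.05, v = 0.05,
                       levy_lambda = 1.5, levy_scale = 0.01,
                       brownian_l = 0.05, predation_threshold = 0.1,
                       levy_normal = FALSE, theta_range = c(0, 2 * pi),
                       mutation_p = 0, mutation_sd = 0.5) {
  dim <- as.integer(dim)
  pop_size <- as.integer(pop_size)
  max_iter <- as.integer(max_iter)
  if (dim < 1L) stop("`dim` must be a positive integer")
  if (pop_size < 4L || pop_size %% 2L != 0L)
    stop("`pop_size` must be an even integer >= 4")
  if (max_iter < 1L) stop("`max_iter` must be >= 1")
  lower <- rep_len(as.numeric(lower), dim)
  upper <- rep_len(as.numeric(upper), dim)
  if (any(!is.finite(lower)) || any(!is.finite(upper)))
    stop("bounds must be finite")
  if (any(lower >= upper)) stop("`lower` must be < `upper` elementwise")
  if (levy_lambda <= 0 || levy_lambda > 2)
    stop("`levy_lambda` must lie in (0, 2]")
  if (length(theta_range) != 2L || theta_range[1] >= theta_range[2])
    stop("`theta_range` must be an increasing pair")
  if (mutation_p < 0 || mutation_p > 1)
    stop("`mutation_p` must lie in [0, 1]")
  if (mutation_sd < 0) stop("`mutation_sd` must be non-negative")
  structure(list(
    dim = dim, lower = lower, upper = upper,
    pop_size = pop_size, max_iter = max_iter,
    u = u, v = v,
    levy_lambda = levy_lambda, levy_scale = levy_scale,
    brownian_l = brownian_l, predation_threshold = predation_threshold,
    levy_normal = isTRUE(levy_normal), theta_range = as.numeric(theta_range),
    mutation_p = mutation_p, mutation_sd = mutation_sd
  ), class = "sho_params")
}

#' Mantegna scale factor of the Levy flight
#'
#' Closed form
#' \deqn{\sigma = \left[\frac{\Gamma(1+\lambda)\,\sin(\pi\lambda/2)}
#'   {\Gamma((1+\lambda)/2)\,\lambda\,2^{(\lambda-1)/2}}\right]^{1/\lambda}.}
#' At \eqn{\lambda = 1} the expression collapses to 1.
#'
#' @param levy_lambda exponent \eqn{\lambda} in (0, 2].
#' @return positive scalar.
#' @export
levy_sigma <- function(levy_lambda) {
  if (levy_lambda <= 0 || levy_lambda > 2)
    stop("`levy_lambda` must lie in (0, 2]")
  lam <- levy_lambda
  num <- gamma(1 + lam) * sin(pi * lam / 2)
  den <- gamma((1 + lam) / 2) * lam * 2^((lam - 1) / 2)
  (num / den)^(1 / lam)
}

# Levy step from pre-drawn variates: s * w * sigma / |k|^(1/lambda)
.levy_from_draws <- function(w, k, params) {
  sigma <- levy_sigma(params$levy_lambda)
  params$levy_scale * w * sigma / abs(k)^(1 / params$levy_lambda)
}

# draw the w (numerator) and k (denominator) variates of the Levy step;
# uniform variant re-draws k == 0 so the step stays finite
.levy_draws <- function(n, params) {
  if (params$levy_normal) {
    w <- stats::rnorm(n)
    k <- stats::rnorm(n)
    while (any(k == 0)) k[k == 0] <- stats::rnorm(sum(k == 0))
  } else {
    w <- stats::runif(n)
    k <- stats::runif(n)
    while (any(k == 0)) k[k == 0] <- stats::runif(sum(k == 0))
  }
  list(w = w, k = k)
}

#' Draw Levy-flight step sizes
#'
#' Heavy-tailed step lengths used by the spiral movement of SHO, computed as
#' \code{s * w * sigma / |k|^(1/lambda)} with \code{sigma} from
#' [levy_sigma()].
#'
#' @param params an [sho_params()] object.
#' @param n number of draws.
#' @return numeric vector of length \code{n}; consumes RNG state.
#' @export
levy_step <- function(params, n = 1L) {
  d <- .levy_draws(n, params)
  .levy_from_draws(d$w, d$k, params)
}

#' Linearly vanishing predation step-size schedule
#'
#' \eqn{\alpha(t) = (1 - t/T)^{2t/T}}: equals 1 at \eqn{t = 0}, 0.5 at
#' \eqn{t = T/2} and 0 at \eqn{t = T}, shrinking the elite-directed predation
#' step as iterations advance.
#'
#' @param t current iteration (0-based schedule argument).
#' @param max_iter total iterations \code{T}.
#' @return scalar in [0, 1].
#' @export
sho_alpha <- function(t, max_iter) {
  (1 - t / max_iter)^(2 * t / max_iter)
}

.clip <- function(x, lower, upper) {
  pp <- nrow(x)
  pmin(pmax(x, matrix(lower, pp, length(lower), byrow = TRUE)),
       matrix(upper, pp, length(upper), byrow = TRUE))
}

.eval_rows <- function(objective, x) {
  f <- vapply(seq_len(nrow(x)), function(i) as.numeric(objective(x[i, ])),
              numeric(1))
  bad <- which(!is.finite(f))
  if (length(bad))
    stop("objective returned a non-finite value for individual ", bad[1])
  f
}

#' Initialize a sea horse population
#'
#' Each coordinate is drawn uniformly inside the box,
#' \code{x_ij = rand * (ub_j - lb_j) + lb_j}; the lowest-fitness individual
#' becomes the elite.
#'
#' @param params an [sho_params()] object.
#' @param objective function mapping a length-\code{dim} numeric vector to a
#'   finite scalar (minimized).
#' @return an object of class \code{"sho_population"} with elements
#'   \code{positions}, \code{fitness}, \code{elite_position},
#'   \code{elite_fitness}, \code{best_position}, \code{best_fitness}.
#' @export
sho_init <- function(params, objective) {
  pp <- params$pop_size
  dm <- params$dim
  rnd <- matrix(stats::runif(pp * dm), pp, dm)
  span <- matrix(params$upper - params$lower, pp, dm, byrow = TRUE)
  positions <- rnd * span + matrix(params$lower, pp, dm, byrow = TRUE)
  fitness <- .eval_rows(objective, positions)
  i <- which.min(fitness)
  structure(list(
    positions = positions, fitness = fitness,
    elite_position = positions[i, ], elite_fitness = fitness[i],
    best_position = positions[i, ], best_fitness = fitness[i],
    iteration = 0L
  ), class = "sho_population")
}

#' Random draws consumed by one movement phase
#'
#' Drawn in a fixed order so a seeded run is reproducible and a scalar-loop
#' oracle can replay the same numbers. The branch selector \code{r1}
#' (standard normal) and the spiral angle \code{theta} are scalar per
#' individual; the Levy variates \code{w}, \code{k}, the Brownian
#' standard-normal factor \code{beta} and the Brownian uniform \code{rand}
#' are drawn per coordinate (pp x dim matrices), giving genuinely diffusive
#' exploration in high dimension.
#'
#' @param pp population size.
#' @param params an [sho_params()] object.
#' @return named list: vectors \code{r1}, \code{theta} of length \code{pp};
#'   matrices \code{w}, \code{k}, \code{beta}, \code{rand} of size
#'   \code{pp x dim}.
#' @export
sho_move_draws <- function(pp, params) {
  dm <- params$dim
  r1 <- stats::rnorm(pp)
  theta <- stats::runif(pp, params$theta_range[1], params$theta_range[2])
  lv <- .levy_draws(pp * dm, params)
  beta <- matrix(stats::rnorm(pp * dm), pp, dm)
  rand <- matrix(stats::runif(pp * dm), pp, dm)
  list(r1 = r1, theta = theta,
       w = matrix(lv$w, pp, dm), k = matrix(lv$k, pp, dm),
       beta = beta, rand = rand)
}

#' Movement phase: spiral exploitation or Brownian exploration
#'
#' Per individual, the sign of a standard-normal draw \code{r1} selects the
#' branch. Spiral (\code{r1 > 0}): the individual rides a logarithmic spiral
#' towards the elite, \code{Xnew1 = Levy * (X_elite - X_i) * x*y*z + X_elite}
#' with spiral components \code{x = rho*cos(theta)}, \code{y = rho*sin(theta)},
#' \code{z = rho*theta}, \code{rho = u*exp(theta*v)}. Brownian
#' (\code{r1 <= 0}): a diffusive step
#' \code{Xnew1 = X_i + rand * l * beta * (X_i - beta * X_elite)}. Results are
#' clipped to the bounds.
#'
#' @param positions pp x dim matrix of current positions.
#' @param elite elite position vector.
#' @param params an [sho_params()] object.
#' @param draws optional pre-drawn variates from [sho_move_draws()]; drawn
#'   internally when \code{NULL}.
#' @return pp x dim matrix of moved positions.
#' @export
sho_move <- function(positions, elite, params, draws = NULL) {
  pp <- nrow(positions)
  if (is.null(draws)) draws <- sho_move_draws(pp, params)
  elite_m <- matrix(elite, pp, ncol(positions), byrow = TRUE)
  rho <- params$u * exp(draws$theta * params$v)
  xyz <- (rho * cos(draws$theta)) * (rho * sin(draws$theta)) *
    (rho * draws$theta)
  levy <- .levy_from_draws(draws$w, draws$k, params)
  spiral <- (elite_m - positions) * (levy * xyz) + elite_m
  brown <- positions +
    (draws$rand * params$brownian_l * draws$beta) *
      (positions - draws$beta * elite_m)
  new1 <- spiral
  explore <- draws$r1 <= 0
  new1[explore, ] <- brown[explore, ]
  .clip(new1, params$lower, params$upper)
}

#' Random draws consumed by one predation phase
#'
#' @param pp population size.
#' @param params an [sho_params()] object.
#' @return list with \code{r2} (success gate, Uniform(0, 1) per individual)
#'   and \code{rand} (update variate, Uniform(0, 1) per coordinate:
#'   a pp x dim matrix).
#' @export
sho_predation_draws <- function(pp, params) {
  list(r2 = stats::runif(pp),
       rand = matrix(stats::runif(pp * params$dim), pp, params$dim))
}

#' Predation phase: elite-directed exploitation gated by success probability
#'
#' With probability 0.9 (\code{r2 >} threshold) predation succeeds and the
#' individual is pulled onto the elite,
#' \code{Xnew2 = alpha*(X_elite - rand*Xnew1) + (1-alpha)*X_elite}; otherwise
#' it explores away, \code{Xnew2 = (1-alpha)*(Xnew1 - rand*X_elite) +
#' alpha*Xnew1}. The step size \code{alpha} follows [sho_alpha()].
#'
#' @param new1 pp x dim matrix produced by [sho_move()].
#' @param elite elite position vector.
#' @param params an [sho_params()] object.
#' @param t current iteration (1-based within the main loop).
#' @param draws optional pre-drawn variates from [sho_predation_draws()].
#' @return pp x dim matrix clipped to the bounds.
#' @export
sho_predation <- function(new1, elite, params, t, draws = NULL) {
  pp <- nrow(new1)
  if (is.null(draws)) draws <- sho_predation_draws(pp, params)
  elite_m <- matrix(elite, pp, ncol(new1), byrow = TRUE)
  alpha <- sho_alpha(t, params$max_iter)
  success <- alpha * (elite_m - draws$rand * new1) + (1 - alpha) * elite_m
  failure <- (1 - alpha) * (new1 - draws$rand * elite_m) + alpha * new1
  new2 <- success
  fail <- draws$r2 <= params$predation_threshold
  new2[fail, ] <- failure[fail, ]
  .clip(new2, params$lower, params$upper)
}

#' Breeding phase: convex recombination of the fitness-sorted halves
#'
#' The population is sorted by ascending fitness; the fitter half are the
#' fathers, the other half the mothers. Father i pairs with mother i and the
#' single offspring is \code{r3 * father + (1 - r3) * mother} with
#' \code{r3 ~ Uniform(0, 1)} per pair.
#'
#' @param positions pp x dim matrix (post-predation).
#' @param fitness fitness of those positions.
#' @param params an [sho_params()] object.
#' @param r3 optional pre-drawn Uniform(0, 1) vector of length \code{pp/2}.
#' @return (pp/2) x dim matrix of offspring.
#' @export
sho_breeding <- function(positions, fitness, params, r3 = NULL) {
  pp <- nrow(positions)
  if (pp %% 2L != 0L) stop("population size must be even for breeding")
  half <- pp %/% 2L
  if (is.null(r3)) r3 <- stats::runif(half)
  ord <- order(fitness)
  sorted <- positions[ord, , drop = FALSE]
  fathers <- sorted[seq_len(half), , drop = FALSE]
  mothers <- sorted[half + seq_len(half), , drop = FALSE]
  r3 * fathers + (1 - r3) * mothers
}

#' Sparse Gaussian mutation of offspring
#'
#' Each offspring coordinate is perturbed with probability
#' \code{params$mutation_p} by zero-mean Gaussian noise of SD
#' \code{params$mutation_sd}, then clipped to the box. With the default
#' \code{mutation_p = 0} this phase is skipped entirely, leaving the pure
#' convex breeding of [sho_breeding()].
#'
#' @param offspring matrix of offspring positions.
#' @param params an [sho_params()] object.
#' @param draws optional list with \code{mask} (uniforms) and \code{noise}
#'   (normals), both matrices matching \code{offspring}.
#' @return mutated offspring matrix within bounds.
#' @export
sho_mutate <- function(offspring, params, draws = NULL) {
  n <- length(offspring)
  if (is.null(draws))
    draws <- list(mask = matrix(stats::runif(n), nrow(offspring)),
                  noise = matrix(stats::rnorm(n), nrow(offspring)))
  hit <- draws$mask < params$mutation_p
  out <- offspring + hit * params$mutation_sd * draws$noise
  .clip(out, params$lower, params$upper)
}

#' Elitist selection of the next generation
#'
#' Pools the predated population with the offspring (1.5 pp candidates) and
#' keeps the \code{pp} lowest-fitness individuals.
#'
#' @param positions,fitness predated population and its fitness.
#' @param offspring,off_fitness offspring block and its fitness.
#' @param params an [sho_params()] object.
#' @return list with \code{positions}, \code{fitness} of size \code{pp}.
#' @export
sho_select <- function(positions, fitness, offspring, off_fitness, params) {
  pool <- rbind(positions, offspring)
  poolf <- c(fitness, off_fitness)
  keep <- order(poolf)[seq_len(params$pop_size)]
  list(positions = pool[keep, , drop = FALSE], fitness = poolf[keep])
}

#' Minimize an objective with Sea Horse Optimization
#'
#' Runs the full SHO loop: random initialization inside the box, then
#' \code{max_iter} iterations of movement, predation, fitness evaluation,
#' breeding and elitist selection. The best-so-far solution is tracked
#' outside the population, so it never worsens even if selection loses the
#' historical best.
#'
#' @param objective function mapping a length-\code{dim} numeric vector to a
#'   finite scalar; minimized.
#' @param params an [sho_params()] object.
#' @param seed optional integer; when given, \code{set.seed(seed)} makes the
#'   whole trajectory reproducible bit for bit.
#' @return an object of class \code{"sho_result"}: \code{best_position},
#'   \code{best_fitness}, \code{history} (best-so-far per iteration, length
#'   \code{max_iter + 1} including initialization) and \code{evaluations}.
#' @examples
#' sphere <- function(x) sum(x^2)
#' p <- sho_params(dim = 5, lower = -10, upper = 10,
#'                 pop_size = 20, max_iter = 50)
#' res <- sho_minimize(sphere, p, seed = 1)
#' res$best_fitness
#' @export
sho_minimize <- function(objective, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pop <- sho_init(params, objective)
  evals <- params$pop_size
  history <- numeric(params$max_iter + 1L)
  history[1] <- pop$best_fitness
  for (t in seq_len(params$max_iter)) {
    new1 <- sho_move(pop$positions, pop$elite_position, params)
    new2 <- sho_predation(new1, pop$elite_position, params, t)
    f2 <- .eval_rows(objective, new2)
    evals <- evals + params$pop_size
    offspring <- sho_breeding(new2, f2, params)
    if (params$mutation_p > 0) offspring <- sho_mutate(offspring, params)
    fo <- .eval_rows(objective, offspring)
    evals <- evals + nrow(offspring)
    sel <- sho_select(new2, f2, offspring, fo, params)
    pop$positions <- sel$positions
    pop$fitness <- sel$fitness
    i <- which.min(sel$fitness)
    pop$elite_position <- sel$positions[i, ]
    pop$elite_fitness <- sel$fitness[i]
    if (sel$fitness[i] < pop$best_fitness) {
      pop$best_fitness <- sel$fitness[i]
      pop$best_position <- sel$positions[i, ]
    }
    pop$iteration <- t
    history[t + 1L] <- pop$best_fitness
  }
  structure(list(
    best_position = pop$best_position,
    best_fitness = pop$best_fitness,
    history = history,
    evaluations = evals,
    params = params
  ), class = "sho_result")
}

#' @export
print.sho_result <- function(x, ...) {
  cat("Sea Horse Optimization result\n")
  cat(sprintf("  dimension   : %d\n", x$params$dim))
  cat(sprintf("  iterations  : %d (evaluations: %d)\n",
              length(x$history) - 1L, x$evaluations))
  cat(sprintf("  best fitness: %.6g\n", x$best_fitness))
  invisible(x)
}

#' Write a per-iteration optimization trace
#'
#' @param result an [sho_minimize()] result.
#' @param path output CSV path with columns iteration, best_fitness.
#' @return the path, invisibly.
#' @export
write_sho_trace <- function(result, path) {
  df <- data.frame(iteration = seq_along(result$history) - 1L,
                   best_fitness = result$history)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
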