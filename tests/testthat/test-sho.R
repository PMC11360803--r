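test_that("parameter validation rejects degenerate configurations", {
  expect_error(sho_params(dim = 2, lower = 0, upper = 1, pop_size = 5),
               "even")
  expect_error(sho_params(dim = 2, lower = 0, upper = 1, pop_size = 2),
               "even")
  expect_error(sho_params(dim = 2, lower = 1, upper = 1), "lower")
  expect_error(sho_params(dim = 2, lower = 0, upper = 1, levy_lambda = 2.5),
               "levy_lambda")
})

test_that("Levy sigma matches its closed form", {
  # lambda = 1 collapses the expression to 1 exactly
  expect_equal(levy_sigma(1), 1, tolerance = 1e-12)
  # independent evaluation through log-gamma
  lam <- 1.5
  ref <- exp((lgamma(1 + lam) + log(sin(pi * lam / 2)) -
              lgamma((1 + lam) / 2) - log(lam) -
              (lam - 1) / 2 * log(2)) / lam)
  expect_equal(levy_sigma(1.5), ref, tolerance = 1e-12)
  for (lam in c(0.5, 1.0, 1.5, 2.0))
    expect_true(is.finite(levy_sigma(lam)) && levy_sigma(lam) > 0)
})

test_that("Levy steps are finite, scale-proportional and heavy-tailed", {
  p <- sho_params(dim = 1, lower = 0, upper = 1)
  p0 <- sho_params(dim = 1, lower = 0, upper = 1, levy_scale = 0)
  set.seed(1)
  expect_true(all(levy_step(p0, 100) == 0))
  set.seed(42)
  draws <- abs(levy_step(p, 1e5))
  expect_true(all(is.finite(draws)))
  expect_gt(stats::quantile(draws, 0.99), 10 * stats::median(draws))
  # fixed seed reproduces the same sequence
  set.seed(9); a <- levy_step(p, 50)
  set.seed(9); b <- levy_step(p, 50)
  expect_identical(a, b)
})

test_that("predation step-size schedule hits its endpoints", {
  T <- 100
  expect_equal(sho_alpha(0, T), 1)
  expect_equal(sho_alpha(T / 2, T), 0.5)
  expect_equal(sho_alpha(T, T), 0)
})

test_that("initialization respects bounds, elite and determinism", {
  p <- sho_params(dim = 1, lower = 0, upper = 1, pop_size = 4, max_iter = 5)
  sphere <- function(x) sum(x^2)
  set.seed(3)
  pop <- sho_init(p, sphere)
  expect_true(all(pop$positions >= 0 & pop$positions <= 1))
  expect_equal(pop$elite_fitness, min(pop$fitness))
  set.seed(11); a <- sho_init(p, sphere)
  set.seed(11); b <- sho_init(p, sphere)
  expect_identical(a, b)
  expect_error(sho_init(p, function(x) NaN), "non-finite")
})

test_that("movement: elite is a fixed point of the spiral branch", {
  p <- sho_params(dim = 3, lower = -5, upper = 5, pop_size = 4)
  elite <- c(1, -2, 0.5)
  positions <- matrix(rep(elite, 4), 4, 3, byrow = TRUE)
  set.seed(2)
  draws <- sho_move_draws(4, p)
  draws$r1 <- rep(1, 4)  # force the spiral branch
  out <- sho_move(positions, elite, p, draws)
  expect_equal(out, matrix(rep(elite, 4), 4, 3, byrow = TRUE))
})

test_that("vectorized movement equals a scalar-loop oracle", {
  set.seed(7)
  p <- sho_params(dim = 3, lower = -2, upper = 2, pop_size = 4)
  positions <- matrix(stats::runif(12, -2, 2), 4, 3)
  elite <- stats::runif(3, -2, 2)
  draws <- sho_move_draws(4, p)
  sig <- levy_sigma(p$levy_lambda)
  ref <- matrix(NA_real_, 4, 3)
  for (i in 1:4) {
    rho <- p$u * exp(draws$theta[i] * p$v)
    xyz <- (rho * cos(draws$theta[i])) * (rho * sin(draws$theta[i])) *
      (rho * draws$theta[i])
    for (j in 1:3) {
      levy <- p$levy_scale * draws$w[i, j] * sig /
        abs(draws$k[i, j])^(1 / p$levy_lambda)
      v <- if (draws$r1[i] > 0) {
        levy * (elite[j] - positions[i, j]) * xyz + elite[j]
      } else {
        positions[i, j] + draws$rand[i, j] * p$brownian_l * draws$beta[i, j] *
          (positions[i, j] - draws$beta[i, j] * elite[j])
      }
      ref[i, j] <- min(max(v, p$lower[j]), p$upper[j])
    }
  }
  expect_equal(sho_move(positions, elite, p, draws), ref)
})

test_that("vectorized predation equals a scalar-loop oracle and its algebra", {
  set.seed(8)
  p <- sho_params(dim = 3, lower = -2, upper = 2, pop_size = 4, max_iter = 10)
  new1 <- matrix(stats::runif(12, -2, 2), 4, 3)
  elite <- stats::runif(3, -2, 2)
  draws <- sho_predation_draws(4, p)
  t <- 4
  alpha <- sho_alpha(t, p$max_iter)
  ref <- matrix(NA_real_, 4, 3)
  for (i in 1:4) for (j in 1:3) {
    v <- if (draws$r2[i] > p$predation_threshold) {
      alpha * (elite[j] - draws$rand[i, j] * new1[i, j]) +
        (1 - alpha) * elite[j]
    } else {
      (1 - alpha) * (new1[i, j] - draws$rand[i, j] * elite[j]) +
        alpha * new1[i, j]
    }
    ref[i, j] <- min(max(v, p$lower[j]), p$upper[j])
  }
  expect_equal(sho_predation(new1, elite, p, t, draws), ref)
  # alpha endpoints: t = 0 success branch collapses to elite - rand*new1,
  # t = T failure branch to new1 - rand*elite (bounds wide enough not to clip)
  pw <- sho_params(dim = 3, lower = -50, upper = 50, pop_size = 4,
                   max_iter = 10)
  d0 <- list(r2 = rep(1, 4), rand = matrix(0.5, 4, 3))
  expect_equal(sho_predation(new1, elite, pw, 0, d0),
               matrix(elite, 4, 3, byrow = TRUE) - 0.5 * new1)
  dT <- list(r2 = rep(0, 4), rand = matrix(0.5, 4, 3))
  expect_equal(sho_predation(new1, elite, pw, 10, dT),
               new1 - 0.5 * matrix(elite, 4, 3, byrow = TRUE))
})

test_that("breeding pairs sorted halves and stays convex", {
  p <- sho_params(dim = 2, lower = -1, upper = 1, pop_size = 4)
  pos <- matrix(c(0.1, 0.1,
                  0.9, -0.9,
                  -0.5, 0.5,
                  0.3, -0.3), 4, 2, byrow = TRUE)
  fit <- c(4, 1, 3, 2)  # sorted order: rows 2, 4, 3, 1
  # r3 = 1 reproduces the father, r3 = 0 the mother
  expect_equal(sho_breeding(pos, fit, p, r3 = c(1, 1)),
               pos[c(2, 4), ])
  expect_equal(sho_breeding(pos, fit, p, r3 = c(0, 0)),
               pos[c(3, 1), ])
  # convexity: every offspring coordinate between its parents' coordinates
  set.seed(5)
  for (rep in 1:20) {
    pp <- 6
    pos <- matrix(stats::runif(pp * 3, -1, 1), pp, 3)
    fit <- stats::runif(pp)
    pr <- sho_params(dim = 3, lower = -1, upper = 1, pop_size = pp)
    off <- sho_breeding(pos, fit, pr)
    ord <- order(fit)
    fa <- pos[ord[1:3], , drop = FALSE]
    mo <- pos[ord[4:6], , drop = FALSE]
    expect_true(all(off >= pmin(fa, mo) - 1e-12 & off <= pmax(fa, mo) + 1e-12))
  }
  expect_error(sho_breeding(pos[1:3, ], fit[1:3], p), "even")
})

test_that("mutation perturbs only masked coordinates and respects bounds", {
  p <- sho_params(dim = 3, lower = -1, upper = 1, pop_size = 4,
                  mutation_p = 0.5, mutation_sd = 10)
  off <- matrix(0, 2, 3)
  draws <- list(mask = matrix(c(0, 1, 0, 1, 0, 1), 2, 3),
                noise = matrix(1, 2, 3))
  out <- sho_mutate(off, p, draws)
  expect_equal(out, matrix(c(1, 0, 1, 0, 1, 0), 2, 3))  # clipped at +1
})

test_that("selection keeps the best pp from the 1.5 pp pool", {
  p <- sho_params(dim = 2, lower = -1, upper = 1, pop_size = 4)
  pos <- matrix(seq_len(8) / 10, 4, 2)
  off <- matrix(seq_len(4) / 10, 2, 2)
  sel <- sho_select(pos, c(5, 1, 4, 2), off, c(0.5, 3), p)
  expect_equal(nrow(sel$positions), 4L)
  expect_equal(sort(sel$fitness), c(0.5, 1, 2, 3))
  expect_equal(min(sel$fitness), 0.5)  # pool minimum survives
})

test_that("full optimization: history, determinism, bounds, constants", {
  p <- sho_params(dim = 4, lower = -3, upper = 3, pop_size = 6, max_iter = 25)
  sphere <- function(x) sum(x^2)
  res <- sho_minimize(sphere, p, seed = 13)
  expect_length(res$history, 26L)
  expect_true(all(diff(res$history) <= 0))
  expect_true(all(res$best_position >= -3 & res$best_position <= 3))
  expect_identical(res, sho_minimize(sphere, p, seed = 13))
  # constant objective: flat history at that constant
  resc <- sho_minimize(function(x) 7, p, seed = 1)
  expect_true(all(resc$history == 7))
  # evaluations: pp + T * 1.5 pp
  expect_equal(res$evaluations, 6L + 25L * 9L)
  # trace writer round-trips the history
  path <- tempfile(fileext = ".csv")
  write_sho_trace(res, path)
  tr <- read.csv(path)
  expect_equal(tr$best_fitness, res$history)
})
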