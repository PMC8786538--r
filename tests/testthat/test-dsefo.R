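box <- function(lo, hi, d) matrix(rep(c(lo, hi), d), 2)
sphere <- function(x) sum(x^2)

test_that("population initialization is uniform within the bounds", {
  p <- efo_params(box(0, 1, 2), pop_size = 10, seed = 1)
  pop <- init_population(p, sphere)
  expect_true(all(pop$positions >= 0 & pop$positions <= 1))
  expect_equal(pop$evaluations, 10)
  # degenerate bound pins that coordinate
  pd <- efo_params(matrix(c(0, 0, -1, 1), 2), pop_size = 8, seed = 2)
  popd <- init_population(pd, sphere)
  expect_true(all(popd$positions[, 1] == 0))
  # uniformity: Kolmogorov-Smirnov on 1e4 draws per coordinate
  pu <- efo_params(box(0, 1, 1), pop_size = 10000, seed = 3)
  popu <- init_population(pu, function(x) 0)
  expect_gt(suppressWarnings(stats::ks.test(popu$positions[, 1], "punif"))$p.value,
            0.01)
})

test_that("frequency map sends best to fr_max, worst to fr_min, affinely invariant", {
  p <- efo_params(box(0, 1, 2), pop_size = 3, seed = 1)
  pop <- init_population(p, sphere)
  pop$fitness <- c(1, 2, 3)
  pop <- update_frequencies(pop, p)
  expect_equal(pop$frequency, c(1, 0.5, 0))
  pop$fitness <- 100 * c(1, 2, 3) - 7        # affine rescale
  pop2 <- update_frequencies(pop, p)
  expect_equal(pop2$frequency, c(1, 0.5, 0))
  pop$fitness <- c(5, 5, 5)
  pop3 <- update_frequencies(pop, p)
  expect_equal(pop3$frequency, c(1, 1, 1))
})

test_that("amplitude smoothing follows the geometric recursion", {
  p0 <- efo_params(box(0, 1, 1), pop_size = 2, beta = 0, seed = 1)
  pop <- init_population(p0, sphere)
  pop$frequency <- c(0.3, 0.7); pop$amplitude <- c(0, 0)
  expect_equal(update_amplitudes(pop, p0)$amplitude, c(0.3, 0.7))
  p1 <- efo_params(box(0, 1, 1), pop_size = 2, beta = 1, seed = 1)
  pop$amplitude <- c(0.4, 0.6)
  expect_equal(update_amplitudes(pop, p1)$amplitude, c(0.4, 0.6))
  # beta = 0.5, constant frequency 1, amp0 = 0: amp after k steps = 1 - 2^-k
  ph <- efo_params(box(0, 1, 1), pop_size = 2, beta = 0.5, seed = 1)
  pop$amplitude <- c(0, 0); pop$frequency <- c(1, 1)
  for (k in 1:6) pop <- update_amplitudes(pop, ph)
  expect_equal(pop$amplitude, rep(1 - 2^-6, 2))
})

test_that("active range, distance and moves obey their closed forms", {
  p <- efo_params(box(0, 1, 4), pop_size = 2, seed = 1)
  expect_equal(active_range(0, p), 0)
  expect_equal(active_range(0.3, p), 0.3)
  p2 <- efo_params(box(0, 2, 4), pop_size = 2, seed = 1)
  expect_equal(active_range(0.3, p2), 0.6)     # doubles with the bounds
  expect_equal(efo_distance(c(1, 2), c(1, 2)), 0)
  expect_equal(efo_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(efo_distance(c(3, 4), c(0, 0)), 5)
  set.seed(4)
  x <- c(0.5, 0.5, 0.5, 0.5)
  expect_identical(active_move(x, 0, p), x)
  for (i in 1:20) {
    y <- active_move(x, 0.2, p)
    expect_true(all(y >= 0 & y <= 1))
    expect_true(all(abs(y - x) <= 0.2 + 1e-12))
  }
})

test_that("passive move contracts towards the amplitude-weighted reference", {
  p <- efo_params(box(0, 1, 2), pop_size = 4, seed = 1)
  # single active individual: reference equals its position, so the move stays
  # on the segment between the current position and that individual
  set.seed(7)
  pos <- c(0.1, 0.9)
  ref <- c(0.8, 0.2)
  for (i in 1:20) {
    y <- passive_move(pos, matrix(ref, 1), 0.7, p)
    expect_true(all(y >= pmin(pos, ref) - 1e-12 & y <= pmax(pos, ref) + 1e-12))
  }
  expect_error(passive_move(pos, matrix(numeric(0), 0, 2), numeric(0), p),
               class = "ocuclean_argument_error")
})

test_that("stochastic reinitialization triggers at the configured rate", {
  p0 <- efo_params(box(0, 1, 3), pop_size = 2, reinit_prob = 0, seed = 1)
  set.seed(8)
  x <- c(0.2, 0.4, 0.6)
  for (i in 1:10) expect_identical(stochastic_reinit(x, p0), x)
  p1 <- efo_params(box(0, 1, 3), pop_size = 2, reinit_prob = 1, seed = 1)
  for (i in 1:10) {
    y <- stochastic_reinit(x, p1)
    expect_equal(sum(y != x), 1)
  }
  pr <- efo_params(box(0, 1, 3), pop_size = 2, reinit_prob = 0.1, seed = 1)
  set.seed(9)
  hits <- mean(vapply(1:10000, function(i) any(stochastic_reinit(x, pr) != x),
                      logical(1)))
  expect_lt(abs(hits - 0.1), 3 * sqrt(0.1 * 0.9 / 10000))
})

test_that("distance-sorted mode rule follows the mean-distance criterion", {
  p <- efo_params(box(0, 10, 2), pop_size = 4, seed = 1)
  pop <- init_population(p, sphere)
  pop$positions <- rbind(c(0, 0), c(0.5, 0), c(6, 6), c(7, 7))
  pop$fitness <- c(0, 1, 72, 98)
  pop$amplitude <- rep(0.5, 4)   # active range 5: individual 2 is in range of 1
  expect_equal(dsefo_select_mode(1, pop, p), "active")
  expect_equal(dsefo_select_mode(3, pop, p), "passive")   # farther than the mean
  # all coincident: mean distance 0, strict inequality makes everyone passive
  pop$positions <- matrix(1, 4, 2)
  pop$fitness <- rep(1, 4)
  expect_equal(dsefo_select_mode(1, pop, p), "passive")
})

test_that("the optimizer is elitist, within budget, and solves a quadratic", {
  p <- efo_params(box(-5, 5, 5), pop_size = 10, iterations = 100, seed = 1)
  r <- efo_optimize(sphere, p, "DS-EFO")
  expect_true(all(diff(r$trace$best_fitness) <= 0))
  expect_lte(r$evaluations, 10 + 10 * 100)
  expect_lt(r$best_fitness, 0.1)
  expect_true(all(r$best_position >= -5 & r$best_position <= 5))
  # same seed reproduces the run exactly
  r2 <- efo_optimize(sphere, p, "DS-EFO")
  expect_identical(r$best_position, r2$best_position)
  # plain EFO shares everything but the mode rule and also converges
  re <- efo_optimize(sphere, p, "EFO")
  expect_true(all(diff(re$trace$best_fitness) <= 0))
  expect_lt(re$best_fitness, 0.1)
  # identical initial populations across variants (shared update law)
  expect_identical(init_population(p, sphere)$positions,
                   init_population(p, sphere)$positions)
  # non-finite objective values are rejected with a warning, search continues
  bad <- function(x) if (x[1] > 0) NaN else sum(x^2)
  pb <- efo_params(box(-5, 5, 2), pop_size = 6, iterations = 30, seed = 2)
  expect_warning(rb <- efo_optimize(bad, pb, "DS-EFO"))
  expect_true(is.finite(rb$best_fitness))
})
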