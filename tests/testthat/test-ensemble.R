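# Ensemble propagation, credible tubes, HDIs and condition comparison.

# build a synthetic posterior_samples container directly so ensemble
# operations can be tested without running MCMC
fake_samples <- function(draws, seed = 1, sigma_fixed = NULL) {
  est_names <- setdiff(names(draws), c("log_posterior", "chain"))
  structure(list(draws = tibble::as_tibble(draws),
                 est_names = est_names,
                 is_log = rep(FALSE, length(est_names)),
                 has_sigma = "sigma" %in% est_names,
                 sigma_fixed = sigma_fixed,
                 diagnostics = list(n_chains = 1L, seed = seed),
                 config = run_config(seed = seed),
                 condition_id = "c1", observable_id = "o1"),
            class = "posterior_samples")
}

rtf_draws <- function(n, seed = 2, sigma = 0.05) {
  set.seed(seed)
  tibble::tibble(Asus = rnorm(n, 1, 0.05), t1 = rexp(n) + 1,
                 Atrans = rnorm(n, 1.5, 0.05), t11 = runif(n, 0.3, 0.7),
                 t2 = runif(n, 1, 2), p0 = rnorm(n, 0.5, 0.02),
                 sigma = rexp(n, 1 / sigma) + 0.01)
}

test_that("a single draw yields exactly its model trajectory", {
  dr <- rtf_draws(1)
  s <- fake_samples(dr)
  grid <- seq(0, 10, length.out = 11)
  ens <- simulate_ensemble(s, get_model("rtf"), grid,
                           fixed = c(Tshift = -2, Trange = 10))
  th <- c(as.list(dr[1, setdiff(names(dr), "sigma")]), Tshift = -2,
          Trange = 10)
  expect_equal(drop(ens$values), rtf_evaluate(grid, th))
})

test_that("subsampling is capped, seed-stable, and identical draws collapse the tube", {
  dr <- rtf_draws(1000)
  s <- fake_samples(dr, seed = 4)
  grid <- seq(0, 10, length.out = 21)
  e1 <- simulate_ensemble(s, get_model("rtf"), grid, max_draws = 100,
                          fixed = c(Tshift = -2, Trange = 10))
  e2 <- simulate_ensemble(s, get_model("rtf"), grid, max_draws = 100,
                          fixed = c(Tshift = -2, Trange = 10))
  expect_equal(nrow(e1$values), 100L)
  expect_identical(e1$values, e2$values)

  dr1 <- rtf_draws(1)
  same <- fake_samples(dr1[rep(1, 50), ])
  e3 <- simulate_ensemble(same, get_model("rtf"), grid,
                          fixed = c(Tshift = -2, Trange = 10))
  tube <- credible_tube(e3)
  expect_equal(tube$lower, tube$upper)
  expect_equal(tube$lower, tube$median)
})

test_that("tube percentiles equal the brute-force sort oracle exactly", {
  set.seed(71)
  for (i in 1:100) {
    P <- sample(25:200, 1)
    G <- sample(3:12, 1)
    vals <- matrix(rnorm(P * G), P, G)
    ens <- structure(list(grid = seq_len(G), values = vals, sigma = NULL),
                     class = "ensemble_trajectories")
    alpha <- runif(1, 0.02, 0.5)
    tube <- credible_tube(ens, alpha)
    for (g in seq_len(G)) {
      expect_identical(tube$lower[g], sort_percentile(vals[, g], alpha / 2))
      expect_identical(tube$median[g], sort_percentile(vals[, g], 0.5))
      expect_identical(tube$upper[g], sort_percentile(vals[, g], 1 - alpha / 2))
    }
  }
})

test_that("constant trajectories 1..100 give the textbook percentile bounds", {
  vals <- matrix(rep(1:100, 5), nrow = 100)
  ens <- structure(list(grid = 1:5, values = vals, sigma = NULL),
                   class = "ensemble_trajectories")
  tube <- credible_tube(ens, 0.05)
  # type-7 interpolated order statistics of 1..100
  expect_equal(tube$lower, rep(1 + 99 * 0.025, 5))
  expect_equal(tube$upper, rep(1 + 99 * 0.975, 5))
  expect_equal(tube$median, rep(50.5, 5))
})

test_that("narrower levels give nested tubes", {
  set.seed(72)
  vals <- matrix(rnorm(500 * 8), 500, 8)
  ens <- structure(list(grid = 1:8, values = vals, sigma = NULL),
                   class = "ensemble_trajectories")
  t95 <- credible_tube(ens, 0.05)
  t50 <- credible_tube(ens, 0.5)
  expect_true(all(t50$upper - t50$lower <= t95$upper - t95$lower))
  expect_true(all(t50$lower >= t95$lower & t50$upper <= t95$upper))
})

test_that("tube validates alpha and warns on tiny ensembles", {
  vals <- matrix(rnorm(10 * 3), 10, 3)
  ens <- structure(list(grid = 1:3, values = vals, sigma = NULL),
                   class = "ensemble_trajectories")
  expect_warning(credible_tube(ens, 0.05), "fewer than 20")
  expect_error(credible_tube(ens, 1.5), "alpha")
})

test_that("posterior predictive adds noise: zero sigma is the ensemble itself", {
  dr <- rtf_draws(200)
  dr$sigma <- rep(1e-300, 200)  # effectively noiseless
  s <- fake_samples(dr)
  grid <- seq(0, 10, length.out = 11)
  ens <- simulate_ensemble(s, get_model("rtf"), grid,
                           fixed = c(Tshift = -2, Trange = 10))
  ppd <- posterior_predictive(ens, seed = 3)
  expect_equal(ppd$values, ens$values, tolerance = 1e-12)
})

test_that("PPD pointwise variance dominates the ensemble variance", {
  dr <- rtf_draws(2000, sigma = 0.2)
  s <- fake_samples(dr, seed = 6)
  grid <- seq(0, 10, length.out = 15)
  ens <- simulate_ensemble(s, get_model("rtf"), grid, max_draws = 2000,
                           fixed = c(Tshift = -2, Trange = 10))
  ppd <- posterior_predictive(ens, seed = 7)
  v_ens <- apply(ens$values, 2, var)
  v_ppd <- apply(ppd$values, 2, var)
  expect_true(all(v_ppd >= v_ens))
})

test_that("PPD noise has the configured spread", {
  # single fixed parameter draw, sigma = 1: predictive SD should be 1
  dr <- rtf_draws(1)
  big <- dr[rep(1, 2e5), ]
  big$sigma <- 1
  s <- fake_samples(big)
  ens <- simulate_ensemble(s, get_model("rtf"), grid = c(0, 5),
                           max_draws = 2e5,
                           fixed = c(Tshift = -2, Trange = 10))
  ppd <- posterior_predictive(ens, seed = 8)
  expect_equal(sd(ppd$values[, 1]), 1, tolerance = 0.01)
})

test_that("missing sigma makes the PPD fail loudly", {
  dr <- rtf_draws(50)
  dr$sigma <- NULL
  s <- fake_samples(dr)
  ens <- simulate_ensemble(s, get_model("rtf"), grid = c(0, 5),
                           fixed = c(Tshift = -2, Trange = 10))
  expect_error(posterior_predictive(ens, seed = 1), "sigma")
})

test_that("HDI matches analytic intervals for known shapes", {
  set.seed(73)
  z <- rnorm(1e5)
  h <- hdi(z, 0.95)
  expect_lt(abs(h[["lower"]] + 1.96), 0.05)
  expect_lt(abs(h[["upper"]] - 1.96), 0.05)
  u <- runif(1e5)
  hu <- hdi(u, 0.95)
  expect_lt(abs((hu[["upper"]] - hu[["lower"]]) - 0.95), 0.01)
  pm <- rep(2.5, 300)
  hp <- hdi(pm, 0.95)
  expect_identical(unname(hp[1]), unname(hp[2]))
  expect_error(hdi(z, 1.2), "level")
})

test_that("condition comparison flags separation and identity", {
  grid <- seq(0, 10, length.out = 21)
  mk_tube <- function(lo, hi, id) {
    structure(tibble::tibble(time = grid, median = (lo + hi) / 2,
                             lower = lo, upper = hi),
              class = c("credible_tube", class(tibble::tibble())),
              level = 0.95, condition_id = id)
  }
  a <- mk_tube(0, 1, "a")
  b <- mk_tube(2, 3, "b")
  cmp <- compare_conditions(list(a = a, b = b))
  expect_equal(cmp$pairs$fraction_disjoint, 1)
  cmp_same <- compare_conditions(list(a = a, a2 = a))
  expect_equal(cmp_same$pairs$fraction_disjoint, 0)
  expect_error(compare_conditions(list(a = a)), "at least two")
})

test_that("condition comparison is symmetric under role swap", {
  set.seed(74)
  grid <- seq(0, 5, length.out = 11)
  mk <- function(center, id) {
    lo <- center - runif(11, 0.1, 0.5)
    hi <- center + runif(11, 0.1, 0.5)
    structure(tibble::tibble(time = grid, median = center, lower = lo,
                             upper = hi),
              class = c("credible_tube", class(tibble::tibble())),
              level = 0.95, condition_id = id)
  }
  a <- mk(0, "a")
  b <- mk(0.7, "b")
  c_ab <- compare_conditions(list(a = a, b = b))
  c_ba <- compare_conditions(list(b = b, a = a))
  expect_equal(c_ab$pairs$fraction_disjoint, c_ba$pairs$fraction_disjoint)
  expect_equal(c_ab$pointwise$disjoint, c_ba$pointwise$disjoint)
})

test_that("marginal HDI comparison mirrors the credibly-lower readout", {
  set.seed(75)
  n <- 2000
  marg <- list(
    low = tibble::tibble(p0 = rnorm(n, 0, 0.1)),
    mid = tibble::tibble(p0 = rnorm(n, 5, 0.1)),
    high = tibble::tibble(p0 = rnorm(n, 6, 0.1)))
  grid <- seq(0, 5, length.out = 11)
  tubes <- lapply(c(low = 0, mid = 5, high = 6), function(ctr) {
    structure(tibble::tibble(time = grid, median = ctr, lower = ctr - 0.3,
                             upper = ctr + 0.3),
              class = c("credible_tube", class(tibble::tibble())),
              level = 0.95, condition_id = "x")
  })
  cmp <- compare_conditions(tubes, marginals = marg)
  par_tab <- cmp$parameters
  low_rows <- par_tab[par_tab$condition_a == "low", ]
  expect_true(all(low_rows$disjoint))
  expect_true(all(low_rows$direction == "a_below_b"))
  mid_high <- par_tab[par_tab$condition_a == "mid" &
                        par_tab$condition_b == "high", ]
  expect_true(all(mid_high$disjoint))
})

test_that("tubes on different grids are re-interpolated to the intersection", {
  mk <- function(grid, id) {
    structure(tibble::tibble(time = grid, median = grid, lower = grid - 1,
                             upper = grid + 1),
              class = c("credible_tube", class(tibble::tibble())),
              level = 0.95, condition_id = id)
  }
  a <- mk(seq(0, 10, by = 1), "a")
  b <- mk(seq(2, 12, by = 0.5), "b")
  cmp <- compare_conditions(list(a = a, b = b))
  expect_gte(min(cmp$pointwise$time), 2)
  expect_lte(max(cmp$pointwise$time), 10)
  expect_equal(cmp$pairs$fraction_disjoint, 0)
})
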