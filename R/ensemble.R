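# Propagation of posterior samples into the data space: trajectory
# ensembles, posterior predictive draws, percentile credible tubes,
# highest-density intervals, and condition comparison.

#' Evaluate the model over a posterior ensemble
#'
#' Computes the trajectory \eqn{s^{(i)}(t) = s(t, \theta^{(i)})} for every
#' retained posterior draw on a dense evaluation grid, *without* adding
#' measurement noise. If the sample holds more than `max_draws` draws, a
#' seed-controlled uniform subsample (without replacement) is used.
#'
#' @param samples A `posterior_samples` object.
#' @param model A [model_spec()]; defaults to the model the samples were
#'   drawn with.
#' @param grid Strictly ascending numeric time grid; defaults to
#'   `config$grid_n` points over the observation interval.
#' @param max_draws Cap on the number of trajectories (default from the
#'   run config).
#' @param fixed Named fixed parameter values (as used in the fit).
#' @return An object of class `"ensemble_trajectories"`: list with `grid`
#'   and `values` (matrix, one row per draw), plus the per-draw `sigma`
#'   vector when available.
#' @export
simulate_ensemble <- function(samples, model = NULL, grid = NULL,
                              max_draws = NULL, fixed = NULL) {
  stopifnot(inherits(samples, "posterior_samples"))
  if (is.null(model)) model <- get_model(samples$config$model_id)
  if (is.null(max_draws)) max_draws <- samples$config$max_draws %||% 1000L
  if (nrow(samples$draws) == 0L) stop("empty posterior sample", call. = FALSE)
  if (is.null(grid)) {
    stop("an evaluation grid is required (supply `grid`)", call. = FALSE)
  }
  if (is.unsorted(grid, strictly = TRUE)) {
    stop("grid must be strictly ascending", call. = FALSE)
  }
  P <- nrow(samples$draws)
  if (P > max_draws) {
    set.seed(derive_seed(samples$config$seed, 7919L))
    take <- sort(sample.int(P, max_draws))
  } else {
    take <- seq_len(P)
  }
  full <- model$fixed_parameters
  if (!is.null(fixed)) full[names(fixed)] <- as.list(fixed)
  par_names <- setdiff(samples$est_names, "sigma")
  draw_mat <- as.matrix(samples$draws[take, par_names, drop = FALSE])
  values <- matrix(NA_real_, length(take), length(grid))
  p <- full
  for (i in seq_along(take)) {
    p[par_names] <- draw_mat[i, ]
    values[i, ] <- model$evaluator(grid, p)
  }
  if (any(!is.finite(values))) {
    stop("non-finite trajectory values in ensemble", call. = FALSE)
  }
  sigma <- if (samples$has_sigma) {
    samples$draws$sigma[take]
  } else if (!is.null(samples$sigma_fixed)) {
    rep(samples$sigma_fixed, length(take))
  } else {
    NULL
  }
  structure(list(grid = grid, values = values, sigma = sigma,
                 condition_id = samples$condition_id),
            class = "ensemble_trajectories")
}

#' Posterior predictive draws
#'
#' Draws from the posterior predictive distribution by adding i.i.d.
#' Gaussian measurement noise \eqn{\varepsilon \sim N(0, \sigma_i^2)} to
#' each ensemble trajectory, using each draw's own noise SD. The ensemble
#' itself (no noise) is a lower bound for the PPD's variability.
#'
#' @param ensemble An `ensemble_trajectories` object carrying per-draw
#'   `sigma` values (estimated or fixed), or a `posterior_samples` object
#'   (then `model`, `grid`, `max_draws` are forwarded to
#'   [simulate_ensemble()]).
#' @param seed Integer seed for the noise draws.
#' @param model,grid,max_draws Passed to [simulate_ensemble()] when
#'   `ensemble` is a `posterior_samples` object.
#' @return An `ensemble_trajectories` object whose `values` include
#'   measurement noise.
#' @export
posterior_predictive <- function(ensemble, seed, model = NULL, grid = NULL,
                                 max_draws = NULL) {
  if (inherits(ensemble, "posterior_samples")) {
    ensemble <- simulate_ensemble(ensemble, model = model, grid = grid,
                                  max_draws = max_draws)
  }
  stopifnot(inherits(ensemble, "ensemble_trajectories"))
  if (is.null(ensemble$sigma)) {
    stop("posterior predictive requires per-draw sigma values", call. = FALSE)
  }
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(derive_seed(seed, 104729L))
  v <- ensemble$values
  noise <- matrix(rnorm(length(v)), nrow(v), ncol(v)) * ensemble$sigma
  out <- ensemble
  out$values <- v + noise
  out$ppd <- TRUE
  out
}

#' Percentile credible tube
#'
#' Summarizes an ensemble of trajectories into a time-continuous
#' \eqn{(1-\alpha) \cdot 100\%} credible band: at each grid point the
#' empirical \eqn{\alpha/2}, 0.5 and \eqn{1-\alpha/2} percentiles of the
#' trajectory values are taken (linear interpolation between order
#' statistics, the "type 7" convention); between grid points the bounds are
#' linearly interpolated.
#'
#' @param ensemble An `ensemble_trajectories` object.
#' @param alpha Tail probability in (0, 1); default 0.05 for a 95% tube.
#' @return A tibble of class `"credible_tube"` with columns `time`,
#'   `median`, `lower`, `upper` and attributes `level`, `condition_id`.
#' @export
credible_tube <- function(ensemble, alpha = 0.05) {
  stopifnot(inherits(ensemble, "ensemble_trajectories"))
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)", call. = FALSE)
  P <- nrow(ensemble$values)
  if (P < 20 && alpha <= 0.05) {
    warn("fewer than 20 trajectories: 95% tube percentiles are unreliable")
  }
  qs <- apply(ensemble$values, 2L, quantile,
              probs = c(alpha / 2, 0.5, 1 - alpha / 2), type = 7,
              names = FALSE)
  structure(tibble(time = ensemble$grid,
                   median = qs[2, ], lower = qs[1, ], upper = qs[3, ]),
            class = c("credible_tube", class(tibble())),
            level = 1 - alpha,
            condition_id = ensemble$condition_id)
}

#' Interpolate a credible tube onto a new grid
#'
#' Tube values between computed grid points are defined by linear
#' interpolation of the pointwise bounds.
#'
#' @param tube A `credible_tube`.
#' @param grid New time grid within the tube's range.
#' @return A `credible_tube` on `grid`.
#' @export
interpolate_tube <- function(tube, grid) {
  stopifnot(inherits(tube, "credible_tube"))
  out <- tibble(
    time = grid,
    median = approx(tube$time, tube$median, xout = grid)$y,
    lower = approx(tube$time, tube$lower, xout = grid)$y,
    upper = approx(tube$time, tube$upper, xout = grid)$y)
  structure(out, class = class(tube), level = attr(tube, "level"),
            condition_id = attr(tube, "condition_id"))
}

#' Highest density interval
#'
#' Shortest contiguous interval containing `level` posterior mass:
#' the sliding window of \eqn{\lceil level \cdot P \rceil} consecutive
#' sorted draws with minimal width (ties broken towards the smallest lower
#' bound).
#'
#' @param draws Numeric vector of >= 100 posterior draws.
#' @param level Probability mass in (0, 1); default 0.95.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
hdi <- function(draws, level = 0.95) {
  if (!(level > 0 && level < 1)) stop("level must be in (0, 1)", call. = FALSE)
  n <- length(draws)
  if (n < 100L) stop("need at least 100 draws for an HDI", call. = FALSE)
  x <- sort(draws)
  m <- ceiling(level * n)
  widths <- x[seq.int(m, n)] - x[seq_len(n - m + 1L)]
  i <- which.min(widths) # which.min takes the first minimum: smallest lower bound
  c(lower = x[i], upper = x[i + m - 1L])
}

#' Compare conditions via tube disjointness and marginal HDIs
#'
#' Two conditions are "credibly different" at a time point when their
#' credible tubes are disjoint there (the upper bound of one lies below the
#' lower bound of the other). For every pair of tubes this reports the
#' pointwise disjointness flags and the fraction of the common grid on
#' which the tubes are disjoint. When marginal posterior draws are
#' supplied, per-parameter 95% HDIs are compared the same way.
#'
#' @param tubes Named list of >= 2 `credible_tube` objects. Tubes on
#'   different grids are linearly re-interpolated onto the intersection of
#'   their time ranges.
#' @param marginals Optional named list (same names) of posterior draw
#'   tibbles/data frames, one column per parameter.
#' @param hdi_level HDI mass for the marginal comparison (default 0.95).
#' @return A list of class `"condition_comparison"` with tibbles
#'   `pointwise` (time, condition_a, condition_b, disjoint),
#'   `pairs` (condition_a, condition_b, fraction_disjoint) and optionally
#'   `parameters` (parameter, condition_a, condition_b, HDI bounds,
#'   disjoint, direction).
#' @export
compare_conditions <- function(tubes, marginals = NULL, hdi_level = 0.95) {
  if (length(tubes) < 2L) {
    stop("need at least two conditions to compare", call. = FALSE)
  }
  if (is.null(names(tubes)) || any(names(tubes) == "")) {
    names(tubes) <- vapply(seq_along(tubes), function(i) {
      attr(tubes[[i]], "condition_id") %||% paste0("condition", i)
    }, character(1))
  }
  lo <- max(vapply(tubes, function(tb) min(tb$time), numeric(1)))
  hi <- min(vapply(tubes, function(tb) max(tb$time), numeric(1)))
  if (!(hi > lo)) stop("tubes have no overlapping time range", call. = FALSE)
  same_grid <- length(unique(lapply(tubes, function(tb) tb$time))) == 1L
  grid <- if (same_grid) tubes[[1]]$time else seq(lo, hi, length.out = 201L)
  tubes_i <- lapply(tubes, interpolate_tube, grid = grid)

  pair_idx <- utils::combn(names(tubes), 2L, simplify = FALSE)
  pointwise <- bind_rows(lapply(pair_idx, function(pr) {
    a <- tubes_i[[pr[1]]]
    b <- tubes_i[[pr[2]]]
    tibble(time = grid, condition_a = pr[1], condition_b = pr[2],
           disjoint = a$upper < b$lower | b$upper < a$lower)
  }))
  pairs <- pointwise |>
    group_by(.data$condition_a, .data$condition_b) |>
    summarise(fraction_disjoint = mean(.data$disjoint), .groups = "drop")

  parameters <- NULL
  if (!is.null(marginals)) {
    stopifnot(all(names(tubes) %in% names(marginals)))
    par_names <- Reduce(intersect, lapply(marginals, names))
    par_names <- setdiff(par_names, c("log_posterior", "chain"))
    parameters <- bind_rows(lapply(pair_idx, function(pr) {
      bind_rows(lapply(par_names, function(pn) {
        ha <- hdi(marginals[[pr[1]]][[pn]], hdi_level)
        hb <- hdi(marginals[[pr[2]]][[pn]], hdi_level)
        disjoint <- ha["upper"] < hb["lower"] || hb["upper"] < ha["lower"]
        tibble(parameter = pn, condition_a = pr[1], condition_b = pr[2],
               lower_a = ha[["lower"]], upper_a = ha[["upper"]],
               lower_b = hb[["lower"]], upper_b = hb[["upper"]],
               disjoint = disjoint,
               direction = if (!disjoint) "overlap"
               else if (ha["upper"] < hb["lower"]) "a_below_b"
               else "b_below_a")
      }))
    }))
  }
  structure(list(pointwise = pointwise, pairs = pairs,
                 parameters = parameters, level = attr(tubes[[1]], "level"),
                 hdi_level = if (is.null(marginals)) NULL else hdi_level),
            class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat("<condition_comparison>\n")
  print(x$pairs)
  if (!is.null(x$parameters)) {
    cat("credibly different parameters (disjoint HDIs):\n")
    print(x$parameters[x$parameters$disjoint, c("parameter", "condition_a",
                                                "condition_b", "direction")])
  }
  invisible(x)
}
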