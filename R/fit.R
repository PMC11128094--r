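# High-level, pipe-friendly front door: fit every (condition, observable)
# dataset of a measurement table, build credible tubes, and expose the
# result through broom-style methods.

#' Fit retarded transient functions to a measurement table
#'
#' Runs the full workflow for each (condition, observable) dataset in a
#' PEtab-dialect measurement table: optional negative-value filtering,
#' data-informed default priors (unless supplied), adaptive
#' Metropolis-Hastings posterior sampling, and ensemble credible tubes.
#' Conditions are fitted independently, one posterior per condition.
#'
#' @param measurements A measurement table: path to a TSV, a tibble with
#'   columns `observableId`, `simulationConditionId`, `time`,
#'   `measurement` (optional `replicateId`), a [ts_dataset()], or a list
#'   of them.
#' @param config A [run_config()]; `seed` may be given instead for
#'   defaults.
#' @param seed Convenience: builds `run_config(seed = seed, ...)` when
#'   `config` is missing.
#' @param priors Optional [prior_spec()] used for every dataset (default:
#'   [default_priors()] per dataset).
#' @param fixed Named fixed parameter values. For the RTF, `Tshift` is
#'   fixed at -2 and `Trange` at the dataset's observation range unless
#'   overridden here or estimated via `priors`.
#' @param ... Further arguments to [run_config()] when `config` is
#'   missing.
#' @return An object of class `"rtf_fit"`: named list of per-condition
#'   results (`samples`, `tube`, `ensemble`, `dataset`, `removed`), plus
#'   the shared `config`. Methods: [tidy()], [glance()], [autoplot()].
#' @examples
#' \donttest{
#' study <- generate_study("steatosis-like", seed = 1)
#' fit <- rtf_fit(study$measurements, seed = 1, chain_length = 2000)
#' tidy(fit)
#' }
#' @export
rtf_fit <- function(measurements, config = NULL, seed = NULL, priors = NULL,
                    fixed = NULL, ...) {
  if (is.null(config)) {
    if (is.null(seed)) stop("supply a run_config() or a seed", call. = FALSE)
    config <- run_config(seed = seed, ...)
  }
  datasets <- as_datasets(measurements)
  model <- get_model(config$model_id)

  results <- lapply(datasets, function(d) {
    removed <- 0L
    if (config$drop_negative) {
      fl <- filter_nonnegative(d)
      d <- fl$dataset
      removed <- fl$removed
    }
    fx <- fixed
    if (config$model_id == "rtf") {
      if (is.null(fx)) fx <- c()
      if (!"Trange" %in% c(names(fx), priors$parameter)) {
        fx <- c(fx, Trange = time_range(d))
      }
      if (!"Tshift" %in% c(names(fx), priors$parameter)) {
        fx <- c(fx, Tshift = -2)
      }
    }
    pr <- priors
    if (is.null(pr)) {
      pr <- default_priors(d, model, estimate_sigma = config$estimate_sigma)
      pr <- prior_spec(as_tibble(pr)[!(pr$parameter %in% names(fx)), ])
    }
    samples <- sample_posterior(d, pr, model, config, fixed = fx)
    grid <- seq(min(d$time), max(d$time), length.out = config$grid_n)
    ens <- simulate_ensemble(samples, model, grid,
                             max_draws = config$max_draws, fixed = fx)
    tube <- credible_tube(ens, alpha = config$alpha)
    list(samples = samples, tube = tube, ensemble = ens, dataset = d,
         removed = removed, fixed = fx)
  })
  structure(list(results = results, config = config),
            class = "rtf_fit")
}

# normalize the accepted measurement inputs into a named list of datasets
as_datasets <- function(measurements) {
  if (inherits(measurements, "ts_dataset")) {
    d <- measurements
    return(setNames(list(d), paste0(attr(d, "condition_id"), "/",
                                    attr(d, "observable_id"))))
  }
  if (is.character(measurements) && length(measurements) == 1L) {
    return(read_measurement_table(measurements))
  }
  if (is.data.frame(measurements)) {
    path <- tempfile(fileext = ".tsv")
    on.exit(unlink(path))
    readr::write_tsv(measurements, path, progress = FALSE)
    return(read_measurement_table(path))
  }
  if (is.list(measurements) &&
      all(vapply(measurements, inherits, logical(1), "ts_dataset"))) {
    nm <- vapply(measurements, function(d) {
      paste0(attr(d, "condition_id"), "/", attr(d, "observable_id"))
    }, character(1))
    return(setNames(measurements, nm))
  }
  stop("cannot interpret `measurements`: supply a path, tibble, ",
       "ts_dataset or list of ts_datasets", call. = FALSE)
}

#' @export
print.rtf_fit <- function(x, ...) {
  cat(sprintf("<rtf_fit> %d condition(s), model '%s'\n",
              length(x$results), x$config$model_id))
  for (nm in names(x$results)) {
    s <- x$results[[nm]]$samples
    cat(sprintf("  %s: %d draws, acceptance %.2f\n", nm, nrow(s$draws),
                s$diagnostics$acceptance_rate))
  }
  invisible(x)
}

#' Tidy posterior summaries of a fit
#'
#' One row per condition and estimated parameter with posterior median,
#' mean, SD, 95% HDI bounds, ESS and split-R-hat.
#'
#' @param x An `rtf_fit` or `posterior_samples` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.rtf_fit <- function(x, ...) {
  bind_rows(lapply(names(x$results), function(nm) {
    out <- tidy(x$results[[nm]]$samples)
    out$condition <- attr(x$results[[nm]]$dataset, "condition_id")
    out$observable <- attr(x$results[[nm]]$dataset, "observable_id")
    select(out, "condition", "observable", dplyr::everything())
  }))
}

#' @rdname tidy.rtf_fit
#' @export
tidy.posterior_samples <- function(x, ...) {
  bind_rows(lapply(x$est_names, function(nm) {
    dr <- x$draws[[nm]]
    hd <- hdi(dr, 0.95)
    dg <- x$diagnostics$parameters[[nm]]
    tibble(parameter = nm, median = median(dr), mean = mean(dr),
           sd = sd(dr), hdi_lower = hd[["lower"]], hdi_upper = hd[["upper"]],
           ess = dg$ess, rhat = dg$rhat)
  }))
}

#' One-row fit summaries
#'
#' @param x An `rtf_fit` or `posterior_samples` object.
#' @param ... Unused.
#' @return A tibble with one row per condition: draw counts, acceptance
#'   rate, minimum ESS, maximum R-hat, records removed by filtering.
#' @export
glance.rtf_fit <- function(x, ...) {
  bind_rows(lapply(names(x$results), function(nm) {
    g <- glance(x$results[[nm]]$samples)
    g$condition <- attr(x$results[[nm]]$dataset, "condition_id")
    g$removed <- x$results[[nm]]$removed
    select(g, "condition", dplyr::everything())
  }))
}

#' @rdname glance.rtf_fit
#' @export
glance.posterior_samples <- function(x, ...) {
  ess <- vapply(x$diagnostics$parameters, `[[`, numeric(1), "ess")
  rhat <- vapply(x$diagnostics$parameters, `[[`, numeric(1), "rhat")
  tibble(n_draws = nrow(x$draws),
         n_parameters = length(x$est_names),
         n_chains = x$diagnostics$n_chains,
         acceptance_rate = x$diagnostics$acceptance_rate,
         min_ess = min(ess),
         max_rhat = if (all(is.na(rhat))) NA_real_ else max(rhat, na.rm = TRUE),
         seed = x$diagnostics$seed)
}

#' Credible tubes of a fit as one tidy table
#'
#' @param fit An `rtf_fit`.
#' @return Tibble with columns `condition`, `time`, `median`, `lower`,
#'   `upper`.
#' @export
fit_tubes <- function(fit) {
  stopifnot(inherits(fit, "rtf_fit"))
  bind_rows(lapply(names(fit$results), function(nm) {
    tb <- fit$results[[nm]]$tube
    tibble(condition = attr(fit$results[[nm]]$dataset, "condition_id"),
           time = tb$time, median = tb$median, lower = tb$lower,
           upper = tb$upper)
  }))
}

#' Compare the fitted conditions of one fit
#'
#' Convenience wrapper around [compare_conditions()] using each
#' condition's tube and marginal posterior draws.
#'
#' @param fit An `rtf_fit` with >= 2 conditions.
#' @param hdi_level HDI mass for marginal comparison.
#' @return A `condition_comparison` object.
#' @export
compare_fit <- function(fit, hdi_level = 0.95) {
  stopifnot(inherits(fit, "rtf_fit"))
  tubes <- lapply(fit$results, `[[`, "tube")
  names(tubes) <- vapply(fit$results, function(r) {
    attr(r$dataset, "condition_id")
  }, character(1))
  marginals <- lapply(fit$results, function(r) r$samples$draws)
  names(marginals) <- names(tubes)
  compare_conditions(tubes, marginals, hdi_level = hdi_level)
}
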