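# Adaptive Metropolis-Hastings sampling of the posterior, with an optional
# parallel-tempering ladder for multimodal targets.
#
# The proposal is a multivariate Gaussian whose covariance is adapted from
# the chain history (Haario-style: 2.38^2/d * empirical covariance +
# 1e-10 * I, refreshed every 50 iterations after an initial window of 500),
# with an additional Robbins-Monro global scale factor tuned towards the
# canonical acceptance rate 0.234.

ADAPT_START <- 500L
ADAPT_EVERY <- 50L
TARGET_ACCEPT <- 0.234
COV_REG <- 1e-10

# derive a 32-bit sub-seed deterministically from (seed, stream)
derive_seed <- function(seed, stream) {
  (as.double(seed) * 48271 + 2654435761 * as.double(stream)) %% 2147483647
}

# one adaptive Metropolis chain over a box-bounded target.
# log_target(x) must return -Inf outside the box (bounds are also checked
# here to skip evaluations). Returns draws, log-target values, acceptance.
run_adaptive_chain <- function(log_target, init, lower, upper, n_iter,
                               beta = 1) {
  d <- length(init)
  x <- init
  lt <- log_target(x)
  if (!is.finite(lt)) stop("initial point has non-finite log target",
                           call. = FALSE)
  draws <- matrix(NA_real_, n_iter, d)
  lts <- numeric(n_iter)
  # initial proposal: independent components at 5% of the box width
  L <- diag(0.05 * (upper - lower), d, d)
  log_s <- 0
  sx <- numeric(d)
  sxx <- matrix(0, d, d)
  n_acc <- 0L
  scale_d <- 2.38^2 / d
  for (i in seq_len(n_iter)) {
    prop <- x + exp(log_s) * drop(rnorm(d) %*% L)
    acc <- 0
    if (all(prop >= lower) && all(prop <= upper)) {
      lt_prop <- log_target(prop)
      if (beta * (lt_prop - lt) > log(runif(1))) {
        x <- prop
        lt <- lt_prop
        acc <- 1
      }
    }
    n_acc <- n_acc + acc
    draws[i, ] <- x
    lts[i] <- lt
    sx <- sx + x
    sxx <- sxx + tcrossprod(x)
    log_s <- log_s + i^-0.7 * (acc - TARGET_ACCEPT)
    if (i >= ADAPT_START && i %% ADAPT_EVERY == 0L) {
      mu <- sx / i
      cov_hat <- (sxx - i * tcrossprod(mu)) / (i - 1)
      ch <- tryCatch(chol(scale_d * cov_hat + COV_REG * diag(d)),
                     error = function(e) NULL)
      if (!is.null(ch)) L <- ch
    }
  }
  list(draws = draws, log_target = lts, acceptance = n_acc / n_iter)
}

# draw an in-support initial point: the best (highest log-target) of
# n_scout finite prior draws, so chains start near the bulk of the
# posterior instead of a random corner of a wide prior box
init_from_prior <- function(log_target, lower, upper, max_tries = 1000L,
                            n_scout = 200L) {
  d <- length(lower)
  scouts <- list()
  scout_lt <- numeric(0)
  n_finite <- 0L
  for (k in seq_len(max_tries)) {
    x <- lower + runif(d) * (upper - lower)
    lt <- log_target(x)
    if (is.finite(lt)) {
      n_finite <- n_finite + 1L
      scouts[[n_finite]] <- x
      scout_lt[n_finite] <- lt
      if (n_finite >= n_scout) break
    }
  }
  if (n_finite == 0L) {
    stop("initialization failed: no finite log-posterior point found in ",
         max_tries, " prior draws", call. = FALSE)
  }
  # multi-start derivative-free polish: the RTF posterior can have local
  # optima, so refine the best few scouts and keep the overall winner, so
  # every chain starts in the global basin rather than random-walking
  # towards it
  pen <- function(x) {
    if (any(x < lower) || any(x > upper)) return(1e10)
    lt <- log_target(x)
    if (!is.finite(lt)) 1e10 else -lt
  }
  top <- order(scout_lt, decreasing = TRUE)[seq_len(min(5L, n_finite))]
  best_x <- scouts[[top[1]]]
  best_lt <- scout_lt[top[1]]
  for (j in top) {
    opt <- tryCatch(
      if (d == 1L) {
        stats::optim(scouts[[j]], pen, method = "Brent", lower = lower,
                     upper = upper)
      } else {
        stats::optim(scouts[[j]], pen, method = "Nelder-Mead",
                     control = list(maxit = 500L))
      },
      error = function(e) NULL)
    if (!is.null(opt) && is.finite(opt$value) && -opt$value > best_lt) {
      best_lt <- -opt$value
      best_x <- opt$par
    }
  }
  best_x
}

# assemble retained chains into the posterior_samples container
make_posterior_samples <- function(chains, post, config, dataset,
                                   swap_rates = NULL) {
  n_burn <- floor(config$burn_in * nrow(chains[[1]]$draws))
  retained <- lapply(chains, function(ch) {
    keep <- seq.int(n_burn + 1L, nrow(ch$draws))
    list(draws = ch$draws[keep, , drop = FALSE],
         log_target = ch$log_target[keep])
  })
  draw_mat <- do.call(rbind, lapply(retained, `[[`, "draws"))
  colnames(draw_mat) <- post$est_names
  lts <- unlist(lapply(retained, `[[`, "log_target"))
  chain_id <- rep(seq_along(retained),
                  vapply(retained, function(r) nrow(r$draws), integer(1)))

  lin <- draw_mat
  lin[, post$is_log] <- 10^lin[, post$is_log, drop = FALSE]
  draws <- as_tibble(as.data.frame(lin))
  draws$log_posterior <- lts
  draws$chain <- chain_id

  ess <- vapply(post$est_names, function(nm) {
    sum(vapply(retained, function(r) {
      ch <- r$draws[, match(nm, post$est_names)]
      if (length(ch) < 100L) return(NA_real_)
      suppressWarnings(effective_sample_size(ch))
    }, numeric(1)))
  }, numeric(1))
  rhat <- if (length(retained) >= 2L) {
    vapply(seq_along(post$est_names), function(j) {
      gelman_rubin(lapply(retained, function(r) r$draws[, j]))
    }, numeric(1))
  } else {
    rep(NA_real_, length(post$est_names))
  }
  names(rhat) <- post$est_names
  if (any(is.finite(rhat) & rhat > 1.1)) {
    warn(paste0("R-hat > 1.1 for: ",
                paste(post$est_names[is.finite(rhat) & rhat > 1.1],
                      collapse = ", "),
                " - chains may not have converged"))
  }
  diagnostics <- list(
    parameters = setNames(lapply(seq_along(post$est_names), function(j) {
      list(ess = unname(ess[j]), rhat = unname(rhat[j]))
    }), post$est_names),
    acceptance_rate = mean(vapply(chains, `[[`, numeric(1), "acceptance")),
    n_chains = length(chains),
    seed = config$seed)
  if (!is.null(swap_rates)) diagnostics$swap_rates <- swap_rates

  structure(list(draws = draws,
                 draws_sampling = draw_mat,
                 est_names = post$est_names,
                 is_log = post$is_log,
                 has_sigma = post$has_sigma,
                 sigma_fixed = post$sigma_fixed,
                 diagnostics = diagnostics,
                 config = config,
                 condition_id = attr(dataset, "condition_id"),
                 observable_id = attr(dataset, "observable_id")),
            class = "posterior_samples")
}

#' Sample the posterior with adaptive Metropolis-Hastings
#'
#' Runs `config$n_chains` independent adaptive Metropolis chains on the
#' posterior of the model parameters (and, by default, the pooled noise SD
#' `sigma`), discards the burn-in fraction of each chain, concatenates the
#' retained draws and attaches convergence diagnostics (per-parameter ESS
#' and split-R-hat, acceptance rate). Fully reproducible given
#' `(seed, config, data)`.
#'
#' @param dataset A [ts_dataset()].
#' @param priors A [prior_spec()]; see [default_priors()].
#' @param model A [model_spec()].
#' @param config A [run_config()]; `config$temperatures` switches to
#'   [parallel_tempering()].
#' @param fixed Named fixed parameter values overriding model defaults.
#' @return A `posterior_samples` object: tibble `$draws` (linear scale, one
#'   column per estimated parameter plus `log_posterior` and `chain`),
#'   `$diagnostics`, and metadata. Methods: [tidy()], [glance()],
#'   [autoplot()].
#' @export
sample_posterior <- function(dataset, priors, model = get_model("rtf"),
                             config, fixed = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$temperatures) && length(config$temperatures) > 1L) {
    return(parallel_tempering(dataset, priors, model, config, fixed))
  }
  post <- build_posterior(dataset, priors, model, fixed,
                          sigma_fixed = config$sigma_fixed)
  chains <- lapply(seq_len(config$n_chains), function(ci) {
    set.seed(derive_seed(config$seed, ci))
    init <- init_from_prior(post$log_lik, post$lower, post$upper)
    run_adaptive_chain(post$log_lik, init, post$lower, post$upper,
                       config$chain_length)
  })
  make_posterior_samples(chains, post, config, dataset)
}

#' Sample a multimodal posterior with parallel tempering
#'
#' Runs a ladder of adaptive Metropolis chains targeting the likelihood
#' raised to inverse temperatures `1/T`, with stochastic even/odd
#' replica-swap moves every iteration block. Only the cold chain
#' (temperature 1) contributes draws; swap acceptance rates are logged in
#' the diagnostics. `config$n_chains` independent tempered runs are
#' performed and their cold chains pooled.
#'
#' @inheritParams sample_posterior
#' @return A `posterior_samples` object (cold-chain draws only).
#' @export
parallel_tempering <- function(dataset, priors, model = get_model("rtf"),
                               config, fixed = NULL) {
  stopifnot(inherits(config, "run_config"))
  temps <- config$temperatures
  if (is.null(temps)) temps <- 1
  if (temps[1] != 1 || is.unsorted(temps, strictly = TRUE)) {
    stop("temperature ladder must be strictly ascending with coldest = 1",
         call. = FALSE)
  }
  post <- build_posterior(dataset, priors, model, fixed,
                          sigma_fixed = config$sigma_fixed)
  if (length(temps) == 1L) {
    cfg1 <- config
    cfg1$temperatures <- NULL
    return(sample_posterior(dataset, priors, model, cfg1, fixed))
  }
  betas <- 1 / temps
  K <- length(temps)
  d <- length(post$lower)
  n_iter <- config$chain_length

  runs <- lapply(seq_len(config$n_chains), function(ci) {
    set.seed(derive_seed(config$seed, ci))
    x <- lapply(seq_len(K), function(k) {
      init_from_prior(post$log_lik, post$lower, post$upper)
    })
    lt <- vapply(x, post$log_lik, numeric(1))
    L <- lapply(seq_len(K), function(k) {
      diag(0.05 * (post$upper - post$lower), d, d)
    })
    log_s <- numeric(K)
    sx <- lapply(seq_len(K), function(k) numeric(d))
    sxx <- lapply(seq_len(K), function(k) matrix(0, d, d))
    n_acc <- numeric(K)
    swap_att <- numeric(K - 1)
    swap_acc <- numeric(K - 1)
    draws <- matrix(NA_real_, n_iter, d)
    lts <- numeric(n_iter)
    scale_d <- 2.38^2 / d

    for (i in seq_len(n_iter)) {
      for (k in seq_len(K)) {
        prop <- x[[k]] + exp(log_s[k]) * drop(rnorm(d) %*% L[[k]])
        acc <- 0
        if (all(prop >= post$lower) && all(prop <= post$upper)) {
          lt_prop <- post$log_lik(prop)
          if (betas[k] * (lt_prop - lt[k]) > log(runif(1))) {
            x[[k]] <- prop
            lt[k] <- lt_prop
            acc <- 1
          }
        }
        n_acc[k] <- n_acc[k] + acc
        sx[[k]] <- sx[[k]] + x[[k]]
        sxx[[k]] <- sxx[[k]] + tcrossprod(x[[k]])
        log_s[k] <- log_s[k] + i^-0.7 * (acc - TARGET_ACCEPT)
        if (i >= ADAPT_START && i %% ADAPT_EVERY == 0L) {
          mu <- sx[[k]] / i
          cov_hat <- (sxx[[k]] - i * tcrossprod(mu)) / (i - 1)
          ch <- tryCatch(chol(scale_d * cov_hat + COV_REG * diag(d)),
                         error = function(e) NULL)
          if (!is.null(ch)) L[[k]] <- ch
        }
      }
      # alternating even/odd neighbour swaps
      start <- if (i %% 2L == 1L) 1L else 2L
      ks <- if (start > K - 1L) integer(0) else seq.int(start, K - 1L, by = 2L)
      for (k in ks) {
        swap_att[k] <- swap_att[k] + 1
        log_alpha <- (betas[k] - betas[k + 1]) * (lt[k + 1] - lt[k])
        if (log_alpha > log(runif(1))) {
          tmp <- x[[k]]; x[[k]] <- x[[k + 1]]; x[[k + 1]] <- tmp
          tmp <- lt[k]; lt[k] <- lt[k + 1]; lt[k + 1] <- tmp
          swap_acc[k] <- swap_acc[k] + 1
        }
      }
      draws[i, ] <- x[[1]]
      lts[i] <- lt[1]
    }
    list(draws = draws, log_target = lts, acceptance = n_acc[1] / n_iter,
         swap_rates = swap_acc / pmax(swap_att, 1))
  })
  swap_rates <- colMeans(do.call(rbind, lapply(runs, `[[`, "swap_rates")))
  make_posterior_samples(runs, post, config, dataset,
                         swap_rates = swap_rates)
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat(sprintf("<posterior_samples> %s/%s: %d draws x %d parameters, %d chain(s)\n",
              x$condition_id %||% "?", x$observable_id %||% "?",
              nrow(x$draws), length(x$est_names),
              x$diagnostics$n_chains))
  cat(sprintf("  acceptance %.3f, min ESS %.0f, max R-hat %s\n",
              x$diagnostics$acceptance_rate,
              min(vapply(x$diagnostics$parameters, `[[`, numeric(1), "ess")),
              {
                r <- vapply(x$diagnostics$parameters, `[[`, numeric(1), "rhat")
                if (all(is.na(r))) "NA" else sprintf("%.3f", max(r, na.rm = TRUE))
              }))
  invisible(x)
}
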