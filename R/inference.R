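# Likelihood, priors and posterior construction.
#
# The error model is additive i.i.d. Gaussian noise with a single pooled
# standard deviation sigma shared by all time points and replicates of a
# dataset; sigma is estimated jointly by default.

#' Uniform prior specification
#'
#' One row per estimated parameter: uniform bounds on the declared scale.
#' Parameters with scale `"log10"` are sampled uniformly in log10 space
#' (bounds stored on the linear scale, both positive); `"lin"` parameters
#' uniformly on the linear scale.
#'
#' @param priors Data frame with columns `parameter`, `lower`, `upper`,
#'   `scale` (`"lin"` or `"log10"`).
#' @return A tibble of class `"prior_spec"`.
#' @export
prior_spec <- function(priors) {
  stopifnot(is.data.frame(priors),
            all(c("parameter", "lower", "upper", "scale") %in% names(priors)))
  p <- as_tibble(priors)
  if (any(!p$scale %in% c("lin", "log10"))) {
    stop("scale must be 'lin' or 'log10'", call. = FALSE)
  }
  if (any(p$lower >= p$upper)) {
    stop("prior lower bounds must be < upper bounds", call. = FALSE)
  }
  if (any(p$scale == "log10" & p$lower <= 0)) {
    stop("log10-scaled parameters need positive linear-domain bounds",
         call. = FALSE)
  }
  structure(p, class = c("prior_spec", class(p)))
}

#' Data-informed default priors
#'
#' Builds wide uniform priors around the measurement data, the standard
#' choice for RTF fits. With \eqn{\Delta = \max(m) - \min(m)} and `R` the
#' observation range:
#' amplitudes `Asus`, `Atrans` uniform on \eqn{[-2\Delta, 2\Delta]};
#' baseline `p0` uniform on \eqn{[\min(m) - \Delta, \max(m) + \Delta]};
#' timescales `t1`, `t11`, `t2` log10-uniform on \eqn{[R/100, 10R]};
#' noise SD `sigma` log10-uniform on \eqn{[\Delta/1000, 2\Delta]}.
#'
#' @param dataset A [ts_dataset()].
#' @param model A [model_spec()] (default the RTF model).
#' @param estimate_sigma Include a prior row for `sigma`.
#' @return A [prior_spec()] tibble.
#' @export
default_priors <- function(dataset, model = get_model("rtf"),
                           estimate_sigma = TRUE) {
  stopifnot(inherits(dataset, "ts_dataset"))
  m <- dataset$measurement
  delta <- max(m) - min(m)
  if (delta == 0) {
    stop("constant data (max(m) == min(m)): default priors are undefined, ",
         "supply priors manually", call. = FALSE)
  }
  R <- time_range(dataset)
  rows <- list()
  for (nm in model$parameter_names) {
    rows[[nm]] <- switch(
      nm,
      Asus = ,
      Atrans = tibble(parameter = nm, lower = -2 * delta, upper = 2 * delta,
                      scale = "lin"),
      p0 = tibble(parameter = nm, lower = min(m) - delta,
                  upper = max(m) + delta, scale = "lin"),
      t1 = ,
      t11 = ,
      t2 = tibble(parameter = nm, lower = R / 100, upper = 10 * R,
                  scale = "log10"),
      ka = ,
      ke = tibble(parameter = nm, lower = 1e-3, upper = 1e3, scale = "log10"),
      V = ,
      dose = tibble(parameter = nm, lower = 1e-3, upper = 1e3,
                    scale = "log10"),
      c0 = tibble(parameter = nm, lower = 0, upper = max(m) + delta,
                  scale = "lin"),
      NULL)
  }
  tab <- bind_rows(rows[!vapply(rows, is.null, logical(1))])
  if (estimate_sigma) {
    tab <- bind_rows(tab, tibble(parameter = "sigma", lower = delta / 1000,
                                 upper = 2 * delta, scale = "log10"))
  }
  prior_spec(tab)
}

#' Gaussian log-likelihood of a dataset
#'
#' Pooled-noise Gaussian likelihood: for each record \eqn{m^{(j)}(t_k)},
#' \deqn{\log L = \sum_k \sum_j \left[ -\log(\sigma\sqrt{2\pi}) -
#'   \frac{(s(t_k, \theta) - m^{(j)}(t_k))^2}{2\sigma^2} \right].}
#' The model is evaluated once per distinct time point and reused across
#' replicates. Non-finite model output yields `-Inf` (the point is
#' rejected), never an error.
#'
#' @param dataset A [ts_dataset()].
#' @param params Named parameter vector/list for the model.
#' @param sigma Noise standard deviation (> 0).
#' @param model A [model_spec()].
#' @return Scalar log-likelihood.
#' @export
log_likelihood <- function(dataset, params, sigma, model = get_model("rtf")) {
  stopifnot(inherits(dataset, "ts_dataset"), sigma > 0)
  tu <- sort(unique(dataset$time))
  idx <- match(dataset$time, tu)
  s <- tryCatch(model$evaluator(tu, params), error = function(e) NA_real_)
  if (length(s) != length(tu) || any(!is.finite(s))) return(-Inf)
  resid <- s[idx] - dataset$measurement
  n <- length(resid)
  -n * log(sigma * sqrt(2 * pi)) - sum(resid^2) / (2 * sigma^2)
}

# ---- internal posterior construction ---------------------------------------

# Precompiles dataset, priors and model into a fast log-posterior over the
# sampling-scale vector x (log10 for log10-scaled parameters). With uniform
# priors the log prior is 0 inside bounds and -Inf outside; sampling
# uniformly on the log10 scale carries the scale's Jacobian implicitly.
# Returns a list with the closure and bookkeeping used by the samplers.
build_posterior <- function(dataset, priors, model, fixed = NULL,
                            sigma_fixed = NULL) {
  stopifnot(inherits(dataset, "ts_dataset"), inherits(priors, "prior_spec"),
            inherits(model, "model_spec"))
  est_names <- priors$parameter
  has_sigma <- "sigma" %in% est_names
  if (!has_sigma && is.null(sigma_fixed)) {
    stop("sigma must be either estimated (prior row) or fixed", call. = FALSE)
  }
  is_log <- priors$scale == "log10"
  lower <- priors$lower
  upper <- priors$upper
  lower[is_log] <- log10(lower[is_log])
  upper[is_log] <- log10(upper[is_log])

  full <- model$fixed_parameters
  if (!is.null(fixed)) full[names(fixed)] <- as.list(fixed)
  model_par_names <- setdiff(est_names, "sigma")
  missing_pars <- setdiff(model$parameter_names,
                          c(model_par_names, names(full)))
  if (length(missing_pars) > 0L) {
    stop("model parameter(s) neither estimated nor fixed: ",
         paste(missing_pars, collapse = ", "), call. = FALSE)
  }

  tu <- sort(unique(dataset$time))
  idx <- match(dataset$time, tu)
  m <- dataset$measurement
  n <- length(m)
  evaluator <- model$evaluator
  template <- full
  sig_i <- if (has_sigma) which(est_names == "sigma") else 0L
  par_i <- which(est_names != "sigma")
  log_2pi_half <- 0.5 * log(2 * pi)

  # x on sampling scale -> named linear-scale parameter list
  to_linear <- function(x) {
    v <- ifelse(is_log, 10^x, x)
    names(v) <- est_names
    v
  }

  if (model$model_id == "rtf" &&
      all(c("Tshift", "Trange") %in% names(full)) &&
      !any(c("Tshift", "Trange") %in% est_names)) {
    # Tshift/Trange fixed: pre-transform the time axis once and evaluate the
    # RTF core directly (dominant cost inside the MCMC loop)
    tt <- .transform_time_fast(tu, full$Tshift, full$Trange)
    core_names <- c("Asus", "t1", "Atrans", "t11", "t2", "p0")
    base <- vapply(core_names,
                   function(nm) if (is.null(full[[nm]])) NA_real_
                   else full[[nm]], numeric(1))
    slot <- match(est_names, core_names) # NA for sigma
    log_lik <- function(x) {
      v <- x
      v[is_log] <- 10^x[is_log]
      sigma <- if (has_sigma) v[sig_i] else sigma_fixed
      th <- base
      th[slot[par_i]] <- v[par_i]
      s <- .rtf_core(tt, th[1], th[2], th[3], th[4], th[5], th[6])
      if (any(!is.finite(s))) return(-Inf)
      r <- s[idx] - m
      -n * (log(sigma) + log_2pi_half) - sum(r * r) / (2 * sigma * sigma)
    }
  } else {
    log_lik <- function(x) {
      v <- x
      v[is_log] <- 10^x[is_log]
      sigma <- if (has_sigma) v[sig_i] else sigma_fixed
      p <- template
      p[est_names[par_i]] <- v[par_i]
      s <- tryCatch(evaluator(tu, p), error = function(e) NA_real_)
      if (any(!is.finite(s)) || length(s) != length(tu)) return(-Inf)
      r <- s[idx] - m
      -n * (log(sigma) + log_2pi_half) - sum(r * r) / (2 * sigma * sigma)
    }
  }

  in_bounds <- function(x) all(x >= lower & x <= upper)

  list(log_lik = log_lik, in_bounds = in_bounds, lower = lower,
       upper = upper, est_names = est_names, is_log = is_log,
       to_linear = to_linear, has_sigma = has_sigma,
       sigma_fixed = sigma_fixed)
}

#' Log-posterior density
#'
#' Unnormalized log-posterior \eqn{\log p(\theta \mid D) = \log L_D(\theta)
#' + \log p(\theta)} with uniform priors: constant inside the prior box and
#' `-Inf` outside. Evaluated on the sampling scale (log10 for log10-scaled
#' parameters), so the log10 Jacobian is implicit in sampling uniformly on
#' that scale.
#'
#' @param x Numeric vector on the sampling scale, ordered as
#'   `priors$parameter`.
#' @param dataset A [ts_dataset()].
#' @param priors A [prior_spec()].
#' @param model A [model_spec()].
#' @param fixed Optional named fixed parameter values overriding model
#'   defaults.
#' @param sigma_fixed Fixed noise SD if sigma is not in `priors`.
#' @return Scalar log-posterior.
#' @export
log_posterior <- function(x, dataset, priors, model = get_model("rtf"),
                          fixed = NULL, sigma_fixed = NULL) {
  post <- build_posterior(dataset, priors, model, fixed, sigma_fixed)
  if (!post$in_bounds(x)) return(-Inf)
  post$log_lik(x)
}
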