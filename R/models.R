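# Simulation models: the retarded transient function (RTF) and a
# two-compartment pharmacokinetic model, behind a small model registry.

# Exponent clip: exp(x) overflows above ~709.78, so proposals far outside the
# plausible region evaluate to finite (huge or zero) values instead of Inf/NaN,
# which would poison the MCMC acceptance ratio.
.EXP_CLIP <- 700

safe_exp <- function(x) exp(pmin(pmax(x, -.EXP_CLIP), .EXP_CLIP))

# log10(10^a + 10^b), overflow-safe, exact when a == b is impossible but
# |a - b| is large. Vectorized over a.
log10_add_exp <- function(a, b) {
  m <- pmax(a, b)
  m + log10(1 + 10^(-abs(a - b)))
}

#' RTF parameter set
#'
#' Bundles the seven parameters of the retarded transient function together
#' with the fixed observation-range constant `Trange`. The RTF is a
#' closed-form response curve
#' \deqn{f(t) = A_{sus}(1 - e^{-t/t_1}) + A_{trans}(1 - e^{-t/t_{11}})\,
#'   e^{-t/t_2} + p_0}
#' evaluated on a nonlinearly transformed time axis (see
#' [transform_time()]), so responses can be delayed via `Tshift` without
#' changing the value at `t = 0`.
#'
#' @param Asus Amplitude of the sustained (saturating) response, in
#'   observable units. May be negative for decreasing dynamics.
#' @param t1 Timescale of the sustained response (> 0), in transformed time
#'   units.
#' @param Atrans Amplitude of the transient (rise-then-decay) response.
#' @param t11 Rise timescale of the transient response (> 0).
#' @param t2 Decay timescale of the transient response (> 0).
#' @param Tshift Response-delay shift on the log10 time axis
#'   (dimensionless). `-2` corresponds to an effectively immediate response
#'   and is the default used throughout.
#' @param p0 Baseline offset, in observable units; the curve value at
#'   `t = 0` is exactly `p0`.
#' @param Trange Fixed range of the observation interval (> 0), in real time
#'   units. Not estimated; set it to `max(time) - min(time)` of the data.
#'
#' @return A named list of class `"rtf_params"`.
#' @examples
#' th <- rtf_params(Asus = 1, t1 = 1, Atrans = 0.5, t11 = 0.2, t2 = 2,
#'                  p0 = 0, Trange = 5)
#' rtf_evaluate(c(0, 0.5, 5), th)
#' @export
rtf_params <- function(Asus, t1, Atrans, t11, t2, Tshift = -2, p0 = 0,
                       Trange = 10) {
  th <- list(Asus = Asus, t1 = t1, Atrans = Atrans, t11 = t11, t2 = t2,
             Tshift = Tshift, p0 = p0, Trange = Trange)
  vals <- unlist(th)
  if (!all(is.finite(vals))) {
    stop("all RTF parameters must be finite", call. = FALSE)
  }
  if (t1 <= 0 || t11 <= 0 || t2 <= 0) {
    stop("timescales t1, t11, t2 must be strictly positive", call. = FALSE)
  }
  if (Trange <= 0) stop("Trange must be strictly positive", call. = FALSE)
  structure(th, class = "rtf_params")
}

#' Nonlinear time transformation of the RTF
#'
#' Maps real (experimental) time onto the transformed axis the RTF is
#' evaluated on:
#' \deqn{t = \log_{10}(10^{10\,t_{real}/T_{range}} + 10^{T_{shift}})
#'   - \log_{10}(1 + 10^{T_{shift}}).}
#' The transformation leaves \eqn{t = 0} invariant for every `Tshift`, is
#' strictly increasing in `t_real`, and approaches the linear rescaling
#' \eqn{10\,t_{real}/T_{range}} as `Tshift` tends to \eqn{-\infty}
#' (immediate response). Larger `Tshift` flattens the early part of the
#' curve, delaying the response. The observation interval
#' `[0, Trange]` maps approximately onto transformed time `[0, 10]`.
#'
#' @param t_real Numeric vector of nonnegative real times.
#' @param Tshift Delay shift (finite scalar).
#' @param Trange Observation-interval range (> 0).
#' @return Numeric vector of transformed times.
#' @examples
#' transform_time(0:5, Tshift = -2, Trange = 5)
#' @export
transform_time <- function(t_real, Tshift = -2, Trange = 10) {
  if (!is.numeric(t_real) || anyNA(t_real) || any(!is.finite(t_real))) {
    stop("t_real must be finite numeric", call. = FALSE)
  }
  if (length(Tshift) != 1L || !is.finite(Tshift)) {
    stop("Tshift must be a finite scalar", call. = FALSE)
  }
  if (length(Trange) != 1L || !is.finite(Trange)) {
    stop("Trange must be a finite scalar", call. = FALSE)
  }
  if (Trange <= 0) stop("Trange must be > 0", call. = FALSE)
  .transform_time_fast(t_real, Tshift, Trange)
}

# hot path without argument validation (the samplers call this per iteration)
.transform_time_fast <- function(t_real, Tshift, Trange) {
  g <- 10 * t_real / Trange
  # both terms computed with the same stable log-sum rule so that t(0) == 0
  # holds exactly in floating point
  log10_add_exp(g, Tshift) - log10_add_exp(0, Tshift)
}

# RTF on pre-transformed time (validation-free hot path). With tt >= 0 and
# positive timescales all exponents are <= 0, so plain exp() cannot
# overflow; underflow to 0 is the correct limit.
.rtf_core <- function(tt, Asus, t1, Atrans, t11, t2, p0) {
  Asus * (1 - exp(-tt / t1)) +
    Atrans * (1 - exp(-tt / t11)) * exp(-tt / t2) + p0
}

#' Evaluate the retarded transient function
#'
#' Computes the RTF on a grid of real times: the time axis is transformed via
#' [transform_time()] and the sustained + transient response evaluated on it.
#' `rtf_evaluate(0, th)` equals `p0` exactly; with `Atrans = 0` and
#' `Asus > 0` the curve saturates monotonically at `Asus + p0`.
#'
#' @param t_real Sorted (ascending) numeric vector of nonnegative real times.
#' @param params An [rtf_params()] object, or a named list/vector with the
#'   same fields.
#' @return Numeric vector of response values, one per element of `t_real`.
#' @export
rtf_evaluate <- function(t_real, params) {
  p <- as.list(params)
  need <- c("Asus", "t1", "Atrans", "t11", "t2", "Tshift", "p0", "Trange")
  if (!all(need %in% names(p))) {
    stop("params must contain fields: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (p$t1 <= 0 || p$t11 <= 0 || p$t2 <= 0 || p$Trange <= 0) {
    stop("timescales and Trange must be strictly positive", call. = FALSE)
  }
  if (is.unsorted(t_real)) stop("t_real must be sorted ascending", call. = FALSE)
  tt <- transform_time(t_real, p$Tshift, p$Trange)
  p$Asus * (1 - safe_exp(-tt / p$t1)) +
    p$Atrans * (1 - safe_exp(-tt / p$t11)) * safe_exp(-tt / p$t2) + p$p0
}

#' Two-compartment pharmacokinetic model
#'
#' Standard first-order absorption / first-order elimination solution for a
#' single oral dose:
#' \deqn{c(t) = \frac{D\,k_a}{V (k_a - k_e)} (e^{-k_e t} - e^{-k_a t}) + c_0,}
#' with the flip-flop limit \eqn{c(t) = (D/V)\, k t e^{-k t} + c_0} used when
#' \eqn{k_a = k_e = k}. Serves as the mechanistic alternative to the RTF for
#' drug-concentration time courses.
#'
#' @param t_real Sorted numeric vector of times since dosing.
#' @param params Named list/vector with `dose`, `ka` (absorption rate, > 0),
#'   `ke` (elimination rate, > 0), `V` (distribution volume, > 0) and
#'   optionally `c0` (baseline concentration, >= 0, default 0).
#' @return Numeric vector of concentrations.
#' @export
pk2c_evaluate <- function(t_real, params) {
  p <- as.list(params)
  need <- c("dose", "ka", "ke", "V")
  if (!all(need %in% names(p))) {
    stop("params must contain fields: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (p$ka <= 0 || p$ke <= 0 || p$V <= 0) {
    stop("ka, ke and V must be strictly positive", call. = FALSE)
  }
  if (is.unsorted(t_real)) stop("t_real must be sorted ascending", call. = FALSE)
  c0 <- if (is.null(p$c0)) 0 else p$c0
  # near ka == ke the generic formula is 0/0; switch to the analytic limit
  if (abs(p$ka - p$ke) < 1e-8 * max(p$ka, p$ke)) {
    k <- (p$ka + p$ke) / 2
    (p$dose / p$V) * k * t_real * safe_exp(-k * t_real) + c0
  } else {
    (p$dose * p$ka) / (p$V * (p$ka - p$ke)) *
      (safe_exp(-p$ke * t_real) - safe_exp(-p$ka * t_real)) + c0
  }
}

# ---- model registry ---------------------------------------------------------

.model_registry <- new.env(parent = emptyenv())

#' Model specification
#'
#' A model spec couples an ordered set of parameter names, a map of fixed
#' parameter values, and a deterministic evaluator
#' `function(t_real, params)` mapping a time grid and a full named parameter
#' vector to trajectory values.
#'
#' @param model_id Registry key (string, case-sensitive).
#' @param parameter_names Ordered character vector of estimable parameters.
#' @param fixed_parameters Named numeric vector/list of fixed values;
#'   names must be disjoint from `parameter_names`.
#' @param evaluator Function `(t_real, params)` returning a numeric vector.
#' @return A list of class `"model_spec"`.
#' @export
model_spec <- function(model_id, parameter_names, fixed_parameters = list(),
                       evaluator) {
  stopifnot(is.character(model_id), length(model_id) == 1L,
            is.character(parameter_names), is.function(evaluator))
  fixed_parameters <- as.list(fixed_parameters)
  if (length(intersect(parameter_names, names(fixed_parameters))) > 0L) {
    stop("parameter_names and fixed_parameters must be disjoint",
         call. = FALSE)
  }
  structure(list(model_id = model_id,
                 parameter_names = parameter_names,
                 fixed_parameters = fixed_parameters,
                 evaluator = evaluator),
            class = "model_spec")
}

#' Register a model
#'
#' Adds a [model_spec()] to the package registry so it can be referenced by
#' id from run configurations and the command line. Built-in models
#' (`"rtf"`, `"pk2c"`) cannot be overwritten.
#'
#' @param spec A [model_spec()].
#' @param overwrite Allow replacing a previously user-registered spec.
#' @return `spec`, invisibly.
#' @export
register_model <- function(spec, overwrite = FALSE) {
  stopifnot(inherits(spec, "model_spec"))
  id <- spec$model_id
  if (id %in% c("rtf", "pk2c") && exists(id, envir = .model_registry)) {
    stop("built-in model '", id, "' cannot be overwritten", call. = FALSE)
  }
  if (exists(id, envir = .model_registry) && !overwrite) {
    stop("model '", id, "' is already registered", call. = FALSE)
  }
  assign(id, spec, envir = .model_registry)
  invisible(spec)
}

#' Look up a registered model
#'
#' @param model_id Registry key; `"rtf"` and `"pk2c"` are built in.
#' @return The registered [model_spec()].
#' @export
get_model <- function(model_id) {
  stopifnot(is.character(model_id), length(model_id) == 1L)
  if (!exists(model_id, envir = .model_registry, inherits = FALSE)) {
    stop("unknown model '", model_id, "'; available: ",
         paste(sort(ls(.model_registry)), collapse = ", "), call. = FALSE)
  }
  get(model_id, envir = .model_registry, inherits = FALSE)
}

#' List registered model ids
#' @return Character vector of model ids.
#' @export
list_models <- function() sort(ls(.model_registry))

.register_builtin_models <- function() {
  register_model(model_spec(
    model_id = "rtf",
    parameter_names = c("Asus", "t1", "Atrans", "t11", "t2", "Tshift", "p0"),
    fixed_parameters = list(Trange = 10),
    evaluator = function(t_real, params) rtf_evaluate(t_real, params)
  ))
  register_model(model_spec(
    model_id = "pk2c",
    parameter_names = c("dose", "ka", "ke", "V", "c0"),
    fixed_parameters = list(),
    evaluator = function(t_real, params) pk2c_evaluate(t_real, params)
  ))
}
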