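# Synthetic replicate time-series generator realizing the package's data
# model exactly: m^(j)(t_k) = s(t_k, theta*) + eps, eps ~ N(0, sigma*^2)
# i.i.d. Used for validation studies, demos and acceptance runs; no
# external data are required anywhere in the package.

#' Specification of a synthetic dataset
#'
#' @param theta True parameters: an [rtf_params()] object, or a named
#'   list/vector understood by the chosen model.
#' @param times Numeric vector of >= 2 distinct measurement times (need not
#'   be equidistant).
#' @param n_replicates Replicates per time point (scalar or one value per
#'   time point).
#' @param sigma True noise SD (>= 0).
#' @param seed Integer RNG seed (mandatory).
#' @param model_id Registered model id (default `"rtf"`).
#' @param condition_id,observable_id Identifiers for the emitted dataset.
#' @return A list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(theta, times, n_replicates = 4L, sigma = 0.1,
                           seed, model_id = "rtf",
                           condition_id = "condition1",
                           observable_id = "observable1") {
  if (missing(seed) || is.null(seed)) {
    stop("seed is mandatory in synthetic_spec()", call. = FALSE)
  }
  if (length(unique(times)) < 2L) {
    stop("need at least 2 distinct time points", call. = FALSE)
  }
  if (any(n_replicates < 1L)) stop("n_replicates must be >= 1", call. = FALSE)
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  if (length(n_replicates) == 1L) {
    n_replicates <- rep(as.integer(n_replicates), length(times))
  }
  stopifnot(length(n_replicates) == length(times))
  structure(list(theta = theta, times = sort(times),
                 n_replicates = n_replicates, sigma = sigma,
                 seed = as.integer(seed), model_id = model_id,
                 condition_id = condition_id, observable_id = observable_id),
            class = "synthetic_spec")
}

#' Generate a synthetic replicate dataset
#'
#' Simulates the noiseless model curve at the spec's time points and adds
#' i.i.d. Gaussian noise per replicate. Reproducible by seed.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `dataset` (a [ts_dataset()]) and `truth` (list with
#'   `theta`, `sigma` and the noiseless `curve` tibble).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  model <- get_model(spec$model_id)
  s <- model$evaluator(spec$times, spec$theta)
  set.seed(derive_seed(spec$seed, 1L))
  rows <- purrr::map2(seq_along(spec$times), spec$n_replicates,
                      function(k, nk) {
                        tibble(time = spec$times[k],
                               replicateId = paste0("r", seq_len(nk)),
                               measurement = s[k] + rnorm(nk, 0, spec$sigma))
                      })
  d <- ts_dataset(bind_rows(rows), condition_id = spec$condition_id,
                  observable_id = spec$observable_id)
  list(dataset = d,
       truth = list(theta = spec$theta, sigma = spec$sigma,
                    curve = tibble(time = spec$times, value = s)))
}

#' Generate a multi-condition synthetic study
#'
#' Merges several per-condition synthetic datasets into one PEtab-dialect
#' measurement table, together with a truth table for recovery checks. Two
#' presets emulate the shapes of typical in-vivo studies:
#'
#' * `"pvl-like"`: 5 conditions (one baseline-shifted, two with sustained
#'   decrease, two with a transient peak), 5 time points (days 0, 1, 2, 3,
#'   5) x 5 replicates — the shape of a cross-sectional perfusion-MRI
#'   study after portal vein ligation.
#' * `"steatosis-like"`: 3 conditions with peak-and-elimination dynamics
#'   and replicate counts 4, 6, 6 over 8 time points in 0–6 h — the shape
#'   of a drug-cocktail pharmacokinetics study under increasing hepatic
#'   steatosis (slower clearance at higher steatosis).
#'
#' @param specs Either a list of [synthetic_spec()] objects with distinct
#'   condition ids, or a preset name (`"pvl-like"`, `"steatosis-like"`).
#' @param seed Seed used to build preset specs (ignored when explicit specs
#'   are given; their own seeds apply).
#' @return List with `measurements` (merged PEtab-dialect tibble), `truths`
#'   (named list of per-condition truth records) and `datasets` (named list
#'   of [ts_dataset()]).
#' @export
generate_study <- function(specs, seed = NULL) {
  if (is.character(specs) && length(specs) == 1L) {
    if (is.null(seed)) stop("seed is mandatory for presets", call. = FALSE)
    specs <- study_preset(specs, seed)
  }
  if (length(specs) < 2L) stop("need >= 2 conditions", call. = FALSE)
  ids <- vapply(specs, function(sp) sp$condition_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate condition ids: ", paste(ids[duplicated(ids)],
                                            collapse = ", "), call. = FALSE)
  }
  gens <- lapply(specs, generate_dataset)
  datasets <- setNames(lapply(gens, `[[`, "dataset"), ids)
  truths <- setNames(lapply(gens, `[[`, "truth"), ids)
  measurements <- bind_rows(lapply(datasets, function(d) {
    tibble(observableId = attr(d, "observable_id"),
           simulationConditionId = attr(d, "condition_id"),
           time = d$time, measurement = d$measurement,
           replicateId = d$replicateId)
  }))
  list(measurements = measurements, truths = truths, datasets = datasets)
}

#' Truth table of a synthetic study
#'
#' Flattens the per-condition truth records of [generate_study()] into a
#' tibble (one row per condition and parameter) suitable for writing next
#' to the measurement table, so downstream checks never parse logs.
#'
#' @param study Result of [generate_study()].
#' @return Tibble with columns `conditionId`, `parameter`, `value`.
#' @export
study_truth_table <- function(study) {
  bind_rows(lapply(names(study$truths), function(cid) {
    tr <- study$truths[[cid]]
    th <- unlist(as.list(tr$theta))
    tibble(conditionId = cid,
           parameter = c(names(th), "sigma"),
           value = c(unname(th), tr$sigma))
  }))
}

study_preset <- function(name, seed) {
  switch(
    name,
    "pvl-like" = {
      # perfusion units ~[50, 200]; days 0,1,2,3,5; immediate response
      times <- c(0, 1, 2, 3, 5)
      mk <- function(i, Asus, t1, Atrans, t11, t2, p0, cid) {
        synthetic_spec(
          rtf_params(Asus = Asus, t1 = t1, Atrans = Atrans, t11 = t11,
                     t2 = t2, Tshift = -2, p0 = p0, Trange = 5),
          times = times, n_replicates = 5L, sigma = 8,
          seed = derive_seed(seed, 100L + i), condition_id = cid,
          observable_id = "perfusion")
      }
      list(
        # ligated-like lobes: sustained decrease of ~30-50%
        mk(1, Asus = -45, t1 = 1.5, Atrans = 0, t11 = 1, t2 = 1, p0 = 100,
           cid = "lobe_lig1"),
        mk(2, Asus = -35, t1 = 1.0, Atrans = 0, t11 = 1, t2 = 1, p0 = 105,
           cid = "lobe_lig2"),
        mk(3, Asus = -50, t1 = 2.0, Atrans = 0, t11 = 1, t2 = 1, p0 = 80,
           cid = "lobe_lig3"),
        # nonligated-like lobes: transient hyperperfusion peaking ~day 1
        mk(4, Asus = 0, t1 = 1, Atrans = 60, t11 = 1.2, t2 = 2.5, p0 = 100,
           cid = "lobe_nonlig1"),
        mk(5, Asus = 0, t1 = 1, Atrans = 40, t11 = 1.5, t2 = 4, p0 = 95,
           cid = "lobe_nonlig2"))
    },
    "steatosis-like" = {
      # drug concentration time course: fast absorption, slower elimination;
      # clearance slows with steatosis severity; hours 0-6, 8 time points
      times <- c(0, 0.25, 0.5, 1, 2, 3, 4, 6)
      mk <- function(i, t2, peak, n, cid) {
        synthetic_spec(
          rtf_params(Asus = 0, t1 = 1, Atrans = peak, t11 = 0.4, t2 = t2,
                     Tshift = -2, p0 = 0.05, Trange = 6),
          times = times, n_replicates = n, sigma = 0.08,
          seed = derive_seed(seed, 200L + i), condition_id = cid,
          observable_id = "drug_concentration")
      }
      list(mk(1, t2 = 1.2, peak = 1.0, n = 4L, cid = "control"),
           mk(2, t2 = 1.6, peak = 1.1, n = 6L, cid = "steatosis_2wk"),
           mk(3, t2 = 3.0, peak = 1.4, n = 6L, cid = "steatosis_4wk"))
    },
    stop("unknown preset '", name, "'; available: pvl-like, steatosis-like",
         call. = FALSE))
}
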