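# PEtab-dialect table reading/writing and dataset assembly.
#
# Only the measurement-table columns observableId, simulationConditionId,
# time, measurement (plus optional replicateId) and the parameter-table
# columns parameterId, lowerBound, upperBound, estimate, parameterScale
# (plus optional nominalValue) are interpreted; extra columns are carried
# along untouched. Files are strict TSV: tab separator, UTF-8, "." decimal.

MEASUREMENT_COLS <- c("observableId", "simulationConditionId", "time",
                      "measurement")
PARAMETER_COLS <- c("parameterId", "lowerBound", "upperBound", "estimate",
                    "parameterScale")

#' Construct a replicate time-series dataset
#'
#' A dataset holds all replicate measurements of one observable under one
#' experimental condition: records \eqn{m^{(j)}(t_k)} over time points
#' \eqn{k = 1, \dots, T} with (possibly varying) replicate counts per time
#' point.
#'
#' @param data Data frame with columns `time`, `measurement` and optionally
#'   `replicateId` (inferred positionally per time point when absent).
#' @param condition_id,observable_id Identifier strings.
#' @return A tibble of class `"ts_dataset"` with attributes `condition_id`,
#'   `observable_id`.
#' @export
ts_dataset <- function(data, condition_id = "condition1",
                       observable_id = "observable1") {
  stopifnot(is.data.frame(data), all(c("time", "measurement") %in% names(data)))
  d <- as_tibble(data)
  if (!is.numeric(d$time) || !is.numeric(d$measurement)) {
    stop("time and measurement must be numeric", call. = FALSE)
  }
  if (anyNA(d$time) || any(!is.finite(d$time)) || any(d$time < 0)) {
    stop("times must be finite and >= 0", call. = FALSE)
  }
  if (anyNA(d$measurement) || any(!is.finite(d$measurement))) {
    stop("measurements must be finite", call. = FALSE)
  }
  if (length(unique(d$time)) < 2L) {
    stop("a dataset needs at least 2 distinct time points", call. = FALSE)
  }
  if (!"replicateId" %in% names(d)) {
    d <- d |>
      group_by(.data$time) |>
      mutate(replicateId = paste0("r", row_number())) |>
      ungroup()
  }
  structure(d, class = c("ts_dataset", class(d)),
            condition_id = condition_id, observable_id = observable_id)
}

#' @export
print.ts_dataset <- function(x, ...) {
  cat(sprintf("<ts_dataset> condition=%s observable=%s: %d records, %d time points\n",
              attr(x, "condition_id"), attr(x, "observable_id"),
              nrow(x), length(unique(x$time))))
  NextMethod()
}

#' Number of distinct time points of a dataset
#' @param dataset A [ts_dataset()].
#' @return Integer count.
#' @export
n_timepoints <- function(dataset) length(unique(dataset$time))

#' Observation-interval range of a dataset
#' @param dataset A [ts_dataset()].
#' @return `max(time) - min(time)`.
#' @export
time_range <- function(dataset) diff(range(dataset$time))

#' Read a PEtab-dialect measurement table
#'
#' Reads a tab-separated measurement table and splits it into one dataset
#' per (condition, observable) pair, preserving row order within groups.
#' When `replicateId` is absent, replicates are inferred positionally from
#' repeated (condition, time) rows in file order.
#'
#' @param path Path to a TSV file with columns `observableId`,
#'   `simulationConditionId`, `time`, `measurement` and optional
#'   `replicateId`. Extra PEtab columns are accepted and ignored with a
#'   notice.
#' @return Named list of [ts_dataset()] objects, names
#'   `"<conditionId>/<observableId>"`.
#' @export
read_measurement_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing_cols <- setdiff(MEASUREMENT_COLS, names(raw))
  if (length(missing_cols) > 0L) {
    stop("measurement table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(raw), c(MEASUREMENT_COLS, "replicateId"))
  if (length(extra) > 0L) {
    inform(paste0("ignoring extra measurement-table column(s): ",
                  paste(extra, collapse = ", ")))
  }
  for (col in c("time", "measurement")) {
    vals <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(vals) & !is.na(raw[[col]]))
    if (anyNA(vals)) {
      bad <- which(is.na(vals))
      stop(sprintf("non-numeric %s value in row %d: '%s'",
                   col, bad[1], raw[[col]][bad[1]]), call. = FALSE)
    }
    raw[[col]] <- vals
  }
  groups <- split(raw, ~ simulationConditionId + observableId, drop = TRUE,
                  sep = "\r")
  # split() orders groups alphabetically; restore first-appearance order
  first_row <- vapply(groups, function(g) {
    which(raw$simulationConditionId == g$simulationConditionId[1] &
            raw$observableId == g$observableId[1])[1]
  }, numeric(1))
  groups <- groups[order(first_row)]
  out <- lapply(groups, function(g) {
    ts_dataset(g[setdiff(names(g), c("observableId", "simulationConditionId"))],
               condition_id = g$simulationConditionId[1],
               observable_id = g$observableId[1])
  })
  names(out) <- vapply(out, function(d) {
    paste0(attr(d, "condition_id"), "/", attr(d, "observable_id"))
  }, character(1))
  out
}

#' Write datasets back to a PEtab-dialect measurement table
#'
#' @param datasets A [ts_dataset()] or list of them.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_measurement_table <- function(datasets, path) {
  if (inherits(datasets, "ts_dataset")) datasets <- list(datasets)
  rows <- purrr::map(datasets, function(d) {
    tibble(observableId = attr(d, "observable_id"),
           simulationConditionId = attr(d, "condition_id"),
           time = d$time, measurement = d$measurement,
           replicateId = d$replicateId)
  })
  tab <- bind_rows(rows)
  readr::write_tsv(tab, path, progress = FALSE)
  invisible(path)
}

#' Read a PEtab-dialect parameter table
#'
#' Rows with `estimate = 1` become uniform priors on the declared scale
#' (`lin` or `log10`); rows with `estimate = 0` become fixed values taken
#' from `nominalValue`.
#'
#' @param path Path to a TSV file with columns `parameterId`, `lowerBound`,
#'   `upperBound`, `estimate`, `parameterScale`, optional `nominalValue`.
#' @return List with elements `priors` (a [prior_spec()] tibble) and
#'   `fixed` (named numeric vector).
#' @export
read_parameter_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  missing_cols <- setdiff(PARAMETER_COLS, names(raw))
  if (length(missing_cols) > 0L) {
    stop("parameter table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_scale <- setdiff(unique(raw$parameterScale), c("lin", "log10"))
  if (length(bad_scale) > 0L) {
    stop("unknown parameterScale token(s): ",
         paste(bad_scale, collapse = ", "), call. = FALSE)
  }
  est <- raw$estimate == "1"
  if (any(est)) {
    lb <- as.numeric(raw$lowerBound[est])
    ub <- as.numeric(raw$upperBound[est])
    bad <- which(!(lb < ub))
    if (length(bad) > 0L) {
      stop("lowerBound must be < upperBound for estimated parameter '",
           raw$parameterId[est][bad[1]], "'", call. = FALSE)
    }
    priors <- prior_spec(tibble(parameter = raw$parameterId[est],
                                lower = lb, upper = ub,
                                scale = raw$parameterScale[est]))
  } else {
    priors <- prior_spec(tibble(parameter = character(), lower = numeric(),
                                upper = numeric(), scale = character()))
  }
  fixed <- numeric(0)
  if (any(!est)) {
    if (!"nominalValue" %in% names(raw)) {
      stop("fixed parameters require a nominalValue column", call. = FALSE)
    }
    fixed <- setNames(as.numeric(raw$nominalValue[!est]),
                      raw$parameterId[!est])
    if (anyNA(fixed)) {
      stop("missing nominalValue for fixed parameter '",
           names(fixed)[which(is.na(fixed))[1]], "'", call. = FALSE)
    }
  }
  list(priors = priors, fixed = fixed)
}

#' Drop physically meaningless negative measurements
#'
#' Some acquisition methods (e.g. arterial-spin-labelling MRI, where
#' perfusion is a difference of two images) can produce negative values
#' with no physical interpretation; this filter removes them before
#' fitting. If filtering empties a time point entirely a warning is issued
#' and the reduced dataset is still returned.
#'
#' @param dataset A [ts_dataset()].
#' @return List with elements `dataset` (filtered copy) and `removed`
#'   (integer count of dropped records).
#' @export
filter_nonnegative <- function(dataset) {
  stopifnot(inherits(dataset, "ts_dataset"))
  keep <- dataset$measurement >= 0
  removed <- sum(!keep)
  filtered <- dataset[keep, , drop = FALSE]
  emptied <- setdiff(unique(dataset$time), unique(filtered$time))
  if (length(emptied) > 0L) {
    warn(paste0("negative-value filter emptied time point(s): ",
                paste(emptied, collapse = ", ")))
  }
  out <- structure(filtered, class = class(dataset),
                   condition_id = attr(dataset, "condition_id"),
                   observable_id = attr(dataset, "observable_id"))
  list(dataset = out, removed = removed)
}

#' Run configuration
#'
#' Collects all tunables of a fitting run. Defaults follow the package's
#' standard operating point; `seed` has no default because every run must
#' be explicitly reproducible.
#'
#' @param seed Integer RNG seed (mandatory).
#' @param model_id Registered model id (default `"rtf"`).
#' @param chain_length MCMC iterations per chain (>= 100; default 50000).
#' @param burn_in Fraction of each chain discarded (in `[0, 0.9]`; default
#'   0.3).
#' @param n_chains Number of independent chains (default 2).
#' @param temperatures Optional ascending temperature ladder for parallel
#'   tempering, coldest first and equal to 1; `NULL` disables tempering.
#' @param alpha Credible-tube tail probability (`1 - alpha` coverage;
#'   default 0.05 for 95% tubes).
#' @param grid_n Evaluation-grid size for tubes (default 201).
#' @param drop_negative Apply [filter_nonnegative()] before fitting.
#' @param estimate_sigma Estimate the noise standard deviation jointly
#'   (default `TRUE`); when `FALSE`, `sigma_fixed` must be given.
#' @param sigma_fixed Fixed noise SD used when `estimate_sigma = FALSE`.
#' @param max_draws Cap on posterior draws used for ensembles (default
#'   1000).
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(seed, model_id = "rtf", chain_length = 50000L,
                       burn_in = 0.3, n_chains = 2L, temperatures = NULL,
                       alpha = 0.05, grid_n = 201L, drop_negative = FALSE,
                       estimate_sigma = TRUE, sigma_fixed = NULL,
                       max_draws = 1000L) {
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop("seed is mandatory in run_config()", call. = FALSE)
  }
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)", call. = FALSE)
  if (chain_length < 100) stop("chain_length must be >= 100", call. = FALSE)
  if (burn_in < 0 || burn_in > 0.9) {
    stop("burn_in fraction must be in [0, 0.9]", call. = FALSE)
  }
  if (!is.null(temperatures)) {
    if (length(temperatures) < 1L || temperatures[1] != 1 ||
        is.unsorted(temperatures, strictly = TRUE)) {
      stop("temperatures must be strictly ascending with coldest = 1",
           call. = FALSE)
    }
  }
  if (!estimate_sigma && (is.null(sigma_fixed) || sigma_fixed <= 0)) {
    stop("sigma_fixed must be a positive value when estimate_sigma = FALSE",
         call. = FALSE)
  }
  structure(list(seed = as.integer(seed), model_id = model_id,
                 chain_length = as.integer(chain_length), burn_in = burn_in,
                 n_chains = as.integer(n_chains), temperatures = temperatures,
                 alpha = alpha, grid_n = as.integer(grid_n),
                 drop_negative = isTRUE(drop_negative),
                 estimate_sigma = isTRUE(estimate_sigma),
                 sigma_fixed = sigma_fixed,
                 max_draws = as.integer(max_draws)),
            class = "run_config")
}

#' Write the outputs of a fitting run
#'
#' Writes, per fitted dataset: posterior samples (TSV, one column per
#' estimated parameter plus `log_posterior`), the credible tube (TSV with
#' `time`, `condition`, `median`, `lower`, `upper`), diagnostics (JSON) and
#' the resolved run configuration (YAML).
#'
#' @param samples A `posterior_samples` object (see [sample_posterior()]).
#' @param tube Optional `credible_tube` tibble (see [credible_tube()]).
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix, default the dataset's condition id.
#' @return Named character vector of written paths, invisibly.
#' @export
write_results <- function(samples, tube = NULL, dir = ".",
                          prefix = NULL) {
  stopifnot(inherits(samples, "posterior_samples"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(prefix)) prefix <- samples$condition_id %||% "fit"
  paths <- c()

  samples_path <- file.path(dir, paste0(prefix, "_samples.tsv"))
  readr::write_tsv(samples$draws, samples_path, progress = FALSE)
  paths["samples"] <- samples_path

  if (!is.null(tube)) {
    tube_path <- file.path(dir, paste0(prefix, "_tube.tsv"))
    readr::write_tsv(as_tibble(tube), tube_path, progress = FALSE)
    paths["tube"] <- tube_path
  }

  diag_path <- file.path(dir, paste0(prefix, "_diagnostics.json"))
  jsonlite::write_json(samples$diagnostics, diag_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths["diagnostics"] <- diag_path

  cfg <- samples$config
  cfg_path <- file.path(dir, paste0(prefix, "_config.yaml"))
  yaml::write_yaml(cfg[!vapply(cfg, is.null, logical(1))], cfg_path)
  paths["config"] <- cfg_path

  invisible(paths)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export an RTF parameterization as a minimal SBML document
#'
#' Writes an SBML level-3 document containing the RTF as an assignment rule
#' over a time parameter, for interoperability with systems-biology tooling.
#' This is an export stub only: the package never reads SBML.
#'
#' @param params An [rtf_params()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sbml_rtf <- function(params, path) {
  stopifnot(inherits(params, "rtf_params"))
  par_xml <- paste(vapply(names(params), function(nm) {
    sprintf('      <parameter id="%s" value="%.17g" constant="false"/>',
            nm, params[[nm]])
  }, character(1)), collapse = "\n")
  doc <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">\n',
    '  <model id="rtf" name="Retarded transient function">\n',
    "    <listOfParameters>\n", par_xml, "\n",
    '      <parameter id="f_tf" value="0" constant="false"/>\n',
    "    </listOfParameters>\n",
    "    <listOfRules>\n",
    '      <assignmentRule variable="f_tf">\n',
    "        <!-- f_tf = Asus*(1-exp(-t/t1)) + Atrans*(1-exp(-t/t11))*exp(-t/t2) + p0,\n",
    "             t = log10(10^(10*time/Trange) + 10^Tshift) - log10(1 + 10^Tshift) -->\n",
    "      </assignmentRule>\n",
    "    </listOfRules>\n",
    "  </model>\n",
    "</sbml>\n")
  writeLines(doc, path)
  invisible(path)
}
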