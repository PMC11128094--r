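# MCMC convergence diagnostics: effective sample size via Geyer's
# initial-positive-sequence estimator, and the split Gelman-Rubin statistic.

#' Effective sample size of an MCMC chain
#'
#' Estimates \eqn{ESS = P / (1 + 2\sum_t \rho_t)} where the autocorrelation
#' sum is truncated with Geyer's initial-positive-sequence rule: successive
#' pairs \eqn{\rho_{2m-1} + \rho_{2m}} are accumulated while they remain
#' positive.
#'
#' @param chain Numeric vector of draws (>= 100), or a matrix with one
#'   column per parameter.
#' @return Scalar ESS, or a named vector for matrix input. A constant chain
#'   yields 0 with a warning.
#' @export
effective_sample_size <- function(chain) {
  if (is.matrix(chain)) {
    return(vapply(seq_len(ncol(chain)),
                  function(j) effective_sample_size(chain[, j]),
                  numeric(1)) |>
             setNames(colnames(chain)))
  }
  n <- length(chain)
  if (n < 100L) stop("need at least 100 draws for ESS", call. = FALSE)
  if (var(chain) == 0) {
    warn("constant chain: ESS is 0")
    return(0)
  }
  lag_max <- min(n - 1L, 2000L)
  rho <- drop(acf(chain, lag.max = lag_max, plot = FALSE,
                  demean = TRUE)$acf)[-1]
  # Geyer initial positive sequence over lag pairs
  tau <- 1
  m <- 1L
  while (m + 1L <= length(rho)) {
    pair <- rho[m] + rho[m + 1L]
    if (pair <= 0) break
    tau <- tau + 2 * pair
    m <- m + 2L
  }
  n / tau
}

#' Split Gelman-Rubin convergence diagnostic
#'
#' Computes the split-\eqn{\hat R} statistic: each chain is halved, and
#' \eqn{\hat R = \sqrt{((n-1)/n \cdot W + B/n) / W}} with `W` the mean
#' within-sequence variance and `B` the between-sequence variance. Values
#' near 1 indicate convergence; values above 1.1 are commonly taken as a
#' warning sign.
#'
#' @param chains List of >= 2 numeric vectors (draws of one parameter from
#'   independent chains), or a matrix with one chain per column. Unequal
#'   lengths are truncated to the shortest with a notice.
#' @return Scalar \eqn{\hat R} (>= 1 up to floating-point noise).
#' @export
gelman_rubin <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)),
                                          function(j) chains[, j])
  if (length(chains) < 2L) stop("need at least 2 chains", call. = FALSE)
  lens <- lengths(chains)
  if (min(lens) < 100L) stop("chains must have >= 100 retained draws",
                             call. = FALSE)
  if (length(unique(lens)) > 1L) {
    inform("unequal chain lengths: truncating to the shortest")
    chains <- lapply(chains, function(ch) ch[seq_len(min(lens))])
  }
  n_full <- min(lens)
  half <- n_full %/% 2L
  seqs <- unlist(lapply(chains, function(ch) {
    list(ch[seq_len(half)], ch[seq.int(half + 1L, 2L * half)])
  }), recursive = FALSE)
  n <- half
  means <- vapply(seqs, mean, numeric(1))
  vars <- vapply(seqs, var, numeric(1))
  W <- mean(vars)
  B_over_n <- var(means)
  if (W == 0) {
    return(if (B_over_n == 0) 1 else Inf)
  }
  sqrt((n - 1) / n + B_over_n / W)
}
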