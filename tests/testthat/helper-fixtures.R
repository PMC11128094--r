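# Shared fixtures, built in code at test time.

# canonical well-identified RTF truth: fast transient + slower sustained
# rise, resolvable on a 10-point grid densified at early times
fixture_theta <- function() {
  rtf_params(Asus = 1, t1 = 3, Atrans = 1.5, t11 = 0.5, t2 = 1.5,
             Tshift = -2, p0 = 0.5, Trange = 10)
}

fixture_times <- function() c(0, 0.3, 0.7, 1.2, 2, 3, 4.5, 6, 8, 10)

# small replicate dataset for fast fits
make_dataset <- function(seed = 42, n_replicates = 4, sigma = 0.05,
                         theta = fixture_theta(), times = fixture_times()) {
  spec <- synthetic_spec(theta, times = times, n_replicates = n_replicates,
                         sigma = sigma, seed = seed)
  generate_dataset(spec)
}

# random dataset with arbitrary content for likelihood-oracle sweeps
random_dataset <- function() {
  tp <- sort(runif(sample(3:8, 1), 0, 10))
  rows <- do.call(rbind, lapply(tp, function(tk) {
    nk <- sample(1:6, 1)
    data.frame(time = rep(tk, nk), measurement = rnorm(nk, 0, 2))
  }))
  ts_dataset(rows)
}

# priors/fixed pair for RTF fits of a dataset (Tshift/Trange fixed)
rtf_setup <- function(dataset, trange = 10) {
  list(priors = default_priors(dataset),
       fixed = c(Tshift = -2, Trange = trange))
}

# independent naive likelihood oracle: per-record loop, no vectorization
naive_loglik <- function(dataset, params, sigma, model = get_model("rtf")) {
  total <- 0
  for (i in seq_len(nrow(dataset))) {
    s_i <- model$evaluator(dataset$time[i], params)
    total <- total - log(sigma * sqrt(2 * pi)) -
      (s_i - dataset$measurement[i])^2 / (2 * sigma^2)
  }
  total
}

# independent percentile oracle: full sort + manual linear interpolation
# between adjacent order statistics ((1-h)-weighted, the type-7 convention)
sort_percentile <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  idx <- (n - 1) * p + 1
  lo <- floor(idx)
  hi <- ceiling(idx)
  h <- idx - lo
  (1 - h) * xs[lo] + h * xs[hi]
}
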