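# Shared fixtures, memoised so expensive simulations run once per session.

.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

fx_cubes <- function() memo("cubes", build_stimulus_set())
fx_pairs <- function() memo("pairs", enumerate_pairs(fx_cubes()))

# small noisy cohort generated from the reference descriptive coefficients
fx_small_study <- function() {
  memo("small_study", {
    sim <- simulate_study(n_participants = 6, seed = 202)
    prep <- suppressWarnings(preprocess_estimates(sim$estimates))
    list(sim = sim, prep = prep, recs = retained_estimates(prep))
  })
}

# noise-free, unit-scale cohort (exact-recovery limit)
fx_clean_study <- function(n = 3, model = generating_model()) {
  base <- observer_profile(noise_sd = 0, outlier_rate = 0)
  sim <- simulate_study(n_participants = n, seed = 300, model = model,
                        base = base, scale_spread = 0)
  prep <- preprocess_estimates(sim$estimates)
  list(sim = sim, recs = retained_estimates(prep))
}

# true (logV, logW) ratios of the default pair set
fx_pair_space <- function() {
  memo("pair_space", {
    cubes <- fx_cubes()
    lk <- cubes[, c("cube_id", "volume", "weight")]
    d <- merge(merge(fx_pairs(),
                     stats::setNames(lk, c("cube_a", "v1", "w1")), by = "cube_a"),
               stats::setNames(lk, c("cube_b", "v2", "w2")), by = "cube_b")
    tibble::tibble(pair_id = d$pair_id,
                   logV_ratio = log(d$v1 / d$v2),
                   logW_ratio = log(d$w1 / d$w2))
  })
}

# independent two-pass R^2 oracle
naive_r2 <- function(obs, pred) {
  ssr <- 0; sst <- 0; m <- sum(obs) / length(obs)
  for (i in seq_along(obs)) {
    ssr <- ssr + (obs[i] - pred[i])^2
    sst <- sst + (obs[i] - m)^2
  }
  1 - ssr / sst
}

# a ridge-shaped 3-component ratio prior used in self-consistency tests
fx_ratio_prior <- function() {
  ratio_prior(
    tibble::tibble(sd_logV = c(0.3, 0.8, 2), sd_logW = c(0.35, 0.9, 2),
                   correlation = c(0.95, 0.9, 0.6), weight = c(0.5, 0.3, 0.2)),
    C_b = 0.002
  )
}
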