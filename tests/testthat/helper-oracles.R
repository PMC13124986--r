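# Shared fixtures and independent oracles.

# One medium simulated bundle reused across files (cached per session).
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_reports = 4000, seed = 101, duplicate_rate = 0.15,
                        planted_rr = data.frame(drug = 1, event = c(28, 5),
                                                rr = c(8, 6)))
      cache <<- list(cfg = cfg, sim = simulate_reports(cfg))
    }
    cache
  }
})

sim_to_dir <- function(sim) {
  d <- withr::local_tempdir(.local_envir = parent.frame())
  write_sim_bundle(sim, d)
  d
}

# Monte-Carlo oracle for the BCPNN credible bound: sample the three
# independent Beta posteriors (uniform priors) and take the empirical
# quantile of ic = log2(p_xy / (p_x p_y)).
bcpnn_mc_quantile <- function(a, b, c, d, q = 0.025, n = 1e5, seed = 1) {
  set.seed(seed)
  N <- a + b + c + d
  ic <- log2(rbeta(n, a + 1, N - a + 1)) -
    log2(rbeta(n, a + b + 1, N - (a + b) + 1)) -
    log2(rbeta(n, a + c + 1, N - (a + c) + 1))
  unname(quantile(ic, q))
}

# Numerical-integration oracle for the posterior geometric mean of the
# gamma-mixture posterior (independent of the digamma closed form).
ebgm_integration_oracle <- function(a, E, prior) {
  l1 <- dnbinom(a, size = prior$alpha1,
                prob = prior$beta1 / (prior$beta1 + E), log = TRUE)
  l2 <- dnbinom(a, size = prior$alpha2,
                prob = prior$beta2 / (prior$beta2 + E), log = TRUE)
  m <- max(l1, l2)
  w1 <- prior$P * exp(l1 - m); w2 <- (1 - prior$P) * exp(l2 - m)
  s <- w1 + w2; w1 <- w1 / s; w2 <- w2 / s
  # integrate each gamma component over its own quantile-bounded support
  # (a near-point-mass component defeats quadrature on (0, Inf))
  comp <- function(shape, rate) {
    lo <- qgamma(1e-13, shape, rate)
    hi <- qgamma(1 - 1e-13, shape, rate)
    integrate(function(x) log(x) * dgamma(x, shape, rate), lo, hi,
              rel.tol = 1e-11, subdivisions = 1000L)$value
  }
  exp(w1 * comp(prior$alpha1 + a, prior$beta1 + E) +
        w2 * comp(prior$alpha2 + a, prior$beta2 + E))
}

# Hand-built prior object for controlled posterior tests.
make_prior <- function(alpha1, beta1, alpha2, beta2, P) {
  structure(list(alpha1 = alpha1, beta1 = beta1, alpha2 = alpha2,
                 beta2 = beta2, P = P, loglik = NA_real_, n_cells = 0L,
                 converged = TRUE),
            class = "mgps_prior")
}

# Minimal assembled-records structure for temporal tests.
make_records <- function(event_dates, start_dates, drug = "Vortioxetine",
                         pts = NULL) {
  n <- length(event_dates)
  ids <- seq_len(n)
  list(
    reports = data.table::data.table(
      primaryid = ids, caseid = ids,
      fda_date = as.Date("2024-06-30"),
      event_date = as.Date(event_dates, format = "%Y%m%d"),
      sex = NA_character_, age_years = NA_real_, weight_kg = NA_real_,
      country = NA_character_, reporter = NA_character_,
      outcomes = NA_character_),
    drugs = data.table::data.table(
      primaryid = ids, drug_name_raw = drug, role = "PS",
      therapy_start_date = as.Date(start_dates, format = "%Y%m%d")),
    reactions = data.table::data.table(
      primaryid = rep(ids, each = 1L),
      pt = if (is.null(pts)) rep("Nausea", n) else pts))
}
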