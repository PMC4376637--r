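# Shared fixtures, built once per test run. All fixtures are generated in
# code under fixed seeds; nothing is read from disk.

fixture_env <- new.env()

# Discriminative 2x100 stimulus set shared across fitting tests.
shared_stimuli <- function(cost_type = "effort") {
  key <- paste0("stim_", cost_type)
  if (is.null(fixture_env[[key]])) {
    fixture_env[[key]] <- design_exp1_stimuli(100, 2, cost_type = cost_type,
                                              seed = 20260909)
  }
  fixture_env[[key]]
}

# One-pair stimulus set repeated n times (for calibration checks).
repeated_pair <- function(n, m1, c1, m2, c2, cost_type = "effort") {
  structure(list(
    pairs = data.frame(block = rep(1L, n), trial = seq_len(n),
                       m1 = rep(m1, n), c1 = rep(c1, n),
                       m2 = rep(m2, n), c2 = rep(c2, n)),
    cost_type = cost_type), class = "stimulus_set")
}

# A minimal posterior_fit-shaped object for scoring functions that only
# need the point estimates.
point_fit <- function(model, params, beta, alpha = 1) {
  structure(list(model = model_spec(model),
                 params = c(as.list(params), list(beta = beta)),
                 alpha = alpha),
            class = "posterior_fit")
}

# Drive one PEST staircase against a psychometric agent: accept with
# probability plogis(slope * (offered - m_star)); slope = Inf gives the
# deterministic threshold chooser. Returns the offer sequence and states.
run_staircase <- function(m_star, slope, n_choices, init_mag, init_step,
                          jitter, seed) {
  st <- pest_init(level = 0.5, init_mag, init_step, jitter, seed = seed)
  offers <- numeric(n_choices)
  reinit_at <- integer(0)
  set.seed(seed + 1)
  for (t in seq_len(n_choices)) {
    offers[t] <- st$magnitude
    acc <- if (is.infinite(slope)) st$magnitude >= m_star else
      runif(1) < plogis(slope * (st$magnitude - m_star))
    before <- st$reinits
    st <- pest_update(st, acc)
    if (st$reinits > before) reinit_at <- c(reinit_at, t)
  }
  list(offers = offers, reinits = reinit_at, state = st)
}

# Brute-force indifference magnitude of a discounting agent at effort E:
# solves V(m, E) = V(D, 0) with uniroot (independent of the staircase and
# psychometric machinery).
analytic_indifference <- function(model, params, D, E, upper = 1e5) {
  target <- subjective_value(model, params, D, 0)
  f <- function(m) subjective_value(model, params, m, E) - target
  stats::uniroot(f, c(0, upper), tol = 1e-8)$root
}
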