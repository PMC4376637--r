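#' Define a synthetic choice agent
#'
#' An agent is a generating discounting model with fixed native parameters
#' and a softmax temperature; simulated choices are Bernoulli draws from the
#' softmax over the agent's subjective values.
#'
#' @param model model name or `model_spec`.
#' @param params named list: `k` (and `p` where applicable), native space.
#' @param beta softmax temperature (> 0, or 0 for a pure coin-flipper).
#' @param alpha utility exponent (default 1).
#' @param id agent/subject identifier.
#' @return object of class `agent`.
#' @export
agent <- function(model, params, beta, alpha = 1, id = "a1") {
  if (is.character(model)) model <- model_spec(model)
  if (beta < 0) stop("beta must be non-negative")
  structure(list(model = model, params = as.list(params), beta = beta,
                 alpha = alpha, id = id),
            class = "agent")
}

# Deterministic (beta -> Inf) preference of an agent: 1, 2, or 0 for a tie.
#' @keywords internal
agent_preference <- function(ag, m1, c1, m2, c2) {
  V1 <- subjective_value(ag$model, ag$params, m1, c1, alpha = ag$alpha)
  V2 <- subjective_value(ag$model, ag$params, m2, c2, alpha = ag$alpha)
  ifelse(V1 > V2, 1L, ifelse(V2 > V1, 2L, 0L))
}

#' Default agent grids for stimulus design
#'
#' Nine agents per model family, spanning shallow to steep discounting:
#' hyperbolic `k` log-spaced on `[0.5, 30]`, linear `k` log-spaced on
#' `[5, 75]`, and the concave family represented by the sigmoidal model
#' (`k` log-spaced on `[3, 30]` crossed with turning points
#' `p in {0.3, 0.5, 0.7}`).
#'
#' @return named list of lists of [agent()]s, one list per family
#'   (`hyperbolic`, `linear`, `concave`).
#' @export
default_agent_grids <- function() {
  logspace <- function(a, b, n) exp(seq(log(a), log(b), length.out = n))
  hyp <- lapply(logspace(0.5, 30, 9), function(k) {
    agent("hyperbolic", list(k = k), beta = Inf)
  })
  lin <- lapply(logspace(5, 75, 9), function(k) {
    agent("linear", list(k = k), beta = Inf)
  })
  sig_par <- expand.grid(k = logspace(3, 30, 3), p = c(0.3, 0.5, 0.7))
  sig <- lapply(seq_len(nrow(sig_par)), function(i) {
    agent("sigmoidal", list(k = sig_par$k[i], p = sig_par$p[i]), beta = Inf)
  })
  list(hyperbolic = hyp, linear = lin, concave = sig)
}

# TRUE if the candidate pair discriminates between model families for at
# least `min_agents` agent indices: for agent index j, the deterministic
# preferences of the three families' j-th agents must not all coincide
# (ties never discriminate).
#' @keywords internal
is_discriminative <- function(m1, c1, m2, c2, agent_grids, min_agents = 2) {
  n_agents <- length(agent_grids[[1]])
  count <- 0L
  for (j in seq_len(n_agents)) {
    prefs <- vapply(agent_grids, function(fam) {
      agent_preference(fam[[j]], m1, c1, m2, c2)
    }, integer(1))
    prefs <- prefs[prefs != 0L]
    if (length(prefs) >= 2 && length(unique(prefs)) >= 2) count <- count + 1L
    if (count >= min_agents) return(TRUE)
  }
  FALSE
}

#' Design a discriminative Experiment-1-style stimulus set
#'
#' Builds `n_blocks` blocks of `n_per_block` two-option choice pairs
#' (integer magnitudes 0-75 display units, costs on a 0.05 grid in
#' `[0, 1]`) by rejection sampling under the design rules: every retained
#' pair must be discriminative (for at least two agent indices, at least two
#' of the hyperbolic / linear / concave families deterministically prefer
#' different options); trivial pairs (cost difference < 0.1 with magnitude
#' difference > 40) are excluded; pairs where both costs exceed 0.4 are
#' capped at 15% of the set; no exact duplicates.
#'
#' @param n_per_block pairs per block (default 100).
#' @param n_blocks number of blocks (default 2).
#' @param agent_grids per-family agent lists, see [default_agent_grids()].
#' @param cost_type `"effort"` or `"delay"` tag carried by the set.
#' @param seed RNG seed.
#' @param max_tries sampling attempts before giving up.
#' @return object of class `stimulus_set`: data.frame `pairs` with columns
#'   `block`, `trial`, `m1`, `c1`, `m2`, `c2`, plus the cost type.
#' @export
design_exp1_stimuli <- function(n_per_block = 100, n_blocks = 2,
                                agent_grids = default_agent_grids(),
                                cost_type = c("effort", "delay"),
                                seed = 1, max_tries = NULL) {
  cost_type <- match.arg(cost_type)
  n_total <- n_per_block * n_blocks
  max_tries <- max_tries %||% (500 * n_total)
  high_cost_cap <- floor(0.15 * n_total)
  with_seed(seed, {
    kept <- vector("list", n_total)
    n_kept <- 0L; n_high <- 0L
    reject <- c(trivial = 0L, high_cost_cap = 0L, not_discriminative = 0L,
                duplicate = 0L)
    seen <- new.env(hash = TRUE)
    tries <- 0L
    while (n_kept < n_total && tries < max_tries) {
      tries <- tries + 1L
      m1 <- sample(0:75, 1); m2 <- sample(0:75, 1)
      c1 <- sample(seq(0, 1, by = 0.05), 1); c2 <- sample(seq(0, 1, by = 0.05), 1)
      if (abs(c1 - c2) < 0.1 && abs(m1 - m2) > 40) {
        reject["trivial"] <- reject["trivial"] + 1L; next
      }
      high <- (c1 > 0.4 && c2 > 0.4)
      if (high && n_high >= high_cost_cap) {
        reject["high_cost_cap"] <- reject["high_cost_cap"] + 1L; next
      }
      key <- paste(m1, c1, m2, c2)
      if (!is.null(seen[[key]])) {
        reject["duplicate"] <- reject["duplicate"] + 1L; next
      }
      if (!is_discriminative(m1, c1, m2, c2, agent_grids)) {
        reject["not_discriminative"] <- reject["not_discriminative"] + 1L; next
      }
      n_kept <- n_kept + 1L
      if (high) n_high <- n_high + 1L
      seen[[key]] <- TRUE
      kept[[n_kept]] <- c(m1 = m1, c1 = c1, m2 = m2, c2 = c2)
    }
    if (n_kept < n_total) {
      binding <- names(which.max(reject))
      stop(sprintf(
        "could not find %d discriminative pairs in %d attempts; binding constraint: %s (rejections: %s)",
        n_total, tries, binding,
        paste(sprintf("%s=%d", names(reject), reject), collapse = ", ")))
    }
    pairs <- as.data.frame(do.call(rbind, kept))
    pairs <- cbind(block = rep(seq_len(n_blocks), each = n_per_block),
                   trial = rep(seq_len(n_per_block), n_blocks),
                   pairs)
    structure(list(pairs = pairs, cost_type = cost_type),
              class = "stimulus_set")
  })
}

#' @export
print.stimulus_set <- function(x, ...) {
  cat(sprintf("<stimulus_set> %s: %d pairs in %d block(s)\n",
              x$cost_type, nrow(x$pairs), length(unique(x$pairs$block))))
  invisible(x)
}

#' Simulate a cohort of agents on a shared stimulus set
#'
#' Every agent sees the identical stimulus set (as in a fixed-design study);
#' per trial, option 1 is chosen with probability
#' `choice_probability(beta, V1, V2)`. Realized-effort flags are assigned to
#' an exact fraction of trials without replacement and do not influence the
#' simulated choices.
#'
#' @param agents list of [agent()]s.
#' @param stimuli a `stimulus_set`.
#' @param seed RNG seed (one stream for the whole cohort; identical inputs
#'   give byte-identical tables).
#' @param realized_fraction fraction of trials flagged realized
#'   (default 0.3, the Experiment-1 effort convention).
#' @return list of [choice_dataset()]s, one per agent.
#' @export
simulate_cohort <- function(agents, stimuli, seed = 1,
                            realized_fraction = 0.3) {
  if (nrow(stimuli$pairs) == 0) stop("empty stimulus set")
  with_seed(seed, {
    lapply(seq_along(agents), function(i) {
      ag <- agents[[i]]
      pr <- stimuli$pairs
      V1 <- subjective_value(ag$model, ag$params, pr$m1, pr$c1, alpha = ag$alpha)
      V2 <- subjective_value(ag$model, ag$params, pr$m2, pr$c2, alpha = ag$alpha)
      P1 <- if (is.infinite(ag$beta)) {
        ifelse(V1 > V2, 1, ifelse(V2 > V1, 0, 0.5))
      } else {
        choice_probability(ag$beta, V1, V2)
      }
      chosen <- ifelse(stats::runif(nrow(pr)) < P1, 1L, 2L)
      n_real <- round(realized_fraction * nrow(pr))
      realized <- logical(nrow(pr))
      realized[sample(nrow(pr), n_real)] <- TRUE
      trials <- data.frame(block = pr$block, trial = pr$trial,
                           m1 = pr$m1, c1 = pr$c1, m2 = pr$m2, c2 = pr$c2,
                           chosen = chosen, realized = realized,
                           is_default1 = FALSE)
      choice_dataset(trials, subject = ag$id, cost_type = stimuli$cost_type)
    })
  })
}
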