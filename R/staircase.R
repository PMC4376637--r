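#' Initialize a PEST staircase for one effort level
#'
#' Parameter Estimation by Sequential Testing: the offered magnitude of the
#' effortful option is titrated toward indifference with the no-effort
#' default. The staircase starts at `init_mag` jittered by `+/- jitter`
#' (uniform), with step size `init_step`.
#'
#' @param level effort level of this staircase (normalized cost).
#' @param init_mag initial offered magnitude (display units; e.g. 60 for
#'   the 40p block, 260 for the 200p block).
#' @param init_step initial step size (8 and 24 for the two blocks).
#' @param jitter re/initialization jitter half-width (6 and 20).
#' @param seed seed for the (re)initialization jitter; each staircase owns
#'   its own deterministic jitter stream.
#' @return object of class `staircase_state`: `level`, `magnitude`, `step`,
#'   `init_mag`, `init_step`, `jitter`, `dir` (last step direction, 0 before
#'   the first update), `run_length`, `reinits`, `history` (signed steps).
#' @export
pest_init <- function(level, init_mag, init_step, jitter = 0, seed = 1) {
  mag <- with_seed(seed, init_mag + stats::runif(1, -jitter, jitter))
  structure(list(level = level, magnitude = max(0, mag), step = init_step,
                 init_mag = init_mag, init_step = init_step,
                 jitter = jitter, seed = seed,
                 dir = 0L, run_length = 0L, reinits = 0L,
                 history = numeric(0)),
            class = "staircase_state")
}

#' Advance a PEST staircase by one choice
#'
#' Rejecting the effortful option raises the next offer by the current step;
#' accepting lowers it. PEST rules: the step halves on a direction reversal
#' and doubles after the third consecutive same-direction step (capped at
#' the initial step). When a halving brings the step to a fourth of its
#' initial size or less, the staircase re-initializes: the magnitude is
#' re-jittered around the initial magnitude, the step is restored, and the
#' run history restarts.
#'
#' @param state a `staircase_state`.
#' @param accepted TRUE if the effortful (variable) option was chosen.
#' @return the updated `staircase_state`.
#' @export
pest_update <- function(state, accepted) {
  dir <- if (accepted) -1L else 1L
  if (state$dir == 0L) {
    state$run_length <- 1L
  } else if (dir == state$dir) {
    state$run_length <- state$run_length + 1L
    if (state$run_length > 3L) {
      state$step <- min(state$step * 2, state$init_step)
    }
  } else {
    state$step <- state$step / 2
    state$run_length <- 1L
    if (state$step <= state$init_step / 4 + 1e-12) {
      # Re-initialize: fresh jittered magnitude, full step, clean history.
      state$reinits <- state$reinits + 1L
      mag <- with_seed(state$seed + 7919L * state$reinits,
                       state$init_mag + stats::runif(1, -state$jitter, state$jitter))
      state$magnitude <- max(0, mag)
      state$step <- state$init_step
      state$dir <- 0L
      state$run_length <- 0L
      state$history <- c(state$history, NA_real_)
      return(state)
    }
  }
  state$dir <- dir
  state$magnitude <- max(0, state$magnitude + dir * state$step)
  state$history <- c(state$history, dir * state$step)
  state
}

#' Default Experiment-2 session configuration
#'
#' Two blocks of 96 trials: a no-effort default option (40 then 200 display
#' units) against a variable effortful option whose magnitude is driven by
#' six interleaved PEST staircases, one per effort level, 16 choices per
#' level per block. Staircases start at 60 +/- 6 (block 1) and 260 +/- 20
#' (block 2) with initial steps 8 and 24; effort is realized on 15% of
#' trials. The effort levels default to `[0.15 0.25 0.4 0.55 0.75 1]`
#' (the study's figure convention; the alternative printed set
#' `[0.15 0.25 0.35 0.5 0.75 1]` can be configured instead).
#'
#' @return list of block configs plus `levels`, `n_per_level`,
#'   `realized_fraction`.
#' @export
exp2_config <- function() {
  list(
    levels = c(0.15, 0.25, 0.4, 0.55, 0.75, 1),
    n_per_level = 16,
    realized_fraction = 0.15,
    blocks = list(
      list(default = 40, init_mag = 60, init_step = 8, jitter = 6),
      list(default = 200, init_mag = 260, init_step = 24, jitter = 20)
    )
  )
}

#' Simulate an Experiment-2 staircase session for one agent
#'
#' Runs the interleaved PEST staircases against a softmax agent choosing
#' between the no-effort default `(D, 0)` and the offered effortful option
#' `(m, E)`. Level order is randomized within each block; the six staircases
#' never share state.
#'
#' @param ag an [agent()].
#' @param config see [exp2_config()].
#' @param seed RNG seed (choice noise, level order, jitters, realized flags).
#' @return list with `dataset` (a [choice_dataset()]; option 1 is the
#'   default, `is_default1 = TRUE`) and `traces`: per block, per level, the
#'   data.frame of offered magnitudes, acceptances, and step sizes.
#' @export
simulate_exp2_session <- function(ag, config = exp2_config(), seed = 1) {
  levels <- config$levels
  if (length(levels) != 6) stop("staircase config must specify six effort levels")
  n_per_level <- config$n_per_level
  with_seed(seed, {
    all_trials <- list()
    traces <- list()
    for (b in seq_along(config$blocks)) {
      bc <- config$blocks[[b]]
      states <- lapply(seq_along(levels), function(i) {
        pest_init(levels[i], bc$init_mag, bc$init_step, bc$jitter,
                  seed = sample.int(.Machine$integer.max %/% 2, 1))
      })
      order_lv <- sample(rep(seq_along(levels), n_per_level))
      n_block <- length(order_lv)
      rows <- vector("list", n_block)
      tr_rows <- lapply(seq_along(levels), function(i) list())
      for (t in seq_len(n_block)) {
        i <- order_lv[t]
        st <- states[[i]]
        m_off <- st$magnitude
        V_def <- subjective_value(ag$model, ag$params, bc$default, 0,
                                  alpha = ag$alpha)
        V_eff <- subjective_value(ag$model, ag$params, m_off, levels[i],
                                  alpha = ag$alpha)
        p_eff <- if (is.infinite(ag$beta)) {
          ifelse(V_eff > V_def, 1, ifelse(V_def > V_eff, 0, 0.5))
        } else {
          choice_probability(ag$beta, V_eff, V_def)
        }
        accepted <- stats::runif(1) < p_eff
        rows[[t]] <- data.frame(
          block = b, trial = t, m1 = bc$default, c1 = 0,
          m2 = m_off, c2 = levels[i],
          chosen = if (accepted) 2L else 1L, realized = FALSE,
          is_default1 = TRUE)
        tr_rows[[i]] <- c(tr_rows[[i]], list(data.frame(
          trial = t, offered = m_off, accepted = accepted, step = st$step)))
        states[[i]] <- pest_update(st, accepted)
      }
      block_trials <- do.call(rbind, rows)
      n_real <- round(config$realized_fraction * n_block)
      idx <- sample(n_block, n_real)
      block_trials$realized[idx] <- TRUE
      all_trials[[b]] <- block_trials
      traces[[b]] <- lapply(tr_rows, function(x) do.call(rbind, x))
      names(traces[[b]]) <- paste0("level_", levels)
    }
    ds <- choice_dataset(do.call(rbind, all_trials), subject = ag$id,
                         cost_type = "effort")
    list(dataset = ds, traces = traces)
  })
}

#' Fit psychometric indifference points per effort level
#'
#' For each effort level, pools all choices (across staircase
#' re-initializations) and fits the acceptance probability
#' `1 / (1 + exp(-b (x - x50)))` of the effortful option as a function of
#' its offered magnitude `x` by Bernoulli maximum likelihood. The
#' indifference point `x50` is where the curve crosses 0.5. Complete
#' separation (a threshold-deterministic chooser) is resolved by the
#' midpoint between the highest rejected and lowest accepted magnitude,
#' with the slope flagged unbounded. Levels with fewer than `min_choices`
#' choices or only one outcome are flagged unconverged.
#'
#' @param choices_by_level named list (one entry per effort level, names =
#'   levels) of data.frames with columns `offered` and `accepted`; the
#'   `traces` element of [simulate_exp2_session()] for one block works
#'   directly.
#' @param min_choices minimum choices per level (default 6).
#' @return object of class `indifference_curve`: data.frame with `level`,
#'   `x50`, `slope`, `n`, `flag` (`"ok"`, `"separated"`, `"unconverged"`).
#' @export
estimate_indifference_points <- function(choices_by_level, min_choices = 6) {
  lv_names <- names(choices_by_level)
  levels <- as.numeric(sub("^level_", "", lv_names))
  rows <- lapply(seq_along(choices_by_level), function(i) {
    ch <- choices_by_level[[i]]
    x <- ch$offered; y <- as.numeric(ch$accepted)
    out <- data.frame(level = levels[i], x50 = NA_real_, slope = NA_real_,
                      n = length(y), flag = "unconverged")
    if (length(y) < min_choices || length(unique(y)) < 2) return(out)
    hi_rej <- suppressWarnings(max(x[y == 0]))
    lo_acc <- suppressWarnings(min(x[y == 1]))
    if (hi_rej < lo_acc) {
      # complete separation: deterministic threshold between the two
      out$x50 <- (hi_rej + lo_acc) / 2
      out$slope <- Inf
      out$flag <- "separated"
      return(out)
    }
    fit <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
    b <- stats::coef(fit)
    if (!fit$converged || !all(is.finite(b)) || abs(b[2]) < 1e-12) return(out)
    out$x50 <- -b[1] / b[2]
    out$slope <- b[2]
    out$flag <- "ok"
    out
  })
  structure(do.call(rbind, rows), class = c("indifference_curve", "data.frame"))
}

#' Transform indifference points between representations
#'
#' `raw` returns the indifference magnitudes `x50(E)` themselves;
#' `multiplicative` returns `D / x50(E)` (the relative residual value of
#' the effortful reward, 1 = no devaluation); `additive` returns
#' `D - (x50(E) - D)` (the default magnitude minus the premium demanded,
#' which can go negative once `x50 > 2D`).
#'
#' @param curve an `indifference_curve` (or data.frame with `x50`).
#' @param mode `"raw"`, `"multiplicative"`, or `"additive"`.
#' @param default_magnitude the block's default (no-effort) magnitude `D`.
#' @return numeric vector of per-level values.
#' @export
transform_indifference <- function(curve,
                                   mode = c("raw", "multiplicative", "additive"),
                                   default_magnitude) {
  mode <- match.arg(mode)
  if (default_magnitude <= 0) stop("default magnitude must be positive")
  x50 <- curve$x50
  switch(mode,
    raw = x50,
    multiplicative = {
      if (any(x50 <= 0, na.rm = TRUE)) {
        stop("multiplicative representation undefined for x50 <= 0")
      }
      default_magnitude / x50
    },
    additive = default_magnitude - (x50 - default_magnitude)
  )
}

#' Classify an indifference-point profile as concave
#'
#' With multiplicative indifference values at six effort levels and the
#' implicit anchor (0, 1), draws the chord from (0, 1) to the sixth point
#' and counts how many of points 1-5 lie strictly above it. The profile is
#' concave when at least three do — small devaluation at low effort that
#' accelerates at high effort.
#'
#' @param values six multiplicative indifference values (levels 1-6).
#' @param levels the six effort levels (default [exp2_config()] levels).
#' @return list: `concave` (logical), `n_above` (count of points 1-5
#'   strictly above the chord).
#' @export
classify_concavity <- function(values, levels = exp2_config()$levels) {
  if (length(values) != 6 || length(levels) != 6) {
    stop("need six per-level values and six levels")
  }
  if (!all(is.finite(values))) stop("non-finite indifference values")
  chord <- 1 + (values[6] - 1) * levels / levels[6]
  n_above <- sum(values[1:5] > chord[1:5])
  list(concave = n_above >= 3, n_above = n_above)
}
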