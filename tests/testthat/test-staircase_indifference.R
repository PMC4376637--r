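test_that("PEST state machine: initial steps, halving, re-initialization", {
  cfg <- exp2_config()
  b1 <- cfg$blocks[[1]]
  expect_equal(b1$init_step, 8)
  expect_equal(cfg$blocks[[2]]$init_step, 24)
  st <- pest_init(0.5, b1$init_mag, b1$init_step, jitter = 0, seed = 1)
  expect_equal(st$magnitude, 60)
  expect_equal(st$step, 8)
  # reject, reject: same direction, no halving
  st <- pest_update(st, FALSE); st <- pest_update(st, FALSE)
  expect_equal(st$step, 8)
  expect_equal(st$magnitude, 60 + 16)
  # first reversal halves to 4
  st <- pest_update(st, TRUE)
  expect_equal(st$step, 4)
  # second reversal halves to 2 = 8/4: re-init, step restored, history reset
  st2 <- pest_update(st, FALSE)
  expect_equal(st2$reinits, 1L)
  expect_equal(st2$step, 8)
  expect_equal(st2$dir, 0L)
  expect_equal(st2$magnitude, 60)  # jitter = 0
})

test_that("PEST doubles the step after the third consecutive same-direction
          step, capped at the initial step", {
  st <- pest_init(0.5, 60, 8, jitter = 0, seed = 1)
  st <- pest_update(st, TRUE)   # direction set, run 1
  st <- pest_update(st, FALSE)  # reversal: step 4
  expect_equal(st$step, 4)
  mags <- st$magnitude
  for (i in 1:4) {              # same direction runs 2..5
    st <- pest_update(st, FALSE)
    mags <- c(mags, st$magnitude)
  }
  # steps taken: 4, 4, 8 (doubled after 3rd), 8 (capped at initial)
  expect_equal(diff(mags), c(4, 4, 8, 8))
})

test_that("alternating accept/reject oscillates within a bounded band", {
  st <- pest_init(0.5, 60, 8, jitter = 0, seed = 2)
  mags <- numeric(60)
  for (t in 1:60) {
    mags[t] <- st$magnitude
    st <- pest_update(st, t %% 2 == 0)
  }
  # after the initial transient the trajectory stays within a tight band
  late <- mags[20:60]
  expect_lt(max(late) - min(late), 4 * 8)
  # offers never go negative under sustained acceptance
  st <- pest_init(0.5, 5, 8, jitter = 0, seed = 3)
  for (t in 1:20) st <- pest_update(st, TRUE)
  expect_gte(st$magnitude, 0)
})

test_that("six interleaved staircases never exchange state", {
  # drive six independent staircases with fixed choice sequences; flipping
  # one level's choices must leave every other level's offers unchanged
  run6 <- function(flip_level = NULL) {
    states <- lapply(1:6, function(i) pest_init(i / 6, 60, 8, 6, seed = 100 + i))
    offers <- vector("list", 6)
    set.seed(9)
    sched <- sample(rep(1:6, 10))
    for (s in sched) {
      offers[[s]] <- c(offers[[s]], states[[s]]$magnitude)
      acc <- (length(offers[[s]]) %% 3 == 0)
      if (!is.null(flip_level) && s == flip_level) acc <- !acc
      states[[s]] <- pest_update(states[[s]], acc)
    }
    offers
  }
  base <- run6()
  pert <- run6(flip_level = 4)
  for (lv in setdiff(1:6, 4)) expect_identical(base[[lv]], pert[[lv]])
  expect_false(identical(base[[4]], pert[[4]]))
})

test_that("exp2 session: 16 choices per level per block, default option costless", {
  ag <- agent("sigmoidal", list(k = 4, p = 1), beta = 0.3, id = "e2")
  ses <- simulate_exp2_session(ag, seed = 4)
  tr <- ses$dataset$trials
  expect_equal(nrow(tr), 192)
  for (b in 1:2) {
    tb <- tr[tr$block == b, ]
    expect_equal(nrow(tb), 96)
    expect_equal(as.vector(table(tb$c2)), rep(16L, 6))
    expect_true(all(tb$c1 == 0))
    expect_true(all(tb$is_default1))
  }
  expect_equal(sum(tr$realized), 2 * round(0.15 * 96))
  expect_identical(ses, simulate_exp2_session(ag, seed = 4))
  # always-rejecting agent: offers ratchet upward by the full step until a
  # re-initialization drops them back near the starting magnitude
  stubborn <- agent("linear", list(k = 1e6), beta = 1e6, id = "no")
  tra <- simulate_exp2_session(stubborn, seed = 5)$traces[[1]][[1]]
  d <- diff(tra$offered)
  expect_true(all(abs(d - 8) < 1e-9 | d < 0))
  expect_gt(max(tra$offered), 60 + 3 * 8)
  bad_cfg <- exp2_config(); bad_cfg$levels <- c(0.5, 1)
  expect_error(simulate_exp2_session(ag, config = bad_cfg, seed = 1), "six")
})

test_that("deterministic threshold agent: staircase estimate lands within one
          final step of the true indifference magnitude", {
  m_star <- 72
  run <- run_staircase(m_star, Inf, 40, init_mag = 60, init_step = 8,
                       jitter = 0, seed = 10)
  # mean of the last four offers before the first re-initialization
  stopifnot(length(run$reinits) > 0)
  pre <- run$offers[max(1, run$reinits[1] - 3):run$reinits[1]]
  expect_lt(abs(mean(pre) - m_star), 8)
})

test_that("psychometric indifference fitting: separation convention, symmetry,
          and recovery from a known generating curve", {
  # deterministic threshold: x50 inside the gap, slope flagged unbounded
  ch <- list(level_0.5 = data.frame(offered = c(50, 58, 66, 74, 82, 90),
                                    accepted = c(F, F, F, T, T, T)))
  cv <- estimate_indifference_points(ch)
  expect_equal(cv$x50, 70)
  expect_true(is.infinite(cv$slope))
  expect_equal(cv$flag, "separated")
  # symmetric accept/reject pattern around 100
  ch2 <- list(level_0.2 = data.frame(
    offered = c(80, 90, 95, 105, 110, 120, 85, 115),
    accepted = c(F, F, T, F, T, T, F, T)))
  cv2 <- estimate_indifference_points(ch2)
  expect_equal(cv2$x50, 100, tolerance = 1e-6)
  # too few or one-sided choices are flagged
  cv3 <- estimate_indifference_points(list(level_1 = data.frame(
    offered = c(10, 20, 30, 40, 50, 60), accepted = rep(TRUE, 6))))
  expect_equal(cv3$flag, "unconverged")
  # recovery: x50 = 60, slope 0.2, 16 trials x 50 replicates
  set.seed(11)
  est <- replicate(50, {
    x <- runif(16, 30, 90)
    y <- runif(16) < plogis(0.2 * (x - 60))
    estimate_indifference_points(
      list(level_0.5 = data.frame(offered = x, accepted = y)))$x50
  })
  expect_lt(abs(median(est, na.rm = TRUE) - 60) / 60, 0.10)
})

test_that("indifference-point representations follow the defining arithmetic", {
  cv <- data.frame(level = c(0.15, 0.4), x50 = c(40, 80))
  expect_equal(transform_indifference(cv, "raw", 40), c(40, 80))
  expect_equal(transform_indifference(cv, "multiplicative", 40), c(1, 0.5))
  expect_equal(transform_indifference(cv, "additive", 40), c(40, 0))
  # additive goes negative once x50 > 2D
  expect_lt(transform_indifference(data.frame(x50 = 90), "additive", 40), 0)
  expect_error(transform_indifference(data.frame(x50 = -5), "multiplicative", 40))
  expect_error(transform_indifference(cv, "raw", 0), "positive")
})

test_that("concavity rule: chord baseline, quadratic concave, steep hyperbolic
          convex (indifference points solved by brute force)", {
  lv <- exp2_config()$levels
  # five points exactly on the chord: count 0, not concave
  chord_vals <- 1 + (0.3 - 1) * lv / lv[6]
  cc <- classify_concavity(chord_vals, lv)
  expect_equal(cc$n_above, 0)
  expect_false(cc$concave)
  D <- 40
  mult_points <- function(model, params) {
    x50 <- vapply(lv, function(E) analytic_indifference(model, params, D, E),
                  numeric(1))
    D / x50
  }
  cq <- classify_concavity(mult_points("quadratic", list(k = 30)), lv)
  expect_true(cq$concave)
  expect_equal(cq$n_above, 5)
  chyp <- classify_concavity(mult_points("hyperbolic", list(k = 8)), lv)
  expect_false(chyp$concave)
  expect_equal(chyp$n_above, 0)
  expect_error(classify_concavity(c(1, NA, 1, 1, 1, 1), lv), "non-finite")
})

test_that("magnitude-effect diagnostic: a multiplicative agent yields the same
          multiplicative curve in both blocks; an additive agent the same
          premium x50 - D", {
  lv <- exp2_config()$levels
  # sigmoidal is multiplicative: V = M f(C)
  mult_agent <- agent("sigmoidal", list(k = 4, p = 1), beta = Inf, id = "m")
  ses <- simulate_exp2_session(mult_agent, seed = 12)
  m40 <- transform_indifference(
    estimate_indifference_points(ses$traces[[1]]), "multiplicative", 40)
  m200 <- transform_indifference(
    estimate_indifference_points(ses$traces[[2]]), "multiplicative", 200)
  ok <- is.finite(m40) & is.finite(m200)
  expect_gte(sum(ok), 4)
  expect_lt(max(abs(m40[ok] - m200[ok])), 0.15)
  # quadratic is additive: V = M - kC^2, so x50 - D = kC^2 in every block
  add_agent <- agent("quadratic", list(k = 60), beta = Inf, id = "a")
  ses2 <- simulate_exp2_session(add_agent, seed = 13)
  a40 <- estimate_indifference_points(ses2$traces[[1]])$x50 - 40
  a200 <- estimate_indifference_points(ses2$traces[[2]])$x50 - 200
  ok2 <- is.finite(a40) & is.finite(a200)
  expect_gte(sum(ok2), 4)
  expect_lt(max(abs(a40[ok2] - a200[ok2])), 12)
})
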