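test_that("trial tables round-trip losslessly and validate on read", {
  st <- shared_stimuli()
  ags <- list(agent("sigmoidal", list(k = 9, p = 0.6), beta = 0.3, id = "s1"),
              agent("hyperbolic", list(k = 2), beta = 0.2, id = "s2"))
  ds <- simulate_cohort(ags, st, seed = 30)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(ds, path)
  back <- read_trials(path)
  expect_length(back, 2)
  for (i in 1:2) {
    expect_equal(back[[i]]$subject, ds[[i]]$subject)
    expect_equal(back[[i]]$cost_type, ds[[i]]$cost_type)
    expect_equal(back[[i]]$trials, ds[[i]]$trials,
                 ignore_attr = TRUE, tolerance = 0)
  }
  # malformed rows are reported with line and column
  tab <- utils::read.csv(path)
  tab$chosen[5] <- 3
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab, bad, row.names = FALSE)
  expect_error(read_trials(bad), "line 6, column 'chosen'")
  tab <- utils::read.csv(path)
  tab$c1[2] <- 1.4
  utils::write.csv(tab, bad, row.names = FALSE)
  expect_error(read_trials(bad), "column 'c1'")
  expect_error(read_trials("/nonexistent/file.csv"), "not found")
})

test_that("a written cohort reproduces identical downstream free energies", {
  st <- shared_stimuli()
  stn <- st; stn$pairs <- st$pairs[1:60, ]
  ags <- lapply(1:3, function(i) {
    agent("sigmoidal", list(k = 6 + 2 * i, p = 0.6), beta = 0.3,
          id = sprintf("s%d", i))
  })
  ds <- simulate_cohort(ags, stn, seed = 31)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(ds, path)
  back <- read_trials(path)
  for (i in seq_along(ds)) {
    expect_identical(fit_model(ds[[i]], "hyperbolic")$F,
                     fit_model(back[[i]], "hyperbolic")$F)
  }
})

test_that("choice regression recovers the value-based sign pattern and is
          invariant to trial duplication", {
  st <- shared_stimuli()
  ag <- agent("linear", list(k = 30), beta = 0.4, id = "r")
  ds <- simulate_cohort(list(ag), st, seed = 32)[[1]]
  co <- choice_logistic_regression(ds)
  est <- setNames(co$estimate, co$term)
  expect_gt(est[["m1"]], 0); expect_lt(est[["c1"]], 0)
  expect_lt(est[["m2"]], 0); expect_gt(est[["c2"]], 0)
  dup <- ds
  dup$trials <- rbind(ds$trials, ds$trials)
  co2 <- choice_logistic_regression(dup)
  expect_equal(co2$estimate, co$estimate, tolerance = 1e-6)
  expect_false(attr(co, "separated"))
  # deterministic magnitude-only chooser gives complete separation
  sep <- ds
  sep$trials$chosen <- ifelse(sep$trials$m1 >= sep$trials$m2, 1L, 2L)
  co3 <- choice_logistic_regression(sep)
  expect_true(attr(co3, "separated"))
  expect_true(all(is.finite(co3$estimate)))
  short <- ds; short$trials <- ds$trials[1:10, ]
  expect_error(choice_logistic_regression(short), "at least 20")
})

test_that("fatigue tests: argument validation and degenerate inputs", {
  st <- shared_stimuli()
  ag <- agent("sigmoidal", list(k = 8, p = 0.7), beta = 0.3, id = "f")
  ds <- simulate_cohort(list(ag), st, seed = 33)[[1]]
  expect_error(fatigue_tests(ds, n_perm = 0), "positive")
  none <- ds
  none$trials$realized <- FALSE
  rep0 <- fatigue_tests(none, n_perm = 10)
  expect_false(rep0$applicable)
  rep1 <- fatigue_tests(ds, n_perm = 199, seed = 1)
  expect_true(rep1$applicable)
  for (nm in c("post_effort", "hard_vs_easy", "first_vs_second_half")) {
    expect_true(rep1[[nm]]$p > 0 && rep1[[nm]]$p <= 1)
  }
  # determinism in the permutation stream
  rep2 <- fatigue_tests(ds, n_perm = 199, seed = 1)
  expect_identical(rep1, rep2)
})

test_that("cross-task parameter correlations mirror the expected layout", {
  set.seed(34)
  eff <- data.frame(subject = sprintf("s%02d", 1:23),
                    sigmoidal_k = rlnorm(23, 2, 0.4),
                    sigmoidal_p = runif(23, 0.4, 0.9))
  del <- data.frame(subject = sprintf("s%02d", 1:23),
                    hyperbolic_k = rlnorm(23, 1.5, 0.5))
  tab <- parameter_correlations(eff, del)
  expect_equal(nrow(tab), 2)
  expect_true(all(abs(tab$r) <= 1) && all(tab$p >= 0 & tab$p <= 1))
  # a vector against itself correlates perfectly
  self <- parameter_correlations(
    eff[, c("subject", "sigmoidal_k")],
    data.frame(subject = eff$subject, sigmoidal_k = eff$sigmoidal_k))
  expect_equal(self$r, 1)
  expect_error(parameter_correlations(eff[1:2, ], del[1:2, ]), "at least 3")
  expect_error(parameter_correlations(eff, del[c(2:23, 1), ]), NA)
  del_bad <- del; del_bad$subject[1] <- "zz"
  expect_error(parameter_correlations(eff, del_bad), "match")
  del_const <- del; del_const$hyperbolic_k <- 1
  expect_error(parameter_correlations(eff, del_const), "zero-variance")
})

test_that("pipeline: deterministic manifests, config validation, demo recovery", {
  cfg <- pipeline_config(n_subjects = 4, n_trials = 60, seed = 40)
  out1 <- withr::local_tempdir(); out2 <- withr::local_tempdir()
  cfg$output_dir <- out1
  r1 <- run_pipeline(cfg)
  cfg$output_dir <- out2
  r2 <- run_pipeline(cfg)
  # identical configs give identical output checksums
  expect_identical(r1$manifest$files, r2$manifest$files)
  expect_true(file.exists(file.path(out1, "manifest.json")))
  expect_true(file.exists(file.path(out1, "summary.txt")))
  # the sigmoidal-vs-hyperbolic recovery demo selects the generating model
  expect_equal(names(which.max(r1$bms$xp)), "sigmoidal")
  # config errors fire before any computation
  bad <- cfg; bad$models <- c("hyperbolic", "exponential")
  expect_error(run_pipeline(bad), "unknown model")
  bad2 <- cfg; bad2$typo <- 1
  expect_error(run_pipeline(bad2), "unknown config key")
  bad3 <- cfg; bad3$seeds$bms <- NULL
  expect_error(run_pipeline(bad3), "seed")
  # JSON config round trip
  cfg_path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(unclass(cfg), cfg_path, auto_unbox = TRUE)
  cfg_back <- read_config(cfg_path)
  expect_equal(cfg_back$models, cfg$models)
  expect_equal(cfg_back$seeds$bms, cfg$seeds$bms)
})
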