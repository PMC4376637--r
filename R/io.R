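trial_columns <- c("subject", "block", "trial", "cost_type", "m1", "c1",
                   "m2", "c2", "chosen", "realized", "is_default1")

#' Write choice datasets to a delimited trial table
#'
#' Comma-separated UTF-8 with a fixed header, one row per trial; magnitudes
#' in display units, costs as decimals on `[0, 1]`, numbers at full
#' precision. The round trip through [read_trials()] is lossless.
#'
#' @param datasets a [choice_dataset()] or list of them.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(datasets, path) {
  if (inherits(datasets, "choice_dataset")) datasets <- list(datasets)
  rows <- lapply(datasets, function(d) {
    cbind(subject = d$subject, d$trials[, c("block", "trial")],
          cost_type = d$cost_type,
          d$trials[, c("m1", "c1", "m2", "c2", "chosen", "realized",
                       "is_default1")])
  })
  tab <- do.call(rbind, rows)[, trial_columns]
  utils::write.csv(format(tab, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a delimited trial table into choice datasets
#'
#' Validates every row; a malformed value raises an error naming the
#' offending line (1-based, including the header) and column.
#'
#' @param path input file path.
#' @return list of [choice_dataset()]s, one per subject, in file order.
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(trial_columns, names(tab))
  if (length(missing_cols)) {
    stop("trial table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  check <- function(col, ok) {
    bad <- which(!ok)
    if (length(bad)) {
      stop(sprintf("malformed trial table: line %d, column '%s' (value: %s)",
                   bad[1] + 1L, col, tab[[col]][bad[1]]))
    }
  }
  num <- function(col) suppressWarnings(as.numeric(tab[[col]]))
  for (col in c("m1", "m2")) {
    v <- num(col); check(col, is.finite(v) & v >= 0); tab[[col]] <- v
  }
  for (col in c("c1", "c2")) {
    v <- num(col); check(col, is.finite(v) & v >= 0 & v <= 1); tab[[col]] <- v
  }
  ch <- suppressWarnings(as.integer(tab$chosen))
  check("chosen", !is.na(ch) & ch %in% c(1L, 2L)); tab$chosen <- ch
  for (col in c("realized", "is_default1")) {
    v <- as.logical(tab[[col]]); check(col, !is.na(v)); tab[[col]] <- v
  }
  check("cost_type", tab$cost_type %in% c("effort", "delay"))
  lapply(unique(tab$subject), function(s) {
    sub <- tab[tab$subject == s, ]
    choice_dataset(sub[, setdiff(trial_columns, c("subject", "cost_type"))],
                   subject = s, cost_type = sub$cost_type[1])
  })
}

#' Logistic regression of choices on offer attributes
#'
#' Bernoulli regression (IRLS via `glm`) of choosing option 1 on both
#' options' magnitudes and costs (four predictors plus intercept). In
#' value-guided data the own-magnitude coefficients come out positive and
#' the own-cost coefficients negative. Perfect separation is flagged and the
#' coefficients re-estimated under a small ridge penalty.
#'
#' @param dataset a [choice_dataset()] with at least 20 trials.
#' @param ridge L2 penalty used only when separation is detected.
#' @return data.frame with `term`, `estimate`, `se`, `z`, and an attribute
#'   `separated` (logical).
#' @export
choice_logistic_regression <- function(dataset, ridge = 1e-2) {
  tr <- dataset$trials
  if (nrow(tr) < 20) stop("need at least 20 trials")
  X <- cbind(m1 = tr$m1, c1 = tr$c1, m2 = tr$m2, c2 = tr$c2)
  if (any(apply(X, 2, stats::sd) == 0)) stop("degenerate (constant) predictor")
  y <- as.numeric(tr$chosen == 1L)
  fit <- suppressWarnings(stats::glm(y ~ X, family = stats::binomial(),
                                     control = list(maxit = 200)))
  # separation: the MLE diverges, i.e. a per-SD slope beyond any plausible
  # psychometric steepness. Saturated-but-overlapping softmax data keep
  # finite slopes and are not flagged.
  std_slope <- stats::coef(fit)[-1] * apply(X, 2, stats::sd)
  separated <- !fit$converged || any(!is.finite(std_slope)) ||
    any(abs(std_slope) > 15)
  if (separated) {
    # ridge-stabilized Bernoulli fit; penalty scales with n so that
    # duplicating trials leaves the solution unchanged
    Xs <- cbind(1, scale(X))
    nll <- function(b) {
      eta <- drop(Xs %*% b)
      -sum(y * eta - log1p(exp(eta))) + ridge * nrow(Xs) * sum(b[-1]^2)
    }
    opt <- stats::optim(rep(0, 5), nll, method = "BFGS",
                        control = list(maxit = 500))
    H <- stats::optimHess(opt$par, nll)
    se_s <- sqrt(diag(solve(H)))
    sds <- attr(Xs, "scaled:scale")
    est <- c(opt$par[1] - sum(opt$par[-1] * attr(Xs, "scaled:center") / sds),
             opt$par[-1] / sds)
    se <- c(se_s[1], se_s[-1] / sds)
  } else {
    est <- stats::coef(fit)
    se <- summary(fit)$coefficients[, "Std. Error"]
  }
  out <- data.frame(term = c("(Intercept)", "m1", "c1", "m2", "c2"),
                    estimate = unname(est), se = unname(se),
                    z = unname(est / se))
  attr(out, "separated") <- separated
  out
}

# HRHC indicator: 1 if the chosen option is the higher-reward/higher-cost
# one, 0 if the lower/lower one, NA when the pair is not ordered that way.
#' @keywords internal
hrhc_chosen <- function(tr) {
  o1_hrhc <- tr$m1 >= tr$m2 & tr$c1 >= tr$c2 & (tr$m1 > tr$m2 | tr$c1 > tr$c2)
  o2_hrhc <- tr$m2 >= tr$m1 & tr$c2 >= tr$c1 & (tr$m2 > tr$m1 | tr$c2 > tr$c1)
  ifelse(o1_hrhc, as.numeric(tr$chosen == 1L),
         ifelse(o2_hrhc, as.numeric(tr$chosen == 2L), NA_real_))
}

# Two-sided permutation p with the add-one convention; permutations tying
# the observed statistic count half (mid-p). Binary outcomes make exact ties
# common, and counting them fully would make null p-values conservative
# rather than uniform.
#' @keywords internal
perm_pvalue <- function(x, y, n_perm) {
  obs <- mean(x) - mean(y)
  pool <- c(x, y)
  nx <- length(x)
  b <- 0
  for (i in seq_len(n_perm)) {
    idx <- sample(length(pool), nx)
    d <- abs(mean(pool[idx]) - mean(pool[-idx])) - abs(obs)
    if (d > 1e-12) b <- b + 1
    else if (d > -1e-12) b <- b + 0.5
  }
  list(statistic = obs, p = (b + 1) / (n_perm + 1))
}

#' Fatigue control tests on choice behavior
#'
#' Three permutation tests on the fraction of higher-reward/higher-cost
#' (HRHC) choices, probing whether realized effort exertion shifted
#' subsequent choices: (a) trials following a realized effort vs an
#' equally-sized random subset of trials following no effort; (b) trials
#' following a hard vs an easy realized effort (median split on the
#' previous trial's chosen cost); (c) first vs second half of the session.
#' Two-sided p-values use the add-one convention `(b + 1) / (n_perm + 1)`.
#'
#' @param dataset a [choice_dataset()] with realized-effort flags.
#' @param n_perm permutations per test (default 100000).
#' @param seed RNG seed.
#' @return object of class `fatigue_report`: per test, group fractions,
#'   difference, and p-value; `applicable = FALSE` when no realized trials
#'   exist.
#' @export
fatigue_tests <- function(dataset, n_perm = 100000, seed = 1) {
  if (n_perm < 1) stop("n_perm must be positive")
  tr <- dataset$trials
  h <- hrhc_chosen(tr)
  if (!any(tr$realized)) {
    return(structure(list(applicable = FALSE), class = "fatigue_report"))
  }
  with_seed(seed, {
    prev_realized <- c(FALSE, tr$realized[-nrow(tr)])
    prev_same_block <- c(FALSE, tr$block[-1] == tr$block[-nrow(tr)])
    post_eff <- which(prev_realized & prev_same_block & !is.na(h))
    post_no <- which(!prev_realized & prev_same_block & !is.na(h))

    tests <- list()
    if (length(post_eff) >= 2 && length(post_no) >= length(post_eff)) {
      matched <- sample(post_no, length(post_eff))
      pt <- perm_pvalue(h[post_eff], h[matched], n_perm)
      tests$post_effort <- list(frac_post_effort = mean(h[post_eff]),
                                frac_post_no_effort = mean(h[matched]),
                                diff = pt$statistic, p = pt$p)
    }
    prev_cost <- c(NA, ifelse(tr$chosen == 1L, tr$c1, tr$c2)[-nrow(tr)])
    eff_cost <- prev_cost[post_eff]
    if (length(post_eff) >= 4) {
      med <- stats::median(eff_cost)
      hard <- post_eff[eff_cost > med]
      easy <- post_eff[eff_cost <= med]
      if (length(hard) >= 2 && length(easy) >= 2) {
        pt <- perm_pvalue(h[hard], h[easy], n_perm)
        tests$hard_vs_easy <- list(median_cost = med,
                                   frac_post_hard = mean(h[hard]),
                                   frac_post_easy = mean(h[easy]),
                                   diff = pt$statistic, p = pt$p)
      }
    }
    half <- seq_len(nrow(tr)) <= nrow(tr) / 2
    h1 <- h[half & !is.na(h)]; h2 <- h[!half & !is.na(h)]
    if (length(h1) >= 2 && length(h2) >= 2) {
      pt <- perm_pvalue(h1, h2, n_perm)
      tests$first_vs_second_half <- list(frac_first = mean(h1),
                                         frac_second = mean(h2),
                                         diff = pt$statistic, p = pt$p)
    }
    structure(c(list(applicable = TRUE, n_perm = n_perm), tests),
              class = "fatigue_report")
  })
}

#' @export
print.fatigue_report <- function(x, ...) {
  if (!x$applicable) {
    cat("<fatigue_report> inapplicable: no realized trials\n")
    return(invisible(x))
  }
  cat("<fatigue_report>", x$n_perm, "permutations\n")
  for (nm in setdiff(names(x), c("applicable", "n_perm"))) {
    cat(sprintf("  %s: diff = %+.3f, p = %.4f\n", nm, x[[nm]]$diff, x[[nm]]$p))
  }
  invisible(x)
}

#' Cross-task correlations of fitted parameters
#'
#' Pearson correlations (with uncorrected p-values, as is conventional for
#' this table) between every effort-task and delay-task parameter column,
#' across subjects matched by id.
#'
#' @param fits_effort,fits_delay data.frames with a `subject` column and
#'   one column per parameter (e.g. `hyperbolic_k`, `sigmoidal_k`,
#'   `sigmoidal_p`).
#' @return data.frame: `effort_param`, `delay_param`, `r`, `p`, `n`.
#' @export
parameter_correlations <- function(fits_effort, fits_delay) {
  if (!all(sort(fits_effort$subject) == sort(fits_delay$subject))) {
    stop("subject ids do not match between tasks")
  }
  fits_delay <- fits_delay[match(fits_effort$subject, fits_delay$subject), ]
  n <- nrow(fits_effort)
  if (n < 3) stop("need at least 3 matched subjects")
  e_cols <- setdiff(names(fits_effort), "subject")
  d_cols <- setdiff(names(fits_delay), "subject")
  rows <- list()
  for (ec in e_cols) for (dc in d_cols) {
    x <- fits_effort[[ec]]; y <- fits_delay[[dc]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero-variance parameter vector")
    ct <- stats::cor.test(x, y, method = "pearson")
    rows[[length(rows) + 1]] <- data.frame(
      effort_param = ec, delay_param = dc,
      r = unname(ct$estimate), p = ct$p.value, n = n)
  }
  do.call(rbind, rows)
}
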