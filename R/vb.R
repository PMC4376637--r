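#' Default Gaussian prior for a discounting model
#'
#' Priors live in the unconstrained estimation space: `ln k` and `ln beta`
#' are standard-normal-location with variance 10 (weakly informative over
#' several orders of magnitude in native space), and the sigmoidal turning
#' point / power exponent `p` is `Normal(0.5, 1)` on the identity scale
#' (deliberately not clipped at 1; turning points beyond the maximum cost
#' are conceptually possible). Robustness to these choices is the contract
#' checked by [prior_sensitivity()].
#'
#' @param model a `model_spec` or model name.
#' @param fixed optional named list of parameters held fixed in native space
#'   (removed from the prior).
#' @return list with `mean`, `cov` (estimation space), `names`, `transforms`.
#' @export
default_prior <- function(model, fixed = NULL) {
  if (is.character(model)) model <- model_spec(model)
  all_names <- names(model$transforms)
  free <- setdiff(all_names, names(fixed))
  # p's prior follows its scale: N(0.5, 1) for the sigmoidal turning point
  # (identity), N(0, 1) for the log power exponent (median exponent 1)
  p_tr <- unname(model$transforms["p"])
  p_mean <- if (!is.na(p_tr) && p_tr == "log") 0 else 0.5
  mu <- c(k = 0, p = p_mean, beta = 0)[free]
  v  <- c(k = 10, p = 1, beta = 10)[free]
  names(mu) <- names(v) <- free
  list(mean = mu, cov = diag(v, nrow = length(v)),
       names = free, transforms = model$transforms[free])
}

# Estimation space <-> native space, per transform tag.
#' @keywords internal
est_to_native <- function(theta, transforms) {
  out <- ifelse(transforms[names(theta)] == "log", exp(theta), theta)
  names(out) <- names(theta)
  out
}

#' @keywords internal
native_to_est <- function(x, transforms) {
  out <- ifelse(transforms[names(x)] == "log", log(x), x)
  names(out) <- names(x)
  out
}

# Log-likelihood over a matrix of native parameter vectors (rows): the
# vectorized engine shared by fit_model and the quadrature oracle. A single
# parameter vector vectorizes over trials (the optimizer's hot path); a
# parameter grid loops over trials and vectorizes over grid points.
#' @keywords internal
grid_loglik <- function(dataset, model, par_matrix, alpha = 1) {
  if (is.character(model)) model <- model_spec(model)
  tr <- dataset$trials
  k <- par_matrix[, "k"]
  p <- if ("p" %in% colnames(par_matrix)) par_matrix[, "p"] else NULL
  beta <- par_matrix[, "beta"]
  if (nrow(par_matrix) == 1L) {
    pars <- list(k = k, p = p)
    V1 <- subjective_value(model, pars, M = tr$m1, C = tr$c1, alpha = alpha)
    V2 <- subjective_value(model, pars, M = tr$m2, C = tr$c2, alpha = alpha)
    s <- ifelse(tr$chosen == 1L, 1, -1)
    return(sum(log(pmax(sigmoid(s * beta * (V1 - V2)), 1e-300))))
  }
  ll <- numeric(nrow(par_matrix))
  for (i in seq_len(nrow(tr))) {
    pars <- list(k = k, p = p)
    V1 <- subjective_value(model, pars, M = tr$m1[i], C = tr$c1[i], alpha = alpha)
    V2 <- subjective_value(model, pars, M = tr$m2[i], C = tr$c2[i], alpha = alpha)
    s <- if (tr$chosen[i] == 1L) 1 else -1
    pr <- sigmoid(s * beta * (V1 - V2))
    ll <- ll + log(pmax(pr, 1e-300))
  }
  ll
}

#' Bernoulli log-likelihood of a choice dataset under a discounting model
#'
#' Sum over trials of the log softmax probability of the observed choice.
#' Probabilities are clipped at 1e-300 before the log so the result is
#' always finite.
#'
#' @param dataset a [choice_dataset()].
#' @param model a `model_spec` or model name.
#' @param params named list/vector with `k` (and `p` where applicable) and
#'   `beta`, in native space.
#' @param alpha utility exponent (default 1).
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(dataset, model, params, alpha = 1) {
  params <- as.list(params)
  if (is.null(params$beta)) stop("params must include the softmax temperature 'beta'")
  if (!all(vapply(params, function(x) all(is.finite(x)), logical(1)))) {
    stop("non-finite parameters")
  }
  m <- matrix(unlist(params), nrow = 1,
              dimnames = list(NULL, names(params)))
  grid_loglik(dataset, model, m, alpha = alpha)
}

# Negative log joint (likelihood + Gaussian prior) in estimation space,
# with log-scale parameters exponentiated inside. Used by the MAP ascent.
#' @keywords internal
neg_log_joint <- function(theta, dataset, model, prior, alpha, fixed = NULL) {
  names(theta) <- prior$names
  native <- est_to_native(theta, prior$transforms)
  full <- c(as.list(native), fixed)
  m <- matrix(unlist(full), nrow = 1, dimnames = list(NULL, names(full)))
  ll <- grid_loglik(dataset, model, m, alpha = alpha)
  dm <- theta - prior$mean
  lp <- -0.5 * drop(dm %*% solve(prior$cov, dm))
  -(ll + lp)
}

#' Fit a discounting model to one subject by variational Laplace
#'
#' MAP ascent (quasi-Newton, adaptive step) in the unconstrained estimation
#' space from a deterministic multi-start grid, followed by a Laplace
#' Gaussian approximation to the posterior. Returns the free energy
#' `F = accuracy - complexity`, an approximation to the log model evidence:
#' `accuracy` is the expected log-likelihood under the Gaussian posterior
#' (to second order) and `complexity` the Kullback-Leibler divergence from
#' the posterior to the prior. The fit kept is the initialization with the
#' maximal free energy.
#'
#' @param dataset a [choice_dataset()].
#' @param model a `model_spec` or model name.
#' @param prior a prior from [default_prior()] (or same structure).
#' @param n_init_per_param number of initialization values spanned per
#'   parameter (staggered jointly into that many multi-starts).
#' @param alpha utility exponent; 0.8 re-fits in utility units.
#' @param fixed named list of native-space parameters to hold fixed
#'   (e.g. `list(beta = 0)` for a zero-information control).
#' @param control list: `maxit` (default 300), `reltol` (default 1e-8).
#' @return object of class `posterior_fit`: posterior `mean` and `cov`
#'   (estimation space), `params` (native point estimates incl. fixed),
#'   `F`, `accuracy`, `complexity`, `init_index`, `init_F` (all starts),
#'   `convergence`, `ridge` (regularization actually applied, 0 if none),
#'   `accuracy_order` (metadata: "second" — curvature correction included).
#' @export
fit_model <- function(dataset, model, prior = NULL, n_init_per_param = 8,
                      alpha = 1, fixed = NULL, control = list()) {
  if (is.character(model)) model <- model_spec(model)
  if (n_trials(dataset) == 0) stop("empty dataset")
  if (is.null(prior)) prior <- default_prior(model, fixed = fixed)
  maxit <- control$maxit %||% 300
  reltol <- control$reltol %||% 1e-8
  d <- length(prior$names)
  n_init <- max(1L, as.integer(n_init_per_param))

  # Deterministic staggered (cyclic Latin) starts spanning each parameter's
  # range jointly: start i takes the i-th value in dimension 1, offset
  # cyclically in higher dimensions, so n_init starts cover all ranges.
  rng <- model$init_range[prior$names, , drop = FALSE]
  vals <- lapply(seq_len(d), function(j) {
    seq(rng[j, 1], rng[j, 2], length.out = n_init)
  })
  shift <- floor(n_init / max(1, d))
  starts <- vapply(seq_len(n_init), function(i) {
    vapply(seq_len(d), function(j) {
      vals[[j]][((i - 1 + (j - 1) * shift) %% n_init) + 1]
    }, numeric(1))
  }, numeric(d))
  starts <- if (d == 1) matrix(starts, ncol = 1) else t(starts)
  colnames(starts) <- prior$names

  evaluate_start <- function(theta0) {
    opt <- tryCatch(
      stats::optim(theta0, neg_log_joint, dataset = dataset, model = model,
                   prior = prior, alpha = alpha, fixed = fixed,
                   method = "BFGS",
                   control = list(maxit = maxit, reltol = reltol)),
      error = function(e) NULL)
    if (is.null(opt)) return(NULL)
    mu <- opt$par
    names(mu) <- prior$names
    H <- tryCatch(
      stats::optimHess(mu, neg_log_joint, dataset = dataset, model = model,
                       prior = prior, alpha = alpha, fixed = fixed),
      error = function(e) NULL)
    if (is.null(H)) return(NULL)
    H <- (H + t(H)) / 2
    # Ridge-regularize a non-PD Hessian (flat or saddle directions).
    ridge <- 0
    base <- mean(abs(diag(H))) + 1e-12
    repeat {
      ok <- tryCatch({chol(H + diag(ridge, d)); TRUE}, error = function(e) FALSE)
      if (ok) break
      ridge <- if (ridge == 0) 1e-8 * base else ridge * 10
      if (ridge > 1e6 * base) return(NULL)
    }
    if (ridge > 0) {
      warning("singular posterior Hessian; ridge-regularized (ridge = ",
              signif(ridge, 3), ")", call. = FALSE)
    }
    Sigma <- solve(H + diag(ridge, d))
    Sigma <- (Sigma + t(Sigma)) / 2
    dimnames(Sigma) <- list(prior$names, prior$names)

    native <- est_to_native(mu, prior$transforms)
    full <- c(as.list(native), fixed)
    ll_mu <- log_likelihood(dataset, model, full, alpha = alpha)
    # Second-order expected log-likelihood under the posterior.
    Hll <- tryCatch(
      stats::optimHess(mu, function(th) {
        names(th) <- prior$names
        nat <- est_to_native(th, prior$transforms)
        -log_likelihood(dataset, model, c(as.list(nat), fixed), alpha = alpha)
      }),
      error = function(e) matrix(0, d, d))
    accuracy <- ll_mu - 0.5 * sum(Hll * Sigma)

    S0 <- prior$cov
    dm <- mu - prior$mean
    S0i_S <- solve(S0, Sigma)
    complexity <- 0.5 * (sum(diag(S0i_S)) + drop(dm %*% solve(S0, dm)) - d +
                           determinant(S0)$modulus - determinant(Sigma)$modulus)
    complexity <- max(0, as.numeric(complexity))
    list(mean = mu, cov = Sigma, params = full,
         F = accuracy - complexity, accuracy = accuracy,
         complexity = complexity, convergence = opt$convergence,
         ridge = ridge)
  }

  fits <- lapply(seq_len(n_init), function(i) evaluate_start(starts[i, ]))
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) {
    stop("optimizer failed to converge on all ", n_init,
         " initializations (model ", model$name, ", subject ",
         dataset$subject, ")")
  }
  Fs <- vapply(fits, function(f) if (is.null(f)) -Inf else f$F, numeric(1))
  best <- which.max(Fs)
  fit <- fits[[best]]
  structure(
    c(fit, list(model = model, prior = prior, alpha = alpha,
                init_index = best, init_F = Fs,
                accuracy_order = "second", subject = dataset$subject)),
    class = "posterior_fit"
  )
}

#' @export
print.posterior_fit <- function(x, ...) {
  cat(sprintf("<posterior_fit> %s (subject %s): F = %.2f = %.2f - %.2f\n",
              x$model$name, x$subject, x$F, x$accuracy, x$complexity))
  cat("  native parameters:",
      paste(sprintf("%s = %.4g", names(x$params), unlist(x$params)),
            collapse = ", "), "\n")
  invisible(x)
}

#' Brute-force log model evidence by dense quadrature
#'
#' Numerically integrates the marginal likelihood over the Gaussian prior in
#' estimation space — the independent oracle against which the variational
#' free energy is validated. Three stages: (1) an iteratively zooming coarse
#' scan over `span` prior standard deviations per dimension locates the
#' posterior mass; (2) the integrand's mean and covariance are estimated
#' from the weighted coarse grid and the final grid is laid out in the
#' whitened eigenbasis (so thin correlated ridges — e.g. the k-p ridge of
#' the sigmoidal model — are resolved as well as axis-aligned peaks);
#' (3) with `refine = TRUE` the density is doubled until the result is
#' stable to < 0.05 nats, otherwise an error is raised.
#'
#' @param dataset a [choice_dataset()].
#' @param model a `model_spec` or model name (at most 2 model parameters
#'   plus beta).
#' @param prior as in [fit_model()].
#' @param grid_spec list: `n` points per dimension for the dense pass
#'   (default 48 for <= 2 dimensions, 32 for 3), `span` prior standard
#'   deviations scanned (default 6), `refine` (default TRUE), `drop`
#'   log-density window retained around the peak (default 30 nats),
#'   `span_sd` whitened window half-width in integrand standard deviations
#'   (default 8).
#' @param alpha utility exponent.
#' @param fixed named list of fixed native parameters.
#' @param loglik_fn validation hook: a function mapping an estimation-space
#'   parameter matrix (rows = grid points) to a log-likelihood vector,
#'   replacing the choice likelihood. Lets known closed-form evidences
#'   (e.g. conjugate Gaussian toys) certify the quadrature itself.
#' @return scalar log evidence.
#' @export
evidence_oracle <- function(dataset, model, prior = NULL, grid_spec = list(),
                            alpha = 1, fixed = NULL, loglik_fn = NULL) {
  if (is.null(loglik_fn)) {
    if (is.character(model)) model <- model_spec(model)
  }
  if (is.null(prior)) prior <- default_prior(model, fixed = fixed)
  d <- length(prior$names)
  if (d > 3) stop("oracle supports at most 2 model parameters plus beta")
  span <- grid_spec$span %||% 6
  n <- grid_spec$n %||% (if (d <= 2) 48 else 32)
  refine <- grid_spec$refine %||% TRUE
  drop_win <- grid_spec$drop %||% 30
  span_sd <- grid_spec$span_sd %||% 8

  sd0 <- sqrt(diag(prior$cov))
  lo <- prior$mean - span * sd0
  hi <- prior$mean + span * sd0
  S0inv <- solve(prior$cov)

  # log posterior density (unnormalized: loglik + logprior) at a point matrix
  lp_points <- function(grid) {
    colnames(grid) <- prior$names
    ll <- if (!is.null(loglik_fn)) {
      loglik_fn(grid)
    } else {
      nat <- grid
      for (j in seq_len(d)) {
        if (prior$transforms[j] == "log") nat[, j] <- exp(grid[, j])
      }
      if (!is.null(fixed)) {
        nat <- cbind(nat, matrix(rep(unlist(fixed), each = nrow(nat)),
                                 nrow = nrow(nat),
                                 dimnames = list(NULL, names(fixed))))
      }
      grid_loglik(dataset, model, nat, alpha = alpha)
    }
    dm <- sweep(grid, 2, prior$mean)
    ll - 0.5 * rowSums((dm %*% S0inv) * dm) -
      0.5 * (d * log(2 * pi) + as.numeric(determinant(prior$cov)$modulus))
  }

  # Stage 1: iteratively zoom an axis-aligned coarse scan onto the mass
  # region, so sharp posteriors inside a diffuse prior are located. The zoom
  # stops only when no dimension is still shrinking; genuinely wide
  # dimensions (e.g. weakly identified beta) stay wide.
  box_lo <- lo; box_hi <- hi
  coarse_grid <- NULL; coarse_lp <- NULL
  for (pass in 1:5) {
    axes <- lapply(seq_len(d), function(j) {
      seq(box_lo[j], box_hi[j], length.out = 21)
    })
    coarse_grid <- as.matrix(expand.grid(axes, KEEP.OUT.ATTRS = FALSE))
    coarse_lp <- lp_points(coarse_grid)
    keep <- coarse_lp > max(coarse_lp) - drop_win
    pad <- (box_hi - box_lo) / 20
    new_lo <- pmax(lo, apply(coarse_grid[keep, , drop = FALSE], 2, min) - pad)
    new_hi <- pmin(hi, apply(coarse_grid[keep, , drop = FALSE], 2, max) + pad)
    shrink <- (new_hi - new_lo) / (box_hi - box_lo)
    box_lo <- new_lo; box_hi <- new_hi
    if (all(shrink > 0.7)) break
  }

  # Stage 2: moment-match the integrand from a weighted grid, floor each
  # eigen-scale at the local cell size (a peak inside one coarse cell would
  # otherwise collapse the window), and integrate on a whitened grid.
  moments <- function(grid, lp, cell) {
    w <- exp(lp - max(lp))
    w <- w / sum(w)
    mu <- colSums(grid * w)
    dm <- sweep(grid, 2, mu)
    S <- crossprod(dm * sqrt(w))
    S <- (S + t(S)) / 2
    list(mu = mu, S = S + diag(cell^2, d))
  }

  whitened_axes <- function(mu, S, npts) {
    eg <- eigen(S, symmetric = TRUE)
    scales <- sqrt(pmax(eg$values, 1e-12))
    u <- seq(-span_sd, span_sd, length.out = npts)
    ugrid <- as.matrix(expand.grid(rep(list(u), d), KEEP.OUT.ATTRS = FALSE))
    pts <- sweep(ugrid %*% diag(scales, d) %*% t(eg$vectors), 2, mu, `+`)
    h <- u[2] - u[1]
    list(pts = pts, log_vol = d * log(h) + sum(log(scales)))
  }

  mo <- moments(coarse_grid, coarse_lp, cell = (box_hi - box_lo) / 20)

  integrate_at <- function(npts, mu, S) {
    wa <- whitened_axes(mu, S, npts)
    lp <- lp_points(wa$pts)
    list(z = logsumexp(lp) + wa$log_vol, pts = wa$pts, lp = lp)
  }

  # Iterative moment refinement: each cheap whitened scan re-estimates the
  # integrand's location and scale, shrinking the window geometrically until
  # even posterior ridges orders of magnitude narrower than the prior are
  # resolved. Stops when no eigen-scale is still shrinking.
  n_scan <- min(n, if (d <= 2) 32 else 24)
  for (pass in 1:12) {
    scan <- integrate_at(n_scan, mo$mu, mo$S)
    cell <- sqrt(pmax(diag(mo$S), 1e-12)) * (2 * span_sd / n_scan)
    mo_new <- moments(scan$pts, scan$lp, cell = cell)
    ratio <- sqrt(diag(mo_new$S) / diag(mo$S))
    mo <- mo_new
    if (all(ratio > 0.75)) break
  }
  mu <- mo$mu; S <- mo$S
  z1 <- integrate_at(n, mu, S)$z
  if (!refine) return(z1)
  # Stage 3: refine until doubling the density is stable to < 0.05 nats
  last_move <- Inf
  for (r in 1:2) {
    z2 <- integrate_at(2 * n, mu, S)$z
    last_move <- abs(z2 - z1)
    if (last_move <= 0.05) return(z2)
    n <- 2 * n
    z1 <- z2
  }
  stop(sprintf(
    "evidence grid too coarse: doubling density still moved the result by %.3f nats",
    last_move))
}

#' Fraction of choices correctly predicted by a fitted model
#'
#' For each trial, the option with modeled choice probability above 0.5 is
#' the prediction; exact ties (probability 0.5) contribute 0.5. This is the
#' descriptive "% choices correctly predicted" statistic — model comparison
#' proper goes through the free energies, which penalize complexity.
#'
#' @param fit a `posterior_fit`.
#' @param dataset the dataset to score (usually the one that was fitted).
#' @return fraction in `[0, 1]`.
#' @export
predicted_choice_accuracy <- function(fit, dataset) {
  if (n_trials(dataset) == 0) stop("empty dataset")
  tr <- dataset$trials
  pars <- fit$params
  V1 <- subjective_value(fit$model, pars, tr$m1, tr$c1, alpha = fit$alpha)
  V2 <- subjective_value(fit$model, pars, tr$m2, tr$c2, alpha = fit$alpha)
  P1 <- choice_probability(pars$beta, V1, V2)
  score <- ifelse(P1 == 0.5, 0.5, (P1 > 0.5) == (tr$chosen == 1L))
  mean(score)
}

#' Sensitivity of a fit to the prior covariance scale
#'
#' Repeats [fit_model()] with the prior covariance multiplied by each
#' factor, the robustness control for the evidence's prior dependence.
#'
#' @param dataset,model,prior,... as in [fit_model()].
#' @param factors covariance scale factors (default one order of magnitude
#'   down and up).
#' @return data.frame with one row per factor: `factor`, `F`, `accuracy`,
#'   `complexity`, and native parameter estimates; the full fits are in
#'   `attr(, "fits")`.
#' @export
prior_sensitivity <- function(dataset, model, prior = NULL,
                              factors = c(0.1, 10), ...) {
  if (is.character(model)) model <- model_spec(model)
  if (is.null(prior)) prior <- default_prior(model)
  fits <- lapply(factors, function(f) {
    pr <- prior
    pr$cov <- prior$cov * f
    fit_model(dataset, model, prior = pr, ...)
  })
  rows <- lapply(seq_along(factors), function(i) {
    f <- fits[[i]]
    cbind(data.frame(factor = factors[i], F = f$F, accuracy = f$accuracy,
                     complexity = f$complexity),
          as.data.frame(lapply(f$params, as.numeric)))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(factor = numeric(0), F = numeric(0),
               accuracy = numeric(0), complexity = numeric(0))
  attr(out, "fits") <- fits
  out
}
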