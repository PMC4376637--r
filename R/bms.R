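#' Random-effects group Bayesian model selection
#'
#' Treats the model identity as a random effect across subjects: given a
#' subjects x models table of log model evidences (free energies), a
#' variational algorithm estimates the posterior Dirichlet distribution over
#' population model frequencies `r`. Reported per model are the Dirichlet
#' concentrations `alpha`, the posterior mean frequency `mp`, and the
#' exceedance probability `xp` — the probability that the model is the most
#' frequent one in the population.
#'
#' Subject responsibilities are computed with log-sum-exp stabilization, so
#' arbitrarily large within-subject evidence spreads never overflow. Only
#' within-subject evidence differences matter: adding a constant to a
#' subject's row leaves the result unchanged.
#'
#' @param evidence numeric matrix, subjects in rows, models in columns
#'   (column names = model names); no missing values, at least 2 models.
#' @param alpha0 prior Dirichlet count per model (default 1: uniform over
#'   frequencies).
#' @param xp_samples Dirichlet Monte Carlo draws for `xp` when there are
#'   more than two models (an exact Beta computation is used for K = 2).
#' @param seed RNG seed for the Monte Carlo draws.
#' @param tol convergence threshold on `max |delta alpha|`.
#' @return object of class `bms_result`: `alpha`, `mp`, `xp`, `iterations`,
#'   `xp_method` ("exact-beta" or "dirichlet-mc").
#' @export
#' @examples
#' F <- cbind(m1 = c(-100, -95, -102), m2 = c(-110, -100, -104))
#' rfx_bms(F)
rfx_bms <- function(evidence, alpha0 = 1, xp_samples = 1e6, seed = 1,
                    tol = 1e-4) {
  evidence <- as.matrix(evidence)
  if (!all(is.finite(evidence))) stop("non-finite model evidences")
  n <- nrow(evidence); K <- ncol(evidence)
  if (n < 1 || K < 2) stop("need >= 1 subject and >= 2 models")
  if (is.null(colnames(evidence))) {
    colnames(evidence) <- paste0("model", seq_len(K))
  }
  alpha <- rep(alpha0, K)
  it <- 0L
  repeat {
    it <- it + 1L
    w <- sweep(evidence, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    u <- exp(w - apply(w, 1, max))
    u <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol || it >= 10000L) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }
  mp <- alpha / sum(alpha)
  if (K == 2) {
    xp <- c(pairwise_exceedance_exact(alpha[1], alpha[2]))
    xp <- c(xp, 1 - xp)
    method <- "exact-beta"
  } else {
    xp <- with_seed(seed, {
      draws <- matrix(stats::rgamma(xp_samples * K, shape = rep(alpha, each = xp_samples)),
                      nrow = xp_samples)
      tabulate(max.col(draws), nbins = K) / xp_samples
    })
    method <- "dirichlet-mc"
  }
  names(alpha) <- names(mp) <- names(xp) <- colnames(evidence)
  structure(list(alpha = alpha, mp = mp, xp = xp, iterations = it,
                 xp_method = method, n_subjects = n),
            class = "bms_result")
}

#' @export
print.bms_result <- function(x, ...) {
  cat(sprintf("<bms_result> %d subjects, %d models (%s, %d iterations)\n",
              x$n_subjects, length(x$alpha), x$xp_method, x$iterations))
  print(data.frame(alpha = round(x$alpha, 3), mp = round(x$mp, 4),
                   xp = round(x$xp, 4)))
  invisible(x)
}

#' Exact two-model exceedance probability
#'
#' For K = 2 the frequency of model 1 is Beta(alpha1, alpha2) distributed,
#' so `xp(1) = P(r1 > 0.5)` has the closed form
#' `1 - I_{0.5}(alpha1, alpha2)` (regularized incomplete beta).
#'
#' @param alpha1,alpha2 positive Dirichlet concentrations.
#' @return exceedance probability of model 1.
#' @export
#' @examples
#' pairwise_exceedance_exact(2, 1) # 0.75
pairwise_exceedance_exact <- function(alpha1, alpha2) {
  if (alpha1 <= 0 || alpha2 <= 0) stop("concentrations must be positive")
  stats::pbeta(0.5, alpha1, alpha2, lower.tail = FALSE)
}

#' Build an evidence table from a list of fits
#'
#' Convenience: stacks `posterior_fit` free energies into the subjects x
#' models matrix [rfx_bms()] consumes.
#'
#' @param fits nested list: `fits[[subject]][[model_name]]` of
#'   `posterior_fit` objects (all subjects fitted with the same models).
#' @return numeric matrix with subject ids as row names and model names as
#'   column names.
#' @export
evidence_table <- function(fits) {
  models <- names(fits[[1]])
  out <- t(vapply(fits, function(sub) {
    vapply(models, function(m) sub[[m]]$F, numeric(1))
  }, numeric(length(models))))
  colnames(out) <- models
  rownames(out) <- names(fits) %||% paste0("s", seq_along(fits))
  out
}
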