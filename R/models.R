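#' Discounting model specifications
#'
#' A `model_spec` names one of the five candidate discount functions and
#' carries its parameter list, the unconstrained estimation-space transform
#' used per parameter during fitting, and the native-space initialization
#' ranges spanned by the multi-start grid.
#'
#' The five models map a reward magnitude `M` (display units, 0-75) and a
#' normalized cost `C` (0 = no cost, 1 = maximum cost: 75 weeks of delay or
#' 100% of the participant-scaled maximum grip force) to a subjective value:
#'
#' * `hyperbolic`:  V = M / (1 + kC)
#' * `linear`:      V = M - kC
#' * `quadratic`:   V = M - kC^2
#' * `sigmoidal`:   V = M (1 - (s(k(C - p)) - s(-kp)) (1 + e^(-kp))),
#'   with `s` the logistic function; the subtraction of `s(-kp)` forces the
#'   curve through (0, M) and the trailing factor makes it converge to 0 for
#'   large C rather than to a positive floor
#' * `power`:       V = M - kC^p (flexible two-parameter power function)
#'
#' `k` is the discount slope; `p` is the sigmoidal turning point or the power
#' exponent. One-parameter models fit `(k, beta)`, two-parameter models
#' `(k, p, beta)`, with `beta` the softmax temperature.
#'
#' @param name one of `"hyperbolic"`, `"linear"`, `"quadratic"`,
#'   `"sigmoidal"`, `"power"`.
#' @return an object of class `model_spec`: list with `name`, `params`
#'   (parameter names excluding beta), `transforms` (per parameter, including
#'   beta; `"log"` or `"identity"`), and `init_range` (estimation-space
#'   ranges spanned by the initialization grid).
#' @export
#' @examples
#' model_spec("sigmoidal")
model_spec <- function(name = c("hyperbolic", "linear", "quadratic",
                                "sigmoidal", "power")) {
  name <- match.arg(name)
  two_par <- name %in% c("sigmoidal", "power")
  params <- if (two_par) c("k", "p") else "k"
  # The sigmoidal turning point lives on the identity scale (not clipped at
  # 1: turning points beyond the maximum cost are admissible, and p <= 0 is
  # a legal degenerate curve). The power exponent is intrinsically positive
  # (C^p diverges at C = 0 for p < 0), so it is estimated on the log scale.
  transforms <- c(
    k = "log",
    if (name == "sigmoidal") c(p = "identity"),
    if (name == "power") c(p = "log"),
    beta = "log"
  )
  # Estimation-space ranges covered by the multi-start grid ("the relevant
  # parameter range"): k from 0.1 to 50, sigmoidal p from 0.05 to 1.2,
  # power exponent from 0.5 to 4, beta from 0.01 to 5 in display-unit
  # value space.
  init_range <- rbind(
    k = log(c(0.1, 50)),
    if (name == "sigmoidal") rbind(p = c(0.05, 1.2)),
    if (name == "power") rbind(p = log(c(0.5, 4))),
    beta = log(c(0.01, 5))
  )
  rownames(init_range) <- names(transforms)
  structure(
    list(name = name, params = params, transforms = transforms,
         init_range = init_range),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", x$name, "\n  parameters:",
      paste(x$params, collapse = ", "), "+ beta\n")
  invisible(x)
}

#' All candidate model names
#' @return character vector of the five model names.
#' @export
model_names <- function() {
  c("hyperbolic", "linear", "quadratic", "sigmoidal", "power")
}

#' Subjective (discounted) value of an offer
#'
#' Evaluates the chosen discount function at magnitude `M` and cost `C`.
#' Vectorized over `M` and `C`. Costs outside `[0, 1]` are accepted without
#' error: optimizers and the staircase engine probe values beyond the
#' stimulus range, and the sigmoidal model is defined on the whole real line.
#' When `alpha != 1` the magnitude is replaced by the utility `M^alpha`
#' before discounting (the transform never touches `C`).
#'
#' @param model a `model_spec` or model name.
#' @param params named list/vector with `k` (and `p` for two-parameter
#'   models) in native space.
#' @param M reward magnitude(s), `>= 0`.
#' @param C normalized cost(s).
#' @param alpha utility exponent in `(0, 1]`; default 1 (identity).
#' @return numeric vector of subjective values in the (possibly
#'   utility-transformed) units of `M`.
#' @export
#' @examples
#' subjective_value("hyperbolic", list(k = 4.86), M = 75, C = 1)
#' subjective_value("sigmoidal", list(k = 10.49, p = 0.70), M = 75, C = 0.5)
subjective_value <- function(model, params, M, C, alpha = 1) {
  if (is.character(model)) model <- model_spec(model)
  stopifnot(inherits(model, "model_spec"))
  params <- as.list(params)
  k <- params$k
  if (is.null(k) || !all(is.finite(k))) stop("non-finite or missing parameter 'k'")
  if (any(M < 0)) stop("negative magnitude")
  M <- apply_utility(M, alpha)
  switch(model$name,
    hyperbolic = M / (1 + k * C),
    linear     = M - k * C,
    quadratic  = M - k * C^2,
    power      = {
      p <- params$p
      if (is.null(p) || !all(is.finite(p))) stop("non-finite or missing parameter 'p'")
      M - k * ifelse(C < 0, NA_real_, C)^p
    },
    sigmoidal  = {
      p <- params$p
      if (is.null(p) || !all(is.finite(p))) stop("non-finite or missing parameter 'p'")
      # V = M (1 - (s(k(C-p)) - s(-kp)) (1 + e^{-kp})) simplifies exactly to
      # V = M s(-k(C-p)) / s(kp); evaluated in log space so that deep logistic
      # saturation (k|C-p| or k|p| >> 700) neither overflows nor cancels.
      M * exp(stats::plogis(-k * (C - p), log.p = TRUE) -
                stats::plogis(k * p, log.p = TRUE))
    }
  )
}

#' Softmax probability of choosing option 1
#'
#' `P(choose 1) = 1 / (1 + exp(-beta (V1 - V2)))`. The temperature `beta`
#' sets how sensitive choice is to the value difference; `beta = 0` is a
#' coin flip and large `beta` approaches deterministic maximization.
#'
#' @param beta softmax temperature, `>= 0`.
#' @param V1,V2 subjective values of the two options (finite; vectorized).
#' @return probability/ies in `(0, 1)`.
#' @export
#' @examples
#' choice_probability(1, log(3), 0) # 0.75
choice_probability <- function(beta, V1, V2) {
  if (any(beta < 0)) stop("negative softmax temperature beta")
  if (!all(is.finite(V1)) || !all(is.finite(V2))) stop("non-finite subjective values")
  sigmoid(beta * (V1 - V2))
}

#' Utility transform of a reward magnitude
#'
#' Generic concave utility `u(M) = M^alpha`; the population-average
#' `alpha = 0.8` is used when fitting in utility rather than money units.
#'
#' @param M magnitude(s), `>= 0`.
#' @param alpha exponent in `(0, 1]`.
#' @return `M^alpha` (identity when `alpha = 1`).
#' @export
apply_utility <- function(M, alpha = 1) {
  if (any(M < 0)) stop("negative magnitude")
  if (length(alpha) != 1 || !is.finite(alpha) || alpha <= 0 || alpha > 1) {
    stop("alpha must be a single value in (0, 1]")
  }
  if (alpha == 1) M else M^alpha
}
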