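#' Published group-mean evidence decomposition (reference values)
#'
#' Group-averaged accuracy and complexity terms reported in the original
#' effort/delay discounting study for the sigmoidal and hyperbolic models on
#' the effort and delay tasks. The log model evidence is not stored: it is
#' always recomputed as `accuracy - complexity`, which is the identity this
#' table exists to exercise (e.g. -95.3 = -85.6 - 9.7 for the effort-task
#' sigmoidal model). Used by the acceptance checks; the human choice data
#' behind these numbers is not publicly available.
#'
#' @return data.frame with `task`, `model`, `accuracy`, `complexity`.
#' @export
reference_evidence_decomposition <- function() {
  data.frame(
    task = c("effort", "effort", "delay", "delay"),
    model = c("sigmoidal", "hyperbolic", "sigmoidal", "hyperbolic"),
    accuracy = c(-85.6, -124.8, -153.6, -151.4),
    complexity = c(9.7, 5.8, 5.7, 5.0)
  )
}

#' Published group-mean parameter estimates (reference values)
#'
#' Winning-model group means: sigmoidal `k = 10.49`, `p = 0.70` for the
#' effort task and hyperbolic `k = 4.86` for the delay task. Default
#' centers for synthetic cohorts that emulate the study's populations.
#'
#' @return named list with `effort_sigmoidal` (`k`, `p`) and
#'   `delay_hyperbolic` (`k`).
#' @export
reference_group_parameters <- function() {
  list(effort_sigmoidal = list(k = 10.49, p = 0.70),
       delay_hyperbolic = list(k = 4.86))
}
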