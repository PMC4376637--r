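#' Construct a trial-level choice dataset
#'
#' The container every fitting and reporting function consumes: one subject's
#' two-alternative choices. Each trial offers option 1 `(m1, c1)` against
#' option 2 `(m2, c2)` (magnitudes in display units, costs normalized to
#' `[0, 1]`), records which option was chosen, and whether the trial's effort
#' was realized (actually exerted).
#'
#' @param trials data.frame with columns `block`, `trial`, `m1`, `c1`, `m2`,
#'   `c2`, `chosen` (1 or 2), `realized` (logical), and optionally
#'   `is_default1` (logical; marks option 1 as the no-effort default of the
#'   staircase task).
#' @param subject subject identifier (scalar).
#' @param cost_type `"effort"` or `"delay"`.
#' @return an object of class `choice_dataset`.
#' @export
choice_dataset <- function(trials, subject = "s1",
                           cost_type = c("effort", "delay")) {
  cost_type <- match.arg(cost_type)
  required <- c("block", "trial", "m1", "c1", "m2", "c2", "chosen", "realized")
  missing_cols <- setdiff(required, names(trials))
  if (length(missing_cols)) {
    stop("trial table missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!all(trials$chosen %in% c(1L, 2L))) {
    bad <- which(!(trials$chosen %in% c(1L, 2L)))[1]
    stop(sprintf("invalid 'chosen' value at row %d (must be 1 or 2)", bad))
  }
  if (any(trials$m1 < 0) || any(trials$m2 < 0)) stop("negative magnitudes")
  if (!"is_default1" %in% names(trials)) trials$is_default1 <- FALSE
  for (col in c("m1", "c1", "m2", "c2")) trials[[col]] <- as.numeric(trials[[col]])
  trials$block <- as.integer(trials$block)
  trials$trial <- as.integer(trials$trial)
  trials$chosen <- as.integer(trials$chosen)
  trials$realized <- as.logical(trials$realized)
  trials$is_default1 <- as.logical(trials$is_default1)
  structure(
    list(subject = subject, cost_type = cost_type, trials = trials),
    class = "choice_dataset"
  )
}

#' @export
print.choice_dataset <- function(x, ...) {
  cat(sprintf("<choice_dataset> subject %s, %s task: %d trials, %d block(s), %.1f%% realized\n",
              x$subject, x$cost_type, nrow(x$trials),
              length(unique(x$trials$block)), 100 * mean(x$trials$realized)))
  invisible(x)
}

#' Number of trials in a choice dataset
#' @param x a `choice_dataset`.
#' @return integer trial count.
#' @export
n_trials <- function(x) nrow(x$trials)
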