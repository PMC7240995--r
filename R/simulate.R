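#' Simulate a single two-stage trial
#'
#' Draws stage-1 responses `x1 ~ Binomial(n1, p)`, applies the stage-1
#' stopping rule (Simon: stop and reject if `x1 <= r1`; Fleming: stop
#' and reject if `x1 <= a1`, stop and accept if `x1 >= r1`), and if the
#' trial continues draws `x2 ~ Binomial(n2, p)` and applies the final
#' rule (Simon: reject iff `x1 + x2 <= r`; Fleming: accept iff
#' `x1 + x2 >= r`).  Uses the current RNG state; seed with
#' [set.seed()] for reproducibility.
#'
#' @param design a [two_stage_design()] object.
#' @param p true response probability.
#' @return a list of class `"ph2_trial"`: `decision`
#'   (`"reject_treatment"` or `"accept_treatment"`), `stopped_early`,
#'   `n_used`, `responses`.
#' @export
simulate_trial <- function(design, p) {
  design <- as_ph2_design(design)
  stopifnot(length(p) == 1L, is.numeric(p), p >= 0, p <= 1)
  x1 <- rbinom(1L, design$n1, p)
  if (design$family == "simon") {
    if (x1 <= design$r1) {
      out <- list(decision = "reject_treatment", stopped_early = TRUE,
                  n_used = design$n1, responses = x1)
      return(structure(out, class = "ph2_trial"))
    }
    x2 <- rbinom(1L, design$n2, p)
    dec <- if (x1 + x2 <= design$r) "reject_treatment" else "accept_treatment"
  } else {
    if (x1 <= design$a1) {
      return(structure(list(decision = "reject_treatment",
                            stopped_early = TRUE, n_used = design$n1,
                            responses = x1), class = "ph2_trial"))
    }
    if (x1 >= design$r1) {
      return(structure(list(decision = "accept_treatment",
                            stopped_early = TRUE, n_used = design$n1,
                            responses = x1), class = "ph2_trial"))
    }
    x2 <- rbinom(1L, design$n2, p)
    dec <- if (x1 + x2 >= design$r) "accept_treatment" else "reject_treatment"
  }
  structure(list(decision = dec, stopped_early = FALSE,
                 n_used = design$n, responses = x1 + x2),
            class = "ph2_trial")
}

#' @export
print.ph2_trial <- function(x, ...) {
  cat(sprintf("%s after %d patients (%d responses%s)\n",
              x$decision, x$n_used, x$responses,
              if (x$stopped_early) ", stopped at stage 1" else ""))
  invisible(x)
}

#' Monte Carlo estimate of operating characteristics
#'
#' Simulates `reps` independent trials under response rate `p` and
#' returns the empirical rejection probability, early-termination
#' probability and mean sample size, with standard errors (binomial for
#' the two proportions, `sd/sqrt(reps)` for the sample size).  A single
#' root seed makes the whole replicate stream reproducible.  The
#' simulator exists as an independent verification of the exact
#' operating characteristics and for teaching; design ranking always
#' uses the exact values.
#'
#' @param design a [two_stage_design()] object.
#' @param p true response probability.
#' @param reps number of simulated trials (>= 1).
#' @param seed optional integer seed.
#' @return a list of class `"ph2_sim"`: `reject`, `pet1`, `en` and a
#'   list `se` of their standard errors, plus `reps`.
#' @examples
#' d <- two_stage_design("simon", n1 = 9, n2 = 8, r1 = 0, r = 2)
#' estimate_oc(d, 0.05, reps = 10000, seed = 1)
#' @export
estimate_oc <- function(design, p, reps, seed = NULL) {
  design <- as_ph2_design(design)
  stopifnot(length(p) == 1L, is.numeric(p), p >= 0, p <= 1,
            length(reps) == 1L, reps >= 1, reps == floor(reps))
  reps <- as.integer(reps)
  if (!is.null(seed)) set.seed(seed)
  x1 <- rbinom(reps, design$n1, p)
  if (design$family == "simon") {
    early <- x1 <= design$r1
    reject <- early
    cont <- !early
    if (any(cont)) {
      x2 <- rbinom(sum(cont), design$n2, p)
      reject[cont] <- (x1[cont] + x2) <= design$r
    }
  } else {
    fut <- x1 <= design$a1
    eff <- x1 >= design$r1
    early <- fut | eff
    reject <- fut
    cont <- !early
    if (any(cont)) {
      x2 <- rbinom(sum(cont), design$n2, p)
      reject[cont] <- (x1[cont] + x2) < design$r
    }
  }
  n_used <- ifelse(early, design$n1, design$n)
  pr <- mean(reject); pe <- mean(early)
  structure(list(reject = pr, pet1 = pe, en = mean(n_used),
                 se = list(reject = sqrt(pr * (1 - pr) / reps),
                           pet1 = sqrt(pe * (1 - pe) / reps),
                           en = sd(n_used) / sqrt(reps)),
                 reps = reps),
            class = "ph2_sim")
}

#' @export
print.ph2_sim <- function(x, ...) {
  cat(sprintf(
    "Monte Carlo (%d trials):\n  P(reject treatment) = %.4f (SE %.4f)\n  PET1                = %.4f (SE %.4f)\n  mean sample size    = %.3f (SE %.3f)\n",
    x$reps, x$reject, x$se$reject, x$pet1, x$se$pet1, x$en, x$se$en))
  invisible(x)
}
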