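#' Exact probability of rejecting the treatment
#'
#' Probability that a two-stage trial ends by declaring the treatment not
#' promising (failing to reject H0), as a function of the true response
#' rate `p`.  For Simon's rule this is
#' \deqn{P(R) = B(r_1; n_1, p) + \sum_{x = r_1 + 1}^{n_1}
#'   b(x; n_1, p)\, B(r - x; n_2, p),}
#' the early futility stop plus continuation paths whose total stays at
#' or below `r`.  For Fleming's rule the continuation region is
#' `a1 < x1 < r1` and the trial rejects at the end when the total falls
#' short of the acceptance point `r`:
#' \deqn{P(R) = B(a_1; n_1, p) + \sum_{x = a_1 + 1}^{r_1 - 1}
#'   b(x; n_1, p)\, B(r - 1 - x; n_2, p).}
#' Out-of-range cumulative arguments follow the 0/1 conventions of
#' [binom_cdf()], so no special cases arise at the boundaries.
#'
#' @param design a [two_stage_design()] object.
#' @param p true response probability; may be a vector.
#' @return rejection probability (same length as `p`).
#' @examples
#' d <- two_stage_design("simon", n1 = 9, n2 = 8, r1 = 0, r = 2)
#' 1 - reject_prob(d, 0.05)  # attained type I error
#' @export
reject_prob <- function(design, p) {
  design <- as_ph2_design(design)
  stopifnot(is.numeric(p), !anyNA(p), all(p >= 0), all(p <= 1))
  vapply(p, function(pp) reject_prob_scalar(design, pp), numeric(1))
}

reject_prob_scalar <- function(d, p) {
  if (d$family == "simon") {
    out <- pbinom(d$r1, d$n1, p)
    if (d$r1 < d$n1) {
      x <- seq.int(d$r1 + 1L, d$n1)
      out <- out + sum(dbinom(x, d$n1, p) * pbinom(d$r - x, d$n2, p))
    }
    out
  } else {
    x <- seq.int(d$a1 + 1L, d$r1 - 1L)
    pbinom(d$a1, d$n1, p) +
      sum(dbinom(x, d$n1, p) * pbinom(d$r - 1L - x, d$n2, p))
  }
}

#' Probability of early termination after stage 1
#'
#' For Simon's rule only futility stops the trial early, so
#' `PET1 = B(r1; n1, p)`.  Fleming's rule also stops early for efficacy:
#' `PET1 = B(a1; n1, p) + P(x1 >= r1)`.
#'
#' @inheritParams reject_prob
#' @return early termination probability (same length as `p`).
#' @export
pet1 <- function(design, p) {
  design <- as_ph2_design(design)
  stopifnot(is.numeric(p), !anyNA(p), all(p >= 0), all(p <= 1))
  if (design$family == "simon") {
    pbinom(design$r1, design$n1, p)
  } else {
    pbinom(design$a1, design$n1, p) +
      1 - pbinom(design$r1 - 1L, design$n1, p)
  }
}

#' Expected sample size of a two-stage design
#'
#' `EN = n1 + (1 - PET1) * n2`, the expected number of patients enrolled
#' when the true response rate is `p`.  Design comparisons in this
#' package always evaluate EN (and PET1) under the null rate `p0`.
#'
#' @inheritParams reject_prob
#' @return expected sample size, in `[n1, n1 + n2]`.
#' @export
expected_n <- function(design, p) {
  design <- as_ph2_design(design)
  design$n1 + (1 - pet1(design, p)) * design$n2
}

#' Operating characteristics of a design under given parameters
#'
#' Evaluates the attained type I error `alpha_T = 1 - P(R | p0)`, the
#' attained power `1 - P(R | p1)`, and the early-termination probability
#' and expected sample size under the null response rate `p0`.
#'
#' @param design a [two_stage_design()] object.
#' @param params a [design_params()] object.
#' @return an object of class `"ph2_oc"`: list with elements `alpha_T`,
#'   `power`, `pet1`, `en`.
#' @examples
#' d <- two_stage_design("simon", n1 = 9, n2 = 8, r1 = 0, r = 2)
#' operating_chars(d, design_params(0.05, 0.25, 0.05, 0.20))
#' @export
operating_chars <- function(design, params) {
  design <- as_ph2_design(design)
  stopifnot(inherits(params, "ph2_params"))
  structure(list(alpha_T = 1 - reject_prob(design, params$p0),
                 power   = 1 - reject_prob(design, params$p1),
                 pet1    = pet1(design, params$p0),
                 en      = expected_n(design, params$p0)),
            class = "ph2_oc")
}

#' @export
print.ph2_oc <- function(x, ...) {
  cat(sprintf(
    "alpha_T = %.4f, power = %.4f, PET1 = %.4f, EN = %.2f\n",
    x$alpha_T, x$power, x$pet1, x$en))
  invisible(x)
}

#' Does a design meet the error constraints?
#'
#' Inclusive comparisons on the unrounded attained values:
#' `alpha_T <= alpha` and `power >= 1 - beta`.
#'
#' @param oc an `"ph2_oc"` object (or any list with `alpha_T`, `power`).
#' @param params a [design_params()] object.
#' @return `TRUE` or `FALSE`.
#' @export
is_feasible <- function(oc, params) {
  stopifnot(inherits(params, "ph2_params"))
  isTRUE(oc$alpha_T <= params$alpha && oc$power >= 1 - params$beta)
}
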