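#' Design parameters for a two-stage phase II search
#'
#' Bundles the hypotheses and error constraints that define feasibility of
#' a two-stage design: the largest uninteresting response rate `p0`, the
#' smallest response rate `p1` that would warrant further study, the
#' one-sided type I error bound `alpha` and the type II error bound
#' `beta`, together with the range of total sample sizes to search.
#'
#' A design is feasible when its attained type I error is at most `alpha`
#' and its attained power at `p1` is at least `1 - beta`; both comparisons
#' are made on unrounded exact probabilities.
#'
#' `n_max` defaults to `max(100, 2 * single_stage_n(...))`, which
#' comfortably contains the optimal two-stage design for conventional
#' phase II settings (the single-stage design is an upper benchmark on
#' the sample size actually needed).
#'
#' @param p0 response probability under the null hypothesis, in (0, 1).
#' @param p1 response probability targeted by the alternative; must
#'   exceed `p0`.
#' @param alpha nominal one-sided type I error bound, in (0, 1).
#' @param beta nominal type II error bound, in (0, 1).
#' @param n_min smallest total sample size scanned (default 1).
#' @param n_max largest total sample size scanned; `NULL` for the default
#'   described above.
#' @return an object of class `"ph2_params"`: a list with elements `p0`,
#'   `p1`, `alpha`, `beta`, `n_min`, `n_max`.
#' @examples
#' design_params(0.05, 0.25, alpha = 0.05, beta = 0.10)
#' @export
design_params <- function(p0, p1, alpha, beta, n_min = 1L, n_max = NULL) {
  for (nm in c("p0", "p1", "alpha", "beta")) {
    v <- get(nm)
    if (length(v) != 1L || !is.numeric(v) || is.na(v) || v <= 0 || v >= 1) {
      stop(sprintf("'%s' must be a single number in (0, 1)", nm),
           call. = FALSE)
    }
  }
  if (p0 >= p1) stop("'p0' must be strictly less than 'p1'", call. = FALSE)
  if (length(n_min) != 1L || n_min < 1 || n_min != floor(n_min)) {
    stop("'n_min' must be a single integer >= 1", call. = FALSE)
  }
  n_min <- as.integer(n_min)
  if (is.null(n_max)) {
    ss <- ss_n_scan(p0, p1, alpha, beta, n_lo = n_min, n_hi = 1000L)
    if (is.na(ss)) {
      stop("no single-stage design with n <= 1000 meets the error ",
           "constraints; supply 'n_max' explicitly", call. = FALSE)
    }
    n_max <- max(100L, 2L * ss)
  }
  if (length(n_max) != 1L || n_max != floor(n_max) || n_max < n_min) {
    stop("'n_max' must be a single integer >= n_min", call. = FALSE)
  }
  structure(list(p0 = p0, p1 = p1, alpha = alpha, beta = beta,
                 n_min = n_min, n_max = as.integer(n_max)),
            class = "ph2_params")
}

#' @export
print.ph2_params <- function(x, ...) {
  cat(sprintf(
    "Two-stage phase II design parameters\n  H0: p <= %g  vs  H1: p > %g (power computed at p1 = %g)\n  alpha <= %g, beta <= %g; total n searched in [%d, %d]\n",
    x$p0, x$p0, x$p1, x$alpha, x$beta, x$n_min, x$n_max))
  invisible(x)
}

#' Specify a two-stage stopping rule
#'
#' Constructs a Simon or Fleming two-stage design.  The decision
#' conventions follow the standard tabulations of each family:
#'
#' * **Simon** (futility stopping only): after stage 1 (`n1` patients),
#'   stop and reject the treatment if `x1 <= r1`; otherwise enrol `n2`
#'   more.  At the end, reject the treatment iff the total number of
#'   responses is `<= r` (declare it promising iff `x1 + x2 >= r + 1`).
#' * **Fleming** (futility and efficacy stopping): after stage 1, stop
#'   and reject if `x1 <= a1`; stop and accept (declare promising) if
#'   `x1 >= r1`; continue when `a1 < x1 < r1`.  At the end, accept iff
#'   `x1 + x2 >= r` and reject otherwise.
#'
#' So `r1` and `r` are *rejection points* for Simon (largest counts that
#' still reject) but *acceptance points* for Fleming (smallest counts
#' that accept), matching how each family's designs are printed in the
#' literature.  "Rejecting the treatment" means failing to reject
#' H0: p <= p0, i.e. concluding the treatment is not promising.
#'
#' A Fleming design needs a non-empty continuation region, hence
#' `a1 <= r1 - 2`; degenerate rules that always stop at stage 1 are
#' rejected rather than treated as single-stage designs.
#'
#' @param family `"simon"` or `"fleming"`.
#' @param n1,n2 stage-1 and stage-2 sample sizes (both >= 1).
#' @param r1 stage-1 threshold: futility bound for Simon (stop if
#'   `x1 <= r1`), efficacy bound for Fleming (stop if `x1 >= r1`).
#' @param r final threshold: Simon rejects iff total responses `<= r`
#'   (requires `r1 <= r <= n - 1`); Fleming accepts iff total `>= r`
#'   (requires `r1 <= r <= n`).
#' @param a1 Fleming stage-1 futility bound (stop if `x1 <= a1`);
#'   must satisfy `0 <= a1 <= r1 - 2`.  Ignored for Simon.
#' @return an object of class `"ph2_design"`.
#' @examples
#' two_stage_design("simon", n1 = 9, n2 = 8, r1 = 0, r = 2)
#' two_stage_design("fleming", n1 = 9, n2 = 21, a1 = 0, r1 = 4, r = 4)
#' @export
two_stage_design <- function(family = c("simon", "fleming"),
                             n1, n2, r1, r, a1 = NULL) {
  family <- match.arg(family)
  for (nm in c("n1", "n2", "r1", "r")) {
    v <- get(nm)
    if (length(v) != 1L || !is.numeric(v) || is.na(v) || v != floor(v)) {
      stop(sprintf("'%s' must be a single integer", nm), call. = FALSE)
    }
  }
  n1 <- as.integer(n1); n2 <- as.integer(n2)
  r1 <- as.integer(r1); r <- as.integer(r)
  if (n1 < 1L || n2 < 1L) stop("'n1' and 'n2' must be >= 1", call. = FALSE)
  n <- n1 + n2
  if (family == "simon") {
    if (!is.null(a1) && !is.na(a1)) {
      stop("'a1' applies only to Fleming designs", call. = FALSE)
    }
    if (r1 < 0L || r1 > n1) stop("need 0 <= r1 <= n1", call. = FALSE)
    if (r < r1 || r > n - 1L) stop("need r1 <= r <= n - 1", call. = FALSE)
    a1 <- NA_integer_
  } else {
    if (is.null(a1) || is.na(a1)) {
      stop("Fleming designs require 'a1'", call. = FALSE)
    }
    a1 <- as.integer(a1)
    if (r1 < 1L || r1 > n1) stop("need 1 <= r1 <= n1", call. = FALSE)
    if (a1 < 0L || a1 > r1 - 2L) {
      stop("need 0 <= a1 <= r1 - 2 (non-empty continuation region)",
           call. = FALSE)
    }
    if (r < r1 || r > n) stop("need r1 <= r <= n", call. = FALSE)
  }
  structure(list(family = family, n1 = n1, n2 = n2, n = n,
                 a1 = a1, r1 = r1, r = r),
            class = "ph2_design")
}

#' @export
print.ph2_design <- function(x, ...) {
  if (x$family == "simon") {
    cat(sprintf(
      "Simon two-stage design: n1 = %d, n2 = %d (n = %d)\n  stage 1: stop for futility if x1 <= %d\n  final:   reject the treatment if total responses <= %d\n",
      x$n1, x$n2, x$n, x$r1, x$r))
  } else {
    cat(sprintf(
      "Fleming two-stage design: n1 = %d, n2 = %d (n = %d)\n  stage 1: stop for futility if x1 <= %d; stop for efficacy if x1 >= %d\n  final:   accept the treatment if total responses >= %d\n",
      x$n1, x$n2, x$n, x$a1, x$r1, x$r))
  }
  invisible(x)
}

as_ph2_design <- function(x) {
  if (inherits(x, "ph2_design")) return(x)
  stop("expected a 'ph2_design' object (see two_stage_design())",
       call. = FALSE)
}
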