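#' Binomial probability mass with out-of-support convention
#'
#' Exact binomial probability mass b(x; n, p), evaluated through the
#' numerically stable log-gamma implementation in [stats::dbinom()].
#' Counts outside the support return 0, so downstream two-stage rejection
#' probabilities need no special-casing when a stage-2 threshold falls
#' below 0 or above n2.
#'
#' @param x integer count(s); any integer is allowed, values outside
#'   `0:n` have mass 0.
#' @param n number of trials (single positive integer).
#' @param p success probability in `[0, 1]`.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @seealso [binom_cdf()]
#' @examples
#' binom_pmf(0, 9, 0.05)   # 0.95^9
#' binom_pmf(-1, 5, 0.3)   # 0
#' @export
binom_pmf <- function(x, n, p) {
  check_binom_args(x, n, p, "x")
  out <- numeric(length(x))
  ok <- x >= 0 & x <= n
  out[ok] <- dbinom(x[ok], n, p)
  out
}

#' Cumulative binomial distribution with boundary conventions
#'
#' B(k; n, p) = sum of b(x; n, p) over x = 0..k, with B(k) = 0 for k < 0
#' and B(k) = 1 for k >= n.
#'
#' @param k integer upper summation limit(s).
#' @inheritParams binom_pmf
#' @return numeric vector of probabilities in `[0, 1]`.
#' @examples
#' binom_cdf(-1, 9, 0.05)  # 0
#' binom_cdf(9, 9, 0.05)   # 1
#' @export
binom_cdf <- function(k, n, p) {
  check_binom_args(k, n, p, "k")
  pbinom(k, n, p)
}

check_binom_args <- function(x, n, p, xname) {
  if (length(n) != 1L || !is.numeric(n) || is.na(n) || n < 1 ||
      n != floor(n)) {
    stop("'n' must be a single integer >= 1", call. = FALSE)
  }
  if (length(p) != 1L || !is.numeric(p) || is.na(p) || p < 0 || p > 1) {
    stop("'p' must be a single probability in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(x) || anyNA(x) || any(x != floor(x))) {
    stop(sprintf("'%s' must be integer-valued", xname), call. = FALSE)
  }
  invisible(TRUE)
}
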