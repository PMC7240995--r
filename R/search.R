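# Exhaustive design search.
#
# The per-n kernels below enumerate every admissible stopping rule exactly;
# the only shortcuts are (i) necessary-condition masks that can never drop
# a feasible rule (a rule whose stage-1 futility stop alone already costs
# more than beta in power, or whose stage-1 efficacy stop alone already
# spends more than alpha, has no feasible final threshold), and (ii) an
# expected-sample-size dominance cut against the best rule found so far,
# which cannot drop the EN-minimising rule.  Rejection probabilities for
# all final thresholds r at once are obtained from cumulative-sum tables
# of b(x; n1, p) * B(.; n2, p), so each (stage-1 rule) costs one O(n)
# vector scan.

ss_n_scan <- function(p0, p1, alpha, beta, n_lo = 1L, n_hi = 1000L) {
  for (n in n_lo:n_hi) {
    cc <- qbinom(1 - alpha, n, p0)  # smallest c with B(c; n, p0) >= 1 - alpha
    if (pbinom(cc, n, p1) <= beta) return(as.integer(n))
  }
  NA_integer_
}

#' Smallest single-stage sample size meeting the error constraints
#'
#' The smallest `n` for which some cutoff `c` satisfies
#' `1 - B(c; n, p0) <= alpha` and `1 - B(c; n, p1) >= 1 - beta`
#' (reject H0 iff more than `c` responses).  Used as a benchmark when
#' choosing default search caps: a two-stage design is only interesting
#' if it does not cost much more than the single-stage test.
#'
#' @param params a [design_params()] object.
#' @return a single integer sample size.
#' @export
single_stage_n <- function(params) {
  stopifnot(inherits(params, "ph2_params"))
  n <- ss_n_scan(params$p0, params$p1, params$alpha, params$beta,
                 n_lo = params$n_min, n_hi = params$n_max)
  if (is.na(n)) {
    stop(sprintf(
      "no single-stage design with n <= %d meets the error constraints (search-cap exhaustion)",
      params$n_max), call. = FALSE)
  }
  n
}

# numerical slack for inclusive feasibility comparisons and EN ties
.feas_eps <- 1e-12
.en_tol <- 1e-12

# Per-n search kernel, Simon family.  Returns NULL or a list with the
# stage-1 rule, the smallest feasible final threshold r, and exact
# operating characteristics.  Tie-breaks (EN ties within .en_tol):
# smallest n1, then smallest r1, then smallest r.
best_simon_n <- function(pa, n) {
  p0 <- pa$p0; p1 <- pa$p1; alpha <- pa$alpha; beta <- pa$beta
  best <- NULL; best_en <- Inf
  for (n1 in seq_len(n - 1L)) {
    n2 <- n - n1
    cdf0 <- pbinom(0:n1, n1, p0)
    cdf1 <- pbinom(0:n1, n1, p1)
    en_all <- n1 + (1 - cdf0) * n2              # EN indexed by r1 + 1
    # necessary: futility stop alone must not spend more than beta
    viable <- cdf1 <= beta + .feas_eps & en_all < best_en - .en_tol
    if (!any(viable)) next
    b0 <- dbinom(0:n1, n1, p0)
    b1 <- dbinom(0:n1, n1, p1)
    lv0 <- c(0, pbinom(0:n2, n2, p0))
    lv1 <- c(0, pbinom(0:n2, n2, p1))
    kk <- outer(0:n1, 0:(n - 1L), function(x, r) r - x)
    ind <- pmin(pmax(kk, -1L), n2) + 2L
    M0 <- b0 * matrix(lv0[ind], n1 + 1L)
    M1 <- b1 * matrix(lv1[ind], n1 + 1L)
    U0 <- M0; U1 <- M1
    if (n1 >= 1L) {
      for (i in seq.int(2L, n1 + 1L)) {
        U0[i, ] <- U0[i - 1L, ] + M0[i, ]
        U1[i, ] <- U1[i - 1L, ] + M1[i, ]
      }
    }
    for (r1 in (which(viable) - 1L)) {
      en_i <- en_all[r1 + 1L]
      if (en_i >= best_en - .en_tol) next
      idx <- (r1 + 1L):n                         # columns for r = r1..n-1
      pr0 <- cdf0[r1 + 1L] + (U0[n1 + 1L, idx] - U0[r1 + 1L, idx])
      j <- which(pr0 >= 1 - alpha - .feas_eps)[1L]  # smallest feasible r
      if (is.na(j)) next
      pr1 <- cdf1[r1 + 1L] + (U1[n1 + 1L, idx[j]] - U1[r1 + 1L, idx[j]])
      if (pr1 > beta + .feas_eps) next
      best_en <- en_i
      best <- list(n1 = n1, n2 = n2, a1 = NA_integer_,
                   r1 = r1, r = r1 + j - 1L)
    }
  }
  best
}

# Per-n search kernel, Fleming family.  Continuation region a1 < x1 < r1,
# final acceptance iff total >= r.  Tie-breaks: smallest n1, then
# smallest r1, then largest a1, then smallest r.
best_fleming_n <- function(pa, n) {
  p0 <- pa$p0; p1 <- pa$p1; alpha <- pa$alpha; beta <- pa$beta
  best <- NULL; best_en <- Inf
  for (n1 in seq_len(n - 1L)) {
    if (n1 < 2L) next                            # need a1 >= 0, r1 >= a1 + 2
    n2 <- n - n1
    cdf0 <- pbinom(0:n1, n1, p0)
    cdf1 <- pbinom(0:n1, n1, p1)
    # necessary: stage-1 efficacy stop alone must not spend more than alpha
    r1s <- which(1 - cdf0[seq_len(n1)] <= alpha + .feas_eps)
    r1s <- r1s[r1s >= 2L]
    # necessary: stage-1 futility stop alone must not spend more than beta
    a1s_all <- which(cdf1 <= beta + .feas_eps) - 1L
    if (!length(r1s) || !length(a1s_all)) next
    built <- FALSE
    T0 <- T1 <- NULL
    for (r1 in r1s) {
      a1s <- a1s_all[a1s_all <= r1 - 2L]
      if (!length(a1s)) next
      pet <- cdf0[a1s + 1L] + 1 - cdf0[r1]
      en_v <- n1 + (1 - pet) * n2
      keep <- en_v < best_en - .en_tol
      if (!any(keep)) next
      for (i in order(a1s, decreasing = TRUE)) {  # prefer largest a1 on ties
        if (!keep[i]) next
        en_i <- en_v[i]
        if (en_i >= best_en - .en_tol) next
        a1 <- a1s[i]
        if (!built) {
          b0 <- dbinom(0:n1, n1, p0)
          b1 <- dbinom(0:n1, n1, p1)
          lv0 <- c(0, pbinom(0:n2, n2, p0))
          lv1 <- c(0, pbinom(0:n2, n2, p1))
          kk <- outer(0:n1, 0:n, function(x, r) r - 1L - x)
          ind <- pmin(pmax(kk, -1L), n2) + 2L
          M0 <- b0 * matrix(lv0[ind], n1 + 1L)
          M1 <- b1 * matrix(lv1[ind], n1 + 1L)
          T0 <- M0; T1 <- M1
          for (ii in seq.int(2L, n1 + 1L)) {
            T0[ii, ] <- T0[ii - 1L, ] + M0[ii, ]
            T1[ii, ] <- T1[ii - 1L, ] + M1[ii, ]
          }
          built <- TRUE
        }
        idx <- (r1 + 1L):(n + 1L)                # columns for r = r1..n
        pr0 <- cdf0[a1 + 1L] + (T0[r1, idx] - T0[a1 + 1L, idx])
        j <- which(pr0 >= 1 - alpha - .feas_eps)[1L]
        if (is.na(j)) next
        pr1 <- cdf1[a1 + 1L] + (T1[r1, idx[j]] - T1[a1 + 1L, idx[j]])
        if (pr1 > beta + .feas_eps) next
        best_en <- en_i
        best <- list(n1 = n1, n2 = n2, a1 = a1, r1 = r1, r = r1 + j - 1L)
      }
    }
  }
  best
}

#' Best feasible design for a fixed total sample size
#'
#' Among all stopping rules of the requested family with total sample
#' size `n` that meet the error constraints, returns the one minimising
#' the expected sample size under `p0` (the per-n *candidate design*).
#' EN ties (within 1e-12) are broken towards the smallest `n1`, then the
#' smallest `r1`, then (Fleming) the largest `a1`, then the smallest `r`;
#' note that EN does not depend on `r`, so the smallest feasible final
#' threshold is reported.
#'
#' @param params a [design_params()] object.
#' @param n total sample size (single integer >= 2).
#' @param family `"simon"` or `"fleming"`.
#' @return a list of class `"ph2_candidate"` with elements `design` (a
#'   [two_stage_design()] object) and `oc` (its [operating_chars()]),
#'   or `NULL` when no feasible design of size `n` exists.
#' @export
best_for_n <- function(params, n, family = c("simon", "fleming")) {
  stopifnot(inherits(params, "ph2_params"))
  family <- match.arg(family)
  if (length(n) != 1L || n != floor(n) || n < 2L) {
    stop("'n' must be a single integer >= 2", call. = FALSE)
  }
  b <- if (family == "simon") best_simon_n(params, n)
       else best_fleming_n(params, n)
  if (is.null(b)) return(NULL)
  d <- two_stage_design(family, n1 = b$n1, n2 = b$n2,
                        r1 = b$r1, r = b$r,
                        a1 = if (family == "fleming") b$a1 else NULL)
  structure(list(design = d, oc = operating_chars(d, params)),
            class = "ph2_candidate")
}

#' @export
print.ph2_candidate <- function(x, ...) {
  print(x$design)
  print(x$oc)
  invisible(x)
}

#' Enumerate all feasible designs of a given total size
#'
#' Plain exhaustive enumeration (no pruning) of every stopping rule with
#' total sample size `n` that satisfies the error constraints, evaluated
#' with the reference operating-characteristic functions.  Intended for
#' verification and for inspecting the feasible set at small `n`; the
#' search kernels used by [candidate_set()] are independent of this code
#' path.
#'
#' @inheritParams best_for_n
#' @return a data frame with one row per feasible design (columns `n1`,
#'   `n2`, `a1`, `r1`, `r`, `alpha_T`, `power`, `pet1`, `en`); zero rows
#'   when none is feasible.
#' @export
enumerate_feasible <- function(params, n, family = c("simon", "fleming")) {
  stopifnot(inherits(params, "ph2_params"))
  family <- match.arg(family)
  if (length(n) != 1L || n != floor(n) || n < 2L) {
    stop("'n' must be a single integer >= 2", call. = FALSE)
  }
  rows <- list()
  for (n1 in seq_len(n - 1L)) {
    n2 <- n - n1
    if (family == "simon") {
      for (r1 in 0:n1) {
        for (r in r1:(n - 1L)) {
          d <- list(family = "simon", n1 = n1, n2 = n2, n = n,
                    a1 = NA_integer_, r1 = r1, r = r)
          class(d) <- "ph2_design"
          oc <- operating_chars(d, params)
          if (is_feasible(oc, params)) {
            rows[[length(rows) + 1L]] <-
              data.frame(n1 = n1, n2 = n2, a1 = NA_integer_, r1 = r1,
                         r = r, alpha_T = oc$alpha_T, power = oc$power,
                         pet1 = oc$pet1, en = oc$en)
          }
        }
      }
    } else {
      if (n1 < 2L) next
      for (r1 in 2:n1) {
        for (a1 in 0:(r1 - 2L)) {
          for (r in r1:n) {
            d <- list(family = "fleming", n1 = n1, n2 = n2, n = n,
                      a1 = a1, r1 = r1, r = r)
            class(d) <- "ph2_design"
            oc <- operating_chars(d, params)
            if (is_feasible(oc, params)) {
              rows[[length(rows) + 1L]] <-
                data.frame(n1 = n1, n2 = n2, a1 = a1, r1 = r1, r = r,
                           alpha_T = oc$alpha_T, power = oc$power,
                           pet1 = oc$pet1, en = oc$en)
            }
          }
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(n1 = integer(), n2 = integer(), a1 = integer(),
                      r1 = integer(), r = integer(), alpha_T = numeric(),
                      power = numeric(), pet1 = numeric(), en = numeric()))
  }
  do.call(rbind, rows)
}

#' Search for all candidate designs between minimax and optimal
#'
#' Scans total sample sizes upward from `n_min`.  The smallest `n`
#' admitting any feasible design gives the *minimax* design (EN breaking
#' ties among rules at that `n`); scanning continues to `n_max`, and the
#' candidate with the globally smallest expected sample size under `p0`
#' is the *optimal* design (smallest `n` on EN ties).  The returned set
#' holds the per-n EN-minimising candidate for every feasible `n`
#' between the minimax and the optimal total size; sizes with no
#' feasible design are simply absent.
#'
#' @param params a [design_params()] object.
#' @param family `"simon"` or `"fleming"`.
#' @return an object of class `"ph2_candidate_set"`: a list with
#'   `params`, `family`, `candidates` (data frame ordered by increasing
#'   `n`, columns as in [enumerate_feasible()] plus `n`), and the row
#'   indices `minimax` and `optimal`.
#' @examples
#' \donttest{
#' ps <- design_params(0.05, 0.25, alpha = 0.05, beta = 0.20)
#' cs <- candidate_set(ps, "simon")
#' cs$candidates[c(cs$minimax, cs$optimal), ]
#' }
#' @export
candidate_set <- function(params, family = c("simon", "fleming")) {
  stopifnot(inherits(params, "ph2_params"))
  family <- match.arg(family)
  kernel <- if (family == "simon") best_simon_n else best_fleming_n
  rows <- vector("list", params$n_max)
  for (n in max(2L, params$n_min):params$n_max) {
    b <- kernel(params, n)
    if (is.null(b)) next
    d <- list(family = family, n1 = b$n1, n2 = b$n2, n = n,
              a1 = b$a1, r1 = b$r1, r = b$r)
    class(d) <- "ph2_design"
    oc <- operating_chars(d, params)
    rows[[n]] <- data.frame(n = n, n1 = b$n1, n2 = b$n2, a1 = b$a1,
                            r1 = b$r1, r = b$r,
                            alpha_T = oc$alpha_T, power = oc$power,
                            pet1 = oc$pet1, en = oc$en)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    stop(sprintf(
      "no feasible %s design with n <= %d (search-cap exhaustion; raise 'n_max')",
      family, params$n_max), call. = FALSE)
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  opt <- which(df$en <= min(df$en) + .en_tol)[1L]  # smallest n on EN ties
  df <- df[seq_len(opt), , drop = FALSE]
  if (df$n[opt] == params$n_max) {
    warning(sprintf(
      "optimal design sits at the search cap n_max = %d; the cap may be truncating the search",
      params$n_max), call. = FALSE)
  }
  structure(list(params = params, family = family, candidates = df,
                 minimax = 1L, optimal = opt),
            class = "ph2_candidate_set")
}

#' @export
print.ph2_candidate_set <- function(x, digits = 4, ...) {
  cat(sprintf(
    "%s candidate designs for (p0, p1, alpha, beta) = (%g, %g, %g, %g)\n",
    cap1(x$family), x$params$p0, x$params$p1,
    x$params$alpha, x$params$beta))
  cat(sprintf("  minimax n = %d, optimal n = %d (EN = %.1f)\n\n",
              x$candidates$n[x$minimax], x$candidates$n[x$optimal],
              x$candidates$en[x$optimal]))
  print(format(x$candidates, digits = digits), ...)
  invisible(x)
}
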