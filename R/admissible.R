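#' Expected loss of a design under a sample-size weight
#'
#' The loss that trades the maximum sample size against the expected
#' sample size: `rho(q, d) = q * n(d) + (1 - q) * EN(d)`, where the
#' weight `q` in `[0, 1]` expresses the relative importance of the worst
#' case (`q = 1` recovers the minimax criterion, `q = 0` the optimal
#' one).
#'
#' @param q weight in `[0, 1]` (vectorised).
#' @param n maximum total sample size of the design.
#' @param en expected sample size of the design under `p0`.
#' @return numeric, `q * n + (1 - q) * en`.
#' @examples
#' expected_loss(0.5, 25, 20.4)  # 22.7
#' @export
expected_loss <- function(q, n, en) {
  if (!is.numeric(q) || anyNA(q) || any(q < 0) || any(q > 1)) {
    stop("'q' must lie in [0, 1]", call. = FALSE)
  }
  q * n + (1 - q) * en
}

#' Indifference weight between two candidate designs
#'
#' For two designs that genuinely conflict -- `d_a` has the smaller
#' maximum sample size but the larger expected sample size -- the weight
#' at which their expected losses coincide is
#' `q = dEN / (dEN + dn)` with `dEN = en_a - en_b`, `dn = n_b - n_a`.
#' Below the breakpoint the larger-`n`, smaller-`EN` design is the Bayes
#' design; above it the smaller-`n` design is.
#'
#' @param d_a,d_b numeric vectors `c(n, en)` (or lists with elements `n`
#'   and `en`); `d_a` must have the smaller `n` and the larger `en`.
#' @return the indifference weight, in (0, 1).
#' @examples
#' q_breakpoint(c(16, 13.8), c(17, 12.0))  # 0.643 at 3 d.p.
#' @export
q_breakpoint <- function(d_a, d_b) {
  pt <- function(d) {
    if (is.list(d)) c(n = as.numeric(d$n), en = as.numeric(d$en))
    else c(n = as.numeric(d[[1]]), en = as.numeric(d[[2]]))
  }
  a <- pt(d_a); b <- pt(d_b)
  dn <- b["n"] - a["n"]; den <- a["en"] - b["en"]
  if (!(dn > 0 && den > 0)) {
    stop("designs do not conflict (one dominates); no indifference weight",
         call. = FALSE)
  }
  unname(den / (den + dn))
}

# Lower convex hull (indices) of points ordered by strictly increasing n.
# Collinear middle points within 'tol' of the chord are retained: they
# attain the Bayes risk at the shared breakpoint.
lower_hull_idx <- function(n, en, tol = 1e-9) {
  m <- length(n)
  if (m <= 2L) return(seq_len(m))
  h <- c(1L, 2L)
  for (i in 3:m) {
    repeat {
      k <- length(h)
      if (k < 2L) break
      a <- h[k - 1L]; b <- h[k]
      cross <- (n[b] - n[a]) * (en[i] - en[a]) -
               (en[b] - en[a]) * (n[i] - n[a])
      # pop b when it lies strictly above the chord a--i
      if (cross < -tol * max(1, abs(en[a]))) h <- h[-k] else break
    }
    h <- c(h, i)
  }
  h
}

#' Classify candidate designs as minimax / optimal / admissible
#'
#' A candidate design is *admissible* when its expected loss
#' `q * n + (1 - q) * EN` attains the minimum over all candidates for
#' some weight `q` in `[0, 1]`; geometrically, the admissible designs
#' are the lower convex hull of the candidates' `(n, EN)` points.  The
#' largest-`n` hull design is the optimal design (its interval starts at
#' `q = 0`), the smallest-`n` hull design is the minimax design (its
#' interval ends at `q = 1`), and consecutive hull designs share an
#' interval endpoint at their indifference weight.  Candidates off the
#' hull are never the Bayes design for any weight and are labelled
#' inadmissible, with no interval.
#'
#' Hull membership is decided on unrounded expected sample sizes
#' (collinear points within relative 1e-9 are all retained, the middle
#' one with a degenerate interval).  The reported interval endpoints are
#' computed from EN at the 0.1-patient precision of the output tables,
#' so a reader recomputing `dEN / (dEN + dn)` from a printed table
#' recovers exactly the printed weights; endpoints are then rounded
#' half-up to 3 decimals.  Intervals are closed on both sides and
#' adjacent intervals share their endpoint.
#'
#' @param cands a [candidate_set()] object, or a data frame with at
#'   least columns `n` and `en` (one candidate per row, `n` strictly
#'   increasing).
#' @return a data frame of class `"ph2_classified"`: the candidate
#'   columns plus `label` (one of `"minimax"`, `"optimal"`,
#'   `"admissible"`, `"inadmissible"`, `"optimal+minimax"`), `q_lo` and
#'   `q_hi` (`NA` for inadmissible designs).  The hull row indices are
#'   kept in `attr(, "hull")`.
#' @examples
#' pts <- data.frame(n = c(25, 26, 27, 28), en = c(20.4, 18.4, 18.0, 17.2))
#' classify_designs(pts)
#' @export
classify_designs <- function(cands) {
  if (inherits(cands, "ph2_candidate_set")) {
    df <- cands$candidates
  } else if (is.data.frame(cands)) {
    df <- cands
  } else {
    stop("'cands' must be a candidate_set or a data frame", call. = FALSE)
  }
  if (!nrow(df)) stop("empty candidate set", call. = FALSE)
  if (!all(c("n", "en") %in% names(df))) {
    stop("candidates need columns 'n' and 'en'", call. = FALSE)
  }
  if (is.unsorted(df$n, strictly = TRUE)) {
    stop("candidate 'n' must be strictly increasing", call. = FALSE)
  }
  m <- nrow(df)
  hull <- lower_hull_idx(df$n, df$en)
  label <- rep("inadmissible", m)
  q_lo <- rep(NA_real_, m)
  q_hi <- rep(NA_real_, m)
  h <- length(hull)
  if (h == 1L) {
    label[hull] <- "optimal+minimax"
    q_lo[hull] <- 0; q_hi[hull] <- 1
  } else {
    en_r <- round_half_up(df$en, 1)             # table display precision
    qb <- numeric(h - 1L)
    for (i in seq_len(h - 1L)) {
      a <- hull[i]; b <- hull[i + 1L]
      den <- en_r[a] - en_r[b]; dn <- df$n[b] - df$n[a]
      qb[i] <- if (den <= 0) 0 else den / (den + dn)
    }
    qb <- round_half_up(qb, 3)
    for (i in seq_len(h)) {
      j <- hull[i]
      label[j] <- if (i == 1L) "minimax"
                  else if (i == h) "optimal"
                  else "admissible"
      q_hi[j] <- if (i == 1L) 1 else qb[i - 1L]
      q_lo[j] <- if (i == h) 0 else qb[i]
    }
  }
  df$label <- label
  df$q_lo <- q_lo
  df$q_hi <- q_hi
  attr(df, "hull") <- hull
  class(df) <- c("ph2_classified", "data.frame")
  df
}

#' @export
print.ph2_classified <- function(x, digits = 4, ...) {
  y <- as.data.frame(x)
  y$q <- ifelse(is.na(y$q_lo), "-",
                sprintf("[%.3f, %.3f]", y$q_lo, y$q_hi))
  y$q_lo <- y$q_hi <- NULL
  print(format(y, digits = digits), ...)
  invisible(x)
}
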