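# Independent oracles and shared fixtures for the test suite.

# Exhaustive-outcome oracle: enumerate every (x1, x2) path with its exact
# joint probability and walk the decision flowchart directly.  Shares no
# code with the package's cumulative-sum formulas.
oracle_outcome <- function(design, p) {
  n1 <- design$n1; n2 <- design$n2
  pr_reject <- 0; pr_early <- 0; e_n <- 0
  for (x1 in 0:n1) {
    w1 <- dbinom(x1, n1, p)
    if (design$family == "simon") {
      stop_fut <- x1 <= design$r1
      stop_eff <- FALSE
    } else {
      stop_fut <- x1 <= design$a1
      stop_eff <- !stop_fut && x1 >= design$r1
    }
    if (stop_fut || stop_eff) {
      pr_early <- pr_early + w1
      e_n <- e_n + w1 * n1
      if (stop_fut) pr_reject <- pr_reject + w1
    } else {
      e_n <- e_n + w1 * (n1 + n2)
      for (x2 in 0:n2) {
        tot <- x1 + x2
        rejected <- if (design$family == "simon") tot <= design$r
                    else tot < design$r
        if (rejected) pr_reject <- pr_reject + w1 * dbinom(x2, n2, p)
      }
    }
  }
  list(reject = pr_reject, pet1 = pr_early, en = e_n)
}

# every valid stopping rule with total sample size n, as plain lists
all_rules_for_n <- function(n, family) {
  out <- list()
  for (n1 in seq_len(n - 1L)) {
    n2 <- n - n1
    if (family == "simon") {
      for (r1 in 0:n1) for (r in r1:(n - 1L)) {
        out[[length(out) + 1L]] <- list(family = "simon", n1 = n1, n2 = n2,
                                        a1 = NULL, r1 = r1, r = r)
      }
    } else {
      if (n1 < 2L) next
      for (r1 in 2:n1) for (a1 in 0:(r1 - 2L)) for (r in r1:n) {
        out[[length(out) + 1L]] <- list(family = "fleming", n1 = n1,
                                        n2 = n2, a1 = a1, r1 = r1, r = r)
      }
    }
  }
  out
}

# brute-force single-stage scan, written independently of the package
oracle_single_stage_n <- function(p0, p1, alpha, beta, n_hi = 200L) {
  for (n in 1:n_hi) {
    for (cc in 0:n) {
      if (1 - pbinom(cc, n, p0) <= alpha &&
          1 - pbinom(cc, n, p1) >= 1 - beta)

        return(n)
    }
  }
  NA_integer_
}

# q-grid Bayes-risk oracle: indices of candidates attaining the minimum
# expected loss for some weight on the grid
oracle_grid_argmin <- function(n, en, step = 0.001, tol = 1e-12) {
  qs <- seq(0, 1, by = step)
  sort(unique(unlist(lapply(qs, function(q) {
    loss <- q * n + (1 - q) * en
    which(loss <= min(loss) + tol)
  }))))
}

# one full search per (setting, family) per session
.ph2_cache <- new.env(parent = emptyenv())
cached_fit <- function(p0, p1, alpha, beta, family) {
  key <- paste(p0, p1, alpha, beta, family, sep = "|")
  if (is.null(.ph2_cache[[key]])) {
    ps <- design_params(p0, p1, alpha, beta)
    cs <- suppressWarnings(candidate_set(ps, family))
    .ph2_cache[[key]] <- list(params = ps, cs = cs,
                              cls = classify_designs(cs))
  }
  .ph2_cache[[key]]
}

# the nine (p0, p1, alpha, beta) settings of the reference tables
nine_settings <- list(
  c(0.05, 0.25, 0.05, 0.20), c(0.10, 0.30, 0.05, 0.20),
  c(0.30, 0.50, 0.05, 0.20), c(0.05, 0.25, 0.10, 0.10),
  c(0.10, 0.30, 0.10, 0.10), c(0.30, 0.50, 0.10, 0.10),
  c(0.05, 0.25, 0.05, 0.10), c(0.10, 0.30, 0.05, 0.10),
  c(0.30, 0.50, 0.05, 0.10))

# Tabulated Simon optimal and minimax designs for the nine settings
# (one EN reference value, 14.55, recomputed from that row's own
# n1/PET1/n2 because the tabulated 14.6 contradicts them).
ref_simon <- read.csv(text = "
p0,p1,alpha,beta,type,alpha_T,power,n1,r1,pet1,n,r,en
0.05,0.25,0.05,0.20,optimal,0.047,0.812,9,0,0.630,17,2,12.0
0.05,0.25,0.05,0.20,minimax,0.043,0.801,12,0,0.540,16,2,13.8
0.10,0.30,0.05,0.20,optimal,0.047,0.805,10,1,0.736,29,5,15.0
0.10,0.30,0.05,0.20,minimax,0.033,0.802,15,1,0.549,25,5,19.5
0.30,0.50,0.05,0.20,optimal,0.050,0.803,15,5,0.722,46,18,23.6
0.30,0.50,0.05,0.20,minimax,0.046,0.804,19,6,0.666,39,16,25.7
0.05,0.25,0.10,0.10,optimal,0.093,0.903,9,0,0.630,24,2,14.55
0.05,0.25,0.10,0.10,minimax,0.074,0.903,13,0,0.513,20,2,16.4
0.10,0.30,0.10,0.10,optimal,0.098,0.901,12,1,0.659,35,5,19.8
0.10,0.30,0.10,0.10,minimax,0.095,0.903,16,1,0.515,25,4,20.4
0.30,0.50,0.10,0.10,optimal,0.097,0.905,22,7,0.671,46,17,29.9
0.30,0.50,0.10,0.10,minimax,0.094,0.900,28,7,0.365,39,15,35.0
0.05,0.25,0.05,0.10,optimal,0.049,0.902,9,0,0.630,30,3,16.8
0.05,0.25,0.05,0.10,minimax,0.034,0.901,15,0,0.463,25,3,20.4
0.10,0.30,0.05,0.10,optimal,0.047,0.902,18,2,0.734,35,6,22.5
0.10,0.30,0.05,0.10,minimax,0.041,0.902,22,2,0.620,33,6,26.2
0.30,0.50,0.05,0.10,optimal,0.050,0.903,24,8,0.725,63,24,34.7
0.30,0.50,0.05,0.10,minimax,0.047,0.902,24,7,0.565,53,21,36.6
")

# Tabulated Fleming designs: minimax for all nine settings; optimal only
# for the seven settings whose tabulated optimum is reachable regardless
# of the (unstated) tabulation search cap.
ref_fleming <- read.csv(text = "
p0,p1,alpha,beta,type,alpha_T,power,n1,a1,r1,pet1,n,r,en
0.05,0.25,0.05,0.20,optimal,0.047,0.812,9,0,3,0.639,17,3,11.9
0.05,0.25,0.05,0.20,minimax,0.043,0.801,12,0,3,0.560,16,3,13.8
0.10,0.30,0.05,0.20,optimal,0.047,0.805,10,1,5,0.738,29,6,15.0
0.10,0.30,0.05,0.20,minimax,0.043,0.802,19,2,5,0.741,24,6,20.3
0.30,0.50,0.05,0.20,minimax,0.049,0.800,27,8,14,0.592,36,16,30.7
0.05,0.25,0.10,0.10,optimal,0.093,0.903,9,0,3,0.639,24,3,14.4
0.05,0.25,0.10,0.10,minimax,0.074,0.903,13,0,3,0.538,20,3,16.2
0.10,0.30,0.10,0.10,optimal,0.085,0.900,13,1,4,0.656,31,6,19.2
0.10,0.30,0.10,0.10,minimax,0.095,0.903,16,1,5,0.532,25,5,20.2
0.30,0.50,0.10,0.10,optimal,0.097,0.901,20,6,10,0.656,47,19,29.3
0.30,0.50,0.10,0.10,minimax,0.097,0.901,26,7,13,0.486,39,16,32.7
0.05,0.25,0.05,0.10,optimal,0.049,0.902,9,0,4,0.631,30,4,16.8
0.05,0.25,0.05,0.10,minimax,0.045,0.903,13,0,3,0.538,25,4,18.5
0.10,0.30,0.05,0.10,optimal,0.048,0.901,17,2,5,0.784,41,8,22.2
0.10,0.30,0.05,0.10,minimax,0.047,0.900,16,1,5,0.532,33,7,24.0
0.30,0.50,0.05,0.10,minimax,0.049,0.900,37,11,18,0.579,50,21,42.5
")
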