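#' Format classified designs as a publication-style result table
#'
#' One row per candidate design, ordered by decreasing total sample size
#' (optimal first, minimax last).  Probabilities are rounded half-up to
#' 3 decimals, EN to 1 decimal, matching the display precision of the
#' standard design tables; the `a1` column is `NA` for Simon designs so
#' that Simon and Fleming outputs share one schema.
#'
#' @param classified a [classify_designs()] result.
#' @param params the [design_params()] used for the search.
#' @return a data frame with columns `p0, p1, alpha, beta, alpha_T,
#'   power, n1, a1, r1, pet1, n, r, en, label, q_lo, q_hi`.
#' @export
result_table <- function(classified, params) {
  stopifnot(inherits(classified, "ph2_classified"),
            inherits(params, "ph2_params"))
  df <- as.data.frame(classified)
  ord <- order(df$n, decreasing = TRUE)
  df <- df[ord, , drop = FALSE]
  out <- data.frame(
    p0 = params$p0, p1 = params$p1,
    alpha = params$alpha, beta = params$beta,
    alpha_T = round_half_up(df$alpha_T, 3),
    power = round_half_up(df$power, 3),
    n1 = df$n1, a1 = df$a1, r1 = df$r1,
    pet1 = round_half_up(df$pet1, 3),
    n = df$n, r = df$r,
    en = round_half_up(df$en, 1),
    label = cap1(df$label),
    q_lo = round_half_up(df$q_lo, 3),
    q_hi = round_half_up(df$q_hi, 3),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write EN-versus-n curve data for a candidate set
#'
#' One record per candidate design, ordered by increasing `n`, with its
#' expected sample size and classification label -- the data behind the
#' usual scatter of EN against maximum sample size on which the
#' minimax, admissible and optimal designs are highlighted.
#'
#' @param classified a [classify_designs()] result.
#' @param path file to write (CSV).
#' @return the curve data frame, invisibly.
#' @export
write_curve <- function(classified, path) {
  stopifnot(inherits(classified, "ph2_classified"))
  cur <- data.frame(n = classified$n,
                    en = classified$en,
                    label = cap1(classified$label))
  cur <- cur[order(cur$n), , drop = FALSE]
  write.csv(cur, path, row.names = FALSE, quote = FALSE)
  invisible(cur)
}

write_result_table <- function(tab, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    write.csv(tab, path, row.names = FALSE, na = "", quote = FALSE)
  } else {
    jsonlite::write_json(tab, path, dataframe = "rows", na = "null",
                         digits = NA, pretty = TRUE)
  }
  invisible(tab)
}

#' Run a full design search and report the result table
#'
#' Convenience wrapper chaining [design_params()], [candidate_set()],
#' [classify_designs()] and [result_table()]; optionally writes the
#' table (CSV or JSON) and the EN-versus-n curve data.  All output is a
#' deterministic function of the inputs.
#'
#' @param p0,p1,alpha,beta,n_min,n_max see [design_params()].
#' @param family `"simon"` or `"fleming"`.
#' @param out optional path for the result table.
#' @param format `"csv"` (default) or `"json"`.
#' @param curve optional path for the EN-versus-n curve CSV.
#' @param verbose print one line per feasible `n` scanned.
#' @return invisibly, a list with `params`, `candidates`, `classified`
#'   and `table`.
#' @examples
#' \donttest{
#' res <- run_search(0.05, 0.25, 0.05, 0.20, family = "simon")
#' res$table
#' }
#' @export
run_search <- function(p0, p1, alpha, beta, family = c("simon", "fleming"),
                       n_min = 1L, n_max = NULL, out = NULL,
                       format = c("csv", "json"), curve = NULL,
                       verbose = FALSE) {
  family <- match.arg(family)
  format <- match.arg(format)
  params <- design_params(p0, p1, alpha, beta, n_min = n_min, n_max = n_max)
  cands <- candidate_set(params, family)
  if (verbose) {
    apply(cands$candidates, 1L, function(rw) {
      message(sprintf("n = %3d: best EN = %.2f", rw[["n"]], rw[["en"]]))
    })
  }
  cls <- classify_designs(cands)
  if (verbose && !any(cls$label == "admissible")) {
    message("no admissible design strictly between optimal and minimax ",
            "for this setting")
  }
  tab <- result_table(cls, params)
  if (!is.null(out)) write_result_table(tab, out, format)
  if (!is.null(curve)) write_curve(cls, curve)
  invisible(list(params = params, candidates = cands, classified = cls,
                 table = tab))
}
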