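# Incremental cost-effectiveness statistics.

#' Incremental cost-effectiveness ratio of one strategy versus a reference
#'
#' `ICER = (C1 - C0) / (E1 - E0)` on unrounded totals. When the QALY
#' difference is exactly zero the ratio is undefined and a sentinel is
#' returned instead; sign conventions: `dominant` means cheaper and more
#' effective (`dC < 0`, `dE > 0`), `dominated` means costlier and less
#' effective (`dC > 0`, `dE < 0`).
#'
#' @param ref,alt `strategy_result` objects computed under the same
#'   [model_config()].
#' @return a list of class `icer_record` with `strategy`, `delta_cost`,
#'   `delta_effect`, `icer` (numeric), and `sentinel` (`"dominant"`,
#'   `"dominated"`, `"undefined"`, or `NA` when the ICER is a plain number).
#' @export
compute_icer <- function(ref, alt) {
  if (!is.null(ref$config) && !is.null(alt$config) &&
      !identical(ref$config, alt$config))
    stop("results were computed under different model configurations")
  dc <- alt$total_cost - ref$total_cost
  de <- alt$total_qaly - ref$total_qaly
  sentinel <- NA_character_
  icer <- NA_real_
  if (de == 0) {
    sentinel <- "undefined"
  } else {
    icer <- dc / de
    if (dc < 0 && de > 0) sentinel <- "dominant"
    if (dc > 0 && de < 0) sentinel <- "dominated"
  }
  x <- list(strategy = alt$strategy, delta_cost = dc, delta_effect = de,
            icer = icer, sentinel = sentinel)
  class(x) <- "icer_record"
  x
}

#' @export
print.icer_record <- function(x, ...) {
  lab <- if (!is.na(x$sentinel) && x$sentinel != "undefined")
    sprintf("%.0f (%s)", x$icer, x$sentinel)
  else if (is.na(x$icer)) x$sentinel else sprintf("%.0f", x$icer)
  cat(sprintf("<icer_record> %s: dC = %.2f, dE = %.5f, ICER = %s $/QALY\n",
              x$strategy, x$delta_cost, x$delta_effect, lab))
  invisible(x)
}

#' Net monetary benefit
#'
#' `NMB = wtp * QALY - cost`; linear in the willingness-to-pay threshold.
#' Comparing NMB at a threshold is the decision rule equivalent to comparing
#' the ICER with the threshold, and remains well defined in every
#' cost/effect quadrant.
#'
#' @param result a `strategy_result`.
#' @param wtp willingness-to-pay threshold in $/QALY, `>= 0`.
#' @return a list with `strategy`, `wtp`, `nmb`.
#' @export
nmb <- function(result, wtp) {
  if (any(wtp < 0)) stop("wtp must be >= 0")
  list(strategy = result$strategy, wtp = wtp,
       nmb = wtp * result$total_qaly - result$total_cost)
}

#' Pairwise league table versus the reference strategy
#'
#' One [compute_icer()] record per non-reference strategy, all compared with
#' the same reference, in input order.
#'
#' @param results list of `strategy_result` objects.
#' @param ref_name name of the reference strategy; must be present.
#' @return list of `icer_record` objects.
#' @export
league_table <- function(results, ref_name = "SOC") {
  nms <- vapply(results, `[[`, "", "strategy")
  if (!ref_name %in% nms) stop("reference strategy '", ref_name, "' not found")
  ref <- results[[match(ref_name, nms)]]
  lapply(results[nms != ref_name], function(alt) compute_icer(ref, alt))
}

#' League table as a data frame
#'
#' @param results list of `strategy_result` objects.
#' @param ref_name reference strategy name.
#' @return a `data.frame` with per-strategy totals and pairwise ICERs versus
#'   the reference (NA for the reference row).
#' @export
league_table_df <- function(results, ref_name = "SOC") {
  recs <- league_table(results, ref_name)
  nms <- vapply(results, `[[`, "", "strategy")
  icer <- stats::setNames(rep(NA_real_, length(results)), nms)
  sentinel <- stats::setNames(rep(NA_character_, length(results)), nms)
  for (r in recs) {
    icer[r$strategy] <- r$icer
    sentinel[r$strategy] <- r$sentinel
  }
  data.frame(strategy = nms,
             cost = vapply(results, `[[`, 0, "total_cost"),
             qaly = vapply(results, `[[`, 0, "total_qaly"),
             icer_vs_ref = unname(icer), sentinel = unname(sentinel),
             row.names = NULL)
}

#' Cost-effectiveness frontier (supplementary)
#'
#' Classical efficiency frontier with strict and extended dominance removed,
#' with sequential ICERs along the frontier. Provided for completeness; the
#' bundled analysis reports pairwise ICERs versus the reference only.
#'
#' @param results list of `strategy_result` objects.
#' @return a `data.frame` of frontier strategies ordered by cost, with the
#'   sequential ICER against the previous frontier point.
#' @export
ce_frontier <- function(results) {
  df <- data.frame(strategy = vapply(results, `[[`, "", "strategy"),
                   cost = vapply(results, `[[`, 0, "total_cost"),
                   qaly = vapply(results, `[[`, 0, "total_qaly"))
  df <- df[order(df$cost, df$qaly), ]
  # strict dominance: drop anything with no more QALYs than a cheaper option
  keep <- rep(TRUE, nrow(df))
  best <- -Inf
  for (i in seq_len(nrow(df))) {
    if (df$qaly[i] <= best) keep[i] <- FALSE else best <- df$qaly[i]
  }
  df <- df[keep, ]
  # extended dominance: enforce increasing sequential ICERs
  repeat {
    if (nrow(df) < 3L) break
    icers <- diff(df$cost) / diff(df$qaly)
    bad <- which(diff(icers) < 0)
    if (!length(bad)) break
    df <- df[-(bad[1L] + 1L), ]
  }
  df$icer_sequential <- c(NA, diff(df$cost) / diff(df$qaly))
  rownames(df) <- NULL
  df
}
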