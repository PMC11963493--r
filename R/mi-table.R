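# Period-stratified mutual information tables: every daily summary variable
# against the three prediction targets (mean daily sap flow, predawn and
# midday leaf water potential), for the full experiment and for the drydown
# and recovery strata separately.

#' Mutual information between summary variables and prediction targets
#'
#' For every (measurement, target, period) triple, pairs the two variables on
#' the same day (pairwise-complete), discretizes, and computes plug-in mutual
#' information in bits. Periods are `drydown` (days before the rewatering
#' day), `recovery` (the rewatering day onward) and `full`. A period with no
#' days in the summary yields no rows.
#'
#' Two pooling modes are offered because replicate handling is a genuine
#' analysis choice: `"pooled"` (default) treats each (tree, day) pair as a
#' sample, which keeps the short recovery stratum away from the degenerate
#' two-sample case; `"mean"` first averages across trees so samples are days.
#'
#' @param summary a [summarize_daily()] result.
#' @param targets character subset of `sap_flow`, `psi_pd`, `psi_md`.
#' @param periods character subset of `full`, `drydown`, `recovery`.
#' @param n_bins,scheme discretization settings (see [discretize()]).
#' @param pooling `"pooled"` or `"mean"`.
#' @param min_pairs pairs below which a row is flagged unreliable.
#' @return tibble ordered by measurement group: measurement, group, target,
#'   period, mi_bits, h_x, h_y, h_xy, n, n_bins, scheme, reliable.
#' @export
mi_table <- function(summary, targets = c("sap_flow", "psi_pd", "psi_md"),
                     periods = c("full", "drydown", "recovery"),
                     n_bins = 2, scheme = c("quantile", "equal_width"),
                     pooling = c("pooled", "mean"), min_pairs = 3) {
  scheme <- match.arg(scheme)
  pooling <- match.arg(pooling)
  if (!inherits(summary, "daily_summary")) {
    stop("`summary` must be a daily_summary")
  }
  groups <- summary_variable_groups()
  bad <- setdiff(targets, c("sap_flow", "psi_pd", "psi_md"))
  if (length(bad) > 0) {
    stop("unknown target(s) ", paste(bad, collapse = ", "),
         "; valid targets: sap_flow, psi_pd, psi_md")
  }
  bad_p <- setdiff(periods, c("full", "drydown", "recovery"))
  if (length(bad_p) > 0) {
    stop("unknown period(s) ", paste(bad_p, collapse = ", "))
  }
  tbl <- if (pooling == "pooled") summary$per_tree else summary$pooled
  rw <- summary$rewater_day

  rows <- list()
  for (measurement in names(groups)) {
    for (target in targets) {
      for (period in periods) {
        keep <- switch(period,
                       full = rep(TRUE, nrow(tbl)),
                       drydown = tbl$day < rw,
                       recovery = tbl$day >= rw)
        if (!any(keep)) next
        sub <- tbl[keep, ]
        res <- mutual_information(sub[[measurement]], sub[[target]],
                                  n_bins = n_bins, scheme = scheme)
        rows[[length(rows) + 1]] <- tibble::tibble(
          measurement = measurement, group = groups[[measurement]],
          target = target, period = period,
          mi_bits = res$mi, h_x = res$h_x, h_y = res$h_y, h_xy = res$h_xy,
          n = res$n, n_bins = n_bins, scheme = scheme,
          reliable = !is.na(res$mi) && res$n >= min_pairs)
      }
    }
  }
  dplyr::bind_rows(rows)
}
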