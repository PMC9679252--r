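#' F_ST outlier windows at an FDR threshold
#'
#' @param qvalues Benjamini-Hochberg q-values per window.
#' @param alpha FDR significance level (default 0.05).
#' @return logical mask, `FALSE` where the q-value is `NA`.
#' @export
find_outlier_windows <- function(qvalues, alpha = 0.05) {
  !is.na(qvalues) & qvalues < alpha
}

#' Window F_ST threshold from an empirical quantile
#'
#' The fixed island threshold (0.03 by default in [find_islands()]) can
#' instead be derived as an upper quantile of all windows' weighted F_ST
#' (linear-interpolation quantile), e.g. the value above which the top
#' 10% of windows lie.
#'
#' @param window_fst weighted F_ST of all windows.
#' @param q quantile (default 0.90).
#' @return the threshold.
#' @export
fst_threshold_from_quantile <- function(window_fst, q = 0.90) {
  window_fst <- window_fst[!is.na(window_fst)]
  if (!length(window_fst)) stop("no window F_ST values")
  unname(stats::quantile(window_fst, q, type = 7))
}

#' Call islands of differentiation from a window series
#'
#' An island is a maximal run of at least `min_run` consecutive windows
#' (centre spacing exactly `step`; a gap breaks the run) whose weighted
#' F_ST exceeds `threshold`. Runs never cross linkage-group boundaries.
#' The island interval is `[first_center - step/2, last_center + step/2]`,
#' so its length is `n_windows x step`; islands are numbered left to
#' right within each linkage group (`LG12_1`, `LG12_2`, ...).
#'
#' @param windows a [scan_windows()] result (or any data.frame with `lg`,
#'   `center`, `wfst`, ordered by centre within linkage group).
#' @param threshold weighted F_ST threshold (default 0.03; see
#'   [fst_threshold_from_quantile()] for a data-driven alternative).
#' @param min_run minimum run length in windows (default 4).
#' @param step centre spacing in bp; defaults to the scan's
#'   [window_scheme()] step.
#' @return data.frame with one row per island: `island_id`, `lg`,
#'   `first_center`, `last_center`, `start`, `end`, `n_windows`,
#'   `mean_wfst`, `mean_wdxy` (if `wdxy` present).
#' @export
find_islands <- function(windows, threshold = 0.03, min_run = 4L, step = NULL) {
  if (is.null(step)) {
    scheme <- attr(windows, "scheme")
    if (is.null(scheme)) stop("supply `step` for windows without a scheme attribute")
    step <- scheme$step
  }
  res <- list()
  for (lg in unique(windows$lg)) {
    w <- windows[windows$lg == lg, , drop = FALSE]
    w <- w[order(w$center), , drop = FALSE]
    above <- !is.na(w$wfst) & w$wfst > threshold
    if (!any(above)) next
    # break runs at threshold failures and at centre-spacing gaps
    new_run <- c(TRUE, diff(w$center) != step | !above[-nrow(w)] | !above[-1])
    run_id <- cumsum(new_run)
    ord <- 0L
    for (r in unique(run_id[above])) {
      idx <- which(run_id == r & above)
      if (length(idx) < min_run) next
      ord <- ord + 1L
      res[[length(res) + 1L]] <- data.frame(
        island_id = sprintf("%s_%d", lg, ord), lg = lg,
        first_center = w$center[idx[1]], last_center = w$center[idx[length(idx)]],
        start = w$center[idx[1]] - step / 2,
        end = w$center[idx[length(idx)]] + step / 2,
        n_windows = length(idx),
        mean_wfst = mean(w$wfst[idx]),
        mean_wdxy = if ("wdxy" %in% names(w)) mean(w$wdxy[idx]) else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(res)) {
    return(data.frame(
      island_id = character(0), lg = character(0), first_center = numeric(0),
      last_center = numeric(0), start = numeric(0), end = numeric(0),
      n_windows = integer(0), mean_wfst = numeric(0), mean_wdxy = numeric(0),
      stringsAsFactors = FALSE
    ))
  }
  do.call(rbind, res)
}

#' Summarize islands against genome-wide quantiles
#'
#' Populates the per-island summary columns: counts of member windows
#' whose d_XY exceeds the genome-wide upper 5% quantile and the
#' genome-wide mean, and per-superpool mean Tajima's D and nucleotide
#' diversity with counts of member windows below the genome-wide lower 5%
#' quantile. Quantiles are computed over all windows of the comparison.
#'
#' @param islands a [find_islands()] result.
#' @param windows the [scan_windows()] result the islands were called
#'   from.
#' @return `islands` with the summary columns added: `n_dxy_gt_q95`,
#'   `n_dxy_gt_mean` and, per superpool `<sp>`, `mean_tajd_<sp>`,
#'   `n_tajd_lt_q05_<sp>`, `mean_pi_<sp>`, `n_pi_lt_q05_<sp>`.
#' @export
island_summary <- function(islands, windows) {
  pair <- attr(windows, "pair")
  if (is.null(pair)) {
    pair <- sub("^pi_", "", grep("^pi_", names(windows), value = TRUE))
  }
  dxy_q95 <- stats::quantile(windows$wdxy, 0.95, na.rm = TRUE, type = 7)
  dxy_mean <- mean(windows$wdxy, na.rm = TRUE)
  q05 <- list()
  for (sp in pair) {
    q05[[paste0("tajd_", sp)]] <-
      stats::quantile(windows[[paste0("tajd_", sp)]], 0.05, na.rm = TRUE, type = 7)
    q05[[paste0("pi_", sp)]] <-
      stats::quantile(windows[[paste0("pi_", sp)]], 0.05, na.rm = TRUE, type = 7)
  }
  islands$n_dxy_gt_q95 <- NA_integer_
  islands$n_dxy_gt_mean <- NA_integer_
  for (sp in pair) {
    islands[[paste0("mean_tajd_", sp)]] <- NA_real_
    islands[[paste0("n_tajd_lt_q05_", sp)]] <- NA_integer_
    islands[[paste0("mean_pi_", sp)]] <- NA_real_
    islands[[paste0("n_pi_lt_q05_", sp)]] <- NA_integer_
  }
  for (k in seq_len(nrow(islands))) {
    member <- windows$lg == islands$lg[k] &
      windows$center >= islands$first_center[k] &
      windows$center <= islands$last_center[k]
    islands$n_dxy_gt_q95[k] <- sum(windows$wdxy[member] > dxy_q95, na.rm = TRUE)
    islands$n_dxy_gt_mean[k] <- sum(windows$wdxy[member] > dxy_mean, na.rm = TRUE)
    for (sp in pair) {
      td <- windows[[paste0("tajd_", sp)]][member]
      pi <- windows[[paste0("pi_", sp)]][member]
      islands[[paste0("mean_tajd_", sp)]][k] <- mean(td, na.rm = TRUE)
      islands[[paste0("n_tajd_lt_q05_", sp)]][k] <-
        sum(td < q05[[paste0("tajd_", sp)]], na.rm = TRUE)
      islands[[paste0("mean_pi_", sp)]][k] <- mean(pi, na.rm = TRUE)
      islands[[paste0("n_pi_lt_q05_", sp)]][k] <-
        sum(pi < q05[[paste0("pi_", sp)]], na.rm = TRUE)
    }
  }
  islands
}

#' Coefficient of variation of outlier-window counts per linkage group
#'
#' Measures how unevenly significant windows are spread across linkage
#' groups: sample standard deviation over mean of the per-linkage-group
#' outlier counts.
#'
#' @param outlier_mask logical mask of outlier windows (e.g. from
#'   [find_outlier_windows()]).
#' @param lg linkage-group label per window.
#' @return the CV, or `NA` if no outliers at all (mean 0).
#' @export
outlier_cv_per_lg <- function(outlier_mask, lg) {
  lgs <- unique(lg)
  if (length(lgs) < 2) stop("need >= 2 linkage groups")
  counts <- vapply(lgs, function(g) sum(outlier_mask[lg == g]), integer(1))
  if (mean(counts) == 0) return(NA_real_)
  stats::sd(counts) / mean(counts)
}

#' Match called islands against ground-truth intervals
#'
#' Evaluation helper for synthetic data: a truth island counts as
#' recovered when some called island overlaps it reciprocally by at least
#' `min_reciprocal` (the intersection covers that fraction of both
#' intervals); a called island counts as false when it does not intersect
#' any truth interval at all.
#'
#' @param called a [find_islands()] result.
#' @param truth data.frame with `lg`, `start`, `end` (bp) of the injected
#'   islands (see [simulate_dataset()]'s truth record).
#' @param min_reciprocal reciprocal-overlap fraction (default 0.5).
#' @return list with `n_truth`, `n_called`, `n_recovered`, `n_false`, and
#'   a logical `recovered` flag per truth island.
#' @export
match_islands <- function(called, truth, min_reciprocal = 0.5) {
  recovered <- rep(FALSE, nrow(truth))
  touches_truth <- rep(FALSE, nrow(called))
  for (i in seq_len(nrow(truth))) {
    for (j in seq_len(nrow(called))) {
      if (truth$lg[i] != called$lg[j]) next
      ov <- min(truth$end[i], called$end[j]) - max(truth$start[i], called$start[j])
      if (ov <= 0) next
      touches_truth[j] <- TRUE
      if (ov >= min_reciprocal * (truth$end[i] - truth$start[i]) &&
          ov >= min_reciprocal * (called$end[j] - called$start[j])) {
        recovered[i] <- TRUE
      }
    }
  }
  list(
    n_truth = nrow(truth), n_called = nrow(called),
    n_recovered = sum(recovered), n_false = sum(!touches_truth),
    recovered = recovered
  )
}
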