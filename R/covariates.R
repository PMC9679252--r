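#' Scalar current velocity from components
#'
#' `w = sqrt(u^2 + v^2)` from the east (`u`) and north (`v`) velocity
#' components; rotation-invariant and nonnegative.
#'
#' @param u,v velocity components in m/s (vectorized).
#' @return scalar velocity in m/s.
#' @export
scalar_velocity <- function(u, v) {
  if (any(!is.finite(u)) || any(!is.finite(v))) stop("inputs must be finite")
  sqrt(u^2 + v^2)
}

#' Light transmission from optical depth
#'
#' Optical depth is the natural-log ratio of sub-surface to at-depth
#' downwelling irradiance, so transmission is `exp(-od)`: a difference of
#' `ln(10) ~ 2.303` optical-depth units corresponds to an order of
#' magnitude in light transmission.
#'
#' @param od optical depth (>= 0, vectorized).
#' @return fraction of sub-surface downwelling irradiance reaching depth.
#' @export
optical_depth_transmission <- function(od) {
  if (any(od < 0)) stop("optical depth must be >= 0")
  exp(-od)
}

#' Convergence of replicate association runs
#'
#' Pairwise Pearson correlations among replicate runs of a per-SNP
#' association statistic (e.g. Bayes factors from an external
#' environmental-association tool). Averaging across runs is sanctioned
#' only when every pairwise correlation exceeds `floor`.
#'
#' @param bf_runs numeric matrix, one column per replicate run (>= 2
#'   columns, >= 3 rows).
#' @param floor minimum pairwise correlation for averaging (default 0.9).
#' @return list with `correlations` (data.frame `run_a`, `run_b`, `r`)
#'   and `averaging_ok`.
#' @export
run_convergence <- function(bf_runs, floor = 0.9) {
  bf_runs <- as.matrix(bf_runs)
  if (ncol(bf_runs) < 2) stop("need >= 2 replicate runs")
  if (nrow(bf_runs) < 3) stop("need >= 3 SNPs")
  if (any(apply(bf_runs, 2, stats::sd) == 0)) {
    stop("constant run vector; correlation undefined")
  }
  if (is.null(colnames(bf_runs))) {
    colnames(bf_runs) <- sprintf("run%d", seq_len(ncol(bf_runs)))
  }
  pairs <- utils::combn(ncol(bf_runs), 2)
  cors <- data.frame(
    run_a = colnames(bf_runs)[pairs[1, ]],
    run_b = colnames(bf_runs)[pairs[2, ]],
    r = vapply(seq_len(ncol(pairs)), function(k) {
      stats::cor(bf_runs[, pairs[1, k]], bf_runs[, pairs[2, k]])
    }, numeric(1)),
    stringsAsFactors = FALSE
  )
  list(correlations = cors, averaging_ok = all(cors$r > floor))
}

#' Read a per-SNP Bayes-factor table
#'
#' TSV with columns `lg`, `pos`, `covariate`, `run`, `bf_db` (the log10
#' Bayes factor in decibans), as produced per run and covariate by an
#' external association tool.
#'
#' @param path TSV path.
#' @return data.frame of class `bf_table`.
#' @export
read_bf_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  req <- c("lg", "pos", "covariate", "run", "bf_db")
  if (!all(req %in% names(tab))) {
    stop("Bayes-factor table must have columns: ", paste(req, collapse = ", "))
  }
  class(tab) <- c("bf_table", "data.frame")
  tab
}

#' Average Bayes factors over replicate runs
#'
#' Checks convergence per covariate via [run_convergence()] and, when all
#' pairwise correlations exceed `floor`, averages `bf_db` over runs for
#' each SNP and covariate. The average necessarily lies between the
#' per-run minimum and maximum.
#'
#' @param bf a [read_bf_table()] data.frame (long format with a `run`
#'   column).
#' @param floor convergence floor passed to [run_convergence()].
#' @return data.frame `lg`, `pos`, `covariate`, `bf_db` (run-averaged).
#' @export
average_bf_runs <- function(bf, floor = 0.9) {
  for (cov in unique(bf$covariate)) {
    sub <- bf[bf$covariate == cov, ]
    wide <- stats::reshape(
      sub[, c("lg", "pos", "run", "bf_db")],
      idvar = c("lg", "pos"), timevar = "run", direction = "wide"
    )
    runs <- as.matrix(wide[, grep("^bf_db", names(wide)), drop = FALSE])
    if (ncol(runs) >= 2) {
      conv <- run_convergence(runs, floor)
      if (!conv$averaging_ok) {
        stop("replicate runs for covariate '", cov,
             "' have not converged (pairwise r <= ", floor, ")")
      }
    }
  }
  agg <- stats::aggregate(bf_db ~ lg + pos + covariate, data = bf, FUN = mean)
  agg[order(agg$covariate, agg$lg, agg$pos), , drop = FALSE]
}

#' Count decisive association SNPs per island and covariate
#'
#' For each island and covariate, counts the SNPs inside the island
#' interval whose run-averaged Bayes factor exceeds `threshold_db`
#' (30 dB by default: the alternative is 10^30 times more likely than the
#' null). Counts are monotone non-increasing in the threshold.
#'
#' @param bf run-averaged Bayes-factor data.frame (`lg`, `pos`,
#'   `covariate`, `bf_db`), e.g. from [average_bf_runs()].
#' @param islands a [find_islands()] result.
#' @param threshold_db deciban threshold (default 30).
#' @return integer matrix, islands x covariates.
#' @export
tabulate_bf_outliers <- function(bf, islands, threshold_db = 30) {
  covs <- sort(unique(bf$covariate))
  out <- matrix(0L, nrow(islands), length(covs),
                dimnames = list(islands$island_id, covs))
  hot <- bf[bf$bf_db > threshold_db, , drop = FALSE]
  for (i in seq_len(nrow(islands))) {
    inside <- hot$lg == islands$lg[i] &
      hot$pos >= islands$start[i] & hot$pos <= islands$end[i]
    if (!any(inside)) next
    tab <- table(hot$covariate[inside])
    out[i, names(tab)] <- as.integer(tab)
  }
  out
}

#' Assemble a site covariate table
#'
#' Standardizes a raw covariate table (chlorophyll, salinity, bottom
#' temperature, current components) and derives scalar velocity. Raw
#' units: chlorophyll mg/m^3 (surface), salinity psu (bottom),
#' temperature degrees C (bottom), u/v current components m/s.
#'
#' @param sites data.frame with `site`, `chl`, `sal`, `tmp`, `u`, `v`.
#' @param scale z-score the covariates for downstream association tools
#'   (default TRUE); `site` and the raw columns are retained either way.
#' @return data.frame with derived `vel` (scalar velocity) and, when
#'   `scale` is TRUE, z-scored columns `chl_z`, `sal_z`, `tmp_z`,
#'   `vel_z`.
#' @export
covariate_table <- function(sites, scale = TRUE) {
  req <- c("site", "chl", "sal", "tmp", "u", "v")
  if (!all(req %in% names(sites))) {
    stop("covariate table must have columns: ", paste(req, collapse = ", "))
  }
  sites$vel <- scalar_velocity(sites$u, sites$v)
  if (scale) {
    for (v in c("chl", "sal", "tmp", "vel")) {
      sites[[paste0(v, "_z")]] <- as.numeric(scale(sites[[v]]))
    }
  }
  sites
}
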