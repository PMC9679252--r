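#' Bootstrap null reference for kernel-weighted window F_ST
#'
#' For each window SNP count `n`, builds the null distribution of the
#' kernel-weighted average of `n` per-SNP F_ST values resampled with
#' replacement from the genome-wide pool, with kernel weights computed at
#' `n` positions drawn uniformly at random across the window span
#' (`[c - 3 sigma, c + 3 sigma]`). Each distribution holds `B` replicates
#' and is stored sorted.
#'
#' @param per_snp_fst genome-wide per-SNP F_ST values for the comparison
#'   (`NA`s are dropped).
#' @param scheme a [window_scheme()] (supplies `sigma`).
#' @param n_values integer vector of SNP counts to build distributions
#'   for; default `1:n_max`. Building only the counts that actually occur
#'   keeps the reference cheap.
#' @param n_max largest SNP count represented; windows with more SNPs are
#'   compared against the `n_max` distribution.
#' @param B bootstrap replicates per distribution. The resolution floor of
#'   the resulting p-values is `1/B`.
#' @param seed integer seed; the reference is deterministic given the
#'   seed.
#' @return an object of class `null_reference`: list with `dists` (named
#'   list of sorted numeric vectors keyed by `n`), `B`, `sigma`, `n_max`,
#'   `seed`.
#' @export
build_null_reference <- function(per_snp_fst, scheme = window_scheme(),
                                 n_values = NULL, n_max = 2000L,
                                 B = 10000L, seed = 1L) {
  vals <- per_snp_fst[!is.na(per_snp_fst)]
  if (!length(vals)) stop("no defined per-SNP F_ST values")
  if (n_max < 1) stop("n_max must be >= 1")
  if (B < 1) stop("B must be >= 1")
  if (is.null(n_values)) n_values <- seq_len(n_max)
  n_values <- sort(unique(pmin(as.integer(n_values), as.integer(n_max))))
  set.seed(seed)
  h <- 3 * scheme$sigma
  dists <- vector("list", length(n_values))
  names(dists) <- as.character(n_values)
  for (k in seq_along(n_values)) {
    n <- n_values[k]
    f <- matrix(sample(vals, n * B, replace = TRUE), nrow = n)
    w <- matrix(exp(-stats::runif(n * B, -h, h)^2 / (2 * scheme$sigma^2)),
                nrow = n)
    dists[[k]] <- sort(colSums(w * f) / colSums(w))
  }
  structure(
    list(dists = dists, B = as.integer(B), sigma = scheme$sigma,
         n_max = as.integer(n_max), seed = as.integer(seed)),
    class = "null_reference"
  )
}

#' @export
print.null_reference <- function(x, ...) {
  cat(sprintf(
    "null_reference: %d distributions (n in %s..%s), B = %d, sigma = %g, seed = %d\n",
    length(x$dists), names(x$dists)[1], names(x$dists)[length(x$dists)],
    x$B, x$sigma, x$seed
  ))
  invisible(x)
}

#' Bootstrap p-value for a window's weighted F_ST
#'
#' The proportion of bootstrap replicates greater than or equal to the
#' observed kernel-weighted F_ST, using the null distribution matching the
#' window's SNP count (`min(S_n, n_max)`). A reported 0 means "below the
#' resolution floor 1/B".
#'
#' @param weighted_fst observed kernel-weighted window F_ST (vectorized).
#' @param S_n window SNP count (vectorized; the count of values that
#'   entered the weighted average).
#' @param null a [build_null_reference()] object containing distributions
#'   for every `min(S_n, n_max)` requested.
#' @return p-values in `[0, 1]`; `NA` where `S_n == 0` or `weighted_fst`
#'   is `NA` (excluded from FDR adjustment downstream).
#' @export
window_pvalue <- function(weighted_fst, S_n, null) {
  stopifnot(inherits(null, "null_reference"))
  n_use <- pmin(S_n, null$n_max)
  out <- rep(NA_real_, length(weighted_fst))
  for (i in seq_along(weighted_fst)) {
    if (is.na(weighted_fst[i]) || S_n[i] < 1) next
    d <- null$dists[[as.character(n_use[i])]]
    if (is.null(d)) {
      stop("null reference has no distribution for n = ", n_use[i])
    }
    out[i] <- sum(d >= weighted_fst[i]) / null$B
  }
  out
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up q-values `q_i = min_{k >= i} (p_(k) m / k)` with the
#' original order restored (delegated to [stats::p.adjust()]); `NA`
#' p-values (windows with no SNPs) pass through as `NA` and do not count
#' toward `m`.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return q-values in `[0, 1]`.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Attach bootstrap p-values and q-values to a window scan
#'
#' Builds (or reuses) a bootstrap null reference from the scan's own
#' per-SNP F_ST values and annotates every window with its p-value and
#' Benjamini-Hochberg q-value.
#'
#' @param windows a [scan_windows()] result.
#' @param null optional prebuilt [build_null_reference()]; by default one
#'   is built from the scan's per-SNP F_ST at the SNP counts present.
#' @param B,n_max,seed passed to [build_null_reference()] when `null` is
#'   not supplied.
#' @return `windows` with `pvalue` and `qvalue` columns added.
#' @export
scan_significance <- function(windows, null = NULL, B = 10000L,
                              n_max = 2000L, seed = 1L) {
  scheme <- attr(windows, "scheme")
  if (is.null(null)) {
    per_snp <- attr(windows, "per_snp")
    if (is.null(per_snp)) stop("windows carry no per-SNP statistics; supply `null`")
    null <- build_null_reference(
      per_snp$fst, scheme,
      n_values = unique(windows$n_fst[windows$n_fst > 0]),
      n_max = n_max, B = B, seed = seed
    )
  }
  windows$pvalue <- window_pvalue(windows$wfst, windows$n_fst, null)
  windows$qvalue <- bh_adjust(windows$pvalue)
  attr(windows, "null_seed") <- null$seed
  windows
}

#' Write / read a null reference as a flat text file
#'
#' One header line (`B`, `sigma`, `n_max`, `seed`) followed by one line
#' per distribution: the SNP count, a tab, then the sorted replicate
#' values comma-separated. Plain text so runs are resumable and
#' auditable.
#'
#' @param null a [build_null_reference()] object.
#' @param path file path.
#' @return `write_null_reference` returns `path` invisibly;
#'   `read_null_reference` returns the reconstructed `null_reference`.
#' @export
write_null_reference <- function(null, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#null_reference\tB=%d\tsigma=%g\tn_max=%d\tseed=%d",
                     null$B, null$sigma, null$n_max, null$seed), con)
  for (n in names(null$dists)) {
    writeLines(paste0(n, "\t",
                      paste(format(null$dists[[n]], digits = 17), collapse = ",")),
               con)
  }
  invisible(path)
}

#' @rdname write_null_reference
#' @export
read_null_reference <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(sub("^#null_reference\t", "", lines[1]), "\t")[[1]]
  meta <- stats::setNames(
    as.numeric(sub("^[^=]*=", "", hdr)),
    sub("=.*$", "", hdr)
  )
  dists <- list()
  for (line in lines[-1]) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    dists[[parts[1]]] <- as.numeric(strsplit(parts[2], ",", fixed = TRUE)[[1]])
  }
  structure(
    list(dists = dists, B = as.integer(meta[["B"]]), sigma = meta[["sigma"]],
         n_max = as.integer(meta[["n_max"]]), seed = as.integer(meta[["seed"]])),
    class = "null_reference"
  )
}
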