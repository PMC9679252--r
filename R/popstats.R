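#' Superpool frequency from member pool frequencies
#'
#' The allele frequency of a superpool is the unweighted arithmetic mean of
#' its member pool frequencies.
#'
#' @param pool_freqs numeric vector of member pool frequencies in `[0, 1]`.
#' @return a single frequency.
#' @export
superpool_frequency <- function(pool_freqs) {
  if (!length(pool_freqs)) stop("empty frequency list")
  if (any(pool_freqs < 0 | pool_freqs > 1, na.rm = TRUE)) {
    stop("frequencies must lie in [0, 1]")
  }
  mean(pool_freqs)
}

#' Nei's F_ST from group allele frequencies
#'
#' Relative divergence from expected heterozygosities,
#' \deqn{F_{ST} = (\hat H_T - \hat H_S) / \hat H_T,}
#' where \eqn{\hat H_T = 2 \bar p (1 - \bar p)} uses the unweighted mean
#' \eqn{\bar p} of the group frequencies and \eqn{\hat H_S} is the mean of
#' the within-group expected heterozygosities \eqn{2 p_i (1 - p_i)}. Groups
#' are weighted equally regardless of how many pools they aggregate. For
#' two groups this reduces algebraically to
#' \eqn{(p_1 - p_2)^2 / (4 \bar p (1 - \bar p))}, which also shows the
#' estimator cannot go negative under equal weighting. This plain
#' expected-heterozygosity estimator carries a known upward bias from
#' finite pool ploidy; the bias is shared across comparisons made at equal
#' pool size and depth.
#'
#' @param p either a numeric vector of group frequencies for one locus
#'   (length >= 2), or a matrix with one row per locus and one column per
#'   group.
#' @return F_ST per locus; `NA` where the locus is monomorphic across
#'   groups (\eqn{\hat H_T = 0}).
#' @export
fst_nei <- function(p) {
  if (is.matrix(p)) {
    if (ncol(p) < 2) stop("need >= 2 groups")
    if (any(p < 0 | p > 1, na.rm = TRUE)) stop("frequencies must lie in [0, 1]")
    pbar <- rowMeans(p)
    ht <- 2 * pbar * (1 - pbar)
    hs <- rowMeans(2 * p * (1 - p))
    ifelse(ht > 0, (ht - hs) / ht, NA_real_)
  } else {
    if (length(p) < 2) stop("need >= 2 groups")
    fst_nei(matrix(p, nrow = 1))[1]
  }
}

#' Absolute divergence d_XY for unphased pooled data
#'
#' Expected per-site nucleotide difference between two populations,
#' \eqn{d_{XY} = p_X q_Y + q_X p_Y} with \eqn{q = 1 - p}. Unlike F_ST its
#' expectation does not depend on within-population diversity. Symmetric in
#' its arguments; equals \eqn{2p(1-p)} when both frequencies are equal.
#'
#' @param p_x,p_y frequencies in `[0, 1]` (vectorized).
#' @return d_XY per locus, in `[0, 1]`.
#' @export
dxy <- function(p_x, p_y) {
  if (any(p_x < 0 | p_x > 1 | p_y < 0 | p_y > 1, na.rm = TRUE)) {
    stop("frequencies must lie in [0, 1]")
  }
  p_x * (1 - p_y) + (1 - p_x) * p_y
}

#' Lin's concordance correlation coefficient
#'
#' Agreement of two measurement vectors with the identity line,
#' \deqn{\rho_c = \frac{2 \rho \sigma_X \sigma_Y}
#'       {\sigma_X^2 + \sigma_Y^2 + (\mu_X - \mu_Y)^2}.}
#' Moments use the population (n-denominator) convention, so
#' \eqn{\rho_c = 1} exactly when `x == y` elementwise. Used to quantify how
#' well replicate pools reproduce each other's allele-frequency calls.
#'
#' @param x,y numeric vectors of equal length >= 2; at least one must be
#'   non-constant.
#' @return a list of class `concordance` with elements `rho_c`, `pearson`,
#'   `mu_x`, `mu_y`, `var_x`, `var_y` and `n`.
#' @export
lin_ccc <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    stop("x and y must have equal length >= 2")
  }
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  if (vx == 0 && vy == 0) stop("both vectors are constant; concordance undefined")
  cxy <- mean((x - mx) * (y - my))
  rho <- if (vx == 0 || vy == 0) NA_real_ else cxy / sqrt(vx * vy)
  structure(
    list(
      rho_c = 2 * cxy / (vx + vy + (mx - my)^2),
      pearson = rho, mu_x = mx, mu_y = my, var_x = vx, var_y = vy, n = n
    ),
    class = "concordance"
  )
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("Lin's concordance: rho_c = %.6f (Pearson %.6f, n = %d)\n",
              x$rho_c, x$pearson, x$n))
  invisible(x)
}

#' Pairwise concordance among all pools
#'
#' @param m a [pool_matrix()]
#' @return data.frame with one row per unordered pool pair: `pool_a`,
#'   `pool_b`, `rho_c`, `pearson`, `n_snps`.
#' @export
pairwise_concordance <- function(m) {
  freqs <- pool_freqs(m)
  ids <- m$pools$pool_id
  pairs <- utils::combn(length(ids), 2)
  out <- data.frame(
    pool_a = ids[pairs[1, ]], pool_b = ids[pairs[2, ]],
    rho_c = NA_real_, pearson = NA_real_, n_snps = NA_integer_,
    stringsAsFactors = FALSE
  )
  for (k in seq_len(ncol(pairs))) {
    cc <- lin_ccc(freqs[, pairs[1, k]], freqs[, pairs[2, k]])
    out$rho_c[k] <- cc$rho_c
    out$pearson[k] <- cc$pearson
    out$n_snps[k] <- cc$n
  }
  out
}

#' Global pairwise F_ST between pools
#'
#' Whole-genome pairwise F_ST for every pool pair: the unweighted mean of
#' per-SNP Nei F_ST over all SNPs that are variable within the pair
#' (\eqn{\hat H_T > 0}), equivalent to a single window spanning the entire
#' genome.
#'
#' @param m a [pool_matrix()]
#' @return symmetric numeric matrix (zero diagonal) with pool ids as
#'   dimnames.
#' @export
pairwise_global_fst <- function(m) {
  if (n_pools(m) < 2) stop("need >= 2 pools")
  freqs <- pool_freqs(m)
  k <- ncol(freqs)
  out <- matrix(0, k, k, dimnames = list(m$pools$pool_id, m$pools$pool_id))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      fst <- fst_nei(freqs[, c(i, j)])
      out[i, j] <- out[j, i] <- mean(fst, na.rm = TRUE)
    }
  }
  out
}

#' Folded minor-allele-frequency spectrum of a pool
#'
#' Histogram of `min(p, 1 - p)` over the ploidy grid `{0, 1/C, ..., 0.5}`.
#' A pool whose spectrum is skewed toward rare alleles relative to the
#' other pools (e.g. from library artefacts) can be screened out before
#' association analyses.
#'
#' @param pool_freqs numeric vector of frequencies on the `1/C` grid.
#' @param C pool ploidy.
#' @return named integer vector of counts per grid bin.
#' @export
minor_allele_spectrum <- function(pool_freqs, C) {
  pool_freqs <- pool_freqs[!is.na(pool_freqs)]
  j <- pool_freqs * C
  if (any(abs(j - round(j)) > 1e-8)) {
    stop("frequencies are not on the 1/C grid")
  }
  maf <- pmin(pool_freqs, 1 - pool_freqs)
  bins <- seq(0, floor(C / 2)) / C
  counts <- tabulate(match(round(maf * C), round(bins * C)), nbins = length(bins))
  stats::setNames(counts, format(bins, trim = TRUE))
}

#' Flag pools with an excess of low-frequency minor alleles
#'
#' For each pool, the share of SNPs with MAF `<= max_maf` is compared with
#' the mean and standard deviation of that share across the other pools; a
#' pool is flagged when its z-score exceeds `z`.
#'
#' @param m a [pool_matrix()]
#' @param max_maf MAF cutoff defining "low frequency"; default `2/C` for
#'   each pool's ploidy `C`.
#' @param z z-score threshold (default 3).
#' @return data.frame with `pool_id`, `low_maf_share`, `zscore`, `flagged`.
#' @export
flag_maf_skew <- function(m, max_maf = NULL, z = 3) {
  freqs <- pool_freqs(m)
  k <- ncol(freqs)
  share <- vapply(seq_len(k), function(i) {
    cutoff <- if (is.null(max_maf)) 2 / m$pools$ploidy[i] else max_maf
    f <- freqs[, i]
    f <- f[!is.na(f)]
    mean(pmin(f, 1 - f) <= cutoff + 1e-12)
  }, numeric(1))
  zs <- vapply(seq_len(k), function(i) {
    others <- share[-i]
    s <- stats::sd(others)
    if (is.na(s) || s == 0) return(NA_real_)
    (share[i] - mean(others)) / s
  }, numeric(1))
  data.frame(
    pool_id = m$pools$pool_id, low_maf_share = share, zscore = zs,
    flagged = !is.na(zs) & zs > z, stringsAsFactors = FALSE
  )
}

#' Per-SNP divergence statistics between two superpools
#'
#' Computes superpool frequencies (arithmetic pool means), per-SNP Nei
#' F_ST and per-SNP d_XY for one pair of superpools.
#'
#' @param m a [pool_matrix()]
#' @param pair character vector of two superpool labels.
#' @return data.frame with `lg`, `pos`, `p_x`, `p_y`, `fst` (`NA` at sites
#'   monomorphic within the pair) and `dxy`.
#' @export
per_snp_stats <- function(m, pair) {
  if (length(pair) != 2) stop("`pair` must name two superpools")
  sp <- superpool_freqs(m, pair)
  data.frame(
    lg = m$snps$lg, pos = m$snps$pos,
    p_x = sp[, 1], p_y = sp[, 2],
    fst = fst_nei(sp), dxy = dxy(sp[, 1], sp[, 2]),
    stringsAsFactors = FALSE
  )
}
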