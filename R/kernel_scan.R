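#' Sliding-window geometry for the kernel scan
#'
#' Windows are centred every `step` bp and span `c - 3*sigma` to
#' `c + 3*sigma`: the Gaussian kernel is truncated at three standard
#' deviations, so the full window covers `6*sigma` bp (180,000 bp at the
#' defaults of step 20 kb and sigma 30 kb).
#'
#' @param step step size between consecutive window centres, in bp.
#' @param sigma Gaussian kernel standard deviation, in bp.
#' @return an object of class `window_scheme` with fields `step`, `sigma`,
#'   `half_span` (`3*sigma`) and `span` (`6*sigma`).
#' @export
window_scheme <- function(step = 20000L, sigma = 30000L) {
  stopifnot(step > 0, sigma > 0)
  structure(
    list(step = as.integer(step), sigma = as.numeric(sigma),
         half_span = 3 * as.numeric(sigma), span = 6 * as.numeric(sigma)),
    class = "window_scheme"
  )
}

#' @export
print.window_scheme <- function(x, ...) {
  cat(sprintf("window_scheme: step %d bp, sigma %g bp, span %g bp\n",
              x$step, x$sigma, x$span))
  invisible(x)
}

#' Window centres along linkage groups
#'
#' The first centre sits at `half_span` and centres advance by `step`
#' while the full window still fits (`centre + half_span <= length`).
#' Windows never span linkage groups; a linkage group shorter than one
#' full window yields no windows.
#'
#' @param lg_lengths named numeric vector of linkage-group lengths in bp.
#' @param scheme a [window_scheme()].
#' @return data.frame with `lg` and `center` (bp).
#' @export
make_windows <- function(lg_lengths, scheme = window_scheme()) {
  if (any(lg_lengths <= 0)) stop("linkage-group lengths must be positive")
  if (is.null(names(lg_lengths))) {
    names(lg_lengths) <- sprintf("LG%02d", seq_along(lg_lengths))
  }
  out <- lapply(names(lg_lengths), function(lg) {
    L <- lg_lengths[[lg]]
    if (L < scheme$span) {
      return(data.frame(lg = character(0), center = numeric(0)))
    }
    centers <- seq(scheme$half_span, L - scheme$half_span, by = scheme$step)
    data.frame(lg = lg, center = centers, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Gaussian kernel weight of a SNP in a window
#'
#' `exp(-(p - c)^2 / (2 sigma^2))` for positions within `3*sigma` of the
#' centre, and 0 beyond the truncation point.
#'
#' @param p SNP position (bp, vectorized).
#' @param c window centre (bp).
#' @param sigma kernel standard deviation (bp).
#' @return weights in `[0, 1]`, maximal (1) at `p == c`.
#' @export
kernel_weight <- function(p, c, sigma) {
  w <- exp(-(p - c)^2 / (2 * sigma^2))
  w[abs(p - c) > 3 * sigma] <- 0
  w
}

#' Kernel-weighted window F_ST
#'
#' Weighted average `sum(w_i fst_i) / sum(w_i)` over the SNPs in the
#' window with a defined per-SNP F_ST; sites monomorphic within the
#' compared pair (undefined F_ST) are excluded, as F_ST is undefined for
#' invariable positions.
#'
#' @param per_snp_fst per-SNP F_ST values (`NA` = undefined).
#' @param positions SNP positions (bp), same length.
#' @param c window centre (bp).
#' @param sigma kernel standard deviation (bp).
#' @return the weighted mean, or `NA` if no SNP in the window has a
#'   defined F_ST.
#' @export
weighted_window_fst <- function(per_snp_fst, positions, c, sigma) {
  w <- kernel_weight(positions, c, sigma)
  keep <- w > 0 & !is.na(per_snp_fst)
  if (!any(keep)) return(NA_real_)
  sum(w[keep] * per_snp_fst[keep]) / sum(w[keep])
}

#' Total kernel mass over every bp of a window
#'
#' `sum over integer offsets d in [-3 sigma, 3 sigma] of
#' exp(-d^2 / (2 sigma^2))`: the normalizing constant that turns a kernel
#' sum over SNPs into a per-bp quantity.
#'
#' @param sigma kernel standard deviation (bp).
#' @return total kernel mass (bp-equivalents).
#' @export
kernel_bp_mass <- function(sigma) {
  d <- seq(-floor(3 * sigma), floor(3 * sigma))
  sum(exp(-d^2 / (2 * sigma^2)))
}

#' Kernel-weighted window d_XY (per bp)
#'
#' `sum(w_i dxy_i) / W` where the sum runs over SNPs in the window and
#' `W` is the kernel mass over every bp position in the span
#' ([kernel_bp_mass()]). Monomorphic sites contribute 0 to the numerator,
#' so d_XY is effectively averaged over all sites and comes out as a
#' per-bp quantity (order 1e-4 to 1e-3 at realistic SNP densities).
#'
#' @param per_snp_dxy per-SNP d_XY values.
#' @param positions SNP positions (bp), same length.
#' @param c window centre (bp).
#' @param sigma kernel standard deviation (bp).
#' @param W optional precomputed [kernel_bp_mass()] for `sigma`.
#' @return per-bp weighted d_XY (0 when the window holds no SNPs).
#' @export
weighted_window_dxy <- function(per_snp_dxy, positions, c, sigma, W = NULL) {
  if (is.null(W)) W <- kernel_bp_mass(sigma)
  w <- kernel_weight(positions, c, sigma)
  keep <- w > 0 & !is.na(per_snp_dxy)
  if (!any(keep)) return(0)
  sum(w[keep] * per_snp_dxy[keep]) / W
}

#' Window nucleotide diversity for a superpool
#'
#' \deqn{\pi = \sum_{sites} \frac{2 j (C - j)}{C (C - 1)} / n,}
#' where `j` is the allele count on the superpool ploidy grid
#' (`round(freq * C)`; `2j(C-j)` is symmetric, so the reference/derived
#' labeling does not matter), `C` the superpool ploidy and `n` the full
#' window length in bp. Monomorphic sites add 0, so only SNPs need to be
#' supplied. The sum is unweighted.
#'
#' @param superpool_freqs superpool allele frequencies at the window's
#'   SNPs.
#' @param positions SNP positions (bp), same length.
#' @param c window centre (bp).
#' @param sigma kernel standard deviation (bp; sites beyond `3*sigma` are
#'   outside the window).
#' @param n window length in bp (default `6*sigma`).
#' @param C superpool ploidy (pool ploidy x number of member pools).
#' @return list with `pi` (per bp) and `pi_sum` (per-window total, the
#'   scale used by [window_tajimas_d()]).
#' @export
window_pi <- function(superpool_freqs, positions, c, sigma, C, n = 6 * sigma) {
  if (C < 2) stop("superpool ploidy must be >= 2")
  inwin <- abs(positions - c) <= 3 * sigma & !is.na(superpool_freqs)
  j <- round(superpool_freqs[inwin] * C)
  pi_sum <- sum(2 * j * (C - j) / (C * (C - 1)))
  list(pi = pi_sum / n, pi_sum = pi_sum)
}

#' Watterson's theta for a window
#'
#' `theta_W = S_n / a1` with `a1 = sum_{i=1}^{upper} 1/i`, where `S_n` is
#' the number of SNPs in the window and `C` the superpool ploidy. The
#' standard Watterson estimator sums to `C - 1`; `theta_sum_upper = "C"`
#' extends the sum to `C` for compatibility with pipelines that use that
#' convention.
#'
#' @param S_n number of segregating sites in the window.
#' @param C superpool ploidy (>= 2).
#' @param theta_sum_upper `"C-1"` (default, standard) or `"C"`.
#' @return theta_W on the per-window scale.
#' @export
window_theta_w <- function(S_n, C, theta_sum_upper = c("C-1", "C")) {
  if (C < 2) stop("ploidy must be >= 2")
  if (any(S_n < 0)) stop("S_n must be >= 0")
  theta_sum_upper <- match.arg(theta_sum_upper)
  upper <- if (theta_sum_upper == "C-1") C - 1 else C
  S_n / sum(1 / seq_len(upper))
}

#' Tajima (1989) variance constants
#'
#' @param C sample size (superpool ploidy).
#' @return named list of the constants `a1, a2, b1, b2, c1, c2, e1, e2`.
#' @export
tajima_constants <- function(C) {
  if (C < 2) stop("sample size must be >= 2")
  a1 <- sum(1 / seq_len(C - 1))
  a2 <- sum(1 / seq_len(C - 1)^2)
  b1 <- (C + 1) / (3 * (C - 1))
  b2 <- 2 * (C^2 + C + 3) / (9 * C * (C - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (C + 2) / (a1 * C) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D for a window
#'
#' \deqn{D = \frac{\pi - \theta_W}{\sqrt{\widehat{var}(\pi - \theta_W)}},}
#' with `var = e1 S_n + e2 S_n (S_n - 1)` from the Tajima (1989)
#' constants at sample size `C`. `pi_sum` is the per-window pi total (not
#' divided by window length), so that pi and theta_W are on the same
#' scale. Negative D indicates an excess of rare alleles.
#'
#' @param pi_sum per-window pi total (see [window_pi()]).
#' @param S_n number of SNPs in the window.
#' @param C superpool ploidy.
#' @return D, or `NA` when `S_n == 0` (undefined).
#' @export
window_tajimas_d <- function(pi_sum, S_n, C) {
  k <- tajima_constants(C)
  ifelse(S_n >= 1,
         (pi_sum - S_n / k$a1) / sqrt(k$e1 * S_n + k$e2 * S_n * (S_n - 1)),
         NA_real_)
}

#' Genome scan: kernel-smoothed window statistics for a superpool pair
#'
#' Runs the full sliding-window computation for one superpool comparison:
#' per-SNP F_ST and d_XY from [per_snp_stats()], then for every window the
#' kernel-weighted F_ST and per-bp d_XY, the SNP count, and per-superpool
#' nucleotide diversity and Tajima's D.
#'
#' @param m a filtered [pool_matrix()].
#' @param pair character vector of two superpool labels to compare.
#' @param scheme a [window_scheme()].
#' @param lg_lengths named vector of linkage-group lengths in bp; default
#'   is the largest SNP position per linkage group.
#' @param theta_sum_upper passed to [window_theta_w()].
#' @return data.frame of class `scan_windows`, one row per window: `lg`,
#'   `center`, `start`, `end` (span, 1-based inclusive), `n_snps` (SNPs in
#'   the window), `n_fst` (SNPs with defined pairwise F_ST), `wfst`,
#'   `wdxy`, and `pi_<superpool>`, `theta_w_<superpool>`,
#'   `tajd_<superpool>` for both superpools. The `scheme`, `pair` and
#'   per-SNP statistics are attached as attributes.
#' @export
scan_windows <- function(m, pair, scheme = window_scheme(),
                         lg_lengths = NULL, theta_sum_upper = c("C-1", "C")) {
  theta_sum_upper <- match.arg(theta_sum_upper)
  stats <- per_snp_stats(m, pair)
  sp <- superpool_freqs(m, pair)
  C_sp <- attr(sp, "ploidy")

  if (is.null(lg_lengths)) {
    lg_lengths <- tapply(m$snps$pos, m$snps$lg, max)
    lg_lengths <- stats::setNames(as.numeric(lg_lengths), names(lg_lengths))
  }
  win <- make_windows(lg_lengths, scheme)
  n_win <- nrow(win)

  out <- data.frame(
    lg = win$lg, center = win$center,
    start = win$center - scheme$half_span + 1,
    end = win$center + scheme$half_span,
    n_snps = 0L, n_fst = 0L, wfst = NA_real_, wdxy = 0,
    stringsAsFactors = FALSE
  )
  for (lab in pair) {
    out[[paste0("pi_", lab)]] <- 0
    out[[paste0("theta_w_", lab)]] <- 0
    out[[paste0("tajd_", lab)]] <- NA_real_
  }

  W <- kernel_bp_mass(scheme$sigma)
  for (lg in unique(win$lg)) {
    snp_idx <- which(stats$lg == lg)
    pos <- stats$pos[snp_idx]
    for (wi in which(win$lg == lg)) {
      c0 <- win$center[wi]
      lo <- findInterval(c0 - scheme$half_span - 0.5, pos) + 1
      hi <- findInterval(c0 + scheme$half_span, pos)
      if (hi < lo) next
      idx <- snp_idx[lo:hi]
      p <- stats$pos[idx]
      fst <- stats$fst[idx]
      out$n_snps[wi] <- length(idx)
      out$n_fst[wi] <- sum(!is.na(fst))
      out$wfst[wi] <- weighted_window_fst(fst, p, c0, scheme$sigma)
      out$wdxy[wi] <- weighted_window_dxy(stats$dxy[idx], p, c0, scheme$sigma, W = W)
      for (lab in pair) {
        pw <- window_pi(sp[idx, lab], p, c0, scheme$sigma, C_sp[[lab]])
        out[[paste0("pi_", lab)]][wi] <- pw$pi
        out[[paste0("theta_w_", lab)]][wi] <-
          window_theta_w(length(idx), C_sp[[lab]], theta_sum_upper)
        out[[paste0("tajd_", lab)]][wi] <-
          window_tajimas_d(pw$pi_sum, length(idx), C_sp[[lab]])
      }
    }
  }
  attr(out, "scheme") <- scheme
  attr(out, "pair") <- pair
  attr(out, "per_snp") <- stats
  class(out) <- c("scan_windows", "data.frame")
  out
}
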