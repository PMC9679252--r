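#' Pooled allele-count matrix
#'
#' The central container of the package: per-SNP, per-pool reference-allele
#' counts at a fixed pool ploidy, together with SNP positions on named
#' linkage groups and pool metadata. Pool allele frequencies are
#' `counts / ploidy` and therefore lie on a grid of `1/ploidy` (0.05 at the
#' default ploidy of 20).
#'
#' @param snps data.frame with columns `lg` (linkage-group name), `pos`
#'   (1-based bp, strictly increasing within a linkage group), `ref`, `alt`
#'   (allele labels). Extra columns are retained.
#' @param counts integer matrix, one row per SNP and one column per pool,
#'   holding reference-allele counts in `[0, ploidy]`; `NA` marks missing
#'   data for that pool at that SNP.
#' @param pools data.frame with columns `pool_id`, `ploidy` and `superpool`
#'   (the population grouping used when forming superpool frequencies).
#' @param depths optional integer matrix of per-SNP, per-pool read depths
#'   (same shape as `counts`), required by [filter_depth()].
#'
#' @return An object of class `pool_matrix`.
#' @seealso [read_pool_table()], [filter_depth()],
#'   [filter_complete_biallelic_variant()], [superpool_freqs()]
#' @export
pool_matrix <- function(snps, counts, pools, depths = NULL) {
  stopifnot(is.data.frame(snps), is.data.frame(pools))
  req <- c("lg", "pos", "ref", "alt")
  if (!all(req %in% names(snps))) {
    stop("`snps` must have columns: ", paste(req, collapse = ", "))
  }
  if (!all(c("pool_id", "ploidy", "superpool") %in% names(pools))) {
    stop("`pools` must have columns pool_id, ploidy, superpool")
  }
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(snps) || ncol(counts) != nrow(pools)) {
    stop("`counts` must be n_snps x n_pools")
  }
  if (!is.null(depths)) {
    depths <- as.matrix(depths)
    if (!all(dim(depths) == dim(counts))) stop("`depths` must match `counts` in shape")
    if (any(depths < 0, na.rm = TRUE)) stop("read depths must be >= 0")
  }
  C <- rep(pools$ploidy, each = nrow(counts))
  if (any(counts < 0 | counts > C, na.rm = TRUE)) {
    stop("allele counts must lie in [0, ploidy]")
  }
  snps$lg <- as.character(snps$lg)
  snps$pos <- as.integer(snps$pos)

  ord <- order(snps$lg, snps$pos)
  snps <- snps[ord, , drop = FALSE]
  counts <- counts[ord, , drop = FALSE]
  if (!is.null(depths)) depths <- depths[ord, , drop = FALSE]
  if (anyDuplicated(paste(snps$lg, snps$pos))) {
    stop("duplicate (lg, pos) entries: positions must be strictly increasing within a linkage group")
  }
  rownames(snps) <- NULL
  colnames(counts) <- pools$pool_id
  if (!is.null(depths)) colnames(depths) <- pools$pool_id

  structure(
    list(snps = snps, counts = counts, depths = depths, pools = pools),
    class = "pool_matrix"
  )
}

#' @export
print.pool_matrix <- function(x, ...) {
  cat(sprintf(
    "pool_matrix: %d SNPs x %d pools on %d linkage group(s)\n",
    n_snps(x), n_pools(x), length(unique(x$snps$lg))
  ))
  cat("  superpools:",
      paste(sprintf("%s (%d)", names(table(x$pools$superpool)),
                    as.integer(table(x$pools$superpool))), collapse = ", "), "\n")
  cat("  depths:", if (is.null(x$depths)) "absent" else "present", "\n")
  invisible(x)
}

#' Number of SNPs / pools in a pool_matrix
#' @param m a [pool_matrix()]
#' @return integer count.
#' @export
n_snps <- function(m) nrow(m$counts)

#' @rdname n_snps
#' @export
n_pools <- function(m) ncol(m$counts)

#' Per-pool allele frequencies
#'
#' Reference-allele frequencies `counts / ploidy`, one column per pool.
#'
#' @param m a [pool_matrix()]
#' @return numeric matrix on the `1/ploidy` grid, `NA` where counts are
#'   missing.
#' @export
pool_freqs <- function(m) {
  sweep(m$counts, 2, m$pools$ploidy, "/")
}

#' Superpool allele frequencies
#'
#' A superpool treats a set of pools as one population; its allele frequency
#' at a SNP is the unweighted arithmetic mean of the member pool
#' frequencies. The effective ploidy of a superpool is
#' `ploidy x n_members` (e.g. 120 for six pools at ploidy 20).
#'
#' @param m a [pool_matrix()]
#' @param superpools character vector of superpool labels to return;
#'   default all labels present in `m$pools$superpool`.
#' @return numeric matrix, one column per superpool, with attribute
#'   `"ploidy"` giving each superpool's effective ploidy.
#' @export
superpool_freqs <- function(m, superpools = NULL) {
  freqs <- pool_freqs(m)
  labs <- if (is.null(superpools)) unique(m$pools$superpool) else superpools
  out <- matrix(NA_real_, n_snps(m), length(labs), dimnames = list(NULL, labs))
  ploidy <- integer(length(labs))
  for (i in seq_along(labs)) {
    members <- which(m$pools$superpool == labs[i])
    if (!length(members)) stop("no pools in superpool ", labs[i])
    out[, i] <- rowMeans(freqs[, members, drop = FALSE])
    ploidy[i] <- sum(m$pools$ploidy[members])
  }
  attr(out, "ploidy") <- stats::setNames(ploidy, labs)
  out
}

#' Subset a pool_matrix by SNP index
#' @param m a [pool_matrix()]
#' @param i integer or logical index over SNPs.
#' @return a [pool_matrix()] with the selected SNPs.
#' @export
subset_snps <- function(m, i) {
  pool_matrix(
    m$snps[i, , drop = FALSE],
    m$counts[i, , drop = FALSE],
    m$pools,
    if (is.null(m$depths)) NULL else m$depths[i, , drop = FALSE]
  )
}
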