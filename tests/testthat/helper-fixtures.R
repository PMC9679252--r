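# Shared fixture builders: everything is generated in code at test time.

# A minimal pool_matrix with explicit counts (rows = SNPs, cols = pools).
make_pm <- function(counts, pos = seq_len(nrow(counts)) * 1000L,
                    lg = "LG01", ploidy = 20L, superpool = NULL,
                    depths = NULL) {
  counts <- as.matrix(counts)
  k <- ncol(counts)
  ids <- sprintf("p%d", seq_len(k))
  if (is.null(superpool)) superpool <- ids
  pool_matrix(
    data.frame(lg = rep_len(lg, nrow(counts)), pos = pos,
               ref = "A", alt = "T", stringsAsFactors = FALSE),
    counts,
    data.frame(pool_id = ids, ploidy = ploidy, superpool = superpool,
               stringsAsFactors = FALSE),
    depths
  )
}

# Small two-population design (3 + 3 pools) for fast simulations.
small_pools <- function() {
  data.frame(
    pool_id = c("X1", "X2", "X3", "Y1", "Y2", "Y3"),
    population = c("EBS", "EBS", "EBS", "AI", "AI", "AI"),
    superpool = c("EBS", "EBS", "EBS", "AI", "AI", "AI"),
    ploidy = 20L,
    mean_depth = 60,
    perturb_fst = 0,
    stringsAsFactors = FALSE
  )
}

# Reference step-up implementation of Benjamini-Hochberg, used as the
# independent oracle for bh_adjust.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}
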