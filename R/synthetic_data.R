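#' Pool layout emulating an 11-pool cod Pool-Seq design
#'
#' Eleven pools of ~43-48 diploids genotyped at pool ploidy 20, grouped
#' into three superpools: a six-pool Bering Sea-like group (`EBS`,
#' including a temporal replicate pair), a three-pool Aleutian-like group
#' (`AI`) and a two-pool Washington-like replicate pair (`WA`). Mean read
#' depths span the 60-98x range of such designs. Pools within a
#' population share the same population allele frequency (replicate
#' grade); a nonzero `perturb_fst` adds a small extra Balding-Nichols
#' jitter to an individual pool, mimicking a temporal replicate of
#' near-identical rather than identical composition.
#'
#' @return data.frame with `pool_id`, `population`, `superpool`, `ploidy`,
#'   `mean_depth`, `perturb_fst`.
#' @export
cod_pool_layout <- function() {
  data.frame(
    pool_id = c("Near", "Kiska", "Adak",
                "Pervenets_A", "Pervenets_B", "Pribilof", "Zhemchug",
                "Kodiak_2003", "Kodiak_2005",
                "Washington_A", "Washington_B"),
    population = c("AI", "AI", "AI",
                   "EBS", "EBS", "EBS", "EBS", "EBS", "EBS",
                   "WA", "WA"),
    superpool = c("AI", "AI", "AI",
                  "EBS", "EBS", "EBS", "EBS", "EBS", "EBS",
                  "WA", "WA"),
    ploidy = 20L,
    mean_depth = c(60, 60, 71, 98, 88, 84, 71, 70, 79, 87, 81),
    perturb_fst = c(0, 0, 0, 0, 0, 0, 0, 0, 0.001, 0, 0),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic Pool-Seq generator
#'
#' Defines the genome geometry, pool design, divergence structure and
#' injected islands of a simulated pooled dataset. `background_fst` and
#' each island's `fst` are targets for the *measured* superpool Nei F_ST
#' of the `comparison` pair, including the upward contribution of
#' binomial pool sampling at finite ploidy; [simulate_dataset()] converts
#' them into per-population Balding-Nichols parameters (see
#' [bn_param_for_target()]).
#'
#' @param n_lg number of linkage groups.
#' @param lg_length length of each linkage group in bp (scalar or vector
#'   of length `n_lg`).
#' @param snp_density expected SNPs per bp (positions are Poisson in
#'   number, uniform in location).
#' @param pools pool design data.frame as in [cod_pool_layout()].
#' @param background_fst genome-wide target F_ST between the `comparison`
#'   superpools, in `[0, 1)`. Zero disables population divergence
#'   entirely (all populations sit at the ancestral frequency, so pools
#'   differ only by binomial sampling); positive values are targets for
#'   the measured superpool F_ST and must exceed what pool-sampling noise
#'   alone produces.
#' @param islands `NULL` or data.frame with `lg` (linkage-group name or
#'   index), `start`, `end` (bp, within the linkage group, non-overlapping)
#'   and `fst` (> `background_fst`): regions where the `island_pop`
#'   population is more strongly diverged.
#' @param island_pop population receiving the island-level divergence.
#' @param comparison two superpool labels whose measured F_ST the
#'   calibration targets.
#' @param ancestral_beta shape parameters of the Beta distribution of
#'   ancestral allele frequencies.
#' @param ancestral_range truncation interval for ancestral frequencies;
#'   the default `[0.05, 0.95]` keeps pooled quantization at ploidy 20
#'   from fixing SNPs too often.
#' @param missing_frac fraction of SNPs given depth 0 (missing call) in
#'   one random pool, to exercise the completeness filter.
#' @param seed mandatory integer seed; the simulation is deterministic
#'   given the config.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_lg = 5L, lg_length = 2e6, snp_density = 1e-3,
                       pools = cod_pool_layout(), background_fst = 0.02,
                       islands = NULL, island_pop = "AI",
                       comparison = c("EBS", "AI"),
                       ancestral_beta = c(0.5, 0.5),
                       ancestral_range = c(0.05, 0.95),
                       missing_frac = 0.01, seed) {
  if (missing(seed)) stop("`seed` is mandatory")
  if (background_fst < 0 || background_fst >= 1) {
    stop("background_fst must lie in [0, 1)")
  }
  lg_length <- rep_len(lg_length, n_lg)
  lg_names <- sprintf("LG%02d", seq_len(n_lg))
  if (!all(comparison %in% pools$superpool)) {
    stop("comparison superpools not present in pool design")
  }
  if (!island_pop %in% pools$population) stop("unknown island_pop")
  if (!is.null(islands) && nrow(islands)) {
    if (is.numeric(islands$lg)) islands$lg <- lg_names[islands$lg]
    if (!all(islands$lg %in% lg_names)) stop("island on unknown linkage group")
    for (g in unique(islands$lg)) {
      isl <- islands[islands$lg == g, , drop = FALSE]
      L <- lg_length[match(g, lg_names)]
      if (any(isl$start < 1 | isl$end > L | isl$start >= isl$end)) {
        stop("island intervals must lie within their linkage group")
      }
      isl <- isl[order(isl$start), , drop = FALSE]
      if (nrow(isl) > 1 && any(isl$start[-1] < isl$end[-nrow(isl)])) {
        stop("island intervals must not overlap")
      }
    }
    if (any(islands$fst <= background_fst)) {
      stop("island fst must exceed background_fst")
    }
  }
  structure(
    list(n_lg = as.integer(n_lg), lg_length = lg_length, lg_names = lg_names,
         snp_density = snp_density, pools = pools,
         background_fst = background_fst, islands = islands,
         island_pop = island_pop, comparison = comparison,
         ancestral_beta = ancestral_beta, ancestral_range = ancestral_range,
         missing_frac = missing_frac, seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Read a simulation config from a YAML file
#'
#' Keys mirror the arguments of [sim_config()]; `pools` and `islands` are
#' given as lists of records.
#'
#' @param path YAML file path.
#' @return a [sim_config()].
#' @export
read_sim_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$pools)) {
    y$pools <- do.call(rbind, lapply(y$pools, as.data.frame))
    if (is.null(y$pools$perturb_fst)) y$pools$perturb_fst <- 0
    if (is.null(y$pools$superpool)) y$pools$superpool <- y$pools$population
  }
  if (!is.null(y$islands)) {
    y$islands <- do.call(rbind, lapply(y$islands, as.data.frame))
    for (v in c("start", "end", "fst")) {
      y$islands[[v]] <- as.numeric(y$islands[[v]])
    }
  }
  # YAML 1.1 only treats exponents with an explicit sign as numbers
  for (v in intersect(c("lg_length", "snp_density", "background_fst",
                        "missing_frac"), names(y))) {
    y[[v]] <- as.numeric(y[[v]])
  }
  do.call(sim_config, y)
}

#' Balding-Nichols population frequency draw
#'
#' Draws a population allele frequency around an ancestral frequency `p`
#' at divergence `F`: `Beta(p (1-F)/F, (1-p)(1-F)/F)`, which has mean `p`
#' and variance `F p (1-p)`. `F = 0` returns `p` exactly.
#'
#' @param ancestral_p ancestral frequency in `(0, 1)` (vectorized).
#' @param F divergence parameter in `[0, 1)`.
#' @param n number of draws (default `length(ancestral_p)`).
#' @return population frequencies.
#' @export
draw_population_freq <- function(ancestral_p, F, n = length(ancestral_p)) {
  if (any(ancestral_p <= 0 | ancestral_p >= 1)) {
    stop("ancestral frequency must lie in (0, 1)")
  }
  if (F < 0 || F >= 1) stop("F must lie in [0, 1)")
  if (F == 0) return(rep_len(ancestral_p, n))
  k <- (1 - F) / F
  stats::rbeta(n, ancestral_p * k, (1 - ancestral_p) * k)
}

#' Binomial pool allele count
#'
#' A pool call assigns exactly `C` allele copies per locus, so the
#' reference count is `Binomial(C, pop_freq)` and the pool frequency
#' `count / C` lies on a `1/C` grid.
#'
#' @param pop_freq population frequency in `[0, 1]` (vectorized).
#' @param C pool ploidy (>= 1).
#' @param n number of draws (default `length(pop_freq)`).
#' @return integer counts in `[0, C]`.
#' @export
sample_pool_counts <- function(pop_freq, C, n = length(pop_freq)) {
  if (any(pop_freq < 0 | pop_freq > 1)) stop("frequency must lie in [0, 1]")
  if (C < 1) stop("ploidy must be >= 1")
  stats::rbinom(n, C, rep_len(pop_freq, n))
}

#' Balding-Nichols parameter for a target measured F_ST
#'
#' Measured superpool Nei F_ST exceeds the population-process divergence
#' because binomial pool sampling at ploidy `C` adds variance
#' `~ p(1-p)/(C k)` to a `k`-pool superpool frequency. To first order,
#' with both populations at Balding-Nichols parameter `F'`, the expected
#' per-SNP Nei F_ST is `u / (2 - u)` with
#' `u = F' + (a + b)(1 - F')/2`, `a = 1/(C kX)`, `b = 1/(C kY)`. This
#' function inverts that relation: given the target measured `F`, it
#' returns the `F'` each population should be drawn with. Accurate to a
#' few percent at weak divergence (the background regime); increasingly
#' approximate for strongly diverged regions.
#'
#' @param target target measured Nei F_ST between the two superpools.
#' @param k_x,k_y number of pools in each superpool.
#' @param C pool ploidy.
#' @param fixed_other `NULL` for the symmetric case; otherwise the already
#'   assigned `F'` of the non-diverged population, in which case the
#'   returned parameter applies to the diverged population only (used for
#'   island regions).
#' @return the Balding-Nichols parameter.
#' @export
bn_param_for_target <- function(target, k_x, k_y, C = 20, fixed_other = NULL) {
  a <- 1 / (C * k_x)
  b <- 1 / (C * k_y)
  u <- 2 * target / (1 + target)
  if (is.null(fixed_other)) {
    fp <- (u - (a + b) / 2) / (1 - (a + b) / 2)
  } else {
    fp <- (2 * u - fixed_other * (1 - a) - (a + b)) / (1 - b)
  }
  if (fp <= 0 || fp >= 1) {
    stop("target F_ST unattainable for this pool design (sampling noise alone ",
         "meets or exceeds it, or the required divergence is >= 1)")
  }
  fp
}

#' Simulate a pooled allele-count dataset with ground truth
#'
#' Generates SNP positions (Poisson counts, uniform locations, sorted)
#' per linkage group, ancestral frequencies from a truncated Beta,
#' per-population frequencies from the Balding-Nichols model calibrated
#' against the config's `background_fst` target, elevated divergence of
#' the `island_pop` population inside island intervals, binomial pool
#' counts at the pool ploidy, Poisson read depths, and a configurable
#' fraction of single-pool missing calls. Deterministic for a fixed
#' config (including seed).
#'
#' @param config a [sim_config()].
#' @return a list of class `pool_sim` with elements:
#'   \describe{
#'     \item{matrix}{the [pool_matrix()] of counts and depths.}
#'     \item{truth}{list with `snps` (per-SNP `snp_id`, `lg`, `pos`,
#'       `ancestral_p`, `island_id` (`NA` outside islands)), `pop_freqs`
#'       (true population frequency matrix), `islands` (per-island `lg`,
#'       `start`, `end`, target `fst` and the Balding-Nichols parameter
#'       used) and `bn_background` (the background parameter).}
#'   }
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  pools <- config$pools
  pops <- unique(pools$population)
  C <- pools$ploidy[1]
  k_x <- sum(pools$superpool == config$comparison[1])
  k_y <- sum(pools$superpool == config$comparison[2])
  f_bg <- if (config$background_fst == 0) 0 else
    bn_param_for_target(config$background_fst, k_x, k_y, C)

  # positions
  per_lg <- lapply(seq_len(config$n_lg), function(i) {
    n <- stats::rpois(1, config$lg_length[i] * config$snp_density)
    n <- min(n, config$lg_length[i])
    sort(sample.int(config$lg_length[i], n))
  })
  lg <- rep(config$lg_names, lengths(per_lg))
  pos <- unlist(per_lg)
  n <- length(pos)

  # ancestral frequencies: Beta truncated to ancestral_range
  ab <- config$ancestral_beta
  lo <- stats::pbeta(config$ancestral_range[1], ab[1], ab[2])
  hi <- stats::pbeta(config$ancestral_range[2], ab[1], ab[2])
  anc <- stats::qbeta(stats::runif(n, lo, hi), ab[1], ab[2])

  # island membership
  island_id <- rep(NA_character_, n)
  truth_islands <- NULL
  if (!is.null(config$islands) && nrow(config$islands)) {
    ti <- config$islands
    ti$island_id <- sprintf("%s_truth%d", ti$lg, as.integer(stats::ave(
      seq_len(nrow(ti)), ti$lg, FUN = seq_along)))
    ti$bn_param <- vapply(ti$fst, function(f) {
      bn_param_for_target(f, k_x, k_y, C, fixed_other = f_bg)
    }, numeric(1))
    for (r in seq_len(nrow(ti))) {
      hit <- lg == ti$lg[r] & pos >= ti$start[r] & pos <= ti$end[r]
      island_id[hit] <- ti$island_id[r]
    }
    truth_islands <- ti
  }

  # population frequencies
  pop_freqs <- matrix(NA_real_, n, length(pops), dimnames = list(NULL, pops))
  for (pp in pops) {
    pop_freqs[, pp] <- draw_population_freq(anc, f_bg)
  }
  if (!is.null(truth_islands)) {
    for (r in seq_len(nrow(truth_islands))) {
      hit <- which(island_id == truth_islands$island_id[r])
      if (length(hit)) {
        pop_freqs[hit, config$island_pop] <-
          draw_population_freq(anc[hit], truth_islands$bn_param[r])
      }
    }
  }

  # pool counts and depths
  counts <- matrix(NA_integer_, n, nrow(pools))
  depths <- matrix(NA_integer_, n, nrow(pools))
  for (j in seq_len(nrow(pools))) {
    f <- pop_freqs[, pools$population[j]]
    if (pools$perturb_fst[j] > 0) {
      ok <- f > 0 & f < 1
      f[ok] <- draw_population_freq(f[ok], pools$perturb_fst[j])
    }
    counts[, j] <- sample_pool_counts(f, C)
    depths[, j] <- stats::rpois(n, pools$mean_depth[j])
  }

  # missing calls: depth 0 in one pool for a fraction of SNPs
  n_miss <- round(config$missing_frac * n)
  if (n_miss > 0) {
    rows <- sample.int(n, n_miss)
    cols <- sample.int(nrow(pools), n_miss, replace = TRUE)
    counts[cbind(rows, cols)] <- NA_integer_
    depths[cbind(rows, cols)] <- 0L
  }

  snps <- data.frame(
    lg = lg, pos = pos,
    ref = "A", alt = "T",
    stringsAsFactors = FALSE
  )
  pm <- pool_matrix(snps, counts,
                    pools[, c("pool_id", "ploidy", "superpool")], depths)
  truth_snps <- data.frame(
    snp_id = sprintf("%s_%d", lg, pos), lg = lg, pos = pos,
    ancestral_p = anc, island_id = island_id, stringsAsFactors = FALSE
  )
  structure(
    list(matrix = pm,
         truth = list(snps = truth_snps, pop_freqs = pop_freqs,
                      islands = truth_islands, bn_background = f_bg),
         config = config),
    class = "pool_sim"
  )
}

#' @export
print.pool_sim <- function(x, ...) {
  cat(sprintf(
    "pool_sim: %d SNPs on %d linkage group(s), %d pools, %d injected island(s), seed %d\n",
    n_snps(x$matrix), x$config$n_lg, n_pools(x$matrix),
    if (is.null(x$truth$islands)) 0L else nrow(x$truth$islands),
    x$config$seed
  ))
  invisible(x)
}

#' Write the ground-truth SNP table of a simulation
#'
#' TSV with columns `snp_id`, `lg`, `pos`, `ancestral_p`, `island_id`
#' (`.` outside islands).
#'
#' @param sim a [simulate_dataset()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(sim, path) {
  t <- sim$truth$snps
  t$island_id[is.na(t$island_id)] <- "."
  utils::write.table(t, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
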