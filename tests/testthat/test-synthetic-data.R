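test_that("Balding-Nichols draws have the model's mean and variance", {
  expect_identical(draw_population_freq(0.5, 0), 0.5)
  expect_identical(draw_population_freq(c(0.2, 0.9), 0), c(0.2, 0.9))

  set.seed(101)
  draws <- draw_population_freq(rep(0.5, 1e5), 0.1, n = 1e5)
  expect_true(all(draws >= 0 & draws <= 1))
  expect_lt(abs(mean(draws) - 0.5), 0.01)
  expect_lt(abs(var(draws) - 0.025) / 0.025, 0.10)  # F p (1 - p)

  expect_error(draw_population_freq(0.5, 1), "F must")
  expect_error(draw_population_freq(0, 0.1), "ancestral")
  expect_error(draw_population_freq(1, 0.1), "ancestral")
})

test_that("pool counts are binomial on the ploidy grid", {
  expect_identical(sample_pool_counts(1.0, 20), 20L)
  expect_identical(sample_pool_counts(0.0, 20), 0L)

  set.seed(102)
  draws <- sample_pool_counts(rep(0.5, 1e5), 20, n = 1e5)
  expect_true(all(draws >= 0 & draws <= 20))
  expect_lt(abs(mean(draws) - 10), 0.05)
})

test_that("simulated SNP counts follow the Poisson expectation", {
  cfg <- sim_config(n_lg = 1, lg_length = 1e6, snp_density = 1e-3,
                    pools = small_pools(), missing_frac = 0, seed = 5)
  sim <- simulate_dataset(cfg)
  expect_lt(abs(n_snps(sim$matrix) - 1000), 3 * sqrt(1000))
})

test_that("simulation is deterministic and structurally sound", {
  isl <- data.frame(lg = 1, start = 4e5, end = 6e5, fst = 0.15)
  cfg <- sim_config(n_lg = 2, lg_length = 1e6, pools = small_pools(),
                    islands = isl, missing_frac = 0.02, seed = 11)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$matrix$counts, b$matrix$counts)
  expect_identical(a$matrix$depths, b$matrix$depths)
  expect_identical(a$truth$pop_freqs, b$truth$pop_freqs)

  m <- a$matrix
  expect_true(all(m$counts >= 0 & m$counts <= 20, na.rm = TRUE))
  for (g in unique(m$snps$lg)) {
    p <- m$snps$pos[m$snps$lg == g]
    expect_true(all(diff(p) > 0))
    expect_true(all(p >= 1 & p <= 1e6))
  }
  # island flags agree with the configured interval
  t <- a$truth$snps
  flagged <- !is.na(t$island_id)
  in_interval <- t$lg == "LG01" & t$pos >= 4e5 & t$pos <= 6e5
  expect_identical(flagged, in_interval)
  # missing-data fraction materialized as single-pool depth-0 cells
  expect_equal(sum(apply(is.na(m$counts), 1, any)),
               round(0.02 * n_snps(m)))
})

test_that("config invariants are enforced", {
  expect_error(sim_config(pools = small_pools()), "seed")
  expect_error(
    sim_config(pools = small_pools(), seed = 1,
               islands = data.frame(lg = 1, start = 5e5, end = 3e6, fst = 0.2)),
    "within their linkage group")
  expect_error(
    sim_config(pools = small_pools(), seed = 1,
               islands = data.frame(lg = c(1, 1), start = c(1e5, 2e5),
                                    end = c(3e5, 4e5), fst = 0.2)),
    "overlap")
  expect_error(
    sim_config(pools = small_pools(), seed = 1, background_fst = 0.1,
               islands = data.frame(lg = 1, start = 1e5, end = 2e5, fst = 0.05)),
    "exceed background")
})

test_that("replicate pools at zero divergence differ only by sampling noise", {
  # two pools of the same population, no population divergence at all
  pools <- small_pools()[c(1, 4), ]
  pools$population <- pools$superpool <- c("P", "P")
  cfg <- sim_config(n_lg = 2, lg_length = 5e6, snp_density = 2e-3,
                    pools = pools, background_fst = 0, comparison = c("P", "P"),
                    island_pop = "P", missing_frac = 0, seed = 21)
  sim <- simulate_dataset(cfg)
  expect_gt(n_snps(sim$matrix), 1e4)
  f <- pool_freqs(sim$matrix)
  cc <- lin_ccc(f[, 1], f[, 2])
  expect_gt(cc$rho_c, 0.9)
})

test_that("measured background F_ST matches the calibration target", {
  cfg <- sim_config(n_lg = 2, lg_length = 5e6, snp_density = 2e-3,
                    pools = small_pools(), background_fst = 0.02,
                    missing_frac = 0, seed = 31)
  sim <- simulate_dataset(cfg)
  st <- per_snp_stats(sim$matrix, c("EBS", "AI"))
  expect_gt(n_snps(sim$matrix), 1e4)
  expect_lt(abs(mean(st$fst, na.rm = TRUE) - 0.02) / 0.02, 0.20)
})

test_that("island SNPs are more diverged than background SNPs", {
  isl <- data.frame(lg = 1, start = 2e5, end = 8e5, fst = 0.15)
  fst_means <- vapply(1:3, function(seed) {
    cfg <- sim_config(n_lg = 2, lg_length = 1e6, pools = small_pools(),
                      islands = isl, missing_frac = 0, seed = seed)
    sim <- simulate_dataset(cfg)
    st <- per_snp_stats(sim$matrix, c("EBS", "AI"))
    bg <- is.na(sim$truth$snps$island_id)
    c(mean(st$fst[!bg], na.rm = TRUE), mean(st$fst[bg], na.rm = TRUE))
  }, numeric(2))
  expect_true(all(fst_means[1, ] > fst_means[2, ]))
})

test_that("a YAML config round-trips through read_sim_config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "n_lg: 2", "lg_length: 1.0e6", "snp_density: 1.0e-4",
    "background_fst: 0.02", "missing_frac: 0", "seed: 3",
    "comparison: [EBS, AI]",
    "pools:",
    "  - {pool_id: X1, population: EBS, ploidy: 20, mean_depth: 60}",
    "  - {pool_id: X2, population: EBS, ploidy: 20, mean_depth: 60}",
    "  - {pool_id: Y1, population: AI, ploidy: 20, mean_depth: 60}",
    "  - {pool_id: Y2, population: AI, ploidy: 20, mean_depth: 60}",
    "islands:",
    "  - {lg: 1, start: 100000, end: 300000, fst: 0.2}"
  ), path)
  cfg <- read_sim_config(path)
  expect_s3_class(cfg, "sim_config")
  expect_identical(cfg$seed, 3L)
  expect_identical(nrow(cfg$pools), 4L)
  sim <- simulate_dataset(cfg)
  expect_s3_class(sim, "pool_sim")
})
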