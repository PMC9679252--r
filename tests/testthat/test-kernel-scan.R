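test_that("window centres tile linkage groups without spanning them", {
  sch <- window_scheme()  # step 20 kb, sigma 30 kb, span 180 kb
  expect_equal(sch$span, 180000)

  w <- make_windows(c(A = 220000), sch)
  expect_equal(w$center, c(90000, 110000, 130000))
  expect_equal(make_windows(c(A = 180000), sch)$center, 90000)
  expect_equal(nrow(make_windows(c(A = 100000), sch)), 0)

  w2 <- make_windows(c(A = 500000, B = 100000, C = 200000), sch)
  expect_false("B" %in% w2$lg)
  expect_true(all(diff(w2$center[w2$lg == "A"]) == sch$step))
})

test_that("the Gaussian kernel weight is truncated at three sigma", {
  expect_equal(kernel_weight(100, 100, 30), 1)
  expect_equal(kernel_weight(130, 100, 30), 0.606531, tolerance = 1e-6)
  expect_equal(kernel_weight(190, 100, 30), 0.011109, tolerance = 1e-4)
  expect_equal(kernel_weight(191, 100, 30), 0)
})

test_that("weighted window F_ST is the kernel-weighted mean of defined values", {
  expect_equal(weighted_window_fst(0.07, 50000, 90000, 30000), 0.07)
  # SNPs at c and c + sigma: (0.1 + 0.606531 * 0.2) / 1.606531
  expect_equal(
    weighted_window_fst(c(0.1, 0.2), c(90000, 120000), 90000, 30000),
    0.137754, tolerance = 1e-5)
  # constancy and NA exclusion
  expect_equal(
    weighted_window_fst(c(0.05, NA, 0.05), c(80000, 90000, 100000),
                        90000, 30000), 0.05)
  expect_true(is.na(weighted_window_fst(NA_real_, 90000, 90000, 30000)))
  # degeneracy: all SNPs at the centre -> arithmetic mean
  v <- c(0.01, 0.2, 0.07)
  expect_equal(weighted_window_fst(v, rep(90000, 3), 90000, 30000), mean(v))
})

test_that("per-bp d_XY uses the all-positions kernel mass", {
  expect_equal(kernel_bp_mass(1), 2.505950, tolerance = 1e-6)
  expect_equal(weighted_window_dxy(0.5, 3, 3, 1), 0.199525, tolerance = 1e-6)
  expect_equal(weighted_window_dxy(numeric(0), numeric(0), 90000, 30000), 0)
  d <- c(0.2, 0.5); p <- c(80000, 95000)
  expect_equal(weighted_window_dxy(2 * d, p, 90000, 30000),
               2 * weighted_window_dxy(d, p, 90000, 30000))
})

test_that("window pi sums site heterozygosities over the window length", {
  expect_equal(window_pi(numeric(0), numeric(0), 90000, 30000, C = 20)$pi, 0)
  # one SNP, j = 10, C = 20, n = 7
  pw <- window_pi(0.5, 3, 3, sigma = 1, C = 20, n = 7)
  expect_equal(pw$pi, 0.075188, tolerance = 1e-6)
  expect_equal(pw$pi_sum, 200 / 380)
  # one SNP, j = 1, C = 20, n = 1
  expect_equal(window_pi(0.05, 3, 3, sigma = 1, C = 20, n = 1)$pi, 0.1)
  # sites outside +-3 sigma do not contribute
  expect_equal(window_pi(c(0.5, 0.5), c(3, 100), 3, sigma = 1, C = 20, n = 1)$pi_sum,
               200 / 380)
})

test_that("Watterson's theta uses the harmonic-number normalizer", {
  expect_equal(window_theta_w(0, 20), 0)
  expect_equal(window_theta_w(1, 20), 0.281870, tolerance = 1e-5)  # 1 / H_19
  expect_equal(window_theta_w(10, 2), 10)
  expect_equal(window_theta_w(1, 20, theta_sum_upper = "C"),
               1 / sum(1 / 1:20))
})

test_that("Tajima's D matches an independent implementation of the 1989 constants", {
  # independent oracle: build constants step by step
  C <- 20
  a1 <- sum(1 / 1:19); a2 <- sum(1 / (1:19)^2)
  b1 <- 21 / 57; b2 <- 2 * (400 + 20 + 3) / (9 * 20 * 19)
  c1 <- b1 - 1 / a1
  c2 <- b2 - 22 / (a1 * 20) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  S <- 16; pi_sum <- 3.0
  oracle <- (pi_sum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  expect_equal(oracle, -1.244363, tolerance = 1e-5)
  expect_equal(window_tajimas_d(3.0, 16, 20), oracle, tolerance = 1e-12)

  expect_equal(window_tajimas_d(window_theta_w(7, 20), 7, 20), 0)
  expect_true(is.na(window_tajimas_d(0, 0, 20)))
  # sign(D) = sign(pi_sum - theta_W)
  set.seed(60)
  for (i in 1:20) {
    S <- sample(1:50, 1)
    ps <- runif(1, 0, 20)
    expect_equal(sign(window_tajimas_d(ps, S, 20)),
                 sign(ps - window_theta_w(S, 20)))
  }
})

test_that("scan_windows agrees with brute-force direct summation", {
  set.seed(61)
  pools <- small_pools()
  cfg <- sim_config(n_lg = 2, lg_length = 4e5, snp_density = 1e-4,
                    pools = pools, missing_frac = 0, seed = 62)
  sim <- simulate_dataset(cfg)
  pm <- sim$matrix
  sch <- window_scheme()
  lgl <- c(LG01 = 4e5, LG02 = 4e5)
  w <- scan_windows(pm, c("EBS", "AI"), sch, lg_lengths = lgl)
  expect_true(all(w$n_snps <= 60))  # sparse: small windows

  sp <- superpool_freqs(pm, c("EBS", "AI"))
  C_sp <- attr(sp, "ploidy")
  fst <- fst_nei(sp)
  dv <- dxy(sp[, 1], sp[, 2])
  Wmass <- sum(exp(-(-90000:90000)^2 / (2 * 30000^2)))

  for (i in seq_len(nrow(w))) {
    idx <- which(pm$snps$lg == w$lg[i] & abs(pm$snps$pos - w$center[i]) <= 90000)
    wt <- exp(-(pm$snps$pos[idx] - w$center[i])^2 / (2 * 30000^2))
    def <- !is.na(fst[idx])
    expect_identical(w$n_snps[i], length(idx))
    expect_identical(w$n_fst[i], sum(def))
    if (any(def)) {
      expect_equal(w$wfst[i],
                   sum(wt[def] * fst[idx][def]) / sum(wt[def]),
                   tolerance = 1e-12)
    } else {
      expect_true(is.na(w$wfst[i]))
    }
    expect_equal(w$wdxy[i], sum(wt * dv[idx]) / Wmass, tolerance = 1e-12)
    for (sp_lab in c("EBS", "AI")) {
      j <- round(sp[idx, sp_lab] * C_sp[[sp_lab]])
      ps <- sum(2 * j * (C_sp[[sp_lab]] - j) /
                  (C_sp[[sp_lab]] * (C_sp[[sp_lab]] - 1)))
      expect_equal(w[[paste0("pi_", sp_lab)]][i], ps / 180000,
                   tolerance = 1e-12)
      a1 <- sum(1 / seq_len(C_sp[[sp_lab]] - 1))
      expect_equal(w[[paste0("theta_w_", sp_lab)]][i], length(idx) / a1,
                   tolerance = 1e-12)
    }
  }
})

test_that("weighted averages are bounded by their inputs and fixed on constants", {
  set.seed(63)
  for (rep in 1:25) {
    n <- sample(1:20, 1)
    pos <- sort(sample(1:180000, n))
    vals <- runif(n)
    wf <- weighted_window_fst(vals, pos, 90000, 30000)
    expect_gte(wf, min(vals) - 1e-12)
    expect_lte(wf, max(vals) + 1e-12)
    expect_equal(weighted_window_fst(rep(0.3, n), pos, 90000, 30000), 0.3)
  }
})
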