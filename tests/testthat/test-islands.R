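test_that("outlier masks and quantile thresholds are as defined", {
  expect_identical(find_outlier_windows(c(0.01, 0.2)), c(TRUE, FALSE))
  expect_identical(find_outlier_windows(rep(1, 3)), rep(FALSE, 3))
  expect_identical(find_outlier_windows(c(0.5, NA), alpha = 1), c(TRUE, FALSE))

  expect_equal(fst_threshold_from_quantile(rep(0.04, 10)), 0.04)
  expect_equal(fst_threshold_from_quantile((1:100) * 0.001, q = 0.90), 0.0901)
  expect_equal(fst_threshold_from_quantile(c(0.1, 0.9, 0.3), q = 1), 0.9)
})

test_that("islands are maximal runs of consecutive above-threshold windows", {
  mkw <- function(fst, lg = "LG01", start_center = 90000) {
    data.frame(lg = lg, center = start_center + (seq_along(fst) - 1) * 20000,
               wfst = fst, wdxy = 1e-4, stringsAsFactors = FALSE)
  }
  isl <- find_islands(mkw(c(0.01, 0.031, 0.04, 0.05, 0.035, 0.02)),
                      threshold = 0.03, min_run = 4, step = 20000)
  expect_identical(nrow(isl), 1L)
  expect_equal(isl$first_center, 110000)
  expect_equal(isl$last_center, 170000)
  expect_equal(isl$n_windows, 4L)
  expect_equal(isl$end - isl$start, 4 * 20000)
  expect_equal(isl$mean_wfst, mean(c(0.031, 0.04, 0.05, 0.035)))

  expect_identical(nrow(find_islands(mkw(c(0.04, 0.04, 0.04)),
                                     min_run = 4, step = 20000)), 0L)
  expect_identical(nrow(find_islands(mkw(rep(0.02, 10)), step = 20000)), 0L)

  # a centre-spacing gap breaks a run
  w <- mkw(rep(0.05, 8))
  w$center[5:8] <- w$center[5:8] + 60000
  isl <- find_islands(w, min_run = 4, step = 20000)
  expect_identical(isl$n_windows, c(4L, 4L))
  expect_identical(isl$island_id, c("LG01_1", "LG01_2"))

  # runs never cross linkage groups
  w2 <- rbind(mkw(rep(0.05, 3), lg = "LG01"), mkw(rep(0.05, 3), lg = "LG02"))
  expect_identical(nrow(find_islands(w2, min_run = 4, step = 20000)), 0L)
})

test_that("called islands are disjoint, sorted and maximal", {
  set.seed(80)
  for (rep in 1:20) {
    fst <- runif(60, 0, 0.06)
    w <- data.frame(lg = "LG01", center = 90000 + (0:59) * 20000,
                    wfst = fst, stringsAsFactors = FALSE)
    isl <- find_islands(w, threshold = 0.03, min_run = 4, step = 20000)
    if (nrow(isl) < 1) next
    expect_true(all(diff(isl$start) > 0))
    if (nrow(isl) > 1) expect_true(all(isl$start[-1] > isl$end[-nrow(isl)]))
    for (k in seq_len(nrow(isl))) {
      members <- w$center >= isl$first_center[k] & w$center <= isl$last_center[k]
      expect_true(all(w$wfst[members] > 0.03))
      # maximality: the neighbours just outside fail the threshold
      lo <- which(w$center == isl$first_center[k]) - 1
      hi <- which(w$center == isl$last_center[k]) + 1
      if (lo >= 1) expect_lte(w$wfst[lo], 0.03)
      if (hi <= nrow(w)) expect_lte(w$wfst[hi], 0.03)
    }
  }
})

test_that("island summaries count windows against genome-wide quantiles", {
  n <- 100
  w <- data.frame(
    lg = "LG01", center = 90000 + (0:(n - 1)) * 20000,
    wfst = rep(0.01, n), wdxy = seq(1e-4, 1e-3, length.out = n),
    pi_EBS = seq(1e-4, 1e-3, length.out = n),
    tajd_EBS = seq(-2, 2, length.out = n),
    stringsAsFactors = FALSE
  )
  attr(w, "pair") <- "EBS"
  w$wfst[10:12] <- 0.05
  w$wdxy[10] <- max(w$wdxy) + 1e-6         # above any q95 and the mean
  w$wdxy[11] <- mean(w$wdxy) + 5e-5        # above the mean, below q95
  w$wdxy[12] <- min(w$wdxy)
  q95 <- unname(quantile(w$wdxy, 0.95))    # final, genome-wide quantities
  mu <- mean(w$wdxy)
  isl <- find_islands(w, min_run = 3, step = 20000)
  expect_identical(nrow(isl), 1L)
  out <- island_summary(isl, w)
  expect_identical(out$n_dxy_gt_q95, sum(w$wdxy[10:12] > q95))
  expect_identical(out$n_dxy_gt_mean, sum(w$wdxy[10:12] > mu))
  expect_identical(out$n_dxy_gt_q95, 1L)
  expect_identical(out$n_dxy_gt_mean, 2L)
  expect_equal(out$mean_tajd_EBS, mean(w$tajd_EBS[10:12]))
  expect_equal(out$mean_pi_EBS, mean(w$pi_EBS[10:12]))
  expect_identical(out$n_tajd_lt_q05_EBS, 0L)
  # an island sitting at the low tail of pi is counted below the 5% quantile
  w$wfst[1:3] <- 0.05
  isl2 <- find_islands(w, min_run = 3, step = 20000)
  out2 <- island_summary(isl2, w)
  expect_gte(out2$n_pi_lt_q05_EBS[1], 1L)
})

test_that("outlier CV per linkage group uses the sample standard deviation", {
  lg <- rep(c("a", "b", "c"), each = 4)
  mask <- rep(c(TRUE, TRUE, FALSE, FALSE), 3)
  expect_equal(outlier_cv_per_lg(mask, lg), 0)

  lg <- rep(c("a", "b"), each = 4)
  mask <- c(rep(FALSE, 4), rep(TRUE, 4))
  expect_equal(outlier_cv_per_lg(mask, lg), 1.414214, tolerance = 1e-6)

  lg <- rep(c("a", "b", "c"), each = 4)
  mask <- c(TRUE, rep(FALSE, 3), TRUE, rep(FALSE, 3), rep(TRUE, 4))
  expect_equal(outlier_cv_per_lg(mask, lg), 0.866025, tolerance = 1e-6)

  expect_true(is.na(outlier_cv_per_lg(rep(FALSE, 4), rep(c("a", "b"), 2))))
  expect_error(outlier_cv_per_lg(TRUE, "a"), ">= 2")
})

test_that("island matching applies reciprocal overlap", {
  truth <- data.frame(lg = "LG01", start = 1e5, end = 3e5)
  called <- data.frame(lg = "LG01", start = 0.9e5, end = 3.2e5,
                       island_id = "LG01_1")
  m <- match_islands(called, truth)
  expect_identical(m$n_recovered, 1L)
  expect_identical(m$n_false, 0L)
  # called interval too wide for 50% reciprocal overlap
  wide <- data.frame(lg = "LG01", start = 0, end = 9e5, island_id = "x")
  m2 <- match_islands(wide, truth)
  expect_identical(m2$n_recovered, 0L)
  expect_identical(m2$n_false, 0L)  # still touches the truth interval
  # disjoint call counts as false
  off <- data.frame(lg = "LG01", start = 5e5, end = 6e5, island_id = "y")
  expect_identical(match_islands(off, truth)$n_false, 1L)
})
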