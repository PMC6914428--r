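test_that("mean framewise displacement matches hand-computed values", {
  expect_equal(mean_framewise_displacement(matrix(0, 10, 6)), 0)
  # one +0.1 mm translation step, T = 2 -> (0 + 0.1) / 2
  m <- matrix(0, 2, 6); m[2, 1] <- 0.1
  expect_equal(mean_framewise_displacement(m), 0.05)
  # one 0.002 rad rotation step, T = 2 -> 50 * 0.002 / 2
  m <- matrix(0, 2, 6); m[2, 5] <- 0.002
  expect_equal(mean_framewise_displacement(m), 0.05)
  expect_error(mean_framewise_displacement(matrix(0, 5, 5)), "6 columns")
})

test_that("subject screening removes high-motion subjects", {
  mk <- function(id, fd) subject_record(id, matrix(rnorm(30), 10, 3),
                                        age = 30, sex = 0, mean_fd = fd)
  cohort <- list(mk("a", 0.05), mk("b", 0.25))
  scr <- screen_subjects(cohort)
  expect_length(scr$retained, 1)
  expect_equal(scr$excluded$subject_id, "b")
  expect_length(screen_subjects(cohort, fd_max = Inf)$retained, 2)
  expect_error(screen_subjects(cohort, fd_max = 0.01), "no subjects")
})

test_that("a planted 494-subject cohort retains 434 at FD > 0.2", {
  set.seed(42)
  fd <- c(runif(434, 0.02, 0.2), runif(60, 0.201, 0.6))
  cohort <- lapply(seq_along(fd), function(i)
    subject_record(paste0("s", i), matrix(rnorm(12), 4, 3), 30, 0, fd[i]))
  scr <- screen_subjects(cohort, fd_max = 0.2)
  expect_length(scr$retained, 434)
  expect_equal(nrow(scr$excluded), 60)
})

test_that("SNR screening flags whole pairs outside mu +/- k*sd", {
  rt <- toy_regions(c(A = 25, B = 25))  # 50 pairs, 100 regions
  set.seed(7)
  # all regions: mean 100, sd 10 -> snr ~ 10, with one planted outlier
  mk <- function() {
    ts <- matrix(rnorm(50 * 100, mean = 100, sd = 10), 50, 100)
    ts[, 3] <- rnorm(50, mean = 1000, sd = 10)  # region 3 at huge SNR
    ts
  }
  cohort <- lapply(1:4, function(i)
    subject_record(paste0("s", i), mk(), 30, 0, 0.1))
  scr <- screen_regions_by_snr(cohort, rt)
  excl <- scr$regions[!scr$regions$included, ]
  expect_equal(nrow(excl), 2)  # the whole homotopic pair
  expect_setequal(excl$pair_index, rt$pair_index[3])
  expect_equal(attr(scr$report, "excluded_pairs"), rt$pair_index[3])
})

test_that("SNR screening degenerate cases", {
  rt <- toy_regions(c(A = 2))
  # identical SNR everywhere -> sigma = 0 -> nothing excluded
  set.seed(1)
  base <- rnorm(40)
  ts <- matrix(rep(base, 4), 40, 4)
  cohort <- list(subject_record("s", ts, 30, 0, 0.1))
  scr <- screen_regions_by_snr(cohort, rt)
  expect_true(all(scr$regions$included))
  # zero-variance region is force-excluded with a warning
  ts2 <- matrix(rnorm(160), 40, 4); ts2[, 2] <- 5
  expect_warning(scr2 <- screen_regions_by_snr(
    list(subject_record("s", ts2, 30, 0, 0.1)), rt), "zero variance")
  expect_false(all(scr2$regions$included))
})

test_that("SNR screening is permutation-invariant over subjects and regions", {
  rt <- toy_regions(c(A = 3, B = 3))
  set.seed(11)
  cohort <- lapply(1:5, function(i)
    subject_record(paste0("s", i),
                   matrix(rnorm(30 * 12, 50, 5), 30, 12), 30, 0, 0.1))
  ref <- screen_regions_by_snr(cohort, rt, k_sd = 1)
  # permute subjects
  alt <- screen_regions_by_snr(cohort[c(3, 1, 5, 2, 4)], rt, k_sd = 1)
  expect_equal(alt$regions$included, ref$regions$included)
  # permute regions (joint column/table permutation)
  perm <- sample(12)
  rtp <- rt[perm, ]
  cohortp <- lapply(cohort, function(s)
    subject_record(s$subject_id, s$timeseries[, perm], s$age, s$sex,
                   s$mean_fd))
  altp <- screen_regions_by_snr(cohortp, rtp, k_sd = 1)
  expect_equal(altp$regions$included, ref$regions$included[perm])
})

test_that("fisher z is odd, monotone, and matches atanh", {
  expect_equal(fisher_z(0.2), atanh(0.2))
  expect_equal(fisher_z(0.2), 0.202732554054, tolerance = 1e-10)
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_true(all(diff(fisher_z(r)) > 0))
  expect_true(is.finite(fisher_z(1)))  # clipped, large finite
  expect_gt(fisher_z(1), 13)
})

test_that("connectivity_matrix computes Fisher-z correlations", {
  rt <- toy_regions(c(A = 2))
  set.seed(5)
  base <- rnorm(100)
  ts <- cbind(base, base, rnorm(100), rnorm(100))
  z <- connectivity_matrix(ts, rt)
  expect_equal(unname(diag(z)), rep(0, 4))
  expect_equal(z, t(z))
  expect_gt(z[1, 2], 13)  # r = 1 clipped -> atanh(1 - 1e-12)
  # independent columns at large T stay near zero
  set.seed(6)
  ts2 <- matrix(rnorm(10000 * 4), ncol = 4)
  z2 <- connectivity_matrix(ts2, rt)
  expect_lt(max(abs(z2[upper.tri(z2)])), 0.05)  # ~3/sqrt(T)
  # constant column errors with the region named
  ts3 <- ts; ts3[, 3] <- 1
  expect_error(connectivity_matrix(ts3, rt), "constant time series")
})

test_that("absolute thresholding keeps strictly-greater entries", {
  z <- matrix(0, 3, 3)
  z[1, 2] <- z[2, 1] <- -0.5
  z[1, 3] <- z[3, 1] <- 0.2
  z[2, 3] <- z[3, 2] <- 0.21
  zt <- threshold_absolute(z, 0.2)
  expect_equal(zt[1, 2], 0)    # negative removed
  expect_equal(zt[1, 3], 0)    # boundary removed (strict >)
  expect_equal(zt[2, 3], 0.21)
  expect_equal(threshold_absolute(matrix(0.1, 4, 4), 0.2),
               matrix(0, 4, 4), ignore_attr = TRUE)
  # theta = 0 removes negatives, keeps all positives
  z0 <- rand_sym(6)
  zt0 <- threshold_absolute(z0, 0)
  expect_true(all(zt0[z0 > 0 & row(z0) != col(z0)] > 0))
  expect_true(all(zt0[z0 < 0] == 0))
  expect_error(threshold_absolute(z, -0.1), "configuration")
})

test_that("proportional thresholding keeps the strongest edges", {
  # 4 nodes, distinct weights; density for 2 of 6 edges
  z <- matrix(0, 4, 4)
  w <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  z[upper.tri(z)] <- w
  z <- z + t(z)
  zt <- threshold_proportional(z, 2 / 6)
  kept <- sort(zt[upper.tri(zt)][zt[upper.tri(zt)] > 0])
  expect_equal(kept, c(0.5, 0.6))  # sort oracle: two largest
  # ties at the cutoff are all retained
  z2 <- matrix(0, 4, 4)
  z2[upper.tri(z2)] <- c(0.1, 0.5, 0.5, 0.5, 0.6, 0.2)
  z2 <- z2 + t(z2)
  zt2 <- threshold_proportional(z2, 2 / 6)
  expect_equal(sum(zt2[upper.tri(zt2)] > 0), 4)  # 0.6 + three tied 0.5
  # density 1 on an all-positive matrix = remove nothing
  z3 <- abs(rand_sym(5)) + 0.01; diag(z3) <- 0
  expect_equal(threshold_proportional(z3, 1), z3, ignore_attr = TRUE)
  expect_error(threshold_proportional(z, 0), "configuration")
  expect_error(threshold_proportional(z, 1.2), "configuration")
})

test_that("thresholded matrices are non-negative, symmetric, zero-diagonal; density within 1 edge", {
  set.seed(9)
  for (rep in 1:10) {
    z <- rand_sym(12)
    for (zt in list(threshold_absolute(z, 0.2),
                    threshold_proportional(z, runif(1, 0.05, 0.9)))) {
      expect_true(all(zt >= 0))
      expect_equal(zt, t(zt), ignore_attr = TRUE)
      expect_equal(diag(zt), rep(0, 12))
    }
    d <- runif(1, 0.1, 0.6)
    zt <- threshold_proportional(z, d)
    e <- sum(upper.tri(z))
    target <- ceiling(d * e)
    got <- sum(zt[upper.tri(zt)] > 0)
    n_pos <- sum(z[upper.tri(z)] > 0)
    expect_true(got >= min(target, n_pos) - 1 && got <= min(target, n_pos) + 1)
  }
})
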