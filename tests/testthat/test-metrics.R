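# 3 pairs: network A = pairs 0-1, network B = pair 2
toy_world <- function(seed = 1, networks = c(A = 2, B = 1)) {
  rt <- toy_regions(networks)
  set.seed(seed)
  z <- rand_sym(nrow(rt))
  labs <- rep(rep(seq_along(networks), networks), 2)
  list(rt = rt, z = z, p = partition(labs, symmetric = TRUE),
       labs = labs, hemis = rt$hemisphere)
}

test_that("within-hemisphere sum matches the hand-derived toy value", {
  # 2-node network + 1 outside node, all z = 0.5, one hemisphere
  w <- toy_world()
  z <- matrix(0.5, 6, 6); diag(z) <- 0
  sll <- within_hemisphere_sum(z, w$p, w$rt, network = 1, hemi = "L")
  expect_equal(sll, 1.5)  # 0.5 within pair + 2 x 0.5 to the outside node
  # double-count convention counts the within pair twice
  expect_equal(within_hemisphere_sum(z, w$p, w$rt, 1, "L",
                                     double_count_within = TRUE), 2.0)
  # isolated network
  z2 <- matrix(0, 6, 6)
  expect_equal(within_hemisphere_sum(z2, w$p, w$rt, 1, "L"), 0)
  # linearity
  expect_equal(within_hemisphere_sum(2 * z, w$p, w$rt, 1, "L"), 3.0)
  expect_error(within_hemisphere_sum(z, w$p, w$rt, 99, "L"), "empty")
})

test_that("homotopic sum sums the LR block of the same network", {
  rt <- toy_regions(c(A = 1, B = 1))
  z <- matrix(0, 4, 4)
  z[1, 3] <- z[3, 1] <- 0.8  # A_L <-> A_R
  p <- partition(c(1, 2, 1, 2), symmetric = TRUE)
  expect_equal(homotopic_sum(z, p, rt, 1, "L"), 0.8)
  expect_equal(homotopic_sum(z, p, rt, 2, "L"), 0)
  # mirror-symmetric z gives equal L and R values
  set.seed(2)
  w <- toy_world(2)
  zs <- w$z
  n <- 3
  perm <- c(n + 1:n, 1:n)
  zs <- (zs + zs[perm, perm]) / 2  # symmetrize across hemispheres
  expect_equal(homotopic_sum(zs, w$p, w$rt, 1, "L"),
               homotopic_sum(zs, w$p, w$rt, 1, "R"))
})

test_that("segregation ratio follows its closed form", {
  expect_equal(hemispheric_segregation(2, 0.5), 0.75)
  expect_equal(hemispheric_segregation(3, 0), 1)
  expect_equal(hemispheric_segregation(1.7, 1.7), 0)
  expect_warning(out <- hemispheric_segregation(0, 0.5), "undefined")
  expect_true(is.na(out))
})

test_that("brute-force oracles agree on random toy matrices (1e-12)", {
  for (seed in 1:5) {
    w <- toy_world(seed, networks = c(A = 2, B = 2, C = 2))
    for (network in 1:3) {
      for (hemi in c("L", "R")) {
        expect_equal(
          within_hemisphere_sum(w$z, w$p, w$rt, network, hemi),
          bf_within_sum(w$z, rep(w$labs, 1), w$hemis, network, hemi),
          tolerance = 1e-12)
        expect_equal(
          homotopic_sum(w$z, w$p, w$rt, network, hemi),
          bf_homotopic_sum(w$z, w$labs, w$hemis, network, hemi),
          tolerance = 1e-12)
        expect_equal(
          whole_contralateral_sum(w$z, w$p, w$rt, network, hemi),
          bf_whole_contra_sum(w$z, w$labs, w$hemis, network, hemi),
          tolerance = 1e-12)
      }
    }
  }
})

test_that("participation coefficients match closed forms and the loop oracle", {
  rt <- toy_regions(c(A = 2, B = 2))
  # node 1: all weight inside own community -> P = 0
  z <- matrix(0, 8, 8)
  z[1, 2] <- z[2, 1] <- 1
  z[3, 4] <- z[4, 3] <- 1
  p <- partition(rep(rep(1:2, c(2, 2)), 2), symmetric = TRUE)
  pc <- participation_coefficients(z, p, rt, "L")
  expect_equal(unname(pc), rep(0, 4))
  # equal split across 2 communities -> 0.5
  z2 <- matrix(0, 8, 8)
  z2[1, 2] <- z2[2, 1] <- 1   # own community
  z2[1, 3] <- z2[3, 1] <- 1   # other community
  pc2 <- participation_coefficients(z2, p, rt, "L")
  expect_equal(unname(pc2[1]), 0.5)
  # equal split across S communities -> 1 - 1/S
  rtS <- toy_regions(c(A = 1, B = 1, C = 1, D = 1))
  zS <- matrix(0, 8, 8)
  zS[1, 2:4] <- 1; zS[2:4, 1] <- 1
  pS <- partition(rep(1:4, 2), symmetric = TRUE)
  pcS <- participation_coefficients(zS, pS, rtS, "L")
  expect_equal(unname(pcS[1]), 1 - 1 / 3)  # weight in 3 other communities
  # random 20-node matrices vs the per-node loop oracle
  rt20 <- toy_regions(c(A = 5, B = 5, C = 5, D = 5))
  for (seed in 1:5) {
    set.seed(seed)
    z20 <- abs(rand_sym(40))
    p20 <- partition(rep(rep(1:4, each = 5), 2), symmetric = TRUE)
    got <- participation_coefficients(z20, p20, rt20, "L")
    want <- bf_participation(z20[1:20, 1:20], rep(1:4, each = 5))
    expect_equal(unname(got), want, tolerance = 1e-12)
  }
})

test_that("intra-hemispheric integration averages node participation", {
  rt <- toy_regions(c(A = 2, B = 1))
  p <- partition(c(1, 1, 2, 1, 1, 2), symmetric = TRUE)
  pc <- c(`0` = 0.2, `1` = 0.4, `2` = 0.9)
  expect_equal(intra_hemispheric_integration(pc, p, rt, 1, "L"), 0.3)
  expect_error(intra_hemispheric_integration(pc, p, rt, 9, "L"), "empty")
})

test_that("metrics table has one row per network x hemisphere", {
  nets <- stats::setNames(rep(2, 11), paste0("N", 1:11))
  rt <- toy_regions(nets)
  set.seed(3)
  z <- rand_sym(44)
  zt <- threshold_absolute(z, 0.2)
  p <- partition(rep(rep(1:11, each = 2), 2), symmetric = TRUE)
  mt <- metrics_table(z, zt, p, rt)
  expect_equal(nrow(mt), 22)
  expect_equal(mt$inter_integration, mt$sum_z_homotopic)
  expect_true(all(mt$intra_integration >= 0 & mt$intra_integration < 1))
})

test_that("metrics are invariant under joint node permutation", {
  w <- toy_world(4, networks = c(A = 2, B = 2))
  zt <- threshold_absolute(w$z, 0.1)
  ref <- metrics_table(w$z, zt, w$p, w$rt)
  set.seed(5)
  perm <- sample(nrow(w$rt))
  rtp <- w$rt[perm, ]
  pp <- partition(w$labs[perm], symmetric = TRUE)
  got <- metrics_table(w$z[perm, perm], zt[perm, perm], pp, rtp)
  expect_equal(got, ref)
})

test_that("segregation is scale-invariant; LR shrink raises segregation", {
  w <- toy_world(6, networks = c(A = 3, B = 3))
  z <- abs(w$z)
  for (network in 1:2) {
    sll <- within_hemisphere_sum(z, w$p, w$rt, network, "L")
    slr <- homotopic_sum(z, w$p, w$rt, network, "L")
    seg <- hemispheric_segregation(sll, slr)
    sll2 <- within_hemisphere_sum(3 * z, w$p, w$rt, network, "L")
    slr2 <- homotopic_sum(3 * z, w$p, w$rt, network, "L")
    expect_equal(sll2, 3 * sll)
    expect_equal(hemispheric_segregation(sll2, slr2), seg)
    # damp the LR block only
    n <- nrow(z)
    zl <- z
    li <- w$rt$hemisphere == "L"
    zl[li, !li] <- zl[li, !li] * 0.5
    zl[!li, li] <- zl[!li, li] * 0.5
    slr3 <- homotopic_sum(zl, w$p, w$rt, network, "L")
    expect_lte(slr3, slr)
    expect_gte(hemispheric_segregation(
      within_hemisphere_sum(zl, w$p, w$rt, network, "L"), slr3), seg)
  }
})

test_that("mirror-symmetric matrices give identical L and R metrics", {
  w <- toy_world(7, networks = c(A = 2, B = 2))
  n <- 4
  perm <- c(n + 1:n, 1:n)
  zs <- (abs(w$z) + abs(w$z)[perm, perm]) / 2
  zt <- threshold_absolute(zs, 0.1)
  mt <- metrics_table(zs, zt, w$p, w$rt)
  for (net in unique(mt$network)) {
    lrow <- mt[mt$network == net & mt$hemisphere == "L", ]
    rrow <- mt[mt$network == net & mt$hemisphere == "R", ]
    for (col in c("sum_z_within", "sum_z_homotopic", "segregation",
                  "intra_integration", "whole_contra_integration"))
      expect_equal(lrow[[col]], rrow[[col]], tolerance = 1e-12)
  }
})
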