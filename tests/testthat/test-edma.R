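test_that("form matrix gives the expected distances and pair counts", {
  # unit segment
  m <- rbind(a = c(0, 0, 0), b = c(1, 0, 0))
  fm <- form_matrix(m)
  expect_equal(fm$distances, 1)
  expect_identical(fm$pairs$a, "a")

  # C(K, 2) combinatorics for the analysis sets
  expect_length(form_matrix(random_dataset(1, 7, seed = 1))$distances, 21)
  expect_length(form_matrix(random_dataset(1, 24, seed = 2))$distances,
                276)

  # brute-force pairwise oracle on a random configuration
  ds <- random_dataset(1, 10, seed = 3)
  fm <- form_matrix(ds)
  x <- ds$coords[1, , ]
  for (i in seq_len(nrow(fm$pairs))) {
    a <- match(fm$pairs$a[i], ds$labels)
    b <- match(fm$pairs$b[i], ds$labels)
    expect_equal(fm$distances[i], sqrt(sum((x[a, ] - x[b, ])^2)))
  }

  # coincident landmarks are a hard error
  bad <- rbind(a = c(0, 0, 0), b = c(0, 0, 0), c = c(1, 1, 1))
  expect_error(form_matrix(bad), "coincident.*a-b")
})

test_that("mean form estimators: single specimen, zero variance, and a
           hand-computed three-specimen case", {
  ds1 <- random_dataset(1, 5, seed = 4)
  fm <- form_matrix(ds1)
  expect_equal(mean_form(ds1, "arithmetic")$mean_distances, fm$distances)
  expect_equal(mean_form(ds1, "moment")$mean_distances, fm$distances,
               tolerance = 1e-6)

  # identical specimens: moment correction vanishes
  coords <- array(NA_real_, dim = c(3, 5, 3))
  for (i in 1:3) coords[i, , ] <- ds1$coords[1, , ]
  dsz <- landmark_dataset(coords, ds1$labels,
                          specimen_id = sprintf("s%d", 1:3))
  expect_equal(mean_form(dsz, "moment")$mean_distances, fm$distances,
               tolerance = 1e-6)

  # collinear 2-landmark specimens with distances exactly {2, 3, 4}
  coords <- array(0, dim = c(3, 2, 3))
  coords[1, 2, 1] <- 2
  coords[2, 2, 1] <- 3
  coords[3, 2, 1] <- 4
  ds3 <- landmark_dataset(coords, c("a", "b"),
                          specimen_id = sprintf("s%d", 1:3))
  expect_equal(mean_form(ds3, "arithmetic")$mean_distances, 3)
  # moment: sqrt(mean(d^2) - var(d)) = sqrt(29/3 - 1), frozen by hand
  expect_equal(mean_form(ds3, "moment")$mean_distances,
               sqrt(29 / 3 - 1))
})

test_that("form-difference ratios: identity, global scaling, and exact
           noiseless subset scaling", {
  ds <- random_dataset(4, 6, seed = 5, genotype = "affected")
  fd <- form_difference_matrix(ds, ds)
  expect_equal(fd$ratio, rep(1, 15))

  fd130 <- form_difference_matrix(scale_dataset(ds, 1.30), ds)
  expect_equal(fd130$ratio, rep(1.30, 15))

  # noiseless generator with a 1.20 scaling on a 4-landmark subset:
  # exactly the C(4,2) = 6 within-subset ratios equal 1.20
  sp <- small_spec(n = 5, seed = 8, noise_sd = 0,
                   group_scaling = list(labels = c("laottr", "raottr",
                                                   "lttr", "rttr"),
                                        factor = 1.20))
  sim <- simulate_two_genotypes(sp)
  fd <- form_difference_matrix(sim$affected, sim$unaffected)
  in_subset <- fd$pairs$a %in% c("laottr", "raottr", "lttr", "rttr") &
    fd$pairs$b %in% c("laottr", "raottr", "lttr", "rttr")
  expect_equal(sum(in_subset), 6)
  expect_equal(fd$ratio[in_subset], rep(1.20, 6))
  untouched <- !(fd$pairs$a %in% c("laottr", "raottr", "lttr", "rttr")) &
    !(fd$pairs$b %in% c("laottr", "raottr", "lttr", "rttr"))
  expect_equal(fd$ratio[untouched], rep(1, sum(untouched)))
})

test_that("rigid motions leave form matrices, FDMs, CIs and T unchanged", {
  num <- random_dataset(4, 6, seed = 6, genotype = "affected")
  den <- random_dataset(4, 6, seed = 7)
  rot <- rotation_matrix()
  num_r <- transform_dataset(num, rot, shift = c(5, -2, 1))
  den_r <- transform_dataset(den, rot, shift = c(-1, 4, 2))
  expect_equal(form_matrix(subset_configurations(num, 1))$distances,
               form_matrix(subset_configurations(num_r, 1))$distances,
               tolerance = 1e-12)
  ci <- bootstrap_fdm_ci(num, den, n_boot = 100, seed = 31)
  ci_r <- bootstrap_fdm_ci(num_r, den_r, n_boot = 100, seed = 31)
  expect_equal(ci$ratio, ci_r$ratio, tolerance = 1e-12)
  expect_equal(ci$ci_lo, ci_r$ci_lo, tolerance = 1e-12)
  expect_equal(ci$ci_hi, ci_r$ci_hi, tolerance = 1e-12)
  t1 <- form_difference_test(num, den, n_boot = 99, seed = 17)
  t2 <- form_difference_test(num_r, den_r, n_boot = 99, seed = 17)
  expect_equal(t1$statistic_T, t2$statistic_T, tolerance = 1e-12)
  expect_equal(t1$p_value, t2$p_value)
})

test_that("swapping numerator and denominator reciprocates ratios and
           swaps direction flags", {
  num <- random_dataset(5, 5, seed = 8, genotype = "affected")
  den <- scale_dataset(random_dataset(5, 5, seed = 8), 1.15)
  f1 <- form_difference_matrix(num, den)
  f2 <- form_difference_matrix(den, num)
  expect_equal(f1$ratio, 1 / f2$ratio)
  # with the exhaustive bootstrap, CI endpoints reciprocate too
  n3a <- random_dataset(3, 4, seed = 9, genotype = "affected")
  n3b <- scale_dataset(random_dataset(3, 4, seed = 10), 1.2)
  e1 <- bootstrap_fdm_ci(n3a, n3b, method = "exhaustive")
  e2 <- bootstrap_fdm_ci(n3b, n3a, method = "exhaustive")
  expect_equal(e1$ci_lo, 1 / e2$ci_hi, tolerance = 1e-12)
  expect_equal(e1$ci_hi, 1 / e2$ci_lo, tolerance = 1e-12)
  larger1 <- e1$direction == "larger"
  expect_identical(e2$direction[larger1],
                   rep("smaller", sum(larger1)))
})

test_that("bootstrap CI with two identical specimens per group is
           degenerate at 1", {
  one <- random_dataset(1, 5, seed = 12)
  coords <- array(NA_real_, dim = c(2, 5, 3))
  coords[1, , ] <- one$coords[1, , ]
  coords[2, , ] <- one$coords[1, , ]
  ds <- landmark_dataset(coords, one$labels,
                         specimen_id = c("s1", "s2"))
  ci <- bootstrap_fdm_ci(ds, ds, n_boot = 50, seed = 1)
  expect_equal(ci$ratio, rep(1, 10))
  expect_equal(ci$ci_lo, rep(1, 10))
  expect_equal(ci$ci_hi, rep(1, 10))
  expect_false(any(ci$significant))
})

test_that("exhaustive percentile CI endpoints match an independent
           enumeration oracle at n = 3 per group", {
  num <- random_dataset(3, 4, seed = 13, genotype = "affected")
  den <- random_dataset(3, 4, seed = 14)
  got <- bootstrap_fdm_ci(num, den, alpha = 0.10, method = "exhaustive")

  # oracle: recompute every ordered resample's mean form from raw
  # coordinates with nested loops
  idx <- as.matrix(expand.grid(1:3, 1:3, 1:3))
  pair_idx <- combn(4, 2)
  mf_of <- function(ds, rows) {
    d <- matrix(NA_real_, length(rows), ncol(pair_idx))
    for (r in seq_along(rows)) {
      x <- ds$coords[rows[r], , ]
      for (j in seq_len(ncol(pair_idx))) {
        d[r, j] <- sqrt(sum((x[pair_idx[1, j], ] -
                             x[pair_idx[2, j], ])^2))
      }
    }
    colMeans(d)
  }
  m_num <- t(apply(idx, 1, function(rw) mf_of(num, rw)))
  m_den <- t(apply(idx, 1, function(rw) mf_of(den, rw)))
  for (j in seq_len(ncol(pair_idx))) {
    ratios <- as.vector(outer(m_num[, j], 1 / m_den[, j]))
    expect_equal(got$ci_lo[j],
                 quantile(ratios, 0.05, type = 1, names = FALSE),
                 tolerance = 1e-12)
    expect_equal(got$ci_hi[j],
                 quantile(ratios, 0.95, type = 1, names = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("same-seed bootstrap output is bit-identical", {
  num <- random_dataset(5, 5, seed = 15, genotype = "affected")
  den <- random_dataset(5, 5, seed = 16)
  a <- bootstrap_fdm_ci(num, den, n_boot = 200, seed = 99)
  b <- bootstrap_fdm_ci(num, den, n_boot = 200, seed = 99)
  expect_identical(a$ci_lo, b$ci_lo)
  expect_identical(a$ci_hi, b$ci_hi)
})

test_that("overall form-difference test: degenerate identity and
           argument validation", {
  one <- random_dataset(1, 5, seed = 17)
  coords <- array(NA_real_, dim = c(3, 5, 3))
  for (i in 1:3) coords[i, , ] <- one$coords[1, , ]
  ds <- landmark_dataset(coords, one$labels,
                         specimen_id = sprintf("s%d", 1:3))
  tst <- form_difference_test(ds, ds, n_boot = 99, seed = 1)
  expect_equal(tst$statistic_T, 1)
  expect_equal(tst$p_value, 1)

  num <- random_dataset(4, 5, seed = 18)
  expect_error(bootstrap_fdm_ci(num, num, alpha = 1.2), "alpha")
  expect_error(bootstrap_fdm_ci(num, num, n_boot = 0), "n_boot")
})

test_that("overall test p-values are roughly uniform under the null and
           powered under a subset scaling", {
  # null calibration at reduced scale
  ps <- vapply(1:40, function(r) {
    sp <- small_spec(n = 8, seed = 5000 + r)
    a <- simulate_dataset(sp, "affected")
    u <- simulate_dataset(sp, "unaffected")
    form_difference_test(a, u, n_boot = 99, seed = 6000 + r)$p_value
  }, numeric(1))
  expect_gt(mean(ps), 0.3)   # mean of Uniform(0,1) is 0.5
  expect_lt(mean(ps), 0.7)
  expect_lte(mean(ps <= 0.05), 0.2)

  # power: a 1.25 scaling on a 4-landmark subset is detected
  ps_alt <- vapply(1:10, function(r) {
    sp <- small_spec(n = 10, seed = 7000 + r,
                     group_scaling = list(labels = c("laottr", "raottr",
                                                     "lttr", "rttr"),
                                          factor = 1.25))
    sim <- simulate_two_genotypes(sp)
    form_difference_test(sim$affected, sim$unaffected, n_boot = 99,
                         seed = 8000 + r)$p_value
  }, numeric(1))
  expect_gte(mean(ps_alt <= 0.10), 0.8)
})
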