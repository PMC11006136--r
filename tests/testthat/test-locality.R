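test_that("buffered extraction equals the brute-force haversine oracle", {
  set.seed(3)
  g <- toy_grid(matrix(runif(48, 0.70, 0.76), 6, 8))
  g$values[2, 5] <- NA
  pts <- tibble::tibble(lon = runif(8, 10.1, 13.9), lat = runif(8, 57.1, 59.9))
  for (r in c(15, 40, 120, 400)) {
    for (i in seq_len(nrow(pts))) {
      expect_equal(extract_buffered(g, pts$lon[i], pts$lat[i], r),
                   oracle_buffered_mean(g, pts$lon[i], pts$lat[i], r),
                   tolerance = 1e-12)
    }
  }
})

test_that("tiny buffers fall back to the containing cell", {
  g <- toy_grid()
  # point near a cell corner, radius much smaller than half a cell
  expect_equal(extract_buffered(g, 10.51, 59.51, 0.5), g$values[1, 2])
  expect_error(extract_buffered(g, 50, 50, 10), "outside")
})

test_that("constant rasters give the constant at any radius", {
  g <- const_grid(0.72)
  for (r in c(1, 50, 5000)) {
    expect_equal(extract_buffered(g, 11, 59, r), 0.72)
  }
})

test_that("two-cell toy buffer averages both cell values", {
  g <- raster_grid(matrix(c(0.710, 0.730), 1, 2), xmin = 10, ymax = 60,
                   xres = 0.2)
  # radius covering both centers (cells ~11 km apart at this latitude)
  expect_equal(extract_buffered(g, 10.2, 59.9, 50), 0.720)
})

test_that("deltas have the sample-minus-isoscape sign and shift equivariance", {
  truth <- small_truth(seed = 12)
  ind <- simulate_individuals(truth, 30, frac_nonlocal = 0, seed = 1)
  o <- load_oxygen_isoscape(truth$o_field)
  d <- compute_deltas(ind, truth$sr_field, o$mean, radius_km = 10)
  expect_equal(d$delta_sr, d$sr87_86 - d$buffered_sr)
  # sample equal to buffered mean -> delta 0
  ind2 <- ind
  ind2$sr87_86 <- d$buffered_sr
  d2 <- compute_deltas(ind2, truth$sr_field, o$mean, radius_km = 10)
  expect_equal(d2$delta_sr, rep(0, nrow(ind2)))
  # shifting every sample by +c shifts every delta by +c exactly
  ind3 <- ind
  ind3$sr87_86 <- ind3$sr87_86 + 0.01
  d3 <- compute_deltas(ind3, truth$sr_field, o$mean, radius_km = 10)
  expect_equal(d3$delta_sr, d$delta_sr + 0.01, tolerance = 1e-12)
})

test_that("the 1-sigma rule flags exactly the constructed outlier", {
  # 9 deltas at 0 and one at 10: mean 1, sd sqrt(10) ~ 3.16
  d <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:10),
    lon = rep(11, 10), lat = rep(58, 10),
    sr87_86 = c(rep(0, 9), 10) + 0.72, d18o_water = rep(-12, 10)
  )
  g_sr <- const_grid(0.72)
  g_o <- const_grid(-12)
  dt <- compute_deltas(d, g_sr, g_o, radius_km = 5)
  expect_equal(attr(dt, "delta_stats")$sd_sr, sqrt(10), tolerance = 1e-9)
  dt <- classify_local(dt)
  expect_equal(dt$local_flag, c(rep(TRUE, 9), FALSE))
})

test_that("identical deltas classify everything local with a warning", {
  d <- tibble::tibble(
    sample_id = sprintf("s%d", 1:5), lon = rep(11, 5), lat = rep(58, 5),
    sr87_86 = rep(0.72, 5), d18o_water = rep(-12, 5)
  )
  dt <- compute_deltas(d, const_grid(0.72), const_grid(-12), radius_km = 5)
  expect_warning(dt <- classify_local(dt), "zero spread")
  expect_true(all(dt$local_flag))
})

test_that("classification is invariant to a joint shift of samples and isoscape", {
  truth <- small_truth(seed = 13)
  ind <- simulate_individuals(truth, 60, frac_nonlocal = 0.2, seed = 2)
  o <- load_oxygen_isoscape(truth$o_field)
  d1 <- classify_local(compute_deltas(ind, truth$sr_field, o$mean, 10))
  shift <- 0.005
  ind2 <- ind; ind2$sr87_86 <- ind2$sr87_86 + shift
  sr2 <- isorigin:::rg_map(truth$sr_field, function(v) v + shift)
  d2 <- classify_local(compute_deltas(ind2, sr2, o$mean, 10))
  expect_equal(d1$local_flag, d2$local_flag)
})

test_that("buffer-radius scan maximizes R2 with smallest-radius tie-breaking", {
  truth <- small_truth(seed = 14)
  ind <- simulate_individuals(truth, 60, frac_nonlocal = 0, seed = 3,
                              tissue_sr_sd = 0.001)
  scan <- scan_buffer_radius(ind, truth$sr_field, c(5, 25, 100, 250))
  expect_true(all(scan$table$r2 <= 1, na.rm = TRUE))
  # locals generated at cell scale: agreement decays as the buffer grows
  # beyond the landscape correlation length (~80 km)
  expect_lte(scan$best_radius, 100)
  # single radius is returned as-is
  one <- scan_buffer_radius(ind, truth$sr_field, 10)
  expect_equal(one$best_radius, 10)
})

test_that("Mann-Whitney agrees with exhaustive enumeration and rank identities", {
  # identical tied groups: p = 1 under enumeration
  res <- group_difference_test(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(res$p, 1)
  expect_equal(res$method, "exact enumeration")
  # complete separation: U = 0 for the lower group
  res <- group_difference_test(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(res$u, 0)
  # U_A + U_B = n_A * n_B
  set.seed(5)
  for (i in 1:5) {
    v <- sample(1:10, 8, replace = TRUE)
    gl <- rep(c("a", "b"), each = 4)
    ua <- group_difference_test(v, gl)$u
    ub <- group_difference_test(v, rev(gl))$u
    expect_equal(ua + ub, 16)
  }
})

test_that("Mann-Whitney matches wilcox.test on tie-free data in both regimes", {
  set.seed(8)
  # exact regime
  v <- c(rnorm(6), rnorm(7, 1))
  gl <- rep(c("a", "b"), c(6, 7))
  ours <- group_difference_test(v, gl)
  ref <- wilcox.test(v[gl == "a"], v[gl == "b"], exact = TRUE)
  expect_equal(ours$u, unname(ref$statistic))
  expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
  # large-sample regime vs normal approximation without continuity correction
  v <- c(rnorm(20), rnorm(25, 0.5))
  gl <- rep(c("a", "b"), c(20, 25))
  ours <- group_difference_test(v, gl)
  ref <- wilcox.test(v[gl == "a"], v[gl == "b"], exact = FALSE, correct = FALSE)
  expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
  expect_error(group_difference_test(v, rep("a", 45)), "two groups")
})

test_that("group comparisons run the sex and tissue contrasts", {
  truth <- small_truth(seed = 15)
  ind <- simulate_individuals(truth, 80, frac_nonlocal = 0, seed = 4)
  o <- load_oxygen_isoscape(truth$o_field)
  d <- compute_deltas(ind, truth$sr_field, o$mean, 10)
  res <- group_comparisons(d)
  expect_true(all(c("sex_all", "sex_bone", "tissue_all") %in% res$comparison))
  expect_true(all(res$p >= 0 & res$p <= 1))
  # the simulated antler offset should make the tissue O contrast strong
  tiss_o <- res$p[res$comparison == "tissue_all" & res$axis == "o"]
  expect_lt(tiss_o, 0.05)
})

test_that("forest-cover regression recovers exact linear structure and rejects
           degenerate cover", {
  truth <- small_truth(seed = 16)
  ind <- simulate_individuals(truth, 40, frac_nonlocal = 0, seed = 5)
  cov <- sapply(seq_len(nrow(ind)), function(i) {
    extract_buffered(truth$forest_cover, ind$lon[i], ind$lat[i], 10)
  })
  ind$d13c_suess <- -20 + 0.05 * cov # exactly linear in buffered cover
  res <- forest_cover_regression(ind, truth$forest_cover, radius_km = 10)
  expect_equal(res$r2[res$group == "combined"], 1, tolerance = 1e-9)
  expect_equal(res$slope[res$group == "combined"], 0.05, tolerance = 1e-9)
  expect_error(forest_cover_regression(ind, const_grid(50, 40, 40, 10, 70, 0.15),
                                       radius_km = 10),
               "constant")
})
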