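test_that("uniform evidence gives the uniform posterior", {
  m <- const_grid(0.72, 10, 10)
  s <- const_grid(0.005, 10, 10)
  p <- posterior_surface(0.715, m, s)
  expect_equal(sum(p$values), 1, tolerance = 1e-9)
  expect_true(all(abs(p$values - 1 / 100) < 1e-12))
})

test_that("two-cell posterior matches hand-computed normal densities", {
  m <- raster_grid(matrix(c(0.710, 0.730), 1, 2), 10, 60, 0.5)
  s <- raster_grid(matrix(0.005, 1, 2), 10, 60, 0.5)
  p <- posterior_surface(0.710, m, s)
  # phi(0) / (phi(0) + phi(4))
  expected <- dnorm(0) / (dnorm(0) + dnorm(4))
  expect_equal(p$values[1, 1], expected, tolerance = 1e-9)
  expect_equal(p$values[1, 1], 0.99967, tolerance = 1e-4)
})

test_that("posteriors always normalize, even for distant observations", {
  truth <- small_truth(seed = 21, sea_margin_cols = 3)
  o <- load_oxygen_isoscape(truth$o_field)
  # observation far outside the field range would underflow linear densities
  p <- posterior_surface(30, o$mean, o$sd)
  expect_equal(sum(p$values, na.rm = TRUE), 1, tolerance = 1e-9)
  expect_true(all(p$values >= 0, na.rm = TRUE))
  expect_true(all(is.na(p$values[, 1:3])))
})

test_that("nonpositive sd cells are rejected with their location", {
  m <- const_grid(0.72, 3, 3)
  s <- const_grid(0.005, 3, 3)
  s$values[2, 3] <- 0
  expect_error(posterior_surface(0.72, m, s), "row 2, col 3")
})

test_that("joint combination is commutative and respects uniform identity", {
  m <- toy_grid(matrix(seq(0.70, 0.76, length.out = 12), 3, 4))
  s <- toy_grid(matrix(0.004, 3, 4))
  pa <- posterior_surface(0.72, m, s)
  uni <- posterior_surface(0.5, const_grid(0.5, 3, 4, 10, 60, 0.5),
                           const_grid(1, 3, 4, 10, 60, 0.5))
  expect_equal(joint_posterior(pa, uni)$values, pa$values, tolerance = 1e-12)
  pb <- posterior_surface(0.74, m, s)
  expect_equal(joint_posterior(pa, pb)$values, joint_posterior(pb, pa)$values)
  # two-cell product renormalization by hand: {0.8,0.2} x {0.5,0.5} -> {0.8,0.2}
  g1 <- raster_grid(matrix(c(0.8, 0.2), 1, 2), 0, 1, 1)
  p1 <- structure(c(g1, list(sample_id = "x", system = "Sr")),
                  class = c("posterior_surface", "raster_grid"))
  g2 <- raster_grid(matrix(c(0.5, 0.5), 1, 2), 0, 1, 1)
  p2 <- structure(c(g2, list(sample_id = "x", system = "O")),
                  class = c("posterior_surface", "raster_grid"))
  expect_equal(joint_posterior(p1, p2)$values, matrix(c(0.8, 0.2), 1, 2))
})

test_that("self-joint equals renormalized squared masses", {
  m <- toy_grid(matrix(seq(0.70, 0.76, length.out = 12), 3, 4))
  s <- toy_grid(matrix(0.004, 3, 4))
  p <- posterior_surface(0.72, m, s)
  jj <- joint_posterior(p, p)
  expect_equal(jj$values, p$values^2 / sum(p$values^2), tolerance = 1e-12)
})

test_that("sharper evidence concentrates posterior mass", {
  m <- toy_grid(matrix(seq(0.70, 0.76, length.out = 12), 3, 4))
  s1 <- toy_grid(matrix(0.01, 3, 4))
  s2 <- toy_grid(matrix(0.005, 3, 4))
  p1 <- posterior_surface(0.72, m, s1)
  p2 <- posterior_surface(0.72, m, s2)
  expect_gte(max(p2$values), max(p1$values))
})

test_that("top-quantile regions have the prescribed area and respect point masses", {
  m <- const_grid(0.72, 10, 10)
  s <- const_grid(0.005, 10, 10)
  uni <- posterior_surface(0.715, m, s)
  mask <- top_quantile_region(uni, q = 0.05)
  expect_equal(sum(mask$values), 100) # uniform: everything tied at threshold
  # distinct masses: exactly ceil(q N) cells
  mv <- toy_grid(matrix(seq(0.70, 0.76, length.out = 12), 3, 4))
  sv <- toy_grid(matrix(0.004, 3, 4))
  p <- posterior_surface(0.72, mv, sv)
  expect_equal(sum(top_quantile_region(p, 0.25)$values), 3) # ceil(0.25*12)
  # near-point mass: the heavy cell alone for small q
  g <- raster_grid(matrix(c(0.99, 0.01), 1, 2), 0, 1, 1)
  pp <- structure(c(g, list(sample_id = "x", system = "Sr")),
                  class = c("posterior_surface", "raster_grid"))
  expect_equal(top_quantile_region(pp, 0.5)$values, matrix(c(1, 0), 1, 2))
})

test_that("distance densities conserve mass and localize point masses", {
  m <- toy_grid(matrix(seq(0.70, 0.76, length.out = 12), 3, 4))
  s <- toy_grid(matrix(0.002, 3, 4))
  p <- posterior_surface(0.703, m, s)
  dd <- distance_density(p, 10.25, 59.75, bin_width_km = 10)
  expect_equal(sum(dd$mass), 1, tolerance = 1e-9)
  expect_true(all(dd$bin_hi_km - dd$bin_lo_km == 10))
  # concentrated observation: nearly all mass in the bin containing its cell
  heavy <- dd$mass[which.max(dd$mass)]
  expect_gt(heavy, 0.5)
})

test_that("a ring of equidistant cells lands in a single distance bin", {
  # death site at the center of a 3x3 grid; corner/edge cells form rings
  g <- raster_grid(matrix(1, 3, 3), xmin = 0, ymax = 1.5, xres = 0.5)
  mass <- matrix(0, 3, 3)
  mass[c(1, 3, 7, 9)] <- 0.25 # the four corner cells, equidistant from center
  p <- structure(c(raster_grid(mass, 0, 1.5, 0.5), list(sample_id = "x", system = "Sr")),
                 class = c("posterior_surface", "raster_grid"))
  center_lon <- 0.75; center_lat <- 0.75
  d_corner <- oracle_haversine_km(0.25, 0.25, center_lon, center_lat)
  dd <- distance_density(p, center_lon, center_lat, bin_width_km = 20)
  expect_equal(nrow(dd[dd$mass > 0, ]), 1)
  hot <- dd[dd$mass > 0, ]
  expect_true(hot$bin_lo_km <= d_corner && d_corner < hot$bin_hi_km)
  expect_equal(hot$mass, 1)
})

test_that("binned and sorted-array distance densities agree exactly", {
  truth <- small_truth(seed = 22)
  o <- load_oxygen_isoscape(truth$o_field)
  p <- posterior_surface(-11, o$mean, o$sd)
  dd <- distance_density(p, 12, 67, bin_width_km = 25)
  # independent route: flat vectors, order by distance, split by bin index
  g <- truth$o_field
  lons <- rep(rg_lon_centers(g), each = nrow(g$values))
  lats <- rep(rg_lat_centers(g), times = ncol(g$values))
  d <- oracle_haversine_km(lons, lats, 12, 67)
  fl <- tibble::tibble(d = d, mass = as.vector(p$values))
  fl <- fl[order(fl$d), ]
  ref <- tapply(fl$mass, floor(fl$d / 25), sum)
  ref <- ref[order(as.numeric(names(ref)))]
  expect_equal(dd$mass, as.numeric(ref), tolerance = 1e-12)
})

test_that("batch assignment covers exactly the non-local samples", {
  truth <- small_truth(seed = 23)
  ind <- simulate_individuals(truth, 40, frac_nonlocal = 0.25, seed = 3)
  o <- load_oxygen_isoscape(truth$o_field)
  d <- classify_local(compute_deltas(ind, truth$sr_field, o$mean, 10))
  sd_sr <- const_grid(0.003, 40, 40, 10, 70, 0.15)
  res <- assign_outliers(d, truth$sr_field, sd_sr, o$mean, o$sd)
  expect_equal(sort(names(res)), sort(d$sample_id[!d$local_flag]))
  for (a in res) {
    expect_equal(sum(a$sr$values, na.rm = TRUE), 1, tolerance = 1e-9)
    expect_equal(sum(a$joint$values, na.rm = TRUE), 1, tolerance = 1e-9)
    expect_equal(sum(a$distance$mass), 1, tolerance = 1e-9)
  }
  # zero non-locals -> empty result
  all_local <- d
  all_local$local_flag <- TRUE
  expect_equal(assign_outliers(all_local, truth$sr_field, sd_sr), list())
})

test_that("area weighting remains a proper posterior", {
  truth <- small_truth(seed = 24)
  o <- load_oxygen_isoscape(truth$o_field)
  p <- posterior_surface(-11, o$mean, o$sd, area_weight = TRUE)
  expect_equal(sum(p$values, na.rm = TRUE), 1, tolerance = 1e-9)
})
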