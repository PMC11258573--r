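test_that("ring areas around a circular ROI match the annulus formula", {
  roi <- circle_roi(side = 260L, radius = 30)
  r <- build_rings(roi, sholl_config(n_rings = 3L, ring_thickness_um = 30), 1)
  got <- attr(r, "ring_area_um2")
  want <- pi * ((30 + 30 * (1:3))^2 - (30 + 30 * (0:2))^2)
  expect_true(all(abs(got / want - 1) < 0.03))
  expect_false(any(attr(r, "clipped")))
  # strictly increasing ring areas for a convex unclipped ROI
  expect_true(all(diff(got) > 0))
})

test_that("rings partition the distance band and exclude the ROI interior", {
  cfg <- halo_scene(seed = 5, n_plaques = 3L)
  g <- generate_pathology(cfg)
  r <- build_rings(g$truth$plaque_labels, sholl_config(), 1)
  d <- neuroprox:::dist_to_mask(g$truth$plaque_mask)
  expect_true(all((r > 0) == (d > 0 & d <= 90)))   # exhaustive pixel check
  expect_true(all(r[g$truth$plaque_mask] == 0L))
  for (k in 1:3) {
    expect_true(all((r == k) == (d > (k - 1) * 30 & d <= k * 30)))
  }
})

test_that("build_rings is invariant to ROI label permutation", {
  cfg <- halo_scene(seed = 6, n_plaques = 3L)
  g <- generate_pathology(cfg)
  labs <- g$truth$plaque_labels
  perm <- labs
  perm[labs == 1L] <- 3L
  perm[labs == 3L] <- 1L
  r1 <- build_rings(labs, sholl_config(), 1)
  r2 <- build_rings(perm, sholl_config(), 1)
  expect_identical(unclass(r1), unclass(r2))
})

test_that("distant ROIs produce the disjoint union of per-ROI rings", {
  roi <- matrix(0L, 400, 400)
  roi[neuroprox:::disc_mask(400, 400, 100, 100, 15)] <- 1L
  roi[neuroprox:::disc_mask(400, 400, 300, 300, 15)] <- 2L
  cfgr <- sholl_config(n_rings = 2L, ring_thickness_um = 20)
  r_both <- build_rings(roi, cfgr, 1)
  r1 <- build_rings((roi == 1L) * 1L, cfgr, 1)
  r2 <- build_rings((roi == 2L) * 1L, cfgr, 1)
  expect_identical(matrix(as.integer(r_both), 400, 400),
                   pmax(matrix(as.integer(r1), 400, 400),
                        matrix(as.integer(r2), 400, 400)))
  expect_equal(attr(r_both, "ring_area_um2"),
               attr(r1, "ring_area_um2") + attr(r2, "ring_area_um2"))
})

test_that("empty ROI sets and too-thin rings are rejected", {
  expect_error(build_rings(matrix(0L, 20, 20), sholl_config(), 1), "empty ROI")
  roi <- matrix(0L, 20, 20); roi[10, 10] <- 1L
  expect_error(build_rings(roi, sholl_config(ring_thickness_um = 0.4), 1),
               "at least 1 px")
})

test_that("border-clipped rings are flagged and fully clipped rings missing", {
  roi <- matrix(0L, 80, 80)
  roi[neuroprox:::disc_mask(80, 80, 40, 40, 10)] <- 1L
  r <- build_rings(roi, sholl_config(n_rings = 3L, ring_thickness_um = 30), 1)
  expect_true(any(attr(r, "clipped")))
  expect_true(all(attr(r, "retained_fraction") <= 1))
  prof <- ring_coverage(r, matrix(1, 80, 80), threshold = 0.5)
  expect_true(all(prof$coverage_pct[!is.na(prof$coverage_pct)] == 100))
  # a ring completely outside the canvas would be NA, not zero
  roi2 <- matrix(0L, 34, 34); roi2[neuroprox:::disc_mask(34, 34, 17, 17, 15)] <- 1L
  r2 <- build_rings(roi2, sholl_config(n_rings = 3L, ring_thickness_um = 30), 1)
  p2 <- ring_coverage(r2, matrix(1, 34, 34), threshold = 0.5)
  expect_true(is.na(p2$coverage_pct[3]))
})

test_that("coverage of an everywhere-positive target is 100% in all rings", {
  roi <- circle_roi(200L, 20)
  r <- build_rings(roi, sholl_config(n_rings = 2L), 1)
  prof <- ring_coverage(r, matrix(5, 200, 200), threshold = 1)
  expect_equal(prof$coverage_pct, c(100, 100))
})

test_that("Bernoulli target coverage sits within binomial error of p", {
  roi <- circle_roi(260L, 30)
  r <- build_rings(roi, sholl_config(), 1)
  set.seed(11)
  targ <- matrix(rbinom(260 * 260, 1, 0.2), 260, 260)
  prof <- ring_coverage(r, targ, threshold = 0.5)
  for (k in 1:3) {
    n <- attr(r, "ring_area_um2")[k]
    se <- 100 * sqrt(0.2 * 0.8 / n)
    expect_lt(abs(prof$coverage_pct[k] - 20), 3 * se)
  }
})

test_that("ROI-interior coverage appears as ring 0 when requested", {
  roi <- circle_roi(140L, 15)
  r <- build_rings(roi, sholl_config(n_rings = 2L, exclude_roi_interior = FALSE), 1)
  expect_true(all(r[roi > 0] == 0L))  # ring raster still excludes interior
  prof <- ring_coverage(r, matrix(1, 140, 140), threshold = 0.5)
  expect_equal(prof$ring[1], 0L)
  expect_equal(prof$coverage_pct[1], 100)
})

test_that("halo coverage decreases across rings over seeds", {
  mono <- vapply(1:30, function(s) {
    cfg <- halo_scene(seed = s, tau = 30)
    g <- generate_pathology(cfg)
    noisy <- add_noise(g$stack, cfg)
    r <- build_rings(g$truth$plaque_labels, sholl_config(), 1)
    cov <- ring_coverage(r, noisy[["oligomer"]], threshold = 25)$coverage_pct
    all(diff(cov) < 0)
  }, logical(1))
  expect_gte(mean(mono), 0.95)
})

test_that("profile comparison contracts hold", {
  prof <- data.frame(ring = 1:3, ring_area_um2 = c(100, 200, 300),
                     coverage_pct = c(30, 20, 10),
                     retained_fraction = 1, clipped = FALSE)
  class(prof) <- c("sholl_profile", "data.frame")
  # single profile -> error
  expect_error(compare_profiles(list(A = list(img1 = prof))),
               "at least two")
  # identical profiles -> zero contrasts and zero marker effect
  same <- list(A = list(i1 = prof, i2 = prof), B = list(i1 = prof, i2 = prof))
  cmp <- compare_profiles(same)
  expect_true(all(cmp$between$contrast == 0))
  expect_equal(cmp$marker_effect$effects$statistic[1], 0)
  # unequal ring configurations rejected
  short <- prof[1:2, ]
  class(short) <- c("sholl_profile", "data.frame")
  expect_error(compare_profiles(list(A = list(i1 = prof), B = list(i1 = short))),
               "unequal ring")
})

test_that("markers with different decay lengths separate at ring 1", {
  ring1 <- function(seed, tau) {
    cfg <- scene_config(width_px = 160L, height_px = 160L, n_plaques = 3L,
                        plaque_radius_um = c(7, 10),
                        diffuse_oligomer_fraction = 0, n_nuclei = 0L,
                        cell_specs = list(cell_spec("M", 18L, soma_radius_um = 3,
                                                    n_processes = 2L,
                                                    process_length_um = 10,
                                                    attraction_weight = 1,
                                                    attraction_tau_um = tau)),
                        noise = noise_config(1, 1, 1), seed = seed)
    g <- generate_pathology(cfg)
    pc <- place_cells(cfg, g$truth)
    noisy <- add_noise(pc$stack, cfg)
    r <- build_rings(g$truth$plaque_labels, sholl_config(), 1)
    ring_coverage(r, noisy[["M"]], threshold = "otsu")$coverage_pct[1]
  }
  a <- vapply(1:6, function(i) ring1(1000 + i, 20), numeric(1))
  b <- vapply(1:6, function(i) ring1(2000 + i, 200), numeric(1))
  expect_lt(stats::t.test(a, b)$p.value, 0.05)
  expect_gt(mean(a), mean(b))
})
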