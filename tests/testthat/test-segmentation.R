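test_that("blank probability map yields zero objects", {
  p <- identify_primary(matrix(0, 50, 50))
  expect_equal(attr(p, "n_objects"), 0L)
  expect_true(all(p == 0L))
})

test_that("non-touching synthetic nuclei are counted exactly", {
  cfg <- nuclei_scene(seed = 2, n_nuclei = 25L, side = 256L)
  g <- generate_pathology(cfg)
  noisy <- add_noise(g$stack, cfg)
  p <- identify_primary(pmin(noisy[["nuclei"]] / 100, 1))
  expect_equal(attr(p, "n_objects"), 25L)
  expect_dense_labels(p)
})

test_that("shape declumping separates two overlapping discs", {
  d2 <- matrix(0, 80, 120)
  # radius 15 discs, centres 21 px apart: overlap ~30% of the radius
  for (i in 1:80) for (j in 1:120) {
    if ((i - 40)^2 + (j - 45)^2 <= 225 || (i - 40)^2 + (j - 66)^2 <= 225) {
      d2[i, j] <- 1
    }
  }
  prm <- segmentation_params(size_filter_um2 = c(10, 2000))
  p <- identify_primary(d2, prm)
  expect_equal(attr(p, "n_objects"), 2L)
  # distance-transform oracle: the two seed points stay in different objects
  expect_true(p[40, 45] != p[40, 66])
  p_off <- identify_primary(d2, segmentation_params(declump = "none",
                                                    size_filter_um2 = c(10, 2000)))
  expect_equal(attr(p_off, "n_objects"), 1L)
})

test_that("identify_primary is idempotent on a binary map", {
  cfg <- nuclei_scene(seed = 3, n_nuclei = 15L, side = 200L)
  g <- generate_pathology(cfg)
  bin <- (g$stack[["nuclei"]] > 0) * 1
  p1 <- identify_primary(bin)
  p2 <- identify_primary(bin)
  expect_identical(unclass(p1), unclass(p2))
})

test_that("threshold outside (0,1) is rejected", {
  expect_error(segmentation_params(nuclei_threshold = 0))
  expect_error(segmentation_params(nuclei_threshold = 1.2))
})

test_that("zero expansion distance returns the primaries unchanged", {
  cfg <- nuclei_scene(seed = 4, n_nuclei = 10L, side = 150L)
  g <- generate_pathology(cfg)
  p <- identify_primary((g$stack[["nuclei"]] > 0) * 1)
  s <- identify_secondary(p, matrix(1, 150, 150),
                          segmentation_params(max_expansion_um = 0))
  expect_identical(unclass_labels <- as.integer(s), as.integer(p))
})

test_that("secondary growth in uniform signal matches morphological dilation", {
  prim <- matrix(0L, 120, 120)
  prim[neuroprox:::disc_mask(120, 120, 60, 60, 8)] <- 1L
  prim <- neuroprox:::new_label_image(prim, 1)
  for (method in c("expansion", "watershed")) {
    s <- identify_secondary(prim, matrix(1, 120, 120),
                            segmentation_params(secondary_method = method,
                                                max_expansion_um = 5))
    brush <- 1 * (outer((-5:5)^2, (-5:5)^2, `+`) <= 25)
    oracle <- sum(EBImage::dilate(matrix(as.numeric(prim > 0), 120, 120),
                                  brush))
    expect_lt(abs(sum(s > 0) / oracle - 1), 0.05)
    # nesting: primary subset of secondary with matching labels
    expect_true(all(s[prim > 0] == prim[prim > 0]))
  }
})

test_that("contested pixels go to the nearer primary, ties to lower label", {
  prim <- matrix(0L, 60, 100)
  prim[neuroprox:::disc_mask(60, 100, 30, 35, 4)] <- 1L
  prim[neuroprox:::disc_mask(60, 100, 30, 65, 4)] <- 2L
  prim <- neuroprox:::new_label_image(prim, 1)
  s <- identify_secondary(prim, matrix(1, 60, 100),
                          segmentation_params(secondary_method = "expansion",
                                              max_expansion_um = 12))
  idx <- which(s > 0, arr.ind = TRUE)
  p1 <- which(prim == 1L, arr.ind = TRUE)
  p2 <- which(prim == 2L, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    d1 <- sqrt(min((p1[, 1] - idx[k, 1])^2 + (p1[, 2] - idx[k, 2])^2))
    d2 <- sqrt(min((p2[, 1] - idx[k, 1])^2 + (p2[, 2] - idx[k, 2])^2))
    want <- if (d1 < d2) 1L else if (d2 < d1) 2L else 1L  # tie: lower label
    expect_equal(s[idx[k, 1], idx[k, 2]], want)
  }
})

test_that("secondaries stop at the signal-probability threshold", {
  prim <- matrix(0L, 80, 80)
  prim[neuroprox:::disc_mask(80, 80, 40, 40, 5)] <- 1L
  prim <- neuroprox:::new_label_image(prim, 1)
  sig <- matrix(0, 80, 80)
  sig[, 1:40] <- 1  # signal only on the left half
  s <- identify_secondary(prim, sig,
                          segmentation_params(secondary_method = "expansion",
                                              max_expansion_um = 10))
  grown <- s > 0 & !(prim > 0)
  expect_true(all(which(grown, arr.ind = TRUE)[, 2] <= 40))
})

test_that("tertiary objects satisfy the exact area identity", {
  cfg <- nuclei_scene(seed = 6, n_nuclei = 20L, side = 250L)
  g <- generate_pathology(cfg)
  p <- identify_primary((g$stack[["nuclei"]] > 0) * 1)
  s <- identify_secondary(p, matrix(1, 250, 250),
                          segmentation_params(max_expansion_um = 6))
  t <- identify_tertiary(s, p)
  ap <- object_areas(p); as_ <- object_areas(s); at <- object_areas(t)
  expect_identical(unname(at), unname(as_ - ap))
  expect_equal(sum(at), sum(as_) - sum(ap))
  # secondary == primary -> all tertiary objects empty
  t0 <- identify_tertiary(p, p)
  expect_true(all(t0 == 0L))
  expect_equal(attr(t0, "n_objects"), attr(p, "n_objects"))
})

test_that("label mismatch between tiers is a pairing error", {
  p <- matrix(0L, 20, 20); p[5:7, 5:7] <- 1L
  s <- matrix(0L, 20, 20); s[4:8, 4:8] <- 2L
  expect_error(identify_tertiary(neuroprox:::new_label_image(s, 1),
                                 neuroprox:::new_label_image(p, 1)),
               "pairing")
})

test_that("nucleus counts are recovered across seeds at 500/mm^2", {
  detected <- vapply(1:20, function(s) {
    cfg <- nuclei_scene(seed = s)
    g <- generate_pathology(cfg)
    noisy <- add_noise(g$stack, cfg)
    attr(identify_primary(pmin(noisy[["nuclei"]] / 100, 1)), "n_objects")
  }, integer(1))
  expect_lte(sum(abs(detected - 45L)), 0.01 * 20 * 45)
})
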