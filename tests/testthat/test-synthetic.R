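test_that("configured object counts are realised exactly", {
  cfg <- scene_config(n_plaques = 5L, n_nuclei = 12L,
                      cell_specs = list(cell_spec("A", 7L, n_processes = 1L),
                                        cell_spec("B", 4L)),
                      seed = 3)
  sim <- simulate_scene(cfg)
  expect_equal(max(sim$truth$plaque_labels), 5L)
  expect_equal(sort(unique(sim$truth$plaque_labels[sim$truth$plaque_labels > 0])),
               1:5)
  expect_equal(max(sim$truth$nuclei_labels), 12L)
  expect_equal(nrow(sim$truth$cells), 11L)
  expect_equal(as.vector(table(sim$truth$cells$marker)[c("A", "B")]), c(7L, 4L))
})

test_that("no pathology sources means an all-background oligomer channel", {
  cfg <- scene_config(n_plaques = 0L, diffuse_oligomer_fraction = 0,
                      n_nuclei = 5L, seed = 1)
  g <- generate_pathology(cfg)
  expect_true(all(g$stack[["oligomer"]] == 0))
  expect_false(any(g$truth$oligomer_mask))
})

test_that("ground-truth masks and rendered channels are consistent", {
  sim <- simulate_scene(scene_config(seed = 9, n_nuclei = 20L))
  expect_identical(sim$clean[["plaque"]] > 0, sim$truth$plaque_mask)
  expect_identical(sim$clean[["nuclei"]] > 0, sim$truth$nuclei_labels > 0)
  expect_identical(sim$clean[["oligomer"]] > 0, sim$truth$oligomer_mask)
})

test_that("oligomer halo decays with the configured length", {
  # tau = 30: mean intensity ratio between the 0-30 and 60-90 um annuli is
  # approximately e^2; oracle recomputes distances by brute force
  cfg <- halo_scene(seed = 3, tau = 30, n_plaques = 2L, side = 300L,
                    radius = c(10, 14))
  g <- generate_pathology(cfg)
  I <- g$stack[["oligomer"]]
  pl <- which(g$truth$plaque_mask, arr.ind = TRUE)
  set.seed(42)
  idx <- sample(which(!g$truth$plaque_mask), 4000)
  rr <- ((idx - 1) %% 300) + 1
  cc <- ((idx - 1) %/% 300) + 1
  d_brute <- vapply(seq_along(idx), function(k) {
    sqrt(min((pl[, 1] - rr[k])^2 + (pl[, 2] - cc[k])^2))
  }, numeric(1))
  in1 <- d_brute > 0 & d_brute <= 30
  in2 <- d_brute > 60 & d_brute <= 90
  oracle_ratio <- mean(100 * exp(-d_brute[in1] / 30)) /
    mean(100 * exp(-d_brute[in2] / 30))
  got_ratio <- mean(I[idx[in1]]) / mean(I[idx[in2]])
  expect_lt(abs(got_ratio / oracle_ratio - 1), 0.02)
  expect_lt(abs(got_ratio / exp(2) - 1), 0.10)
})

test_that("w = 0 placement is complete spatial randomness", {
  base <- halo_scene(seed = 1)
  base$cell_specs <- list(cell_spec("M", 40L, soma_radius_um = 3,
                                    n_processes = 0L, attraction_weight = 0))
  g <- generate_pathology(base)
  dmap <- neuroprox:::dist_to_mask(g$truth$pathology_mask)
  ref <- as.numeric(dmap[4:196, 4:196])  # uniform-placement null distances
  ok <- vapply(1:50, function(s) {
    cfg <- base
    cfg$seed <- s
    pc <- place_cells(cfg, g$truth)
    suppressWarnings(
      stats::ks.test(pc$truth$cells$dist_pathology_um, ref)$p.value) > 0.01
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("full attraction pulls cells closer than random placement", {
  base <- halo_scene(seed = 2)
  base$cell_specs <- list(cell_spec("M", 30L, soma_radius_um = 3,
                                    n_processes = 0L, attraction_weight = 0,
                                    attraction_tau_um = 30))
  g <- generate_pathology(base)
  m0 <- median(place_cells(base, g$truth)$truth$cells$dist_pathology_um)
  cfg1 <- base
  cfg1$cell_specs[[1]]$attraction_weight <- 1
  m1 <- median(place_cells(cfg1, g$truth)$truth$cells$dist_pathology_um)
  expect_lt(m1, m0)
})

test_that("zero cells gives empty records and no channel", {
  cfg <- halo_scene(seed = 1)
  cfg$cell_specs <- list(cell_spec("M", 0L))
  g <- generate_pathology(cfg)
  pc <- place_cells(cfg, g$truth)
  expect_equal(nrow(pc$truth$cells), 0L)
  expect_true(all(pc$stack[["M"]] == 0))
})

test_that("somata never overlap", {
  cfg <- scene_config(seed = 5, n_nuclei = 0L, n_plaques = 2L,
                      cell_specs = list(cell_spec("A", 15L, soma_radius_um = 4),
                                        cell_spec("B", 15L, soma_radius_um = 6)))
  sim <- simulate_scene(cfg)
  areas <- table(sim$truth$soma_labels[sim$truth$soma_labels > 0])
  expect_equal(length(areas), 30L)  # every soma disjoint, none overwritten
  expect_equal(sum(areas), sum(sim$truth$cells$soma_area_um2))
})

test_that("infeasible configurations raise the infeasible-scene error", {
  expect_error(scene_config(width_px = 32L, height_px = 32L, n_plaques = 50L,
                            plaque_radius_um = c(10, 15)),
               class = "neuroprox_infeasible_scene")
  cfg <- scene_config(width_px = 64L, height_px = 64L, n_plaques = 0L,
                      n_nuclei = 0L,
                      cell_specs = list(cell_spec("M", 25L, soma_radius_um = 6,
                                                  n_processes = 0L)))
  g <- generate_pathology(cfg)
  expect_error(place_cells(cfg, g$truth),
               class = "neuroprox_infeasible_scene")
})

test_that("noise model is seed-deterministic and calibrated", {
  cfg <- scene_config(seed = 8, n_nuclei = 10L)
  sim1 <- simulate_scene(cfg)
  sim2 <- simulate_scene(cfg)
  expect_identical(sim1$noisy$channels, sim2$noisy$channels)  # byte-identical
  # pure background: sample mean within 3 SE of background_mean
  flat <- channel_stack(list(z = matrix(0, 200, 200)))
  cfgn <- scene_config(seed = 4, noise = noise_config(background_mean = 10,
                                                      gaussian_sd = 2,
                                                      poisson_scale = 0))
  noisy <- add_noise(flat, cfgn)
  se <- 2 / sqrt(200 * 200)
  expect_lt(abs(mean(noisy[["z"]]) - 10), 3 * se)
  # huge poisson_scale limit: output ~ input within 1%
  img <- channel_stack(list(z = matrix(runif(100 * 100, 50, 150), 100, 100)))
  cfg0 <- scene_config(seed = 4, noise = noise_config(0, 0, 1e6))
  out <- add_noise(img, cfg0)
  expect_lt(max(abs(out[["z"]] - img[["z"]]) / img[["z"]]), 0.01)
  expect_error(noise_config(background_mean = -1))
})
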