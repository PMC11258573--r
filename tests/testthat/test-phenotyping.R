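test_that("cell table rows reproduce generator records", {
  cfg <- scene_config(seed = 4, n_plaques = 2L, n_nuclei = 0L,
                      cell_specs = list(cell_spec("A", 12L, soma_radius_um = 4,
                                                  n_processes = 0L)))
  sim <- simulate_scene(cfg)
  st <- channel_stack(sim$clean$channels["A"], 1)
  ct <- build_cell_table(sim$truth$soma_labels, st)
  expect_equal(nrow(ct), 12L)
  expect_true(all(abs(ct$area_um2 / sim$truth$cells$soma_area_um2 - 1) < 0.05))
  expect_true(all(ct$A == 100))   # uniform soma intensity -> exact means
})

test_that("empty label image yields an empty table, not an error", {
  st <- channel_stack(list(A = matrix(0, 20, 20)))
  ct <- build_cell_table(matrix(0L, 20, 20), st)
  expect_s3_class(ct, "cell_table")
  expect_equal(nrow(ct), 0L)
})

test_that("label raster and stack must be co-registered", {
  st <- channel_stack(list(A = matrix(0, 20, 20)))
  expect_error(build_cell_table(matrix(0L, 10, 10), st), "co-registered")
})

test_that("intensity transforms keep their contracts", {
  set.seed(5)
  tab <- table_from_matrix(cbind(M1 = rexp(100, 0.1), M2 = rnorm(100, 50, 5)))
  z <- transform_intensities(tab, "zscore")
  expect_lt(abs(mean(z$M1_t)), 1e-9)
  expect_lt(abs(stats::sd(z$M1_t) - 1), 1e-9)
  # arcsinh approaches x / cofactor for a large cofactor
  big <- transform_intensities(tab, "arcsinh", cofactor = 1e8)
  expect_lt(max(abs(big$M1_t - tab$M1 / 1e8)), 1e-12)
  # monotone
  a5 <- transform_intensities(tab, "arcsinh", cofactor = 5)
  expect_true(all(diff(a5$M1_t[order(tab$M1)]) >= 0))
  # percentile clip pins the extremes to the quantiles
  pc <- transform_intensities(tab, "percentile", probs = c(0.01, 0.99))
  expect_equal(min(pc$M1_t), stats::quantile(tab$M1, 0.01, names = FALSE))
  expect_equal(max(pc$M1_t), stats::quantile(tab$M1, 0.99, names = FALSE))
  # zero-variance marker under z-score: warning, set to 0
  flat <- table_from_matrix(cbind(M1 = rep(3, 50), M2 = rnorm(50)))
  expect_warning(zf <- transform_intensities(flat, "zscore"), "zero variance")
  expect_true(all(zf$M1_t == 0))
})

test_that("three well-separated populations are recovered", {
  d <- three_pop_data(seed = 1)
  tab <- cluster_cells(table_from_matrix(d$X), k_neighbors = 15, seed = 1)
  expect_gte(mclust::adjustedRandIndex(tab$cluster, d$truth), 0.9)
  expect_gte(attr(tab, "modularity"), 0)  # beats the single-cluster partition
  cs <- cluster_summary(tab)
  # summary rows equal member means exactly
  for (cl in rownames(cs$means)) {
    sel <- tab$cluster == as.integer(cl)
    expect_equal(unname(cs$means[cl, ]),
                 unname(colMeans(as.matrix(tab[sel, c("M1", "M2")]))))
  }
  expect_equal(sum(cs$sizes), nrow(tab))
})

test_that("clustering is invariant to row order at a fixed seed", {
  d <- three_pop_data(seed = 2)
  tab <- table_from_matrix(d$X)
  c1 <- cluster_cells(tab, seed = 3)
  perm <- sample(nrow(tab))
  tabp <- table_from_matrix(d$X[perm, ])
  c2 <- cluster_cells(tabp, seed = 3)
  expect_equal(mclust::adjustedRandIndex(c1$cluster[perm], c2$cluster), 1)
})

test_that("a single homogeneous population stays one dominant cluster", {
  set.seed(9)
  X <- matrix(rnorm(600), 300, 2, dimnames = list(NULL, c("M1", "M2")))
  tab <- cluster_cells(table_from_matrix(X), seed = 1)
  expect_gte(max(table(tab$cluster)) / nrow(tab), 0.9)
})

test_that("degenerate and undersized inputs are handled", {
  X <- matrix(1, 40, 2, dimnames = list(NULL, c("M1", "M2")))
  expect_warning(tab <- cluster_cells(table_from_matrix(X), k_neighbors = 5),
                 "identical")
  expect_true(all(tab$cluster == 1L))
  X2 <- matrix(rnorm(30), 15, 2, dimnames = list(NULL, c("M1", "M2")))
  expect_error(cluster_cells(table_from_matrix(X2), k_neighbors = 15),
               "k_neighbors")
})

test_that("median ARI across seeds stays high on the 3-population benchmark", {
  ari <- vapply(1:20, function(s) {
    d <- three_pop_data(seed = s)
    tab <- cluster_cells(table_from_matrix(d$X), k_neighbors = 15, seed = 1)
    mclust::adjustedRandIndex(tab$cluster, d$truth)
  }, numeric(1))
  expect_gte(median(ari), 0.9)
})

test_that("phenotype rules name clusters by marker positivity", {
  means <- matrix(c(5, 0, 0,   0, 5, 0,   0, 0, 0),
                  3, 3, byrow = TRUE,
                  dimnames = list(1:3, c("IBA1_t", "APOE_t", "GFAP_t")))
  cs <- structure(list(means = means, sizes = c(`1` = 10L, `2` = 10L, `3` = 10L),
                       modularity = 0.5), class = "cluster_summary")
  ph <- assign_phenotypes(cs, list(
    "DAM-like" = c("IBA1+"),
    "astro" = c("APOE+", "IBA1-"),
    "rest" = c("IBA1-", "APOE-")))
  expect_equal(ph$phenotype, c("DAM-like", "astro", "rest"))
  # identical cluster means -> nothing is positive -> all unassigned
  flat <- structure(list(means = matrix(1, 3, 2,
                                        dimnames = list(1:3, c("A", "B"))),
                         sizes = c(`1` = 5L, `2` = 5L, `3` = 5L),
                         modularity = 0), class = "cluster_summary")
  ph2 <- assign_phenotypes(flat, list(x = c("A+")))
  expect_true(all(ph2$phenotype == "unassigned"))
  expect_error(assign_phenotypes(cs, list(x = c("NOPE+"))), "unknown marker")
})

test_that("generator-assigned phenotypes are recovered end to end", {
  set.seed(12)
  n_per <- 100
  X <- rbind(
    cbind(IBA1 = rnorm(n_per, 8), APOE = rnorm(n_per, 8), GFAP = rnorm(n_per, 0)),
    cbind(IBA1 = rnorm(n_per, 0), APOE = rnorm(n_per, 0), GFAP = rnorm(n_per, 8)),
    cbind(IBA1 = rnorm(n_per, 0), APOE = rnorm(n_per, 0), GFAP = rnorm(n_per, 0)))
  truth <- rep(c("DAM-like", "activated-astro", "homeostatic"), each = n_per)
  tab <- cluster_cells(table_from_matrix(X), seed = 2)
  cs <- cluster_summary(tab)
  ph <- assign_phenotypes(cs, list(
    "DAM-like" = c("IBA1+", "APOE+", "GFAP-"),
    "activated-astro" = c("GFAP+", "IBA1-"),
    "homeostatic" = c("IBA1-", "APOE-", "GFAP-")))
  # majority phenotype of each cluster matches its dominant true label
  for (i in seq_len(nrow(ph))) {
    sel <- tab$cluster == as.integer(ph$cluster[i])
    expect_equal(ph$phenotype[i], names(which.max(table(truth[sel]))))
  }
})
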