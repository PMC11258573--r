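# Shared fixtures: small synthetic scenes and geometric constructions used
# across the unit and acceptance tests. Everything is generated in code.

# pathology-only scene: plaques with an exponential oligomer halo
halo_scene <- function(seed = 1, tau = 30, n_plaques = 3L, side = 200L,
                       radius = c(8, 12), noise = noise_config(2, 2, 1)) {
  scene_config(width_px = side, height_px = side, n_plaques = n_plaques,
               plaque_radius_um = radius, oligomer_halo_tau_um = tau,
               diffuse_oligomer_fraction = 0, n_nuclei = 0L,
               noise = noise, seed = seed)
}

# nuclei-only scene for segmentation counting (45 nuclei on 0.09 mm^2 = 500/mm^2)
nuclei_scene <- function(seed = 1, n_nuclei = 45L, side = 300L) {
  scene_config(width_px = side, height_px = side, n_plaques = 0L,
               diffuse_oligomer_fraction = 0, n_nuclei = n_nuclei,
               nucleus_radius_um = 3, noise = noise_config(1, 1, 1),
               seed = seed)
}

# compact-object scene for classifier accuracy (no thin processes)
classifier_scene <- function(seed = 11, noise = noise_config(2, 17, 1)) {
  scene_config(width_px = 192L, height_px = 192L, n_plaques = 3L,
               plaque_radius_um = c(9, 12), oligomer_halo_tau_um = 5,
               halo_reach_um = 1e-6, diffuse_oligomer_fraction = 0,
               n_nuclei = 15L,
               cell_specs = list(cell_spec("IBA1", 8L, soma_radius_um = 5,
                                           n_processes = 0L,
                                           attraction_weight = 0.5)),
               noise = noise, seed = seed)
}

# circular ROI label image for the ring-geometry oracle
circle_roi <- function(side = 260L, radius = 30) {
  roi <- matrix(0L, side, side)
  ctr <- (side + 1) / 2
  for (i in seq_len(side)) {
    dr2 <- (i - ctr)^2
    cols <- which(dr2 + (seq_len(side) - ctr)^2 <= radius^2)
    roi[i, cols] <- 1L
  }
  roi
}

# label image with cells on a grid plus painted per-cell marker values
grid_cells <- function(n_r = 10, n_c = 10, spacing = 12, radius = 3,
                       values = NULL) {
  side_r <- (n_r + 1) * spacing
  side_c <- (n_c + 1) * spacing
  labs <- matrix(0L, side_r, side_c)
  k <- 0L
  for (i in seq_len(n_r)) {
    for (j in seq_len(n_c)) {
      k <- k + 1L
      ri <- i * spacing
      cj <- j * spacing
      for (dr in -radius:radius) {
        dc <- floor(sqrt(radius^2 - dr^2))
        labs[ri + dr, (cj - dc):(cj + dc)] <- k
      }
    }
  }
  labs
}

paint_cells <- function(labs, values) {
  out <- matrix(0, nrow(labs), ncol(labs))
  sel <- labs > 0L
  out[sel] <- values[labs[sel]]
  out
}

# synthetic cell table from a plain matrix of marker values
table_from_matrix <- function(X, markers = colnames(X)) {
  if (is.null(markers)) markers <- paste0("M", seq_len(ncol(X)))
  df <- data.frame(id = seq_len(nrow(X)), image = "img1", x_um = 0,
                   y_um = 0, area_um2 = 10)
  for (i in seq_along(markers)) df[[markers[i]]] <- X[, i]
  structure(df, class = c("cell_table", "data.frame"), markers = markers,
            pixel_size_um = 1)
}

# 3 well-separated Gaussian populations (5 sigma offsets per marker)
three_pop_data <- function(seed, n = 300L, delta = 5) {
  set.seed(seed)
  mu <- matrix(c(0, 0, delta, 0, 0, delta), 3, 2, byrow = TRUE)
  g <- sample(1:3, n, replace = TRUE)
  X <- mu[g, ] + matrix(stats::rnorm(2 * n), n, 2)
  colnames(X) <- c("M1", "M2")
  list(X = X, truth = g)
}

expect_dense_labels <- function(labels) {
  u <- sort(unique(labels[labels > 0]))
  expect_identical(as.integer(u), seq_len(length(u)))
}
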