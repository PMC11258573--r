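#' Generate amyloid pathology channels with exhaustive ground truth
#'
#' Renders the pathology layers of a synthetic scene: `n_plaques` compact
#' plaque-like deposits (discs with a smooth +/-20% angular boundary
#' perturbation, mutually disjoint), an oligomer halo whose noiseless
#' intensity at distance d from the nearest plaque edge is
#' `I0 * exp(-d / tau)` (truncated at `halo_reach_um`), a diffuse oligomer
#' component covering `diffuse_oligomer_fraction` of the plaque-free area,
#' and nuclei scattered by a hard-core point process. All randomness derives
#' from `config$seed`.
#'
#' @param config a [scene_config()].
#' @return list with elements `stack` (a [channel_stack()] with channels
#'   `plaque`, `oligomer`, `nuclei`) and `truth` (a `ground_truth` list with
#'   plaque label image and mask, oligomer/diffuse masks, the noiseless halo,
#'   nucleus centres and label image, the pathology-object mask used for cell
#'   attraction, and a config echo).
#' @export
generate_pathology <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  validate_scene_config(config)
  set.seed(config$seed)
  nr <- config$height_px
  nc <- config$width_px
  px <- config$pixel_size_um

  plaque_labels <- matrix(0L, nr, nc)
  plaque_mask <- matrix(FALSE, nr, nc)
  max_retry <- 10000L
  for (k in seq_len(config$n_plaques)) {
    placed <- FALSE
    for (try in seq_len(max_retry)) {
      r_um <- stats::runif(1, config$plaque_radius_um[1], config$plaque_radius_um[2])
      r_px <- r_um / px
      amp <- stats::runif(1, 0, 0.2)
      ph <- stats::runif(2, 0, 2 * pi)
      wts <- stats::runif(2, 0.3, 1)
      margin <- r_px * 1.25 + 1
      if (2 * margin >= min(nr, nc)) {
        stop_infeasible("plaque radius too large for the image")
      }
      cr <- stats::runif(1, margin, nr - margin)
      cc <- stats::runif(1, margin, nc - margin)
      m <- render_blob(nr, nc, cr, cc, r_px, amp, ph, wts)
      # require a 1-px gap to previously placed plaques so labels stay distinct
      if (!any(m & plaque_mask) && min_gap_ok(m, plaque_mask)) {
        plaque_mask <- plaque_mask | m
        plaque_labels[m] <- k
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop_infeasible(sprintf("could not place plaque %d without overlap", k))
    }
  }

  plaque_ch <- matrix(0, nr, nc)
  plaque_ch[plaque_mask] <- config$plaque_intensity

  d_um <- dist_to_mask(plaque_mask) * px
  halo <- matrix(0, nr, nc)
  if (config$n_plaques > 0L) {
    halo <- config$oligomer_peak_intensity * exp(-d_um / config$oligomer_halo_tau_um)
    halo[d_um > config$halo_reach_um] <- 0
  }

  diffuse_mask <- matrix(FALSE, nr, nc)
  if (config$diffuse_oligomer_fraction > 0) {
    free <- !plaque_mask
    target <- round(config$diffuse_oligomer_fraction * sum(free))
    free_idx <- which(free)
    guard <- 0L
    while (sum(diffuse_mask) < target && guard < 100000L) {
      guard <- guard + 1L
      ctr <- free_idx[sample.int(length(free_idx), 1L)]
      rr <- ((ctr - 1L) %% nr) + 1L
      cc2 <- ((ctr - 1L) %/% nr) + 1L
      rad <- stats::runif(1, 1, 3) / px
      diffuse_mask <- diffuse_mask | (disc_mask(nr, nc, rr, cc2, rad) & free)
    }
  }
  oligomer_ch <- halo
  oligomer_ch[diffuse_mask] <- pmax(oligomer_ch[diffuse_mask],
                                    0.5 * config$oligomer_peak_intensity)

  # nuclei: hard-core process (centre separation >= 2r + 1 px)
  nuc_r_px <- config$nucleus_radius_um / px
  nuc_centres <- matrix(numeric(0), 0, 2)
  nuclei_labels <- matrix(0L, nr, nc)
  nuclei_ch <- matrix(0, nr, nc)
  for (k in seq_len(config$n_nuclei)) {
    placed <- FALSE
    for (try in seq_len(max_retry)) {
      cr <- stats::runif(1, nuc_r_px + 1, nr - nuc_r_px - 1)
      cc2 <- stats::runif(1, nuc_r_px + 1, nc - nuc_r_px - 1)
      if (nrow(nuc_centres) > 0) {
        dd <- sqrt((nuc_centres[, 1] - cr)^2 + (nuc_centres[, 2] - cc2)^2)
        if (min(dd) < 2 * nuc_r_px + 1) next
      }
      nuc_centres <- rbind(nuc_centres, c(cr, cc2))
      m <- disc_mask(nr, nc, cr, cc2, nuc_r_px)
      nuclei_labels[m] <- k
      nuclei_ch[m] <- config$nuclei_intensity
      placed <- TRUE
      break
    }
    if (!placed) stop_infeasible(sprintf("could not place nucleus %d (hard core)", k))
  }

  stack <- channel_stack(list(plaque = plaque_ch, oligomer = oligomer_ch,
                              nuclei = nuclei_ch), pixel_size_um = px)
  truth <- structure(list(
    plaque_labels = plaque_labels,
    plaque_mask = plaque_mask,
    halo = halo,
    diffuse_mask = diffuse_mask,
    oligomer_mask = oligomer_ch > 0,
    nuclei_centres = data.frame(
      id = seq_len(nrow(nuc_centres)),
      y_px0 = if (nrow(nuc_centres)) nuc_centres[, 1] - 1 else numeric(0),
      x_px0 = if (nrow(nuc_centres)) nuc_centres[, 2] - 1 else numeric(0)),
    nuclei_labels = nuclei_labels,
    pathology_mask = plaque_mask | diffuse_mask,
    cells = NULL, soma_labels = NULL,
    config = config), class = "ground_truth")
  list(stack = stack, truth = truth)
}

# blob boundary r(theta) = r0 * (1 + amp * p(theta)) with p a smooth
# two-harmonic perturbation normalised to max |p| = 1
render_blob <- function(nr, nc, cr, cc, r_px, amp, ph, wts) {
  rmax <- r_px * (1 + amp)
  r0 <- max(1L, floor(cr - rmax)); r1 <- min(nr, ceiling(cr + rmax))
  c0 <- max(1L, floor(cc - rmax)); c1 <- min(nc, ceiling(cc + rmax))
  rows <- r0:r1; cols <- c0:c1
  dr <- outer(rows - cr, rep(1, length(cols)))
  dc <- outer(rep(1, length(rows)), cols - cc)
  dd <- sqrt(dr * dr + dc * dc)
  th <- atan2(dr, dc)
  p <- wts[1] * sin(2 * th + ph[1]) + wts[2] * sin(3 * th + ph[2])
  p <- p / max(sum(abs(wts)), 1e-9)
  out <- matrix(FALSE, nr, nc)
  out[rows, cols] <- dd <= r_px * (1 + amp * p)
  out
}

# TRUE when mask m keeps at least a 1-px 8-neighbour gap from `other`
min_gap_ok <- function(m, other) {
  if (!any(other)) return(TRUE)
  idx <- which(m)
  nr <- nrow(m)
  for (d in c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)) {
    nb <- idx + d
    nb <- nb[nb >= 1L & nb <= length(m)]
    if (any(other[nb])) return(FALSE)
  }
  TRUE
}

#' Place marker-specific cells with distance-dependent pathology attraction
#'
#' Cell centroids for each [cell_spec()] are sampled from the pixel density
#' `lambda(d) = w * exp(-d / tau) + (1 - w)` where d is the distance (um) to
#' the nearest pathology object (plaques plus diffuse oligomer deposits).
#' Somata are hard-core (no overlap between any two cells); each cell is
#' rendered as a soma disc plus `n_processes` random-walk polylines. With no
#' pathology in the scene the density falls back to uniform.
#'
#' @param config a [scene_config()].
#' @param truth the `ground_truth` returned by [generate_pathology()].
#' @return list(stack, truth): `stack` holds one channel per marker;
#'   `truth` is the input ground truth extended with a `cells` data frame
#'   (marker, id, 0-based centroid pixel and um coordinates, soma radius and
#'   pixel-exact area, distance to nearest pathology) and a global
#'   `soma_labels` image (labels follow `cells$id`).
#' @export
place_cells <- function(config, truth) {
  stopifnot(inherits(config, "scene_config"), inherits(truth, "ground_truth"))
  set.seed(config$seed + 1L)
  nr <- config$height_px
  nc <- config$width_px
  px <- config$pixel_size_um
  d_um <- dist_to_mask(truth$pathology_mask) * px
  has_pathology <- any(truth$pathology_mask)

  channels <- list()
  cells <- list()
  soma_labels <- matrix(0L, nr, nc)
  placed_r <- numeric(0)  # soma radii (px) of placed cells, across markers
  placed_pos <- matrix(numeric(0), 0, 2)
  next_id <- 1L
  max_retry <- 10000L

  for (spec in config$cell_specs) {
    ch <- matrix(0, nr, nc)
    r_px <- spec$soma_radius_um / px
    w <- spec$attraction_weight
    lam <- if (has_pathology) {
      w * exp(-d_um / spec$attraction_tau_um) + (1 - w)
    } else {
      matrix(1, nr, nc)
    }
    # keep somata fully inside the image
    margin <- ceiling(r_px) + 1
    ok <- matrix(FALSE, nr, nc)
    if (nr - margin >= margin && nc - margin >= margin) {
      ok[margin:(nr - margin), margin:(nc - margin)] <- TRUE
    }
    lam[!ok] <- 0
    if (spec$n_cells > 0L && sum(lam) <= 0) {
      stop_infeasible(sprintf("marker %s: no feasible placement density", spec$marker))
    }
    lam_p <- as.numeric(lam) / sum(lam)
    for (k in seq_len(spec$n_cells)) {
      placed <- FALSE
      for (try in seq_len(max_retry)) {
        pix <- sample.int(nr * nc, 1L, prob = lam_p)
        cr <- ((pix - 1L) %% nr) + 1L
        cc <- ((pix - 1L) %/% nr) + 1L
        if (nrow(placed_pos) > 0) {
          dd <- sqrt((placed_pos[, 1] - cr)^2 + (placed_pos[, 2] - cc)^2)
          if (any(dd < placed_r + r_px + 1)) next
        }
        placed_pos <- rbind(placed_pos, c(cr, cc))
        placed_r <- c(placed_r, r_px)
        soma <- disc_mask(nr, nc, cr, cc, r_px)
        soma_labels[soma] <- next_id
        ch[soma] <- pmax(ch[soma], spec$soma_intensity)
        for (p in seq_len(spec$n_processes)) {
          pts <- random_walk_process(cr, cc, r_px,
                                     spec$process_length_um / px, nr, nc)
          ch[pts] <- pmax(ch[pts], spec$process_intensity)
        }
        cells[[length(cells) + 1L]] <- data.frame(
          marker = spec$marker, id = next_id,
          y_px0 = cr - 1, x_px0 = cc - 1,
          x_um = (cc - 1) * px, y_um = (cr - 1) * px,
          soma_radius_um = spec$soma_radius_um,
          soma_area_um2 = sum(soma) * px^2,
          dist_pathology_um = d_um[cr, cc])
        next_id <- next_id + 1L
        placed <- TRUE
        break
      }
      if (!placed) {
        stop_infeasible(sprintf(
          "marker %s: cell %d unplaceable without soma overlap after %d retries",
          spec$marker, k, max_retry))
      }
    }
    channels[[spec$marker]] <- ch
  }

  truth$cells <- if (length(cells)) do.call(rbind, cells) else
    data.frame(marker = character(0), id = integer(0), y_px0 = numeric(0),
               x_px0 = numeric(0), x_um = numeric(0), y_um = numeric(0),
               soma_radius_um = numeric(0), soma_area_um2 = numeric(0),
               dist_pathology_um = numeric(0))
  truth$soma_labels <- soma_labels
  stack <- if (length(channels)) {
    channel_stack(channels, pixel_size_um = px)
  } else {
    NULL
  }
  list(stack = stack, truth = truth)
}

# persistent-heading random walk leaving the soma boundary; returns linear
# pixel indices of the drawn polyline (clipped to the image)
random_walk_process <- function(cr, cc, r_px, len_px, nr, nc) {
  n_steps <- max(0L, round(len_px))
  if (n_steps == 0L) return(integer(0))
  heading <- stats::runif(1, 0, 2 * pi)
  pos <- c(cr + r_px * sin(heading), cc + r_px * cos(heading))
  pts <- integer(n_steps)
  m <- 0L
  for (s in seq_len(n_steps)) {
    heading <- heading + stats::rnorm(1, 0, 0.25)
    pos <- pos + c(sin(heading), cos(heading))
    rr <- round(pos[1]); cc2 <- round(pos[2])
    if (rr < 1 || rr > nr || cc2 < 1 || cc2 > nc) break
    m <- m + 1L
    pts[m] <- rr + (cc2 - 1L) * nr
  }
  pts[seq_len(m)]
}

#' Apply the Poisson-plus-Gaussian noise model to a stack
#'
#' Per pixel: `Poisson(poisson_scale * I) / poisson_scale +
#' Normal(background_mean, gaussian_sd)`, clipped at 0. Deterministic given
#' `config$seed`; channels are processed in their stack order.
#'
#' @param stack a [channel_stack()] of noiseless intensities.
#' @param config a [scene_config()] (its `noise` and `seed` fields are used).
#' @return A [channel_stack()] of the same shape.
#' @export
add_noise <- function(stack, config) {
  stopifnot(inherits(stack, "channel_stack"), inherits(config, "scene_config"))
  nz <- do.call(noise_config, config$noise)  # re-validates non-negativity
  set.seed(config$seed + 2L)
  out <- stack$channels
  for (i in seq_along(out)) {
    v <- as.numeric(out[[i]])
    if (nz$poisson_scale > 0) {
      v <- stats::rpois(length(v), nz$poisson_scale * v) / nz$poisson_scale
    }
    v <- v + stats::rnorm(length(v), nz$background_mean, nz$gaussian_sd)
    v[v < 0] <- 0
    out[[i]] <- matrix(v, nrow(out[[i]]), ncol(out[[i]]))
  }
  channel_stack(out, pixel_size_um = stack$pixel_size_um)
}

#' Simulate a full synthetic scene
#'
#' Convenience wrapper running [generate_pathology()], [place_cells()] and
#' [add_noise()] and merging all channels into one stack.
#'
#' @param config a [scene_config()].
#' @return list with `clean` (noiseless [channel_stack()]), `noisy` (after
#'   [add_noise()]) and `truth` (the extended `ground_truth`).
#' @export
simulate_scene <- function(config) {
  path <- generate_pathology(config)
  cel <- place_cells(config, path$truth)
  channels <- path$stack$channels
  if (!is.null(cel$stack)) channels <- c(channels, cel$stack$channels)
  clean <- channel_stack(channels, pixel_size_um = config$pixel_size_um)
  noisy <- add_noise(clean, config)
  list(clean = clean, noisy = noisy, truth = cel$truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("ground_truth: %d plaque(s), %d nuclei, %d cell(s)\n",
              max(x$plaque_labels), max(x$nuclei_labels),
              if (is.null(x$cells)) 0L else nrow(x$cells)))
  invisible(x)
}
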