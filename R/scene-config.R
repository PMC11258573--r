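#' Scene configuration for the synthetic-tissue generator
#'
#' Describes a simulated cortical/hippocampal field at micrometre resolution:
#' compact amyloid-plaque-like deposits, an oligomer halo whose intensity
#' decays exponentially with distance from the nearest plaque edge, a diffuse
#' oligomer component, scattered nuclei, and soma-plus-process cells whose
#' placement is attracted to pathology with configurable strength.
#'
#' @param width_px,height_px image size in pixels (positive integers).
#' @param pixel_size_um physical pixel size in micrometres per pixel
#'   (default 1, the ablation resolution of imaging mass cytometry).
#' @param n_plaques number of compact plaque-like deposits.
#' @param plaque_radius_um length-2 range (min, max) of plaque radii in
#'   micrometres; each plaque draws its radius uniformly from this range and
#'   its boundary is smoothly perturbed by up to 20%.
#' @param plaque_intensity noiseless intensity rendered inside plaques.
#' @param oligomer_halo_tau_um decay length (micrometres) of the oligomer
#'   halo: noiseless intensity at distance d from the nearest plaque edge is
#'   `oligomer_peak_intensity * exp(-d / tau)`.
#' @param oligomer_peak_intensity halo intensity at the plaque edge (and
#'   inside plaques).
#' @param halo_reach_um distance beyond which the halo is truncated to zero
#'   (default `6 * oligomer_halo_tau_um`).
#' @param diffuse_oligomer_fraction fraction in \[0, 1\] of the plaque-free
#'   area covered by small diffuse oligomer deposits.
#' @param n_nuclei number of scattered nuclei (hard-core point process).
#' @param nucleus_radius_um nucleus disc radius in micrometres.
#' @param nuclei_intensity noiseless intensity of nucleus discs.
#' @param cell_specs list of [cell_spec()] entries, one per marker.
#' @param noise list as produced by [noise_config()].
#' @param seed integer seed from which all scene randomness derives.
#'
#' @return An object of class `scene_config` (a validated list).
#' @seealso [generate_pathology()], [place_cells()], [simulate_scene()]
#' @export
scene_config <- function(width_px = 256L, height_px = 256L, pixel_size_um = 1,
                         n_plaques = 5L, plaque_radius_um = c(8, 15),
                         plaque_intensity = 100,
                         oligomer_halo_tau_um = 30,
                         oligomer_peak_intensity = 100,
                         halo_reach_um = 6 * oligomer_halo_tau_um,
                         diffuse_oligomer_fraction = 0.05,
                         n_nuclei = 50L, nucleus_radius_um = 3,
                         nuclei_intensity = 100,
                         cell_specs = list(),
                         noise = noise_config(),
                         seed = 1L) {
  cfg <- list(width_px = as.integer(width_px), height_px = as.integer(height_px),
              pixel_size_um = pixel_size_um,
              n_plaques = as.integer(n_plaques),
              plaque_radius_um = sort(plaque_radius_um),
              plaque_intensity = plaque_intensity,
              oligomer_halo_tau_um = oligomer_halo_tau_um,
              oligomer_peak_intensity = oligomer_peak_intensity,
              halo_reach_um = halo_reach_um,
              diffuse_oligomer_fraction = diffuse_oligomer_fraction,
              n_nuclei = as.integer(n_nuclei),
              nucleus_radius_um = nucleus_radius_um,
              nuclei_intensity = nuclei_intensity,
              cell_specs = cell_specs,
              noise = noise,
              seed = as.integer(seed))
  class(cfg) <- "scene_config"
  validate_scene_config(cfg)
  cfg
}

#' Marker-specific cell population specification
#'
#' @param marker channel name for this population (must be unique in a scene
#'   and not one of the reserved names "plaque", "oligomer", "nuclei").
#' @param n_cells number of cells to place (realised exactly or an
#'   infeasible-scene error is raised).
#' @param soma_radius_um soma disc radius in micrometres.
#' @param n_processes number of process polylines per cell.
#' @param process_length_um length of each process in micrometres.
#' @param attraction_weight mixing weight w in \[0, 1\] of the pathology
#'   attraction: placement density is proportional to
#'   `w * exp(-d / attraction_tau_um) + (1 - w)` where d is the distance to
#'   the nearest pathology object. w = 0 gives complete spatial randomness,
#'   w = 1 strong clustering around pathology.
#' @param attraction_tau_um attraction decay length in micrometres.
#' @param soma_intensity,process_intensity noiseless rendered intensities.
#' @return A list of class `cell_spec`.
#' @export
cell_spec <- function(marker, n_cells, soma_radius_um = 5, n_processes = 3L,
                      process_length_um = 15, attraction_weight = 0.5,
                      attraction_tau_um = 30, soma_intensity = 100,
                      process_intensity = 60) {
  stopifnot(is.character(marker), length(marker) == 1L, nzchar(marker),
            n_cells >= 0, soma_radius_um > 0, n_processes >= 0,
            process_length_um >= 0, attraction_tau_um > 0,
            soma_intensity >= 0, process_intensity >= 0)
  if (attraction_weight < 0 || attraction_weight > 1) {
    stop("attraction_weight must be in [0, 1]")
  }
  structure(list(marker = marker, n_cells = as.integer(n_cells),
                 soma_radius_um = soma_radius_um,
                 n_processes = as.integer(n_processes),
                 process_length_um = process_length_um,
                 attraction_weight = attraction_weight,
                 attraction_tau_um = attraction_tau_um,
                 soma_intensity = soma_intensity,
                 process_intensity = process_intensity),
            class = "cell_spec")
}

#' Noise model parameters
#'
#' Per pixel the noisy value is
#' `Poisson(poisson_scale * I) / poisson_scale + Normal(background_mean,
#' gaussian_sd)`, clipped at 0. `poisson_scale = 0` disables shot noise.
#'
#' @param background_mean additive background level.
#' @param gaussian_sd standard deviation of the additive Gaussian read noise.
#' @param poisson_scale scaling of the Poisson (shot-noise) component;
#'   larger values mean relatively less shot noise.
#' @return A named list.
#' @export
noise_config <- function(background_mean = 2, gaussian_sd = 1,
                         poisson_scale = 1) {
  if (background_mean < 0 || gaussian_sd < 0 || poisson_scale < 0) {
    stop("noise parameters must be non-negative")
  }
  list(background_mean = background_mean, gaussian_sd = gaussian_sd,
       poisson_scale = poisson_scale)
}

validate_scene_config <- function(cfg) {
  stopifnot(cfg$width_px >= 8L, cfg$height_px >= 8L, cfg$pixel_size_um > 0,
            cfg$n_plaques >= 0L, length(cfg$plaque_radius_um) == 2L,
            all(cfg$plaque_radius_um > 0), cfg$oligomer_halo_tau_um > 0,
            cfg$halo_reach_um > 0, cfg$n_nuclei >= 0L,
            cfg$nucleus_radius_um > 0)
  if (cfg$diffuse_oligomer_fraction < 0 || cfg$diffuse_oligomer_fraction > 1) {
    stop("diffuse_oligomer_fraction must be in [0, 1]")
  }
  cfg$noise <- do.call(noise_config, cfg$noise)
  markers <- vapply(cfg$cell_specs, function(s) s$marker, character(1))
  if (anyDuplicated(markers)) stop("cell_specs markers must be unique")
  if (any(markers %in% c("plaque", "oligomer", "nuclei"))) {
    stop("cell marker names \"plaque\", \"oligomer\", \"nuclei\" are reserved")
  }
  for (s in cfg$cell_specs) {
    if (!inherits(s, "cell_spec")) stop("cell_specs must be built with cell_spec()")
  }
  # coarse physical feasibility: configured object area must fit the image
  px <- cfg$pixel_size_um
  area_um2 <- cfg$width_px * cfg$height_px * px^2
  obj <- cfg$n_plaques * pi * mean(cfg$plaque_radius_um)^2 +
    cfg$n_nuclei * pi * cfg$nucleus_radius_um^2 +
    sum(vapply(cfg$cell_specs,
               function(s) s$n_cells * pi * s$soma_radius_um^2, numeric(1)))
  if (obj > area_um2) {
    stop_infeasible(sprintf(
      "configured object area (%.0f um^2) exceeds image area (%.0f um^2)",
      obj, area_um2))
  }
  invisible(cfg)
}

#' @export
print.scene_config <- function(x, ...) {
  cat(sprintf("scene_config: %d x %d px @ %g um/px, seed %d\n",
              x$width_px, x$height_px, x$pixel_size_um, x$seed))
  cat(sprintf("  %d plaques (r %g-%g um), halo tau %g um, diffuse %.0f%%, %d nuclei\n",
              x$n_plaques, x$plaque_radius_um[1], x$plaque_radius_um[2],
              x$oligomer_halo_tau_um, 100 * x$diffuse_oligomer_fraction,
              x$n_nuclei))
  for (s in x$cell_specs) {
    cat(sprintf("  marker %s: %d cells, soma r %g um, %d processes x %g um, w=%.2f tau=%g um\n",
                s$marker, s$n_cells, s$soma_radius_um, s$n_processes,
                s$process_length_um, s$attraction_weight, s$attraction_tau_um))
  }
  invisible(x)
}
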