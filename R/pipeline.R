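#' Pipeline configuration
#'
#' Bundles the per-stage parameters of the end-to-end run. The default demo
#' scene is a 256 x 256 px field at 1 um/px with 5 plaques and three cell
#' markers of graded pathology attraction.
#'
#' @param scene a [scene_config()].
#' @param segmentation a [segmentation_params()].
#' @param sholl a [sholl_config()].
#' @param expansion_px cell-mask expansion for the correlation stage.
#' @param k_neighbors clustering neighbourhood size.
#' @param n_training_px_per_class training pixels per class for the pixel
#'   classifier.
#' @param phenotype_rules optional rules list for [assign_phenotypes()].
#' @param seed master seed; every stage derives its randomness from it.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(scene = demo_scene(),
                            segmentation = segmentation_params(),
                            sholl = sholl_config(),
                            expansion_px = 4,
                            k_neighbors = 15L,
                            n_training_px_per_class = 833L,
                            phenotype_rules = NULL,
                            seed = 1L) {
  stopifnot(inherits(scene, "scene_config"),
            inherits(segmentation, "segmentation_params"),
            inherits(sholl, "sholl_config"))
  structure(list(scene = scene, segmentation = segmentation, sholl = sholl,
                 expansion_px = expansion_px, k_neighbors = k_neighbors,
                 n_training_px_per_class = as.integer(n_training_px_per_class),
                 phenotype_rules = phenotype_rules,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @export
demo_scene <- function(seed = 1L) {
  scene_config(
    width_px = 256L, height_px = 256L, pixel_size_um = 1,
    n_plaques = 5L, plaque_radius_um = c(8, 14),
    oligomer_halo_tau_um = 30, diffuse_oligomer_fraction = 0.03,
    n_nuclei = 40L,
    cell_specs = list(
      cell_spec("IBA1", 20L, soma_radius_um = 4, attraction_weight = 0.9,
                attraction_tau_um = 30),
      cell_spec("GFAP", 15L, soma_radius_um = 5, attraction_weight = 0.5,
                attraction_tau_um = 60),
      cell_spec("NEUN", 25L, soma_radius_um = 5, n_processes = 1L,
                attraction_weight = 0.1, attraction_tau_um = 100)),
    noise = noise_config(background_mean = 2, gaussian_sd = 2,
                         poisson_scale = 1),
    seed = seed)
}

#' Run the full analysis pipeline on a synthetic scene
#'
#' Executes simulate, classify, segment, quantify, Sholl, correlate,
#' cluster and stats in order, writing every artefact (TIFF images, label
#' masks, full-precision CSV tables) plus a run manifest into `out_dir`.
#' Re-running with the same configuration reproduces bit-identical label
#' images and CSVs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created; an `images/`, `labels/` and
#'   `tables/` subtree plus `manifest.yaml`).
#' @param seed overrides `config$seed` when given.
#' @return list of in-memory stage results, invisibly; the manifest records
#'   package version, seeds, per-stage parameters, timings and MD5 hashes
#'   of every written file.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, seed = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!is.null(seed)) {
    config$seed <- as.integer(seed)
    config$scene$seed <- as.integer(seed)
  } else {
    config$scene$seed <- config$seed
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (d in c("images", "labels", "tables")) {
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  }
  timings <- list()
  tic <- function() proc.time()[["elapsed"]]
  res <- list()

  t0 <- tic()
  sim <- simulate_scene(config$scene)
  write_stack(sim$noisy, file.path(out_dir, "images", "stack.tiff"))
  write_stack(sim$clean, file.path(out_dir, "images", "clean.tiff"))
  write_label_image(new_label_image(sim$truth$plaque_labels,
                                    config$scene$pixel_size_um),
                    file.path(out_dir, "labels", "true_plaques.tiff"))
  write_csv_full(sim$truth$cells, file.path(out_dir, "tables", "true_cells.csv"))
  res$scene <- sim
  timings$simulate <- tic() - t0

  t0 <- tic()
  feats <- extract_features(sim$noisy, feature_config())
  ann <- annotation_from_truth(sim$truth, sim$clean,
                               n_per_class = config$n_training_px_per_class,
                               seed = config$seed + 10L)
  model <- train_pixel_classifier(feats, ann, seed = config$seed + 11L)
  probs <- predict_probabilities(model, feats)
  res$probs <- probs
  timings$classify <- tic() - t0

  t0 <- tic()
  px <- config$scene$pixel_size_um
  primary <- identify_primary(probs$nuclei, config$segmentation, px)
  secondary <- identify_secondary(primary, probs$signal, config$segmentation)
  tertiary <- identify_tertiary(secondary, primary)
  write_label_image(primary, file.path(out_dir, "labels", "primary.tiff"))
  write_label_image(secondary, file.path(out_dir, "labels", "secondary.tiff"))
  write_label_image(tertiary, file.path(out_dir, "labels", "tertiary.tiff"))
  res$segmentation <- list(primary = primary, secondary = secondary,
                           tertiary = tertiary)
  timings$segment <- tic() - t0

  t0 <- tic()
  area_mm2 <- nrow(primary) * ncol(primary) * px^2 / 1e6
  marker_names <- vapply(config$scene$cell_specs, function(s) s$marker,
                         character(1))
  load_df <- do.call(rbind, lapply(c("plaque", "oligomer", marker_names),
    function(m) {
      od <- suppressWarnings(optical_density(sim$noisy[[m]]))
      data.frame(marker = m,
                 area_fraction_pct = area_fraction(sim$noisy[[m]], "otsu"),
                 mean_od = as.numeric(od),
                 od_clipped_px = attr(od, "n_clipped"),
                 region_area_mm2 = area_mm2)
    }))
  dens <- cell_density(unclass_label(primary), area_mm2)
  load_df$primary_density_per_mm2 <- dens
  write_csv_full(load_df, file.path(out_dir, "tables", "marker_load.csv"))
  morph <- perisomatic_morphometry(primary, sim$noisy[[marker_names[1]]],
                                   radius_um = 10)
  write_csv_full(as.data.frame(morph),
                 file.path(out_dir, "tables", "morphometry.csv"))
  res$quantification <- list(load = load_df, morphometry = morph,
                             density_per_mm2 = dens)
  timings$quantify <- tic() - t0

  t0 <- tic()
  plaque_rois <- label_components(sim$noisy$channels$plaque >=
                                    otsu_threshold(sim$noisy$channels$plaque),
                                  connectivity = 4L)
  sholl_res <- NULL
  if (max(plaque_rois) > 0) {
    rings <- build_rings(plaque_rois, config$sholl, px)
    profs <- lapply(c("oligomer", marker_names), function(m) {
      ring_coverage(rings, sim$noisy[[m]], threshold = "otsu")
    })
    names(profs) <- c("oligomer", marker_names)
    for (m in names(profs)) {
      write_sholl_profile(profs[[m]],
                          file.path(out_dir, "tables",
                                    sprintf("sholl_%s.csv", m)))
    }
    sholl_res <- profs
  }
  res$sholl <- sholl_res
  timings$sholl <- tic() - t0

  t0 <- tic()
  marker_stack <- channel_stack(sim$noisy$channels[marker_names],
                                pixel_size_um = px)
  corr <- NULL
  if (attr(secondary, "n_objects") >= 3L) {
    corr <- cell_marker_correlation(secondary, marker_stack,
                                    expansion_px = config$expansion_px)
    write_correlation_matrix(corr,
                             file.path(out_dir, "tables", "correlation.csv"))
  }
  res$correlation <- corr
  timings$correlate <- tic() - t0

  t0 <- tic()
  ct <- build_cell_table(secondary, marker_stack)
  clustered <- NULL
  if (nrow(ct) > config$k_neighbors) {
    ct <- transform_intensities(ct, "arcsinh")
    clustered <- cluster_cells(ct, k_neighbors = config$k_neighbors,
                               seed = config$seed + 20L)
    write_cell_table(clustered, file.path(out_dir, "tables", "cells.csv"))
    cs <- cluster_summary(clustered)
    write_csv_full(data.frame(cluster = rownames(cs$means),
                              size = as.integer(cs$sizes),
                              round(cs$means, 9)),
                   file.path(out_dir, "tables", "clusters.csv"))
    if (!is.null(config$phenotype_rules)) {
      write_csv_full(assign_phenotypes(cs, config$phenotype_rules),
                     file.path(out_dir, "tables", "phenotypes.csv"))
    }
    res$clusters <- list(table = clustered, summary = cs)
  } else {
    write_cell_table(ct, file.path(out_dir, "tables", "cells.csv"))
    res$clusters <- list(table = ct, summary = NULL)
  }
  timings$cluster <- tic() - t0

  t0 <- tic()
  stats_written <- FALSE
  if (!is.null(res$clusters$summary)) {
    tab <- res$clusters$table
    ok_clusters <- names(which(base::table(tab$cluster) >= 2L))
    sub <- tab[tab$cluster %in% ok_clusters, ]
    if (length(ok_clusters) >= 2L) {
      a <- one_way_anova(split(sub$area_um2, sub$cluster))
      write_anova_result(a, file.path(out_dir, "tables", "anova_area.csv"))
      res$stats <- a
      stats_written <- TRUE
    }
  }
  timings$stats <- tic() - t0

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.yaml"]
  hashes <- as.list(tools::md5sum(files))
  names(hashes) <- sub(paste0("^", gsub("([[:punct:]])", "\\\\\\1", out_dir), "/?"),
                       "", names(hashes))
  manifest <- list(
    tool = "neuroprox",
    version = as.character(utils::packageVersion("neuroprox")),
    seed = config$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    parameters = list(
      scene = config$scene[setdiff(names(config$scene), "cell_specs")],
      cell_specs = lapply(config$scene$cell_specs, unclass),
      segmentation = unclass(config$segmentation),
      sholl = unclass(config$sholl),
      expansion_px = config$expansion_px,
      k_neighbors = config$k_neighbors),
    timings_s = lapply(timings, round, 3),
    stats_stage_ran = stats_written,
    file_md5 = hashes)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  res$manifest <- manifest
  invisible(res)
}
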