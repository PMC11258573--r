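#' Marker area fraction within a region
#'
#' Percentage of region pixels at or above a threshold — the "relative area
#' (%) occupied" measure used for amyloid load.
#'
#' @param raster numeric matrix.
#' @param threshold numeric threshold, `"otsu"`, or NULL for strictly
#'   positive pixels.
#' @param region_mask optional logical matrix restricting the measurement;
#'   default is the whole image.
#' @return percentage in \[0, 100\].
#' @export
area_fraction <- function(raster, threshold, region_mask = NULL) {
  if (is.null(region_mask)) region_mask <- matrix(TRUE, nrow(raster), ncol(raster))
  stopifnot(identical(dim(raster), dim(region_mask)))
  n <- sum(region_mask)
  if (n == 0L) stop("degenerate region: the region mask is empty")
  thr <- resolve_threshold(threshold, raster[region_mask])
  100 * sum(raster[region_mask] >= thr) / n
}

#' Mean optical density of a chromogenic stain
#'
#' Beer-Lambert optical density `-log10(I / I0)` averaged over a region.
#' `I0` defaults to the 99th-percentile intensity of the region (a robust
#' per-image background estimate). Intensities are clipped to
#' `[I0 * 1e-3, I0]`, so per-pixel OD lies in \[0, 3\]; the number of
#' clipped pixels is reported as attribute `n_clipped` with a warning when
#' the lower floor is hit.
#'
#' @param raster numeric matrix of intensities.
#' @param region_mask optional logical matrix (default whole image).
#' @param I0 reference (background) intensity; must be > 0.
#' @return mean OD (numeric scalar with attribute `n_clipped`).
#' @export
optical_density <- function(raster, region_mask = NULL, I0 = NULL) {
  if (is.null(region_mask)) region_mask <- matrix(TRUE, nrow(raster), ncol(raster))
  stopifnot(identical(dim(raster), dim(region_mask)))
  v <- raster[region_mask]
  if (length(v) == 0L) stop("degenerate region: the region mask is empty")
  if (is.null(I0)) I0 <- stats::quantile(v, 0.99, names = FALSE)
  if (!is.finite(I0) || I0 <= 0) stop("I0 must be a positive number")
  floor_i <- I0 * 1e-3
  n_low <- sum(v < floor_i)
  if (n_low > 0) {
    warning(sprintf("%d pixel(s) below the OD intensity floor (I0 * 1e-3) were clipped",
                    n_low))
  }
  v <- pmin(pmax(v, floor_i), I0)
  out <- mean(-log10(v / I0))
  attr(out, "n_clipped") <- n_low
  out
}

#' Cell density per square millimetre
#'
#' Density is calculated as cell count / area.
#'
#' @param cells a label matrix (count = number of distinct labels) or a
#'   single count.
#' @param region_area_mm2 region area in mm^2 (> 0).
#' @return cells per mm^2.
#' @export
cell_density <- function(cells, region_area_mm2) {
  if (region_area_mm2 <= 0) stop("region area must be positive")
  count <- if (is.matrix(cells)) length(unique(cells[cells > 0])) else as.numeric(cells)
  count / region_area_mm2
}

#' Perisomatic process morphometry
#'
#' For every soma, measures marker-positive process area and skeletonised
#' process length within an annulus extending `radius_um` (default 10 um)
#' outward from the soma boundary. Annulus pixels contested between somata
#' are assigned to the nearer soma (exact Euclidean distance, ties to the
#' lower label). Marker-positive fragments not reaching any soma's annulus
#' are excluded from all cells and reported via attribute
#' `excluded_fragments` (count of 4-connected positive components fully
#' outside all annuli and somata).
#'
#' Skeleton length uses the chain-code definition: orthogonally adjacent
#' skeleton pixels contribute 1 px and diagonal pairs sqrt(2) px, times the
#' pixel size.
#'
#' @param soma_labels `label_image` (or integer matrix) of somata.
#' @param marker_raster co-registered marker intensity matrix.
#' @param radius_um perisomatic annulus depth in micrometres.
#' @param threshold positive-marker threshold (numeric, `"otsu"`, or NULL
#'   for strictly positive pixels).
#' @param pixel_size_um pixel size; defaults to the label image's attribute.
#' @return data frame of class `morphometry` with one row per cell:
#'   `cell_id`, `soma_area_um2`, `process_length_um`, `process_area_um2`,
#'   `perisomatic_radius_um`.
#' @export
perisomatic_morphometry <- function(soma_labels, marker_raster, radius_um = 10,
                                    threshold = "otsu",
                                    pixel_size_um = attr(soma_labels, "pixel_size_um") %||% 1) {
  stopifnot(identical(dim(soma_labels), dim(marker_raster)), radius_um > 0)
  labs <- unclass_label(soma_labels)
  n <- max(labs, 0L)
  px <- pixel_size_um
  thr <- resolve_threshold(threshold, marker_raster)
  pos <- marker_raster >= thr
  out <- data.frame(cell_id = seq_len(n), soma_area_um2 = 0,
                    process_length_um = 0, process_area_um2 = 0,
                    perisomatic_radius_um = radius_um)
  if (n > 0L) {
    out$soma_area_um2 <- label_areas_px(labs, n) * px^2
    ex <- nearest_label_expand(labs, radius_um / px)
    annulus <- ex$labels
    annulus[labs > 0L] <- 0L  # annulus excludes the soma itself
    for (i in seq_len(n)) {
      sel <- annulus == i & pos
      out$process_area_um2[i] <- sum(sel) * px^2
      if (any(sel)) {
        crop <- crop_to_bbox(sel, pad = 1L)
        skel <- skeletonize(crop)
        out$process_length_um[i] <- skeleton_length_px(skel, mask = crop) * px
      }
    }
    covered <- ex$labels > 0L
  } else {
    covered <- matrix(FALSE, nrow(labs), ncol(labs))
  }
  stray <- pos & !covered
  n_frag <- if (any(stray)) {
    frag <- label_components(stray, connectivity = 4L)
    attr(frag, "n_objects")
  } else 0L
  structure(out, class = c("morphometry", "data.frame"),
            excluded_fragments = n_frag, pixel_size_um = px,
            threshold = thr)
}

crop_to_bbox <- function(mask, pad = 0L) {
  idx <- which(mask, arr.ind = TRUE)
  r0 <- max(1L, min(idx[, 1]) - pad); r1 <- min(nrow(mask), max(idx[, 1]) + pad)
  c0 <- max(1L, min(idx[, 2]) - pad); c1 <- min(ncol(mask), max(idx[, 2]) + pad)
  mask[r0:r1, c0:c1, drop = FALSE]
}
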