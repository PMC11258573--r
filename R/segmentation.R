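#' Segmentation parameters
#'
#' Defaults follow common practice for nucleus-seeded cell segmentation at
#' 1 um/px: nuclei probability threshold 0.5, nucleus size filter 10-500
#' um^2, shape-based declumping (distance-transform maxima + watershed),
#' probability-guided watershed for secondary objects with a 10 um expansion
#' cap.
#'
#' @param nuclei_threshold probability threshold in (0, 1) for primary
#'   (nucleus) detection.
#' @param size_filter_um2 length-2 (min, max) nucleus area filter in um^2.
#' @param declump `"shape"` (distance-transform watershed) or `"none"`
#'   (4-connected components).
#' @param secondary_method `"watershed"` (probability-guided) or
#'   `"expansion"` (bounded nearest-nucleus expansion).
#' @param signal_threshold probability threshold stopping secondary growth.
#' @param max_expansion_um expansion distance cap in micrometres.
#' @param watershed_tolerance minimum object-height separation for the
#'   declumping watershed, in distance-transform units (pixels).
#' @return list of class `segmentation_params`.
#' @export
segmentation_params <- function(nuclei_threshold = 0.5,
                                size_filter_um2 = c(10, 500),
                                declump = c("shape", "none"),
                                secondary_method = c("watershed", "expansion"),
                                signal_threshold = 0.5,
                                max_expansion_um = 10,
                                watershed_tolerance = 1) {
  declump <- match.arg(declump)
  secondary_method <- match.arg(secondary_method)
  stopifnot(length(size_filter_um2) == 2L,
            size_filter_um2[1] < size_filter_um2[2],
            max_expansion_um >= 0, watershed_tolerance > 0)
  if (nuclei_threshold <= 0 || nuclei_threshold >= 1) {
    stop("nuclei_threshold must be inside (0, 1)")
  }
  if (signal_threshold < 0 || signal_threshold > 1) {
    stop("signal_threshold must be in [0, 1]")
  }
  structure(list(nuclei_threshold = nuclei_threshold,
                 size_filter_um2 = size_filter_um2, declump = declump,
                 secondary_method = secondary_method,
                 signal_threshold = signal_threshold,
                 max_expansion_um = max_expansion_um,
                 watershed_tolerance = watershed_tolerance),
            class = "segmentation_params")
}

#' Identify primary objects (nuclei)
#'
#' Thresholds the nuclei probability map, fills holes, declumps touching
#' nuclei (optionally, via distance-transform watershed), applies the size
#' filter and returns a dense label image. Labels are ordered by the first
#' (column-major) pixel of each object, so re-running on identical input
#' reproduces identical labels.
#'
#' @param nuclei_probs matrix of nuclei probabilities in \[0, 1\] (a plane of
#'   a `probability_maps` object, or any binary/probability raster).
#' @param params a [segmentation_params()].
#' @param pixel_size_um pixel size used for the area filter.
#' @return integer label matrix (class `label_image`) with attributes
#'   `n_objects` and `pixel_size_um`.
#' @export
identify_primary <- function(nuclei_probs, params = segmentation_params(),
                             pixel_size_um = 1) {
  stopifnot(inherits(params, "segmentation_params"))
  if (any(nuclei_probs < 0 | nuclei_probs > 1)) {
    stop("nuclei probabilities must lie in [0, 1]")
  }
  mask <- nuclei_probs >= params$nuclei_threshold
  if (!any(mask)) {
    return(new_label_image(matrix(0L, nrow(mask), ncol(mask)), pixel_size_um))
  }
  mask <- matrix(as.logical(EBImage::fillHull(mask * 1)), nrow(mask), ncol(mask))
  if (params$declump == "shape") {
    dm <- EBImage::distmap(mask * 1)
    labs <- EBImage::watershed(dm, tolerance = params$watershed_tolerance, ext = 1)
    labs <- matrix(as.integer(labs), nrow(mask), ncol(mask))
  } else {
    labs <- label_components(mask, connectivity = 4L)
  }
  labs <- filter_by_area(labs, params$size_filter_um2, pixel_size_um)
  new_label_image(labs, pixel_size_um)
}

filter_by_area <- function(labs, size_filter_um2, pixel_size_um) {
  n <- max(labs)
  if (n == 0L) return(labs)
  areas <- label_areas_px(labs, n) * pixel_size_um^2
  drop <- which(areas < size_filter_um2[1] | areas > size_filter_um2[2])
  if (length(drop)) labs[labs %in% drop] <- 0L
  relabel_dense(labs)
}

new_label_image <- function(labs, pixel_size_um) {
  structure(labs, class = c("label_image", class(labs)),
            n_objects = max(labs, 0L), pixel_size_um = pixel_size_um)
}

#' @export
print.label_image <- function(x, ...) {
  cat(sprintf("label_image: %d object(s), %d x %d px @ %g um/px\n",
              attr(x, "n_objects"), nrow(x), ncol(x), attr(x, "pixel_size_um")))
  invisible(x)
}

#' Identify secondary objects (whole cells) around primaries
#'
#' Grows exactly one secondary object per primary. Growth stops at the
#' expansion-distance cap and where the signal probability falls below the
#' threshold; primary pixels always belong to their own secondary. Contested
#' pixels go to the nearer primary by exact Euclidean distance, ties to the
#' lower label index (`"expansion"` method); the `"watershed"` method
#' propagates seeds through the signal-probability landscape inside the same
#' candidate region.
#'
#' @param primary `label_image` of primaries.
#' @param signal_probs matrix of signal probabilities in \[0, 1\].
#' @param params a [segmentation_params()].
#' @return `label_image` of secondaries, labels matching `primary`.
#' @export
identify_secondary <- function(primary, signal_probs,
                               params = segmentation_params()) {
  stopifnot(inherits(params, "segmentation_params"),
            identical(dim(primary), dim(signal_probs)))
  px <- attr(primary, "pixel_size_um")
  if (is.null(px)) px <- 1
  max_px <- params$max_expansion_um / px
  prim <- unclass_label(primary)
  if (max_px == 0 || max(prim) == 0L) {
    return(new_label_image(prim, px))
  }
  candidate <- signal_probs >= params$signal_threshold | prim > 0L
  if (params$secondary_method == "expansion") {
    ex <- nearest_label_expand(prim, max_px)
    sec <- ex$labels
    sec[!candidate] <- 0L
  } else {
    d <- dist_to_mask(prim > 0L)
    mask <- candidate & d <= max_px
    sec <- EBImage::propagate(signal_probs, seeds = prim, mask = mask,
                              lambda = 1e-4)
    sec <- matrix(as.integer(sec), nrow(prim), ncol(prim))
  }
  sec[prim > 0L] <- prim[prim > 0L]  # secondary always contains its primary
  new_label_image(sec, px)
}

#' Identify tertiary objects (cytoplasm = cell minus nucleus)
#'
#' @param secondary,primary matching `label_image`s (same label sets, with
#'   each primary nested inside its secondary).
#' @return `label_image` where object i is `secondary(i)` minus
#'   `primary(i)`; the per-object area identity
#'   `area(tertiary_i) = area(secondary_i) - area(primary_i)` holds exactly.
#' @export
identify_tertiary <- function(secondary, primary) {
  stopifnot(identical(dim(secondary), dim(primary)))
  sec <- unclass_label(secondary)
  prim <- unclass_label(primary)
  ls <- sort(unique(sec[sec > 0L]))
  lp <- sort(unique(prim[prim > 0L]))
  if (!identical(ls, lp)) {
    stop(sprintf("label pairing error: labels only in secondary {%s}, only in primary {%s}",
                 paste(setdiff(ls, lp), collapse = ","),
                 paste(setdiff(lp, ls), collapse = ",")))
  }
  inside <- prim > 0L
  if (any(sec[inside] != prim[inside])) {
    stop("label pairing error: some primary pixels lie outside their secondary")
  }
  ter <- sec
  ter[inside] <- 0L
  out <- new_label_image(ter, attr(secondary, "pixel_size_um") %||% 1)
  attr(out, "n_objects") <- length(ls)  # objects may be empty sets
  out
}

unclass_label <- function(x) {
  y <- unclass(x)
  attributes(y) <- list(dim = dim(x))
  storage.mode(y) <- "integer"
  y
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-object areas of a label image
#'
#' @param labels a label matrix.
#' @param pixel_size_um pixel size; defaults to the image's own attribute.
#' @return named numeric vector of areas in um^2 for labels 1..N (empty
#'   objects report 0).
#' @export
object_areas <- function(labels, pixel_size_um = attr(labels, "pixel_size_um") %||% 1) {
  n <- if (!is.null(attr(labels, "n_objects"))) attr(labels, "n_objects") else max(labels, 0L)
  a <- label_areas_px(unclass_label(labels), n) * pixel_size_um^2
  if (length(a)) names(a) <- seq_along(a)
  a
}
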