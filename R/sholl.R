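#' Ring-expansion (Sholl) configuration
#'
#' Defaults follow the object-centric area-coverage variant used for amyloid
#' proximity profiling: 3 concentric rings of 30 um thickness grown outward
#' from the ROI boundaries, ROI interior excluded.
#'
#' @param n_rings number of rings (>= 1).
#' @param ring_thickness_um ring thickness in micrometres (> 0).
#' @param exclude_roi_interior if TRUE (default) the ROI interior is not
#'   part of any ring; if FALSE coverage inside the ROI is additionally
#'   reported as ring 0 by [ring_coverage()].
#' @return list of class `sholl_config`.
#' @export
sholl_config <- function(n_rings = 3L, ring_thickness_um = 30,
                         exclude_roi_interior = TRUE) {
  stopifnot(n_rings >= 1L, ring_thickness_um > 0)
  structure(list(n_rings = as.integer(n_rings),
                 ring_thickness_um = ring_thickness_um,
                 exclude_roi_interior = isTRUE(exclude_roi_interior)),
            class = "sholl_config")
}

#' Build concentric distance rings around a set of ROIs
#'
#' Ring k contains the pixels whose exact Euclidean distance to the nearest
#' ROI pixel lies in `((k-1) * t, k * t]`. The ROI set is treated as a
#' union: a pixel reachable from several ROIs takes the smallest ring index
#' automatically through the global distance transform. Rings clipped by the
#' image border are retained and flagged: the full (unclipped) ring area is
#' computed on a canvas padded by the total ring reach, and the retained
#' fraction is reported per ring.
#'
#' @param roi_labels label matrix (or `label_image`) with >= 1 ROI.
#' @param config a [sholl_config()].
#' @param pixel_size_um pixel size; defaults to the label image's attribute.
#' @return integer matrix of ring indices (0 = outside all rings / ROI
#'   interior), class `ring_image`, with attributes `ring_area_um2`,
#'   `full_ring_area_um2`, `retained_fraction`, `clipped` (logical per
#'   ring), `interior` (ROI mask), `config`, `pixel_size_um`.
#' @export
build_rings <- function(roi_labels, config = sholl_config(),
                        pixel_size_um = attr(roi_labels, "pixel_size_um") %||% 1) {
  stopifnot(inherits(config, "sholl_config"))
  roi <- roi_labels > 0
  if (!any(roi)) stop("empty ROI set: at least one ROI pixel is required")
  px <- pixel_size_um
  t_px <- config$ring_thickness_um / px
  if (t_px < 1) stop("ring thickness must convert to at least 1 px")
  n <- config$n_rings
  nr <- nrow(roi); nc <- ncol(roi)
  pad <- as.integer(ceiling(n * t_px)) + 1L
  padded <- matrix(FALSE, nr + 2L * pad, nc + 2L * pad)
  padded[pad + seq_len(nr), pad + seq_len(nc)] <- roi
  d <- dist_to_mask(padded)
  ring_pad <- matrix(0L, nrow(padded), ncol(padded))
  sel <- d > 0 & d <= n * t_px
  ring_pad[sel] <- as.integer(ceiling(d[sel] / t_px))
  rings <- ring_pad[pad + seq_len(nr), pad + seq_len(nc)]
  full_area <- tabulate(ring_pad[ring_pad > 0L], nbins = n) * px^2
  area <- tabulate(rings[rings > 0L], nbins = n) * px^2
  retained <- ifelse(full_area > 0, area / full_area, 0)
  structure(rings, class = c("ring_image", class(rings)),
            ring_area_um2 = area, full_ring_area_um2 = full_area,
            retained_fraction = retained,
            clipped = retained < 1 - 1e-12,
            interior = roi, config = config, pixel_size_um = px)
}

#' @export
print.ring_image <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("ring_image: %d ring(s) x %g um, %d x %d px\n",
              cfg$n_rings, cfg$ring_thickness_um, nrow(x), ncol(x)))
  df <- data.frame(ring = seq_len(cfg$n_rings),
                   area_um2 = attr(x, "ring_area_um2"),
                   retained = round(attr(x, "retained_fraction"), 3),
                   clipped = attr(x, "clipped"))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Target-marker area coverage per ring
#'
#' `coverage_k = 100 * (target-positive pixels in ring k) / (ring k
#' pixels)`. A ring entirely clipped away by the image border is reported as
#' missing (NA), not zero. When the ring image was built with
#' `exclude_roi_interior = FALSE`, an additional ring-0 row measures
#' coverage inside the ROI itself.
#'
#' @param rings a `ring_image` from [build_rings()].
#' @param target co-registered target-marker matrix.
#' @param threshold positive-target rule: numeric, `"otsu"`, or NULL for
#'   strictly positive pixels.
#' @return data frame of class `sholl_profile` with columns `ring`,
#'   `ring_area_um2`, `coverage_pct`, `retained_fraction`, `clipped`.
#' @export
ring_coverage <- function(rings, target, threshold = NULL) {
  stopifnot(inherits(rings, "ring_image"), identical(dim(rings), dim(target)))
  cfg <- attr(rings, "config")
  px <- attr(rings, "pixel_size_um")
  thr <- resolve_threshold(threshold, target)
  pos <- target >= thr
  n <- cfg$n_rings
  ring_idx <- seq_len(n)
  area <- attr(rings, "ring_area_um2")
  cov <- rep(NA_real_, n)
  for (k in ring_idx) {
    sel <- rings == k
    npix <- sum(sel)
    if (npix > 0L) cov[k] <- 100 * sum(pos[sel]) / npix
  }
  out <- data.frame(ring = ring_idx, ring_area_um2 = area,
                    coverage_pct = cov,
                    retained_fraction = attr(rings, "retained_fraction"),
                    clipped = attr(rings, "clipped"))
  if (!cfg$exclude_roi_interior) {
    interior <- attr(rings, "interior")
    out <- rbind(data.frame(ring = 0L,
                            ring_area_um2 = sum(interior) * px^2,
                            coverage_pct = 100 * sum(pos[interior]) / sum(interior),
                            retained_fraction = 1, clipped = FALSE),
                 out)
  }
  structure(out, class = c("sholl_profile", "data.frame"),
            config = cfg, threshold = thr)
}

#' @export
plot.sholl_profile <- function(x, ...) {
  graphics::barplot(x$coverage_pct, names.arg = x$ring,
                    xlab = "ring", ylab = "area coverage (%)", ...)
  invisible(x)
}

#' Combine Sholl profiles into a long table
#'
#' @param profiles nested named list: `profiles[[marker]][[image]]` is a
#'   `sholl_profile`.
#' @return long data frame with columns marker, image, ring, coverage_pct.
#' @export
combine_profiles <- function(profiles) {
  rows <- list()
  for (marker in names(profiles)) {
    imgs <- profiles[[marker]]
    if (is.null(names(imgs))) names(imgs) <- paste0("image", seq_along(imgs))
    for (img in names(imgs)) {
      p <- imgs[[img]]
      rows[[length(rows) + 1L]] <- data.frame(
        marker = marker, image = img, ring = p$ring,
        coverage_pct = p$coverage_pct)
    }
  }
  do.call(rbind, rows)
}

#' Compare Sholl profiles across rings and markers
#'
#' Within each marker, a one-way ANOVA of coverage across rings (with eta
#' squared); between each pair of markers, a per-ring contrast (paired t
#' when the image sets match, two-sample otherwise) with Cohen's d; and,
#' when the design is balanced, a marker x ring two-way ANOVA whose marker
#' main effect summarises the overall profile difference.
#'
#' @param profiles either the long data frame produced by
#'   [combine_profiles()] (columns marker, image, ring, coverage_pct) or a
#'   nested list accepted by it. At least two profiles (marker x image
#'   combinations) are required, and all profiles must share one ring set.
#' @return list of class `sholl_comparison` with elements `within`
#'   (per-marker ANOVA summary), `between` (per-ring marker contrasts) and
#'   `marker_effect` (an `anova_result`, or NULL when unbalanced).
#' @export
compare_profiles <- function(profiles) {
  long <- if (is.data.frame(profiles)) profiles else combine_profiles(profiles)
  need <- c("marker", "image", "ring", "coverage_pct")
  if (!all(need %in% names(long))) {
    stop("profiles must provide columns marker, image, ring, coverage_pct")
  }
  long <- long[!is.na(long$coverage_pct), ]
  n_profiles <- nrow(unique(long[, c("marker", "image")]))
  if (n_profiles < 2L) stop("at least two profiles are required")
  ring_sets <- tapply(long$ring, paste(long$marker, long$image),
                      function(r) paste(sort(unique(r)), collapse = ","))
  if (length(unique(ring_sets)) != 1L) {
    stop("profiles have unequal ring configurations")
  }

  markers <- unique(long$marker)
  within <- do.call(rbind, lapply(markers, function(m) {
    sub <- long[long$marker == m, ]
    groups <- split(sub$coverage_pct, sub$ring)
    if (length(groups) < 2L || any(lengths(groups) < 2L)) {
      return(data.frame(marker = m, F = NA_real_, df1 = NA_real_,
                        df2 = NA_real_, p = NA_real_, eta_sq = NA_real_))
    }
    a <- one_way_anova(groups)
    ss_tot <- a$effects$sumsq[1] + a$residual$sumsq
    data.frame(marker = m, F = a$effects$statistic[1],
               df1 = a$effects$df[1], df2 = a$residual$df,
               p = a$effects$p_value[1],
               eta_sq = if (ss_tot > 0) a$effects$sumsq[1] / ss_tot else 0)
  }))

  between <- list()
  if (length(markers) >= 2L) {
    prs <- utils::combn(markers, 2L, simplify = FALSE)
    for (pr in prs) {
      for (k in sort(unique(long$ring))) {
        a <- long[long$marker == pr[1] & long$ring == k, ]
        b <- long[long$marker == pr[2] & long$ring == k, ]
        paired <- setequal(a$image, b$image) && nrow(a) == nrow(b)
        if (paired) {
          a <- a[order(a$image), ]; b <- b[order(b$image), ]
        }
        diff_mean <- mean(a$coverage_pct) - mean(b$coverage_pct)
        sd_pool <- sqrt((stats::var(a$coverage_pct) * (nrow(a) - 1) +
                         stats::var(b$coverage_pct) * (nrow(b) - 1)) /
                        max(nrow(a) + nrow(b) - 2, 1))
        d_eff <- if (is.na(sd_pool) || sd_pool == 0) {
          if (diff_mean == 0) 0 else Inf * sign(diff_mean)
        } else diff_mean / sd_pool
        pv <- if (nrow(a) >= 2 && nrow(b) >= 2 &&
                  (stats::var(a$coverage_pct) > 0 || stats::var(b$coverage_pct) > 0)) {
          if (paired) stats::t.test(a$coverage_pct, b$coverage_pct,
                                    paired = TRUE)$p.value
          else stats::t.test(a$coverage_pct, b$coverage_pct,
                             var.equal = TRUE)$p.value
        } else if (diff_mean == 0) 1 else NA_real_
        between[[length(between) + 1L]] <- data.frame(
          marker_a = pr[1], marker_b = pr[2], ring = k, paired = paired,
          contrast = diff_mean, cohens_d = d_eff, p = pv)
      }
    }
  }
  between <- if (length(between)) do.call(rbind, between) else NULL

  marker_effect <- NULL
  tab <- table(long$marker, long$ring)
  if (length(markers) >= 2L && length(unique(as.vector(tab))) == 1L &&
      all(tab >= 2L)) {
    marker_effect <- two_way_anova(long$coverage_pct, long$marker, long$ring)
  }
  structure(list(within = within, between = between,
                 marker_effect = marker_effect),
            class = "sholl_comparison")
}

#' @export
print.sholl_comparison <- function(x, ...) {
  cat("Sholl profile comparison\n\nWithin-marker (coverage across rings):\n")
  print(x$within, row.names = FALSE)
  if (!is.null(x$between)) {
    cat("\nBetween-marker per-ring contrasts:\n")
    print(x$between, row.names = FALSE)
  }
  if (!is.null(x$marker_effect)) {
    cat("\nMarker main effect (marker x ring ANOVA):\n")
    print(x$marker_effect)
  }
  invisible(x)
}
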