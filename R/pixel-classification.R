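#' Feature configuration for pixel classification
#'
#' Three feature families at one or more Gaussian scales (sigma, in pixels):
#' smoothed intensity, gradient magnitude (edge), and texture operationalised
#' as the two structure-tensor eigenvalues plus the Laplacian of Gaussian.
#' The default single scale of 10 px mirrors common interactive pixel
#' classifiers at IMC resolution.
#'
#' @param scales positive smoothing scales (sigma) in pixels.
#' @param families subset of `c("intensity", "edge", "texture")`.
#' @return list of class `feature_config`.
#' @export
feature_config <- function(scales = 10,
                           families = c("intensity", "edge", "texture")) {
  families <- match.arg(families, c("intensity", "edge", "texture"),
                        several.ok = TRUE)
  stopifnot(length(scales) >= 1L, all(scales > 0), length(families) >= 1L)
  structure(list(scales = scales, families = families),
            class = "feature_config")
}

#' Extract per-pixel features from a raster or stack
#'
#' For each channel the raw intensity plane is always included (so crisp
#' object boundaries stay resolvable at pixel precision); then, per scale
#' sigma: the Gaussian-smoothed intensity, the gradient magnitude of the
#' smoothed image (central differences, replicated borders), and texture
#' planes (larger/smaller structure-tensor eigenvalue and Laplacian of
#' Gaussian). Per channel this yields 1 raw plane plus, per scale, 1
#' smoothed-intensity plane, 1 edge plane and 3 texture planes when all
#' families are enabled. Constant input yields exactly zero edge and
#' texture planes.
#'
#' @param x numeric matrix or [channel_stack()] with finite values.
#' @param config a [feature_config()].
#' @return 3-D array (rows x cols x features) of class `feature_stack` with
#'   named feature planes and the config attached.
#' @export
extract_features <- function(x, config = feature_config()) {
  stopifnot(inherits(config, "feature_config"))
  channels <- if (inherits(x, "channel_stack")) x$channels else list(ch1 = x)
  for (nm in names(channels)) {
    bad <- which(!is.finite(channels[[nm]]))
    if (length(bad)) {
      rr <- ((bad[1] - 1L) %% nrow(channels[[nm]]))
      cc <- ((bad[1] - 1L) %/% nrow(channels[[nm]]))
      stop(sprintf(
        "channel '%s' has %d non-finite pixel(s); first at (row=%d, col=%d) [0-based]",
        nm, length(bad), rr, cc))
    }
  }
  planes <- list()
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if ("intensity" %in% config$families) {
      planes[[sprintf("%s.raw", nm)]] <- ch
    }
    for (s in config$scales) {
      sm <- gauss_smooth(ch, s)
      if ("intensity" %in% config$families) {
        planes[[sprintf("%s.intensity.s%g", nm, s)]] <- sm
      }
      if ("edge" %in% config$families || "texture" %in% config$families) {
        gx <- central_diff(sm, axis = 2L)
        gy <- central_diff(sm, axis = 1L)
      }
      if ("edge" %in% config$families) {
        planes[[sprintf("%s.edge.s%g", nm, s)]] <- sqrt(gx^2 + gy^2)
      }
      if ("texture" %in% config$families) {
        si <- max(s / 2, 1)
        jxx <- gauss_smooth(gx * gx, si)
        jyy <- gauss_smooth(gy * gy, si)
        jxy <- gauss_smooth(gx * gy, si)
        half_tr <- (jxx + jyy) / 2
        disc <- sqrt(pmax((jxx - jyy)^2 / 4 + jxy^2, 0))
        planes[[sprintf("%s.st_max.s%g", nm, s)]] <- half_tr + disc
        planes[[sprintf("%s.st_min.s%g", nm, s)]] <- half_tr - disc
        planes[[sprintf("%s.log.s%g", nm, s)]] <- laplacian(sm)
      }
    }
  }
  out <- array(0, dim = c(nrow(channels[[1]]), ncol(channels[[1]]), length(planes)),
               dimnames = list(NULL, NULL, names(planes)))
  for (i in seq_along(planes)) out[, , i] <- planes[[i]]
  structure(out, class = "feature_stack", config = config)
}

gauss_smooth <- function(x, sigma) {
  size <- 2L * ceiling(3 * sigma) + 1L
  # kernel may not exceed the image; clamp for small rasters
  cap <- min(nrow(x), ncol(x))
  cap <- if (cap %% 2L == 0L) cap - 1L else cap
  size <- min(size, cap)
  k <- EBImage::makeBrush(size, shape = "Gaussian", sigma = sigma)
  matrix(as.numeric(EBImage::filter2(x, k, boundary = "replicate")),
         nrow(x), ncol(x))
}

central_diff <- function(x, axis) {
  n <- dim(x)[axis]
  hi <- c(2:n, n)
  lo <- c(1, 1:(n - 1))
  if (axis == 1L) (x[hi, , drop = FALSE] - x[lo, , drop = FALSE]) / 2
  else (x[, hi, drop = FALSE] - x[, lo, drop = FALSE]) / 2
}

laplacian <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  up <- x[c(1, 1:(nr - 1)), , drop = FALSE]
  dn <- x[c(2:nr, nr), , drop = FALSE]
  lf <- x[, c(1, 1:(nc - 1)), drop = FALSE]
  rt <- x[, c(2:nc, nc), drop = FALSE]
  up + dn + lf + rt - 4 * x
}

#' Train a probabilistic pixel classifier
#'
#' Fits a bagged decision-tree ensemble (random-forest style probability
#' forest: 100 trees, depth <= 12) on annotated pixels. Annotations are
#' canonically sorted before training so the fitted model is invariant to
#' annotation row order at a fixed seed.
#'
#' @param features a `feature_stack` from [extract_features()].
#' @param annotation data frame with columns `x`, `y` (0-based pixel column
#'   and row) and `class`. Every class in `classes` must be present with at
#'   least 10 pixels.
#' @param seed integer seed for the ensemble.
#' @param classes required class set (default signal/nuclei/background).
#' @param num_trees,max_depth ensemble size and depth cap.
#' @param mtry features considered per split; the default of half the
#'   feature count keeps the decisive raw-intensity planes in play at most
#'   splits while retaining ensemble diversity.
#' @return object of class `pixel_model`.
#' @export
train_pixel_classifier <- function(features, annotation, seed = 1L,
                                   classes = c("signal", "nuclei", "background"),
                                   num_trees = 100L, max_depth = 12L,
                                   mtry = NULL) {
  stopifnot(inherits(features, "feature_stack"),
            all(c("x", "y", "class") %in% names(annotation)),
            length(classes) >= 2L)
  nr <- dim(features)[1]; nc <- dim(features)[2]
  if (any(annotation$x < 0 | annotation$x >= nc |
          annotation$y < 0 | annotation$y >= nr)) {
    stop("annotation coordinates out of image bounds")
  }
  cnt <- table(factor(annotation$class, levels = classes))
  if (any(cnt < 10L)) {
    stop(sprintf("insufficient annotation: class(es) %s have fewer than 10 pixels",
                 paste(names(cnt)[cnt < 10L], collapse = ", ")))
  }
  extra <- setdiff(unique(annotation$class), classes)
  if (length(extra)) {
    stop(sprintf("annotation contains unknown class(es): %s",
                 paste(extra, collapse = ", ")))
  }
  ann <- annotation[order(annotation$class, annotation$y, annotation$x), ]
  fmat <- matrix(features, nr * nc, dim(features)[3])
  colnames(fmat) <- dimnames(features)[[3]]
  pix <- (ann$y + 1L) + ann$x * nr
  x_train <- fmat[pix, , drop = FALSE]
  y_train <- factor(ann$class, levels = classes)
  if (is.null(mtry)) mtry <- max(1L, floor(ncol(x_train) / 2))
  fit <- ranger::ranger(x = as.data.frame(x_train), y = y_train,
                        num.trees = num_trees, max.depth = max_depth,
                        mtry = mtry, probability = TRUE, seed = seed,
                        num.threads = 1L)
  pr <- stats::predict(fit, data = as.data.frame(x_train),
                       num.threads = 1L)$predictions
  acc <- mean(colnames(pr)[max.col(pr, ties.method = "first")] == as.character(y_train))
  structure(list(forest = fit, classes = classes,
                 feature_names = dimnames(features)[[3]],
                 feature_config = attr(features, "config"),
                 seed = seed, training_accuracy = acc),
            class = "pixel_model")
}

#' @export
print.pixel_model <- function(x, ...) {
  cat(sprintf("pixel_model: %d trees, classes {%s}, %d features, training accuracy %.3f\n",
              x$forest$num.trees, paste(x$classes, collapse = ", "),
              length(x$feature_names), x$training_accuracy))
  invisible(x)
}

#' Predict per-class probability maps
#'
#' @param model a `pixel_model`.
#' @param features a `feature_stack` computed with the same [feature_config()]
#'   (and channel layout) the model was trained on.
#' @return object of class `probability_maps`: a named list of per-class
#'   matrices whose per-pixel values sum to 1.
#' @export
predict_probabilities <- function(model, features) {
  stopifnot(inherits(model, "pixel_model"), inherits(features, "feature_stack"))
  if (!identical(dimnames(features)[[3]], model$feature_names)) {
    stop("feature planes do not match the model's feature configuration")
  }
  nr <- dim(features)[1]; nc <- dim(features)[2]
  fmat <- matrix(features, nr * nc, dim(features)[3])
  colnames(fmat) <- model$feature_names
  pr <- stats::predict(model$forest, data = as.data.frame(fmat),
                       num.threads = 1L)$predictions
  pr <- pr / rowSums(pr)
  maps <- lapply(model$classes, function(cl) matrix(pr[, cl], nr, nc))
  names(maps) <- model$classes
  structure(maps, class = "probability_maps")
}

#' Hard class map from probability maps
#'
#' @param probs a `probability_maps` object.
#' @return character matrix of per-pixel argmax classes (first class wins
#'   exact ties).
#' @export
argmax_map <- function(probs) {
  stopifnot(inherits(probs, "probability_maps"))
  nr <- nrow(probs[[1]]); nc <- ncol(probs[[1]])
  pm <- vapply(probs, as.numeric, numeric(nr * nc))
  matrix(names(probs)[max.col(pm, ties.method = "first")], nr, nc)
}

#' @export
print.probability_maps <- function(x, ...) {
  cat(sprintf("probability_maps: classes {%s}, %d x %d px\n",
              paste(names(x), collapse = ", "), nrow(x[[1]]), ncol(x[[1]])))
  invisible(x)
}

#' Sample training annotations from ground-truth class masks
#'
#' Builds a pixel annotation of roughly one 50 x 50 patch worth of pixels
#' per class by sampling from the true class map of a synthetic scene
#' (signal = any pathology or marker channel above 25% of its noiseless
#' peak, so the far tail of the oligomer halo counts as background; nuclei
#' = nucleus discs; background = the rest).
#'
#' @param truth a `ground_truth` from [simulate_scene()].
#' @param clean the noiseless [channel_stack()] of the scene.
#' @param n_per_class pixels sampled per class (default 833, about 2500
#'   total across the three classes).
#' @param seed sampling seed.
#' @return data frame with columns x, y (0-based), class.
#' @export
annotation_from_truth <- function(truth, clean, n_per_class = 833L, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"), inherits(clean, "channel_stack"))
  set.seed(seed)
  cm <- class_map_from_truth(truth, clean)
  nr <- nrow(cm)
  pick <- function(cl) {
    idx <- which(cm == cl)
    idx <- idx[sample.int(length(idx), min(n_per_class, length(idx)))]
    data.frame(x = (idx - 1L) %/% nr, y = (idx - 1L) %% nr, class = cl)
  }
  rbind(pick("signal"), pick("nuclei"), pick("background"))
}

#' Ground-truth pixel class map of a synthetic scene
#'
#' The reference against which predicted class maps are scored: `nuclei`
#' on nucleus discs, `signal` where any pathology or marker channel of the
#' noiseless stack exceeds 25% of its peak, `background` elsewhere.
#'
#' @param truth a `ground_truth`.
#' @param clean the noiseless [channel_stack()] of the same scene.
#' @return character matrix of classes.
#' @export
class_map_from_truth <- function(truth, clean) {
  nuc <- truth$nuclei_labels > 0
  marker_ch <- setdiff(names(clean$channels), "nuclei")
  sig <- Reduce(`|`,
                lapply(clean$channels[marker_ch],
                       function(m) m > 0.25 * max(m, 1e-12)),
                init = matrix(FALSE, nrow(nuc), ncol(nuc)))
  out <- matrix("background", nrow(nuc), ncol(nuc))
  out[sig & !nuc] <- "signal"
  out[nuc] <- "nuclei"
  out
}
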