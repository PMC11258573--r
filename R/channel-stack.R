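#' Named multi-channel image stack
#'
#' A set of co-registered single-channel rasters with a shared physical pixel
#' size. The workhorse container passed between all pipeline stages.
#'
#' @param channels named list of numeric matrices of identical dimensions.
#' @param pixel_size_um physical pixel size in micrometres per pixel.
#' @return An object of class `channel_stack`.
#' @export
channel_stack <- function(channels, pixel_size_um = 1) {
  stopifnot(is.list(channels), length(channels) >= 1L, pixel_size_um > 0)
  nm <- names(channels)
  if (is.null(nm) || any(!nzchar(nm)) || anyDuplicated(nm)) {
    stop("channels must be uniquely named")
  }
  d <- dim(channels[[1]])
  for (i in seq_along(channels)) {
    if (!is.matrix(channels[[i]])) stop("each channel must be a matrix")
    if (!identical(dim(channels[[i]]), d)) {
      stop(sprintf("channel '%s' has mismatched dimensions", nm[i]))
    }
  }
  structure(list(channels = channels, pixel_size_um = pixel_size_um),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("channel_stack: %d channel(s), %d x %d px @ %g um/px\n",
              length(x$channels), d[1], d[2], x$pixel_size_um))
  for (nm in names(x$channels)) {
    ch <- x$channels[[nm]]
    cat(sprintf("  %-12s range [%.3g, %.3g]\n", nm, min(ch), max(ch)))
  }
  invisible(x)
}

#' @export
`[[.channel_stack` <- function(x, i) .subset2(x, "channels")[[i]]

#' @export
names.channel_stack <- function(x) names(.subset2(x, "channels"))

#' Display the channels of a stack as grey-level images
#'
#' @param x a [channel_stack()].
#' @param channels channel names to draw (default all).
#' @param ... ignored.
#' @export
plot.channel_stack <- function(x, channels = names(x$channels), ...) {
  n <- length(channels)
  op <- graphics::par(mfrow = c(1, n), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  for (nm in channels) {
    ch <- x$channels[[nm]]
    rng <- range(ch)
    if (diff(rng) == 0) rng <- rng + c(0, 1)
    graphics::image(t(ch)[, nrow(ch):1, drop = FALSE],
                    col = grDevices::gray.colors(256, 0, 1),
                    zlim = rng, axes = FALSE, main = nm, asp = nrow(ch) / ncol(ch))
  }
  invisible(x)
}

# shared shape check used by stages taking a stack plus a label raster
check_coregistered <- function(labels, stack) {
  d <- dim(stack$channels[[1]])
  if (!identical(dim(labels), d)) {
    stop(sprintf("label raster (%d x %d) and stack (%d x %d) are not co-registered",
                 nrow(labels), ncol(labels), d[1], d[2]))
  }
  invisible(TRUE)
}
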