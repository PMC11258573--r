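#' Write a channel stack as a multi-page 32-bit TIFF
#'
#' Pages are written in channel order. Because 32-bit TIFF pages are stored
#' on the \[0, 1\] scale, each channel is scaled by its own factor; channel
#' names, scale factors and the pixel size live in a sidecar CSV at
#' `<path>.channels.csv`. Round trip is exact to about six significant
#' digits of the channel's full scale (label images use 16-bit storage and
#' round-trip bit-exactly, see [write_label_image()]).
#'
#' @param stack a [channel_stack()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "channel_stack"))
  scales <- vapply(stack$channels, function(ch) {
    mx <- max(ch)
    if (!is.finite(mx) || mx <= 0) 1 else mx
  }, numeric(1))
  pages <- mapply(function(ch, s) ch / s, stack$channels, scales,
                  SIMPLIFY = FALSE)
  tiff::writeTIFF(unname(pages), path, bits.per.sample = 32L)
  side <- data.frame(channel = names(stack$channels), scale = scales,
                     pixel_size_um = stack$pixel_size_um)
  write_csv_full(side, sidecar_path(path))
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".channels.csv")

#' Read a multi-page TIFF into a channel stack
#'
#' Channel names and intensity scales come from the sidecar CSV written by
#' [write_stack()] when present, else from `channel_names`. Pixel size
#' precedence: the `pixel_size_um` argument, then the sidecar, then 1 um.
#'
#' @param path TIFF path.
#' @param channel_names channel names when no sidecar exists.
#' @param pixel_size_um pixel size override.
#' @return a [channel_stack()].
#' @export
read_stack <- function(path, channel_names = NULL, pixel_size_um = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- dim(pages[[1]])
  for (i in seq_along(pages)) {
    if (!identical(dim(pages[[i]]), d)) {
      stop(sprintf("page %d has shape %s, expected %s", i,
                   paste(dim(pages[[i]]), collapse = "x"),
                   paste(d, collapse = "x")))
    }
  }
  scales <- rep(1, length(pages))
  px <- 1
  if (file.exists(sidecar_path(path))) {
    side <- utils::read.csv(sidecar_path(path))
    check_schema(side, c("channel", "scale", "pixel_size_um"), sidecar_path(path))
    if (nrow(side) != length(pages)) {
      stop("sidecar lists a different number of channels than the TIFF has pages")
    }
    if (is.null(channel_names)) channel_names <- side$channel
    scales <- side$scale
    px <- side$pixel_size_um[1]
  }
  if (is.null(channel_names)) {
    stop("channel names are required: none in a sidecar and none supplied")
  }
  if (length(channel_names) != length(pages)) {
    stop("channel_names length does not match the number of TIFF pages")
  }
  if (!is.null(pixel_size_um)) px <- pixel_size_um
  channels <- mapply(function(p, s) matrix(as.numeric(p), d[1], d[2]) * s,
                     pages, scales, SIMPLIFY = FALSE)
  names(channels) <- channel_names
  channel_stack(channels, pixel_size_um = px)
}

#' Write / read a label image as 16-bit TIFF
#'
#' Labels up to 65535 round-trip bit-exactly; the pixel size is stored in a
#' `<path>.meta.csv` sidecar.
#'
#' @param labels integer label matrix (or `label_image`).
#' @param path TIFF path.
#' @return `path` invisibly (write); a `label_image` (read).
#' @export
write_label_image <- function(labels, path) {
  mx <- max(labels, 0L)
  if (mx > 65535L) stop("more than 65535 labels cannot be stored as 16-bit TIFF")
  tiff::writeTIFF(unclass_label(labels) / 65535, path, bits.per.sample = 16L)
  write_csv_full(data.frame(pixel_size_um = attr(labels, "pixel_size_um") %||% 1),
                 paste0(path, ".meta.csv"))
  invisible(path)
}

#' @rdname write_label_image
#' @export
read_label_image <- function(path) {
  m <- tiff::readTIFF(path, all = FALSE)
  labs <- matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
  px <- 1
  meta <- paste0(path, ".meta.csv")
  if (file.exists(meta)) px <- utils::read.csv(meta)$pixel_size_um[1]
  new_label_image(labs, px)
}

# deterministic full-precision CSV writer (UTF-8, comma, ".", %.17g floats)
write_csv_full <- function(df, path) {
  out <- df
  for (i in seq_along(out)) {
    if (is.double(out[[i]])) out[[i]] <- sprintf("%.17g", out[[i]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

check_schema <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  extra <- setdiff(names(df), required)
  if (length(missing)) {
    stop(sprintf("schema mismatch in %s: missing column(s) {%s}%s", path,
                 paste(missing, collapse = ", "),
                 if (length(extra)) sprintf(", unexpected {%s}",
                                            paste(extra, collapse = ", ")) else ""))
  }
  invisible(TRUE)
}

#' CSV round trip for the package's tabular results
#'
#' Values are written at full double precision (17 significant digits) with
#' units encoded in column names, and re-read losslessly; a malformed
#' header is a schema error naming the column difference.
#'
#' @param x the object to write.
#' @param path CSV path.
#' @name table-io
NULL

#' @rdname table-io
#' @export
write_cell_table <- function(x, path) {
  stopifnot(inherits(x, "cell_table"))
  df <- as.data.frame(x)
  write_csv_full(df, path)
  meta <- data.frame(markers = paste(attr(x, "markers"), collapse = ";"),
                     pixel_size_um = attr(x, "pixel_size_um") %||% 1)
  write_csv_full(meta, paste0(path, ".meta.csv"))
  invisible(path)
}

#' @rdname table-io
#' @export
read_cell_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_schema(df, c("id", "image", "x_um", "y_um", "area_um2"),
               path)
  meta <- paste0(path, ".meta.csv")
  markers <- setdiff(names(df), c("id", "image", "x_um", "y_um", "area_um2",
                                  "cluster"))
  markers <- markers[!grepl("_t$", markers)]
  px <- 1
  if (file.exists(meta)) {
    m <- utils::read.csv(meta)
    markers <- strsplit(m$markers, ";")[[1]]
    px <- m$pixel_size_um[1]
  }
  out <- structure(df, class = c("cell_table", "data.frame"),
                   markers = markers, pixel_size_um = px)
  if (any(grepl("_t$", names(df)))) {
    attr(out, "transformed_markers") <- grep("_t$", names(df), value = TRUE)
  }
  out
}

#' @rdname table-io
#' @export
write_sholl_profile <- function(x, path) {
  stopifnot(inherits(x, "sholl_profile"))
  write_csv_full(as.data.frame(x), path)
  invisible(path)
}

#' @rdname table-io
#' @export
read_sholl_profile <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_schema(df, c("ring", "ring_area_um2", "coverage_pct",
                     "retained_fraction", "clipped"), path)
  df$clipped <- as.logical(df$clipped)
  structure(df, class = c("sholl_profile", "data.frame"))
}

#' @rdname table-io
#' @export
write_correlation_matrix <- function(x, path) {
  stopifnot(inherits(x, "correlation_matrix"))
  mk <- rownames(x$r)
  prs <- which(upper.tri(x$r, diag = TRUE), arr.ind = TRUE)
  df <- data.frame(marker_a = mk[prs[, 1]], marker_b = mk[prs[, 2]],
                   r = x$r[prs], p = x$p[prs], n = x$n,
                   expansion_px = x$expansion_px)
  write_csv_full(df, path)
  invisible(path)
}

#' @rdname table-io
#' @export
read_correlation_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_schema(df, c("marker_a", "marker_b", "r", "p", "n", "expansion_px"),
               path)
  mk <- unique(c(df$marker_a, df$marker_b))
  k <- length(mk)
  r <- matrix(NA_real_, k, k, dimnames = list(mk, mk))
  p <- r
  for (i in seq_len(nrow(df))) {
    r[df$marker_a[i], df$marker_b[i]] <- r[df$marker_b[i], df$marker_a[i]] <- df$r[i]
    p[df$marker_a[i], df$marker_b[i]] <- p[df$marker_b[i], df$marker_a[i]] <- df$p[i]
  }
  structure(list(r = r, p = p, n = df$n[1], expansion_px = df$expansion_px[1],
                 means = NULL,
                 missing = mk[is.na(diag(r))]),
            class = "correlation_matrix")
}

#' @rdname table-io
#' @export
write_anova_result <- function(x, path) {
  stopifnot(inherits(x, "anova_result"))
  df <- rbind(x$effects,
              data.frame(term = "Residuals", df = x$residual$df,
                         sumsq = x$residual$sumsq, meansq = x$residual$meansq,
                         statistic = NA_real_, p_value = NA_real_))
  write_csv_full(df, path)
  invisible(path)
}

#' @rdname table-io
#' @export
read_anova_result <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_schema(df, c("term", "df", "sumsq", "meansq", "statistic", "p_value"),
               path)
  res <- df[df$term == "Residuals", ]
  eff <- df[df$term != "Residuals", ]
  new_anova_result(eff, list(df = res$df, sumsq = res$sumsq,
                             meansq = res$meansq), design = NULL)
}
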