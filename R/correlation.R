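#' Per-cell marker correlation with pixel expansion
#'
#' Mean marker intensities are computed per cell over the cell mask dilated
#' by `expansion_px` pixels (the conventional 4-pixel expansion captures
#' perisomatic signal; contested pixels go to the nearer cell, ties to the
#' lower label), then Pearson correlation is computed across cells for every
#' marker pair.
#'
#' @param cells label matrix (or `label_image`) of >= 3 cells.
#' @param stack co-registered [channel_stack()] of marker channels.
#' @param expansion_px mask expansion in pixels (default 4).
#' @return object of class `correlation_matrix`: list with symmetric
#'   unit-diagonal `r`, p-value matrix `p`, number of cells `n`,
#'   `expansion_px`, the per-cell `means` matrix, and `missing` (markers
#'   with zero variance across cells, whose r/p are NA).
#' @export
cell_marker_correlation <- function(cells, stack, expansion_px = 4) {
  stopifnot(inherits(stack, "channel_stack"), expansion_px >= 0)
  check_coregistered(cells, stack)
  labs <- unclass_label(cells)
  n_cells <- length(unique(labs[labs > 0L]))
  if (n_cells < 3L) stop("at least 3 cells are required for correlation")
  means <- cell_mean_intensities(labs, stack, expansion_px)
  markers <- colnames(means)
  k <- length(markers)
  sds <- apply(means, 2, stats::sd)
  missing <- markers[sds == 0 | !is.finite(sds)]
  r <- matrix(NA_real_, k, k, dimnames = list(markers, markers))
  p <- matrix(NA_real_, k, k, dimnames = list(markers, markers))
  diag(r) <- 1
  diag(p) <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (markers[i] %in% missing || markers[j] %in% missing) next
      ct <- pearson_cor(means[, i], means[, j])
      r[i, j] <- r[j, i] <- ct$r
      p[i, j] <- p[j, i] <- ct$p
    }
  }
  structure(list(r = r, p = p, n = n_cells, expansion_px = expansion_px,
                 means = means, missing = missing),
            class = "correlation_matrix")
}

# per-cell mean channel intensities over (optionally expanded) cell masks
cell_mean_intensities <- function(labs, stack, expansion_px) {
  n <- max(labs)
  region <- if (expansion_px > 0) {
    nearest_label_expand(labs, expansion_px)$labels
  } else {
    labs
  }
  sel <- region > 0L
  f <- region[sel]
  counts <- tabulate(f, nbins = n)
  out <- vapply(stack$channels, function(ch) {
    sums <- rowsum(ch[sel], f)
    v <- numeric(n)
    v[as.integer(rownames(sums))] <- sums[, 1]
    v / pmax(counts, 1L)
  }, numeric(n))
  out <- matrix(out, nrow = n, dimnames = list(NULL, names(stack$channels)))
  out[counts > 0L, , drop = FALSE]
}

#' @export
print.correlation_matrix <- function(x, digits = 3, ...) {
  cat(sprintf("correlation_matrix: %d cells, %g px expansion\n",
              x$n, x$expansion_px))
  print(round(x$r, digits))
  if (length(x$missing)) {
    cat("markers with zero variance (correlation undefined):",
        paste(x$missing, collapse = ", "), "\n")
  }
  invisible(x)
}
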