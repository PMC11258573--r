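#' Build a single-cell marker table
#'
#' One row per labelled cell: 0-based centroid in micrometres, pixel-exact
#' area, and the mean intensity of every stack channel over the (optionally
#' expanded) cell mask.
#'
#' @param labels label matrix (or `label_image`) of cells.
#' @param stack co-registered [channel_stack()].
#' @param expansion_px mask expansion in pixels before intensity extraction.
#' @param image_id identifier recorded in the `image` column.
#' @return data frame of class `cell_table` with attribute `markers`; an
#'   empty label image yields an empty table.
#' @export
build_cell_table <- function(labels, stack, expansion_px = 0,
                             image_id = "image1") {
  stopifnot(inherits(stack, "channel_stack"))
  check_coregistered(labels, stack)
  labs <- unclass_label(labels)
  px <- attr(labels, "pixel_size_um") %||% stack$pixel_size_um
  n <- max(labs, 0L)
  markers <- names(stack$channels)
  if (n == 0L) {
    out <- data.frame(id = integer(0), image = character(0),
                      x_um = numeric(0), y_um = numeric(0),
                      area_um2 = numeric(0))
    for (m in markers) out[[m]] <- numeric(0)
    return(structure(out, class = c("cell_table", "data.frame"),
                     markers = markers, pixel_size_um = px))
  }
  idx <- which(labs > 0L)
  f <- labs[idx]
  counts <- tabulate(f, nbins = n)
  keep <- which(counts > 0L)
  rows0 <- (idx - 1L) %% nrow(labs)
  cols0 <- (idx - 1L) %/% nrow(labs)
  cx <- rowsum(cols0, f)[, 1] / counts[keep]
  cy <- rowsum(rows0, f)[, 1] / counts[keep]
  means <- cell_mean_intensities(labs, stack, expansion_px)
  out <- data.frame(id = keep, image = image_id,
                    x_um = cx * px, y_um = cy * px,
                    area_um2 = counts[keep] * px^2)
  for (m in markers) out[[m]] <- means[, m]
  structure(out, class = c("cell_table", "data.frame"),
            markers = markers, pixel_size_um = px)
}

#' Transform per-cell marker intensities
#'
#' Adds transformed columns `<marker>_t` to a cell table. `arcsinh` is the
#' cytometry-standard `asinh(x / cofactor)` (inverse
#' `cofactor * sinh(y)`); `zscore` centres and scales per marker (a
#' zero-variance marker is reported and set to 0); `percentile` clips each
#' marker to the given quantiles.
#'
#' @param table a `cell_table`.
#' @param method one of `"arcsinh"`, `"zscore"`, `"percentile"`.
#' @param cofactor arcsinh cofactor (default 5).
#' @param probs clip quantiles for `"percentile"`.
#' @return the table with `<marker>_t` columns and attribute
#'   `transformed_markers`.
#' @export
transform_intensities <- function(table, method = c("arcsinh", "zscore", "percentile"),
                                  cofactor = 5, probs = c(0.01, 0.99)) {
  method <- match.arg(method)
  stopifnot(inherits(table, "cell_table"))
  if (method == "arcsinh" && cofactor <= 0) stop("cofactor must be positive")
  if (method == "percentile" &&
      (length(probs) != 2L || probs[1] >= probs[2] || any(probs < 0 | probs > 1))) {
    stop("probs must be two increasing values in [0, 1]")
  }
  markers <- attr(table, "markers")
  for (m in markers) {
    x <- table[[m]]
    y <- switch(method,
      arcsinh = asinh(x / cofactor),
      zscore = {
        s <- stats::sd(x)
        if (length(x) == 0L) {
          numeric(0)
        } else if (is.na(s) || s == 0) {
          warning(sprintf("marker %s has zero variance; z-score set to 0", m))
          rep(0, length(x))
        } else (x - mean(x)) / s
      },
      percentile = {
        q <- stats::quantile(x, probs, names = FALSE)
        pmin(pmax(x, q[1]), q[2])
      })
    table[[paste0(m, "_t")]] <- y
  }
  attr(table, "transformed_markers") <- paste0(markers, "_t")
  attr(table, "transform") <- list(method = method, cofactor = cofactor,
                                   probs = probs)
  table
}

#' Graph-based cell clustering (Phenograph-style)
#'
#' Builds a k-nearest-neighbour graph on the transformed marker profiles
#' (Euclidean), weights each edge by the Jaccard overlap of the two cells'
#' neighbour sets, partitions by greedy (Louvain) modularity maximisation,
#' then consolidates the partition: two communities are merged while the
#' edge weight crossing between them exceeds `merge_threshold` of the
#' smaller community's total incident weight. Plain modularity maximisation
#' fragments large homogeneous populations on sparse neighbourhood graphs;
#' genuinely distinct populations have near-zero cross-linkage, so the
#' consolidation removes those fragments without joining separated
#' phenotypes. Deterministic given the seed; clusters are renumbered by
#' decreasing size.
#'
#' @param table a `cell_table` (transformed columns are used when present,
#'   raw marker columns otherwise).
#' @param k_neighbors number of neighbours (default 15); `nrow(table)` must
#'   exceed it.
#' @param seed clustering seed.
#' @param merge_threshold consolidation threshold in (0, 1); communities
#'   whose relative cross-linkage exceeds it are parts of one population.
#' @return the table with a `cluster` column, plus attributes `modularity`
#'   and `k_neighbors`.
#' @export
cluster_cells <- function(table, k_neighbors = 15L, seed = 1L,
                          merge_threshold = 0.04) {
  stopifnot(inherits(table, "cell_table"))
  cols <- attr(table, "transformed_markers") %||% attr(table, "markers")
  X <- as.matrix(table[, cols, drop = FALSE])
  n <- nrow(X)
  if (n < k_neighbors + 1L) {
    stop(sprintf("need more cells (%d) than k_neighbors (%d)", n, k_neighbors))
  }
  if (all(apply(X, 2, function(v) length(unique(v)) == 1L))) {
    warning("all cells identical: a single cluster is returned")
    table$cluster <- 1L
    attr(table, "modularity") <- NA_real_
    attr(table, "k_neighbors") <- k_neighbors
    return(table)
  }
  # canonical processing order: row-order invariance at a fixed seed
  ord <- do.call(order, as.data.frame(X))
  X <- X[ord, , drop = FALSE]
  D <- as.matrix(stats::dist(X))
  diag(D) <- Inf
  nn <- t(apply(D, 1, function(d) order(d)[seq_len(k_neighbors)]))
  # candidate edges: i - j for j in knn(i)
  from <- rep(seq_len(n), each = k_neighbors)
  to <- as.integer(t(nn))
  e <- unique(cbind(pmin(from, to), pmax(from, to)))
  # Jaccard overlap of neighbour sets
  nnl <- lapply(seq_len(n), function(i) nn[i, ])
  w <- vapply(seq_len(nrow(e)), function(r) {
    a <- nnl[[e[r, 1]]]; b <- nnl[[e[r, 2]]]
    inter <- length(intersect(a, b))
    inter / (2 * k_neighbors - inter)
  }, numeric(1))
  keep <- w > 0
  e <- e[keep, , drop = FALSE]
  w <- w[keep]
  g <- igraph::make_graph(t(e), n = n, directed = FALSE)
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, weights = w)
  memb <- consolidate_communities(e, w, as.integer(igraph::membership(cl)),
                                  merge_threshold)
  mod <- igraph::modularity(g, memb, weights = w)
  memb <- memb[order(ord)]  # back to the caller's row order
  sizes <- base::table(memb)
  relab <- stats::setNames(seq_along(sizes),
                           names(sort(sizes, decreasing = TRUE)))
  table$cluster <- as.integer(relab[as.character(memb)])
  attr(table, "modularity") <- mod
  attr(table, "k_neighbors") <- k_neighbors
  table
}

# merge communities while the strongest relative cross-linkage
# (cross weight / total incident weight of the smaller community)
# exceeds the threshold
consolidate_communities <- function(e, w, memb, threshold) {
  repeat {
    cls <- sort(unique(memb))
    k <- length(cls)
    if (k < 2L) break
    idx <- match(memb, cls)
    W <- matrix(0, k, k)
    ea <- idx[e[, 1]]
    eb <- idx[e[, 2]]
    for (r in seq_along(w)) {
      W[ea[r], eb[r]] <- W[ea[r], eb[r]] + w[r]
      if (ea[r] != eb[r]) W[eb[r], ea[r]] <- W[eb[r], ea[r]] + w[r]
    }
    vol <- rowSums(W)
    ratio <- W / outer(vol, vol, pmin)
    diag(ratio) <- 0
    best <- which.max(ratio)
    if (ratio[best] <= threshold) break
    a <- ((best - 1L) %% k) + 1L
    b <- ((best - 1L) %/% k) + 1L
    memb[idx == max(a, b)] <- cls[min(a, b)]
  }
  match(memb, sort(unique(memb)))
}

#' Summarise clusters by mean transformed marker intensity
#'
#' @param table a clustered `cell_table`.
#' @return object of class `cluster_summary`: list with `means` (cluster x
#'   marker matrix of mean transformed intensities, rows exactly equal to
#'   the means of the member cells), `sizes`, and `modularity`.
#' @export
cluster_summary <- function(table) {
  stopifnot(inherits(table, "cell_table"), "cluster" %in% names(table))
  cols <- attr(table, "transformed_markers") %||% attr(table, "markers")
  cl <- table$cluster
  X <- as.matrix(table[, cols, drop = FALSE])
  means <- rowsum(X, cl) / as.vector(base::table(cl))
  sizes <- as.integer(base::table(cl))
  names(sizes) <- rownames(means)
  structure(list(means = means, sizes = sizes,
                 modularity = attr(table, "modularity")),
            class = "cluster_summary")
}

#' @export
print.cluster_summary <- function(x, digits = 3, ...) {
  cat(sprintf("cluster_summary: %d cluster(s), %d cells, modularity %.3f\n",
              nrow(x$means), sum(x$sizes),
              if (is.null(x$modularity) || is.na(x$modularity)) NA else x$modularity))
  print(round(x$means, digits))
  invisible(x)
}

#' Heat map of cluster mean intensities
#'
#' @param x a `cluster_summary`.
#' @param ... passed to [stats::heatmap()].
#' @export
plot.cluster_summary <- function(x, ...) {
  if (nrow(x$means) < 2L) {
    graphics::image(t(x$means), axes = FALSE, main = "cluster means")
    return(invisible(x))
  }
  stats::heatmap(x$means, scale = "none", ...)
  invisible(x)
}

#' Name clusters by marker positivity rules
#'
#' A cluster is positive for a marker when its mean transformed intensity
#' exceeds the across-cluster median plus 0.5 raw MAD for that marker. Each
#' rule lists required signs (e.g. `c("IBA1+", "APOE+", "TREM2+")`); a rule
#' matches when all its constraints hold. The most specific matching rule
#' (most constraints) names the cluster; exact ties report all tied names
#' joined by "|"; a cluster matching no rule is named "unassigned".
#'
#' @param summary a `cluster_summary`.
#' @param rules named list: rule name -> character vector of
#'   `"<marker>+"`/`"<marker>-"` constraints (transformed-column suffixes
#'   `_t` may be omitted).
#' @return data frame (cluster, phenotype, n_cells) with the positivity
#'   matrix as attribute `positive`.
#' @export
assign_phenotypes <- function(summary, rules) {
  stopifnot(inherits(summary, "cluster_summary"), length(rules) >= 1L,
            !is.null(names(rules)))
  means <- summary$means
  cn <- sub("_t$", "", colnames(means))
  colnames(means) <- cn
  med <- apply(means, 2, stats::median)
  madv <- apply(means, 2, stats::mad, constant = 1)
  pos <- sweep(means, 2, med + 0.5 * madv, `>`)
  parsed <- lapply(rules, function(rl) {
    sgn <- substring(rl, nchar(rl))
    mk <- sub("_t$", "", substring(rl, 1, nchar(rl) - 1L))
    if (!all(sgn %in% c("+", "-"))) stop("rule constraints must end in + or -")
    bad <- setdiff(mk, cn)
    if (length(bad)) {
      stop(sprintf("rule references unknown marker(s): %s",
                   paste(bad, collapse = ", ")))
    }
    list(markers = mk, positive = sgn == "+")
  })
  phen <- character(nrow(means))
  for (i in seq_len(nrow(means))) {
    ok <- vapply(parsed, function(p) {
      all(pos[i, p$markers] == p$positive)
    }, logical(1))
    if (!any(ok)) {
      phen[i] <- "unassigned"
    } else {
      nc <- vapply(parsed, function(p) length(p$markers), integer(1))
      best <- max(nc[ok])
      phen[i] <- paste(names(rules)[ok & nc == best], collapse = "|")
    }
  }
  structure(data.frame(cluster = rownames(means), phenotype = phen,
                       n_cells = as.integer(summary$sizes)),
            positive = pos)
}
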