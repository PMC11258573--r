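# Internal raster helpers shared by the segmentation, quantification and
# spatial modules. All operate on plain numeric/integer matrices indexed
# [row, col]; physical coordinates are 0-based pixel indices times the pixel
# size, so reported x_um corresponds to (col - 1) * pixel_size_um.

# Euclidean distance from every pixel to the nearest TRUE pixel of `mask`.
# Pixels inside the mask get 0. If the mask is empty, all distances are Inf.
# The transform is computed in single precision; distances are snapped to
# 1e-3 px so that thresholding at integer radii is position-independent.
dist_to_mask <- function(mask) {
  if (!any(mask)) {
    return(matrix(Inf, nrow(mask), ncol(mask)))
  }
  src <- matrix(1, nrow(mask), ncol(mask))
  src[mask] <- 0
  d <- EBImage::distmap(src, metric = "euclidean")
  round(matrix(as.numeric(d), nrow(mask), ncol(mask)), 3)
}

# Render a filled disc into a logical matrix. Centre given in 1-based matrix
# indices (may be fractional), radius in pixels.
disc_mask <- function(nr, nc, centre_row, centre_col, radius_px) {
  r0 <- max(1L, floor(centre_row - radius_px))
  r1 <- min(nr, ceiling(centre_row + radius_px))
  c0 <- max(1L, floor(centre_col - radius_px))
  c1 <- min(nc, ceiling(centre_col + radius_px))
  out <- matrix(FALSE, nr, nc)
  if (r0 > r1 || c0 > c1) return(out)
  rows <- r0:r1
  cols <- c0:c1
  dr <- outer(rows - centre_row, rep(1, length(cols)))
  dc <- outer(rep(1, length(rows)), cols - centre_col)
  out[rows, cols] <- (dr * dr + dc * dc) <= radius_px * radius_px
  out
}

# 4- or 8-connected components of a logical mask. Labels are dense 1..N and
# ordered by the smallest column-major pixel index of each component, so the
# labelling is deterministic and independent of how the mask was produced.
label_components <- function(mask, connectivity = 4L) {
  stopifnot(connectivity %in% c(4L, 8L))
  nr <- nrow(mask)
  nc <- ncol(mask)
  idx <- which(mask)
  out <- matrix(0L, nr, nc)
  if (length(idx) == 0L) {
    attr(out, "n_objects") <- 0L
    return(out)
  }
  # edges to the pixel below and to the right (and diagonals for 8-conn)
  edge_from <- integer(0)
  edge_to <- integer(0)
  row_of <- ((idx - 1L) %% nr) + 1L
  col_of <- ((idx - 1L) %/% nr) + 1L
  add_edges <- function(dr, dc) {
    ok <- row_of + dr >= 1L & row_of + dr <= nr & col_of + dc >= 1L & col_of + dc <= nc
    nb <- idx[ok] + dr + dc * nr
    keep <- mask[nb]
    list(from = idx[ok][keep], to = nb[keep])
  }
  steps <- list(c(1L, 0L), c(0L, 1L))
  if (connectivity == 8L) steps <- c(steps, list(c(1L, 1L), c(-1L, 1L)))
  for (s in steps) {
    e <- add_edges(s[1], s[2])
    edge_from <- c(edge_from, e$from)
    edge_to <- c(edge_to, e$to)
  }
  vid <- match(idx, idx)  # 1..n in column-major order
  g <- igraph::make_graph(rbind(match(edge_from, idx), match(edge_to, idx)),
                          n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  # relabel so component labels follow the first (smallest index) pixel
  first_seen <- !duplicated(comp)
  relab <- integer(max(comp))
  relab[comp[first_seen]] <- seq_len(sum(first_seen))
  out[idx] <- relab[comp]
  attr(out, "n_objects") <- sum(first_seen)
  out
}

# Compact labels to 1..N, ordered by smallest column-major pixel index.
relabel_dense <- function(labels) {
  idx <- which(labels > 0L)
  out <- labels
  out[] <- 0L
  if (length(idx) == 0L) {
    attr(out, "n_objects") <- 0L
    return(out)
  }
  lab <- labels[idx]
  first <- !duplicated(lab)
  relab <- integer(max(lab))
  relab[lab[first]] <- seq_len(sum(first))
  out[idx] <- relab[lab]
  attr(out, "n_objects") <- sum(first)
  out
}

# Exact Euclidean nearest-label expansion. Every pixel within `max_dist_px`
# of some labelled object is assigned the label of the nearest labelled
# pixel; distance ties go to the lower label index (labels are visited in
# increasing order and only a strictly smaller distance displaces an
# assignment). Returns list(labels, dist).
nearest_label_expand <- function(labels, max_dist_px) {
  labs <- sort(unique(labels[labels > 0L]))
  nr <- nrow(labels)
  nc <- ncol(labels)
  best_d <- matrix(Inf, nr, nc)
  best_l <- matrix(0L, nr, nc)
  for (l in labs) {
    d <- dist_to_mask(labels == l)
    upd <- d < best_d
    best_d[upd] <- d[upd]
    best_l[upd] <- l
  }
  best_l[best_d > max_dist_px] <- 0L
  list(labels = best_l, dist = best_d)
}

# Per-label pixel counts, as a named integer vector over labels 1..N.
label_areas_px <- function(labels, n = max(labels, 0L)) {
  if (n == 0L) return(integer(0))
  tabulate(labels[labels > 0L], nbins = n)
}

# Zhang-Suen thinning of a logical mask down to a 1-px skeleton.
skeletonize <- function(mask) {
  m <- mask
  nr <- nrow(m)
  nc <- ncol(m)
  if (!any(m)) return(m)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- m
  shift <- function(x, dr, dc) {
    out <- matrix(FALSE, nrow(x), ncol(x))
    rs <- max(1, 1 + dr):min(nrow(x), nrow(x) + dr)
    cs <- max(1, 1 + dc):min(ncol(x), ncol(x) + dc)
    out[rs, cs] <- x[rs - dr, cs - dc]
    out
  }
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p2 <- shift(pad, -1, 0); p3 <- shift(pad, -1, 1); p4 <- shift(pad, 0, 1)
      p5 <- shift(pad, 1, 1);  p6 <- shift(pad, 1, 0);  p7 <- shift(pad, 1, -1)
      p8 <- shift(pad, 0, -1); p9 <- shift(pad, -1, -1)
      bsum <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      # number of 0->1 transitions in the ordered ring p2..p9,p2
      a <- (!p2 & p3) + (!p3 & p4) + (!p4 & p5) + (!p5 & p6) +
           (!p6 & p7) + (!p7 & p8) + (!p8 & p9) + (!p9 & p2)
      if (sub == 1) {
        cond <- pad & bsum >= 2 & bsum <= 6 & a == 1 &
          !(p2 & p4 & p6) & !(p4 & p6 & p8)
      } else {
        cond <- pad & bsum >= 2 & bsum <= 6 & a == 1 &
          !(p2 & p4 & p8) & !(p2 & p6 & p8)
      }
      if (any(cond)) {
        pad[cond] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  pad[2:(nr + 1L), 2:(nc + 1L)]
}

# Geometric length of a skeleton: orthogonally adjacent skeleton pixel pairs
# contribute 1 px, diagonal pairs sqrt(2) px; a diagonal link is skipped when
# the step is already covered by two orthogonal links through a shared
# neighbour (avoids double counting at corners). Thinning erodes the ends of
# elongated shapes by roughly their half-width, so when the original mask is
# supplied each skeleton endpoint (<= 1 skeleton neighbour; an isolated pixel
# counts as two endpoints) is compensated by the mask's distance-transform
# value there, i.e. the local inscribed radius.
skeleton_length_px <- function(skel, mask = NULL) {
  if (!any(skel)) return(0)
  nr <- nrow(skel)
  nc <- ncol(skel)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- skel
  at <- function(dr, dc) pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc, drop = FALSE]
  ctr <- pad[2:(nr + 1L), 2:(nc + 1L), drop = FALSE]
  n_orth <- sum(ctr & at(1, 0)) + sum(ctr & at(0, 1))
  # diagonal neighbours down-right and up-right, minus triangle shortcuts
  dr_ok <- ctr & at(1, 1) & !(at(1, 0) | at(0, 1))
  ur_ok <- ctr & at(-1, 1) & !(at(-1, 0) | at(0, 1))
  n_diag <- sum(dr_ok) + sum(ur_ok)
  len <- n_orth + sqrt(2) * n_diag
  if (!is.null(mask)) {
    nbr <- at(-1, -1) + at(-1, 0) + at(-1, 1) + at(0, -1) + at(0, 1) +
      at(1, -1) + at(1, 0) + at(1, 1)
    ends <- ctr & nbr <= 1L
    if (any(ends)) {
      dt <- matrix(as.numeric(EBImage::distmap(mask * 1)), nr, nc)
      w <- ifelse(nbr[ends] == 0L, 2, 1)  # isolated pixel: both ends eroded
      len <- len + sum(w * dt[ends])
    }
  }
  len
}

# Otsu threshold for an arbitrary-range raster.
otsu_threshold <- function(x) {
  rng <- range(x, finite = TRUE)
  if (diff(rng) <= 0) return(rng[1])
  as.numeric(EBImage::otsu(EBImage::Image((x - rng[1]) / diff(rng)),
                           range = c(0, 1))) * diff(rng) + rng[1]
}

# Resolve a threshold rule: numeric -> itself; "otsu" -> data-driven;
# NULL -> strictly-positive rule encoded as just-above-zero.
resolve_threshold <- function(rule, raster) {
  if (is.null(rule)) return(.Machine$double.xmin)
  if (is.character(rule) && identical(rule, "otsu")) return(otsu_threshold(raster))
  if (is.numeric(rule) && length(rule) == 1L) return(rule)
  stop("threshold rule must be a single number, \"otsu\", or NULL (positive pixels)")
}

stop_infeasible <- function(msg) {
  stop(structure(class = c("neuroprox_infeasible_scene", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
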