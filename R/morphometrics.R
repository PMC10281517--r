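#' Measure cell axes from labelled line-segment annotations
#'
#' Consumes draw-a-line annotations (the manual measurement workflow:
#' lateral, apical, basal and width segments per cell, drawn on junction or
#' cytoskeleton staining) and converts them to calibrated lengths. Each
#' segment length is the Euclidean endpoint distance times `pixel_size`;
#' the length/width ratio is lateral over width. Cells flagged as not
#' integrated into the epithelial sheet (rounded-up dividing cells) are
#' excluded and listed in the `excluded_cells` attribute.
#'
#' @param annotations data.frame with columns `cell_id`, `role` (one of
#'   `"lateral"`, `"apical"`, `"basal"`, `"width"`), `x0`, `y0`, `x1`, `y1`
#'   (px), and optionally `exclude` (logical).
#' @param pixel_size micrometres per pixel.
#' @param exclude optional vector of cell ids to drop (merged with any
#'   `exclude` column).
#' @return data.frame: `cell_id`, `lateral`, `apical`, `basal`, `width`
#'   (um; `NA` where the role is missing) and `length_width`; excluded ids
#'   in `attr(, "excluded_cells")`.
#' @export
measure_cell_axes <- function(annotations, pixel_size = 1, exclude = NULL) {
  stopifnot(all(c("cell_id", "role", "x0", "y0", "x1", "y1") %in% names(annotations)),
            pixel_size > 0)
  flagged <- unique(c(exclude,
                      if ("exclude" %in% names(annotations))
                        annotations$cell_id[isTRUE_vec(annotations$exclude)]))
  keep <- !(annotations$cell_id %in% flagged)
  if (length(flagged))
    message("excluding ", length(flagged),
            " cell(s) not integrated into the epithelial sheet: ",
            paste(flagged, collapse = ", "))
  ann <- annotations[keep, , drop = FALSE]
  len <- sqrt((ann$x1 - ann$x0)^2 + (ann$y1 - ann$y0)^2) * pixel_size
  ids <- unique(ann$cell_id)
  get_role <- function(id, role) {
    w <- which(ann$cell_id == id & ann$role == role)
    if (length(w) == 0) NA_real_ else len[w[1]]
  }
  out <- data.frame(cell_id = ids,
                    lateral = vapply(ids, get_role, numeric(1), role = "lateral"),
                    apical = vapply(ids, get_role, numeric(1), role = "apical"),
                    basal = vapply(ids, get_role, numeric(1), role = "basal"),
                    width = vapply(ids, get_role, numeric(1), role = "width"))
  out$length_width <- out$lateral / out$width
  miss <- is.na(out$length_width) & !(out$cell_id %in% flagged)
  if (any(miss))
    message(sum(miss), " cell(s) lack a lateral or width segment; ",
            "length/width reported as NA")
  attr(out, "excluded_cells") <- flagged
  out
}

isTRUE_vec <- function(x) !is.na(x) & x

# Crofton perimeter (4 directions) from the 2x2 pixel-configuration
# histogram; the standard estimator that keeps mask-based circularity <= 1
# where naive pixel-edge counting overshoots.
crofton_perimeter <- function(mask) {
  m <- matrix(0L, nrow(mask) + 2, ncol(mask) + 2)
  m[2:(nrow(mask) + 1), 2:(ncol(mask) + 1)] <- as.integer(mask > 0)
  nr <- nrow(m); nc <- ncol(m)
  a <- m[1:(nr - 1), 1:(nc - 1)]; b <- m[1:(nr - 1), 2:nc]
  d <- m[2:nr, 1:(nc - 1)]; e <- m[2:nr, 2:nc]
  code <- a + 4L * b + 2L * d + 8L * e
  h <- tabulate(code + 1L, nbins = 16L)
  s2 <- sqrt(2)
  coefs <- c(0, pi / 4 * (1 + 1 / s2), pi / (4 * s2), pi / (2 * s2),
             0, pi / 4 * (1 + 1 / s2), 0, pi / (4 * s2),
             pi / 4, pi / 2, pi / (4 * s2), pi / (4 * s2),
             pi / 4, pi / 2, 0, 0)
  sum(coefs * h)
}

# Pairwise proper-intersection test for polygon self-intersection.
segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2); d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
      ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

#' Nucleus circularity
#'
#' Computes circularity `4 * pi * area / perimeter^2` — 1 for a perfect
#' circle, decreasing with elongation or irregularity. For a traced outline
#' polygon, area is the shoelace formula and perimeter the exact vertex
#' chain; for a labelled mask, area is the pixel count and perimeter the
#' Crofton 4-direction estimator. Circularity is invariant under rotation
#' and uniform scaling of a polygon.
#'
#' @param outline either a two-column matrix of polygon vertices (closed
#'   implicitly; simple, i.e. non-self-intersecting) or a logical/integer
#'   mask matrix of one nucleus.
#' @return circularity (dimensionless scalar).
#' @export
nucleus_circularity <- function(outline) {
  if (is.matrix(outline) && ncol(outline) == 2 && !is.logical(outline) &&
      nrow(outline) >= 3 && max(abs(outline)) > 0 && !all(outline %in% c(0, 1))) {
    xy <- outline
    n <- nrow(xy)
    if (n > 3) {
      for (i in 1:(n - 1)) for (j in (i + 1):n) {
        if (abs(i - j) <= 1 || (i == 1 && j == n)) next
        if (segments_intersect(xy[i, ], xy[i %% n + 1, ], xy[j, ], xy[j %% n + 1, ]))
          stop("polygon is self-intersecting (edges ", i, " and ", j, ")")
      }
    }
    p <- polygon_perimeter(xy)
    if (p == 0) return(0)
    return(4 * pi * polygon_area(xy) / p^2)
  }
  mask <- outline > 0
  a <- sum(mask)
  if (a == 0) return(NA_real_)
  p <- crofton_perimeter(mask)
  4 * pi * a / p^2
}

#' Per-cell marker intensity (nuclear + ring cytoplasm)
#'
#' The per-cell score for a phospho-marker (e.g. pERK or pAKT): mean
#' intensity over the nuclear region plus mean intensity over the ring
#' cytoplasm region, added up as one per-cell value. Raw integrated sums
#' are also emitted. Cells whose ring is empty (fully contested) get a
#' nuclear-only score and are flagged.
#'
#' @param marker 2D intensity matrix.
#' @param nuclei,rings matching label maps.
#' @return data.frame: `cell`, `score` (mean nuclear + mean ring),
#'   `nuclear_mean`, `ring_mean`, `nuclear_sum`, `ring_sum`,
#'   `ring_missing`.
#' @export
per_cell_marker_intensity <- function(marker, nuclei, rings) {
  stopifnot(identical(dim(marker), dim(nuclei)), identical(dim(marker), dim(rings)))
  ids <- sort(unique(nuclei[nuclei > 0]))
  do.call(rbind, lapply(ids, function(k) {
    wn <- which(nuclei == k); wr <- which(rings == k)
    nm <- mean(marker[wn])
    rm_ <- if (length(wr)) mean(marker[wr]) else NA_real_
    data.frame(cell = k,
               score = nm + if (length(wr)) rm_ else 0,
               nuclear_mean = nm, ring_mean = rm_,
               nuclear_sum = sum(marker[wn]),
               ring_sum = if (length(wr)) sum(marker[wr]) else 0,
               ring_missing = length(wr) == 0)
  }))
}

# 1D Otsu threshold over a vector of per-object means: exhaustive search
# over midpoints between consecutive sorted values.
otsu_on_means <- function(v) {
  u <- sort(unique(v))
  if (length(u) < 2) return(u[1])
  cand <- (u[-1] + u[-length(u)]) / 2
  bc <- vapply(cand, function(th) {
    g1 <- v[v <= th]; g2 <- v[v > th]
    w1 <- length(g1) / length(v); w2 <- 1 - w1
    w1 * w2 * (mean(g1) - mean(g2))^2
  }, numeric(1))
  cand[which.max(bc)]
}

#' Fraction of marker-positive nuclei in one plane
#'
#' A nucleus is positive iff its mean marker intensity exceeds the
#' threshold — fixed, or Otsu over the per-nucleus means (so the call is
#' invariant under any strictly monotone intensity transform when the two
#' populations are separated).
#'
#' @param marker 2D intensity matrix.
#' @param nuclei nucleus label map.
#' @param rule `"otsu"` or `"fixed"`.
#' @param threshold threshold for `rule = "fixed"`.
#' @return list: `positives`, `total`, `fraction` (`NA` with zero nuclei),
#'   `threshold`, and `per_cell` data.frame (`cell`, `mean`, `positive`).
#' @export
positive_fraction_2d <- function(marker, nuclei, rule = c("otsu", "fixed"),
                                 threshold = NULL) {
  rule <- match.arg(rule)
  ids <- sort(unique(nuclei[nuclei > 0]))
  if (length(ids) == 0) {
    message("no nuclei in label map; fraction undefined")
    return(list(positives = 0L, total = 0L, fraction = NA_real_,
                threshold = NA_real_, per_cell = data.frame()))
  }
  means <- vapply(ids, function(k) mean(marker[nuclei == k]), numeric(1))
  th <- if (rule == "fixed") {
    if (is.null(threshold)) stop("fixed rule needs a threshold")
    threshold
  } else otsu_on_means(means)
  pos <- means > th
  list(positives = sum(pos), total = length(ids), fraction = mean(pos),
       threshold = th,
       per_cell = data.frame(cell = ids, mean = means, positive = pos))
}

# ---- 3D helpers ------------------------------------------------------------

shift3 <- function(a, dr, dc, dz, fill = 0L) {
  d <- dim(a)
  out <- array(fill, d)
  rs <- max(1, 1 + dr):min(d[1], d[1] + dr)
  cs <- max(1, 1 + dc):min(d[2], d[2] + dc)
  zs <- max(1, 1 + dz):min(d[3], d[3] + dz)
  out[rs, cs, zs] <- a[rs - dr, cs - dc, zs - dz]
  out
}

offsets26 <- function() {
  out <- list()
  for (dr in -1:1) for (dc in -1:1) for (dz in -1:1)
    if (dr || dc || dz) out[[length(out) + 1L]] <- c(dr, dc, dz)
  out
}

erode3 <- function(mask) {
  out <- mask
  for (off in offsets26())
    out <- out & shift3(mask, off[1], off[2], off[3], FALSE)
  out
}

# 26-connected 3D components: per-plane 2D labelling then union-find
# merging of labels overlapping between adjacent planes (incl. diagonal
# shifts).
label3d <- function(mask) {
  d <- dim(mask)
  planes <- lapply(seq_len(d[3]), function(z)
    if (any(mask[, , z])) as.matrix(EBImage::bwlabel(EBImage::Image(mask[, , z])))
    else matrix(0L, d[1], d[2]))
  offs <- as.integer(cumsum(c(0, vapply(planes, max, numeric(1))))[seq_len(d[3])])
  lab <- array(0L, d)
  for (z in seq_len(d[3])) {
    p <- planes[[z]]
    p[p > 0] <- p[p > 0] + offs[z]
    lab[, , z] <- as.integer(p)
  }
  total <- max(lab)
  if (total == 0) return(lab)
  parent <- seq_len(total)
  find <- function(x) { x <- as.integer(x); while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  union <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
  for (z in seq_len(d[3] - 1)) {
    a <- lab[, , z]; b <- lab[, , z + 1]
    for (dr in -1:1) for (dc in -1:1) {
      bs <- shift_mat(b, dr, dc, 0L)
      sel <- a > 0 & bs > 0
      if (any(sel)) {
        pairs <- unique(cbind(a[sel], bs[sel]))
        for (r in seq_len(nrow(pairs))) union(pairs[r, 1], pairs[r, 2])
      }
    }
  }
  roots <- vapply(seq_len(total), find, integer(1))
  lab[lab > 0] <- roots[lab[lab > 0]]
  # renumber sequentially
  ids <- sort(unique(lab[lab > 0]))
  map <- integer(max(ids)); map[ids] <- seq_along(ids)
  lab[lab > 0] <- map[lab[lab > 0]]
  lab
}

#' Count nuclei (total and marker-positive) in a 3D stack
#'
#' Per-plane thresholding (Otsu by default) followed by 26-connected 3D
#' component labelling and a minimum-volume filter. Optionally splits
#' touching objects by distance-core seeding: the mask is eroded until
#' cores separate, and every foreground voxel is assigned to the nearest
#' core (a seeded-watershed surrogate). Positivity of a component uses its
#' volumetric mean marker intensity, thresholded as in
#' [positive_fraction_2d()]. A single-plane input falls back to 2D with a
#' warning.
#'
#' @param volume 3D numeric array (rows, cols, z) of the nuclear channel.
#' @param marker optional 3D marker array of the same shape.
#' @param threshold fixed intensity threshold, or `NULL` for per-plane Otsu.
#' @param min_volume smallest component kept, voxels.
#' @param split_touching split touching components via distance cores.
#' @param z_ratio z-step / pixel-size anisotropy ratio (recorded; counting
#'   itself is connectivity-based and does not resample).
#' @return list: `total`, `positive` (`NA` without a marker), `labels`
#'   (3D integer array), `table` (per-component volume and marker mean).
#' @export
count_nuclei_3d <- function(volume, marker = NULL, threshold = NULL,
                            min_volume = 30, split_touching = FALSE, z_ratio = 1) {
  if (is.matrix(volume)) volume <- array(volume, c(dim(volume), 1))
  d <- dim(volume)
  if (d[3] == 1) warning("single-plane input; counting falls back to 2D")
  mask <- array(FALSE, d)
  for (z in seq_len(d[3])) {
    pl <- volume[, , z]
    th <- threshold %||%
      (if (max(pl) > min(pl)) EBImage::otsu(EBImage::Image(clamp(pl, 0, 1))) else Inf)
    mask[, , z] <- pl > th
  }
  if (!any(mask))
    return(list(total = 0L, positive = if (is.null(marker)) NA_integer_ else 0L,
                labels = array(0L, d), table = data.frame()))
  if (split_touching) {
    lab_core <- label3d(erode3(mask))
    if (max(lab_core) >= 1) {
      # assign remaining voxels to the nearest core by BFS dilation
      lab <- lab_core
      repeat {
        remaining <- mask & lab == 0
        if (!any(remaining)) break
        prev <- lab
        for (off in offsets26()) {
          cand <- shift3(prev, off[1], off[2], off[3], 0L)
          take <- remaining & cand > 0 & lab == 0
          lab[take] <- cand[take]
        }
        if (identical(lab, prev)) break   # voxels unreachable from any core
      }
    } else lab <- label3d(mask)
  } else {
    lab <- label3d(mask)
  }
  sizes <- tabulate(lab[lab > 0])
  drop <- which(sizes > 0 & sizes < min_volume)
  if (length(drop)) lab[array(lab %in% drop, dim(lab))] <- 0L
  ids <- sort(unique(lab[lab > 0]))
  if (length(ids) == 0)
    return(list(total = 0L, positive = if (is.null(marker)) NA_integer_ else 0L,
                labels = lab, table = data.frame()))
  tab <- do.call(rbind, lapply(ids, function(k)
    data.frame(label = k, volume_vox = sum(lab == k),
               marker_mean = if (is.null(marker)) NA_real_ else mean(marker[lab == k]))))
  positive <- NA_integer_
  if (!is.null(marker)) {
    th <- otsu_on_means(tab$marker_mean)
    tab$positive <- tab$marker_mean > th
    positive <- sum(tab$positive)
  }
  list(total = length(ids), positive = positive, labels = lab, table = tab)
}

#' Classify an organoid silhouette as spherical or budding
#'
#' Computes solidity (mask area over convex-hull area) and classifies the
#' silhouette as budding when solidity falls below the threshold. The
#' default cut of 0.92 is calibrated on the synthetic silhouette suite
#' (disks vs multi-lobed shapes separate with a wide margin) and is an
#' automated surrogate for manual phenotype counting: when a manual label
#' is supplied it overrides the automated call and is reported alongside.
#'
#' @param mask logical or 0/1 matrix; if disconnected, the largest
#'   component is classified with a warning.
#' @param threshold solidity cut below which the shape is called budding.
#' @param manual_label optional `"spherical"`/`"budding"` manual call.
#' @return list: `class`, `solidity`, `area_px`, `overridden`.
#' @export
classify_budding <- function(mask, threshold = 0.92, manual_label = NULL) {
  mask <- mask > 0
  if (!any(mask)) stop("empty mask")
  lab <- as.matrix(EBImage::bwlabel(EBImage::Image(mask)))
  if (max(lab) > 1) {
    warning("disconnected mask; classifying the largest component")
    sizes <- tabulate(lab[lab > 0])
    mask <- lab == which.max(sizes)
  }
  pts <- which(mask, arr.ind = TRUE)
  hull <- grDevices::chull(pts[, 1], pts[, 2])
  hxy <- pts[hull, , drop = FALSE]
  # hull of pixel centres, corrected to approximate pixel coverage
  hull_area <- polygon_area(hxy) + polygon_perimeter(hxy) / 2 + 1
  solidity <- nrow(pts) / hull_area
  auto <- if (solidity < threshold) "budding" else "spherical"
  cls <- manual_label %||% auto
  list(class = cls, solidity = solidity, area_px = nrow(pts),
       overridden = !is.null(manual_label) && !identical(manual_label, auto))
}
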