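#' Segmentation parameters
#'
#' Settings for nuclear and organoid segmentation. The pipeline standardises
#' on Gaussian smoothing, Otsu (or fixed) thresholding, hole filling and an
#' optional distance-transform watershed to split touching nuclei; every
#' knob is exposed here. `ring_width` is the width, in 1-px dilation steps,
#' of the ring used as the cytoplasmic proxy region around each nucleus
#' (default 5 px).
#'
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param fixed_threshold intensity threshold when `threshold_method="fixed"`.
#' @param min_nucleus_area smallest object kept, px.
#' @param watershed_split split touching blobs by distance-transform watershed.
#' @param ring_width cytoplasm ring width in dilation steps (>= 1).
#' @param smoothing_sigma Gaussian pre-smoothing sigma, px (0 = none). The
#'   default of 2 px places the segmented boundary just outside the
#'   partial-volume rim of a nucleus, so ring pixels adjacent to the
#'   segmentation carry pure cytoplasmic signal; touching nuclei are still
#'   separated by the watershed.
#' @param connectivity 4 or 8; structuring element for ring dilation
#'   (8 = 3x3 square, the default).
#' @param measure_erosion erosion steps applied to the nuclear mask before
#'   measuring nuclear intensity (the ring stays anchored to the uneroded
#'   segmentation). Smoothing and thresholding place the segmented boundary
#'   about a pixel outside the true nucleus, so the rim mixes nuclear and
#'   cytoplasmic signal; eroding the measurement mask keeps the nuclear
#'   mean uncontaminated. Default 2 px.
#' @return object of class `seg_params`.
#' @export
seg_params <- function(threshold_method = c("otsu", "fixed"), fixed_threshold = 0.5,
                       min_nucleus_area = 20, watershed_split = TRUE,
                       ring_width = 5, smoothing_sigma = 2, connectivity = 8,
                       measure_erosion = 2) {
  threshold_method <- match.arg(threshold_method)
  stopifnot(ring_width >= 1, min_nucleus_area >= 1, connectivity %in% c(4, 8),
            measure_erosion >= 0)
  structure(list(threshold_method = threshold_method, fixed_threshold = fixed_threshold,
                 min_nucleus_area = min_nucleus_area, watershed_split = watershed_split,
                 ring_width = as.integer(ring_width), smoothing_sigma = smoothing_sigma,
                 connectivity = as.integer(connectivity),
                 measure_erosion = as.integer(measure_erosion)),
            class = "seg_params")
}

#' Erode a label map (labels preserved)
#'
#' Removes `steps` one-pixel layers from every labelled object (3x3
#' structuring element). Used to shrink nuclear masks for intensity
#' measurement so the boundary rim does not contaminate the nuclear mean.
#'
#' @param labels integer label map.
#' @param steps erosion steps (0 returns the input).
#' @return eroded integer label map.
#' @export
erode_labels <- function(labels, steps = 1) {
  if (steps < 1) return(labels)
  mask <- labels > 0
  for (s in seq_len(steps)) {
    m <- mask
    for (off in neighbour_offsets(8L))
      m <- m & shift_mat(mask, off[1], off[2], FALSE)
    mask <- m
  }
  out <- labels
  out[!mask] <- 0L
  out
}

# Deterministic relabelling: labels numbered 1..n by first (column-major)
# pixel occurrence.
relabel_sequential <- function(lab) {
  ids <- unique(lab[lab > 0])
  if (length(ids) == 0) return(matrix(0L, nrow(lab), ncol(lab)))
  first <- vapply(ids, function(k) which(lab == k)[1], numeric(1))
  ids <- ids[order(first)]
  out <- matrix(0L, nrow(lab), ncol(lab))
  for (i in seq_along(ids)) out[lab == ids[i]] <- i
  out
}

#' Segment nuclei from a nuclear-dye channel
#'
#' Gaussian smoothing, thresholding (Otsu by default), hole filling,
#' optional watershed splitting of touching nuclei on the distance
#' transform, and a minimum-area filter. Returns an integer label map
#' (0 = background) with a `provenance` attribute recording the parameters.
#'
#' @param img 2D numeric matrix (one plane of the nuclear channel),
#'   intensities in `[0, 1]`.
#' @param params a [seg_params()].
#' @return integer matrix of nucleus labels.
#' @export
segment_nuclei <- function(img, params = seg_params()) {
  stopifnot(is.matrix(img), all(is.finite(img)))
  x <- img
  if (params$smoothing_sigma > 0)
    x <- as.matrix(EBImage::gblur(EBImage::Image(x), sigma = params$smoothing_sigma))
  thr <- if (params$threshold_method == "otsu") {
    if (max(x) > min(x)) EBImage::otsu(EBImage::Image(clamp(x, 0, 1))) else Inf
  } else params$fixed_threshold
  mask <- x > thr
  if (!any(mask)) {
    warning("no foreground found; returning empty label map")
    out <- matrix(0L, nrow(img), ncol(img))
    attr(out, "provenance") <- unclass(params)
    return(out)
  }
  mask <- as.matrix(EBImage::fillHull(EBImage::Image(mask))) > 0
  lab <- if (params$watershed_split) {
    dm <- EBImage::distmap(EBImage::Image(mask))
    as.matrix(EBImage::watershed(dm, tolerance = 1, ext = 1))
  } else {
    as.matrix(EBImage::bwlabel(EBImage::Image(mask)))
  }
  sizes <- tabulate(lab[lab > 0])
  drop <- which(sizes > 0 & sizes < params$min_nucleus_area)
  if (length(drop)) lab[lab %in% drop] <- 0L
  out <- relabel_sequential(lab)
  attr(out, "provenance") <- unclass(params)
  out
}

#' Ring-shaped cytoplasm proxy around each nucleus
#'
#' For each nucleus label, the ring is the set of pixels reached within
#' `ring_width` successive 1-px morphological dilations of that nucleus,
#' excluding all nucleus pixels (of any label) and clipped at the image
#' border. A pixel reachable from several nuclei is assigned to the nucleus
#' reached in the fewest dilation steps, ties going to the smaller label id
#' (`contested = "nearest"`), or dropped entirely (`contested = "exclude"`).
#' Ring labels mirror nucleus labels. Dilation uses a 3x3 square element by
#' default (`connectivity = 8`; step distance is then the Chebyshev
#' distance to the nucleus) or a cross element (`connectivity = 4`,
#' Manhattan distance).
#'
#' @param nuclei integer nucleus label map.
#' @param ring_width ring width in dilation steps (>= 1).
#' @param connectivity 4 or 8.
#' @param contested `"nearest"` (default) or `"exclude"`.
#' @return integer matrix of ring labels, disjoint from the nuclei.
#' @export
ring_cytoplasm <- function(nuclei, ring_width = 5, connectivity = 8,
                           contested = c("nearest", "exclude")) {
  contested <- match.arg(contested)
  if (ring_width < 1) stop("ring_width must be >= 1")
  stopifnot(is.matrix(nuclei), connectivity %in% c(4, 8))
  ids <- sort(unique(nuclei[nuclei > 0]))
  nr <- nrow(nuclei); nc <- ncol(nuclei)
  best_step <- matrix(Inf, nr, nc)
  best_lab <- matrix(0L, nr, nc)
  tie <- matrix(FALSE, nr, nc)
  for (k in ids) {   # ascending ids: ties keep the smaller label
    cur <- nuclei == k
    step_k <- matrix(Inf, nr, nc)
    step_k[cur] <- 0
    for (s in seq_len(ring_width)) {
      grown <- dilate_once(cur, connectivity)
      new <- grown & !is.finite(step_k)
      step_k[new] <- s
      cur <- grown
    }
    better <- step_k < best_step
    equal <- is.finite(step_k) & step_k == best_step
    tie[equal] <- TRUE
    tie[better] <- FALSE
    best_step[better] <- step_k[better]
    best_lab[better] <- k
  }
  ring <- best_lab
  ring[nuclei > 0] <- 0L          # never inside any nucleus
  ring[!is.finite(best_step) | best_step == 0] <- 0L
  if (contested == "exclude") ring[tie] <- 0L
  ring
}

#' Segment organoids and measure their projected areas
#'
#' Thresholds a silhouette or transmitted-light image (optionally
#' inverted, so dark organoids on a bright background become foreground),
#' fills holes, removes small objects and reports per-object pixel counts
#' and calibrated areas. Logical input is used as the mask directly.
#'
#' @param img 2D numeric matrix or logical mask.
#' @param pixel_size micrometres per pixel.
#' @param threshold fixed threshold, or `NULL` for Otsu.
#' @param invert invert intensities before thresholding.
#' @param min_area smallest object kept, px.
#' @param fill_holes fill interior holes before measuring.
#' @return list with `labels` (integer matrix) and `table` (data.frame:
#'   `label`, `area_px`, `area_um2`, `centroid_row`, `centroid_col`).
#' @export
segment_organoid_area <- function(img, pixel_size = 1, threshold = NULL,
                                  invert = FALSE, min_area = 50, fill_holes = TRUE) {
  stopifnot(pixel_size > 0)
  if (is.logical(img)) {
    mask <- img
  } else {
    x <- if (invert) max(img) - img else img
    thr <- threshold %||%
      (if (max(x) > min(x)) EBImage::otsu(EBImage::Image(clamp(x, 0, 1))) else Inf)
    mask <- x > thr
  }
  if (fill_holes && any(mask))
    mask <- as.matrix(EBImage::fillHull(EBImage::Image(mask))) > 0
  lab <- if (any(mask)) as.matrix(EBImage::bwlabel(EBImage::Image(mask)))
         else matrix(0L, nrow(img), ncol(img))
  sizes <- tabulate(lab[lab > 0])
  drop <- which(sizes > 0 & sizes < min_area)
  if (length(drop)) lab[lab %in% drop] <- 0L
  lab <- relabel_sequential(lab)
  ids <- sort(unique(lab[lab > 0]))
  tab <- do.call(rbind, lapply(ids, function(k) {
    w <- which(lab == k, arr.ind = TRUE)
    data.frame(label = k, area_px = nrow(w),
               area_um2 = nrow(w) * pixel_size^2,
               centroid_row = mean(w[, 1]) - 1, centroid_col = mean(w[, 2]) - 1)
  }))
  if (is.null(tab))
    tab <- data.frame(label = integer(0), area_px = integer(0), area_um2 = numeric(0),
                      centroid_row = numeric(0), centroid_col = numeric(0))
  list(labels = lab, table = tab)
}

#' Select non-consecutive z planes for per-plane analysis
#'
#' Mirrors the acquisition practice of analysing at least three
#' non-consecutive z planes per time point, reusing the same relative z
#' positions for every frame. Default strategy spaces `n_planes` indices
#' evenly; an explicit 0-based index list is accepted (mirroring a manual
#' choice) and checked for adjacency.
#'
#' @param n_z number of z levels in the stack (or a 5D `(T,Z,C,Y,X)` array,
#'   from which Z is taken).
#' @param n_planes number of planes to select.
#' @param indices optional explicit 0-based indices, returned verbatim
#'   after validation.
#' @return integer vector of 0-based z indices.
#' @export
select_planes <- function(n_z, n_planes = 3, indices = NULL) {
  if (is.array(n_z)) n_z <- dim(n_z)[2]
  n_z <- as.integer(n_z)
  max_feasible <- as.integer(ceiling(n_z / 2))
  if (!is.null(indices)) {
    indices <- as.integer(indices)
    if (any(indices < 0 | indices >= n_z)) stop("indices out of range [0, ", n_z - 1, "]")
    if (length(indices) > 1 && any(diff(sort(indices)) < 2))
      stop("indices must be non-consecutive (pairwise gap >= 2)")
    return(sort(indices))
  }
  if (n_planes > n_z) stop("stack has only ", n_z, " z levels")
  idx <- as.integer(floor((seq_len(n_planes) - 0.5) * n_z / n_planes))
  if (length(idx) > 1 && any(diff(idx) < 2))
    stop("cannot select ", n_planes, " non-consecutive planes from ", n_z,
         " z levels; maximum feasible n_planes is ", max_feasible)
  idx
}
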