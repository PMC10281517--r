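#' Specification of a synthetic epithelial sheet on a closed contour
#'
#' Describes trapezoidal epithelial cells tiled around a circular organoid
#' contour. Per-cell lateral (apico-basal), apical and basal lengths are
#' drawn from the given means and SDs, which lets the generator produce the
#' three canonical shape regimes: columnar (lateral much longer than the
#' cell width; the self-renewing tip-progenitor phenotype), cuboidal
#' (comparable lengths) and squamous (flattened). Setting
#' `apical_length < basal_length` produces apical constriction.
#'
#' @param n_cells number of cells around the contour.
#' @param lateral_length,apical_length,basal_length mean lengths, um.
#' @param lateral_sd,apical_sd,basal_sd per-cell SDs, um (0 = identical cells).
#' @param nucleus_axes nucleus ellipse semi-axes, um (radial, tangential).
#' @param contour_radius basal-contour radius in um, or `NULL` to derive it
#'   from the drawn basal lengths (their sum is then the circumference, so
#'   the tiling closes exactly).
#' @param pixel_size micrometres per pixel for rendering.
#' @return an object of class `epithelium_spec`.
#' @export
epithelium_spec <- function(n_cells = 40, lateral_length = 30, apical_length = 5,
                            basal_length = 10, lateral_sd = 0, apical_sd = 0,
                            basal_sd = 0, nucleus_axes = c(3.5, 2),
                            contour_radius = NULL, pixel_size = 0.5) {
  stopifnot(n_cells >= 3, lateral_length > 0, apical_length > 0, basal_length > 0,
            all(nucleus_axes > 0), pixel_size > 0)
  if (!is.null(contour_radius)) {
    # cells may stretch or compress tangentially by up to 20%
    circ <- 2 * pi * contour_radius
    n_lo <- ceiling(circ / (basal_length * 1.2))
    n_hi <- floor(circ / (basal_length * 0.8))
    if (n_cells < n_lo || n_cells > n_hi)
      stop(sprintf(paste0("n_cells = %d cannot tile a contour of radius %g um with ",
                          "basal length %g um; feasible n_cells range is [%d, %d]"),
                   n_cells, contour_radius, basal_length, n_lo, n_hi))
  }
  structure(list(n_cells = as.integer(n_cells), lateral_length = lateral_length,
                 apical_length = apical_length, basal_length = basal_length,
                 lateral_sd = lateral_sd, apical_sd = apical_sd, basal_sd = basal_sd,
                 nucleus_axes = nucleus_axes, contour_radius = contour_radius,
                 pixel_size = pixel_size),
            class = "epithelium_spec")
}

# Perimeter of a polygon given vertex matrix (closed implicitly).
polygon_perimeter <- function(xy) {
  d <- xy[c(2:nrow(xy), 1), ] - xy
  sum(sqrt(rowSums(d^2)))
}

# Shoelace area (absolute).
polygon_area <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  xn <- x[c(2:length(x), 1)]; yn <- y[c(2:length(y), 1)]
  abs(sum(x * yn - xn * y)) / 2
}

# 64-gon approximation of an ellipse (axes a, b; rotation theta; centre c).
ellipse_polygon <- function(centre, a, b, theta = 0, n = 64) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  x <- a * cos(t); y <- b * sin(t)
  cbind(centre[1] + x * cos(theta) - y * sin(theta),
        centre[2] + x * sin(theta) + y * cos(theta))
}

# Draw an anti-aliased line segment of ~`width` px into `img`.
draw_segment <- function(img, p0, p1, value = 0.8, width = 1.5) {
  lo <- floor(pmin(p0, p1)) - ceiling(width) - 1
  hi <- ceiling(pmax(p0, p1)) + ceiling(width) + 1
  rows <- max(0, lo[1]):min(nrow(img) - 1, hi[1])
  cols <- max(0, lo[2]):min(ncol(img) - 1, hi[2])
  if (length(rows) < 1 || length(cols) < 1) return(img)
  rr <- matrix(rows, length(rows), length(cols))
  cc <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  v <- p1 - p0
  L2 <- sum(v^2)
  t <- if (L2 == 0) 0 else clamp(((rr - p0[1]) * v[1] + (cc - p0[2]) * v[2]) / L2, 0, 1)
  d <- sqrt((rr - (p0[1] + t * v[1]))^2 + (cc - (p0[2] + t * v[2]))^2)
  a <- clamp(width / 2 + 0.5 - d, 0, 1)
  sub <- img[rows + 1, cols + 1, drop = FALSE]
  img[rows + 1, cols + 1] <- pmax(sub, a * value)
  img
}

#' Generate a synthetic epithelium: images, ground truth and annotations
#'
#' Tiles trapezoidal cells around a circular contour, renders a
#' junction-marker image (cell outlines as bright ridges, emulating
#' ZO1/E-cadherin staining) and a nuclear-dye image (one ellipse per cell),
#' and returns ground truth plus an annotation table of labelled line
#' segments in the same format the morphometrics module consumes — so the
#' full draw-lines-and-measure workflow can be validated round-trip.
#'
#' Cells are laid out in polar coordinates: each cell occupies an angular
#' sector of the basal contour proportional to its drawn basal length
#' (arc-length convention, so the basal lengths always sum to the
#' circumference), and extends inward by its lateral length. Ground-truth
#' lengths are the drawn lengths; the annotation segments are straight lines
#' of exactly those lengths (lateral along the cell's radial midline,
#' apical/basal/width tangential at the corresponding radius), so measuring
#' them recovers the truth without discretisation error.
#'
#' @param spec an [epithelium_spec()].
#' @param seed integer RNG seed.
#' @param image_shape output image size in pixels, or `NULL` to fit the
#'   contour with a margin.
#' @return list with `junction` and `nuclear` image matrices, `truth`
#'   data.frame (per-cell lengths in um, length/width ratio, nucleus
#'   circularity), `annotations` data.frame (image, cell_id, role, x0, y0,
#'   x1, y1 in px), `nucleus_polygons` (list of vertex matrices, px),
#'   `pixel_size`, `contour_radius` (um) and `seed`.
#' @export
generate_epithelium <- function(spec, seed = 1, image_shape = NULL) {
  stopifnot(inherits(spec, "epithelium_spec"))
  with_seed(seed, {
    n <- spec$n_cells
    lat <- pmax(1e-3, rnorm(n, spec$lateral_length, spec$lateral_sd))
    api <- pmax(1e-3, rnorm(n, spec$apical_length, spec$apical_sd))
    bas <- pmax(1e-3, rnorm(n, spec$basal_length, spec$basal_sd))
    R <- spec$contour_radius %||% (sum(bas) / (2 * pi))
    # angular sectors proportional to basal arc lengths
    ang <- 2 * pi * cumsum(c(0, bas)) / sum(bas)
    mid <- (ang[-1] + ang[-(n + 1)]) / 2
    px <- spec$pixel_size
    margin <- 6 / px
    if (is.null(image_shape)) {
      side <- ceiling(2 * (R / px + margin))
      image_shape <- c(side, side)
    }
    ctr <- (image_shape - 1) / 2
    junction <- matrix(0.05, image_shape[1], image_shape[2])
    nuclear <- matrix(0.05, image_shape[1], image_shape[2])
    # polar -> pixel coords (row, col)
    pol <- function(r_um, theta) c(ctr[1] + (r_um / px) * sin(theta),
                                   ctr[2] + (r_um / px) * cos(theta))
    ann <- list(); npoly <- list(); circ_truth <- numeric(n)
    for (i in seq_len(n)) {
      r_out <- R
      r_in <- R - lat[i]
      corners <- rbind(pol(r_out, ang[i]), pol(r_out, ang[i + 1]),
                       pol(r_in, ang[i + 1]), pol(r_in, ang[i]))
      for (k in 1:4)
        junction <- draw_segment(junction, corners[k, ], corners[(k %% 4) + 1, ])
      # nucleus ellipse at the radial midpoint, radially oriented
      nc_r <- (r_out + r_in) / 2
      centre <- pol(nc_r, mid[i])
      theta_px <- mid[i]
      a_px <- spec$nucleus_axes[1] / px; b_px <- spec$nucleus_axes[2] / px
      # rotation in (row, col): radial direction is (sin t, cos t)
      poly <- {
        t <- seq(0, 2 * pi, length.out = 65)[-65]
        ex <- a_px * cos(t); ey <- b_px * sin(t)
        cbind(centre[1] + ex * sin(theta_px) + ey * cos(theta_px),
              centre[2] + ex * cos(theta_px) - ey * sin(theta_px))
      }
      npoly[[i]] <- poly
      circ_truth[i] <- 4 * pi * polygon_area(poly) / polygon_perimeter(poly)^2
      grid_lo <- floor(apply(poly, 2, min)); grid_hi <- ceiling(apply(poly, 2, max))
      rows <- max(0, grid_lo[1]):min(image_shape[1] - 1, grid_hi[1])
      cols <- max(0, grid_lo[2]):min(image_shape[2] - 1, grid_hi[2])
      if (length(rows) && length(cols)) {
        rr <- matrix(rows, length(rows), length(cols))
        cc <- matrix(cols, length(rows), length(cols), byrow = TRUE)
        dx <- (rr - centre[1]) * sin(theta_px) + (cc - centre[2]) * cos(theta_px)
        dy <- (rr - centre[1]) * cos(theta_px) - (cc - centre[2]) * sin(theta_px)
        inside <- (dx / a_px)^2 + (dy / b_px)^2 <= 1
        sub <- nuclear[rows + 1, cols + 1, drop = FALSE]
        sub[inside] <- 0.8
        nuclear[rows + 1, cols + 1] <- sub
      }
      # annotation segments of exactly the true lengths (in px on the image)
      seg <- function(role, centre_r, theta, len_um, radial = FALSE) {
        half <- len_um / 2 / px
        if (radial) {
          p0 <- pol(centre_r - len_um / 2, theta); p1 <- pol(centre_r + len_um / 2, theta)
        } else {
          c0 <- pol(centre_r, theta)
          tang <- c(cos(theta), -sin(theta))
          p0 <- c0 - half * tang; p1 <- c0 + half * tang
        }
        data.frame(image = "epithelium", cell_id = i, role = role,
                   x0 = p0[2], y0 = p0[1], x1 = p1[2], y1 = p1[1])
      }
      width_um <- (api[i] + bas[i]) / 2
      ann[[length(ann) + 1L]] <- rbind(
        seg("lateral", (r_out + r_in) / 2, mid[i], lat[i], radial = TRUE),
        seg("apical", r_in, mid[i], api[i]),
        seg("basal", r_out, mid[i], bas[i]),
        seg("width", nc_r, mid[i], width_um))
    }
    truth <- data.frame(cell = seq_len(n), lateral = lat, apical = api, basal = bas,
                        width = (api + bas) / 2,
                        length_width = lat / ((api + bas) / 2),
                        circularity = circ_truth)
    list(junction = junction, nuclear = nuclear, truth = truth,
         annotations = do.call(rbind, ann), nucleus_polygons = npoly,
         pixel_size = px, contour_radius = R, seed = as.integer(seed))
  })
}
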