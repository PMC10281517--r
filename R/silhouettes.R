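#' Generate a synthetic organoid silhouette (spherical or budding)
#'
#' Spherical organoids are rasterised disks; budding organoids are a core
#' disk with `n_lobes` lobes (smaller disks centred beyond the core rim),
#' giving a multi-lobed outline with clear convex deficiency for three or
#' more lobes. Two-lobed shapes are supported but approach a convex
#' capsule and can score near-spherical solidity. A pixel
#' belongs to the mask iff its centre lies inside the shape. The true pixel
#' area is recorded as ground truth. Fixed seed implies a byte-identical
#' mask.
#'
#' @param kind `"spherical"` or `"budding"`.
#' @param n_lobes number of lobes for budding shapes (>= 2).
#' @param radius core radius in px (>= 10).
#' @param seed integer RNG seed (jitters lobe angles and sizes).
#' @param image_shape image size in px, or `NULL` to fit the shape.
#' @return list with `mask` (logical matrix), `truth` (list with `area_px`,
#'   `kind`, `n_lobes`), and `seed`.
#' @export
generate_silhouette <- function(kind = c("spherical", "budding"), n_lobes = 3,
                                radius = 60, seed = 1, image_shape = NULL) {
  kind <- match.arg(kind)
  if (radius < 10) stop("radius must be at least 10 px")
  if (kind == "budding" && n_lobes < 2) stop("budding shapes need n_lobes >= 2")
  with_seed(seed, {
    lobe_r <- lobe_cy <- lobe_cx <- numeric(0)
    if (kind == "budding") {
      ang <- 2 * pi * (seq_len(n_lobes) - 1) / n_lobes + runif(1, 0, 2 * pi) +
        runif(n_lobes, -0.25, 0.25) / n_lobes * 2 * pi
      lobe_r <- radius * runif(n_lobes, 0.38, 0.5)
      dist <- radius * runif(n_lobes, 1.15, 1.3)
      lobe_cy <- dist * sin(ang); lobe_cx <- dist * cos(ang)
    }
    extent <- radius + if (kind == "budding") max(sqrt(lobe_cy^2 + lobe_cx^2) + lobe_r) - radius else 0
    if (is.null(image_shape)) {
      side <- as.integer(ceiling(2 * extent + 8))
      image_shape <- c(side, side)
    }
    ctr <- (image_shape - 1) / 2
    grid <- pixel_grid(image_shape)
    mask <- (grid$row - ctr[1])^2 + (grid$col - ctr[2])^2 <= radius^2
    if (kind == "budding") {
      for (i in seq_len(n_lobes))
        mask <- mask | ((grid$row - ctr[1] - lobe_cy[i])^2 +
                          (grid$col - ctr[2] - lobe_cx[i])^2 <= lobe_r[i]^2)
    }
    list(mask = mask,
         truth = list(area_px = sum(mask), kind = kind,
                      n_lobes = if (kind == "budding") n_lobes else 0L),
         seed = as.integer(seed))
  })
}
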