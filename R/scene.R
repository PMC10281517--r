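#' Synthetic KTR imaging scene
#'
#' Builds the full specification of a synthetic two-channel reporter movie:
#' non-overlapping cells (concentric nucleus/cell disks) scattered over a
#' dark background, a shared latent activity trace driving the reporter
#' kinetics, and per-cell kinetic heterogeneity. All geometry is specified
#' in micrometres and rasterised through `pixel_size`; the defaults (0.5
#' um/px, 4 um nuclear radius, 8 um cell radius) sit in the range of a
#' 25-40x confocal acquisition of an epithelial organoid. Given the same
#' seed, a scene and everything rendered from it are byte-identical across
#' runs.
#'
#' @param n_cells number of cells to place.
#' @param image_shape image size in pixels, `c(rows, cols)`.
#' @param pixel_size micrometres per pixel.
#' @param frame_times acquisition times in minutes (default: 13 frames at
#'   10-min spacing, a 120-min movie).
#' @param params [kinetics_params()] for the reporter model.
#' @param activity [activity_trace()] driving all cells; default is a step
#'   from 0 to 1 at time 0 (stimulation at the start of imaging).
#' @param nucleus_radius_um,cell_radius_um mean nucleus / cell radii (um).
#' @param radius_jitter_um uniform half-width of per-cell radius jitter.
#' @param tau_jitter relative half-width of per-cell jitter on `tau`.
#' @param r0_spread fraction of the `[r_min, r_max]` span over which initial
#'   ratios are drawn uniformly above `r_min`.
#' @param seed integer RNG seed; fully determines the scene.
#' @return an object of class `ktr_scene`.
#' @export
ktr_scene <- function(n_cells = 20, image_shape = c(256, 256), pixel_size = 0.5,
                      frame_times = seq(0, 120, by = 10),
                      params = kinetics_params(),
                      activity = step_activity(frame_times),
                      nucleus_radius_um = 4, cell_radius_um = 8,
                      radius_jitter_um = 0.5, tau_jitter = 0.1,
                      r0_spread = 0.05, seed = 1) {
  stopifnot(n_cells >= 1, length(image_shape) == 2, pixel_size > 0)
  stopifnot(inherits(params, "kinetics_params"), inherits(activity, "activity_trace"))
  if (!identical(activity$times, as.numeric(frame_times)))
    stop("activity trace must be sampled at frame_times")
  cells <- with_seed(seed, {
    rn <- (nucleus_radius_um + runif(n_cells, -radius_jitter_um, radius_jitter_um)) / pixel_size
    rc <- (cell_radius_um + runif(n_cells, -radius_jitter_um, radius_jitter_um)) / pixel_size
    cy <- cx <- numeric(n_cells)
    placed <- 0L
    attempts <- 0L
    while (placed < n_cells) {
      attempts <- attempts + 1L
      if (attempts > 5000L * n_cells)
        stop("could not place ", n_cells, " non-overlapping cells in the image; ",
             "enlarge image_shape or reduce n_cells")
      i <- placed + 1L
      y <- runif(1, rc[i] + 1, image_shape[1] - rc[i] - 2)
      x <- runif(1, rc[i] + 1, image_shape[2] - rc[i] - 2)
      ok <- TRUE
      if (placed > 0L) {
        dd <- sqrt((cy[seq_len(placed)] - y)^2 + (cx[seq_len(placed)] - x)^2)
        ok <- all(dd >= rc[seq_len(placed)] + rc[i] + 2)
      }
      if (ok) { cy[i] <- y; cx[i] <- x; placed <- i }
    }
    tau_f <- runif(n_cells, 1 - tau_jitter, 1 + tau_jitter)
    r0 <- params$r_min + runif(n_cells, 0, r0_spread) * (params$r_max - params$r_min)
    data.frame(cell = seq_len(n_cells), cy = cy, cx = cx,
               nucleus_r = rn, cell_r = rc, tau_factor = tau_f, r0 = r0)
  })
  structure(list(n_cells = n_cells, image_shape = as.integer(image_shape),
                 pixel_size = pixel_size, frame_times = as.numeric(frame_times),
                 params = params, activity = activity, cells = cells,
                 nuclear_intensity = 0.8, reporter_nuclear_intensity = 0.3,
                 background = 0.05, seed = as.integer(seed)),
            class = "ktr_scene")
}

#' True per-cell C/N ratio matrix of a scene
#'
#' Integrates the kinetic model for every cell (each with its own initial
#' ratio and jittered time constant) at the scene's frame times.
#'
#' @param scene a [ktr_scene()].
#' @return numeric matrix, `n_cells x n_frames`.
#' @export
scene_true_ratios <- function(scene) {
  stopifnot(inherits(scene, "ktr_scene"))
  t(vapply(seq_len(scene$n_cells), function(i) {
    p <- scene$params
    pc <- kinetics_params(p$r_min, p$r_max, p$tau * scene$cells$tau_factor[i], p$noise_sd)
    simulate_ktr_kinetics(scene$activity, pc, r0 = scene$cells$r0[i])
  }, numeric(length(scene$frame_times))))
}

# Anti-aliased disk coverage: 1 fully inside, 0 fully outside, linear over
# the 1-px boundary band. Pixel centres are at integer (row, col), 0-based.
disk_alpha <- function(grid, cy, cx, r) {
  d <- sqrt((grid$row - cy)^2 + (grid$col - cx)^2)
  clamp(r + 0.5 - d, 0, 1)
}

#' Ground-truth compartment label maps of a scene
#'
#' Returns nucleus and cytoplasm label maps containing only pixels fully
#' inside their compartment: the 1-px anti-aliased boundary band belongs to
#' neither, so region means measured on these masks are free of boundary
#' ambiguity.
#'
#' @param scene a [ktr_scene()].
#' @return list with integer matrices `nuclei` and `cytoplasm` (0 = background).
#' @export
scene_truth_masks <- function(scene) {
  stopifnot(inherits(scene, "ktr_scene"))
  grid <- pixel_grid(scene$image_shape)
  nuc <- cyt <- matrix(0L, scene$image_shape[1], scene$image_shape[2])
  for (i in seq_len(scene$n_cells)) {
    cc <- scene$cells[i, ]
    dn <- sqrt((grid$row - cc$cy)^2 + (grid$col - cc$cx)^2)
    nuc[dn <= cc$nucleus_r - 0.5] <- i
    cyt[dn >= cc$nucleus_r + 0.5 & dn <= cc$cell_r - 0.5] <- i
  }
  list(nuclei = nuc, cytoplasm = cyt)
}

#' Render one two-channel frame of a KTR scene
#'
#' The nuclear-dye channel shows bright nuclei on a dark background. In the
#' reporter channel each cell has uniform nuclear intensity and uniform
#' cytoplasmic intensity whose ratio equals the requested true C/N ratio
#' exactly (before noise); the additive background floor applies outside the
#' cell footprint, and optional multiplicative Gaussian noise is applied to
#' the whole image afterwards. Compartment boundaries get a 1-px
#' anti-aliased blend.
#'
#' @param scene a [ktr_scene()].
#' @param ratios true C/N ratio per cell (length `n_cells`), all > 0.
#' @param noise_sd multiplicative noise SD; defaults to the scene's kinetic
#'   parameter. Noise draws use the current RNG state.
#' @return list of matrices `nuclear` and `reporter`, values in `[0, 1]`.
#' @export
render_frame <- function(scene, ratios, noise_sd = scene$params$noise_sd) {
  stopifnot(inherits(scene, "ktr_scene"))
  if (length(ratios) != scene$n_cells)
    stop("need one ratio per cell (", scene$n_cells, ")")
  if (any(ratios <= 0)) stop("C/N ratios must be > 0")
  grid <- pixel_grid(scene$image_shape)
  b <- scene$background
  nuclear <- matrix(b, scene$image_shape[1], scene$image_shape[2])
  reporter <- matrix(b, scene$image_shape[1], scene$image_shape[2])
  In <- scene$reporter_nuclear_intensity
  # keep the brightest compartment within the dynamic range
  In <- min(In, 0.95 / max(c(ratios, 1)))
  for (i in seq_len(scene$n_cells)) {
    cc <- scene$cells[i, ]
    a_cell <- disk_alpha(grid, cc$cy, cc$cx, cc$cell_r)
    sel <- a_cell > 0
    a_nuc <- disk_alpha(grid, cc$cy, cc$cx, cc$nucleus_r)[sel]
    Ic <- ratios[i] * In
    v <- a_nuc * In + (1 - a_nuc) * Ic
    reporter[sel] <- a_cell[sel] * v + (1 - a_cell[sel]) * b
    an <- disk_alpha(grid, cc$cy, cc$cx, cc$nucleus_r)
    seln <- an > 0
    nuclear[seln] <- an[seln] * scene$nuclear_intensity + (1 - an[seln]) * b
  }
  if (noise_sd > 0) {
    n <- length(nuclear)
    nuclear <- clamp(nuclear * (1 + noise_sd * rnorm(n)), 0, 1)
    reporter <- clamp(reporter * (1 + noise_sd * rnorm(n)), 0, 1)
  }
  list(nuclear = nuclear, reporter = reporter)
}

#' Render the full movie of a KTR scene
#'
#' Simulates the per-cell kinetics and renders every frame. Noise is seeded
#' from the scene seed, so the movie is byte-identical across runs.
#'
#' @param scene a [ktr_scene()].
#' @param noise_sd multiplicative noise SD (default: the scene's value; set
#'   0 for a noise-free render).
#' @return object of class `ktr_movie`: list with `frames` (each a list of
#'   `nuclear`/`reporter` matrices), `truth_ratios` (cells x frames), and
#'   the `scene`.
#' @export
render_movie <- function(scene, noise_sd = scene$params$noise_sd) {
  stopifnot(inherits(scene, "ktr_scene"))
  truth <- scene_true_ratios(scene)
  frames <- with_seed(scene$seed + 1L, {
    lapply(seq_along(scene$frame_times), function(k)
      render_frame(scene, truth[, k], noise_sd = noise_sd))
  })
  structure(list(frames = frames, truth_ratios = truth, scene = scene),
            class = "ktr_movie")
}

#' Write a rendered movie plus ground truth to disk
#'
#' Writes a 16-bit multi-page TIFF in (T, Z, C, Y, X) page order (Z is a
#' singleton; channel 1 nuclear dye, channel 2 reporter), a ground-truth CSV
#' (one row per cell per frame) and a YAML scene file recording geometry,
#' kinetic parameters and the seed.
#'
#' @param movie a [render_movie()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(movie, dir) {
  stopifnot(inherits(movie, "ktr_movie"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scene <- movie$scene
  pages <- list()
  for (f in movie$frames) {
    pages[[length(pages) + 1L]] <- quantise16(f$nuclear)
    pages[[length(pages) + 1L]] <- quantise16(f$reporter)
  }
  dims <- list(T = length(movie$frames), Z = 1L, C = 2L,
               Y = scene$image_shape[1], X = scene$image_shape[2])
  tif <- file.path(dir, "movie.tif")
  tiff::writeTIFF(pages, tif, bits.per.sample = 16)
  jsonlite::write_json(dims, dims_sidecar(tif), auto_unbox = TRUE)
  truth <- do.call(rbind, lapply(seq_along(scene$frame_times), function(k)
    data.frame(cell = seq_len(scene$n_cells), frame = k - 1L,
               time_min = scene$frame_times[k],
               true_ratio = movie$truth_ratios[, k],
               cy = scene$cells$cy, cx = scene$cells$cx,
               nucleus_r = scene$cells$nucleus_r, cell_r = scene$cells$cell_r)))
  utils::write.csv(truth, file.path(dir, "truth.csv"), row.names = FALSE)
  yaml::write_yaml(list(
    image_shape = scene$image_shape, pixel_size = scene$pixel_size,
    frame_times = scene$frame_times, seed = scene$seed,
    channels = list(nuclear_dye = 1L, reporter = 2L),
    kinetics = unclass(scene$params),
    n_cells = scene$n_cells), file.path(dir, "scene.yaml"))
  invisible(dir)
}
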