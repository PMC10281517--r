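#' Write a 5D image stack as a 16-bit multi-page TIFF
#'
#' Pages are ordered (T, Z, C) slowest-to-fastest; every page is a
#' `(Y, X)` plane. Axis lengths are recorded in a small JSON sidecar
#' (`<path>.dims.json`) so [read_stack()] restores the canonical array.
#' Intensities are clipped to `[0, 1]` and quantised to the 16-bit grid.
#'
#' @param stack 5D numeric array `(T, Z, C, Y, X)` (missing leading axes
#'   may be supplied as singletons).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  d <- dim(stack)
  stopifnot(length(d) == 5)
  pages <- list()
  for (t in seq_len(d[1])) for (z in seq_len(d[2])) for (ch in seq_len(d[3]))
    pages[[length(pages) + 1L]] <- quantise16(matrix(stack[t, z, ch, , ], d[4], d[5]))
  dims <- list(T = d[1], Z = d[2], C = d[3], Y = d[4], X = d[5])
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  jsonlite::write_json(dims, dims_sidecar(path), auto_unbox = TRUE)
  invisible(path)
}

#' Read a multi-page TIFF into the canonical (T, Z, C, Y, X) array
#'
#' If a JSON dimension sidecar (as written by [write_stack()] or
#' [write_scene()]) sits next to the file the full shape is restored;
#' otherwise the axis layout must be given and missing axes become
#' singletons. Page order must be (T, Z, C) slowest-to-fastest.
#'
#' @param path TIFF file.
#' @param layout axis layout of the pages when no embedded record exists,
#'   a string over `T`, `Z`, `C` naming the page-order axes (e.g. `"TC"`
#'   for a multi-frame two-channel movie); ignored if the file is
#'   self-describing.
#' @param dims named integer vector giving the length of each axis in
#'   `layout` (e.g. `c(T = 13, C = 2)`).
#' @return 5D numeric array `(T, Z, C, Y, X)` with a `pages` attribute.
#' @export
read_stack <- function(path, layout = NULL, dims = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  np <- length(pages)
  shape <- NULL
  if (file.exists(dims_sidecar(path))) {
    parsed <- tryCatch(jsonlite::fromJSON(dims_sidecar(path)), error = function(e) NULL)
    if (is.list(parsed) && all(c("T", "Z", "C", "Y", "X") %in% names(parsed)))
      shape <- c(parsed$T, parsed$Z, parsed$C, parsed$Y, parsed$X)
  }
  if (is.null(shape)) {
    y <- nrow(pages[[1]]); x <- ncol(pages[[1]])
    full <- c(T = 1L, Z = 1L, C = 1L)
    if (!is.null(layout)) {
      axes <- strsplit(layout, "")[[1]]
      if (!all(axes %in% c("T", "Z", "C")))
        stop("layout must name page axes out of T, Z, C")
      if (is.null(dims) || !all(axes %in% names(dims)))
        stop("dims must give a length for every layout axis")
      full[axes] <- as.integer(dims[axes])
    }
    if (prod(full) != np)
      stop("axis mismatch: layout implies ", prod(full), " pages, file has ", np)
    shape <- c(full, y, x)
  }
  shape <- as.integer(unname(shape))
  if (prod(shape[1:3]) != np)
    stop("axis mismatch: embedded shape implies ", prod(shape[1:3]),
         " pages, file has ", np)
  out <- array(0, shape)
  i <- 0L
  for (t in seq_len(shape[1])) for (z in seq_len(shape[2])) for (ch in seq_len(shape[3])) {
    i <- i + 1L
    if (!all(dim(pages[[i]])[1:2] == shape[4:5]))
      stop("page ", i, " has shape ", paste(dim(pages[[i]]), collapse = "x"),
           ", expected ", shape[4], "x", shape[5])
    pg <- pages[[i]]
    if (length(dim(pg)) == 3) pg <- pg[, , 1]   # greyscale stored with channels
    out[t, z, ch, , ] <- pg
  }
  attr(out, "pages") <- np
  out
}

run_config_schema <- function() {
  list(
    paths = c("movie", "nuclear_image", "marker_image", "annotations",
              "silhouette", "output_dir"),
    top = c("paths", "channels", "pixel_size", "z_step", "frame_interval",
            "seed", "segmentation", "ktr", "positivity", "budding"),
    segmentation = c("threshold_method", "fixed_threshold", "min_nucleus_area",
                     "watershed_split", "ring_width", "smoothing_sigma",
                     "connectivity"),
    ktr = c("guard", "by_plane", "max_displacement"),
    positivity = c("rule", "threshold"),
    budding = c("threshold"))
}

#' Read and strictly validate a run configuration
#'
#' Loads a YAML run configuration. Unknown keys are rejected (strict mode)
#' so that typos cannot silently fall back to defaults. The frame interval
#' defaults to 10 minutes.
#'
#' @param path YAML file.
#' @return named list with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  sch <- run_config_schema()
  check <- function(block, allowed, where) {
    bad <- setdiff(names(block), allowed)
    if (length(bad))
      stop("unknown config key(s) in ", where, ": ", paste(bad, collapse = ", "),
           "; allowed: ", paste(allowed, collapse = ", "))
  }
  check(cfg, sch$top, "top level")
  for (blk in c("segmentation", "ktr", "positivity", "budding"))
    if (!is.null(cfg[[blk]])) check(cfg[[blk]], sch[[blk]], blk)
  if (!is.null(cfg$paths)) check(cfg$paths, sch$paths, "paths")
  cfg$pixel_size <- cfg$pixel_size %||% 0.5
  if (cfg$pixel_size <= 0) stop("pixel_size must be > 0")
  cfg$frame_interval <- cfg$frame_interval %||% 10
  cfg$seed <- cfg$seed %||% 1L
  cfg$channels <- cfg$channels %||% list(nuclear_dye = 1L, reporter = 2L)
  cfg
}

#' Resolve a channel name to its index in a stack
#'
#' @param channels named channel map from the run configuration.
#' @param name requested channel name.
#' @param n_channels number of channels actually present.
#' @return integer channel index.
#' @export
resolve_channel <- function(channels, name, n_channels) {
  if (!name %in% names(channels))
    stop("channel '", name, "' not in channel map; available: ",
         paste(names(channels), collapse = ", "))
  idx <- as.integer(channels[[name]])
  if (idx < 1 || idx > n_channels)
    stop("channel '", name, "' maps to index ", idx, " but the stack has ",
         n_channels, " channels")
  idx
}

# Dimension record accompanying every stack TIFF (the TIFF container
# itself only orders pages; axis lengths live here).
dims_sidecar <- function(path) paste0(path, ".dims.json")

# Sidecar JSON recording provenance next to every CSV artifact.
write_sidecar <- function(csv_path, cfg, seed) {
  cfg_str <- paste(deparse(cfg), collapse = "")
  info <- list(package = "organoidquant",
               version = as.character(utils::packageVersion("organoidquant")),
               seed = seed,
               config_hash = sprintf("%08x", sum(utf8ToInt(cfg_str) *
                                                   seq_along(utf8ToInt(cfg_str)))))
  jsonlite::write_json(info, paste0(csv_path, ".json"), auto_unbox = TRUE)
  invisible(NULL)
}
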