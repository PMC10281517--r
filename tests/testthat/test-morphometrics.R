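test_that("segment lengths are Euclidean distances scaled by pixel size", {
  ann <- data.frame(cell_id = 1, role = c("lateral", "width"),
                    x0 = c(0, 0), y0 = c(0, 0), x1 = c(0, 8), y1 = c(30, 6))
  out <- measure_cell_axes(ann, pixel_size = 1)
  expect_equal(out$lateral, 30)
  expect_equal(out$width, 10)
  expect_equal(out$length_width, 3)
  out2 <- measure_cell_axes(ann, pixel_size = 0.5)
  expect_equal(out2$lateral, 15)
})

test_that("zero-SD columnar epithelium is recovered exactly via annotations", {
  spec <- epithelium_spec(n_cells = 30, lateral_length = 30, apical_length = 5,
                          basal_length = 10)
  ep <- generate_epithelium(spec, seed = 1)
  ax <- measure_cell_axes(ep$annotations, pixel_size = ep$pixel_size)
  expect_equal(ax$lateral, rep(30, 30), tolerance = 1e-9)
  expect_equal(ax$apical, rep(5, 30), tolerance = 1e-9)
  expect_equal(ax$basal, rep(10, 30), tolerance = 1e-9)
})

test_that("noisy epithelium means are recovered within 2 SEM at 100 cells", {
  spec <- epithelium_spec(n_cells = 100, lateral_length = 30, apical_length = 5,
                          basal_length = 10, lateral_sd = 3, apical_sd = 0.8,
                          basal_sd = 1.2)
  ep <- generate_epithelium(spec, seed = 7)
  ax <- measure_cell_axes(ep$annotations, pixel_size = ep$pixel_size)
  for (col in c("lateral", "apical", "basal")) {
    sem <- sd(ep$truth[[col]]) / sqrt(100)
    expect_lt(abs(mean(ax[[col]]) - mean(ep$truth[[col]])), 1e-9)  # same draws
    expect_lt(abs(mean(ax[[col]]) - spec[[paste0(col, "_length")]]), 2 * sem)
  }
})

test_that("flagged cells are excluded from output and listed in the log", {
  ann <- data.frame(cell_id = rep(1:3, each = 2),
                    role = rep(c("lateral", "width"), 3),
                    x0 = 0, y0 = 0, x1 = rep(c(0, 5), 3), y1 = rep(c(20, 0), 3))
  expect_message(out <- measure_cell_axes(ann, exclude = 2), "not integrated")
  expect_equal(out$cell_id, c(1, 3))
  expect_equal(attr(out, "excluded_cells"), 2)
})

test_that("a regular 64-gon has circularity at least 0.995", {
  t <- seq(0, 2 * pi, length.out = 65)[-65]
  poly <- cbind(cos(t), sin(t))
  expect_gte(nucleus_circularity(poly), 0.995)
})

test_that("a 2:1 ellipse polygon matches the brute-force vertex-chain oracle", {
  t <- seq(0, 2 * pi, length.out = 257)[-257]
  poly <- cbind(2 * cos(t), sin(t))
  # independent oracle: explicit loops for shoelace area and perimeter
  a_or <- 0; p_or <- 0; n <- nrow(poly)
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    a_or <- a_or + poly[i, 1] * poly[j, 2] - poly[j, 1] * poly[i, 2]
    p_or <- p_or + sqrt(sum((poly[j, ] - poly[i, ])^2))
  }
  oracle <- 4 * pi * abs(a_or / 2) / p_or^2
  expect_equal(nucleus_circularity(poly), oracle, tolerance = 1e-12)
  expect_lt(oracle, 0.85)   # clearly below a circle
})

test_that("circularity is invariant under rotation and uniform scaling", {
  set.seed(12)
  t <- sort(runif(40, 0, 2 * pi))
  poly <- cbind((1 + 0.2 * sin(3 * t)) * cos(t), (1 + 0.2 * sin(3 * t)) * sin(t))
  c0 <- nucleus_circularity(poly)
  for (theta in c(0.3, 1.1, 2.9)) {
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2)
    expect_equal(nucleus_circularity(3.7 * poly %*% R), c0, tolerance = 1e-9)
  }
})

test_that("degenerate and self-intersecting polygons are handled", {
  t <- seq(0, 2 * pi, length.out = 33)[-33]
  sliver <- cbind(cos(t), 0.001 * sin(t))
  expect_lt(nucleus_circularity(sliver), 0.02)
  bowtie <- cbind(c(0, 1, 0.2, 1.2, 0.6, -0.3, 0.9, -0.1),
                  c(0, 1, 1.3, 0.1, -0.4, 0.8, 0.5, -0.2))
  expect_error(nucleus_circularity(bowtie), "self-intersecting")
})

test_that("mask circularity uses the Crofton perimeter and stays near 1 for disks", {
  mask <- disk_pixels(c(120, 120), 59.5, 59.5, 45)
  circ <- nucleus_circularity(mask)
  expect_gt(circ, 0.98)
  expect_lte(circ, 1.02)   # discretisation tolerance
  # elongated mask scores much lower
  rows <- matrix(0:119, 120, 120); cols <- matrix(0:119, 120, 120, byrow = TRUE)
  ell <- ((rows - 59.5) / 50)^2 + ((cols - 59.5) / 12)^2 <= 1
  expect_lt(nucleus_circularity(ell), 0.75)
})

test_that("per-cell marker score adds nuclear and ring means", {
  nuc <- matrix(0L, 40, 40); nuc[disk_pixels(c(40, 40), 19.5, 19.5, 6)] <- 1L
  ring <- ring_cytoplasm(nuc, 3)
  uni <- matrix(0.4, 40, 40)
  out <- per_cell_marker_intensity(uni, nuc, ring)
  expect_equal(out$score, 0.8)
  marker <- matrix(0, 40, 40); marker[nuc == 1L] <- 0.6
  out2 <- per_cell_marker_intensity(marker, nuc, ring)
  expect_equal(out2$score, 0.6)
  expect_false(out2$ring_missing)
})

test_that("graded markers preserve rank order of per-cell scores", {
  ps <- generate_positivity_scene(50, 0, seed = 9)
  nuc <- segment_nuclei(ps$nuclear, seg_params(smoothing_sigma = 1,
                                               min_nucleus_area = 10))
  ring <- ring_cytoplasm(nuc, 3)
  # marker intensity increases with column position of the nucleus
  grad <- matrix(rep(seq(0.1, 0.9, length.out = ncol(ps$nuclear)),
                     each = nrow(ps$nuclear)), nrow(ps$nuclear))
  out <- per_cell_marker_intensity(grad, nuc, ring)
  cent <- vapply(out$cell, function(k) mean(which(nuc == k, arr.ind = TRUE)[, 2]),
                 numeric(1))
  expect_gte(cor(out$score, cent, method = "spearman"), 0.999)
})

test_that("3D counting finds disjoint spheres and splits touching ones", {
  vol <- array(0, c(50, 50, 24))
  centres <- rbind(c(10, 10, 6), c(10, 30, 6), c(30, 10, 6), c(30, 30, 6),
                   c(10, 10, 17), c(10, 30, 17), c(30, 10, 17), c(30, 30, 17),
                   c(40, 40, 6), c(40, 40, 17))
  for (i in seq_len(nrow(centres))) {
    cc <- centres[i, ]
    for (z in 1:24) for (r in 1:50) for (cl in 1:50) {
      if ((r - cc[1])^2 + (cl - cc[2])^2 + (z - cc[3])^2 <= 16)
        vol[r, cl, z] <- 0.9
    }
  }
  res <- count_nuclei_3d(vol, min_volume = 20)
  expect_equal(res$total, 10)
  # two spheres touching in exactly one voxel
  vol2 <- array(0, c(40, 40, 16))
  for (z in 1:16) for (r in 1:40) for (cl in 1:40) {
    if ((r - 20)^2 + (cl - 12)^2 + (z - 8)^2 <= 25) vol2[r, cl, z] <- 0.9
    if ((r - 20)^2 + (cl - 22)^2 + (z - 8)^2 <= 25) vol2[r, cl, z] <- 0.9
  }
  merged <- count_nuclei_3d(vol2, min_volume = 20)
  expect_equal(merged$total, 1)
  split <- count_nuclei_3d(vol2, min_volume = 20, split_touching = TRUE)
  expect_equal(split$total, 2)
})

test_that("3D counting on an empty volume gives zero and 2D agrees on one plane", {
  expect_equal(count_nuclei_3d(array(0, c(20, 20, 5)))$total, 0)
  ps <- generate_positivity_scene(12, 0.5, seed = 4)
  expect_warning(res3 <- count_nuclei_3d(array(ps$nuclear, c(dim(ps$nuclear), 1)),
                                         min_volume = 10),
                 "single-plane")
  nuc2 <- segment_nuclei(ps$nuclear, seg_params(smoothing_sigma = 0,
                                                min_nucleus_area = 10))
  expect_equal(res3$total, max(nuc2))
})

test_that("3D positivity counts match the generated labels", {
  ps <- generate_positivity_scene(30, 0.4, seed = 15)
  vol <- array(ps$nuclear, c(dim(ps$nuclear), 1))
  mvol <- array(ps$marker, c(dim(ps$marker), 1))
  expect_warning(res <- count_nuclei_3d(vol, marker = mvol, min_volume = 10),
                 "single-plane")
  expect_equal(res$total, 30)
  expect_equal(res$positive, 12)
})

test_that("budding classification separates disks from lobed shapes", {
  disk <- generate_silhouette("spherical", radius = 60, seed = 3)
  expect_equal(classify_budding(disk$mask)$class, "spherical")
  lobed <- generate_silhouette("budding", n_lobes = 4, radius = 60, seed = 3)
  expect_equal(classify_budding(lobed$mask)$class, "budding")
})

test_that("a zero-misclassification solidity interval exists and contains 0.92", {
  sol_disk <- vapply(0:99, function(s)
    classify_budding(generate_silhouette("spherical", radius = 40 + (s %% 5) * 10,
                                         seed = s)$mask)$solidity, numeric(1))
  sol_lobe <- vapply(100:199, function(s)
    classify_budding(generate_silhouette("budding", n_lobes = 3 + (s %% 3),
                                         radius = 40 + (s %% 5) * 10,
                                         seed = s)$mask)$solidity, numeric(1))
  expect_gt(min(sol_disk), max(sol_lobe))        # interval exists
  expect_gt(min(sol_disk), 0.92)                 # and contains the default cut
  expect_lt(max(sol_lobe), 0.92)
})

test_that("manual phenotype labels override the automated call", {
  disk <- generate_silhouette("spherical", radius = 40, seed = 2)
  res <- classify_budding(disk$mask, manual_label = "budding")
  expect_equal(res$class, "budding")
  expect_true(res$overridden)
})

test_that("disconnected silhouettes classify the largest component with a warning", {
  mask <- disk_pixels(c(100, 160), 50, 40, 30) | disk_pixels(c(100, 160), 50, 130, 10)
  expect_warning(res <- classify_budding(mask), "largest component")
  expect_equal(res$class, "spherical")
})
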