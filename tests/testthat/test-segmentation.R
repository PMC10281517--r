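test_that("disjoint binary disks are recovered label-for-label, pixel-for-pixel", {
  shape <- c(220, 220)
  img <- matrix(0, shape[1], shape[2])
  centres <- expand.grid(cy = seq(25, 195, length.out = 5)[1:4] * 1,
                         cx = seq(22, 198, length.out = 5))
  centres <- centres[1:20, ]
  disks <- list()
  for (i in 1:20) {
    d <- disk_pixels(shape, centres$cy[i], centres$cx[i], 8)
    disks[[i]] <- d
    img[d] <- 0.9
  }
  lab <- segment_nuclei(img, seg_params(smoothing_sigma = 0,
                                        watershed_split = FALSE))
  expect_equal(max(lab), 20)
  for (i in 1:20) {
    k <- unique(lab[disks[[i]]])
    expect_length(k, 1)
    expect_identical(lab == k, disks[[i]])
  }
})

test_that("watershed splits two overlapping disks into two labels", {
  shape <- c(80, 120)
  img <- matrix(0, shape[1], shape[2])
  # two radius-10 disks whose rims overlap by ~2 px
  img[disk_pixels(shape, 40, 45, 10)] <- 0.9
  img[disk_pixels(shape, 40, 63, 10)] <- 0.9
  lab_split <- segment_nuclei(img, seg_params(smoothing_sigma = 0,
                                              watershed_split = TRUE))
  lab_nosplit <- segment_nuclei(img, seg_params(smoothing_sigma = 0,
                                                watershed_split = FALSE))
  expect_equal(max(lab_nosplit), 1)
  expect_equal(max(lab_split), 2)
  # split roughly at the midline between the two known centres
  w1 <- which(lab_split == 1, arr.ind = TRUE)
  w2 <- which(lab_split == 2, arr.ind = TRUE)
  expect_lt(abs(mean(w1[, 2]) - 46), 2.5)
  expect_lt(abs(mean(w2[, 2]) - 64), 2.5)
})

test_that("an empty image yields an empty label map with a warning, not an error", {
  expect_warning(lab <- segment_nuclei(matrix(0, 40, 40), seg_params()),
                 "no foreground")
  expect_equal(max(lab), 0)
})

test_that("small objects are removed by the area filter", {
  img <- matrix(0, 60, 60)
  img[disk_pixels(c(60, 60), 20, 20, 8)] <- 0.9
  img[30, 50] <- 0.9   # single-pixel speck
  lab <- segment_nuclei(img, seg_params(smoothing_sigma = 0, min_nucleus_area = 20))
  expect_equal(max(lab), 1)
})

test_that("organoid areas are exact on binary input and calibrated to um^2", {
  mask <- disk_pixels(c(240, 240), 119.5, 119.5, 100)
  res <- segment_organoid_area(mask, pixel_size = 1)
  expect_equal(nrow(res$table), 1)
  expect_equal(res$table$area_px, sum(mask))
  expect_equal(res$table$area_um2, sum(mask))
  res2 <- segment_organoid_area(mask, pixel_size = 0.5)
  expect_equal(res2$table$area_um2, sum(mask) * 0.25)
})

test_that("multiple silhouettes in one frame give one record each", {
  shape <- c(150, 260)
  mask <- disk_pixels(shape, 70, 60, 40) | disk_pixels(shape, 70, 190, 30)
  res <- segment_organoid_area(mask, pixel_size = 1)
  expect_equal(nrow(res$table), 2)
  expect_equal(sort(res$table$area_px),
               sort(c(sum(disk_pixels(shape, 70, 60, 40)),
                      sum(disk_pixels(shape, 70, 190, 30)))))
})

test_that("noisy graylevel silhouettes are measured within 2% of truth", {
  shape <- c(160, 160)
  truth_mask <- disk_pixels(shape, 79.5, 79.5, 55)
  errs <- vapply(1:50, function(seed) {
    set.seed(seed + 100)
    img <- ifelse(truth_mask, 0.8, 0.1) + rnorm(prod(shape), 0, 0.014)
    res <- segment_organoid_area(matrix(img, shape[1], shape[2]), pixel_size = 1)
    abs(res$table$area_px[which.max(res$table$area_px)] / sum(truth_mask) - 1)
  }, numeric(1))
  expect_lt(max(errs), 0.02)
})

test_that("even z-plane selection matches the arithmetic rule and adjacency checks", {
  expect_equal(select_planes(9, 3), c(1L, 4L, 7L))
  expect_equal(select_planes(7, 3), c(1L, 3L, 5L))
  expect_equal(select_planes(10, 3, indices = c(0, 2, 4)), c(0L, 2L, 4L))
  expect_error(select_planes(3, 3), "maximum feasible n_planes is 2")
  expect_error(select_planes(10, 3, indices = c(0, 1, 4)), "non-consecutive")
  expect_error(select_planes(5, 2, indices = c(0, 7)), "out of range")
})
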