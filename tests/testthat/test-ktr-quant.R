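make_records <- function(ratios, times, cells = seq_along(ratios[, 1]),
                         organoid = 1L) {
  # ratios: cells x times matrix
  do.call(rbind, lapply(seq_along(times), function(k)
    data.frame(cell = cells, time_min = times[k], z = 0L, organoid = organoid,
               nuclear_mean = 0.5, cyto_mean = 0.5 * ratios[, k],
               nuclear_area = 100L, ring_area = 150L,
               centroid_row = 0, centroid_col = 0)))
}

test_that("the C/N ratio is mean cytoplasmic over mean nuclear intensity", {
  rec <- data.frame(nuclear_mean = c(100, 100), cyto_mean = c(150, 100))
  out <- cn_ratio(rec, guard = 1)
  expect_equal(out$ratio, c(1.5, 1.0))
  expect_false(any(out$excluded))
})

test_that("the nuclear-intensity guard excludes dim records with a message", {
  rec <- data.frame(nuclear_mean = c(0.5, 0.004, NA), cyto_mean = c(0.6, 0.5, 0.2))
  expect_message(out <- cn_ratio(rec), "2 cell record")
  expect_equal(out$excluded, c(FALSE, TRUE, TRUE))
  expect_true(is.na(out$ratio[2]))
  expect_equal(out$ratio[1], 1.2)
})

test_that("the cohort mean at T0 is exactly 100 percent after normalisation", {
  set.seed(1)
  ratios <- matrix(runif(40, 0.5, 2), 8, 5)
  rec <- cn_ratio(make_records(ratios, seq(0, 40, 10)), guard = 0.01)
  out <- normalize_to_t0(rec)
  expect_equal(mean(out$ratio_pct[out$time_min == 0]), 100, tolerance = 1e-12)
})

test_that("a single constant cell normalises to a flat 100 percent trace", {
  rec <- cn_ratio(make_records(matrix(1.3, 1, 6), seq(0, 50, 10)))
  out <- normalize_to_t0(rec)
  expect_equal(out$ratio_pct, rep(100, 6))
})

test_that("two-cell worked example: T0 mean 2.0 gives 50/200/125 percent", {
  ratios <- cbind(c(1, 3), c(1, 4))
  rec <- cn_ratio(make_records(ratios, c(0, 10)))
  out <- normalize_to_t0(rec)
  t1 <- out$ratio_pct[out$time_min == 10]
  expect_equal(sort(t1), c(50, 200))
  expect_equal(mean(t1), 125)
})

test_that("normalisation is idempotent", {
  set.seed(2)
  ratios <- matrix(runif(30, 0.5, 2), 6, 5)
  rec <- cn_ratio(make_records(ratios, seq(0, 40, 10)))
  once <- normalize_to_t0(rec)
  again <- once
  again$ratio <- once$ratio_pct
  twice <- normalize_to_t0(again)
  expect_equal(twice$ratio_pct, once$ratio_pct, tolerance = 1e-12)
})

test_that("an absent or zero T0 baseline is a hard error naming the movie", {
  rec <- data.frame(time_min = c(0, 10), ratio = c(NA, 1.2),
                    excluded = c(TRUE, FALSE))
  expect_error(normalize_to_t0(rec, movie = "movie_A"), "movie_A")
})

test_that("per-organoid aggregation: identical cells give zero-width CIs", {
  ratios <- matrix(1.5, 5, 3)
  rec <- normalize_to_t0(cn_ratio(make_records(ratios, c(0, 10, 20))))
  agg <- aggregate_per_organoid(rec)
  expect_equal(agg$mean, rep(100, 3))
  expect_equal(agg$ci_hi - agg$ci_lo, rep(0, 3))
  expect_equal(agg$n, rep(5, 3))
})

test_that("three values 90/100/110 average to 100 and n=1 has no CI", {
  rec <- data.frame(organoid = 1L, time_min = 0, ratio_pct = c(90, 100, 110))
  agg <- aggregate_per_organoid(rec)
  expect_equal(agg$mean, 100)
  rec1 <- data.frame(organoid = 1L, time_min = 0, ratio_pct = 104)
  agg1 <- aggregate_per_organoid(rec1)
  expect_true(is.na(agg1$ci_lo) && is.na(agg1$ci_hi))
})

test_that("the t-based 95% CI covers the true mean at the nominal rate", {
  hits <- vapply(1:1000, function(i) {
    set.seed(i + 5000)
    v <- rnorm(25, 120, 10)
    rec <- data.frame(organoid = 1L, time_min = 0, ratio_pct = v)
    agg <- aggregate_per_organoid(rec)
    agg$ci_lo <= 120 && 120 <= agg$ci_hi
  }, logical(1))
  # binomial 99% band around 0.95 at n = 1000
  expect_gte(mean(hits), 0.932)
  expect_lte(mean(hits), 0.968)
})

test_that("static scenes track as the identity assignment", {
  tab <- data.frame(cell = 1:4, centroid_row = c(10, 30, 50, 70),
                    centroid_col = c(10, 30, 50, 70))
  out <- match_cells_across_time(list(tab, tab, tab), max_displacement = 5)
  expect_equal(out[[1]]$track_id, out[[2]]$track_id)
  expect_equal(out[[2]]$track_id, out[[3]]$track_id)
})

test_that("a slowly translating cell keeps a single persistent id", {
  tabs <- lapply(0:5, function(k)
    data.frame(cell = 1L, centroid_row = 20 + 2 * k, centroid_col = 20))
  out <- match_cells_across_time(tabs, max_displacement = 5)
  ids <- vapply(out, function(t) t$track_id, integer(1))
  expect_equal(length(unique(ids)), 1L)
})

test_that("displacement beyond the cap terminates tracks and starts new ids", {
  # two cells trade sides but land away from both previous positions, so no
  # candidate pair is within the cap
  t1 <- data.frame(cell = 1:2, centroid_row = c(10, 40), centroid_col = c(10, 10))
  t2 <- data.frame(cell = 1:2, centroid_row = c(25, 55), centroid_col = c(10, 10))
  out <- match_cells_across_time(list(t1, t2), max_displacement = 5)
  expect_length(intersect(out[[1]]$track_id, out[[2]]$track_id), 0)
  expect_equal(sort(unique(c(out[[1]]$track_id, out[[2]]$track_id))), 1:4)
  # brute-force check: best assignment under the cap is indeed empty
  d <- as.matrix(dist(rbind(as.matrix(t1[, 2:3]), as.matrix(t2[, 2:3]))))[1:2, 3:4]
  expect_true(all(d > 5))
})

test_that("an exact position swap cross-links tracks (nearest-neighbour limit)", {
  # when cells exchange exact positions the nearest-neighbour matcher (like
  # any positional tracker) follows the positions, not the identities
  t1 <- data.frame(cell = 1:2, centroid_row = c(10, 40), centroid_col = c(10, 10))
  t2 <- data.frame(cell = 1:2, centroid_row = c(40, 10), centroid_col = c(10, 10))
  out <- match_cells_across_time(list(t1, t2), max_displacement = 5)
  expect_equal(out[[2]]$track_id, c(2L, 1L))
})

test_that("replicate-mean ANOVA flags separation and ignores identical groups", {
  same <- anova_t0_vs_t(c(100, 100, 100), c(100, 100, 100))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)
  set.seed(3)
  sep <- anova_t0_vs_t(c(100, 100, 100) + rnorm(3, 0, 1e-3),
                       c(200, 200, 200) + rnorm(3, 0, 1e-3))
  expect_lt(sep$p, 1e-6)
  expect_error(anova_t0_vs_t(100, c(110, 120)), "at least 2")
})

test_that("two-group ANOVA equals the squared pooled-variance t test", {
  set.seed(9)
  a <- rnorm(6, 100, 8); b <- rnorm(6, 112, 8)
  res <- anova_t0_vs_t(a, b)
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
})

test_that("a step activity yields a non-decreasing cohort-mean trace", {
  sc <- ktr_scene(n_cells = 10, image_shape = c(192, 192), seed = 21,
                  params = kinetics_params(noise_sd = 0))
  res <- ktr_pipeline(render_movie(sc, noise_sd = 0))
  expect_true(all(diff(res$trace$mean) > -1e-9))
  expect_equal(res$trace$mean[1], 100, tolerance = 1e-9)
})
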