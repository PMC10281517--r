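#' Measure per-cell nuclear and ring-cytoplasm intensities
#'
#' For every nucleus label present, records the mean intensity of a channel
#' over the nuclear region and over the matching ring-cytoplasm region,
#' together with region areas — one row per cell, the substrate for C/N
#' ratio computation and per-cell marker scores.
#'
#' @param img 2D intensity matrix (reporter or marker channel).
#' @param nuclei integer nucleus label map.
#' @param rings integer ring label map mirroring the nucleus labels
#'   (e.g. from [ring_cytoplasm()]).
#' @param time_min frame time in minutes (recorded per row).
#' @param z z-plane index (recorded per row).
#' @param organoid organoid id (recorded per row).
#' @return data.frame with columns `cell`, `time_min`, `z`, `organoid`,
#'   `nuclear_mean`, `cyto_mean`, `nuclear_area`, `ring_area`,
#'   `centroid_row`, `centroid_col`.
#' @export
measure_cells <- function(img, nuclei, rings, time_min = 0, z = 0L, organoid = 1L) {
  stopifnot(is.matrix(img), identical(dim(img), dim(nuclei)),
            identical(dim(img), dim(rings)))
  ids <- sort(unique(nuclei[nuclei > 0]))
  if (length(ids) == 0)
    return(data.frame(cell = integer(0), time_min = numeric(0), z = integer(0),
                      organoid = integer(0), nuclear_mean = numeric(0),
                      cyto_mean = numeric(0), nuclear_area = integer(0),
                      ring_area = integer(0), centroid_row = numeric(0),
                      centroid_col = numeric(0)))
  do.call(rbind, lapply(ids, function(k) {
    wn <- which(nuclei == k)
    wr <- which(rings == k)
    pos <- which(nuclei == k, arr.ind = TRUE)
    data.frame(cell = k, time_min = time_min, z = as.integer(z),
               organoid = as.integer(organoid),
               nuclear_mean = mean(img[wn]),
               cyto_mean = if (length(wr)) mean(img[wr]) else NA_real_,
               nuclear_area = length(wn), ring_area = length(wr),
               centroid_row = mean(pos[, 1]) - 1, centroid_col = mean(pos[, 2]) - 1)
  }))
}

#' Cytoplasm-to-nucleus intensity ratio
#'
#' Adds the C/N ratio (mean cytoplasmic intensity divided by mean nuclear
#' intensity) to a cell-record table. Records whose nuclear mean falls at or
#' below `guard` (default 1% of the channel dynamic range, here `[0, 1]`)
#' or that lack a ring region are flagged `excluded` with `ratio = NA` and
#' reported via a message — a division guard, not an error.
#'
#' @param records data.frame from [measure_cells()].
#' @param guard exclusion threshold on the nuclear mean.
#' @return `records` with added columns `ratio` and `excluded`.
#' @export
cn_ratio <- function(records, guard = 0.01) {
  stopifnot(all(c("nuclear_mean", "cyto_mean") %in% names(records)))
  excluded <- !is.finite(records$nuclear_mean) | records$nuclear_mean <= guard |
    !is.finite(records$cyto_mean)
  ratio <- ifelse(excluded, NA_real_, records$cyto_mean / records$nuclear_mean)
  if (any(excluded))
    message(sum(excluded), " cell record(s) excluded by the nuclear-intensity guard")
  records$ratio <- ratio
  records$excluded <- excluded
  records
}

#' Normalise C/N ratios to the cohort mean at time 0
#'
#' Divides every ratio by the mean ratio over all scored (non-excluded)
#' cells at the first time point and expresses it as a percentage, so the
#' cohort mean at T0 is exactly 100%. Normalisation pools cells across
#' z-planes by default; set `by_plane = TRUE` to normalise each z plane by
#' its own T0 mean.
#'
#' @param records data.frame with columns `time_min`, `ratio` (and
#'   optionally `excluded`, `z`).
#' @param by_plane normalise each z plane separately.
#' @param movie label used in error messages.
#' @return `records` with an added `ratio_pct` column.
#' @export
normalize_to_t0 <- function(records, by_plane = FALSE, movie = "movie") {
  stopifnot(all(c("time_min", "ratio") %in% names(records)))
  ok <- if ("excluded" %in% names(records)) !records$excluded else rep(TRUE, nrow(records))
  ok <- ok & is.finite(records$ratio)
  t0 <- min(records$time_min)
  norm_one <- function(idx, label) {
    sel <- idx & ok & records$time_min == t0
    m0 <- mean(records$ratio[sel])
    if (!sum(sel) || !is.finite(m0) || m0 <= 0)
      stop("no valid T0 baseline in ", movie, label)
    records$ratio[idx] / m0 * 100
  }
  records$ratio_pct <- NA_real_
  if (by_plane && "z" %in% names(records)) {
    for (zz in unique(records$z)) {
      idx <- records$z == zz
      records$ratio_pct[idx] <- norm_one(idx, paste0(" (z=", zz, ")"))
    }
  } else {
    records$ratio_pct <- norm_one(rep(TRUE, nrow(records)), "")
  }
  records
}

#' Match cells across frames by nearest nucleus centroid
#'
#' Greedy frame-to-frame assignment: candidate pairs are sorted by distance
#' (ties by smaller previous then smaller current label) and accepted while
#' both endpoints are unassigned and the displacement is within
#' `max_displacement`. Unmatched detections start new track ids; unmatched
#' tracks terminate. Deterministic given the input tables.
#'
#' @param tables list of per-frame data.frames with columns `cell`,
#'   `centroid_row`, `centroid_col` (e.g. from [measure_cells()]).
#' @param max_displacement maximum allowed centroid displacement, px.
#' @return the input list with a `track_id` column added to every table.
#' @export
match_cells_across_time <- function(tables, max_displacement = 5) {
  stopifnot(length(tables) >= 1)
  next_id <- 0L
  new_ids <- function(n) {
    ids <- next_id + seq_len(n)
    next_id <<- next_id + n
    ids
  }
  tables[[1]]$track_id <- new_ids(nrow(tables[[1]]))
  if (length(tables) == 1) return(tables)
  for (f in 2:length(tables)) {
    prev <- tables[[f - 1]]; cur <- tables[[f]]
    cur$track_id <- NA_integer_
    if (nrow(prev) && nrow(cur)) {
      d <- outer(seq_len(nrow(prev)), seq_len(nrow(cur)), function(i, j)
        sqrt((prev$centroid_row[i] - cur$centroid_row[j])^2 +
               (prev$centroid_col[i] - cur$centroid_col[j])^2))
      cand <- which(d <= max_displacement, arr.ind = TRUE)
      if (nrow(cand)) {
        ord <- order(d[cand], prev$cell[cand[, 1]], cur$cell[cand[, 2]])
        used_p <- rep(FALSE, nrow(prev)); used_c <- rep(FALSE, nrow(cur))
        for (r in ord) {
          i <- cand[r, 1]; j <- cand[r, 2]
          if (!used_p[i] && !used_c[j]) {
            cur$track_id[j] <- prev$track_id[i]
            used_p[i] <- TRUE; used_c[j] <- TRUE
          }
        }
      }
    }
    unm <- is.na(cur$track_id)
    if (any(unm)) cur$track_id[unm] <- new_ids(sum(unm))
    tables[[f]] <- cur
  }
  tables
}

#' Aggregate normalised traces per organoid (or cohort) per time point
#'
#' Arithmetic mean across cells at each time point with a t-based 95%
#' confidence band, `mean +/- t(0.975, n-1) * sd / sqrt(n)`. With a single
#' cell at a time point the CI is reported as missing (not zero).
#'
#' @param records data.frame with columns `organoid`, `time_min` and the
#'   value column (`ratio_pct` by default).
#' @param value name of the value column to aggregate.
#' @param conf confidence level.
#' @return data.frame: `organoid`, `time_min`, `mean`, `sd`, `n`,
#'   `ci_lo`, `ci_hi`.
#' @export
aggregate_per_organoid <- function(records, value = "ratio_pct", conf = 0.95) {
  stopifnot(all(c("organoid", "time_min", value) %in% names(records)))
  v <- records[[value]]
  keep <- is.finite(v)
  if ("excluded" %in% names(records)) keep <- keep & !records$excluded
  records <- records[keep, , drop = FALSE]
  v <- v[keep]
  key <- interaction(records$organoid, records$time_min, drop = TRUE)
  out <- do.call(rbind, lapply(split(seq_along(v), key), function(idx) {
    n <- length(idx)
    m <- mean(v[idx]); s <- if (n > 1) stats::sd(v[idx]) else NA_real_
    hw <- if (n > 1) stats::qt(1 - (1 - conf) / 2, n - 1) * s / sqrt(n) else NA_real_
    data.frame(organoid = records$organoid[idx[1]],
               time_min = records$time_min[idx[1]],
               mean = m, sd = s, n = n, ci_lo = m - hw, ci_hi = m + hw)
  }))
  out <- out[order(out$organoid, out$time_min), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' One-way ANOVA between replicate means at T0 and a later time point
#'
#' Tests whether the per-replicate mean normalised C/N ratio differs
#' between the baseline frame and a target frame (e.g. T1 or T12 of a
#' 10-min-interval movie), using one replicate-level mean per group member —
#' a two-group one-way ANOVA, equivalent to the squared pooled-variance
#' two-sample t test.
#'
#' @param means_t0 per-replicate means at T0 (length >= 2).
#' @param means_t per-replicate means at the target time (length >= 2).
#' @return list with `F`, `df`, `p` (see [one_way_anova()]).
#' @export
anova_t0_vs_t <- function(means_t0, means_t) {
  if (length(means_t0) < 2 || length(means_t) < 2)
    stop("need at least 2 replicate means per group")
  one_way_anova(list(T0 = means_t0, Tt = means_t))
}

#' End-to-end KTR movie quantification
#'
#' Runs the full reporter analysis on a rendered (or loaded) movie: nuclear
#' segmentation per frame, ring-cytoplasm extraction, per-cell C/N ratios,
#' T0 normalisation and the cohort-mean trace with confidence band. Frames
#' are treated as independent cohorts (no tracking), which is sufficient
#' for cohort/organoid means; per-cell tracks can be added with
#' [match_cells_across_time()].
#'
#' @param movie a `ktr_movie` from [render_movie()], or a list with
#'   `frames` (each `list(nuclear=, reporter=)`) and `frame_times`.
#' @param params a [seg_params()].
#' @param organoid organoid id recorded in the outputs.
#' @return list with `records` (per-cell table incl. `ratio_pct`) and
#'   `trace` (cohort mean per time with 95% CI).
#' @export
ktr_pipeline <- function(movie, params = seg_params(), organoid = 1L) {
  frames <- movie$frames
  times <- if (inherits(movie, "ktr_movie")) movie$scene$frame_times else movie$frame_times
  stopifnot(length(frames) == length(times))
  recs <- do.call(rbind, lapply(seq_along(frames), function(k) {
    nuc <- segment_nuclei(frames[[k]]$nuclear, params)
    rng <- ring_cytoplasm(nuc, ring_width = params$ring_width,
                          connectivity = params$connectivity)
    nuc_m <- erode_labels(nuc, params$measure_erosion)
    measure_cells(frames[[k]]$reporter, nuc_m, rng,
                  time_min = times[k], organoid = organoid)
  }))
  recs <- cn_ratio(recs)
  recs <- normalize_to_t0(recs)
  trace <- aggregate_per_organoid(recs)
  list(records = recs, trace = trace)
}
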