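# Independent oracles used across tests. These deliberately share no code
# with the package implementation.

# Brute-force ring assignment: for every pixel, the step distance to each
# nucleus label is the Chebyshev (8-connectivity) or Manhattan
# (4-connectivity) distance to that label's nearest pixel — dilation is
# unobstructed, so the step count equals the metric ball radius. Assign to
# the label with the fewest steps (<= ring_width), ties to the smaller id;
# nucleus pixels are never ring.
ring_oracle <- function(nuclei, ring_width, connectivity = 8,
                        contested = "nearest") {
  nr <- nrow(nuclei); nc <- ncol(nuclei)
  ids <- sort(unique(nuclei[nuclei > 0]))
  best <- matrix(Inf, nr, nc); lab <- matrix(0L, nr, nc); tie <- matrix(FALSE, nr, nc)
  rows <- matrix(seq_len(nr), nr, nc); cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (k in ids) {
    pts <- which(nuclei == k, arr.ind = TRUE)
    dmin <- matrix(Inf, nr, nc)
    for (i in seq_len(nrow(pts))) {
      dr <- abs(rows - pts[i, 1]); dc <- abs(cols - pts[i, 2])
      d <- if (connectivity == 8) pmax(dr, dc) else dr + dc
      dmin <- pmin(dmin, d)
    }
    tie[is.finite(dmin) & dmin == best] <- TRUE
    sel <- dmin < best
    tie[sel] <- FALSE
    best[sel] <- dmin[sel]; lab[sel] <- k
  }
  lab[best == 0 | best > ring_width | nuclei > 0] <- 0L
  if (contested == "exclude") lab[tie & best <= ring_width] <- 0L
  lab
}

# Random non-trivial label maps for property tests: a few disks/rectangles,
# possibly touching.
random_label_map <- function(seed, max_side = 64) {
  set.seed(seed)
  nr <- sample(16:max_side, 1); nc <- sample(16:max_side, 1)
  n_obj <- sample(1:6, 1)
  lab <- matrix(0L, nr, nc)
  rows <- matrix(seq_len(nr), nr, nc); cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (k in seq_len(n_obj)) {
    cy <- runif(1, 2, nr - 1); cx <- runif(1, 2, nc - 1); r <- runif(1, 1.5, 7)
    sel <- (rows - cy)^2 + (cols - cx)^2 <= r^2 & lab == 0L
    lab[sel] <- k
  }
  lab
}

# Exhaustive Mann-Whitney two-sided p: enumerate all C(n1+n2, n1) group
# assignments of the pooled values and count assignments whose U is at
# least as extreme (min(U, n1*n2 - U) <= observed) as the observed one.
mw_exact_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pool <- c(a, b)
  u_of <- function(idx) {
    x <- pool[idx]; y <- pool[-idx]
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  m_obs <- min(u_obs, n1 * n2 - u_obs)
  combs <- utils::combn(n1 + n2, n1)
  us <- apply(combs, 2, u_of)
  mean(pmin(us, n1 * n2 - us) <= m_obs)
}

# Closed-form ratio trace for piecewise-constant activity (zero-order
# hold), written independently of the package integrator.
kinetics_closed_form <- function(times, activity, r_min, r_max, tau, r0) {
  r <- numeric(length(times)); r[1] <- r0
  for (k in seq_len(length(times) - 1)) {
    rinf <- r_min + (r_max - r_min) * activity[k]
    r[k + 1] <- rinf - (rinf - r[k]) * exp(-(times[k + 1] - times[k]) / tau)
  }
  r
}

# Rasterised disk pixel set (centres at 0-based integer coordinates).
disk_pixels <- function(shape, cy, cx, r) {
  rows <- matrix(0:(shape[1] - 1), shape[1], shape[2])
  cols <- matrix(0:(shape[2] - 1), shape[1], shape[2], byrow = TRUE)
  (rows - cy)^2 + (cols - cx)^2 <= r^2
}
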