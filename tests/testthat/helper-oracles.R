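# Independent brute-force oracles used to cross-check the package's
# vectorised / library-backed implementations. Deliberately naive: plain
# loops, no shared code with R/.

# Exhaustive Otsu search: 256-level histogram of the min-max scaled
# image, explicit loop over every candidate split maximising
# between-class variance; ties resolved as the midpoint of the first and
# last maximising bins. Returns the threshold on the original scale.
oracle_otsu_threshold <- function(px, levels = 256) {
  rng <- range(px)
  scaled <- (px - rng[1]) / diff(rng)
  counts <- integer(levels)
  for (v in scaled) {
    b <- ceiling(v * levels)
    if (b < 1) b <- 1L
    if (b > levels) b <- levels
    counts[b] <- counts[b] + 1L
  }
  breaks <- seq(0, 1, length.out = levels + 1)
  mids <- (breaks[-1] + breaks[-(levels + 1)]) / 2
  best_var <- -Inf
  best <- integer(0)
  for (t in seq_len(levels)) {
    w1 <- 0; m1 <- 0
    for (i in 1:t) { w1 <- w1 + counts[i]; m1 <- m1 + counts[i] * mids[i] }
    w2 <- 0; m2 <- 0
    if (t < levels) {
      for (i in (t + 1):levels) { w2 <- w2 + counts[i]; m2 <- m2 + counts[i] * mids[i] }
    }
    if (w1 == 0 || w2 == 0) next
    v <- w1 * w2 * (m2 / w2 - m1 / w1)^2
    if (v > best_var) {
      best_var <- v
      best <- t
    } else if (v == best_var) {
      best <- c(best, t)
    }
  }
  t01 <- (mids[best[1]] + mids[best[length(best)]]) / 2
  rng[1] + t01 * diff(rng)
}

# All-pairs maximum permeation distance: for every flagged pixel, loop
# over every boundary pixel for the minimum Euclidean distance; return
# the maximum, scaled by pixel size.
oracle_max_distance <- function(mask, boundary, pixel_size_um = 1) {
  best <- 0
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      if (!mask[i, j]) next
      dmin <- Inf
      for (k in seq_len(nrow(boundary))) {
        d <- sqrt((i - boundary[k, 1])^2 + (j - boundary[k, 2])^2)
        if (d < dmin) dmin <- d
      }
      if (dmin > best) best <- dmin
    }
  }
  best * pixel_size_um
}

# Naive weighted complex least-squares objective, one frequency at a time.
oracle_chi_sq <- function(spectrum, params, weighting = "modulus") {
  total <- 0
  for (i in seq_along(spectrum$frequencies)) {
    zm <- spectrum$z[i]
    zc <- z_circuit(params, spectrum$frequencies[i])
    w_re <- switch(weighting, unit = 1, modulus = 1 / Mod(zm)^2,
                   proportional = 1 / Re(zm)^2)
    w_im <- switch(weighting, unit = 1, modulus = 1 / Mod(zm)^2,
                   proportional = 1 / Im(zm)^2)
    total <- total + w_re * (Re(zm) - Re(zc))^2 + w_im * (Im(zm) - Im(zc))^2
  }
  total
}

# Direct triangulation of a height map, one pixel cell at a time, using
# explicit 3-D vertex coordinates and the cross-product area formula.
oracle_area_ratio <- function(heights, pixel_x, pixel_y) {
  cross_area <- function(p1, p2, p3) {
    u <- p2 - p1; v <- p3 - p1
    cr <- c(u[2] * v[3] - u[3] * v[2],
            u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
    0.5 * sqrt(sum(cr^2))
  }
  total <- 0
  for (i in seq_len(nrow(heights) - 1)) {
    for (j in seq_len(ncol(heights) - 1)) {
      p00 <- c((j - 1) * pixel_x, (i - 1) * pixel_y, heights[i, j])
      p10 <- c((j - 1) * pixel_x, i * pixel_y, heights[i + 1, j])
      p01 <- c(j * pixel_x, (i - 1) * pixel_y, heights[i, j + 1])
      p11 <- c(j * pixel_x, i * pixel_y, heights[i + 1, j + 1])
      total <- total + cross_area(p00, p10, p11) + cross_area(p00, p01, p11)
    }
  }
  total / ((nrow(heights) - 1) * pixel_y * (ncol(heights) - 1) * pixel_x)
}

# Seeded bimodal test image (background vs bright blob populations).
make_bimodal_image <- function(seed, n = 32) {
  withr::with_seed(seed, {
    px <- matrix(rnorm(n * n, 0.25, 0.05), n, n)
    blob <- matrix(runif(n * n) < 0.3, n, n)
    px[blob] <- rnorm(sum(blob), 0.75, 0.05)
    pmin(pmax(px, 0), 1)
  })
}

# Seeded random mask + boundary pair for distance-oracle checks.
make_random_mask <- function(seed, nr = 48, nc = 48, p = 0.05) {
  withr::with_seed(seed, {
    mask <- matrix(runif(nr * nc) < p, nr, nc)
    k <- sample(3:8, 1)
    boundary <- cbind(sample(nr, k, replace = TRUE),
                      sample(nc, k, replace = TRUE))
    list(mask = mask, boundary = boundary)
  })
}

PAR_NAMES <- c("r_s", "c_dl_specific", "alpha", "c_q_specific",
               "r_ct", "w_mag", "b")

par_vec <- function(p) unlist(p[PAR_NAMES])

rel_err <- function(fit_params, truth, names = PAR_NAMES) {
  abs(unlist(fit_params[names]) / unlist(truth[names]) - 1)
}
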