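# Independent oracles used by the tests. These deliberately re-derive
# results by brute force or closed form, without calling the package's
# own code paths.

# 8-connected component count by an explicit flood fill (stack-based).
oracle_component_count <- function(m) {
  h <- nrow(m); w <- ncol(m)
  seen <- matrix(FALSE, h, w)
  ncomp <- 0
  for (r0 in seq_len(h)) for (c0 in seq_len(w)) {
    if (m[r0, c0] == 1 && !seen[r0, c0]) {
      ncomp <- ncomp + 1
      stack <- list(c(r0, c0)); seen[r0, c0] <- TRUE
      while (length(stack) > 0) {
        p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
        for (dr in -1:1) for (dc in -1:1) {
          r <- p[1] + dr; c <- p[2] + dc
          if (r >= 1 && r <= h && c >= 1 && c <= w &&
              m[r, c] == 1 && !seen[r, c]) {
            seen[r, c] <- TRUE
            stack[[length(stack) + 1]] <- c(r, c)
          }
        }
      }
    }
  }
  ncomp
}

# Scalar crossing-number point-in-polygon test per pixel centre
# (half-open: strict x < intersection).
oracle_rasterize <- function(poly, h, w) {
  if (all(poly[1, ] == poly[nrow(poly), ])) poly <- poly[-nrow(poly), , drop = FALSE]
  n <- nrow(poly)
  m <- matrix(0L, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    x <- c - 1; y <- r - 1
    crossings <- 0
    for (i in seq_len(n)) {
      j <- if (i == 1) n else i - 1
      yi <- poly[i, 2]; yj <- poly[j, 2]
      if ((yi > y) != (yj > y)) {
        xint <- poly[i, 1] + (y - yi) * (poly[j, 1] - poly[i, 1]) / (yj - yi)
        if (x < xint) crossings <- crossings + 1
      }
    }
    if (crossings %% 2 == 1) m[r, c] <- 1L
  }
  m
}

# Principal eigenvector of the 2x2 covariance of foreground pixel centres,
# by the closed-form quadratic solution (no eigen()).
oracle_principal_axis <- function(m) {
  idx <- which(m == 1, arr.ind = TRUE)
  x <- idx[, 2] - 1; y <- idx[, 1] - 1
  x <- x - mean(x); y <- y - mean(y)
  sxx <- mean(x * x); syy <- mean(y * y); sxy <- mean(x * y)
  tr <- sxx + syy; det <- sxx * syy - sxy^2
  lam1 <- tr / 2 + sqrt(tr^2 / 4 - det)
  v <- if (abs(sxy) > 1e-12) c(lam1 - syy, sxy) else
    if (sxx >= syy) c(1, 0) else c(0, 1)
  v / sqrt(sum(v^2))
}

# Sort-and-scan equal-area tripartition: project pixel centres on the axis,
# order with ties broken by row-major index, cut at ceiling(A/3) and
# ceiling(2A/3). Returns the full label matrix.
oracle_tripartition <- function(m, direction) {
  idx <- which(m == 1, arr.ind = TRUE)
  x <- idx[, 2] - 1; y <- idx[, 1] - 1
  w <- ncol(m)
  rowmajor <- y * w + x
  proj <- x * direction[1] + y * direction[2]
  ord <- order(proj, rowmajor)
  a <- length(ord)
  n1 <- ceiling(a / 3); n2 <- ceiling(2 * a / 3)
  lab <- integer(a)
  lab[ord[1:n1]] <- 1L
  lab[ord[(n1 + 1):n2]] <- 2L
  lab[ord[(n2 + 1):a]] <- 3L
  out <- matrix(0L, nrow(m), ncol(m))
  out[idx] <- lab
  out
}

# Textbook HSI formulas, scalar transcription.
oracle_hsi <- function(r, g, b) {
  i <- (r + g + b) / (3 * 255)
  s <- if (r + g + b == 0) 0 else 1 - 3 * min(r, g, b) / (r + g + b)
  if (s == 0) return(list(h = NA_real_, s = s, i = i))
  num <- 0.5 * ((r - g) + (r - b))
  den <- sqrt((r - g)^2 + (r - b) * (g - b))
  theta <- acos(max(-1, min(1, num / den))) * 180 / pi
  h <- if (b <= g) theta else 360 - theta
  list(h = h, s = s, i = i)
}

# Brute-force per-pixel recount of class pixels per region.
oracle_recount <- function(class_masks, labels) {
  out <- list()
  for (cl in names(class_masks)) {
    counts <- c(base = 0, middle = 0, tip = 0)
    m <- class_masks[[cl]]
    for (r in seq_len(nrow(m))) for (c in seq_len(ncol(m))) {
      if (m[r, c] && labels[r, c] > 0) {
        counts[labels[r, c]] <- counts[labels[r, c]] + 1
      }
    }
    out[[cl]] <- counts
  }
  out
}

# One-way F statistic from explicit sums of squares.
oracle_oneway_f <- function(values, groups) {
  groups <- as.factor(groups)
  grand <- mean(values)
  ssb <- 0; ssw <- 0
  for (g in levels(groups)) {
    v <- values[groups == g]
    ssb <- ssb + length(v) * (mean(v) - grand)^2
    ssw <- ssw + sum((v - mean(v))^2)
  }
  dfb <- nlevels(groups) - 1
  dfw <- length(values) - nlevels(groups)
  (ssb / dfb) / (ssw / dfw)
}

# Exhaustive within-leaflet permutation p-value for a leaflets x 3 matrix,
# by explicit nested enumeration of all 6^n orderings.
oracle_exhaustive_perm_p <- function(vals) {
  perms <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  n <- nrow(vals)
  region_idx <- rep(1:3, times = n)
  obs <- oracle_oneway_f(as.vector(t(vals)), region_idx)
  combo <- rep(1L, n)
  total <- 6^n; hits <- 0
  for (k in 0:(total - 1)) {
    kk <- k
    for (i in 1:n) { combo[i] <- kk %% 6 + 1; kk <- kk %/% 6 }
    permuted <- t(vapply(1:n, function(i) vals[i, perms[[combo[i]]]],
                         numeric(3)))
    f <- oracle_oneway_f(as.vector(t(permuted)), region_idx)
    if (f >= obs - 1e-12) hits <- hits + 1
  }
  hits / total
}

# Simulated cohort of regional distributions around a design (percent
# triplets with Gaussian noise, renormalized to 100).
simulate_cohort <- function(design, n, sd, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    repeat {
      p <- design + rnorm(3, 0, sd)
      if (all(p > 0)) break
    }
    p <- 100 * p / sum(p)
    distribution_from_counts(
      c(base = p[1], middle = p[2], tip = p[3]) * 100, "stain")
  })
}

# Small convenience: one-class zero-noise scene.
single_class_scene <- function(name = "elastin", dist = c(26.4, 20.7, 52.9),
                               budget = 1000, color = c(45, 40, 40)) {
  stain_scene(list(list(name = name, dist = dist, budget = budget,
                        color = color, noise_sd = 0)))
}
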