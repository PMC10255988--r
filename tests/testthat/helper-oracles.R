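# Independent brute-force oracles the kernels are checked against.

# Greedy farthest-point sampling recomputing all distances at every step.
fps_oracle <- function(x, m, start = 1L) {
  sel <- start
  for (j in seq_len(m - 1L)) {
    d2 <- rep(Inf, nrow(x))
    for (i in seq_len(nrow(x)))
      for (s in sel)
        d2[i] <- min(d2[i], sum((x[i, ] - x[s, ])^2))
    sel <- c(sel, which.max(d2))  # which.max takes the lowest index on ties
  }
  sel
}

# Exhaustive max pairwise distance.
rfst_oracle <- function(x) max(dist(x))

# Exhaustive in-radius filter (ascending index order, no cap, no padding).
ball_filter_oracle <- function(x, centre, radius) {
  d <- sqrt(colSums((t(x) - centre)^2))
  which(d <= radius)
}

# Direct evaluation of inverse-distance-squared kNN interpolation.
idw_oracle <- function(fine, coarse, feats, k) {
  out <- matrix(0, nrow(fine), ncol(feats))
  for (i in seq_len(nrow(fine))) {
    d <- sqrt(colSums((t(coarse) - fine[i, ])^2))
    nn <- order(d)[seq_len(k)]
    if (d[nn[1]] < 1e-10) {
      out[i, ] <- feats[nn[1], ]
    } else {
      w <- 1 / d[nn]^2
      out[i, ] <- colSums(feats[nn, , drop = FALSE] * w) / sum(w)
    }
  }
  out
}

rand_cloud <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  point_cloud(matrix(rnorm(n * 3), n, 3))
}

# A small scan dataset shared by the slower model tests.
tiny_dataset <- function(ids = c(1, 10), frames = 6, seed = 42,
                         detail = 0.035) {
  make_dataset(pig_roster(ids), frames,
               scene_config(seed = seed, point_density = 1500,
                            surface_detail = detail))
}
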