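# Independent oracles used across test files.

# Dense-grid SASA oracle: voxelizes space around the atoms and counts surface
# area via the fraction of sphere-point shells outside all other atoms,
# using a randomized (fixed-seed) point cloud independent of the engine's
# Fibonacci spiral. Suitable for <= 20-atom toys only.
grid_sasa_oracle <- function(xyz, radii, probe = 1.4, n_points = 20000, seed = 99) {
  R <- radii + probe
  withr::with_seed(seed, {
    total <- 0
    for (i in seq_len(nrow(xyz))) {
      # uniform random points on the unit sphere
      v <- matrix(stats::rnorm(3 * n_points), ncol = 3)
      v <- v / sqrt(rowSums(v^2))
      pts <- sweep(v * R[i], 2, xyz[i, ], "+")
      free <- rep(TRUE, n_points)
      for (j in seq_len(nrow(xyz))[-i]) {
        d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
              (pts[, 3] - xyz[j, 3])^2
        free <- free & d2 >= R[j]^2
      }
      total <- total + mean(free) * 4 * pi * R[i]^2
    }
    total
  })
}

# Closed-form accessible area of two intersecting spheres (expanded radii
# R1, R2 at centre distance d): each sphere loses a spherical cap.
two_sphere_area <- function(R1, R2, d) {
  if (d >= R1 + R2) return(4 * pi * (R1^2 + R2^2))
  h1 <- R1 - (d^2 + R1^2 - R2^2) / (2 * d)
  h2 <- R2 - (d^2 + R2^2 - R1^2) / (2 * d)
  (4 * pi * R1^2 - 2 * pi * R1 * h1) + (4 * pi * R2^2 - 2 * pi * R2 * h2)
}

# Two-sided Fisher p-value by full hypergeometric enumeration on a 2x2 table
# (a b / c d), point-probability criterion.
fisher_enumeration <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Hand (textbook) Welch two-sample t statistic.
welch_t_oracle <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  (mean(a) - mean(b)) / sqrt(va + vb)
}

# Straight-line C-alpha chain model, spacing in Angstrom.
line_model <- function(n, spacing = 3.8, aa = "A") {
  structure_model(data.frame(chain = "A", resno = seq_len(n), resname = aa,
                             element = "C", x = (seq_len(n) - 1) * spacing,
                             y = 0, z = 0, stringsAsFactors = FALSE))
}

residue_multiset <- function(s) sort(strsplit(s, "", fixed = TRUE)[[1]])
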