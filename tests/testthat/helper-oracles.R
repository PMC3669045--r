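# Shared oracles and generators for the test suite.

# Sum pairwise-force rows back into per-atom forces (n x 3).  Independent
# reconstruction used to check decomposition exactness and conservation.
reconstruct_forces <- function(pw, n) {
  f <- matrix(0, n, 3)
  for (r in seq_len(nrow(pw))) {
    v <- c(pw$fx[r], pw$fy[r], pw$fz[r])
    f[pw$i[r] + 1L, ] <- f[pw$i[r] + 1L, ] + v
    f[pw$j[r] + 1L, ] <- f[pw$j[r] + 1L, ] - v
  }
  f
}

# Brute-force punctual stress from a scalar table: for every entity, sum
# |value| over all rows that touch it.
brute_stress <- function(scalars, n) {
  vapply(0:(n - 1L), function(id) {
    sum(abs(scalars$value[scalars$i == id | scalars$j == id]))
  }, 0)
}

# One random term of each supported kind over 4 atoms, fixed parameters.
random_terms <- function() {
  list(
    bonded_term("BOND", c(0, 1), list(k = 1200, b0 = 0.12)),
    bonded_term("ANGLE", c(0, 1, 2), list(k = 350, theta0 = 1.85)),
    bonded_term("DIHEDRAL_PERIODIC", c(0, 1, 2, 3),
                list(k = 8, n = 3, phis = 0.4)),
    bonded_term("IMPROPER_HARMONIC", c(0, 1, 2, 3),
                list(k = 60, xi0 = 0.3)),
    bonded_term("CROSS_BOND_BOND", c(0, 1, 2),
                list(krr = 250, r1 = 0.14, r2 = 0.16)),
    bonded_term("CROSS_BOND_ANGLE", c(0, 1, 2),
                list(krt = 180, r1 = 0.14, r2 = 0.16, r3 = 0.24)))
}

# Random well-separated 4-atom configurations (avoids accidental
# near-collinear geometries that trip the angle fallback).
random_config <- function() {
  repeat {
    fr <- frame(matrix(stats::rnorm(12, sd = 0.25), 4, 3))
    g <- tryCatch({
      a <- fr$coords
      ok <- TRUE
      for (p in list(c(1, 2), c(2, 3), c(3, 4), c(1, 3), c(2, 4)))
        if (sqrt(sum((a[p[1], ] - a[p[2], ])^2)) < 0.05) ok <- FALSE
      th1 <- angle_sin(a[1, ], a[2, ], a[3, ])
      th2 <- angle_sin(a[2, ], a[3, ], a[4, ])
      ok && th1 > 0.1 && th2 > 0.1
    }, error = function(e) FALSE)
    if (g) return(fr)
  }
}

angle_sin <- function(ri, rj, rk) {
  u <- ri - rj; v <- rk - rj
  cu <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  sqrt(max(0, 1 - cu^2))
}

expect_rel_equal <- function(actual, expected, tol, scale = NULL) {
  if (is.null(scale)) scale <- max(abs(expected), 1e-12)
  expect_lt(max(abs(actual - expected)) / scale, tol)
}
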