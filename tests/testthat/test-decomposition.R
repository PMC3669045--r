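# Pairwise decomposition of bonded forces, nonbonded pair enumeration,
# and the per-frame store.

test_that("bond decomposition is the force itself; per-atom sums are exact for all kinds", {
  set.seed(7)
  fr <- random_config()
  tb <- bonded_term("BOND", c(0, 1), list(k = 1200, b0 = 0.12))
  ev <- eval_bonded_term(tb, fr)
  pw <- decompose_bonded(tb, fr, ev$forces)
  expect_equal(nrow(pw), 1)
  expect_equal(c(pw$fx, pw$fy, pw$fz), unname(ev$forces[1, ]))

  for (term in random_terms()) {
    for (rep in 1:10) {
      frr <- random_config()
      ev <- eval_bonded_term(term, frr)
      pw <- decompose_bonded(term, frr, ev$forces)
      recon <- reconstruct_forces(pw, 4)
      scale <- max(abs(ev$forces), 1)
      expect_lt(max(abs(recon[term$atoms + 1L, ] - ev$forces)) / scale,
                1e-10)
      # pairs stay within the term's atoms
      expect_true(all(c(pw$i, pw$j) %in% term$atoms))
    }
  }
})

test_that("dihedral pairwise forces are generally non-central; harmonic-angle pairs are central", {
  # For a torsion the (i,j) pair carries the full analytic force on i,
  # which is perpendicular to the first bond plane and hence generically
  # misaligned with the i-j separation.
  set.seed(7)
  td <- bonded_term("DIHEDRAL_PERIODIC", c(0, 1, 2, 3),
                    list(k = 8, n = 3, phis = 0.4))
  misalign <- function(pw, sel_i, sel_j, fr) {
    row <- pw[pw$i == sel_i & pw$j == sel_j, ]
    v <- c(row$fx, row$fy, row$fz)
    nv <- sqrt(sum(v^2))
    if (nv < 1e-8) return(0)
    d <- fr$coords[sel_i + 1L, ] - fr$coords[sel_j + 1L, ]
    acos(min(1, abs(sum(v * d)) / (nv * sqrt(sum(d^2)))))
  }
  worst <- 0
  for (rep in 1:50) {
    fr <- random_config()
    worst <- max(worst, misalign(decompose_bonded(td, fr), 0, 1, fr))
  }
  expect_gt(worst, 1e-3)

  # For the harmonic angle the 2x2-solve scheme happens to yield three
  # central pairs: F_ik = (dV/dtheta / (sin t |rij| |rkj|)) * (rkj - rij)
  # is parallel to r_ik by construction.  Assert that documented identity.
  ta <- bonded_term("ANGLE", c(0, 1, 2), list(k = 350, theta0 = 1.85))
  for (rep in 1:20) {
    fr <- random_config()
    expect_lt(misalign(decompose_bonded(ta, fr), 0, 2, fr), 1e-6)
  }
})

test_that("angle at its reference geometry decomposes to zero pairs", {
  sys <- make_toy_system("TRIATOMIC_ANGLE")
  term <- sys$topology$terms[[3]]
  pw <- decompose_bonded(term, sys$frame)
  expect_lt(max(abs(c(pw$fx, pw$fy, pw$fz))), 1e-10)
})

test_that("near-collinear angles fall back to an exact central split with a warning", {
  term <- bonded_term("ANGLE", c(0, 1, 2), list(k = 350, theta0 = 1.85))
  eps <- 1e-8
  fr <- frame(rbind(c(-0.15, eps, 0), c(0, 0, 0), c(0.15, 0, 0),
                    c(0, 0, 1)))
  ev <- eval_bonded_term(term, fr)
  expect_warning(pw <- decompose_bonded(term, fr, ev$forces),
                 class = "pf_collinear_fallback")
  recon <- reconstruct_forces(pw, 4)
  expect_lt(max(abs(recon[1:3, ] - ev$forces)),
            1e-10 * max(abs(ev$forces)))
})

test_that("dihedral pair (i,j) carries exactly the analytic force on i", {
  set.seed(11)
  term <- bonded_term("DIHEDRAL_PERIODIC", c(0, 1, 2, 3),
                      list(k = 8, n = 3, phis = 0.4))
  fr <- random_config()
  ev <- eval_bonded_term(term, fr)
  pw <- decompose_bonded(term, fr, ev$forces)
  ij <- pw[pw$i == 0 & pw$j == 1, ]
  expect_equal(c(ij$fx, ij$fy, ij$fz), unname(ev$forces[1, ]))
  lk <- pw[pw$i == 3 & pw$j == 2, ]
  expect_equal(c(lk$fx, lk$fy, lk$fz), unname(ev$forces[4, ]))
})

test_that("pair list honours cutoff, exclusions, groups and 1-4 scaling", {
  atoms <- data.frame(name = paste0("A", 1:4), resid = 0:3, mass = 1,
                      charge = c(0.5, -0.5, 0.5, -0.5), sigma = 0.3,
                      epsilon = 0.2)
  top <- topology(atoms, exclusions = rbind(c(0, 1)),
                  pairs14 = rbind(c(0, 3)),
                  fudge_lj = 0.5, fudge_qq = 0.8333)
  fr <- frame(rbind(c(0, 0, 0), c(0.3, 0, 0), c(0.6, 0, 0), c(1.9, 0, 0)))
  all4 <- group_spec(0:3, 0:3)

  pl <- build_pair_list(fr, top, all4, cutoff = 1.0)
  key <- paste(pl$i, pl$j)
  expect_false("0 1" %in% key)       # excluded
  expect_false("0 3" %in% key)       # beyond cutoff (1.9 nm)
  expect_false("1 3" %in% key)       # beyond cutoff (1.6 nm)
  expect_true(all(c("0 2", "1 2") %in% key))
  expect_true(all(pl$scale == 1))

  # bring the 1-4 pair inside the cutoff: its scale factors appear
  fr2 <- frame(rbind(c(0, 0, 0), c(0.3, 0, 0), c(0.6, 0, 0), c(0.9, 0, 0)))
  pl2 <- build_pair_list(fr2, top, all4, cutoff = 1.0)
  p14 <- pl2[pl2$i == 0 & pl2$j == 3, ]
  expect_equal(p14$scale[p14$kind == "LJ"], 0.5)
  expect_equal(p14$scale[p14$kind == "COULOMB"], 0.8333)

  # disjoint groups never emit same-group pairs
  gs <- group_spec(c(0, 1), c(2, 3))
  pld <- build_pair_list(fr2, top, gs, cutoff = 1.0)
  expect_true(all((pld$i %in% c(0, 1) & pld$j %in% c(2, 3)) |
                  (pld$i %in% c(2, 3) & pld$j %in% c(0, 1))))

  # cutoff beyond the half-box is a configuration error
  frb <- frame(fr$coords, box = c(1.5, 1.5, 1.5))
  expect_error(build_pair_list(frb, top, all4, cutoff = 1.0),
               class = "pf_config_error")
})

test_that("SUMMED equals the itype-wise sum of DETAILED on the butane-like chain", {
  sys <- make_toy_system("CHAIN4_DIHEDRAL")
  gs <- group_spec(0:3, 0:3)
  for (fr in perturb_configurations(sys$frame, 5, 0.03, seed = 9)) {
    det <- compute_frame_pairwise(fr, sys$topology, gs, cutoff = 10,
                                  mode = "DETAILED")
    sm <- compute_frame_pairwise(fr, sys$topology, gs, cutoff = 10,
                                 mode = "SUMMED")
    col <- collapse_store(det)
    expect_equal(col$i, sm$i)
    expect_equal(col$j, sm$j)
    expect_equal(col$fx, sm$fx, tolerance = 1e-12)
    expect_equal(col$fy, sm$fy, tolerance = 1e-12)
    expect_equal(col$fz, sm$fz, tolerance = 1e-12)
  }
  # the middle bond pair is shared by at least two interaction kinds
  det <- compute_frame_pairwise(sys$frame, sys$topology, gs, cutoff = 10,
                                mode = "DETAILED")
  expect_gte(length(unique(det$itype[det$i == 1 & det$j == 2])), 2)
})

test_that("full-group decomposition reconstructs total analytic forces and conserves momentum", {
  sys <- make_toy_system("BEAD_CHAIN_N", n_beads = 6)
  n <- 6
  gs <- group_spec(0:(n - 1), 0:(n - 1))
  for (fr in perturb_configurations(sys$frame, 5, 0.05, seed = 13)) {
    st <- compute_frame_pairwise(fr, sys$topology, gs, cutoff = 1e6)
    recon <- reconstruct_forces(st, n)
    ref <- system_forces(sys$topology, fr)
    expect_lt(max(abs(recon - ref)), 1e-8 * max(abs(ref), 1))
    expect_lt(max(abs(colSums(recon))), 1e-9 * max(abs(ref), 1))
  }
})

test_that("store queries are antisymmetric and itype filters restrict content", {
  sys <- make_toy_system("CHAIN4_DIHEDRAL")
  gs <- group_spec(0:3, 0:3)
  st <- compute_frame_pairwise(sys$frame, sys$topology, gs, cutoff = 10)
  expect_equal(pair_force(st, 2, 1), -pair_force(st, 1, 2))
  expect_equal(pair_force(st, 0, 3), -pair_force(st, 3, 0))

  co <- compute_frame_pairwise(sys$frame, sys$topology, gs, cutoff = 10,
                               mode = "DETAILED", itypes = "COULOMB")
  expect_true(all(co$itype == "COULOMB"))

  # a system with no charges yields an empty Coulomb store
  sys0 <- make_toy_system("TRIATOMIC_ANGLE")
  st0 <- compute_frame_pairwise(sys0$frame, sys0$topology,
                                group_spec(0:2, 0:2), cutoff = 10,
                                itypes = "COULOMB")
  expect_equal(nrow(st0), 0)
})
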