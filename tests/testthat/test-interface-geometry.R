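two_residue_complex <- function(sep) {
  mk <- function(ch, x0) {
    data.frame(chain = ch, resno = 1, aa = "A",
               elety = c("N", "CA", "CB"),
               x = x0 + c(-1.2, 0, 0), y = c(0.5, 0, 0), z = 0, plddt = 90)
  }
  complex_pair(bs_structure(rbind(mk("R", 0), mk("B", sep))), "R", "B")
}

test_that("contact cutoff is inclusive at exactly 8 A", {
  expect_equal(nrow(contact_pairs(two_residue_complex(7.9))$pairs), 1)
  expect_equal(nrow(contact_pairs(two_residue_complex(8.0))$pairs), 1)
  expect_equal(nrow(contact_pairs(two_residue_complex(8.1))$pairs), 0)
})

test_that("separated chains give an empty interface", {
  ifc <- contact_pairs(two_residue_complex(50))
  expect_equal(nrow(ifc$pairs), 0)
  expect_length(ifc$receptor_interface, 0)
  expect_length(ifc$binder_interface, 0)
})

test_that("contact_pairs matches exhaustive double-loop enumeration on random complexes", {
  for (seed in 1:12) {
    cp <- random_complex(n_rec = 10, n_bind = 7, seed = seed, spread = 9)
    got <- contact_pairs(cp)$pairs
    want <- brute_contacts(cp)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      want <- want[order(want$receptor_residue, want$binder_residue), ]
      got <- got[order(got$receptor_residue, got$binder_residue), ]
      expect_equal(got$receptor_residue, want$receptor_residue)
      expect_equal(got$binder_residue, want$binder_residue)
      expect_equal(got$cb_distance, want$cb_distance)
    }
  }
})

test_that("contact_pairs is symmetric under swapping chain roles", {
  cp <- random_complex(n_rec = 9, n_bind = 6, seed = 42, spread = 8)
  swapped <- complex_pair(cp$structure, "B", "R")
  a <- contact_pairs(cp)$pairs
  b <- contact_pairs(swapped)$pairs
  expect_equal(nrow(a), nrow(b))
  ka <- sort(paste(a$receptor_residue, a$binder_residue))
  kb <- sort(paste(b$binder_residue, b$receptor_residue))
  expect_equal(ka, kb)
})

test_that("contact_density is pair count over binder length and scales linearly", {
  ifc <- contact_pairs(two_residue_complex(50))
  expect_equal(contact_density(ifc, 10), 0)
  fx <- make_ideal_complex(fixture_spec(n_contacts = 25, binder_length = 10))
  ifc <- contact_pairs(fx$native)
  expect_equal(contact_density(ifc, 10), 2.5)
  expect_equal(contact_density(ifc, 5), 2 * contact_density(ifc, 10))
  expect_error(contact_density(ifc, 0), ">= 1")
})

test_that("superpose_receptor recovers a known proper transform", {
  fx <- make_ideal_complex(fixture_spec(n_contacts = 10))
  expect_equal(superpose_receptor(fx$native, fx$native)$rotation, diag(3),
               tolerance = 1e-9)
  expect_equal(superpose_receptor(fx$native, fx$native)$rmsd, 0,
               tolerance = 1e-9)
  set.seed(11)
  for (i in 1:5) {
    R <- random_rotation()
    t <- runif(3, -20, 20)
    moved <- transform_complex(fx$native, R, t)
    tr <- superpose_receptor(fx$native, moved)
    expect_lt(tr$rmsd, 1e-6)
    # recovered transform inverts the applied one
    expect_equal(tr$rotation %*% R, diag(3), tolerance = 1e-6,
                 ignore_attr = TRUE)
    expect_equal(abs(det(tr$rotation)), 1, tolerance = 1e-9)
    expect_equal(crossprod(tr$rotation), diag(3), tolerance = 1e-9,
                 ignore_attr = TRUE)
  }
})

test_that("superposition onto a mirror image stays a proper rotation with large RMSD", {
  fx <- make_ideal_complex(fixture_spec(n_contacts = 10))
  mirrored <- fx$native
  at <- mirrored$structure$atoms
  at$x <- -at$x
  mirrored <- complex_pair(bs_structure(at), "R", "B")
  tr <- superpose_receptor(fx$native, mirrored)
  expect_equal(det(tr$rotation), 1, tolerance = 1e-9)
  expect_gt(tr$rmsd, 1)
})

test_that("superposition agrees with an independent least-squares fit and is optimal", {
  fx <- make_ideal_complex(fixture_spec(n_contacts = 10,
                                        displacement = c(1, 2, -1)))
  set.seed(3)
  R <- random_rotation()
  t <- c(4, -7, 2)
  moved <- transform_complex(fx$predicted, R, t)
  tr <- superpose_receptor(fx$native, moved)

  nat_ca <- fx$native$structure$atoms
  nat_ca <- as.matrix(nat_ca[nat_ca$chain == "R" & nat_ca$elety == "CA",
                             c("x", "y", "z")])
  mov_ca <- moved$structure$atoms
  mov_ca <- as.matrix(mov_ca[mov_ca$chain == "R" & mov_ca$elety == "CA",
                             c("x", "y", "z")])
  xyz_fit <- bio3d::fit.xyz(as.numeric(t(nat_ca)), as.numeric(t(mov_ca)),
                            fixed.inds = seq_len(length(nat_ca)),
                            mobile.inds = seq_len(length(nat_ca)))
  ref_rmsd <- sqrt(mean(rowSums(
    (matrix(xyz_fit, ncol = 3, byrow = TRUE) - nat_ca)^2)))
  expect_equal(tr$rmsd, ref_rmsd, tolerance = 1e-6)
  # optimality: no random proper transform does better
  rmsd_of <- function(Rr, tt) {
    sqrt(mean(rowSums((sweep(mov_ca %*% t(Rr), 2, tt, "+") - nat_ca)^2)))
  }
  for (i in 1:25) {
    expect_gte(rmsd_of(random_rotation(), runif(3, -5, 5)) + 1e-12, tr$rmsd)
  }
})

test_that("superpose_receptor needs at least three pairable CA residues", {
  mk <- function(n) {
    bs_structure(data.frame(chain = rep(c("R", "B"), each = n),
                            resno = rep(seq_len(n), 2), aa = "A",
                            elety = "CA",
                            x = c(seq_len(n) * 4, seq_len(n) * 4 + 5),
                            y = 0, z = 0, plddt = 90))
  }
  a <- complex_pair(mk(2), "R", "B")
  expect_error(superpose_receptor(a, a), ">= 3")
})

test_that("interface RMSD: identity, uniform displacement, and receptor-frame invariance", {
  fx0 <- make_ideal_complex(fixture_spec(n_contacts = 12))
  expect_equal(interface_rmsd(fx0$native, fx0$native), 0, tolerance = 1e-9)

  fx <- make_ideal_complex(fixture_spec(n_contacts = 12,
                                        displacement = c(0, 1.5, 0)))
  expect_equal(interface_rmsd(fx$native, fx$predicted), 1.5,
               tolerance = 1e-9)

  # rotating the whole predicted complex changes nothing: the receptor
  # alignment absorbs the transform
  base <- interface_rmsd(fx$native, fx$predicted)
  set.seed(5)
  rot <- transform_complex(fx$predicted, random_rotation(), runif(3, -30, 30))
  expect_equal(interface_rmsd(fx$native, rot), base, tolerance = 1e-6)
})

test_that("interface RMSD error paths: empty interface, unpairable positions", {
  far <- two_residue_complex(50)
  expect_error(interface_rmsd(far, far), "no binder interface")

  fx <- make_ideal_complex(fixture_spec(n_contacts = 12, binder_length = 15))
  short_at <- fx$predicted$structure$atoms
  short_at <- short_at[!(short_at$chain == "B" & short_at$resno > 5), ]
  short <- complex_pair(bs_structure(short_at), "R", "B")
  expect_error(interface_rmsd(fx$native, short, contact_pairs(fx$native)),
               "position")
})

test_that("delta_com: identity, 3-4-5 displacement, centroid oracle", {
  fx <- make_ideal_complex(fixture_spec(n_contacts = 8))
  b <- binder_atoms(fx$native)
  expect_equal(delta_com(b, b), 0)

  moved <- b
  moved$x <- moved$x + 3
  moved$y <- moved$y + 4
  expect_equal(delta_com(moved, b), 5)

  # independent coordinate-averaging oracle on an arbitrary fixture
  cp <- random_complex(seed = 9)
  pb <- binder_atoms(cp)
  rb <- binder_atoms(random_complex(seed = 10))
  pca <- pb[pb$elety == "CA", ]
  rca <- rb[rb$elety == "CA", ]
  cen <- function(df) c(sum(df$x), sum(df$y), sum(df$z)) / nrow(df)
  expect_equal(delta_com(pb, rb), sqrt(sum((cen(pca) - cen(rca))^2)))
})

test_that("delta_com is invariant under joint proper rigid transforms", {
  fx <- make_ideal_complex(fixture_spec(n_contacts = 8,
                                        displacement = c(2, -1, 3)))
  ref <- binder_atoms(fx$native)
  base <- delta_com(binder_atoms(fx$predicted), ref)
  set.seed(21)
  for (i in 1:10) {
    moved <- transform_complex(fx$predicted, random_rotation(),
                               runif(3, -15, 15))
    tr <- superpose_receptor(fx$native, moved)
    expect_equal(delta_com(binder_atoms(moved), ref, tr), base,
                 tolerance = 1e-6)
  }
})

test_that("receptor_if_distance matches an exhaustive min-distance loop", {
  # coincident atoms give zero
  one <- data.frame(chain = "R", resno = 1, aa = "A", elety = "CA",
                    x = 1, y = 2, z = 3, plddt = 90)
  expect_equal(receptor_if_distance(one, transform(one, chain = "B")), 0)

  # single target atom at distance 6 from nearest binder atom
  b2 <- data.frame(chain = "B", resno = 1, aa = "A", elety = c("CA", "CB"),
                   x = c(7, 30), y = 2, z = 3, plddt = 90)
  expect_equal(receptor_if_distance(one, b2), 6)

  cp <- random_complex(n_rec = 6, n_bind = 4, seed = 31, spread = 7)
  rec <- receptor_atoms(cp)
  tat <- rec[rec$resno %in% c(1, 3, 5), ]
  bnd <- binder_atoms(cp)
  mins <- c()
  for (i in seq_len(nrow(tat))) {
    best <- Inf
    for (j in seq_len(nrow(bnd))) {
      best <- min(best, sqrt(sum((as.numeric(tat[i, c("x", "y", "z")]) -
                                    as.numeric(bnd[j, c("x", "y", "z")]))^2)))
    }
    mins <- c(mins, best)
  }
  expect_equal(receptor_if_distance(tat, bnd), mean(mins))
  expect_error(receptor_if_distance(tat[0, ], bnd), "target")
})
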