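# Shared fixture builders and independent brute-force oracles. The
# oracles deliberately use plain element-wise loops so they share no code
# path with the implementation they check.

# Random two-chain complex: residues at random centres, five heavy atoms
# each (N, CA, C, O, CB) at small random offsets around the centre.
random_complex <- function(n_rec = 8, n_bind = 5, seed = 1,
                           spread = 12, plddt = NULL) {
  set.seed(seed)
  mk_chain <- function(n, ch, offset) {
    rows <- lapply(seq_len(n), function(i) {
      centre <- runif(3, -spread, spread) + offset
      el <- c("N", "CA", "C", "O", "CB")
      xyz <- t(vapply(el, function(e) centre + runif(3, -0.8, 0.8),
                      numeric(3)))
      data.frame(chain = ch, resno = i,
                 aa = sample(setdiff(binderscore::AA_CATEGORIES$Hydrophobic,
                                     "G"), 1),
                 elety = el, x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                 plddt = if (is.null(plddt)) runif(1, 40, 100) else plddt)
    })
    do.call(rbind, rows)
  }
  st <- bs_structure(rbind(mk_chain(n_rec, "R", c(0, 0, 0)),
                           mk_chain(n_bind, "B", c(6, 0, 0))))
  complex_pair(st, "R", "B")
}

# Brute-force cross-chain contact enumeration via an explicit double loop.
brute_contacts <- function(cp, cutoff = 8.0) {
  rec <- receptor_atoms(cp)
  bnd <- binder_atoms(cp)
  out <- NULL
  for (rr in unique(rec$resno)) {
    rcb <- effective_cb(rec[rec$resno == rr, ])
    for (br in unique(bnd$resno)) {
      bcb <- effective_cb(bnd[bnd$resno == br, ])
      d <- sqrt(sum((rcb - bcb)^2))
      if (d <= cutoff) {
        out <- rbind(out, data.frame(receptor_residue = rr,
                                     binder_residue = br, cb_distance = d))
      }
    }
  }
  out
}

# Exhaustive bind-score oracle: every atom pair enumerated, the two
# directed minima-means taken, the formula evaluated literally.
brute_loss <- function(predicted, target_residues, reference_binder,
                       frame = identity_transform()) {
  rec <- receptor_atoms(predicted)
  tat <- rec[rec$resno %in% target_residues & !(rec$elesy %in% c("H", "D")), ]
  bnd <- binder_atoms(predicted)
  bat <- bnd[!(bnd$elesy %in% c("H", "D")), ]
  txyz <- apply_transform(frame, as.matrix(tat[, c("x", "y", "z")]))
  bxyz <- apply_transform(frame, as.matrix(bat[, c("x", "y", "z")]))
  di <- numeric(nrow(txyz))
  for (i in seq_len(nrow(txyz))) {
    best <- Inf
    for (j in seq_len(nrow(bxyz))) {
      best <- min(best, sqrt(sum((txyz[i, ] - bxyz[j, ])^2)))
    }
    di[i] <- best
  }
  dj <- numeric(nrow(bxyz))
  for (j in seq_len(nrow(bxyz))) {
    best <- Inf
    for (i in seq_len(nrow(txyz))) {
      best <- min(best, sqrt(sum((txyz[i, ] - bxyz[j, ])^2)))
    }
    dj[j] <- best
  }
  # CA centroid displacement oracle
  pca <- bnd[bnd$elety == "CA", c("x", "y", "z")]
  cen_p <- apply_transform(frame, colMeans(as.matrix(pca)))
  rca <- reference_binder[reference_binder$elety == "CA", c("x", "y", "z")]
  cen_r <- colMeans(as.matrix(rca))
  dcom <- sqrt(sum((cen_p - cen_r)^2))
  plddt <- mean_plddt(predicted$structure, predicted$binder_chain)
  (1 / plddt) * (mean(di) + mean(dj) * 0.5 * dcom)
}

# Pairwise-comparison (Mann-Whitney) AUC with half credit for ties.
mw_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) {
    for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# Uniform-ish random proper rotation (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Apply a rigid transform (R, t) to every atom of a bs_structure.
transform_structure <- function(st, R, t) {
  xyz <- as.matrix(st$atoms[, c("x", "y", "z")])
  st$atoms[, c("x", "y", "z")] <- sweep(xyz %*% t(R), 2, t, "+")
  bs_structure(st$atoms)
}

transform_complex <- function(cp, R, t) {
  complex_pair(transform_structure(cp$structure, R, t),
               cp$receptor_chain, cp$binder_chain)
}

# Brute-force window oracle: score every window of length L with
# explicit loops over residues and target atoms.
brute_best_window <- function(scaffold, receptor, targets, L, cutoff = 8) {
  res <- unique(scaffold$resno)
  n <- length(res)
  L <- min(L, n)
  tat <- receptor[receptor$resno %in% targets, ]
  tcb <- t(vapply(unique(tat$resno), function(rn) {
    effective_cb(tat[tat$resno == rn, ])
  }, numeric(3)))
  scb <- t(vapply(res, function(rn) {
    effective_cb(scaffold[scaffold$resno == rn, ])
  }, numeric(3)))
  counts <- integer(n - L + 1)
  for (s in seq_len(n - L + 1)) {
    k <- 0
    for (i in s:(s + L - 1)) {
      for (j in seq_len(nrow(tcb))) {
        if (sqrt(sum((scb[i, ] - tcb[j, ])^2)) <= cutoff) k <- k + 1
      }
    }
    counts[s] <- k
  }
  list(start = which.max(counts), count = max(counts))
}

# Random single-chain scaffold used in crop-search tests.
random_scaffold <- function(n, seed, spread = 25) {
  set.seed(seed)
  rows <- lapply(seq_len(n), function(i) {
    centre <- c(runif(1, -spread, spread), runif(1, -spread, spread),
                i * 1.2)
    el <- c("N", "CA", "C", "CB")
    xyz <- t(vapply(el, function(e) centre + runif(3, -0.6, 0.6),
                    numeric(3)))
    data.frame(chain = "S", resno = i, aa = "A", elety = el,
               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], plddt = 90)
  })
  do.call(rbind, rows)
}
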