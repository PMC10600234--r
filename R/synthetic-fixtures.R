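# Synthetic receptor-binder complexes with controlled geometry. Chains
# are ideal poly-alanine helices (1.5 A rise, 100 degree twist per
# residue) carrying full N/CA/C/O/CB records; the binder helix faces the
# receptor and their separation is tuned until the complex has exactly
# the requested number of beta-carbon contacts at the 8 A cutoff. The
# "predicted" complex is the native one with the binder rigidly
# displaced (and the whole complex optionally rotated), so interface
# RMSD and delta-COM have planted analytic values equal to the
# displacement magnitude.

#' Specification of a synthetic receptor-binder fixture
#'
#' @param receptor_length,binder_length chain lengths in residues (>= 1).
#' @param n_contacts target number of cross-chain beta-carbon contacts
#'   at the 8 A cutoff in the native complex.
#' @param displacement rigid displacement of the predicted binder:
#'   a 3-vector in Angstrom, or a scalar applied along x.
#' @param rotation_deg optional rotation (degrees, about z) applied to
#'   the whole predicted complex; receptor superposition absorbs it.
#' @param receptor_plddt,binder_plddt per-residue plDDT values
#'   (recycled to chain length), 0-100.
#' @param rng_seed integer seed (reserved for randomised variants).
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(receptor_length = 40, binder_length = 15,
                         n_contacts = 12, displacement = c(0, 0, 0),
                         rotation_deg = 0, receptor_plddt = 90,
                         binder_plddt = 85, rng_seed = 1) {
  stopifnot(receptor_length >= 1, binder_length >= 1, n_contacts >= 0)
  if (n_contacts > receptor_length * binder_length) {
    stop("n_contacts exceeds receptor_length * binder_length")
  }
  if (length(displacement) == 1) displacement <- c(displacement, 0, 0)
  stopifnot(length(displacement) == 3)
  structure(list(
    receptor_length = receptor_length, binder_length = binder_length,
    n_contacts = n_contacts, displacement = displacement,
    rotation_deg = rotation_deg,
    receptor_plddt = rep_len(receptor_plddt, receptor_length),
    binder_plddt = rep_len(binder_plddt, binder_length),
    rng_seed = rng_seed
  ), class = "fixture_spec")
}

# Ideal helix chain: CA on a cylinder of radius 2.3 A, 1.5 A rise and
# 100 degree twist per residue; CB pointing radially outward; N/C/O at
# fixed offsets in the local azimuthal frame. `phase` rotates the helix
# about its own axis so side chains can face a partner; `origin` places
# the axis.
helix_chain <- function(n, chain_id, origin = c(0, 0, 0), phase = 0,
                        plddt = 90, aa = "A", start_resno = 1) {
  plddt <- rep_len(plddt, n)
  aa <- rep_len(aa, n)
  th <- phase + seq_len(n) * 100 * pi / 180
  u <- cbind(cos(th), sin(th), 0)          # radial unit vectors
  v <- cbind(-sin(th), cos(th), 0)         # azimuthal unit vectors
  ca <- sweep(2.3 * u + cbind(0, 0, 1.5 * seq_len(n)), 2, origin, "+")
  atom_sets <- list(
    N = ca - 0.85 * v + rep(c(0, 0, -0.9), each = n),
    CA = ca,
    C = ca + 0.85 * v + rep(c(0, 0, 0.9), each = n),
    O = ca + 0.85 * v + 0.6 * u + rep(c(0, 0, 1.5), each = n),
    CB = ca + 1.53 * u
  )
  rows <- do.call(rbind, lapply(names(atom_sets), function(el) {
    data.frame(chain = chain_id, resno = start_resno + seq_len(n) - 1,
               aa = aa, elety = el,
               x = atom_sets[[el]][, 1], y = atom_sets[[el]][, 2],
               z = atom_sets[[el]][, 3], plddt = plddt)
  }))
  rows <- rows[!(rows$elety == "CB" & rows$aa == "G"), ]
  rows <- rows[order(rows$resno,
                     match(rows$elety, c("N", "CA", "C", "O", "CB"))), ]
  rownames(rows) <- NULL
  rows
}

# CB positions of an ideal helix without building the atom table;
# used to tune chain separation cheaply.
helix_cb <- function(n, origin = c(0, 0, 0), phase = 0) {
  th <- phase + seq_len(n) * 100 * pi / 180
  sweep(cbind((2.3 + 1.53) * cos(th), (2.3 + 1.53) * sin(th),
              1.5 * seq_len(n)), 2, origin, "+")
}

# Count CB contacts between two atom tables at the given cutoff.
count_cb_contacts <- function(a, b, cutoff = 8.0) {
  sum(cross_dist(scaffold_cb(a), scaffold_cb(b)) <= cutoff)
}

#' Build a native/predicted complex pair with planted ground truth
#'
#' @param spec a [fixture_spec].
#' @param cutoff contact cutoff in Angstrom (default 8).
#' @return List with `native` and `predicted` [complex_pair] objects
#'   (receptor chain "R", binder chain "B") and `ground_truth`:
#'   `n_contacts`, `interface_rmsd` and `delta_com` (both equal to the
#'   displacement magnitude), `displacement`.
#' @export
make_ideal_complex <- function(spec, cutoff = 8.0) {
  rec <- helix_chain(spec$receptor_length, "R", plddt = spec$receptor_plddt)
  z0 <- 1.5 * (spec$receptor_length - spec$binder_length) / 2
  rec_cb <- helix_cb(spec$receptor_length)
  # tune the helix separation (and, if needed, a small axial shift) until
  # the native complex has exactly the requested contact count
  found <- NULL
  if (spec$n_contacts == 0) {
    found <- c(60, 0)
  } else {
    for (zshift in seq(0, 1.45, by = 0.05)) {
      bnd_cb0 <- helix_cb(spec$binder_length, c(0, 0, z0 + zshift), pi)
      count_at <- function(sep) {
        sum(cross_dist(rec_cb,
                       sweep(bnd_cb0, 2, c(sep, 0, 0), "+")) <= cutoff)
      }
      # coarse scan for the bracket where the count crosses the target,
      # then a fine scan inside it
      prev <- 28
      for (sep in seq(28, 3, by = -0.2)) {
        k <- count_at(sep)
        if (k == spec$n_contacts) {
          found <- c(sep, zshift)
          break
        }
        if (k > spec$n_contacts) {
          for (fine in seq(prev, sep, by = -0.02)) {
            if (count_at(fine) == spec$n_contacts) {
              found <- c(fine, zshift)
              break
            }
          }
          break
        }
        prev <- sep
      }
      if (!is.null(found)) break
    }
  }
  if (is.null(found)) {
    stop("no helix separation yields exactly ", spec$n_contacts,
         " contacts for these chain lengths")
  }
  bnd <- helix_chain(spec$binder_length, "B",
                     origin = c(found[1], 0, z0 + found[2]), phase = pi,
                     plddt = spec$binder_plddt)
  native <- complex_pair(bs_structure(rbind(rec, bnd)), "R", "B")

  pb <- bnd
  pb[, c("x", "y", "z")] <- sweep(as.matrix(pb[, c("x", "y", "z")]), 2,
                                  spec$displacement, "+")
  pred_atoms <- rbind(rec, pb)
  if (spec$rotation_deg != 0) {
    th <- spec$rotation_deg * pi / 180
    R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
    xyz <- as.matrix(pred_atoms[, c("x", "y", "z")]) %*% t(R)
    pred_atoms[, c("x", "y", "z")] <- sweep(xyz, 2, c(5, -3, 2), "+")
  }
  predicted <- complex_pair(bs_structure(pred_atoms), "R", "B")

  disp <- sqrt(sum(spec$displacement^2))
  list(native = native, predicted = predicted,
       ground_truth = list(n_contacts = spec$n_contacts,
                           interface_rmsd = disp, delta_com = disp,
                           displacement = spec$displacement))
}

#' Simulate a per-design campaign table with planted structure
#'
#' Generates a reproducible design table whose loss/RMSD relationship is
#' controlled: the loss is a noisy monotone function of the interface
#' RMSD (`loss = 0.05 * rmsd * exp(noise)`), successes (RMSD <= 2 A)
#' occur with probability `success_prob` on average — scaled linearly
#' with the seed contact density, so dense seeds succeed more often —
#' and plDDT decreases with RMSD. With `noise_sd = 0` the loss orders
#' designs exactly as RMSD does, so loss-based ROC selection of
#' successes is perfect.
#'
#' @param n_targets number of target interfaces.
#' @param designs_per_target designs generated per target.
#' @param success_prob probability a design is successful.
#' @param rng_seed integer seed.
#' @param noise_sd standard deviation of the log-normal noise coupling
#'   loss to RMSD (default 0.1).
#' @return data.frame with columns `target_id`, `design_id`,
#'   `design_order`, `length`, `loss`, `binder_plddt`, `interface_rmsd`,
#'   `contact_density`, `contact_recovery`, `seq_recovery`, `success`.
#' @export
make_design_table <- function(n_targets, designs_per_target, success_prob,
                              rng_seed = 1, noise_sd = 0.1) {
  stopifnot(n_targets >= 1, designs_per_target >= 1,
            success_prob >= 0, success_prob <= 1)
  with_seed(rng_seed, {
    n <- n_targets * designs_per_target
    # seed contact density drives the success odds: per-design success
    # probability is proportional to density (mean across the density
    # range equals success_prob), mirroring the observation that dense
    # seeds make designable interfaces
    density <- stats::runif(n, 0.5, 9)
    success <- stats::runif(n) < pmin(1, success_prob * density /
                                        mean(c(0.5, 9)))
    rmsd <- ifelse(success,
                   stats::runif(n, 0.2, 2.0),
                   stats::runif(n, 2.3, 20))
    loss <- 0.05 * rmsd * exp(stats::rnorm(n, 0, noise_sd))
    plddt <- pmin(99, pmax(20, 95 - 3.5 * rmsd + stats::rnorm(n, 0, 4)))
    data.frame(
      target_id = rep(sprintf("T%04d", seq_len(n_targets)),
                      each = designs_per_target),
      design_id = sprintf("D%06d", seq_len(n)),
      design_order = rep(seq_len(designs_per_target), n_targets),
      length = sample(c(10L, 20L, 30L, 40L, 50L), n, replace = TRUE),
      loss = loss,
      binder_plddt = plddt,
      interface_rmsd = rmsd,
      contact_density = density,
      contact_recovery = pmin(1, pmax(0, 1 - rmsd / 20 +
                                        stats::rnorm(n, 0, 0.05))),
      seq_recovery = pmin(1, pmax(0, 0.9 - rmsd / 25 +
                                    stats::rnorm(n, 0, 0.08))),
      success = success
    )
  })
}
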