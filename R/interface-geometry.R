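# Geometric core: every score in the package reduces to contacts,
# superposition, and distances computed here.

# Pairwise Euclidean distance matrix between two n x 3 / m x 3 coordinate
# matrices.
cross_dist <- function(a, b) {
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

#' Cross-chain beta-carbon contacts and interface definition
#'
#' The interface of a two-chain complex is the set of residue pairs whose
#' effective beta carbons (CA for glycine) lie within the cutoff of each
#' other; the comparison is inclusive (distance <= cutoff). Interface
#' residue sets are the projections of the contact pairs.
#'
#' @param complex a [complex_pair].
#' @param cutoff contact cutoff in Angstrom (default 8).
#' @return Object of class `interface_def`: list with `cutoff`, `pairs`
#'   (data.frame: `receptor_residue`/`binder_residue` author numbers,
#'   `receptor_pos`/`binder_pos` chain ordinals, `cb_distance` in
#'   Angstrom), `receptor_interface` and `binder_interface` (sorted
#'   residue-number vectors), and the `_pos` ordinal counterparts.
#' @export
contact_pairs <- function(complex, cutoff = 8.0) {
  rc <- effective_cb_coords(complex$structure, complex$receptor_chain)
  bc <- effective_cb_coords(complex$structure, complex$binder_chain)
  d <- cross_dist(rc, bc)
  hit <- which(d <= cutoff, arr.ind = TRUE)
  pairs <- data.frame(
    receptor_residue = as.integer(rownames(rc))[hit[, 1]],
    binder_residue = as.integer(rownames(bc))[hit[, 2]],
    receptor_pos = attr(rc, "pos")[hit[, 1]],
    binder_pos = attr(bc, "pos")[hit[, 2]],
    cb_distance = d[hit]
  )
  pairs <- pairs[order(pairs$receptor_pos, pairs$binder_pos), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(
    cutoff = cutoff,
    pairs = pairs,
    receptor_interface = sort(unique(pairs$receptor_residue)),
    binder_interface = sort(unique(pairs$binder_residue)),
    receptor_interface_pos = sort(unique(pairs$receptor_pos)),
    binder_interface_pos = sort(unique(pairs$binder_pos))
  ), class = "interface_def")
}

#' @export
print.interface_def <- function(x, ...) {
  cat(sprintf(
    "interface (Cb cutoff %.1f A): %d contact pairs, %d receptor / %d binder residues\n",
    x$cutoff, nrow(x$pairs),
    length(x$receptor_interface), length(x$binder_interface)))
  invisible(x)
}

#' Contact density of an interface
#'
#' Number of cross-chain beta-carbon contacts divided by the binder
#' length: contacts per binder residue. Dense seeds (many contacts per
#' residue) are the strongest predictor of design success.
#'
#' @param interface an [contact_pairs] result.
#' @param binder_length binder length in residues (>= 1).
#' @return Contacts per residue.
#' @export
contact_density <- function(interface, binder_length) {
  if (binder_length < 1) stop("binder_length must be >= 1")
  nrow(interface$pairs) / binder_length
}

#' Kabsch superposition of predicted receptor onto native receptor
#'
#' Least-squares rigid-body fit of the predicted receptor's CA atoms onto
#' the native receptor's, pairing residues by author residue number.
#' Reflections are disallowed: the returned rotation is always proper
#' (determinant +1), so a mirror-image receptor fits poorly rather than
#' inverting chirality.
#'
#' @param native,predicted [complex_pair] objects sharing >= 3 receptor
#'   residues (by residue number) that carry CA atoms.
#' @return Object of class `rigid_transform`: list with `rotation` (3x3,
#'   det +1), `translation` (length 3), and `rmsd` (post-fit CA RMSD in
#'   Angstrom). Apply with [apply_transform].
#' @export
superpose_receptor <- function(native, predicted) {
  nat <- ca_coords(native$structure, native$receptor_chain)
  prd <- ca_coords(predicted$structure, predicted$receptor_chain)
  shared <- intersect(rownames(nat), rownames(prd))
  if (length(shared) < 3) {
    stop("need >= 3 receptor residues pairable by residue number with CA; got ",
         length(shared))
  }
  x <- prd[shared, , drop = FALSE]   # moving
  y <- nat[shared, , drop = FALSE]   # fixed
  kabsch(x, y)
}

# Kabsch algorithm: proper rotation R and translation t minimising
# ||R x + t - y||^2 over paired coordinate rows.
kabsch <- function(x, y) {
  cx <- colMeans(x)
  cy <- colMeans(y)
  xs <- sweep(x, 2, cx)
  ys <- sweep(y, 2, cy)
  s <- svd(crossprod(xs, ys))        # covariance xs' ys = U D V'
  d <- sign(det(tcrossprod(s$v, s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cy - as.numeric(R %*% cx)
  fitted <- sweep(tcrossprod(x, R), 2, t, "+")
  structure(list(rotation = R, translation = t,
                 rmsd = sqrt(mean(rowSums((fitted - y)^2)))),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("rigid_transform: rotation %.2f deg, |t| = %.3f A, fit RMSD %.4f A\n",
              ang, sqrt(sum(x$translation^2)), x$rmsd))
  invisible(x)
}

#' Identity rigid transform
#' @return A `rigid_transform` that leaves coordinates unchanged.
#' @export
identity_transform <- function() {
  structure(list(rotation = diag(3), translation = numeric(3), rmsd = 0),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#'
#' @param transform a `rigid_transform`.
#' @param coords n x 3 coordinate matrix (or length-3 vector).
#' @return Transformed coordinates, same shape.
#' @export
apply_transform <- function(transform, coords) {
  if (is.null(dim(coords))) {
    return(as.numeric(transform$rotation %*% coords + transform$translation))
  }
  out <- sweep(tcrossprod(coords, transform$rotation), 2,
               transform$translation, "+")
  dimnames(out) <- dimnames(coords)
  out
}

#' Binder interface RMSD after receptor superposition
#'
#' Deviation of the binder's interface beta carbons between the predicted
#' and native complexes, measured in the receptor frame: the predicted
#' receptor is first superposed onto the native receptor on CA atoms, then
#' the RMSD is taken over the effective beta carbons of the binder
#' residues belonging to the native interface. Native and predicted
#' binder residues are paired by sequence position (1..N within the
#' chain), since designed sequences carry no meaningful author numbering.
#' A complex is conventionally called successful when this RMSD is
#' at most 2 Angstrom.
#'
#' @param native,predicted [complex_pair] objects.
#' @param interface interface definition of the native complex (from
#'   [contact_pairs]); computed from `native` when omitted.
#' @return RMSD in Angstrom.
#' @export
interface_rmsd <- function(native, predicted, interface = NULL) {
  if (is.null(interface)) interface <- contact_pairs(native)
  ipos <- interface$binder_interface_pos
  if (length(ipos) == 0) stop("native complex has no binder interface residues")
  tr <- superpose_receptor(native, predicted)
  natc <- effective_cb_coords(native$structure, native$binder_chain)
  prdc <- effective_cb_coords(predicted$structure, predicted$binder_chain)
  if (max(ipos) > nrow(prdc)) {
    bad <- ipos[ipos > nrow(prdc)]
    stop("predicted binder has no residue at interface position(s): ",
         paste(bad, collapse = ", "))
  }
  prdc <- apply_transform(tr, prdc)
  dev <- natc[ipos, , drop = FALSE] - prdc[ipos, , drop = FALSE]
  sqrt(mean(rowSums(dev^2)))
}

#' Centre-of-mass displacement of the binder (Delta-COM)
#'
#' Euclidean distance between the CA centroids of the predicted binder
#' and a reference binder (the seed, or the native binder when no seed
#' exists), after mapping the predicted coordinates into the
#' receptor-aligned frame. The term anchors the bind score to the
#' intended interface: a binder placed on the mirror-image side of the
#' receptor can achieve the same interface distances but not the same
#' centroid.
#'
#' @param predicted_binder,reference_binder atom tables (data.frames with
#'   `elety`, `x`, `y`, `z`) of the two binder chains.
#' @param frame `rigid_transform` from [superpose_receptor], applied to
#'   the predicted binder; defaults to the identity.
#' @return Distance in Angstrom.
#' @export
delta_com <- function(predicted_binder, reference_binder,
                      frame = identity_transform()) {
  pca <- predicted_binder[predicted_binder$elety == "CA", c("x", "y", "z")]
  rca <- reference_binder[reference_binder$elety == "CA", c("x", "y", "z")]
  if (nrow(pca) == 0 || nrow(rca) == 0) stop("binder chain has no CA atoms")
  cp <- apply_transform(frame, colMeans(as.matrix(pca)))
  cr <- colMeans(as.matrix(rca))
  sqrt(sum((cp - cr)^2))
}

#' Mean shortest distance from receptor target residues to the binder
#'
#' For every heavy atom of the listed receptor target residues, the
#' minimum distance to any binder heavy atom is found; the mean of those
#' per-atom minima is returned. Low values indicate a binder packed
#' against the chosen interface region.
#'
#' @param target_atoms atom table of the receptor target residues.
#' @param binder atom table of the binder chain.
#' @return Mean of per-target-atom shortest distances, Angstrom.
#' @export
receptor_if_distance <- function(target_atoms, binder) {
  ta <- heavy_coords(target_atoms)
  ba <- heavy_coords(binder)
  if (nrow(ta) == 0) stop("no heavy atoms in target residue set")
  if (nrow(ba) == 0) stop("no heavy atoms in binder")
  mean(apply(cross_dist(ta, ba), 1, min))
}
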