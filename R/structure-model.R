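AA3TO1 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)
AA1TO3 <- structure(names(AA3TO1), names = unname(AA3TO1))
STANDARD_AA <- unname(AA3TO1)

#' Construct a structure object from an atom table
#'
#' The package represents a structure as a flat atom table, one row per
#' atom, with per-residue predicted confidence (plDDT, 0-100 scale)
#' attached to every atom of the residue. This mirrors the convention of
#' AlphaFold2-style predictors, which store plDDT in the B-factor column
#' of their PDB output.
#'
#' @param atoms data.frame with columns `chain` (single character),
#'   `resno` (author residue number, integer), `aa` (one-letter code,
#'   "X" for non-standard residues), `elety` (atom name, e.g. "CA"),
#'   `x`, `y`, `z` (coordinates in Angstrom), `plddt` (0-100), and
#'   optionally `elesy` (element symbol).
#' @return An object of class `bs_structure`: the validated atom table
#'   plus a `pos` column giving the 1-based ordinal of each residue
#'   within its chain (used for positional pairing of designed
#'   sequences, which carry no meaningful author numbering).
#' @export
bs_structure <- function(atoms) {
  need <- c("chain", "resno", "aa", "elety", "x", "y", "z", "plddt")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) {
    stop("atom table is missing columns: ", paste(miss, collapse = ", "))
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite atom coordinates")
  if (anyNA(atoms$plddt) || any(atoms$plddt < 0 | atoms$plddt > 100)) {
    stop("plddt values must lie in [0, 100]")
  }
  bad_aa <- setdiff(unique(atoms$aa), c(STANDARD_AA, "X"))
  if (length(bad_aa)) {
    stop("invalid amino-acid codes: ", paste(bad_aa, collapse = ", "))
  }
  if (is.null(atoms$elesy)) {
    atoms$elesy <- substr(gsub("[0-9]", "", atoms$elety), 1, 1)
  }
  atoms <- atoms[order(match(atoms$chain, unique(atoms$chain))), , drop = FALSE]
  # ordinal residue position within each chain, in file order
  atoms$pos <- stats::ave(atoms$resno, atoms$chain, FUN = function(r) {
    match(r, unique(r))
  })
  for (ch in unique(atoms$chain)) {
    rn <- unique(atoms$resno[atoms$chain == ch])
    if (any(diff(rn) <= 0)) {
      stop("residue numbers in chain ", ch, " are not strictly increasing")
    }
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms), class = "bs_structure")
}

#' @export
print.bs_structure <- function(x, ...) {
  a <- x$atoms
  chains <- unique(a$chain)
  cat("bs_structure:", length(chains), "chain(s),",
      nrow(unique(a[, c("chain", "resno")])), "residues,",
      nrow(a), "atoms\n")
  for (ch in chains) {
    s <- a[a$chain == ch, ]
    cat(sprintf("  chain %s: %d residues, mean plDDT %.1f\n",
                ch, length(unique(s$resno)), mean_plddt(x, ch)))
  }
  invisible(x)
}

#' Read a structure from a PDB file
#'
#' Parses ATOM/HETATM records, reading the B-factor column as per-residue
#' plDDT (the AlphaFold2 convention). Alternate locations are resolved to
#' the highest-occupancy conformer (ties keep the first encountered);
#' hydrogens are retained in the table but excluded from all distance
#' calculations downstream. Non-standard residues are mapped to "X".
#' Residues missing all backbone atoms (N, CA, C) are flagged in the
#' `backbone_report` attribute rather than dropped.
#'
#' B-factor values on a 0-1 scale are rejected: plDDT here is always
#' 0-100 and silent rescaling would shift every loss value by 100x.
#'
#' @param path path to a PDB file.
#' @param format only "pdb" is supported.
#' @return A [bs_structure] with attribute `backbone_report` (character
#'   vector of "chain:resno" for residues lacking N, CA and C).
#' @export
read_structure <- function(path, format = "pdb") {
  format <- match.arg(format, "pdb")
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, verbose = FALSE, multi = FALSE, rm.alt = FALSE),
    error = function(e) stop("failed to parse PDB file ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- pdb$atom
  if (nrow(at) == 0) stop("no atoms in ", path)
  at$chain[is.na(at$chain)] <- " "
  # alternate locations: keep highest occupancy, tie -> first encountered;
  # original file order is preserved
  occ <- ifelse(is.na(at$o), 1, at$o)
  key <- paste(at$chain, at$resno, at$elety)
  ranked <- order(key, -occ, seq_len(nrow(at)))
  at <- at[sort(ranked[!duplicated(key[ranked])]), ]
  b <- ifelse(is.na(at$b), 0, at$b)
  if (max(b) <= 1 && max(b) > 0) {
    stop("B-factor column looks like plDDT on a 0-1 scale; ",
         "rescale to 0-100 before reading (values are never auto-rescaled)")
  }
  atoms <- data.frame(
    chain = at$chain,
    resno = at$resno,
    aa = ifelse(at$resid %in% names(AA3TO1), AA3TO1[at$resid], "X"),
    elety = at$elety,
    x = at$x, y = at$y, z = at$z,
    plddt = b,
    elesy = ifelse(is.na(at$elesy) | at$elesy == "",
                   substr(gsub("[0-9]", "", at$elety), 1, 1), at$elesy),
    stringsAsFactors = FALSE
  )
  st <- bs_structure(atoms)
  a <- st$atoms
  resk <- paste(a$chain, a$resno, sep = ":")
  has_bb <- tapply(a$elety %in% c("N", "CA", "C"), resk, any)
  attr(st, "backbone_report") <- names(has_bb)[!has_bb]
  st
}

#' Write a structure to a PDB file
#'
#' Emits standard ATOM records with 3-decimal coordinates; plDDT is
#' written to the B-factor column so that a write/read round trip
#' preserves it.
#'
#' @param x a [bs_structure].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  a <- x$atoms
  resid3 <- ifelse(a$aa %in% names(AA1TO3), AA1TO3[a$aa], "UNK")
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
    resno = a$resno, chain = a$chain, resid = resid3,
    elety = a$elety, b = a$plddt, o = rep(1, nrow(a)),
    elesy = a$elesy
  )
  invisible(path)
}

#' Pair a receptor and binder chain within one structure
#'
#' @param structure a [bs_structure] containing both chains.
#' @param receptor_chain,binder_chain distinct single-character chain ids.
#' @return Object of class `bs_complex`.
#' @export
complex_pair <- function(structure, receptor_chain, binder_chain) {
  chains <- unique(structure$atoms$chain)
  if (!receptor_chain %in% chains) stop("receptor chain '", receptor_chain, "' not found")
  if (!binder_chain %in% chains) stop("binder chain '", binder_chain, "' not found")
  if (identical(receptor_chain, binder_chain)) {
    stop("receptor and binder chains must be distinct")
  }
  structure(list(structure = structure,
                 receptor_chain = receptor_chain,
                 binder_chain = binder_chain),
            class = "bs_complex")
}

#' @export
print.bs_complex <- function(x, ...) {
  cat("bs_complex: receptor chain", x$receptor_chain,
      "/ binder chain", x$binder_chain, "\n")
  print(x$structure)
  invisible(x)
}

chain_atoms <- function(structure, chain) {
  a <- structure$atoms[structure$atoms$chain == chain, , drop = FALSE]
  if (nrow(a) == 0) stop("chain '", chain, "' is empty or absent")
  a
}

#' Atom tables of the receptor / binder chain of a complex
#'
#' @param cp a [complex_pair].
#' @return data.frame of atom rows for the chain.
#' @export
receptor_atoms <- function(cp) chain_atoms(cp$structure, cp$receptor_chain)

#' @rdname receptor_atoms
#' @export
binder_atoms <- function(cp) chain_atoms(cp$structure, cp$binder_chain)

#' One-letter sequence of a chain
#'
#' @param structure a [bs_structure].
#' @param chain chain id.
#' @return Character scalar, one letter per residue in chain order.
#' @export
chain_sequence <- function(structure, chain) {
  a <- chain_atoms(structure, chain)
  paste(a$aa[!duplicated(a$resno)], collapse = "")
}

#' Effective beta-carbon coordinate of a residue
#'
#' Returns the CB coordinate when present, otherwise falls back to CA
#' (the glycine convention: glycine has no beta carbon, and the fallback
#' is applied identically to native and predicted structures so metric
#' differences cancel).
#'
#' @param residue data.frame of atom rows for a single residue (columns
#'   `elety`, `x`, `y`, `z`).
#' @return Numeric length-3 coordinate vector in Angstrom.
#' @export
effective_cb <- function(residue) {
  i <- match("CB", residue$elety)
  if (is.na(i)) i <- match("CA", residue$elety)
  if (is.na(i)) {
    stop("residue has neither CB nor CA atom",
         if (nrow(residue)) paste0(" (resno ", residue$resno[1], ")") else "")
  }
  as.numeric(residue[i, c("x", "y", "z")])
}

# Matrix of effective-CB coordinates for every residue of a chain,
# one row per residue; rownames are author resno, `pos` attribute gives
# chain ordinals.
effective_cb_coords <- function(structure, chain) {
  a <- chain_atoms(structure, chain)
  resnos <- unique(a$resno)
  m <- t(vapply(resnos, function(rn) {
    effective_cb(a[a$resno == rn, , drop = FALSE])
  }, numeric(3)))
  rownames(m) <- resnos
  attr(m, "pos") <- seq_along(resnos)
  m
}

# CA coordinates per residue of a chain (residues lacking CA are dropped).
ca_coords <- function(structure, chain) {
  a <- chain_atoms(structure, chain)
  ca <- a[a$elety == "CA", , drop = FALSE]
  m <- as.matrix(ca[, c("x", "y", "z")])
  rownames(m) <- ca$resno
  m
}

# Heavy-atom coordinates (hydrogens and deuteriums excluded).
heavy_coords <- function(atoms) {
  elesy <- if (is.null(atoms$elesy)) {
    substr(gsub("[0-9]", "", atoms$elety), 1, 1)
  } else atoms$elesy
  h <- elesy %in% c("H", "D")
  as.matrix(atoms[!h, c("x", "y", "z"), drop = FALSE])
}

#' Mean per-residue plDDT of a chain
#'
#' @param structure a [bs_structure].
#' @param chain chain id.
#' @return Arithmetic mean of the per-residue plDDT values, in [0, 100].
#' @export
mean_plddt <- function(structure, chain) {
  a <- chain_atoms(structure, chain)
  mean(a$plddt[!duplicated(a$resno)])
}
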