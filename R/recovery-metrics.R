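# Sequence-level design metrics. Amino acids are grouped into five
# physicochemical categories; contact recovery asks whether the designed
# binder preserves the *kinds* of interaction each receptor interface
# position sees, rather than the exact residues — a one-position register
# shift can zero sequence identity while leaving the interactions intact.

#' Amino-acid categories
#'
#' Five physicochemical groups partitioning the 20 standard amino acids:
#' Hydrophobic (A, F, I, L, M, P, V, W, Y), Small (G), Polar
#' (N, C, Q, S, T), Positive (R, H, K), Negative (D, E).
#'
#' @format Named list of character vectors.
#' @export
AA_CATEGORIES <- list(
  Hydrophobic = c("A", "F", "I", "L", "M", "P", "V", "W", "Y"),
  Small = "G",
  Polar = c("N", "C", "Q", "S", "T"),
  Positive = c("R", "H", "K"),
  Negative = c("D", "E")
)

#' Category of an amino acid
#'
#' @param code one-letter code(s) of standard amino acids.
#' @return Category name(s): Hydrophobic, Small, Polar, Positive or
#'   Negative.
#' @export
aa_category <- function(code) {
  lut <- rep(names(AA_CATEGORIES), lengths(AA_CATEGORIES))
  names(lut) <- unlist(AA_CATEGORIES)
  out <- lut[code]
  if (anyNA(out)) {
    stop("non-standard amino-acid code(s): ",
         paste(unique(code[is.na(out)]), collapse = ", "))
  }
  unname(out)
}

#' Contact recovery of a designed binder
#'
#' For each receptor residue in the native interface, the set of unique
#' amino-acid categories of its contacting binder residues is annotated
#' for the native and the designed complex; repeat contacts within a
#' category are not counted (a receptor position contacting A, F and R
#' natively is annotated {Hydrophobic, Positive}). The recovery is the
#' fraction of native category annotations that the design preserves at
#' the same receptor position, summed over positions — a recall: extra
#' design categories do not penalise it.
#'
#' @param native_interface,design_interface [contact_pairs] results for
#'   the native and designed complexes, against the same receptor chain.
#' @param native_binder_seq,design_seq binder sequences (one-letter
#'   strings), indexed by chain position.
#' @return List of class `recovery_result`: `fraction` in [0, 1],
#'   `recovered` and `total` annotation counts, and `per_position` (list
#'   per receptor residue: `native` and `design` category sets).
#' @export
contact_recovery <- function(native_interface, design_interface,
                             native_binder_seq, design_seq) {
  nat <- native_interface$pairs
  if (nrow(nat) == 0) stop("native interface is empty")
  des <- design_interface$pairs
  nat_chr <- strsplit(native_binder_seq, "")[[1]]
  des_chr <- strsplit(design_seq, "")[[1]]

  cats_at <- function(pairs, rec_res, seq_chr) {
    bpos <- pairs$binder_pos[pairs$receptor_residue == rec_res]
    bpos <- bpos[bpos <= length(seq_chr)]
    aa <- setdiff(unique(seq_chr[bpos]), "X")
    if (length(aa) == 0) character(0) else unique(aa_category(aa))
  }

  rec_res <- sort(unique(nat$receptor_residue))
  per_position <- lapply(rec_res, function(rr) {
    list(native = cats_at(nat, rr, nat_chr),
         design = cats_at(des, rr, des_chr))
  })
  names(per_position) <- rec_res
  total <- sum(vapply(per_position, function(p) length(p$native), 0L))
  recovered <- sum(vapply(per_position, function(p) {
    length(intersect(p$native, p$design))
  }, 0L))
  if (total == 0) stop("native interface carries no category annotations")
  structure(list(fraction = recovered / total, recovered = recovered,
                 total = total, per_position = per_position),
            class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf("contact recovery: %.3f (%d / %d category annotations over %d receptor positions)\n",
              x$fraction, x$recovered, x$total, length(x$per_position)))
  invisible(x)
}

#' Interface sequence recovery
#'
#' Identity between native and designed binder at the native interface
#' positions, treating the binder as a linear sequence 1..N: the number
#' of identical residue-position combinations divided by the number of
#' interface positions.
#'
#' @param native_seq,design_seq binder sequences (one-letter strings).
#' @param interface_positions native binder interface positions (1-based
#'   chain ordinals).
#' @return Fraction in [0, 1].
#' @export
interface_sequence_recovery <- function(native_seq, design_seq,
                                        interface_positions) {
  if (length(interface_positions) == 0) stop("no interface positions given")
  nat <- strsplit(native_seq, "")[[1]]
  des <- strsplit(design_seq, "")[[1]]
  if (max(interface_positions) > length(des) ||
      max(interface_positions) > length(nat)) {
    stop("interface position beyond sequence length")
  }
  mean(nat[interface_positions] == des[interface_positions])
}

#' Mutation scan over binder contact positions
#'
#' Generates, for each k in 1..L (L = number of contact positions),
#' `per_count` sequences differing from the native binder at exactly k
#' randomly chosen contact positions, each substituted by a random
#' non-identical standard amino acid — the probe used to test whether a
#' structure evaluator's confidence degrades as true interface residues
#' are corrupted. Total output is `per_count * L` sequences.
#'
#' @param native_seq native binder sequence (one-letter string).
#' @param contact_positions positions (1-based) in contact with the
#'   receptor.
#' @param per_count sequences per mutation count k (default 10).
#' @param rng_seed integer seed; identical seeds give identical output.
#' @return data.frame with columns `n_mutations`, `replicate`,
#'   `sequence`.
#' @export
mutation_scan <- function(native_seq, contact_positions, per_count = 10,
                          rng_seed = 1) {
  stopifnot(per_count >= 1)
  nat <- strsplit(native_seq, "")[[1]]
  if (length(contact_positions) &&
      (min(contact_positions) < 1 || max(contact_positions) > length(nat))) {
    stop("contact positions out of range 1..", length(nat))
  }
  L <- length(contact_positions)
  if (L == 0) {
    return(data.frame(n_mutations = integer(0), replicate = integer(0),
                      sequence = character(0)))
  }
  out <- with_seed(rng_seed, {
    rows <- vector("list", per_count * L)
    i <- 0
    for (k in seq_len(L)) {
      for (r in seq_len(per_count)) {
        s <- nat
        pos <- sample_exact(contact_positions, k)
        for (p in pos) {
          s[p] <- sample_exact(setdiff(STANDARD_AA, nat[p]), 1)
        }
        i <- i + 1
        rows[[i]] <- data.frame(n_mutations = k, replicate = r,
                                sequence = paste(s, collapse = ""))
      }
    }
    do.call(rbind, rows)
  })
  rownames(out) <- NULL
  out
}

# sample() treats a length-1 numeric vector as 1:n; avoid that trap.
sample_exact <- function(x, size) {
  if (length(x) == 1) return(rep(x, size))
  sample(x, size)
}

# Evaluate `expr` under a fixed RNG state, restoring the caller's state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
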