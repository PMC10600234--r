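# Seed cropping: contiguous 10-50 residue backbone windows from scaffold
# hits, ranked by the number of beta-carbon contacts they make to the
# chosen receptor target interface. The best crop becomes the starting
# backbone for inverse folding.

#' Best contiguous crop of a scaffold against a target interface
#'
#' Scans every contiguous window of the requested length along the
#' scaffold and returns the one with the most beta-carbon contacts
#' (effective-CB distance <= cutoff) to the listed receptor target
#' residues. Ties go to the smallest start. A scaffold shorter than the
#' requested length is returned whole (as many residues as possible).
#'
#' @param scaffold atom table of the scaffold chain (or a
#'   [bs_structure] with one chain).
#' @param receptor atom table of the receptor chain.
#' @param target_interface receptor residue numbers defining the target
#'   interface.
#' @param length desired crop length L, conventionally in
#'   {10, 20, 30, 40, 50}.
#' @param cutoff contact cutoff in Angstrom (default 8).
#' @param source_id identifier carried into the result.
#' @return Object of class `seed_crop`: `source_id`, `start` (1-based
#'   scaffold ordinal, inclusive), `length`, `contact_count`,
#'   `contact_density` (= contact_count / length), `zero_contact` flag,
#'   and `positions` (the scaffold ordinals of the crop).
#' @export
best_crop <- function(scaffold, receptor, target_interface, length,
                      cutoff = 8.0, source_id = NA_character_) {
  stopifnot(length >= 1)
  sc <- scaffold_cb(scaffold)
  rc <- receptor_target_cb(receptor, target_interface)
  n <- nrow(sc)
  # contacts made by each scaffold residue to the target interface
  per_res <- if (nrow(rc) == 0) integer(n) else {
    colSums(cross_dist(rc, sc) <= cutoff)
  }
  L <- min(length, n)
  # sliding-window sums over all n - L + 1 windows
  cs <- c(0, cumsum(per_res))
  win <- cs[(L + 1):(n + 1)] - cs[1:(n - L + 1)]
  start <- which.max(win)          # which.max takes the first maximum
  crop(source_id, start, L, win[start])
}

crop <- function(source_id, start, length, contact_count) {
  start <- unname(as.integer(start))
  contact_count <- unname(contact_count)
  structure(list(
    source_id = source_id, start = start, length = length,
    contact_count = as.integer(contact_count),
    contact_density = contact_count / length,
    zero_contact = contact_count == 0,
    positions = seq(start, start + length - 1)
  ), class = "seed_crop")
}

#' @export
print.seed_crop <- function(x, ...) {
  cat(sprintf("seed_crop %s: residues %d-%d (L = %d), %d contacts (density %.2f)%s\n",
              if (is.na(x$source_id)) "" else x$source_id,
              x$start, x$start + x$length - 1, x$length,
              x$contact_count, x$contact_density,
              if (x$zero_contact) " [zero-contact]" else ""))
  invisible(x)
}

scaffold_cb <- function(scaffold) {
  if (inherits(scaffold, "bs_structure")) {
    ch <- unique(scaffold$atoms$chain)
    if (length(ch) != 1) stop("scaffold structure must have exactly one chain")
    return(effective_cb_coords(scaffold, ch))
  }
  if (nrow(scaffold) == 0) stop("scaffold is empty")
  resnos <- unique(scaffold$resno)
  m <- t(vapply(resnos, function(rn) {
    effective_cb(scaffold[scaffold$resno == rn, , drop = FALSE])
  }, numeric(3)))
  rownames(m) <- resnos
  m
}

receptor_target_cb <- function(receptor, target_interface) {
  tat <- receptor[receptor$resno %in% target_interface, , drop = FALSE]
  if (nrow(tat) == 0) {
    return(matrix(numeric(0), 0, 3))
  }
  scaffold_cb(tat)
}

#' Rank crops across scaffold hits and lengths
#'
#' Computes the [best_crop] of every hit at every requested length and
#' orders them by contact count (descending), breaking ties by contact
#' density then by hit id.
#'
#' @param hits named list of scaffold atom tables (names are hit ids).
#' @param receptor atom table of the receptor chain.
#' @param target_interface receptor residue numbers of the target
#'   interface.
#' @param lengths crop lengths to evaluate (default 10, 20, 30, 40, 50).
#' @param cutoff contact cutoff in Angstrom.
#' @return List of `seed_crop` objects, best first.
#' @export
rank_crops <- function(hits, receptor, target_interface,
                       lengths = c(10, 20, 30, 40, 50), cutoff = 8.0) {
  if (length(hits) == 0) stop("no scaffold hits given")
  ids <- names(hits)
  if (is.null(ids)) ids <- as.character(seq_along(hits))
  crops <- list()
  for (i in seq_along(hits)) {
    for (L in lengths) {
      crops[[length(crops) + 1]] <-
        best_crop(hits[[i]], receptor, target_interface, L, cutoff,
                  source_id = ids[i])
    }
  }
  ord <- order(-vapply(crops, `[[`, 0, "contact_count"),
               -vapply(crops, `[[`, 0, "contact_density"),
               vapply(crops, `[[`, "", "source_id"))
  crops[ord]
}

#' Read a Foldseek-style tab-separated hit table
#'
#' Default Foldseek tabular output: query, target, fident, alnlen,
#' mismatch, gapopen, qstart, qend, tstart, tend, evalue, bits. Headerless
#' files are given these names; files with a header keep their own.
#'
#' @param path path to the TSV file.
#' @return data.frame of hits.
#' @export
read_foldseek_hits <- function(path) {
  if (!file.exists(path)) stop("hit table not found: ", path)
  first <- readLines(path, n = 1)
  has_header <- grepl("query", first, ignore.case = TRUE)
  cols <- c("query", "target", "fident", "alnlen", "mismatch", "gapopen",
            "qstart", "qend", "tstart", "tend", "evalue", "bits")
  df <- utils::read.delim(path, header = has_header,
                          stringsAsFactors = FALSE)
  if (!has_header && ncol(df) <= length(cols)) {
    names(df) <- cols[seq_len(ncol(df))]
  }
  df
}

#' Assemble the inverse-folding design input
#'
#' Concatenates backbone blocks in the order receptor, mask, binder
#' seed. Placing the binder first biases sequence generators toward a
#' methionine at position 1 (the most common protein start), so the
#' receptor always leads and a masked spacer of `mask_length` positions
#' separates the chains; masked positions carry a flag, not coordinates.
#'
#' @param receptor,seed atom tables carrying N, CA and C for every
#'   residue.
#' @param mask_length number of masked spacer positions (default 10).
#' @return Object of class `design_input`: `blocks` (data.frame with
#'   `block` in {receptor, mask, binder_seed}, `position`, `masked`, and
#'   backbone coordinates `n_xyz`/`ca_xyz`/`c_xyz` as NA for masked
#'   rows), and `mask_length`.
#' @export
build_design_input <- function(receptor, seed, mask_length = 10) {
  stopifnot(mask_length >= 0)
  rec <- backbone_block(receptor, "receptor")
  bnd <- backbone_block(seed, "binder_seed")
  msk <- if (mask_length > 0) {
    data.frame(block = "mask", resno = NA_integer_, masked = TRUE,
               n_x = NA_real_, n_y = NA_real_, n_z = NA_real_,
               ca_x = NA_real_, ca_y = NA_real_, ca_z = NA_real_,
               c_x = NA_real_, c_y = NA_real_, c_z = NA_real_)[rep(1, mask_length), ]
  } else NULL
  blocks <- rbind(rec, msk, bnd)
  blocks$position <- seq_len(nrow(blocks))
  rownames(blocks) <- NULL
  structure(list(blocks = blocks, mask_length = mask_length),
            class = "design_input")
}

backbone_block <- function(atoms, label) {
  resnos <- unique(atoms$resno)
  rows <- lapply(resnos, function(rn) {
    r <- atoms[atoms$resno == rn, , drop = FALSE]
    co <- lapply(c("N", "CA", "C"), function(el) {
      i <- match(el, r$elety)
      if (is.na(i)) {
        stop("residue ", rn, " in ", label, " block is missing backbone atom ", el)
      }
      as.numeric(r[i, c("x", "y", "z")])
    })
    data.frame(block = label, resno = rn, masked = FALSE,
               n_x = co[[1]][1], n_y = co[[1]][2], n_z = co[[1]][3],
               ca_x = co[[2]][1], ca_y = co[[2]][2], ca_z = co[[2]][3],
               c_x = co[[3]][1], c_y = co[[3]][2], c_z = co[[3]][3])
  })
  do.call(rbind, rows)
}

#' Serialize / deserialize a design input as JSON
#'
#' @param x a `design_input`.
#' @param path output (or input) JSON path.
#' @return `write_design_input` returns `path` invisibly;
#'   `read_design_input` returns the `design_input`.
#' @export
write_design_input <- function(x, path) {
  jsonlite::write_json(list(mask_length = x$mask_length, blocks = x$blocks),
                       path, digits = NA, na = "null", auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_design_input
#' @export
read_design_input <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  blocks <- as.data.frame(j$blocks)
  blocks$masked <- as.logical(blocks$masked)
  structure(list(blocks = blocks, mask_length = j$mask_length),
            class = "design_input")
}
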