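# Campaign-level analytics over per-design result tables.

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the unique score values as thresholds (one curve vertex per
#' unique score, so tied scores move the curve diagonally in one step)
#' and integrates the area by the trapezoid rule — numerically identical
#' to the Mann-Whitney pairwise formulation with half credit for ties.
#' For loss-based selection lower scores rank positive: pass
#' `higher_is_positive = FALSE`.
#'
#' @param scores numeric scores, one per observation.
#' @param labels binary labels (1/TRUE = positive).
#' @param higher_is_positive if FALSE, lower scores indicate positives.
#' @return Object of class `roc_result`: `points` (data.frame `fpr`,
#'   `tpr`, `threshold`, from (0,0) to (1,1)) and `auc`.
#' @export
roc_auc <- function(scores, labels, higher_is_positive = TRUE) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present to form a ROC curve")
  }
  s <- if (higher_is_positive) scores else -scores
  thr <- sort(unique(s), decreasing = TRUE)
  tp <- vapply(thr, function(t) sum(labels & s >= t), 0)
  fp <- vapply(thr, function(t) sum(!labels & s >= t), 0)
  points <- data.frame(
    fpr = c(0, fp / n_neg),
    tpr = c(0, tp / n_pos),
    threshold = c(Inf, if (higher_is_positive) thr else -thr)
  )
  auc <- sum(diff(points$fpr) * (points$tpr[-1] + points$tpr[-nrow(points)]) / 2)
  structure(list(points = points, auc = auc), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f over %d thresholds\n",
              x$auc, nrow(x$points) - 1))
  invisible(x)
}

#' Success rate versus number of designs per target
#'
#' For each n in 1..max_n, the fraction of targets whose first n designs
#' (by generation order) contain at least one success. Targets with fewer
#' than n designs contribute their full design set. The curve is
#' non-decreasing in n by construction.
#'
#' @param records data.frame with columns `target_id`, `design_order`,
#'   `success` (logical).
#' @param max_n largest number of designs considered (>= 1).
#' @return data.frame with columns `n` and `success_rate`.
#' @export
success_curve <- function(records, max_n) {
  if (max_n < 1) stop("max_n must be >= 1")
  by_target <- split(records, records$target_id)
  first_success <- vapply(by_target, function(d) {
    d <- d[order(d$design_order), ]
    i <- which(d$success)[1]
    if (is.na(i)) Inf else i
  }, 0)
  n <- seq_len(max_n)
  rate <- vapply(n, function(k) mean(first_success <= k), 0)
  data.frame(n = n, success_rate = rate)
}

#' Specificity of designed binders: on-target versus off-target plDDT
#'
#' Designed binders predicted in complex with their intended receptor
#' should score systematically higher plDDT than the same binders forced
#' onto unrelated receptors. Summarised by the two medians and the AUC
#' for discriminating on-target complexes by higher plDDT.
#'
#' @param on_target,off_target numeric plDDT vectors (non-empty).
#' @return List of class `specificity_summary`: `on_target_median`,
#'   `off_target_median`, `median_ratio`, `auc`.
#' @export
specificity_summary <- function(on_target, off_target) {
  if (length(on_target) == 0 || length(off_target) == 0) {
    stop("both plDDT lists must be non-empty")
  }
  roc <- roc_auc(c(on_target, off_target),
                 c(rep(TRUE, length(on_target)), rep(FALSE, length(off_target))),
                 higher_is_positive = TRUE)
  structure(list(
    on_target_median = stats::median(on_target),
    off_target_median = stats::median(off_target),
    median_ratio = stats::median(on_target) / stats::median(off_target),
    auc = roc$auc
  ), class = "specificity_summary")
}

#' @export
print.specificity_summary <- function(x, ...) {
  cat(sprintf("specificity: median plDDT on-target %.1f vs off-target %.1f (ratio %.2f), AUC = %.3f\n",
              x$on_target_median, x$off_target_median, x$median_ratio, x$auc))
  invisible(x)
}

#' Success rate as a function of contact density
#'
#' Sorts designs by seed contact density, splits them into
#' `n_partitions` near-equal contiguous blocks (any remainder spread one
#' record at a time over the leading blocks), and reports the mean
#' density and success fraction per block together with the Spearman
#' rank correlation between the two across blocks.
#'
#' @param records data.frame with columns `contact_density` and
#'   `success` (logical).
#' @param n_partitions number of blocks (default 30).
#' @return List of class `density_profile`: `partitions` (data.frame
#'   `partition`, `n`, `mean_density`, `success_rate`) and `rho`.
#' @export
density_success_profile <- function(records, n_partitions = 30) {
  N <- nrow(records)
  if (N < n_partitions) {
    stop("need at least ", n_partitions, " records; got ", N)
  }
  rec <- records[order(records$contact_density), ]
  base <- N %/% n_partitions
  sizes <- rep(base, n_partitions)
  extra <- N %% n_partitions
  if (extra > 0) sizes[seq_len(extra)] <- base + 1
  idx <- rep(seq_len(n_partitions), times = sizes)
  parts <- data.frame(
    partition = seq_len(n_partitions),
    n = sizes,
    mean_density = as.numeric(tapply(rec$contact_density, idx, mean)),
    success_rate = as.numeric(tapply(as.numeric(rec$success), idx, mean))
  )
  rho <- spearman_rho(parts$mean_density, parts$success_rate)
  structure(list(partitions = parts, rho = rho), class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("density profile: %d partitions, Spearman rho = %.3f\n",
              nrow(x$partitions), x$rho))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties receive average ranks).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return Correlation in [-1, 1].
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    stop("rank correlation undefined for a constant vector")
  }
  stats::cor(x, y, method = "spearman")
}

#' Secondary-structure composition of an interface
#'
#' Counts the Helix/Sheet/Loop states of the interface residues and
#' normalises to fractions summing to one. Labels typically come from a
#' DSSP run reduced with [reduce_dssp].
#'
#' @param ss_labels named character vector of per-residue labels in
#'   {Helix, Sheet, Loop}; names are residue numbers.
#' @param interface_residues residue numbers of the interface
#'   (non-empty, all labelled).
#' @return Named numeric vector c(Helix=, Sheet=, Loop=) summing to 1.
#' @export
interface_ss_fractions <- function(ss_labels, interface_residues) {
  if (length(interface_residues) == 0) stop("interface is empty")
  lab <- ss_labels[as.character(interface_residues)]
  if (anyNA(lab)) {
    stop("unlabelled interface residue(s): ",
         paste(interface_residues[is.na(lab)], collapse = ", "))
  }
  bad <- setdiff(unique(lab), c("Helix", "Sheet", "Loop"))
  if (length(bad)) stop("unknown secondary-structure label(s): ",
                        paste(bad, collapse = ", "))
  counts <- c(Helix = sum(lab == "Helix"), Sheet = sum(lab == "Sheet"),
              Loop = sum(lab == "Loop"))
  counts / sum(counts)
}

#' Reduce 8-state DSSP codes to Helix / Sheet / Loop
#'
#' H, G and I map to Helix; E and B to Sheet; everything else to Loop.
#'
#' @param codes character vector of one-letter DSSP states.
#' @return Character vector of three-state labels, names preserved.
#' @export
reduce_dssp <- function(codes) {
  out <- ifelse(codes %in% c("H", "G", "I"), "Helix",
                ifelse(codes %in% c("E", "B"), "Sheet", "Loop"))
  names(out) <- names(codes)
  out
}

#' Read / write per-design result tables
#'
#' Comma- or tab-separated tables with one row per evaluated design.
#' Expected columns (extra ones pass through): `target_id`, `design_id`,
#' `design_order`, `length`, `loss`, `binder_plddt`, `interface_rmsd`,
#' `contact_recovery`, `seq_recovery`, `success`.
#'
#' @param path file path; delimiter inferred from the extension
#'   (".tsv"/".txt" = tab, otherwise comma).
#' @param records data.frame to write.
#' @return `read_design_table` returns a data.frame with `success`
#'   coerced to logical; `write_design_table` returns `path` invisibly.
#' @export
read_design_table <- function(path) {
  if (!file.exists(path)) stop("design table not found: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if ("success" %in% names(df)) df$success <- as.logical(df$success)
  df
}

#' @rdname read_design_table
#' @export
write_design_table <- function(records, path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(records, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
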