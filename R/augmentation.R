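# Mixup augmentation restricted to the top fraction of training lines.
#
# A synthetic line is a convex combination of two parents: markers
# x = lam*x_i + (1-lam)*x_j and phenotype y = lam*y_i + (1-lam)*y_j. The
# augmented training set is the top-fraction parents plus their synthetic
# offspring; the model never sees the rest of the training lines.

#' Mixup configuration
#'
#' @param lam mixing coefficient in `[0, 1]`; 0.5 averages the parents.
#' @param top_fraction fraction of training lines (by phenotype) used as
#'   parents, in `(0, 1]`.
#' @param pair_scheme `"all_pairs"` (one synthetic line per unordered pair
#'   of parents, deterministic) or `"random_pairs"` (`n_synthetic` draws of
#'   distinct-parent pairs, seeded).
#' @param n_synthetic number of synthetic lines under `"random_pairs"`, or
#'   `"auto"` for as many as `"all_pairs"` would make.
#' @param seed integer seed for `"random_pairs"`.
#' @param direction `"high_is_top"` (yield-type traits) or `"low_is_top"`
#'   (disease-type traits).
#' @return A `mixup_config` list.
#' @export
mixup_config <- function(lam = 0.5, top_fraction = 0.2,
                         pair_scheme = c("all_pairs", "random_pairs"),
                         n_synthetic = "auto", seed = NULL,
                         direction = c("high_is_top", "low_is_top")) {
  if (!is.numeric(lam) || lam < 0 || lam > 1)
    stop("lam must be in [0, 1]")
  if (!is.numeric(top_fraction) || top_fraction <= 0 || top_fraction > 1)
    stop("top_fraction must be in (0, 1]")
  if (!identical(n_synthetic, "auto") &&
      (!is.numeric(n_synthetic) || n_synthetic < 1))
    stop("n_synthetic must be a positive integer or \"auto\"")
  structure(list(lam = lam, top_fraction = top_fraction,
                 pair_scheme = match.arg(pair_scheme),
                 n_synthetic = n_synthetic, seed = seed,
                 direction = match.arg(direction)),
            class = "mixup_config")
}

#' Mix two lines
#'
#' @param xi,xj marker rows of equal length.
#' @param yi,yj parent phenotypes.
#' @param lam mixing coefficient in `[0, 1]`.
#' @return `list(x =, y =)` with `x = lam*xi + (1-lam)*xj` and
#'   `y = lam*yi + (1-lam)*yj`.
#' @export
mixup_pair <- function(xi, yi, xj, yj, lam) {
  if (length(xi) != length(xj)) stop("marker rows differ in length")
  if (lam < 0 || lam > 1) stop("lam must be in [0, 1]")
  list(x = lam * xi + (1 - lam) * xj, y = lam * yi + (1 - lam) * yj)
}

#' Select the top fraction of lines by phenotype
#'
#' Returns the `ceiling(fraction * n)` line ids with the largest
#' (`"high_is_top"`) or smallest (`"low_is_top"`) values; ties are broken
#' by ascending line id for determinism.
#'
#' @param t trait vector.
#' @param fraction fraction in `(0, 1]`.
#' @param direction which tail is "top".
#' @return Character vector of line ids.
#' @export
select_top_fraction <- function(t, fraction,
                                direction = c("high_is_top", "low_is_top")) {
  direction <- match.arg(direction)
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (length(t) == 0) stop("empty trait vector")
  k <- ceiling(fraction * length(t))
  v <- if (direction == "high_is_top") -as.numeric(t) else as.numeric(t)
  ids <- names(t)[order(v, names(t))]
  ids[seq_len(k)]
}

#' Build the augmented training set
#'
#' Selects the top fraction of the training lines, generates synthetic
#' lines by mixup, and returns the parents plus synthetic lines with
#' per-row provenance. Inputs are never modified.
#'
#' @param m training marker matrix (complete).
#' @param t training trait vector, aligned with `m`.
#' @param cfg a [mixup_config()].
#' @return An `augmented_set` list: `markers` (real top rows then synthetic
#'   rows), `phenotypes` (aligned trait vector), `provenance` (data.frame
#'   with `id`, `type`, `parent_i`, `parent_j`).
#' @export
build_augmented_set <- function(m, t, cfg = mixup_config()) {
  stopifnot(inherits(cfg, "mixup_config"))
  top <- select_top_fraction(t, cfg$top_fraction, cfg$direction)
  if (length(top) < 2)
    stop("top fraction yields fewer than 2 lines; cannot form pairs")
  if (cfg$pair_scheme == "all_pairs") {
    pr <- utils::combn(top, 2)
    pi <- pr[1, ]
    pj <- pr[2, ]
  } else {
    n_syn <- if (identical(cfg$n_synthetic, "auto"))
      choose(length(top), 2) else as.integer(cfg$n_synthetic)
    if (!is.null(cfg$seed)) set.seed(cfg$seed)
    pi <- character(n_syn)
    pj <- character(n_syn)
    for (s in seq_len(n_syn)) {
      pair <- sample(top, 2, replace = FALSE)
      pi[s] <- pair[1]
      pj[s] <- pair[2]
    }
  }
  syn_x <- cfg$lam * m[pi, , drop = FALSE] +
    (1 - cfg$lam) * m[pj, , drop = FALSE]
  syn_y <- cfg$lam * as.numeric(t[pi]) + (1 - cfg$lam) * as.numeric(t[pj])
  syn_ids <- make.unique(paste0("SYN_", pi, "_", pj), sep = "~")
  rownames(syn_x) <- syn_ids

  markers <- rbind(m[top, , drop = FALSE], syn_x)
  phen <- trait_vector(c(as.numeric(t[top]), syn_y), c(top, syn_ids),
                       .trait_name(t))
  prov <- data.frame(
    id = c(top, syn_ids),
    type = c(rep("real", length(top)), rep("synthetic", length(syn_ids))),
    parent_i = c(rep(NA_character_, length(top)), pi),
    parent_j = c(rep(NA_character_, length(top)), pj),
    stringsAsFactors = FALSE)
  structure(list(markers = markers, phenotypes = phen, provenance = prov),
            class = "augmented_set")
}

#' Export an augmented set in the marker/phenotype delimited formats
#'
#' Writes the marker matrix, the phenotype table, and a provenance table.
#'
#' @param aug `augmented_set`.
#' @param marker_path,phenotype_path,provenance_path output paths.
#' @param dialect `"csv"` or `"tsv"`.
#' @export
write_augmented_set <- function(aug, marker_path, phenotype_path,
                                provenance_path,
                                dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  write_markers(aug$markers, marker_path, dialect)
  write_phenotypes(aug$phenotypes, phenotype_path, dialect)
  utils::write.table(aug$provenance, provenance_path,
                     sep = .sep_for(dialect), row.names = FALSE,
                     quote = FALSE)
  invisible(NULL)
}
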