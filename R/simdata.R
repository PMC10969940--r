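# Synthetic genotypes and phenotypes: unlinked biallelic dosage markers
# with bounded MAF, and an additive polygenic trait with an exactly
# controlled realized heritability over a positive baseline.

#' Simulation configuration
#'
#' @param n_lines number of lines (>= 2).
#' @param n_markers number of markers (>= 1).
#' @param maf_low,maf_high allele-frequency bounds, `0 < maf_low <=
#'   maf_high <= 0.5`.
#' @param n_qtl number of causal markers (<= n_markers).
#' @param h2 heritability in `[0, 1]`; enforced on the realized variances.
#' @param seed integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_lines = 200, n_markers = 1000, maf_low = 0.05,
                       maf_high = 0.5, n_qtl = 100, h2 = 0.5, seed = 1) {
  if (!is.numeric(n_lines) || n_lines < 2) stop("invalid n_lines")
  if (!is.numeric(n_markers) || n_markers < 1) stop("invalid n_markers")
  if (!is.numeric(maf_low) || maf_low <= 0 || maf_low > maf_high ||
      maf_high > 0.5)
    stop("invalid maf_low/maf_high: need 0 < maf_low <= maf_high <= 0.5")
  if (!is.numeric(n_qtl) || n_qtl < 1 || n_qtl > n_markers)
    stop("invalid n_qtl")
  if (!is.numeric(h2) || h2 < 0 || h2 > 1) stop("invalid h2: must be in [0, 1]")
  structure(list(n_lines = as.integer(n_lines),
                 n_markers = as.integer(n_markers),
                 maf_low = maf_low, maf_high = maf_high,
                 n_qtl = as.integer(n_qtl), h2 = h2,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate biallelic dosage genotypes
#'
#' Per marker an allele frequency is drawn uniformly from
#' `[maf_low, maf_high]`; dosages are independent Binomial(2, p) draws per
#' line (no linkage disequilibrium).
#'
#' @param cfg a [sim_config()].
#' @return Marker matrix with entries in \{0, 1, 2\}.
#' @export
sim_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  p <- stats::runif(cfg$n_markers, cfg$maf_low, cfg$maf_high)
  m <- vapply(p, function(pk) stats::rbinom(cfg$n_lines, 2, pk),
              numeric(cfg$n_lines))
  rownames(m) <- sprintf("L%04d", seq_len(cfg$n_lines))
  colnames(m) <- sprintf("M%05d", seq_len(cfg$n_markers))
  m
}

#' Simulate an additive polygenic phenotype
#'
#' Draws `n_qtl` causal markers with standard normal effects, forms the
#' genetic value from centered dosages, and rescales the genetic and noise
#' components so the realized variances are exactly `h2` and `1 - h2`
#' (total phenotypic variance 1). Phenotypes sit on a baseline of 100 so
#' the NRMSE normalizer is positive.
#'
#' @param m marker matrix from [sim_genotypes()].
#' @param cfg the same [sim_config()].
#' @return `list(trait =, truth =)`: a [trait_vector()] and a truth record
#'   with `qtl_ids`, `beta` (effects on the rescaled genetic values),
#'   `u` (genetic values as added to y), `h2_realized`.
#' @export
sim_phenotypes <- function(m, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  qtl <- sort(sample(ncol(m), cfg$n_qtl))
  beta <- stats::rnorm(cfg$n_qtl)
  w <- sweep(m[, qtl, drop = FALSE], 2, colMeans(m[, qtl, drop = FALSE]))
  u <- drop(w %*% beta)
  e <- stats::rnorm(nrow(m))
  e <- e - mean(e)

  if (cfg$h2 > 0 && stats::var(u) < .Machine$double.eps)
    stop("degenerate simulation: zero genetic variance with h2 > 0")
  su <- if (cfg$h2 == 0) 0 else sqrt(cfg$h2 / stats::var(u))
  se <- if (cfg$h2 == 1) 0 else sqrt((1 - cfg$h2) / stats::var(e))
  u <- u * su
  e <- e * se
  y <- 100 + u + e

  h2_real <- if (cfg$h2 %in% c(0, 1)) cfg$h2 else
    stats::var(u) / (stats::var(u) + stats::var(e))
  list(trait = trait_vector(y, rownames(m), "sim_trait"),
       truth = list(qtl_ids = colnames(m)[qtl], beta = beta * su, u = u,
                    h2_realized = h2_real))
}
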