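# GBLUP: y_i = mu + g_i + e_i with g ~ N(0, sigma_g^2 G), e ~ N(0,
# sigma_e^2 I). Variance components by REML after a single
# eigendecomposition of the training block of G; genetic values of
# unphenotyped lines by projection through G.

.jitter <- function(g) 1e-8 * mean(diag(g))

.new_gblup_fit <- function(mu, sigma_g2, sigma_e2, g_hat, train_ids,
                           loglik = NA_real_) {
  stopifnot(sigma_g2 >= 0, sigma_e2 > 0)
  structure(list(mu = mu, sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
                 h2 = sigma_g2 / (sigma_g2 + sigma_e2),
                 g_hat = stats::setNames(as.numeric(g_hat), train_ids),
                 train_ids = train_ids, loglik = loglik),
            class = "gblup_fit")
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat("GBLUP fit:", length(x$train_ids), "training lines\n")
  cat(sprintf("  mu = %.4f  sigma_g2 = %.4f  sigma_e2 = %.4f  h2 = %.3f\n",
              x$mu, x$sigma_g2, x$sigma_e2, x$h2))
  invisible(x)
}

# Negative restricted log-likelihood profiled over mu and sigma_e2, as a
# function of log(lambda) with lambda = sigma_g2 / sigma_e2, in the
# eigenbasis of G (d = eigenvalues, z = U'y, x = U'1).
.reml_negll <- function(loglam, d, z, x) {
  lam <- exp(loglam)
  v <- lam * d + 1
  w <- 1 / v
  xwx <- sum(w * x * x)
  mu <- sum(w * x * z) / xwx
  r <- z - mu * x
  n <- length(z)
  s2e <- sum(w * r * r) / (n - 1)
  0.5 * ((n - 1) * log(s2e) + sum(log(v)) + log(xwx) + (n - 1))
}

#' Fit GBLUP by REML
#'
#' Eigendecomposes the training block of G once, then maximizes the
#' restricted likelihood over the variance ratio lambda = sigma_g2 /
#' sigma_e2 on a 100-point log grid over `[1e-5, 1e5]` refined by bounded
#' scalar search. The intercept comes from generalized least squares and
#' the genetic values from `g_hat = sigma_g2 G V^{-1} (y - mu)`.
#'
#' @param y trait vector; its ids must be a subset of the GRM's ids.
#' @param g GRM covering at least the phenotyped lines.
#' @return A `gblup_fit`: `mu`, `sigma_g2`, `sigma_e2`, `h2`, `g_hat`,
#'   `train_ids`, `loglik` (restricted log-likelihood at the optimum).
#' @export
fit_reml <- function(y, g) {
  ids <- names(y)
  if (is.null(ids)) stop("trait vector must carry line ids as names")
  if (!all(ids %in% rownames(g)))
    stop("trait ids missing from GRM: ",
         paste(setdiff(ids, rownames(g)), collapse = ", "))
  n <- length(y)
  if (n < 3) stop("need at least 3 phenotyped lines")
  if (!all(is.finite(y))) stop("non-finite phenotype values")
  if (stats::sd(y) < .Machine$double.eps)
    stop("phenotype has zero variance")

  gt <- grm_submatrix(g, ids, ids)
  eg <- eigen(gt, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  u <- eg$vectors
  z <- drop(crossprod(u, as.numeric(y)))
  x <- drop(crossprod(u, rep(1, n)))

  grid <- seq(log(1e-5), log(1e5), length.out = 100)
  vals <- vapply(grid, .reml_negll, numeric(1), d = d, z = z, x = x)
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- stats::optimize(.reml_negll, c(lo, hi), d = d, z = z, x = x,
                         tol = 1e-10)
  loglam <- if (opt$objective <= vals[i]) opt$minimum else grid[i]

  lam <- exp(loglam)
  v <- lam * d + 1
  w <- 1 / v
  xwx <- sum(w * x * x)
  mu <- sum(w * x * z) / xwx
  r <- z - mu * x
  s2e <- sum(w * r * r) / (n - 1)
  s2g <- lam * s2e
  g_hat <- drop(u %*% ((lam * d / v) * r))
  .new_gblup_fit(mu, s2g, s2e, g_hat, ids,
                 loglik = -.reml_negll(loglam, d, z, x))
}

#' BLUP at a fixed variance ratio
#'
#' Solves the mixed-model equations at a known ratio = sigma_e2 / sigma_g2:
#' `mu` by GLS under `V = G + ratio I`, then
#' `g_hat = G (G + ratio I)^{-1} (y - mu)`. Equivalent to kernel ridge
#' regression with kernel G and regularization `ratio` after intercept
#' absorption.
#'
#' @param y trait vector.
#' @param g GRM covering the phenotyped lines.
#' @param ratio positive finite noise-to-genetic variance ratio.
#' @return A `gblup_fit` with `sigma_g2 = 1`, `sigma_e2 = ratio`.
#' @export
blup_given_ratio <- function(y, g, ratio) {
  if (!is.finite(ratio) || ratio <= 0)
    stop("ratio must be finite and positive")
  ids <- names(y)
  gt <- grm_submatrix(g, ids, ids)
  n <- length(y)
  k <- gt + diag(ratio + .jitter(gt), n)
  kinv_y <- solve(k, as.numeric(y))
  kinv_1 <- solve(k, rep(1, n))
  mu <- sum(kinv_y) / sum(kinv_1)
  g_hat <- drop(gt %*% solve(k, as.numeric(y) - mu))
  .new_gblup_fit(mu, 1, ratio, g_hat, ids)
}

#' Predict genetic merit of lines from a GBLUP fit
#'
#' Training lines get their fitted values `mu + g_hat` exactly; other lines
#' get `mu + G[target, train] G[train, train]^{-1} g_hat` (jittered solve),
#' the conditional expectation of their genetic value given the training
#' BLUPs.
#'
#' @param object `gblup_fit`.
#' @param g GRM covering training and target lines.
#' @param target_ids line ids to predict.
#' @param ... unused.
#' @return A [trait_vector()] of predicted values for `target_ids`.
#' @export
predict.gblup_fit <- function(object, g, target_ids, ...) {
  unknown <- setdiff(c(target_ids, object$train_ids), rownames(g))
  if (length(unknown) > 0)
    stop("unknown line id(s): ", paste(unknown, collapse = ", "))
  pred <- stats::setNames(numeric(length(target_ids)), target_ids)
  in_train <- target_ids %in% object$train_ids
  pred[in_train] <- object$mu + object$g_hat[target_ids[in_train]]
  out <- target_ids[!in_train]
  if (length(out) > 0) {
    tr <- object$train_ids
    ktt <- grm_submatrix(g, tr, tr)
    ktt <- ktt + diag(.jitter(ktt), length(tr))
    alpha <- solve(ktt, object$g_hat)
    pred[out] <- object$mu + drop(grm_submatrix(g, out, tr) %*% alpha)
  }
  trait_vector(pred, target_ids, "predicted")
}

#' Export a GBLUP fit summary as delimited text
#'
#' @param fit `gblup_fit`.
#' @param path output path.
#' @export
write_fit_summary <- function(fit, path) {
  df <- data.frame(mu = fit$mu, sigma_g2 = fit$sigma_g2,
                   sigma_e2 = fit$sigma_e2, h2 = fit$h2,
                   n_train = length(fit$train_ids))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
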