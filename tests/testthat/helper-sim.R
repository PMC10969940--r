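# Shared fixtures, built in code.

# Small complete dataset used across integration tests: 50 lines x 200
# markers, moderate polygenic signal.
fixture_dataset <- function(seed = 11, h2 = 0.6) {
  cfg <- sim_config(n_lines = 50, n_markers = 200, n_qtl = 40, h2 = h2,
                    seed = seed)
  m <- sim_genotypes(cfg)
  ph <- sim_phenotypes(m, cfg)
  list(markers = m, trait = ph$trait, truth = ph$truth, cfg = cfg)
}

# Random raw dosage matrix with ids, entries in {0,1,2}.
random_dosage <- function(n, p, seed = 1) {
  set.seed(seed)
  m <- matrix(as.numeric(sample(0:2, n * p, replace = TRUE)), n, p,
              dimnames = list(paste0("L", seq_len(n)),
                              paste0("M", seq_len(p))))
  m
}

# Elementwise double-loop VanRaden oracle, independent of the matrix-algebra
# implementation path.
grm_bruteforce <- function(m) {
  n <- nrow(m)
  p <- ncol(m)
  freq <- numeric(p)
  for (k in seq_len(p)) freq[k] <- mean(m[, k]) / 2
  denom <- 0
  for (k in seq_len(p)) denom <- denom + 2 * freq[k] * (1 - freq[k])
  g <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      acc <- 0
      for (k in seq_len(p))
        acc <- acc + (m[i, k] - 2 * freq[k]) * (m[j, k] - 2 * freq[k])
      g[i, j] <- acc / denom
    }
  }
  g
}

# Direct mixed-model-equation solve: inverts the full (n+1) x (n+1)
# coefficient matrix [X'X X'Z; Z'X Z'Z + ratio*G^{-1}] for y = 1*mu + g + e.
blup_mme_oracle <- function(y, g, ratio) {
  n <- length(y)
  x <- matrix(1, n, 1)
  z <- diag(n)
  ginv <- solve(g)
  lhs <- rbind(cbind(crossprod(x), crossprod(x, z)),
               cbind(crossprod(z, x), crossprod(z) + ratio * ginv))
  rhs <- rbind(crossprod(x, y), crossprod(z, y))
  sol <- solve(lhs, rhs)
  list(mu = sol[1], g_hat = drop(sol[-1]))
}
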