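# Independent oracles used by the likelihood and MLE tests. These deliberately
# re-derive the quantities from first principles (explicit sum over the latent
# occupancy state, dense grid search) and share no code with the package
# internals they check.

# Log-likelihood by explicit enumeration of the latent state z_i in {0, 1}:
# L_i = psi_i * prod_t Bern(y_it; p_it) + (1 - psi_i) * [all y_it == 0].
oracle_loglik_enum <- function(psi_vec, p_mat, y_mat) {
  total <- 0
  for (i in seq_len(nrow(y_mat))) {
    obs <- which(!is.na(y_mat[i, ]))
    lik_z1 <- psi_vec[i]
    for (t in obs) {
      lik_z1 <- lik_z1 * if (y_mat[i, t] == 1) p_mat[i, t] else 1 - p_mat[i, t]
    }
    lik_z0 <- (1 - psi_vec[i]) * as.numeric(all(y_mat[i, obs] == 0))
    total <- total + log(lik_z1 + lik_z0)
  }
  total
}

# Constant-model MLE by dense grid search over (psi, p).
oracle_grid_mle <- function(y_mat, step = 0.001) {
  grid <- seq(0.01, 0.99, by = step)
  d <- rowSums(y_mat == 1, na.rm = TRUE)
  k <- rowSums(!is.na(y_mat))
  best <- c(NA, NA); best_ll <- -Inf
  for (p in grid) {
    # vectorized over psi for speed
    ll_det <- sum(ifelse(d > 0, d * log(p) + (k - d) * log(1 - p), 0))
    q <- (1 - p)^k
    ll <- vapply(grid, function(psi) {
      sum(ifelse(d > 0, log(psi), log(psi * q + (1 - psi)))) + ll_det
    }, 0)
    j <- which.max(ll)
    if (ll[j] > best_ll) { best_ll <- ll[j]; best <- c(grid[j], p) }
  }
  list(psi = best[1], p = best[2], loglik = best_ll)
}

# Random small detection-history instance with valid rows (>= 1 visit each).
random_instance <- function(S, K, miss_prob = 0.2) {
  repeat {
    y <- matrix(rbinom(S * K, 1, runif(1, 0.2, 0.8)), S, K)
    y[matrix(runif(S * K) < miss_prob, S, K)] <- NA
    if (all(rowSums(!is.na(y)) >= 1)) return(y)
  }
}

# A small synthetic study with a single 6-night month (fixed K = 6), observer
# effect on p and zone effect on psi -- the generating model of the
# selection-consistency and coverage checks.
one_month_config <- function(...) {
  study_config(occasions_per_month = c(6, 6), months = "Feb", ...)
}
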