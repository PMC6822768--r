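# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: losses are counted entry by entry, Gaussian
# densities are evaluated from an explicitly assembled and inverted
# covariance, and covariances are estimated by plain Monte Carlo.

# Entry-by-entry loss counter (oracle for ternary_losses).
oracle_losses <- function(S_true, S_est) {
  match_nz <- 0; est_nz <- 0; true_nz <- 0; true_z <- 0; match_z <- 0; err <- 0
  for (i in seq_len(nrow(S_true))) {
    for (j in seq_len(ncol(S_true))) {
      s <- S_true[i, j]; e <- S_est[i, j]
      if (e != 0) est_nz <- est_nz + 1
      if (s != 0) true_nz <- true_nz + 1 else true_z <- true_z + 1
      if (s == e && e != 0) match_nz <- match_nz + 1
      if (s == 0 && e == 0) match_z <- match_z + 1
      if (s != e) err <- err + 1
    }
  }
  list(fdr = if (est_nz > 0) 1 - match_nz / est_nz else NA_real_,
       fnr = if (true_nz > 0) 1 - match_nz / true_nz else NA_real_,
       fpr = if (true_z > 0) 1 - match_z / true_z else NA_real_,
       error_rate = err / length(S_true))
}

# Dense zero-mean Gaussian log-density from an explicitly built covariance.
oracle_gauss_loglik <- function(y, Sigma) {
  m <- length(y)
  -m / 2 * log(2 * pi) -
    0.5 * as.numeric(determinant(Sigma, logarithm = TRUE)$modulus) -
    0.5 * drop(t(y) %*% solve(Sigma) %*% y)
}

# Full covariance matrix of all CRT stacked samples (conditions included),
# assembled sample pair by sample pair from analytic_covariance.
oracle_full_covariance <- function(A, noise, design) {
  n <- nrow(as.matrix(A))
  grid <- expand.grid(t = seq_len(design$T), r = seq_len(design$R),
                      c = seq_len(design$C))
  m <- nrow(grid)
  S <- matrix(0, m * n, m * n)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      blk <- analytic_covariance(A, noise, design$sampling,
                                 unlist(grid[i, c("c", "r", "t")]),
                                 unlist(grid[j, c("c", "r", "t")]))
      S[(i - 1) * n + seq_len(n), (j - 1) * n + seq_len(n)] <- blk
    }
  }
  list(S = S, grid = grid)
}

# Stack a tensor in the (t fastest, then r, then c) order matching
# oracle_full_covariance.
oracle_stack <- function(Y) {
  d <- dim(Y)
  out <- numeric(0)
  for (c in seq_len(d[1])) for (r in seq_len(d[2])) for (t in seq_len(d[3])) {
    out <- c(out, Y[c, r, t, ])
  }
  out
}

random_ternary <- function(n, m = n, p_edge = 0.4) {
  matrix(sample(c(-1, 0, 1), n * m, replace = TRUE,
                prob = c(p_edge / 2, 1 - p_edge, p_edge / 2)), n, m)
}
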