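# Deterministic lagged tensor: X(t+1) = X(t) A exactly, X(1) random.
noiseless_tensor <- function(A, C, T, seed) {
  n <- nrow(A)
  set.seed(seed)
  Y <- array(0, dim = c(C, 1, T, n))
  X <- matrix(rnorm(C * n), C, n)
  Y[, 1, 1, ] <- X
  for (t in 2:T) {
    X <- X %*% A
    Y[, 1, t, ] <- X
  }
  Y
}

test_that("lagged design has the right rows and bookkeeping", {
  d <- design_spec(1, 1, 2, "multi_shot")
  Y <- simulate_glm(matrix(0.5), d, noise_model(1, 0, 0), seed = 1)
  ld <- build_lagged_design(Y)
  expect_equal(ld$n_rows, 1L)
  expect_error(build_lagged_design(
    simulate_glm(matrix(0.5), design_spec(2, 1, 1, "multi_shot"),
                 noise_model(1, 0, 0), seed = 1)), "T >= 2")

  for (C in c(5, 15)) {
    for (R in c(1, 3)) {
      d <- design_spec(C, R, 6, "one_shot")
      Y <- simulate_glm(matrix(0.3), d, noise_model(0.5, 0.5, 0.1), seed = C + R)
      expect_equal(build_lagged_design(Y, TRUE)$n_rows, C * 5L)
      expect_equal(build_lagged_design(Y, FALSE)$n_rows, C * R * 5L)
      # rows pair consecutive times of one (condition, replicate)
      ld <- build_lagged_design(Y, FALSE)
      i <- nrow(ld$Psi1)
      expect_equal(ld$Psi1[i, ],
                   Y[ld$meta$condition[i], ld$meta$replicate[i],
                     ld$meta$time_to[i], ])
      expect_equal(ld$Psi0[i, ],
                   Y[ld$meta$condition[i], ld$meta$replicate[i],
                     ld$meta$time_from[i], ])
    }
  }
  # with R = 1 averaging is immaterial
  d1 <- design_spec(8, 1, 4, "one_shot")
  Y1 <- simulate_glm(matrix(0.3), d1, noise_model(0.6, 0.8, 0), seed = 2)
  la <- build_lagged_design(Y1, TRUE); lb <- build_lagged_design(Y1, FALSE)
  expect_equal(la$Psi1, lb$Psi1)
  expect_equal(la$Psi0, lb$Psi0)
})

test_that("build-up recovers a planted parent exactly", {
  A <- matrix(0, 5, 5)
  A[1, 2] <- 0.8
  Y <- noiseless_tensor(A, C = 20, T = 4, seed = 3)
  ld <- build_lagged_design(Y)
  bu <- best_subset_stage(ld, j = 2, k = 2)
  expect_equal(bu$support, 1L)
  expect_equal(bu$coef, 0.8, tolerance = 1e-8)
  expect_lt(bu$rss, 1e-16)
})

test_that("build-up minimizes RSS over an explicit enumeration", {
  set.seed(4)
  d <- design_spec(12, 1, 5, "one_shot")
  Y <- simulate_glm(sample_network(network_prior(6, 2), seed = 5), d,
                    homogeneous_noise(6, 0.5, sigma_te = 0.5), seed = 6)
  ld <- build_lagged_design(Y)
  gram <- grnshot:::lagged_gram(ld)
  for (j in c(1, 4)) {
    bu <- best_subset_stage(ld, j, k = 2)
    # oracle: refit every subset with lm
    resp <- ld$Psi1[, j]
    cand <- setdiff(1:6, j)
    subsets <- c(list(integer(0)), as.list(cand),
                 combn(cand, 2, simplify = FALSE))
    rss_all <- vapply(subsets, function(s) {
      X <- cbind(ld$Psi0[, c(s, j), drop = FALSE], 1)
      sum(stats::lm.fit(X, resp)$residuals^2)
    }, numeric(1))
    expect_equal(length(subsets), 1 + 5 + 10)
    expect_lte(bu$rss, min(rss_all) + 1e-8)
    # and the reported RSS matches the direct fit of the chosen support
    Xb <- cbind(ld$Psi0[, c(bu$support, j), drop = FALSE], 1)
    expect_equal(bu$rss, sum(stats::lm.fit(Xb, resp)$residuals^2),
                 tolerance = 1e-8)
  }
})

test_that("exhaustive scan size matches the binomial count", {
  d <- design_spec(30, 1, 6, "one_shot")
  Y <- simulate_glm(sample_network(network_prior(20, 3), seed = 7), d,
                    homogeneous_noise(20, 0.5), seed = 8)
  ld <- build_lagged_design(Y)
  bu <- best_subset_stage(ld, j = 1, k = 3)
  expect_equal(bu$n_evaluated, sum(choose(19, 0:3)))  # 1160
})

test_that("tear-down F equals the squared t-statistic of the coefficient", {
  set.seed(9)
  n <- 6
  A <- matrix(0, n, n)
  A[c(1, 3, 5), 2] <- c(0.7, -0.6, 0.5)
  d <- design_spec(20, 1, 6, "multi_shot")
  Y <- simulate_glm(A, d, homogeneous_noise(n, 0.5, sigma_te = 0.2), seed = 10)
  ld <- build_lagged_design(Y)
  bu <- best_subset_stage(ld, j = 2, k = 3)
  td <- teardown_stage(bu, ld, j = 2, alpha = 0.05, k = 3)
  expect_equal(sort(bu$support), c(1, 3, 5))
  fit <- stats::lm(ld$Psi1[, 2] ~ ld$Psi0[, c(bu$support, 2)])
  tstats <- summary(fit)$coefficients[1 + seq_along(bu$support), "t value"]
  expect_equal(td$F, unname(tstats^2), tolerance = 1e-8)
})

test_that("an always-null single candidate is pruned at rate 1 - alpha", {
  # n = 2, k = 1: the sole candidate parent is always selected, so its
  # F-statistic is a clean F(1, df) draw under the null
  set.seed(11)
  n_reps <- 400
  pvals <- numeric(n_reps)
  for (i in seq_len(n_reps)) {
    Y <- array(rnorm(40 * 6 * 2), dim = c(40, 1, 6, 2))
    ld <- build_lagged_design(Y)
    bu <- best_subset_stage(ld, j = 2, k = 1)
    td <- teardown_stage(bu, ld, j = 2, alpha = 0.05, k = 1)
    pvals[i] <- td$p[1]
  }
  prune_rate <- mean(pvals > 0.05)
  expect_lt(abs(prune_rate - 0.95), 3 * sqrt(0.95 * 0.05 / n_reps))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("a planted parent in noiseless data survives the F -> Inf limit", {
  A <- matrix(0, 4, 4)
  A[3, 1] <- -0.9
  Y <- noiseless_tensor(A, C = 15, T = 5, seed = 12)
  ld <- build_lagged_design(Y)
  bu <- best_subset_stage(ld, j = 1, k = 1)
  td <- teardown_stage(bu, ld, j = 1, alpha = 0.05, k = 1)
  expect_equal(td$parents, 3L)
  expect_equal(td$signs, -1)
  expect_equal(td$p[match(3, bu$support)], 0)
})

test_that("bslr composes the stages and reports signs off the diagonal", {
  pr <- network_prior(8, 2)
  A <- sample_network(pr, seed = 13)
  d <- design_spec(15, 1, 6, "multi_shot")
  Y <- simulate_glm(A, d, homogeneous_noise(8, 0.5), seed = 14)
  S <- bslr(Y, k = 2)
  expect_true(all(S %in% c(-1, 0, 1)))
  expect_true(all(diag(S) == 0))

  # scale invariance: any nonzero rescaling leaves the output unchanged
  for (c0 in c(3.7, -2)) {
    Yc <- structure(unclass(Y) * c0, class = "expression_tensor",
                    design = d, noise = attr(Y, "noise"))
    expect_identical(bslr(Yc, k = 2), S)
  }
})

test_that("infeasible degrees of freedom raise an explicit error", {
  d <- design_spec(1, 30, 6, "one_shot")   # C(T-1) = 5, k = 3 -> df = 0
  Y <- simulate_glm(sample_network(network_prior(20, 3), seed = 15), d,
                    homogeneous_noise(20, 0.5), seed = 16)
  expect_error(bslr(Y, k = 3), "degrees of freedom")
  # boundary: df = 1 is feasible
  d2 <- design_spec(2, 1, 6, "one_shot")   # C(T-1) = 10, k = 5 -> df = 3
  Y2 <- simulate_glm(sample_network(network_prior(8, 2), seed = 17), d2,
                     homogeneous_noise(8, 0.5), seed = 18)
  expect_silent(bslr(Y2, k = 5, alpha = 0.5))
})

test_that("a zero tensor yields an empty structure with a warning", {
  d <- design_spec(10, 1, 6, "one_shot")
  Y <- simulate_glm(matrix(0, 3, 3), d, noise_model(0, 0, 0, n = 3), seed = 19)
  expect_warning(S <- bslr(Y, k = 1), "zero")
  expect_equal(S, matrix(0, 3, 3))
})

test_that("noiseless multi-shot losses do not depend on gamma", {
  # multi-shot, sigma_te = 0: the data law depends on the driving noise only
  # through sigma_co^2 + sigma_bi^2, so losses at different gamma agree in
  # distribution; compare Monte-Carlo means within a generous band
  pr <- network_prior(10, 2)
  d <- design_spec(10, 3, 6, "multi_shot")
  mean_fdr <- function(gam, seed0) {
    f <- vapply(1:80, function(i) {
      A <- sample_network(pr, seed = seed0 + i)
      Y <- simulate_glm(A, d, homogeneous_noise(10, gam), seed = seed0 + 500 + i)
      ternary_losses(sign_structure(A), bslr(Y, k = 2))$fdr
    }, numeric(1))
    mean(f, na.rm = TRUE)
  }
  f1 <- mean_fdr(0.2, 20000)
  f2 <- mean_fdr(0.8, 21000)
  expect_lt(abs(f1 - f2), 0.12)   # ~3 x pooled SE at 80 reps
})
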