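test_that("design_spec derives the number of individuals from the mode", {
  expect_equal(design_spec(3, 2, 4, "one_shot")$K, 24L)
  expect_equal(design_spec(3, 2, 4, "multi_shot")$K, 6L)
  expect_error(design_spec(0, 1, 1), "positive")
})

test_that("noise model derives gamma and validates levels", {
  nm <- noise_model(sqrt(0.8), sqrt(0.2), 1, n = 3)
  expect_equal(nm$gamma, rep(0.8, 3))
  expect_true(is.na(noise_model(0, 0, 1)$gamma))
  expect_error(noise_model(-1, 0, 0), "nonnegative")
  expect_equal(homogeneous_noise(2, gamma = 0.25, sigma2 = 4)$sigma_co,
               rep(1, 2))
})

test_that("noiseless static system stays at zero", {
  d <- design_spec(2, 2, 3, "one_shot")
  Y <- simulate_glm(matrix(0, 2, 2), d, noise_model(0, 0, 0, n = 2), seed = 1)
  expect_true(all(Y == 0))
})

test_that("with only condition noise, replicates are identical", {
  for (mode in c("one_shot", "multi_shot")) {
    d <- design_spec(C = 3, R = 4, T = 5, sampling = mode)
    Y <- simulate_glm(matrix(0.5), d, noise_model(1, 0, 0), seed = 2)
    for (r in 2:4) expect_equal(Y[, r, , ], Y[, 1, , ])
  }
})

test_that("one-shot and multi-shot share condition-noise draws per seed", {
  A <- matrix(0.5)
  noise <- noise_model(1, 0, 0)
  y1 <- simulate_glm(A, design_spec(2, 3, 4, "one_shot"), noise, seed = 9)
  y2 <- simulate_glm(A, design_spec(2, 3, 4, "multi_shot"), noise, seed = 9)
  # with sigma_bi = sigma_te = 0 the data are a function of the shared
  # condition stream only, so the paired tensors coincide exactly
  expect_equal(unclass(y1)[, , , ], unclass(y2)[, , , ])
})

test_that("analytic covariance implements the case formulas", {
  A <- matrix(c(0.3, 0.1, -0.2, 0.4), 2, 2)
  noise <- noise_model(c(0.6, 0.5), c(0.4, 0.7), c(0.3, 0.2), n = 2)
  # different conditions: zero
  expect_equal(analytic_covariance(A, noise, "one_shot", c(1, 1, 2), c(2, 1, 2)),
               matrix(0, 2, 2))
  # A = 0, same sample: plain sum of the three variance components
  z <- matrix(0, 2, 2)
  expect_equal(analytic_covariance(z, noise, "multi_shot", c(1, 2, 3), c(1, 2, 3)),
               diag(noise$sigma_co^2 + noise$sigma_bi^2 + noise$sigma_te^2))
  # hand-evaluated single-gene case: same condition, different replicates
  n1 <- noise_model(0.8, 0.1, 0.5)
  got <- analytic_covariance(matrix(0.5), n1, "one_shot", c(1, 1, 2), c(1, 2, 2))
  expect_equal(drop(got), 0.8^2 * (1 + 0.25))
  # same-individual multi-shot at different times: includes sigma_bi, no te
  got2 <- analytic_covariance(matrix(0.5), n1, "multi_shot", c(1, 1, 1), c(1, 1, 2))
  expect_equal(drop(got2), (0.8^2 + 0.1^2) * 0.5)
})

test_that("simulated covariances match the analytic formulas (Monte Carlo)", {
  # n = 2, C = 2, R = 2, T = 3; estimate a handful of entries by simulation
  A <- matrix(c(0.5, 0.2, -0.3, 0.1), 2, 2)
  noise <- noise_model(c(0.7, 0.5), c(0.5, 0.6), c(0.2, 0.4), n = 2)
  n_reps <- 20000
  for (mode in c("one_shot", "multi_shot")) {
    d <- design_spec(n_reps, 2, 3, sampling = mode)   # conditions as reps
    Y <- simulate_glm(A, d, noise, seed = 101)
    pairs <- list(list(c(1, 1, 2), c(1, 1, 2)),   # same sample
                  list(c(1, 1, 1), c(1, 1, 3)),   # same (c, r), t != t'
                  list(c(1, 1, 2), c(1, 2, 3)))   # same c, r != r'
    for (pr in pairs) {
      i1 <- pr[[1]]; i2 <- pr[[2]]
      want <- analytic_covariance(A, noise, mode, i1, i2)
      x1 <- Y[, i1[2], i1[3], ]; x2 <- Y[, i2[2], i2[3], ]
      got <- crossprod(x1, x2) / n_reps
      se <- 3 * sqrt(diag(want)[1] * diag(want)[2] + max(want)^2) / sqrt(n_reps)
      expect_true(all(abs(got - want) < 6 * se + 0.01))
    }
  }
})

test_that("replicate averaging preserves condition variance, shrinks the rest", {
  d <- design_spec(C = 2000, R = 4, T = 2, sampling = "one_shot")
  A <- matrix(0.5)
  # condition-only noise: averaging changes nothing
  Yco <- simulate_glm(A, d, noise_model(1, 0, 0), seed = 5)
  expect_equal(replicate_average(Yco)[, , 1], Yco[, 1, , 1])
  # biological-only noise: variance shrinks by ~ R
  Ybi <- simulate_glm(A, d, noise_model(0, 1, 0), seed = 6)
  v_single <- var(Ybi[, 1, 1, 1])
  v_avg <- var(replicate_average(Ybi)[, 1, 1])
  expect_lt(abs(v_avg / v_single - 1 / 4), 0.05)
  # R = 1 averaging is the identity
  d1 <- design_spec(3, 1, 2, "one_shot")
  Y1 <- simulate_glm(A, d1, noise_model(1, 1, 1), seed = 7)
  expect_equal(replicate_average(Y1)[, , 1], Y1[, 1, , 1])
})

test_that("stationary covariance solves the Lyapunov fixed point", {
  n1 <- noise_model(sqrt(0.5), sqrt(0.5), 0)
  expect_equal(drop(stationary_covariance(matrix(0), n1)), 1)
  expect_equal(drop(stationary_covariance(matrix(0.5), n1)), 4 / 3)
  # transient covariances converge to the fixed point
  A <- matrix(c(0.4, 0.2, -0.1, 0.3), 2, 2)
  noise2 <- noise_model(c(0.6, 0.4), c(0.5, 0.8), 0, n = 2)
  lim <- transient_covariances(A, noise2, 200)[[200]]
  expect_equal(lim, stationary_covariance(A, noise2), tolerance = 1e-8)
  expect_error(stationary_covariance(matrix(1.1), n1), "spectral radius")
})

test_that("transient covariances: first step, scaled-orthogonal case, MC", {
  noise2 <- noise_model(c(0.6, 0.4), c(0.5, 0.8), 0, n = 2)
  Q <- diag(noise2$sigma_co^2 + noise2$sigma_bi^2)
  expect_equal(transient_covariances(matrix(c(0.3, 0.1, 0, 0.2), 2, 2),
                                     noise2, 1)[[1]], Q)
  # A*A = rho I: Sigma_t = (sum_{tau=0}^{t-1} rho^tau) Q for scalar Q
  rho <- 0.49
  th <- 0.7
  A <- sqrt(rho) * matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  unit <- noise_model(sqrt(0.5), sqrt(0.5), 0, n = 2)
  got <- transient_covariances(A, unit, 4)
  for (t in 1:4) {
    expect_equal(got[[t]], sum(rho^(0:(t - 1))) * diag(1, 2), tolerance = 1e-12)
  }
  # Monte-Carlo check of Cov(X(t)) via one individual per condition
  d <- design_spec(C = 30000, R = 1, T = 3, sampling = "multi_shot")
  Y <- simulate_glm(A, d, unit, seed = 8)
  for (t in 1:3) {
    emp <- crossprod(Y[, 1, t, ]) / d$C
    expect_true(all(abs(emp - got[[t]]) < 6 / sqrt(d$C) * max(1, got[[t]][1])))
  }
})

test_that("with no biological noise both sampling modes share one law", {
  A <- matrix(c(0.5, -0.2, 0.1, 0.3), 2, 2)
  noise <- noise_model(c(0.7, 0.9), 0, c(0.2, 0.1), n = 2)
  idx <- expand.grid(c = 1:2, r = 1:2, t = 1:3)
  for (i in seq_len(nrow(idx))) {
    for (j in seq_len(nrow(idx))) {
      i1 <- unlist(idx[i, ]); i2 <- unlist(idx[j, ])
      expect_equal(analytic_covariance(A, noise, "one_shot", i1, i2),
                   analytic_covariance(A, noise, "multi_shot", i1, i2))
    }
  }
})

test_that("multi-shot R=1 law depends on the driving noise only via the sum", {
  A <- matrix(c(0.5, -0.2, 0.1, 0.3), 2, 2)
  na <- noise_model(c(0.8, 0.3), c(0.2, 0.9), 0.4, n = 2)
  sum2 <- na$sigma_co^2 + na$sigma_bi^2
  nb <- noise_model(sqrt(0.3 * sum2), sqrt(0.7 * sum2), 0.4, n = 2)
  for (t1 in 1:3) for (t2 in 1:3) {
    expect_equal(
      analytic_covariance(A, na, "multi_shot", c(1, 1, t1), c(1, 1, t2)),
      analytic_covariance(A, nb, "multi_shot", c(1, 1, t1), c(1, 1, t2)))
  }
})

test_that("one-shot sampling without condition effect cannot identify signs", {
  A <- matrix(c(0.5, -0.2, 0.1, 0.3), 2, 2)
  noise <- noise_model(0, c(1, 0.7), c(0.3, 0.2), n = 2)
  idx <- expand.grid(c = 1:2, r = 1:2, t = 1:3)
  for (i in seq_len(nrow(idx))) {
    for (j in seq_len(nrow(idx))) {
      i1 <- unlist(idx[i, ]); i2 <- unlist(idx[j, ])
      expect_identical(analytic_covariance(A, noise, "one_shot", i1, i2),
                       analytic_covariance(-A, noise, "one_shot", i1, i2))
    }
  }
})

test_that("two rotations with equal scale share transient covariances", {
  rho <- 0.64
  mk <- function(th) sqrt(rho) * matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  unit <- noise_model(1, 0, 0, n = 2)
  s1 <- transient_covariances(mk(0.4), unit, 5)
  s2 <- transient_covariances(mk(1.9), unit, 5)
  expect_false(isTRUE(all.equal(mk(0.4), mk(1.9))))
  for (t in 1:5) expect_equal(s1[[t]], s2[[t]], tolerance = 1e-12)
})

test_that("expression tensors round-trip through long TSV", {
  dir <- withr::local_tempdir()
  d <- design_spec(2, 2, 3, "multi_shot")
  Y <- simulate_glm(matrix(c(0.4, 0, 0.1, 0.2), 2, 2), d,
                    homogeneous_noise(2, 0.5, sigma_te = 0.3), seed = 12)
  path <- file.path(dir, "y.tsv")
  write_tensor_tsv(Y, path, seed = 12)
  Y2 <- read_tensor_tsv(path)
  expect_equal(unclass(Y2)[, , , ], unclass(Y)[, , , ], tolerance = 1e-12)
  expect_equal(attr(Y2, "design")$sampling, "multi_shot")
  expect_equal(attr(Y2, "noise")$sigma_te, rep(0.3, 2))
})
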