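#' Factorial sampling design
#'
#' A full factorial design with `C` conditions, `R` replicates and `T`
#' sampling times (`C * R * T` samples in total), under one of two sampling
#' modes.  Under *multi-shot* sampling the same individual is measured at
#' every time (`K = C * R` individuals, true trajectories); under *one-shot*
#' sampling every sample comes from a distinct individual measured only at
#' its target time (`K = C * R * T` individuals).
#'
#' @param C,R,T positive integers: conditions, replicates, sampling times.
#' @param sampling `"one_shot"` or `"multi_shot"`.
#' @return A list of class `"design_spec"` with fields `C`, `R`, `T`,
#'   `sampling` and `K` (number of individuals grown).
#' @export
design_spec <- function(C, R, T, sampling = c("one_shot", "multi_shot")) {
  sampling <- match.arg(sampling)
  if (any(c(C, R, T) < 1) || any(c(C, R, T) != round(c(C, R, T)))) {
    stop("C, R and T must be positive integers")
  }
  structure(
    list(C = as.integer(C), R = as.integer(R), T = as.integer(T),
         sampling = sampling,
         K = as.integer(if (sampling == "one_shot") C * R * T else C * R)),
    class = "design_spec"
  )
}

#' Per-gene noise model
#'
#' Holds the three per-gene standard deviations of the expression model:
#' condition variation `sigma_co` (driving noise shared by all individuals
#' under the same condition), biological variation `sigma_bi` (driving noise
#' independent per individual) and technical variation `sigma_te` (additive
#' observation noise outside the dynamics).  The derived ratio
#' \eqn{\gamma_j = \sigma_{co,j}^2 / (\sigma_{co,j}^2 + \sigma_{bi,j}^2)}
#' is the fraction of driving-noise variance that is condition-shared.
#'
#' @param sigma_co,sigma_bi,sigma_te nonnegative numeric vectors, recycled
#'   to the number of genes `n`.
#' @param n number of genes.
#' @return A list of class `"noise_model"` with the three vectors and the
#'   derived `gamma` (NA for genes with zero total driving variance).
#' @seealso [homogeneous_noise()] for the `(gamma, sigma2)` parameterization.
#' @export
noise_model <- function(sigma_co, sigma_bi, sigma_te = 0, n = NULL) {
  if (is.null(n)) n <- max(length(sigma_co), length(sigma_bi), length(sigma_te))
  sigma_co <- rep_len(as.numeric(sigma_co), n)
  sigma_bi <- rep_len(as.numeric(sigma_bi), n)
  sigma_te <- rep_len(as.numeric(sigma_te), n)
  if (any(c(sigma_co, sigma_bi, sigma_te) < 0)) {
    stop("noise levels must be nonnegative")
  }
  tot <- sigma_co^2 + sigma_bi^2
  structure(
    list(n = as.integer(n), sigma_co = sigma_co, sigma_bi = sigma_bi,
         sigma_te = sigma_te,
         gamma = ifelse(tot > 0, sigma_co^2 / tot, NA_real_)),
    class = "noise_model"
  )
}

#' Homogeneous noise model from the condition-variation fraction
#'
#' Convenience constructor for the homogeneous-gene case used in the
#' simulation studies: every gene has
#' \eqn{\sigma_{co}^2 = \gamma\,\sigma^2},
#' \eqn{\sigma_{bi}^2 = (1-\gamma)\,\sigma^2}.
#'
#' @param n number of genes.
#' @param gamma condition-variation fraction in \[0, 1\].
#' @param sigma2 total driving variance \eqn{\sigma^2 = \sigma_{co}^2 +
#'   \sigma_{bi}^2} (default 1).
#' @param sigma_te technical noise standard deviation (default 0).
#' @return A `"noise_model"`.
#' @export
homogeneous_noise <- function(n, gamma, sigma2 = 1, sigma_te = 0) {
  stopifnot(gamma >= 0, gamma <= 1, sigma2 >= 0)
  noise_model(sigma_co = sqrt(gamma * sigma2),
              sigma_bi = sqrt((1 - gamma) * sigma2),
              sigma_te = sigma_te, n = n)
}

# Index bookkeeping shared by the simulator: individual k <-> (c, r[, s]).
# Rows are ordered with condition slowest, then replicate, then (one-shot
# only) target time fastest.
individual_index <- function(design) {
  if (design$sampling == "multi_shot") {
    data.frame(c = rep(seq_len(design$C), each = design$R),
               r = rep(seq_len(design$R), times = design$C))
  } else {
    data.frame(c = rep(seq_len(design$C), each = design$R * design$T),
               r = rep(rep(seq_len(design$R), each = design$T), times = design$C),
               s = rep(seq_len(design$T), times = design$C * design$R))
  }
}

#' Simulate the Gaussian linear expression model
#'
#' Simulates gene expression under the linear dynamics
#' \deqn{X_j^k(t+1) = \sum_i X_i^k(t) A_{ij}
#'   + \sigma_{co,j} W_{co,j}^{c_k}(t+1) + \sigma_{bi,j} W_{bi,j}^k(t+1)}
#' with initial state \eqn{X(0) = 0}, condition-noise draws shared by all
#' individuals with the same condition label at each time, and independent
#' per-individual biological noise.  The observation is
#' \eqn{Y_j^{c,r,t} = X_j(t) + \sigma_{te,j} Z_j^{c,r,t}} where under
#' multi-shot sampling individual `(c, r)` is read at every time, while
#' under one-shot sampling individual `(c, r, s)` is read only at its
#' target time `s`.
#'
#' Expression values are signed reals (e.g. log-scale expression); no
#' clipping is applied.  The random stream is laid out condition-noise
#' first, so one-shot and multi-shot runs with the same seed share their
#' condition-noise draws — useful for paired sampling-method comparisons.
#'
#' @param A n-by-n adjacency matrix driving the dynamics.
#' @param design a [design_spec()].
#' @param noise a [noise_model()] with `n` genes.
#' @param seed optional integer seed.
#' @param keep_latent logical; retain the latent trajectories `X` and the
#'   driving noises on the result (for white-box testing).  Default `FALSE`.
#' @return An array of class `"expression_tensor"` with dimensions
#'   `c(C, R, T, n)` and attributes `design` and `noise` (plus `latent`
#'   when requested).
#' @examples
#' d <- design_spec(C = 2, R = 3, T = 4, sampling = "one_shot")
#' y <- simulate_glm(matrix(0.5), d, noise_model(1, 0, 0), seed = 1)
#' dim(y)
#' @export
simulate_glm <- function(A, design, noise, seed = NULL, keep_latent = FALSE) {
  A <- as.matrix(A)
  n <- nrow(A)
  if (ncol(A) != n) stop("A must be square")
  stopifnot(inherits(design, "design_spec"), inherits(noise, "noise_model"))
  if (noise$n != n) stop("noise model has ", noise$n, " genes but A has ", n)
  C <- design$C; R <- design$R; Tn <- design$T
  with_seed(seed, {
    # Fixed draw order: condition noise, then biological noise, then
    # observation noise, so the condition stream is shared across modes.
    W_co <- array(rnorm(C * Tn * n), dim = c(C, Tn, n))
    idx <- individual_index(design)
    K <- nrow(idx)
    W_bi <- array(rnorm(K * Tn * n), dim = c(K, Tn, n))
    Z <- array(rnorm(C * R * Tn * n), dim = c(C, R, Tn, n))

    sco <- matrix(noise$sigma_co, K, n, byrow = TRUE)
    sbi <- matrix(noise$sigma_bi, K, n, byrow = TRUE)
    S <- matrix(0, K, n)                       # X(0) = 0
    X <- array(NA_real_, dim = c(K, Tn, n))
    for (t in seq_len(Tn)) {
      S <- S %*% A + sco * matrix(W_co[idx$c, t, ], K, n) +
        sbi * matrix(W_bi[, t, ], K, n)
      X[, t, ] <- S
    }

    Y <- array(NA_real_, dim = c(C, R, Tn, n))
    if (design$sampling == "multi_shot") {
      for (k in seq_len(K)) Y[idx$c[k], idx$r[k], , ] <- X[k, , ]
    } else {
      for (k in seq_len(K)) Y[idx$c[k], idx$r[k], idx$s[k], ] <- X[k, idx$s[k], ]
    }
    Y <- Y + Z * rep(noise$sigma_te, each = C * R * Tn)

    structure(Y, class = "expression_tensor", design = design, noise = noise,
              latent = if (keep_latent) list(X = X, idx = idx, W_co = W_co,
                                             W_bi = W_bi, Z = Z))
  })
}

# sum_{tau=1}^{min(t,tp)} (A^T)^(t-tau) diag(qd) A^(tp-tau)
cross_cov_sum <- function(A, qd, t, tp) {
  n <- nrow(A)
  Apow <- list(diag(1, n))                      # A^0, A^1, ...
  for (m in seq_len(max(t, tp))) Apow[[m + 1L]] <- Apow[[m]] %*% A
  M <- matrix(0, n, n)
  for (tau in seq_len(min(t, tp))) {
    M <- M + t(Apow[[t - tau + 1L]]) %*% (qd * Apow[[tp - tau + 1L]])
  }
  M
}

#' Exact covariance between two samples of the linear model
#'
#' Evaluates the closed-form covariance
#' \eqn{E[(Y^{c,r,t})^* Y^{c',r',t'}]} of the Gaussian linear model for the
#' requested sampling mode.  Samples from different conditions are
#' independent (zero covariance).  Within a condition the covariance is a
#' sum over common driving-noise times of
#' \eqn{(A^*)^{t-\tau} Q A^{t'-\tau}}, where `Q` is
#' \eqn{\Sigma_{co} + \Sigma_{bi}} when the two samples come from the same
#' individual and \eqn{\Sigma_{co}} otherwise; the technical-noise term
#' \eqn{\Sigma_{te}} enters only for the exact same sample.  Under one-shot
#' sampling two samples with \eqn{(r,t) \neq (r',t')} always come from
#' different individuals.
#'
#' @param A adjacency matrix.
#' @param noise a [noise_model()].
#' @param sampling `"one_shot"` or `"multi_shot"`.
#' @param idx1,idx2 integer triples `c(condition, replicate, time)` with
#'   times in `1:T`.
#' @return An n-by-n covariance matrix.
#' @export
analytic_covariance <- function(A, noise, sampling = c("one_shot", "multi_shot"),
                                idx1, idx2) {
  sampling <- match.arg(sampling)
  A <- as.matrix(A)
  stopifnot(length(idx1) == 3L, length(idx2) == 3L)
  c1 <- idx1[1]; r1 <- idx1[2]; t1 <- idx1[3]
  c2 <- idx2[1]; r2 <- idx2[2]; t2 <- idx2[3]
  if (t1 < 1 || t2 < 1) stop("times must be >= 1 (X(0) = 0 is not observed)")
  n <- nrow(A)
  q_full <- noise$sigma_co^2 + noise$sigma_bi^2
  q_co <- noise$sigma_co^2
  if (c1 != c2) return(matrix(0, n, n))
  same_sample <- (r1 == r2) && (t1 == t2)
  same_individual <- if (sampling == "multi_shot") r1 == r2 else same_sample
  M <- cross_cov_sum(A, if (same_individual) q_full else q_co, t1, t2)
  if (same_sample) M <- M + diag(noise$sigma_te^2, n)
  M
}

#' Average an expression tensor over replicates
#'
#' @param Y an `"expression_tensor"` (array `C x R x T x n`).
#' @return Array with dimensions `c(C, T, n)`: the arithmetic mean over the
#'   replicate axis.  Averaging reduces biological and technical variance by
#'   a factor of `R` but leaves the condition-shared variation unchanged.
#' @export
replicate_average <- function(Y) {
  stopifnot(length(dim(Y)) == 4L)
  d <- dim(Y)
  out <- apply(Y, c(1, 3, 4), mean)
  dim(out) <- d[c(1, 3, 4)]
  out
}

#' Stationary covariance of the linear dynamics
#'
#' Solves the discrete-time Lyapunov fixed point
#' \eqn{\Sigma = A^* \Sigma A + Q} with driving covariance
#' \eqn{Q = \Sigma_{co} + \Sigma_{bi}} (the unit-variance case `Q = I` is
#' the special case \eqn{\sigma_{co}^2 + \sigma_{bi}^2 = 1}).  Requires the
#' spectral radius of `A` to be below 1.
#'
#' @inheritParams analytic_covariance
#' @return Symmetric positive semi-definite n-by-n matrix.
#' @export
stationary_covariance <- function(A, noise) {
  A <- as.matrix(A)
  n <- nrow(A)
  if (max(Mod(eigen(A, only.values = TRUE)$values)) >= 1) {
    stop("spectral radius of A is >= 1: no stationary state exists")
  }
  Q <- diag(noise$sigma_co^2 + noise$sigma_bi^2, n)
  M <- diag(1, n * n) - kronecker(t(A), t(A))
  S <- matrix(solve(M, as.vector(Q)), n, n)
  (S + t(S)) / 2
}

#' Transient state covariances of the linear dynamics
#'
#' Returns \eqn{\Sigma_t = Cov(X(t)) = \sum_{\tau=1}^{t} (A^*)^{t-\tau} Q
#' A^{t-\tau}} for `t = 1, ..., T`, computed by the recursion
#' \eqn{\Sigma_{t} = A^* \Sigma_{t-1} A + Q} from \eqn{\Sigma_0 = 0}.
#'
#' @inheritParams analytic_covariance
#' @param T number of time steps.
#' @return List of `T` n-by-n matrices.
#' @export
transient_covariances <- function(A, noise, T) {
  A <- as.matrix(A)
  n <- nrow(A)
  Q <- diag(noise$sigma_co^2 + noise$sigma_bi^2, n)
  out <- vector("list", T)
  S <- matrix(0, n, n)
  for (t in seq_len(T)) {
    S <- t(A) %*% S %*% A + Q
    out[[t]] <- S
  }
  out
}

#' Write / read an expression tensor as long-format TSV
#'
#' Tensors are stored with columns `condition`, `replicate`, `time`,
#' `gene`, `value`; the design, noise model and seed are recorded in a JSON
#' sidecar `<path>.json`.
#'
#' @param Y an `"expression_tensor"`.
#' @param path output TSV path.
#' @param seed optional seed to record in the sidecar.
#' @return `write_tensor_tsv()` returns `path` invisibly;
#'   `read_tensor_tsv()` returns an `"expression_tensor"`.
#' @export
write_tensor_tsv <- function(Y, path, seed = NULL) {
  stopifnot(length(dim(Y)) == 4L)
  d <- dim(Y)
  grid <- expand.grid(condition = seq_len(d[1]), replicate = seq_len(d[2]),
                      time = seq_len(d[3]), gene = seq_len(d[4]))
  grid$value <- as.vector(Y)
  write.table(grid, path, sep = "\t", quote = FALSE, row.names = FALSE)
  design <- attr(Y, "design"); noise <- attr(Y, "noise")
  jsonlite::write_json(
    list(design = design[c("C", "R", "T", "sampling")],
         noise = if (!is.null(noise)) noise[c("sigma_co", "sigma_bi", "sigma_te")],
         seed = seed),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_tensor_tsv
#' @export
read_tensor_tsv <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE)
  d <- c(max(tab$condition), max(tab$replicate), max(tab$time), max(tab$gene))
  Y <- array(NA_real_, dim = d)
  Y[cbind(tab$condition, tab$replicate, tab$time, tab$gene)] <- tab$value
  design <- NULL; noise <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$design)) {
      design <- design_spec(meta$design$C, meta$design$R, meta$design$T,
                            meta$design$sampling)
    }
    if (!is.null(meta$noise)) {
      noise <- noise_model(meta$noise$sigma_co, meta$noise$sigma_bi,
                           meta$noise$sigma_te, n = d[4])
    }
  }
  structure(Y, class = "expression_tensor", design = design, noise = noise)
}
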