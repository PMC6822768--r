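#' Configuration of a factorial simulation study
#'
#' Describes one of the package's simulation studies: the estimator under
#' test, the fixed sample budget `CR * T` (the number of conditions is
#' derived as `CR / R` for every `R` in `R_grid`), the grid of
#' condition-variation fractions `gamma`, the observation noise level and
#' the Monte-Carlo size.  All cells of one study share the budget, so
#' designs are comparable.
#'
#' @param estimator `"glrt"` (single-gene sign recovery) or `"bslr"`
#'   (multi-gene reconstruction).
#' @param CR total number of condition-replicate pairs (default 30).
#' @param T number of sampling times (default 6).
#' @param R_grid replicate counts to scan; each must divide `CR`.
#' @param gamma_grid condition-variation fractions to scan.
#' @param sigma_te technical noise level.
#' @param sampling_modes subset of `c("one_shot", "multi_shot")`.
#' @param n_reps Monte-Carlo replications per cell (defaults: 10000 for
#'   the single-gene GLRT study, 200 for the 20-gene BSLR studies).
#' @param master_seed integer; every cell derives an independent
#'   reproducible substream from it.
#' @param a_true true single-gene coefficient (GLRT studies).
#' @param glrt_mode `"known_params"` or `"joint_estimation"`.
#' @param prior a [network_prior()] for BSLR studies (default: 20 genes,
#'   `d_max = 3`).
#' @param k,alpha BSLR subset size and tear-down level.
#' @return A list of class `"experiment_config"`.
#' @export
experiment_config <- function(estimator = c("glrt", "bslr"),
                              CR = 30, T = 6,
                              R_grid = c(1, 2, 3, 5, 6, 10, 15, 30),
                              gamma_grid = seq(0, 1, by = 0.2),
                              sigma_te = 0,
                              sampling_modes = c("one_shot", "multi_shot"),
                              n_reps = NULL, master_seed = 1,
                              a_true = 0.5,
                              glrt_mode = "known_params",
                              prior = network_prior(n = 20, d_max = 3),
                              k = 3, alpha = 0.05) {
  estimator <- match.arg(estimator)
  if (any(CR %% R_grid != 0)) {
    stop("every R in R_grid must divide the budget CR = ", CR)
  }
  if (is.null(n_reps)) n_reps <- if (estimator == "glrt") 10000L else 200L
  structure(
    list(estimator = estimator, CR = as.integer(CR), T = as.integer(T),
         R_grid = as.integer(R_grid), gamma_grid = gamma_grid,
         sigma_te = sigma_te, sampling_modes = sampling_modes,
         n_reps = as.integer(n_reps), master_seed = as.integer(master_seed),
         a_true = a_true, glrt_mode = glrt_mode, prior = prior,
         k = k, alpha = alpha),
    class = "experiment_config"
  )
}

# One BSLR Monte-Carlo cell: n_reps draws of (network, data) -> losses.
bslr_cell <- function(prior, design, noise, k, alpha, n_reps, seed) {
  losses <- matrix(NA_real_, n_reps, 3,
                   dimnames = list(NULL, c("fdr", "fnr", "fpr")))
  for (i in seq_len(n_reps)) {
    s <- derive_seed(seed, i)
    A <- sample_network(prior, seed = s)
    Y <- simulate_glm(A, design, noise, seed = s + 1L)
    est <- bslr(Y, k = k, alpha = alpha)
    l <- ternary_losses(sign_structure(A), est)
    losses[i, ] <- c(l$fdr, l$fnr, l$fpr)
  }
  losses
}

#' Run a factorial simulation study
#'
#' Evaluates the configured estimator on every grid cell
#' (sampling mode x gamma x R) with `n_reps` independent draws per cell,
#' and returns a tidy results table with per-cell mean losses and
#' confidence half-widths (normal-approximation binomial for the GLRT
#' error rate, Hoeffding at level 0.05 for the BSLR losses).  Cells where
#' the estimator is infeasible (e.g. BSLR with tear-down degrees of
#' freedom below 1) are reported as explicit `infeasible` rows, never
#' silently dropped.  Results are bit-for-bit reproducible from
#' `master_seed`: each cell uses an independently derived substream, so
#' the table does not depend on evaluation order.
#'
#' @param config an [experiment_config()].
#' @return A data frame with one row per (cell, loss type): columns
#'   `sampling`, `gamma`, `R`, `C`, `loss`, `mean`, `half_width`,
#'   `n_defined`, `infeasible`.  The configuration is attached as
#'   attribute `"config"`.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  cells <- expand.grid(sampling = config$sampling_modes,
                       gamma = config$gamma_grid, R = config$R_grid,
                       stringsAsFactors = FALSE)
  cells$C <- config$CR %/% cells$R
  out <- list()
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, , drop = FALSE]
    rownames(cell) <- NULL
    cell_seed <- derive_seed(config$master_seed, i)
    design <- design_spec(cell$C, cell$R, config$T, sampling = cell$sampling)
    if (config$estimator == "glrt") {
      noise <- homogeneous_noise(1, gamma = cell$gamma, sigma2 = 1,
                                 sigma_te = config$sigma_te)
      gcfg <- glrt_config(mode = config$glrt_mode, gamma = cell$gamma,
                          sigma2 = 1, sigma_te = config$sigma_te)
      res <- tryCatch(
        glrt_sign_error_rate(config$n_reps, config$a_true, design, noise,
                             gcfg, seed = cell_seed),
        error = function(e) e)
      if (inherits(res, "error")) {
        out[[i]] <- data.frame(cell, loss = "error_rate", mean = NA_real_,
                               half_width = NA_real_, n_defined = 0L,
                               infeasible = TRUE)
      } else {
        p <- res$error_rate
        out[[i]] <- data.frame(cell, loss = "error_rate", mean = p,
                               half_width = qnorm(0.975) *
                                 sqrt(p * (1 - p) / res$n_reps),
                               n_defined = res$n_reps, infeasible = FALSE)
      }
    } else {
      noise <- homogeneous_noise(config$prior$n, gamma = cell$gamma,
                                 sigma2 = 1, sigma_te = config$sigma_te)
      losses <- tryCatch(
        bslr_cell(config$prior, design, noise, config$k, config$alpha,
                  config$n_reps, cell_seed),
        error = function(e) e)
      if (inherits(losses, "error")) {
        out[[i]] <- data.frame(cell, loss = c("fdr", "fnr", "fpr"),
                               mean = NA_real_, half_width = NA_real_,
                               n_defined = 0L, infeasible = TRUE)
      } else {
        hw <- sqrt(log(2 / 0.05) / (2 * config$n_reps))
        out[[i]] <- data.frame(
          cell, loss = c("fdr", "fnr", "fpr"),
          mean = apply(losses, 2, mean, na.rm = TRUE),
          half_width = hw,
          n_defined = apply(losses, 2, function(v) sum(!is.na(v))),
          infeasible = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "config") <- config
  res
}

# Ternary FDR / FNR restricted to edges whose source gene lies in `rows`.
losses_by_rows <- function(S_true, S_est, rows) {
  St <- S_true[rows, , drop = FALSE]
  Se <- S_est[rows, , drop = FALSE]
  n_match <- sum(St == Se & Se != 0)
  c(fdr = if (sum(Se != 0) > 0) 1 - n_match / sum(Se != 0) else NA_real_,
    fnr = if (sum(St != 0) > 0) 1 - n_match / sum(St != 0) else NA_real_)
}

#' Per-source-class losses under heterogeneous condition effects
#'
#' Simulation study for the setting where only part of the genes are
#' directly differentially expressed (DDEGs, genes with
#' \eqn{\sigma_{co,j} > 0}).  For each replication a network is drawn from
#' the prior, data are simulated under the given heterogeneous noise
#' model, BSLR is applied, and the ternary FDR / FNR are computed
#' separately for edges whose source gene is a DDEG and for edges out of
#' non-DDEGs.
#'
#' @param prior a [network_prior()].
#' @param design a [design_spec()].
#' @param noise a heterogeneous [noise_model()]; the DDEG class is the set
#'   of genes with `sigma_co > 0` unless `classes` is supplied.
#' @param classes optional logical vector (TRUE = DDEG) overriding the
#'   class labels.
#' @param k,alpha BSLR parameters.
#' @param n_reps Monte-Carlo replications.
#' @param seed master seed.
#' @return Data frame with one row per class: mean `fdr`, `fnr`, the
#'   number of defined replications for each, and the class size.
#' @export
ddeg_split_report <- function(prior, design, noise, classes = NULL,
                              k = 3, alpha = 0.05, n_reps = 200, seed = 1) {
  if (is.null(classes)) classes <- noise$sigma_co > 0
  stopifnot(length(classes) == prior$n)
  acc <- array(NA_real_, dim = c(n_reps, 2, 2),
               dimnames = list(NULL, c("ddeg", "non_ddeg"), c("fdr", "fnr")))
  for (i in seq_len(n_reps)) {
    s <- derive_seed(seed, i)
    A <- sample_network(prior, seed = s)
    Y <- simulate_glm(A, design, noise, seed = s + 1L)
    est <- bslr(Y, k = k, alpha = alpha)
    St <- sign_structure(A)
    acc[i, "ddeg", ] <- losses_by_rows(St, est, which(classes))
    acc[i, "non_ddeg", ] <- losses_by_rows(St, est, which(!classes))
  }
  data.frame(
    class = c("ddeg", "non_ddeg"),
    n_genes = c(sum(classes), sum(!classes)),
    fdr = apply(acc[, , "fdr", drop = FALSE], 2, mean, na.rm = TRUE),
    n_fdr = apply(acc[, , "fdr", drop = FALSE], 2, function(v) sum(!is.na(v))),
    fnr = apply(acc[, , "fnr", drop = FALSE], 2, mean, na.rm = TRUE),
    n_fnr = apply(acc[, , "fnr", drop = FALSE], 2, function(v) sum(!is.na(v))),
    row.names = NULL
  )
}
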