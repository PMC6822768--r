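#' Time-lagged regression design from an expression tensor
#'
#' Builds the stacked response/predictor pair used by BSLR: response rows
#' are expression at times `2..T` and predictor rows the matching
#' expression at times `1..T-1`.  With replicate averaging (the default)
#' replicates are first averaged within each condition, giving
#' `C * (T - 1)` rows; without averaging each replicate contributes its own
#' consecutive-time pairs, giving `C * R * (T - 1)` rows (rows pair samples
#' of the same `(condition, replicate)` label — meaningful as trajectories
#' only for multi-shot data, though still computable for one-shot data).
#'
#' @param Y an `"expression_tensor"` (array `C x R x T x n`).
#' @param replicate_averaging logical (default `TRUE`).
#' @return A list of class `"lagged_design"` with matrices `Psi1`, `Psi0`
#'   (rows x genes), a row `meta` data frame (condition, replicate, time
#'   pair) and `n_rows`.
#' @export
build_lagged_design <- function(Y, replicate_averaging = TRUE) {
  stopifnot(length(dim(Y)) == 4L)
  d <- dim(Y)
  C <- d[1]; R <- d[2]; T <- d[3]; n <- d[4]
  if (T < 2) stop("at least two sampling times are required (T >= 2)")
  if (replicate_averaging) {
    Ybar <- replicate_average(Y)                       # C x T x n
    Psi1 <- do.call(rbind, lapply(2:T, function(t) matrix(Ybar[, t, ], C, n)))
    Psi0 <- do.call(rbind, lapply(2:T, function(t) matrix(Ybar[, t - 1, ], C, n)))
    meta <- data.frame(condition = rep(seq_len(C), times = T - 1),
                       replicate = NA_integer_,
                       time_from = rep(1:(T - 1), each = C),
                       time_to = rep(2:T, each = C))
  } else {
    rows1 <- list(); rows0 <- list()
    for (t in 2:T) {
      rows1[[t - 1]] <- matrix(Y[, , t, ], C * R, n)
      rows0[[t - 1]] <- matrix(Y[, , t - 1, ], C * R, n)
    }
    Psi1 <- do.call(rbind, rows1)
    Psi0 <- do.call(rbind, rows0)
    meta <- data.frame(condition = rep(rep(seq_len(C), times = R), times = T - 1),
                       replicate = rep(rep(seq_len(R), each = C), times = T - 1),
                       time_from = rep(1:(T - 1), each = C * R),
                       time_to = rep(2:T, each = C * R))
  }
  structure(list(Psi1 = Psi1, Psi0 = Psi0, meta = meta,
                 n = n, n_rows = nrow(Psi1),
                 replicate_averaging = isTRUE(replicate_averaging)),
            class = "lagged_design")
}

# Gram quantities reused across target genes: P = [Psi0, 1].
lagged_gram <- function(design) {
  P <- cbind(design$Psi0, 1)
  list(P = P, G = crossprod(P), GY = crossprod(P, design$Psi1),
       yty = colSums(design$Psi1^2))
}

#' Best-subset build-up stage of BSLR
#'
#' For target gene `j`, exhaustively searches all parent subsets of size at
#' most `k` from the other genes; every fit also includes the self term
#' (lagged expression of `j` itself, a nuisance absorbing autoregulation
#' and mRNA carry-over) and an intercept.  The subset with minimal residual
#' sum of squares wins; ties go to the smaller, lexicographically earlier
#' subset.  Rank-deficient subsets are fitted by minimum-norm least
#' squares, so collinear candidates never abort the scan.
#'
#' @param design a [build_lagged_design()] result.
#' @param j target gene index.
#' @param k maximum subset size (`k < n`).
#' @param gram optional precomputed Gram list (internal use by [bslr()]).
#' @return List with `support` (selected parent indices, sorted), `coef`
#'   (their coefficients), `d` (self-term coefficient), `b` (intercept),
#'   `rss` (unrestricted RSS) and `n_evaluated` (number of subsets
#'   scanned).
#' @export
best_subset_stage <- function(design, j, k, gram = NULL) {
  stopifnot(inherits(design, "lagged_design"))
  n <- design$n
  if (k >= n) stop("subset size k must be smaller than the number of genes")
  if (design$n_rows <= k + 2) {
    stop("not enough rows (", design$n_rows, ") to fit k + 2 = ", k + 2,
         " parameters")
  }
  if (is.null(gram)) gram <- lagged_gram(design)
  candidates <- setdiff(seq_len(n), j)
  mandatory <- c(j, n + 1L)
  tol <- 1e-10 * max(gram$yty[j], 1)
  res <- subset_scan_cpp(gram$G, gram$GY[, j], gram$yty[j],
                         as.integer(candidates), as.integer(mandatory),
                         as.integer(k), tol)
  s <- length(res$subset)
  ord <- order(res$subset)
  list(support = res$subset[ord],
       coef = if (s > 0) res$coef[seq_len(s)][ord] else numeric(0),
       d = res$coef[s + 1L], b = res$coef[s + 2L],
       rss = res$rss, n_evaluated = res$n_evaluated)
}

#' Granger F-test tear-down stage of BSLR
#'
#' For each selected parent `i` of gene `j`, refits the model with `i`
#' removed (all other selected parents, the self term and the intercept are
#' retained regardless of the outcomes of their own tests) and computes
#' \deqn{F = \frac{RSS_r - RSS_u}{RSS_u / df}, \qquad df = N - k - 2,}
#' where `N` is the number of regression rows (`C(T-1)` with replicate
#' averaging, `CR(T-1)` without).  The parent is pruned when the p-value of
#' `F` against the `F(1, df)` law exceeds `alpha`.  A perfect unrestricted
#' fit (`RSS_u = 0`) is treated as the `F -> Inf` limit: p-value 0, parent
#' retained.
#'
#' @param buildup result of [best_subset_stage()] for gene `j`.
#' @param design the [build_lagged_design()] used in the build-up.
#' @param j target gene index.
#' @param alpha significance level in (0, 1).
#' @param k configured subset size (sets the degrees of freedom as above).
#' @param gram optional precomputed Gram list.
#' @return List with `parents` (retained parent indices), `signs` (their
#'   coefficient signs), and per-tested-parent vectors `F` and `p`.
#' @export
teardown_stage <- function(buildup, design, j, alpha, k, gram = NULL) {
  df <- design$n_rows - k - 2
  if (df < 1) {
    stop("BSLR infeasible: degrees of freedom ", design$n_rows, " - ", k,
         " - 2 = ", df, " < 1")
  }
  if (is.null(gram)) gram <- lagged_gram(design)
  support <- buildup$support
  n <- design$n
  mandatory <- c(j, n + 1L)
  Fv <- pv <- numeric(length(support))
  for (ii in seq_along(support)) {
    idx <- c(setdiff(support, support[ii]), mandatory)
    b <- solve_gram(gram$G[idx, idx, drop = FALSE], gram$GY[idx, j])
    rss_r <- gram$yty[j] - 2 * sum(b * gram$GY[idx, j]) +
      drop(crossprod(b, gram$G[idx, idx, drop = FALSE] %*% b))
    rss_r <- max(rss_r, 0)
    if (buildup$rss <= 0) {
      Fv[ii] <- Inf; pv[ii] <- 0
    } else {
      Fv[ii] <- max(rss_r - buildup$rss, 0) / (buildup$rss / df)
      pv[ii] <- pf(Fv[ii], 1, df, lower.tail = FALSE)
    }
  }
  keep <- pv <= alpha
  list(parents = support[keep], signs = sign(buildup$coef[keep]),
       F = Fv, p = pv)
}

#' BSLR: best-subset lagged regression network reconstruction
#'
#' Two-stage reconstruction of the signed gene regulatory network from a
#' factorial expression tensor: a best-subset build-up stage on
#' time-lagged (by default replicate-averaged) linear regressions, followed
#' by a per-parent Granger F-test tear-down stage.  The output is the
#' ternary matrix of estimated regulation signs; the diagonal is always 0
#' (the self term is a nuisance parameter, not a reported edge).
#'
#' @param Y an `"expression_tensor"` (array `C x R x T x n`).
#' @param k best-subset size (default 3).
#' @param alpha tear-down significance level (default 0.05).
#' @param replicate_averaging average replicates before regression
#'   (default `TRUE`).
#' @param audit logical; attach a per-gene audit table (chosen subsets, F
#'   statistics, p-values) as attribute `"audit"`.
#' @return n-by-n matrix with entries in \{-1, 0, +1\}.
#' @examples
#' prior <- network_prior(n = 8, d_max = 2)
#' A <- sample_network(prior, seed = 1)
#' d <- design_spec(C = 10, R = 1, T = 6, sampling = "multi_shot")
#' y <- simulate_glm(A, d, homogeneous_noise(8, gamma = 0.5), seed = 2)
#' S <- bslr(y, k = 2)
#' ternary_losses(sign_structure(A), S)
#' @export
bslr <- function(Y, k = 3, alpha = 0.05, replicate_averaging = TRUE,
                 audit = FALSE) {
  design <- build_lagged_design(Y, replicate_averaging)
  n <- design$n
  df <- design$n_rows - k - 2
  if (df < 1) {
    stop("BSLR infeasible: degrees of freedom ", design$n_rows, " - ", k,
         " - 2 = ", df, " < 1")
  }
  S <- matrix(0, n, n)
  if (all(Y == 0)) {
    warning("input tensor is identically zero; returning the empty structure")
    return(S)
  }
  gram <- lagged_gram(design)
  audit_rows <- list()
  for (j in seq_len(n)) {
    bu <- best_subset_stage(design, j, k, gram = gram)
    td <- teardown_stage(bu, design, j, alpha, k, gram = gram)
    if (length(td$parents) > 0) S[td$parents, j] <- td$signs
    if (audit && length(bu$support) > 0) {
      audit_rows[[j]] <- data.frame(
        gene = j, parent = bu$support, coef = bu$coef,
        F = td$F, p = td$p, retained = bu$support %in% td$parents)
    }
  }
  if (audit) {
    attr(S, "audit") <- do.call(rbind, audit_rows)
  }
  S
}
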