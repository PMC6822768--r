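#' Parameters of the four-gene circadian clock SDE model
#'
#' Loads the parameter registry for the 12-equation clock model (genes
#' LHY, TOC1, X and Y; per gene one mRNA, one cytoplasmic-protein and one
#' nuclear-protein species).  The registry is a plain `key = value` text
#' file; the file shipped with the package
#' (`extdata/locke_params_synthetic.txt`) is a synthetic parameter set
#' tuned to give sustained nonnegative oscillatory dynamics of this model
#' in the dark condition — see the file header and the methods vignette.
#'
#' @param path path to a registry file; defaults to the shipped synthetic
#'   registry.
#' @return A named list of class `"locke_params"`: transcription maxima
#'   `n1..n5`, activation/repression thresholds `g1..g6`, Michaelis
#'   constants `k1..k12`, maximal degradation rates `m1..m14`, translation
#'   rates `p1..p4`, nuclear transport rates `r1..r8` and Hill exponents
#'   `a..f`.
#' @export
locke_params <- function(path = system.file("extdata",
                                            "locke_params_synthetic.txt",
                                            package = "grnshot")) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  p <- stats::setNames(as.numeric(trimws(vapply(kv, `[`, "", 2L))),
                       trimws(vapply(kv, `[`, "", 1L)))
  p <- as.list(p)
  expected <- c(paste0("n", 1:5), paste0("g", 1:6), paste0("k", 1:12),
                paste0("m", 1:14), paste0("p", 1:4), paste0("r", 1:8),
                letters[1:6])
  missing <- setdiff(expected, names(p))
  if (length(missing)) stop("registry is missing: ", paste(missing, collapse = ", "))
  vals <- unlist(p[expected])
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all clock parameters must be strictly positive")
  }
  if (any(unlist(p[letters[1:6]]) < 1)) stop("Hill exponents must be >= 1")
  structure(p[expected], class = "locke_params")
}

# Column layout of the clock state: x1..x4 (mRNA), y1..y4 (cytoplasmic
# protein), z1..z4 (nuclear protein).
clock_species <- function() {
  c(paste0("x", 1:4), paste0("y", 1:4), paste0("z", 1:4))
}

#' Drift of the clock SDE system
#'
#' Evaluates the deterministic part of the twelve clock equations (dark
#' condition) at one or more states.  Transcription of LHY is activated by
#' nuclear X protein; TOC1 is activated by nuclear Y protein and repressed
#' by nuclear LHY protein; X is activated by nuclear LHY protein; Y is
#' repressed by nuclear TOC1 and LHY proteins.  All species degrade by
#' Michaelis–Menten kinetics and proteins shuttle between cytoplasm and
#' nucleus with linear transport.
#'
#' @param state numeric vector of length 12 (or a `K x 12` matrix of
#'   states), columns ordered `x1..x4, y1..y4, z1..z4`; nonnegative.
#' @param params a [locke_params()] list.
#' @return Drift with the same shape as `state`.
#' @export
clock_drift <- function(state, params) {
  vec <- is.null(dim(state))
  S <- if (vec) matrix(state, 1L) else state
  q <- params
  x <- S[, 1:4, drop = FALSE]; y <- S[, 5:8, drop = FALSE]
  z <- S[, 9:12, drop = FALSE]
  hill_act <- function(zv, g, h) zv^h / (g^h + zv^h)
  hill_rep <- function(zv, g, h) g^h / (g^h + zv^h)
  mm <- function(v, m, k) m * v / (k + v)

  dx <- cbind(
    q$n1 * hill_act(z[, 3], q$g1, q$a) - mm(x[, 1], q$m1, q$k1),
    q$n2 * hill_act(z[, 4], q$g2, q$b) * hill_rep(z[, 1], q$g3, q$c) -
      mm(x[, 2], q$m4, q$k4),
    q$n3 * hill_act(z[, 1], q$g4, q$d) - mm(x[, 3], q$m9, q$k7),
    q$n5 * hill_rep(z[, 2], q$g5, q$e) * hill_rep(z[, 1], q$g6, q$f) -
      mm(x[, 4], q$m12, q$k10)
  )
  dy <- cbind(
    q$p1 * x[, 1] - q$r1 * y[, 1] + q$r2 * z[, 1] - mm(y[, 1], q$m2, q$k2),
    q$p2 * x[, 2] - q$r3 * y[, 2] + q$r4 * z[, 2] -
      mm(y[, 2], q$m5 + q$m6, q$k5),
    q$p3 * x[, 3] - q$r5 * y[, 3] + q$r6 * z[, 3] - mm(y[, 3], q$m10, q$k8),
    q$p4 * x[, 4] - q$r7 * y[, 4] + q$r8 * z[, 4] - mm(y[, 4], q$m13, q$k11)
  )
  dz <- cbind(
    q$r1 * y[, 1] - q$r2 * z[, 1] - mm(z[, 1], q$m3, q$k3),
    q$r3 * y[, 2] - q$r4 * z[, 2] - mm(z[, 2], q$m7 + q$m8, q$k6),
    q$r5 * y[, 3] - q$r6 * z[, 3] - mm(z[, 3], q$m11, q$k9),
    q$r7 * y[, 4] - q$r8 * z[, 4] - mm(z[, 4], q$m14, q$k12)
  )
  out <- cbind(dx, dy, dz)
  colnames(out) <- clock_species()
  if (vec) drop(out) else out
}

#' Deterministic clock state after a burn-in integration
#'
#' Integrates the noiseless clock ODE by the explicit Euler method from a
#' fixed positive state, returning the state after `burn_in` time units.
#' Used as the common initial condition of the stochastic experiments, so
#' that sampling starts from settled (oscillatory) dynamics rather than an
#' arbitrary point.
#'
#' @param params a [locke_params()] list.
#' @param burn_in burn-in duration in model time units (default 120).
#' @param dt Euler step (default 0.01).
#' @param init starting state (default: every species at 1).
#' @return Named state vector of length 12.
#' @export
clock_burn_in <- function(params, burn_in = 120, dt = 0.01,
                          init = rep(1, 12)) {
  s <- stats::setNames(as.numeric(init), clock_species())
  for (step in seq_len(round(burn_in / dt))) {
    s <- pmax(s + clock_drift(s, params) * dt, 0)
  }
  s
}

#' Simulate the clock SDE under a factorial design
#'
#' Euler–Maruyama integration of the twelve clock equations with
#' multiplicative (linear-diffusion) noise: each species' increment gains
#' `sigma_co * value * dB_co` with a Brownian increment shared by every
#' individual in the same condition, plus `sigma_bi * value * dB_bi` with
#' an individual-specific increment.  The linear diffusion attenuates the
#' noise near zero; a post-step clamp at 0 guards against discretization
#' undershoot.  Under one-shot sampling each `(condition, replicate, time)`
#' sample is a distinct individual (own biological path, shared condition
#' path) observed only at its target time; under multi-shot sampling one
#' individual per `(condition, replicate)` is observed at every time.
#' Only the four mRNA species are observed; proteins stay latent.
#'
#' @param params a [locke_params()] list.
#' @param design a [design_spec()] (its `T` must equal `length(times)`).
#' @param times sampling times (model time units), sorted, multiples of `dt`.
#' @param sigma_co,sigma_bi condition-coupled and individual noise scales
#'   (defaults 0.3 and 0.4).
#' @param dt Euler step (default 0.01).
#' @param seed optional integer seed.
#' @param init initial state; default is [clock_burn_in()] of `params`.
#' @return An `"expression_tensor"` array `C x R x T x 4` of mRNA levels
#'   (genes LHY, TOC1, X, Y).
#' @export
simulate_clock <- function(params, design, times = seq(0, 10, by = 2),
                           sigma_co = 0.3, sigma_bi = 0.4, dt = 0.01,
                           seed = NULL, init = NULL) {
  stopifnot(inherits(design, "design_spec"))
  if (dt <= 0) stop("dt must be positive")
  if (is.unsorted(times)) stop("sampling times must be sorted")
  if (design$T != length(times)) {
    stop("design has T = ", design$T, " but ", length(times),
         " sampling times were given")
  }
  steps <- round(times / dt)
  if (max(abs(times - steps * dt)) > 1e-9) {
    stop("every sampling time must be a multiple of dt")
  }
  if (is.null(init)) init <- clock_burn_in(params, dt = dt)
  C <- design$C; R <- design$R; Tn <- design$T
  idx <- individual_index(design)
  K <- nrow(idx)
  with_seed(seed, {
    S <- matrix(rep(as.numeric(init), each = K), K, 12)
    Y <- array(NA_real_, dim = c(C, R, Tn, 4))
    record <- function(step_i) {
      at <- which(steps == step_i)
      for (t in at) {
        if (design$sampling == "multi_shot") {
          for (k in seq_len(K)) Y[idx$c[k], idx$r[k], t, ] <<- S[k, 1:4]
        } else {
          for (k in which(idx$s == t)) Y[idx$c[k], idx$r[k], t, ] <<- S[k, 1:4]
        }
      }
    }
    record(0L)
    sdt <- sqrt(dt)
    for (step_i in seq_len(max(steps))) {
      dB_co <- matrix(rnorm(C * 12), C, 12) * sdt
      dB_bi <- matrix(rnorm(K * 12), K, 12) * sdt
      S <- S + clock_drift(S, params) * dt +
        sigma_co * S * dB_co[idx$c, , drop = FALSE] + sigma_bi * S * dB_bi
      S <- pmax(S, 0)
      record(step_i)
    }
    structure(Y, class = "expression_tensor", design = design,
              noise = NULL, times = times)
  })
}

#' Ground-truth signed graph of the clock model
#'
#' Derives the signed mRNA-to-mRNA regulation graph from the drift
#' equations: the edge `i -> j` carries the sign of the partial derivative
#' of the transcription drift of gene `j` with respect to the nuclear
#' protein of gene `i`.  Because translation and nuclear transport have
#' positive gain, this is also the sign of the influence of mRNA `i` on
#' mRNA `j`, and it is constant in the state (Hill terms are monotone), so
#' the graph is well defined.  Signs are evaluated numerically at a spread
#' of positive states and checked for consistency.
#'
#' @param params a [locke_params()] list.
#' @return 4-by-4 ternary matrix (rows = regulator, columns = target,
#'   genes LHY, TOC1, X, Y) with zero diagonal.
#' @export
ground_truth_graph <- function(params) {
  genes <- c("LHY", "TOC1", "X", "Y")
  S <- matrix(0, 4, 4, dimnames = list(genes, genes))
  # deterministic spread of positive probe states
  probes <- as.matrix(expand.grid(lo = c(0.05, 0.4, 1.5),
                                  hi = c(0.1, 0.8, 3)))
  states <- lapply(seq_len(nrow(probes)), function(i) {
    rep(c(probes[i, 1], probes[i, 2], probes[i, 1]), each = 4) *
      (1 + 0.3 * sin(seq_len(12) + i))
  })
  h <- 1e-6
  for (i in 1:4) {
    for (j in setdiff(1:4, i)) {
      ds <- vapply(states, function(s) {
        up <- s; up[8 + i] <- up[8 + i] + h
        dn <- s; dn[8 + i] <- max(dn[8 + i] - h, 0)
        (clock_drift(up, params)[j] - clock_drift(dn, params)[j]) /
          (up[8 + i] - dn[8 + i])
      }, numeric(1))
      sgns <- unique(sign(ds[abs(ds) > 1e-12]))
      if (length(sgns) > 1) {
        stop("inconsistent influence sign for edge ", genes[i], " -> ", genes[j])
      }
      S[i, j] <- if (length(sgns) == 1) sgns else 0
    }
  }
  S
}

#' Four-regime BSLR benchmark on the clock model
#'
#' Runs BSLR on clock SDE data under the four regimes (one-shot /
#' multi-shot sampling, with / without replicate averaging) and reports the
#' mean ternary losses against [ground_truth_graph()] with Hoeffding
#' confidence half-widths \eqn{\sqrt{\log(2/\alpha_H)/(2 n)}}.  Within one
#' replication, the two averaging variants are applied to the same
#' simulated data set for each sampling mode.
#'
#' @param n_reps number of Monte-Carlo replications.
#' @param seed master seed.
#' @param params a [locke_params()] list.
#' @param C,R conditions and replicates (defaults 1 and 3).
#' @param times sampling times (defaults 0, 2, ..., 10).
#' @param sigma_co,sigma_bi noise scales (defaults 0.3, 0.4).
#' @param k BSLR subset size (default 2: with a single condition and six
#'   times the printed degrees of freedom `C(T-1) - k - 2` require
#'   `k <= 2` for the averaged variant).
#' @param alpha tear-down significance level (default 0.5).
#' @param dt Euler step.
#' @param hoeffding_level significance level of the Hoeffding bound
#'   (default 0.05).
#' @return Data frame with one row per regime: `sampling`, `averaging`,
#'   mean `fdr`, `fnr`, `fpr` (undefined replication losses dropped, with
#'   counts in `n_fdr`, `n_fnr`, `n_fpr`) and the Hoeffding `half_width`.
#' @export
clock_benchmark <- function(n_reps = 1000, seed = 1, params = locke_params(),
                             C = 1, R = 3, times = seq(0, 10, by = 2),
                             sigma_co = 0.3, sigma_bi = 0.4,
                             k = 2, alpha = 0.5, dt = 0.01,
                             hoeffding_level = 0.05) {
  truth <- ground_truth_graph(params)
  init <- clock_burn_in(params, dt = dt)
  Tn <- length(times)
  regimes <- expand.grid(sampling = c("one_shot", "multi_shot"),
                         averaging = c(TRUE, FALSE),
                         stringsAsFactors = FALSE)
  acc <- array(NA_real_, dim = c(nrow(regimes), n_reps, 3),
               dimnames = list(NULL, NULL, c("fdr", "fnr", "fpr")))
  for (rep_i in seq_len(n_reps)) {
    for (mode in c("one_shot", "multi_shot")) {
      d <- design_spec(C, R, Tn, sampling = mode)
      Y <- simulate_clock(params, d, times = times, sigma_co = sigma_co,
                          sigma_bi = sigma_bi, dt = dt,
                          seed = derive_seed(seed, rep_i), init = init)
      for (avg in c(TRUE, FALSE)) {
        ridx <- which(regimes$sampling == mode & regimes$averaging == avg)
        est <- bslr(Y, k = k, alpha = alpha, replicate_averaging = avg)
        l <- ternary_losses(truth, est)
        acc[ridx, rep_i, ] <- c(l$fdr, l$fnr, l$fpr)
      }
    }
  }
  half_width <- sqrt(log(2 / hoeffding_level) / (2 * n_reps))
  out <- regimes
  for (loss in c("fdr", "fnr", "fpr")) {
    out[[loss]] <- apply(acc[, , loss, drop = FALSE], 1, mean, na.rm = TRUE)
    out[[paste0("n_", loss)]] <- apply(acc[, , loss, drop = FALSE], 1,
                                       function(v) sum(!is.na(v)))
  }
  out$half_width <- half_width
  out
}
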