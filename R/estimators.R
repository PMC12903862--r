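#' Reduced-potential matrix over alchemical states
#'
#' The estimator input: `u_kn[k, n]` is the reduced potential of pooled
#' sample n evaluated in state k; `N_k[k]` counts how many of the pooled
#' samples were drawn from state k.
#'
#' @param u_kn K x N numeric matrix of reduced potentials
#' @param N_k integer vector of per-state sample counts, `sum(N_k) == N`
#' @return an object of class `reduced_potential_matrix`
#' @export
reduced_potential_matrix <- function(u_kn, N_k) {
  u_kn <- as.matrix(u_kn)
  K <- nrow(u_kn)
  if (K < 2L) stop("need at least 2 states")
  if (!all(is.finite(u_kn))) stop("u_kn contains non-finite entries")
  N_k <- as.integer(round(N_k))
  if (length(N_k) != K) stop("N_k length must equal the number of states")
  if (any(N_k < 0L)) stop("N_k must be non-negative")
  if (sum(N_k) == 0L) stop("at least one state must contribute samples")
  if (sum(N_k) != ncol(u_kn)) stop("sum(N_k) must equal ncol(u_kn)")
  structure(list(u_kn = u_kn, N_k = N_k), class = "reduced_potential_matrix")
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Per-state free energies and diagnostics
#'
#' @param f_k per-state reduced free energies, gauge `f_k[1] == 0`
#' @param dG end-to-end free energy (energy units; reduced if `kT = 1`)
#' @param dG_err statistical uncertainty of `dG`
#' @param diagnostics list of diagnostics (overlap matrix, equilibration
#'   indices, statistical inefficiencies, effective sample counts, ...)
#' @return an object of class `free_energy_result`
#' @export
free_energy_result <- function(f_k, dG, dG_err, diagnostics = list()) {
  stopifnot(abs(f_k[1]) < 1e-12, dG_err >= 0)
  structure(list(f_k = f_k, dG = dG, dG_err = dG_err,
                 diagnostics = diagnostics),
            class = "free_energy_result")
}

#' @export
print.free_energy_result <- function(x, ...) {
  cat(sprintf("free_energy_result: dG = %.4f +/- %.4f (%d states)\n",
              x$dG, x$dG_err, length(x$f_k)))
  invisible(x)
}

#' Statistical inefficiency of a correlated time series
#'
#' g = 1 + 2 sum_t C(t) (1 - t/T), with the normalised autocorrelation C(t)
#' truncated at its first non-positive value. g >= 1; independent samples
#' give g ~ 1, and the effective sample count of a series is T/g.
#'
#' @param series numeric time series, length >= 4
#' @return statistical inefficiency g (>= 1). A zero-variance series returns
#'   g = 1 with attribute `degenerate = TRUE`.
#' @export
statistical_inefficiency <- function(series) {
  x <- as.numeric(series)
  T <- length(x)
  if (T < 4L) stop("series too short (need >= 4 points)")
  v <- stats::var(x) * (T - 1) / T
  if (v <= .Machine$double.eps * max(1, mean(x)^2))
    return(structure(1, degenerate = TRUE))
  xc <- x - mean(x)
  # autocovariance via FFT (biased normalisation)
  m <- 2^ceiling(log2(2 * T))
  s <- stats::fft(c(xc, rep(0, m - T)))
  ac <- Re(stats::fft(s * Conj(s), inverse = TRUE))[1:T] / m
  ac <- ac / ac[1]
  g <- 1
  for (t in seq_len(T - 1L)) {
    if (ac[t + 1L] <= 0) break
    g <- g + 2 * ac[t + 1L] * (1 - t / T)
  }
  max(1, g)
}

#' Automated equilibration detection
#'
#' Scans candidate truncation points t0, computes the statistical
#' inefficiency g of the remaining series, and returns the truncation that
#' maximises the effective sample count Neff = (T - t0) / g (ties broken
#' towards smaller t0). This discards the initial transient in the way that
#' maximises the information retained.
#'
#' @param series numeric time series, length >= 10
#' @param max_points cap on the number of candidate truncation points
#'   scanned (every sample for short series, strided beyond)
#' @return list with `t0` (number of leading samples to discard), `g`
#'   (statistical inefficiency of the retained series) and `Neff`
#' @export
detect_equilibration <- function(series, max_points = 1000L) {
  x <- as.numeric(series)
  T <- length(x)
  if (T < 10L) stop("series too short (need >= 10 points)")
  cand <- unique(round(seq(0L, T - 5L,
                           length.out = min(max_points, T - 4L))))
  best <- list(t0 = 0L, g = Inf, Neff = -Inf)
  for (t0 in cand) {
    g <- statistical_inefficiency(x[(t0 + 1L):T])
    neff <- (T - t0) / g
    if (neff > best$Neff + 1e-12) best <- list(t0 = t0, g = as.numeric(g),
                                               Neff = neff)
  }
  best
}

#' Thermodynamic integration over a lambda schedule
#'
#' Trapezoidal quadrature of the ensemble-averaged Hamiltonian derivative
#' dH/dlambda over lambda, with errors propagated assuming independent
#' windows.
#'
#' @param dudl_means per-window ensemble averages of dH/dlambda
#' @param lambdas lambda nodes, strictly monotone in \[0, 1\], >= 2 nodes
#' @param dudl_errs per-window standard errors (default 0)
#' @return a [free_energy_result()]; `dG` is in the units of `dudl_means`
#' @export
ti_estimate <- function(dudl_means, lambdas, dudl_errs = 0) {
  y <- as.numeric(dudl_means); l <- as.numeric(lambdas)
  if (length(l) < 2L) stop("need at least 2 lambda nodes")
  if (length(y) != length(l)) stop("dudl_means and lambdas lengths differ")
  d <- diff(l)
  if (!(all(d > 0) || all(d < 0))) stop("lambda nodes must be sorted")
  if (length(dudl_errs) == 1L) dudl_errs <- rep(dudl_errs, length(l))
  K <- length(l)
  w <- numeric(K)
  w[1] <- d[1] / 2; w[K] <- d[K - 1L] / 2
  if (K > 2L) w[2:(K - 1L)] <- (d[-(K - 1L)] + d[-1]) / 2
  dG <- sum(w * y)
  err <- sqrt(sum((w * dudl_errs)^2))
  free_energy_result(f_k = c(0, cumsum(diff(l) * (y[-K] + y[-1]) / 2)),
                     dG = dG, dG_err = err,
                     diagnostics = list(lambdas = l, dudl = y))
}

#' Bennett acceptance ratio from forward and reverse work samples
#'
#' Solves the self-consistent Bennett equation
#' sum_F 1/(1 + exp(M + w_F - df)) = sum_R 1/(1 + exp(-M + w_R + df)),
#' with M = ln(n_F / n_R), for the reduced free-energy difference df between
#' the two states bracketing the work measurements.
#'
#' @param w_F forward reduced work samples (state 0 -> 1)
#' @param w_R reverse reduced work samples (state 1 -> 0)
#' @param tol convergence tolerance on the implicit equation root
#' @return list with `df` (reduced free energy difference), `err`
#'   (asymptotic standard error) and `overlap_warning` (TRUE when the work
#'   distributions barely overlap and the uncertainty is unreliable)
#' @export
bar_estimate <- function(w_F, w_R, tol = 1e-10) {
  w_F <- as.numeric(w_F); w_R <- as.numeric(w_R)
  if (!length(w_F) || !length(w_R)) stop("both work arrays must be non-empty")
  nF <- length(w_F); nR <- length(w_R)
  M <- log(nF / nR)
  fermi <- function(x) 1 / (1 + exp(x))
  phi <- function(df) sum(fermi(M + w_F - df)) - sum(fermi(-M + w_R + df))
  lo <- -abs(mean(w_F)) - abs(mean(w_R)) - 50
  hi <- -lo
  while (phi(lo) > 0) lo <- lo * 2 - 1
  while (phi(hi) < 0) hi <- hi * 2 + 1
  df <- stats::uniroot(phi, c(lo, hi), tol = tol)$root
  fF <- fermi(M + w_F - df)
  fR <- fermi(-M + w_R + df)
  var <- (mean(fF^2) / mean(fF)^2 - 1) / nF +
         (mean(fR^2) / mean(fR)^2 - 1) / nR
  warn <- !is.finite(var) || var > 25 || mean(fF) < 1e-10 || mean(fR) < 1e-10
  if (warn) warning("work distributions barely overlap; ",
                    "BAR uncertainty is unreliable")
  list(df = df, err = sqrt(max(var, 0)), overlap_warning = warn)
}

# MBAR sample weights W_nk given converged f_k: W_nk = exp(f_k - u_kn - d_n)
# with d_n = log sum_l N_l exp(f_l - u_ln).  Rows satisfy sum_k N_k W_nk = 1,
# columns sum_n W_nk = 1.
mbar_weights <- function(u_kn, N_k, f_k) {
  K <- nrow(u_kn); N <- ncol(u_kn)
  act <- which(N_k > 0L)
  lg <- log(N_k[act])
  A <- sweep(-u_kn[act, , drop = FALSE], 1L, f_k[act] + lg, `+`)
  mx <- apply(A, 2L, max)
  d_n <- mx + log(colSums(exp(sweep(A, 2L, mx, `-`))))
  W <- exp(sweep(sweep(-u_kn, 2L, d_n, `-`), 1L, f_k, `+`))
  list(W = t(W), d_n = d_n)  # W returned N x K
}

mbar_solve <- function(u_kn, N_k, tol = 1e-12, max_sc = 2000L) {
  K <- nrow(u_kn)
  act <- which(N_k > 0L)
  f <- numeric(K)
  lgN <- log(N_k[act])
  update <- function(f) {
    A <- sweep(-u_kn[act, , drop = FALSE], 1L, f[act] + lgN, `+`)
    mx <- apply(A, 2L, max)
    d_n <- mx + log(colSums(exp(sweep(A, 2L, mx, `-`))))
    B <- sweep(-u_kn, 2L, d_n, `-`)
    fn <- -apply(B, 1L, logsumexp)
    fn - fn[1]
  }
  # self-consistent iteration to get close
  for (it in seq_len(200L)) {
    fn <- update(f)
    if (max(abs(fn - f)) < 1e-8) { f <- fn; break }
    f <- fn
  }
  # Newton polish on the active states (f[act][1] gauge-fixed)
  free <- act[act != act[1]]
  for (it in seq_len(max_sc)) {
    w <- mbar_weights(u_kn, N_k, f)$W
    colsum <- colSums(w)
    grad <- N_k * (colsum - 1)
    if (max(abs(colsum[act] - 1)) < tol) break
    Wa <- w[, free, drop = FALSE] * rep(N_k[free], each = nrow(w))
    H <- -(t(Wa) %*% Wa)
    diag(H) <- diag(H) + N_k[free] * colsum[free]
    step <- tryCatch(solve(H, grad[free]), error = function(e) NULL)
    if (is.null(step)) { f <- update(f); next }
    fnew <- f
    fnew[free] <- f[free] - step
    fnew <- fnew - fnew[1]
    # fall back to self-consistent update if Newton overshoots
    wn <- mbar_weights(u_kn, N_k, fnew)$W
    if (max(abs(colSums(wn)[act] - 1)) < max(abs(colsum[act] - 1)) ||
        max(abs(step)) < 1e-13) f <- fnew else f <- update(f)
  }
  # free energies of unsampled (perturbative) states from the final weights
  if (length(act) < K) f <- update(f)
  f - f[1]
}

# Asymptotic covariance of the reduced free energies from the weight matrix
# (SVD form of the standard MBAR estimator covariance).
mbar_covariance <- function(W, N_k) {
  sv <- svd(W)
  S <- diag(sv$d, length(sv$d))
  Ndiag <- diag(as.numeric(N_k), length(N_k))
  M <- diag(1, length(sv$d)) - S %*% t(sv$v) %*% Ndiag %*% sv$v %*% S
  # pseudo-inverse of M
  msv <- svd(M)
  pos <- msv$d > max(msv$d) * 1e-12
  Minv <- msv$v[, pos, drop = FALSE] %*%
    diag(1 / msv$d[pos], sum(pos)) %*% t(msv$u[, pos, drop = FALSE])
  sv$v %*% S %*% Minv %*% S %*% t(sv$v)
}

#' Multistate Bennett acceptance ratio (MBAR)
#'
#' Solves the MBAR self-consistency equations for the per-state reduced free
#' energies (self-consistent iteration polished by a Newton stage), reports
#' the asymptotic covariance and the state-overlap matrix. States with
#' `N_k = 0` are treated perturbatively. The gauge is `f_k[1] = 0`.
#'
#' @param m a [reduced_potential_matrix()]
#' @param kT thermal energy used to convert the end-to-end reduced free
#'   energy difference into `dG` (default 1: `dG` in reduced units)
#' @return a [free_energy_result()]; `dG = kT * (f_k[K] - f_k[1])`
#' @export
mbar_estimate <- function(m, kT = 1) {
  stopifnot(inherits(m, "reduced_potential_matrix"))
  u_kn <- m$u_kn; N_k <- m$N_k
  K <- nrow(u_kn)
  f <- mbar_solve(u_kn, N_k)
  W <- mbar_weights(u_kn, N_k, f)$W
  theta <- mbar_covariance(W, N_k)
  dvar <- theta[1, 1] + theta[K, K] - 2 * theta[1, K]
  O <- overlap_matrix(m, f)
  free_energy_result(
    f_k = f,
    dG = kT * (f[K] - f[1]),
    dG_err = kT * sqrt(max(dvar, 0)),
    diagnostics = list(theta = theta, overlap = O, N_k = N_k))
}

#' MBAR state-overlap matrix
#'
#' O_ij = sum_n W_ni W_nj N_j; rows sum to 1. Off-diagonal mass measures the
#' phase-space overlap between states; the spectral gap of O is a
#' connectivity diagnostic (a gap near 0 flags disconnected blocks).
#'
#' @param m a [reduced_potential_matrix()]
#' @param f_k converged reduced free energies (from [mbar_estimate()])
#' @return K x K row-stochastic matrix with attribute `eigen_gap`
#' @export
overlap_matrix <- function(m, f_k) {
  stopifnot(inherits(m, "reduced_potential_matrix"))
  W <- mbar_weights(m$u_kn, m$N_k, f_k)$W
  O <- t(W) %*% (W * rep(as.numeric(m$N_k), each = nrow(W)))
  ev <- sort(abs(eigen(O, only.values = TRUE)$values), decreasing = TRUE)
  attr(O, "eigen_gap") <- if (length(ev) > 1L) ev[1] - ev[2] else NA_real_
  O
}

#' Octanol/water partition coefficient from two solvation legs
#'
#' log P = (dG_hyd - dG_oct) / (2.303 R T), with R = 1.9872e-3
#' kcal/(mol K).
#'
#' @param dG_hyd hydration (water-leg) solvation free energy (kcal/mol)
#' @param dG_oct octanol-leg solvation free energy (kcal/mol)
#' @param temperature temperature (K)
#' @return log P (dimensionless, base 10)
#' @export
log_p <- function(dG_hyd, dG_oct, temperature = 298.15) {
  stopifnot(temperature > 0)
  (dG_hyd - dG_oct) / (2.303 * kB_kcal * temperature)
}

#' Write a reduced-potential matrix as delimited text plus JSON sidecar
#'
#' The matrix is stored at full double precision (17 significant digits), so
#' a read-back reproduces the estimate bit-for-bit. The sidecar records K,
#' N_k and any thermodynamic metadata supplied.
#'
#' @param m a [reduced_potential_matrix()]
#' @param path output path for the matrix (sidecar gets `.json` appended)
#' @param meta named list of extra metadata (temperature, pressure, lambdas)
#' @return `path`, invisibly
#' @export
write_ukn <- function(m, path, meta = list()) {
  stopifnot(inherits(m, "reduced_potential_matrix"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  lines <- apply(m$u_kn, 1L, function(row)
    paste(sprintf("%.17g", row), collapse = "\t"))
  writeLines(lines, path)
  side <- c(list(K = nrow(m$u_kn), N = ncol(m$u_kn), N_k = m$N_k), meta)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a reduced-potential matrix written by [write_ukn()]
#'
#' @param path matrix path (expects sidecar at `paste0(path, ".json")`)
#' @return list with `matrix` (a [reduced_potential_matrix()]) and `meta`
#'   (the sidecar contents)
#' @export
read_ukn <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  u <- as.matrix(utils::read.table(path, sep = "\t"))
  dimnames(u) <- NULL
  m <- reduced_potential_matrix(u, side$N_k)
  list(matrix = m, meta = side)
}
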