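#' Atomic configuration with an alchemical solute partition
#'
#' The unit of all energy evaluations: positions, periodic box (or none for
#' gas phase), per-atom species labels, the set of solute atoms being
#' alchemically decoupled, and the coupling parameter lambda.
#'
#' @param positions N x 3 matrix of coordinates (Angstrom, or reduced)
#' @param species character vector of per-atom element labels
#' @param solute integer indices (1-based) of the solute atoms
#' @param lambda coupling parameter in \[0, 1\]; 1 = fully coupled
#' @param box 3 x 3 matrix of lattice vectors (rows), or a length-3 vector
#'   for an orthorhombic box, or `NULL` for gas phase
#' @param velocities optional N x 3 velocity matrix
#' @param masses per-atom masses (default 1)
#' @return an object of class `alchemical_system`
#' @export
alchemical_system <- function(positions, species = rep("X", nrow(positions)),
                              solute = integer(0), lambda = 1, box = NULL,
                              velocities = NULL, masses = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L) stop("positions must be N x 3")
  n <- nrow(positions)
  if (length(species) != n) stop("species length must match atom count")
  solute <- as.integer(solute)
  if (length(solute) && (min(solute) < 1L || max(solute) > n))
    stop("solute indices out of range 1..", n)
  if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]")
  if (!is.null(box)) {
    if (is.vector(box) && length(box) == 3L) box <- diag(box)
    box <- as.matrix(box)
    if (!all(dim(box) == c(3L, 3L))) stop("box must be 3 x 3 or length 3")
  }
  if (is.null(masses)) masses <- rep(1, n)
  structure(list(positions = positions, species = as.character(species),
                 solute = solute, lambda = lambda, box = box,
                 velocities = velocities, masses = masses),
            class = "alchemical_system")
}

#' @export
print.alchemical_system <- function(x, ...) {
  cat(sprintf("alchemical_system: %d atoms (%d solute), lambda = %.3f, %s\n",
              nrow(x$positions), length(x$solute), x$lambda,
              if (is.null(x$box)) "gas phase" else "periodic"))
  invisible(x)
}

system_volume <- function(system) {
  if (is.null(system$box)) stop("gas-phase system has no volume")
  abs(det(system$box))
}

is_solute <- function(system) {
  s <- logical(nrow(system$positions)); s[system$solute] <- TRUE; s
}

#' Alchemical scaling factors for graph edges
#'
#' Edges crossing the solute/solvent boundary are scaled by lambda; all
#' other edges (solute-solute, solvent-solvent) are left at 1. This is the
#' rule that decouples two-body features between the solute and its
#' environment while leaving both subsystems internally intact.
#'
#' @param system an [alchemical_system()]
#' @param edges m x 2 integer matrix of atom index pairs
#' @return numeric vector of per-edge factors alpha_ij
#' @export
edge_scaling_factors <- function(system, edges) {
  edges <- matrix(as.integer(edges), ncol = 2L)
  n <- nrow(system$positions)
  if (nrow(edges) && (min(edges) < 1L || max(edges) > n))
    stop("edge endpoints out of range 1..", n)
  sol <- is_solute(system)
  cross <- xor(sol[edges[, 1L]], sol[edges[, 2L]])
  ifelse(cross, system$lambda, 1)
}

#' Lennard-Jones and Beutler softcore parameters
#'
#' Defaults follow the original Beutler parametrisation alpha_LJ = 0.5,
#' n = 4, m = 2.
#'
#' @param epsilon well depth (energy units), > 0
#' @param sigma radius (length units), > 0
#' @param alpha_lj softcore strength, >= 0
#' @param m,n softcore exponents, >= 1
#' @return an object of class `lj_params`
#' @export
lj_params <- function(epsilon = 1, sigma = 1, alpha_lj = 0.5, m = 2, n = 4) {
  stopifnot(epsilon > 0, sigma > 0, alpha_lj >= 0, m >= 1, n >= 1)
  structure(list(epsilon = epsilon, sigma = sigma, alpha_lj = alpha_lj,
                 m = m, n = n), class = "lj_params")
}

#' Beutler softcore Lennard-Jones energy
#'
#' U(lambda, r) = 4 eps lambda^n \[ (alpha_LJ (1-lambda)^m + (r/sigma)^6)^-2 -
#' (alpha_LJ (1-lambda)^m + (r/sigma)^6)^-1 \], which stays finite as r -> 0
#' for any lambda < 1 and reduces exactly to the standard Lennard-Jones
#' potential at lambda = 1.
#'
#' @param r separation, >= 0; vectorised
#' @param lambda coupling parameter in \[0, 1\]
#' @param params an [lj_params()]
#' @return softcore energies (units of epsilon)
#' @export
beutler_softcore_lj <- function(r, lambda, params = lj_params()) {
  stopifnot(inherits(params, "lj_params"), lambda >= 0, lambda <= 1)
  r <- as.numeric(r)
  if (any(r < 0)) stop("separations must be non-negative")
  if (lambda == 1 && any(r == 0))
    stop("singular evaluation: r = 0 at lambda = 1")
  s <- params$alpha_lj * (1 - lambda)^params$m + (r / params$sigma)^6
  4 * params$epsilon * lambda^params$n * (s^-2 - s^-1)
}

# dU/dr of the Beutler softcore LJ (for analytic forces)
beutler_softcore_lj_dr <- function(r, lambda, params) {
  s <- params$alpha_lj * (1 - lambda)^params$m + (r / params$sigma)^6
  4 * params$epsilon * lambda^params$n * (-2 * s^-3 + s^-2) *
    6 * r^5 / params$sigma^6
}

#' Linear mixing of two Hamiltonians
#'
#' Builds H(x, lambda) = lambda H1(x) + (1 - lambda) H0(x). The returned
#' function takes a configuration and evaluates the mixed energy; its
#' `"dudl"` attribute evaluates dH/dlambda = H1(x) - H0(x).
#'
#' @param u0,u1 energy functions of a configuration at the two end states
#' @param lambda mixing parameter in \[0, 1\]
#' @return the mixed energy function with attribute `dudl`
#' @export
linear_hamiltonian <- function(u0, u1, lambda) {
  stopifnot(is.function(u0), is.function(u1), lambda >= 0, lambda <= 1)
  f <- function(x) lambda * u1(x) + (1 - lambda) * u0(x)
  attr(f, "dudl") <- function(x) u1(x) - u0(x)
  f
}

# ---------------------------------------------------------------------------
# Model interface: every potential implements potential_energy(); forces fall
# back to central finite differences unless a model provides them analytically.

#' Potential energy of a system under a model
#'
#' @param model a potential model object
#' @param system an [alchemical_system()]
#' @return potential energy (model units)
#' @export
potential_energy <- function(model, system) UseMethod("potential_energy")

#' Forces on all atoms under a model
#'
#' @param model a potential model object
#' @param system an [alchemical_system()]
#' @param h finite-difference step for the default numerical method
#' @return N x 3 matrix of forces, F = -grad E
#' @export
potential_forces <- function(model, system, h = 1e-5)
  UseMethod("potential_forces")

#' @export
potential_forces.default <- function(model, system, h = 1e-5) {
  x <- system$positions
  f <- matrix(0, nrow(x), 3L)
  s <- system
  for (i in seq_len(nrow(x))) for (d in 1:3) {
    s$positions <- x; s$positions[i, d] <- x[i, d] + h
    ep <- potential_energy(model, s)
    s$positions[i, d] <- x[i, d] - h
    em <- potential_energy(model, s)
    f[i, d] <- -(ep - em) / (2 * h)
  }
  f
}

# Minimum-image pair displacements for an orthorhombic box (diagonal lattice).
# Returns list(d = distances, dx = m x 3 displacement matrix) for given pairs.
pair_displacements <- function(positions, pairs, box = NULL) {
  dx <- positions[pairs[, 2L], , drop = FALSE] -
    positions[pairs[, 1L], , drop = FALSE]
  if (!is.null(box)) {
    L <- diag(box)
    for (d in 1:3) dx[, d] <- dx[, d] - L[d] * round(dx[, d] / L[d])
  }
  list(dx = dx, d = sqrt(rowSums(dx^2)))
}

.pair_cache <- new.env(parent = emptyenv())

all_pairs <- function(n) {
  if (n < 2L) return(matrix(integer(0), 0L, 2L))
  key <- as.character(n)
  if (!is.null(.pair_cache[[key]])) return(.pair_cache[[key]])
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(k) (k + 1L):n))
  .pair_cache[[key]] <- cbind(i, j, deparse.level = 0L)
  .pair_cache[[key]]
}

check_box_cutoff <- function(system, cutoff) {
  if (is.null(system$box)) return(invisible(TRUE))
  L <- diag(system$box)
  if (any(abs(system$box[upper.tri(system$box) | lower.tri(system$box)]) > 1e-12))
    stop("only orthorhombic boxes are supported")
  if (min(L) < 2 * cutoff)
    stop("minimum box dimension ", signif(min(L), 6),
         " violates the minimum image convention for cutoff ", cutoff)
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# Simple models used as fixtures and oracles

#' Ideal-gas model (no interactions)
#'
#' @param kB Boltzmann constant in model units
#' @return model object
#' @export
ideal_gas_model <- function(kB = 1) {
  structure(list(kB = kB, cutoff = 0), class = c("ideal_gas_model"))
}

#' @export
potential_energy.ideal_gas_model <- function(model, system) 0

#' @export
potential_forces.ideal_gas_model <- function(model, system, h = 1e-5)
  matrix(0, nrow(system$positions), 3L)

#' Tethered-particle harmonic model with lambda-interpolated spring constant
#'
#' E = 1/2 k(lambda) |x - x0|^2 summed over atoms, with k(lambda) linearly
#' interpolated between `k0` (lambda = 0) and `k1` (lambda = 1). The free
#' energy of the 0 -> 1 leg is (d/2) kB T ln(k1/k0) per atom in d dimensions,
#' the closed-form oracle used throughout the tests.
#'
#' @param k0,k1 spring constants at the two end states, > 0
#' @param x0 tether centre (length-3)
#' @param kB Boltzmann constant in model units
#' @return model object
#' @export
harmonic_model <- function(k0, k1, x0 = c(0, 0, 0), kB = 1) {
  stopifnot(k0 > 0, k1 > 0)
  structure(list(k0 = k0, k1 = k1, x0 = x0, kB = kB, cutoff = 0),
            class = "harmonic_model")
}

harmonic_k <- function(model, lambda) (1 - lambda) * model$k0 + lambda * model$k1

#' @export
potential_energy.harmonic_model <- function(model, system) {
  k <- harmonic_k(model, system$lambda)
  dx <- sweep(system$positions, 2L, model$x0)
  0.5 * k * sum(dx^2)
}

#' @export
potential_forces.harmonic_model <- function(model, system, h = 1e-5) {
  k <- harmonic_k(model, system$lambda)
  -k * sweep(system$positions, 2L, model$x0)
}

#' Alchemical Lennard-Jones fluid
#'
#' Solvent-solvent pairs interact through a truncated-and-shifted
#' Lennard-Jones potential; solute-solvent pairs through the Beutler
#' softcore form at the system's lambda (also truncated and shifted), so the
#' solute decouples smoothly as lambda -> 0. Reduced units (epsilon = sigma
#' = kB = 1 by default).
#'
#' @param epsilon,sigma Lennard-Jones parameters
#' @param cutoff interaction cutoff (default 2.5 sigma)
#' @param softcore an [lj_params()] carrying the softcore constants
#' @param kB Boltzmann constant in model units
#' @return model object
#' @export
lj_fluid_model <- function(epsilon = 1, sigma = 1, cutoff = 2.5 * sigma,
                           softcore = lj_params(epsilon, sigma), kB = 1) {
  structure(list(epsilon = epsilon, sigma = sigma, cutoff = cutoff,
                 softcore = softcore, kB = kB),
            class = "lj_fluid_model")
}

lj_plain <- function(r, epsilon, sigma) {
  sr6 <- (sigma / r)^6
  4 * epsilon * (sr6^2 - sr6)
}

#' @export
potential_energy.lj_fluid_model <- function(model, system) {
  check_box_cutoff(system, model$cutoff)
  n <- nrow(system$positions)
  pairs <- all_pairs(n)
  pd <- pair_displacements(system$positions, pairs, system$box)
  keep <- pd$d < model$cutoff
  if (!any(keep)) return(0)
  d <- pd$d[keep]; pr <- pairs[keep, , drop = FALSE]
  sol <- is_solute(system)
  cross <- xor(sol[pr[, 1L]], sol[pr[, 2L]])
  e <- numeric(length(d))
  if (any(!cross))
    e[!cross] <- lj_plain(d[!cross], model$epsilon, model$sigma) -
      lj_plain(model$cutoff, model$epsilon, model$sigma)
  if (any(cross)) {
    lam <- system$lambda
    e[cross] <- beutler_softcore_lj(d[cross], lam, model$softcore) -
      beutler_softcore_lj(model$cutoff, lam, model$softcore)
  }
  sum(e)
}

#' @export
potential_forces.lj_fluid_model <- function(model, system, h = 1e-5) {
  check_box_cutoff(system, model$cutoff)
  n <- nrow(system$positions)
  pairs <- all_pairs(n)
  pd <- pair_displacements(system$positions, pairs, system$box)
  keep <- pd$d < model$cutoff & pd$d > 0
  f <- matrix(0, n, 3L)
  if (!any(keep)) return(f)
  d <- pd$d[keep]; dx <- pd$dx[keep, , drop = FALSE]
  pr <- pairs[keep, , drop = FALSE]
  sol <- is_solute(system)
  cross <- xor(sol[pr[, 1L]], sol[pr[, 2L]])
  dudr <- numeric(length(d))
  if (any(!cross)) {
    r <- d[!cross]; sr6 <- (model$sigma / r)^6
    dudr[!cross] <- 4 * model$epsilon * (-12 * sr6^2 + 6 * sr6) / r
  }
  if (any(cross))
    dudr[cross] <- beutler_softcore_lj_dr(d[cross], system$lambda,
                                          model$softcore)
  # force on atom j (pair second member) along +dx is -dU/dr * dx/d
  g <- -dudr / d
  fx <- dx * g
  acc_j <- rowsum(fx, pr[, 2L])
  acc_i <- rowsum(fx, pr[, 1L])
  jj <- as.integer(rownames(acc_j)); ii <- as.integer(rownames(acc_i))
  f[jj, ] <- f[jj, ] + acc_j
  f[ii, ] <- f[ii, ] - acc_i
  f
}

# interaction energy of a test particle at `pos` with all existing atoms,
# fully coupled (lambda = 1 LJ); used by Widom insertion
test_particle_energy <- function(model, system, pos) UseMethod("test_particle_energy")

#' @export
test_particle_energy.lj_fluid_model <- function(model, system, pos) {
  dx <- sweep(system$positions, 2L, pos)
  if (!is.null(system$box)) {
    L <- diag(system$box)
    for (d in 1:3) dx[, d] <- dx[, d] - L[d] * round(dx[, d] / L[d])
  }
  r <- sqrt(rowSums(dx^2))
  keep <- r < model$cutoff
  if (!any(keep)) return(0)
  sum(lj_plain(r[keep], model$epsilon, model$sigma) -
        lj_plain(model$cutoff, model$epsilon, model$sigma))
}

#' @export
test_particle_energy.ideal_gas_model <- function(model, system, pos) 0
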