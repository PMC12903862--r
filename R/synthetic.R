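#' Analytic dimer curve with exact callables
#'
#' Generates a tabulated dimer curve from a closed-form pair potential
#' (Lennard-Jones or Morse) together with exact energy, force and
#' force-derivative callables, so softcore fits can be checked against
#' closed-form differentiation rather than finite differences.
#'
#' @param kind `"lj"` or `"morse"`
#' @param params for LJ: `epsilon`, `sigma`; for Morse: `D` (well depth),
#'   `a` (stiffness), `r_e` (equilibrium separation)
#' @param r grid of separations; default covers the wall and the well
#' @param pair pair label
#' @return a [dimer_curve()] with `energy_fn`, `force_fn`, `dforce_fn`
#'   attached
#' @export
analytic_dimer <- function(kind = c("lj", "morse"), params = list(),
                           r = NULL, pair = NULL) {
  kind <- match.arg(kind)
  if (kind == "lj") {
    eps <- params$epsilon %||% 1; sig <- params$sigma %||% 1
    energy <- function(r) 4 * eps * ((sig / r)^12 - (sig / r)^6)
    force <- function(r) 4 * eps * (12 * sig^12 / r^13 - 6 * sig^6 / r^7)
    dforce <- function(r) 4 * eps * (-156 * sig^12 / r^14 + 42 * sig^6 / r^8)
    if (is.null(r)) r <- seq(0.70 * sig, 3 * sig, length.out = 200L)
    if (is.null(pair)) pair <- "LJ-LJ"
  } else {
    D <- params$D %||% 1; a <- params$a %||% 1.5; re <- params$r_e %||% 1.2
    energy <- function(r) D * (1 - exp(-a * (r - re)))^2 - D
    force <- function(r) -2 * D * a * (1 - exp(-a * (r - re))) *
      exp(-a * (r - re))
    dforce <- function(r) -2 * D * a^2 * exp(-a * (r - re)) *
      (2 * exp(-a * (r - re)) - 1)
    if (is.null(r)) r <- seq(re - 0.9 / a, re + 4 / a, length.out = 200L)
    if (is.null(pair)) pair <- "Morse-Morse"
  }
  dimer_curve(pair, r, energy(r), force(r),
              energy_fn = energy, force_fn = force, dforce_fn = dforce)
}

#' Harmonic lambda-family with exact reduced free energies
#'
#' A set of d-dimensional harmonic oscillators, one per window, with spring
#' constants `k`. The exact reduced free energy of window i relative to
#' window 1 is (d/2) ln(k_i / k_1), making this the workhorse oracle for
#' the TI/BAR/MBAR estimators.
#'
#' @param k per-window spring constants (> 0)
#' @param d dimension
#' @param temperature temperature (reduced; kB = 1)
#' @return an object of class `harmonic_family` with element `f_exact`
#' @export
harmonic_family <- function(k, d = 1L, temperature = 1) {
  k <- as.numeric(k)
  stopifnot(all(k > 0), d >= 1L, temperature > 0)
  structure(list(k = k, d = as.integer(d), temperature = temperature,
                 f_exact = (d / 2) * log(k / k[1])),
            class = "harmonic_family")
}

#' Exact Gaussian samples of a harmonic family as a u_kn matrix
#'
#' Draws `n` configurations per window from each window's exact Boltzmann
#' distribution and evaluates every window's reduced Hamiltonian on every
#' sample.
#'
#' @param family a [harmonic_family()]
#' @param n samples per window
#' @param seed RNG seed
#' @return a [reduced_potential_matrix()]
#' @export
sample_harmonic_ukn <- function(family, n, seed = 1L) {
  stopifnot(inherits(family, "harmonic_family"), n >= 1L)
  K <- length(family$k); d <- family$d; kT <- family$temperature
  s <- rng_stream(seed)
  # r2[n] = |x|^2 of sample n, drawn from its window's Gaussian
  r2 <- unlist(lapply(family$k, function(kk) {
    x <- with_stream(s, matrix(stats::rnorm(n * d, sd = sqrt(kT / kk)),
                               n, d))
    rowSums(x^2)
  }))
  u_kn <- outer(family$k, r2, function(kk, rr) 0.5 * kk * rr / kT)
  reduced_potential_matrix(u_kn, rep(n, K))
}

#' Crooks-consistent Gaussian work samples
#'
#' Forward reduced work is N(mu, sigma2); the fluctuation theorem then fixes
#' the reverse-work distribution to N(-(mu - sigma2), sigma2) and the
#' implied free-energy difference to df = mu - sigma2 / 2.
#'
#' @param mu forward work mean (reduced)
#' @param sigma2 forward work variance (reduced)
#' @param n_F,n_R forward and reverse sample counts
#' @param seed RNG seed
#' @return list with `w_F`, `w_R` and the implied `df_exact`
#' @export
gaussian_work_samples <- function(mu, sigma2, n_F, n_R = n_F, seed = 1L) {
  stopifnot(sigma2 >= 0)
  s <- rng_stream(seed)
  w_F <- with_stream(s, stats::rnorm(n_F, mu, sqrt(sigma2)))
  w_R <- with_stream(s, -stats::rnorm(n_R, mu - sigma2, sqrt(sigma2)))
  list(w_F = w_F, w_R = w_R, df_exact = mu - sigma2 / 2)
}

#' Widom test-particle insertion
#'
#' Estimates the excess chemical potential mu_ex = -kB T ln < exp(-beta
#' dU) > by inserting ghost particles at uniform random positions into each
#' frame of an equilibrated fluid trajectory, the independent oracle for the
#' alchemical decoupling pipeline.
#'
#' @param frames list of periodic [alchemical_system()] snapshots (solvent
#'   only)
#' @param model fluid model providing insertion energies
#' @param state a [thermo_state()]
#' @param n_insertions insertions per frame
#' @param stream an [rng_stream()]
#' @return list with `mu_ex`, standard error `se` (over frames, corrected
#'   for frame autocorrelation) and `low_reliability` (TRUE when nearly all
#'   insertions overlap)
#' @export
widom_insertion <- function(frames, model, state, n_insertions = 200L,
                            stream = rng_stream(1L)) {
  stopifnot(length(frames) >= 2L)
  beta <- 1 / (state$kB * state$temperature)
  per_frame <- vapply(frames, function(fr) {
    L <- diag(fr$box)
    pos <- with_stream(stream,
                       matrix(stats::runif(3L * n_insertions), ncol = 3L))
    pos <- sweep(pos, 2L, L, `*`)
    du <- vapply(seq_len(n_insertions), function(i)
      test_particle_energy(model, fr, pos[i, ]), numeric(1))
    mean(exp(-beta * du))
  }, numeric(1))
  mbar_mean <- mean(per_frame)
  low <- mbar_mean < 1e-12
  if (low) warning("nearly all insertions overlap; ",
                   "Widom estimate is unreliable")
  g <- statistical_inefficiency(per_frame)
  n_eff <- max(2, length(per_frame) / as.numeric(g))
  se_mean <- stats::sd(per_frame) / sqrt(n_eff)
  mu_ex <- -log(mbar_mean) / beta
  list(mu_ex = mu_ex, se = se_mean / (beta * mbar_mean),
       low_reliability = low)
}
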