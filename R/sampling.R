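#' Draw Maxwell-Boltzmann velocities for a system
#'
#' @param system an [alchemical_system()]
#' @param temperature temperature (model units)
#' @param stream an [rng_stream()]
#' @param kB Boltzmann constant in model units
#' @return the system with fresh velocities
#' @export
init_velocities <- function(system, temperature, stream, kB = 1) {
  n <- nrow(system$positions)
  sd <- sqrt(kB * temperature / system$masses)
  v <- with_stream(stream, matrix(stats::rnorm(3L * n), n, 3L)) * sd
  system$velocities <- v
  system
}

check_forces_finite <- function(f, system) {
  if (all(is.finite(f))) return(invisible(TRUE))
  bad <- which(!is.finite(rowSums(f)))[1]
  pairs <- all_pairs(nrow(system$positions))
  pd <- pair_displacements(system$positions, pairs, system$box)
  i <- which.min(pd$d)
  stop(sprintf(
    "non-finite force on atom %d; closest pair (%d, %d) at separation %.3g",
    bad, pairs[i, 1], pairs[i, 2], pd$d[i]))
}

#' One BAOAB Langevin dynamics step
#'
#' The BAOAB splitting (kick / drift / Ornstein-Uhlenbeck / drift / kick)
#' gives high configurational accuracy at time steps of the order of 1 fs.
#' Deterministic given the stream state.
#'
#' @param system an [alchemical_system()] with velocities (see
#'   [init_velocities()])
#' @param model potential model
#' @param dt time step (model time units; fs-scale in physical units)
#' @param friction friction coefficient (inverse time units; 1/ps-scale)
#' @param temperature temperature
#' @param stream an [rng_stream()]
#' @param kB Boltzmann constant in model units
#' @param forces optional precomputed forces at the current positions
#' @return the updated system; the forces at the new positions are cached in
#'   attribute `"forces"`
#' @export
langevin_step <- function(system, model, dt, friction, temperature, stream,
                          kB = 1, forces = NULL) {
  if (is.null(system$velocities))
    stop("system has no velocities; call init_velocities() first")
  if (is.null(forces)) forces <- potential_forces(model, system)
  check_forces_finite(forces, system)
  m <- system$masses
  v <- system$velocities + 0.5 * dt * forces / m      # B
  x <- system$positions + 0.5 * dt * v                # A
  c1 <- exp(-friction * dt)                           # O
  c2 <- sqrt((1 - c1^2) * kB * temperature / m)
  xi <- with_stream(stream, matrix(stats::rnorm(length(v)), nrow(v), 3L))
  v <- c1 * v + c2 * xi
  x <- x + 0.5 * dt * v                               # A
  system$positions <- x
  f2 <- potential_forces(model, system)               # B
  check_forces_finite(f2, system)
  system$velocities <- v + 0.5 * dt * f2 / m
  attr(system, "forces") <- f2
  system
}

#' Run several Langevin steps (optionally with the MC barostat)
#'
#' @inheritParams langevin_step
#' @param n_steps number of steps
#' @param state a [thermo_state()]; pressure present and
#'   `barostat_interval > 0` enables isotropic volume moves
#' @param barostat_interval attempt a volume move every this many steps
#' @param max_dV initial maximum volume-change proposal
#' @return list with `system`, the adapted `max_dV` and the barostat
#'   acceptance fraction
#' @export
run_md <- function(system, model, state, n_steps, dt, friction, stream,
                   barostat_interval = 0L, max_dV = NULL) {
  kB <- state$kB
  if (is.null(system$velocities))
    system <- init_velocities(system, state$temperature, stream, kB)
  if (is.null(max_dV) && !is.null(system$box))
    max_dV <- 0.05 * system_volume(system)
  f <- potential_forces(model, system)
  acc <- 0L; att <- 0L
  for (i in seq_len(n_steps)) {
    system <- langevin_step(system, model, dt, friction, state$temperature,
                            stream, kB, forces = f)
    f <- attr(system, "forces")
    if (barostat_interval > 0L && i %% barostat_interval == 0L) {
      mv <- mc_barostat_move(system, model, state, stream, max_dV)
      system <- mv$system
      att <- att + 1L; acc <- acc + mv$accepted
      max_dV <- mv$max_dV
      if (mv$accepted) f <- potential_forces(model, system)
    }
  }
  list(system = system, max_dV = max_dV,
       barostat_acceptance = if (att) acc / att else NA_real_)
}

#' Monte Carlo barostat volume move
#'
#' Proposes an isotropic volume change dV uniform in \[-max_dV, max_dV\],
#' rescales positions and box, and accepts with the Metropolis weight
#' exp(-\[dU + p dV - N kB T ln(V'/V)\] / kB T). `max_dV` is auto-tuned
#' towards ~40% acceptance.
#'
#' @param system periodic [alchemical_system()]
#' @param model potential model
#' @param state a [thermo_state()] carrying a pressure
#' @param stream an [rng_stream()]
#' @param max_dV maximum volume-change proposal
#' @param tune adapt `max_dV` based on acceptance (default TRUE)
#' @return list with `system`, `accepted` (logical) and the updated `max_dV`
#' @export
mc_barostat_move <- function(system, model, state, stream, max_dV,
                             tune = TRUE) {
  if (is.null(system$box)) stop("barostat requires a periodic system")
  if (is.null(state$pressure)) stop("barostat requires a pressure")
  kB <- state$kB
  beta <- 1 / (kB * state$temperature)
  n <- nrow(system$positions)
  V <- system_volume(system)
  dV <- with_stream(stream, stats::runif(1, -max_dV, max_dV))
  Vp <- V + dV
  accepted <- FALSE
  if (Vp > 0) {
    s <- (Vp / V)^(1 / 3)
    cand <- system
    cand$positions <- system$positions * s
    cand$box <- system$box * s
    u0 <- potential_energy(model, system)
    u1 <- potential_energy(model, cand)
    arg <- -beta * (u1 - u0 + state$pressure * state$pv_to_energy * dV) +
      n * log(Vp / V)
    if (dV == 0 || arg >= 0 ||
        with_stream(stream, stats::runif(1)) < exp(arg)) {
      system <- cand
      accepted <- TRUE
    }
  }
  # up 1.03 on accept / down 0.98 on reject equilibrates near 40% acceptance
  if (tune) max_dV <- max_dV * if (accepted) 1.03 else 0.98
  list(system = system, accepted = accepted, max_dV = max_dV)
}

#' Energy minimisation by L-BFGS
#'
#' Steep repulsive walls are handled by clipping the gradient norm and
#' capping the energy passed to the line search, which keeps the Wolfe
#' interpolation well-conditioned when a trial step lands on the wall;
#' convergence is still judged on the true (unclipped) forces.
#'
#' @param system an [alchemical_system()]
#' @param model potential model
#' @param gtol gradient max-norm convergence target
#' @param max_iter iteration cap
#' @param grad_clip line-search gradient-norm clip
#' @return the relaxed system, with attributes `converged`, `energy` and
#'   `iterations`
#' @export
minimize <- function(system, model, gtol = 1e-6, max_iter = 500L,
                     grad_clip = 100) {
  x0 <- as.vector(system$positions)
  s <- system
  e_raw <- function(x) {
    s$positions <- matrix(x, ncol = 3L)
    potential_energy(model, s)
  }
  e0 <- e_raw(x0)
  fn <- function(x) min(e_raw(x), e0 + 1e6)
  gr <- function(x) {
    s$positions <- matrix(x, ncol = 3L)
    g <- -as.vector(potential_forces(model, s))
    nrm <- sqrt(sum(g^2))
    if (is.finite(nrm) && nrm > grad_clip) g <- g * grad_clip / nrm
    g
  }
  if (!is.finite(e0)) stop("non-finite starting energy")
  res <- stats::optim(x0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = max_iter,
                                     pgtol = gtol, factr = 10))
  # keep the better of start and finish (divergent line searches fall back)
  if (!is.finite(res$value) || res$value > e0) {
    res$par <- x0; res$value <- e0
  }
  res$value <- e_raw(res$par)
  system$positions <- matrix(res$par, ncol = 3L)
  gmax <- max(abs(potential_forces(model, system)))
  attr(system, "converged") <- gmax <= max(gtol, 1e-4) ||
    res$convergence == 0
  attr(system, "energy") <- res$value
  attr(system, "iterations") <- res$counts[["function"]]
  system
}

#' Replica ensemble for Hamiltonian replica exchange
#'
#' Each replica holds a configuration and currently occupies one slot of the
#' lambda schedule; swaps exchange thermodynamic states (the lambda values),
#' not coordinates. Swap attempts and the per-iteration state occupancy are
#' recorded for the transition-matrix diagnostic.
#'
#' @param systems list of K [alchemical_system()] configurations
#' @param schedule lambda schedule (strictly monotone, spanning 0 and 1)
#' @param state_template a [thermo_state()] supplying temperature/pressure
#' @return an object of class `replica_ensemble`
#' @export
replica_ensemble <- function(systems, schedule, state_template) {
  K <- length(systems)
  schedule <- as.numeric(schedule)
  if (length(schedule) != K) stop("schedule length must match replica count")
  if (!(all(diff(schedule) > 0) || all(diff(schedule) < 0)))
    stop("lambda schedule must be strictly monotone")
  if (min(schedule) != 0 || max(schedule) != 1)
    stop("lambda schedule must span 0 and 1")
  states <- lapply(schedule, function(l) {
    st <- state_template; st$lambda <- l; st
  })
  for (k in seq_len(K)) systems[[k]]$lambda <- schedule[k]
  structure(list(systems = systems, schedule = schedule, states = states,
                 state_index = seq_len(K),
                 swap_records = data.frame(iteration = integer(0),
                                           i = integer(0), j = integer(0),
                                           accepted = logical(0)),
                 state_history = matrix(seq_len(K), nrow = 1L),
                 iteration = 0L),
            class = "replica_ensemble")
}

replica_reduced_potential <- function(model, system, state) {
  system$lambda <- state$lambda
  u <- potential_energy(model, system)
  vol <- if (!is.null(state$pressure)) system_volume(system) else NULL
  reduced_potential(u, state, vol)
}

#' One replica-exchange sweep
#'
#' Attempts `n_attempts` randomly chosen adjacent-window swaps (state pairs
#' (s, s+1) of the lambda schedule). Each attempt accepts with the Metropolis
#' probability min(1, exp(-Delta)) where Delta = \[u*_i(x_j) + u*_j(x_i)\] -
#' \[u*_i(x_i) + u*_j(x_j)\]; accepted swaps exchange the replicas'
#' thermodynamic states. Many attempts per sweep approximate all-pair
#' mixing.
#'
#' @param ensemble a [replica_ensemble()]
#' @param model potential model
#' @param stream an [rng_stream()] for swap decisions
#' @param n_attempts swap attempts in this sweep (default K)
#' @return the updated ensemble (swap records and state history appended)
#' @export
replica_exchange_sweep <- function(ensemble, model, stream,
                                   n_attempts = NULL) {
  K <- length(ensemble$systems)
  if (is.null(n_attempts)) n_attempts <- K
  ensemble$iteration <- ensemble$iteration + 1L
  recs <- vector("list", n_attempts)
  for (a in seq_len(n_attempts)) {
    si <- with_stream(stream, sample.int(K - 1L, 1L))
    sj <- si + 1L
    ri <- which(ensemble$state_index == si)
    rj <- which(ensemble$state_index == sj)
    xi <- ensemble$systems[[ri]]; xj <- ensemble$systems[[rj]]
    sti <- ensemble$states[[si]]; stj <- ensemble$states[[sj]]
    delta <- replica_reduced_potential(model, xj, sti) +
      replica_reduced_potential(model, xi, stj) -
      replica_reduced_potential(model, xi, sti) -
      replica_reduced_potential(model, xj, stj)
    accept <- delta <= 0 ||
      with_stream(stream, stats::runif(1)) < exp(-delta)
    if (accept) {
      ensemble$state_index[ri] <- sj
      ensemble$state_index[rj] <- si
      ensemble$systems[[ri]]$lambda <- ensemble$schedule[sj]
      ensemble$systems[[rj]]$lambda <- ensemble$schedule[si]
    }
    recs[[a]] <- data.frame(iteration = ensemble$iteration, i = si, j = sj,
                            accepted = accept)
  }
  ensemble$swap_records <- rbind(ensemble$swap_records, do.call(rbind, recs))
  ensemble$state_history <- rbind(ensemble$state_history,
                                  ensemble$state_index)
  ensemble
}

#' Empirical state-transition probability matrix of a replica ensemble
#'
#' Row-stochastic matrix of the frequencies with which a replica occupying
#' lambda state s at one iteration occupies state s' at the next, the
#' standard mixing diagnostic of replica-exchange runs (healthy schedules
#' are at least tridiagonally connected).
#'
#' @param ensemble a [replica_ensemble()] with at least one recorded sweep
#' @return K x K row-stochastic matrix
#' @export
transition_probability_matrix <- function(ensemble) {
  h <- ensemble$state_history
  if (nrow(h) < 2L) stop("need at least one recorded sweep")
  K <- ncol(h)
  counts <- matrix(0, K, K)
  for (t in seq_len(nrow(h) - 1L))
    for (r in seq_len(K))
      counts[h[t, r], h[t + 1L, r]] <- counts[h[t, r], h[t + 1L, r]] + 1
  rs <- rowSums(counts)
  out <- counts / ifelse(rs == 0, 1, rs)
  out[rs == 0, ] <- diag(K)[rs == 0, ]
  out
}
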