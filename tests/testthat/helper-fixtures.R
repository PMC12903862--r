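# Shared fixtures: analytic Lennard-Jones callables (reduced units) and a
# compact harmonic replica-exchange runner used across test files.

lj_energy <- function(r, eps = 1, sig = 1) 4 * eps * ((sig / r)^12 - (sig / r)^6)
lj_force <- function(r, eps = 1, sig = 1)
  4 * eps * (12 * sig^12 / r^13 - 6 * sig^6 / r^7)
lj_dforce <- function(r, eps = 1, sig = 1)
  4 * eps * (-156 * sig^12 / r^14 + 42 * sig^6 / r^8)

# random gas-phase toy system with a solute partition
random_toy_system <- function(n = 6, lambda = 0.5, seed = 1) {
  set.seed(seed)
  pos <- matrix(runif(3 * n, 0, 4), n, 3)
  species <- sample(c("C", "H", "O"), n, replace = TRUE)
  alchemical_system(pos, species, solute = seq_len(max(1, n %/% 3)),
                    lambda = lambda)
}

# run a harmonic-tether REMD ensemble and return it; states are the lambda
# schedule of a k0 -> k1 linear interpolation
run_harmonic_remd <- function(schedule, k0 = 1, k1 = 4, n_iter = 100,
                              steps = 5, dt = 0.08, seed = 1,
                              n_attempts = NULL, temperature = 1) {
  model <- harmonic_model(k0, k1)
  K <- length(schedule)
  seeds <- spawn_seeds(seed, K + 1)
  state0 <- thermo_state(temperature, kB = 1, pv_to_energy = 1)
  base <- alchemical_system(matrix(0, 1, 3), solute = 1)
  systems <- lapply(seq_len(K), function(k)
    init_velocities(base, temperature, rng_stream(seeds[k]), 1))
  ens <- replica_ensemble(systems, schedule, state0)
  streams <- lapply(seeds[seq_len(K)], rng_stream)
  swap_stream <- rng_stream(seeds[K + 1])
  traj <- vector("list", n_iter)
  for (it in seq_len(n_iter)) {
    for (r in seq_len(K)) {
      st <- ens$states[[ens$state_index[r]]]
      ens$systems[[r]] <- run_md(ens$systems[[r]], model, st, steps, dt,
                                 friction = 1, stream = streams[[r]])$system
    }
    # record x-coordinate per state slot
    xs <- numeric(K)
    for (r in seq_len(K)) xs[ens$state_index[r]] <- ens$systems[[r]]$positions[1, 1]
    traj[[it]] <- xs
    if (is.null(n_attempts) || n_attempts > 0)
      ens <- replica_exchange_sweep(ens, model, swap_stream, n_attempts)
    else
      ens$state_history <- rbind(ens$state_history, ens$state_index)
  }
  list(ensemble = ens, x_by_state = do.call(rbind, traj), model = model)
}

# thin a correlated series to near-independence using its statistical
# inefficiency, for KS-type tests
thin_series <- function(x, factor = 2) {
  g <- as.numeric(statistical_inefficiency(x))
  x[unique(round(seq(1, length(x), by = factor * g)))]
}
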