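#' Build a periodic box of solvent around a solute
#'
#' Places solvent particles on a jittered cubic lattice around the solute
#' (at the box centre) at the requested number density. The box side is
#' raised when needed to honour the minimum-image requirement of a model
#' cutoff or an explicit padding request; any raise is logged.
#'
#' @param n_solvent number of solvent particles
#' @param density target number density (particles per volume, reduced)
#' @param solute matrix of solute coordinates (default a single particle),
#'   or `NULL` for a pure solvent box
#' @param seed build seed (deterministic configurations)
#' @param cutoff model cutoff; enforces box side >= 2 * cutoff
#' @param padding requested minimum distance from solute to box edge
#' @param species solvent species label
#' @param solute_species solute species label
#' @param jitter lattice jitter amplitude as a fraction of the spacing
#' @param min_spacing smallest admissible lattice spacing before the build
#'   errors out (overlap guard)
#' @return a periodic [alchemical_system()] with the solute first
#' @export
build_box <- function(n_solvent, density, solute = matrix(0, 1, 3),
                      seed = 1L, cutoff = NULL, padding = NULL,
                      species = "Ar", solute_species = "Xe",
                      jitter = 0.1, min_spacing = 0.9) {
  n_solute <- if (is.null(solute)) 0L else nrow(solute)
  n_total <- n_solvent + n_solute
  side <- (n_total / density)^(1 / 3)
  if (!is.null(cutoff) && side < 2 * cutoff) {
    message("box side raised from ", signif(side, 6), " to ",
            signif(2 * cutoff, 6), " to satisfy the minimum image convention")
    side <- 2 * cutoff
  }
  if (!is.null(padding) && n_solute > 0L) {
    ext <- max(apply(solute, 2L, function(z) diff(range(z))))
    need <- ext + 2 * padding
    if (side < need) {
      message("box side raised from ", signif(side, 6), " to ",
              signif(need, 6), " to satisfy the padding request")
      side <- need
    }
  }
  m <- ceiling(n_total^(1 / 3))
  spacing <- side / m
  if (spacing < min_spacing)
    stop("density too high: lattice spacing ", signif(spacing, 4),
         " below the overlap guard ", min_spacing)
  cells <- as.matrix(expand.grid(x = seq_len(m), y = seq_len(m),
                                 z = seq_len(m))) - 0.5
  cells <- cells * spacing
  centre <- rep(side / 2, 3L)
  ord <- order(rowSums(sweep(cells, 2L, centre)^2))
  cells <- cells[ord, , drop = FALSE]
  s <- rng_stream(seed)
  pos_solute <- if (n_solute > 0L)
    sweep(solute, 2L, colMeans(solute)) + rep(centre, each = n_solute)
  else NULL
  # skip the cells nearest the centre (occupied by the solute)
  cells <- cells[(n_solute + 1L):nrow(cells), , drop = FALSE]
  pick <- cells[seq_len(n_solvent), , drop = FALSE]
  jit <- with_stream(s, matrix(stats::runif(3L * n_solvent, -1, 1),
                               n_solvent, 3L)) * jitter * spacing
  pos <- rbind(pos_solute, pick + jit)
  alchemical_system(pos,
                    species = c(rep(solute_species, n_solute),
                                rep(species, n_solvent)),
                    solute = seq_len(n_solute), lambda = 1,
                    box = diag(rep(side, 3L)))
}

#' Default lambda schedule concentrating windows in the curvature region
#'
#' Monotone schedule from 0 to 1 with about half of the windows inside
#' \[0.15, 0.4\], where the curvature of dH/dlambda is greatest for
#' decoupling transformations; endpoints are exact.
#'
#' @param K number of windows (>= 4), default 16
#' @return numeric vector of K lambda values
#' @export
default_lambda_schedule <- function(K = 16L) {
  K <- as.integer(K)
  if (K < 4L) stop("need at least 4 windows")
  n_mid <- as.integer(ceiling(K / 2))
  n_lo <- max(1L, as.integer(round((K - n_mid) * 0.3)))
  n_hi <- K - n_mid - n_lo
  lows <- seq(0, 0.15, length.out = n_lo + 1L)[seq_len(n_lo)]
  mids <- seq(0.15, 0.4, length.out = n_mid)
  highs <- seq(0.4, 1, length.out = n_hi + 1L)[-1L]
  c(lows, mids, highs)
}

pipeline_defaults <- function() {
  list(
    system = list(kind = "lj_fluid", n_solvent = 32L, density = 0.3),
    model = list(kind = "lj_fluid"),
    schedule = NULL,
    n_windows = 16L,
    state = list(temperature = 2.0, pressure = NULL, kB = 1,
                 pv_to_energy = 1),
    sampler = list(dt = 0.004, friction = 1, steps_per_iteration = 1000L,
                   n_iterations = 100L, equilibration_steps = 2000L,
                   barostat_interval = 25L, swap_attempts = NULL,
                   minimize = TRUE),
    output = list(dir = NULL, trajectories = FALSE),
    seed = 1L)
}

#' Validated run configuration for a solvation leg
#'
#' Merges user settings over the defaults and validates everything at once,
#' reporting every violation in a single error. Protocol defaults mirror the
#' standard replica-exchange solvation protocol (16 windows, swap attempts
#' every 1000 steps of 1 fs-scale dynamics, 1/ps-scale friction, NPT
#' equilibration before production), all configurable.
#'
#' @param ... named settings overriding the defaults: `system`, `model`,
#'   `schedule`, `n_windows`, `state`, `sampler`, `output`, `seed`
#' @return an object of class `run_config`
#' @export
run_config <- function(...) {
  cfg <- utils::modifyList(pipeline_defaults(), list(...))
  errs <- character(0)
  if (is.null(cfg$schedule)) {
    if (cfg$n_windows < 4L) errs <- c(errs, "n_windows must be >= 4")
    else cfg$schedule <- default_lambda_schedule(cfg$n_windows)
  } else {
    sch <- as.numeric(cfg$schedule)
    if (min(sch) != 0 || max(sch) != 1)
      errs <- c(errs, "schedule must include lambda = 0 and lambda = 1")
    if (!(all(diff(sch) > 0) || all(diff(sch) < 0)))
      errs <- c(errs, "schedule must be strictly monotone")
    cfg$schedule <- sch
    cfg$n_windows <- length(sch)
  }
  if (is.null(cfg$state$temperature) || cfg$state$temperature <= 0)
    errs <- c(errs, "state$temperature must be positive")
  sm <- cfg$sampler
  for (f in c("dt", "friction", "steps_per_iteration", "n_iterations"))
    if (is.null(sm[[f]]) || sm[[f]] <= 0)
      errs <- c(errs, paste0("sampler$", f, " must be positive"))
  if (!is.null(cfg$system$path) && !file.exists(cfg$system$path))
    errs <- c(errs, paste0("system$path not resolvable: ", cfg$system$path))
  if (length(errs))
    stop("invalid run configuration:\n  - ",
         paste(errs, collapse = "\n  - "))
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' @param path YAML file with the [run_config()] keys
#' @return a validated `run_config`
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

build_model_from_config <- function(cfg) {
  mc <- cfg$model
  switch(mc$kind,
    lj_fluid = lj_fluid_model(
      epsilon = mc$epsilon %||% 1, sigma = mc$sigma %||% 1,
      cutoff = mc$cutoff %||% 2.5 * (mc$sigma %||% 1),
      softcore = lj_params(mc$epsilon %||% 1, mc$sigma %||% 1),
      kB = cfg$state$kB),
    harmonic = harmonic_model(k0 = mc$k0, k1 = mc$k1,
                              x0 = mc$x0 %||% c(0, 0, 0),
                              kB = cfg$state$kB),
    ideal_gas = ideal_gas_model(kB = cfg$state$kB),
    body_ordered = {
      tbl <- NULL
      if (!is.null(mc$softcore_dir)) {
        files <- list.files(mc$softcore_dir, pattern = "\\.softcore\\.dat$",
                            full.names = TRUE)
        tbl <- lapply(files, read_softcore_curve)
        names(tbl) <- vapply(tbl, `[[`, character(1), "pair")
      }
      body_ordered_model(species = mc$species, cutoff = mc$cutoff %||% 5,
                         seed = mc$seed %||% 1L, pair_table = tbl)
    },
    stop("unknown model kind: ", mc$kind))
}

build_system_from_config <- function(cfg, model) {
  sc <- cfg$system
  switch(sc$kind,
    lj_fluid = build_box(n_solvent = sc$n_solvent, density = sc$density,
                         seed = spawn_seeds(cfg$seed, 1L),
                         cutoff = model$cutoff %||% NULL),
    single_particle = alchemical_system(matrix(sc$x0 %||% c(0, 0, 0), 1, 3),
                                        species = sc$species %||% "X",
                                        solute = 1L, lambda = 1),
    xyz = read_xyz(sc$path, solute = sc$solute %||% integer(0))[[1L]],
    pdb = read_pdb_system(sc$path, solute_resname = sc$solute_resname,
                          solute = sc$solute %||% integer(0)),
    stop("unknown system kind: ", sc$kind))
}

#' Run one alchemical solvation free-energy leg
#'
#' Executes the full protocol: build -> minimize -> NPT/NVT equilibration ->
#' Hamiltonian replica exchange over the lambda schedule -> per-window
#' equilibration detection and decorrelation -> MBAR. The reduced-potential
#' matrix, swap log and report are archived when an output directory is
#' configured, and the reported free energy is reproducible bit-for-bit from
#' the archived matrix via [estimate_from_ukn()].
#'
#' @param config a [run_config()]
#' @return an object of class `solvation_report`: `dG` and `dG_err` (model
#'   energy units; the free energy of coupling, G(lambda = 1) -
#'   G(lambda = 0)), per-window diagnostics, overlap and transition
#'   matrices, and a convergence trace of dG vs simulation time
#' @export
run_solvation_leg <- function(config) {
  stopifnot(inherits(config, "run_config"))
  model <- build_model_from_config(config)
  system <- build_system_from_config(config, model)
  schedule <- config$schedule
  K <- length(schedule)
  st <- config$state
  state0 <- thermo_state(st$temperature, st$pressure, lambda = 1,
                         kB = st$kB, pv_to_energy = st$pv_to_energy %||% 1)
  sm <- config$sampler
  seeds <- spawn_seeds(config$seed, K + 2L)
  eq_stream <- rng_stream(seeds[K + 1L])
  swap_stream <- rng_stream(seeds[K + 2L])

  if (isTRUE(sm$minimize)) system <- minimize(system, model)
  system <- init_velocities(system, st$temperature, eq_stream, st$kB)
  eq <- run_md(system, model, state0, n_steps = sm$equilibration_steps,
               dt = sm$dt, friction = sm$friction, stream = eq_stream,
               barostat_interval = if (is.null(st$pressure)) 0L
                                   else sm$barostat_interval)
  seed_frame <- eq$system

  replicas <- lapply(seq_len(K), function(k) seed_frame)
  ens <- replica_ensemble(replicas, schedule, state0)
  streams <- lapply(seeds[seq_len(K)], rng_stream)
  max_dVs <- rep(list(eq$max_dV), K)

  n_iter <- sm$n_iterations
  u_all <- array(NA_real_, dim = c(K, n_iter, K))  # [state_eval, iter, state_src]
  for (it in seq_len(n_iter)) {
    for (r in seq_len(K)) {
      s_idx <- ens$state_index[r]
      stt <- ens$states[[s_idx]]
      out <- run_md(ens$systems[[r]], model, stt,
                    n_steps = sm$steps_per_iteration, dt = sm$dt,
                    friction = sm$friction, stream = streams[[r]],
                    barostat_interval = if (is.null(st$pressure)) 0L
                                        else sm$barostat_interval,
                    max_dV = max_dVs[[r]])
      ens$systems[[r]] <- out$system
      max_dVs[r] <- list(out$max_dV)
      u_all[, it, s_idx] <- vapply(seq_len(K), function(k)
        replica_reduced_potential(model, out$system, ens$states[[k]]),
        numeric(1))
    }
    ens <- replica_exchange_sweep(ens, model, swap_stream,
                                  n_attempts = sm$swap_attempts %||% K)
  }

  # pool samples grouped by source state
  u_kn <- matrix(NA_real_, K, K * n_iter)
  for (k in seq_len(K))
    u_kn[, ((k - 1L) * n_iter + 1L):(k * n_iter)] <- u_all[, , k]
  m <- reduced_potential_matrix(u_kn, rep(n_iter, K))

  meta <- list(lambdas = schedule, temperature = st$temperature,
               pressure = st$pressure, kB = st$kB, n_per_state = n_iter,
               seed = config$seed)
  ukn_path <- NULL
  if (!is.null(config$output$dir)) {
    dir.create(config$output$dir, recursive = TRUE, showWarnings = FALSE)
    ukn_path <- file.path(config$output$dir, "ukn.tsv")
    write_ukn(m, ukn_path, meta)
    utils::write.table(ens$swap_records,
                       file.path(config$output$dir, "swaps.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (isTRUE(config$output$trajectories))
      write_xyz(ens$systems, file.path(config$output$dir, "final_frames.xyz"))
    # read the archive back so the report is provably reproducible from it
    m <- read_ukn(ukn_path)$matrix
  }

  est <- estimate_ukn_matrix(m, kT = st$kB * st$temperature)
  trace <- dg_convergence_trace(m, n_iter, kT = st$kB * st$temperature)
  report <- structure(list(
    dG = est$dG, dG_err = est$dG_err, f_k = est$f_k,
    windows = est$windows, overlap = est$overlap,
    transition_matrix = transition_probability_matrix(ens),
    trace = trace, schedule = schedule, ukn_path = ukn_path,
    barostat_acceptance = eq$barostat_acceptance,
    mbar_converged = est$converged), class = "solvation_report")
  if (!est$converged) warning("MBAR did not fully converge; report flagged")
  if (!is.null(config$output$dir))
    jsonlite::write_json(
      list(dG = report$dG, dG_err = report$dG_err, schedule = schedule,
           windows = report$windows),
      file.path(config$output$dir, "report.json"),
      auto_unbox = TRUE, digits = NA)
  report
}

#' @export
print.solvation_report <- function(x, ...) {
  cat(sprintf("solvation_report: dG = %.4f +/- %.4f (%d windows)\n",
              x$dG, x$dG_err, length(x$schedule)))
  invisible(x)
}

# equilibration-detect, decorrelate and MBAR a pooled u_kn matrix whose
# samples are grouped by source state in iteration order
estimate_ukn_matrix <- function(m, kT = 1) {
  K <- nrow(m$u_kn)
  N_k <- m$N_k
  offs <- c(0L, cumsum(N_k))
  keep_idx <- integer(0)
  new_Nk <- integer(K)
  windows <- data.frame(state = seq_len(K), t0 = NA_integer_,
                        g = NA_real_, Neff = NA_real_)
  for (k in seq_len(K)) {
    idx <- (offs[k] + 1L):offs[k + 1L]
    series <- m$u_kn[k, idx]             # own-state reduced potential
    eq <- detect_equilibration(series)
    stride <- max(1, eq$g)
    sub <- idx[unique(round(seq(eq$t0 + 1L, length(idx), by = stride)))]
    keep_idx <- c(keep_idx, sub)
    new_Nk[k] <- length(sub)
    windows$t0[k] <- eq$t0; windows$g[k] <- eq$g
    windows$Neff[k] <- length(sub)
  }
  sub_m <- reduced_potential_matrix(m$u_kn[, keep_idx, drop = FALSE], new_Nk)
  est <- mbar_estimate(sub_m, kT = kT)
  W <- mbar_weights(sub_m$u_kn, sub_m$N_k, est$f_k)$W
  converged <- max(abs(colSums(W)[sub_m$N_k > 0] - 1)) < 1e-8
  list(dG = est$dG, dG_err = est$dG_err, f_k = est$f_k,
       overlap = est$diagnostics$overlap, windows = windows,
       converged = converged)
}

dg_convergence_trace <- function(m, n_iter, kT = 1,
                                 fractions = c(0.25, 0.5, 0.75, 1)) {
  K <- nrow(m$u_kn)
  out <- lapply(fractions, function(fr) {
    n <- max(10L, as.integer(round(fr * n_iter)))
    n <- min(n, n_iter)
    idx <- unlist(lapply(seq_len(K), function(k)
      (k - 1L) * n_iter + seq_len(n)))
    mm <- reduced_potential_matrix(m$u_kn[, idx, drop = FALSE], rep(n, K))
    est <- tryCatch(estimate_ukn_matrix(mm, kT = kT),
                    error = function(e) list(dG = NA_real_,
                                             dG_err = NA_real_))
    data.frame(fraction = fr, n_per_state = n, dG = est$dG,
               dG_err = est$dG_err)
  })
  do.call(rbind, out)
}

#' Re-estimate a solvation free energy from an archived u_kn matrix
#'
#' Reads the matrix and sidecar written by [run_solvation_leg()] and reruns
#' equilibration detection, decorrelation and MBAR, reproducing the
#' archived report bit-for-bit.
#'
#' @param path path to the archived matrix (`.../ukn.tsv`), or the output
#'   directory containing it
#' @return list with `dG`, `dG_err`, `f_k`, per-window diagnostics and the
#'   sidecar metadata
#' @export
estimate_from_ukn <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "ukn.tsv")
  archive <- read_ukn(path)
  meta <- archive$meta
  kT <- (meta$kB %||% 1) * meta$temperature
  est <- estimate_ukn_matrix(archive$matrix, kT = kT)
  c(est, list(meta = meta))
}

#' Compute log P from a water-like and an octanol-like solvation leg
#'
#' Runs both legs with the shared solute definition, forms
#' log P = (dG_hyd - dG_oct) / (2.303 kB T) and propagates the two leg
#' uncertainties in quadrature.
#'
#' @param config_water,config_octanol [run_config()] objects for the two
#'   legs; both must share the same solute definition and temperature
#' @return list with `log_p`, `log_p_err` and the two leg reports
#' @export
run_logp <- function(config_water, config_octanol) {
  sol_w <- config_water$system$solute %||% config_water$system$kind
  sol_o <- config_octanol$system$solute %||% config_octanol$system$kind
  if (!identical(sol_w, sol_o))
    stop("the two legs must share the same solute definition")
  rw <- run_solvation_leg(config_water)
  ro <- run_solvation_leg(config_octanol)
  Tw <- config_water$state$temperature
  denom <- 2.303 * config_water$state$kB * Tw
  list(log_p = (rw$dG - ro$dG) / denom,
       log_p_err = sqrt(rw$dG_err^2 + ro$dG_err^2) / denom,
       water = rw, octanol = ro)
}
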