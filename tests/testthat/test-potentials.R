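test_that("edge scaling applies lambda only across the alchemical boundary", {
  sys <- random_toy_system(n = 6, lambda = 0.3)   # solute = atoms 1..2
  edges <- rbind(c(1, 4), c(1, 2), c(3, 5), c(2, 6))
  expect_equal(edge_scaling_factors(sys, edges), c(0.3, 1, 1, 0.3))
  sys$lambda <- 1
  expect_equal(edge_scaling_factors(sys, edges), rep(1, 4))
  expect_error(edge_scaling_factors(sys, rbind(c(1, 9))), "out of range")
})

test_that("Beutler softcore has correct end states and r = 0 value", {
  p <- lj_params(epsilon = 1, sigma = 1, alpha_lj = 0.5, m = 2, n = 4)
  r <- seq(0.8, 2.5, length.out = 40)
  expect_equal(beutler_softcore_lj(r, 1, p), lj_energy(r), tolerance = 1e-14)
  expect_equal(beutler_softcore_lj(1, 1, p), 0)
  expect_equal(beutler_softcore_lj(r, 0, p), rep(0, length(r)))
  # hand evaluation at full overlap, half coupling: inner term 0.5 * 0.25,
  # prefactor 4 * 0.5^4, bracket 64 - 8 -> 14 epsilon
  expect_equal(beutler_softcore_lj(0, 0.5, p), 14)
  p2 <- lj_params(epsilon = 2.5, sigma = 1.1, alpha_lj = 0.5, m = 2, n = 4)
  expect_equal(beutler_softcore_lj(0, 0.5, p2), 14 * 2.5)
  expect_true(all(is.finite(beutler_softcore_lj(c(0, 0.1), 0.99, p))))
  expect_error(beutler_softcore_lj(0, 1, p), "singular")
  expect_error(lj_params(epsilon = -1), "epsilon")
})

test_that("linear Hamiltonian mixing reproduces pointwise mixtures", {
  u0 <- function(x) 0.5 * 1 * x^2
  u1 <- function(x) 0.5 * 4 * x^2
  xs <- seq(-2, 2, length.out = 21)
  for (lam in c(0, 0.25, 0.7, 1)) {
    h <- linear_hamiltonian(u0, u1, lam)
    expect_equal(h(xs), 0.5 * (lam * 4 + (1 - lam) * 1) * xs^2)
    expect_equal(attr(h, "dudl")(xs), u1(xs) - u0(xs))
  }
  expect_identical(linear_hamiltonian(u0, u1, 0)(xs), u0(xs))
  expect_identical(linear_hamiltonian(u0, u1, 1)(xs), u1(xs))
  hd <- linear_hamiltonian(u0, u0, 0.4)
  expect_equal(hd(xs), u0(xs))
  expect_equal(attr(hd, "dudl")(xs), rep(0, length(xs)))
})

test_that("reduced potential implements u/kBT (+ pV/kBT in NPT)", {
  st <- thermo_state(298.15, kB = kB_kcal)
  expect_equal(reduced_potential(0, st), 0)
  expect_equal(reduced_potential(kB_kcal * 298.15, st), 1)
  expect_equal(reduced_potential(1, st), 1 / (0.0019872 * 298.15),
               tolerance = 1e-6)
  stp <- thermo_state(298.15, pressure = 1, kB = kB_kcal)
  v <- 1000
  expect_equal(reduced_potential(1, stp, volume = v),
               (1 + 1 * atm_A3_kcal * v) / (kB_kcal * 298.15))
  expect_error(reduced_potential(1, stp), "volume")
})

test_that("decoupled end state splits into isolated solute and solvent", {
  for (seed in 1:5) {
    sys <- random_toy_system(n = 7, lambda = 0, seed = seed)
    model <- body_ordered_model(c("C", "H", "O"), cutoff = 5, seed = seed)
    nsol <- length(sys$solute)
    solu <- alchemical_system(sys$positions[sys$solute, , drop = FALSE],
                              sys$species[sys$solute],
                              solute = seq_len(nsol), lambda = 0)
    solv_idx <- setdiff(seq_len(nrow(sys$positions)), sys$solute)
    solv <- alchemical_system(sys$positions[solv_idx, , drop = FALSE],
                              sys$species[solv_idx], lambda = 0)
    expect_lt(abs(potential_energy(model, sys) -
                    potential_energy(model, solu) -
                    potential_energy(model, solv)), 1e-8)
  }
})

test_that("fully coupled state equals the unmodified model", {
  sys <- random_toy_system(n = 7, lambda = 1, seed = 3)
  model <- body_ordered_model(c("C", "H", "O"), cutoff = 5, seed = 2)
  plain <- sys
  plain$solute <- integer(0)   # no alchemical boundary at all
  expect_identical(potential_energy(model, sys),
                   potential_energy(model, plain))
})

test_that("two-atom site energies match the hand-expanded readout", {
  # single layer, body orders 1..3: E_i = sum_k c1k A + c2k A^2 + c3k A^3
  # with A_ik = alpha * R_k(r) * fcut(r) * w[species_j, k]
  model <- body_ordered_model(c("A", "B"), cutoff = 4, n_radial = 3,
                              nu_max = 3, n_layers = 1, seed = 11)
  r <- 1.7; lam <- 0.5
  sys <- alchemical_system(rbind(c(0, 0, 0), c(r, 0, 0)),
                           species = c("A", "B"), solute = 1, lambda = lam)
  env <- 0.5 * (cos(pi * r / model$cutoff) + 1)
  Rk <- exp(-(r - model$centers)^2 / (2 * model$width^2)) * env
  A1 <- lam * Rk * model$embedding["B", ]
  A2 <- lam * Rk * model$embedding["A", ]
  e_hand <- sum(model$readout[1, 1, ] * A1 + model$readout[1, 2, ] * A1^2 +
                  model$readout[1, 3, ] * A1^3) +
    sum(model$readout[1, 1, ] * A2 + model$readout[1, 2, ] * A2^2 +
          model$readout[1, 3, ] * A2^3)
  expect_equal(potential_energy(model, sys), e_hand, tolerance = 1e-12)
})

test_that("model energy is invariant under rotation, translation, permutation", {
  sys <- random_toy_system(n = 8, lambda = 0.37, seed = 9)
  model <- body_ordered_model(c("C", "H", "O"), cutoff = 5, seed = 5)
  e0 <- potential_energy(model, sys)
  th <- 0.83
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- sys; rot$positions <- sys$positions %*% R
  expect_equal(potential_energy(model, rot), e0, tolerance = 1e-10)
  tr <- sys; tr$positions <- sweep(sys$positions, 2, c(1.3, -2, 0.4), `+`)
  expect_equal(potential_energy(model, tr), e0, tolerance = 1e-10)
  # permute two solvent atoms of the same species
  sp <- sys$species
  same <- which(duplicated(sp) | duplicated(sp, fromLast = TRUE))
  same <- setdiff(same, sys$solute)
  i <- same[1]; j <- same[which(sp[same] == sp[i])[2]]
  pm <- sys
  pm$positions[c(i, j), ] <- sys$positions[c(j, i), ]
  pm$species[c(i, j)] <- sys$species[c(j, i)]
  expect_equal(potential_energy(model, pm), e0, tolerance = 1e-10)
})

test_that("model energy is smooth in lambda for fixed coordinates", {
  sys <- random_toy_system(n = 6, lambda = 0, seed = 4)
  model <- body_ordered_model(c("C", "H", "O"), cutoff = 5, seed = 7)
  lams <- seq(0, 1, length.out = 101)
  es <- vapply(lams, function(l) { s <- sys; s$lambda <- l
    potential_energy(model, s) }, numeric(1))
  dl <- lams[2] - lams[1]
  dE <- diff(es) / dl               # forward-difference derivative on the grid
  # derivative of a smooth function: successive finite-difference slopes
  # change by O(dl), far below the derivative scale itself
  expect_lt(max(abs(diff(dE))), 50 * dl * max(1, max(abs(dE))))
})

test_that("softcore pair table bounds the energy of overlapping atoms", {
  curve <- analytic_dimer("lj")
  spec <- fit_force_polynomial(curve, select_switch_point(curve, 200))
  model <- body_ordered_model(c("C", "O"), cutoff = 5, seed = 1,
                              pair_table = list("C-O" = spec))
  cap <- softened_energy(spec, 0)
  for (lam in c(0, 0.5, 0.9)) {
    sys <- alchemical_system(rbind(c(0, 0, 0), c(1e-3, 0, 0)),
                             species = c("C", "O"), solute = 1, lambda = lam)
    e <- potential_energy(model, sys)
    expect_true(is.finite(e))
    # pair term is bounded by the softcore cap; the smooth graph term at
    # contact adds only an O(1) feature contribution
    expect_lt(e, cap + 10)
  }
})

test_that("model rejects unknown species and undersized boxes", {
  model <- body_ordered_model(c("C", "H"), cutoff = 5, seed = 1)
  sys <- alchemical_system(matrix(rnorm(6), 2, 3), species = c("C", "Zr"))
  expect_error(potential_energy(model, sys), "species")
  sys2 <- alchemical_system(matrix(runif(6, 0, 3), 2, 3),
                            species = c("C", "H"), box = rep(6, 3))
  expect_error(potential_energy(model, sys2), "minimum image")
})

test_that("forces equal -grad E by central differences", {
  # analytic LJ fluid forces vs the generic numerical fallback
  lj <- lj_fluid_model(cutoff = 1.8)
  sys <- build_box(12, 0.25, seed = 6, cutoff = 1.8)
  f_an <- potential_forces(lj, sys)
  f_num <- alchemfe:::potential_forces.default(lj, sys)
  expect_lt(max(abs(f_an - f_num)), 1e-5)
  # harmonic tether
  hm <- harmonic_model(2, 5)
  s2 <- alchemical_system(matrix(c(0.3, -0.2, 0.5), 1, 3), solute = 1,
                          lambda = 0.4)
  expect_lt(max(abs(potential_forces(hm, s2) -
                      alchemfe:::potential_forces.default(hm, s2))), 1e-5)
})

test_that("alchemical system validates its invariants", {
  expect_error(alchemical_system(matrix(0, 2, 2)), "N x 3")
  expect_error(alchemical_system(matrix(0, 2, 3), solute = 5), "out of range")
  expect_error(alchemical_system(matrix(0, 2, 3), lambda = 1.2), "lambda")
})
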