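#' Miniature invariant body-ordered potential with alchemical edge scaling
#'
#' A toy graph potential that mirrors the structure of body-ordered
#' machine-learned potentials in the invariant (l = 0) limit: per-edge
#' two-body features phi_k(r_ij, species_j) = R_k(r_ij) f_cut(r_ij)
#' w\[species_j, k\] are pooled into per-atom features
#' A_ik = sum_j alpha_ij phi_k, and site energies are nonlinear (body order
#' up to `nu_max`) polynomial readouts of the pooled features. Alchemical
#' decoupling enters purely through the edge factors alpha_ij: edges crossing
#' the solute/solvent boundary are scaled by lambda, so at lambda = 0 the
#' graph is identical to that of the separated components, and at lambda = 1
#' the factors vanish from the expression entirely.
#'
#' With `n_layers = 2` the pooled features of the first pass become node
#' features for a second interaction pass (a message-passing layer), with
#' the same alpha scaling applied at each layer.
#'
#' An optional softcore pair table adds an explicit alpha-scaled two-body
#' term using the softened curves, which bounds the energy of overlapping
#' atoms by the table's short-range cap.
#'
#' @param species element labels the model covers
#' @param cutoff radial cutoff (Angstrom)
#' @param n_radial number of radial basis channels
#' @param nu_max maximum body order of the site-energy readout (1..3)
#' @param n_layers number of interaction layers (1 or 2)
#' @param seed seed fixing the random embedding/readout weights
#' @param pair_table named list of `softcore_spec` objects keyed by pair
#'   label ("A-B"; both orders looked up), or `NULL`
#' @return an object of class `body_ordered_model`
#' @export
body_ordered_model <- function(species, cutoff = 5, n_radial = 4L,
                               nu_max = 3L, n_layers = 2L, seed = 1L,
                               pair_table = NULL) {
  stopifnot(nu_max >= 1L, nu_max <= 3L, n_layers %in% c(1L, 2L))
  s <- rng_stream(seed)
  nsp <- length(species)
  emb <- with_stream(s, matrix(stats::rnorm(nsp * n_radial, sd = 1),
                               nsp, n_radial,
                               dimnames = list(species, NULL)))
  read <- with_stream(s, array(stats::rnorm(n_layers * nu_max * n_radial,
                                            sd = 0.3),
                               dim = c(n_layers, nu_max, n_radial)))
  mix <- with_stream(s, matrix(stats::rnorm(n_radial * n_radial,
                                            sd = 1 / sqrt(n_radial)),
                               n_radial, n_radial))
  centers <- seq(0.75, cutoff, length.out = n_radial)
  width <- (cutoff - 0.75) / n_radial
  structure(list(species = species, cutoff = cutoff, n_radial = n_radial,
                 nu_max = nu_max, n_layers = n_layers, seed = seed,
                 embedding = emb, readout = read, mix = mix,
                 centers = centers, width = width, pair_table = pair_table,
                 kB = kB_kcal),
            class = "body_ordered_model")
}

# Gaussian radial basis under a smooth cosine cutoff envelope
radial_basis <- function(model, r) {
  env <- ifelse(r < model$cutoff, 0.5 * (cos(pi * r / model$cutoff) + 1), 0)
  sapply(seq_len(model$n_radial), function(k)
    exp(-(r - model$centers[k])^2 / (2 * model$width^2)) * env)
}

lookup_pair_spec <- function(table, si, sj) {
  if (is.null(table)) return(NULL)
  table[[paste(si, sj, sep = "-")]] %||% table[[paste(sj, si, sep = "-")]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
potential_energy.body_ordered_model <- function(model, system) {
  unknown <- setdiff(unique(system$species), model$species)
  if (length(unknown))
    stop("species not covered by the model: ", paste(unknown, collapse = ", "))
  check_box_cutoff(system, model$cutoff)
  n <- nrow(system$positions)
  pairs <- all_pairs(n)
  if (!nrow(pairs)) return(0)
  pd <- pair_displacements(system$positions, pairs, system$box)
  keep <- pd$d < model$cutoff
  pr <- pairs[keep, , drop = FALSE]; d <- pd$d[keep]
  if (!nrow(pr)) return(0)
  alpha <- edge_scaling_factors(system, pr)
  R <- radial_basis(model, d)                       # m x K
  if (is.null(dim(R))) R <- matrix(R, nrow = length(d))
  K <- model$n_radial
  sp_idx <- match(system$species, model$species)

  # layer 1: pool species-embedded two-body features
  A1 <- matrix(0, n, K)
  wj <- model$embedding[sp_idx[pr[, 2L]], , drop = FALSE]
  wi <- model$embedding[sp_idx[pr[, 1L]], , drop = FALSE]
  contrib_i <- alpha * R * wj                       # features gathered at i
  contrib_j <- alpha * R * wi
  for (k in seq_len(K)) {
    A1[, k] <- A1[, k] +
      as.vector(tapply(contrib_i[, k], factor(pr[, 1L], levels = 1:n),
                       sum, default = 0)) +
      as.vector(tapply(contrib_j[, k], factor(pr[, 2L], levels = 1:n),
                       sum, default = 0))
  }
  A1[is.na(A1)] <- 0
  feats <- list(A1)

  if (model$n_layers == 2L) {
    h <- tanh(A1 %*% model$mix)                     # node features, layer 2
    A2 <- matrix(0, n, K)
    c_i <- alpha * R * h[pr[, 2L], , drop = FALSE]
    c_j <- alpha * R * h[pr[, 1L], , drop = FALSE]
    for (k in seq_len(K)) {
      A2[, k] <- A2[, k] +
        as.vector(tapply(c_i[, k], factor(pr[, 1L], levels = 1:n),
                         sum, default = 0)) +
        as.vector(tapply(c_j[, k], factor(pr[, 2L], levels = 1:n),
                         sum, default = 0))
    }
    A2[is.na(A2)] <- 0
    feats <- c(feats, list(A2))
  }

  e <- 0
  for (t in seq_along(feats)) {
    A <- feats[[t]]
    for (ord in seq_len(model$nu_max))
      e <- e + sum(A^ord %*% model$readout[t, ord, ])
  }

  # explicit softcore pair term (alpha-scaled across the boundary)
  if (!is.null(model$pair_table)) {
    for (m in seq_len(nrow(pr))) {
      spec <- lookup_pair_spec(model$pair_table,
                               system$species[pr[m, 1L]],
                               system$species[pr[m, 2L]])
      if (!is.null(spec)) e <- e + alpha[m] * softened_energy(spec, d[m])
    }
  }
  e
}
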