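#' Tabulated dimer curve for one element pair
#'
#' Holds the reference pairwise energy and radial force of a diatomic as a
#' function of separation, the raw material from which a softcore short-range
#' curve is constructed. The force convention is F = -dE/dr, so the repulsive
#' wall carries positive force.
#'
#' Analytic callables (exact energy/force/force-derivative functions) may be
#' attached; fitting then uses them instead of finite differences.
#'
#' @param pair ordered element pair label, e.g. `c("Br", "O")` or `"Br-O"`
#' @param r separations (Angstrom), strictly increasing, at least 10 points
#' @param energy pair energies (kcal/mol)
#' @param force radial forces (kcal/mol/A), convention F = -dE/dr
#' @param energy_fn,force_fn,dforce_fn optional analytic callables for the
#'   reference energy, force and force derivative
#' @param force_tol relative tolerance for the consistency check of `force`
#'   against -dE/dr by central finite differences on the interior grid
#'   (loose by design: the check guards against sign or column errors, not
#'   against the O(h^2) discretisation error of coarse grids)
#' @return an object of class `dimer_curve`
#' @export
dimer_curve <- function(pair, r, energy, force,
                        energy_fn = NULL, force_fn = NULL, dforce_fn = NULL,
                        force_tol = 0.25) {
  pair <- pair_label(pair)
  r <- as.numeric(r); energy <- as.numeric(energy); force <- as.numeric(force)
  if (length(r) < 10L) stop("dimer curve needs at least 10 grid points")
  if (length(energy) != length(r) || length(force) != length(r))
    stop("r, energy and force must have equal length")
  if (any(diff(r) <= 0)) stop("separations r must be strictly increasing")
  if (!all(is.finite(c(r, energy, force)))) stop("non-finite curve data")
  # F = -dE/dr by central differences on the interior grid
  n <- length(r)
  fd <- -(energy[3:n] - energy[1:(n - 2)]) / (r[3:n] - r[1:(n - 2)])
  scale <- pmax(abs(force[2:(n - 1)]), max(abs(force)) * 1e-2)
  if (any(abs(fd - force[2:(n - 1)]) > force_tol * scale + 1e-8))
    stop("force column inconsistent with -dE/dr (tolerance ", force_tol, ")")
  structure(list(pair = pair, r = r, energy = energy, force = force,
                 energy_fn = energy_fn, force_fn = force_fn,
                 dforce_fn = dforce_fn),
            class = "dimer_curve")
}

pair_label <- function(pair) {
  if (length(pair) == 2L) paste(pair, collapse = "-") else as.character(pair)
}

#' @export
print.dimer_curve <- function(x, ...) {
  cat(sprintf("dimer_curve %s: %d points, r in [%.3f, %.3f] A\n",
              x$pair, length(x$r), min(x$r), max(x$r)))
  invisible(x)
}

#' Read a tabulated dimer curve from whitespace-delimited text
#'
#' Expects three columns (separation, energy, force); lines starting with
#' `#` are comments. The curve invariants are validated on read.
#'
#' @param path file path
#' @param pair pair label; defaults to a `pair:` entry in the header
#'   comments, else the file name
#' @param ... passed to [dimer_curve()]
#' @return a [dimer_curve()]
#' @export
read_dimer_curve <- function(path, pair = NULL, ...) {
  lines <- readLines(path)
  hdr <- grep("^\\s*#", lines, value = TRUE)
  if (is.null(pair)) {
    m <- regmatches(hdr, regexpr("pair:\\s*\\S+", hdr))
    pair <- if (length(m)) sub("pair:\\s*", "", m[[1]])
            else sub("\\.[^.]*$", "", basename(path))
  }
  tab <- utils::read.table(text = lines, comment.char = "#",
                           col.names = c("r", "energy", "force"))
  dimer_curve(pair, tab$r, tab$energy, tab$force, ...)
}

# Interpolants for a curve's force and force derivative.  Analytic callables
# win when present; otherwise the force derivative is built from 4th-order
# central differences on a uniform grid (2nd-order one-sided at the ends,
# spline fallback for non-uniform grids) and interpolated by spline.
curve_force_fun <- function(curve) {
  if (!is.null(curve$force_fn)) return(curve$force_fn)
  stats::splinefun(curve$r, curve$force, method = "fmm")
}

curve_dforce_fun <- function(curve) {
  if (!is.null(curve$dforce_fn)) return(curve$dforce_fn)
  r <- curve$r; f <- curve$force; n <- length(r)
  h <- diff(r)
  if (max(h) - min(h) < 1e-8 * mean(h)) {
    hh <- mean(h)
    d <- numeric(n)
    i <- 3:(n - 2)
    d[i] <- (-f[i + 2] + 8 * f[i + 1] - 8 * f[i - 1] + f[i - 2]) / (12 * hh)
    d[2] <- (f[3] - f[1]) / (2 * hh)
    d[n - 1] <- (f[n] - f[n - 2]) / (2 * hh)
    d[1] <- (-3 * f[1] + 4 * f[2] - f[3]) / (2 * hh)
    d[n] <- (3 * f[n] - 4 * f[n - 1] + f[n - 2]) / (2 * hh)
    stats::splinefun(r, d, method = "fmm")
  } else {
    sf <- stats::splinefun(r, f, method = "fmm")
    function(x) sf(x, deriv = 1L)
  }
}

curve_energy_fun <- function(curve) {
  if (!is.null(curve$energy_fn)) return(curve$energy_fn)
  stats::splinefun(curve$r, curve$energy, method = "fmm")
}

# Separation of the curve's energy minimum, refined off-grid.
curve_minimum <- function(curve) {
  i <- which.min(curve$energy)
  lo <- curve$r[max(1L, i - 1L)]; hi <- curve$r[min(length(curve$r), i + 1L)]
  if (lo == hi) return(curve$r[i])
  ef <- curve_energy_fun(curve)
  stats::optimize(ef, c(lo, hi), tol = 1e-10)$minimum
}

#' Fit the a r^10 + b softcore force polynomial at a switching point
#'
#' Matches the value and first derivative of the reference radial force at
#' `r_switch` with a polynomial `a * r^10 + b`, which approaches the constant
#' `b` as r -> 0. Below the switching point the curve follows the polynomial;
#' above it the reference is untouched, so equilibrium properties are
#' preserved.
#'
#' @param curve a [dimer_curve()]
#' @param r_switch switching separation (Angstrom); must lie inside the grid
#'   and strictly below the energy-minimum separation
#' @param gradient_floor recorded diagnostic floor on |dF/dr| at the
#'   switching point (kcal/mol/A^2); default 3 eV/A^2 in working units
#' @return an object of class `softcore_spec` with coefficients `a`
#'   (kcal/mol/A^11), `b` (kcal/mol/A), `E_switch` (kcal/mol) and the
#'   reference curve attached
#' @export
fit_force_polynomial <- function(curve, r_switch,
                                 gradient_floor = 3 * ev_kcal) {
  stopifnot(inherits(curve, "dimer_curve"))
  if (r_switch < min(curve$r) || r_switch > max(curve$r))
    stop("r_switch ", r_switch, " lies outside the curve grid [",
         min(curve$r), ", ", max(curve$r), "]")
  r_min <- curve_minimum(curve)
  if (r_switch >= r_min)
    stop("r_switch ", signif(r_switch, 6), " at or beyond the energy minimum (",
         signif(r_min, 6), " A) would soften the minimum")
  Ffun <- curve_force_fun(curve)
  dFfun <- curve_dforce_fun(curve)
  F0 <- Ffun(r_switch); dF0 <- dFfun(r_switch)
  a <- dF0 / (10 * r_switch^9)
  b <- F0 - a * r_switch^10
  E_switch <- curve_energy_fun(curve)(r_switch)
  structure(list(pair = curve$pair, r_switch = r_switch, a = a, b = b,
                 E_switch = E_switch, gradient_floor = gradient_floor,
                 curve = curve),
            class = "softcore_spec")
}

#' @export
print.softcore_spec <- function(x, ...) {
  cat(sprintf(
    "softcore_spec %s: r_switch = %.4f A, a = %.6g, b = %.6g, E(0) = %.4g kcal/mol\n",
    x$pair, x$r_switch, x$a, x$b, softened_energy(x, 0)))
  invisible(x)
}

#' Select the softcore switching point on the repulsive wall
#'
#' Returns the largest separation strictly below the energy minimum at which
#' the magnitude of the force gradient |dF/dr| still reaches `gradient_floor`.
#' This minimises the gradient at the switching point subject to the floor,
#' keeping the position and curvature of the minimum untouched while capping
#' the short-range energy at a numerically stable value.
#'
#' @param curve a [dimer_curve()]
#' @param gradient_floor minimum allowed |dF/dr| at the switching point
#'   (kcal/mol/A^2); default 3 eV/A^2 in working units. A non-positive floor
#'   binds nowhere and returns the grid point immediately below the minimum.
#' @param tol bisection tolerance on r (Angstrom)
#' @return the switching separation (Angstrom)
#' @export
select_switch_point <- function(curve, gradient_floor = 3 * ev_kcal,
                                tol = 1e-6) {
  stopifnot(inherits(curve, "dimer_curve"))
  r_min <- curve_minimum(curve)
  wall <- curve$r[curve$r < r_min]
  if (!length(wall)) stop("curve has no grid points below its energy minimum")
  r_hi <- max(wall)
  if (gradient_floor <= 0) return(r_hi)
  dFfun <- curve_dforce_fun(curve)
  g <- function(r) abs(dFfun(r)) - gradient_floor
  if (g(r_hi) >= 0) return(r_hi)
  r_lo <- min(curve$r)
  if (g(r_lo) < 0) {
    grid <- seq(r_lo, r_hi, length.out = 512L)
    stop("unsoftenable curve ", curve$pair, ": |dF/dr| never reaches ",
         signif(gradient_floor, 6), " on the wall (max ",
         signif(max(abs(dFfun(grid))), 6), ")")
  }
  # |dF/dr| decays towards the minimum; bisect for the sign change
  while (r_hi - r_lo > tol) {
    mid <- 0.5 * (r_lo + r_hi)
    if (g(mid) >= 0) r_lo <- mid else r_hi <- mid
  }
  0.5 * (r_lo + r_hi)
}

#' Softened pair energy from a fitted softcore spec
#'
#' Above the switching point the reference energy is returned unchanged.
#' Below it, the energy is the analytic integral of the fitted force
#' polynomial, `E_switch + a (r_s^11 - r^11)/11 + b (r_s - r)`, which is C1
#' at the seam and finite down to r = 0.
#'
#' @param spec a `softcore_spec` from [fit_force_polynomial()]
#' @param r separations (Angstrom), r >= 0; vectorised
#' @return softened energies (kcal/mol)
#' @export
softened_energy <- function(spec, r) {
  stopifnot(inherits(spec, "softcore_spec"))
  r <- as.numeric(r)
  if (any(r < 0)) stop("separations must be non-negative")
  out <- numeric(length(r))
  below <- r <= spec$r_switch
  rs <- spec$r_switch
  out[below] <- spec$E_switch + spec$a * (rs^11 - r[below]^11) / 11 +
    spec$b * (rs - r[below])
  if (any(!below)) out[!below] <- curve_energy_fun(spec$curve)(r[!below])
  out
}

#' Softened radial force from a fitted softcore spec
#'
#' @param spec a `softcore_spec`
#' @param r separations (Angstrom); vectorised
#' @return softened forces (kcal/mol/A), convention F = -dE/dr
#' @export
softened_force <- function(spec, r) {
  stopifnot(inherits(spec, "softcore_spec"))
  r <- as.numeric(r)
  out <- numeric(length(r))
  below <- r <= spec$r_switch
  out[below] <- spec$a * r[below]^10 + spec$b
  if (any(!below)) out[!below] <- curve_force_fun(spec$curve)(r[!below])
  out
}

#' Build softcore specs for a table of element pairs
#'
#' Runs switching-point selection and polynomial fitting for every pair,
#' optionally serialising each softened curve to a 3-column text file.
#' Per-pair failures (e.g. unsoftenable curves) are reported, not silently
#' dropped; successful pairs are unaffected.
#'
#' @param curves named list of [dimer_curve()] objects (or a list; names are
#'   taken from the curves' pair labels)
#' @param gradient_floor floor on |dF/dr| at the switching point
#' @param out_dir directory for serialised softened curves, or `NULL` to skip
#' @return a list with `specs` (named list of `softcore_spec`), `report`
#'   (data frame: pair, ok, r_switch, a, b, energy cap E(0) - E(min), message)
#'   and `files` (written paths)
#' @export
build_softcore_table <- function(curves, gradient_floor = 3 * ev_kcal,
                                 out_dir = NULL) {
  if (inherits(curves, "dimer_curve")) curves <- list(curves)
  specs <- list(); files <- character(0)
  rows <- lapply(curves, function(curve) {
    res <- tryCatch({
      rs <- select_switch_point(curve, gradient_floor)
      spec <- fit_force_polynomial(curve, rs, gradient_floor)
      e_min <- curve_energy_fun(curve)(curve_minimum(curve))
      cap <- softened_energy(spec, 0) - e_min
      specs[[curve$pair]] <<- spec
      if (!is.null(out_dir)) {
        path <- file.path(out_dir, paste0(gsub("[^A-Za-z0-9-]", "_",
                                               curve$pair), ".softcore.dat"))
        write_softcore_curve(spec, path)
        files <<- c(files, path)
      }
      data.frame(pair = curve$pair, ok = TRUE, r_switch = rs,
                 a = spec$a, b = spec$b, cap = cap, message = "",
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      data.frame(pair = curve$pair, ok = FALSE, r_switch = NA_real_,
                 a = NA_real_, b = NA_real_, cap = NA_real_,
                 message = conditionMessage(e), stringsAsFactors = FALSE)
    })
    res
  })
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  if (any(!report$ok))
    warning("softcore table incomplete: ",
            paste(report$pair[!report$ok], collapse = ", "), " failed")
  list(specs = specs, report = report, files = files)
}

#' Serialise a softened curve as 3-column delimited text
#'
#' Writes the softened energy and force on the reference grid extended down
#' to r = 0, with header comments recording the pair, switching point and
#' polynomial coefficients at full double precision.
#'
#' @param spec a `softcore_spec`
#' @param path output file
#' @param n_below number of grid points inserted between 0 and the first
#'   reference grid point
#' @return `path`, invisibly
#' @export
write_softcore_curve <- function(spec, path, n_below = 20L) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  r_lo <- seq(0, min(spec$curve$r), length.out = n_below + 1L)
  r <- c(r_lo[-length(r_lo)], spec$curve$r)
  e <- softened_energy(spec, r)
  f <- softened_force(spec, r)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    sprintf("# pair: %s", spec$pair),
    sprintf("# r_switch: %.17g", spec$r_switch),
    sprintf("# a: %.17g", spec$a),
    sprintf("# b: %.17g", spec$b),
    sprintf("# E_switch: %.17g", spec$E_switch),
    "# columns: r  energy  force"), con)
  writeLines(sprintf("%.17g %.17g %.17g", r, e, f), con)
  invisible(path)
}

#' Read back a serialised softened curve
#'
#' Reconstructs a tabulated `softcore_spec`: the polynomial coefficients come
#' from the header, the outer (r > r_switch) region from the tabulated grid.
#'
#' @param path file written by [write_softcore_curve()]
#' @return a `softcore_spec` with a tabulated reference curve
#' @export
read_softcore_curve <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^\\s*#", lines, value = TRUE)
  grab <- function(key) {
    m <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (!length(m)) stop("missing header field ", key, " in ", path)
    sub(paste0("^#\\s*", key, ":\\s*"), "", m[[1]])
  }
  tab <- utils::read.table(text = lines, comment.char = "#",
                           col.names = c("r", "energy", "force"))
  rs <- as.numeric(grab("r_switch"))
  ef <- stats::splinefun(tab$r, tab$energy, method = "fmm")
  ff <- stats::splinefun(tab$r, tab$force, method = "fmm")
  curve <- structure(list(pair = grab("pair"), r = tab$r, energy = tab$energy,
                          force = tab$force, energy_fn = ef, force_fn = ff,
                          dforce_fn = NULL),
                     class = "dimer_curve")
  structure(list(pair = grab("pair"), r_switch = rs,
                 a = as.numeric(grab("a")), b = as.numeric(grab("b")),
                 E_switch = as.numeric(grab("E_switch")),
                 gradient_floor = NA_real_, curve = curve,
                 table = tab),
            class = "softcore_spec")
}
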