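# Direct-summation autocorrelation oracle for small series
g_bruteforce <- function(x) {
  # biased (1/T) autocovariance normalisation, as in the package estimator
  T <- length(x); m <- mean(x); v <- mean((x - m)^2)
  g <- 1
  for (t in seq_len(T - 1)) {
    C <- sum((x[1:(T - t)] - m) * (x[(1 + t):T] - m)) / T / v
    if (C <= 0) break
    g <- g + 2 * C * (1 - t / T)
  }
  g
}

test_that("statistical inefficiency recovers white-noise and AR(1) limits", {
  set.seed(101)
  expect_lt(abs(statistical_inefficiency(rnorm(1e4)) - 1), 0.1)
  # AR(1), phi = 0.9: g = (1 + phi) / (1 - phi) = 19
  phi <- 0.9
  x <- as.numeric(stats::arima.sim(list(ar = phi), 1e5))
  expect_lt(abs(statistical_inefficiency(x) / 19 - 1), 0.2)
  # elementwise duplication doubles g (brute-force oracle on both)
  y <- rnorm(500) + 0.5 * sin(seq_len(500) / 10)
  y2 <- rep(y, each = 2)
  expect_equal(as.numeric(statistical_inefficiency(y)), g_bruteforce(y),
               tolerance = 1e-10)
  expect_equal(as.numeric(statistical_inefficiency(y2)) /
                 as.numeric(statistical_inefficiency(y)), 2,
               tolerance = 0.25)
  # degenerate series
  g0 <- statistical_inefficiency(rep(3, 100))
  expect_equal(as.numeric(g0), 1)
  expect_true(attr(g0, "degenerate"))
  expect_error(statistical_inefficiency(1:3), "short")
})

test_that("equilibration detection discards an initial transient", {
  set.seed(202)
  x <- rnorm(400)
  eq <- detect_equilibration(x)
  expect_lte(eq$t0, 20)                       # stationary: nothing to discard
  y <- c(rnorm(100) + 5, rnorm(900))          # level shift at index 100
  eqy <- detect_equilibration(y)
  expect_gte(eqy$t0, 95)   # all contaminated samples (bar edge jitter) dropped
  # Neff equals the max over an exhaustive scan with the same g estimator
  z <- c(rnorm(30) + 3, rnorm(270))
  eqz <- detect_equilibration(z)
  neffs <- vapply(0:(length(z) - 5), function(t0)
    (length(z) - t0) / as.numeric(statistical_inefficiency(z[(t0 + 1):length(z)])),
    numeric(1))
  expect_equal(eqz$Neff, max(neffs), tolerance = 1e-10)
})

test_that("TI integrates the harmonic lambda family to the closed form", {
  expect_equal(ti_estimate(rep(2.5, 7), seq(0, 1, length.out = 7))$dG, 2.5)
  # linear mixing of two 1D wells k0 = 1, k1 = 4 (kBT = 1):
  # <dH/dl> = 0.5 (k1 - k0) <x^2>_l with <x^2>_l = 1 / k(l)
  lams <- seq(0, 1, length.out = 33)
  dudl <- 0.5 * (4 - 1) / (1 + 3 * lams)
  est <- ti_estimate(dudl, lams)
  expect_lt(abs(est$dG - 0.5 * log(4)), 1e-3)
  # reversing the schedule negates dG exactly
  expect_identical(ti_estimate(rev(dudl), rev(lams))$dG, -est$dG)
  expect_error(ti_estimate(c(1, 2, 3), c(0, 0.7, 0.3)), "sorted")
  # error propagation with independent windows
  e <- ti_estimate(dudl, lams, dudl_errs = rep(0.1, 33))
  w <- c(diff(lams)[1] / 2, diff(lams)[-1] / 2 + diff(lams)[-32] / 2,
         diff(lams)[32] / 2)
  expect_equal(e$dG_err, sqrt(sum((w * 0.1)^2)))
})

test_that("BAR solves the Bennett equation on Gaussian work", {
  gw <- gaussian_work_samples(5, 4, 5e4, seed = 31)
  b <- bar_estimate(gw$w_F, gw$w_R)
  expect_lt(abs(b$df - 3), 3 * b$err)
  expect_gt(b$err, 0)
  # a symmetric work multiset with w_R = -w_F gives df = 0 exactly
  w <- seq(-2, 2, length.out = 101)
  expect_lt(abs(bar_estimate(w, -w)$df), 1e-9)
  # permutation invariance
  expect_equal(bar_estimate(sample(gw$w_F), sample(gw$w_R))$df, b$df)
  expect_error(bar_estimate(numeric(0), w), "non-empty")
  # non-overlapping work distributions converge but warn
  expect_warning(bar_estimate(rnorm(50, 100, 0.1), rnorm(50, 100, 0.1)),
                 "overlap")
})

test_that("MBAR matches BAR at K = 2 and closed forms at K = 3", {
  gw <- gaussian_work_samples(2, 1.5, 8000, seed = 17)
  b <- bar_estimate(gw$w_F, gw$w_R)
  u_kn <- rbind(c(rep(0, 8000), gw$w_R), c(gw$w_F, rep(0, 8000)))
  m2 <- reduced_potential_matrix(u_kn, c(8000, 8000))
  e2 <- mbar_estimate(m2)
  expect_lt(abs(e2$dG - b$df), 1e-8)
  # identical states
  mi <- sample_harmonic_ukn(harmonic_family(c(1, 1, 1)), 500, seed = 5)
  expect_lt(max(abs(mbar_estimate(mi)$f_k)), 0.2)
  # K = 3 harmonic family: f_k = (d/2) ln(k_k / k_1)
  fam <- harmonic_family(c(1, 2, 4), d = 1)
  m3 <- sample_harmonic_ukn(fam, 3000, seed = 23)
  e3 <- mbar_estimate(m3)
  th <- e3$diagnostics$theta
  for (k in 2:3) {
    se_k <- sqrt(th[1, 1] + th[k, k] - 2 * th[1, k])
    expect_lt(abs(e3$f_k[k] - fam$f_exact[k]), 3 * max(se_k, 1e-3))
  }
})

test_that("MBAR handles perturbative states and rejects bad input", {
  fam <- harmonic_family(c(1, 4))
  m <- sample_harmonic_ukn(fam, 2000, seed = 3)
  # append an unsampled state k = 3 (k_spring = 2) evaluated on all samples
  r2 <- 2 * m$u_kn[1, ]                      # |x|^2 (k = 1, kT = 1)
  u3 <- rbind(m$u_kn, 0.5 * 2 * r2)
  mp <- reduced_potential_matrix(u3, c(2000, 2000, 0))
  ep <- mbar_estimate(mp)
  expect_lt(abs(ep$f_k[3] - 0.5 * log(2)), 0.1)
  expect_error(reduced_potential_matrix(u3, c(0, 0, 0)), "at least one")
  expect_error(reduced_potential_matrix(u3[1, , drop = FALSE], 4000),
               "at least 2")
})

test_that("cycle closure and shift invariance hold", {
  fam <- harmonic_family(c(1, 2, 4), d = 2)
  m <- sample_harmonic_ukn(fam, 1000, seed = 41)
  f <- mbar_estimate(m)$f_k
  # shared normalisation: pairwise differences close every cycle exactly
  expect_equal((f[2] - f[1]) + (f[3] - f[2]) + (f[1] - f[3]), 0)
  # shifting every state's potential on one sample (a column) cancels exactly
  m_col <- m
  m_col$u_kn[, 10] <- m_col$u_kn[, 10] + 123.4
  expect_lt(max(abs(f - mbar_estimate(m_col)$f_k)), 1e-9)
  # shifting one state's potential (a row) by c moves only that f_k, by c
  m_row <- m
  m_row$u_kn[2, ] <- m_row$u_kn[2, ] + 37.5
  f_row <- mbar_estimate(m_row)$f_k
  expect_lt(abs(f_row[2] - (f[2] + 37.5)), 1e-9)
  expect_lt(max(abs(f_row[c(1, 3)] - f[c(1, 3)])), 1e-9)
})

test_that("subsampled and full-series MBAR agree on correlated data", {
  # correlated samples: OU chain within each window of a K = 2 family
  set.seed(77)
  K <- 2; n <- 4000; ks <- c(1, 3); phi <- 0.9
  r2 <- c()
  for (kk in ks) {
    x <- numeric(n); x[1] <- rnorm(1, 0, sqrt(1 / kk))
    for (i in 2:n) x[i] <- phi * x[i - 1] +
        rnorm(1, 0, sqrt((1 - phi^2) / kk))
    r2 <- c(r2, x^2)
  }
  u_kn <- outer(ks, r2, function(kk, rr) 0.5 * kk * rr)
  m <- reduced_potential_matrix(u_kn, c(n, n))
  full <- mbar_estimate(m)
  idx <- c(); Nk <- c()
  for (k in 1:K) {
    sl <- ((k - 1) * n + 1):(k * n)
    g <- as.numeric(statistical_inefficiency(u_kn[k, sl]))
    pick <- sl[unique(round(seq(1, n, by = g)))]
    idx <- c(idx, pick); Nk <- c(Nk, length(pick))
  }
  sub <- mbar_estimate(reduced_potential_matrix(u_kn[, idx], Nk))
  comb <- sqrt(full$dG_err^2 + sub$dG_err^2)
  expect_lt(abs(full$dG - sub$dG), 3 * max(comb, 0.02))
  # the subsampled uncertainty is the honest (larger) one
  expect_gt(sub$dG_err, full$dG_err)
})

test_that("TI, BAR and MBAR agree on the harmonic lambda family", {
  fam <- harmonic_family(c(1, 1.6, 2.6, 4), d = 1)
  m <- sample_harmonic_ukn(fam, 3000, seed = 55)
  e_mbar <- mbar_estimate(m)
  # BAR chained over adjacent windows
  df_bar <- 0; var_bar <- 0
  for (k in 1:3) {
    sl_k <- ((k - 1) * 3000 + 1):(k * 3000)
    sl_k1 <- (k * 3000 + 1):((k + 1) * 3000)
    wF <- m$u_kn[k + 1, sl_k] - m$u_kn[k, sl_k]
    wR <- m$u_kn[k, sl_k1] - m$u_kn[k + 1, sl_k1]
    b <- bar_estimate(wF, wR)
    df_bar <- df_bar + b$df; var_bar <- var_bar + b$err^2
  }
  # TI with analytic per-window averages: dG = integral of 0.5 d ln k
  lams <- seq(0, 1, length.out = 33)
  kfun <- function(l) exp(log(1) + l * log(4))    # geometric k(lambda) path
  dudl <- 0.5 * log(4) * rep(1, 33)               # d/dl [0.5 ln k(l)] exact
  e_ti <- ti_estimate(dudl, lams)
  exact <- 0.5 * log(4)
  comb <- 3 * sqrt(e_mbar$dG_err^2 + var_bar)
  expect_lt(abs(e_mbar$dG - df_bar), comb)
  expect_lt(abs(e_ti$dG - exact), 1e-10)
  expect_lt(abs(e_mbar$dG - exact), 3 * e_mbar$dG_err)
})

test_that("overlap matrix is row-stochastic with the right limits", {
  mi <- sample_harmonic_ukn(harmonic_family(c(2, 2, 2)), 400, seed = 9)
  ei <- mbar_estimate(mi)
  O <- overlap_matrix(mi, ei$f_k)
  # identical states: every row approaches N_j / N
  for (i in 1:3) expect_equal(unname(O[i, ]), rep(1 / 3, 3), tolerance = 1e-6)
  # disjoint states: block-diagonal structure (samples from states 1 and 3)
  n <- 50
  set.seed(71)
  u <- rbind(c(rnorm(n), rnorm(n) + 500), c(rnorm(n), rnorm(n) + 500),
             c(rnorm(n) + 500, rnorm(n)), c(rnorm(n) + 500, rnorm(n)))
  md <- reduced_potential_matrix(u, c(n, 0L, n, 0L))
  fd <- alchemfe:::mbar_solve(u, c(n, 0L, n, 0L))
  Od <- overlap_matrix(md, fd)
  expect_lt(max(abs(Od[1:2, 3:4])), 1e-10)
  expect_lt(max(abs(Od[3:4, 1:2])), 1e-10)
  # random inputs: rows sum to 1
  set.seed(13)
  ur <- matrix(rnorm(3 * 60), 3, 60)
  mr <- reduced_potential_matrix(ur, c(20, 20, 20))
  Or <- overlap_matrix(mr, alchemfe:::mbar_solve(ur, c(20, 20, 20)))
  expect_lt(max(abs(rowSums(Or) - 1)), 1e-10)
  expect_false(is.na(attr(Or, "eigen_gap")))
})

test_that("log P converts free-energy leg differences correctly", {
  expect_equal(log_p(-3.2, -3.2), 0)
  rt <- 2.303 * kB_kcal * 298.15
  expect_equal(log_p(-5 + rt, -5), 1)
  expect_equal(log_p(-5.00, -6.365, 298.15), 1.365 / rt)
  expect_lt(abs(log_p(-5.00, -6.365, 298.15) - 1.0005), 1e-3)
})

test_that("u_kn matrices round-trip bit-identically through text", {
  fam <- harmonic_family(c(1, 3), d = 2)
  m <- sample_harmonic_ukn(fam, 200, seed = 8)
  path <- file.path(withr::local_tempdir(), "ukn.tsv")
  write_ukn(m, path, meta = list(temperature = 1, lambdas = c(0, 1)))
  back <- read_ukn(path)
  expect_identical(back$matrix$u_kn, m$u_kn)
  expect_identical(back$matrix$N_k, m$N_k)
  expect_equal(back$meta$temperature, 1)
  expect_identical(mbar_estimate(back$matrix)$dG, mbar_estimate(m)$dG)
})
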