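test_that("GFT is orthonormal: basis-vector input, Parseval, round trip", {
  b <- random_basis(8, 31)
  set.seed(31)
  x <- matrix(rnorm(8 * 20), 8, 20)

  # every column equal to harmonic u_3 -> only row 3 nonzero
  x3 <- matrix(b$U[, 3], 8, 5)
  xhat3 <- gft(b, x3)
  expect_lt(max(abs(xhat3[-3, ])), 1e-12)
  expect_equal(xhat3[3, ], rep(1, 5), tolerance = 1e-12)

  xhat <- gft(b, x)
  expect_equal(sum(xhat^2), sum(x^2), tolerance = 1e-9)
  expect_equal(inverse_gft(b, xhat), x, tolerance = 1e-9)

  expect_error(gft(b, matrix(0, 5, 3)), "match")
})

test_that("mean energy density averages over timepoints and subjects", {
  expect_equal(mean_energy_density(matrix(c(1, 0, 0), 3, 1)), c(1, 0, 0))
  expect_equal(mean_energy_density(matrix(c(1, 0, 0, 1), 2, 2)), c(0.5, 0.5))
  expect_equal(
    mean_energy_density(list(matrix(c(2, 0), 2, 1) * sqrt(1),
                             matrix(c(0, 2), 2, 1))),
    c(2, 2)
  )
  expect_error(mean_energy_density(list()), "at least one")
})

test_that("cutoff selection halves the cumulative energy", {
  cu <- select_cutoff(rep(0.25, 4))
  expect_equal(cu$C, 2L)
  expect_equal(cu$low_band, 1:2)
  expect_equal(cu$energy_fraction_low, 0.5)

  expect_equal(select_cutoff(c(0.9, 0.05, 0.05))$C, 1L)

  cu5 <- select_cutoff(rep(0.2, 5))
  expect_equal(cu5$C, 3L)
  expect_equal(cu5$energy_fraction_low, 0.6)

  expect_error(select_cutoff(rep(0, 3)), "all zero")
})

test_that("band filtering reconstructs, splits energy, and is idempotent", {
  n <- 10
  b <- random_basis(n, 32)
  set.seed(32)
  x <- matrix(rnorm(n * 30), n, 30)
  cu <- band_cutoff(4, n)
  f <- filter_signals(b, x, cu)

  expect_equal(f$X_coupled + f$X_decoupled, x, tolerance = 1e-9)
  # per-timepoint orthogonality of the two components
  expect_lt(max(abs(colSums(f$X_coupled * f$X_decoupled))) / sum(x^2), 1e-8)
  # Pythagorean split
  expect_equal(sum(f$X_coupled^2) + sum(f$X_decoupled^2), sum(x^2),
               tolerance = 1e-9)
  # idempotence
  f2 <- filter_signals(b, f$X_coupled, cu)
  expect_equal(f2$X_coupled, f$X_coupled, tolerance = 1e-10)
  expect_lt(max(abs(f2$X_decoupled)), 1e-10)

  # degenerate full-band cutoff
  fall <- filter_signals(b, x, band_cutoff(n, n))
  expect_equal(fall$X_coupled, x)
  expect_equal(fall$X_decoupled, matrix(0, n, 30))

  # signal already inside the low band stays there
  xlow <- b$U[, 1:3] %*% matrix(rnorm(3 * 7), 3, 7)
  flow <- filter_signals(b, xlow, band_cutoff(3, n))
  expect_lt(max(abs(flow$X_decoupled)), 1e-12)
})

test_that("complementary masks swap the outputs exactly", {
  n <- 8
  b <- random_basis(n, 33)
  set.seed(33)
  x <- matrix(rnorm(n * 12), n, 12)
  f1 <- filter_signals(b, x, band_cutoff(3, n))
  # swapped bands: low <-> high
  swapped <- structure(list(C = 5L, low_band = 4:8, high_band = 1:3, n = n,
                            energy_fraction_low = NA_real_),
                       class = "spectral_cutoff")
  f2 <- filter_signals(b, x, swapped)
  expect_equal(f2$X_coupled, f1$X_decoupled)
  expect_equal(f2$X_decoupled, f1$X_coupled)
})

test_that("outputs are invariant to per-column sign flips of the basis", {
  n <- 9
  b <- random_basis(n, 34)
  set.seed(34)
  x <- matrix(rnorm(n * 15), n, 15)
  cu <- band_cutoff(4, n)
  f <- filter_signals(b, x, cu)
  for (r in 1:3) {
    flips <- sample(c(-1, 1), n, replace = TRUE)
    bflip <- structure(list(U = sweep(b$U, 2, flips, `*`),
                            lambdas = b$lambdas), class = "harmonic_basis")
    ff <- filter_signals(bflip, x, cu)
    expect_equal(ff$X_coupled, f$X_coupled, tolerance = 1e-10)
    expect_equal(ff$X_decoupled, f$X_decoupled, tolerance = 1e-10)
    sf <- compute_sdi(ff)
    expect_equal(sf$sdi, compute_sdi(f)$sdi, tolerance = 1e-10)
  }
})

test_that("projectors match the explicit brute-force construction", {
  for (n in c(5, 10)) {
    b <- random_basis(n, 35 + n)
    for (c_idx in c(1, n %/% 2, n - 1)) {
      u_low <- b$U[, 1:c_idx, drop = FALSE]
      p_low <- u_low %*% t(u_low)
      set.seed(35 + n + c_idx)
      x <- matrix(rnorm(n * 6), n, 6)
      f <- filter_signals(b, x, band_cutoff(c_idx, n))
      expect_equal(f$X_coupled, p_low %*% x, tolerance = 1e-12)
      expect_equal(f$X_decoupled, (diag(n) - p_low) %*% x, tolerance = 1e-12)
    }
  }
})
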