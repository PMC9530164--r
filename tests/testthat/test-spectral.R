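test_that("closed-form two-species eigenvalues match the worked cases", {
  sys <- two_species_system(0.1, 0.2, beta_eta = 0.5)
  lam <- two_species_eigenvalues(sys)
  expect_equal(Re(lam), c(-0.2, -0.2))
  expect_equal(Im(lam), c(1, -1) * sqrt(0.06), tolerance = 1e-10)

  sys <- two_species_system(0.1, 0.2, beta_eta = 0.3)
  lam <- two_species_eigenvalues(sys)
  expect_true(all(Im(lam) == 0))
  expect_equal(Re(lam), c(-0.07947423, -0.58719244), tolerance = 1e-6)

  # marginal feasibility: lambda+ -> 0, lambda- -> -(k - alpha1)
  sys <- two_species_system(0.05, 0.2, beta_eta = 0.2 / 0.95 + 1e-12)
  lam <- two_species_eigenvalues(sys)
  expect_equal(Re(lam[1]), 0, tolerance = 1e-6)
  expect_equal(Re(lam[2]), -0.95, tolerance = 1e-6)

  expect_error(two_species_eigenvalues(two_species_system(0.1, 0.2, 0.1)),
               "infeasible")
})

test_that("closed form agrees with the numerical community-matrix spectrum", {
  set.seed(2)
  for (i in 1:2000) {
    d <- draw_feasible_pair()
    sys <- two_species_system(d$alpha1, d$alpha2, d$beta * d$eta)
    lam <- two_species_eigenvalues(sys)
    web <- two_species_web(d$alpha1, d$alpha2, d$beta, d$eta)
    num <- spectrum(community_matrix(web))
    expect_lt(max(abs(sort(Re(lam)) - sort(Re(num)))), 1e-10)
    expect_lt(max(abs(sort(Im(lam)) - sort(Im(num)))), 1e-10)
  }
})

test_that("the purely-real criterion matches the numerical verdict", {
  # threshold at alpha1=0.1, alpha2=0.2, k=1: (gamma + sqrt(gamma^2 +
  # gamma))/2 with gamma = 2/9
  g <- 0.2 / 0.9
  thr <- (g + sqrt(g^2 + g)) / 2
  expect_equal(thr, 0.37169, tolerance = 1e-4)
  expect_false(purely_real_condition(two_species_system(0.1, 0.2, 0.5)))
  expect_true(purely_real_condition(two_species_system(0.1, 0.2, 0.3)))

  # enormous producer growth rate: criterion always satisfied
  expect_true(purely_real_condition(
    two_species_system(0.1, 0.2, beta_eta = 0.99, k = 1e6)))

  set.seed(3)
  disagreements <- 0
  for (i in 1:5000) {
    d <- draw_feasible_pair()
    sys <- two_species_system(d$alpha1, d$alpha2, d$beta * d$eta)
    pred <- purely_real_condition(sys)
    obs <- all(abs(Im(two_species_eigenvalues(sys))) < 1e-9)
    if (pred != obs) {
      bnd <- (sys$gamma + sqrt(sys$gamma^2 + sys$k * sys$gamma)) / 2
      expect_lt(abs(sys$beta_eta - bnd), 1e-8)
      disagreements <- disagreements + 1
    }
  }
  expect_lte(disagreements / 5000, 0.001)
})

test_that("purely-real fraction counts |Im| below tolerance", {
  expect_equal(purely_real_fraction(-0.8 + 0i), 1)
  expect_equal(purely_real_fraction(complex(real = -0.2,
                                            imaginary = c(0.245, -0.245))),
               0)
  expect_equal(purely_real_fraction(c(-1 + 0i, -0.5 + 0.3i, -0.2 - 0.3i,
                                      -2 + 0i)), 0.5)
  expect_error(purely_real_fraction(complex(0)), "eigenvalue")
})

test_that("real-part scaling starts at -1 and is idempotent", {
  x <- c(-2, -1, 0)
  s <- scale_real_parts(x)
  expect_equal(s, c(-1, -0.5, 0))
  expect_equal(scale_real_parts(scale_real_parts(x)), s)
  expect_error(scale_real_parts(c(0, 1)), "negative")

  d <- real_part_distribution(complex(real = c(-2, -1, 0)), bins = 4)
  expect_equal(sum(d$mass), 1)
  expect_equal(d$bin_left[1], -1)
  expect_equal(d$mass[c(1, 3, 4)], c(1, 1, 1) / 3)
})

test_that("complex-plane histogram conserves counts and symmetry", {
  h <- complex_plane_histogram(-0.5 + 0.2i, re_bins = 10, im_bins = 10)
  expect_equal(sum(h$counts), 1)

  pair <- complex(real = c(-0.2, -0.2), imaginary = c(0.3, -0.3))
  h <- complex_plane_histogram(pair, re_bins = 5, im_bins = 6)
  expect_equal(sum(h$counts), 2)
  expect_equal(h$counts, h$counts[, rev(seq_len(ncol(h$counts)))])

  set.seed(5)
  ev <- complex(real = rnorm(200), imaginary = rnorm(200))
  h <- complex_plane_histogram(ev, re_bins = 12, im_bins = 9)
  expect_equal(sum(h$counts), 200)
})

test_that("pool_spectra merges histories and spectrum sets by richness", {
  cfg <- assembly_config(mode = "treelike", beta = 0.75, attempts = 120,
                         seed = 8)
  h <- evolve(cfg)
  ps <- pool_spectra(h, min_richness = 2)
  expect_s3_class(ps, "spectrum_set")
  expect_true(all(as.integer(names(ps)) >= 2))
  for (nm in names(ps))
    expect_equal(length(ps[[nm]]) %% as.integer(nm), 0)

  df <- data.frame(richness = c(3, 3, 4), re = c(-1, -2, -3),
                   im = c(0, 0, 0))
  ps2 <- pool_spectra(h, df, min_richness = 3)
  expect_equal(length(ps2[["3"]]),
               sum(h$eigenvalues$richness == 3) + 2)
})

test_that("two-species eigenvalue real parts stay within the parameter bound", {
  set.seed(6)
  worst_min <- 0; worst_max <- -1
  for (i in 1:3000) {
    d <- draw_feasible_pair()
    lam <- two_species_eigenvalues(
      two_species_system(d$alpha1, d$alpha2, d$beta * d$eta))
    worst_min <- min(worst_min, Re(lam))
    worst_max <- max(worst_max, Re(lam))
  }
  expect_gte(worst_min, -0.95)
  expect_lte(worst_max, 1e-10)
})
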