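test_that("fractional distributions normalize and are scale-invariant", {
  expect_equal(fractional_distribution(c(90, 10, 0, 0, 0, 0)),
               c(0.9, 0.1, 0, 0, 0, 0))
  set.seed(5)
  for (i in 1:10) {
    I <- runif(6, 0, 100)
    f <- fractional_distribution(I)
    expect_equal(f, I / sum(I))  # independent ratio computation
    expect_equal(fractional_distribution(I * runif(1, 0.1, 50)), f)
    expect_equal(sum(f), 1)
  }
  expect_error(fractional_distribution(rep(0, 6)), "all-zero")
  expect_error(fractional_distribution(c(1, -2, 3)))
})

test_that("percent incorporation is the labeled-molecule percentage", {
  expect_equal(percent_label_incorporation(c(1, 0, 0, 0, 0, 0)), 0)
  expect_equal(percent_label_incorporation(c(0.5, 0.5, 0, 0)), 50)
  set.seed(6)
  for (i in 1:10) {
    f <- fractional_distribution(runif(6))
    expect_equal(percent_label_incorporation(f), 100 * (1 - f[1]))
  }
  expect_error(percent_label_incorporation(c(0.5, 0.2)), "normalized")
})

test_that("mean enrichment is the atom-weighted labeled fraction", {
  expect_equal(mean_enrichment(c(0, 0, 0, 0, 0, 1)), 1)
  n <- 5
  uniform <- rep(1 / (n + 1), n + 1)
  expect_equal(mean_enrichment(uniform), 0.5)  # mean of 0..n is n/2
  expect_equal(mean_enrichment(c(1, 0, 0, 0, 0, 0)), 0)
  expect_error(mean_enrichment(c(0.5, 0.5), n = 3), "does not match")
})

test_that("the correction matrix is a truncated binomial convolution", {
  M <- na_correction_matrix(n = 4, n_atoms = 4, abundance = 0.0107)
  expect_true(all(M[upper.tri(M)] == 0))
  # window covers the full binomial support here, so columns sum to one
  expect_equal(colSums(M), rep(1, 5), tolerance = 1e-12)
  for (j in 0:4) {
    expect_equal(M[(j + 1):5, j + 1], dbinom(0:(4 - j), 4 - j, 0.0107))
  }
  # zero abundance collapses correction to the identity
  expect_equal(na_correction_matrix(3, 10, abundance = 0), diag(4))
})

test_that("correction inverts a forward natural-abundance convolution", {
  raw <- c(80, 20, 5)
  noab <- correct_natural_abundance(raw, n_atoms = 6, abundance = 0)
  expect_equal(noab$fractions, fractional_distribution(raw))
  expect_false(noab$flagged)
  # forward-convolve a known MID at 1.1% 13C, then correct it back
  truth <- c(0.55, 0.25, 0.12, 0.05, 0.02, 0.01)
  n_atoms <- 10  # e.g. AMP carbons
  observed <- convolve_natural_abundance(truth, n_atoms, abundance = 0.011)
  rec <- correct_natural_abundance(observed * 1e6, n_atoms, abundance = 0.011)
  expect_equal(rec$fractions, truth, tolerance = 1e-6)
  # and re-convolving the corrected MID reproduces the observation
  expect_equal(convolve_natural_abundance(rec$fractions, n_atoms,
                                          abundance = 0.011),
               observed, tolerance = 1e-9)
})

test_that("moiety labeling fractions match per-channel classification", {
  sch <- label_scheme("C", 10, 5)
  grid <- oracle_grid(10, 5)
  # all signal in the all-ribose channel (k = 5, j = 0)
  grid$area <- ifelse(grid$k == 5 & grid$j == 0, 100, 0)
  ml <- moiety_labeling(grid, sch)
  expect_equal(ml$fragment_labeled, 0)
  expect_equal(ml$remainder_labeled, 1)
  expect_true(ml$complete)
  grid$area <- ifelse(grid$k == 0, 50, 0)
  ml0 <- moiety_labeling(grid, sch)
  expect_equal(c(ml0$fragment_labeled, ml0$remainder_labeled), c(0, 0))
  set.seed(8)
  grid$area <- runif(nrow(grid))
  ml_r <- moiety_labeling(grid, sch)
  tot <- sum(grid$area)
  expect_equal(ml_r$fragment_labeled,
               sum(grid$area[grid$j >= 1]) / tot)      # enumeration oracle
  expect_equal(ml_r$remainder_labeled,
               sum(grid$area[(grid$k - grid$j) >= 1]) / tot)
  expect_warning(moiety_labeling(grid[1:10, ], sch), "incomplete")
  expect_error(moiety_labeling(data.frame(k = 1, j = 1, area = 0)),
               "all-zero")
})

test_that("presentation formats are mutually consistent", {
  set.seed(9)
  I <- runif(6, 0, 1000)
  f <- fractional_distribution(I)
  expect_equal(percent_label_incorporation(f),
               100 * sum(f[-1]))
  corrected <- correct_natural_abundance(I, n_atoms = 10)
  expect_equal(percent_label_incorporation(corrected$fractions),
               100 * (1 - corrected$fractions[1]))
})
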