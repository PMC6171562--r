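test_that("strategy enrichment is the labeled share of the feeding pool", {
  expect_equal(precursor_enrichment("conditioning", labeled = 0.5,
                                    unlabeled_medium = 0.5), 0.5)
  expect_equal(precursor_enrichment("medium_swap", labeled = 1), 1.0)
  expect_equal(precursor_enrichment("spike_in", labeled = 1,
                                    unlabeled_medium = 1,
                                    internal_pool = 1), 1 / 3)
  expect_error(precursor_enrichment("spike_in", 0, 0, 0), "zero")
  expect_error(precursor_enrichment("medium_swap", 1, unlabeled_medium = 0.5),
               "replaces")
})

test_that("single-pool simulation matches the closed form", {
  A <- 0.5; F <- 0.8; P <- 2
  m <- pool_chain_model(pool_sizes = P, flux = F, input = A)
  times <- seq(0, 20, 0.25)
  sim <- simulate_chain(m, times)
  expect_equal(sim$pool_1, A * (1 - exp(-(F / P) * times)), tolerance = 1e-6)
})

test_that("high flux labels faster and zero input stays unlabeled", {
  times <- seq(0, 30, 0.5)
  slow <- simulate_chain(pool_chain_model(c(1, 1), flux = 0.2, input = 0.5),
                         times)
  fast <- simulate_chain(pool_chain_model(c(1, 1), flux = 2, input = 0.5),
                         times)
  t_half <- function(sim) times[which(sim$pool_2 >= 0.25)[1]]
  expect_lt(t_half(fast), t_half(slow))
  zero <- simulate_chain(pool_chain_model(1, flux = 1, input = 0), times)
  expect_true(all(zero$pool_1 == 0))
})

test_that("h = 1 linear chains are monotone, bounded, and reach the input", {
  times <- seq(0, 100, 0.5)
  set.seed(12)
  for (i in 1:5) {
    np <- sample(1:4, 1)
    m <- pool_chain_model(pool_sizes = runif(np, 0.5, 3),
                          flux = runif(1, 0.3, 3), input = 0.5)
    sim <- simulate_chain(m, times)
    for (p in paste0("pool_", seq_len(np))) {
      expect_true(all(diff(sim[[p]]) >= -1e-9))          # monotone
      expect_true(all(sim[[p]] <= 0.5 + 1e-7))           # bounded by input
      expect_equal(sim[[p]][length(times)], 0.5, tolerance = 1e-3)
    }
  }
})

test_that("adding a pool lengthens the terminal lag", {
  times <- seq(0, 50, 0.25)
  t_half <- function(np) {
    sim <- simulate_chain(pool_chain_model(rep(1, np), flux = 1, input = 1),
                          times)
    times[which(sim[[paste0("pool_", np)]] >= 0.5)[1]]
  }
  halves <- vapply(1:4, t_half, numeric(1))
  expect_true(all(diff(halves) > 0))
})

test_that("cyclic recycling slows initial labeling but reaches the input", {
  times <- seq(0, 200, 0.5)
  lin <- simulate_chain(pool_chain_model(c(1, 1), flux = 1, input = 0.5),
                        times)
  cyc <- simulate_chain(pool_chain_model(c(1, 1), flux = 1, input = 0.5,
                                         topology = "cyclic",
                                         recycle_fraction = 0.5), times)
  expect_lt(cyc$pool_2[times == 2], lin$pool_2[times == 2])
  expect_equal(cyc$pool_2[length(times)], 0.5, tolerance = 1e-3)
})

test_that("multi-input convolution matches exhaustive enumeration", {
  expect_equal(simulate_multi_input(cbind(0.5, 0.5),
                                    n_atoms = c(1, 1))$fully_labeled, 0.25)
  traj <- cbind(seq(0, 0.8, length.out = 5), 0)
  expect_equal(simulate_multi_input(traj, c(3, 4))$fully_labeled, rep(0, 5))
  # brute force: enumerate all joint atom-label states for <= 10 atoms
  set.seed(13)
  p <- c(0.35, 0.7)
  n_atoms <- c(4, 5)
  got <- simulate_multi_input(matrix(p, 1), n_atoms)$distribution[1, ]
  atom_p <- rep(p, n_atoms)
  states <- expand.grid(rep(list(0:1), sum(n_atoms)))
  probs <- apply(states, 1, function(s) prod(ifelse(s == 1, atom_p,
                                                    1 - atom_p)))
  want <- vapply(0:sum(n_atoms),
                 function(k) sum(probs[rowSums(states) == k]), numeric(1))
  expect_equal(unname(got), want, tolerance = 1e-12)
})

test_that("curve fits recover known parameters and flag degenerate data", {
  t <- seq(0, 12, 0.5)
  y <- 0.5 * (1 - exp(-0.3 * t))
  fit <- fit_labeling_curve(t, y, model = "exponential")
  expect_true(fit$converged)
  expect_equal(fit$plateau, 0.5, tolerance = 1e-4)
  expect_equal(fit$rate, 0.3, tolerance = 1e-4)
  expect_equal(half_time(fit), log(2) / 0.3, tolerance = 1e-4)
  expect_s3_class(fit, "labeling_fit")
  expect_equal(unname(coef(fit)[["plateau"]]), fit$plateau)
  expect_equal(predict(fit, t), y, tolerance = 1e-6)
  expect_equal(residuals(fit), y - fitted(fit))
  zero <- fit_labeling_curve(t, rep(0, length(t)))
  expect_true(zero$degenerate)
  expect_equal(zero$plateau, 0)
  # lagged and sigmoidal families fit their own noise-free curves
  y_lag <- 0.6 * (1 - (0.9 * exp(-0.2 * t) - 0.2 * exp(-0.9 * t)) / 0.7)
  lag_fit <- fit_labeling_curve(t, y_lag, model = "lagged")
  expect_equal(lag_fit$plateau, 0.6, tolerance = 1e-3)
  expect_equal(lag_fit$rate, 0.2, tolerance = 1e-3)
  y_sig <- 0.7 * t^2 / (3^2 + t^2)
  sig_fit <- fit_labeling_curve(t, y_sig, model = "sigmoidal")
  expect_equal(sig_fit$plateau, 0.7, tolerance = 1e-3)
  expect_equal(sig_fit$shape, 2, tolerance = 1e-3)
})

test_that("moiety comparison reports rate and half-time ratios", {
  t <- seq(0, 10, 0.5)
  fit_fast <- fit_labeling_curve(t, 0.5 * (1 - exp(-1.0 * t)))
  fit_slow <- fit_labeling_curve(t, 0.5 * (1 - exp(-0.2 * t)))
  cmp <- compare_moieties(fit_fast, fit_slow, n_boot = 30, seed = 1)
  expect_equal(cmp$rate_ratio, 5.0, tolerance = 1e-3)
  expect_equal(cmp$half_time_ratio, 5.0, tolerance = 1e-3)
  same <- compare_moieties(fit_fast, fit_fast, n_boot = 30, seed = 1)
  expect_equal(same$rate_ratio, 1.0)
  zero <- fit_labeling_curve(t, rep(0, length(t)))
  expect_error(compare_moieties(fit_fast, zero), "converged")
})
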