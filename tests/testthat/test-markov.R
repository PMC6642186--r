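test_that("transition counting matches direct enumeration", {
  c1 <- count_transitions(c(0, 1, 0, 1, 0))
  expect_equal(unname(c1), matrix(c(0L, 2L, 2L, 0L), 2, byrow = TRUE))
  c2 <- count_transitions(rep(1, 5))
  expect_equal(unname(c2), matrix(c(0L, 0L, 0L, 4L), 2, byrow = TRUE))
  expect_equal(sum(c2), 4)
  # random series vs a naive pair loop
  set.seed(31)
  s <- as.integer(runif(1000) < 0.4)
  counts <- count_transitions(s)
  loop <- matrix(0L, 2, 2)
  for (t in 2:length(s))
    loop[s[t - 1] + 1, s[t] + 1] <- loop[s[t - 1] + 1, s[t] + 1] + 1L
  expect_equal(unname(counts), loop)
  expect_equal(sum(counts), length(s) - 1)
  expect_error(count_transitions(c(1)), "length")
})

test_that("posterior mean is symmetric for symmetric counts", {
  counts <- matrix(c(50L, 50L, 50L, 50L), 2)
  est <- posterior_probability(counts, n_samples = 5000, seed = 1)
  expect_lt(abs(est$mean_probability - 0.5), 3 * est$error)
  expect_gt(est$error, 0)
})

test_that("posterior recovers the analytic stationary probability", {
  s <- make_markov_series(0.2, 0.1, 10000, seed = 2)
  expect_equal(s$truth, 2 / 3)
  est <- posterior_probability(count_transitions(s$values),
                               n_samples = 5000, seed = 3)
  expect_lt(abs(est$mean_probability - 2 / 3), 3 * est$error)
})

test_that("an all-ones series drives the posterior mean towards 1", {
  est <- posterior_probability(count_transitions(rep(1L, 5000)),
                               n_samples = 5000, seed = 4)
  expect_gt(est$mean_probability, 0.99)
})

test_that("estimates are reproducible for identical inputs and seed", {
  counts <- count_transitions(make_markov_series(0.3, 0.2, 500,
                                                 seed = 5)$values)
  a <- posterior_probability(counts, n_samples = 1000, seed = 42)
  b <- posterior_probability(counts, n_samples = 1000, seed = 42)
  expect_identical(a$mean_probability, b$mean_probability)
  expect_identical(a$error, b$error)
  expect_error(posterior_probability(counts, n_samples = 1000),
               "seed")
  expect_error(posterior_probability(counts, n_samples = 50, seed = 1),
               "n_samples")
})

test_that("label exchange maps the stationary probability to its complement", {
  set.seed(6)
  for (rep in 1:5) {
    s <- make_markov_series(runif(1, 0.1, 0.5), runif(1, 0.1, 0.5),
                            2000, seed = 100 + rep)$values
    est <- posterior_probability(count_transitions(s), 4000, seed = 7)
    est_sw <- posterior_probability(count_transitions(1L - s), 4000,
                                    seed = 7)
    expect_lt(abs(est_sw$mean_probability - (1 - est$mean_probability)),
              3 * sqrt(est$error^2 + est_sw$error^2))
  }
})

test_that("posterior converges and tightens with series length", {
  lens <- c(100, 1000, 10000)
  errs <- sapply(lens, function(L) {
    mean(sapply(1:20, function(k) {
      s <- make_markov_series(0.2, 0.1, L, seed = 1000 * L + k)$values
      posterior_probability(count_transitions(s), 1000,
                            seed = k)$error
    }))
  })
  expect_true(all(diff(errs) < 0))
  # convergence of the mean at the longest length
  s <- make_markov_series(0.2, 0.1, 10000, seed = 8)$values
  est <- posterior_probability(count_transitions(s), 2000, seed = 9)
  expect_lt(abs(est$mean_probability - 2 / 3), 0.05)
})

test_that("matrix summaries report per-residue, per-bit estimates", {
  pc <- make_planted_complex(c("apolar", "hbond_protein_donor"))
  fs <- frame_series(rep(list(pc$model), 60))
  fpm <- suppressMessages(   # fixture has no waters; notice is expected
    compute_fingerprint_matrix(fs, "L", 901, topology = pc$topology))
  tab <- summarize_matrix(fpm, n_samples = 500, seed = 10)
  # always-on planted bits give probability near 1
  on <- tab[tab$bit %in% c("apolar", "hbond_protein_donor"), ]
  expect_equal(nrow(on), 2)
  expect_true(all(on$probability > 0.9))
  expect_true(all(on$empirical == 1))
  # all-zero series are dropped by default but reportable
  full <- summarize_matrix(fpm, n_samples = 500, seed = 10,
                           drop_zero = FALSE)
  zero <- full[full$probability == 0, ]
  expect_true(all(zero$error == 0))
  expect_equal(nrow(full), 2 * 9)
})

test_that("an all-zero matrix summarizes to empty (or all-zero) output", {
  pc <- make_planted_complex(c("apolar"))
  m <- pc$model
  # pull the ligand far away so nothing interacts
  lig <- m$atoms$chain == "L"
  m$atoms$z[lig] <- m$atoms$z[lig] + 500
  fpm <- suppressMessages(
    compute_fingerprint_matrix(structure_model(m$atoms), "L", 901,
                               topology = pc$topology))
  expect_equal(sum(fpm), 0)
  expect_equal(nrow(summarize_matrix(fpm, n_samples = 500, seed = 1)), 0)
})
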