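test_that("particle decoding takes the top-M scores with canonical tie-breaks", {
  nm <- paste0("f", 1:10)
  pos <- rep(0, 10); pos[c(2, 5, 9)] <- 10
  expect_equal(decode_particle(pos, 3, nm), c("f2", "f5", "f9"))
  ## all-equal scores: first M names in canonical order
  expect_equal(decode_particle(rep(1, 10), 3, nm), c("f1", "f2", "f3"))
  ## permutation consistency
  perm <- c(7, 3, 1, 10, 4, 2, 9, 5, 8, 6)
  pos2 <- runif(10)
  expect_setequal(decode_particle(pos2[perm], 4, nm[perm]),
                  decode_particle(pos2, 4, nm))
  expect_error(decode_particle(c(1, NA), 1, c("a", "b")), "finite")
})

test_that("k-fold splits partition the indices with balanced sizes", {
  folds <- kfold_split(678, 4, seed = 1)
  expect_setequal(unlist(folds), 1:678)
  expect_setequal(lengths(folds), c(170, 170, 169, 169))
  expect_identical(kfold_split(678, 4, seed = 1), folds)
  expect_false(identical(kfold_split(678, 4, seed = 2), folds))
  expect_error(kfold_split(10, 1), ">= 2")
  expect_error(kfold_split(3, 4), "exceed")
})

test_that("fitness is set-semantic, exact on realizable subsets, noise-resistant", {
  fm <- build_features(noiseless_cohort(n = 300, seed = 2))
  cfg <- swarm_config(seed = 5)
  truth <- c("age", "gender", "bmi", "adipsin/CRP")
  f_truth <- fitness(truth, fm, cfg)
  expect_lt(f_truth, 1e-6)
  expect_equal(fitness(rev(truth), fm, cfg), f_truth)

  ## a pure-noise extra feature never helps materially, on average over seeds
  fm_noisy <- build_features(small_cohort(n = 400, seed = 3))
  diffs <- vapply(1:6, function(s) {
    cfg_s <- swarm_config(seed = s)
    fitness(c(truth, "leptin"), fm_noisy, cfg_s) -
      fitness(truth, fm_noisy, cfg_s)
  }, numeric(1))
  expect_gt(mean(diffs), -0.02 * fitness(truth, fm_noisy, swarm_config(seed = 1)))
})

test_that("degenerate targets earn the penalty fitness", {
  fm <- build_features(small_cohort(n = 50, seed = 4))
  dat <- list(X = fm$X, y = rep(1000, 50))
  expect_equal(fitness(c("age", "bmi"), dat), 1e12)
  expect_error(fitness(character(0), fm), "non-empty")
  expect_error(fitness("nope", fm), "unknown")
})

test_that("a degenerate swarm is still defined and gbest never worsens", {
  fm <- build_features(small_cohort(n = 80, seed = 6))
  cfg1 <- swarm_config(swarm_size = 1, iterations = 0, n_starts = 1, seed = 2)
  res <- pso_search(fm, 3, cfg1)
  expect_length(res$subset, 3)
  expect_equal(res$fitness, fitness(res$subset, fm, cfg1))

  for (s in 1:4) {
    r <- pso_search(fm, 3, swarm_config(swarm_size = 10, iterations = 15,
                                        seed = s))
    expect_true(all(diff(r$history) <= 0))
  }
})

test_that("PSO matches the exhaustive oracle on a 12-feature space", {
  ## reduced space: the 12 dimensional variables only
  fm <- build_features(small_cohort(n = 250, seed = 8))
  dat <- list(X = fm$X[, fm$dimensional], y = fm$target)
  hits <- 0
  for (s in 1:5) {
    cfg <- swarm_config(seed = s)
    folds <- kfold_split(250, 4, seed = s)
    oracle <- min(vapply(enumerate_subsets(fm$dimensional, 3), fitness,
                         numeric(1), data = dat, cfg = cfg, folds = folds))
    got <- pso_search(dat, 3, cfg, folds = folds)$fitness
    expect_gte(got, oracle - 1e-9)  # cannot beat exhaustive search
    hits <- hits + (abs(got - oracle) < 1e-9)
  }
  expect_gte(hits, 4)
})

test_that("AIC algebra matches its closed form", {
  expect_equal(aic_score(100, 2 * 50, 4) - aic_score(100, 50, 4), 100 * log(2))
  expect_equal(aic_score(80, 10, 6) - aic_score(80, 10, 5), 2)
  expect_warning(a <- aic_score(10, 0, 2), "degenerate")
  expect_identical(a, -Inf)
  expect_error(aic_score(0, 1, 2), "positive")
})

test_that("Monte-Carlo selection bookkeeping is sound and mc_repeats=1 is one search", {
  fm <- build_features(small_cohort(n = 150, seed = 10))
  cfg <- swarm_config(mc_repeats = 1, swarm_size = 10, iterations = 10,
                      n_starts = 1, seed = 3)
  mc <- monte_carlo_select(fm, 3, cfg)
  folds <- kfold_split(150, 4, ipfpfis:::derive_seed(3L, 17L, 1L, 3L))
  single <- pso_search(fm, 3, cfg, folds = folds,
                       seed = ipfpfis:::derive_seed(3L, 19L, 1L, 3L))
  expect_identical(mc$subset, single$subset)
  expect_equal(mc$fitness, single$fitness)

  expect_true(all(mc$frequency >= 0 & mc$frequency <= 1))
  ## with one repeat the frequencies are the indicator of the chosen subset
  expect_equal(sum(mc$frequency), 3)
})

test_that("selection is deterministic under one master seed", {
  fm <- build_features(small_cohort(n = 120, seed = 12))
  cfg <- swarm_config(swarm_size = 10, iterations = 10, n_starts = 2,
                      mc_repeats = 2, seed = 9)
  a <- select_subsets(fm, 2:3, cfg)
  b <- select_subsets(fm, 2:3, cfg)
  expect_identical(a, b)
  expect_equal(a$winner$aic, min(a$aic))
})
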