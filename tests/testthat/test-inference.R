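test_that("conditional probability is the logistic local field", {
  zero <- maxent_model(c("a", "b", "c"))
  expect_equal(conditional_probability(zero, c(0, 1, 1), "a"), 0.5)
  ind <- maxent_model(c("a", "b"), h = c(1.2, -0.4))
  expect_equal(conditional_probability(ind, c(0, 0), "a"), plogis(1.2))
  expect_equal(conditional_probability(ind, c(0, 1), "a"), plogis(1.2))
  # against the exact conditional from enumeration
  m <- random_sparse_model(n_factors = 10, n_pairs = 10, n_triplets = 2,
                           seed = 81)
  oracle <- enum_oracle(m)
  key <- apply(oracle$patterns, 1, paste, collapse = "")
  set.seed(82)
  for (r in 1:50) {
    ctx <- rbinom(10, 1, 0.4)
    t_idx <- sample(10, 1)
    x1 <- ctx; x1[t_idx] <- 1
    x0 <- ctx; x0[t_idx] <- 0
    p1 <- oracle$prob[match(paste(x1, collapse = ""), key)]
    p0 <- oracle$prob[match(paste(x0, collapse = ""), key)]
    expect_equal(conditional_probability(m, ctx, m$factors[t_idx]),
                 p1 / (p1 + p0), tolerance = 1e-10)
  }
  expect_error(conditional_probability(m, rep(0, 10), "nope"),
               "not in model")
})

test_that("conditional probability rises with a positive coupling partner", {
  m <- maxent_model(c("a", "b"), h = c(-1, 0),
                    J = data.frame(i = 1, j = 2, value = 1.5))
  expect_gt(conditional_probability(m, c(0, 1), "a"),
            conditional_probability(m, c(0, 0), "a"))
})

test_that("profile imputation reproduces logistic regression on order-2 models", {
  m <- random_sparse_model(n_factors = 8, n_pairs = 10, seed = 83)
  dat <- sample_dataset(m, 500, seed = 84, method = "exact")
  target <- m$factors[3]
  keep <- setdiff(m$factors, target)
  ctx <- chromatin_code(dat$bins, dat$calls[, keep, drop = FALSE])
  p <- impute_profile(m, ctx, target)
  expect_length(p, 500)
  # manual logistic score with weights (h_t, J_t.)
  w <- numeric(8)
  rel <- m$J[m$J$i == 3 | m$J$j == 3, ]
  w[ifelse(rel$i == 3, rel$j, rel$i)] <- rel$value
  eta <- m$h[3] + as.numeric(dat$calls[, keep] %*% w[-3])
  expect_equal(p, plogis(eta), tolerance = 1e-12)
  # independence model gives a constant vector
  ind <- fit_independent(dat)
  expect_equal(unique(impute_profile(ind, ctx, target)),
               unname(plogis(ind$h[target])))
  # single-bin input
  one <- chromatin_code(dat$bins[1, ], dat$calls[1, keep, drop = FALSE])
  expect_length(impute_profile(m, one, target), 1)
  expect_error(impute_profile(m, chromatin_code(dat$bins,
                                                dat$calls[, 1:3]),
                              target), "minus the target")
})

test_that("imputation recovers held-out profiles of strongly coupled factors", {
  mi <- random_sparse_model(n_factors = 12, n_pairs = 18,
                            j_magnitude = c(2, 3), seed = 8)
  di <- sample_dataset(mi, 10000, seed = 9, method = "exact")
  aucs <- vapply(mi$factors, function(f) {
    ctx <- chromatin_code(di$bins,
                          di$calls[, setdiff(mi$factors, f),
                                   drop = FALSE])
    p <- impute_profile(mi, ctx, f)
    if (length(unique(di$calls[, f])) < 2) return(NA_real_)
    auc(p, di$calls[, f])
  }, numeric(1))
  expect_gt(mean(aucs, na.rm = TRUE), 0.8)
})

test_that("AUC follows the Mann-Whitney formulation with half tie credit", {
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0)
  # scores = labels with ties: pairs (1 pos x 2 neg): one win, one tie
  expect_equal(auc(c(1, 0, 0), c(1, 0, 1)), 0.75)
  expect_error(auc(1:3, c(1, 1, 1)), "both classes")
  set.seed(85)
  expect_lt(abs(auc(runif(10000), rbinom(10000, 1, 0.4)) - 0.5), 0.02)
})

test_that("joint imputation reduces to the single-target conditional for one target", {
  m <- random_sparse_model(n_factors = 8, n_pairs = 8, seed = 88)
  dat <- sample_dataset(m, 200, seed = 89, method = "exact")
  target <- m$factors[2]
  ctx <- chromatin_code(dat$bins, dat$calls[, -2, drop = FALSE])
  joint <- impute_profiles_joint(m, ctx, target, n_sweeps = 5,
                                 burn_in = 1, seed = 90)
  expect_equal(unname(joint[, target]),
               impute_profile(m, ctx, target), tolerance = 1e-12)
  # two targets: probabilities stay in [0,1] and deterministic by seed
  t2 <- m$factors[1:2]
  ctx2 <- chromatin_code(dat$bins, dat$calls[, -(1:2), drop = FALSE])
  j2 <- impute_profiles_joint(m, ctx2, t2, n_sweeps = 20, burn_in = 5,
                              seed = 91)
  expect_true(all(j2 >= 0 & j2 <= 1))
  expect_identical(j2, impute_profiles_joint(m, ctx2, t2, n_sweeps = 20,
                                             burn_in = 5, seed = 91))
})

test_that("cross-model prediction requires the shared factor set and matches locally", {
  m <- random_sparse_model(n_factors = 8, n_pairs = 8, seed = 86)
  dat <- sample_dataset(m, 300, seed = 87, method = "exact")
  target <- m$factors[1]
  ctx <- chromatin_code(dat$bins,
                        dat$calls[, -1, drop = FALSE])
  expect_identical(cross_model_predict(m, ctx, m$factors, target),
                   impute_profile(m, ctx, target))
  expect_error(cross_model_predict(m, ctx, m$factors[-8], target),
               "shared")
})
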