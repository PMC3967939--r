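test_that("pattern energy follows the self + pair + triplet sum", {
  m <- maxent_model(c("a", "b", "c"), h = c(0.5, -1, 2),
                    J = data.frame(i = c(1, 1, 2), j = c(2, 3, 3),
                                   value = c(0.3, -0.2, 0.7)),
                    K = data.frame(i = 1, j = 2, k = 3, value = -0.4))
  expect_identical(pattern_energy(m, c(0, 0, 0)), 0)
  expect_identical(pattern_energy(m, c(0, 1, 0)), -1)
  expect_equal(pattern_energy(m, c(1, 1, 1)),
               0.5 - 1 + 2 + 0.3 - 0.2 + 0.7 - 0.4)
})

test_that("exact log partition matches closed forms and caps at 20 factors", {
  expect_equal(exact_log_partition(maxent_model("a")), log(2))
  expect_equal(exact_log_partition(maxent_model(c("a", "b"))), log(4))
  m <- maxent_model(c("a", "b"),
                    J = data.frame(i = 1, j = 2, value = log(2)))
  expect_equal(exact_log_partition(m), log(5))
  big <- maxent_model(sprintf("f%02d", 1:21))
  expect_error(exact_log_partition(big), "20")
})

test_that("log probabilities normalize and match the enumeration oracle", {
  m <- random_sparse_model(n_factors = 10, n_pairs = 9, n_triplets = 1,
                           seed = 31)
  m$logZ <- exact_log_partition(m)
  oracle <- enum_oracle(m)
  expect_equal(m$logZ, oracle$logZ)
  pick <- seq(1, 1024, by = 11)
  expect_equal(exp(pattern_log_prob(m, oracle$patterns[pick, ])),
               oracle$prob[pick], tolerance = 1e-12)
  expect_equal(sum(exp(pattern_log_prob(m, oracle$patterns))), 1)
  expect_error(pattern_log_prob(maxent_model("a"), 1), "logZ")
})

test_that("probabilities are invariant under factor permutation", {
  m <- random_sparse_model(n_factors = 7, n_pairs = 6, n_triplets = 1,
                           seed = 5)
  perm <- c(3, 1, 7, 5, 2, 6, 4)
  inv <- order(perm)
  mp <- maxent_model(
    m$factors[perm],
    h = m$h[perm],
    J = data.frame(i = inv[m$J$i], j = inv[m$J$j], value = m$J$value),
    K = data.frame(i = inv[m$K$i], j = inv[m$K$j], k = inv[m$K$k],
                   value = m$K$value))
  m$logZ <- exact_log_partition(m)
  mp$logZ <- exact_log_partition(mp)
  expect_equal(mp$logZ, m$logZ)
  x <- rbinom(7, 1, 0.5)
  expect_equal(pattern_log_prob(mp, x[perm]), pattern_log_prob(m, x))
})

test_that("Gibbs samples reproduce enumerated distributions and marginals", {
  # uniform model: marginals 1/2
  u <- maxent_model(sprintf("f%d", 1:10))
  s <- gibbs_sample(u, 50000, burn_in = 200, seed = 1)
  mc_se <- sqrt(0.25 / 50000)
  expect_true(all(abs(colMeans(s$calls) - 0.5) < 4 * mc_se))
  # independence model: marginal = plogis(h)
  p <- c(0.1, 0.3, 0.6, 0.85)
  ind <- maxent_model(sprintf("f%d", 1:4), h = qlogis(p))
  si <- gibbs_sample(ind, 50000, burn_in = 200, seed = 2)
  expect_true(all(abs(colMeans(si$calls) - p) < 0.01))
  # pairwise model: total-variation distance against enumeration
  m <- random_sparse_model(n_factors = 8, n_pairs = 8, seed = 3)
  oracle <- enum_oracle(m)
  sm <- gibbs_sample(m, 3e5, burn_in = 500, seed = 4)
  key <- apply(oracle$patterns, 1, paste, collapse = "")
  emp <- table(factor(apply(sm$calls, 1, paste, collapse = ""),
                      levels = key)) / nrow(sm$calls)
  tv <- 0.5 * sum(abs(as.numeric(emp) - oracle$prob))
  expect_lt(tv, 0.02)
  # determinism
  expect_identical(gibbs_sample(m, 100, burn_in = 10, seed = 9)$calls,
                   gibbs_sample(m, 100, burn_in = 10, seed = 9)$calls)
})

test_that("independent Bernoulli fit recovers logit marginals with closed-form Z", {
  X <- cbind(a = rep(c(1L, 0L), each = 500),
             b = rep(c(1L, 0L, 0L, 0L), 250))
  fit <- fit_independent(tiny_code(X))
  N <- 1000
  expect_equal(unname(fit$h),
               qlogis(c(500.5, 250.5) / 1001))
  expect_equal(fit$logZ, sum(log1p(exp(fit$h))))
  # product-of-marginals factorization over all patterns
  oracle <- enum_oracle(fit)
  pm <- plogis(fit$h)
  prod_prob <- apply(oracle$patterns, 1, function(x) {
    prod(ifelse(x == 1, pm, 1 - pm))
  })
  expect_equal(oracle$prob, unname(prod_prob), tolerance = 1e-12)
  # constant column triggers clamping warning
  expect_warning(fit_independent(tiny_code(
    cbind(a = rep(1L, 100), b = rep(0:1, 50)))), "clamp")
})

test_that("parameter counting distinguishes dense and sparse views", {
  m73 <- maxent_model(sprintf("f%02d", 1:73), order = 2L)
  expect_equal(unname(count_parameters(m73, dense = TRUE)),
               c(73, 2628, 0))
  expect_equal(sum(count_parameters(m73, dense = TRUE)), 2701)
  ind <- maxent_model(sprintf("f%02d", 1:73), order = 1L)
  expect_equal(unname(count_parameters(ind, dense = TRUE)), c(73, 0, 0))
  sp <- random_sparse_model(n_factors = 10, n_pairs = 5, seed = 1)
  expect_equal(unname(count_parameters(sp, dense = FALSE))[2], 5)
})
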