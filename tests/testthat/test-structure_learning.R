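test_that("pseudo-likelihood value and gradient have the analytic form", {
  X <- tiny_code(cbind(a = c(1L, 0L, 1L, 0L), b = c(1L, 1L, 0L, 0L),
                       c = c(0L, 1L, 1L, 0L)))
  zero <- maxent_model(c("a", "b", "c"), order = 2L)
  r <- neg_log_pseudolikelihood(zero, X)
  expect_equal(r$value, 3 * log(2))  # every conditional is 1/2
  # independence stationarity: h at the marginal logits zeroes the h-gradient
  m <- maxent_model(c("a", "b", "c"), h = qlogis(colMeans(X$calls)),
                    order = 2L)
  expect_equal(unname(neg_log_pseudolikelihood(m, X)$gradient$h),
               rep(0, 3), tolerance = 1e-12)
})

test_that("pseudo-likelihood gradient matches central finite differences", {
  set.seed(42)
  m0 <- random_sparse_model(n_factors = 8, n_pairs = 8, n_triplets = 2,
                            seed = 7)
  dat <- sample_dataset(m0, 200, seed = 8, method = "exact")
  d <- chromcode:::pl_design(dat$calls, order = 3L)
  theta <- rnorm(d$n_par, sd = 0.4)
  g <- chromcode:::pl_value_grad(theta, d)$grad
  idx <- sample(d$n_par, 20)
  eps <- 1e-5
  num <- vapply(idx, function(i) {
    tp <- theta; tp[i] <- tp[i] + eps
    tm <- theta; tm[i] <- tm[i] - eps
    (chromcode:::pl_value_grad(tp, d)$value -
       chromcode:::pl_value_grad(tm, d)$value) / (2 * eps)
  }, numeric(1))
  expect_equal(num, g[idx], tolerance = 1e-6)
})

test_that("large penalties empty the support; lambda = 0 matches a generic optimizer", {
  m0 <- random_sparse_model(n_factors = 6, n_pairs = 5, seed = 11)
  dat <- sample_dataset(m0, 5000, seed = 12, method = "exact")
  strong <- fit_pairwise_l1(dat, 1e3)
  expect_equal(nrow(strong$J), 0L)
  ind <- fit_independent(dat, pseudocount = 0)
  expect_equal(unname(strong$h), unname(ind$h), tolerance = 1e-4)
  # unpenalized optimum vs stats::optim (independent convex solver)
  fit0 <- fit_pairwise_l1(dat, 0)
  d <- chromcode:::pl_design(dat$calls, order = 2L)
  o <- optim(numeric(d$n_par),
             fn = function(th) chromcode:::pl_value_grad(th, d)$value,
             gr = function(th) chromcode:::pl_value_grad(th, d)$grad,
             method = "L-BFGS-B",
             control = list(maxit = 2000, factr = 1e3))
  expect_equal(chromcode:::pl_value(chromcode:::model_to_theta(fit0, d), d),
               o$value, tolerance = 1e-4)
})

test_that("penalized objective value is monotone non-decreasing in lambda", {
  m0 <- random_sparse_model(n_factors = 8, n_pairs = 6, seed = 13)
  dat <- sample_dataset(m0, 4000, seed = 14, method = "exact")
  grid <- lambda_grid(dat, 2, length = 6)
  objs <- vapply(rev(grid), function(l) {
    attr(fit_pairwise_l1(dat, l, partial = TRUE), "objective")
  }, numeric(1))
  expect_true(all(diff(objs) >= -1e-6))
})

test_that("group-L1 output is hierarchical and empties under a large penalty", {
  m0 <- random_sparse_model(n_factors = 8, n_pairs = 8, n_triplets = 2,
                            seed = 15)
  dat <- sample_dataset(m0, 6000, seed = 16, method = "exact")
  big <- fit_hierarchical_group_l1(dat, 10)
  expect_equal(nrow(big$J), 0L)
  expect_equal(nrow(big$K), 0L)
  m <- fit_hierarchical_group_l1(dat, 0.02)
  expect_true(m$hierarchy_flag)
  if (nrow(m$K)) {
    jk <- paste(m$J$i, m$J$j)
    expect_true(all(paste(m$K$i, m$K$j) %in% jk &
                      paste(m$K$i, m$K$k) %in% jk &
                      paste(m$K$j, m$K$k) %in% jk))
  }
})

test_that("lambda selection by validation pseudo-likelihood behaves sanely", {
  m0 <- random_sparse_model(n_factors = 8, n_pairs = 6, seed = 17)
  tr <- sample_dataset(m0, 8000, seed = 18, method = "exact")
  va <- sample_dataset(m0, 3000, seed = 19, method = "exact")
  one <- select_lambda(tr, va, grid = 0.05, order = 2L)
  expect_equal(one$best_lambda, 0.05)
  sel <- select_lambda(tr, va, grid = lambda_grid(tr, 2, length = 8),
                       order = 2L)
  sc <- sel$path$val_score
  best <- sc[sel$path$lambda == sel$best_lambda]
  expect_lte(best, sc[1])
  expect_lte(best, sc[length(sc)])
  # under an independence truth the selected support is near-empty
  null_mod <- random_sparse_model(n_factors = 10, pair_density = 0,
                                  seed = 5)
  ntr <- sample_dataset(null_mod, 20000, seed = 6, method = "exact")
  nva <- sample_dataset(null_mod, 5000, seed = 7, method = "exact")
  nsel <- select_lambda(ntr, nva, grid = lambda_grid(ntr, 2, length = 10),
                        order = 2L)
  expect_lte(nrow(nsel$best_model$J), 2L)
})
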