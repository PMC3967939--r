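test_that("interaction score tables rank nonzero energies with signs", {
  m <- maxent_model(c("a", "b", "c"),
                    J = data.frame(i = c(1, 1), j = c(2, 3),
                                   value = c(2, -1)))
  tab <- interaction_energy_scores(m, order = 2L)
  expect_equal(tab$factor_a[1], "a")
  expect_equal(tab$factor_b[1], "b")
  expect_equal(tab$score, c(2, -1))
  expect_equal(tab$rank, 1:2)
  expect_error(interaction_energy_scores(m, order = 3L), "order-2")
  # relabeling invariance up to the name mapping
  m2 <- maxent_model(c("x", "y", "z"),
                     J = data.frame(i = c(1, 1), j = c(2, 3),
                                    value = c(2, -1)))
  expect_equal(interaction_energy_scores(m2, order = 2L)$score,
               tab$score)
})

test_that("pair scores are stable to adding a non-interacting factor", {
  base <- random_sparse_model(n_factors = 8, n_pairs = 8, seed = 91)
  aug <- maxent_model(c(base$factors, "extra"),
                      h = c(base$h, extra = -1.5),
                      J = base$J, order = 2L)
  # one dataset from the augmented model; fit with and without the
  # extra column so sampling noise cancels in the comparison
  tr2 <- sample_dataset(aug, 40000, seed = 92, method = "exact")
  tr1 <- chromatin_code(tr2$bins,
                        tr2$calls[, base$factors, drop = FALSE])
  f1 <- fit_pairwise_l1(tr1, 0.01, partial = TRUE)
  f2 <- fit_pairwise_l1(tr2, 0.01, partial = TRUE)
  k1 <- paste(f1$J$i, f1$J$j)
  k2 <- paste(f2$J$i, f2$J$j)
  planted <- paste(base$J$i, base$J$j)
  comm <- Reduce(intersect, list(planted, k1, k2))
  expect_gt(length(comm), 0)
  expect_lt(max(abs(f1$J$value[match(comm, k1)] -
                      f2$J$value[match(comm, k2)])), 0.1)
})

test_that("bootstrap precision-recall is exact for perfect rankings", {
  sc <- data.frame(factor_a = paste0("L", 1:30),
                   factor_b = paste0("R", 1:30), score = 30:1)
  std <- evaluation_standard(data.frame(a = paste0("L", 1:6),
                                        b = paste0("R", 1:6)))
  for (seed in c(1, 99)) {
    pr <- precision_recall_bootstrap(sc, std, n_boot = 200, seed = seed)
    expect_true(all(pr$curve$precision == 1))
  }
  expect_equal(pr$background_precision, 6 / 30)
  # n_boot = 1 equals the plain PR curve of the (resampled) standard
  pr1 <- precision_recall_bootstrap(sc, std, n_boot = 1, seed = 3)
  expect_true(all(pr1$curve$precision == 1))
  expect_error(precision_recall_bootstrap(
    sc, evaluation_standard(data.frame(a = character(0),
                                       b = character(0))), seed = 1),
    "empty")
})

test_that("random rankings recover background precision (simulation oracle)", {
  set.seed(95)
  n_pair <- 100
  n_pos <- 10
  std <- evaluation_standard(data.frame(a = paste0("L", 1:n_pos),
                                        b = paste0("R", 1:n_pos)))
  # independent oracle: expected mean precision of a random ranking,
  # computed from scratch with a plain cumsum-based PR curve
  oracle_mean <- mean(replicate(300, {
    pos_at <- sample(n_pair, n_pos)
    hit <- seq_len(n_pair) %in% pos_at
    prec <- cumsum(hit) / seq_len(n_pair)
    rec <- cumsum(hit) / n_pos
    mean(vapply(seq(0.01, 1, length.out = 100), function(r) {
      prec[which(rec >= r)[1]]
    }, numeric(1)))
  }))
  got <- mean(replicate(20, {
    sc <- data.frame(factor_a = paste0("L", 1:n_pair),
                     factor_b = paste0("R", 1:n_pair),
                     score = rnorm(n_pair))
    mean(precision_recall_bootstrap(sc, std, n_boot = 100,
                                    seed = 7)$curve$precision)
  }))
  expect_lt(abs(got - oracle_mean), 0.03)
  # mean precision sits above the 0.1 background rate (averaging bias)
  expect_gt(oracle_mean, 0.1)
})

test_that("baseline association scores behave on known structures", {
  # identical binary columns: MI equals the marginal entropy
  x <- rep(c(1L, 0L), c(300, 700))
  cc <- tiny_code(cbind(a = x, b = x))
  mi <- baseline_scores(cc, "mutual_information")
  H <- -(0.3 * log(0.3) + 0.7 * log(0.7))
  expect_equal(mi$score[1], H, tolerance = 1e-12)
  # independent continuous columns: small correlations
  set.seed(96)
  sm <- signal_matrix(tiny_bins(10000),
                      matrix(rnorm(50000), 10000, 5,
                             dimnames = list(NULL, paste0("f", 1:5))))
  pc <- baseline_scores(sm, "pearson")
  expect_gt(mean(abs(pc$score) < 0.05), 0.9)
  # Gaussian chain X -> Y -> Z: partial correlation screens off X-Z
  set.seed(97)
  X <- rnorm(20000)
  Y <- 0.8 * X + rnorm(20000, sd = 0.6)
  Z <- 0.8 * Y + rnorm(20000, sd = 0.6)
  smc <- signal_matrix(tiny_bins(20000),
                       cbind(X = X, Y = Y, Z = Z))
  pear <- baseline_scores(smc, "pearson")
  part <- baseline_scores(smc, "partial_correlation")
  key <- function(t) paste(t$factor_a, t$factor_b)
  xz <- which(key(pear) == "X Z")
  expect_gt(pear$score[xz], 0.3)
  xz2 <- which(key(part) == "X Z")
  expect_lt(abs(part$score[xz2]), 0.05)
  expect_error(baseline_scores(cc, "pearson"), "SignalMatrix")
})
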