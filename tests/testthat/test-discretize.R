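test_that("binning averages by extent and applies the coverage rule", {
  # fully covered window, values {1,3} -> mean 2
  nat <- signal_matrix(data.frame(chrom = "c", start = c(0L, 100L),
                                  end = c(100L, 200L)),
                       cbind(A = c(1, 3)))
  expect_equal(unname(bin_track(nat, 200)$values[1, 1]), 2)
  # 40% covered window is withheld (coverage recorded below 0.5)
  nat40 <- signal_matrix(data.frame(chrom = "c", start = 0L, end = 80L),
                         cbind(A = 5))
  bt <- bin_track(nat40, 200)
  expect_lt(bt$coverage[1], 0.5)
  expect_true(is.na(bt$values[1, 1]))
  # 1000 bp at native 5 bp resolution -> 5 bins of 200 bp
  nat5 <- signal_matrix(data.frame(chrom = "c", start = seq(0L, 995L, 5L),
                                   end = seq(5L, 1000L, 5L)),
                        cbind(A = rnorm(200)))
  expect_equal(nrow(bin_track(nat5, 200)$values), 5L)
  expect_error(bin_track(nat5, 0), "positive")
})

test_that("mixture fit recovers side and weight of a one-sided signal", {
  set.seed(101)
  v <- c(rnorm(45000), rnorm(5000, 4))
  f <- fit_background_signal(v)
  expect_equal(f$side, "right")
  expect_lt(abs(f$signal_weight - 0.10), 0.02)
  # densities integrate to ~1 on the grid
  dx <- f$grid[2] - f$grid[1]
  expect_equal(sum(f$background) * dx, 1, tolerance = 1e-3)
  expect_equal(sum(f$signal) * dx, 1, tolerance = 1e-3)
  # mirror image: same weight, left side
  fm <- fit_background_signal(-v)
  expect_equal(fm$side, "left")
  expect_equal(fm$signal_weight, f$signal_weight, tolerance = 1e-12)
  # degenerate input
  expect_error(fit_background_signal(rep(2, 5000)), "degenerate")
})

test_that("pure symmetric background yields a flagged near-zero weight", {
  set.seed(202)
  expect_warning(f <- fit_background_signal(rnorm(50000)), "below floor")
  expect_lt(f$signal_weight, 0.01)
  expect_true(f$low_signal)
})

test_that("threshold sits at the weighted-density crossing", {
  set.seed(303)
  v <- c(rnorm(45000), rnorm(5000, 4))
  f <- fit_background_signal(v)
  thr <- optimal_threshold(f)
  # closed-form crossing of 0.9 N(0,1) + 0.1 N(4,1)
  expect_lt(abs(thr - (log(9) + 8) / 4), 0.15)
  # local crossing property: background side dominated by background
  wsig <- f$signal * f$signal_weight
  wbg <- f$background * (1 - f$signal_weight)
  below <- f$grid > f$mode & f$grid < thr - 0.05
  above <- f$grid > thr + 0.25 & f$grid < 6
  expect_true(all(wbg[below] >= wsig[below]))
  expect_true(all(wsig[above] >= wbg[above]))
  # translation equivariance
  f2 <- fit_background_signal(v + 3)
  expect_lt(abs(optimal_threshold(f2) - (thr + 3)), 0.05)
})

test_that("binarize calls by side, drops withheld rows jointly, marks depletion", {
  fit_r <- structure(list(side = "right", threshold = 2.5,
                          low_signal = FALSE), class = "MixtureFit")
  fit_l <- structure(list(side = "left", threshold = -2.5,
                          low_signal = FALSE), class = "MixtureFit")
  sig <- signal_matrix(tiny_bins(3),
                       cbind(enr = c(1, 3, 0), dep = c(-3, 0, -4)),
                       coverage = c(1, 1, 0.4))
  cc <- binarize(sig, list(enr = fit_r, dep = fit_l))
  expect_equal(nrow(cc$calls), 2L)  # low-coverage row gone everywhere
  expect_equal(unname(cc$calls[, "enr"]), c(0L, 1L))
  expect_equal(colnames(cc$calls), c("enr", "dep-"))
  expect_equal(unname(cc$calls[, "dep-"]), c(1L, 0L))
  expect_error(binarize(sig, list(enr = fit_r)), "dep")
})

test_that("binarization rate tracks the signal mass beyond the threshold", {
  set.seed(404)
  n <- 40000
  lab <- rbinom(n, 1, 0.15)
  v <- rnorm(n) + 4 * lab
  f <- fit_background_signal(v)
  thr <- optimal_threshold(f)
  rate <- mean(v >= thr)
  expected <- 0.15 * (1 - pnorm(thr - 4)) + 0.85 * (1 - pnorm(thr))
  expect_lt(abs(rate - expected), 0.01)
})

test_that("expression discretization separates bimodal log-RPKM", {
  set.seed(505)
  lab <- rep(0:1, c(6000, 4000))
  lx <- rnorm(10000, mean = ifelse(lab == 1, 7, 2), sd = 0.8)
  rpkm <- pmax(2^lx - 1, 0)
  cls <- discretize_expression(rpkm)
  expect_gt(mean(cls == lab), 0.95)
  thr <- attr(cls, "threshold")
  expect_gt(thr, 2)
  expect_lt(thr, 7)
  expect_error(discretize_expression(numeric(10)), "all-zero")
  expect_error(discretize_expression(c(-1, 2)), "nonnegative")
  # unimodal expression propagates the low-signal flag
  set.seed(506)
  uni <- suppressWarnings(discretize_expression(pmax(2^rnorm(5000, 3) - 1, 0)))
  expect_true(attr(uni, "fit")$low_signal)
})
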