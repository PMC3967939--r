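# Penalized pseudo-likelihood structure learning.
#
# Pairwise model: mean negative log PL + lambda * sum |J_ij|, solved by
# FISTA (proximal gradient with backtracking); self-energies are never
# penalized. Third-order model: overlapping group-L1 where the group for
# pair (i,j) contains J_ij and every candidate K_ijk, solved by ADMM on
# the duplicated-variable formulation (exact zeros from the group
# soft-threshold). A triplet can survive only if all three of its pair
# groups are active, which yields a hierarchical support.

soft_threshold <- function(v, t) sign(v) * pmax(abs(v) - t, 0)

# FISTA minimizing f(theta) + lambda * sum(|theta[pen]|); fg returns
# value+gradient, fv value only (cheap backtracking)
fista_l1 <- function(theta0, fg, fv, pen_idx, lambda, tol = 1e-5,
                     max_iter = 5000L) {
  theta <- theta0
  y <- theta0
  tk <- 1
  step <- 1
  for (it in seq_len(max_iter)) {
    vg_y <- fg(y)
    # backtracking on the smooth part; value-only evaluations
    repeat {
      cand <- y - step * vg_y$grad
      cand[pen_idx] <- soft_threshold(cand[pen_idx], step * lambda)
      dlt <- cand - y
      if (fv(cand) <= vg_y$value + sum(vg_y$grad * dlt) +
          sum(dlt^2) / (2 * step) + 1e-12) break
      step <- step / 2
      if (step < 1e-12) break
    }
    theta_new <- cand
    tk_new <- (1 + sqrt(1 + 4 * tk^2)) / 2
    y_new <- theta_new + ((tk - 1) / tk_new) * (theta_new - theta)
    # restart if momentum points uphill
    if (sum((theta_new - theta) * (y_new - theta_new)) < 0) {
      y_new <- theta_new
      tk_new <- 1
    }
    y <- y_new
    theta <- theta_new
    tk <- tk_new
    step <- min(step * 1.5, 1e3)
    if (it %% 10 == 0) {
      vg <- fg(theta)
      g <- vg$grad
      opt <- max(c(abs(g[-pen_idx]),
                   abs(g[pen_idx] + lambda * sign(theta[pen_idx]))[
                     theta[pen_idx] != 0],
                   pmax(abs(g[pen_idx][theta[pen_idx] == 0]) - lambda, 0)))
      if (opt < tol) {
        return(list(theta = theta, converged = TRUE, iter = it,
                    objective = vg$value +
                      lambda * sum(abs(theta[pen_idx]))))
      }
    }
  }
  vg <- fg(theta)
  list(theta = theta, converged = FALSE, iter = max_iter,
       objective = vg$value + lambda * sum(abs(theta[pen_idx])))
}

#' Fit an L1-penalized pairwise maximum-entropy model
#'
#' Minimizes the mean negative log pseudo-likelihood plus
#' `lambda * sum_(i<j) |J_ij|`; `h` is unpenalized. The problem is convex
#' and solved by proximal gradient (FISTA) with backtracking; exact zeros
#' come from the soft-threshold step and entries below `1e-8` are
#' dropped.
#'
#' @param data a [chromatin_code()].
#' @param lambda nonnegative L1 penalty weight (on the per-row-mean
#'   objective scale).
#' @param tol optimality tolerance on the subgradient residual.
#' @param max_iter iteration cap; non-convergence raises an error
#'   carrying diagnostics unless `partial = TRUE`.
#' @param init optional warm-start [maxent_model()].
#' @param partial return the best iterate instead of erroring on
#'   non-convergence (used for warm-started paths).
#' @return a [maxent_model()] of order 2 with attributes `converged`,
#'   `iter`, `objective`, `lambda`.
#' @export
fit_pairwise_l1 <- function(data, lambda, tol = 1e-5, max_iter = 5000L,
                            init = NULL, partial = FALSE) {
  stopifnot(lambda >= 0)
  d <- pl_design(data$calls, order = 2L)
  theta0 <- if (is.null(init)) {
    c(qlogis(pmin(pmax(colMeans(d$X), 1 / (d$N + 2)),
                  1 - 1 / (d$N + 2))), numeric(d$npair))
  } else {
    model_to_theta(init, d)
  }
  pen <- d$n + seq_len(d$npair)
  fit <- fista_l1(theta0, function(th) pl_value_grad(th, d),
                  function(th) pl_value(th, d), pen, lambda, tol = tol,
                  max_iter = max_iter)
  if (!fit$converged && !partial) {
    stop("fit_pairwise_l1 did not converge in ", fit$iter,
         " iterations (lambda=", lambda, ", objective=",
         format(fit$objective), "); increase max_iter")
  }
  m <- theta_to_model(fit$theta, d, data$factors, order = 2L)
  attr(m, "converged") <- fit$converged
  attr(m, "iter") <- fit$iter
  attr(m, "objective") <- fit$objective
  attr(m, "lambda") <- lambda
  m
}

#' Fit a hierarchical group-L1 third-order maximum-entropy model
#'
#' Minimizes the mean negative log pseudo-likelihood plus
#' `lambda * sum_(i<j) ||theta_G(i,j)||_2`, where the group for pair
#' `(i, j)` contains `J_ij` and every candidate triplet energy `K_ijk`.
#' Groups overlap (each triplet sits in three groups), so a triplet can
#' be nonzero only when all three of its pair groups are active -- the
#' hierarchical constraint. Solved by ADMM on the duplicated-variable
#' formulation; group soft-thresholds give exact zeros. Any triplet whose
#' member pairs did not all survive is pruned from the returned support.
#'
#' @inheritParams fit_pairwise_l1
#' @param rho ADMM augmented-Lagrangian weight.
#' @param max_iter ADMM outer iteration cap.
#' @param triples optional candidate triple index matrix (rows `i<j<k`);
#'   default all `choose(n,3)` triples (intended for n <= 40).
#' @return a [maxent_model()] of order 3 with `hierarchy_flag = TRUE`.
#' @export
fit_hierarchical_group_l1 <- function(data, lambda, rho = 2,
                                      tol = 2e-4, max_iter = 2000L,
                                      init = NULL, triples = NULL,
                                      partial = TRUE) {
  stopifnot(lambda >= 0)
  d <- pl_design(data$calls, order = 3L, triples = triples)
  n <- d$n
  # copies: one per (group, member); group g = pair index
  cp_par <- c(n + seq_len(d$npair),                 # J_ij in own group
              n + d$npair + d$t_par)                # K in its 3 pair groups
  cp_grp <- c(seq_len(d$npair),
              d$pair_id[cbind(
                c(d$triples[, 1], d$triples[, 1], d$triples[, 2]),
                c(d$triples[, 2], d$triples[, 3], d$triples[, 3]))])
  ncp <- length(cp_par)
  theta <- if (is.null(init)) {
    c(qlogis(pmin(pmax(colMeans(d$X), 1 / (d$N + 2)),
                  1 - 1 / (d$N + 2))),
      numeric(d$npair + d$ntrip))
  } else {
    model_to_theta(init, d)
  }
  z <- theta[cp_par]
  u <- numeric(ncp)
  # number of copies per parameter (h: 0)
  ncopy <- numeric(d$n_par)
  tab <- table(cp_par)
  ncopy[as.integer(names(tab))] <- as.numeric(tab)
  # linearized ADMM: the theta-step replaces f by its linearization at
  # the current iterate plus a (1/2*eta) proximal term, giving a closed
  # form and costing one gradient per outer iteration; eta is adapted by
  # a descent-style backtracking on the smooth part
  eta <- 1
  vg <- pl_value_grad(theta, d)
  pri <- dua <- Inf
  par_ids <- sort(unique(cp_par))
  for (it in seq_len(max_iter)) {
    sp <- numeric(d$n_par)
    sp[par_ids] <- as.numeric(rowsum(z - u, cp_par, reorder = TRUE))
    repeat {
      th_new <- (theta / eta - vg$grad + rho * sp) /
        (1 / eta + rho * ncopy)
      dlt <- th_new - theta
      f_new <- pl_value(th_new, d)
      if (f_new <= vg$value + sum(vg$grad * dlt) +
          sum(dlt^2) / (2 * eta) + 1e-12) break
      eta <- eta / 2
      if (eta < 1e-10) break
    }
    theta <- th_new
    # z-step: group soft-threshold
    v <- theta[cp_par] + u
    z_old <- z
    grp_norm <- sqrt(as.numeric(rowsum(v^2, cp_grp, reorder = TRUE)))
    shrink <- pmax(0, 1 - (lambda / rho) / pmax(grp_norm, 1e-300))
    z <- v * shrink[cp_grp]
    u <- u + theta[cp_par] - z
    vg <- pl_value_grad(theta, d)
    pri <- sqrt(sum((theta[cp_par] - z)^2)) / sqrt(max(1, ncp))
    dua <- rho * sqrt(sum((z - z_old)^2)) / sqrt(max(1, ncp))
    if (pri < tol && dua < tol) break
    if (it %% 25 == 0) eta <- min(eta * 2, 1)
  }
  # support: a parameter survives iff all of its copies are nonzero
  zeroed <- unique(cp_par[z == 0])
  theta_out <- theta
  theta_out[zeroed] <- 0
  # consensus value: average copies into parameters that survive
  zs <- rowsum(z, cp_par, reorder = TRUE)
  idx <- as.integer(rownames(zs))
  theta_out[idx] <- ifelse(idx %in% zeroed, 0,
                           as.numeric(zs) / ncopy[idx])
  m <- theta_to_model(theta_out, d, data$factors, order = 3L,
                      hierarchy = TRUE)
  attr(m, "converged") <- (pri < tol && dua < tol)
  attr(m, "iter") <- it
  attr(m, "objective") <- {
    p <- theta_split(theta_out, d)
    gl <- sqrt(as.numeric(rowsum(c(p$Jv, p$Kv[d$t_par])^2, cp_grp,
                                 reorder = TRUE)))
    pl_value_grad(theta_out, d)$value + lambda * sum(gl)
  }
  attr(m, "lambda") <- lambda
  if (!attr(m, "converged") && !partial) {
    stop("fit_hierarchical_group_l1 did not converge (lambda=", lambda,
         ")")
  }
  m
}

#' Largest useful penalty for a regularization path
#'
#' The smallest `lambda` at which the penalized fit has empty interaction
#' support, computed from the pseudo-likelihood gradient at the
#' independence fit (all interactions zero, `h` at the marginal logits):
#' the max absolute pair gradient (order 2) or max pair-group gradient
#' norm (order 3).
#'
#' @param data a [chromatin_code()].
#' @param order 2 or 3.
#' @return positive scalar.
#' @export
lambda_max <- function(data, order = 2L) {
  d <- pl_design(data$calls, order = order)
  theta <- c(qlogis(pmin(pmax(colMeans(d$X), 1 / (d$N + 2)),
                         1 - 1 / (d$N + 2))),
             numeric(d$npair + d$ntrip))
  g <- theta_split(pl_value_grad(theta, d)$grad, d)
  if (order == 2L) {
    max(abs(g$Jv))
  } else {
    cp_grp <- c(seq_len(d$npair),
                d$pair_id[cbind(
                  c(d$triples[, 1], d$triples[, 1], d$triples[, 2]),
                  c(d$triples[, 2], d$triples[, 3], d$triples[, 3]))])
    vals <- c(g$Jv, g$Kv[d$t_par])
    max(sqrt(rowsum(vals^2, cp_grp, reorder = TRUE)))
  }
}

#' Default descending log-spaced penalty grid
#'
#' @inheritParams lambda_max
#' @param length grid size.
#' @param ratio smallest / largest lambda.
#' @return descending numeric vector from `lambda_max` down to
#'   `lambda_max * ratio`.
#' @export
lambda_grid <- function(data, order = 2L, length = 30L, ratio = 1e-3) {
  lmax <- lambda_max(data, order)
  exp(seq(log(lmax), log(lmax * ratio), length.out = length))
}

#' Select the penalty by validation pseudo-likelihood
#'
#' Fits one model per grid value (warm starts along the path) and picks
#' the `lambda` whose model attains the lowest mean negative log
#' pseudo-likelihood on the validation data; ties go to the larger
#' (sparser) `lambda`.
#'
#' @param train,val [chromatin_code()] objects with identical factors.
#' @param grid descending penalty grid (default [lambda_grid()]).
#' @param order 2 (L1 pairwise) or 3 (hierarchical group-L1).
#' @param ... passed to the underlying fitter.
#' @return list with `best_lambda`, `best_model`, and `path`: a
#'   data.frame of `lambda`, `val_score`, `n_pair`, `n_triplet` plus the
#'   fitted models as an attribute.
#' @export
select_lambda <- function(train, val, grid = NULL, order = 2L, ...) {
  stopifnot(identical(train$factors, val$factors))
  if (is.null(grid)) grid <- lambda_grid(train, order)
  stopifnot(length(grid) >= 1, !is.unsorted(rev(grid)))
  models <- vector("list", length(grid))
  scores <- numeric(length(grid))
  counts <- matrix(0, length(grid), 2)
  init <- NULL
  for (g in seq_along(grid)) {
    m <- if (order == 2L) {
      fit_pairwise_l1(train, grid[g], init = init, partial = TRUE, ...)
    } else {
      fit_hierarchical_group_l1(train, grid[g], init = init, ...)
    }
    models[[g]] <- m
    init <- m
    scores[g] <- neg_log_pseudolikelihood(m, val, order = m$order)$value
    counts[g, ] <- c(nrow(m$J), nrow(m$K))
  }
  # ties at printed precision go to the sparser (larger) lambda
  best <- which(scores <= min(scores) + 1e-12)[1]
  path <- data.frame(lambda = grid, val_score = scores,
                     n_pair = counts[, 1], n_triplet = counts[, 2])
  attr(path, "models") <- models
  list(best_lambda = grid[best], best_model = models[[best]],
       path = path)
}
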