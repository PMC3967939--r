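# Pseudo-likelihood objective for binary maximum-entropy models.
#
# The conditional of one factor given the rest is logistic in its local
# field  h_i + sum_j J_ij x_j + sum_(j<k) K_ijk x_j x_k,  so the negative
# log pseudo-likelihood (mean over rows, summed over factors) is a convex,
# exactly differentiable surrogate for the likelihood. All fitting
# routines work on a flat parameter vector
#   theta = c(h [n], J [n(n-1)/2], K [#candidate triples])
# laid out by a design object that also caches the pairwise product
# columns used by triplet terms.

pl_design <- function(X, order = 2L, triples = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  dimnames(X) <- NULL
  n <- ncol(X)
  pairs <- if (n >= 2) t(utils::combn(n, 2)) else matrix(0L, 0, 2)
  npair <- nrow(pairs)
  pair_id <- matrix(NA_integer_, n, n)
  if (npair) {
    pair_id[pairs] <- seq_len(npair)
    pair_id[pairs[, 2:1, drop = FALSE]] <- seq_len(npair)
  }
  if (order >= 3) {
    if (is.null(triples)) {
      triples <- if (n >= 3) t(utils::combn(n, 3)) else matrix(0L, 0, 3)
    }
    ntrip <- nrow(triples)
    P <- X[, pairs[, 1], drop = FALSE] * X[, pairs[, 2], drop = FALSE]
    # row/col skeleton of the (npair x n) map carrying K values into
    # local fields: triple (i,j,k) adds K to field of i via column jk, etc.
    t_rows <- c(pair_id[triples[, c(2, 3), drop = FALSE]],
                pair_id[triples[, c(1, 3), drop = FALSE]],
                pair_id[triples[, c(1, 2), drop = FALSE]])
    t_cols <- c(triples[, 1], triples[, 2], triples[, 3])
    t_par <- rep(seq_len(ntrip), 3)
  } else {
    triples <- matrix(0L, 0, 3)
    ntrip <- 0L
    P <- NULL
    t_rows <- t_cols <- t_par <- integer(0)
  }
  list(X = X, n = n, N = nrow(X), order = as.integer(order),
       pairs = pairs, npair = npair, pair_id = pair_id,
       triples = triples, ntrip = ntrip, P = P,
       t_rows = t_rows, t_cols = t_cols, t_par = t_par,
       n_par = n + npair + ntrip)
}

theta_split <- function(theta, d) {
  list(h = theta[seq_len(d$n)],
       Jv = theta[d$n + seq_len(d$npair)],
       Kv = if (d$ntrip) theta[d$n + d$npair + seq_len(d$ntrip)]
            else numeric(0))
}

# local fields, N x n
pl_fields <- function(theta, d) {
  p <- theta_split(theta, d)
  Jm <- matrix(0, d$n, d$n)
  if (d$npair) {
    Jm[d$pairs] <- p$Jv
    Jm[d$pairs[, 2:1, drop = FALSE]] <- p$Jv
  }
  L <- d$X %*% Jm
  L <- sweep(L, 2, p$h, "+")
  if (d$ntrip) {
    Tm <- Matrix::sparseMatrix(i = d$t_rows, j = d$t_cols,
                               x = p$Kv[d$t_par],
                               dims = c(d$npair, d$n))
    L <- L + as.matrix(d$P %*% Tm)
  }
  L
}

# value only (used by backtracking line searches)
pl_value <- function(theta, d) {
  L <- pl_fields(theta, d)
  sum(log1p(exp(-abs(L))) + pmax(L, 0) - d$X * L) / d$N
}

# value and gradient of the (unpenalized) mean negative log PL
pl_value_grad <- function(theta, d) {
  L <- pl_fields(theta, d)
  # -log P(x_i | rest) = log(1+exp(L)) - x_i L, numerically stable form
  val <- sum(log1p(exp(-abs(L))) + pmax(L, 0) - d$X * L) / d$N
  R <- stats::plogis(L) - d$X
  gh <- colSums(R) / d$N
  gJ <- numeric(0)
  gK <- numeric(0)
  if (d$npair) {
    G2 <- crossprod(R, d$X) / d$N
    gJ <- G2[d$pairs] + G2[d$pairs[, 2:1, drop = FALSE]]
  }
  if (d$ntrip) {
    G3 <- crossprod(d$P, R) / d$N
    gK <- as.numeric(rowsum(G3[cbind(d$t_rows, d$t_cols)],
                            d$t_par, reorder = TRUE))
  }
  list(value = val, grad = c(gh, gJ, gK))
}

# model -> theta on a design (dense parameterization of given order)
model_to_theta <- function(model, d) {
  theta <- numeric(d$n_par)
  theta[seq_len(d$n)] <- unname(model$h)
  if (nrow(model$J)) {
    theta[d$n + d$pair_id[cbind(model$J$i, model$J$j)]] <- model$J$value
  }
  if (nrow(model$K) && d$ntrip) {
    key <- paste(d$triples[, 1], d$triples[, 2], d$triples[, 3])
    pos <- match(paste(model$K$i, model$K$j, model$K$k), key)
    if (anyNA(pos)) stop("model triplet outside design candidate set")
    theta[d$n + d$npair + pos] <- model$K$value
  }
  theta
}

theta_to_model <- function(theta, d, factors, zero_tol = 1e-8,
                           order = d$order, hierarchy = FALSE) {
  p <- theta_split(theta, d)
  keepJ <- which(abs(p$Jv) > zero_tol)
  J <- data.frame(i = d$pairs[keepJ, 1], j = d$pairs[keepJ, 2],
                  value = p$Jv[keepJ])
  K <- NULL
  if (d$ntrip) {
    keepK <- which(abs(p$Kv) > zero_tol)
    K <- data.frame(i = d$triples[keepK, 1], j = d$triples[keepK, 2],
                    k = d$triples[keepK, 3], value = p$Kv[keepK])
    if (hierarchy && nrow(K)) {
      jkey <- paste(J$i, J$j)
      ok <- paste(K$i, K$j) %in% jkey & paste(K$i, K$k) %in% jkey &
        paste(K$j, K$k) %in% jkey
      K <- K[ok, , drop = FALSE]
    }
  }
  maxent_model(factors, h = p$h, J = J, K = K, order = order,
               hierarchy_flag = hierarchy)
}

#' Negative log pseudo-likelihood and its gradient
#'
#' The pseudo-likelihood replaces the joint likelihood by the product over
#' factors of the conditional probability of each factor given the rest;
#' its negative log (mean over rows, summed over factors) is convex and
#' needs no partition function. The gradient is returned for every
#' parameter of the dense parameterization at the requested order.
#'
#' @param model a [maxent_model()] whose factors match `data`.
#' @param data a [chromatin_code()].
#' @param order interaction order of the dense parameterization for the
#'   gradient (defaults to the model's order).
#' @return list with `value` (scalar) and `gradient`: a list with `h`
#'   (named numeric), `J` (data.frame `i, j, grad`) and, for order 3,
#'   `K` (data.frame `i, j, k, grad`).
#' @export
neg_log_pseudolikelihood <- function(model, data, order = model$order) {
  stopifnot(identical(model$factors, data$factors))
  d <- pl_design(data$calls, order = max(2L, order))
  vg <- pl_value_grad(model_to_theta(model, d), d)
  g <- theta_split(vg$grad, d)
  out <- list(value = vg$value,
              gradient = list(
                h = stats::setNames(g$h, model$factors),
                J = data.frame(i = d$pairs[, 1], j = d$pairs[, 2],
                               grad = g$Jv)))
  if (order >= 3) {
    out$gradient$K <- data.frame(i = d$triples[, 1], j = d$triples[, 2],
                                 k = d$triples[, 3], grad = g$Kv)
  }
  out
}
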