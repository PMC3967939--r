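#' Energy of binary patterns under a maximum-entropy model
#'
#' `E(x) = sum_i h_i x_i + sum_(i<j) J_ij x_i x_j +
#'  sum_(i<j<k) K_ijk x_i x_j x_k`. The all-zero pattern has energy 0, so
#' `P(all-zero) = 1/Z` -- the identity used by the Monte-Carlo partition
#' function estimator.
#'
#' @param model a [maxent_model()].
#' @param x a 0/1 vector of length `n`, or a 0/1 matrix with `n` columns
#'   (one pattern per row).
#' @return numeric vector of energies, one per pattern.
#' @export
pattern_energy <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- length(model$factors)
  stopifnot(ncol(x) == n, all(x %in% c(0, 1)))
  e <- as.numeric(x %*% model$h)
  if (nrow(model$J)) {
    for (r in seq_len(nrow(model$J))) {
      e <- e + model$J$value[r] * x[, model$J$i[r]] * x[, model$J$j[r]]
    }
  }
  if (nrow(model$K)) {
    for (r in seq_len(nrow(model$K))) {
      e <- e + model$K$value[r] *
        x[, model$K$i[r]] * x[, model$K$j[r]] * x[, model$K$k[r]]
    }
  }
  e
}

# all 2^n patterns as a 0/1 matrix (rows = patterns); n capped upstream
enumerate_patterns <- function(n) {
  stopifnot(n >= 1, n <= 20)
  m <- matrix(0L, 2L^n, n)
  ids <- 0:(2L^n - 1L)
  for (i in seq_len(n)) m[, i] <- bitwAnd(ids, bitwShiftL(1L, i - 1L)) > 0
  storage.mode(m) <- "integer"
  m
}

#' Exact log partition function by enumeration
#'
#' Sums `exp(E(x))` over all `2^n` patterns with a stable log-sum-exp.
#' Enumeration is intractable for large factor sets; a hard cap of
#' `n <= 20` is enforced -- use [estimate_log_partition_mc()] beyond it.
#'
#' @inheritParams pattern_energy
#' @return log Z (numeric scalar).
#' @export
exact_log_partition <- function(model) {
  n <- length(model$factors)
  if (n > 20) {
    stop("exact enumeration capped at 20 factors (2^n patterns); ",
         "use estimate_log_partition_mc()")
  }
  e <- pattern_energy(model, enumerate_patterns(n))
  m <- max(e)
  m + log(sum(exp(e - m)))
}

#' Log probability of patterns under a model
#'
#' `log P(x) = E(x) - log Z`. The model must carry `logZ` (exact via
#' [exact_log_partition()] or estimated via
#' [estimate_log_partition_mc()]).
#'
#' @inheritParams pattern_energy
#' @return numeric vector of log probabilities.
#' @export
pattern_log_prob <- function(model, x) {
  if (is.null(model$logZ)) {
    stop("model has no logZ; compute it with exact_log_partition() or ",
         "estimate_log_partition_mc()")
  }
  pattern_energy(model, x) - model$logZ
}

#' Draw samples from a model by sequential Gibbs sampling
#'
#' Single-site Gibbs updates in fixed factor order; one retained sample
#' per full sweep after `burn_in` sweeps. Deterministic given `seed`.
#'
#' @inheritParams pattern_energy
#' @param n_samples number of retained samples (sweeps).
#' @param burn_in discarded initial sweeps.
#' @param seed integer RNG seed (mandatory).
#' @param init optional 0/1 start state (default all-zero).
#' @return a [chromatin_code()] with `n_samples` rows on a synthetic
#'   chromosome at 200 bp pitch.
#' @export
gibbs_sample <- function(model, n_samples, burn_in = 1000L, seed,
                         init = NULL) {
  stopifnot(n_samples >= 1)
  if (missing(seed)) stop("seed is mandatory")
  n <- length(model$factors)
  if (is.null(init)) init <- integer(n)
  stopifnot(length(init) == n)
  tr <- triple_arrays(model)
  X <- withr_seed(seed, {
    .gibbs_sample_cpp(unname(model$h), j_matrix(model), tr$idx, tr$val,
                      as.integer(n_samples), as.integer(burn_in),
                      as.integer(init))
  })
  colnames(X) <- model$factors
  chromatin_code(synthetic_bins(nrow(X)), X)
}

# evaluate expr with a local RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

synthetic_bins <- function(n, chrom = "chrSim", width = 200L) {
  data.frame(chrom = chrom,
             start = (seq_len(n) - 1L) * width,
             end = seq_len(n) * width)
}

#' Fit the independent Bernoulli baseline
#'
#' No interactions; `h_i` is the logit of the (pseudocount-smoothed)
#' marginal frequency, and the partition function is available in closed
#' form, `log Z = sum_i log(1 + exp(h_i))`.
#'
#' @param data a [chromatin_code()].
#' @param pseudocount added to both the success and failure counts
#'   (Jeffreys-style 0.5 by default) so degenerate marginals stay finite.
#' @return a [maxent_model()] of order 1 with exact `logZ`.
#' @export
fit_independent <- function(data, pseudocount = 0.5) {
  stopifnot(inherits(data, "ChromatinCodeMatrix"), nrow(data$calls) >= 1)
  N <- nrow(data$calls)
  cnt <- colSums(data$calls)
  p <- (cnt + pseudocount) / (N + 2 * pseudocount)
  h <- qlogis(p)
  if (any(cnt == 0L | cnt == N)) {
    warning("constant factor column(s): ",
            paste(data$factors[cnt == 0L | cnt == N], collapse = ", "),
            "; smoothed self-energies clamped to |h| <= 15")
  }
  h <- pmin(pmax(h, -15), 15)
  maxent_model(data$factors, h = h, logZ = sum(log1p(exp(h))), order = 1L)
}

#' Count model parameters
#'
#' @inheritParams pattern_energy
#' @param dense if TRUE, count the full parameterization at the model's
#'   interaction order (`n`, `choose(n,2)`, `choose(n,3)`); if FALSE,
#'   count stored nonzero entries.
#' @return named integer vector `(n_self, n_pair, n_triplet)`.
#' @export
count_parameters <- function(model, dense = FALSE) {
  n <- length(model$factors)
  if (dense) {
    c(n_self = n,
      n_pair = if (model$order >= 2) choose(n, 2) else 0L,
      n_triplet = if (model$order >= 3) choose(n, 3) else 0L)
  } else {
    c(n_self = sum(model$h != 0),
      n_pair = nrow(model$J),
      n_triplet = nrow(model$K))
  }
}
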