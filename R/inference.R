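#' Conditional probability of one factor given the others
#'
#' Under the model the conditional of a single factor is logistic in its
#' local field:
#' `P(x_t = 1 | rest) = plogis(h_t + sum_j J_tj x_j +
#'  sum_(j<k) K_tjk x_j x_k)`
#' with sums over the observed active coordinates. No partition function
#' is needed, which is what makes context-based profile imputation cheap.
#'
#' @param model a [maxent_model()].
#' @param context 0/1 vector over the model factors (the target entry is
#'   ignored), or a 0/1 matrix with one context per row.
#' @param target factor name to predict.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
conditional_probability <- function(model, context, target) {
  t_idx <- match(target, model$factors)
  if (is.na(t_idx)) stop("target factor '", target, "' not in model")
  if (is.null(dim(context))) context <- matrix(context, nrow = 1)
  X <- as.matrix(context)
  storage.mode(X) <- "double"
  stopifnot(ncol(X) == length(model$factors))
  X[, t_idx] <- 0  # target coordinate never contributes to its own field
  field <- rep(unname(model$h[t_idx]), nrow(X))
  J <- model$J
  touch <- which(J$i == t_idx | J$j == t_idx)
  for (r in touch) {
    o <- if (J$i[r] == t_idx) J$j[r] else J$i[r]
    field <- field + J$value[r] * X[, o]
  }
  K <- model$K
  touchK <- which(K$i == t_idx | K$j == t_idx | K$k == t_idx)
  for (r in touchK) {
    oth <- setdiff(c(K$i[r], K$j[r], K$k[r]), t_idx)
    field <- field + K$value[r] * X[, oth[1]] * X[, oth[2]]
  }
  stats::plogis(field)
}

#' Impute a factor's genome-wide profile from the others
#'
#' Applies [conditional_probability()] at every bin of a dataset that
#' lacks the target factor's column, returning the per-bin probability
#' that the target is present -- the model-based reconstruction of an
#' unmeasured chromatin profile.
#'
#' @param model a [maxent_model()].
#' @param data a [chromatin_code()] whose factors are the model factors
#'   minus `target` (any order), or including `target` (ignored).
#' @param target factor name to impute.
#' @return numeric vector, one probability per bin, in input row order.
#' @export
impute_profile <- function(model, data, target) {
  if (!target %in% model$factors) stop("target not in model")
  need <- setdiff(model$factors, target)
  if (!setequal(setdiff(data$factors, target), need)) {
    stop("data factors must be the model factors minus the target")
  }
  X <- matrix(0, nrow(data$calls), length(model$factors),
              dimnames = list(NULL, model$factors))
  X[, setdiff(data$factors, target)] <-
    data$calls[, setdiff(data$factors, target)]
  conditional_probability(model, X, target)
}

#' Area under the ROC curve (Mann-Whitney)
#'
#' The probability that the score of a randomly chosen positive exceeds
#' that of a randomly chosen negative, with ties counting 1/2; computed
#' from rank sums.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 (or logical) true labels; both classes required.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels),
            all(labels %in% c(0L, 1L)))
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC undefined: both classes must be present")
  }
  r <- rank(scores)  # midranks give the 1/2 tie credit
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Jointly impute several missing factors (experimental)
#'
#' Single-target imputation ([impute_profile()]) conditions on fully
#' observed contexts. When several factors are missing at once their
#' joint conditional is not a product of logistics, so this routine
#' runs sequential Gibbs sampling over the missing coordinates only
#' (observed coordinates stay clamped) and reports each target's
#' posterior mean occupancy per bin. Experimental: chains are short by
#' default and no convergence diagnostic is applied.
#'
#' @param model a [maxent_model()].
#' @param data a [chromatin_code()] over the observed factors.
#' @param targets character vector of missing factor names (>= 1).
#' @param n_sweeps retained Gibbs sweeps per bin.
#' @param burn_in discarded initial sweeps.
#' @param seed integer RNG seed.
#' @return matrix (bins x targets) of posterior mean probabilities.
#' @export
impute_profiles_joint <- function(model, data, targets, n_sweeps = 200L,
                                  burn_in = 50L, seed) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(all(targets %in% model$factors))
  obs <- setdiff(model$factors, targets)
  if (!setequal(data$factors, obs)) {
    stop("data factors must be the model factors minus the targets")
  }
  nb <- nrow(data$calls)
  X <- matrix(0, nb, length(model$factors),
              dimnames = list(NULL, model$factors))
  X[, obs] <- data$calls[, obs]
  acc <- matrix(0, nb, length(targets),
                dimnames = list(NULL, targets))
  withr_seed(seed, {
    for (sweep in seq_len(burn_in + n_sweeps)) {
      for (t in targets) {
        p <- conditional_probability(model, X, t)
        X[, t] <- as.numeric(runif(nb) < p)
        if (sweep > burn_in) acc[, t] <- acc[, t] + p
      }
    }
  })
  acc / n_sweeps
}

#' Impute a profile with a model trained on another dataset
#'
#' Cross-context (e.g. cross-cell-type) prediction: a model trained on
#' another cell type's data for the shared factor set is applied to this
#' dataset's context. The foreign model must have been trained on exactly
#' the shared factors -- no marginalization over non-shared factors is
#' attempted.
#'
#' @param model_other a [maxent_model()] trained on the shared set.
#' @param data a [chromatin_code()] over the shared factors minus the
#'   target.
#' @param shared_factors the consensus factor set.
#' @param target factor to impute (must be in `shared_factors`).
#' @return per-bin probability vector.
#' @export
cross_model_predict <- function(model_other, data, shared_factors,
                                target) {
  if (!setequal(model_other$factors, shared_factors)) {
    stop("model factor set must equal the shared factor set; retrain ",
         "on the consensus factors")
  }
  if (!target %in% shared_factors) stop("target not in shared factors")
  impute_profile(model_other, data, target)
}
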