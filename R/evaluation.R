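#' Monte-Carlo estimate of the log partition function
#'
#' Because the all-zero pattern has energy 0, its probability is exactly
#' `1/Z`; drawing Gibbs samples and inverting the observed all-zero
#' fraction therefore estimates `Z`. The all-zero pattern is typically
#' the most common chromatin code, which keeps this estimator reliable.
#'
#' @inheritParams gibbs_sample
#' @param n_samples Gibbs sweeps retained (default one million).
#' @return estimated log Z.
#' @export
estimate_log_partition_mc <- function(model, n_samples = 1e6,
                                      burn_in = 1000L, seed) {
  s <- gibbs_sample(model, n_samples, burn_in = burn_in, seed = seed)
  n0 <- sum(rowSums(s$calls) == 0L)
  if (n0 == 0L) {
    stop("no all-zero pattern among ", n_samples, " samples; use ",
         "exact_log_partition() for small models or more samples")
  }
  if (n0 < 10L) {
    warning("all-zero pattern seen only ", n0, " times; logZ estimate ",
            "is unstable")
  }
  -log(n0 / n_samples)
}

#' Coherence score of a model on held-out data
#'
#' The exponential of the mean per-pattern log-likelihood on test data --
#' a per-bin geometric-mean probability, in `(0, 1]`, higher is better.
#' Scores of competing models are conventionally reported normalized to
#' the best model (see [normalize_coherence()]).
#'
#' @param model a [maxent_model()] with `logZ` set.
#' @param test a [chromatin_code()] with matching factors.
#' @return scalar coherence score.
#' @export
coherence_score <- function(model, test) {
  stopifnot(identical(model$factors, test$factors))
  exp(mean(pattern_log_prob(model, test$calls)))
}

#' Normalize coherence scores to the best model
#'
#' @param scores named numeric vector of coherence scores.
#' @return scores divided by their maximum (best model = 1).
#' @export
normalize_coherence <- function(scores) scores / max(scores)

#' Predicted versus observed pattern frequencies on a factor subset
#'
#' Model frequencies are obtained by Gibbs sampling and marginalizing to
#' the subset coordinates (fraction of samples matching each pattern);
#' observed frequencies come from the test rows. Patterns are enumerated
#' exhaustively for subsets of up to `enumerate_max` factors, otherwise
#' the union of observed and sampled patterns is tabulated.
#'
#' @inheritParams coherence_score
#' @param factor_subset character vector of factor names.
#' @param observed a [chromatin_code()] providing observed frequencies.
#' @param n_samples Gibbs sweeps.
#' @param seed integer RNG seed.
#' @param min_count drop patterns observed fewer than this many times in
#'   the test data (0 keeps all, including never-seen enumerated ones).
#' @param enumerate_max subset size up to which all `2^k` patterns are
#'   listed.
#' @return data.frame `pattern` (e.g. "0101"), `predicted`, `observed`,
#'   `n_observed`.
#' @export
predict_pattern_frequencies <- function(model, factor_subset, observed,
                                        n_samples = 1e5, seed,
                                        min_count = 0L,
                                        enumerate_max = 10L) {
  stopifnot(all(factor_subset %in% model$factors),
            identical(model$factors, observed$factors))
  s <- gibbs_sample(model, n_samples, seed = seed)
  key <- function(M) apply(M[, factor_subset, drop = FALSE], 1, paste,
                           collapse = "")
  samp <- table(key(s$calls))
  obs <- table(key(observed$calls))
  k <- length(factor_subset)
  pats <- if (k <= enumerate_max) {
    apply(enumerate_patterns(k), 1, paste, collapse = "")
  } else {
    sort(union(names(samp), names(obs)))
  }
  n_obs <- as.integer(obs[pats])
  n_obs[is.na(n_obs)] <- 0L
  pred <- as.numeric(samp[pats]) / n_samples
  pred[is.na(pred)] <- 0
  out <- data.frame(pattern = pats, predicted = pred,
                    observed = n_obs / nrow(observed$calls),
                    n_observed = n_obs, stringsAsFactors = FALSE)
  if (min_count > 0L) out <- out[out$n_observed >= min_count, ,
                                 drop = FALSE]
  out
}

#' Split genomic bins into train / validation / test slices
#'
#' The genome (in bin order) is cut into `n_slices` contiguous slices of
#' near-equal bin counts (sizes differ by at most 1). Half the slices
#' (rounded down) are assigned to training at random; the remaining
#' slices alternate validation, test in genome order. Contiguous slices
#' minimize dependency between the sets while keeping each set spread
#' over the genome.
#'
#' @param bins data.frame `chrom, start, end`, sorted by (chrom, start).
#' @param n_slices number of slices (default 50).
#' @param seed integer RNG seed for the slice-to-set assignment.
#' @return factor vector (length = rows of `bins`) with levels
#'   `train`, `val`, `test`.
#' @export
split_genome <- function(bins, n_slices = 50L, seed) {
  nb <- nrow(bins)
  if (nb < n_slices) stop("fewer bins (", nb, ") than slices (",
                          n_slices, ")")
  ord <- order(bins$chrom, bins$start)
  if (!identical(ord, seq_len(nb))) {
    stop("bins must be sorted by (chrom, start)")
  }
  sizes <- rep(nb %/% n_slices, n_slices)
  extra <- nb %% n_slices
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  slice <- rep(seq_len(n_slices), times = sizes)
  n_train <- n_slices %/% 2L
  train_slices <- withr_seed(seed, sample(n_slices, n_train))
  rest <- setdiff(seq_len(n_slices), train_slices)
  lab <- character(n_slices)
  lab[train_slices] <- "train"
  lab[rest] <- rep_len(c("val", "test"), length(rest))
  factor(lab[slice], levels = c("train", "val", "test"))
}
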