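# Planted-model fixture generation. All test and benchmark surfaces run
# on models and datasets produced here, where the ground truth
# (interaction support, signs, magnitudes, class labels) is known.

#' Draw a random sparse maximum-entropy model
#'
#' Pairs enter the support independently with probability
#' `pair_density`; triplets are drawn (with probability
#' `triplet_density`) only among triples whose three member pairs were
#' all selected, so the support is hierarchical by construction.
#' Magnitudes are uniform in the given ranges, negated with probability
#' `neg_fraction`; self-energies are uniform in `h_range`. Deterministic
#' given `seed`.
#'
#' The defaults mirror the package's fixed recovery benchmark: 15
#' factors with 12 planted pairs of `|J|` in `[0.8, 2]`, a 30% negative
#' fraction, and self-energies in `[-2.5, -1]`. The self-energy range
#' keeps per-factor occupancy sparse (roughly 0.1-0.4 after interaction
#' effects), matching binarized chromatin data, where the all-zero code
#' is the most common pattern.
#'
#' @param n_factors number of factors.
#' @param pair_density probability a pair carries a nonzero `J`.
#' @param triplet_density probability an eligible triple carries a
#'   nonzero `K`.
#' @param h_range,j_magnitude,k_magnitude uniform ranges.
#' @param neg_fraction probability an interaction is negative.
#' @param seed integer RNG seed.
#' @param n_pairs optionally plant exactly this many pairs (overrides
#'   `pair_density`).
#' @param n_triplets optionally plant exactly this many triplets among
#'   the eligible triples (overrides `triplet_density`; best effort with
#'   a warning when fewer are eligible).
#' @return a [maxent_model()] with `hierarchy_flag = TRUE`.
#' @export
random_sparse_model <- function(n_factors = 15L,
                                pair_density = 12 / choose(15, 2),
                                triplet_density = 0,
                                h_range = c(-2.5, -1),
                                j_magnitude = c(0.8, 2),
                                k_magnitude = c(0.8, 1.5),
                                neg_fraction = 0.3, seed,
                                n_pairs = NULL, n_triplets = NULL) {
  stopifnot(pair_density >= 0, pair_density <= 1,
            triplet_density >= 0, triplet_density <= 1)
  if (missing(seed)) stop("seed is mandatory")
  withr_seed(seed, {
    factors <- sprintf("F%02d", seq_len(n_factors))
    h <- runif(n_factors, h_range[1], h_range[2])
    pairs <- t(utils::combn(n_factors, 2))
    pid <- matrix(NA_integer_, n_factors, n_factors)
    pid[pairs] <- seq_len(nrow(pairs))
    pid[pairs[, 2:1, drop = FALSE]] <- seq_len(nrow(pairs))
    planted_trip <- NULL
    if (!is.null(n_triplets) && n_triplets > 0) {
      # plant triplets first and close their triangles, so the
      # hierarchical support is guaranteed
      trip_all <- t(utils::combn(n_factors, 3))
      planted_trip <- trip_all[sample.int(nrow(trip_all), n_triplets), ,
                               drop = FALSE]
      required <- unique(c(pid[planted_trip[, c(1, 2), drop = FALSE]],
                           pid[planted_trip[, c(1, 3), drop = FALSE]],
                           pid[planted_trip[, c(2, 3), drop = FALSE]]))
    } else {
      required <- integer(0)
    }
    sel <- if (is.null(n_pairs)) {
      union(required, which(runif(nrow(pairs)) < pair_density))
    } else {
      if (length(required) > n_pairs) {
        warning("n_pairs raised to ", length(required),
                " to close the planted triangles")
      }
      extra <- setdiff(seq_len(nrow(pairs)), required)
      union(required,
            extra[sample.int(length(extra),
                             max(0L, n_pairs - length(required)))])
    }
    sel <- sort(sel)
    J <- NULL
    if (length(sel)) {
      mag <- runif(length(sel), j_magnitude[1], j_magnitude[2])
      sgn <- ifelse(runif(length(sel)) < neg_fraction, -1, 1)
      J <- data.frame(i = pairs[sel, 1], j = pairs[sel, 2],
                      value = mag * sgn)
    }
    K <- NULL
    want_trip <- triplet_density > 0 ||
      (!is.null(n_triplets) && n_triplets > 0)
    if (want_trip) {
      if (is.null(J) || nrow(J) < 3) {
        warning("no triple has all three pairs planted; ",
                "triplet support empty")
      } else {
        jkey <- paste(J$i, J$j)
        trip <- t(utils::combn(n_factors, 3))
        ok <- paste(trip[, 1], trip[, 2]) %in% jkey &
          paste(trip[, 1], trip[, 3]) %in% jkey &
          paste(trip[, 2], trip[, 3]) %in% jkey
        cand <- which(ok)
        if (!length(cand)) {
          warning("no triple has all three pairs planted; ",
                  "triplet support empty")
        } else {
          ksel <- if (!is.null(planted_trip)) {
            key <- paste(trip[, 1], trip[, 2], trip[, 3])
            match(paste(planted_trip[, 1], planted_trip[, 2],
                        planted_trip[, 3]), key)
          } else {
            cand[runif(length(cand)) < triplet_density]
          }
          if (length(ksel)) {
            mag <- runif(length(ksel), k_magnitude[1], k_magnitude[2])
            sgn <- ifelse(runif(length(ksel)) < neg_fraction, -1, 1)
            K <- data.frame(i = trip[ksel, 1], j = trip[ksel, 2],
                            k = trip[ksel, 3], value = mag * sgn)
          }
        }
      }
    }
    maxent_model(factors, h = h, J = J, K = K,
                 order = if (want_trip) 3L else
                   if (pair_density > 0 || !is.null(n_pairs)) 2L else 1L,
                 hierarchy_flag = TRUE)
  })
}

#' Sample a dataset from a model
#'
#' `method = "exact"` enumerates all `2^n` patterns and draws rows from
#' the exact categorical distribution (n <= 20); `method = "gibbs"` uses
#' the sequential Gibbs sampler. Bins are laid out on a synthetic
#' chromosome at 200 bp pitch.
#'
#' @param model a [maxent_model()].
#' @param n_bins rows to draw.
#' @param seed integer RNG seed.
#' @param method `"exact"` or `"gibbs"`.
#' @param burn_in Gibbs burn-in sweeps.
#' @return a [chromatin_code()].
#' @export
sample_dataset <- function(model, n_bins, seed,
                           method = c("exact", "gibbs"),
                           burn_in = 1000L) {
  method <- match.arg(method)
  if (missing(seed)) stop("seed is mandatory")
  n <- length(model$factors)
  if (method == "gibbs") {
    return(gibbs_sample(model, n_bins, burn_in = burn_in, seed = seed))
  }
  if (n > 20) stop("exact sampling capped at 20 factors; use gibbs")
  pats <- enumerate_patterns(n)
  e <- pattern_energy(model, pats)
  p <- exp(e - max(e))
  rows <- withr_seed(seed, {
    sample.int(nrow(pats), n_bins, replace = TRUE, prob = p)
  })
  calls <- pats[rows, , drop = FALSE]
  colnames(calls) <- model$factors
  chromatin_code(synthetic_bins(n_bins), calls)
}

#' Continuous mixture tracks for a binary code
#'
#' Emulates the signal model the thresholding stage assumes: each value
#' is a symmetric mean-zero background draw plus `signal_shift` times
#' the binary call, with the shift negated for depletion factors (whose
#' informative signal is loss). Coverage is full.
#'
#' @param code a [chromatin_code()].
#' @param background_sd background standard deviation.
#' @param signal_shift mean shift of the signal component (> 0).
#' @param depletion_factors factor names whose shift is negated.
#' @param seed integer RNG seed.
#' @return a [signal_matrix()].
#' @export
synthetic_signal_tracks <- function(code, background_sd = 1,
                                    signal_shift = 4,
                                    depletion_factors = character(0),
                                    seed) {
  stopifnot(signal_shift >= 0)
  if (missing(seed)) stop("seed is mandatory")
  bad <- setdiff(depletion_factors, code$factors)
  if (length(bad)) stop("unknown depletion factor: ",
                        paste(bad, collapse = ", "))
  shift <- ifelse(code$factors %in% depletion_factors,
                  -signal_shift, signal_shift)
  vals <- withr_seed(seed, {
    matrix(rnorm(length(code$calls), sd = background_sd),
           nrow(code$calls), ncol(code$calls)) +
      sweep(code$calls, 2, shift, "*")
  })
  colnames(vals) <- code$factors
  signal_matrix(code$bins, vals)
}

#' The fixed planted-model recovery benchmark configuration
#'
#' A versioned configuration (15 factors, 12 planted pairs with `|J|` in
#' `[0.8, 2]`, 30% negative, 20,000 training bins plus validation of the
#' same size, seeds offset from `seed`) used by the recovery tests and
#' the acceptance script, so benchmark numbers are stable.
#'
#' @param seed base integer seed.
#' @param n_bins training rows.
#' @return list with `model`, `train`, `val` ([chromatin_code()]s).
#' @export
planted_benchmark <- function(seed, n_bins = 20000L) {
  model <- random_sparse_model(n_factors = 15L, n_pairs = 12L,
                               seed = seed)
  train <- sample_dataset(model, n_bins, seed = seed + 1000L,
                          method = "exact")
  val <- sample_dataset(model, max(n_bins %/% 4L, 1000L),
                        seed = seed + 2000L, method = "exact")
  list(model = model, train = train, val = val)
}
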