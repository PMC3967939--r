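#' Extract ranked interaction energy scores from a fitted model
#'
#' The interaction energy score of a pair (triple) is its fitted `J_ij`
#' (`K_ijk`): the log fold change in pattern frequency attributable to
#' that interaction, conditioned on all other modeled factors -- which is
#' what lets it discount transitive correlations. Rows are ranked by
#' descending score (strong positive interactions first), signs
#' preserved.
#'
#' @param model a fitted [maxent_model()].
#' @param order 2 for pairwise scores, 3 for triplet scores (requires an
#'   order-3 model).
#' @return data.frame with `factor_a`, `factor_b` (+ `factor_c` for
#'   order 3), `score`, `rank`.
#' @export
interaction_energy_scores <- function(model, order = 2L) {
  if (order == 3L && model$order < 3L) {
    stop("triplet scores requested from an order-", model$order, " model")
  }
  f <- model$factors
  if (order == 2L) {
    tab <- data.frame(factor_a = f[model$J$i], factor_b = f[model$J$j],
                      score = model$J$value, stringsAsFactors = FALSE)
  } else {
    tab <- data.frame(factor_a = f[model$K$i], factor_b = f[model$K$j],
                      factor_c = f[model$K$k], score = model$K$value,
                      stringsAsFactors = FALSE)
  }
  tab <- tab[order(-tab$score), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}

pair_key <- function(a, b) {
  ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
}

#' Bootstrap-averaged precision-recall against an interaction standard
#'
#' The curated positives are resampled with replacement `n_boot` times;
#' a precision-recall curve over the scored pair universe is computed per
#' round (negatives = all scored pairs outside the resampled positive
#' set, resample multiplicities kept as weights), precision is read off
#' at a fixed recall grid by step interpolation, and the rounds are
#' averaged. Standard pairs missing from the score table are kept as
#' positives with score `-Inf` (ranked last).
#'
#' @param scores an interaction score table
#'   ([interaction_energy_scores()] or [baseline_scores()]).
#' @param standard an [evaluation_standard()].
#' @param n_boot bootstrap rounds (default 2000).
#' @param seed integer RNG seed.
#' @param recall_grid recall levels at which precision is averaged.
#' @param k_grid top-k cutoffs for the precision-at-k table.
#' @return list with `curve` (data.frame `recall`, `precision`),
#'   `precision_at_k` (data.frame `k`, `precision` averaged over rounds
#'   for the top-k predictions), and `background_precision`
#'   (positives / universe size).
#' @export
precision_recall_bootstrap <- function(scores, standard, n_boot = 2000L,
                                       seed,
                                       recall_grid = seq(0.01, 1,
                                                         length.out = 100),
                                       k_grid = c(5L, 10L, 15L, 20L,
                                                  50L)) {
  stopifnot(inherits(standard, "EvaluationStandard"))
  if (nrow(standard$pairs) == 0L) stop("empty evaluation standard")
  key <- pair_key(scores$factor_a, scores$factor_b)
  sc <- scores$score
  pos_key <- pair_key(standard$pairs$factor_a, standard$pairs$factor_b)
  extra <- setdiff(pos_key, key)
  if (length(extra)) {  # unscored standard pairs rank last
    key <- c(key, extra)
    sc <- c(sc, rep(-Inf, length(extra)))
  }
  ord <- order(-sc)
  key <- key[ord]
  n_univ <- length(key)
  n_pos <- length(pos_key)
  pos_idx <- match(pos_key, key)
  k_grid <- k_grid[k_grid <= n_univ]
  prec_sum <- numeric(length(recall_grid))
  pk_sum <- numeric(length(k_grid))
  # negatives are the scored pairs outside the curated standard; original
  # positives left out of a resample are excluded, not counted as false
  neg_flag <- !(seq_len(n_univ) %in% pos_idx)
  fp <- cumsum(neg_flag)
  withr_seed(seed, {
    for (b in seq_len(n_boot)) {
      draw <- pos_idx[sample.int(n_pos, n_pos, replace = TRUE)]
      w <- tabulate(draw, nbins = n_univ)  # positive weight per ranked pair
      tp <- cumsum(w)
      recall <- tp / n_pos
      precision <- tp / (tp + fp)
      # step interpolation: precision at the first rank reaching recall r
      idx <- findInterval(recall_grid, recall, left.open = TRUE) + 1
      p <- ifelse(idx <= length(precision), precision[idx],
                  precision[length(precision)])
      prec_sum <- prec_sum + p
      if (length(k_grid)) pk_sum <- pk_sum + precision[k_grid]
    }
  })
  list(curve = data.frame(recall = recall_grid,
                          precision = prec_sum / n_boot),
       precision_at_k = data.frame(k = k_grid,
                                   precision = pk_sum / n_boot),
       background_precision = n_pos / n_univ)
}

#' Baseline pairwise association scores
#'
#' Local pairwise measures for comparison with model interaction
#' energies: Pearson correlation and partial correlation on continuous
#' signal, plug-in mutual information (natural log, 2x2 tables) on
#' binarized data. Partial correlation is read from the inverse
#' covariance (precision) matrix; a ridge term can be supplied when the
#' covariance is singular.
#'
#' @param data a [signal_matrix()] (`pearson`, `partial_correlation`) or
#'   a [chromatin_code()] (`mutual_information`).
#' @param method one of `pearson`, `mutual_information`,
#'   `partial_correlation`.
#' @param ridge nonnegative ridge added to the covariance diagonal for
#'   partial correlation (0 = error on singularity).
#' @return ranked score table as in [interaction_energy_scores()].
#' @export
baseline_scores <- function(data,
                            method = c("pearson", "mutual_information",
                                       "partial_correlation"),
                            ridge = 0) {
  method <- match.arg(method)
  if (method == "mutual_information") {
    stopifnot(inherits(data, "ChromatinCodeMatrix"))
    M <- data$calls
  } else {
    if (!inherits(data, "SignalMatrix")) {
      stop(method, " is computed on continuous data; pass a SignalMatrix")
    }
    M <- data$values
  }
  f <- colnames(M)
  n <- ncol(M)
  if (method == "pearson") {
    C <- stats::cor(M, use = "pairwise.complete.obs")
    score_fun <- function(i, j) C[i, j]
  } else if (method == "partial_correlation") {
    S <- stats::cov(M, use = "pairwise.complete.obs")
    if (ridge > 0) S <- S + diag(ridge, n)
    P <- tryCatch(solve(S), error = function(e) {
      stop("singular covariance; supply ridge > 0")
    })
    D <- sqrt(diag(P))
    score_fun <- function(i, j) -P[i, j] / (D[i] * D[j])
  } else {
    score_fun <- function(i, j) {
      t2 <- table(factor(M[, i], levels = 0:1),
                  factor(M[, j], levels = 0:1)) / nrow(M)
      px <- rowSums(t2)
      py <- colSums(t2)
      sum(ifelse(t2 > 0, t2 * log(t2 / outer(px, py)), 0))
    }
  }
  pr <- t(utils::combn(n, 2))
  tab <- data.frame(factor_a = f[pr[, 1]], factor_b = f[pr[, 2]],
                    score = vapply(seq_len(nrow(pr)), function(r) {
                      score_fun(pr[r, 1], pr[r, 2])
                    }, numeric(1)),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$score), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}
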