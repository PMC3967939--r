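#' Construct a continuous per-bin signal matrix
#'
#' A `SignalMatrix` holds continuous chromatin signal (e.g. standardized
#' ChIP intensity) for a set of genomic bins (rows) and chromatin factors
#' (columns), prior to binarization. Missing entries are allowed and are
#' resolved during binarization. Each bin carries a coverage fraction in
#' `[0, 1]` recording how much of the bin is supported by underlying
#' measurements (probes or bases); bins below the coverage cutoff are
#' withheld downstream.
#'
#' @param bins data.frame with columns `chrom` (character), `start`, `end`
#'   (integer, 0-based half-open).
#' @param values numeric matrix, one row per bin, one column per factor;
#'   column names are the factor names. `NA` entries allowed.
#' @param coverage numeric vector in `[0, 1]`, one per bin; defaults to 1.
#' @return An object of class `SignalMatrix`.
#' @export
signal_matrix <- function(bins, values, coverage = NULL) {
  bins <- as.data.frame(bins)
  stopifnot(all(c("chrom", "start", "end") %in% names(bins)))
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(colnames(values)) || anyNA(colnames(values))) {
    stop("signal values must have factor names as column names")
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicated factor names: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  }
  if (nrow(values) != nrow(bins)) {
    stop("values row count (", nrow(values), ") != bin count (",
         nrow(bins), ")")
  }
  bad <- which(!(bins$start < bins$end))
  if (length(bad)) {
    stop("bin with start >= end at row ", bad[1])
  }
  if (is.null(coverage)) coverage <- rep(1, nrow(bins))
  stopifnot(length(coverage) == nrow(bins),
            all(coverage >= 0 & coverage <= 1, na.rm = TRUE))
  rownames(values) <- NULL
  rownames(bins) <- NULL
  structure(
    list(bins = bins[, c("chrom", "start", "end")],
         factors = colnames(values),
         values = values,
         coverage = as.numeric(coverage)),
    class = "SignalMatrix")
}

#' Construct a binary chromatin-code matrix
#'
#' A `ChromatinCodeMatrix` is the binarized counterpart of a
#' [signal_matrix()]: a bins x factors 0/1 occupancy matrix with no
#' missing entries. Each row is one chromatin code -- the combinatorial
#' pattern of factors called present at that genomic bin.
#'
#' @param bins data.frame with `chrom`, `start`, `end` (0-based half-open).
#' @param calls 0/1 matrix with factor names as column names.
#' @return An object of class `ChromatinCodeMatrix`.
#' @export
chromatin_code <- function(bins, calls) {
  bins <- as.data.frame(bins)
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (anyNA(calls)) stop("binary calls may not contain missing entries")
  if (!all(calls %in% c(0L, 1L))) stop("calls must be 0/1")
  if (is.null(colnames(calls))) stop("calls must carry factor names")
  if (anyDuplicated(colnames(calls))) stop("duplicated factor names")
  if (nrow(calls) != nrow(bins)) stop("calls rows != bin count")
  bad <- which(!(bins$start < bins$end))
  if (length(bad)) stop("bin with start >= end at row ", bad[1])
  rownames(calls) <- NULL
  rownames(bins) <- NULL
  structure(
    list(bins = bins[, c("chrom", "start", "end")],
         factors = colnames(calls),
         calls = calls),
    class = "ChromatinCodeMatrix")
}

#' Construct an interaction evaluation standard
#'
#' Holds the set of unordered factor pairs with experimental support
#' (physical interaction, modification-reader binding, enzyme-substrate),
#' used as positives in precision-recall evaluation of interaction scores.
#'
#' @param pairs data.frame or 2-column matrix of factor-name pairs.
#' @return An object of class `EvaluationStandard`.
#' @export
evaluation_standard <- function(pairs) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  if (ncol(pairs) < 2) stop("standard needs two factor-name columns")
  a <- as.character(pairs[[1]])
  b <- as.character(pairs[[2]])
  if (any(a == b)) stop("self-pairs are not allowed in a standard")
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  keep <- !duplicated(paste(lo, hi, sep = "\r"))
  structure(
    list(pairs = data.frame(factor_a = lo[keep], factor_b = hi[keep],
                            stringsAsFactors = FALSE)),
    class = "EvaluationStandard")
}

#' Construct a maximum-entropy chromatin-code model
#'
#' The model assigns each binary pattern `x` an energy
#' `E(x) = sum_i h_i x_i + sum_(i<j) J_ij x_i x_j +
#'  sum_(i<j<k) K_ijk x_i x_j x_k`
#' and probability `P(x) = exp(E(x)) / Z`. Positive `J` therefore means
#' enriched co-occurrence. `J` and `K` are sparse and symmetric, stored
#' once per unordered pair / triple.
#'
#' @param factors character vector of factor names (length `n`).
#' @param h numeric self-energies: either a full named vector over
#'   `factors` or a named subset (others are 0).
#' @param J data.frame with columns `i`, `j` (indices into `factors`,
#'   `i < j`) and `value`; or NULL.
#' @param K data.frame with columns `i`, `j`, `k` (`i < j < k`) and
#'   `value`; or NULL.
#' @param logZ optional known/estimated log partition function.
#' @param order interaction order of the parameterization (1, 2, or 3);
#'   defaults to the highest order with stored entries.
#' @param hierarchy_flag logical; TRUE asserts that every triplet has all
#'   three member pairs present in `J` (checked).
#' @return An object of class `MaxEntModel`.
#' @export
maxent_model <- function(factors, h = NULL, J = NULL, K = NULL,
                         logZ = NULL, order = NULL,
                         hierarchy_flag = FALSE) {
  factors <- as.character(factors)
  n <- length(factors)
  if (anyDuplicated(factors)) stop("duplicated factor names")
  hh <- stats::setNames(numeric(n), factors)
  if (!is.null(h)) {
    if (is.null(names(h))) {
      stopifnot(length(h) == n)
      hh[] <- h
    } else {
      unknown <- setdiff(names(h), factors)
      if (length(unknown)) stop("h names unknown factors: ",
                                paste(unknown, collapse = ", "))
      hh[names(h)] <- h
    }
  }
  J <- canon_pairs(J, n)
  K <- canon_triples(K, n)
  if (hierarchy_flag && nrow(K)) {
    jk <- paste(J$i, J$j)
    need <- rbind(cbind(K$i, K$j), cbind(K$i, K$k), cbind(K$j, K$k))
    if (!all(paste(need[, 1], need[, 2]) %in% jk)) {
      stop("hierarchy violated: triplet present without all member pairs")
    }
  }
  if (is.null(order)) {
    order <- if (nrow(K)) 3L else if (nrow(J)) 2L else 1L
  }
  order <- as.integer(order)
  stopifnot(order %in% 1:3)
  structure(
    list(factors = factors, h = hh, J = J, K = K,
         logZ = logZ, order = order, hierarchy_flag = hierarchy_flag),
    class = "MaxEntModel")
}

# canonicalize a pair table: i < j, indices valid, nonzero, unique
canon_pairs <- function(J, n) {
  if (is.null(J) || NROW(J) == 0) {
    return(data.frame(i = integer(0), j = integer(0), value = numeric(0)))
  }
  J <- as.data.frame(J)
  stopifnot(all(c("i", "j", "value") %in% names(J)))
  i <- pmin(J$i, J$j); j <- pmax(J$i, J$j)
  if (any(i < 1 | j > n | i == j)) stop("invalid pair index")
  keep <- J$value != 0
  out <- data.frame(i = as.integer(i), j = as.integer(j),
                    value = as.numeric(J$value))[keep, , drop = FALSE]
  if (anyDuplicated(out[c("i", "j")])) stop("duplicate pair entries")
  out[order(out$i, out$j), , drop = FALSE]
}

canon_triples <- function(K, n) {
  if (is.null(K) || NROW(K) == 0) {
    return(data.frame(i = integer(0), j = integer(0), k = integer(0),
                      value = numeric(0)))
  }
  K <- as.data.frame(K)
  stopifnot(all(c("i", "j", "k", "value") %in% names(K)))
  idx <- t(apply(as.matrix(K[, c("i", "j", "k")]), 1, sort))
  if (any(idx < 1 | idx > n) ||
      any(idx[, 1] == idx[, 2] | idx[, 2] == idx[, 3])) {
    stop("invalid triple index")
  }
  keep <- K$value != 0
  out <- data.frame(i = as.integer(idx[, 1]), j = as.integer(idx[, 2]),
                    k = as.integer(idx[, 3]),
                    value = as.numeric(K$value))[keep, , drop = FALSE]
  if (anyDuplicated(out[c("i", "j", "k")])) stop("duplicate triple entries")
  out[order(out$i, out$j, out$k), , drop = FALSE]
}

#' @export
print.SignalMatrix <- function(x, ...) {
  cat("SignalMatrix:", nrow(x$values), "bins x", length(x$factors),
      "factors\n")
  cat("  missing entries:", sum(is.na(x$values)),
      "| bins with coverage < 0.5:", sum(x$coverage < 0.5), "\n")
  invisible(x)
}

#' @export
print.ChromatinCodeMatrix <- function(x, ...) {
  cat("ChromatinCodeMatrix:", nrow(x$calls), "bins x", length(x$factors),
      "factors\n")
  cat("  mean occupancy:", format(mean(x$calls), digits = 3), "\n")
  invisible(x)
}

#' @export
print.MaxEntModel <- function(x, ...) {
  cat("MaxEntModel: ", length(x$factors), " factors, order ", x$order,
      "\n  nonzero: h=", sum(x$h != 0), " J=", nrow(x$J),
      " K=", nrow(x$K), sep = "")
  if (!is.null(x$logZ)) cat("  logZ=", format(x$logZ, digits = 6), sep = "")
  cat("\n")
  invisible(x)
}

#' @export
print.EvaluationStandard <- function(x, ...) {
  cat("EvaluationStandard:", nrow(x$pairs), "positive pairs\n")
  invisible(x)
}

# dense symmetric n x n matrix of pairwise energies (diag 0)
j_matrix <- function(model) {
  n <- length(model$factors)
  M <- matrix(0, n, n)
  if (nrow(model$J)) {
    M[cbind(model$J$i, model$J$j)] <- model$J$value
    M[cbind(model$J$j, model$J$i)] <- model$J$value
  }
  M
}

# triples as 0-based integer matrix + values, for the C++ sampler
triple_arrays <- function(model) {
  if (nrow(model$K)) {
    list(idx = cbind(model$K$i, model$K$j, model$K$k) - 1L,
         val = model$K$value)
  } else {
    list(idx = matrix(0L, 0, 3), val = numeric(0))
  }
}
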