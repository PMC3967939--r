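# Signal binarization by symmetric-background mixture thresholding.
#
# The observed per-bin signal distribution is modeled nonparametrically
# as a symmetric background plus a signal component confined to one side
# of the background mode. Only symmetry is assumed: the background
# density is recovered by reflecting the clean (non-signal) side of the
# kernel density estimate around its mode, the signal density is the
# positive excess on the signal side, and the binarization threshold is
# the point where the two weighted densities are equally likely.

#' Fit the symmetric-background + one-sided-signal mixture
#'
#' Steps: (i) the signal side is the heavier tail -- the sign of the
#' third moment about the median; (ii) the background center is the
#' point where the empirical mass a fixed (robust-scale) distance to
#' either side balances -- a CDF-level symmetry criterion that locates
#' the center at near-root-n accuracy, where the argmax of a kernel
#' density estimate jitters badly on a flat peak; (iii) the signal
#' weight is the (clamped) difference between the two tail masses about
#' the center, exact under the model because the signal has negligible
#' mass on the background side; (iv) the background density is the
#' clean-side kernel density reflected about the center, and the signal
#' density is the renormalized positive excess of the total density over
#' it on the signal side.
#'
#' @param values finite numeric vector (>= 1000 values recommended; a
#'   warning is issued below that).
#' @param n_grid KDE evaluation grid size (>= 512).
#' @param weight_floor below this signal mass the factor is flagged as
#'   having no detectable signal.
#' @return an object of class `MixtureFit`: list with `grid`, `total`,
#'   `background`, `signal` (unit-mass densities on `grid`),
#'   `signal_weight`, `side` ("right"/"left"), `mode` (background
#'   center), `threshold` (NA until [optimal_threshold()]),
#'   `low_signal` flag, `bandwidth`.
#' @export
fit_background_signal <- function(values, n_grid = 512L,
                                  weight_floor = 0.005) {
  values <- values[is.finite(values)]
  if (length(values) < 2L || stats::sd(values) == 0) {
    stop("degenerate input: need non-constant finite values")
  }
  if (length(values) < 1000L) {
    warning("fewer than 1000 values; mixture fit may be unstable")
  }
  n_grid <- max(as.integer(n_grid), 512L)
  de <- stats::density(values, bw = "nrd0", n = n_grid)
  g <- de$x
  f <- de$y
  dx <- g[2] - g[1]
  # coarse center: KDE argmax (background peak dominates while the
  # signal carries less than half the mass)
  mode0 <- g[which.max(f)]
  side <- if (sum((values - mode0)^3) >= 0) "right" else "left"
  # background scale from the clean (non-signal) side only, so a large
  # signal share cannot inflate it
  clean <- if (side == "right") values[values <= mode0]
           else values[values >= mode0]
  s0 <- 1.4826 * stats::median(abs(clean - mode0))
  if (!is.finite(s0) || s0 == 0) s0 <- stats::sd(values)
  # refined center: root of B(c) = [F(c+t) - F(c)] - [F(c) - F(c-t)]
  # with t ~ one background scale; B = 0 at the center of any symmetric
  # density provided the signal stays out of the +/- t window. This
  # CDF-level criterion locates the center at near-root-n accuracy,
  # where the raw argmax jitters on the flat peak.
  Fn <- stats::ecdf(values)
  cand <- seq(mode0 - 1.2 * s0, mode0 + 1.2 * s0, length.out = 301L)
  # pooling the squared criterion over several window widths damps the
  # ecdf noise of any single width
  B2 <- Reduce(`+`, lapply(c(0.6, 0.8, 1, 1.2, 1.4) * s0, function(t) {
    ((Fn(cand + t) - Fn(cand)) - (Fn(cand) - Fn(cand - t)))^2
  }))
  mode <- cand[which.min(B2)]
  # signal weight from tail-mass imbalance about the center: exact under
  # the model, since the signal has negligible mass on the clean side
  w <- if (side == "right") 1 - 2 * Fn(mode) else 2 * Fn(mode) - 1
  w <- max(0, w)
  refl <- stats::approx(g, f, xout = 2 * mode - g, yleft = 0,
                        yright = 0)$y
  bg <- if (side == "right") ifelse(g <= mode, f, refl)
        else ifelse(g >= mode, f, refl)
  excess <- pmax(f - bg, 0)
  on_side <- if (side == "right") g > mode else g < mode
  excess[!on_side] <- 0
  w_kde <- sum(excess) * dx
  sig <- if (w_kde > 0) excess / w_kde else excess
  bg_mass <- sum(bg) * dx
  if (bg_mass > 0) bg <- bg / bg_mass
  fit <- structure(
    list(grid = g, total = f, background = bg, signal = sig,
         signal_weight = w, side = side, mode = mode,
         threshold = NA_real_, low_signal = (w < weight_floor),
         bandwidth = de$bw),
    class = "MixtureFit")
  if (fit$low_signal) {
    warning("signal weight ", format(w, digits = 3), " below floor ",
            weight_floor, "; no detectable one-sided signal")
  }
  fit
}

#' @export
print.MixtureFit <- function(x, ...) {
  cat("MixtureFit: side =", x$side,
      "| signal weight =", format(x$signal_weight, digits = 3),
      "| mode =", format(x$mode, digits = 3), "\n")
  if (!is.na(x$threshold)) {
    cat("  threshold =", format(x$threshold, digits = 4), "\n")
  }
  invisible(x)
}

#' Equal-likelihood binarization threshold
#'
#' Scans the density grid outward from the background mode on the signal
#' side for the first point where the (weighted) signal density exceeds
#' the (weighted) background density -- the value at which an observation
#' is equally likely to come from either component -- and refines the
#' crossing by linear interpolation. Values beyond the threshold (toward
#' the signal side) are called present.
#'
#' @param fit a `MixtureFit` from [fit_background_signal()].
#' @param fallback if TRUE, return the 0.95 background quantile (with a
#'   warning) when the densities never cross; if FALSE, error.
#' @return threshold on the signal scale.
#' @export
optimal_threshold <- function(fit, fallback = FALSE) {
  stopifnot(inherits(fit, "MixtureFit"))
  if (fit$low_signal && !fallback) {
    stop("signal weight below floor; no reliable threshold ",
         "(set fallback = TRUE for a background-quantile threshold)")
  }
  g <- fit$grid
  # mixture-weighted component densities
  w_sig <- fit$signal * fit$signal_weight
  w_bg <- fit$background * (1 - fit$signal_weight)
  diff <- w_sig - w_bg
  idx <- if (fit$side == "right") which(g > fit$mode) else
    rev(which(g < fit$mode))
  cross <- NA_real_
  for (p in seq_along(idx)) {
    i <- idx[p]
    if (diff[i] >= 0) {
      if (p == 1L) { cross <- g[i]; break }
      i0 <- idx[p - 1L]
      d0 <- diff[i0]; d1 <- diff[i]
      cross <- if (d1 == d0) g[i] else
        g[i0] + (g[i] - g[i0]) * (0 - d0) / (d1 - d0)
      break
    }
  }
  if (is.na(cross)) {
    if (!fallback) {
      stop("weighted densities never cross on the signal side")
    }
    warning("no density crossing; falling back to the 0.95 background ",
            "quantile")
    cross <- background_quantile(fit, 0.95)
  }
  cross
}

# quantile of the reflected-background density (toward the signal side)
background_quantile <- function(fit, q) {
  g <- fit$grid
  bg <- fit$background
  cdf <- cumsum(bg) / sum(bg)
  if (fit$side == "right") {
    g[which(cdf >= q)[1]]
  } else {
    g[rev(which(cdf <= 1 - q))[1]]
  }
}

#' Aggregate native-resolution signal into fixed-width bins
#'
#' Averages contributing rows within each `bin_width` window per
#' chromosome, weighting by row extent. Coverage of an output bin is the
#' fraction of its width supported by input rows; bins with coverage
#' below `coverage_min` are withheld (flagged by their stored coverage
#' and dropped jointly during [binarize()]). Per-factor values inside a
#' retained bin are averaged over non-missing contributions; a factor
#' covering less than `coverage_min` of the bin is set missing.
#'
#' @param signal a [signal_matrix()] at native (e.g. probe) resolution.
#' @param bin_width output bin width in bp (default 200).
#' @param coverage_min minimum covered fraction (default 0.5).
#' @return a [signal_matrix()] on the regular bin grid, with `coverage`
#'   filled in.
#' @export
bin_track <- function(signal, bin_width = 200L, coverage_min = 0.5) {
  if (bin_width <= 0) stop("bin_width must be positive")
  b <- signal$bins
  V <- signal$values
  out <- list()
  for (ch in unique(b$chrom)) {
    rows <- which(b$chrom == ch)
    lo <- (min(b$start[rows]) %/% bin_width) * bin_width
    hi <- ceiling(max(b$end[rows]) / bin_width) * bin_width
    starts <- seq(lo, hi - bin_width, by = bin_width)
    nb <- length(starts)
    cov_f <- matrix(0, nb, ncol(V))   # covered bp per factor
    val_f <- matrix(0, nb, ncol(V))   # extent-weighted value sums
    cov_b <- numeric(nb)              # covered bp regardless of factor
    for (r in rows) {
      s <- b$start[r]; e <- b$end[r]
      first <- (s %/% bin_width)
      last <- ((e - 1L) %/% bin_width)
      for (w in first:last) {
        ov <- min(e, (w + 1) * bin_width) - max(s, w * bin_width)
        bi <- w - lo %/% bin_width + 1L
        cov_b[bi] <- cov_b[bi] + ov
        ok <- which(!is.na(V[r, ]))
        cov_f[bi, ok] <- cov_f[bi, ok] + ov
        val_f[bi, ok] <- val_f[bi, ok] + ov * V[r, ok]
      }
    }
    vals <- val_f / cov_f
    vals[cov_f / bin_width < coverage_min] <- NA_real_
    colnames(vals) <- signal$factors
    out[[ch]] <- list(
      bins = data.frame(chrom = ch, start = starts,
                        end = starts + bin_width),
      values = vals,
      coverage = pmin(cov_b / bin_width, 1))
  }
  signal_matrix(do.call(rbind, lapply(out, `[[`, "bins")),
                do.call(rbind, lapply(out, `[[`, "values")),
                unlist(lapply(out, `[[`, "coverage"), use.names = FALSE))
}

#' Binarize a signal matrix with per-factor mixture fits
#'
#' A call of 1 marks values beyond the factor's threshold toward its
#' signal side. For depletion factors (signal side = left) the call marks
#' depletion and the factor name is suffixed with `-`. Bins withheld for
#' low coverage, or still missing any value, are dropped jointly across
#' all factors so every retained row is a complete chromatin code.
#'
#' @param signal a binned [signal_matrix()].
#' @param fits named list of `MixtureFit` objects, one per factor.
#' @param coverage_min bins with lower coverage are withheld.
#' @param fallback passed to [optimal_threshold()] for factors whose
#'   densities do not cross.
#' @return a [chromatin_code()].
#' @export
binarize <- function(signal, fits, coverage_min = 0.5, fallback = TRUE) {
  missing_fit <- setdiff(signal$factors, names(fits))
  if (length(missing_fit)) {
    stop("no mixture fit for factor(s): ",
         paste(missing_fit, collapse = ", "))
  }
  n <- length(signal$factors)
  calls <- matrix(0L, nrow(signal$values), n)
  out_names <- character(n)
  for (fi in seq_len(n)) {
    f <- signal$factors[fi]
    fit <- fits[[f]]
    thr <- if (!is.na(fit$threshold)) fit$threshold else
      optimal_threshold(fit, fallback = fallback)
    v <- signal$values[, fi]
    calls[, fi] <- if (fit$side == "right") as.integer(v >= thr)
                   else as.integer(v <= thr)
    out_names[fi] <- if (fit$side == "left") paste0(f, "-") else f
  }
  keep <- signal$coverage >= coverage_min &
    rowSums(is.na(signal$values)) == 0L
  calls[is.na(calls)] <- 0L
  colnames(calls) <- out_names
  chromatin_code(signal$bins[keep, , drop = FALSE],
                 calls[keep, , drop = FALSE])
}

#' Binarize gene expression (RPKM) into high/low classes
#'
#' Applies the same symmetric-background thresholding machinery to
#' `log2(RPKM + 1)` per gene; the high-expression class is coded 1. This
#' lets an expression track enter the model as one more binary "factor".
#'
#' @param rpkm nonnegative per-gene RPKM values.
#' @return integer 0/1 vector with attributes `threshold` (on the
#'   log2(RPKM+1) scale) and `fit` (the `MixtureFit`).
#' @export
discretize_expression <- function(rpkm) {
  if (any(rpkm < 0, na.rm = TRUE)) stop("RPKM values must be nonnegative")
  if (all(rpkm == 0, na.rm = TRUE)) stop("all-zero expression")
  lx <- log2(rpkm + 1)
  fit <- fit_background_signal(lx)
  thr <- optimal_threshold(fit, fallback = TRUE)
  cls <- if (fit$side == "right") as.integer(lx >= thr)
         else as.integer(lx <= thr)  # high class is the signal side
  attr(cls, "threshold") <- thr
  attr(cls, "fit") <- fit
  cls
}
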