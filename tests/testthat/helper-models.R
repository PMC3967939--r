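# Shared fixtures: tiny hand-built models, enumeration oracles, and
# planted-recovery metrics. Everything is generated in code; no files.

tiny_bins <- function(n) {
  data.frame(chrom = "chrT", start = (seq_len(n) - 1L) * 200L,
             end = seq_len(n) * 200L)
}

tiny_code <- function(calls, factors = NULL) {
  calls <- as.matrix(calls)
  if (!is.null(factors)) colnames(calls) <- factors
  chromatin_code(tiny_bins(nrow(calls)), calls)
}

# brute-force pattern distribution by direct summation (independent of
# pattern_energy / exact_log_partition internals beyond the energy rule)
enum_oracle <- function(model) {
  n <- length(model$factors)
  pats <- as.matrix(expand.grid(rep(list(0:1), n)))
  colnames(pats) <- model$factors
  e <- apply(pats, 1, function(x) {
    v <- sum(model$h * x)
    J <- model$J
    if (nrow(J)) {
      v <- v + sum(J$value * x[J$i] * x[J$j])
    }
    K <- model$K
    if (nrow(K)) {
      v <- v + sum(K$value * x[K$i] * x[K$j] * x[K$k])
    }
    v
  })
  w <- exp(e)
  list(patterns = pats, prob = w / sum(w), logZ = log(sum(w)))
}

# support / sign / magnitude recovery of a fitted pairwise model against
# the planted truth; "support" is thresholded at the same relevance
# cutoff used for the sign check
pair_recovery <- function(true_model, fit_model, rel_thr = 0.2) {
  tk <- paste(true_model$J$i, true_model$J$j)
  est <- fit_model$J
  ek_all <- paste(est$i, est$j)
  big <- est[abs(est$value) > rel_thr, , drop = FALSE]
  bk <- paste(big$i, big$j)
  tp <- length(intersect(tk, bk))
  f1 <- if (nrow(big) + length(tk) > 0) {
    2 * tp / (nrow(big) + length(tk))
  } else NA_real_
  sign_ok <- vapply(seq_len(nrow(big)), function(r) {
    tr <- true_model$J[tk == bk[r], , drop = FALSE]
    if (!nrow(tr)) NA else sign(tr$value) == sign(big$value[r])
  }, logical(1))
  comm <- intersect(tk, ek_all)
  spear <- if (length(comm) >= 3) {
    stats::cor(abs(true_model$J$value[match(comm, tk)]),
               abs(est$value[match(comm, ek_all)]),
               method = "spearman")
  } else NA_real_
  list(f1 = f1, sign_ok = sign_ok, spearman = spear,
       n_selected = nrow(big))
}
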