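#' Maximum-likelihood fine-tuning by Monte-Carlo gradient ascent
#'
#' Refines the parameters of a structure-fixed model toward the maximum
#' likelihood estimate. The likelihood gradient for each active feature
#' (occupancy `x_i`, co-occupancy `x_i x_j`, triple co-occupancy
#' `x_i x_j x_k`) is the empirical moment minus the model moment; the
#' model moments are estimated each iteration from Gibbs samples and a
#' fixed-step update is applied. The sampler chain persists across
#' iterations, so only the first iteration pays burn-in. Progress is
#' monitored by the Pearson correlation between the observed and
#' model-sampled feature statistics.
#'
#' @param init a fitted [maxent_model()]; only parameters present in
#'   `init` (its support) are updated.
#' @param data a [chromatin_code()] with matching factors.
#' @param n_iter maximum gradient iterations.
#' @param samples_per_iter Gibbs sweeps (= samples) per iteration.
#' @param step_size fixed gradient step.
#' @param seed integer RNG seed.
#' @param burn_in burn-in sweeps for the first iteration only.
#' @param r_stop stop early once the moment correlation exceeds this.
#' @return list with `model` (logZ cleared; re-estimate after tuning) and
#'   `trace`: data.frame of `iter`, `pearson_r`, `max_moment_err`,
#'   `mean_abs_param`.
#' @export
fit_mle_mcmc <- function(init, data, n_iter = 500L,
                         samples_per_iter = 10000L, step_size = 0.05,
                         seed, burn_in = 1000L, r_stop = 0.999) {
  stopifnot(inherits(init, "MaxEntModel"),
            identical(init$factors, data$factors))
  if (missing(seed)) stop("seed is mandatory")
  n <- length(init$factors)
  X <- data$calls
  storage.mode(X) <- "double"
  # empirical moments of the active features
  emp_h <- colMeans(X)
  pj <- as.matrix(init$J[, c("i", "j"), drop = FALSE])
  pk <- as.matrix(init$K[, c("i", "j", "k"), drop = FALSE])
  emp_J <- if (nrow(pj)) colMeans(X[, pj[, 1], drop = FALSE] *
                                    X[, pj[, 2], drop = FALSE]) else numeric(0)
  emp_K <- if (nrow(pk)) colMeans(X[, pk[, 1], drop = FALSE] *
                                    X[, pk[, 2], drop = FALSE] *
                                    X[, pk[, 3], drop = FALSE]) else numeric(0)
  emp <- c(emp_h, emp_J, emp_K)

  h <- unname(init$h)
  Jv <- init$J$value
  Kv <- init$K$value
  state <- integer(n)
  trace <- vector("list", n_iter)
  withr_seed(seed, {
    for (it in seq_len(n_iter)) {
      Jm <- matrix(0, n, n)
      if (nrow(pj)) {
        Jm[pj] <- Jv
        Jm[pj[, 2:1, drop = FALSE]] <- Jv
      }
      tr_idx <- if (nrow(pk)) pk - 1L else matrix(0L, 0, 3)
      S <- .gibbs_sample_cpp(h, Jm, tr_idx, Kv,
                             as.integer(samples_per_iter),
                             if (it == 1L) as.integer(burn_in) else 0L,
                             state)
      state <- S[nrow(S), ]
      Sd <- S
      storage.mode(Sd) <- "double"
      mod_h <- colMeans(Sd)
      mod_J <- if (nrow(pj)) colMeans(Sd[, pj[, 1], drop = FALSE] *
                                        Sd[, pj[, 2], drop = FALSE]) else numeric(0)
      mod_K <- if (nrow(pk)) colMeans(Sd[, pk[, 1], drop = FALSE] *
                                        Sd[, pk[, 2], drop = FALSE] *
                                        Sd[, pk[, 3], drop = FALSE]) else numeric(0)
      mod <- c(mod_h, mod_J, mod_K)
      h <- h + step_size * (emp_h - mod_h)
      if (length(emp_J)) Jv <- Jv + step_size * (emp_J - mod_J)
      if (length(emp_K)) Kv <- Kv + step_size * (emp_K - mod_K)
      pars <- c(h, Jv, Kv)
      if (mean(abs(pars)) > 50) {
        stop("fine-tuning diverged at iteration ", it,
             ": mean |parameter| = ", format(mean(abs(pars))),
             " exceeds 50; reduce step_size")
      }
      r <- if (stats::sd(emp) > 0 && stats::sd(mod) > 0) {
        stats::cor(emp, mod)
      } else NA_real_
      trace[[it]] <- data.frame(iter = it, pearson_r = r,
                                max_moment_err = max(abs(emp - mod)),
                                mean_abs_param = mean(abs(pars)))
      if (!is.na(r) && r > r_stop && it >= 10L) break
    }
  })
  trace <- do.call(rbind, trace[!vapply(trace, is.null, logical(1))])
  model <- maxent_model(init$factors, h = h,
                        J = if (nrow(pj)) data.frame(i = pj[, 1],
                                                     j = pj[, 2],
                                                     value = Jv),
                        K = if (nrow(pk)) data.frame(i = pk[, 1],
                                                     j = pk[, 2],
                                                     k = pk[, 3],
                                                     value = Kv),
                        order = init$order,
                        hierarchy_flag = init$hierarchy_flag)
  list(model = model, trace = trace)
}
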