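# End-to-end pipeline: simulate/load -> discretize -> split -> fit ->
# fine-tune -> evaluate -> score -> predict, with every stochastic stage
# seeded and a manifest recording inputs, outputs and seeds.

#' Read a flat key = value run configuration
#'
#' Lines of `key = value` (or `key: value`); `#` comments and blank
#' lines ignored. Values are parsed as numbers where possible.
#'
#' @param path config file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=:]+)[=:](.*)$", lines))
  bad <- which(vapply(kv, length, integer(1)) != 3)
  if (length(bad)) stop("malformed config line: ", lines[bad[1]])
  keys <- trimws(vapply(kv, `[`, character(1), 2))
  vals <- trimws(vapply(kv, `[`, character(1), 3))
  out <- lapply(vals, function(v) {
    nv <- suppressWarnings(as.numeric(v))
    if (!is.na(nv)) nv else v
  })
  stats::setNames(out, keys)
}

pipeline_defaults <- function() {
  list(seed = 1, n_factors = 12, n_pairs = 10, n_bins = 8000,
       signal_shift = 4, background_sd = 1,
       bin_width = 200, coverage_min = 0.5,
       order = 2, lambda_grid_length = 12, lambda_ratio = 1e-3,
       finetune = 1, finetune_iter = 100, finetune_samples = 5000,
       finetune_step = 0.05,
       z_samples = 200000, n_slices = 50,
       predict_target = "")
}

#' Run the full modeling pipeline
#'
#' Stages, in order: obtain a continuous signal matrix (from
#' `input_signal`, or simulated from a planted sparse model when absent);
#' mixture-threshold binarization; genome-slice train/val/test split;
#' penalized pseudo-likelihood fit with validation-selected penalty;
#' optional MCMC maximum-likelihood fine-tuning; partition-function and
#' coherence evaluation against the independence baseline; interaction
#' scoring; conditional-probability imputation of one held-out factor.
#' Intermediate artifacts are written under `out_dir` and listed in
#' `manifest.json` together with every seed used. Reruns with the same
#' configuration are byte-identical.
#'
#' @param config named list (see [read_run_config()]); recognized keys
#'   and defaults: `seed` (1), `input_signal` (path; simulate when
#'   absent), `n_factors` (12), `n_pairs` (10), `n_bins` (8000),
#'   `order` (2), `lambda_grid_length` (12), `lambda_ratio` (1e-3),
#'   `finetune` (1), `finetune_iter` (100), `finetune_samples` (5000),
#'   `finetune_step` (0.05), `z_samples` (2e5), `n_slices` (50),
#'   `coverage_min` (0.5), `predict_target` (first factor), `standards`
#'   (path, optional), `out_dir` (required).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  cfg <- utils::modifyList(pipeline_defaults(), as.list(config))
  if (is.null(cfg$out_dir)) stop("config must set out_dir")
  if (!is.null(cfg$input_signal) && !file.exists(cfg$input_signal)) {
    stop("input_signal path does not exist: ", cfg$input_signal)
  }
  if (!is.null(cfg$standards) && !file.exists(cfg$standards)) {
    stop("standards path does not exist: ", cfg$standards)
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)
  manifest <- list(config = cfg, seeds = list(base = seed),
                   stages = list(), outputs = character(0))
  log_stage <- function(name) {
    message("[chromcode] stage: ", name)
    manifest$stages[[name]] <<- TRUE
  }
  emit <- function(file) {
    manifest$outputs <<- c(manifest$outputs, file)
    file
  }
  tryCatch({
    # --- signal acquisition ---------------------------------------
    if (!is.null(cfg$input_signal)) {
      log_stage("load")
      signal <- read_signal_matrix(cfg$input_signal)
      truth <- NULL
    } else {
      log_stage("simulate")
      truth <- random_sparse_model(n_factors = as.integer(cfg$n_factors),
                                   n_pairs = as.integer(cfg$n_pairs),
                                   seed = seed)
      code0 <- sample_dataset(truth, as.integer(cfg$n_bins),
                              seed = seed + 1L, method = if
                              (length(truth$factors) <= 20) "exact"
                              else "gibbs")
      signal <- synthetic_signal_tracks(code0,
                                        background_sd = cfg$background_sd,
                                        signal_shift = cfg$signal_shift,
                                        seed = seed + 2L)
      write_maxent_model(truth,
                         emit(file.path(cfg$out_dir, "true_model.json")))
      write_signal_matrix(signal,
                          emit(file.path(cfg$out_dir, "signal.tsv")))
    }
    # --- discretize ------------------------------------------------
    log_stage("discretize")
    fits <- lapply(seq_along(signal$factors), function(i) {
      fit_background_signal(signal$values[, i])
    })
    names(fits) <- signal$factors
    code <- binarize(signal, fits, coverage_min = cfg$coverage_min)
    write_binary_calls(code, paste0(file.path(cfg$out_dir, "calls_")))
    emit(file.path(cfg$out_dir, "calls_calls.tsv"))
    # --- split -----------------------------------------------------
    log_stage("split")
    sets <- split_genome(code$bins,
                         n_slices = min(as.integer(cfg$n_slices),
                                        nrow(code$bins)),
                         seed = seed + 3L)
    subcode <- function(which) {
      chromatin_code(code$bins[sets == which, , drop = FALSE],
                     code$calls[sets == which, , drop = FALSE])
    }
    train <- subcode("train")
    val <- subcode("val")
    test <- subcode("test")
    # --- fit -------------------------------------------------------
    log_stage("fit")
    grid <- lambda_grid(train, order = as.integer(cfg$order),
                        length = as.integer(cfg$lambda_grid_length),
                        ratio = cfg$lambda_ratio)
    sel <- select_lambda(train, val, grid = grid,
                         order = as.integer(cfg$order))
    model <- sel$best_model
    utils::write.table(sel$path,
                       emit(file.path(cfg$out_dir, "lambda_path.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    # --- finetune --------------------------------------------------
    if (isTRUE(cfg$finetune == 1)) {
      log_stage("finetune")
      ft <- fit_mle_mcmc(model, train,
                         n_iter = as.integer(cfg$finetune_iter),
                         samples_per_iter =
                           as.integer(cfg$finetune_samples),
                         step_size = cfg$finetune_step,
                         seed = seed + 4L)
      model <- ft$model
      utils::write.table(ft$trace,
                         emit(file.path(cfg$out_dir,
                                        "finetune_trace.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    # --- evaluate --------------------------------------------------
    log_stage("evaluate")
    model$logZ <- if (length(model$factors) <= 15) {
      exact_log_partition(model)
    } else {
      estimate_log_partition_mc(model,
                                n_samples = as.integer(cfg$z_samples),
                                seed = seed + 5L)
    }
    write_maxent_model(model, emit(file.path(cfg$out_dir, "model.json")))
    indep <- fit_independent(train)
    coh <- c(model = coherence_score(model, test),
             independent = coherence_score(indep, test))
    coh_tab <- data.frame(model = names(coh), coherence = coh,
                          normalized = normalize_coherence(coh))
    utils::write.table(coh_tab,
                       emit(file.path(cfg$out_dir, "coherence.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    # --- score -----------------------------------------------------
    log_stage("score")
    scores <- interaction_energy_scores(model, order = 2L)
    utils::write.table(scores,
                       emit(file.path(cfg$out_dir, "interactions.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(cfg$standards)) {
      log_stage("evaluate-interactions")
      std <- read_standards(cfg$standards)
      pr <- precision_recall_bootstrap(scores, std, n_boot = 2000L,
                                       seed = seed + 6L)
      utils::write.table(pr$curve,
                         emit(file.path(cfg$out_dir, "pr_curve.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    # --- predict ---------------------------------------------------
    log_stage("predict")
    target <- if (nzchar(cfg$predict_target)) cfg$predict_target else
      model$factors[1]
    keep <- setdiff(test$factors, target)
    ctx <- chromatin_code(test$bins, test$calls[, keep, drop = FALSE])
    prob <- impute_profile(model, ctx, target)
    pred_auc <- if (length(unique(test$calls[, target])) == 2) {
      auc(prob, test$calls[, target])
    } else NA_real_
    utils::write.table(
      cbind(test$bins, data.frame(probability = prob,
                                  observed = test$calls[, target])),
      emit(file.path(cfg$out_dir, "prediction.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$results <- list(
      coherence = as.list(coh),
      n_pairs_selected = nrow(model$J),
      best_lambda = sel$best_lambda,
      predict_target = target,
      predict_auc = pred_auc)
  }, error = function(e) {
    stage <- names(manifest$stages)
    stop("pipeline failed at stage '",
         if (length(stage)) stage[length(stage)] else "init",
         "': ", conditionMessage(e), call. = FALSE)
  })
  manifest$seeds <- list(base = seed, simulate = seed + 1L,
                         tracks = seed + 2L, split = seed + 3L,
                         finetune = seed + 4L, partition = seed + 5L,
                         pr_bootstrap = seed + 6L)
  jsonlite::write_json(manifest,
                       file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}
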