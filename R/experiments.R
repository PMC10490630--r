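# Experiment drivers: repeated stratified random splits over the three
# model variants, the single-layer ablation, and report assembly.

derive_seed <- function(master, i) {
  as.integer((as.numeric(master) * 1009 + 104729 * as.numeric(i)) %% 2147483647)
}

#' Class-stratified random train/test split
#'
#' Draws `train_frac` of each class (rounded) for training and uses the
#' remainder for testing, so train-set class counts are equal up to
#' rounding for a balanced input.
#'
#' @param ds an [md_dataset()].
#' @param train_frac fraction of each class used for training.
#' @param seed integer seed.
#' @return list with `train` and `test` [md_dataset()]s.
#' @export
stratified_split <- function(ds, train_frac = 0.5, seed = 1L) {
  set.seed(as.integer(seed))
  idx_tr <- integer(0)
  for (cl in levels(ds$labels)) {
    ci <- which(ds$labels == cl)
    if (length(ci) == 0L) next
    k <- round(train_frac * length(ci))
    if (k < 1L || k >= length(ci))
      stop("split leaves a class empty in train or test")
    idx_tr <- c(idx_tr, sample(ci, k))
  }
  list(train = ds[sort(idx_tr)],
       test = ds[setdiff(seq_len(length(ds)), idx_tr)])
}

row_normalize_pct <- function(cm) {
  sweep(cm, 1, pmax(rowSums(cm), 1), "/") * 100
}

#' Repeated random-split experiment over the model variants
#'
#' For each of `n_trials` trials: draws a fresh stratified train/test
#' split (trial seeds derived deterministically from `seed`), trains the
#' requested variants on the training half, and evaluates on the test
#' half. The rotation-augmented variant warm starts from the trial's
#' trained whitening model, so requesting both costs one extra
#' fine-tuning phase only.
#'
#' @param ds an [md_dataset()].
#' @param train_frac training fraction (0.2 / 0.5 / 0.8 in the standard
#'   protocol).
#' @param n_trials number of independent trials.
#' @param variants subset of `c("base", "model1", "model2")`.
#' @param cfg an [md_train_config][train_config()].
#' @param seed master seed; per-trial seeds are derived from it.
#' @param verbose print one line per trial.
#' @param keep_models keep the fitted models of the last trial in the
#'   report (for example for latent-space diagnostics).
#' @return object of class `md_eval_report`: per-variant `mean` and `sd`
#'   of test accuracy (percent), per-variant trial accuracies, and
#'   row-normalized confusion matrices (percent) averaged over trials;
#'   with `keep_models = TRUE` also `models` and `last_split` of the last
#'   trial.
#' @export
run_split_experiment <- function(ds, train_frac = 0.5, n_trials = 5L,
                                 variants = c("base", "model1", "model2"),
                                 cfg = train_config(), seed = 1L,
                                 verbose = FALSE, keep_models = FALSE) {
  stopifnot(n_trials >= 1)
  acc <- matrix(NA_real_, n_trials, length(variants),
                dimnames = list(NULL, variants))
  nc <- length(activity_classes())
  conf <- lapply(variants, function(v) matrix(0, nc, nc))
  names(conf) <- variants
  trial_seeds <- vapply(seq_len(n_trials), function(i) derive_seed(seed, i),
                        integer(1))
  models <- NULL
  for (tr in seq_len(n_trials)) {
    sp <- stratified_split(ds, train_frac, seed = trial_seeds[tr])
    tcfg <- cfg; tcfg$seed <- derive_seed(trial_seeds[tr], 1L)
    warm <- NULL
    if (keep_models && tr == n_trials) models <- list()
    for (v in variants) {
      fit <- train_variant(sp$train, v, tcfg, seed = derive_seed(trial_seeds[tr], 2L),
                           warm_model = if (v == "model2") warm else NULL)
      if (v == "model1") warm <- fit$model
      ev <- evaluate_model(fit$model, sp$test)
      acc[tr, v] <- ev$accuracy
      conf[[v]] <- conf[[v]] + row_normalize_pct(ev$confusion)
      if (!is.null(models)) models[[v]] <- fit$model
      if (verbose)
        message(sprintf("trial %d %-7s acc %.2f%%", tr, v, ev$accuracy))
    }
  }
  conf <- lapply(conf, function(cm) {
    cm <- cm / n_trials
    dimnames(cm) <- list(true = activity_classes(),
                         predicted = activity_classes())
    cm
  })
  out <- list(train_frac = train_frac, n_trials = n_trials,
              mean = colMeans(acc), sd = apply(acc, 2, stats::sd),
              accuracy = acc, confusion = conf, seed = seed,
              trial_seeds = trial_seeds)
  if (!is.null(models)) {
    out$models <- models
    out$last_split <- stratified_split(ds, train_frac,
                                       seed = trial_seeds[n_trials])
  }
  structure(out, class = "md_eval_report")
}

#' @export
print.md_eval_report <- function(x, ...) {
  cat(sprintf("Random-split experiment: %.0f%%/%.0f%% train/test, %d trial(s)\n",
              100 * x$train_frac, 100 * (1 - x$train_frac), x$n_trials))
  for (v in names(x$mean))
    cat(sprintf("  %-8s mean accuracy %6.2f%%  (sd %.2f)\n",
                v, x$mean[v], x$sd[v]))
  invisible(x)
}

#' Single-layer whitening ablation
#'
#' Starting from the all-BN base architecture, replaces the BN layer of
#' exactly one block with a whitening layer (method 1) or a whitening +
#' rotation layer (method 2), leaving the other BN layers intact, and
#' evaluates each replacement over repeated stratified splits. Method 2
#' warm starts from the trained method-1 network of the same layer and
#' trial.
#'
#' @param ds an [md_dataset()].
#' @param layers block indices to ablate (subset of 1..3).
#' @param methods subset of `c("iternorm", "iternorm_rot")`.
#' @param train_frac training fraction.
#' @param n_trials trials per configuration.
#' @param cfg an [md_train_config][train_config()].
#' @param seed master seed.
#' @param verbose print one line per fit.
#' @return data frame with columns `layer`, `method`, `mean`, `sd` plus
#'   attribute `"accuracy"` holding the per-trial matrix.
#' @export
run_layer_ablation <- function(ds, layers = 1:3,
                               methods = c("iternorm", "iternorm_rot"),
                               train_frac = 0.5, n_trials = 5L,
                               cfg = train_config(), seed = 1L,
                               verbose = FALSE) {
  stopifnot(all(layers %in% 1:3))
  combos <- expand.grid(layer = layers, method = methods,
                        stringsAsFactors = FALSE)
  acc <- matrix(NA_real_, n_trials, nrow(combos))
  trial_seeds <- vapply(seq_len(n_trials), function(i) derive_seed(seed, i),
                        integer(1))
  for (tr in seq_len(n_trials)) {
    sp <- stratified_split(ds, train_frac, seed = trial_seeds[tr])
    tcfg <- cfg; tcfg$seed <- derive_seed(trial_seeds[tr], 1L)
    init_seed <- derive_seed(trial_seeds[tr], 2L)
    for (L in unique(combos$layer)) {
      kinds <- rep("bn", 3L); kinds[L] <- "iternorm"
      m1 <- train_model(build_model(model_config(kinds), init_seed),
                        sp$train, tcfg)
      for (me in methods) {
        ci <- which(combos$layer == L & combos$method == me)
        if (length(ci) == 0L) next
        if (me == "iternorm") {
          ev <- evaluate_model(m1$model, sp$test)
        } else {
          m2 <- train_model(add_rotation_modules(m1$model, layers = L),
                            sp$train, tcfg, epochs = cfg$warm_epochs,
                            lr_init = 0.001)
          ev <- evaluate_model(m2$model, sp$test)
        }
        acc[tr, ci] <- ev$accuracy
        if (verbose)
          message(sprintf("trial %d layer %d %-12s acc %.2f%%",
                          tr, L, me, ev$accuracy))
      }
    }
  }
  out <- cbind(combos,
               mean = colMeans(acc),
               sd = apply(acc, 2, stats::sd))
  attr(out, "accuracy") <- acc
  attr(out, "trial_seeds") <- trial_seeds
  out
}
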