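#' Enumerate the full model-configuration grid
#'
#' Full factorial over feature type (OR, TLR) x batch-harmonization method
#' (none, combat, limma) x discretization (none, FBN32, FBN64, FBW32, FBW64)
#' x feature selector (DT, RF, XGB) x classifier (DT, ET, KNN, RF, SVM, XGB,
#' SGD): 2 * 3 * 5 * 3 * 7 = 630 configurations in deterministic
#' lexicographic order (the last field varies fastest).
#'
#' @return data.frame with 630 rows and columns `feature_type`,
#'   `batch_method`, `discretization`, `selector`, `classifier`.
#' @export
enumerate_grid <- function() {
  g <- expand.grid(classifier = CLASSIFIERS,
                   selector = SELECTORS,
                   discretization = c("none", "FBN32", "FBN64",
                                      "FBW32", "FBW64"),
                   batch_method = c("none", "combat", "limma"),
                   feature_type = c("OR", "TLR"),
                   stringsAsFactors = FALSE)
  g[, c("feature_type", "batch_method", "discretization", "selector",
        "classifier")]
}

parse_discretization <- function(spec) {
  if (spec == "none") return(list(method = "none", n = NA_integer_))
  m <- regmatches(spec, regexec("^(FBN|FBW)([0-9]+)$", spec))[[1]]
  if (!length(m)) stop("unknown discretization spec '", spec, "'")
  list(method = m[2], n = as.integer(m[3]))
}

#' Prepare the OR and TLR feature sets from a cohort
#'
#' Applies the reproducibility (ICC) filter from the segmentation replicates,
#' assembles the origin (OR) and tumor-to-liver-ratio (TLR) feature sets, and
#' prunes redundant features by Pearson correlation — each filter applied
#' once to the full dataset, ahead of the evaluation grid.
#'
#' @param cohort a `synthetic_cohort` (or any list with `tumor_table`,
#'   `liver_table`, `replicates`).
#' @param icc_threshold retention cut for the ICC filter; `NA` skips it.
#' @param r_max Pearson pruning cut; `NA` skips pruning.
#' @return list with `OR` and `TLR` feature tables and `icc` (the
#'   `icc_report`, or NULL).
#' @export
prepare_feature_sets <- function(cohort, icc_threshold = 0.75, r_max = 0.9) {
  tumor <- cohort$tumor_table
  icc <- NULL
  if (!is.na(icc_threshold)) {
    icc <- icc_filter(cohort$replicates$rep_1a, cohort$replicates$rep_1b,
                      cohort$replicates$rep_2, threshold = icc_threshold)
    tumor <- tumor[, icc$retained]
  }
  or_table <- assemble_or(tumor)
  tlr_table <- assemble_tlr(tumor, cohort$liver_table)
  if (!is.na(r_max)) {
    or_table <- correlation_prune(or_table, r_max)
    tlr_table <- correlation_prune(tlr_table, r_max)
  }
  list(OR = or_table, TLR = tlr_table, icc = icc)
}

#' Balanced down-sampling followed by a stratified train/validation split
#'
#' The majority outcome class is randomly down-sampled without replacement to
#' the minority count, then each class is split `train_fraction` /
#' `1 - train_fraction`. All sampling is driven solely by `rng_seed`.
#'
#' @param table a `feature_table` with outcome labels.
#' @param train_fraction fraction of each (balanced) class placed in the
#'   training set; per class, `floor(train_fraction * n)` samples.
#' @param rng_seed integer seed.
#' @return list with `train` and `validation` feature tables.
#' @export
downsample_split <- function(table, train_fraction = 0.8, rng_seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  y <- outcome01(table)
  idx_pos <- which(y == 1)
  idx_neg <- which(y == 0)
  if (length(idx_pos) < 2 || length(idx_neg) < 2)
    stop("each outcome class needs at least 2 samples")
  with_seed(rng_seed, {
    m <- min(length(idx_pos), length(idx_neg))
    if (length(idx_pos) > m) idx_pos <- sort(sample(idx_pos, m))
    if (length(idx_neg) > m) idx_neg <- sort(sample(idx_neg, m))
    n_tr <- floor(train_fraction * m)
    tr_pos <- sort(sample(idx_pos, n_tr))
    tr_neg <- sort(sample(idx_neg, n_tr))
    train_idx <- sort(c(tr_pos, tr_neg))
    val_idx <- sort(c(setdiff(idx_pos, tr_pos), setdiff(idx_neg, tr_neg)))
    list(train = table[train_idx, ], validation = table[val_idx, ])
  })
}

#' Select the top-k most important features on a training table
#'
#' Fits the named tree-based selector and returns the `k` features with the
#' highest importance scores, ties broken by feature (column) order. The
#' scores are retained for use as radiomics-score weights.
#'
#' @param train a `feature_table` with outcome labels.
#' @param selector `"DT"`, `"RF"` or `"XGB"`.
#' @param k number of features to keep.
#' @param rng_seed integer seed for the stochastic selectors.
#' @return data.frame with `feature_id` and `importance`, `k` rows, ranked.
#' @export
select_features <- function(train, selector, k = 10, rng_seed = 1L) {
  stopifnot(k >= 1)
  imp <- feature_importance(train$values, outcome01(train), selector,
                            seed = rng_seed)
  ord <- order(-imp, seq_along(imp))
  top <- ord[seq_len(min(k, length(imp)))]
  data.frame(feature_id = names(imp)[top], importance = unname(imp[top]))
}

#' Harmonize and discretize a feature table per one grid configuration
#'
#' @param tables list with `OR` and `TLR` feature tables (all batches).
#' @param config one row of [enumerate_grid()] (or a list with the same
#'   fields).
#' @param mode `"full"` fits harmonization and discretization on all samples
#'   jointly (the default, matching a fit-before-split workflow);
#'   `"train_only"` fits both on the non-test batches and applies the frozen
#'   models to the test batch.
#' @param test_batch batch label of the held-out scanner (needed for
#'   `mode = "train_only"`).
#' @return the preprocessed `feature_table` (all samples).
#' @export
preprocess_config <- function(tables, config, mode = c("full", "train_only"),
                              test_batch = NULL) {
  mode <- match.arg(mode)
  table <- tables[[config$feature_type]]
  if (is.null(table))
    stop("unknown feature_type '", config$feature_type, "'")
  disc <- parse_discretization(config$discretization)
  if (mode == "full") {
    table <- harmonize(table, config$batch_method)$table
    table <- discretize_fit_transform(table, disc$method, disc$n)$table
    return(table)
  }
  if (is.null(test_batch))
    stop("mode = 'train_only' requires test_batch")
  src_idx <- which(table$sample_meta$batch != test_batch)
  tst_idx <- which(table$sample_meta$batch == test_batch)
  src <- table[src_idx, ]
  tst <- table[tst_idx, ]
  h <- harmonize(src, config$batch_method)
  src <- h$table
  if (config$batch_method != "none") {
    # test scanner unseen at fit time: harmonize it separately (its own
    # batch structure cannot be adjusted from the source scanners)
    tst <- harmonize(tst, "none")$table
  }
  d <- discretize_fit_transform(src, disc$method, disc$n)
  src <- d$table
  tst <- discretize_apply(d$model, tst)
  merged <- table
  merged$values[src_idx, ] <- src$values
  merged$values[tst_idx, ] <- tst$values
  merged
}

#' Evaluate one grid configuration by repeated down-sampled splits
#'
#' Per repeat: balanced down-sampling and a stratified 80/20 train/validation
#' split of the source scanners; top-k feature selection on the training set;
#' classifier training; AUC on the validation set and on the held-out test
#' scanner. The two AUCs are averaged over repeats and their mean is the
#' configuration's final score.
#'
#' @param config one row of [enumerate_grid()].
#' @param tables list with `OR` and `TLR` feature tables (all batches,
#'   outcome labels present).
#' @param test_batch batch label held out as the external test set.
#' @param repeats number of repeated splits.
#' @param seed integer seed driving every repeat.
#' @param k number of selected features.
#' @param mode preprocessing mode, see [preprocess_config()].
#' @param processed optional pre-computed output of [preprocess_config()]
#'   (cache used by [run_grid()]).
#' @return an `evaluation_result` list: `config`, `repeats`,
#'   `auc_validation`, `auc_test`, `auc_mean`, `per_repeat` (data.frame),
#'   `feature_freq` (selection frequencies), `seed`.
#' @export
evaluate_config <- function(config, tables, test_batch, repeats = 100,
                            seed = 1L, k = 10, mode = "full",
                            processed = NULL) {
  if (is.null(processed))
    processed <- preprocess_config(tables, config, mode = mode,
                                   test_batch = test_batch)
  if (!test_batch %in% processed$sample_meta$batch)
    stop("test_batch '", test_batch, "' not present")
  src <- processed[processed$sample_meta$batch != test_batch, ]
  tst <- processed[processed$sample_meta$batch == test_batch, ]
  y_test <- outcome01(tst)
  test_ids <- tst$sample_meta$sample_id
  repeat_seeds <- with_seed(seed,
                            sample.int(.Machine$integer.max, repeats))
  auc_val <- auc_tst <- numeric(repeats)
  sel_all <- character(0)
  for (r in seq_len(repeats)) {
    sp <- downsample_split(src, 0.8, rng_seed = repeat_seeds[r])
    stopifnot(!any(sp$train$sample_meta$sample_id %in% test_ids),
              !any(sp$validation$sample_meta$sample_id %in% test_ids))
    sel <- select_features(sp$train, config$selector, k = k,
                           rng_seed = repeat_seeds[r])
    feats <- sel$feature_id
    fit <- fit_classifier(config$classifier,
                          sp$train$values[, feats, drop = FALSE],
                          outcome01(sp$train), seed = repeat_seeds[r])
    s_val <- predict_scores(fit, sp$validation$values[, feats, drop = FALSE])
    s_tst <- predict_scores(fit, tst$values[, feats, drop = FALSE])
    auc_val[r] <- auc(s_val, outcome01(sp$validation))
    auc_tst[r] <- auc(s_tst, y_test)
    sel_all <- c(sel_all, feats)
  }
  structure(list(config = as.list(config), repeats = repeats,
                 auc_validation = mean(auc_val), auc_test = mean(auc_tst),
                 auc_mean = (mean(auc_val) + mean(auc_tst)) / 2,
                 per_repeat = data.frame(repeat_id = seq_len(repeats),
                                         auc_validation = auc_val,
                                         auc_test = auc_tst),
                 feature_freq = sort(table(sel_all), decreasing = TRUE),
                 seed = seed),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat(sprintf("<evaluation_result> %s | %s | %s | %s | %s\n",
              x$config$feature_type, x$config$batch_method,
              x$config$discretization, x$config$selector,
              x$config$classifier))
  cat(sprintf("  AUC validation %.3f, test %.3f, mean %.3f (%d repeats)\n",
              x$auc_validation, x$auc_test, x$auc_mean, x$repeats))
  invisible(x)
}

#' Run the evaluation grid
#'
#' Evaluates every configuration (or a subset), caching the preprocessing
#' shared by configurations that differ only in selector/classifier. A
#' failing configuration is recorded with its error message and does not
#' abort the grid. The same repeat seeds are used for every configuration,
#' so splits are paired across configurations.
#'
#' @param tables list with `OR` and `TLR` feature tables.
#' @param configs data.frame of configurations (default: the full 630-row
#'   grid).
#' @param test_batch held-out scanner batch label.
#' @param repeats repeated splits per configuration.
#' @param seed integer seed.
#' @param k selected features per repeat.
#' @param mode preprocessing mode, see [preprocess_config()].
#' @param verbose print progress.
#' @return list with `results` (data.frame ranked by `auc_mean`, descending)
#'   and `details` (list of `evaluation_result`, in `configs` order).
#' @export
run_grid <- function(tables, configs = enumerate_grid(), test_batch,
                     repeats = 100, seed = 1L, k = 10, mode = "full",
                     verbose = FALSE) {
  cache <- new.env(parent = emptyenv())
  details <- vector("list", nrow(configs))
  rows <- vector("list", nrow(configs))
  for (i in seq_len(nrow(configs))) {
    cfg <- configs[i, , drop = FALSE]
    key <- paste(cfg$feature_type, cfg$batch_method, cfg$discretization,
                 sep = "|")
    res <- tryCatch({
      if (is.null(cache[[key]]))
        cache[[key]] <- preprocess_config(tables, cfg, mode = mode,
                                          test_batch = test_batch)
      evaluate_config(cfg, tables, test_batch, repeats = repeats,
                      seed = seed, k = k, mode = mode,
                      processed = cache[[key]])
    }, error = function(e) e)
    if (inherits(res, "error")) {
      rows[[i]] <- data.frame(cfg, auc_validation = NA_real_,
                              auc_test = NA_real_, auc_mean = NA_real_,
                              n_repeats = repeats, seed = seed,
                              error = conditionMessage(res))
    } else {
      details[[i]] <- res
      rows[[i]] <- data.frame(cfg, auc_validation = res$auc_validation,
                              auc_test = res$auc_test,
                              auc_mean = res$auc_mean, n_repeats = repeats,
                              seed = seed, error = NA_character_)
    }
    if (verbose)
      message(sprintf("[%d/%d] %s -> %.3f", i, nrow(configs),
                      paste(unlist(cfg), collapse = "/"),
                      rows[[i]]$auc_mean))
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  results <- results[order(-results$auc_mean, na.last = TRUE), ]
  list(results = results, details = details)
}
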