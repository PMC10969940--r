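# Cross-validation experiment (Conventional vs Augmented) and the error
# metrics: NRMSE = RMSE / mean(observed) and MAAPE = mean(arctan of the
# absolute relative error), each on the whole test set and on its top-20%
# (80th-quantile) subset.

#' Normalized root mean square error
#'
#' `sqrt(mean((y - yhat)^2)) / mean(y)`.
#'
#' @param observed,predicted numeric vectors of equal nonzero length.
#' @param allow_nonpositive_mean if TRUE, a nonpositive observed mean is
#'   replaced by its absolute value (with a warning) instead of erroring.
#' @return Nonnegative scalar.
#' @export
nrmse <- function(observed, predicted, allow_nonpositive_mean = FALSE) {
  if (length(observed) == 0 || length(observed) != length(predicted))
    stop("observed and predicted must have equal nonzero length")
  ybar <- mean(observed)
  if (ybar <= 0) {
    if (!allow_nonpositive_mean)
      stop("mean of observed values is not positive; NRMSE undefined")
    warning("nonpositive observed mean; normalizing by |mean|")
    ybar <- abs(ybar)
    if (ybar == 0) stop("observed mean is zero; NRMSE undefined")
  }
  sqrt(mean((observed - predicted)^2)) / ybar
}

#' Mean arctangent absolute percentage error
#'
#' `mean(arctan(|(y - yhat) / y|))`, bounded by pi/2. When `y == 0` the
#' term is `pi/2` if the prediction misses and 0 if it is exact.
#'
#' @param observed,predicted numeric vectors of equal nonzero length.
#' @return Scalar in `[0, pi/2]`.
#' @export
maape <- function(observed, predicted) {
  if (length(observed) == 0 || length(observed) != length(predicted))
    stop("observed and predicted must have equal nonzero length")
  term <- ifelse(observed == 0,
                 ifelse(predicted == observed, 0, pi / 2),
                 atan(abs((observed - predicted) / observed)))
  mean(term)
}

#' Ids of the top quantile of an observed trait vector
#'
#' Returns the lines whose observed value is at or above the empirical
#' `(1 - fraction)` quantile (inclusive nearest rank); ties at the
#' threshold are all included, and at least one id is always returned.
#'
#' @param t observed trait vector.
#' @param fraction top fraction in `(0, 1)`.
#' @return Character vector of line ids.
#' @export
top_quantile_subset <- function(t, fraction = 0.2) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  n <- length(t)
  thr <- sort(as.numeric(t))[ceiling((1 - fraction) * n)]
  names(t)[as.numeric(t) >= thr]
}

#' Repeated random line-partition folds
#'
#' Each fold is an independent seeded random split of the lines into
#' `round(test_fraction * n)` test lines and the rest for training
#' (Monte-Carlo cross-validation, not disjoint k-fold). Per-fold seeds are
#' derived from the master seed, so one seed reproduces every fold.
#'
#' @param line_ids character vector of line ids.
#' @param n_folds number of random splits.
#' @param test_fraction fraction of lines in each test set, in `(0, 1)`.
#' @param seed master seed.
#' @return List of folds: `fold`, `train_ids`, `test_ids`, `seed`.
#' @export
make_folds <- function(line_ids, n_folds = 10, test_fraction = 0.2,
                       seed = 1) {
  if (n_folds < 1) stop("n_folds must be at least 1")
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be in (0, 1)")
  n <- length(line_ids)
  n_test <- round(test_fraction * n)
  if (n_test < 1 || n_test >= n)
    stop("test set would be empty or contain every line")
  set.seed(seed)
  fold_seeds <- sample.int(.Machine$integer.max, n_folds)
  lapply(seq_len(n_folds), function(i) {
    set.seed(fold_seeds[i])
    test <- sort(sample(line_ids, n_test))
    list(fold = i, train_ids = setdiff(line_ids, test), test_ids = test,
         seed = fold_seeds[i])
  })
}

# One fold of the C-vs-A comparison; returns two metric rows.
.eval_fold <- function(m, t, cfg, fold, g_full, top_eval_fraction) {
  train <- fold$train_ids
  test <- fold$test_ids
  y_test <- t[test]
  top_ids <- top_quantile_subset(trait_vector(y_test, test, .trait_name(t)),
                                 top_eval_fraction)

  row_for <- function(method, pred) {
    data.frame(method = method, trait = .trait_name(t), fold = fold$fold,
               nrmse = nrmse(as.numeric(y_test), as.numeric(pred[test])),
               maape = maape(as.numeric(y_test), as.numeric(pred[test])),
               nrmse_80 = nrmse(as.numeric(t[top_ids]),
                                as.numeric(pred[top_ids])),
               maape_80 = maape(as.numeric(t[top_ids]),
                                as.numeric(pred[top_ids])),
               stringsAsFactors = FALSE)
  }

  # Conventional: GBLUP on all training lines, G from original dosages.
  fit_c <- fit_reml(trait_vector(t[train], train, .trait_name(t)), g_full)
  pred_c <- predict(fit_c, g_full, test)

  # Augmented: top-fraction lines + mixup offspring; G recomputed from the
  # stacked augmented-training + test dosage matrix.
  cfg_f <- cfg
  if (is.null(cfg_f$seed)) cfg_f$seed <- fold$seed + 1L
  aug <- build_augmented_set(m[train, , drop = FALSE],
                             trait_vector(t[train], train, .trait_name(t)),
                             cfg_f)
  stacked <- rbind(aug$markers, m[test, , drop = FALSE])
  g_aug <- vanraden_grm(stacked)
  fit_a <- fit_reml(aug$phenotypes, g_aug)
  pred_a <- predict(fit_a, g_aug, test)

  rbind(row_for("C", pred_c), row_for("A", pred_a))
}

#' Run the Conventional-vs-Augmented cross-validation experiment
#'
#' Per fold, the Conventional method (C) fits GBLUP on all training lines
#' with G computed from the original dosages, and the Augmented method (A)
#' fits GBLUP on the top-fraction training lines plus their mixup-synthetic
#' offspring, with G computed from the stacked augmented-training and
#' test-line marker matrix. Both predict the test lines and are scored by
#' NRMSE and MAAPE on the whole test set and on its top-quantile subset.
#'
#' @param m complete marker matrix, aligned with `t`.
#' @param t trait vector.
#' @param cfg a [mixup_config()]; when its seed is NULL the per-fold
#'   augmentation seed is derived from the fold seed.
#' @param folds output of [make_folds()].
#' @param top_eval_fraction fraction defining the top test subset.
#' @return data.frame with one row per method per fold: `method`, `trait`,
#'   `fold`, `nrmse`, `maape`, `nrmse_80`, `maape_80`.
#' @export
run_experiment <- function(m, t, cfg = mixup_config(), folds,
                           top_eval_fraction = 0.2) {
  if (!identical(rownames(m), names(t)))
    stop("markers and trait are not aligned; call align_data() first")
  g_full <- vanraden_grm(m)
  res <- lapply(folds, function(fold) {
    tryCatch(.eval_fold(m, t, cfg, fold, g_full, top_eval_fraction),
             error = function(e)
               stop("fold ", fold$fold, ": ", conditionMessage(e),
                    call. = FALSE))
  })
  do.call(rbind, res)
}

#' Relative gain in percent
#'
#' `100 * (metric_a - metric_b) / metric_b`: the percent by which `metric_a`
#' exceeds `metric_b`. Pass (worse, better) to report "better by X%".
#'
#' @param metric_a,metric_b scalars; `metric_b` must be positive.
#' @return Percent difference.
#' @export
relative_gain <- function(metric_a, metric_b) {
  if (metric_b <= 0) stop("reference metric must be positive")
  100 * (metric_a - metric_b) / metric_b
}

#' Summarize cross-validation metric records
#'
#' Averages each metric over folds per (method, trait), adds an across-trait
#' "AT" row (and across-dataset rows when a `dataset` column with several
#' levels is present), and, when both methods C and A are present, paired
#' gain columns: `gain_<metric>` is the percent by which the worse method
#' exceeds the better one ([relative_gain()]) and `better_<metric>` names
#' the winner.
#'
#' @param records data.frame from [run_experiment()], optionally with a
#'   `dataset` column.
#' @return Wide data.frame, one row per trait (plus "AT"), with per-method
#'   metric means and gain columns.
#' @export
summarize_metrics <- function(records) {
  if (nrow(records) == 0) stop("no records to summarize")
  metrics <- c("nrmse", "maape", "nrmse_80", "maape_80")
  has_dataset <- "dataset" %in% names(records) &&
    length(unique(records$dataset)) > 1
  if (!"dataset" %in% names(records)) records$dataset <- "data"

  fold_means <- stats::aggregate(
    records[metrics],
    by = list(dataset = records$dataset, trait = records$trait,
              method = records$method),
    FUN = mean)

  at <- stats::aggregate(fold_means[metrics],
                         by = list(dataset = fold_means$dataset,
                                   method = fold_means$method),
                         FUN = mean)
  at$trait <- "AT"
  fold_means <- rbind(fold_means, at[, names(fold_means)])
  if (has_dataset) {
    ad <- stats::aggregate(
      fold_means[fold_means$trait == "AT", metrics],
      by = list(method = fold_means$method[fold_means$trait == "AT"]),
      FUN = mean)
    ad$dataset <- "across_data"
    ad$trait <- "AT"
    fold_means <- rbind(fold_means, ad[, names(fold_means)])
  }

  methods <- sort(unique(fold_means$method))
  keys <- unique(fold_means[c("dataset", "trait")])
  out <- keys
  for (mth in methods) {
    sub <- fold_means[fold_means$method == mth, ]
    idx <- match(paste(keys$dataset, keys$trait),
                 paste(sub$dataset, sub$trait))
    for (met in metrics) out[[paste0(mth, "_", met)]] <- sub[[met]][idx]
  }
  if (all(c("C", "A") %in% methods)) {
    for (met in metrics) {
      a <- out[[paste0("A_", met)]]
      c_ <- out[[paste0("C_", met)]]
      worse <- pmax(a, c_)
      better <- pmin(a, c_)
      out[[paste0("gain_", met)]] <-
        mapply(relative_gain, worse, better)
      out[[paste0("better_", met)]] <- ifelse(a < c_, "A",
                                              ifelse(c_ < a, "C", "tie"))
    }
  }
  if (!has_dataset) out$dataset <- NULL
  rownames(out) <- NULL
  out
}

#' Four-panel bar chart of a metrics summary
#'
#' Mirrors the standard layout: (A) MAAPE on the whole test set, (B)
#' MAAPE on the top-20% subset, (C) NRMSE on the whole test set, (D) NRMSE
#' on the top-20% subset, with one bar pair (C vs A) per trait.
#'
#' @param summary output of [summarize_metrics()] with both methods.
#' @export
plot_summary <- function(summary) {
  metrics <- c(maape = "MAAPE", maape_80 = "MAAPE_80",
               nrmse = "NRMSE", nrmse_80 = "NRMSE_80")
  old <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (met in names(metrics)) {
    h <- rbind(C = summary[[paste0("C_", met)]],
               A = summary[[paste0("A_", met)]])
    colnames(h) <- summary$trait
    graphics::barplot(h, beside = TRUE, col = c("darkgreen", "firebrick"),
                      main = metrics[met], ylab = metrics[met],
                      legend.text = c("Conventional", "Augmented"),
                      args.legend = list(bty = "n", cex = 0.8))
  }
  invisible(NULL)
}

#' Write cross-validation records as delimited text
#'
#' @param records data.frame of per-fold records or a summary table.
#' @param path output path.
#' @param dialect `"csv"` or `"tsv"`.
#' @export
write_records <- function(records, path, dialect = c("csv", "tsv")) {
  utils::write.table(records, path, sep = .sep_for(match.arg(dialect)),
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
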