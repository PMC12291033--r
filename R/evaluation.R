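#' Evaluation configuration
#'
#' @param task `"auto"` (infer from the response encoding), `"regression"`
#'   or `"classification"`.
#' @param mccv_repeats Monte Carlo CV repeats (default 1000).
#' @param test_fraction held-out fraction per split (default 0.2).
#' @param kfold_k folds for latent-variable selection (default 5).
#' @param lv_grid candidate component counts for [select_n_components()].
#' @param ci_level confidence level for metric intervals (default 0.90).
#' @param ci_type `"normal"` (mean +/- z*sd/sqrt(repeats)) or
#'   `"percentile"`.
#' @param seed integer seed driving all splits.
#' @return list of class `"eval_config"`.
#' @export
eval_config <- function(task = c("auto", "regression", "classification"),
                        mccv_repeats = 1000, test_fraction = 0.2,
                        kfold_k = 5, lv_grid = 1:8,
                        ci_level = 0.90, ci_type = c("normal", "percentile"),
                        seed = 1) {
  task <- match.arg(task)
  ci_type <- match.arg(ci_type)
  stopifnot(test_fraction > 0, test_fraction < 1,
            length(lv_grid) >= 1, all(lv_grid >= 1),
            mccv_repeats >= 1, kfold_k >= 2,
            ci_level > 0, ci_level < 1)
  structure(list(task = task, mccv_repeats = mccv_repeats,
                 test_fraction = test_fraction, kfold_k = kfold_k,
                 lv_grid = sort(unique(as.integer(lv_grid))),
                 ci_level = ci_level, ci_type = ci_type, seed = seed),
            class = "eval_config")
}

resolve_task <- function(config, y) {
  if (config$task != "auto") return(config$task)
  if (is_binary(y)) "classification" else "regression"
}

primary_metric <- function(task) if (task == "regression") "q2" else "accuracy"

## ---- metrics ---------------------------------------------------------------

#' Out-of-sample predictive R-squared (Q2)
#'
#' `1 - SS_res / SS_tot` with `SS_tot` centered on the *training-set* mean,
#' the out-of-sample convention: a model predicting the training mean for
#' every test sample scores exactly 0.
#'
#' @param y observed test responses.
#' @param yhat predictions.
#' @param train_mean training-set response mean.
#' @return scalar Q2 (can be negative).
#' @export
metric_q2 <- function(y, yhat, train_mean) {
  1 - sum((y - yhat)^2) / sum((y - train_mean)^2)
}

#' Root-mean-squared error
#' @param y observed values.
#' @param yhat predictions.
#' @return scalar RMSE, >= 0.
#' @export
metric_rmse <- function(y, yhat) sqrt(mean((y - yhat)^2))

#' Classification accuracy
#' @param y 0/1 labels.
#' @param labels predicted 0/1 labels.
#' @return fraction correct.
#' @export
metric_accuracy <- function(y, labels) mean(y == labels)

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) estimator; ties receive average ranks.
#'
#' @param y 0/1 labels (1 = positive class).
#' @param scores continuous decision scores.
#' @return AUC in `[0, 1]`.
#' @export
metric_auc <- function(y, scores) {
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' F1 score of the positive class
#' @param y 0/1 labels (1 = positive class).
#' @param labels predicted 0/1 labels.
#' @return F1 in `[0, 1]`; 0 when no positives are predicted or present.
#' @export
metric_f1 <- function(y, labels) {
  tp <- sum(y == 1 & labels == 1)
  fp <- sum(y == 0 & labels == 1)
  fn <- sum(y == 1 & labels == 0)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

## ---- latent variable selection ---------------------------------------------

# betas for nested component counts from one engine fit at max R
nested_betas <- function(eng, grid) {
  P <- do.call(rbind, eng$block_loadings)
  lapply(grid, function(r) {
    W <- eng$w_eff[, seq_len(r), drop = FALSE]
    as.numeric(W %*% solve(crossprod(P[, seq_len(r), drop = FALSE], W),
                           eng$y_loadings[seq_len(r)]))
  })
}

#' Select the number of latent variables by k-fold CV
#'
#' Grid search over `config$lv_grid` with `config$kfold_k`-fold CV (folds
#' stratified by class for classification).  The fold score is Q2 for
#' regression and accuracy for classification.  Returns the smallest
#' component count whose mean score is within one standard error of the
#' best mean score (1-SE parsimony rule).
#'
#' @param dataset a `multiblock_dataset`.
#' @param config an [eval_config()].
#' @param scaling a [scaling_spec()].
#' @return list with `n_components`, `grid`, `mean_score`, `se_score`.
#' @export
select_n_components <- function(dataset, config = eval_config(),
                                scaling = scaling_spec()) {
  task <- resolve_task(config, dataset$y)
  y <- dataset$y
  N <- length(y)
  grid <- config$lv_grid
  grid <- grid[grid <= min(N - ceiling(N / config$kfold_k) - 1,
                           sum(vapply(dataset$blocks, function(b) ncol(b$X), 1L)))]
  if (!length(grid)) stop("no candidate in lv_grid fits the data dimensions")
  if (length(grid) == 1) {
    mbpls_fit(dataset, grid, scaling)  # fit check only
    return(list(n_components = grid, grid = grid,
                mean_score = NA_real_, se_score = NA_real_))
  }
  folds <- with_seed(config$seed, {
    if (task == "classification") {
      f <- integer(N)
      for (cl in unique(y)) {
        idx <- which(y == cl)
        f[idx] <- sample(rep_len(seq_len(config$kfold_k), length(idx)))
      }
      f
    } else sample(rep_len(seq_len(config$kfold_k), N))
  })
  scores <- matrix(NA_real_, config$kfold_k, length(grid))
  for (k in seq_len(config$kfold_k)) {
    tr <- folds != k
    sub_tr <- subset_samples(dataset, which(tr))
    scalers <- lapply(sub_tr$blocks, function(b)
      learn_scaling(b$X, block_scaling_method(scaling, b$assay),
                    b$features$feature_id))
    Xs_tr <- Map(function(b, sc) apply_scaling(b$X, sc), sub_tr$blocks, scalers)
    y_tr <- sub_tr$y
    eng <- mbpls_engine(Xs_tr, y_tr - mean(y_tr), max(grid))
    betas <- nested_betas(eng, grid)
    Xte <- do.call(cbind, Map(function(b, sc)
      apply_scaling(b$X[!tr, , drop = FALSE], sc), dataset$blocks, scalers))
    y_te <- y[!tr]
    for (g in seq_along(grid)) {
      yhat <- as.numeric(Xte %*% betas[[g]]) + mean(y_tr)
      scores[k, g] <- if (task == "regression")
        metric_q2(y_te, yhat, mean(y_tr))
      else metric_accuracy(y_te, as.numeric(yhat >= 0.5))
    }
  }
  mean_score <- colMeans(scores)
  se_score <- apply(scores, 2, stats::sd) / sqrt(config$kfold_k)
  best <- which.max(mean_score)
  ok <- mean_score >= mean_score[best] - se_score[best]
  list(n_components = grid[which(ok)[1]], grid = grid,
       mean_score = mean_score, se_score = se_score)
}

subset_samples <- function(dataset, idx) {
  blocks <- lapply(dataset$blocks, function(b) {
    b$X <- b$X[idx, , drop = FALSE]
    b$sample_ids <- b$sample_ids[idx]
    b
  })
  structure(list(blocks = blocks, y = dataset$y[idx],
                 y_name = dataset$y_name, n_dropped = dataset$n_dropped),
            class = "multiblock_dataset")
}

## ---- Monte Carlo cross-validation ------------------------------------------

#' Evaluate an MB-PLS model by Monte Carlo cross-validation
#'
#' Repeats independent random train/test splits (stratified by class for
#' classification), learns centering/scaling on the training split only,
#' fits the model and scores the held-out samples.  Regression reports Q2
#' and RMSE; classification reports accuracy, AUC and F1.  The CI
#' half-width is `z * sd / sqrt(repeats)` at `config$ci_level`
#' (`ci_type = "percentile"` reports half the central quantile range
#' instead).  A classification split whose training part contains a single
#' class is redrawn; the redraw count is recorded.
#'
#' @param dataset a `multiblock_dataset`.
#' @param n_components latent variables per fit.
#' @param scaling a [scaling_spec()].
#' @param config an [eval_config()].
#' @return list of class `"eval_report"` with `summary` (metric, mean, sd,
#'   ci_halfwidth), `splits` (per-split metric data.frame), `task`,
#'   `n_redraws`.
#' @export
mccv_evaluate <- function(dataset, n_components, scaling = scaling_spec(),
                          config = eval_config()) {
  task <- resolve_task(config, dataset$y)
  y <- dataset$y
  N <- length(y)
  n_test <- max(1L, round(config$test_fraction * N))
  if (n_test >= N) stop("test_fraction leaves no training samples")
  res_all <- with_seed(config$seed, {
    out <- vector("list", config$mccv_repeats)
    redraws <- 0L
    for (i in seq_len(config$mccv_repeats)) {
      repeat {
        test_idx <- if (task == "classification") {
          unlist(lapply(unique(y), function(cl) {
            idx <- which(y == cl)
            sample(idx, max(1L, round(config$test_fraction * length(idx))))
          }))
        } else sample.int(N, n_test)
        tr_idx <- setdiff(seq_len(N), test_idx)
        if (task != "classification" || length(unique(y[tr_idx])) > 1) break
        redraws <- redraws + 1L
      }
      sub_tr <- subset_samples(dataset, tr_idx)
      scalers <- lapply(sub_tr$blocks, function(b)
        learn_scaling(b$X, block_scaling_method(scaling, b$assay),
                      b$features$feature_id))
      Xs_tr <- Map(function(b, sc) apply_scaling(b$X, sc), sub_tr$blocks, scalers)
      mu <- mean(sub_tr$y)
      eng <- mbpls_engine(Xs_tr, sub_tr$y - mu,
                          min(n_components, length(tr_idx) - 1))
      Xte <- do.call(cbind, Map(function(b, sc)
        apply_scaling(b$X[test_idx, , drop = FALSE], sc),
        dataset$blocks, scalers))
      yhat <- as.numeric(Xte %*% eng$beta) + mu
      y_te <- y[test_idx]
      out[[i]] <- if (task == "regression") {
        c(q2 = metric_q2(y_te, yhat, mu), rmse = metric_rmse(y_te, yhat))
      } else {
        lab <- as.numeric(yhat >= 0.5)
        c(accuracy = metric_accuracy(y_te, lab),
          auc = metric_auc(y_te, yhat),
          f1 = metric_f1(y_te, lab))
      }
    }
    list(res = do.call(rbind, out), redraws = redraws)
  })
  res <- res_all$res
  redraws <- res_all$redraws
  z <- stats::qnorm(1 - (1 - config$ci_level) / 2)
  summ <- data.frame(metric = colnames(res),
                     mean = colMeans(res),
                     sd = apply(res, 2, stats::sd),
                     stringsAsFactors = FALSE, row.names = NULL)
  summ$ci_halfwidth <- if (config$ci_type == "normal") {
    z * summ$sd / sqrt(nrow(res))
  } else {
    a <- (1 - config$ci_level) / 2
    apply(res, 2, function(v) diff(stats::quantile(v, c(a, 1 - a))) / 2)
  }
  structure(list(summary = summ,
                 splits = as.data.frame(res),
                 task = task,
                 n_components = n_components,
                 n_redraws = redraws,
                 config = config),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>", x$task, "task,", nrow(x$splits), "MCCV splits, R =",
      x$n_components, "\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-8s %.3f +/- %.3f\n", s$metric[i], s$mean[i],
                s$ci_halfwidth[i]))
  invisible(x)
}

#' Write an evaluation report to delimited text
#'
#' One row per split per metric plus a summary block prefixed `# summary`.
#' @param report an `"eval_report"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  long <- utils::stack(report$splits)
  long <- data.frame(split = rep(seq_len(nrow(report$splits)),
                                 ncol(report$splits)),
                     metric = long$ind, value = sprintf("%.10g", long$values))
  utils::write.table(long, con, sep = ",", row.names = FALSE, quote = FALSE)
  writeLines("# summary", con)
  s <- report$summary
  s$mean <- sprintf("%.10g", s$mean)
  s$sd <- sprintf("%.10g", s$sd)
  s$ci_halfwidth <- sprintf("%.10g", s$ci_halfwidth)
  utils::write.table(s, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
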