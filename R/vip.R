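#' Multiblock variable importance in projection (MB-VIP)
#'
#' Per feature j, `VIP_j = sqrt(M * sum_r(SSY_r * v_jr^2) / sum_r(SSY_r))`
#' where `SSY_r = c_r^2 * t_r't_r` is the response variance captured by
#' component r, `v_r` is the unit-norm concatenation over blocks of the
#' block weights scaled by the super weights, and M is the total feature
#' count.  This reduces to classical PLS VIP for a single block and equals
#' the VIP of a PLS model on the concatenated blocks when all blocks share
#' one scaling.  The mean squared VIP over features is always 1.
#'
#' @param model fitted [mbpls_fit()] model.
#' @return named nonnegative numeric vector, one value per feature.
#' @export
mb_vip <- function(model) {
  stopifnot(inherits(model, "mbpls"))
  ssy <- model$ssy
  M <- sum(model$n_block_features)
  v2 <- model$w_eff^2           # columns already unit norm
  vip <- sqrt(M * as.numeric(v2 %*% ssy) / sum(ssy))
  names(vip) <- model$features$feature_id
  vip
}

#' Permutation-based empirical p-values for MB-VIP
#'
#' Refits the MB-PLS model `n_permutations` times with the response rows
#' permuted by a seeded generator (same number of components and scaling as
#' the observed fit) and records each feature's MB-VIP under the null.  The
#' empirical p-value uses the add-one estimator
#' `p_j = (1 + #\{VIP_j^perm >= VIP_j^obs\}) / (n_permutations + 1)`, so the
#' smallest attainable p-value is `1/(n_permutations + 1)`.
#'
#' Results depend only on `(seed, n_permutations)`; permutations are drawn
#' up front so chunked execution cannot change them.
#'
#' @param dataset a `multiblock_dataset`.
#' @param n_components components for the observed fit and every refit
#'   (held fixed across permutations).
#' @param scaling a [scaling_spec()].
#' @param n_permutations number of Y permutations, >= 1.
#' @param seed integer seed for the permutation stream.
#' @param cutoffs named numeric vector of candidate p-value cutoffs for the
#'   selection masks; default `0.05`, `0.01` and Bonferroni `0.05/M`.
#' @return An object of class `"vip_result"`: `vip`, `p_values`,
#'   `n_permutations`, `perm_mean`/`perm_q95` null summaries, `cutoff_table`
#'   (one logical selection mask per cutoff label), `features` metadata.
#' @export
permutation_pvalues <- function(dataset, n_components,
                                scaling = scaling_spec(),
                                n_permutations = 1000, seed = 1,
                                cutoffs = NULL) {
  stopifnot(inherits(dataset, "multiblock_dataset"))
  if (n_permutations < 1) stop("n_permutations must be >= 1")
  model <- mbpls_fit(dataset, n_components, scaling)
  vip_obs <- mb_vip(model)
  M <- length(vip_obs)
  N <- length(dataset$y)
  # permuting y leaves the X scaling untouched: scale once, refit many times
  Xs <- Map(function(b, sc) apply_scaling(b$X, sc), dataset$blocks, model$scalers)
  yc <- dataset$y - model$y_mean
  perms <- with_seed(seed, replicate(n_permutations, sample.int(N), simplify = FALSE))
  exceed <- numeric(M)
  perm_sum <- numeric(M)
  perm_q <- matrix(0, M, 0)
  keep_q <- min(n_permutations, 200L)  # subsample for the q95 summary
  qidx <- unique(round(seq(1, n_permutations, length.out = keep_q)))
  qstore <- matrix(NA_real_, M, length(qidx))
  for (k in seq_len(n_permutations)) {
    eng <- tryCatch(mbpls_engine(Xs, yc[perms[[k]]], n_components),
                    error = function(e)
                      stop("permutation ", k, ": ", conditionMessage(e)))
    vip_k <- sqrt(M * as.numeric(eng$w_eff^2 %*% eng$ssy) / sum(eng$ssy))
    exceed <- exceed + (vip_k >= vip_obs)
    perm_sum <- perm_sum + vip_k
    hit <- match(k, qidx)
    if (!is.na(hit)) qstore[, hit] <- vip_k
  }
  p <- (1 + exceed) / (n_permutations + 1)
  names(p) <- names(vip_obs)
  if (is.null(cutoffs))
    cutoffs <- c("0.05" = 0.05, "0.01" = 0.01, bonferroni = 0.05 / M)
  cutoff_table <- lapply(cutoffs, function(a) p <= a)
  structure(list(vip = vip_obs,
                 p_values = p,
                 n_permutations = n_permutations,
                 seed = seed,
                 n_components = n_components,
                 perm_mean = perm_sum / n_permutations,
                 perm_q95 = apply(qstore, 1, stats::quantile, 0.95, names = FALSE),
                 cutoffs = cutoffs,
                 cutoff_table = cutoff_table,
                 chosen_cutoff = NA_character_,
                 features = model$features),
            class = "vip_result")
}

#' @export
print.vip_result <- function(x, ...) {
  cat("<vip_result>", length(x$vip), "features,", x$n_permutations,
      "permutations\n")
  for (lab in names(x$cutoff_table))
    cat(sprintf("  %-12s (p <= %.3g): %d selected\n", lab, x$cutoffs[[lab]],
                sum(x$cutoff_table[[lab]])))
  if (!is.na(x$chosen_cutoff)) cat("  chosen cutoff:", x$chosen_cutoff, "\n")
  invisible(x)
}

subset_dataset <- function(dataset, keep_ids) {
  blocks <- list()
  for (b in dataset$blocks) {
    sel <- b$features$feature_id %in% keep_ids
    if (!any(sel)) next
    b$X <- b$X[, sel, drop = FALSE]
    b$features <- b$features[sel, , drop = FALSE]
    blocks[[length(blocks) + 1]] <- b
  }
  if (!length(blocks)) stop("no features left in any block")
  align_blocks(blocks, dataset$y, dataset$y_name)
}

#' Benchmark p-value cutoffs against the all-features baseline
#'
#' For each candidate cutoff, refits the MB-PLS model on the features with
#' `p <= cutoff` and evaluates it by Monte Carlo cross-validation.  The
#' chosen cutoff is the one selecting the fewest features among those whose
#' mean performance is at least the baseline (all features) mean minus one
#' baseline CI half-width; ties go to the most stringent cutoff.  A cutoff
#' selecting zero features is skipped with a warning.  If no cutoff
#' qualifies, the baseline is returned with `fallback = TRUE`.
#'
#' @param dataset a `multiblock_dataset`.
#' @param vip_result result of [permutation_pvalues()].
#' @param config an [eval_config()]; its task/repeat settings drive the MCCV.
#' @param scaling a [scaling_spec()].
#' @param n_components components for all refits (default: the value used
#'   for the VIP fit).
#' @return list of class `"cutoff_benchmark"`: `table` (per-cutoff metrics),
#'   `chosen` label, `selected` feature-id vector, `baseline` summary,
#'   `fallback` flag.  The input `vip_result`'s `chosen_cutoff` is not
#'   modified; store the returned label if needed.
#' @export
benchmark_cutoff <- function(dataset, vip_result, config = eval_config(),
                             scaling = scaling_spec(),
                             n_components = vip_result$n_components) {
  stopifnot(inherits(vip_result, "vip_result"))
  metric <- primary_metric(resolve_task(config, dataset$y))
  base_rep <- mccv_evaluate(dataset, n_components, scaling, config)
  base_mean <- base_rep$summary[base_rep$summary$metric == metric, "mean"]
  base_hw <- base_rep$summary[base_rep$summary$metric == metric, "ci_halfwidth"]
  threshold <- base_mean - base_hw

  labels <- names(vip_result$cutoff_table)
  ord <- order(unlist(vip_result$cutoffs[labels]))   # most stringent first
  labels <- labels[ord]
  rows <- list()
  for (lab in labels) {
    mask <- vip_result$cutoff_table[[lab]]
    n_sel <- sum(mask)
    if (n_sel == 0) {
      warning("cutoff '", lab, "' selects zero features; skipped")
      next
    }
    ids <- names(vip_result$p_values)[mask]
    sub <- subset_dataset(dataset, ids)
    R_sub <- min(n_components, length(sub$y) - 1, sum(mask))
    rep_k <- mccv_evaluate(sub, R_sub, scaling, config)
    m <- rep_k$summary[rep_k$summary$metric == metric, ]
    rows[[lab]] <- data.frame(cutoff = lab,
                              alpha = unname(vip_result$cutoffs[[lab]]),
                              n_selected = n_sel,
                              metric = metric,
                              mean = m$mean,
                              ci_halfwidth = m$ci_halfwidth,
                              meets_baseline = m$mean >= threshold,
                              stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  fallback <- is.null(tab) || !any(tab$meets_baseline)
  if (fallback) {
    chosen <- "baseline"
    selected <- names(vip_result$p_values)
  } else {
    ok <- tab[tab$meets_baseline, ]
    # fewest features; ties resolved toward the most stringent cutoff,
    # which is the first row because rows were built stringent-first
    chosen <- ok$cutoff[which.min(ok$n_selected)]
    selected <- names(vip_result$p_values)[vip_result$cutoff_table[[chosen]]]
  }
  structure(list(table = tab,
                 chosen = chosen,
                 selected = selected,
                 baseline = list(metric = metric, mean = base_mean,
                                 ci_halfwidth = base_hw, threshold = threshold),
                 baseline_report = base_rep,
                 fallback = fallback),
            class = "cutoff_benchmark")
}

#' @export
print.cutoff_benchmark <- function(x, ...) {
  cat("<cutoff_benchmark> baseline", x$baseline$metric,
      sprintf("= %.3f (+/- %.3f)\n", x$baseline$mean, x$baseline$ci_halfwidth))
  if (!is.null(x$table)) print(x$table, row.names = FALSE)
  cat("chosen cutoff:", x$chosen, if (x$fallback) "(fallback: no cutoff met baseline)" else "", "\n")
  invisible(x)
}

#' Write the selected-feature report
#'
#' One row per feature with metadata, MB-VIP, empirical p-value and the
#' selection flag under each cutoff, sorted by p-value then VIP (descending).
#'
#' @param vip_result a `"vip_result"`.
#' @param path output CSV path.
#' @param selected_only write only features selected at `chosen` cutoff.
#' @param chosen cutoff label used when `selected_only = TRUE`.
#' @return the report data.frame, invisibly.
#' @export
write_feature_report <- function(vip_result, path, selected_only = FALSE,
                                 chosen = vip_result$chosen_cutoff) {
  df <- vip_result$features
  df$vip <- unname(vip_result$vip)
  df$p_value <- unname(vip_result$p_values)
  for (lab in names(vip_result$cutoff_table))
    df[[paste0("selected_", gsub("[^0-9A-Za-z]", "_", lab))]] <-
      unname(vip_result$cutoff_table[[lab]])
  df <- df[order(df$p_value, -df$vip, df$feature_id), ]
  if (selected_only) {
    if (is.na(chosen)) stop("no chosen cutoff recorded")
    if (chosen != "baseline") df <- df[vip_result$cutoff_table[[chosen]][df$feature_id], ]
  }
  df$vip <- sprintf("%.10g", df$vip)
  df$p_value <- sprintf("%.10g", df$p_value)
  df$mz <- sprintf("%.10g", df$mz)
  df$rt <- sprintf("%.10g", df$rt)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(df)
}
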