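#' Feature scaling specification
#'
#' Blocks are always mean-centered per feature; the scale divisor is the
#' feature standard deviation (`"unit_variance"`, default), its square root
#' (`"pareto"`), or 1 (`"none"`).  A per-block override map allows different
#' scalings per assay, e.g. `scaling_spec("unit_variance", list(lipids = "pareto"))`.
#'
#' @param method default scaling method.
#' @param overrides named list `assay -> method`.
#' @return An object of class `"scaling_spec"`.
#' @export
scaling_spec <- function(method = c("unit_variance", "pareto", "none"),
                         overrides = list()) {
  method <- match.arg(method)
  ok <- c("unit_variance", "pareto", "none")
  if (length(overrides) && !all(unlist(overrides) %in% ok))
    stop("override methods must be one of: ", paste(ok, collapse = ", "))
  structure(list(method = method, overrides = overrides), class = "scaling_spec")
}

block_scaling_method <- function(spec, assay) {
  if (!is.null(spec$overrides[[assay]])) spec$overrides[[assay]] else spec$method
}

# Learn center/scale for one block; zero-variance features are an error
# because they carry no information and break unit-variance scaling.
learn_scaling <- function(X, method, feature_ids = colnames(X)) {
  ctr <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance feature(s) after scaling: ",
         paste(utils::head(feature_ids[sds == 0], 5), collapse = ", "))
  scl <- switch(method,
                unit_variance = sds,
                pareto = sqrt(sds),
                none = rep(1, length(sds)))
  list(center = ctr, scale = scl)
}

apply_scaling <- function(X, sc) sweep(sweep(X, 2, sc$center), 2, sc$scale, "/")

# NIPALS-style MB-PLS engine on pre-centered/scaled blocks and centered y.
# Returns per-component block weights/scores, super weights/scores, loadings,
# y loadings, effective concatenated weights and regression coefficients.
mbpls_engine <- function(Xs, yc, R, tol = 1e-10, max_iter = 500) {
  B <- length(Xs)
  N <- nrow(Xs[[1]])
  Mb <- vapply(Xs, ncol, 1L)
  M <- sum(Mb)
  tot_ss <- vapply(Xs, function(X) sum(X^2), 1.0)
  Xd <- Xs          # deflated working copies
  yd <- yc
  Wb <- lapply(Mb, function(m) matrix(0, m, R))
  Pb <- lapply(Mb, function(m) matrix(0, m, R))
  Tb <- lapply(seq_len(B), function(b) matrix(0, N, R))
  WT <- matrix(0, B, R)
  TT <- matrix(0, N, R)
  U  <- matrix(0, N, R)
  cvec <- numeric(R)
  Weff <- matrix(0, M, R)
  varexp <- matrix(0, B, R)

  for (r in seq_len(R)) {
    u <- yd
    tT_old <- rep(0, N)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      uu <- sum(u^2)
      wb <- lapply(Xd, function(X) {
        w <- crossprod(X, u) / uu
        nrm <- sqrt(sum(w^2))
        if (nrm < .Machine$double.eps * 100)
          stop("component ", r, ": a block has no remaining covariance with y")
        w / nrm
      })
      Tmat <- vapply(seq_len(B), function(b) as.numeric(Xd[[b]] %*% wb[[b]]),
                     numeric(N))
      wT <- crossprod(Tmat, u) / uu
      wT <- wT / sqrt(sum(wT^2))
      tT <- as.numeric(Tmat %*% wT)          # w_T'w_T = 1
      cc <- sum(yd * tT) / sum(tT^2)
      u  <- yd * cc / (cc * cc)              # Y c (C'C)^-1 for univariate Y
      if (sqrt(sum((tT - tT_old)^2)) <= tol * sqrt(sum(tT^2))) {
        converged <- TRUE
        break
      }
      tT_old <- tT
    }
    if (!converged)
      stop("MB-PLS inner loop did not converge for component ", r,
           " within ", max_iter, " iterations")
    tt <- sum(tT^2)
    cr <- sum(yd * tT) / tt
    for (b in seq_len(B)) {
      p <- crossprod(Xd[[b]], tT) / tt
      Wb[[b]][, r] <- wb[[b]]
      Pb[[b]][, r] <- p
      Tb[[b]][, r] <- Tmat[, b]
      varexp[b, r] <- tt * sum(p^2) / tot_ss[b]
      Xd[[b]] <- Xd[[b]] - tcrossprod(tT, p)
    }
    WT[, r] <- wT
    TT[, r] <- tT
    U[, r]  <- u
    cvec[r] <- cr
    yd <- yd - tT * cr
    Weff[, r] <- unlist(lapply(seq_len(B), function(b) wT[b] * wb[[b]]))
  }
  P <- do.call(rbind, Pb)
  beta <- Weff %*% solve(crossprod(P, Weff), cvec)
  list(block_weights = Wb, block_loadings = Pb, block_scores = Tb,
       super_weights = WT, super_scores = TT, y_scores = U,
       y_loadings = cvec, w_eff = Weff, beta = as.numeric(beta),
       block_variance_explained = varexp, residual_y = yd,
       ssy = cvec^2 * colSums(TT^2), tot_ss = tot_ss)
}

#' Fit a multiblock PLS model
#'
#' Fits an MB-PLS model of a (continuous or 0/1-encoded binary) response on
#' B feature blocks.  Per component, block weights regress the y-scores on
#' each block, block scores are combined through unit-norm super weights
#' into a super score, and all blocks and the response are deflated by that
#' super score.  With identical scaling across blocks the fitted model is
#' equivalent to a single PLS on the column-concatenated matrix.
#'
#' @param dataset a [align_blocks()] `multiblock_dataset`.
#' @param n_components number of latent variables R; must satisfy
#'   `R <= min(N - 1, total features)`.
#' @param scaling a [scaling_spec()].
#' @return An object of class `"mbpls"` with per-component block weights,
#'   block scores, super weights/scores, loadings, y loadings, regression
#'   coefficients `beta` on the concatenated scaled space, per-block
#'   explained variance, and the training scaling parameters.
#' @export
mbpls_fit <- function(dataset, n_components, scaling = scaling_spec()) {
  stopifnot(inherits(dataset, "multiblock_dataset"))
  N <- length(dataset$y)
  Mb <- vapply(dataset$blocks, function(b) ncol(b$X), 1L)
  if (n_components < 1 || n_components > min(N - 1, sum(Mb)))
    stop("n_components must be in [1, min(N-1, total features)] = [1, ",
         min(N - 1, sum(Mb)), "]")
  scalers <- lapply(dataset$blocks, function(b)
    learn_scaling(b$X, block_scaling_method(scaling, b$assay),
                  b$features$feature_id))
  Xs <- Map(function(b, sc) apply_scaling(b$X, sc), dataset$blocks, scalers)
  y_mean <- mean(dataset$y)
  eng <- mbpls_engine(Xs, dataset$y - y_mean, n_components)
  feats <- dataset_features(dataset)
  structure(c(eng, list(
    n_components = n_components,
    assays = vapply(dataset$blocks, `[[`, "", "assay"),
    n_block_features = Mb,
    block_of_feature = rep(vapply(dataset$blocks, `[[`, "", "assay"), Mb),
    features = feats,
    scaling = scaling,
    scalers = scalers,
    y_mean = y_mean,
    y_name = dataset$y_name,
    binary = is_binary(dataset$y),
    sample_ids = names(dataset$y))),
    class = "mbpls")
}

#' @export
print.mbpls <- function(x, ...) {
  cat("<mbpls> ", length(x$assays), " block(s), ", sum(x$n_block_features),
      " features, R = ", x$n_components, "\n", sep = "")
  ve <- round(100 * x$block_variance_explained, 1)
  dimnames(ve) <- list(x$assays, paste0("LV", seq_len(x$n_components)))
  cat("  % X-variance explained per block:\n")
  print(ve)
  invisible(x)
}

scale_new_blocks <- function(model, blocks) {
  if (inherits(blocks, "multiblock_dataset")) blocks <- blocks$blocks
  if (inherits(blocks, "lcms_block")) blocks <- list(blocks)
  if (length(blocks) != length(model$assays))
    stop("expected ", length(model$assays), " blocks, got ", length(blocks))
  Xs <- vector("list", length(blocks))
  for (b in seq_along(blocks)) {
    X <- if (inherits(blocks[[b]], "lcms_block")) blocks[[b]]$X else as.matrix(blocks[[b]])
    trained <- names(model$scalers[[b]]$center)
    if (!identical(colnames(X), trained)) {
      miss <- setdiff(trained, colnames(X))
      extra <- setdiff(colnames(X), trained)
      stop("feature mismatch in block ", model$assays[b],
           if (length(miss)) paste0("; missing: ", paste(utils::head(miss, 5), collapse = ", ")),
           if (length(extra)) paste0("; unexpected: ", paste(utils::head(extra, 5), collapse = ", ")),
           if (!length(miss) && !length(extra)) "; feature order differs")
    }
    Xs[[b]] <- apply_scaling(X, model$scalers[[b]])
  }
  do.call(cbind, Xs)
}

#' Predict from a fitted MB-PLS model
#'
#' Applies the training centering/scaling to new blocks and computes
#' `y_hat = X_scaled %*% beta + y_mean`.  For a binary model,
#' `type = "class"` thresholds the raw score at 0.5 (the midpoint of the
#' 0/1 class encoding).
#'
#' @param object a fitted `"mbpls"` model.
#' @param newdata a `multiblock_dataset`, a list of blocks/matrices in
#'   training order, or a single block for B = 1.
#' @param type `"response"` (raw scores) or `"class"` (0/1 labels,
#'   binary models only).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.mbpls <- function(object, newdata, type = c("response", "class"), ...) {
  type <- match.arg(type)
  Xc <- scale_new_blocks(object, newdata)
  yhat <- as.numeric(Xc %*% object$beta) + object$y_mean
  names(yhat) <- rownames(Xc)
  if (type == "class") {
    if (!object$binary) stop("type='class' requires a model fit on a 0/1 response")
    yhat <- as.numeric(yhat >= 0.5)
    names(yhat) <- rownames(Xc)
  }
  yhat
}

#' Per-block, per-component importance
#'
#' For block b and component r the explained X-variance of the rank-1
#' reconstruction (super score times block loading) is divided by the total
#' scaled sum of squares of the block, then by the number of features in
#' the block, and finally each component's column is renormalized to sum to
#' one across blocks.  This answers "how much of each latent variable comes
#' from each data block", on a per-feature basis.
#'
#' @param model fitted `"mbpls"` model.
#' @return B x R matrix; each column sums to 1.
#' @export
block_importance <- function(model) {
  stopifnot(inherits(model, "mbpls"))
  imp <- model$block_variance_explained / model$n_block_features
  imp <- sweep(imp, 2, colSums(imp), "/")
  dimnames(imp) <- list(model$assays, paste0("LV", seq_len(model$n_components)))
  imp
}

#' Serialize a fitted model to a plain-text archive
#'
#' Writes all model arrays, metadata and scaling parameters to a single
#' JSON-like YAML file with a schema version, so that models survive
#' sessions without binary formats.
#'
#' @param model fitted `"mbpls"` model.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
mbpls_save <- function(model, path) {
  mat2list <- function(m) lapply(seq_len(ncol(m)), function(j) unname(m[, j]))
  ser <- unclass(model)
  ser$scaling <- unclass(ser$scaling)
  ser$scalers <- lapply(ser$scalers, function(s)
    list(feature_id = names(s$center),
         center = unname(s$center), scale = unname(s$scale)))
  for (f in c("super_weights", "super_scores", "y_scores", "w_eff",
              "block_variance_explained"))
    ser[[f]] <- mat2list(ser[[f]])
  for (f in c("block_weights", "block_loadings", "block_scores"))
    ser[[f]] <- lapply(ser[[f]], mat2list)
  ser$features <- as.list(ser$features)
  ser$schema_version <- 1L
  yaml::write_yaml(ser, path, precision = 17)
  invisible(path)
}

#' Restore a model saved by [mbpls_save()]
#' @param path file written by [mbpls_save()].
#' @return an `"mbpls"` model.
#' @export
mbpls_load <- function(path) {
  ser <- yaml::read_yaml(path)
  if (is.null(ser$schema_version) || ser$schema_version != 1L)
    stop("unsupported model schema version")
  ser$schema_version <- NULL
  list2mat <- function(x) do.call(cbind, lapply(x, unlist))
  for (f in c("super_weights", "super_scores", "y_scores", "w_eff",
              "block_variance_explained"))
    ser[[f]] <- list2mat(ser[[f]])
  for (f in c("block_weights", "block_loadings", "block_scores"))
    ser[[f]] <- lapply(ser[[f]], list2mat)
  ser$scalers <- lapply(ser$scalers, function(s) {
    ctr <- unlist(s$center); scl <- unlist(s$scale)
    names(ctr) <- names(scl) <- unlist(s$feature_id)
    list(center = ctr, scale = scl)
  })
  ser$features <- as.data.frame(ser$features, stringsAsFactors = FALSE)
  ser$scaling <- structure(ser$scaling, class = "scaling_spec")
  for (f in c("beta", "y_loadings", "ssy", "tot_ss", "residual_y",
              "n_block_features"))
    ser[[f]] <- unlist(ser[[f]])
  structure(ser, class = "mbpls")
}
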