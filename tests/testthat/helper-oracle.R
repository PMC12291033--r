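# Independent single-matrix NIPALS PLS1 used as an oracle for the
# concatenated-blocks equivalence of MB-PLS.  Deliberately written as the
# textbook single-block recursion, sharing no code with the package engine.
oracle_pls1 <- function(X, y, R, center_scale = TRUE) {
  Xc <- if (center_scale) scale(X) else X
  yc <- y - mean(y)
  M <- ncol(X)
  W <- P <- matrix(0, M, R)
  TT <- matrix(0, nrow(X), R)
  cv <- numeric(R)
  Xd <- Xc
  yd <- yc
  for (r in seq_len(R)) {
    w <- crossprod(Xd, yd)
    w <- w / sqrt(sum(w^2))
    t <- as.numeric(Xd %*% w)
    tt <- sum(t^2)
    p <- crossprod(Xd, t) / tt
    cc <- sum(yd * t) / tt
    Xd <- Xd - tcrossprod(t, p)
    yd <- yd - t * cc
    W[, r] <- w; P[, r] <- p; TT[, r] <- t; cv[r] <- cc
  }
  beta <- as.numeric(W %*% solve(crossprod(P, W), cv))
  list(beta = beta,
       fitted = as.numeric(Xc %*% beta) + mean(y),
       scores = TT, weights = W, y_loadings = cv)
}

# classical single-matrix PLS VIP computed from the oracle fit
oracle_vip <- function(o) {
  ssy <- o$y_loadings^2 * colSums(o$scores^2)
  sqrt(nrow(o$weights) * as.numeric(o$weights^2 %*% ssy) / sum(ssy))
}

# random multiblock regression dataset with plain Gaussian features
random_dataset <- function(N = 60, Ms = c(40, 70), seed = 1,
                           y_fun = NULL, binary = FALSE) {
  set.seed(seed)
  ids <- sprintf("s%03d", seq_len(N))
  blocks <- lapply(seq_along(Ms), function(b) {
    M <- Ms[b]
    X <- matrix(rnorm(N * M), N, M, dimnames = list(ids, NULL))
    fm <- feature_meta(sprintf("blk%d_f%03d", b, seq_len(M)),
                       paste0("assay", b),
                       runif(M, 100, 900), runif(M, 0, 500), "positive")
    new_block(X, fm)
  })
  Xcat <- do.call(cbind, lapply(blocks, function(b) b$X))
  y <- if (is.null(y_fun)) {
    as.numeric(Xcat %*% rnorm(ncol(Xcat), sd = 1 / sqrt(ncol(Xcat)))) + rnorm(N)
  } else y_fun(Xcat)
  if (binary) y <- as.numeric(y > median(y))
  names(y) <- ids
  list(dataset = align_blocks(blocks, y), Xcat = Xcat[sort(ids), , drop = FALSE])
}

# small feature-metadata table builder for structural-search tests
fm_tab <- function(mz, rt, assay = "A", polarity = "positive",
                   ids = sprintf("%s_f%d", assay, seq_along(mz))) {
  feature_meta(ids, assay, mz, rt, polarity)
}

# labels of a structural network as a partition (singletons get unique labels)
network_partition <- function(net) {
  lab <- ifelse(is.na(net$nodes$group),
                paste0("singleton_", seq_len(nrow(net$nodes))),
                paste0("g", net$nodes$group))
  names(lab) <- net$nodes$feature_id
  lab
}

# run the full structural search (within all assays + cross-assay) on a
# feature table, as the pipeline does
search_features <- function(features, ppm_tol = 5, rt_tol = 2) {
  within <- do.call(rbind, lapply(split(features, features$assay),
                                  within_assay_links,
                                  ppm_tol = ppm_tol, rt_tol = rt_tol))
  cross <- if (length(unique(features$assay)) >= 2)
    cross_assay_links(features, ppm_tol = ppm_tol)
  else NULL
  build_structural_groups(rbind(within, cross), features)
}
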