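test_that("single-block MB-PLS reduces to standard PLS", {
  rd <- random_dataset(N = 40, Ms = 30, seed = 2)
  for (R in c(1, 3)) {
    m <- mbpls_fit(rd$dataset, R)
    o <- oracle_pls1(rd$Xcat, rd$dataset$y, R)
    expect_equal(m$beta, o$beta, tolerance = 1e-10)
    expect_equal(unname(predict(m, rd$dataset)), o$fitted, tolerance = 1e-10)
    # with one block, super scores equal block scores and w_T = 1
    expect_equal(m$super_scores, m$block_scores[[1]], tolerance = 1e-10)
    expect_equal(abs(m$super_weights), matrix(1, 1, R), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("two blocks with shared scaling match PLS on the concatenation", {
  rd <- random_dataset(N = 50, Ms = c(25, 40), seed = 3)
  m <- mbpls_fit(rd$dataset, 3)
  o <- oracle_pls1(rd$Xcat, rd$dataset$y, 3)
  expect_lt(max(abs(m$beta - o$beta)) / max(abs(o$beta)), 1e-8)
  expect_lt(max(abs(unname(predict(m, rd$dataset)) - o$fitted)) /
              max(abs(o$fitted - mean(o$fitted))), 1e-8)
})

test_that("a noiseless single-cause response puts the weight on its feature", {
  set.seed(4)
  N <- 50
  ids <- sprintf("s%02d", 1:N)
  X1 <- matrix(rnorm(N * 20), N, dimnames = list(ids, NULL))
  X2 <- matrix(rnorm(N * 15), N, dimnames = list(ids, NULL))
  y <- setNames(3 * X1[, 7], ids)
  ds <- align_blocks(list(new_block(X1, fm_tab(100 + 1:20, 1:20 * 5, "A")),
                          new_block(X2, fm_tab(300 + 1:15, 1:15 * 5, "B"))),
                     y)
  m <- mbpls_fit(ds, 1)
  expect_equal(which.max(abs(m$block_weights[[1]][, 1])), 7L)
  # the training residual vanishes as components accumulate (interpolation)
  rel_res <- vapply(c(1, 10), function(R)
    max(abs(mbpls_fit(ds, R)$residual_y)) / sd(y), 1.0)
  expect_lt(rel_res[2], 0.05)
  expect_lt(rel_res[2], rel_res[1] / 10)
  m10 <- mbpls_fit(ds, 10)
  expect_equal(unname(predict(m10, ds)), unname(y), tolerance = 0.05)
})

test_that("weights are unit norm and super scores orthogonal", {
  rd <- random_dataset(N = 45, Ms = c(20, 30, 10), seed = 6)
  m <- mbpls_fit(rd$dataset, 4)
  for (r in 1:4) {
    for (b in 1:3)
      expect_equal(sum(m$block_weights[[b]][, r]^2), 1, tolerance = 1e-12)
    expect_equal(sum(m$super_weights[, r]^2), 1, tolerance = 1e-12)
  }
  G <- crossprod(m$super_scores)
  off <- G; diag(off) <- 0
  expect_lt(max(abs(off)) / max(diag(G)), 1e-8)
  # explained-variance bookkeeping: nonnegative, cumulative <= 1
  expect_true(all(m$block_variance_explained >= 0))
  expect_true(all(rowSums(m$block_variance_explained) <= 1 + 1e-8))
})

test_that("fitting is deterministic and validates its inputs", {
  rd <- random_dataset(N = 30, Ms = c(10, 12), seed = 8)
  m1 <- mbpls_fit(rd$dataset, 2)
  m2 <- mbpls_fit(rd$dataset, 2)
  expect_identical(m1$beta, m2$beta)
  expect_identical(m1$super_scores, m2$super_scores)

  expect_error(mbpls_fit(rd$dataset, 0), "n_components")
  expect_error(mbpls_fit(rd$dataset, 30), "n_components")

  flat <- rd$dataset
  flat$blocks[[1]]$X[, 3] <- 1
  expect_error(mbpls_fit(flat, 2), "zero-variance.*blk1_f003")
})

test_that("prediction handles single samples and rejects feature mismatch", {
  rd <- random_dataset(N = 30, Ms = c(10, 12), seed = 9)
  m <- mbpls_fit(rd$dataset, 2)
  one <- lapply(rd$dataset$blocks, function(b) b$X[1, , drop = FALSE])
  p1 <- predict(m, one)
  expect_length(p1, 1L)
  expect_equal(unname(p1), unname(predict(m, rd$dataset)[1]))

  swapped <- lapply(rd$dataset$blocks, function(b) b$X[, rev(seq_len(ncol(b$X)))])
  expect_error(predict(m, swapped), "feature mismatch|order differs")
})

test_that("a model trained on permuted y has no out-of-sample skill", {
  set.seed(10)
  rd <- random_dataset(N = 200, Ms = c(30, 30), seed = 10)
  ds <- rd$dataset
  y_perm <- setNames(sample(ds$y), names(ds$y))
  ds_perm <- align_blocks(ds$blocks, y_perm)
  tr <- sprintf("s%03d", 1:150)
  te <- sprintf("s%03d", 151:200)
  sub <- function(d, ids) align_blocks(lapply(d$blocks, function(b) {
    b$X <- b$X[ids, , drop = FALSE]; b$sample_ids <- ids; b
  }), d$y[ids])
  m <- mbpls_fit(sub(ds_perm, tr), 2)
  yhat <- predict(m, sub(ds_perm, te))
  q2 <- metric_q2(y_perm[te], yhat, mean(y_perm[tr]))
  expect_lt(q2, 0.15)   # within null fluctuation of zero
})

test_that("block importance normalizes per feature count and sums to one", {
  rd <- random_dataset(N = 40, Ms = 25, seed = 12)
  m <- mbpls_fit(rd$dataset, 3)
  expect_equal(unname(block_importance(m)), matrix(1, 1, 3))

  # duplicating a block splits every component importance 50/50
  set.seed(13)
  N <- 40; M <- 20
  ids <- sprintf("s%02d", 1:N)
  X <- matrix(rnorm(N * M), N, dimnames = list(ids, NULL))
  y <- setNames(as.numeric(X %*% rnorm(M, sd = 0.3)) + rnorm(N), ids)
  ds2 <- align_blocks(list(new_block(X, fm_tab(100 + 1:M, 1:M, "A")),
                           new_block(X, fm_tab(300 + 1:M, 1:M, "B"))), y)
  imp <- block_importance(mbpls_fit(ds2, 2))
  expect_equal(unname(imp), matrix(0.5, 2, 2), tolerance = 1e-8)

  # a pure-noise block matters less than the informative one on LV1
  set.seed(14)
  Z <- matrix(rnorm(N * M), N, dimnames = list(ids, NULL))
  ysig <- setNames(rowSums(X[, 1:5]) + 0.1 * rnorm(N), ids)
  ds3 <- align_blocks(list(new_block(X, fm_tab(100 + 1:M, 1:M, "A")),
                           new_block(Z, fm_tab(300 + 1:M, 1:M, "B"))), ysig)
  imp3 <- block_importance(mbpls_fit(ds3, 2))
  expect_gt(imp3["A", 1], imp3["B", 1])
})

test_that("models survive plain-text serialization", {
  rd <- random_dataset(N = 25, Ms = c(8, 6), seed = 15)
  m <- mbpls_fit(rd$dataset, 2)
  path <- withr::local_tempfile(fileext = ".yaml")
  mbpls_save(m, path)
  m2 <- mbpls_load(path)
  expect_equal(m2$beta, m$beta, tolerance = 1e-12)
  expect_equal(unname(predict(m2, rd$dataset)), unname(predict(m, rd$dataset)),
               tolerance = 1e-12)
})
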