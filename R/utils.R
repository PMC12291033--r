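# Run code under a fixed seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Pairwise precision and recall between two partitions
#'
#' Compares two partitions of the same items by their co-membership pairs:
#' precision is the fraction of pairs grouped together in `pred` that are
#' also grouped together in `truth`; recall the converse.  Items carrying
#' unique labels (singletons) contribute no pairs.
#'
#' @param truth,pred named label vectors over the same items (names are
#'   item ids; label values are arbitrary).
#' @return list with `precision`, `recall`, `n_true_pairs`, `n_pred_pairs`.
#' @export
partition_scores <- function(truth, pred) {
  stopifnot(!is.null(names(truth)), !is.null(names(pred)))
  ids <- intersect(names(truth), names(pred))
  truth <- truth[ids]; pred <- pred[ids]
  pair_set <- function(labels) {
    out <- character(0)
    for (lv in unique(labels)) {
      members <- sort(ids[labels == lv])
      if (length(members) > 1) {
        cmb <- utils::combn(members, 2)
        out <- c(out, paste(cmb[1, ], cmb[2, ], sep = "\r"))
      }
    }
    out
  }
  tp_pairs <- pair_set(truth)
  pp_pairs <- pair_set(pred)
  hit <- length(intersect(tp_pairs, pp_pairs))
  list(precision = if (length(pp_pairs)) hit / length(pp_pairs) else NA_real_,
       recall = if (length(tp_pairs)) hit / length(tp_pairs) else NA_real_,
       n_true_pairs = length(tp_pairs),
       n_pred_pairs = length(pp_pairs))
}
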