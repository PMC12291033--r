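#' Construct per-feature metadata
#'
#' @param feature_id character vector, unique within a dataset.
#' @param assay single assay label (recycled) or vector.
#' @param mz mass-to-charge ratios in Th (Da per unit charge), all > 0.
#' @param rt retention times in seconds, all >= 0.
#' @param polarity ionization polarity, `"positive"` or `"negative"`;
#'   must be constant within one assay.
#' @return A validated data.frame with columns `feature_id`, `assay`,
#'   `mz`, `rt`, `polarity`.
#' @export
feature_meta <- function(feature_id, assay, mz, rt, polarity) {
  fm <- data.frame(feature_id = as.character(feature_id),
                   assay = as.character(assay),
                   mz = as.numeric(mz),
                   rt = as.numeric(rt),
                   polarity = as.character(polarity),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(fm$feature_id))
    stop("duplicated feature_id: ",
         paste(unique(fm$feature_id[duplicated(fm$feature_id)]), collapse = ", "))
  if (any(!is.finite(fm$mz)) || any(fm$mz <= 0))
    stop("mz must be finite and > 0 for all features; offending: ",
         paste(utils::head(fm$feature_id[!is.finite(fm$mz) | fm$mz <= 0], 5),
               collapse = ", "))
  if (any(!is.finite(fm$rt)) || any(fm$rt < 0))
    stop("rt must be finite and >= 0 (seconds); offending: ",
         paste(utils::head(fm$feature_id[!is.finite(fm$rt) | fm$rt < 0], 5),
               collapse = ", "))
  if (!all(fm$polarity %in% c("positive", "negative")))
    stop("polarity must be 'positive' or 'negative'")
  pol_per_assay <- tapply(fm$polarity, fm$assay, function(p) length(unique(p)))
  if (any(pol_per_assay > 1))
    stop("polarity must be consistent within an assay: ",
         paste(names(pol_per_assay)[pol_per_assay > 1], collapse = ", "))
  fm
}

#' Construct a single-assay feature block
#'
#' A block is one LC-MS assay's feature-intensity table (samples in rows,
#' features in columns) together with its per-feature metadata.
#'
#' @param X numeric matrix, N samples x M features, no missing values.
#' @param features metadata as returned by [feature_meta()]; one row per
#'   column of `X`, same order.
#' @param assay assay label; defaults to the (single) assay in `features`.
#' @param sample_ids sample identifiers; default `rownames(X)`.
#' @return An object of class `"lcms_block"`.
#' @export
new_block <- function(X, features, assay = NULL, sample_ids = rownames(X)) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(sample_ids)) stop("sample_ids are required (rownames of X)")
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  if (nrow(X) != length(sample_ids)) stop("nrow(X) != length(sample_ids)")
  if (ncol(X) != nrow(features))
    stop("column count of X (", ncol(X), ") != feature metadata rows (",
         nrow(features), ")")
  if (anyNA(X)) {
    idx <- which(is.na(X), arr.ind = TRUE)[1, ]
    stop("missing intensity at sample '", sample_ids[idx[1]], "', feature '",
         features$feature_id[idx[2]], "'")
  }
  if (is.null(assay)) {
    assay <- unique(features$assay)
    if (length(assay) != 1) stop("features span several assays; give `assay`")
  }
  rownames(X) <- sample_ids
  colnames(X) <- features$feature_id
  structure(list(assay = assay,
                 polarity = features$polarity[1],
                 X = X,
                 features = features,
                 sample_ids = sample_ids),
            class = "lcms_block")
}

#' @export
print.lcms_block <- function(x, ...) {
  cat("<lcms_block> assay:", x$assay, "(", x$polarity, ")\n")
  cat("  ", nrow(x$X), "samples x", ncol(x$X), "features\n")
  invisible(x)
}

#' @export
dim.lcms_block <- function(x) dim(x$X)

guess_sep <- function(path) {
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

# "<assay>_<mz>_<rt>" or "<mz>_<rt>", both numeric tokens decimal.
NAME_GRAMMAR <- "^(?:([A-Za-z][A-Za-z0-9 .+-]*?)_)?([0-9]+(?:\\.[0-9]+)?)_([0-9]+(?:\\.[0-9]+)?)$"

#' Parse feature metadata from feature names
#'
#' Feature names carry metadata as `"<mz>_<rt>"` with an optional leading
#' assay token, e.g. `"585.2702_141.52"` or `"HILIC+_585.2702_141.52"`.
#' Both numbers are decimal; m/z in Th, RT in seconds.
#'
#' @param names character vector of feature names.
#' @param assay,polarity assay label and polarity to assign.
#' @return feature metadata data.frame (see [feature_meta()]).
#' @export
parse_feature_names <- function(names, assay, polarity) {
  m <- regmatches(names, regexec(NAME_GRAMMAR, names))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad))
    stop("cannot parse mz/rt from feature name(s): ",
         paste(utils::head(names[bad], 5), collapse = ", "),
         "; supply a metadata table instead")
  feature_meta(feature_id = names,
               assay = assay,
               mz = vapply(m, function(g) as.numeric(g[3]), 1.0),
               rt = vapply(m, function(g) as.numeric(g[4]), 1.0),
               polarity = polarity)
}

#' Read a feature-intensity table from delimited text
#'
#' Expects samples in rows (first column = sample id, header row = feature
#' names) unless `transpose = TRUE` is given explicitly; orientation is never
#' guessed.  Feature metadata comes either from a sibling metadata table
#' (`metadata_source = "columns"`, columns `feature_id`, `mz`, `rt`) or is
#' parsed from the feature names (`metadata_source = "parse_names"`).
#'
#' @param path path to a CSV (`,`) or TSV (`\t`, extensions .tsv/.txt) file.
#' @param metadata_source `"columns"` or `"parse_names"`.
#' @param assay assay label for the block.
#' @param polarity `"positive"` or `"negative"`.
#' @param metadata_path path to the metadata table when
#'   `metadata_source = "columns"`.
#' @param transpose set `TRUE` if the file stores features in rows.
#' @param na_policy `"fail"` (default) errors on any missing intensity;
#'   `"drop_feature"` drops features containing missing values.
#' @return An [new_block()] object; column order follows the file.
#' @export
read_feature_table <- function(path,
                               metadata_source = c("columns", "parse_names"),
                               assay,
                               polarity = "positive",
                               metadata_path = NULL,
                               transpose = FALSE,
                               na_policy = c("fail", "drop_feature")) {
  metadata_source <- match.arg(metadata_source)
  na_policy <- match.arg(na_policy)
  raw <- utils::read.table(path, sep = guess_sep(path), header = TRUE,
                           row.names = 1, check.names = FALSE,
                           colClasses = "character",
                           stringsAsFactors = FALSE, comment.char = "")
  if (nrow(raw) == 0 || ncol(raw) == 0) stop("empty feature table: ", path)
  if (transpose) raw <- as.data.frame(t(as.matrix(raw)), stringsAsFactors = FALSE)
  X <- matrix(NA_real_, nrow(raw), ncol(raw),
              dimnames = list(rownames(raw), colnames(raw)))
  for (j in seq_len(ncol(raw))) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- is.na(v) & !(raw[[j]] %in% c("", "NA", "nan", "NaN"))
    if (any(bad))
      stop("non-numeric intensity '", raw[bad, j][1], "' at row '",
           rownames(raw)[which(bad)[1]], "', column '", colnames(raw)[j], "'")
    X[, j] <- v
  }
  if (anyNA(X)) {
    if (na_policy == "fail") {
      idx <- which(is.na(X), arr.ind = TRUE)[1, ]
      stop("missing intensity at row '", rownames(X)[idx[1]], "', column '",
           colnames(X)[idx[2]], "' (na_policy = 'fail')")
    }
    keep <- colSums(is.na(X)) == 0
    if (!any(keep)) stop("all features contain missing values")
    X <- X[, keep, drop = FALSE]
  }
  fm <- if (metadata_source == "parse_names") {
    parse_feature_names(colnames(X), assay = assay, polarity = polarity)
  } else {
    if (is.null(metadata_path)) stop("metadata_path required for metadata_source='columns'")
    md <- utils::read.table(metadata_path, sep = guess_sep(metadata_path),
                            header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
    need <- c("feature_id", "mz", "rt")
    if (!all(need %in% names(md)))
      stop("metadata table must have columns: ", paste(need, collapse = ", "))
    miss <- setdiff(colnames(X), md$feature_id)
    if (length(miss))
      stop("missing mz/rt metadata for feature(s): ",
           paste(utils::head(miss, 5), collapse = ", "))
    md <- md[match(colnames(X), md$feature_id), ]
    if (any(!is.finite(md$mz)) || any(!is.finite(md$rt)))
      stop("missing mz/rt value for feature(s): ",
           paste(md$feature_id[!is.finite(md$mz) | !is.finite(md$rt)], collapse = ", "))
    feature_meta(md$feature_id, assay, md$mz, md$rt, polarity)
  }
  new_block(X, fm, assay = assay)
}

#' Write a feature-intensity table
#'
#' Writes the block's intensity matrix as delimited text (samples in rows,
#' first column `sample_id`) at full double precision, so that
#' `read_feature_table(write_feature_table(b))` round-trips exactly.
#'
#' @param block an `lcms_block`.
#' @param path output path; `.tsv`/`.txt` write tab-separated, else CSV.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(block, path) {
  sep <- guess_sep(path)
  X <- block$X
  out <- cbind(sample_id = rownames(X),
               as.data.frame(apply(X, 2, function(v) sprintf("%.17g", v)),
                             check.names = FALSE))
  utils::write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Align blocks and response into a multiblock dataset
#'
#' Restricts all blocks and the response to the (sorted) intersection of
#' their sample ids, in identical order everywhere.
#'
#' @param blocks list of `lcms_block` objects.
#' @param y named numeric response vector (names = sample ids).  Binary
#'   outcomes must be encoded 0/1 (see [encode_response()]).
#' @param y_name label for the response.
#' @return An object of class `"multiblock_dataset"` with elements
#'   `blocks`, `y`, `y_name`, `n_dropped` (samples discarded per input).
#' @export
align_blocks <- function(blocks, y, y_name = "y") {
  if (inherits(blocks, "lcms_block")) blocks <- list(blocks)
  stopifnot(length(blocks) >= 1, all(vapply(blocks, inherits, TRUE, "lcms_block")))
  if (is.null(names(y))) stop("y must be a named vector (names = sample ids)")
  ids <- Reduce(intersect, c(lapply(blocks, `[[`, "sample_ids"), list(names(y))))
  if (length(ids) == 0) stop("no samples shared between blocks and response")
  ids <- sort(ids)
  n_dropped <- c(vapply(blocks, function(b) length(b$sample_ids) - length(ids), 1L),
                 y = length(y) - length(ids))
  blocks <- lapply(blocks, function(b) {
    b$X <- b$X[ids, , drop = FALSE]
    b$sample_ids <- ids
    b
  })
  names(blocks) <- vapply(blocks, `[[`, "", "assay")
  y <- as.numeric(y[ids])
  names(y) <- ids
  if (!any(is.finite(y)) || length(unique(y)) < 2)
    stop("response is constant or non-finite on the aligned samples")
  if (all(y %in% c(0, 1)) && !all(c(0, 1) %in% y))
    stop("binary response must contain both classes after alignment")
  structure(list(blocks = blocks, y = y, y_name = y_name,
                 n_dropped = n_dropped),
            class = "multiblock_dataset")
}

#' @export
print.multiblock_dataset <- function(x, ...) {
  cat("<multiblock_dataset>", length(x$blocks), "block(s),",
      length(x$y), "samples, response:", x$y_name,
      if (is_binary(x$y)) "(binary)" else "(continuous)", "\n")
  for (b in x$blocks) cat("  -", b$assay, ":", ncol(b$X), "features\n")
  invisible(x)
}

is_binary <- function(y) all(y %in% c(0, 1))

#' Encode a categorical response as 0/1
#'
#' @param y factor or character vector with exactly two levels.
#' @param positive the level encoded as 1; default the lexicographically
#'   larger level.
#' @return named numeric vector in \{0, 1\} with a `"levels"` attribute.
#' @export
encode_response <- function(y, positive = NULL) {
  lv <- sort(unique(as.character(y)))
  if (length(lv) != 2) stop("response must have exactly two levels, got ", length(lv))
  if (is.null(positive)) positive <- lv[2]
  out <- as.numeric(as.character(y) == positive)
  names(out) <- names(y)
  attr(out, "levels") <- c(negative = setdiff(lv, positive), positive = positive)
  out
}

#' Read a region-of-interest (ROI) annotation table
#'
#' ROI files give, per compound and chromatographic assay, a reference m/z
#' and RT used for putative (level-3) annotation.  Column names are mapped
#' via `col_map` because ROI schemas vary between tools.  Window bounds
#' default to `ref_mz * (1 +/- ppm_tol*1e-6)` and `ref_rt +/- rt_tol` when
#' absent.
#'
#' @param path CSV/TSV file with a header row.
#' @param col_map named list mapping roles `compound`, `mz`, `rt` (and
#'   optionally `assay`, `mz_lo`, `mz_hi`, `rt_lo`, `rt_hi`) to column names.
#' @param assay default assay label when the file has no assay column.
#' @param ppm_tol,rt_tol default window half-widths (ppm; seconds).
#' @return data.frame of class `"roi_table"` with columns `compound_name`,
#'   `ref_mz`, `ref_rt`, `assay`, `mz_lo`, `mz_hi`, `rt_lo`, `rt_hi`.
#' @export
read_roi <- function(path,
                     col_map = list(compound = "compound", mz = "mz", rt = "rt"),
                     assay = NA_character_,
                     ppm_tol = 5, rt_tol = 2) {
  df <- utils::read.table(path, sep = guess_sep(path), header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0)
    return(structure(data.frame(compound_name = character(), ref_mz = numeric(),
                                ref_rt = numeric(), assay = character(),
                                mz_lo = numeric(), mz_hi = numeric(),
                                rt_lo = numeric(), rt_hi = numeric()),
                     class = c("roi_table", "data.frame")))
  need <- c("compound", "mz", "rt")
  if (!all(need %in% names(col_map)))
    stop("col_map must map roles: ", paste(need, collapse = ", "))
  pick <- function(role) {
    cn <- col_map[[role]]
    if (is.null(cn) || !cn %in% names(df)) return(NULL)
    df[[cn]]
  }
  num <- function(v, role) {
    out <- suppressWarnings(as.numeric(v))
    if (any(is.na(out) & !is.na(v)))
      stop("malformed numeric value in ROI column for role '", role, "': ",
           v[which(is.na(out) & !is.na(v))[1]])
    out
  }
  ref_mz <- num(pick("mz"), "mz")
  ref_rt <- num(pick("rt"), "rt")
  if (any(!is.finite(ref_mz)) || any(ref_mz <= 0)) stop("ROI ref_mz must be > 0")
  if (any(!is.finite(ref_rt)) || any(ref_rt < 0)) stop("ROI ref_rt must be >= 0")
  as_col <- pick("assay")
  roi <- data.frame(
    compound_name = as.character(pick("compound")),
    ref_mz = ref_mz, ref_rt = ref_rt,
    assay = if (is.null(as_col)) rep(assay, nrow(df)) else as.character(as_col),
    mz_lo = if (is.null(pick("mz_lo"))) ref_mz * (1 - ppm_tol * 1e-6) else num(pick("mz_lo"), "mz_lo"),
    mz_hi = if (is.null(pick("mz_hi"))) ref_mz * (1 + ppm_tol * 1e-6) else num(pick("mz_hi"), "mz_hi"),
    rt_lo = if (is.null(pick("rt_lo"))) pmax(ref_rt - rt_tol, 0) else num(pick("rt_lo"), "rt_lo"),
    rt_hi = if (is.null(pick("rt_hi"))) ref_rt + rt_tol else num(pick("rt_hi"), "rt_hi"),
    stringsAsFactors = FALSE
  )
  bad <- roi$mz_lo > roi$ref_mz | roi$ref_mz > roi$mz_hi |
    roi$rt_lo > roi$ref_rt | roi$ref_rt > roi$rt_hi
  if (any(bad))
    stop("ROI reference outside its own window for compound(s): ",
         paste(roi$compound_name[bad], collapse = ", "))
  structure(roi, class = c("roi_table", "data.frame"))
}

#' Concatenated feature metadata of a dataset
#'
#' @param dataset a `multiblock_dataset`.
#' @return data.frame of all blocks' feature metadata, in block order.
#' @export
dataset_features <- function(dataset) {
  do.call(rbind, lapply(dataset$blocks, `[[`, "features"))
}
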