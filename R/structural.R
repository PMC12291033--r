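ppm_of <- function(err_da, ref_mass) err_da / ref_mass * 1e6

#' Within-assay isotopologue and adduct links
#'
#' Scans all co-eluting feature pairs of one assay (|delta RT| <= `rt_tol`
#' seconds).  A pair is linked as isotopologues when its m/z difference is
#' `k * 1.003355` Da (k = 1..`max_isotopes`) within `ppm_tol` (relative to
#' the lighter ion), and as adducts when the de-adducted neutral masses
#' under some pair of distinct same-polarity rules agree within `ppm_tol`.
#' When several rule pairs match, the lowest-ppm-error pair is primary and
#' alternatives are retained in the `alternatives` column.
#'
#' @param features feature metadata ([feature_meta()]), one assay only.
#' @param rules rule table, see [default_adduct_rules()].
#' @param ppm_tol mass tolerance in parts per million (default 5).
#' @param rt_tol co-elution tolerance in seconds (default 2).
#' @param max_isotopes highest isotopologue index considered (default 3).
#' @return data.frame of edges: `from`, `to`, `edge_type`, `rule`,
#'   `ppm_error`, `rt_diff`, `alternatives`.
#' @export
within_assay_links <- function(features, rules = default_adduct_rules(),
                               ppm_tol = 5, rt_tol = 2, max_isotopes = 3) {
  if (nrow(features) == 0) return(empty_edges())
  if (length(unique(features$assay)) > 1)
    stop("within_assay_links expects features from a single assay")
  validate_rules(rules)
  pol <- features$polarity[1]
  rl <- rules[rules$polarity == pol, , drop = FALSE]
  f <- features[order(features$mz), , drop = FALSE]
  n <- nrow(f)
  out <- list()
  if (n < 2) return(empty_edges())
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      rt_diff <- abs(f$rt[j] - f$rt[i])
      if (rt_diff > rt_tol) next
      dmz <- f$mz[j] - f$mz[i]
      tol_da <- ppm_tol * 1e-6 * f$mz[i]
      # isotopologue: smallest k within tolerance wins
      k_err <- abs(dmz - seq_len(max_isotopes) * C13_SPACING)
      k_hit <- which(k_err <= tol_da)
      if (length(k_hit)) {
        k <- k_hit[which.min(k_err[k_hit])]
        out[[length(out) + 1]] <- data.frame(
          from = f$feature_id[i], to = f$feature_id[j],
          edge_type = "isotopologue",
          rule = sprintf("13C isotopologue k=%d", k),
          ppm_error = ppm_of(k_err[k], f$mz[i]),
          rt_diff = rt_diff, alternatives = "",
          stringsAsFactors = FALSE)
      }
      # adduct: compare de-adducted neutral masses under distinct rules
      hits <- adduct_pair_hits(f$mz[i], f$mz[j], rl, rl, ppm_tol)
      if (nrow(hits)) {
        out[[length(out) + 1]] <- data.frame(
          from = f$feature_id[i], to = f$feature_id[j],
          edge_type = "adduct",
          rule = hits$rule[1],
          ppm_error = hits$ppm_error[1],
          rt_diff = rt_diff,
          alternatives = paste(hits$rule[-1], collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty_edges())
  do.call(rbind, out)
}

# all (rule_i, rule_j) combinations whose implied neutral masses agree,
# sorted by ppm error; rules with identical delta are skipped (same ion)
adduct_pair_hits <- function(mz_i, mz_j, rules_i, rules_j, ppm_tol) {
  hits <- list()
  for (a in seq_len(nrow(rules_i))) {
    Mi <- mz_i - rules_i$delta_mz[a]
    if (Mi <= 0) next
    for (b in seq_len(nrow(rules_j))) {
      if (rules_i$delta_mz[a] == rules_j$delta_mz[b] &&
          rules_i$name[a] == rules_j$name[b]) next
      Mj <- mz_j - rules_j$delta_mz[b]
      if (Mj <= 0) next
      ref <- min(Mi, Mj)
      err <- abs(Mi - Mj)
      if (err <= ppm_tol * 1e-6 * ref) {
        hits[[length(hits) + 1]] <- data.frame(
          rule = paste(rules_i$name[a], rules_j$name[b], sep = "/"),
          ppm_error = ppm_of(err, ref), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits))
    return(data.frame(rule = character(), ppm_error = numeric()))
  hits <- do.call(rbind, hits)
  hits[order(hits$ppm_error), , drop = FALSE]
}

empty_edges <- function() {
  data.frame(from = character(), to = character(), edge_type = character(),
             rule = character(), ppm_error = numeric(), rt_diff = numeric(),
             alternatives = character(), stringsAsFactors = FALSE)
}

#' Cross-assay links via neutral-mass agreement
#'
#' For every feature, candidate neutral masses are computed under all rules
#' compatible with its polarity; features from *different* assays whose
#' candidate neutral masses agree within `ppm_tol` are linked.  Retention
#' time is deliberately not compared: different chromatographies produce
#' incomparable RTs.  Set `require_rt = TRUE` to additionally gate on RT
#' (within `rt_tol`) for assays sharing a chromatography.
#'
#' @param features feature metadata spanning at least two assays.
#' @param rules rule table, see [default_adduct_rules()].
#' @param ppm_tol mass tolerance in ppm (default 5).
#' @param require_rt also require co-elution (default FALSE).
#' @param rt_tol RT tolerance used only when `require_rt = TRUE`.
#' @return edge data.frame as in [within_assay_links()], with
#'   `edge_type = "cross_assay"`.
#' @export
cross_assay_links <- function(features, rules = default_adduct_rules(),
                              ppm_tol = 5, require_rt = FALSE, rt_tol = 2) {
  if (nrow(features) == 0) return(empty_edges())
  if (length(unique(features$assay)) < 2)
    stop("cross_assay_links expects features from at least two assays")
  validate_rules(rules)
  out <- list()
  n <- nrow(features)
  for (i in seq_len(n - 1)) {
    ri <- rules[rules$polarity == features$polarity[i], , drop = FALSE]
    for (j in (i + 1):n) {
      if (features$assay[j] == features$assay[i]) next
      if (require_rt && abs(features$rt[j] - features$rt[i]) > rt_tol) next
      rj <- rules[rules$polarity == features$polarity[j], , drop = FALSE]
      hits <- adduct_pair_hits(features$mz[i], features$mz[j], ri, rj, ppm_tol)
      # across assays the same rule on both sides is a legitimate match
      hits2 <- same_rule_hits(features$mz[i], features$mz[j], ri, rj, ppm_tol)
      hits <- rbind(hits, hits2)
      if (nrow(hits)) {
        hits <- hits[order(hits$ppm_error), , drop = FALSE]
        out[[length(out) + 1]] <- data.frame(
          from = features$feature_id[i], to = features$feature_id[j],
          edge_type = "cross_assay",
          rule = hits$rule[1],
          ppm_error = hits$ppm_error[1],
          rt_diff = abs(features$rt[j] - features$rt[i]),
          alternatives = paste(unique(hits$rule[-1]), collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty_edges())
  do.call(rbind, out)
}

same_rule_hits <- function(mz_i, mz_j, rules_i, rules_j, ppm_tol) {
  shared <- intersect(rules_i$name, rules_j$name)
  hits <- list()
  for (nm in shared) {
    d <- rules_i$delta_mz[rules_i$name == nm]
    Mi <- mz_i - d; Mj <- mz_j - d
    if (Mi <= 0 || Mj <= 0) next
    ref <- min(Mi, Mj)
    err <- abs(Mi - Mj)
    if (err <= ppm_tol * 1e-6 * ref)
      hits[[length(hits) + 1]] <- data.frame(
        rule = paste(nm, nm, sep = "/"),
        ppm_error = ppm_of(err, ref), stringsAsFactors = FALSE)
  }
  if (!length(hits))
    return(data.frame(rule = character(), ppm_error = numeric()))
  do.call(rbind, hits)
}

#' Assemble a typed structural network from link edges
#'
#' Connected components over the union of within-assay and cross-assay
#' edges define structural groups (sets of features presumed to originate
#' from one compound).  Singletons are recorded separately and are not
#' counted as groups.  When correlation-cluster labels are supplied, each
#' group's summary records which clusters its members occupy and whether
#' the group falls entirely within one cluster.
#'
#' @param edges edge data.frame(s) from [within_assay_links()] /
#'   [cross_assay_links()]; pass `rbind(...)` of several.
#' @param features metadata of all candidate (selected) features.
#' @param cluster_labels optional named integer vector (see
#'   [cluster_features()]).
#' @return list of class `"structural_network"`: `graph` (igraph), `nodes`,
#'   `edges`, `groups` (per-group summary), `singletons`,
#'   `cluster_agreement` (fraction of groups within a single cluster, NA
#'   without labels), `annotations` (empty until [annotate_network()]).
#' @export
build_structural_groups <- function(edges, features, cluster_labels = NULL) {
  stopifnot(is.data.frame(features))
  if (is.null(edges) || nrow(edges) == 0) edges <- empty_edges()
  unknown <- setdiff(c(edges$from, edges$to), features$feature_id)
  if (length(unknown))
    stop("edges refer to features not in the node table: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to", "edge_type", "rule", "ppm_error")],
    directed = FALSE,
    vertices = data.frame(name = features$feature_id, features,
                          stringsAsFactors = FALSE))
  comp <- igraph::components(g)
  member <- comp$membership[features$feature_id]
  sizes <- comp$csize[member]
  group_id <- ifelse(sizes > 1, member, NA_integer_)
  # renumber groups 1..G in feature order for stable output
  ug <- unique(group_id[!is.na(group_id)])
  group_id <- match(group_id, ug)
  nodes <- data.frame(features,
                      group = group_id,
                      cluster = if (is.null(cluster_labels)) NA_integer_
                      else unname(cluster_labels[features$feature_id]),
                      stringsAsFactors = FALSE)
  groups <- NULL
  if (length(ug)) {
    groups <- do.call(rbind, lapply(seq_along(ug), function(gi) {
      m <- nodes[!is.na(nodes$group) & nodes$group == gi, ]
      e <- edges[edges$from %in% m$feature_id & edges$to %in% m$feature_id, ]
      data.frame(group = gi,
                 n_features = nrow(m),
                 assays = paste(sort(unique(m$assay)), collapse = ";"),
                 n_assays = length(unique(m$assay)),
                 edge_types = paste(sort(unique(e$edge_type)), collapse = ";"),
                 clusters = paste(sort(unique(m$cluster)), collapse = ";"),
                 within_one_cluster = length(unique(m$cluster)) == 1,
                 stringsAsFactors = FALSE)
    }))
  }
  agreement <- if (is.null(cluster_labels) || is.null(groups)) NA_real_
  else mean(groups$within_one_cluster)
  structure(list(graph = g,
                 nodes = nodes,
                 edges = edges,
                 groups = groups,
                 singletons = nodes$feature_id[is.na(nodes$group)],
                 cluster_agreement = agreement,
                 annotations = NULL),
            class = "structural_network")
}

#' @export
print.structural_network <- function(x, ...) {
  ng <- if (is.null(x$groups)) 0 else nrow(x$groups)
  cat("<structural_network>", nrow(x$nodes), "features,", nrow(x$edges),
      "edges,", ng, "structural group(s),", length(x$singletons),
      "singleton(s)\n")
  if (!is.na(x$cluster_agreement))
    cat(sprintf("  groups within a single correlation cluster: %.0f%%\n",
                100 * x$cluster_agreement))
  if (!is.null(x$annotations) && nrow(x$annotations))
    cat("  annotated features:", nrow(x$annotations), "\n")
  invisible(x)
}

#' Annotate network features against an ROI reference list
#'
#' A feature gets a direct (level-3) annotation when an ROI entry of its
#' own assay matches within `ppm_tol` of the reference m/z and `rt_tol`
#' seconds of the reference RT (ROI entries without an assay label match
#' any assay on m/z + RT).  Direct annotations are then propagated to all
#' members of the feature's structural group as indirect annotations.
#' Distinct compounds directly annotated within one group are all retained
#' and flagged as conflicting.
#'
#' @param network a `"structural_network"`.
#' @param roi an ROI table from [read_roi()] (or a data.frame with
#'   `compound_name`, `ref_mz`, `ref_rt`, `assay`).
#' @param ppm_tol,rt_tol matching tolerances (ppm; seconds).
#' @return the network with an `annotations` data.frame: `feature_id`,
#'   `compound_name`, `match` (`"direct"`/`"indirect"`), `ppm_error`,
#'   `group`, `conflict`.
#' @export
annotate_network <- function(network, roi, ppm_tol = 5, rt_tol = 2) {
  stopifnot(inherits(network, "structural_network"))
  nodes <- network$nodes
  direct <- list()
  for (r in seq_len(nrow(roi))) {
    cand <- nodes[is.na(roi$assay[r]) | nodes$assay == roi$assay[r], ]
    if (!nrow(cand)) next
    dm <- abs(cand$mz - roi$ref_mz[r])
    dr <- abs(cand$rt - roi$ref_rt[r])
    hit <- dm <= ppm_tol * 1e-6 * roi$ref_mz[r] & dr <= rt_tol
    if (any(hit))
      direct[[length(direct) + 1]] <- data.frame(
        feature_id = cand$feature_id[hit],
        compound_name = roi$compound_name[r],
        match = "direct",
        ppm_error = ppm_of(dm[hit], roi$ref_mz[r]),
        stringsAsFactors = FALSE)
  }
  ann <- if (length(direct)) do.call(rbind, direct) else
    data.frame(feature_id = character(), compound_name = character(),
               match = character(), ppm_error = numeric(),
               stringsAsFactors = FALSE)
  ann$group <- nodes$group[match(ann$feature_id, nodes$feature_id)]
  # propagate direct annotations to the whole structural group
  indirect <- list()
  for (gi in unique(ann$group[!is.na(ann$group)])) {
    comps <- unique(ann$compound_name[!is.na(ann$group) & ann$group == gi])
    members <- nodes$feature_id[!is.na(nodes$group) & nodes$group == gi]
    for (cp in comps) {
      has <- ann$feature_id[ann$compound_name == cp & !is.na(ann$group) &
                              ann$group == gi]
      rest <- setdiff(members, has)
      if (length(rest))
        indirect[[length(indirect) + 1]] <- data.frame(
          feature_id = rest, compound_name = cp, match = "indirect",
          ppm_error = NA_real_, group = gi, stringsAsFactors = FALSE)
    }
  }
  if (length(indirect)) ann <- rbind(ann, do.call(rbind, indirect))
  if (nrow(ann)) {
    n_comp_group <- tapply(ann$compound_name[ann$match == "direct"],
                           ann$group[ann$match == "direct"],
                           function(v) length(unique(v)))
    ann$conflict <- !is.na(ann$group) &
      ann$group %in% as.integer(names(n_comp_group)[n_comp_group > 1])
    ann <- ann[order(ann$feature_id, ann$match), ]
    rownames(ann) <- NULL
  } else ann$conflict <- logical(0)
  network$annotations <- ann
  network
}

#' Export a structural network to GraphML and flat tables
#'
#' Writes `network.graphml` (igraph GraphML), `edges.csv`
#' (source/target/edge_type/rule/ppm_error) and `nodes.csv` (feature
#' metadata with cluster label, group id and annotation) into `dir`.
#'
#' @param network a `"structural_network"`.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_network <- function(network, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(graphml = file.path(dir, "network.graphml"),
             edges = file.path(dir, "edges.csv"),
             nodes = file.path(dir, "nodes.csv"))
  igraph::write_graph(network$graph, paths["graphml"], format = "graphml")
  e <- network$edges
  e$ppm_error <- sprintf("%.10g", e$ppm_error)
  e$rt_diff <- sprintf("%.10g", e$rt_diff)
  names(e)[names(e) == "from"] <- "source"
  names(e)[names(e) == "to"] <- "target"
  utils::write.table(e, paths["edges"], sep = ",", row.names = FALSE, quote = FALSE)
  n <- network$nodes
  if (!is.null(network$annotations) && nrow(network$annotations)) {
    first_ann <- network$annotations[!duplicated(network$annotations$feature_id), ]
    n$annotation <- first_ann$compound_name[match(n$feature_id, first_ann$feature_id)]
    n$annotation_match <- first_ann$match[match(n$feature_id, first_ann$feature_id)]
  }
  n$mz <- sprintf("%.10g", n$mz)
  n$rt <- sprintf("%.10g", n$rt)
  utils::write.table(n, paths["nodes"], sep = ",", row.names = FALSE, quote = FALSE)
  invisible(paths)
}
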