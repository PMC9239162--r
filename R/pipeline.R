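#' Run the full prioritization pipeline
#'
#' Chains the whole analysis: per-species zRPKM activity calls, exclusion
#' of clusters with inactive members, per-species fold-change tables,
#' Brownian-motion reconstruction of ancestral fold changes, fold-change
#' differentials of the focal species against a chosen ancestor, and the
#' ranked priority list.
#'
#' @param expr Named list of expression tibbles (one per species; names
#'   must match the tree's tips and the cluster map's columns).
#' @param scog_map Cluster map tibble (see [read_scog_map()]).
#' @param tree Rooted species `phylo` (see [parse_newick()]).
#' @param focal_species Species whose genes are prioritized.
#' @param node Ancestor to contrast against; default the tree's root (the
#'   species' MRCA). Accepts a node name or `"MRCA:leafA,leafB"`.
#' @param z_threshold,activity_rule Passed to [call_activity()].
#' @param pseudocount Passed to [fold_change_table()].
#' @param scale Passed to [contrast_against_node()].
#' @return List of class `expevo_pipeline`: `ranking` (ranked records),
#'   `retained`, `excluded`, `activity`, `fold_changes`, `estimate`
#'   (`bm_ancestral`), `node`, `focal_species`.
#' @export
prioritize_genes <- function(expr, scog_map, tree, focal_species,
                             node = NULL, z_threshold = -3,
                             activity_rule = "mean", pseudocount = 1,
                             scale = "log2") {
  species <- setdiff(names(scog_map), "cluster_id")
  activity <- lapply(expr[species], function(m) {
    call_activity(z_transform(m), z_threshold = z_threshold,
                  rule = activity_rule)
  })
  filt <- filter_scogs(scog_map, activity)
  fold_changes <- lapply(expr[species], fold_change_table,
                         pseudocount = pseudocount)
  estimate <- ancestral_fold_changes(tree, fold_changes, filt$retained)
  if (is.null(node)) {
    po <- ape::reorder.phylo(tree, "postorder")
    root_num <- po$edge[nrow(po$edge), 1L]
    node <- tree$node.label[root_num - length(tree$tip.label)]
  }
  records <- contrast_against_node(fold_changes, filt$retained, estimate,
                                   node, focal_species, scale = scale)
  structure(list(ranking = rank_clusters(records),
                 retained = filt$retained, excluded = filt$excluded,
                 activity = activity, fold_changes = fold_changes,
                 estimate = estimate, node = node,
                 focal_species = focal_species),
            class = "expevo_pipeline")
}

#' @export
print.expevo_pipeline <- function(x, ...) {
  cat("Expression-evolution prioritization (focal species: ",
      x$focal_species, ", ancestor: ", x$node, ")\n", sep = "")
  cat("  clusters retained:", nrow(x$retained),
      " excluded:", length(x$excluded), "\n")
  cat("  top of ranking:\n")
  print(head(dplyr::select(x$ranking, "rank", "cluster_id", "gene_id",
                           "fcd_max", "fcd_linear", "transition_label"), 5L))
  invisible(x)
}

#' @export
#' @method glance expevo_pipeline
glance.expevo_pipeline <- function(x, ...) {
  tibble(n_retained = nrow(x$retained),
         n_excluded = length(x$excluded),
         focal_species = x$focal_species,
         node = x$node,
         top_fcd_max = x$ranking$fcd_max[1L])
}
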