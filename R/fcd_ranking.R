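#' Fold-change differential of one gene against an ancestor
#'
#' For one ortholog cluster, subtracts the ancestral per-transition fold
#' changes from the extant species' fold changes,
#' `fcd[t] = deltaX[t] - deltaY[t]`, and summarizes by the maximum across
#' transitions: the gene's evolved expression increase.
#'
#' @param extant Numeric vector of per-transition log2 fold changes in the
#'   focal species (`deltaX`).
#' @param ancestral Numeric vector of the same length: reconstructed
#'   ancestral fold changes (`deltaY`).
#' @param cluster_id,gene_id Identifiers carried into the record.
#' @param scale `"log2"` (default): differentials on the log2 scale, with
#'   `fcd_linear = 2^fcd_max` reported alongside. `"linear_difference"`:
#'   the literal difference of linear fold changes, `2^deltaX - 2^deltaY`
#'   per transition (then `fcd_linear = fcd_max`).
#' @return One-row tibble: `cluster_id`, `gene_id`, one `fcd_` column per
#'   transition, `fcd_max`, `argmax_t` (0-based; first index on ties),
#'   `transition_label`, `fcd_linear`.
#' @examples
#' fcd(c(3, 0, 0, 0, 0), c(1, 0, 0, 0, 0), "c1", "g1")
#' @export
fcd <- function(extant, ancestral, cluster_id = NA_character_,
                gene_id = NA_character_, scale = c("log2", "linear_difference")) {
  scale <- match.arg(scale)
  if (length(extant) != length(ancestral)) {
    abort(paste0("length mismatch: extant has ", length(extant),
                 " transitions, ancestral has ", length(ancestral)))
  }
  if (anyNA(extant) || anyNA(ancestral) ||
      any(!is.finite(extant)) || any(!is.finite(ancestral))) {
    abort("fold changes must be finite")
  }
  per_t <- switch(scale,
    log2 = extant - ancestral,
    linear_difference = 2^extant - 2^ancestral
  )
  labels <- transition_labels(length(extant) + 1L)
  amax <- which.max(per_t)
  rec <- tibble(cluster_id = cluster_id, gene_id = gene_id)
  for (i in seq_along(per_t)) rec[[paste0("fcd_", labels[i])]] <- per_t[i]
  rec$fcd_max <- per_t[amax]
  rec$argmax_t <- amax - 1L
  rec$transition_label <- labels[amax]
  rec$fcd_linear <- if (scale == "log2") 2^per_t[amax] else per_t[amax]
  rec
}

#' Rank fold-change-differential records
#'
#' Sorts records by `fcd_max`, largest evolved increase first, breaking ties
#' by cluster id (lexical, stable), and assigns ranks `1..N`.
#'
#' @param records Tibble of unranked records (one per cluster), e.g. from
#'   [contrast_against_node()].
#' @return The records sorted, with a `rank` column, classed
#'   `fcd_ranking`.
#' @export
rank_clusters <- function(records) {
  if (anyDuplicated(records$cluster_id)) {
    dup <- unique(records$cluster_id[duplicated(records$cluster_id)])
    abort(paste0("duplicate cluster id(s): ", paste(dup, collapse = ", ")))
  }
  out <- dplyr::arrange(records, dplyr::desc(.data$fcd_max), .data$cluster_id)
  out$rank <- seq_len(nrow(out))
  class(out) <- c("fcd_ranking", class(out))
  out
}

#' Contrast extant fold changes against a reconstructed ancestor
#'
#' The priority-list computation: for every retained ortholog cluster,
#' computes the fold-change differential of the focal species' member gene
#' against the fold changes reconstructed at a chosen ancestral node
#' (default the root, i.e. the species' most recent common ancestor).
#'
#' @param fold_changes Named list, one fold-change tibble per species (from
#'   [fold_change_table()]).
#' @param scog_map Cluster map tibble (see [read_scog_map()]), typically the
#'   `retained` part of [filter_scogs()].
#' @param estimate `bm_ancestral` from [ancestral_fold_changes()].
#' @param node_name Ancestor to contrast against: internal node name or
#'   `"MRCA:leafA,leafB"`.
#' @param focal_species Leaf name whose genes are being prioritized.
#' @param scale See [fcd()].
#' @return Unranked records tibble, one row per cluster (pipe into
#'   [rank_clusters()]).
#' @export
contrast_against_node <- function(fold_changes, scog_map, estimate, node_name,
                                  focal_species,
                                  scale = c("log2", "linear_difference")) {
  scale <- match.arg(scale)
  if (!focal_species %in% estimate$tree$tip.label) {
    abort(paste0("focal species '", focal_species, "' is not a leaf of the tree"))
  }
  if (!focal_species %in% names(fold_changes)) {
    abort(paste0("no fold-change table for focal species '", focal_species, "'"))
  }
  anc <- node_lookup(estimate, node_name)
  fc <- fold_changes[[focal_species]]
  trans <- setdiff(names(fc), "gene_id")
  genes <- scog_map[[focal_species]]
  idx <- match(genes, fc$gene_id)
  if (anyNA(idx)) {
    abort(paste0("gene '", genes[which(is.na(idx))[1L]],
                 "' missing from the focal species' fold-change table"))
  }
  dX <- as.matrix(fc[idx, trans])                       # clusters x transitions
  char_ids <- outer(scog_map$cluster_id, trans, paste, sep = "::")
  dY <- matrix(anc[match(char_ids, names(anc))], nrow = nrow(char_ids))
  if (anyNA(dY)) abort("ancestral estimate does not cover every cluster/transition")
  per_t <- switch(scale, log2 = dX - dY, linear_difference = 2^dX - 2^dY)
  amax <- max.col(per_t, ties.method = "first")
  fmax <- per_t[cbind(seq_len(nrow(per_t)), amax)]
  out <- tibble(cluster_id = scog_map$cluster_id, gene_id = genes)
  for (i in seq_along(trans)) out[[paste0("fcd_", trans[i])]] <- per_t[, i]
  out$fcd_max <- fmax
  out$argmax_t <- amax - 1L
  out$transition_label <- trans[amax]
  out$fcd_linear <- if (scale == "log2") 2^fmax else fmax
  out
}

#' Reconstruct ancestral fold changes for every cluster
#'
#' Builds the species-by-character matrix (one character per cluster and
#' stage transition) from per-species fold-change tables mapped through the
#' cluster map, and reconstructs every character at every internal node
#' under Brownian motion.
#'
#' @inheritParams contrast_against_node
#' @param tree Rooted species `phylo` whose tips match `names(fold_changes)`.
#' @return `bm_ancestral`; character ids are `"<cluster_id>::<transition>"`.
#' @export
ancestral_fold_changes <- function(tree, fold_changes, scog_map) {
  species <- setdiff(names(scog_map), "cluster_id")
  missing_sp <- setdiff(species, names(fold_changes))
  if (length(missing_sp) > 0L) {
    abort(paste0("no fold-change table for species: ",
                 paste(missing_sp, collapse = ", ")))
  }
  trans <- setdiff(names(fold_changes[[species[1L]]]), "gene_id")
  char_ids <- as.vector(t(outer(scog_map$cluster_id, trans, paste, sep = "::")))
  x <- matrix(NA_real_, length(species), length(char_ids),
              dimnames = list(species, char_ids))
  for (sp in species) {
    fc <- fold_changes[[sp]]
    idx <- match(scog_map[[sp]], fc$gene_id)
    if (anyNA(idx)) {
      abort(paste0("gene '", scog_map[[sp]][which(is.na(idx))[1L]],
                   "' missing from fold-change table of species '", sp, "'"))
    }
    x[sp, ] <- as.vector(t(as.matrix(fc[idx, trans])))
  }
  bm_internal_states(tree, x)
}
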