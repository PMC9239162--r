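#' Assign a phylostratigraphic age class to one gene
#'
#' Given a presence/absence map over reference taxa and an ordered stratum
#' hierarchy (oldest first, youngest = the focal lineage alone), a gene is
#' assigned the oldest stratum containing at least one taxon where a
#' homolog is present. A gene present only in the focal species lands in
#' the youngest (orphan) stratum; if the hierarchy has no stratum covering
#' the focal taxon, such genes fall into `"others"`.
#'
#' @param presence Named logical vector: taxon -> homolog detected. Must
#'   include the focal taxon, with value `TRUE`.
#' @param hierarchy Tibble with columns `stratum`, `taxon`; strata ordered
#'   oldest to youngest by first appearance.
#' @param focal_taxon Name of the focal species/lineage.
#' @return The stratum name (character scalar).
#' @examples
#' h <- tibble::tibble(
#'   stratum = c("Eukaryotes", "Dikarya", "orphan"),
#'   taxon = c("yeast", "mushroom", "focal"))
#' assign_stratum(c(focal = TRUE, yeast = FALSE, mushroom = TRUE), h, "focal")
#' @export
assign_stratum <- function(presence, hierarchy, focal_taxon) {
  if (!focal_taxon %in% names(presence)) {
    abort(paste0("focal taxon '", focal_taxon, "' absent from presence map"))
  }
  if (!isTRUE(presence[[focal_taxon]])) {
    abort(paste0("focal taxon '", focal_taxon, "' must be present (it carries the gene)"))
  }
  strata <- unique(hierarchy$stratum)
  for (s in strata) {
    taxa <- hierarchy$taxon[hierarchy$stratum == s]
    taxa <- intersect(taxa, names(presence))
    if (length(taxa) > 0L && any(presence[taxa])) return(s)
  }
  "others"
}

#' Assign strata for a whole genome
#'
#' Vectorized [assign_stratum()] over a presence/absence matrix, joining in
#' functional-annotation flags.
#'
#' @param presence_tbl Tibble from [read_presence_matrix()] (`gene_id` plus
#'   one logical column per taxon).
#' @param hierarchy See [assign_stratum()].
#' @param focal_taxon Focal taxon name; must be a column of `presence_tbl`
#'   and `TRUE` for every gene.
#' @param flags Tibble `gene_id`, `is_functional` covering every gene.
#' @return Tibble `gene_id`, `stratum` (factor ordered oldest to youngest,
#'   `"others"` last), `is_functional`.
#' @export
assign_strata <- function(presence_tbl, hierarchy, focal_taxon, flags) {
  if (!focal_taxon %in% names(presence_tbl)) {
    abort(paste0("focal taxon '", focal_taxon, "' absent from presence matrix"))
  }
  if (!all(presence_tbl[[focal_taxon]])) {
    abort("every gene must be present in the focal taxon")
  }
  strata <- unique(hierarchy$stratum)
  assigned <- rep("others", nrow(presence_tbl))
  remaining <- rep(TRUE, nrow(presence_tbl))
  for (s in strata) {
    taxa <- intersect(hierarchy$taxon[hierarchy$stratum == s], names(presence_tbl))
    if (length(taxa) == 0L) next
    hit <- remaining & Reduce(`|`, lapply(taxa, function(tx) presence_tbl[[tx]]))
    assigned[hit] <- s
    remaining <- remaining & !hit
  }
  idx <- match(presence_tbl$gene_id, flags$gene_id)
  if (anyNA(idx)) {
    abort(paste0("annotation flag missing for gene '",
                 presence_tbl$gene_id[which(is.na(idx))[1L]], "'"))
  }
  tibble(gene_id = presence_tbl$gene_id,
         stratum = factor(assigned, levels = c(strata, "others")),
         is_functional = flags$is_functional[idx])
}

#' Hypothetical/functional counts per stratum
#'
#' Tabulates assignments into per-stratum counts of hypothetical and
#' functional genes, ordered oldest to youngest, with the conventional
#' `"hypothetical/functional"` display label.
#'
#' @param assignments Tibble from [assign_strata()].
#' @return Tibble `stratum`, `n_hypothetical`, `n_functional`, `n_total`,
#'   `label`. Strata with no genes are kept with zero counts; counts sum to
#'   the number of genes.
#' @export
stratum_table <- function(assignments) {
  assignments |>
    dplyr::group_by(.data$stratum, .drop = FALSE) |>
    dplyr::summarise(n_hypothetical = sum(!.data$is_functional),
                     n_functional = sum(.data$is_functional),
                     .groups = "drop") |>
    dplyr::mutate(n_total = .data$n_hypothetical + .data$n_functional,
                  label = paste0(.data$n_hypothetical, "/", .data$n_functional))
}
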