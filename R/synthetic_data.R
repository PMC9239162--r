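#' Simulation configuration
#'
#' Assembles and validates the configuration of the synthetic-data
#' generator. The defaults describe the data-generating process the
#' pipeline assumes: five species on a rooted ultrametric tree of depth 1,
#' six developmental stages, per-transition log2 fold changes evolving by
#' Brownian motion (rate 1 log2-squared per unit branch length), a minority
#' of clusters with a planted lineage-specific activation shift on the
#' focal terminal branch, a minority of silent clusters, a hypothetical
#' gene class evolving at a higher rate, and Poisson count noise mapped
#' back to RPKM.
#'
#' @param n_genes Number of ortholog clusters (default 2000).
#' @param n_species Number of species; used only when `tree` is `NULL`
#'   (default 5, via [default_species_tree()]).
#' @param n_stages Number of developmental stages (default 6).
#' @param tree A rooted `phylo`, or `NULL` for the default five-species
#'   tree (when `n_species == 5`) or a simulated tree otherwise.
#' @param depth Root-to-tip depth of a simulated tree (time units).
#' @param bm_rate Brownian rate sigma^2 per character (log2^2 units;
#'   default 1).
#' @param rate_multiplier Rate multiplier for hypothetical-class genes
#'   (default 4).
#' @param fraction_hypothetical Fraction of clusters in the hypothetical
#'   class (default 0.1).
#' @param n_planted Number of clusters given an activation shift
#'   (default 25).
#' @param shift Planted shift delta in log2 units (default 4).
#' @param planted_leaf Terminal branch carrying the shift (default the
#'   first tip; `"Fgra"` on the default tree).
#' @param planted_transition 0-based transition index of the shift
#'   (default 3, i.e. S3 to S4).
#' @param fraction_silent Fraction of clusters silent (near-zero RPKM) in
#'   all species (default 0.02).
#' @param baseline_log2_mean,baseline_log2_sd Stage-0 log2 RPKM
#'   distribution (default Normal(4, 2^2)).
#' @param root_delta_sd Standard deviation of root fold-change characters
#'   (default 1).
#' @param length_meanlog,length_sdlog LogNormal gene-length parameters in
#'   bp (default meanlog log(1500), sdlog 0.25).
#' @param library_size Mapped reads per library (default 1e7).
#' @param count_noise Draw Poisson counts and convert back to observed
#'   RPKM (default TRUE); `FALSE` emits noiseless RPKM.
#' @param pseudocount Pseudocount used downstream (recorded, default 1).
#' @param seed Integer seed; the generator is deterministic given the
#'   config.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L, n_species = 5L, n_stages = 6L,
                       tree = NULL, depth = 1,
                       bm_rate = 1, rate_multiplier = 4,
                       fraction_hypothetical = 0.1,
                       n_planted = 25L, shift = 4,
                       planted_leaf = NULL, planted_transition = 3L,
                       fraction_silent = 0.02,
                       baseline_log2_mean = 4, baseline_log2_sd = 2,
                       root_delta_sd = 1,
                       length_meanlog = log(1500), length_sdlog = 0.25,
                       library_size = 1e7, count_noise = TRUE,
                       pseudocount = 1, seed = 42L) {
  cfg <- list(n_genes = as.integer(n_genes), n_species = as.integer(n_species),
              n_stages = as.integer(n_stages), tree = tree, depth = depth,
              bm_rate = bm_rate, rate_multiplier = rate_multiplier,
              fraction_hypothetical = fraction_hypothetical,
              n_planted = as.integer(n_planted), shift = shift,
              planted_leaf = planted_leaf,
              planted_transition = as.integer(planted_transition),
              fraction_silent = fraction_silent,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              root_delta_sd = root_delta_sd,
              length_meanlog = length_meanlog, length_sdlog = length_sdlog,
              library_size = library_size, count_noise = isTRUE(count_noise),
              pseudocount = pseudocount, seed = as.integer(seed))
  if (cfg$n_genes < 1L) abort("n_genes must be >= 1")
  if (cfg$n_species < 2L) abort("n_species must be >= 2")
  if (cfg$n_stages < 2L) abort("n_stages must be >= 2")
  if (cfg$bm_rate < 0 || cfg$rate_multiplier < 0) abort("rates must be >= 0")
  if (cfg$fraction_silent < 0 || cfg$fraction_silent >= 1) {
    abort("fraction_silent must be in [0, 1)")
  }
  if (cfg$fraction_hypothetical < 0 || cfg$fraction_hypothetical > 1) {
    abort("fraction_hypothetical must be in [0, 1]")
  }
  if (cfg$n_planted > cfg$n_genes) abort("n_planted cannot exceed n_genes")
  if (cfg$planted_transition < 0L || cfg$planted_transition > cfg$n_stages - 2L) {
    abort("planted_transition must index a stage transition")
  }
  if (cfg$library_size <= 0) abort("library_size must be > 0")
  structure(cfg, class = "sim_config")
}

#' Default five-species study tree
#'
#' A synthetic ultrametric tree (depth 1) for the five sordariomycete
#' species of the study system, with the clade structure of the group —
#' the two *Fusarium* species sister (their common ancestor named
#' `Hypocreales_anc`), *Neurospora* + *Chaetomium* sister, *Magnaporthe*
#' outside them. Branch lengths are the package's own choice: the study
#' tree's lengths are not published, so these are plausible stand-ins.
#'
#' @return A rooted `phylo` with named internal nodes.
#' @export
default_species_tree <- function() {
  parse_newick(paste0(
    "((Fgra:0.2,Fneo:0.2)Hypocreales_anc:0.8,",
    "((Ncra:0.5,Cglo:0.5)Sordariales_anc:0.3,Mory:0.8)Out_anc:0.2)root;"))
}

#' Simulate a random ultrametric species tree
#'
#' Random rooted bifurcating coalescent topology rescaled so every
#' root-to-tip path equals `depth`. Deterministic under `seed`.
#'
#' @param n_species Number of tips (>= 2).
#' @param depth Root-to-tip depth (default 1).
#' @param seed Integer seed.
#' @return A rooted ultrametric `phylo` with tips `t1..tn` and named
#'   internal nodes.
#' @export
simulate_tree <- function(n_species, depth = 1, seed = 1L) {
  if (n_species < 2L) abort("n_species must be >= 2")
  set.seed(seed)
  tr <- ape::rcoal(n_species)
  h <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length / h * depth
  name_internal_nodes(tr)
}

#' Evolve continuous characters along a tree by Brownian motion
#'
#' Starting from root values, each child node receives its parent's value
#' plus independent Normal(0, sigma^2 * branch length) noise, per
#' character.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param root_values Numeric vector: one value per character at the root.
#' @param sigma2 Brownian rate; scalar or one value per character.
#' @param seed Optional integer seed (set only when non-NULL).
#' @return List: `tips` (matrix tips x characters, rownames = tip labels)
#'   and `nodes` (matrix internal nodes x characters, rownames = node
#'   labels).
#' @export
evolve_characters <- function(tree, root_values, sigma2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(sigma2 < 0)) abort("sigma2 must be >= 0")
  n_char <- length(root_values)
  sig <- rep_len(sqrt(sigma2), n_char)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  root <- po$edge[nrow(po$edge), 1L]
  vals <- matrix(NA_real_, n_node, n_char)
  vals[root, ] <- root_values
  # preorder over edges: parents are assigned before children
  edges <- po$edge[rev(seq_len(nrow(po$edge))), , drop = FALSE]
  lens <- po$edge.length[rev(seq_len(nrow(po$edge)))]
  for (e in seq_len(nrow(edges))) {
    p <- edges[e, 1L]; c <- edges[e, 2L]
    vals[c, ] <- vals[p, ] + rnorm(n_char, 0, sig * sqrt(lens[e]))
  }
  labels <- tree$node.label
  if (is.null(labels)) labels <- paste0("N", seq_len(tree$Nnode))
  tips <- vals[seq_len(n_tip), , drop = FALSE]
  rownames(tips) <- tree$tip.label
  nodes <- vals[(n_tip + 1L):n_node, , drop = FALSE]
  rownames(nodes) <- labels
  list(tips = tips, nodes = nodes)
}

#' Plant a lineage-specific activation shift
#'
#' Adds `delta` to the named terminal branch's (leaf's) fold-change value
#' at one transition, for the planted genes only; everything else is
#' untouched.
#'
#' @param tip_values Matrix tips x characters with character ids
#'   `"<gene>::<transition label>"` as produced inside [emit_dataset()].
#' @param tree Tree the tips belong to (used to check the branch is
#'   terminal).
#' @param leaf Leaf (terminal branch) name.
#' @param transition 0-based transition index.
#' @param delta Shift in log2 units.
#' @param genes Character vector of planted gene/cluster ids.
#' @param n_stages Stage count (for the transition label).
#' @return The modified matrix.
#' @export
plant_shift <- function(tip_values, tree, leaf, transition, delta, genes,
                        n_stages = 6L) {
  if (!leaf %in% tree$tip.label) {
    abort(paste0("'", leaf, "' is not a terminal branch of the tree"))
  }
  if (transition < 0L || transition > n_stages - 2L) {
    abort("transition must index a stage transition")
  }
  if (delta == 0 || length(genes) == 0L) return(tip_values)
  label <- transition_labels(n_stages)[transition + 1L]
  cols <- paste0(genes, "::", label)
  missing_cols <- setdiff(cols, colnames(tip_values))
  if (length(missing_cols) > 0L) {
    abort(paste0("no character column(s): ", paste(head(missing_cols, 3L), collapse = ", ")))
  }
  tip_values[leaf, cols] <- tip_values[leaf, cols] + delta
  tip_values
}

#' Generate a complete synthetic dataset
#'
#' Emits everything the pipeline consumes — per-species expression tables,
#' the species tree, a cluster map, annotation flags — plus a truth record
#' of the simulated ancestral states, classes and planted shifts.
#'
#' Per cluster, stage-0 log2 RPKM is drawn from the baseline Normal and
#' shared across species at the root; per-transition log2 fold-change
#' characters start at Normal(0, `root_delta_sd`^2) and evolve by Brownian
#' motion (hypothetical-class clusters at `bm_rate * rate_multiplier`);
#' planted clusters get `shift` added on the focal terminal branch at the
#' chosen transition; stage expression is the cumulative sum of evolved
#' fold changes; silent clusters are overwritten with RPKM ~
#' Uniform(0, 0.05); finally counts are drawn Poisson(RPKM * length_kb *
#' library_millions) and converted back to observed RPKM.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_dataset`: `tree`, `expr` (named list of
#'   expression tibbles), `scog_map`, `flags`, `truth` (list: `genes`
#'   tibble with per-cluster class/silent/planted info, `tip_deltas` and
#'   `node_deltas` character matrices), `config`.
#' @export
emit_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tree <- config$tree
  if (is.null(tree)) {
    tree <- if (config$n_species == 5L) default_species_tree()
            else simulate_tree(config$n_species, config$depth, seed = config$seed)
  }
  species <- tree$tip.label
  n_sp <- length(species)
  ng <- config$n_genes
  n_tr <- config$n_stages - 1L
  labels <- transition_labels(config$n_stages)
  cluster_ids <- sprintf("SCOG%04d", seq_len(ng))
  planted_leaf <- config$planted_leaf %||% species[1L]

  # gene classes
  hypothetical <- runif(ng) < config$fraction_hypothetical
  silent <- runif(ng) < config$fraction_silent
  candidates <- which(!silent)
  planted_idx <- sort(sample(candidates, min(config$n_planted, length(candidates))))
  planted <- seq_len(ng) %in% planted_idx

  # characters: gene x transition fold changes
  char_ids <- as.vector(t(outer(cluster_ids, labels, paste, sep = "::")))
  root_deltas <- rnorm(ng * n_tr, 0, config$root_delta_sd)
  sigma2 <- rep(ifelse(hypothetical, config$bm_rate * config$rate_multiplier,
                       config$bm_rate), each = n_tr)
  evo <- evolve_characters(tree, root_deltas, sigma2)
  colnames(evo$tips) <- char_ids
  colnames(evo$nodes) <- char_ids
  rd <- matrix(root_deltas, nrow = ng, byrow = TRUE,
               dimnames = list(cluster_ids, labels))
  evo$tips <- plant_shift(evo$tips, tree, planted_leaf,
                          config$planted_transition, config$shift,
                          cluster_ids[planted], config$n_stages)

  # stage-0 baseline, shared across species
  base_log2 <- rnorm(ng, config$baseline_log2_mean, config$baseline_log2_sd)
  gene_length <- rlnorm(ng, config$length_meanlog, config$length_sdlog)

  expr <- list()
  scog <- tibble(cluster_id = cluster_ids)
  flags_all <- list()
  for (sp in species) {
    deltas <- matrix(evo$tips[sp, ], nrow = ng, byrow = TRUE)   # gene x transition
    log2_expr <- cbind(base_log2, base_log2 + t(apply(deltas, 1L, cumsum)))
    rpkm <- 2^log2_expr
    if (any(silent)) {
      rpkm[silent, ] <- matrix(runif(sum(silent) * config$n_stages, 0, 0.05),
                               nrow = sum(silent))
    }
    if (config$count_noise) {
      lam <- rpkm * (gene_length / 1e3) * (config$library_size / 1e6)
      counts <- matrix(rpois(length(lam), lam), nrow = ng)
      rpkm <- rpkm_from_counts(counts, gene_length, config$library_size)
    }
    gene_ids <- sprintf("%s_g%04d", sp, seq_len(ng))
    tbl <- dplyr::bind_cols(
      tibble(gene_id = gene_ids),
      as_tibble(setNames(as.data.frame(rpkm),
                         paste0("S", seq_len(config$n_stages) - 1L)))
    )
    attr(tbl, "species") <- sp
    expr[[sp]] <- tbl
    scog[[sp]] <- gene_ids
    flags_all[[sp]] <- tibble(gene_id = gene_ids, is_functional = !hypothetical)
  }
  flags <- dplyr::bind_rows(flags_all)

  truth_genes <- tibble(
    cluster_id = cluster_ids,
    class_label = ifelse(hypothetical, "hypothetical", "functional"),
    silent = silent,
    planted = planted,
    planted_leaf = ifelse(planted, planted_leaf, NA_character_),
    planted_transition = ifelse(planted, config$planted_transition, NA_integer_),
    baseline_log2 = base_log2,
    gene_length_bp = gene_length
  )
  structure(list(tree = tree, expr = expr, scog_map = scog, flags = flags,
                 truth = list(genes = truth_genes, root_deltas = rd,
                              tip_deltas = evo$tips, node_deltas = evo$nodes),
                 config = config),
            class = "sim_dataset")
}

#' Write a synthetic dataset to disk
#'
#' Writes per-species expression TSVs (`expr_<species>.tsv`), the Newick
#' tree (`tree.nwk`), the cluster map (`scog_map.tsv`), annotation flags
#' (`flags.tsv`) and the per-cluster truth table (`truth.tsv`), all in the
#' formats the package readers accept.
#'
#' @param dataset A `sim_dataset` from [emit_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "sim_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (sp in names(dataset$expr)) {
    write_expression_table(dataset$expr[[sp]],
                           file.path(dir, paste0("expr_", sp, ".tsv")))
  }
  write_newick(dataset$tree, file.path(dir, "tree.nwk"))
  readr::write_tsv(dataset$scog_map, file.path(dir, "scog_map.tsv"), progress = FALSE)
  readr::write_tsv(dataset$flags, file.path(dir, "flags.tsv"), progress = FALSE)
  readr::write_tsv(dataset$truth$genes, file.path(dir, "truth.tsv"), progress = FALSE)
  invisible(dir)
}
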