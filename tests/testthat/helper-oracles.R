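# Independent oracles used across the suite. These deliberately take the
# slow, transparent route (dense matrices, enumeration) so they share no
# code with the implementation they check.

# Dense GLS root estimate: y_hat = (1' V^-1 1)^-1 1' V^-1 x with V the
# shared-path-length matrix.
gls_root_oracle <- function(tree, x) {
  V <- ape::vcv(tree)
  x <- x[rownames(V)]
  Vi <- solve(V)
  one <- rep(1, nrow(V))
  denom <- c(t(one) %*% Vi %*% one)
  est <- c(t(one) %*% Vi %*% x) / denom
  resid <- x - est
  sigma2 <- c(t(resid) %*% Vi %*% resid) / length(x)
  list(root_value = est, root_variance = sigma2 / denom, sigma2 = sigma2)
}

# Internal states by solving the graph-Laplacian normal equations of
# min sum_edges (x_p - x_c)^2 / len with tips fixed.
internal_states_oracle <- function(tree, x) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  A <- matrix(0, n_node, n_node)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]; c <- tree$edge[e, 2L]
    w <- 1 / tree$edge.length[e]
    A[p, p] <- A[p, p] + w; A[c, c] <- A[c, c] + w
    A[p, c] <- A[p, c] - w; A[c, p] <- A[c, p] - w
  }
  xt <- x[tree$tip.label]
  int <- (n_tip + 1L):n_node
  sol <- solve(A[int, int], -A[int, seq_len(n_tip)] %*% xt)
  stats::setNames(c(sol), tree$node.label)
}

# Exact two-sided Mann-Whitney p by brute-force enumeration of all
# choose(n+m, n) assignments of group labels to the pooled ranks.
mw_enum_oracle <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  U_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(n + m, n)
  U_all <- apply(combos, 2L, function(ix) sum(r[ix]) - n * (n + 1) / 2)
  p <- min(1, 2 * min(mean(U_all <= U_obs), mean(U_all >= U_obs)))
  list(U = U_obs, p_value = p)
}

# MRCA of two leaves by root-path intersection (independent of ape::getMRCA).
mrca_path_oracle <- function(tree, leaf_a, leaf_b) {
  parent_of <- integer(max(tree$edge))
  parent_of[tree$edge[, 2L]] <- tree$edge[, 1L]
  path_up <- function(node) {
    p <- node
    while (parent_of[p[length(p)]] != 0L) p <- c(p, parent_of[p[length(p)]])
    p
  }
  a <- path_up(match(leaf_a, tree$tip.label))
  b <- path_up(match(leaf_b, tree$tip.label))
  intersect(a, b)[1L]
}

# Random tree + tip data for oracle sweeps.
random_tree_case <- function(seed, n_min = 4L, n_max = 12L) {
  set.seed(seed)
  n <- sample(n_min:n_max, 1L)
  tr <- simulate_tree(n, depth = runif(1, 0.5, 2), seed = seed + 1000L)
  x <- stats::setNames(rnorm(n, sd = 2), tr$tip.label)
  list(tree = tr, x = x)
}

transition_label_set <- function(n_stages = 6L) {
  t <- seq_len(n_stages - 1L) - 1L
  paste0("S", t, "−S", t + 1L)
}

# BM characters on the default five-species tree, optionally with a planted
# activation shift, routed through the package's real ranking surface
# (scog map + fold-change tables + reconstruction + contrast).
planted_character_ranking <- function(seed, delta, n_genes = 2000L,
                                      n_planted = 25L, sigma2 = 1,
                                      focal = "Fgra", transition = 3L) {
  set.seed(seed)
  tree <- default_species_tree()
  labs <- transition_label_set()
  ids <- sprintf("SCOG%04d", seq_len(n_genes))
  root <- rnorm(n_genes * 5L, 0, 1)
  evo <- evolve_characters(tree, root, sigma2)
  colnames(evo$tips) <- as.vector(t(outer(ids, labs, paste, sep = "::")))
  planted <- sort(sample(ids, n_planted))
  tips <- plant_shift(evo$tips, tree, focal, transition, delta, planted)
  species <- tree$tip.label
  fold_changes <- lapply(species, function(sp) {
    d <- matrix(tips[sp, ], nrow = n_genes, byrow = TRUE)
    colnames(d) <- labs
    dplyr::bind_cols(tibble::tibble(gene_id = paste0(sp, "_", ids)),
                     tibble::as_tibble(d))
  })
  names(fold_changes) <- species
  scog <- tibble::tibble(cluster_id = ids)
  for (sp in species) scog[[sp]] <- paste0(sp, "_", ids)
  est <- ancestral_fold_changes(tree, fold_changes, scog)
  recs <- contrast_against_node(fold_changes, scog, est, "root", focal)
  list(ranking = rank_clusters(recs), planted = planted, n_genes = n_genes)
}
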