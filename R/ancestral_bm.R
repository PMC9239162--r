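#' Maximum-likelihood root state under Brownian motion
#'
#' Estimates the ancestral value at the root of a rooted tree for one or
#' more continuous characters evolving by Brownian motion, by Felsenstein
#' pruning (linear time in the number of tips). The point estimate equals
#' the generalized-least-squares estimator
#' `(1' V^-1 1)^-1 1' V^-1 x`, where `V[i, j]` is the shared root-to-MRCA
#' path length of tips `i` and `j`; its variance is `(1' V^-1 1)^-1 *
#' sigma2_hat` with the ML (1/n) rate estimate.
#'
#' @param tree Rooted `phylo` with positive branch lengths (see
#'   [parse_newick()]).
#' @param tip_values Named numeric vector (names = tip labels), or a matrix
#'   with one row per tip (rownames = tip labels) and one column per
#'   character.
#' @return List with `root_value` (numeric, one per character),
#'   `root_variance`, and `sigma2` (ML Brownian rate per character).
#' @details The estimate is a convex combination of the tip values — weights
#'   are positive and sum to one — so it always lies within the tip range,
#'   and it is invariant to rescaling all branch lengths (only the variance
#'   changes).
#' @examples
#' tr <- parse_newick("(A:1,B:1,C:1);")
#' bm_root_estimate(tr, c(A = 1, B = 2, C = 3))$root_value  # 2
#' @export
bm_root_estimate <- function(tree, tip_values) {
  st <- bm_prepare(tree, tip_values)
  up <- bm_upward(st)
  n <- st$n_tip
  root <- st$root
  ch <- st$children[[root]]
  prec <- sum(1 / up$w[ch])
  root_value <- colSums(up$m[ch, , drop = FALSE] / up$w[ch]) / prec
  # ML rate from the pruning contrasts: the GLS quadratic form decomposes
  # over internal nodes as sum_children (m_c - m_node)^2 / w_c.
  Q <- up$Q + colSums((up$m[ch, , drop = FALSE] -
                         rep(root_value, each = length(ch)))^2 / up$w[ch])
  sigma2 <- Q / n
  list(root_value = root_value,
       root_variance = sigma2 / prec,
       sigma2 = sigma2)
}

#' Ancestral states at every internal node under Brownian motion
#'
#' Computes the ML/posterior-mean ancestral value of each internal node for
#' each character, i.e. the values minimizing
#' `sum over edges (x_parent - x_child)^2 / branch length` with tips held
#' fixed. Solved by a two-pass Gaussian message-passing sweep (upward
#' pruning, then downward smoothing), linear in tree size per character.
#'
#' @inheritParams bm_root_estimate
#' @return Object of class `bm_ancestral`: list with `tree`, `node_values`
#'   (matrix, internal nodes x characters, rownames = node labels),
#'   `root_value`, `root_variance`, `sigma2`, and `tip_values`.
#' @examples
#' tr <- parse_newick("((A:1,B:1)N1:1,C:2)root;")
#' fit <- bm_internal_states(tr, c(A = 0, B = 2, C = 4))
#' fit$node_values
#' @export
bm_internal_states <- function(tree, tip_values) {
  st <- bm_prepare(tree, tip_values)
  up <- bm_upward(st)
  n_tip <- st$n_tip
  n_node <- st$n_node
  n_char <- ncol(st$x)
  root <- st$root

  # Downward messages: for each non-root node, the distribution of its state
  # given everything outside its own subtree. d_w = Inf marks "no message"
  # (only meaningful at the root, which has no above-tree).
  d_m <- matrix(0, n_node, n_char)
  d_w <- rep(Inf, n_node)
  preorder <- rev(st$postorder_nodes)        # parents before children
  for (p in preorder) {
    ch <- st$children[[p]]
    prec_above <- if (p == root) 0 else 1 / d_w[p]
    msum_above <- if (p == root) rep(0, n_char) else d_m[p, ] / d_w[p]
    prec_ch <- 1 / up$w[ch]
    for (c in ch) {
      others <- ch[ch != c]
      prec <- prec_above + sum(prec_ch[match(others, ch)])
      if (prec <= 0) next                    # root with a single child: no info
      m <- (msum_above +
              colSums(up$m[others, , drop = FALSE] / up$w[others])) / prec
      d_m[c, ] <- m
      d_w[c] <- 1 / prec + st$len[c]
    }
  }

  internal <- (n_tip + 1L):n_node
  vals <- matrix(NA_real_, length(internal), n_char)
  for (i in seq_along(internal)) {
    node <- internal[i]
    ch <- st$children[[node]]
    prec <- sum(1 / up$w[ch]) + (if (node == root) 0 else 1 / d_w[node])
    m <- colSums(up$m[ch, , drop = FALSE] / up$w[ch])
    if (node != root) m <- m + d_m[node, ] / d_w[node]
    vals[i, ] <- m / prec
  }
  rownames(vals) <- st$node_labels
  colnames(vals) <- colnames(st$x)

  root_fit <- bm_root_estimate(tree, tip_values)
  structure(list(tree = tree,
                 node_values = vals,
                 root_value = root_fit$root_value,
                 root_variance = root_fit$root_variance,
                 sigma2 = root_fit$sigma2,
                 tip_values = st$x),
            class = "bm_ancestral")
}

#' Look up the reconstructed value at a named ancestor
#'
#' @param estimate A `bm_ancestral` from [bm_internal_states()].
#' @param node_name Internal node name (as in the tree's `node.label`), or
#'   `"MRCA:leafA,leafB"` to address the most recent common ancestor of two
#'   leaves.
#' @return Named numeric vector: the node's reconstructed value per
#'   character.
#' @details Leaves are observed data, not estimates, so a leaf name is an
#'   error; unknown names raise an error listing the available ancestors.
#' @export
node_lookup <- function(estimate, node_name) {
  stopifnot(inherits(estimate, "bm_ancestral"))
  tree <- estimate$tree
  if (grepl("^MRCA:", node_name)) {
    leaves <- strsplit(sub("^MRCA:", "", node_name), ",", fixed = TRUE)[[1L]]
    leaves <- trimws(leaves)
    missing_lv <- setdiff(leaves, tree$tip.label)
    if (length(missing_lv) > 0L) {
      abort(paste0("unknown leaf name(s): ", paste(missing_lv, collapse = ", ")))
    }
    node <- ape::getMRCA(tree, leaves)
    node_name <- tree$node.label[node - length(tree$tip.label)]
  }
  if (node_name %in% tree$tip.label) {
    abort(paste0("'", node_name, "' is a leaf: leaves carry data, not estimates"))
  }
  idx <- match(node_name, rownames(estimate$node_values))
  if (is.na(idx)) {
    abort(paste0("unknown node '", node_name, "'; available ancestors: ",
                 paste(rownames(estimate$node_values), collapse = ", ")))
  }
  estimate$node_values[idx, ]
}

#' @export
#' @method tidy bm_ancestral
tidy.bm_ancestral <- function(x, ...) {
  as_tibble(x$node_values, rownames = "node") |>
    tidyr::pivot_longer(-"node", names_to = "character_id", values_to = "value")
}

#' @export
#' @method glance bm_ancestral
glance.bm_ancestral <- function(x, ...) {
  tibble(n_tips = nrow(x$tip_values),
         n_internal = nrow(x$node_values),
         n_characters = ncol(x$node_values),
         mean_sigma2 = mean(x$sigma2),
         mean_root_variance = mean(x$root_variance))
}

#' @export
print.bm_ancestral <- function(x, ...) {
  cat("Brownian-motion ancestral state reconstruction\n")
  cat("  tips:", nrow(x$tip_values),
      " internal nodes:", nrow(x$node_values),
      " characters:", ncol(x$node_values), "\n")
  cat("  root value (first characters):",
      paste(signif(head(x$root_value, 3L), 4L), collapse = ", "), "\n")
  invisible(x)
}

# ---- internal machinery ----------------------------------------------------

# Validate tree + tip values; return traversal tables shared by both passes.
bm_prepare <- function(tree, tip_values) {
  if (!inherits(tree, "phylo")) abort("tree must be a 'phylo' object")
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  if (any(tree$edge.length <= 0)) {
    abort("non-positive branch length(s); floor them first via parse_newick()")
  }
  x <- if (is.matrix(tip_values)) tip_values else
    matrix(tip_values, ncol = 1L, dimnames = list(names(tip_values), NULL))
  if (is.null(rownames(x))) abort("tip_values must be named by tip label")
  missing_tip <- setdiff(tree$tip.label, rownames(x))
  if (length(missing_tip) > 0L) {
    abort(paste0("no value for leaf/leaves: ", paste(missing_tip, collapse = ", ")))
  }
  x <- x[tree$tip.label, , drop = FALSE]
  if (anyNA(x) || any(!is.finite(x))) abort("tip values must be finite")

  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  len <- rep(NA_real_, n_node)
  len[tree$edge[, 2L]] <- tree$edge.length
  children <- vector("list", n_node)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]
    children[[p]] <- c(children[[p]], tree$edge[e, 2L])
  }
  po <- ape::reorder.phylo(tree, "postorder")
  postorder_nodes <- unique(po$edge[, 1L])
  root <- postorder_nodes[length(postorder_nodes)]
  labels <- tree$node.label
  if (is.null(labels)) labels <- paste0("N", seq_len(tree$Nnode))
  list(x = x, n_tip = n_tip, n_node = n_node, root = root, len = len,
       children = children, postorder_nodes = postorder_nodes,
       node_labels = labels)
}

# Upward (pruning) pass. For each non-root node, (m, w) parameterize the
# message sent to its parent: state ~ Normal(m, w * sigma2) given its
# subtree, where w includes its own branch. Q accumulates the GLS quadratic
# form contributions below the root.
bm_upward <- function(st) {
  n_char <- ncol(st$x)
  m <- matrix(0, st$n_node, n_char)
  w <- rep(NA_real_, st$n_node)
  extra <- rep(0, st$n_node)
  m[seq_len(st$n_tip), ] <- st$x
  w[seq_len(st$n_tip)] <- st$len[seq_len(st$n_tip)]
  Q <- rep(0, n_char)
  for (node in st$postorder_nodes) {
    ch <- st$children[[node]]
    prec <- sum(1 / w[ch])
    mn <- colSums(m[ch, , drop = FALSE] / w[ch]) / prec
    m[node, ] <- mn
    extra[node] <- 1 / prec
    if (node != st$root) {
      w[node] <- extra[node] + st$len[node]
      Q <- Q + colSums((m[ch, , drop = FALSE] - rep(mn, each = length(ch)))^2 / w[ch])
    }
  }
  list(m = m, w = w, extra = extra, Q = Q)
}
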