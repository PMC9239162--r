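#' RPKM from raw counts
#'
#' `RPKM = count / (gene length in kb * mapped reads in millions)`.
#'
#' @param counts Nonnegative integer read counts (vector).
#' @param gene_length_bp Gene length(s) in base pairs, > 0.
#' @param mapped_reads Library size (total mapped reads), > 0.
#' @return Numeric vector of RPKM values.
#' @examples
#' rpkm_from_counts(500, 2000, 1e7)  # 25
#' @export
rpkm_from_counts <- function(counts, gene_length_bp, mapped_reads) {
  if (any(gene_length_bp <= 0)) abort("gene_length_bp must be > 0")
  if (any(mapped_reads <= 0)) abort("mapped_reads must be > 0")
  if (any(counts < 0)) abort("counts must be >= 0")
  counts / ((gene_length_bp / 1e3) * (mapped_reads / 1e6))
}

#' Poisson maximum-likelihood expression point estimates across replicates
#'
#' Pools replicate libraries of one stage into a single per-gene expression
#' point estimate under the model `count[g, r] ~ Poisson(a_g * b_r)` with the
#' replicate effects constrained to `sum(b_r) = R` (the number of
#' replicates). The ML solution is closed form — `a_g` is the row sum over
#' `R` and `b_r` is the column sum scaled to the constraint — and is the
#' fixed point of iterative proportional fitting: the fitted means reproduce
#' the row and column sums of the count matrix exactly.
#'
#' @param replicate_counts Matrix (genes x replicates) of nonnegative counts;
#'   a vector is treated as a single replicate.
#' @return List with `a` (per-gene estimates, named if the matrix had
#'   rownames), `b` (per-replicate effects summing to the replicate count),
#'   and `fitted` (the matrix of means `a_g * b_r`).
#' @examples
#' m <- rbind(g1 = c(10, 12), g2 = c(0, 2))
#' poisson_point_estimates(m)$a
#' @export
poisson_point_estimates <- function(replicate_counts) {
  m <- as.matrix(replicate_counts)
  if (any(m < 0)) abort("counts must be >= 0")
  total <- sum(m)
  if (total == 0) abort("all-zero count matrix: expression not estimable")
  R <- ncol(m)
  b <- colSums(m) / total * R
  a <- rowSums(m) / R
  list(a = a, b = b, fitted = outer(a, b))
}

#' Relative expression profile across stages
#'
#' Normalizes a gene's per-stage expression to sum to one, placing it on the
#' stage simplex. Scale-invariant: multiplying all stages by a constant
#' leaves the profile unchanged.
#'
#' @param expr Nonnegative per-stage expression values with positive sum.
#' @return Numeric vector summing to 1, same length and names as `expr`.
#' @export
relative_profile <- function(expr) {
  if (any(expr < 0)) abort("expression values must be >= 0")
  s <- sum(expr)
  if (s <= 0) abort("all-zero expression vector: relative profile undefined")
  expr / s
}

#' Log2 fold changes between adjacent stages
#'
#' `delta[t] = log2((expr[t+1] + pseudocount) / (expr[t] + pseudocount))`
#' for transitions `t = 0..(S-2)`. These additive per-transition characters
#' are what evolves along the phylogeny in the Brownian-motion model.
#'
#' @param expr Nonnegative per-stage expression values (length >= 2).
#' @param pseudocount Added to numerator and denominator; must be > 0 if any
#'   stage is zero (default 1 RPKM).
#' @return Numeric vector of length `length(expr) - 1`, named by transition
#'   (`"S0−S1"`, ... when `expr` has default ordering).
#' @examples
#' log_fold_changes(c(1, 2, 4, 8, 16, 32), pseudocount = 0)
#' @export
log_fold_changes <- function(expr, pseudocount = 1) {
  if (length(expr) < 2L) abort("need at least two stages")
  if (any(expr < 0)) abort("expression values must be >= 0")
  if (pseudocount < 0) abort("pseudocount must be >= 0")
  if (pseudocount == 0 && any(expr == 0)) {
    abort("zero expression with pseudocount = 0: fold change undefined")
  }
  x <- expr + pseudocount
  delta <- log2(x[-1L] / x[-length(x)])
  names(delta) <- transition_labels(length(expr))
  delta
}

# "S0−S1", "S1−S2", ... (U+2212 minus, the convention of published
# priority tables).
transition_labels <- function(n_stages) {
  t <- seq_len(n_stages - 1L) - 1L
  paste0("S", t, "\u2212S", t + 1L)
}

#' Fold-change table for many genes
#'
#' Applies [log_fold_changes()] to every row of an expression tibble.
#'
#' @param matrix Expression tibble (`gene_id` + stage columns).
#' @param pseudocount See [log_fold_changes()].
#' @return Tibble `gene_id` plus one column per transition label.
#' @export
fold_change_table <- function(matrix, pseudocount = 1) {
  stages <- setdiff(names(matrix), "gene_id")
  em <- as.matrix(matrix[stages]) + pseudocount
  if (pseudocount < 0) abort("pseudocount must be >= 0")
  if (any(em <= 0)) abort("zero expression with pseudocount = 0: fold change undefined")
  delta <- log2(em[, -1L, drop = FALSE] / em[, -length(stages), drop = FALSE])
  colnames(delta) <- transition_labels(length(stages))
  dplyr::bind_cols(matrix["gene_id"], as_tibble(delta))
}

#' Relative profiles for many genes
#'
#' Applies [relative_profile()] to every row of an expression tibble.
#'
#' @param matrix Expression tibble (`gene_id` + stage columns).
#' @return Tibble `gene_id` plus stage columns, each row summing to 1.
#' @export
relative_profile_table <- function(matrix) {
  stages <- setdiff(names(matrix), "gene_id")
  em <- as.matrix(matrix[stages])
  if (any(em < 0)) abort("expression values must be >= 0")
  s <- rowSums(em)
  zero <- which(s <= 0)
  if (length(zero) > 0L) {
    abort(paste0("all-zero expression for gene '", matrix$gene_id[zero[1L]],
                 "': relative profile undefined"))
  }
  dplyr::bind_cols(matrix["gene_id"], as_tibble(em / s))
}
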