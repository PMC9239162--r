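#' Mean pairwise Euclidean distance between species' relative profiles
#'
#' For one ortholog cluster, the expression divergence is the Euclidean
#' distance between every unordered pair of species' relative stage
#' profiles, averaged over all `choose(k, 2)` pairs. On the stage simplex
#' this lies in `[0, sqrt(2)]`.
#'
#' @param profiles Numeric matrix, one row per species (rownames = species),
#'   one column per stage; each row must lie on the simplex (nonnegative,
#'   summing to 1 within `tol`).
#' @param tol Simplex tolerance (default 1e-6).
#' @return Named list: `mean_euclid` (overall mean) and `by_species`
#'   (named vector: for each species, the mean over the pairs involving it).
#' @export
pairwise_mean_euclid <- function(profiles, tol = 1e-6) {
  m <- as.matrix(profiles)
  k <- nrow(m)
  if (k < 2L) abort("need profiles for at least two species")
  if (any(m < -tol) || any(abs(rowSums(m) - 1) > tol)) {
    abort("profiles must lie on the simplex (nonnegative, summing to 1)")
  }
  d <- as.matrix(stats::dist(m, method = "euclidean"))
  pairs <- d[upper.tri(d)]
  by_species <- rowSums(d) / (k - 1L)
  if (!is.null(rownames(m))) names(by_species) <- rownames(m)
  list(mean_euclid = mean(pairs), by_species = by_species)
}

#' Classify a cluster as functional or hypothetical
#'
#' A cluster counts as functional when at least `min_functional` of its
#' member genes carry a predicted protein domain at the stringent E-value
#' cutoff; otherwise it is hypothetical.
#'
#' @param member_flags Logical vector, one flag per member gene.
#' @param min_functional Minimum flagged members (default 2).
#' @return `"functional"` or `"hypothetical"`.
#' @export
classify_scog <- function(member_flags, min_functional = 2L) {
  if (anyNA(member_flags)) abort("missing annotation flag for a cluster member")
  if (sum(member_flags) >= min_functional) "functional" else "hypothetical"
}

#' Per-cluster expression divergence table
#'
#' Computes, for every cluster, the averaged pairwise Euclidean distance
#' between the member genes' relative stage profiles (overall and restricted
#' to pairs involving each species), and classifies the cluster as
#' functional or hypothetical from annotation flags.
#'
#' @param expr Named list of expression tibbles, one per species.
#' @param scog_map Cluster map tibble covering those species.
#' @param flags Tibble `gene_id`, `is_functional` covering every member
#'   gene (see [read_annotation_flags()]).
#' @param min_functional See [classify_scog()].
#' @return Tibble: `cluster_id`, `mean_euclid`, one `mean_euclid_<species>`
#'   column per species (pairs involving that species), `n_functional`,
#'   `class_label`.
#' @export
divergence_table <- function(expr, scog_map, flags, min_functional = 2L) {
  species <- setdiff(names(scog_map), "cluster_id")
  missing_sp <- setdiff(species, names(expr))
  if (length(missing_sp) > 0L) {
    abort(paste0("no expression table for species: ",
                 paste(missing_sp, collapse = ", ")))
  }
  stages <- setdiff(names(expr[[species[1L]]]), "gene_id")
  # relative profiles per species, aligned to cluster order
  prof <- lapply(species, function(sp) {
    em <- expr[[sp]]
    idx <- match(scog_map[[sp]], em$gene_id)
    if (anyNA(idx)) {
      abort(paste0("gene '", scog_map[[sp]][which(is.na(idx))[1L]],
                   "' missing from expression table of species '", sp, "'"))
    }
    rp <- relative_profile_table(em[idx, , drop = FALSE])
    as.matrix(rp[, stages])
  })
  names(prof) <- species
  n <- nrow(scog_map)
  total <- matrix(0, n, 1L)
  by_sp <- matrix(0, n, length(species), dimnames = list(NULL, species))
  n_pairs <- 0L
  for (i in seq_along(species)[-length(species)]) {
    for (j in (i + 1L):length(species)) {
      d <- sqrt(rowSums((prof[[i]] - prof[[j]])^2))
      total <- total + d
      by_sp[, i] <- by_sp[, i] + d
      by_sp[, j] <- by_sp[, j] + d
      n_pairs <- n_pairs + 1L
    }
  }
  flag_idx <- lapply(species, function(sp) match(scog_map[[sp]], flags$gene_id))
  for (sp_i in seq_along(species)) {
    if (anyNA(flag_idx[[sp_i]])) {
      abort(paste0("annotation flags missing for member gene(s) of species '",
                   species[sp_i], "'"))
    }
  }
  n_functional <- Reduce(`+`, lapply(flag_idx, function(ix) as.integer(flags$is_functional[ix])))
  out <- tibble(cluster_id = scog_map$cluster_id,
                mean_euclid = as.vector(total) / n_pairs)
  for (sp in species) {
    out[[paste0("mean_euclid_", sp)]] <- by_sp[, sp] / (length(species) - 1L)
  }
  out$n_functional <- n_functional
  out$class_label <- ifelse(n_functional >= min_functional, "functional", "hypothetical")
  out
}

#' Mann-Whitney U rank-sum test
#'
#' Computes the U statistic of `x` from midranks of the pooled sample and a
#' two-sided p-value: exactly from the null U distribution when the number
#' of arrangements `choose(n + m, n)` is at most `1e5` and there are no
#' ties, otherwise by normal approximation with tie and continuity
#' corrections.
#'
#' @param x,y Non-empty numeric samples.
#' @return One-row tibble: `U`, `p_value`, `method` (`"exact"` or
#'   `"normal_approx"`), `n_x`, `n_y`.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) abort("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) abort("samples must not contain NA")
  n <- length(x)
  m <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1L)
  exact_ok <- !has_ties && choose(n + m, n) <= 1e5
  if (exact_ok) {
    p_lo <- pwilcox(U, n, m)
    p_hi <- pwilcox(U - 1, n, m, lower.tail = FALSE)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    mu <- n * m / 2
    tie_term <- sum(ties^3 - ties) / ((n + m) * (n + m - 1))
    sigma <- sqrt(n * m / 12 * ((n + m + 1) - tie_term))
    if (sigma == 0) {
      p <- 1
    } else {
      z <- U - mu
      z <- (z - sign(z) * 0.5) / sigma      # continuity correction
      p <- min(1, 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE)))
    }
    method <- "normal_approx"
  }
  tibble(U = U, p_value = p, method = method, n_x = n, n_y = m)
}

#' Compare divergence of hypothetical vs functional clusters
#'
#' Rank-sum comparison of a divergence column between the two cluster
#' classes, with per-class mean and median summaries. By default the
#' pooled (all-pairs) divergence is tested; pass a
#' `mean_euclid_<species>` column name to test the distances restricted to
#' pairs involving one focal species.
#'
#' @param records Tibble from [divergence_table()] (needs `class_label` and
#'   the value column).
#' @param value Name of the divergence column (default `"mean_euclid"`).
#' @return List of class `divergence_comparison`: `test` (tibble from
#'   [mann_whitney_u()], hypothetical as the first sample), `summaries`
#'   (per-class n/mean/median), `value` (the column tested).
#' @export
compare_groups <- function(records, value = "mean_euclid") {
  if (!value %in% names(records)) abort(paste0("no column '", value, "' in records"))
  hyp <- records[[value]][records$class_label == "hypothetical"]
  fun <- records[[value]][records$class_label == "functional"]
  if (length(hyp) == 0L || length(fun) == 0L) {
    abort("both classes (functional, hypothetical) must be represented")
  }
  test <- mann_whitney_u(hyp, fun)
  summaries <- records |>
    dplyr::group_by(.data$class_label) |>
    dplyr::summarise(n = dplyr::n(),
                     mean = mean(.data[[value]]),
                     median = median(.data[[value]]),
                     .groups = "drop")
  structure(list(test = test, summaries = summaries, value = value),
            class = "divergence_comparison")
}

#' @export
#' @method tidy divergence_comparison
tidy.divergence_comparison <- function(x, ...) x$summaries

#' @export
#' @method glance divergence_comparison
glance.divergence_comparison <- function(x, ...) {
  dplyr::mutate(x$test, value = x$value)
}

#' @export
print.divergence_comparison <- function(x, ...) {
  cat("Expression divergence: hypothetical vs functional clusters (",
      x$value, ")\n", sep = "")
  cat("  U = ", format(x$test$U), ", two-sided p = ",
      format.pval(x$test$p_value, digits = 3), " (", x$test$method, ")\n", sep = "")
  print(x$summaries)
  invisible(x)
}
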