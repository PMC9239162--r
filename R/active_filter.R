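#' Fit zRPKM transformation parameters for one stage
#'
#' Fits the half-Gaussian model underlying the zFPKM/zRPKM transform: a
#' Gaussian kernel density is estimated over log2 of the strictly positive
#' expression values, the mode `mu` is located on the density grid, `U` is
#' the mean of log2 values above the mode, and the scale is
#' `sigma = (U - mu) * sqrt(pi / 2)` — the standard deviation implied by
#' treating the right flank of the density as the half of a Gaussian
#' centred at `mu`.
#'
#' @param stage_values Nonnegative expression values (RPKM) for one stage;
#'   zeros are excluded from the fit.
#' @param min_positive Minimum number of strictly positive values required
#'   for a stable density fit (default 50).
#' @return A list of class `zfit` with elements `mu`, `sigma`, `U`,
#'   `bandwidth` and `n_positive` (all log2 units except the count).
#' @details The density uses Silverman's rule-of-thumb bandwidth and a
#'   512-point grid spanning the data range plus three bandwidths on either
#'   side; on a tied maximum the smallest grid value is taken as `mu`.
#'   A degenerate distribution (all values equal, or no mass above the
#'   mode) is an error: the transform would be undefined.
#' @examples
#' set.seed(1)
#' fit <- fit_z_params(2^rnorm(1000, mean = 4, sd = 2))
#' fit$mu
#' @export
fit_z_params <- function(stage_values, min_positive = 50L) {
  v <- stage_values[stage_values > 0]
  if (length(v) < min_positive) {
    abort(paste0("need >= ", min_positive, " strictly positive values to fit; got ",
                 length(v)))
  }
  x <- log2(v)
  if (max(x) - min(x) < .Machine$double.eps^0.5) {
    abort("degenerate distribution: all positive values identical")
  }
  bw <- stats::bw.nrd0(x)
  d <- density(x, bw = bw, n = 512L, cut = 3)
  mu <- d$x[which.max(d$y)]           # which.max returns the first (smallest) tie
  above <- x[x > mu]
  if (length(above) == 0L) {
    abort("degenerate distribution: no values above the density mode")
  }
  U <- mean(above)
  sigma <- (U - mu) * sqrt(pi / 2)
  if (!is.finite(sigma) || sigma <= 0) {
    abort("degenerate distribution: fitted sigma is not positive")
  }
  structure(list(mu = mu, sigma = sigma, U = U, bandwidth = bw,
                 n_positive = length(v)),
            class = "zfit")
}

#' Z-transform an expression table stage by stage
#'
#' Applies the zRPKM transform `z = (log2(RPKM) - mu) / sigma` independently
#' to every stage column, with `mu` and `sigma` fitted per stage by
#' [fit_z_params()]. A zero RPKM maps to `-Inf`, a sentinel below any finite
#' threshold, so all-zero genes can never be called active.
#'
#' @param matrix Expression tibble from [read_expression_table()] (column
#'   `gene_id` plus numeric stage columns).
#' @param min_positive Passed through to [fit_z_params()].
#' @return Tibble `gene_id` plus one z-score column per stage; the per-stage
#'   fits are attached as attribute `zfits` (a named list).
#' @export
z_transform <- function(matrix, min_positive = 50L) {
  stages <- setdiff(names(matrix), "gene_id")
  fits <- list()
  out <- matrix["gene_id"]
  for (s in stages) {
    fit <- tryCatch(fit_z_params(matrix[[s]], min_positive = min_positive),
                    error = function(e) {
                      abort(paste0("stage '", s, "': ", conditionMessage(e)))
                    })
    fits[[s]] <- fit
    z <- (log2(matrix[[s]]) - fit$mu) / fit$sigma   # log2(0) = -Inf sentinel
    out[[s]] <- z
  }
  attr(out, "zfits") <- fits
  out
}

#' Call actively transcribed genes from z-scores
#'
#' Averages z-scores across stages and calls a gene active when the mean is
#' at or above `z_threshold` (default −3). With `rule = "any_stage"` a gene
#' is instead active when any single stage reaches the threshold, i.e. only
#' genes below threshold throughout development are called inactive.
#'
#' @param zscores Tibble from [z_transform()].
#' @param z_threshold Activity threshold on the z scale (default -3).
#' @param rule `"mean"` (default; average across stages) or `"any_stage"`.
#' @return Tibble `gene_id`, `mean_z`, `active`.
#' @details The threshold comparison is inclusive: a gene with mean z exactly
#'   at the threshold is active. The `-Inf` sentinel from zero RPKM dominates
#'   the mean, so an all-zero gene is always inactive under either rule.
#' @export
call_activity <- function(zscores, z_threshold = -3, rule = c("mean", "any_stage")) {
  rule <- match.arg(rule)
  stages <- setdiff(names(zscores), "gene_id")
  zmat <- as.matrix(zscores[stages])
  mean_z <- rowMeans(zmat)
  active <- switch(rule,
    mean = mean_z >= z_threshold,
    any_stage = apply(zmat >= z_threshold, 1L, any)
  )
  tibble(gene_id = zscores$gene_id, mean_z = mean_z, active = active)
}

#' Filter SCOGs by member activity
#'
#' A cluster is excluded as soon as one or more of its member genes is not
#' actively transcribed in its own species; only clusters whose members are
#' active in all species are retained.
#'
#' @param scog_map Tibble from [read_scog_map()] (`cluster_id` + one gene-id
#'   column per species).
#' @param activity Named list (one element per species column of `scog_map`)
#'   of activity tibbles from [call_activity()].
#' @return List with `retained` (tibble, same shape as `scog_map`) and
#'   `excluded` (character vector of cluster ids).
#' @export
filter_scogs <- function(scog_map, activity) {
  species <- setdiff(names(scog_map), "cluster_id")
  missing_sp <- setdiff(species, names(activity))
  if (length(missing_sp) > 0L) {
    abort(paste0("no activity calls for species: ", paste(missing_sp, collapse = ", ")))
  }
  all_active <- rep(TRUE, nrow(scog_map))
  for (sp in species) {
    calls <- activity[[sp]]
    idx <- match(scog_map[[sp]], calls$gene_id)
    if (anyNA(idx)) {
      gene <- scog_map[[sp]][which(is.na(idx))[1L]]
      abort(paste0("gene '", gene, "' (species '", sp, "') has no activity call"))
    }
    all_active <- all_active & calls$active[idx]
  }
  excluded <- scog_map$cluster_id[!all_active]
  if (length(excluded) > 0L) {
    inform(paste0("excluded ", length(excluded),
                  " cluster(s) with one or more inactive members"))
  }
  list(retained = scog_map[all_active, , drop = FALSE], excluded = excluded)
}

#' Percentage summaries of expressed genes
#'
#' Given per-species totals of annotated and actively transcribed genes,
#' computes the percentage expressed, rounded to one decimal — the summary
#' arithmetic of a transcriptome-survey table.
#'
#' @param counts Tibble with columns `species`, `annotated_genes`,
#'   `expressed_genes`.
#' @return The input with an added `pct_expressed` column.
#' @export
summarize_expressed_fraction <- function(counts) {
  needed <- c("species", "annotated_genes", "expressed_genes")
  if (!all(needed %in% names(counts))) {
    abort(paste0("counts needs columns: ", paste(needed, collapse = ", ")))
  }
  if (any(counts$expressed_genes > counts$annotated_genes)) {
    abort("expressed_genes cannot exceed annotated_genes")
  }
  dplyr::mutate(counts,
    pct_expressed = round(100 * .data$expressed_genes / .data$annotated_genes, 1))
}
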