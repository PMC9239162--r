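test_that("zRPKM fit recovers the generating log2-normal parameters", {
  set.seed(11)
  fit <- fit_z_params(2^rnorm(10000, mean = 4, sd = 2))
  expect_gt(fit$mu, 3.8); expect_lt(fit$mu, 4.2)
  expect_gt(fit$sigma, 1.8); expect_lt(fit$sigma, 2.2)
  expect_gte(fit$U, fit$mu)
  # z of a value exactly at the fitted mode is 0
  expect_equal((log2(2^fit$mu) - fit$mu) / fit$sigma, 0)
})

test_that("zRPKM fit rejects degenerate input", {
  expect_error(fit_z_params(rep(8, 100)), "identical")
  expect_error(fit_z_params(c(rep(0, 100), 2^rnorm(10))), ">= 50")
})

test_that("z-transform is invariant to a multiplicative shift of a stage", {
  set.seed(12)
  n <- 400
  m <- tibble::tibble(gene_id = paste0("g", 1:n),
                      S0 = 2^rnorm(n, 4, 2), S1 = 2^rnorm(n, 5, 1.5))
  z1 <- z_transform(m)
  m2 <- dplyr::mutate(m, S0 = S0 * 2)   # shifts the log2 density by exactly 1
  z2 <- z_transform(m2)
  expect_equal(z2$S0, z1$S0, tolerance = 1e-10)
  expect_equal(z2$S1, z1$S1)
  f1 <- attr(z1, "zfits")$S0; f2 <- attr(z2, "zfits")$S0
  expect_equal(f2$mu - f1$mu, 1, tolerance = 1e-10)
  expect_equal(f2$sigma, f1$sigma, tolerance = 1e-10)
})

test_that("zero RPKM maps to a sentinel below any finite threshold", {
  set.seed(13)
  n <- 100
  m <- tibble::tibble(gene_id = paste0("g", 1:n),
                      S0 = c(0, 2^rnorm(n - 1, 4, 2)),
                      S1 = c(0, 2^rnorm(n - 1, 4, 2)))
  z <- z_transform(m)
  expect_identical(z$S0[1], -Inf)
  act <- call_activity(z)
  expect_false(act$active[1])           # all-zero gene can never be active
  expect_identical(act$mean_z[1], -Inf)
})

test_that("activity boundary is inclusive at the threshold", {
  z <- tibble::tibble(gene_id = c("at", "below", "above"),
                      S0 = c(-3, -3.01, 0), S1 = c(-3, -3.01, 0))
  act <- call_activity(z, z_threshold = -3)
  expect_equal(act$active, c(TRUE, FALSE, TRUE))
  # any_stage rule: only genes below threshold at every stage are inactive
  z2 <- tibble::tibble(gene_id = c("mixed", "allbelow"),
                       S0 = c(-10, -4), S1 = c(-2, -5))
  act2 <- call_activity(z2, rule = "any_stage")
  expect_equal(act2$active, c(TRUE, FALSE))
})

test_that("clusters with planted silent members are excluded, exactly", {
  set.seed(14)
  n <- 80; k_silent <- 3L
  species <- c("spA", "spB")
  expr <- lapply(species, function(sp) {
    vals <- matrix(2^rnorm(n * 6, 6, 1.5), n, 6)
    vals[seq_len(k_silent), ] <- 0       # first k clusters silent everywhere
    dplyr::bind_cols(tibble::tibble(gene_id = paste0(sp, "_g", 1:n)),
                     tibble::as_tibble(stats::setNames(as.data.frame(vals),
                                                       paste0("S", 0:5))))
  })
  names(expr) <- species
  scog <- tibble::tibble(cluster_id = sprintf("c%02d", 1:n),
                         spA = paste0("spA_g", 1:n), spB = paste0("spB_g", 1:n))
  activity <- lapply(expr, function(m) call_activity(z_transform(m)))
  filt <- suppressMessages(filter_scogs(scog, activity))
  expect_setequal(filt$excluded, sprintf("c%02d", seq_len(k_silent)))
  expect_equal(nrow(filt$retained), n - k_silent)
  # retained and excluded partition the input
  expect_setequal(c(filt$retained$cluster_id, filt$excluded), scog$cluster_id)

  # one inactive member among several is enough to exclude
  act_mod <- activity
  act_mod$spB$active[act_mod$spB$gene_id == "spB_g10"] <- FALSE
  filt2 <- suppressMessages(filter_scogs(scog, act_mod))
  expect_true("c10" %in% filt2$excluded)

  # missing activity call is an error
  act_bad <- activity
  act_bad$spA <- act_bad$spA[-1, ]
  expect_error(filter_scogs(scog, act_bad), "no activity call")
})

test_that("lowering the z threshold never shrinks the retained set", {
  set.seed(15)
  n <- 60
  species <- c("spA", "spB", "spC")
  expr <- lapply(species, function(sp) {
    vals <- matrix(2^rnorm(n * 6, 2, 3), n, 6)
    dplyr::bind_cols(tibble::tibble(gene_id = paste0(sp, "_g", 1:n)),
                     tibble::as_tibble(stats::setNames(as.data.frame(vals),
                                                       paste0("S", 0:5))))
  })
  names(expr) <- species
  scog <- tibble::tibble(cluster_id = sprintf("c%02d", 1:n))
  for (sp in species) scog[[sp]] <- paste0(sp, "_g", 1:n)
  zs <- lapply(expr, z_transform)
  retained_at <- function(thr) {
    act <- lapply(zs, call_activity, z_threshold = thr)
    suppressMessages(filter_scogs(scog, act))$retained$cluster_id
  }
  prev <- character(0)
  for (thr in c(0, -1, -2, -3, -5)) {
    cur <- retained_at(thr)
    expect_true(all(prev %in% cur))   # monotone growth as threshold drops
    prev <- cur
  }
  # invariance to gene and species order
  perm <- sample(n)
  scog_perm <- scog[perm, c("cluster_id", rev(species))]
  act <- lapply(zs, call_activity)
  a <- suppressMessages(filter_scogs(scog, act))
  b <- suppressMessages(filter_scogs(scog_perm, act))
  expect_setequal(a$retained$cluster_id, b$retained$cluster_id)
})

test_that("expressed-gene percentage arithmetic rounds to one decimal", {
  counts <- tibble::tibble(species = c("x", "y"),
                           annotated_genes = c(200L, 1000L),
                           expressed_genes = c(123L, 994L))
  out <- summarize_expressed_fraction(counts)
  expect_equal(out$pct_expressed, c(61.5, 99.4))
  bad <- counts; bad$expressed_genes[1] <- 300L
  expect_error(summarize_expressed_fraction(bad), "cannot exceed")
})
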