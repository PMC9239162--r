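test_that("simulated trees are ultrametric, sized right, deterministic", {
  tr <- simulate_tree(5, depth = 1, seed = 3)
  expect_equal(tr$Nnode, 4L)
  depths <- ape::node.depth.edgelength(tr)[seq_len(5)]
  expect_true(all(abs(depths - 1) < 1e-9))
  expect_identical(write_newick(simulate_tree(5, depth = 1, seed = 3)),
                   write_newick(tr))
  expect_false(identical(write_newick(simulate_tree(5, depth = 1, seed = 4)),
                         write_newick(tr)))
  expect_error(simulate_tree(1), ">= 2")
})

test_that("character evolution obeys the BM variance and covariance laws", {
  tree <- default_species_tree()
  set.seed(61)
  n_char <- 2000L
  evo <- evolve_characters(tree, rep(0, n_char), sigma2 = 1)
  # Var(tip - root) = sigma2 * depth (= 1) per tip
  for (sp in tree$tip.label) {
    expect_lt(abs(var(evo$tips[sp, ]) - 1), 0.1)
  }
  # Cov(tip_i, tip_j) = sigma2 * shared path length
  V <- ape::vcv(tree)
  shared <- V["Fgra", "Fneo"]
  expect_lt(abs(cov(evo$tips["Fgra", ], evo$tips["Fneo", ]) - shared),
            0.15 * max(shared, 1))
  shared2 <- V["Ncra", "Cglo"]
  expect_lt(abs(cov(evo$tips["Ncra", ], evo$tips["Cglo", ]) - shared2),
            0.15 * max(shared2, 1))

  # sigma2 = 0: everything equals the root
  flat <- evolve_characters(tree, c(2, -1), sigma2 = 0)
  expect_true(all(flat$tips[, 1] == 2) && all(flat$tips[, 2] == -1))
  expect_true(all(flat$nodes[, 1] == 2))
})

test_that("plant_shift touches exactly the named leaf, transition, genes", {
  tree <- default_species_tree()
  set.seed(62)
  ids <- sprintf("g%03d", 1:50)
  labs <- transition_label_set()
  evo <- evolve_characters(tree, rnorm(250), 1)
  colnames(evo$tips) <- as.vector(t(outer(ids, labs, paste, sep = "::")))

  expect_identical(plant_shift(evo$tips, tree, "Fgra", 2, 0, ids[1:5]),
                   evo$tips)
  shifted <- plant_shift(evo$tips, tree, "Fgra", 2, 4, ids[1:5])
  changed <- which(shifted != evo$tips, arr.ind = TRUE)
  expect_equal(nrow(changed), 5L)
  expect_true(all(rownames(evo$tips)[changed[, 1]] == "Fgra"))
  expect_true(all(grepl("S2−S3", colnames(evo$tips)[changed[, 2]])))
  expect_equal(shifted["Fgra", paste0(ids[1], "::S2−S3")],
               evo$tips["Fgra", paste0(ids[1], "::S2−S3")] + 4,
               ignore_attr = TRUE)
  expect_error(plant_shift(evo$tips, tree, "root", 2, 4, ids[1]), "terminal")
  expect_error(plant_shift(evo$tips, tree, "Fgra", 9, 4, ids[1]), "transition")
})

test_that("datasets are deterministic and round-trip through the readers", {
  cfg <- sim_config(n_genes = 120, seed = 101, n_planted = 5)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(emit_dataset(cfg), d1)
  write_dataset(emit_dataset(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  tree <- parse_newick(file.path(d1, "tree.nwk"))
  species <- tree$tip.label
  expr <- lapply(species, function(sp) {
    read_expression_table(file.path(d1, paste0("expr_", sp, ".tsv")), sp)
  })
  names(expr) <- species
  scog <- read_scog_map(file.path(d1, "scog_map.tsv"), species)
  expect_equal(nrow(scog), 120L)
  flags <- read_annotation_flags(file.path(d1, "flags.tsv"))
  expect_equal(nrow(flags), 120L * 5L)
  expect_true(all(unlist(scog[species]) %in% flags$gene_id))
})

test_that("silent clusters appear at the configured rate and fail activity", {
  cfg <- sim_config(n_genes = 1000, fraction_silent = 0.02, n_planted = 0,
                    seed = 7)
  ds <- emit_dataset(cfg)
  n_silent <- sum(ds$truth$genes$silent)
  # binomial tolerance around 20 of 1000
  expect_gte(n_silent, qbinom(0.001, 1000, 0.02))
  expect_lte(n_silent, qbinom(0.999, 1000, 0.02))
  act <- lapply(ds$expr, function(m) call_activity(z_transform(m)))
  filt <- suppressMessages(filter_scogs(ds$scog_map, act))
  silent_ids <- ds$truth$genes$cluster_id[ds$truth$genes$silent]
  expect_true(all(silent_ids %in% filt$excluded))
})

test_that("noiseless data recover the simulated ancestral states as rates shrink", {
  rmse_at <- function(s2) {
    cfg <- sim_config(n_genes = 150, fraction_silent = 0, n_planted = 0,
                      count_noise = FALSE, bm_rate = s2, rate_multiplier = 1,
                      seed = 5)
    ds <- emit_dataset(cfg)
    fc <- lapply(ds$expr, fold_change_table, pseudocount = 0)
    est <- ancestral_fold_changes(ds$tree, fc, ds$scog_map)
    nodes <- rownames(ds$truth$node_deltas)
    sqrt(mean((est$node_values[nodes, colnames(ds$truth$node_deltas)] -
                 ds$truth$node_deltas)^2))
  }
  errs <- vapply(c(1, 1e-2, 1e-4), rmse_at, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.05)
})

test_that("the full pipeline places planted genes near the top of the list", {
  ds <- emit_dataset(sim_config(seed = 42))
  res <- suppressMessages(
    prioritize_genes(ds$expr, ds$scog_map, ds$tree, focal_species = "Fgra"))
  truth <- ds$truth$genes
  planted <- truth$cluster_id[truth$planted]
  ranks <- res$ranking$rank[match(planted, res$ranking$cluster_id)]
  ranks[is.na(ranks)] <- nrow(res$ranking) + 1L   # excluded = worst
  expect_lte(median(ranks), 50)
  expect_equal(res$node, "root")
  expect_s3_class(glance(res), "tbl_df")
  # ranked list writes in the published shape
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_ranked_list(head(res$ranking, 25), tf)
  expect_length(readLines(tf), 26L)
})

test_that("the hypothetical class is more diverged in most replicates", {
  wins <- vapply(1:100, function(s) {
    ds <- emit_dataset(sim_config(n_genes = 120, fraction_hypothetical = 0.5,
                                  fraction_silent = 0, n_planted = 0,
                                  rate_multiplier = 4, seed = s))
    div <- divergence_table(ds$expr, ds$scog_map, ds$flags)
    mean(div$mean_euclid[div$class_label == "hypothetical"]) >
      mean(div$mean_euclid[div$class_label == "functional"])
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("configuration invariants are enforced before anything is emitted", {
  expect_error(sim_config(fraction_silent = 1), "fraction_silent")
  expect_error(sim_config(n_planted = 10, n_genes = 5), "n_planted")
  expect_error(sim_config(bm_rate = -1), "rates")
  expect_error(sim_config(planted_transition = 5), "transition")
})
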