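test_that("expression tables round-trip and reject malformed input", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tS0\tS1\tS2\tS3\tS4\tS5",
               "g1\t1.5\t2\t4\t8\t0\t32.25",
               "g2\t0\t0\t0\t0\t0\t0"), tf)
  m <- read_expression_table(tf, "spA")
  expect_equal(attr(m, "species"), "spA")
  expect_equal(attr(m, "stages"), paste0("S", 0:5))
  expect_equal(m$S5[1], 32.25)

  # canonical write -> read -> write is byte-identical
  out1 <- withr::local_tempfile(fileext = ".tsv")
  out2 <- withr::local_tempfile(fileext = ".tsv")
  write_expression_table(m, out1)
  write_expression_table(read_expression_table(out1, "spA"), out2)
  expect_identical(readLines(out1), readLines(out2))

  # header-only file: zero genes, stages kept
  hf <- withr::local_tempfile(fileext = ".tsv")
  writeLines("gene_id\tS0\tS1\tS2\tS3\tS4\tS5", hf)
  empty <- read_expression_table(hf, "spA")
  expect_equal(nrow(empty), 0L)
  expect_length(attr(empty, "stages"), 6L)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tS0\tS1", "g1\t1\t2", "g1\t3\t4"), bad)
  expect_error(read_expression_table(bad, "spA"), "duplicate gene id.*g1")
  writeLines(c("gene_id\tS0\tS1", "g1\t-1\t2"), bad)
  expect_error(read_expression_table(bad, "spA"), "negative value.*row 1.*S0")
  writeLines(c("gene_id\tS0\tS1", "g1\tx\t2"), bad)
  expect_error(read_expression_table(bad, "spA"), "non-numeric")
  writeLines(character(0), bad)
  expect_error(read_expression_table(bad, "spA"), "header")
})

test_that("newick parsing validates, floors and names nodes deterministically", {
  tr <- parse_newick("((A:1,B:1):1,C:2);")
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  expect_equal(tr$Nnode, 2L)
  root_children <- tr$edge[tr$edge[, 1] == length(tr$tip.label) + 1L, 2]
  expect_length(root_children, 2L)
  expect_true(all(nzchar(tr$node.label)))
  expect_setequal(tr$node.label, c("N1", "N2"))

  # round trip: parse(write(tree)) isomorphic with equal branch lengths
  tr2 <- parse_newick(write_newick(tr))
  expect_true(ape::all.equal.phylo(tr, tr2, use.edge.length = TRUE))

  expect_error(parse_newick("((A:1,A:1):1,C:2);"), "duplicate leaf.*A")
  expect_error(parse_newick("((A:1,B:1:1,C:2);"), "unclosed")
  expect_error(parse_newick("(A:1,B:1)):1;"), "position")
  expect_error(parse_newick("((A,B),C);"), "lengths missing")

  expect_warning(trf <- parse_newick("((A:0,B:1):1,C:2);"), "floored 1")
  expect_true(all(trf$edge.length > 0))
  expect_equal(min(trf$edge.length), 1e-8)

  # pre-existing internal names are preserved, only gaps are filled
  named <- parse_newick("((A:1,B:1)anc:1,C:2);")
  expect_true("anc" %in% named$node.label)
})

test_that("scog maps are validated strictly", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("cluster_id\tspA\tspB",
               "c1\ta1\tb1", "c2\ta2\tb2", "c3\ta3\tb3"), tf)
  m <- read_scog_map(tf, c("spA", "spB"))
  expect_equal(nrow(m), 3L)
  expect_equal(names(m), c("cluster_id", "spA", "spB"))
  expect_error(read_scog_map(tf, c("spA", "spC")), "spC")

  writeLines(c("cluster_id\tspA\tspB", "c1\ta1\t", "c2\ta2\tb2"), tf)
  expect_error(read_scog_map(tf, c("spA", "spB")), "cluster 'c1'")
  writeLines(c("cluster_id\tspA\tspB", "c1\ta1\tb1", "c2\ta1\tb2"), tf)
  expect_error(read_scog_map(tf, c("spA", "spB")), "more than one cluster")
})

test_that("ranked lists are written in the published table shape", {
  recs <- tibble::tibble(
    rank = 1:2, cluster_id = c("c2", "c1"), gene_id = c("g2", "g1"),
    fcd_linear = c(80.25, 9.549), transition_label = c("S0−S1", "S3−S4"))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_ranked_list(recs, tf)
  lines <- readLines(tf)
  expect_equal(lines[1], "rank\tcluster_id\tgene_id\tFCD\ttransition")
  expect_equal(lines[2], "1\tc2\tg2\t80.2\tS0−S1")
  expect_match(lines[3], "9.5\tS3−S4")

  write_ranked_list(recs[0, ], tf)
  expect_length(readLines(tf), 1L)    # header only

  expect_error(write_ranked_list(recs[2:1, ], tf), "sorted")
  bad <- recs; bad$rank <- c(1L, 3L)
  expect_error(write_ranked_list(bad, tf), "contiguous")
})

test_that("annotation flags default missing genes to FALSE with a warning", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tis_functional", "g1\tTRUE", "g2\t0"), tf)
  fl <- read_annotation_flags(tf)
  expect_equal(fl$is_functional, c(TRUE, FALSE))
  expect_warning(fl2 <- read_annotation_flags(tf, genes = c("g1", "g2", "g3")),
                 "1 gene")
  expect_false(fl2$is_functional[fl2$gene_id == "g3"])
  writeLines(c("gene_id\tis_functional", "g1\tmaybe"), tf)
  expect_error(read_annotation_flags(tf), "unparseable")
})

test_that("config reading merges YAML or key=value over defaults", {
  d <- read_pipeline_config()
  expect_equal(d$z_threshold, -3)
  expect_equal(d$functional_min_members, 2L)
  tf <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("z_threshold: -2.5", "fcd_scale: linear_difference"), tf)
  cfg <- read_pipeline_config(tf)
  expect_equal(cfg$z_threshold, -2.5)
  expect_equal(cfg$fcd_scale, "linear_difference")
  expect_equal(cfg$pseudocount, 1)
  kv <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("pseudocount=0.5", "seed=7"), kv)
  cfg2 <- read_pipeline_config(kv)
  expect_equal(cfg2$pseudocount, 0.5)
  expect_equal(cfg2$seed, 7)
})
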