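#' Read a per-species expression table
#'
#' Reads a tab-separated table of nonnegative expression values (RPKM) with
#' one row per gene and one column per developmental stage. The first column
#' holds gene identifiers; the remaining column names are taken as the stage
#' labels, in order (typically `S0`..`S5`).
#'
#' @param path Path to a TSV file (UTF-8, `.` decimal).
#' @param species_name Name of the species the table belongs to; attached to
#'   the result and used downstream to match SCOG members.
#'
#' @return A tibble with column `gene_id` followed by one numeric column per
#'   stage, with attributes `species` and `stages`.
#'
#' @details Malformed input is rejected rather than coerced: duplicated gene
#'   identifiers, negative, missing or non-numeric values, and tables with
#'   fewer than two stage columns are errors.
#'
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\tS0\tS1\tS2\tS3\tS4\tS5",
#'              "g1\t1\t2\t4\t8\t16\t32"), tf)
#' read_expression_table(tf, "speciesA")
#' @export
read_expression_table <- function(path, species_name) {
  stopifnot(is.character(species_name), length(species_name) == 1L)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L || !nzchar(header)) {
    abort(paste0("'", path, "': missing header row"))
  }
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE)
  if (ncol(tbl) < 3L) {
    abort(paste0("'", path, "': need a gene id column plus >= 2 stage columns, found ",
                 ncol(tbl), " column(s)"))
  }
  names(tbl)[1L] <- "gene_id"
  stages <- names(tbl)[-1L]
  dup <- tbl$gene_id[duplicated(tbl$gene_id)]
  if (length(dup) > 0L) {
    abort(paste0("'", path, "': duplicate gene id(s): ",
                 paste(unique(dup), collapse = ", ")))
  }
  for (s in stages) {
    raw <- tbl[[s]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) | !is.finite(val))
    if (length(bad) > 0L) {
      abort(paste0("'", path, "': non-numeric or missing value at row ", bad[1L],
                   " (gene '", tbl$gene_id[bad[1L]], "'), column '", s, "'"))
    }
    neg <- which(val < 0)
    if (length(neg) > 0L) {
      abort(paste0("'", path, "': negative value at row ", neg[1L],
                   " (gene '", tbl$gene_id[neg[1L]], "'), column '", s, "'"))
    }
    tbl[[s]] <- val
  }
  out <- as_tibble(tbl)
  attr(out, "species") <- species_name
  attr(out, "stages") <- stages
  out
}

#' Write an expression table in canonical form
#'
#' Inverse of [read_expression_table()]; writing then re-reading then writing
#' again is byte-identical.
#'
#' @param x Tibble as returned by [read_expression_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Parse a rooted Newick tree
#'
#' Parses a Newick string (or single-line file) into an `ape` `phylo` object,
#' validating that it is usable for ancestral reconstruction: unique leaf
#' names, a single root, and strictly positive branch lengths after flooring.
#'
#' Zero or negative branch lengths are floored to `epsilon` (with a warning
#' giving the count). Unnamed internal nodes are assigned deterministic names
#' `N1..Nk` in post-order so that any ancestor — e.g. the common ancestor of
#' two sister species — is addressable by name.
#'
#' @param text Newick string ending in `;`, or a path to a file holding one.
#' @param require_lengths Error if any branch length is absent (default TRUE).
#' @param epsilon Floor applied to non-positive branch lengths (default 1e-8).
#' @return A rooted `phylo` with `node.label` fully populated.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' tr$tip.label
#' tr$node.label
#' @export
parse_newick <- function(text, require_lengths = TRUE, epsilon = 1e-8) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!grepl("[();]", text) && file.exists(text)) {
    text <- paste(readLines(text), collapse = "")
  }
  depth <- 0L
  chars <- strsplit(text, "")[[1L]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        abort(paste0("Newick parse error: unbalanced ')' at position ", i))
      }
    }
  }
  if (depth != 0L) {
    abort(paste0("Newick parse error: ", depth,
                 " unclosed '(' by end of string (position ", length(chars), ")"))
  }
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) abort(paste0("Newick parse error: ", conditionMessage(e))))
  if (is.null(tree)) abort("Newick parse error: could not read a tree from input")
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    abort(paste0("duplicate leaf name(s): ", paste(dup, collapse = ", ")))
  }
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    if (require_lengths) {
      abort("Newick parse error: branch lengths missing (set require_lengths = FALSE to allow)")
    }
  } else {
    n_floor <- sum(tree$edge.length <= 0)
    if (n_floor > 0L) {
      warn(paste0("floored ", n_floor, " non-positive branch length(s) to ", epsilon))
      tree$edge.length[tree$edge.length <= 0] <- epsilon
    }
  }
  tree <- name_internal_nodes(tree)
  tree
}

# Deterministic names for unnamed internal nodes: N1..Nk in post-order.
name_internal_nodes <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  labs <- tree$node.label
  if (is.null(labs)) labs <- rep("", n_int)
  labs[is.na(labs)] <- ""
  po <- ape::reorder.phylo(tree, "postorder")
  int_postorder <- unique(po$edge[, 1L])          # internal nodes, post-order
  k <- 0L
  for (node in int_postorder) {
    idx <- node - n_tip
    if (!nzchar(labs[idx])) {
      repeat {
        k <- k + 1L
        cand <- paste0("N", k)
        if (!cand %in% c(tree$tip.label, labs)) break
      }
      labs[idx] <- cand
    }
  }
  # root may not appear as a parent in 2-tip trees handled above; any leftovers:
  for (idx in which(!nzchar(labs))) {
    repeat {
      k <- k + 1L
      cand <- paste0("N", k)
      if (!cand %in% c(tree$tip.label, labs)) break
    }
    labs[idx] <- cand
  }
  if (anyDuplicated(labs)) {
    abort(paste0("duplicate internal node name(s): ",
                 paste(unique(labs[duplicated(labs)]), collapse = ", ")))
  }
  tree$node.label <- labs
  tree
}

#' Write a tree as Newick
#'
#' @param tree A `phylo`.
#' @param path Optional file path; if `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to file.
#' @export
write_newick <- function(tree, path = NULL) {
  s <- ape::write.tree(tree)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' Read a single-copy ortholog (SCOG) map
#'
#' Reads a TSV whose first column is the cluster id and remaining columns are
#' species, each cell holding that species' (single) member gene id.
#'
#' @param path TSV path.
#' @param expected_species Character vector of species the map must cover;
#'   the result is restricted to these columns, in this order.
#' @return Tibble with columns `cluster_id` then one per species.
#' @details Errors: a species column absent; an empty/missing cell (the
#'   cluster is named); a gene id appearing in more than one cluster;
#'   duplicated cluster ids.
#' @export
read_scog_map <- function(path, expected_species) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  names(tbl)[1L] <- "cluster_id"
  missing_sp <- setdiff(expected_species, names(tbl))
  if (length(missing_sp) > 0L) {
    abort(paste0("'", path, "': species column(s) absent: ",
                 paste(missing_sp, collapse = ", ")))
  }
  tbl <- tbl[, c("cluster_id", expected_species)]
  if (anyDuplicated(tbl$cluster_id)) {
    abort(paste0("duplicate cluster id(s): ",
                 paste(unique(tbl$cluster_id[duplicated(tbl$cluster_id)]), collapse = ", ")))
  }
  for (sp in expected_species) {
    bad <- which(is.na(tbl[[sp]]) | !nzchar(tbl[[sp]]))
    if (length(bad) > 0L) {
      abort(paste0("cluster '", tbl$cluster_id[bad[1L]],
                   "' has no member for species '", sp, "'"))
    }
  }
  all_genes <- unlist(tbl[expected_species], use.names = FALSE)
  if (anyDuplicated(all_genes)) {
    dup <- unique(all_genes[duplicated(all_genes)])
    abort(paste0("gene id(s) assigned to more than one cluster: ",
                 paste(head(dup, 5L), collapse = ", ")))
  }
  tbl
}

#' Read per-gene domain-annotation flags
#'
#' Reads a two-column TSV (`gene_id`, `is_functional`) of booleans recording
#' whether a gene carries at least one predicted protein domain at the
#' stringent E-value cutoff used for functional classification.
#'
#' @param path TSV path.
#' @param genes Optional character vector of gene ids that must be covered;
#'   genes absent from the file are filled in as `FALSE` with a warning
#'   giving the count.
#' @return Tibble with columns `gene_id`, `is_functional` (logical).
#' @export
read_annotation_flags <- function(path, genes = NULL) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(tbl) < 2L) abort(paste0("'", path, "': need gene_id and is_functional columns"))
  names(tbl)[1:2] <- c("gene_id", "is_functional")
  if (anyDuplicated(tbl$gene_id)) {
    abort(paste0("duplicate gene id(s) in flags: ",
                 paste(unique(tbl$gene_id[duplicated(tbl$gene_id)]), collapse = ", ")))
  }
  flag <- toupper(trimws(tbl$is_functional))
  parsed <- ifelse(flag %in% c("TRUE", "T", "1", "YES"), TRUE,
                   ifelse(flag %in% c("FALSE", "F", "0", "NO"), FALSE, NA))
  if (anyNA(parsed)) {
    bad <- which(is.na(parsed))[1L]
    abort(paste0("'", path, "': unparseable boolean '", tbl$is_functional[bad],
                 "' for gene '", tbl$gene_id[bad], "'"))
  }
  out <- tibble(gene_id = tbl$gene_id, is_functional = as.logical(parsed))
  if (!is.null(genes)) {
    absent <- setdiff(genes, out$gene_id)
    if (length(absent) > 0L) {
      warn(paste0(length(absent), " gene(s) missing annotation flags; treated as not functional"))
      out <- dplyr::bind_rows(out, tibble(gene_id = absent, is_functional = FALSE))
    }
    out <- out[match(genes, out$gene_id), ]
  }
  out
}

#' Write a ranked priority list
#'
#' Writes ranked fold-change-differential records as a TSV shaped like a
#' published priority table: columns `rank`, `cluster_id`, `gene_id`,
#' `FCD` (linear scale, one decimal) and `transition` (e.g. `"S0−S1"`).
#'
#' @param records Tibble from [rank_clusters()], sorted by `rank`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @details Input must already be sorted by rank with contiguous ranks
#'   `1..N`; anything else is an error, so silent re-ordering never hides an
#'   upstream ranking bug.
#' @export
write_ranked_list <- function(records, path) {
  needed <- c("rank", "cluster_id", "gene_id", "fcd_linear", "transition_label")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0L) {
    abort(paste0("records lack column(s): ", paste(missing_cols, collapse = ", ")))
  }
  n <- nrow(records)
  if (n > 0L) {
    if (is.unsorted(records$rank, strictly = TRUE)) {
      abort("records must be sorted by rank (strictly increasing)")
    }
    if (!identical(as.integer(records$rank), seq_len(n))) {
      abort("ranks must be contiguous 1..N")
    }
  }
  out <- tibble(
    rank = as.integer(records$rank),
    cluster_id = records$cluster_id,
    gene_id = records$gene_id,
    FCD = sprintf("%.1f", records$fcd_linear),
    transition = records$transition_label
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read an ortholog presence/absence matrix
#'
#' First column `gene_id`, remaining columns reference taxa, cells boolean.
#'
#' @param path TSV path.
#' @return Tibble with `gene_id` and one logical column per taxon.
#' @export
read_presence_matrix <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  names(tbl)[1L] <- "gene_id"
  if (anyDuplicated(tbl$gene_id)) {
    abort("duplicate gene id(s) in presence matrix")
  }
  for (tx in names(tbl)[-1L]) {
    flag <- toupper(trimws(tbl[[tx]]))
    parsed <- ifelse(flag %in% c("TRUE", "T", "1", "YES"), TRUE,
                     ifelse(flag %in% c("FALSE", "F", "0", "NO"), FALSE, NA))
    if (anyNA(parsed)) abort(paste0("unparseable boolean in taxon column '", tx, "'"))
    tbl[[tx]] <- as.logical(parsed)
  }
  tbl
}

#' Read the pipeline configuration
#'
#' Accepts either a YAML file or a flat `key=value` file and merges it over
#' the package defaults.
#'
#' @param path Config file path, or `NULL` for pure defaults.
#' @return Named list with at least `z_threshold`, `pseudocount`, `epsilon`,
#'   `functional_min_members`, `fcd_scale`, `seed`.
#' @export
read_pipeline_config <- function(path = NULL) {
  defaults <- list(
    z_threshold = -3,
    pseudocount = 1,
    epsilon = 1e-8,
    functional_min_members = 2L,
    fcd_scale = "log2",
    seed = NULL
  )
  if (is.null(path)) return(defaults)
  lines <- readLines(path)
  body <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  if (length(body) > 0L && all(grepl("=", body)) && !any(grepl(":", body))) {
    kv <- strsplit(body, "=", fixed = TRUE)
    user <- lapply(kv, function(p) {
      v <- trimws(paste(p[-1L], collapse = "="))
      num <- suppressWarnings(as.numeric(v))
      if (!is.na(num)) num else v
    })
    names(user) <- vapply(kv, function(p) trimws(p[1L]), character(1L))
  } else {
    user <- yaml::read_yaml(path)
  }
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0L) {
    warn(paste0("ignoring unknown config key(s): ", paste(unknown, collapse = ", ")))
    user <- user[intersect(names(user), names(defaults))]
  }
  utils::modifyList(defaults, user)
}
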