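#' Pipeline configuration
#'
#' Bundles every option of the end-to-end workflow. By default the input
#' is simulated with [simulate_evolution()]; alternatively, gene tables,
#' family tables and native detector outputs can be supplied as paths.
#'
#' @param sim a [sim_config()] (used unless `gene_tables` is given).
#' @param gene_tables optional named character vector of per-species
#'   gene-order files (GFF3-like).
#' @param families_tsv optional family table path (first clustering).
#' @param abc optional abc similarity file (clustered with
#'   [mcl_cluster()] for the second clustering).
#' @param types_tsv,go_tsv optional label / annotation tables (defaults
#'   come from the simulation truth).
#' @param tree optional newick path for tip annotation.
#' @param mcscanx_collinearity,iadhore_dirs optional named vectors of
#'   native detector outputs (names = clustering provenance labels); when
#'   given, the built-in detector stage is skipped for that detector.
#' @param perturb_merge,perturb_split rates for deriving the alternative
#'   clustering from truth when no `families_tsv`/`abc` input is given.
#' @param profiles list of two [detector_profile()]s.
#' @param cross_removal see [build_network()].
#' @param damping,convits,maxits,preference consensus options.
#' @param focal_type,min_frac,min_size,q_cut,combine_cutoff enrichment
#'   options.
#' @param flank genes on each side of a region member counted as its
#'   syntenic-region neighbourhood in GO enrichment.
#' @param seed master seed.
#' @param out_dir output directory (NULL = no files written).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), gene_tables = NULL,
                            families_tsv = NULL, abc = NULL,
                            types_tsv = NULL, go_tsv = NULL, tree = NULL,
                            mcscanx_collinearity = NULL,
                            iadhore_dirs = NULL,
                            perturb_merge = 0.02, perturb_split = 0.02,
                            profiles = list(profile_mcscanx(),
                                            profile_iadhore()),
                            cross_removal = "exact",
                            damping = 0.9, convits = 100L,
                            maxits = 2000L, preference = "median",
                            focal_type = "R-4-C", min_frac = 0.15,
                            min_size = 10L, q_cut = 0.2,
                            combine_cutoff = 0.375, flank = 3L,
                            seed = sim$seed, out_dir = NULL) {
  for (p in c(gene_tables, families_tsv, abc, types_tsv, go_tsv, tree,
              mcscanx_collinearity, iadhore_dirs)) {
    if (!is.null(p) && !file.exists(p)) stop("input path not found: ", p)
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full synteny-network pipeline
#'
#' Simulate-or-load gene orders; derive two family clusterings; detect
#' collinear blocks under two detector profiles for each clustering (or
#' import native outputs); call tandems, collapse regions, build the
#' weighted multi-evidence network; find consensus clusters; run
#' reaction-type and GO enrichment; export artifacts and a JSON summary.
#'
#' @param config a [pipeline_config()].
#' @return list with elements dataset (or gene_table), families, links,
#'   tandems, regions, network, stats, consensus, type_enrichment,
#'   go_enrichment, summary, and written file paths (if `out_dir` set).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- config
  stage <- "input"
  res <- list()
  on.exit({
    if (!is.null(attr(res, "failed_stage")))
      message("pipeline aborted in stage: ", attr(res, "failed_stage"))
  })
  fail <- function(stage, e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)

  # --- input ------------------------------------------------------------
  dataset <- NULL
  if (is.null(cfg$gene_tables)) {
    dataset <- simulate_evolution(cfg$sim)
    gene_table <- dataset$gene_table
    truth <- family_assignment(dataset$truth_families, "truth")
    type_labels <- dataset$type_labels
    go <- dataset$go_annotations
    focal <- focal_genes(dataset)
    tree <- dataset$tree
  } else {
    gene_table <- read_gene_tables(cfg$gene_tables)
    if (is.null(cfg$families_tsv))
      stop("families_tsv is required with imported gene tables")
    truth <- read_family_table(cfg$families_tsv, provenance = "imported")
    type_labels <- if (!is.null(cfg$types_tsv))
      read_type_labels(cfg$types_tsv) else character(0)
    go <- if (!is.null(cfg$go_tsv)) read_go_annotations(cfg$go_tsv)
          else list()
    focal_fams <- unique(truth$mapping[names(type_labels)])
    focal <- names(truth$mapping)[truth$mapping %in% focal_fams]
    tree <- if (!is.null(cfg$tree)) ape::read.tree(cfg$tree) else NULL
  }
  res$gene_table <- gene_table
  res$dataset <- dataset

  # --- families: two clusterings ---------------------------------------
  stage <- "families"
  fam_a <- truth
  fam_b <- tryCatch({
    if (!is.null(cfg$abc)) {
      mcl_cluster(load_abc(cfg$abc))
    } else if (!is.null(dataset)) {
      mcl_cluster(abc_graph(simulate_similarity_graph(dataset,
                                                      seed = cfg$seed)))
    } else {
      perturb_family_assignment(truth, cfg$perturb_merge,
                                cfg$perturb_split, cfg$seed)
    }
  }, error = function(e) fail(stage, e))
  clusterings <- c(fam_a$provenance, fam_b$provenance)
  res$families <- list(fam_a, fam_b)

  # --- synteny: two detectors x two clusterings ------------------------
  stage <- "synteny"
  detectors <- vapply(cfg$profiles, `[[`, character(1), "name")
  species <- unique(gene_table$species)
  links <- list()
  tandems <- list()
  for (ci in 1:2) {
    fam <- list(fam_a, fam_b)[[ci]]
    for (di in 1:2) {
      prof <- cfg$profiles[[di]]
      label <- paste(detectors[di], clusterings[ci], sep = "+")
      native <- switch(detectors[di],
                       mcscanx = cfg$mcscanx_collinearity[clusterings[ci]],
                       iadhore = cfg$iadhore_dirs[clusterings[ci]])
      if (!is.null(native) && !is.na(native)) {
        blocks <- if (detectors[di] == "mcscanx")
          parse_mcscanx_collinearity(native, clusterings[ci])
        else parse_iadhore_output(native, clusterings[ci])
        links[[label]] <- blocks_to_links(blocks, focal, label)
      } else {
        per_pair <- list()
        for (i in seq_along(species)) {
          for (j in i:length(species)) {
            ga <- gene_table[gene_table$species == species[i], ,
                             drop = FALSE]
            gb <- gene_table[gene_table$species == species[j], ,
                             drop = FALSE]
            blocks <- detect_synteny(ga, gb, fam, prof)
            if (nrow(blocks))
              per_pair[[length(per_pair) + 1L]] <-
                blocks_to_links(blocks, focal, label)
          }
        }
        lk <- do.call(rbind, per_pair)
        if (is.null(lk))
          lk <- data.frame(gene_a = character(0), gene_b = character(0),
                           method = character(0))
        lk <- lk[!duplicated(paste(lk$gene_a, lk$gene_b)), , drop = FALSE]
        links[[label]] <- lk
      }
      tandems[[label]] <- call_tandems(gene_table, fam, prof$tandem_gap)
    }
  }
  res$links <- links
  res$tandems <- tandems

  # --- network ----------------------------------------------------------
  stage <- "network"
  regions <- tryCatch(
    merge_tandem_regions(tandems, focal, gene_table),
    error = function(e) fail(stage, e))
  net <- tryCatch(
    build_network(links, regions, detectors = detectors,
                  clusterings = clusterings,
                  cross_removal = cfg$cross_removal),
    error = function(e) fail(stage, e))
  res$regions <- regions
  res$network <- net
  res$stats <- network_stats(net)

  # --- consensus --------------------------------------------------------
  stage <- "consensus"
  cons <- tryCatch(
    consensus_clusters(net, damping = cfg$damping, convits = cfg$convits,
                       maxits = cfg$maxits, preference = cfg$preference),
    error = function(e) fail(stage, e))
  res$consensus <- cons

  # --- enrichment -------------------------------------------------------
  stage <- "enrichment"
  sel <- select_type_clusters(cons, regions, type_labels,
                              cfg$focal_type, cfg$min_frac, cfg$min_size)
  res$selected_clusters <- sel
  res$type_enrichment <- if (length(sel))
    type_enrichment(cons, regions, type_labels, cfg$focal_type,
                    selected = sel) else NULL
  if (length(go)) {
    fg <- region_neighborhood_genes(net, regions, gene_table, cfg$flank)
    bg <- gene_table$gene
    res$go_enrichment <- go_enrichment(fg, bg, go, design = "PKS-BG",
                                       exclude = focal)
    res$term_network <- term_similarity_network(res$go_enrichment,
                                                q_cut = cfg$q_cut,
                                                combine_cutoff =
                                                  cfg$combine_cutoff)
  }

  # --- report -----------------------------------------------------------
  stage <- "report"
  st <- res$stats
  res$summary <- list(
    n_species = length(species), n_genes = nrow(gene_table),
    n_focal = length(focal), methods = net$methods,
    n_vertices = st$n_vertices, n_edges = st$n_edges,
    possible_edges = st$possible_edges, density_pct = st$density_pct,
    max_tandem_size = st$max_tandem_size,
    n_clusters = length(cons$exemplars),
    consensus_converged = cons$converged,
    selected_clusters = sel,
    type_odds_ratio = if (!is.null(res$type_enrichment))
      res$type_enrichment$odds_ratio else NULL,
    type_p = if (!is.null(res$type_enrichment))
      res$type_enrichment$p else NULL)

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- c(
      graphml = export_network(net, file.path(cfg$out_dir, "network.graphml"),
                               "graphml"),
      edges = export_network(net, file.path(cfg$out_dir, "edges.tsv"),
                             "edgelist"),
      regions = export_network(net, file.path(cfg$out_dir, "regions.tsv"),
                               "regions"),
      membership = write_membership(cons,
                                    file.path(cfg$out_dir,
                                              "membership.tsv")))
    jsonlite::write_json(res$summary,
                         file.path(cfg$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
    log_lines <- c(
      paste("syntnet", as.character(utils::packageVersion("syntnet"))),
      paste("igraph", as.character(utils::packageVersion("igraph"))),
      paste("seed", cfg$seed),
      paste("consensus converged:", cons$converged,
            "iterations:", cons$iterations))
    writeLines(log_lines, file.path(cfg$out_dir, "run.log"))
    res$paths <- c(paths,
                   summary = file.path(cfg$out_dir, "summary.json"),
                   log = file.path(cfg$out_dir, "run.log"))
  }
  if (!is.null(tree) && !is.null(dataset)) res$tree <- tree
  res
}

# genes within `flank` positions of any member of a network region
region_neighborhood_genes <- function(network, regions, gene_table,
                                      flank = 3L) {
  members <- unlist(strsplit(network$vertices$members, ";", fixed = TRUE))
  loc <- gene_table[match(members, gene_table$gene), , drop = FALSE]
  key <- paste(gene_table$species, gene_table$chromosome)
  out <- character(0)
  for (i in seq_len(nrow(loc))) {
    near <- which(key == paste(loc$species[i], loc$chromosome[i]) &
                  abs(gene_table$pos - loc$pos[i]) <= flank)
    out <- c(out, gene_table$gene[near])
  }
  unique(out)
}

#' Annotate a gene tree with cluster membership and type labels
#'
#' Tip labels are suffixed `|<cluster>|<type>`; unmatched tips are
#' annotated `NA` and reported. Stripping the suffixes recovers the input
#' tree.
#'
#' @param tree a phylo object, newick text, or path to a newick file.
#' @param clusters named vector gene -> cluster id (e.g. from
#'   [cluster_genes()] via a consensus assignment).
#' @param type_labels named vector gene -> type label.
#' @return list with `tree` (annotated phylo), `table` (gene, cluster,
#'   type), `unmatched` (character).
#' @export
annotate_tree <- function(tree, clusters, type_labels = character(0)) {
  if (is.character(tree)) {
    tr <- if (file.exists(tree[1])) ape::read.tree(tree)
          else tryCatch(suppressWarnings(ape::read.tree(text = tree)),
                        error = function(e) NULL)
    if (is.null(tr)) stop("malformed newick input")
    tree <- tr
  }
  tips <- tree$tip.label
  cl <- clusters[tips]
  ty <- if (length(type_labels)) type_labels[tips]
        else rep(NA_character_, length(tips))
  tab <- data.frame(gene = tips, cluster = unname(cl),
                    type = unname(ty), stringsAsFactors = FALSE)
  unmatched <- tips[is.na(cl)]
  tree$tip.label <- sprintf("%s|%s|%s", tips,
                            ifelse(is.na(cl), "NA", cl),
                            ifelse(is.na(ty), "NA", ty))
  list(tree = tree, table = tab, unmatched = unmatched)
}

#' Gene-level cluster membership from a consensus assignment
#'
#' @param assignment a `consensus_assignment` over regions.
#' @param regions the corresponding [merge_tandem_regions()] table.
#' @return named integer vector gene -> cluster id.
#' @export
gene_clusters <- function(assignment, regions) {
  cluster_genes(assignment, regions)
}
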