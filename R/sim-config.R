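#' Simulation configuration
#'
#' Parameters of the genome-evolution simulator. A single ancestral genome
#' is evolved along a species tree; on every branch, whole-genome
#' duplication, segmental duplication, gene loss, inversion, translocation
#' and tandem duplication act in a fixed order, each driven by its own
#' reproducible random stream keyed by `(seed, branch, event type)` so that
#' changing one rate perturbs the other event sequences minimally.
#'
#' Event rates are expected event counts per branch (`wgd_probability` is a
#' per-branch probability). The focal family (or families) is planted in the
#' ancestor as `contexts_per_focal` copies embedded in distinct conserved
#' neighbourhoods, so downstream synteny analysis has at least two distinct
#' syntenic contexts to recover.
#'
#' @param seed integer master seed; identical configurations produce
#'   bit-identical datasets.
#' @param species_tree either an integer (number of leaves of a random
#'   tree) or newick text.
#' @param chromosomes_per_genome,genes_per_chromosome ancestral genome
#'   dimensions.
#' @param n_families number of background homology families.
#' @param focal_family_count number of focal families (network analysis
#'   targets the first).
#' @param segmental_duplication,tandem_duplication,gene_loss,inversion,translocation
#'   expected events per branch (Poisson, inversion-sampled).
#' @param wgd_probability per-branch probability of a whole-genome
#'   duplication.
#' @param segmental_window genes per duplicated/rearranged window.
#' @param tandem_max_copies ceiling on the size of one tandem array.
#' @param contexts_per_focal ancestral copies (distinct syntenic contexts)
#'   planted per focal family.
#' @param type_labels character vector of reaction-type labels; focal genes
#'   descending from ancestral context `i` are labelled
#'   `type_labels[min(i, length(type_labels))]`.
#' @param noise standard deviation of the log10 E-value noise used by
#'   [simulate_similarity_graph()].
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       species_tree = 6L,
                       chromosomes_per_genome = 3L,
                       genes_per_chromosome = 200L,
                       n_families = 150L,
                       focal_family_count = 1L,
                       segmental_duplication = 0.5,
                       wgd_probability = 0,
                       tandem_duplication = 2,
                       gene_loss = 1,
                       inversion = 0.5,
                       translocation = 0.25,
                       segmental_window = 8L,
                       tandem_max_copies = 23L,
                       contexts_per_focal = 2L,
                       type_labels = c("R-4-C", "Other"),
                       noise = 0.5) {
  cfg <- list(seed = as.integer(seed), species_tree = species_tree,
              chromosomes_per_genome = as.integer(chromosomes_per_genome),
              genes_per_chromosome = as.integer(genes_per_chromosome),
              n_families = as.integer(n_families),
              focal_family_count = as.integer(focal_family_count),
              segmental_duplication = segmental_duplication,
              wgd_probability = wgd_probability,
              tandem_duplication = tandem_duplication,
              gene_loss = gene_loss, inversion = inversion,
              translocation = translocation,
              segmental_window = as.integer(segmental_window),
              tandem_max_copies = as.integer(tandem_max_copies),
              contexts_per_focal = as.integer(contexts_per_focal),
              type_labels = as.character(type_labels),
              noise = noise)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  rates <- c("segmental_duplication", "wgd_probability", "tandem_duplication",
             "gene_loss", "inversion", "translocation", "noise")
  for (r in rates) {
    if (!is.numeric(cfg[[r]]) || length(cfg[[r]]) != 1L || cfg[[r]] < 0)
      stop("sim_config: '", r, "' must be a single non-negative number")
  }
  if (cfg$wgd_probability > 1)
    stop("sim_config: 'wgd_probability' must be in [0, 1]")
  pos <- c("chromosomes_per_genome", "genes_per_chromosome", "n_families",
           "focal_family_count", "segmental_window", "tandem_max_copies",
           "contexts_per_focal")
  for (p in pos) {
    if (is.na(cfg[[p]]) || cfg[[p]] < 1L)
      stop("sim_config: '", p, "' must be a positive integer")
  }
  if (cfg$segmental_window > cfg$genes_per_chromosome)
    stop("sim_config: 'segmental_window' cannot exceed 'genes_per_chromosome'")
  if (is.numeric(cfg$species_tree) && cfg$species_tree < 1)
    stop("sim_config: species tree must have at least one leaf")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: seed", x$seed, "|",
      if (is.numeric(x$species_tree)) paste(x$species_tree, "species")
      else "user tree", "|",
      x$chromosomes_per_genome, "chr x", x$genes_per_chromosome, "genes |",
      x$n_families, "families,", x$focal_family_count, "focal\n")
  invisible(x)
}

# Resolve the species tree of a config into an ape phylo object.
sim_species_tree <- function(cfg) {
  st <- cfg$species_tree
  if (inherits(st, "phylo")) return(st)
  if (is.character(st)) {
    tr <- tryCatch(ape::read.tree(text = st), error = function(e) NULL)
    if (is.null(tr)) stop("invalid newick species tree")
    return(tr)
  }
  n <- as.integer(st)
  if (n == 1L) {
    return(structure(list(edge = matrix(c(2L, 1L), 1L, 2L),
                          tip.label = "s1", Nnode = 1L, edge.length = 1),
                     class = "phylo"))
  }
  tr <- with_seed(sub_seed(cfg$seed, "tree"), ape::rtree(n))
  tr$tip.label <- sprintf("s%d", seq_len(n))
  tr
}
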