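# Programmatic fixtures shared across test files.

# a single-chromosome gene table from a vector of family ids
chrom_table <- function(families, species = "spA", chromosome = "chr1",
                        prefix = "g") {
  data.frame(gene = sprintf("%s_%s%03d", species, prefix,
                            seq_along(families)),
             species = species, chromosome = chromosome,
             pos = seq_along(families) - 1L, strand = "+",
             stringsAsFactors = FALSE)
}

# named family vector aligned with chrom_table() genes
chrom_families <- function(tab, families) {
  stats::setNames(as.character(families), tab$gene)
}

# desk-scale simulation used by pipeline-level tests
small_sim <- function(seed) {
  sim_config(seed = seed, species_tree = 4, chromosomes_per_genome = 2,
             genes_per_chromosome = 120, n_families = 60,
             tandem_duplication = 1, gene_loss = 0.5)
}

# context purity of a consensus clustering against simulator truth:
# TRUE when no consensus cluster mixes focal genes of different ancestral
# contexts
context_purity_ok <- function(result) {
  gc <- gene_clusters(result$consensus, result$regions)
  ctx <- sub("^(ctx[0-9]+).*$", "\\1", result$dataset$truth_regions)
  common <- intersect(names(gc), names(ctx))
  all(tapply(ctx[common], gc[common],
             function(x) length(unique(x)) == 1L))
}

# toy four-method link table between two single-gene regions
toy_two_region_input <- function(methods) {
  gt <- rbind(chrom_table(c("X", "F1", "Y"), species = "spA"),
              chrom_table(c("Z", "F1", "W"), species = "spB"))
  focal <- gt$gene[c(2, 5)]
  regions <- merge_tandem_regions(list(), focal, gt)
  links <- do.call(rbind, lapply(methods, function(m)
    data.frame(gene_a = min(focal), gene_b = max(focal), method = m,
               stringsAsFactors = FALSE)))
  list(gene_table = gt, focal = focal, regions = regions, links = links)
}
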