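#' Simulate genome evolution along a species tree
#'
#' Evolves a single ancestral genome along the configured species tree.
#' Every branch applies, in a fixed order, whole-genome duplication,
#' segmental duplication, gene loss, inversion, translocation and (last)
#' tandem duplication. Each duplication of a focal gene opens a new syntenic
#' context recorded in `truth_regions`; tandem copies stay in their parent's
#' context. All events are appended to `truth_events`.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `synthetic_dataset` with elements
#'   `gene_table` (gene, species, chromosome, pos, strand), `truth_families`
#'   (named vector gene -> family), `truth_events` (data frame of branch
#'   events), `truth_regions` (named vector focal gene -> context id),
#'   `type_labels` (named vector focal gene -> reaction-type label),
#'   `go_annotations` (named list gene -> GO term vector), `tree` (phylo)
#'   and `config`.
#' @export
simulate_evolution <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  validate_sim_config(config)
  tree <- sim_species_tree(config)
  if (length(tree$tip.label) < 1L) stop("species tree has no leaves")

  env <- new.env(parent = emptyenv())
  env$counter <- 0L
  env$ctx_counter <- 0L
  env$events <- list()
  env$leaves <- list()

  ancestor <- build_ancestor(config, env)
  root <- length(tree$tip.label) + 1L
  evolve_node(root, ancestor, tree, config, env)

  finalize_dataset(config, tree, env)
}

new_gene_ids <- function(env, n) {
  ids <- sprintf("g%06d", env$counter + seq_len(n))
  env$counter <- env$counter + n
  ids
}

# Ancestral genome: list of chromosomes, each a data.frame
# (gene, family, strand, context). context is NA for non-focal genes.
build_ancestor <- function(cfg, env) {
  with_seed(sub_seed(cfg$seed, "ancestor"), {
    nchr <- cfg$chromosomes_per_genome
    len <- cfg$genes_per_chromosome
    total <- nchr * len
    fams <- sprintf("F%04d", seq_len(cfg$n_families))
    assignment <- sample(rep_len(fams, total))
    strands <- sample(c("+", "-"), total, replace = TRUE)
    genes <- new_gene_ids(env, total)
    context <- rep(NA_character_, total)

    # plant focal families: contexts_per_focal copies each, spaced so their
    # neighbourhoods are distinct
    k <- cfg$contexts_per_focal * cfg$focal_family_count
    min_dist <- max(2L * cfg$segmental_window, 10L)
    slots <- integer(0)
    tries <- 0L
    while (length(slots) < k && tries < 10000L) {
      cand <- sample.int(total, 1L)
      if (all(abs(cand - slots) >= min_dist)) slots <- c(slots, cand)
      tries <- tries + 1L
    }
    if (length(slots) < k)
      stop("could not place focal genes; genome too small for spacing")
    slots <- sort(slots)
    i <- 0L
    for (f in seq_len(cfg$focal_family_count)) {
      for (j in seq_len(cfg$contexts_per_focal)) {
        i <- i + 1L
        env$ctx_counter <- env$ctx_counter + 1L
        assignment[slots[i]] <- sprintf("FOC%d", f)
        context[slots[i]] <- sprintf("ctx%d", env$ctx_counter)
      }
    }

    genome <- vector("list", nchr)
    names(genome) <- sprintf("chr%d", seq_len(nchr))
    for (c in seq_len(nchr)) {
      idx <- ((c - 1L) * len + 1L):(c * len)
      genome[[c]] <- data.frame(gene = genes[idx], family = assignment[idx],
                                strand = strands[idx], context = context[idx],
                                stringsAsFactors = FALSE)
    }
    env$ancestor_size <- total
    genome
  })
}

evolve_node <- function(node, genome, tree, cfg, env) {
  children <- tree$edge[tree$edge[, 1] == node, 2]
  if (length(children) == 0L) {
    env$leaves[[tree$tip.label[node]]] <- genome
    return(invisible(NULL))
  }
  for (child in children) {
    branch <- which(tree$edge[, 1] == node & tree$edge[, 2] == child)[1]
    g2 <- evolve_branch(genome, branch, cfg, env)
    evolve_node(child, g2, tree, cfg, env)
  }
  invisible(NULL)
}

record_event <- function(env, branch, kind, chromosome, position, n_change) {
  env$events[[length(env$events) + 1L]] <-
    data.frame(branch = branch, kind = kind, chromosome = chromosome,
               position = position, n_change = n_change,
               stringsAsFactors = FALSE)
}

# Poisson count via inversion so that raising the rate with the same seed
# never decreases the count (monotone coupling).
stream_count <- function(rate) qpois(runif(1L), rate)

genome_sizes <- function(genome) vapply(genome, nrow, integer(1))

# pick a (chromosome, row) from a uniform in (0,1]
pick_position <- function(genome, u) {
  sizes <- genome_sizes(genome)
  total <- sum(sizes)
  idx <- min(max(1L, ceiling(u * total)), total)
  cum <- cumsum(sizes)
  chrom <- which(idx <= cum)[1]
  row <- idx - c(0L, cum)[chrom]
  list(chrom = chrom, row = row)
}

copy_rows <- function(rows, env, ctx_suffix) {
  rows$gene <- new_gene_ids(env, nrow(rows))
  focal <- !is.na(rows$context)
  rows$context[focal] <- paste0(rows$context[focal], ctx_suffix)
  rows
}

insert_rows <- function(chrom_df, rows, at) {
  # insert after row `at` (0 = prepend)
  if (at <= 0L) rbind(rows, chrom_df)
  else if (at >= nrow(chrom_df)) rbind(chrom_df, rows)
  else rbind(chrom_df[seq_len(at), , drop = FALSE], rows,
             chrom_df[(at + 1L):nrow(chrom_df), , drop = FALSE])
}

evolve_branch <- function(genome, branch, cfg, env) {
  # whole-genome duplication
  with_seed(sub_seed(cfg$seed, "branch", branch, "wgd"), {
    if (runif(1L) < cfg$wgd_probability) {
      dup <- lapply(genome, copy_rows, env = env,
                    ctx_suffix = sprintf(".w%d", branch))
      names(dup) <- paste0(names(genome), sprintf("w%d", branch))
      record_event(env, branch, "wgd", NA_character_, NA_integer_,
                   sum(genome_sizes(genome)))
      genome <- c(genome, dup)
    }
  })

  # segmental duplications
  with_seed(sub_seed(cfg$seed, "branch", branch, "segmental"), {
    n <- stream_count(cfg$segmental_duplication)
    for (i in seq_len(n)) {
      u <- runif(4L)
      src <- pick_position(genome, u[1])
      w <- min(cfg$segmental_window, nrow(genome[[src$chrom]]))
      start <- min(src$row, nrow(genome[[src$chrom]]) - w + 1L)
      rows <- genome[[src$chrom]][start:(start + w - 1L), , drop = FALSE]
      rows <- copy_rows(rows, env, sprintf(".s%d.%d", branch, i))
      dest <- pick_position(genome, u[3])
      genome[[dest$chrom]] <- insert_rows(genome[[dest$chrom]], rows,
                                          dest$row)
      record_event(env, branch, "segmental", names(genome)[src$chrom],
                   start, w)
    }
  })

  # gene loss
  with_seed(sub_seed(cfg$seed, "branch", branch, "loss"), {
    n <- stream_count(cfg$gene_loss)
    for (i in seq_len(n)) {
      u <- runif(1L)
      if (sum(genome_sizes(genome)) <= 1L) break
      p <- pick_position(genome, u)
      record_event(env, branch, "loss", names(genome)[p$chrom], p$row, -1L)
      genome[[p$chrom]] <- genome[[p$chrom]][-p$row, , drop = FALSE]
    }
  })

  # inversions
  with_seed(sub_seed(cfg$seed, "branch", branch, "inversion"), {
    n <- stream_count(cfg$inversion)
    for (i in seq_len(n)) {
      u <- runif(1L)
      p <- pick_position(genome, u)
      len <- nrow(genome[[p$chrom]])
      w <- min(cfg$segmental_window, len)
      start <- min(p$row, len - w + 1L)
      idx <- start:(start + w - 1L)
      seg <- genome[[p$chrom]][rev(idx), , drop = FALSE]
      seg$strand <- ifelse(seg$strand == "+", "-", "+")
      genome[[p$chrom]][idx, ] <- seg
      record_event(env, branch, "inversion", names(genome)[p$chrom],
                   start, 0L)
    }
  })

  # translocations
  with_seed(sub_seed(cfg$seed, "branch", branch, "translocation"), {
    n <- stream_count(cfg$translocation)
    for (i in seq_len(n)) {
      u <- runif(4L)
      src <- pick_position(genome, u[1])
      len <- nrow(genome[[src$chrom]])
      w <- min(cfg$segmental_window, len)
      if (len <= w) next
      start <- min(src$row, len - w + 1L)
      idx <- start:(start + w - 1L)
      rows <- genome[[src$chrom]][idx, , drop = FALSE]
      genome[[src$chrom]] <- genome[[src$chrom]][-idx, , drop = FALSE]
      dest <- pick_position(genome, u[3])
      at <- if (dest$chrom == src$chrom)
        min(dest$row, nrow(genome[[dest$chrom]])) else dest$row
      genome[[dest$chrom]] <- insert_rows(genome[[dest$chrom]], rows, at)
      record_event(env, branch, "translocation", names(genome)[src$chrom],
                   start, 0L)
    }
  })

  # tandem duplications (last, so extra tandem events only append copies)
  with_seed(sub_seed(cfg$seed, "branch", branch, "tandem"), {
    n <- stream_count(cfg$tandem_duplication)
    for (i in seq_len(n)) {
      u <- runif(2L)
      target <- NULL
      focal_tab <- focal_positions(genome)
      if (u[1] < 0.5 && nrow(focal_tab) > 0L) {
        j <- min(max(1L, ceiling(u[2] * nrow(focal_tab))), nrow(focal_tab))
        target <- list(chrom = focal_tab$chrom[j], row = focal_tab$row[j])
      } else {
        target <- pick_position(genome, u[2])
      }
      chrom_df <- genome[[target$chrom]]
      fam <- chrom_df$family[target$row]
      run <- same_family_run(chrom_df$family, target$row)
      if (length(run) >= cfg$tandem_max_copies) next
      rows <- chrom_df[target$row, , drop = FALSE]
      rows$gene <- new_gene_ids(env, 1L)  # tandem copy keeps its context
      genome[[target$chrom]] <- insert_rows(chrom_df, rows, target$row)
      record_event(env, branch, "tandem", names(genome)[target$chrom],
                   target$row, 1L)
    }
  })

  genome
}

# table of focal gene positions (chrom index, row index)
focal_positions <- function(genome) {
  out <- data.frame(chrom = integer(0), row = integer(0))
  for (c in seq_along(genome)) {
    rows <- which(!is.na(genome[[c]]$context))
    if (length(rows))
      out <- rbind(out, data.frame(chrom = c, row = rows))
  }
  out
}

# indices of the maximal run of identical family values containing `row`
same_family_run <- function(fams, row) {
  fam <- fams[row]
  lo <- row
  while (lo > 1L && fams[lo - 1L] == fam) lo <- lo - 1L
  hi <- row
  while (hi < length(fams) && fams[hi + 1L] == fam) hi <- hi + 1L
  lo:hi
}

finalize_dataset <- function(cfg, tree, env) {
  species <- tree$tip.label
  tabs <- list()
  families <- character(0)
  regions <- character(0)
  for (sp in species) {
    genome <- env$leaves[[sp]]
    for (ch in names(genome)) {
      df <- genome[[ch]]
      if (nrow(df) == 0L) next
      ids <- sprintf("%s_%s", sp, df$gene)
      tabs[[length(tabs) + 1L]] <-
        data.frame(gene = ids, species = sp, chromosome = ch,
                   pos = seq_len(nrow(df)) - 1L, strand = df$strand,
                   stringsAsFactors = FALSE)
      families[ids] <- df$family
      focal <- which(!is.na(df$context))
      if (length(focal)) regions[ids[focal]] <- df$context[focal]
    }
  }
  gene_table <- do.call(rbind, tabs)
  rownames(gene_table) <- NULL

  # reaction-type labels: focal genes inherit the label of their ancestral
  # context (context id prefix "ctx<i>")
  anc_idx <- as.integer(sub("^ctx(\\d+).*$", "\\1", regions))
  type_labels <- setNames(
    cfg$type_labels[pmin(anc_idx, length(cfg$type_labels))], names(regions))

  go <- simulate_go_annotations(cfg, gene_table, regions, anc_idx)

  ev <- if (length(env$events)) do.call(rbind, env$events)
        else data.frame(branch = integer(0), kind = character(0),
                        chromosome = character(0), position = integer(0),
                        n_change = integer(0))
  structure(list(gene_table = gene_table, truth_families = families,
                 truth_events = ev, truth_regions = regions,
                 type_labels = type_labels, go_annotations = go,
                 tree = tree, ancestor_size = env$ancestor_size,
                 config = cfg),
            class = "synthetic_dataset")
}

# background GO terms plus one planted term per ancestral focal context,
# attached to genes within +-3 positions of each focal gene
simulate_go_annotations <- function(cfg, gene_table, regions, anc_idx) {
  with_seed(sub_seed(cfg$seed, "go"), {
    pool <- sprintf("GO:%07d", seq_len(40L))
    go <- lapply(seq_len(nrow(gene_table)), function(i)
      sample(pool, sample.int(3L, 1L)))
    names(go) <- gene_table$gene
    if (length(regions)) {
      key <- paste(gene_table$species, gene_table$chromosome)
      for (k in seq_along(regions)) {
        g <- names(regions)[k]
        row <- match(g, gene_table$gene)
        near <- which(key == key[row] &
                      abs(gene_table$pos - gene_table$pos[row]) <= 3L)
        term <- sprintf("GO:%07d", 1000000L + anc_idx[k])
        for (j in near) go[[j]] <- union(go[[j]], term)
      }
    }
    go
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset:", length(unique(x$gene_table$species)),
      "species,", nrow(x$gene_table), "genes,",
      length(x$truth_regions), "focal genes in",
      length(unique(x$truth_regions)), "contexts,",
      nrow(x$truth_events), "events\n")
  invisible(x)
}

#' Focal genes of a synthetic dataset
#'
#' @param dataset a `synthetic_dataset`.
#' @return character vector of focal gene identifiers.
#' @export
focal_genes <- function(dataset) names(dataset$truth_regions)

#' Simulate an all-vs-all homology similarity table
#'
#' Emits an "abc"-style table (query, subject, E-value). Within-family
#' pairs receive E-values around 1e-50 on the log10 scale with Gaussian
#' noise of spread `noise`; a small fraction of cross-family pairs receive
#' weak spurious hits (E-value in (0.1, 10]). E-values are clipped to
#' (1e-300, 10].
#'
#' @param dataset a `synthetic_dataset`.
#' @param noise log10-scale noise spread (>= 0); defaults to the
#'   configuration's value.
#' @param seed integer seed for the noise stream.
#' @param spurious_rate fraction of random cross-family pairs receiving a
#'   weak hit.
#' @return data.frame with columns query, subject, evalue.
#' @export
simulate_similarity_graph <- function(dataset, noise = dataset$config$noise,
                                      seed = dataset$config$seed,
                                      spurious_rate = 0.0005) {
  if (noise < 0) stop("noise must be non-negative")
  fams <- dataset$truth_families
  genes <- names(fams)
  if (length(genes) < 2L)
    return(data.frame(query = character(0), subject = character(0),
                      evalue = numeric(0)))
  with_seed(sub_seed(seed, "abc", round(noise * 1000)), {
    qs <- list()
    by_fam <- split(genes, fams)
    for (members in by_fam) {
      m <- length(members)
      if (m < 2L) next
      idx <- utils::combn(m, 2L)
      qs[[length(qs) + 1L]] <-
        data.frame(query = members[idx[1, ]], subject = members[idx[2, ]],
                   score = 50 + rnorm(ncol(idx), 0, noise),
                   stringsAsFactors = FALSE)
    }
    n_spur <- qpois(runif(1L), spurious_rate * length(genes)^2 / 2)
    if (n_spur > 0L) {
      a <- sample(genes, n_spur, replace = TRUE)
      b <- sample(genes, n_spur, replace = TRUE)
      keep <- a != b & fams[a] != fams[b]
      if (any(keep))
        qs[[length(qs) + 1L]] <-
          data.frame(query = a[keep], subject = b[keep],
                     score = runif(sum(keep), 0, 1),
                     stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, qs)
    if (is.null(out))
      return(data.frame(query = character(0), subject = character(0),
                        evalue = numeric(0)))
    ev <- 10^(-out$score)
    out$evalue <- pmin(pmax(ev, 1e-300), 10)
    out$score <- NULL
    rownames(out) <- NULL
    out
  })
}

#' Perturb a family assignment by random merges and splits
#'
#' Produces a second, imperfect family mapping from a reference one, to
#' emulate the disagreement between two independent homology clusterings
#' (e.g. orthogroup inference versus Markov clustering) that drives the
#' multi-evidence grid of the synteny network.
#'
#' @param truth named character vector gene -> family (or a
#'   `family_assignment`).
#' @param merge_rate,split_rate probabilities in \[0, 1\] that a family is
#'   merged into another / split in two.
#' @param seed integer seed.
#' @return a [family_assignment()] with provenance `"perturbed"`.
#' @export
perturb_family_assignment <- function(truth, merge_rate = 0.05,
                                      split_rate = 0.05, seed = 1L) {
  if (inherits(truth, "family_assignment")) truth <- truth$mapping
  if (merge_rate < 0 || merge_rate > 1 || split_rate < 0 || split_rate > 1)
    stop("merge_rate and split_rate must be in [0, 1]")
  mapping <- truth
  with_seed(sub_seed(seed, "perturb"), {
    fams <- sort(unique(mapping))
    # merges: each family may be absorbed into another surviving family
    if (length(fams) > 1L && merge_rate > 0) {
      for (f in fams) {
        if (runif(1L) < merge_rate) {
          others <- setdiff(unique(mapping), f)
          if (length(others) == 0L) break
          target <- others[min(length(others),
                               max(1L, ceiling(runif(1L) * length(others))))]
          mapping[mapping == f] <- target
        }
      }
    }
    # splits: a family of size >= 2 splits into two halves
    if (split_rate > 0) {
      for (f in sort(unique(mapping))) {
        members <- sort(names(mapping)[mapping == f])
        if (length(members) >= 2L && runif(1L) < split_rate) {
          half <- members[seq_len(length(members) %/% 2L)]
          mapping[half] <- paste0(f, ".b")
        }
      }
    }
  })
  family_assignment(mapping, provenance = "perturbed")
}
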