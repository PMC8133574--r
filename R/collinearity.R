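#' Detector profiles for collinear-block detection
#'
#' One anchor-chaining algorithm emulates both classical detectors through
#' parameter profiles. `profile_mcscanx()` mirrors the published MCScanX
#' settings (MATCH_SCORE=50, MATCH_SIZE=5, GAP_PENALTY=-1, MAX GAPS=25);
#' `profile_iadhore()` mirrors the published i-ADHoRe settings
#' (anchor_points=5, gap_size=15, max_gaps_in_alignment=20). Neither
#' reproduces the original tools' block significance statistics - native
#' outputs can be imported with [parse_mcscanx_collinearity()] /
#' [parse_iadhore_output()] instead.
#'
#' @param name profile label attached to blocks.
#' @param min_anchors minimum anchors per reported block (>= 2).
#' @param max_gap maximum intervening non-anchor genes between consecutive
#'   anchors, per genome.
#' @param max_gaps_total maximum total skipped genes per block (both
#'   genomes summed).
#' @param match_score score per anchor.
#' @param gap_penalty score per skipped gene (<= 0).
#' @param tandem_gap maximum intervening genes between two same-family
#'   genes for a tandem call.
#' @return object of class `detector_profile`.
#' @export
detector_profile <- function(name, min_anchors = 5L, max_gap = 25L,
                             max_gaps_total = 25L, match_score = 50,
                             gap_penalty = -1, tandem_gap = 1L) {
  if (min_anchors < 2L) stop("min_anchors must be >= 2")
  if (gap_penalty > 0) stop("gap_penalty must be <= 0")
  if (tandem_gap < 0L) stop("tandem_gap must be >= 0")
  structure(list(name = as.character(name),
                 min_anchors = as.integer(min_anchors),
                 max_gap = as.integer(max_gap),
                 max_gaps_total = as.integer(max_gaps_total),
                 match_score = match_score, gap_penalty = gap_penalty,
                 tandem_gap = as.integer(tandem_gap)),
            class = "detector_profile")
}

#' @rdname detector_profile
#' @export
profile_mcscanx <- function() {
  detector_profile("mcscanx", min_anchors = 5L, max_gap = 25L,
                   max_gaps_total = 25L, match_score = 50, gap_penalty = -1,
                   tandem_gap = 1L)
}

#' @rdname detector_profile
#' @export
profile_iadhore <- function() {
  detector_profile("iadhore", min_anchors = 5L, max_gap = 15L,
                   max_gaps_total = 20L, match_score = 50, gap_penalty = -1,
                   tandem_gap = 1L)
}

#' Find family anchors between two chromosome gene orders
#'
#' Anchors are all cross positions whose genes share a family. When the two
#' inputs are the same chromosome of the same genome, identity pairs are
#' excluded and each unordered pair is listed once (`pos_a < pos_b`).
#'
#' @param chrom_a,chrom_b data.frames with columns gene, pos (0-based
#'   ordinals), as one chromosome of a gene table.
#' @param families a [family_assignment()] (or named vector); genes without
#'   a family yield no anchors.
#' @param self logical: are the two inputs the same chromosome of the same
#'   genome? Defaults to detecting identical gene id sets.
#' @return data.frame with columns gene_a, pos_a, gene_b, pos_b, family.
#' @export
find_anchors <- function(chrom_a, chrom_b, families, self = NULL) {
  mapping <- if (inherits(families, "family_assignment")) families$mapping
             else families
  fa <- mapping[chrom_a$gene]
  fb <- mapping[chrom_b$gene]
  if (is.null(self))
    self <- identical(sort(chrom_a$gene), sort(chrom_b$gene))
  empty <- data.frame(gene_a = character(0), pos_a = integer(0),
                      gene_b = character(0), pos_b = integer(0),
                      family = character(0))
  da <- data.frame(gene_a = chrom_a$gene, pos_a = chrom_a$pos,
                   family = unname(fa), stringsAsFactors = FALSE)
  db <- data.frame(gene_b = chrom_b$gene, pos_b = chrom_b$pos,
                   family = unname(fb), stringsAsFactors = FALSE)
  da <- da[!is.na(da$family), , drop = FALSE]
  db <- db[!is.na(db$family), , drop = FALSE]
  if (nrow(da) == 0L || nrow(db) == 0L) return(empty)
  res <- merge(da, db, by = "family")
  if (self) res <- res[res$pos_b > res$pos_a, , drop = FALSE]
  if (nrow(res) == 0L) return(empty)
  res <- res[, c("gene_a", "pos_a", "gene_b", "pos_b", "family")]
  res <- res[order(res$pos_a, res$pos_b), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Chain anchors into collinear blocks
#'
#' Dynamic program over anchors sorted by a-ordinal: a chain extends when
#' `0 < delta_a <= max_gap+1` and `0 < |delta_b| <= max_gap+1` with a
#' consistent sign (the block orientation); block score is
#' `match_score * n_anchors + gap_penalty * total_skipped_genes`. Maximal
#' blocks with at least `min_anchors` anchors and total skipped genes
#' within `max_gaps_total` are reported greedily by descending score (ties:
#' smaller first a-ordinal, then forward orientation); each anchor joins at
#' most one block.
#'
#' @param anchors data.frame from [find_anchors()].
#' @param profile a [detector_profile()].
#' @return data.frame (class `collinear_blocks`) with one row per anchor:
#'   block, gene_a, pos_a, gene_b, pos_b, family, orientation, score.
#' @export
chain_anchors <- function(anchors, profile) {
  empty <- empty_blocks()
  if (nrow(anchors) == 0L) return(empty)
  res <- chain_anchors_cpp(as.integer(anchors$pos_a),
                           as.integer(anchors$pos_b),
                           profile$min_anchors, profile$max_gap,
                           profile$max_gaps_total, profile$match_score,
                           profile$gap_penalty)
  if (length(res) == 0L) return(empty)
  out <- lapply(seq_along(res), function(k) {
    b <- res[[k]]
    idx <- b$idx + 1L
    data.frame(block = k, gene_a = anchors$gene_a[idx],
               pos_a = anchors$pos_a[idx], gene_b = anchors$gene_b[idx],
               pos_b = anchors$pos_b[idx], family = anchors$family[idx],
               orientation = b$orientation, score = b$score,
               stringsAsFactors = FALSE)
  })
  blocks <- do.call(rbind, out)
  rownames(blocks) <- NULL
  class(blocks) <- c("collinear_blocks", "data.frame")
  blocks
}

empty_blocks <- function() {
  structure(data.frame(block = integer(0), gene_a = character(0),
                       pos_a = integer(0), gene_b = character(0),
                       pos_b = integer(0), family = character(0),
                       orientation = integer(0), score = numeric(0)),
            class = c("collinear_blocks", "data.frame"))
}

#' Detect synteny between two genomes
#'
#' Runs [find_anchors()] and [chain_anchors()] over every chromosome pair
#' of the two genomes. When both genomes are the same species, self
#' chromosome pairs are included (intragenomic duplications) and each
#' unordered chromosome pair is compared once. Blocks carry the detector
#' profile name and the family-assignment provenance as their method label.
#'
#' @param genome_a,genome_b gene tables (data.frame: gene, species,
#'   chromosome, pos, strand), each of a single species.
#' @param families a [family_assignment()].
#' @param profile a [detector_profile()].
#' @return `collinear_blocks` data.frame with additional columns species_a,
#'   chrom_a, species_b, chrom_b, detector, provenance.
#' @export
detect_synteny <- function(genome_a, genome_b, families, profile) {
  for (g in list(genome_a, genome_b)) {
    if (length(unique(g$species)) > 1L)
      stop("each genome must belong to a single species")
  }
  sp_a <- genome_a$species[1]
  sp_b <- genome_b$species[1]
  same_species <- identical(sp_a, sp_b)
  chrs_a <- sort(unique(genome_a$chromosome))
  chrs_b <- sort(unique(genome_b$chromosome))
  prov <- if (inherits(families, "family_assignment")) families$provenance
          else "unknown"
  out <- list()
  nb <- 0L
  for (ca in chrs_a) {
    for (cb in chrs_b) {
      if (same_species && cb < ca) next  # unordered pairs once
      sub_a <- genome_a[genome_a$chromosome == ca, , drop = FALSE]
      sub_b <- genome_b[genome_b$chromosome == cb, , drop = FALSE]
      anchors <- find_anchors(sub_a, sub_b, families,
                              self = same_species && ca == cb)
      blocks <- chain_anchors(anchors, profile)
      if (nrow(blocks) == 0L) next
      blocks$block <- blocks$block + nb
      nb <- max(blocks$block)
      blocks$species_a <- sp_a
      blocks$chrom_a <- ca
      blocks$species_b <- sp_b
      blocks$chrom_b <- cb
      out[[length(out) + 1L]] <- blocks
    }
  }
  if (length(out) == 0L) {
    res <- empty_blocks()
    res$species_a <- character(0); res$chrom_a <- character(0)
    res$species_b <- character(0); res$chrom_b <- character(0)
    res$detector <- character(0); res$provenance <- character(0)
    return(res)
  }
  res <- do.call(rbind, out)
  res$detector <- profile$name
  res$provenance <- prov
  rownames(res) <- NULL
  class(res) <- c("collinear_blocks", "data.frame")
  res
}

#' Call tandem duplicate pairs
#'
#' Emits one call for every same-chromosome, same-family gene pair
#' separated by at most `tandem_gap` intervening genes.
#'
#' @param genome gene table (one or more species).
#' @param families a [family_assignment()].
#' @param tandem_gap maximum intervening genes (>= 0).
#' @return data.frame with columns gene_a, gene_b, species, chromosome.
#' @export
call_tandems <- function(genome, families, tandem_gap = 1L) {
  if (tandem_gap < 0L) stop("tandem_gap must be >= 0")
  mapping <- if (inherits(families, "family_assignment")) families$mapping
             else families
  out <- list()
  for (key in unique(paste(genome$species, genome$chromosome, sep = "\r"))) {
    sc <- strsplit(key, "\r", fixed = TRUE)[[1]]
    sub <- genome[genome$species == sc[1] & genome$chromosome == sc[2], ,
                  drop = FALSE]
    sub <- sub[order(sub$pos), , drop = FALSE]
    fam <- mapping[sub$gene]
    n <- nrow(sub)
    for (i in seq_len(n)) {
      if (is.na(fam[i])) next
      j <- i + 1L
      while (j <= n && sub$pos[j] - sub$pos[i] - 1L <= tandem_gap) {
        if (!is.na(fam[j]) && fam[j] == fam[i]) {
          out[[length(out) + 1L]] <-
            data.frame(gene_a = sub$gene[i], gene_b = sub$gene[j],
                       species = sc[1], chromosome = sc[2],
                       stringsAsFactors = FALSE)
        }
        j <- j + 1L
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      species = character(0), chromosome = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Extract focal-gene synteny links from collinear blocks
#'
#' For every anchor whose two genes are both focal-family members, emits
#' one link tagged with the method label, deduplicated per unordered gene
#' pair.
#'
#' @param blocks a `collinear_blocks` data.frame.
#' @param focal_genes character vector of focal gene ids.
#' @param method_label method label, conventionally
#'   `"<detector>+<clustering>"`; defaults to the blocks' own labels.
#' @return data.frame with columns gene_a, gene_b (gene_a < gene_b),
#'   method.
#' @export
blocks_to_links <- function(blocks, focal_genes, method_label = NULL) {
  if (is.null(method_label)) {
    method_label <- if (nrow(blocks) > 0L && "detector" %in% names(blocks))
      paste(blocks$detector[1], blocks$provenance[1], sep = "+")
    else "unknown"
  }
  keep <- blocks$gene_a %in% focal_genes & blocks$gene_b %in% focal_genes
  sub <- blocks[keep, , drop = FALSE]
  if (nrow(sub) == 0L)
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      method = character(0)))
  a <- pmin(sub$gene_a, sub$gene_b)
  b <- pmax(sub$gene_a, sub$gene_b)
  keep2 <- !duplicated(paste(a, b, sep = "\r")) & a != b
  data.frame(gene_a = a[keep2], gene_b = b[keep2], method = method_label,
             stringsAsFactors = FALSE, row.names = NULL)
}
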