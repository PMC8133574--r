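#' Build a 2x2 contingency table
#'
#' Counts are (a, b, c, d) = (focal in, focal out, non-focal in,
#' non-focal out); rows are focal/non-focal, columns in/out.
#'
#' @param a,b,c,d non-negative integer counts.
#' @return 2x2 integer matrix.
#' @export
contingency_table <- function(a, b, c, d) {
  m <- matrix(as.integer(c(a, c, b, d)), nrow = 2,
              dimnames = list(c("focal", "other"), c("inside", "outside")))
  if (any(m < 0)) stop("counts must be non-negative")
  m
}

#' One-sided (greater) Fisher's exact test
#'
#' Upper hypergeometric tail probability of the observed top-left count
#' with all margins fixed, plus the conditional maximum-likelihood odds
#' ratio (the R `fisher.test` convention) and the sample odds ratio
#' `ad/bc`. An all-zero table returns p = 1 and an NaN odds ratio with a
#' `degenerate` flag.
#'
#' @param table 2x2 matrix (see [contingency_table()]).
#' @return list with `odds_ratio` (conditional MLE), `sample_or`, `p`,
#'   `degenerate`.
#' @export
fisher_one_sided <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2L, 2L))) stop("need a 2x2 table")
  if (any(m < 0)) stop("counts must be non-negative")
  if (sum(m) == 0L)
    return(list(odds_ratio = NaN, sample_or = NaN, p = 1,
                degenerate = TRUE))
  ft <- stats::fisher.test(m, alternative = "greater")
  list(odds_ratio = unname(ft$estimate),
       sample_or = (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1]),
       p = ft$p.value, degenerate = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment `q(i) = min_{j >= i} (m / rank(j)) p(j)`, capped
#' at 1, in the input order.
#'
#' @param pvalues numeric vector in \[0, 1\].
#' @return adjusted q-values, same order and length.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

# expand a consensus assignment over regions to gene level
cluster_genes <- function(assignment, regions) {
  reg_cluster <- assignment$clusters
  sub <- regions[regions$region %in% names(reg_cluster), , drop = FALSE]
  setNames(unname(reg_cluster[sub$region]), sub$gene)
}

#' Select clusters enriched in a focal reaction type
#'
#' A cluster qualifies when strictly more than `min_frac` of its genes
#' carry the focal type label and it contains at least `min_size` genes
#' (region members count individually).
#'
#' @param assignment a `consensus_assignment` over regions.
#' @param regions the [merge_tandem_regions()] table (maps regions to
#'   member genes).
#' @param type_labels named character vector gene -> type label; genes
#'   without a label count as non-focal.
#' @param focal_type the label of interest, e.g. `"R-4-C"`.
#' @param min_frac strict lower bound on the focal-type fraction.
#' @param min_size minimum genes per cluster.
#' @return integer vector of qualifying cluster ids.
#' @export
select_type_clusters <- function(assignment, regions, type_labels,
                                 focal_type = "R-4-C", min_frac = 0.15,
                                 min_size = 10L) {
  gc <- cluster_genes(assignment, regions)
  is_focal <- !is.na(type_labels[names(gc)]) &
    type_labels[names(gc)] == focal_type
  sizes <- table(gc)
  focal_by_cluster <- tapply(is_focal, gc, sum)
  ids <- as.integer(names(sizes))
  frac <- as.numeric(focal_by_cluster[names(sizes)]) /
    as.numeric(sizes)
  sort(ids[frac > min_frac & as.integer(sizes) >= min_size])
}

#' Reaction-type enrichment in selected clusters
#'
#' Tests over-representation of a focal reaction type inside a set of
#' clusters against the rest of the network: the 2x2 table counts
#' focal-type versus other genes, inside versus outside the selected
#' clusters, restricted to genes present in the network (i.e. members of
#' network regions); [fisher_one_sided()] is applied.
#'
#' @inheritParams select_type_clusters
#' @param selected cluster ids to test; defaults to
#'   [select_type_clusters()] with the given thresholds.
#' @param min_frac,min_size selection thresholds (used when `selected` is
#'   NULL).
#' @return one-row data.frame of class `enrichment_result`: label, a, b,
#'   c, d, odds_ratio, sample_or, p, q, design.
#' @export
type_enrichment <- function(assignment, regions, type_labels,
                            focal_type = "R-4-C", selected = NULL,
                            min_frac = 0.15, min_size = 10L) {
  if (is.null(selected))
    selected <- select_type_clusters(assignment, regions, type_labels,
                                     focal_type, min_frac, min_size)
  if (length(selected) == 0L) stop("no clusters selected for enrichment")
  gc <- cluster_genes(assignment, regions)
  is_focal <- !is.na(type_labels[names(gc)]) &
    type_labels[names(gc)] == focal_type
  inside <- gc %in% selected
  tab <- contingency_table(sum(is_focal & inside), sum(is_focal & !inside),
                           sum(!is_focal & inside),
                           sum(!is_focal & !inside))
  ft <- fisher_one_sided(tab)
  res <- data.frame(label = focal_type, a = tab[1, 1], b = tab[1, 2],
                    c = tab[2, 1], d = tab[2, 2],
                    odds_ratio = ft$odds_ratio, sample_or = ft$sample_or,
                    p = ft$p, q = ft$p, design = "type",
                    stringsAsFactors = FALSE)
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' GO-term enrichment of a foreground gene set
#'
#' For each GO term present in the foreground, a one-sided (greater)
#' Fisher test of the 2x2 gene-count table (term/not-term x
#' foreground/background-rest) is run, followed by Benjamini-Hochberg
#' adjustment across all tested terms of the design. Supports the three
#' foreground/background designs of the workflow (focal syntenic regions
#' vs all syntenic genes or all genes, `PKS-BG`; type-enriched clusters vs
#' background, `CHS-BG`; type-enriched clusters vs focal syntenic regions,
#' `CHS-PKS`) via the `design` label, and focal-gene removal via
#' `exclude`.
#'
#' @param foreground character vector of genes (must be a subset of
#'   `background`).
#' @param background character vector of genes (the universe).
#' @param annotations named list gene -> character vector of GO terms.
#' @param design label recorded on the results.
#' @param exclude genes removed from foreground and background before
#'   testing (e.g. the focal-family genes themselves).
#' @return data.frame of class `enrichment_result` (term, a, b, c, d,
#'   odds_ratio, p, q, design), ordered by p; per-term foreground gene
#'   sets attached as attribute `term_genes`.
#' @export
go_enrichment <- function(foreground, background, annotations,
                          design = "PKS-BG", exclude = NULL) {
  if (!all(foreground %in% background))
    stop("foreground must be a subset of background")
  foreground <- setdiff(unique(foreground), exclude)
  background <- setdiff(unique(background), exclude)
  fg_ann <- annotations[intersect(foreground, names(annotations))]
  bg_ann <- annotations[intersect(background, names(annotations))]
  terms <- sort(unique(unlist(fg_ann)))
  empty <- data.frame(term = character(0), a = integer(0), b = integer(0),
                      c = integer(0), d = integer(0),
                      odds_ratio = numeric(0), p = numeric(0),
                      q = numeric(0), design = character(0))
  if (length(terms) == 0L) {
    class(empty) <- c("enrichment_result", "data.frame")
    return(empty)
  }
  n_fg <- length(foreground)
  n_bg <- length(background)
  bg_terms <- lapply(bg_ann, unique)
  bg_flat <- data.frame(gene = rep(names(bg_terms),
                                   lengths(bg_terms)),
                        term = unlist(bg_terms, use.names = FALSE),
                        stringsAsFactors = FALSE)
  fg_set <- foreground
  rows <- lapply(terms, function(tm) {
    with_term <- bg_flat$gene[bg_flat$term == tm]
    a <- sum(with_term %in% fg_set)
    b <- n_fg - a
    c <- length(with_term) - a
    d <- n_bg - n_fg - c
    ft <- fisher_one_sided(contingency_table(a, b, c, d))
    data.frame(term = tm, a = a, b = b, c = c, d = d,
               odds_ratio = ft$odds_ratio, p = ft$p, q = NA_real_,
               design = design, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- bh_adjust(res$p)
  term_genes <- lapply(terms, function(tm)
    intersect(bg_flat$gene[bg_flat$term == tm], fg_set))
  names(term_genes) <- terms
  res <- res[order(res$p, res$term), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "term_genes") <- term_genes
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Enrichment-map style term-similarity network
#'
#' Nodes are terms passing the FDR cutoff; edge weight between two terms
#' is `0.5 * Jaccard + 0.5 * overlap coefficient` of their (foreground)
#' gene sets, and edges at or above `combine_cutoff` are kept.
#'
#' @param results a [go_enrichment()] result (with `term_genes`
#'   attribute), or NULL if `term_genes` is given directly.
#' @param q_cut FDR q-value cutoff for term inclusion.
#' @param combine_cutoff minimum combined similarity for an edge.
#' @param term_genes optional named list term -> gene set, overriding the
#'   attribute.
#' @return data.frame with columns term_a, term_b, weight.
#' @export
term_similarity_network <- function(results = NULL, q_cut = 0.2,
                                    combine_cutoff = 0.375,
                                    term_genes = NULL) {
  if (is.null(term_genes)) term_genes <- attr(results, "term_genes")
  if (is.null(term_genes)) stop("per-term gene sets are required")
  terms <- names(term_genes)
  if (!is.null(results)) {
    keep <- results$term[results$q < q_cut]
    terms <- intersect(terms, keep)
  }
  empty <- data.frame(term_a = character(0), term_b = character(0),
                      weight = numeric(0))
  if (length(terms) < 2L) return(empty)
  out <- list()
  for (i in seq_len(length(terms) - 1L)) {
    for (j in (i + 1L):length(terms)) {
      A <- unique(term_genes[[terms[i]]])
      B <- unique(term_genes[[terms[j]]])
      inter <- length(intersect(A, B))
      uni <- length(union(A, B))
      jac <- if (uni > 0) inter / uni else 0
      ov <- if (min(length(A), length(B)) > 0)
        inter / min(length(A), length(B)) else 0
      w <- 0.5 * jac + 0.5 * ov
      if (w >= combine_cutoff)
        out[[length(out) + 1L]] <-
          data.frame(term_a = terms[i], term_b = terms[j], weight = w,
                     stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
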