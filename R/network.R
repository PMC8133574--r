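#' Collapse tandem calls into tandem gene regions
#'
#' The union of tandem calls over all methods is taken; connected
#' components of the resulting gene graph become multi-gene regions
#' ("genes that form a component"); focal genes never called tandem become
#' singleton regions. Region ids are `"<species>:<chromosome>:<min pos>"`.
#'
#' @param tandem_calls data.frame of calls (gene_a, gene_b) or a list of
#'   such data.frames (one per method); calls whose genes lie on different
#'   chromosomes are rejected.
#' @param focal_genes character vector of focal gene ids (the vertex
#'   universe).
#' @param gene_table gene table covering the focal genes.
#' @return data.frame (class `tandem_regions`) with one row per member
#'   gene: region, species, chromosome, gene, pos.
#' @export
merge_tandem_regions <- function(tandem_calls, focal_genes, gene_table) {
  if (is.data.frame(tandem_calls)) tandem_calls <- list(tandem_calls)
  calls <- do.call(rbind, lapply(tandem_calls, function(d)
    d[, c("gene_a", "gene_b"), drop = FALSE]))
  if (is.null(calls))
    calls <- data.frame(gene_a = character(0), gene_b = character(0))
  calls <- calls[calls$gene_a %in% focal_genes &
                 calls$gene_b %in% focal_genes, , drop = FALSE]
  gt <- gene_table[gene_table$gene %in% focal_genes, , drop = FALSE]
  missing <- setdiff(focal_genes, gt$gene)
  if (length(missing))
    stop("focal genes absent from gene table: ",
         paste(utils::head(missing, 3), collapse = ", "))
  loc <- gt[match(focal_genes, gt$gene), , drop = FALSE]
  rownames(loc) <- focal_genes
  if (nrow(calls)) {
    bad <- loc[calls$gene_a, "chromosome"] != loc[calls$gene_b,
                                                  "chromosome"] |
           loc[calls$gene_a, "species"] != loc[calls$gene_b, "species"]
    if (any(bad))
      stop("tandem call spans chromosomes: ", calls$gene_a[bad][1], " - ",
           calls$gene_b[bad][1])
  }
  g <- igraph::graph_from_data_frame(
    calls, directed = FALSE,
    vertices = data.frame(name = focal_genes))
  comp <- igraph::components(g)$membership
  out <- data.frame(gene = focal_genes,
                    species = loc$species, chromosome = loc$chromosome,
                    pos = loc$pos, comp = comp[focal_genes],
                    stringsAsFactors = FALSE)
  region_id <- vapply(split(out, out$comp), function(d)
    sprintf("%s:%s:%d", d$species[1], d$chromosome[1], min(d$pos)),
    character(1))
  out$region <- region_id[as.character(out$comp)]
  out <- out[order(out$region, out$pos),
             c("region", "species", "chromosome", "gene", "pos")]
  rownames(out) <- NULL
  class(out) <- c("tandem_regions", "data.frame")
  out
}

#' Build the weighted multi-evidence synteny network
#'
#' Gene-level links are lifted to tandem regions. For each of the four
#' detector x clustering method combinations, 0.25 is added to a region
#' pair's weight if that method supports at least one link between them
#' (at most one increment per method per pair). Edges whose support set is
#' exactly one of the two "crossed" pairs - the combinations in which the
#' two detectors agree only under different clusterings - are removed;
#' vertices left without any edge are dropped.
#'
#' @param links data.frame (gene_a, gene_b, method) or list of such
#'   data.frames; method labels must be `"<detector>+<clustering>"` over
#'   the two detectors and two clusterings given.
#' @param regions a [merge_tandem_regions()] result.
#' @param detectors,clusterings character vectors of length 2 naming the
#'   evidence grid.
#' @param cross_removal `"exact"` removes an edge only when its support
#'   set equals a crossed pair; `"none"` disables the filter.
#' @return object of class `synteny_network`: list with `vertices`
#'   (region, species, chromosome, size, members), `edges` (from, to,
#'   weight, support), `methods`, and the full (unpruned) region table as
#'   attribute `all_regions`.
#' @export
build_network <- function(links, regions,
                          detectors = c("mcscanx", "iadhore"),
                          clusterings = c("orthofinder", "mcl"),
                          cross_removal = c("exact", "none")) {
  cross_removal <- match.arg(cross_removal)
  if (!is.data.frame(links)) links <- do.call(rbind, links)
  methods <- as.vector(outer(detectors, clusterings, paste, sep = "+"))
  if (nrow(links)) {
    unknown <- setdiff(unique(links$method), methods)
    if (length(unknown))
      stop("unknown method label(s): ", paste(unknown, collapse = ", "))
  }
  region_of <- setNames(regions$region, regions$gene)
  known <- links$gene_a %in% names(region_of) &
           links$gene_b %in% names(region_of)
  links <- links[known, , drop = FALSE]
  ra <- region_of[links$gene_a]
  rb <- region_of[links$gene_b]
  intra <- ra == rb
  if (any(intra))
    message(sum(intra), " link(s) between genes of one region ignored")
  ra2 <- pmin(ra[!intra], rb[!intra])
  rb2 <- pmax(ra[!intra], rb[!intra])
  meth <- links$method[!intra]
  key <- paste(ra2, rb2, sep = "\r")
  support <- tapply(meth, key, function(m) sort(unique(m)))
  if (length(support) == 0L) {
    edges <- data.frame(from = character(0), to = character(0),
                        weight = numeric(0), support = character(0))
  } else {
    crossed <- list(sort(c(paste(detectors[1], clusterings[1], sep = "+"),
                           paste(detectors[2], clusterings[2], sep = "+"))),
                    sort(c(paste(detectors[1], clusterings[2], sep = "+"),
                           paste(detectors[2], clusterings[1], sep = "+"))))
    drop <- vapply(support, function(s)
      cross_removal == "exact" &&
        (identical(s, crossed[[1]]) || identical(s, crossed[[2]])),
      logical(1))
    support <- support[!drop]
    ab <- strsplit(names(support), "\r", fixed = TRUE)
    edges <- data.frame(
      from = vapply(ab, `[[`, character(1), 1L),
      to = vapply(ab, `[[`, character(1), 2L),
      weight = 0.25 * vapply(support, length, integer(1)),
      support = vapply(support, paste, character(1), collapse = ";"),
      stringsAsFactors = FALSE)
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  }
  vt <- region_vertex_table(regions)
  keep <- vt$region %in% c(edges$from, edges$to)
  net <- structure(list(vertices = vt[keep, , drop = FALSE],
                        edges = edges, methods = methods),
                   class = "synteny_network")
  attr(net, "all_regions") <- regions
  rownames(net$vertices) <- NULL
  net
}

region_vertex_table <- function(regions) {
  sp <- vapply(split(regions, regions$region), function(d)
    c(d$species[1], d$chromosome[1], as.character(nrow(d)),
      paste(d$gene, collapse = ";")), character(4))
  data.frame(region = colnames(sp), species = sp[1, ],
             chromosome = sp[2, ], size = as.integer(sp[3, ]),
             members = sp[4, ], stringsAsFactors = FALSE,
             row.names = NULL)
}

#' @export
print.synteny_network <- function(x, ...) {
  cat("synteny_network:", nrow(x$vertices), "vertices,", nrow(x$edges),
      "edges; methods:", paste(x$methods, collapse = ", "), "\n")
  invisible(x)
}

#' Convert a synteny network to igraph
#'
#' @param network a `synteny_network`.
#' @return an igraph graph with vertex attributes species, chromosome,
#'   size, members and edge attributes weight, support.
#' @export
as_igraph_network <- function(network) {
  igraph::graph_from_data_frame(network$edges, directed = FALSE,
                                vertices = network$vertices)
}

#' Summary statistics of a synteny network
#'
#' Vertex and edge counts, possible edges `n(n-1)/2`, density as a
#' percentage (one decimal, as conventionally printed), tandem-region
#' count and maximum size, per-species vertex counts, and the edge-weight
#' histogram.
#'
#' @param network a `synteny_network`, or NULL when raw counts are given.
#' @param n_vertices,n_edges raw counts, used when `network` is NULL.
#' @return a list of class `network_stats`.
#' @export
network_stats <- function(network = NULL, n_vertices = NULL,
                          n_edges = NULL) {
  if (!is.null(network)) {
    n <- nrow(network$vertices)
    m <- nrow(network$edges)
  } else {
    n <- n_vertices
    m <- n_edges
  }
  possible <- as.numeric(n) * (n - 1) / 2
  out <- list(n_vertices = n, n_edges = m, possible_edges = possible,
              density_pct = if (possible > 0)
                round(100 * m / possible, 1) else NA_real_)
  if (!is.null(network)) {
    sizes <- network$vertices$size
    out$n_tandem_regions <- sum(sizes > 1L)
    out$max_tandem_size <- if (length(sizes)) max(sizes) else 0L
    out$per_species <- table(network$vertices$species)
    out$weight_histogram <- table(network$edges$weight)
  }
  class(out) <- "network_stats"
  out
}

#' @export
print.network_stats <- function(x, ...) {
  cat("vertices:", x$n_vertices, " edges:", x$n_edges,
      " possible:", format(x$possible_edges, big.mark = ","),
      " density:", paste0(x$density_pct, "%"), "\n")
  if (!is.null(x$n_tandem_regions))
    cat("tandem regions:", x$n_tandem_regions, " max size:",
        x$max_tandem_size, "\n")
  invisible(x)
}

#' Export / import a synteny network
#'
#' GraphML (via igraph) or a weighted edge-list TSV with support sets;
#' `"regions"` writes the vertex/member table. `read_network_edgelist()`
#' and `read_network_graphml()` rebuild a `synteny_network` from the
#' corresponding files.
#'
#' @param network a `synteny_network`.
#' @param path output path.
#' @param format one of `"graphml"`, `"edgelist"`, `"regions"`.
#' @return the path, invisibly.
#' @export
export_network <- function(network, path,
                           format = c("graphml", "edgelist", "regions")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- as_igraph_network(network)
    igraph::write_graph(g, path, format = "graphml")
  } else if (format == "edgelist") {
    utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    reg <- attr(network, "all_regions")
    if (is.null(reg)) reg <- network$vertices
    utils::write.table(as.data.frame(reg), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' @rdname export_network
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  va <- igraph::vertex_attr(g)
  name <- if (!is.null(va$name)) va$name else va$id
  vertices <- data.frame(region = name,
                         species = va$species, chromosome = va$chromosome,
                         size = as.integer(va$size), members = va$members,
                         stringsAsFactors = FALSE)
  el <- igraph::as_edgelist(g, names = TRUE)
  edges <- data.frame(from = pmin(el[, 1], el[, 2]),
                      to = pmax(el[, 1], el[, 2]),
                      weight = igraph::edge_attr(g, "weight"),
                      support = igraph::edge_attr(g, "support"),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  methods <- sort(unique(unlist(strsplit(edges$support, ";", fixed = TRUE))))
  structure(list(vertices = vertices, edges = edges, methods = methods),
            class = "synteny_network")
}
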