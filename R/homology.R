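#' Family assignment container
#'
#' A total mapping from gene identifiers to family identifiers together
#' with a provenance label recording how it was derived (`"truth"`,
#' `"mcl"`, `"imported"`, `"perturbed"`, ...).
#'
#' @param mapping named character vector gene -> family.
#' @param provenance single string.
#' @param canonical relabel families canonically (`F0001`, `F0002`, ...
#'   ordered by smallest member gene id)?
#' @return object of class `family_assignment`.
#' @export
family_assignment <- function(mapping, provenance = "imported",
                              canonical = FALSE) {
  if (length(mapping) && is.null(names(mapping)))
    stop("mapping must be a named vector (gene -> family)")
  mapping <- vapply(mapping, as.character, character(1))
  if (canonical) mapping <- canonical_families(mapping)
  structure(list(mapping = mapping, provenance = as.character(provenance)),
            class = "family_assignment")
}

#' @export
print.family_assignment <- function(x, ...) {
  cat("family_assignment [", x$provenance, "]: ", length(x$mapping),
      " genes in ", length(unique(x$mapping)), " families\n", sep = "")
  invisible(x)
}

#' Canonically relabel family ids
#'
#' Families are renamed `F0001`, `F0002`, ... in the order of their
#' smallest (lexicographically first) member gene, so assignments that
#' differ only in arbitrary labels compare equal.
#'
#' @param mapping named character vector gene -> family.
#' @return relabelled named character vector.
#' @export
canonical_families <- function(mapping) {
  if (length(mapping) == 0L) return(mapping)
  firsts <- vapply(split(names(mapping), mapping),
                   function(g) min(g), character(1))
  ord <- names(firsts)[order(firsts)]
  new <- setNames(sprintf("F%04d", seq_along(ord)), ord)
  setNames(unname(new[mapping]), names(mapping))
}

#' Negative-log10 similarity transform with ceiling
#'
#' Maps a homology E-value to the similarity used as edge weight before
#' Markov clustering: `min(-log10(evalue), 200)`, clamped below at 0. An
#' E-value of 0 (or below 1e-200) hits the ceiling 200.
#'
#' @param evalue numeric vector of E-values (>= 0).
#' @return numeric vector of similarities in \[0, 200\].
#' @export
transform_similarity <- function(evalue) {
  if (any(evalue < 0)) stop("E-values must be non-negative")
  s <- ifelse(evalue == 0, 200, -log10(evalue))
  pmin(pmax(s, 0), 200)
}

#' Load an abc similarity table
#'
#' Reads a three-column TSV (query, subject, E-value), applies
#' [transform_similarity()], mirrors pairs into an undirected graph,
#' drops self-hits and keeps the maximum similarity over duplicate pairs.
#'
#' @param path path to the abc file.
#' @return object of class `similarity_graph`: list with `nodes`
#'   (character) and `edges` (data.frame from, to, similarity).
#' @export
load_abc <- function(path) {
  if (!file.exists(path)) stop("abc file not found: ", path)
  raw <- readLines(path)
  raw <- raw[nzchar(raw)]
  if (length(raw) == 0L)
    return(similarity_graph(character(0),
                            data.frame(from = character(0),
                                       to = character(0),
                                       similarity = numeric(0))))
  parts <- strsplit(raw, "[\t ]+")
  bad <- which(vapply(parts, length, integer(1)) < 3L)
  if (length(bad)) stop("malformed abc line ", bad[1], " in ", path)
  ev <- suppressWarnings(as.numeric(vapply(parts, `[[`, character(1), 3L)))
  if (anyNA(ev))
    stop("non-numeric E-value on abc line ", which(is.na(ev))[1], " in ",
         path)
  abc_graph(data.frame(query = vapply(parts, `[[`, character(1), 1L),
                       subject = vapply(parts, `[[`, character(1), 2L),
                       evalue = ev, stringsAsFactors = FALSE))
}

#' Build a similarity graph from an in-memory abc table
#'
#' @param abc data.frame with columns query, subject, evalue.
#' @return a `similarity_graph` (mirrored, max over duplicates, no
#'   self-loops).
#' @export
abc_graph <- function(abc) {
  keep <- abc$query != abc$subject
  abc <- abc[keep, , drop = FALSE]
  nodes <- sort(unique(c(abc$query, abc$subject)))
  if (nrow(abc) == 0L)
    return(similarity_graph(nodes, data.frame(from = character(0),
                                              to = character(0),
                                              similarity = numeric(0))))
  sim <- transform_similarity(abc$evalue)
  a <- pmin(abc$query, abc$subject)
  b <- pmax(abc$query, abc$subject)
  key <- paste(a, b, sep = "\r")
  best <- tapply(sim, key, max)
  ab <- strsplit(names(best), "\r", fixed = TRUE)
  edges <- data.frame(from = vapply(ab, `[[`, character(1), 1L),
                      to = vapply(ab, `[[`, character(1), 2L),
                      similarity = as.numeric(best),
                      stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  similarity_graph(nodes, edges[order(edges$from, edges$to), , drop = FALSE])
}

similarity_graph <- function(nodes, edges) {
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "similarity_graph")
}

#' @export
print.similarity_graph <- function(x, ...) {
  cat("similarity_graph:", length(x$nodes), "genes,", nrow(x$edges),
      "undirected edges\n")
  invisible(x)
}

#' Markov clustering of a similarity graph
#'
#' Small-scale Markov clustering (MCL): the mirrored similarity matrix is
#' regularised with self-loops (each node's maximum incident similarity),
#' column-normalised, then expansion (matrix squaring) and inflation
#' (entrywise power, column renormalisation) alternate until the maximum
#' absolute change drops below `tol` or `max_iter` is reached. Clusters are
#' the connected components of attractor support; every node is assigned.
#' Sparse matrices keep the iteration tractable at a few thousand genes.
#'
#' @param graph a `similarity_graph`.
#' @param inflation inflation exponent (> 1); the conventional default 2.
#' @param max_iter iteration cap.
#' @param tol convergence tolerance on the maximum absolute matrix change.
#' @param prune entries below this value are zeroed after each inflation to
#'   preserve sparsity (numerical housekeeping, not a model parameter).
#' @return a [family_assignment()] with provenance `"mcl"` and attribute
#'   `converged`.
#' @export
mcl_cluster <- function(graph, inflation = 2, max_iter = 100L, tol = 1e-6,
                        prune = 1e-8) {
  if (inflation <= 1) stop("inflation must be > 1")
  nodes <- graph$nodes
  n <- length(nodes)
  if (n == 0L)
    return(family_assignment(setNames(character(0), character(0)), "mcl"))
  e <- graph$edges
  i <- match(e$from, nodes); j <- match(e$to, nodes)
  M <- Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                            x = rep(e$similarity, 2L), dims = c(n, n))
  # self-loops at each node's max incident similarity (isolates get 1)
  mx <- apply(M, 2L, max)
  mx[mx <= 0] <- 1
  M <- M + Matrix::Diagonal(n, mx)
  M <- normalize_cols(M)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M                      # expansion
    M2@x <- M2@x^inflation             # inflation
    M2 <- Matrix::drop0(M2)
    M2@x[M2@x < prune] <- 0
    M2 <- normalize_cols(Matrix::drop0(M2))
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge within ", max_iter, " iterations")
  fam <- mcl_interpret(M, nodes)
  out <- family_assignment(fam, "mcl", canonical = TRUE)
  attr(out, "converged") <- converged
  out
}

normalize_cols <- function(M) {
  cs <- Matrix::colSums(M)
  cs[cs == 0] <- 1
  M %*% Matrix::Diagonal(length(cs), 1 / cs)
}

# Clusters from the limit matrix: attractors are rows with positive
# diagonal; each node joins the attractor it flows to most (ties to the
# smaller attractor index); attractors linked through shared members merge.
mcl_interpret <- function(M, nodes) {
  n <- length(nodes)
  M <- as(M, "CsparseMatrix")
  attractors <- which(Matrix::diag(M) > 1e-9)
  if (length(attractors) == 0L) attractors <- seq_len(n)
  assign_to <- integer(n)
  sub <- M[attractors, , drop = FALSE]
  for (v in seq_len(n)) {
    flows <- sub[, v]
    k <- which(flows == max(flows))[1]
    assign_to[v] <- if (max(flows) > 0) attractors[k] else v
  }
  # merge attractor sets that claim overlapping support (shared rows of the
  # limit matrix), via union-find over attractor pairs co-supported
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (v in seq_len(n)) {
    sup <- which(M[, v] > 1e-9)
    sup <- intersect(sup, attractors)
    for (a in sup[-1]) {
      ra <- find(a); rb <- find(sup[1])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  root <- vapply(assign_to, find, integer(1))
  setNames(sprintf("M%05d", root), nodes)
}

#' Read / write gene-family tables
#'
#' Two-column TSV (gene, family). Reading applies canonical relabelling
#' (see [canonical_families()]); conflicting duplicate gene rows are an
#' error naming the gene.
#'
#' @param path file path.
#' @param provenance provenance label attached on read.
#' @return `read_family_table`: a [family_assignment()].
#' @export
read_family_table <- function(path, provenance = "imported") {
  if (!file.exists(path)) stop("family table not found: ", path)
  raw <- readLines(path)
  raw <- raw[nzchar(raw)]
  if (length(raw) && raw[1] == "gene\tfamily") raw <- raw[-1]
  if (length(raw) == 0L)
    return(family_assignment(setNames(character(0), character(0)),
                             provenance))
  parts <- strsplit(raw, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, integer(1)) < 2L)
  if (length(bad)) stop("malformed family table line ", bad[1])
  gene <- vapply(parts, `[[`, character(1), 1L)
  fam <- vapply(parts, `[[`, character(1), 2L)
  dup <- duplicated(gene)
  if (any(dup)) {
    for (g in unique(gene[dup])) {
      if (length(unique(fam[gene == g])) > 1L)
        stop("conflicting family for gene '", g, "' in ", path)
    }
    fam <- fam[!dup]; gene <- gene[!dup]
  }
  family_assignment(setNames(fam, gene), provenance, canonical = TRUE)
}

#' @rdname read_family_table
#' @param assignment a `family_assignment` (or named vector).
#' @return `write_family_table`: the path, invisibly.
#' @export
write_family_table <- function(assignment, path) {
  mapping <- if (inherits(assignment, "family_assignment"))
    assignment$mapping else assignment
  writeLines(c("gene\tfamily",
               paste(names(mapping), unname(mapping), sep = "\t")), path)
  invisible(path)
}

#' Import OrthoFinder-style orthogroup table
#'
#' One group per line: `OG0000001: geneA geneB ...` (colon optional,
#' whitespace-separated members).
#'
#' @param path file path.
#' @return a [family_assignment()] with provenance `"orthofinder"`.
#' @export
read_orthogroups <- function(path) {
  if (!file.exists(path)) stop("orthogroup file not found: ", path)
  raw <- readLines(path)
  raw <- raw[nzchar(raw)]
  mapping <- character(0)
  for (line in raw) {
    toks <- strsplit(trimws(line), "[[:space:]]+")[[1]]
    grp <- sub(":$", "", toks[1])
    members <- toks[-1]
    mapping[members] <- grp
  }
  family_assignment(mapping, "orthofinder", canonical = TRUE)
}
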