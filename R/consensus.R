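#' Run the four-algorithm community-detection ensemble
#'
#' Applies, on the weighted network, greedy modularity optimisation,
#' short-random-walk clustering (steps = 15), leading-eigenvector
#' clustering (steps = 15) and multi-level modularity optimisation. Each
#' algorithm is run under a fixed internal RNG state so results are
#' deterministic given the vertex ordering. An algorithm that fails on a
#' degenerate graph falls back to connected components (with a message).
#'
#' @param network a `synteny_network` (nonempty).
#' @return object of class `partition_ensemble`: named list of four
#'   membership vectors (region -> integer community), one per algorithm.
#' @export
run_partition_ensemble <- function(network) {
  if (nrow(network$vertices) == 0L) stop("network has no vertices")
  g <- as_igraph_network(network)
  w <- igraph::E(g)$weight
  run <- function(label, fn) {
    res <- tryCatch(
      with_seed(sub_seed(1L, "ensemble", label), fn()),
      error = function(e) {
        message("community detection '", label,
                "' failed; falling back to connected components")
        NULL
      })
    if (is.null(res)) {
      m <- igraph::components(g)$membership
    } else {
      m <- igraph::membership(res)
    }
    setNames(as.integer(m), igraph::V(g)$name)
  }
  ens <- list(
    greedy_modularity = run("greedy", function()
      igraph::cluster_fast_greedy(g, weights = w)),
    random_walk = run("walktrap", function()
      igraph::cluster_walktrap(g, weights = w, steps = 15)),
    leading_eigenvector = run("leading_eigen", function()
      igraph::cluster_leading_eigen(g, weights = w, steps = 15)),
    multilevel = run("multilevel", function()
      igraph::cluster_louvain(g, weights = w)))
  structure(ens, class = "partition_ensemble")
}

#' Binary co-membership distances of a partition ensemble
#'
#' For every vertex pair, each algorithm contributes distance 0 if it
#' places the pair in one community and 1 otherwise; the four binaries are
#' averaged, so distances lie in \{0, 0.25, 0.5, 0.75, 1\}.
#'
#' @param ensemble a [run_partition_ensemble()] result (any list of total
#'   partitions over one vertex set).
#' @return symmetric numeric matrix with zero diagonal.
#' @export
comembership_distance <- function(ensemble) {
  vs <- names(ensemble[[1]])
  for (p in ensemble) {
    if (!setequal(names(p), vs))
      stop("partitions cover different vertex sets")
  }
  n <- length(vs)
  D <- matrix(0, n, n, dimnames = list(vs, vs))
  for (p in ensemble) {
    m <- p[vs]
    D <- D + outer(m, m, "!=")
  }
  D / length(ensemble)
}

#' Affinity propagation clustering
#'
#' Standard responsibility/availability message passing on a square
#' symmetric similarity matrix, with damping, a convergence window on the
#' exemplar set, and no noise injection (ties break deterministically
#' toward the lower vertex index). Defaults mirror the conventional
#' apcluster settings (lam = 0.9, convits = 1000, maxits = 10000).
#'
#' @param similarity square symmetric numeric matrix (larger = more
#'   similar).
#' @param damping damping factor in \[0.5, 1).
#' @param convits stop once the exemplar set is unchanged this many
#'   consecutive iterations.
#' @param maxits iteration cap; if reached without convergence the
#'   best-so-far solution is returned with `converged = FALSE`.
#' @param preference exemplar preference placed on the diagonal: a number,
#'   or `"median"` for the median off-diagonal similarity.
#' @return object of class `consensus_assignment`: list with `clusters`
#'   (named integer vector vertex -> cluster), `exemplars` (named by
#'   cluster), `iterations`, `converged`.
#' @export
affinity_propagation <- function(similarity, damping = 0.9,
                                 convits = 1000L, maxits = 10000L,
                                 preference = "median") {
  S <- as.matrix(similarity)
  n <- nrow(S)
  if (n == 0L) stop("empty similarity matrix")
  if (ncol(S) != n) stop("similarity matrix must be square")
  if (max(abs(S - t(S))) > 1e-8) stop("similarity matrix must be symmetric")
  if (damping < 0.5 || damping >= 1) stop("damping must be in [0.5, 1)")
  vs <- rownames(S)
  if (is.null(vs)) vs <- as.character(seq_len(n))
  if (n == 1L) {
    return(new_consensus(setNames(1L, vs), setNames(vs, "1"), 0L, TRUE))
  }
  off <- S[row(S) != col(S)]
  pref <- if (identical(preference, "median")) median(off)
          else as.numeric(preference)
  diag(S) <- pref
  # No random noise is injected; instead, perfectly symmetric inputs (which
  # make noise-free message passing oscillate) are resolved by an
  # infinitesimal preference penalty growing with vertex index - the
  # deterministic "ties go to the lower index" rule.
  eps <- 1e-6 * max(1, max(abs(S[is.finite(S)])))
  diag(S) <- diag(S) - eps * (seq_len(n) - 1) / n
  R <- A <- matrix(0, n, n)
  lam <- damping
  stable <- 0L
  last_ex <- integer(0)
  it <- 0L
  while (it < maxits) {
    it <- it + 1L
    # responsibilities: r(i,k) = s(i,k) - max_{k' != k} (a(i,k') + s(i,k'))
    AS <- A + S
    max1_idx <- max.col(AS, ties.method = "first")
    max1 <- AS[cbind(seq_len(n), max1_idx)]
    AS2 <- AS
    AS2[cbind(seq_len(n), max1_idx)] <- -Inf
    max2 <- AS2[cbind(seq_len(n), max.col(AS2, ties.method = "first"))]
    Rnew <- S - max1
    Rnew[cbind(seq_len(n), max1_idx)] <- S[cbind(seq_len(n), max1_idx)] -
      max2
    R <- lam * R + (1 - lam) * Rnew
    # availabilities
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    cs <- colSums(Rp)
    Anew <- sweep(-Rp, 2L, cs, "+")           # a(i,k), i != k
    Anew[Anew > 0] <- 0
    diag(Anew) <- cs - diag(Rp)               # a(k,k)
    A <- lam * A + (1 - lam) * Anew
    ex <- which(diag(A) + diag(R) > 0)
    if (identical(ex, last_ex)) stable <- stable + 1L else stable <- 0L
    last_ex <- ex
    if (stable >= convits && length(ex) > 0L) break
  }
  converged <- stable >= convits && length(last_ex) > 0L
  ex <- last_ex
  if (length(ex) == 0L) ex <- which.max(diag(A) + diag(R))
  # assign every vertex to its best exemplar; exemplars to themselves
  assign_idx <- ex[max.col(S[, ex, drop = FALSE], ties.method = "first")]
  assign_idx[ex] <- ex
  ex_sorted <- sort(unique(assign_idx))
  cluster_of_ex <- setNames(seq_along(ex_sorted), ex_sorted)
  clusters <- setNames(as.integer(cluster_of_ex[as.character(assign_idx)]),
                       vs)
  exemplars <- setNames(vs[ex_sorted], seq_along(ex_sorted))
  new_consensus(clusters, exemplars, it, converged)
}

new_consensus <- function(clusters, exemplars, iterations, converged) {
  structure(list(clusters = clusters, exemplars = exemplars,
                 iterations = iterations, converged = converged),
            class = "consensus_assignment")
}

#' @export
print.consensus_assignment <- function(x, ...) {
  cat("consensus_assignment:", length(x$clusters), "vertices in",
      length(x$exemplars), "clusters;",
      if (x$converged) "converged" else "NOT converged", "after",
      x$iterations, "iterations\n")
  invisible(x)
}

#' Consensus syntenic clusters of a network
#'
#' The full two-stage procedure: run the four-algorithm ensemble, convert
#' co-membership disagreement into distances, feed similarity = -distance
#' into affinity propagation, and return the consolidated assignment.
#'
#' @param network a `synteny_network`.
#' @inheritParams affinity_propagation
#' @return a `consensus_assignment` over the network's regions, with the
#'   ensemble attached as attribute `ensemble`.
#' @export
consensus_clusters <- function(network, damping = 0.9, convits = 1000L,
                               maxits = 10000L, preference = "median") {
  ens <- run_partition_ensemble(network)
  D <- comembership_distance(ens)
  res <- affinity_propagation(-D, damping = damping, convits = convits,
                              maxits = maxits, preference = preference)
  attr(res, "ensemble") <- ens
  res
}

#' Write cluster membership table
#'
#' @param assignment a `consensus_assignment`.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_membership <- function(assignment, path) {
  df <- data.frame(region = names(assignment$clusters),
                   cluster = unname(assignment$clusters))
  df$exemplar <- df$region %in% assignment$exemplars
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
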