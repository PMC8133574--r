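# Independent oracles, written separately from the package implementations
# they check.

# adjusted Rand index between two labelings (same names or same order)
ari <- function(x, y) {
  if (!is.null(names(x)) && !is.null(names(y))) y <- y[names(x)]
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  c <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  e <- b * c / choose(n, 2)
  den <- (b + c) / 2 - e
  if (den == 0) return(1)
  (a - e) / den
}

# Brute-force best-chain score: enumerate every subset of anchors, keep
# those forming a valid sign-consistent monotone chain under the profile,
# return the maximum score (-Inf if none).
brute_force_best_chain <- function(pos_a, pos_b, min_anchors, max_gap,
                                   max_gaps_total, match_score,
                                   gap_penalty) {
  n <- length(pos_a)
  ord <- order(pos_a, pos_b)
  pa <- pos_a[ord]; pb <- pos_b[ord]
  best <- -Inf
  for (mask in seq_len(2^n - 1L)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (length(idx) < min_anchors) next
    a <- pa[idx]; b <- pb[idx]
    o <- order(a)
    a <- a[o]; b <- b[o]
    da <- diff(a); db <- diff(b)
    if (any(da <= 0)) next
    if (!(all(db > 0) || all(db < 0))) next
    adb <- abs(db)
    if (any(da > max_gap + 1L) || any(adb > max_gap + 1L)) next
    skips <- sum(da - 1L) + sum(adb - 1L)
    if (skips > max_gaps_total) next
    sc <- match_score * length(idx) + gap_penalty * skips
    if (sc > best) best <- sc
  }
  best
}

# Dense reference MCL: plain matrix loop mirroring the declared algorithm
# (self-loops at max incident similarity, column normalisation, expansion,
# inflation), clusters = connected components of the limit's support.
mcl_dense_oracle <- function(nodes, edges, inflation = 2, iters = 100) {
  n <- length(nodes)
  M <- matrix(0, n, n, dimnames = list(nodes, nodes))
  for (r in seq_len(nrow(edges))) {
    i <- match(edges$from[r], nodes); j <- match(edges$to[r], nodes)
    M[i, j] <- M[i, j] + edges$similarity[r]
    M[j, i] <- M[j, i] + edges$similarity[r]
  }
  mx <- apply(M, 2, max)
  mx[mx <= 0] <- 1
  diag(M) <- mx
  M <- sweep(M, 2, colSums(M), "/")
  for (it in seq_len(iters)) {
    M2 <- M %*% M
    M2 <- M2^inflation
    M2 <- sweep(M2, 2, colSums(M2), "/")
    if (max(abs(M2 - M)) < 1e-9) { M <- M2; break }
    M <- M2
  }
  adj <- (M > 1e-6) | t(M > 1e-6)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (comp[v] > 0L) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  stats::setNames(comp, nodes)
}

# One-sided (greater) Fisher p by direct binomial-coefficient enumeration
# over all tables with the observed margins.
fisher_tail_oracle <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  lo <- max(0L, k - m2); hi <- min(k, m1)
  x <- lo:hi
  logp <- lchoose(m1, x) + lchoose(m2, k - x) - lchoose(m1 + m2, k)
  sum(exp(logp[x >= a]))
}

# Step-up BH from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, m / i * p[o[i]])
    q[o[i]] <- val
    prev <- val
  }
  pmin(q, 1)
}

# Net similarity of an exemplar-set assignment; exhaustive optimum over all
# non-empty exemplar subsets.
ap_net_similarity <- function(S, exemplars) {
  n <- nrow(S)
  assigned <- exemplars[apply(S[, exemplars, drop = FALSE], 1, which.max)]
  assigned[exemplars] <- exemplars
  sum(vapply(seq_len(n), function(i)
    if (i %in% exemplars) S[i, i] else S[i, assigned[i]], numeric(1)))
}

ap_exhaustive_optimum <- function(S) {
  n <- nrow(S)
  best <- -Inf
  for (mask in seq_len(2^n - 1L)) {
    ex <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    v <- ap_net_similarity(S, ex)
    if (v > best) best <- v
  }
  best
}
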