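test_that("one-sided Fisher matches closed forms", {
  r <- fisher_one_sided(contingency_table(0, 10, 10, 0))
  expect_equal(r$p, 1)
  r2 <- fisher_one_sided(contingency_table(9, 1, 1, 9))
  expect_equal(r2$p, 101 / 184756, tolerance = 1e-12)
  # all-zero table is degenerate
  r3 <- fisher_one_sided(contingency_table(0, 0, 0, 0))
  expect_true(r3$degenerate)
  expect_equal(r3$p, 1)
  expect_true(is.nan(r3$odds_ratio))
  expect_error(fisher_one_sided(matrix(1:6, 2)), "2x2")
})

test_that("Fisher p equals the enumeration oracle on sampled tables", {
  set.seed(1)
  for (i in 1:200) {
    m1 <- sample(0:30, 1)
    m2 <- sample(0:30, 1)
    a <- if (m1 > 0) sample(0:m1, 1) else 0L
    c <- if (m2 > 0) sample(0:m2, 1) else 0L
    got <- fisher_one_sided(contingency_table(a, m1 - a, c, m2 - c))$p
    expect_equal(got, fisher_tail_oracle(a, m1 - a, c, m2 - c),
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment is the step-up rule, order-invariant", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.3, 5)), rep(0.3, 5))
  set.seed(2)
  p <- stats::runif(20)
  expect_equal(bh_adjust(p), bh_oracle(p))
  perm <- sample(20)
  expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

# a small clustered universe: clusters of given sizes with given focal counts
toy_assignment <- function(sizes, focal_counts, focal_type = "R-4-C") {
  genes <- sprintf("g%03d", seq_len(sum(sizes)))
  cluster <- rep(seq_along(sizes), sizes)
  types <- unlist(mapply(function(n, k)
    c(rep(focal_type, k), rep("Other", n - k)), sizes, focal_counts,
    SIMPLIFY = FALSE))
  regions <- data.frame(region = genes, species = "spA",
                        chromosome = "chr1", gene = genes,
                        pos = seq_along(genes) - 1L)
  class(regions) <- c("tandem_regions", "data.frame")
  assignment <- structure(
    list(clusters = stats::setNames(cluster, genes),
         exemplars = stats::setNames(genes[!duplicated(cluster)],
                                     unique(cluster)),
         iterations = 0L, converged = TRUE),
    class = "consensus_assignment")
  list(assignment = assignment, regions = regions,
       types = stats::setNames(types, genes))
}

test_that("cluster selection applies the strict 15% and size-10 rules", {
  toy <- toy_assignment(sizes = c(20, 9, 100), focal_counts = c(4, 5, 15))
  sel <- select_type_clusters(toy$assignment, toy$regions, toy$types)
  expect_equal(sel, 1L)  # 20% qualifies; 9-gene cluster and exact 15% fail
  toy2 <- toy_assignment(sizes = c(100), focal_counts = c(16))
  expect_equal(select_type_clusters(toy2$assignment, toy2$regions,
                                    toy2$types), 1L)
})

test_that("type enrichment reflects concentration and dilution", {
  # all focal genes in the selected cluster of a 40-gene universe
  conc <- toy_assignment(sizes = c(20, 20), focal_counts = c(8, 0))
  res <- type_enrichment(conc$assignment, conc$regions, conc$types,
                         selected = 1L)
  expect_equal(unname(unlist(res[, c("a", "b", "c", "d")])),
               c(8, 0, 12, 20))
  expect_equal(res$p, fisher_tail_oracle(8, 0, 12, 20), tolerance = 1e-12)
  expect_lt(res$p, 0.05)

  # uniform spread: odds ratio near 1, p large
  unif <- toy_assignment(sizes = c(20, 20), focal_counts = c(4, 4))
  res2 <- type_enrichment(unif$assignment, unif$regions, unif$types,
                          selected = 1L)
  expect_equal(res2$sample_or, 1)
  expect_gt(res2$p, 0.5)

  # genes absent from the network are excluded from the margins
  extra <- conc
  extra$types <- c(extra$types,
                   stats::setNames(rep("R-4-C", 5), sprintf("zz%d", 1:5)))
  res3 <- type_enrichment(extra$assignment, extra$regions, extra$types,
                          selected = 1L)
  expect_equal(res3$a + res3$b, 8)  # the 5 off-network genes don't count
  expect_error(type_enrichment(conc$assignment, conc$regions, conc$types,
                               selected = integer(0)), "no clusters")
})

test_that("type enrichment is calibrated under label-shuffled nulls", {
  # universe sized so the discrete test's attainable size is near nominal:
  # 400 genes, 80 focal-type, 120 genes inside the selected clusters
  toy <- toy_assignment(sizes = c(120, 280), focal_counts = c(24, 56))
  n_rej <- 0L
  reps <- 1000L
  set.seed(42)
  genes <- names(toy$types)
  for (r in seq_len(reps)) {
    shuffled <- stats::setNames(sample(unname(toy$types)), genes)
    p <- type_enrichment(toy$assignment, toy$regions, shuffled,
                         selected = 1L)$p
    if (p < 0.05) n_rej <- n_rej + 1L
  }
  expect_gte(n_rej / reps, 0.03)
  expect_lte(n_rej / reps, 0.07)
})

test_that("GO enrichment ranks a planted term first on a labelled toy", {
  # 500-gene universe; term T covers all 20 foreground genes and 10% of
  # the background
  bg <- sprintf("g%03d", 1:500)
  fg <- bg[1:20]
  ann <- lapply(bg, function(g) "GO:BASE")
  names(ann) <- bg
  with_term <- c(fg, bg[21:50])  # 50 genes = 10% of 500
  for (g in with_term) ann[[g]] <- c(ann[[g]], "GO:PLANT")
  res <- go_enrichment(fg, bg, ann)
  expect_equal(res$term[1], "GO:PLANT")
  expect_lt(res$q[1], 0.05)
  expect_true(all(res$q >= res$p))
  # a term absent from the foreground is not tested
  ann[["g490"]] <- c(ann[["g490"]], "GO:ELSEWHERE")
  res2 <- go_enrichment(fg, bg, ann)
  expect_false("GO:ELSEWHERE" %in% res2$term)
  # foreground = background -> nothing can be enriched
  res3 <- go_enrichment(bg, bg, ann)
  expect_true(all(res3$p == 1))
  expect_error(go_enrichment(c(fg, "nope"), bg, ann), "subset")
  # focal-gene exclusion removes genes from both sides
  res4 <- go_enrichment(fg, bg, ann, exclude = fg[1:5])
  expect_equal(res4$a[res4$term == "GO:PLANT"], 15)
})

test_that("term similarity combines Jaccard and overlap 50/50", {
  sets <- list(T1 = c("a", "b"), T2 = c("a", "b"), T3 = c("x", "y"),
               T4 = c("a"))
  edges <- term_similarity_network(term_genes = sets)
  key <- paste(edges$term_a, edges$term_b)
  expect_equal(edges$weight[key == "T1 T2"], 1.0)
  expect_false("T1 T3" %in% key)               # disjoint -> dropped
  expect_equal(edges$weight[key == "T1 T4"], 0.75)  # 0.5*0.5 + 0.5*1
  expect_true(all(edges$weight >= 0 & edges$weight <= 1))
  # q-value gate
  res <- data.frame(term = names(sets), q = c(0.01, 0.01, 0.01, 0.5))
  attr(res, "term_genes") <- sets
  edges2 <- term_similarity_network(res)
  expect_false(any(grepl("T4", paste(edges2$term_a, edges2$term_b))))
})
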