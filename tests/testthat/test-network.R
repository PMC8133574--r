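test_that("tandem calls merge into regions by connected components", {
  fams <- c("T", "T", "T", "X", "F")
  gt <- chrom_table(fams)
  focal <- gt$gene[c(1, 2, 3, 5)]
  call1 <- data.frame(gene_a = gt$gene[1], gene_b = gt$gene[2])
  call3 <- data.frame(gene_a = gt$gene[2], gene_b = gt$gene[3])

  # one method only -> its pair forms a region
  r1 <- merge_tandem_regions(list(m1 = call1), focal, gt)
  expect_equal(length(unique(r1$region)), 3L)
  expect_equal(sort(table(r1$region), decreasing = TRUE)[[1]], 2L)

  # chained calls from different methods -> one 3-gene component
  r2 <- merge_tandem_regions(list(m1 = call1, m3 = call3), focal, gt)
  sizes <- table(r2$region)
  expect_equal(max(sizes), 3L)
  expect_equal(length(unique(r2$region)), 2L)

  # no calls -> all singleton regions
  r0 <- merge_tandem_regions(list(), focal, gt)
  expect_equal(length(unique(r0$region)), length(focal))

  # cross-chromosome calls are rejected
  gt2 <- rbind(gt, chrom_table("T", chromosome = "chr2", prefix = "h"))
  bad <- data.frame(gene_a = gt$gene[1], gene_b = gt2$gene[6])
  expect_error(merge_tandem_regions(list(bad), c(focal, gt2$gene[6]), gt2),
               "spans")
})

test_that("edge weights count 0.25 per supporting method", {
  methods <- c("mcscanx+truth", "iadhore+truth", "mcscanx+mcl",
               "iadhore+mcl")
  one <- toy_two_region_input(methods[1])
  net1 <- build_network(one$links, one$regions,
                        detectors = c("mcscanx", "iadhore"),
                        clusterings = c("truth", "mcl"))
  expect_equal(net1$edges$weight, 0.25)

  all4 <- toy_two_region_input(methods)
  net4 <- build_network(all4$links, all4$regions,
                        detectors = c("mcscanx", "iadhore"),
                        clusterings = c("truth", "mcl"))
  expect_equal(net4$edges$weight, 1.0)

  # duplicate links from one method stay a single 0.25 increment
  dup <- toy_two_region_input(rep(methods[1], 3))
  netd <- build_network(dup$links, dup$regions,
                        detectors = c("mcscanx", "iadhore"),
                        clusterings = c("truth", "mcl"))
  expect_equal(netd$edges$weight, 0.25)
})

test_that("crossed-pair support is removed, supersets survive", {
  crossed1 <- c("mcscanx+truth", "iadhore+mcl")
  crossed2 <- c("mcscanx+mcl", "iadhore+truth")
  concordant <- c("mcscanx+truth", "iadhore+truth")
  for (cross in list(crossed1, crossed2)) {
    toy <- toy_two_region_input(cross)
    net <- build_network(toy$links, toy$regions,
                         detectors = c("mcscanx", "iadhore"),
                         clusterings = c("truth", "mcl"))
    expect_equal(nrow(net$edges), 0L)
    expect_equal(nrow(net$vertices), 0L)  # isolates pruned
  }
  # a concordant two-method pair survives
  toyc <- toy_two_region_input(concordant)
  netc <- build_network(toyc$links, toyc$regions,
                        detectors = c("mcscanx", "iadhore"),
                        clusterings = c("truth", "mcl"))
  expect_equal(netc$edges$weight, 0.5)
  # three-method superset containing a crossed pair survives
  toy3 <- toy_two_region_input(c(crossed1, "mcscanx+mcl"))
  net3 <- build_network(toy3$links, toy3$regions,
                        detectors = c("mcscanx", "iadhore"),
                        clusterings = c("truth", "mcl"))
  expect_equal(net3$edges$weight, 0.75)
  # the filter can be disabled
  toyx <- toy_two_region_input(crossed1)
  netx <- build_network(toyx$links, toyx$regions,
                        detectors = c("mcscanx", "iadhore"),
                        clusterings = c("truth", "mcl"),
                        cross_removal = "none")
  expect_equal(netx$edges$weight, 0.5)
})

test_that("unknown method labels and intra-region links are handled", {
  toy <- toy_two_region_input("bogus+label")
  expect_error(build_network(toy$links, toy$regions,
                             detectors = c("mcscanx", "iadhore"),
                             clusterings = c("truth", "mcl")),
               "unknown method")
  # a link inside one region is ignored with a message
  fams <- c("T", "T", "F")
  gt <- chrom_table(fams)
  focal <- gt$gene[c(1, 2, 3)]
  calls <- data.frame(gene_a = gt$gene[1], gene_b = gt$gene[2])
  regions <- merge_tandem_regions(list(calls), focal, gt)
  links <- data.frame(gene_a = gt$gene[1], gene_b = gt$gene[2],
                      method = "mcscanx+truth")
  expect_message(
    net <- build_network(links, regions,
                         detectors = c("mcscanx", "iadhore"),
                         clusterings = c("truth", "mcl")),
    "one region")
  expect_equal(nrow(net$edges), 0L)
})

test_that("network invariants hold on pipeline-scale input", {
  res <- run_pipeline(pipeline_config(sim = small_sim(41)))
  net <- res$network
  expect_true(all(net$edges$weight %in% c(0.25, 0.5, 0.75, 1.0)))
  g <- as_igraph_network(net)
  expect_true(all(igraph::degree(g) >= 1))
  crossed <- c("iadhore+mcl;mcscanx+truth", "iadhore+truth;mcscanx+mcl")
  expect_false(any(net$edges$support %in% crossed))
  # lifting is idempotent: rebuild from the network's own region links
  region_links <- do.call(rbind, lapply(seq_len(nrow(net$edges)),
    function(i) {
      members_a <- strsplit(net$vertices$members[
        net$vertices$region == net$edges$from[i]], ";")[[1]][1]
      members_b <- strsplit(net$vertices$members[
        net$vertices$region == net$edges$to[i]], ";")[[1]][1]
      data.frame(gene_a = members_a, gene_b = members_b,
                 method = strsplit(net$edges$support[i], ";")[[1]])
    }))
  net2 <- build_network(region_links, res$regions,
                        detectors = c("mcscanx", "iadhore"),
                        clusterings = c("truth", "mcl"))
  e1 <- net$edges[order(net$edges$from, net$edges$to), ]
  e2 <- net2$edges[order(net2$edges$from, net2$edges$to), ]
  rownames(e1) <- rownames(e2) <- NULL
  expect_equal(e1, e2)
})

test_that("network statistics report counts, density and tandem sizes", {
  st <- network_stats(n_vertices = 2, n_edges = 1)
  expect_equal(st$possible_edges, 1)
  expect_equal(st$density_pct, 100.0)

  # planted 23-copy tandem array collapses to one max-size-23 region
  fams <- c(rep("FOC", 23), "X", "Y", "FOC")
  gt <- chrom_table(fams)
  fam <- chrom_families(gt, fams)
  focal <- gt$gene[fams == "FOC"]
  calls <- call_tandems(gt, fam, tandem_gap = 1L)
  regions <- merge_tandem_regions(list(calls), focal, gt)
  links <- data.frame(gene_a = gt$gene[1], gene_b = gt$gene[26],
                      method = "mcscanx+truth")
  net <- build_network(links, regions,
                       detectors = c("mcscanx", "iadhore"),
                       clusterings = c("truth", "mcl"))
  st2 <- network_stats(net)
  expect_equal(st2$max_tandem_size, 23L)
})

test_that("networks export and re-import losslessly", {
  toy <- toy_two_region_input(c("mcscanx+truth", "iadhore+truth"))
  net <- build_network(toy$links, toy$regions,
                       detectors = c("mcscanx", "iadhore"),
                       clusterings = c("truth", "mcl"))
  f <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, f, "graphml")
  back <- read_network_graphml(f)
  expect_equal(back$edges$weight, net$edges$weight)
  expect_equal(back$edges$support, net$edges$support)
  expect_setequal(back$vertices$region, net$vertices$region)
  expect_false(any(is.na(back$vertices$species)))
  expect_false(any(is.na(back$vertices$members)))

  # empty network -> valid file with zero edges
  empty <- build_network(
    data.frame(gene_a = character(0), gene_b = character(0),
               method = character(0)),
    toy$regions, detectors = c("mcscanx", "iadhore"),
    clusterings = c("truth", "mcl"))
  f2 <- withr::local_tempfile(fileext = ".graphml")
  export_network(empty, f2, "graphml")
  expect_equal(nrow(read_network_graphml(f2)$edges), 0L)

  # edge list export carries weight and support columns
  f3 <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, f3, "edgelist")
  el <- utils::read.delim(f3)
  expect_equal(el$weight, net$edges$weight)
})
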