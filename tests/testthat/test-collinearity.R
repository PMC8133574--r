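test_that("anchors are the family cross product", {
  a <- chrom_table(c("F1", "F2", "F3", "F4", "F5"), species = "spA")
  b <- chrom_table(c("F1", "F2", "F3", "F4", "F5"), species = "spB")
  fams <- c(chrom_families(a, c("F1", "F2", "F3", "F4", "F5")),
            chrom_families(b, c("F1", "F2", "F3", "F4", "F5")))
  an <- find_anchors(a, b, fams)
  expect_equal(nrow(an), 5L)
  expect_equal(an$pos_a, an$pos_b)

  # zero shared families
  b2 <- chrom_table(c("X1", "X2"), species = "spB")
  fams2 <- c(chrom_families(a, c("F1", "F2", "F3", "F4", "F5")),
             chrom_families(b2, c("X1", "X2")))
  expect_equal(nrow(find_anchors(a, b2, fams2)), 0L)

  # 2 x 3 copies -> 6 anchors
  a3 <- chrom_table(c("F1", "Z1", "F1"), species = "spA")
  b3 <- chrom_table(c("F1", "F1", "Z2", "F1"), species = "spB")
  fams3 <- c(chrom_families(a3, c("F1", "Z1", "F1")),
             chrom_families(b3, c("F1", "F1", "Z2", "F1")))
  expect_equal(nrow(find_anchors(a3, b3, fams3)), 6L)

  # self-comparison excludes identity pairs and lists pairs once
  fams_a <- chrom_families(a, c("F1", "F2", "F1", "F2", "F3"))
  self_an <- find_anchors(a, a, fams_a)
  expect_equal(nrow(self_an), 2L)
  expect_true(all(self_an$pos_b > self_an$pos_a))
})

test_that("chaining honours min_anchors and scores perfect runs", {
  an <- data.frame(gene_a = sprintf("a%d", 1:4), pos_a = 0:3,
                   gene_b = sprintf("b%d", 1:4), pos_b = 0:3,
                   family = sprintf("F%d", 1:4))
  expect_equal(nrow(chain_anchors(an, profile_mcscanx())), 0L)
  an5 <- data.frame(gene_a = sprintf("a%d", 1:5), pos_a = 0:4,
                    gene_b = sprintf("b%d", 1:5), pos_b = 0:4,
                    family = sprintf("F%d", 1:5))
  bl <- chain_anchors(an5, profile_mcscanx())
  expect_equal(length(unique(bl$block)), 1L)
  expect_equal(nrow(bl), 5L)
  expect_equal(unique(bl$score), 250)
  expect_equal(unique(bl$orientation), 1L)
  # reversed second genome -> minus orientation
  an5m <- an5
  an5m$pos_b <- 4:0
  blm <- chain_anchors(an5m, profile_mcscanx())
  expect_equal(unique(blm$orientation), -1L)
})

test_that("chaining matches brute-force enumeration on random instances", {
  prof <- detector_profile("test", min_anchors = 3L, max_gap = 4L,
                           max_gaps_total = 6L, match_score = 50,
                           gap_penalty = -1)
  n_match <- 0L
  for (s in 1:200) {
    set.seed(s)
    n <- sample(6:12, 1)
    an <- data.frame(gene_a = sprintf("a%d", seq_len(n)),
                     pos_a = sample(0:14, n, replace = TRUE),
                     gene_b = sprintf("b%d", seq_len(n)),
                     pos_b = sample(0:14, n, replace = TRUE),
                     family = "F")
    best_oracle <- brute_force_best_chain(an$pos_a, an$pos_b,
                                          prof$min_anchors, prof$max_gap,
                                          prof$max_gaps_total,
                                          prof$match_score,
                                          prof$gap_penalty)
    bl <- chain_anchors(an, prof)
    best_dp <- if (nrow(bl) == 0L) -Inf else max(bl$score)
    expect_equal(best_dp, best_oracle, info = paste("seed", s))
    if (is.finite(best_oracle)) n_match <- n_match + 1L
  }
  expect_gt(n_match, 50L)  # the instances genuinely exercise chaining
})

test_that("reported blocks satisfy their profile constraints", {
  prof <- detector_profile("test", min_anchors = 3L, max_gap = 4L,
                           max_gaps_total = 6L, match_score = 50,
                           gap_penalty = -1)
  for (s in 1:40) {
    set.seed(1000 + s)
    n <- sample(8:12, 1)
    an <- data.frame(gene_a = sprintf("a%d", seq_len(n)),
                     pos_a = sample(0:11, n, replace = TRUE),
                     gene_b = sprintf("b%d", seq_len(n)),
                     pos_b = sample(0:11, n, replace = TRUE),
                     family = "F")
    bl <- chain_anchors(an, prof)
    for (bid in unique(bl$block)) {
      sub <- bl[bl$block == bid, ]
      expect_gte(nrow(sub), prof$min_anchors)
      da <- diff(sub$pos_a)
      db <- diff(sub$pos_b) * sub$orientation[1]
      expect_true(all(da > 0 & da <= prof$max_gap + 1L))
      expect_true(all(db > 0 & db <= prof$max_gap + 1L))
      expect_lte(sum(da - 1L) + sum(db - 1L), prof$max_gaps_total)
      expect_equal(sub$score[1],
                   prof$match_score * nrow(sub) +
                     prof$gap_penalty * (sum(da - 1L) + sum(db - 1L)))
    }
    # anchors used at most once
    expect_false(anyDuplicated(paste(bl$gene_a, bl$gene_b)) > 0)
  }
})

test_that("detect_synteny finds planted duplications and is symmetric", {
  # genome vs itself after a clean segmental duplication of 6 genes
  fams <- sprintf("F%02d", c(1:20, 3:8, 21:30))
  g <- chrom_table(fams, species = "spA")
  fam <- chrom_families(g, fams)
  bl <- detect_synteny(g, g, family_assignment(fam, "truth"),
                       profile_mcscanx())
  expect_equal(length(unique(bl$block)), 1L)
  expect_equal(nrow(bl), 6L)
  expect_setequal(bl$pos_a, 2:7)
  expect_setequal(bl$pos_b, 20:25)

  # two species, no shared families
  h <- chrom_table(sprintf("H%02d", 1:10), species = "spB")
  famh <- c(fam, chrom_families(h, sprintf("H%02d", 1:10)))
  expect_equal(nrow(detect_synteny(g, h, family_assignment(famh, "truth"),
                                   profile_mcscanx())), 0L)

  # symmetry between species
  h2 <- chrom_table(fams[1:12], species = "spB")
  fam2 <- c(fam, chrom_families(h2, fams[1:12]))
  ab <- detect_synteny(g, h2, family_assignment(fam2, "truth"),
                       profile_mcscanx())
  ba <- detect_synteny(h2, g, family_assignment(fam2, "truth"),
                       profile_mcscanx())
  expect_setequal(paste(ab$gene_a, ab$gene_b), paste(ba$gene_b, ba$gene_a))
})

test_that("WGD-derived genomes yield blocks matching the planted history", {
  cfg <- sim_config(seed = 31, species_tree = 1, wgd_probability = 1,
                    segmental_duplication = 0, tandem_duplication = 0,
                    gene_loss = 0, inversion = 0, translocation = 0,
                    chromosomes_per_genome = 2, genes_per_chromosome = 60,
                    n_families = 120)
  ds <- simulate_evolution(cfg)
  gt <- ds$gene_table
  fam <- family_assignment(ds$truth_families, "truth")
  bl <- detect_synteny(gt, gt, fam, profile_mcscanx())
  # each original chromosome must align to its duplicated copy
  pairs <- unique(paste(bl$chrom_a, bl$chrom_b))
  expect_true(all(c("chr1 chr1w1", "chr2 chr2w1") %in% pairs))
})

test_that("tandem calls respect the gap parameter", {
  g <- chrom_table(c("A", "A", "X", "B", "Y", "B"))
  fam <- chrom_families(g, c("A", "A", "X", "B", "Y", "B"))
  calls0 <- call_tandems(g, fam, tandem_gap = 0L)
  expect_equal(nrow(calls0), 1L)
  calls1 <- call_tandems(g, fam, tandem_gap = 1L)
  expect_equal(nrow(calls1), 2L)  # A-A adjacent and B.B with one between
  # same family three apart, gap 1 -> no call
  g2 <- chrom_table(c("C", "X", "Y", "C"))
  fam2 <- chrom_families(g2, c("C", "X", "Y", "C"))
  expect_equal(nrow(call_tandems(g2, fam2, tandem_gap = 1L)), 0L)
  # 4-gene array, gap 0 -> 3 calls forming a path
  g3 <- chrom_table(c("D", "D", "D", "D"))
  fam3 <- chrom_families(g3, rep("D", 4))
  calls3 <- call_tandems(g3, fam3, tandem_gap = 0L)
  expect_equal(nrow(calls3), 3L)
  expect_error(call_tandems(g3, fam3, tandem_gap = -1L), ">= 0")
})

test_that("blocks_to_links keeps focal anchor pairs once", {
  an5 <- data.frame(gene_a = sprintf("a%d", 1:5), pos_a = 0:4,
                    gene_b = sprintf("b%d", 1:5), pos_b = 0:4,
                    family = sprintf("F%d", 1:5))
  bl <- chain_anchors(an5, profile_mcscanx())
  expect_equal(nrow(blocks_to_links(bl, character(0), "m")), 0L)
  one <- blocks_to_links(bl, c("a2", "b2"), "m")
  expect_equal(nrow(one), 1L)
  expect_equal(one$method, "m")
  # same pair in two blocks of one method -> one link
  two_blocks <- rbind(bl, within(bl, block <- block + 1L))
  expect_equal(nrow(blocks_to_links(two_blocks, c("a2", "b2"), "m")), 1L)
})
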