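test_that("no rearrangement means zero non-syntenic fraction", {
  sim <- smallSim(seed = 6L, tipNoise = 0,
                  script = data.frame(branch = character(0),
                                      type = character(0), lg_a = integer(0),
                                      lg_b = integer(0), pi = numeric(0),
                                      breakpoint = numeric(0),
                                      k = integer(0)))
  tv <- truthLinkageGroups(sim)
  cf <- nonsyntenicFraction(tv$vectors, tv$lgs, "A", "C")
  expect_identical(cf$violating, 0L)
  expect_equal(cf$fraction, 0)
})

test_that("the non-syntenic fraction is symmetric and charged per pair", {
  sim <- smallSim(seed = 10L, tipNoise = 0.05)
  tv <- truthLinkageGroups(sim)
  ab <- nonsyntenicFraction(tv$vectors, tv$lgs, "A", "B")
  ba <- nonsyntenicFraction(tv$vectors, tv$lgs, "B", "A")
  expect_equal(ab$fraction, ba$fraction)
  expect_identical(ab$total, nrow(tv$vectors))
  # 5 genes moved in each tip of a 100-gene genome: about 10 violations
  # for any pair, never the whole noise pool of all three tips
  expect_true(ab$violating >= 8L && ab$violating <= 12L)
})

test_that("rate arithmetic is r = c / t with optional per-lineage halving", {
  r <- translocationRate(0.046, 23)
  expect_equal(r$rate, 0.002)
  r2 <- translocationRate(0.046, 23, perLineage = TRUE)
  expect_equal(r2$rate, 0.001)
  expect_error(translocationRate(0.5, 0), "> 0")
  expect_error(translocationRate(1.5, 10), "\\[0, 1\\]")
})

test_that("pairwise rates cover all pairs with the tree's divergence times", {
  sim <- smallSim(seed = 12L, tipNoise = 0.02)
  tv <- truthLinkageGroups(sim)
  rates <- pairwiseRates(tv$vectors, tv$lgs, sim@tree)
  expect_identical(nrow(rates), 3L)
  ab <- rates[rates$genome_a == "A" & rates$genome_b == "B", ]
  expect_equal(ab$t, 10)
  expect_equal(ab$rate, ab$c / ab$t)
  ac <- rates[rates$genome_b == "C", ]
  expect_true(all(ac$t == 15))
})

test_that("translocation rate is recovered within 20 percent", {
  # 20 linkage groups so that moved genes rarely share a (source,
  # destination) cell; concentrated strays would otherwise reach minSupport
  # and absorb part of the signal
  anc <- makeAncestor(20L, 100L)   # 2000 genes
  tree <- readTree("(A:40,B:40)root;")
  sim <- evolveGenomes(anc, tree, rates = c(TRANSLOCATION = 2),
                       seed = 3L, transK = 1L)
  fil <- filterUniversalSingleCopy(sim@orthologs, sim@tips)
  vectors <- assignmentVectors(fil$universal, sim@tips)
  lgs <- clusterLinkageGroups(vectors)
  expect_identical(length(lgs), 20L)
  rates <- pairwiseRates(vectors, lgs, sim@tree)
  # truth: 2 moves/My on each of the two lineages among 2000 genes, and the
  # estimator divides the pair's non-syntenic fraction by t = 40 My, so the
  # recovered rate targets 2 * lambda / n
  rTrue <- 2 * 2 / 2000
  expect_lt(abs(rates$rate - rTrue) / rTrue, 0.2)
})

test_that("occupancy matrix conserves counts and orders greedily", {
  assignments <- data.frame(
    chrom_id = c(rep("c1", 30), rep("c2", 12), rep("c2", 3)),
    mlg_id = c(rep(1L, 28), rep(2L, 2), rep(2L, 12), rep(1L, 3)),
    stringsAsFactors = FALSE)
  occ <- occupancyMatrix(assignments)
  expect_identical(sum(occ), 45L)
  expect_identical(rownames(occ)[1], "c1")
  expect_identical(colnames(occ)[1], "1")
  expect_identical(occ["c1", "1"], 28L)
  expect_identical(occ["c2", "2"], 12L)
})

test_that("dot-plot tables are deterministic and rank within chromosomes", {
  sim <- smallSim(seed = 14L)
  tv <- truthLinkageGroups(sim)
  fil <- filterUniversalSingleCopy(sim@orthologs, sim@tips)
  d1 <- dotplotTable(sim@tips[["A"]], tv$lgs, fil$universal)
  d2 <- dotplotTable(sim@tips[["A"]], tv$lgs, fil$universal)
  expect_identical(d1, d2)
  expect_identical(nrow(d1), 100L)
  for (ch in unique(d1$chrom)) {
    r <- d1$rank[d1$chrom == ch]
    expect_identical(r, seq_along(r))
  }
})

test_that("chromosome mixing reports only multi-group chromosomes as mixed", {
  sim <- smallSim(seed = 15L)   # LG1+LG2 fused (pi = 1) in A and B
  tv <- truthLinkageGroups(sim)
  fil <- filterUniversalSingleCopy(sim@orthologs, sim@tips)
  mixA <- chromosomeMixing(sim@tips[["A"]], tv$lgs, fil$universal)
  fusedRow <- mixA[mixA$n_mlgs == 2L, ]
  expect_identical(nrow(fusedRow), 1L)
  expect_true(fusedRow$mixing_index > 0.5)
  expect_true(fusedRow$well_mixed)
  expect_true(all(is.na(mixA$mixing_index[mixA$n_mlgs == 1L])))
})
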