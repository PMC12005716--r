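test_that("ancestor construction is deterministic and well-formed", {
  anc <- makeAncestor(3L, c(10L, 6L, 4L))
  expect_identical(nChroms(anc$genome), 3L)
  expect_identical(nGenes(anc$genome), 20L)
  expect_identical(sort(unique(anc$truth$lg)), 1:3)
  anc2 <- makeAncestor(3L, c(10L, 6L, 4L))
  expect_identical(geneTable(anc$genome), geneTable(anc2$genome))
  expect_error(makeAncestor(3L, c(10L, 6L)), "length")
})

test_that("events conserve genes (except duplication) and update chromosomes", {
  anc <- makeAncestor(3L, 10L)$genome
  fus <- applyEvent(anc, rearrangementEvent("FUSION", chromA = "A01",
                                            chromB = "A02", pi = 0))
  expect_identical(nChroms(fus), 2L)
  expect_identical(nGenes(fus), 30L)
  # pi = 0 keeps the two blocks in order
  df <- geneTable(fus)
  onFused <- df[df$chrom == "A01+A02", ]
  onFused <- onFused[order(onFused$mid), "gene_id"]
  expect_identical(onFused, sprintf("L%02dg%04d", rep(1:2, each = 10),
                                    rep(1:10, 2)))
  fis <- applyEvent(anc, rearrangementEvent("FISSION", chromA = "A03",
                                            breakpoint = 4L))
  expect_identical(nChroms(fis), 4L)
  expect_identical(nGenes(fis), 30L)
  dup <- applyEvent(anc, rearrangementEvent("DUPLICATION", chromA = "A02"))
  expect_identical(nGenes(dup), 40L)
  expect_error(applyEvent(anc, rearrangementEvent("FUSION", chromA = "A01",
                                                  chromB = "A09")),
               "not in genome")
  expect_error(applyEvent(anc, rearrangementEvent("FISSION", chromA = "A01",
                                                  breakpoint = 10L)),
               "breakpoint")
})

test_that("simulation is reproducible under a seed and differs across seeds", {
  s1 <- smallSim(seed = 7L, tipNoise = 0.02)
  s2 <- smallSim(seed = 7L, tipNoise = 0.02)
  s3 <- smallSim(seed = 8L, tipNoise = 0.02)
  expect_identical(eventLedger(s1), eventLedger(s2))
  for (g in names(s1@tips))
    expect_identical(geneTable(s1@tips[[g]]), geneTable(s2@tips[[g]]))
  expect_false(identical(eventLedger(s1), eventLedger(s3)))
})

test_that("ledger replay reproduces the tip genomes byte-identically", {
  sim <- smallSim(seed = 11L, tipNoise = 0.03)
  rep <- replayLedger(sim)
  d <- freshDir()
  for (g in names(sim@tips)) {
    p1 <- file.path(d, paste0(g, ".orig.bed"))
    p2 <- file.path(d, paste0(g, ".replay.bed"))
    writeGeneBed(sim@tips[[g]], p1)
    writeGeneBed(rep$tips[[g]], p2)
    expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))
  }
})

test_that("ledger chromosome counts match the emitted tips", {
  sim <- smallSim(seed = 2L)
  counts <- ledgerChromCounts(sim)
  for (g in names(sim@tips))
    expect_identical(counts[[g]], nChroms(sim@tips[[g]]))
  # one fusion on the AB stem: A and B have 3 chromosomes, C keeps 4
  expect_identical(counts[["A"]], 3L)
  expect_identical(counts[["B"]], 3L)
  expect_identical(counts[["C"]], 4L)
})

test_that("tip noise moves the requested number of genes", {
  sim <- smallSim(seed = 5L, tipNoise = 0.04, script = data.frame(
    branch = character(0), type = character(0), lg_a = integer(0),
    lg_b = integer(0), pi = numeric(0), breakpoint = numeric(0),
    k = integer(0)))
  led <- eventLedger(sim)
  expect_setequal(unique(led$type), "TRANSLOCATION")
  expect_identical(sort(unique(led$child)), c("A", "B", "C"))
  expect_true(all(led$k == round(0.04 * 100)))
})

test_that("fusion mixing increases with the interleaving parameter pi", {
  a <- paste0("a", 1:30); b <- paste0("b", 1:30)
  meanMix <- function(pi) {
    mean(vapply(1:25, function(s) {
      set.seed(1000 + s)
      ord <- karyolg:::interleaveGenes(a, b, pi)
      mixingIndex(substr(ord, 1, 1))$index
    }, numeric(1)))
  }
  m0 <- meanMix(0); m05 <- meanMix(0.5); m1 <- meanMix(1)
  expect_lt(m0, m05)
  expect_lt(m05, m1)
  # pi = 0 is pure block concatenation: exactly one heterologous junction
  set.seed(1)
  ord0 <- karyolg:::interleaveGenes(a, b, 0)
  expect_identical(mixingIndex(substr(ord0, 1, 1))$observed, 1L)
})

test_that("the emitted dataset round-trips through the package readers", {
  sim <- smallSim(seed = 3L, tipNoise = 0.02)
  d <- freshDir()
  emitDataset(sim, d)
  genomes <- GenomeSet(lapply(names(sim@tips), function(g)
    readGeneTable(file.path(d, paste0(g, ".bed")), genomeId = g)))
  ogs <- readOrthologTable(file.path(d, "orthologs.tsv"), genomes)
  tree <- readTree(file.path(d, "tree.nwk"), genomes)
  expect_identical(names(genomes), names(sim@tips))
  expect_identical(orthoTable(ogs), orthoTable(sim@orthologs))
  expect_setequal(tree$tip.label, names(sim@tips))
  for (g in names(genomes))
    expect_identical(geneTable(genomes[[g]]), geneTable(sim@tips[[g]]))
  expect_error(emitDataset(sim, d), "non-empty")
})

test_that("truthLinkageGroups reflects the simulated ground truth", {
  sim <- smallSim(seed = 4L)
  tv <- truthLinkageGroups(sim)
  expect_identical(length(tv$trueLg), 4L)
  expect_identical(sum(mlgSupport(tv$lgs)), 100L)
  mem <- mlgMembership(tv$lgs)
  lgOf <- setNames(sim@truth$lg, sim@truth$og_id)
  expect_true(all(tv$trueLg[mem$mlg_id] == unname(lgOf[mem$og_id])))
})
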