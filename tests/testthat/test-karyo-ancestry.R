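test_that("Fitch labelings achieve the brute-force minimum change count", {
  set.seed(31)
  for (rep in 1:25) {
    ntips <- sample(3:6, 1)
    tree <- ape::rtree(ntips)
    tipStates <- sample(0:1, ntips, replace = TRUE)
    final <- karyolg:::fitchBinary(tree, tipStates)
    expect_identical(final[seq_len(ntips)], tipStates)
    expect_identical(labelingChanges(tree, final),
                     bruteMinChanges(tree, tipStates))
  }
})

test_that("Fitch on ((A,B),C) resolves the root toward unfused", {
  tree <- smallTree()
  chars <- matrix(c(1L, 1L, 0L), nrow = 3, dimnames =
                    list(c("A", "B", "C"), "1|2"))
  st <- reconstructStates(chars, tree)
  expect_identical(st$nodeChar["root", "1|2"], 0L)
  expect_identical(st$nodeChar["AB", "1|2"], 1L)
  expect_identical(unname(st$counts[c("root", "AB", "A", "C")]),
                   c(2L, 1L, 1L, 2L))
})

test_that("Dollo treats the fusion as a single gain above the 1-tip MRCA", {
  tree <- readTree("((A:1,B:1)AB:1,(C:1,D:1)CD:1)root;")
  chars <- matrix(c(1L, 0L, 1L, 0L), nrow = 4,
                  dimnames = list(c("A", "B", "C", "D"), "1|2"))
  fit <- reconstructStates(chars, tree, mode = "fitch")
  dol <- reconstructStates(chars, tree, mode = "dollo")
  # Fitch (root preference 0): both internal nodes unfused
  expect_identical(unname(fit$nodeChar[c("root", "AB", "CD"), 1]),
                   c(0L, 0L, 0L))
  # Dollo: gained once at the root, lost twice
  expect_identical(unname(dol$nodeChar[c("root", "AB", "CD"), 1]),
                   c(1L, 1L, 1L))
})

test_that("a three-way fusion is decomposed into two pairwise steps", {
  tree <- smallTree()
  # A and B carry {1,2,3} on one chromosome; C keeps all separate
  fused <- list(A = list(c(1L, 2L, 3L), 4L), B = list(c(1L, 2L, 3L), 4L),
                C = list(1L, 2L, 3L, 4L))
  chars <- colocalizationCharacters(fused, 4L)
  st <- reconstructStates(chars, tree)
  ev <- callEvents(st, tree, chars)
  fus <- ev[ev$type == "FUSION", ]
  expect_identical(nrow(fus), 2L)
  expect_identical(unique(fus$merge_id), fus$merge_id[1])
  expect_identical(unique(fus$mlgs), "1,2,3")
  expect_identical(fus$child, c("AB", "AB"))
  expect_true(all(fus$synapomorphy))
  expect_identical(nrow(mergedEvents(ev)), 1L)
})

test_that("synapomorphy flags require presence in all and only descendants", {
  tree <- readTree("((A:1,B:1)AB:1,((C:1,D:1)CD:1,E:1)CDE:1)root;")
  # fusion 1+2 in A, B and (homoplastically) in D
  fused <- list(A = list(c(1L, 2L), 3L), B = list(c(1L, 2L), 3L),
                C = list(1L, 2L, 3L), D = list(c(1L, 2L), 3L),
                E = list(1L, 2L, 3L))
  chars <- colocalizationCharacters(fused, 3L)
  st <- reconstructStates(chars, tree)
  ev <- callEvents(st, tree, chars)
  fus <- ev[ev$type == "FUSION", ]
  expect_identical(sort(fus$child), c("AB", "D"))
  expect_true(all(!fus$synapomorphy))
})

test_that("fissions are called when a parent chromosome splits", {
  tree <- smallTree()
  fused <- list(A = list(1L, 2L, 3L), B = list(c(1L, 2L), 3L),
                C = list(c(1L, 2L), 3L))
  chars <- colocalizationCharacters(fused, 3L)
  st <- reconstructStates(chars, tree)
  # Fitch: root and AB fused (1 change) beats unfused root (2 changes)
  expect_identical(unname(st$counts[c("root", "AB", "A")]), c(2L, 2L, 3L))
  ev <- callEvents(st, tree, chars)
  expect_identical(ev$type, "FISSION")
  expect_identical(ev$child, "A")
  expect_identical(ev$mlgs, "1,2")
})

test_that("the duplication-vs-fission rule applies the threshold arithmetic", {
  genes <- data.frame(
    gene_id = c("m1a", "m1b", "m2a", "m2b", "m3", "m4"),
    chrom = c("chr1", "chr2", "chr1", "chr2", "chr1", "chr1"),
    start = c(1, 1, 101, 101, 201, 301), end = c(50, 50, 150, 150, 250, 350),
    stringsAsFactors = FALSE)
  gset <- GenomeSet(list(KaryoGenome("F", genes)))
  membership <- data.frame(og_id = c("og1", "og2", "og3", "og4"),
                           mlg_id = 1L, stringsAsFactors = FALSE)
  dupTbl <- data.frame(og_id = c("og1", "og1", "og2", "og2"),
                       genome_id = "F",
                       gene_id = c("m1a", "m1b", "m2a", "m2b"),
                       stringsAsFactors = FALSE)
  dup <- new("OrthoGroupSet", tbl = dupTbl)
  # 2 of 4 members duplicated across two chromosomes: fraction 0.5
  cls <- classifyDupFission(1L, "F", dup, gset, membership, threshold = 0.5)
  expect_identical(cls$call, "DUPLICATION")
  expect_equal(cls$fraction, 0.5)
  expect_identical(cls$informative, 4L)
  cls2 <- classifyDupFission(1L, "F", dup, gset, membership, threshold = 0.6)
  expect_identical(cls2$call, "FISSION")
  # both copies on one chromosome is not duplication evidence for the split
  genes2 <- genes; genes2$chrom[2] <- "chr1"
  gset2 <- GenomeSet(list(KaryoGenome("F", genes2)))
  cls3 <- classifyDupFission(1L, "F", dup, gset2, membership, threshold = 0.5)
  expect_identical(cls3$call, "FISSION")
  expect_equal(cls3$fraction, 0.25)
})

test_that("classifier separates simulated duplication from fission", {
  for (seed in 1:5) {
    for (type in c("DUPLICATION", "FISSION")) {
      sim <- twoTipSim(seed, type)
      fil <- filterUniversalSingleCopy(sim@orthologs, sim@tips)
      mem <- data.frame(og_id = sim@truth$og_id, mlg_id = sim@truth$lg,
                        stringsAsFactors = FALSE)
      cls <- classifyDupFission(3L, "F", fil$dupEvidence, sim@tips, mem)
      expect_identical(cls$call, type)
    }
  }
})

test_that("mixing index matches hand computations and flags", {
  # A A B B: 1 junction, expected (4-1)*(1-4/12) = 2 -> index 0.5
  m1 <- mixingIndex(c("A", "A", "B", "B"))
  expect_equal(m1$index, 0.5)
  expect_true(m1$well_mixed)
  # A B A B: 3 junctions -> index 1.5
  m2 <- mixingIndex(c("A", "B", "A", "B"))
  expect_equal(m2$index, 1.5)
  # single label: not applicable
  m3 <- mixingIndex(rep("A", 10))
  expect_false(m3$applicable)
  expect_true(is.na(m3$index))
})

test_that("mean mixing index over random permutations is 1", {
  labels <- rep(1:4, each = 25)
  set.seed(77)
  idx <- vapply(1:500, function(i) mixingIndex(sample(labels))$index,
                numeric(1))
  expect_equal(mean(idx), 1, tolerance = 0.03)
})
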