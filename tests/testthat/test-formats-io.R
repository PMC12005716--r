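test_that("BED round trip preserves coordinates, ids and strand", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3"),
                      chrom = c("chr1", "chr1", "chr2"),
                      start = c(101L, 501L, 11L),
                      end = c(200L, 700L, 60L),
                      strand = c("+", "-", "*"),
                      stringsAsFactors = FALSE)
  kg <- KaryoGenome("toy", genes,
                    chromLengths = c(chr1 = 1000L, chr2 = 100L))
  p <- file.path(freshDir(), "toy.bed")
  writeGeneBed(kg, p)
  back <- readGeneTable(p, genomeId = "toy",
                        chromLengths = c(chr1 = 1000L, chr2 = 100L))
  expect_identical(genomeId(back), "toy")
  a <- geneTable(kg); b <- geneTable(back)
  a <- a[order(a$gene_id), ]; b <- b[order(b$gene_id), ]
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
})

test_that("malformed BED lines are rejected with the line number", {
  d <- freshDir()
  p <- file.path(d, "bad.bed")
  writeLines(c("chr1\t0\t100\tg1", "chr1\t200\t150\tg2"), p)
  expect_error(readGeneTable(p), "line 2")
  writeLines(c("chr1\t0\t100"), p)
  expect_error(readGeneTable(p), ">= 4 columns")
  writeLines(c("chr1\tx\t100\tg1"), p)
  expect_error(readGeneTable(p), "non-numeric")
})

test_that("duplicate gene ids are rejected", {
  p <- file.path(freshDir(), "dup.bed")
  writeLines(c("chr1\t0\t100\tg1", "chr2\t0\t100\tg1"), p)
  expect_error(readGeneTable(p), "duplicate gene_id")
})

test_that("GFF3 gene features are imported with ID as gene id", {
  p <- file.path(freshDir(), "toy.gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t100\t200\t.\t+\t.\tID=gA",
               "chr1\tsrc\tmRNA\t100\t200\t.\t+\t.\tID=tA;Parent=gA",
               "chr2\tsrc\tgene\t50\t80\t.\t-\t.\tID=gB"), p)
  kg <- readGeneTable(p)
  df <- geneTable(kg)
  expect_setequal(df$gene_id, c("gA", "gB"))
  expect_identical(df$start[df$gene_id == "gA"], 100L)
  expect_identical(df$end[df$gene_id == "gB"], 80L)
})

test_that("readTree validates rooting, branch lengths and tip coverage", {
  expect_error(readTree("((A,B),C);"), "branch lengths")
  expect_error(readTree("(A:1,B:1,C:1);"), "root")
  tr <- readTree("((A:10,B:10)AB:5,C:15)root;")
  expect_identical(sort(tr$tip.label), c("A", "B", "C"))
  expect_identical(tr$node.label, c("root", "AB"))
  expect_error(readTree("((A:10,B:10)AB:5,C:15)root;", genomes = c("A", "B")),
               "match no genome")
  # blank internal labels are auto-named deterministically
  tr2 <- readTree("((A:10,B:10):5,C:15);")
  expect_true(all(nzchar(tr2$node.label)))
  tr3 <- readTree("((A:10,B:10):5,C:15);")
  expect_identical(tr2$node.label, tr3$node.label)
})

test_that("divergenceTime is the depth below the MRCA", {
  tr <- smallTree()
  expect_equal(divergenceTime(tr, "A", "B"), 10)
  expect_equal(divergenceTime(tr, "A", "C"), 15)
  expect_equal(divergenceTime(tr, "C", "B"), 15)
  expect_error(divergenceTime(tr, "A", "Z"), "tip not in tree")
})

test_that("ortholog table reader checks schema and cross-references genomes", {
  d <- freshDir()
  p <- file.path(d, "ogs.tsv")
  writeLines(c("og_id\tgenome_id\tgene_id",
               "OG1\tA\tg1", "OG1\tB\tg9"), p)
  ogs <- readOrthologTable(p)
  expect_s4_class(ogs, "OrthoGroupSet")
  expect_identical(nrow(orthoTable(ogs)), 2L)
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 1L, end = 10L)
  genesB <- data.frame(gene_id = "g2", chrom = "chr1", start = 1L, end = 10L)
  gset <- GenomeSet(list(KaryoGenome("A", genes), KaryoGenome("B", genesB)))
  # g9 is listed for genome B but absent from its gene table
  expect_warning(readOrthologTable(p, gset), "absent from the loaded genome")
  writeLines(c("og_id\tgenome_id", "OG1\tA"), p)
  expect_error(readOrthologTable(p), "columns")
})

test_that("mlg assignment TSV round-trips exactly", {
  sim <- smallSim()
  tv <- truthLinkageGroups(sim)
  p <- file.path(freshDir(), "mlg.tsv")
  writeMlgAssignments(tv$lgs, tv$vectors, p)
  back <- readMlgAssignments(p)
  expect_identical(sort(unique(back$mlg_id)), 1:4)
  expect_identical(nrow(back), nrow(tv$vectors) * ncol(tv$vectors))
  # a member's chrom_id equals its assignment-vector slot
  i <- sample(nrow(back), 25)
  expect_identical(back$chrom_id[i],
                   tv$vectors[cbind(back$og_id[i], back$genome_id[i])])
})
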