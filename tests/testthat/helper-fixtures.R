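## Small shared fixtures for the unit tests.

# Three-taxon dated tree with named internal nodes.
smallTree <- function() {
  readTree("((A:10,B:10)AB:5,C:15)root;")
}

# A tiny three-genome simulation: 4 linkage groups x 25 genes, one scripted
# fusion (LG 1 + 2) on the AB stem, no background noise.
smallSim <- function(seed = 1L, tipNoise = 0, script = NULL) {
  anc <- makeAncestor(4L, 25L)
  if (is.null(script))
    script <- data.frame(branch = "AB", type = "FUSION",
                         lg_a = 1L, lg_b = 2L, pi = 1,
                         breakpoint = NA, k = NA,
                         stringsAsFactors = FALSE)
  evolveGenomes(anc, smallTree(), script = script, seed = seed,
                tipNoise = tipNoise)
}

# A two-tip simulation carrying one scripted event of the given type on the
# branch to tip "F"; used by the duplication-vs-fission classifier tests.
twoTipSim <- function(seed, type = c("DUPLICATION", "FISSION"),
                      tipNoise = 0, nLgs = 6L, genesPerLg = 30L,
                      lg = 3L) {
  type <- match.arg(type)
  anc <- makeAncestor(nLgs, genesPerLg)
  tree <- readTree("(R:10,F:10)root;")
  script <- data.frame(branch = "F", type = type, lg_a = lg, lg_b = NA,
                       pi = NA, breakpoint = NA, k = NA,
                       stringsAsFactors = FALSE)
  evolveGenomes(anc, tree, script = script, seed = seed, tipNoise = tipNoise)
}

# Hand-built assignment-vector matrix: `sizes[i]` copies of each row of
# `rows` (a list of character vectors), rownames og001...
vectorsFromClasses <- function(rows, sizes, genomes) {
  m <- do.call(rbind, lapply(rep(seq_along(rows), sizes),
                             function(i) rows[[i]]))
  dimnames(m) <- list(sprintf("og%03d", seq_len(nrow(m))), genomes)
  m
}

freshDir <- function() {
  d <- tempfile("karyolg-test-")
  dir.create(d)
  d
}
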