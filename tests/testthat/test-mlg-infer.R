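test_that("hypergeometric p-values equal exact enumeration on small tables", {
  set.seed(21)
  for (rep in 1:6) {
    N <- sample(8:25, 1)
    va <- sample(paste0("a", 1:3), N, replace = TRUE)
    vb <- sample(paste0("b", 1:3), N, replace = TRUE)
    vectors <- cbind(GA = va, GB = vb)
    rownames(vectors) <- sprintf("og%03d", seq_len(N))
    h <- testChromosomeHomology(vectors, "GA", "GB")
    for (i in seq_len(nrow(h))) {
      expect_equal(h$p_value[i],
                   exactUpperTail(h$shared[i], h$n_a[i], h$n_b[i], N),
                   tolerance = 1e-12)
    }
  }
})

test_that("a perfectly conserved 10-gene chromosome pair scores 1/C(20,10)", {
  vectors <- cbind(GA = rep(c("a1", "a2"), each = 10),
                   GB = rep(c("b1", "b2"), each = 10))
  rownames(vectors) <- sprintf("og%03d", 1:20)
  h <- testChromosomeHomology(vectors, "GA", "GB")
  top <- h[h$chrom_a == "a1" & h$chrom_b == "b1", ]
  expect_equal(top$p_value, 1 / choose(20, 10), tolerance = 1e-12)
  expect_equal(top$p_value, 5.412544e-06, tolerance = 1e-6)
  expect_true(top$significant)
  off <- h[h$chrom_a == "a1" & h$chrom_b == "b2", ]
  expect_equal(off$p_value, 1, tolerance = 1e-12)
  expect_false(off$significant)
})

test_that("clustering groups exact vector classes and renumbers by support", {
  rows <- list(c("c1", "c1", "c1"),   # 6 members -> group 1
               c("c2", "c2", "c2"),   # 5 members -> group 2
               c("c1", "c1", "c2"))   # 1 member  -> stray
  vectors <- vectorsFromClasses(rows, c(6L, 5L, 1L), c("GA", "GB", "GC"))
  # epsilon 0.05 allows floor(0.05 * 3) = 0 deviations: stray becomes noise
  lgs <- clusterLinkageGroups(vectors, minSupport = 5L, epsilon = 0.05)
  expect_identical(length(lgs), 2L)
  expect_identical(mlgSupport(lgs), c(6L, 5L))
  expect_identical(unname(mlgConsensus(lgs)[1, ]), rows[[1]])
  expect_identical(noiseSet(lgs), "og012")
  # epsilon 0.4 allows 1 deviation: the stray attaches to group 1
  lgs2 <- clusterLinkageGroups(vectors, minSupport = 5L, epsilon = 0.4)
  expect_identical(mlgSupport(lgs2), c(7L, 5L))
  expect_identical(length(noiseSet(lgs2)), 0L)
  mem <- mlgMembership(lgs2)
  expect_identical(mem$mlg_id[mem$og_id == "og012"], 1L)
  # a stray equidistant from two groups stays noise even with slack
  rows3 <- list(c("c1", "c1", "c1"), c("c2", "c1", "c1"))
  v3 <- vectorsFromClasses(c(rows3, list(c("c3", "c1", "c1"))),
                           c(5L, 5L, 1L), c("GA", "GB", "GC"))
  lgs3 <- clusterLinkageGroups(v3, minSupport = 5L, epsilon = 0.4)
  expect_identical(noiseSet(lgs3), "og011")
})

test_that("clustering is invariant to input row order", {
  sim <- smallSim(seed = 13L, tipNoise = 0.02)
  fil <- filterUniversalSingleCopy(sim@orthologs, sim@tips)
  vectors <- assignmentVectors(fil$universal, sim@tips)
  lgs <- clusterLinkageGroups(vectors)
  set.seed(5)
  perm <- sample(nrow(vectors))
  lgs2 <- clusterLinkageGroups(vectors[perm, , drop = FALSE])
  expect_identical(mlgSupport(lgs), mlgSupport(lgs2))
  expect_identical(mlgConsensus(lgs), mlgConsensus(lgs2))
  m1 <- mlgMembership(lgs); m1 <- m1[order(m1$og_id), ]
  m2 <- mlgMembership(lgs2); m2 <- m2[order(m2$og_id), ]
  rownames(m1) <- rownames(m2) <- NULL
  expect_identical(m1, m2)
  expect_identical(noiseSet(lgs), noiseSet(lgs2))
})

test_that("minSupport failures are reported", {
  rows <- list(c("c1", "c1"), c("c2", "c2"))
  vectors <- vectorsFromClasses(rows, c(2L, 2L), c("GA", "GB"))
  expect_error(clusterLinkageGroups(vectors, minSupport = 5L), "minSupport")
})

test_that("fused sets partition the linkage groups by consensus chromosome", {
  sim <- smallSim(seed = 1L)   # LG1+LG2 fused on the AB stem
  tv <- truthLinkageGroups(sim)
  expect_identical(tv$trueLg, 1:4)   # equal sizes, tie-broken by lg id
  fsA <- fusedSets(tv$lgs, "A")
  sizes <- sort(vapply(fsA, length, integer(1)))
  expect_identical(unname(sizes), c(1L, 1L, 2L))
  fused <- fsA[[which(vapply(fsA, length, integer(1)) == 2L)]]
  expect_identical(fused, c(1L, 2L))
  fsC <- fusedSets(tv$lgs, "C")
  expect_true(all(vapply(fsC, length, integer(1)) == 1L))
  expect_identical(unname(sort(unlist(fsA))), 1:4)
})
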