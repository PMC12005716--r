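#' @include AllGenerics.R
NULL

#' Per-ortholog chromosome-assignment vectors
#'
#' For every universal single-copy ortholog group, the vector of chromosome
#' ids its single member occupies in each genome. This is the raw material of
#' linkage-group inference: orthologs that have co-resided on one ancestral
#' chromosome share (up to rearrangement) the same vector.
#'
#' @param universal an \linkS4class{OrthoGroupSet} of universal single-copy
#'   groups (see \code{\link{filterUniversalSingleCopy}}).
#' @param genomes a \linkS4class{GenomeSet} covering every genome in the
#'   groups.
#' @return character matrix, rows = og_id, columns = genome ids (fixed order
#'   = \code{names(genomes)}).
#' @export
assignmentVectors <- function(universal, genomes) {
  tb <- orthoTable(universal)
  gms <- names(genomes)
  ogs <- sort(unique(tb$og_id))
  m <- matrix(NA_character_, nrow = length(ogs), ncol = length(gms),
              dimnames = list(ogs, gms))
  for (g in gms) {
    gr <- geneRanges(genomes[[g]])
    chromOf <- setNames(as.character(seqnames(gr)), mcols(gr)$gene_id)
    sub <- tb[tb$genome_id == g, ]
    m[sub$og_id, g] <- unname(chromOf[sub$gene_id])
  }
  if (anyNA(m)) {
    bad <- rownames(m)[apply(is.na(m), 1L, any)]
    stop("group(s) without a placement in some genome (not single-copy ",
         "universal?): ", paste(utils::head(bad, 3), collapse = ", "))
  }
  m
}

#' Hypergeometric test of chromosome-pair homology
#'
#' For one genome pair, tests every chromosome pair for an excess of shared
#' orthologs given the marginal chromosome sizes, with the upper-tail
#' hypergeometric probability P(X >= shared); p-values are BH-adjusted across
#' all chromosome pairs of the genome pair, and a pair is called significant
#' at \code{q <= alpha}. The statistic depends only on counts, so it is
#' invariant to gene relabelling.
#'
#' @param vectors assignment-vector matrix from
#'   \code{\link{assignmentVectors}}.
#' @param genomeA,genomeB column names of the two genomes.
#' @param alpha FDR level (default 0.05).
#' @return data.frame with columns chrom_a, chrom_b, shared, n_a, n_b, total,
#'   p_value, q_value, significant.
#' @export
testChromosomeHomology <- function(vectors, genomeA, genomeB, alpha = 0.05) {
  stopifnot(all(c(genomeA, genomeB) %in% colnames(vectors)))
  a <- vectors[, genomeA]
  b <- vectors[, genomeB]
  N <- length(a)
  if (N == 0L) stop("no orthologs to test")
  tab <- table(a, b)
  nA <- rowSums(tab); nB <- colSums(tab)
  out <- expand.grid(chrom_a = rownames(tab), chrom_b = colnames(tab),
                     stringsAsFactors = FALSE)
  out$shared <- as.integer(tab[cbind(out$chrom_a, out$chrom_b)])
  out$n_a <- as.integer(nA[out$chrom_a])
  out$n_b <- as.integer(nB[out$chrom_b])
  out$total <- N
  # upper tail: P(X >= shared) for X ~ Hypergeom(n_a draws from n_b of N)
  out$p_value <- stats::phyper(out$shared - 1L, out$n_b, N - out$n_b,
                               out$n_a, lower.tail = FALSE)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$q_value <= alpha
  out[order(out$p_value, out$chrom_a, out$chrom_b), , drop = FALSE]
}

#' Cluster orthologs into ancestral linkage groups
#'
#' Groups orthologs by exact identity of their chromosome-assignment vector.
#' Vector classes with at least \code{minSupport} members become linkage
#' groups; every remaining ortholog is attached to the unique linkage group
#' whose vector differs from its own in at most \code{floor(epsilon * G)}
#' genome slots when such a group exists, and otherwise lands in the noise
#' set (these strays are the translocation candidates the rate estimator
#' counts). Groups are renumbered 1..L by descending member count, ties
#' broken by the consensus vector (so numbering is invariant to input row
#' order).
#'
#' @param vectors assignment-vector matrix from
#'   \code{\link{assignmentVectors}}.
#' @param minSupport minimum members for a vector class to seed a linkage
#'   group (default 5).
#' @param epsilon maximum fraction of deviating genome slots for attaching a
#'   near-miss ortholog (default 0.05).
#' @return a \linkS4class{LinkageGroupSet}
#' @export
clusterLinkageGroups <- function(vectors, minSupport = 5L, epsilon = 0.05) {
  G <- ncol(vectors)
  key <- apply(vectors, 1L, paste, collapse = "\r")
  classes <- split(rownames(vectors), key)
  sizes <- vapply(classes, length, integer(1))
  seeds <- names(classes)[sizes >= minSupport]
  if (!length(seeds))
    stop("no vector class reaches minSupport = ", minSupport,
         "; consider lowering the threshold")
  # deterministic order: descending size, then vector string
  seeds <- seeds[order(-sizes[seeds], seeds)]
  consensus <- do.call(rbind, strsplit(seeds, "\r", fixed = TRUE))
  colnames(consensus) <- colnames(vectors)
  member <- lapply(classes[seeds], identity)
  noise <- character(0)
  maxDev <- floor(epsilon * G)
  strays <- setdiff(names(classes), seeds)
  for (s in strays) {
    v <- strsplit(s, "\r", fixed = TRUE)[[1]]
    dev <- rowSums(consensus != matrix(v, nrow = nrow(consensus),
                                       ncol = G, byrow = TRUE))
    hit <- which(dev <= maxDev)
    if (length(hit) == 1L)
      member[[hit]] <- c(member[[hit]], classes[[s]])
    else
      noise <- c(noise, classes[[s]])
  }
  support <- vapply(member, length, integer(1))
  ord <- order(-support, seeds)
  member <- member[ord]; consensus <- consensus[ord, , drop = FALSE]
  support <- support[ord]
  L <- length(member)
  membership <- data.frame(
    og_id = unlist(member, use.names = FALSE),
    mlg_id = rep(seq_len(L), support), stringsAsFactors = FALSE)
  purity <- matrix(1, nrow = L, ncol = G,
                   dimnames = list(NULL, colnames(vectors)))
  for (i in seq_len(L)) {
    vm <- vectors[member[[i]], , drop = FALSE]
    purity[i, ] <- colMeans(vm == matrix(consensus[i, ], nrow = nrow(vm),
                                         ncol = G, byrow = TRUE))
  }
  rownames(consensus) <- NULL
  new("LinkageGroupSet", membership = membership, consensus = consensus,
      support = unname(support), purity = purity, noise = sort(noise),
      params = list(min_support = minSupport, epsilon = epsilon,
                    genomes = colnames(vectors)))
}

#' Partition linkage groups by shared consensus chromosome in one genome
#'
#' Linkage groups whose members sit on one and the same chromosome of the
#' focal genome form a fused set (a fusion signal); groups alone on their
#' chromosome are unfused singletons. The partition covers every linkage
#' group exactly once.
#'
#' @param lgs a \linkS4class{LinkageGroupSet}.
#' @param genome genome id (a column of the consensus matrix).
#' @return named list of integer vectors of mlg_ids, named by chromosome id.
#' @export
fusedSets <- function(lgs, genome) {
  cons <- mlgConsensus(lgs)
  stopifnot(genome %in% colnames(cons))
  sets <- split(seq_len(nrow(cons)), cons[, genome])
  lapply(sets, function(v) sort(unname(v)))
}
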