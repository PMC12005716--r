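#' @include mlg-infer.R
NULL

#' Non-syntenic fraction between two genomes
#'
#' An ortholog is non-syntenic for a genome pair iff its chromosome in
#' either genome differs from its linkage group's consensus chromosome in
#' that genome. Orthologs in the clustering noise set (the translocation
#' candidates) are attributed to the linkage group whose consensus vector is
#' nearest to theirs (unique minimal Hamming distance), so their violation
#' is charged to the genome(s) they were actually moved in; a stray with no
#' unique nearest group counts as violating in both genomes. The fraction
#' is symmetric in the pair by construction.
#'
#' @param vectors assignment-vector matrix (all universal single-copy
#'   orthologs, including noise rows).
#' @param lgs a \linkS4class{LinkageGroupSet}.
#' @param genomeA,genomeB genome ids.
#' @return list(fraction, violating, total).
#' @export
nonsyntenicFraction <- function(vectors, lgs, genomeA, genomeB) {
  stopifnot(all(c(genomeA, genomeB) %in% colnames(vectors)))
  total <- nrow(vectors)
  if (!total) stop("zero shared orthologs between the pair")
  mem <- mlgMembership(lgs)
  cons <- mlgConsensus(lgs)
  mlgOf <- setNames(mem$mlg_id, mem$og_id)
  m <- unname(mlgOf[rownames(vectors)])
  stray <- which(is.na(m))
  for (i in stray) {
    d <- rowSums(cons != matrix(vectors[i, ], nrow = nrow(cons),
                                ncol = ncol(cons), byrow = TRUE))
    best <- which(d == min(d))
    if (length(best) == 1L) m[i] <- best
  }
  violA <- violB <- rep(TRUE, total)
  ok <- !is.na(m)
  violA[ok] <- vectors[ok, genomeA] != cons[m[ok], genomeA]
  violB[ok] <- vectors[ok, genomeB] != cons[m[ok], genomeB]
  viol <- sum(violA | violB)
  list(fraction = viol / total, violating = viol, total = total)
}

#' Translocation rate from a non-syntenic fraction and a divergence time
#'
#' r = c / t, the non-syntenic rate of change divided by the estimated
#' divergence time (per My). Set \code{perLineage = TRUE} to divide by 2t
#' (total branch time separating the pair) instead.
#'
#' @param c non-syntenic fraction in [0, 1].
#' @param t divergence time in My (> 0).
#' @param perLineage normalize by 2t instead of t.
#' @return list(rate, c, t, per_lineage).
#' @export
translocationRate <- function(c, t, perLineage = FALSE) {
  if (t <= 0) stop("divergence time must be > 0")
  if (c < 0 || c > 1) stop("non-syntenic fraction must lie in [0, 1]")
  denom <- if (perLineage) 2 * t else t
  list(rate = c / denom, c = c, t = t, per_lineage = perLineage)
}

#' Translocation rates for all genome pairs
#'
#' @param vectors assignment-vector matrix.
#' @param lgs a \linkS4class{LinkageGroupSet}.
#' @param tree dated \code{phylo} with tips matching the genome columns.
#' @param perLineage see \code{\link{translocationRate}}.
#' @return data.frame genome_a, genome_b, c, t, rate.
#' @export
pairwiseRates <- function(vectors, lgs, tree, perLineage = FALSE) {
  gms <- colnames(vectors)
  prs <- utils::combn(gms, 2L)
  rows <- lapply(seq_len(ncol(prs)), function(i) {
    a <- prs[1, i]; b <- prs[2, i]
    cf <- nonsyntenicFraction(vectors, lgs, a, b)
    t <- divergenceTime(tree, a, b)
    r <- translocationRate(cf$fraction, t, perLineage)
    data.frame(genome_a = a, genome_b = b, c = cf$fraction, t = t,
               rate = r$rate, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Gene-occupancy matrix of a genome against the linkage groups
#'
#' Counts each linkage group's orthologs per chromosome of one genome: the
#' numeric backbone of an Oxford plot against the ancestral groups. Rows
#' and columns are greedily ordered for display, largest cell first.
#'
#' @param assignments long-format assignment table for the genome, with
#'   columns chrom_id and mlg_id (e.g. the relevant rows of
#'   \code{\link{readMlgAssignments}} output, or built from vectors +
#'   membership).
#' @return integer matrix, rows = chromosomes, columns = mlg ids, with a
#'   display ordering applied.
#' @export
occupancyMatrix <- function(assignments) {
  stopifnot(all(c("chrom_id", "mlg_id") %in% names(assignments)))
  tab <- table(assignments$chrom_id, assignments$mlg_id)
  m <- matrix(as.integer(tab), nrow = nrow(tab), dimnames = dimnames(tab))
  # greedy display order: repeatedly take the largest remaining cell
  rowsLeft <- rownames(m); colsLeft <- colnames(m)
  ro <- character(0); co <- character(0)
  mm <- m
  while (length(rowsLeft) && length(colsLeft)) {
    sub <- mm[rowsLeft, colsLeft, drop = FALSE]
    ij <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    ro <- c(ro, rowsLeft[ij[1]]); co <- c(co, colsLeft[ij[2]])
    rowsLeft <- setdiff(rowsLeft, rowsLeft[ij[1]])
    colsLeft <- setdiff(colsLeft, colsLeft[ij[2]])
  }
  m[c(ro, rowsLeft), c(co, colsLeft), drop = FALSE]
}

#' Long-format dot-plot table for Oxford plots
#'
#' One row per placed ortholog of one genome: chromosome, within-chromosome
#' position rank (by gene midpoint), and linkage group. Deterministic:
#' shuffling input rows leaves the output identical.
#'
#' @param genome a \linkS4class{KaryoGenome}.
#' @param lgs a \linkS4class{LinkageGroupSet}.
#' @param universal the universal single-copy \linkS4class{OrthoGroupSet}.
#' @return data.frame gene_id, og_id, chrom, rank, mlg_id.
#' @export
dotplotTable <- function(genome, lgs, universal) {
  tb <- orthoTable(universal)
  tb <- tb[tb$genome_id == genomeId(genome), , drop = FALSE]
  mem <- mlgMembership(lgs)
  mlgOf <- setNames(mem$mlg_id, mem$og_id)
  df <- geneTable(genome)
  df <- df[df$gene_id %in% tb$gene_id, , drop = FALSE]
  df$og_id <- tb$og_id[match(df$gene_id, tb$gene_id)]
  df$mlg_id <- unname(mlgOf[df$og_id])
  df <- df[!is.na(df$mlg_id), , drop = FALSE]
  df <- df[order(df$chrom, df$mid, df$gene_id), ]
  df$rank <- unlist(lapply(split(seq_len(nrow(df)), df$chrom),
                           seq_along), use.names = FALSE)
  rownames(df) <- NULL
  df[, c("gene_id", "og_id", "chrom", "rank", "mlg_id")]
}

#' Oxford plot of a genome against the linkage groups
#'
#' Scatter of ortholog position rank per chromosome, coloured by linkage
#' group. Requires ggplot2.
#'
#' @param dots data.frame from \code{\link{dotplotTable}}.
#' @return a ggplot object.
#' @export
plotOxford <- function(dots) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plotOxford requires the ggplot2 package")
  ggplot2::ggplot(dots,
      ggplot2::aes(x = .data$rank, y = factor(.data$mlg_id),
                   colour = factor(.data$mlg_id))) +
    ggplot2::geom_point(size = 0.4, show.legend = FALSE) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position rank", y = "ancestral linkage group") +
    ggplot2::theme_minimal()
}
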