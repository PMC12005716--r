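#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges seqnames start end strand width
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqlengths seqlevels seqinfo Seqinfo seqlengths<-
NULL

setOldClass("phylo")

#' KaryoGenome: one chromosome-level genome with gene placements
#'
#' Wraps a \link[GenomicRanges]{GRanges} of gene loci (metadata column
#' \code{gene_id}) together with a genome identifier. Chromosome lengths live
#' in the seqinfo; when no assembly lengths are supplied they are inferred as
#' the maximum gene end per chromosome. Coordinates follow the GRanges
#' convention (1-based, inclusive); BED input is converted on read.
#'
#' @slot genomeId single string naming the genome (matches tree tip labels).
#' @slot genes \code{GRanges} with one range per gene and \code{mcols()$gene_id}.
#'
#' @export
setClass("KaryoGenome",
  representation(genomeId = "character", genes = "GRanges"))

setValidity("KaryoGenome", function(object) {
  msg <- character(0)
  if (length(object@genomeId) != 1L || is.na(object@genomeId) ||
      !nzchar(object@genomeId))
    msg <- c(msg, "genomeId must be a single non-empty string")
  gr <- object@genes
  ids <- mcols(gr)$gene_id
  if (is.null(ids))
    msg <- c(msg, "genes must carry a gene_id metadata column")
  else {
    if (anyDuplicated(ids))
      msg <- c(msg, sprintf("duplicate gene_id within genome: %s",
        paste(unique(ids[duplicated(ids)])[1:min(3, sum(duplicated(ids)))],
              collapse = ", ")))
    if (any(is.na(ids) | !nzchar(ids)))
      msg <- c(msg, "gene_id values must be non-empty")
  }
  if (length(gr) && any(width(gr) < 1L))
    msg <- c(msg, "gene ranges must have width >= 1")
  sl <- seqlengths(gr)
  if (length(gr) && !all(is.na(sl))) {
    lens <- sl[as.character(seqnames(gr))]
    bad <- !is.na(lens) & end(gr) > lens
    if (any(bad))
      msg <- c(msg, sprintf("%d gene(s) extend beyond their chromosome length",
                            sum(bad)))
  }
  if (length(msg)) msg else TRUE
})

#' GenomeSet: a named collection of KaryoGenome objects
#'
#' @slot genomes list of \linkS4class{KaryoGenome}, named by genome id.
#' @export
setClass("GenomeSet", representation(genomes = "list"))

setValidity("GenomeSet", function(object) {
  gs <- object@genomes
  if (!length(gs)) return(TRUE)
  if (!all(vapply(gs, is, logical(1), "KaryoGenome")))
    return("all elements must be KaryoGenome objects")
  ids <- vapply(gs, function(g) g@genomeId, character(1))
  if (is.null(names(gs)) || !identical(unname(ids), names(gs)))
    return("list names must equal the genomes' genomeId")
  if (anyDuplicated(ids)) return("duplicate genome ids")
  TRUE
})

#' OrthoGroupSet: cross-genome ortholog groups
#'
#' A long-format table of (og_id, genome_id, gene_id) rows. Per-genome copy
#' numbers are derived, not stored. A gene may belong to at most one group.
#'
#' @slot tbl data.frame with columns og_id, genome_id, gene_id.
#' @export
setClass("OrthoGroupSet", representation(tbl = "data.frame"))

setValidity("OrthoGroupSet", function(object) {
  tb <- object@tbl
  need <- c("og_id", "genome_id", "gene_id")
  if (!all(need %in% names(tb)))
    return(sprintf("tbl must have columns %s", paste(need, collapse = ", ")))
  key <- paste(tb$genome_id, tb$gene_id, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    # same gene listed twice is only an error if under two different groups
    ogs <- split(tb$og_id, key)
    multi <- vapply(ogs, function(x) length(unique(x)) > 1L, logical(1))
    if (any(multi))
      return(sprintf("gene(s) listed under more than one og_id, e.g. %s",
                     sub("\r.*", "", names(ogs)[multi][1])))
  }
  TRUE
})

#' LinkageGroupSet: inferred ancestral linkage groups
#'
#' Result of \code{\link{clusterLinkageGroups}}. Linkage groups are numbered
#' 1..L by descending member count (1 = largest). \code{consensus} holds, for
#' every linkage group and genome, the chromosome carrying the group's members
#' in that genome; \code{purity} the fraction of members actually on that
#' chromosome. Orthologs whose placement vector matched no group are kept in
#' \code{noise}: these are the translocation candidates used by the rate
#' estimator.
#'
#' @slot membership data.frame with columns og_id, mlg_id.
#' @slot consensus character matrix, rows = linkage groups, cols = genomes.
#' @slot support integer vector of member counts per linkage group.
#' @slot purity numeric matrix parallel to \code{consensus}.
#' @slot noise character vector of unassigned og_ids.
#' @slot params list of clustering parameters (min_support, epsilon, genomes).
#' @export
setClass("LinkageGroupSet",
  representation(membership = "data.frame", consensus = "matrix",
                 support = "integer", purity = "matrix", noise = "character",
                 params = "list"))

setValidity("LinkageGroupSet", function(object) {
  L <- nrow(object@consensus)
  if (length(object@support) != L)
    return("support length must equal number of linkage groups")
  if (!identical(dim(object@purity), dim(object@consensus)))
    return("purity and consensus dimensions differ")
  if (L > 1 && any(diff(object@support) > 0))
    return("linkage groups must be ordered by non-increasing support")
  m <- object@membership
  if (!all(c("og_id", "mlg_id") %in% names(m)))
    return("membership must have columns og_id, mlg_id")
  if (nrow(m) && (any(m$mlg_id < 1L) || any(m$mlg_id > L)))
    return("membership mlg_id out of range")
  TRUE
})

#' KaryoSim: a simulated evolutionary scenario with ground truth
#'
#' Holds the tip genomes produced by \code{\link{evolveGenomes}} along with
#' everything needed to audit them: the ancestor, the dated tree, the true
#' ortholog-to-linkage-group map, and the realized event ledger. Replaying the
#' ledger from the ancestor reproduces every tip exactly
#' (see \code{\link{replayLedger}}).
#'
#' @slot ancestor \linkS4class{KaryoGenome} ancestral genome.
#' @slot tips \linkS4class{GenomeSet} of tip genomes.
#' @slot tree \code{phylo} dated tree (branch lengths in My).
#' @slot truth data.frame og_id -> true linkage group (column \code{lg}).
#' @slot ledger data.frame of realized events in application order.
#' @slot orthologs \linkS4class{OrthoGroupSet} true orthology across tips.
#' @slot seed integer seed the scenario was generated under.
#' @export
setClass("KaryoSim",
  representation(ancestor = "KaryoGenome", tips = "GenomeSet", tree = "phylo",
                 truth = "data.frame", ledger = "data.frame",
                 orthologs = "OrthoGroupSet", seed = "integer"))
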