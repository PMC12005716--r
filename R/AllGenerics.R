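#' @include AllClasses.R
NULL

#' Accessors for karyolg classes
#'
#' @param x a karyolg object.
#' @param ... unused.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genomeId", function(x, ...) standardGeneric("genomeId"))

#' @rdname accessors
#' @export
setGeneric("geneRanges", function(x, ...) standardGeneric("geneRanges"))

#' @rdname accessors
#' @export
setGeneric("chromLengths", function(x, ...) standardGeneric("chromLengths"))

#' @rdname accessors
#' @export
setGeneric("nGenes", function(x, ...) standardGeneric("nGenes"))

#' @rdname accessors
#' @export
setGeneric("nChroms", function(x, ...) standardGeneric("nChroms"))

#' @rdname accessors
#' @export
setGeneric("orthoTable", function(x, ...) standardGeneric("orthoTable"))

#' @rdname accessors
#' @export
setGeneric("copyNumber", function(x, ...) standardGeneric("copyNumber"))

#' @rdname accessors
#' @export
setGeneric("mlgMembership", function(x, ...) standardGeneric("mlgMembership"))

#' @rdname accessors
#' @export
setGeneric("mlgConsensus", function(x, ...) standardGeneric("mlgConsensus"))

#' @rdname accessors
#' @export
setGeneric("mlgSupport", function(x, ...) standardGeneric("mlgSupport"))

#' @rdname accessors
#' @export
setGeneric("noiseSet", function(x, ...) standardGeneric("noiseSet"))

#' @rdname accessors
#' @export
setGeneric("eventLedger", function(x, ...) standardGeneric("eventLedger"))

#' @rdname accessors
#' @export
setGeneric("truthMap", function(x, ...) standardGeneric("truthMap"))

## ---- KaryoGenome ----

#' @rdname accessors
#' @export
setMethod("genomeId", "KaryoGenome", function(x, ...) x@genomeId)

#' @rdname accessors
#' @export
setMethod("geneRanges", "KaryoGenome", function(x, ...) x@genes)

#' @rdname accessors
#' @export
setMethod("chromLengths", "KaryoGenome", function(x, ...) {
  sl <- seqlengths(x@genes)
  if (all(is.na(sl)) && length(x@genes)) {
    # infer from furthest gene end
    ends <- tapply(end(x@genes), as.character(seqnames(x@genes)), max)
    sl[names(ends)] <- as.integer(ends)
  }
  sl
})

#' @rdname accessors
#' @export
setMethod("nGenes", "KaryoGenome", function(x, ...) length(x@genes))

#' @rdname accessors
#' @export
setMethod("nChroms", "KaryoGenome", function(x, ...)
  length(seqlevels(x@genes)))

setMethod("show", "KaryoGenome", function(object) {
  cat(sprintf("KaryoGenome '%s': %d genes on %d chromosomes\n",
              object@genomeId, nGenes(object), nChroms(object)))
})

#' Gene table of a genome
#'
#' Plain data.frame view of a genome's gene loci (1-based inclusive
#' coordinates), ordered by chromosome then start.
#'
#' @param x a \linkS4class{KaryoGenome}.
#' @return data.frame with columns gene_id, chrom, start, end, strand, mid.
#' @export
geneTable <- function(x) {
  stopifnot(is(x, "KaryoGenome"))
  gr <- x@genes
  df <- data.frame(gene_id = mcols(gr)$gene_id,
                   chrom = as.character(seqnames(gr)),
                   start = start(gr), end = end(gr),
                   strand = as.character(strand(gr)),
                   stringsAsFactors = FALSE)
  df$mid <- (df$start + df$end) / 2
  df[order(df$chrom, df$mid, df$gene_id), , drop = FALSE]
}

#' Chromosome ids in display order (descending length)
#'
#' @param x a \linkS4class{KaryoGenome}.
#' @export
chromOrder <- function(x) {
  sl <- chromLengths(x)
  names(sl)[order(-as.numeric(sl), names(sl))]
}

## ---- GenomeSet ----

#' Build a GenomeSet from KaryoGenome objects
#' @param ... KaryoGenome objects (or a single list of them).
#' @return a \linkS4class{GenomeSet}
#' @export
GenomeSet <- function(...) {
  gs <- list(...)
  if (length(gs) == 1L && is.list(gs[[1]]) && !is(gs[[1]], "KaryoGenome"))
    gs <- gs[[1]]
  names(gs) <- vapply(gs, genomeId, character(1))
  new("GenomeSet", genomes = gs)
}

#' @rdname accessors
#' @export
setMethod("genomeId", "GenomeSet", function(x, ...) names(x@genomes))

#' @export
setMethod("length", "GenomeSet", function(x) length(x@genomes))

#' @export
setMethod("names", "GenomeSet", function(x) names(x@genomes))

#' @export
setMethod("[[", "GenomeSet", function(x, i) x@genomes[[i]])

setMethod("show", "GenomeSet", function(object) {
  cat(sprintf("GenomeSet of %d genomes: %s\n", length(object),
              paste(names(object), collapse = ", ")))
})

## ---- OrthoGroupSet ----

#' @rdname accessors
#' @export
setMethod("orthoTable", "OrthoGroupSet", function(x, ...) x@tbl)

#' @rdname accessors
#' @export
setMethod("length", "OrthoGroupSet", function(x) length(unique(x@tbl$og_id)))

#' Per-group, per-genome copy numbers
#'
#' @param x an \linkS4class{OrthoGroupSet}.
#' @param genomes optional character vector fixing the column order (genomes
#'   with no member get copy number 0).
#' @return integer matrix, rows = og_id (sorted), columns = genomes.
#' @export
setMethod("copyNumber", "OrthoGroupSet", function(x, genomes = NULL, ...) {
  tb <- x@tbl
  ogs <- sort(unique(tb$og_id))
  gms <- if (is.null(genomes)) sort(unique(tb$genome_id)) else genomes
  m <- matrix(0L, nrow = length(ogs), ncol = length(gms),
              dimnames = list(ogs, gms))
  tab <- table(factor(tb$og_id, levels = ogs),
               factor(tb$genome_id, levels = gms))
  m[] <- as.integer(tab)
  m
})

setMethod("show", "OrthoGroupSet", function(object) {
  cat(sprintf("OrthoGroupSet: %d groups, %d genes, %d genomes\n",
              length(object), nrow(object@tbl),
              length(unique(object@tbl$genome_id))))
})

## ---- LinkageGroupSet ----

#' @rdname accessors
#' @export
setMethod("mlgMembership", "LinkageGroupSet", function(x, ...) x@membership)

#' @rdname accessors
#' @export
setMethod("mlgConsensus", "LinkageGroupSet", function(x, ...) x@consensus)

#' @rdname accessors
#' @export
setMethod("mlgSupport", "LinkageGroupSet", function(x, ...) x@support)

#' @rdname accessors
#' @export
setMethod("noiseSet", "LinkageGroupSet", function(x, ...) x@noise)

#' @export
setMethod("length", "LinkageGroupSet", function(x) nrow(x@consensus))

setMethod("show", "LinkageGroupSet", function(object) {
  cat(sprintf(
    "LinkageGroupSet: %d linkage groups over %d genomes (%d members, %d noise)\n",
    length(object), ncol(object@consensus), nrow(object@membership),
    length(object@noise)))
})

## ---- KaryoSim ----

#' @rdname accessors
#' @export
setMethod("eventLedger", "KaryoSim", function(x, ...) x@ledger)

#' @rdname accessors
#' @export
setMethod("truthMap", "KaryoSim", function(x, ...) x@truth)

setMethod("show", "KaryoSim", function(object) {
  cat(sprintf(
    "KaryoSim: %d tips, %d ancestral linkage groups, %d events (seed %d)\n",
    length(object@tips), length(unique(object@truth$lg)),
    nrow(object@ledger), object@seed))
})
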