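#' @include AllGenerics.R
NULL

#' Construct a KaryoGenome from a gene table
#'
#' @param genomeId genome identifier (matches tree tip label).
#' @param genes data.frame with columns gene_id, chrom, start, end and
#'   optionally strand; coordinates 1-based inclusive.
#' @param chromLengths optional named integer vector of chromosome lengths;
#'   inferred as the maximum gene end per chromosome when absent.
#' @return a \linkS4class{KaryoGenome}
#' @export
KaryoGenome <- function(genomeId, genes, chromLengths = NULL) {
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  strand <- if ("strand" %in% names(genes)) genes$strand else "*"
  strand[is.na(strand) | strand == "."] <- "*"
  chroms <- if (is.null(chromLengths)) unique(genes$chrom) else
    names(chromLengths)
  missing_chr <- setdiff(unique(genes$chrom), chroms)
  if (length(missing_chr))
    stop("gene(s) placed on unknown chromosome(s): ",
         paste(missing_chr, collapse = ", "))
  si <- Seqinfo(seqnames = as.character(chroms),
                seqlengths = if (is.null(chromLengths))
                  rep(NA_integer_, length(chroms)) else
                  as.integer(chromLengths))
  gr <- GRanges(seqnames = factor(genes$chrom, levels = chroms),
                ranges = IRanges(start = genes$start, end = genes$end),
                strand = strand, seqinfo = si)
  mcols(gr)$gene_id <- as.character(genes$gene_id)
  if (is.null(chromLengths)) {
    ends <- tapply(end(gr), as.character(seqnames(gr)), max)
    sl <- setNames(rep(NA_integer_, length(chroms)), chroms)
    sl[names(ends)] <- as.integer(ends)
    seqlengths(gr) <- sl
  }
  new("KaryoGenome", genomeId = as.character(genomeId), genes = gr)
}

#' Read a gene coordinate table (BED or GFF3) into a KaryoGenome
#'
#' BED input (>= 4 columns: chrom, start, end, name) uses 0-based half-open
#' coordinates and is converted to the 1-based inclusive convention used
#' internally. GFF3 input is filtered to \code{gene} features and the
#' \code{ID} attribute becomes the gene id. Records violating basic sanity
#' (start >= end in BED, missing name) raise an error naming the offending
#' line.
#'
#' @param path file path.
#' @param format "bed" or "gff3" (guessed from the extension by default).
#' @param genomeId genome identifier; defaults to the file stem.
#' @param chromLengths optional named vector of chromosome lengths.
#' @return a \linkS4class{KaryoGenome}
#' @export
readGeneTable <- function(path, format = c("auto", "bed", "gff3"),
                          genomeId = NULL, chromLengths = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("gff", "gff3")) "gff3" else "bed"
  }
  if (is.null(genomeId))
    genomeId <- tools::file_path_sans_ext(basename(path))
  if (format == "bed") {
    lines <- readLines(path)
    keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
    idx <- which(keep)
    fields <- strsplit(lines[idx], "\t", fixed = TRUE)
    for (i in seq_along(fields)) {
      f <- fields[[i]]
      ln <- idx[i]
      if (length(f) < 4L)
        stop(sprintf("%s line %d: BED needs >= 4 columns", path, ln))
      s <- suppressWarnings(as.numeric(f[2])); e <- suppressWarnings(as.numeric(f[3]))
      if (is.na(s) || is.na(e))
        stop(sprintf("%s line %d: non-numeric coordinates", path, ln))
      if (s < 0 || s >= e)
        stop(sprintf("%s line %d: requires 0 <= start < end", path, ln))
      if (!nzchar(f[1]) || !nzchar(f[4]))
        stop(sprintf("%s line %d: empty chrom or name", path, ln))
    }
    genes <- data.frame(
      gene_id = vapply(fields, `[`, character(1), 4L),
      chrom = vapply(fields, `[`, character(1), 1L),
      start = vapply(fields, function(f) as.integer(f[2]), integer(1)) + 1L,
      end = vapply(fields, function(f) as.integer(f[3]), integer(1)),
      strand = vapply(fields, function(f)
        if (length(f) >= 6L) f[6] else "*", character(1)),
      stringsAsFactors = FALSE)
  } else {
    gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                   error = function(e)
                     stop("failed to parse GFF3 ", path, ": ",
                          conditionMessage(e)))
    gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
    if (!length(gr)) stop("no gene features in ", path)
    ids <- gr$ID
    if (is.null(ids) || any(is.na(ids)))
      stop("GFF3 gene feature(s) without ID attribute in ", path)
    genes <- data.frame(gene_id = as.character(ids),
                        chrom = as.character(seqnames(gr)),
                        start = start(gr), end = end(gr),
                        strand = as.character(strand(gr)),
                        stringsAsFactors = FALSE)
  }
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id in ", path, ": ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)])[1:3],
               collapse = ", "))
  KaryoGenome(genomeId, genes, chromLengths)
}

#' Write a KaryoGenome as BED4 (+strand)
#'
#' Inverse of \code{readGeneTable(format = "bed")}; emits 0-based half-open
#' coordinates, rows ordered by chromosome (descending length) then start.
#'
#' @param x a \linkS4class{KaryoGenome}.
#' @param path output path.
#' @export
writeGeneBed <- function(x, path) {
  df <- geneTable(x)
  df$chrom <- factor(df$chrom, levels = chromOrder(x))
  df <- df[order(df$chrom, df$start, df$gene_id), ]
  out <- data.frame(df$chrom, df$start - 1L, df$end, df$gene_id, 0L,
                    ifelse(df$strand == "*", ".", df$strand))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ortholog-group table
#'
#' Expects a TSV with header columns og_id, genome_id, gene_id (one row per
#' gene). When a \linkS4class{GenomeSet} is supplied, genes not present in
#' the loaded genomes are reported with a warning.
#'
#' @param path TSV path.
#' @param genomes optional \linkS4class{GenomeSet} for cross-checking.
#' @return an \linkS4class{OrthoGroupSet}
#' @export
readOrthologTable <- function(path, genomes = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tb <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          stringsAsFactors = FALSE)
  if (!nrow(tb)) {
    warning("empty ortholog table: ", path)
    return(new("OrthoGroupSet",
               tbl = data.frame(og_id = character(0), genome_id = character(0),
                                gene_id = character(0))))
  }
  need <- c("og_id", "genome_id", "gene_id")
  if (!all(need %in% names(tb)))
    stop("ortholog table must have columns ", paste(need, collapse = ", "))
  ogs <- new("OrthoGroupSet", tbl = tb[need])
  if (!is.null(genomes)) {
    for (g in names(genomes)) {
      have <- mcols(geneRanges(genomes[[g]]))$gene_id
      listed <- tb$gene_id[tb$genome_id == g]
      miss <- setdiff(listed, have)
      if (length(miss))
        warning(sprintf("%d gene(s) of genome %s in %s are absent from the loaded genome",
                        length(miss), g, path))
    }
  }
  ogs
}

#' Read a rooted, dated newick tree
#'
#' Validates that the tree is rooted and strictly bifurcating at the root,
#' that branch lengths are present and non-negative, and (optionally) that
#' the tip labels match a set of genome ids. Unlabelled internal nodes are
#' auto-named \code{node<k>} by preorder index, deterministically.
#'
#' @param path newick file path (or a newick string).
#' @param genomes optional character vector (or \linkS4class{GenomeSet}) of
#'   genome ids the tips must match.
#' @return an \code{ape} \code{phylo} object.
#' @export
readTree <- function(path, genomes = NULL) {
  tr <- if (file.exists(path)) ape::read.tree(path) else ape::read.tree(text = path)
  if (is.null(tr)) stop("could not parse newick input")
  if (is.null(tr$edge.length))
    stop("tree must carry branch lengths (in My)")
  if (any(tr$edge.length < 0)) stop("negative branch length in tree")
  if (!ape::is.rooted(tr))
    stop("tree is unrooted; please provide a rooted tree (e.g. via outgroup rooting)")
  root <- ape::Ntip(tr) + 1L
  if (sum(tr$edge[, 1] == root) != 2L)
    stop("multifurcating root; please resolve/root the tree before use")
  if (anyDuplicated(tr$tip.label)) stop("duplicate tip labels")
  if (is.null(tr$node.label)) tr$node.label <- rep("", tr$Nnode)
  blank <- !nzchar(tr$node.label)
  if (any(blank)) {
    # deterministic naming by preorder index of the internal node
    ord <- preorderNodes(tr)
    internal <- ord[ord > ape::Ntip(tr)]
    pre_idx <- match(seq_len(tr$Nnode) + ape::Ntip(tr), internal)
    tr$node.label[blank] <- sprintf("node%d", pre_idx[blank])
  }
  if (anyDuplicated(c(tr$tip.label, tr$node.label)))
    stop("duplicate node labels after auto-naming")
  if (!is.null(genomes)) {
    ids <- if (is(genomes, "GenomeSet")) names(genomes) else genomes
    extra <- setdiff(tr$tip.label, ids)
    if (length(extra))
      stop("tree tip(s) match no genome: ", paste(extra, collapse = ", "))
  }
  tr
}

# preorder sequence of node indices (root first), deterministic
preorderNodes <- function(tree) {
  root <- ape::Ntip(tree) + 1L
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  out <- integer(0)
  stack <- root
  while (length(stack)) {
    n <- stack[1]; stack <- stack[-1]
    out <- c(out, n)
    ch <- kids[[as.character(n)]]
    if (!is.null(ch)) stack <- c(ch, stack)
  }
  out
}

# label of a node index (tips then internals, ape convention)
nodeLabel <- function(tree, idx) {
  ifelse(idx <= ape::Ntip(tree), tree$tip.label[idx],
         tree$node.label[idx - ape::Ntip(tree)])
}

#' Divergence time of two tips
#'
#' Mean root-to-tip path length below the pair's most recent common ancestor;
#' for an ultrametric (dated) tree this is the time since the pair diverged,
#' in the tree's branch-length units (My).
#'
#' @param tree a \code{phylo}.
#' @param a,b tip labels.
#' @export
divergenceTime <- function(tree, a, b) {
  ia <- match(a, tree$tip.label); ib <- match(b, tree$tip.label)
  if (is.na(ia) || is.na(ib)) stop("tip not in tree")
  mrca <- ape::getMRCA(tree, c(ia, ib))
  depth <- ape::node.depth.edgelength(tree)
  mean(c(depth[ia], depth[ib])) - depth[mrca]
}

#' Write / read linkage-group assignments
#'
#' The on-disk exchange format is a TSV with columns mlg_id, og_id,
#' genome_id, chrom_id, one row per (member, genome), stably sorted by
#' (mlg_id, og_id, genome_id). \code{readMlgAssignments} inverts
#' \code{writeMlgAssignments} exactly.
#'
#' @param x a \linkS4class{LinkageGroupSet}.
#' @param vectors assignment-vector matrix (og x genome chromosome ids), as
#'   produced by \code{\link{assignmentVectors}}; supplies each member's
#'   actual chromosome per genome.
#' @param path TSV path.
#' @export
writeMlgAssignments <- function(x, vectors, path) {
  stopifnot(is(x, "LinkageGroupSet"))
  m <- mlgMembership(x)
  if (!nrow(m)) stop("no linkage-group members to write")
  vec <- vectors[m$og_id, , drop = FALSE]
  long <- data.frame(
    mlg_id = rep(m$mlg_id, ncol(vec)),
    og_id = rep(m$og_id, ncol(vec)),
    genome_id = rep(colnames(vec), each = nrow(vec)),
    chrom_id = as.vector(vec),
    stringsAsFactors = FALSE)
  long <- long[order(long$mlg_id, long$og_id, long$genome_id), ]
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMlgAssignments
#' @return \code{readMlgAssignments}: data.frame with columns mlg_id, og_id,
#'   genome_id, chrom_id.
#' @export
readMlgAssignments <- function(path) {
  tb <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(mlg_id = "integer", og_id = "character",
                                         genome_id = "character",
                                         chrom_id = "character"))
  tb[order(tb$mlg_id, tb$og_id, tb$genome_id), , drop = FALSE]
}
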