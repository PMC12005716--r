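#' @include AllGenerics.R
NULL

#' Mutual best hits between two genomes
#'
#' A pair (a, b) is returned iff b is a's unique top-scoring target and a is
#' b's unique top-scoring query. Score ties at the top remove the tied gene
#' from consideration entirely (conservative: no arbitrary orthology).
#'
#' @param scores data.frame with columns query_gene, target_gene, bitscore
#'   (queries from genome A, targets from genome B).
#' @return data.frame with columns gene_a, gene_b (sorted by gene_a).
#' @export
mutualBestHits <- function(scores) {
  if (!nrow(scores)) {
    warning("empty score table: no mutual best hits")
    return(data.frame(gene_a = character(0), gene_b = character(0)))
  }
  stopifnot(all(c("query_gene", "target_gene", "bitscore") %in% names(scores)))
  bestUnique <- function(key, val, score) {
    # for each key, the unique top-scoring val (NA when the top is tied)
    o <- order(key, -score)
    key <- key[o]; val <- val[o]; score <- score[o]
    first <- !duplicated(key)
    top <- setNames(val[first], key[first])
    topscore <- setNames(score[first], key[first])
    rest <- which(!first)
    tied <- key[rest][score[rest] == topscore[key[rest]]]
    top[unique(tied)] <- NA
    top
  }
  bA <- bestUnique(scores$query_gene, scores$target_gene, scores$bitscore)
  bB <- bestUnique(scores$target_gene, scores$query_gene, scores$bitscore)
  a <- names(bA)
  b <- unname(bA[a])
  ok <- !is.na(b) & !is.na(bB[b]) & bB[b] == a
  out <- data.frame(gene_a = a[ok], gene_b = b[ok], stringsAsFactors = FALSE)
  out[order(out$gene_a), , drop = FALSE]
}

#' Chain pairwise mutual best hits into ortholog groups
#'
#' Builds a graph whose vertices are (genome, gene) pairs and whose edges are
#' the MBH pairs of every genome pair; connected components become candidate
#' ortholog groups. Group ids \code{OG<rank>} are assigned deterministically
#' by the sorted member gene ids.
#'
#' @param pairsets named list of MBH tables as returned by
#'   \code{\link{mutualBestHits}}; names of the form "A|B" giving the two
#'   genome ids (queries from A, targets from B).
#' @return an \linkS4class{OrthoGroupSet}
#' @export
chainToGroups <- function(pairsets) {
  if (length(pairsets) < 1L) stop("need MBH sets for at least one genome pair")
  edges <- do.call(rbind, lapply(names(pairsets), function(nm) {
    gms <- strsplit(nm, "|", fixed = TRUE)[[1]]
    if (length(gms) != 2L) stop("pairset names must be 'genomeA|genomeB'")
    ps <- pairsets[[nm]]
    if (!nrow(ps)) return(NULL)
    data.frame(from = paste(gms[1], ps$gene_a, sep = "\r"),
               to = paste(gms[2], ps$gene_b, sep = "\r"),
               stringsAsFactors = FALSE)
  }))
  if (is.null(edges) || !nrow(edges))
    return(new("OrthoGroupSet",
               tbl = data.frame(og_id = character(0), genome_id = character(0),
                                gene_id = character(0))))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  comp <- igraph::components(g)
  vert <- names(comp$membership)
  parts <- strsplit(vert, "\r", fixed = TRUE)
  tb <- data.frame(genome_id = vapply(parts, `[`, character(1), 1L),
                   gene_id = vapply(parts, `[`, character(1), 2L),
                   comp = comp$membership, stringsAsFactors = FALSE)
  # deterministic og ids: rank components by their sorted member gene ids
  keys <- vapply(split(tb$gene_id, tb$comp),
                 function(v) paste(sort(v), collapse = ","), character(1))
  ogOf <- setNames(sprintf("OG%05d", rank(keys, ties.method = "first")),
                   names(keys))
  tb$og_id <- unname(ogOf[as.character(tb$comp)])
  tb <- tb[order(tb$og_id, tb$genome_id, tb$gene_id),
           c("og_id", "genome_id", "gene_id")]
  rownames(tb) <- NULL
  new("OrthoGroupSet", tbl = tb)
}

#' Split ortholog groups into universal single-copy and duplication evidence
#'
#' The main set keeps groups present exactly once in every genome: these are
#' the markers linkage-group inference runs on. Groups present once
#' everywhere except exactly one genome where they have two copies are
#' returned separately as the duplication-evidence set consumed by the
#' duplication-vs-fission classifier.
#'
#' @param ogs an \linkS4class{OrthoGroupSet}.
#' @param genomes character vector of genome ids that must all be covered
#'   (or a \linkS4class{GenomeSet}).
#' @return list with elements \code{universal} and \code{dupEvidence}, both
#'   \linkS4class{OrthoGroupSet}s.
#' @export
filterUniversalSingleCopy <- function(ogs, genomes) {
  ids <- if (is(genomes, "GenomeSet")) names(genomes) else genomes
  cn <- copyNumber(ogs, genomes = ids)
  uni <- rownames(cn)[apply(cn == 1L, 1L, all)]
  dup <- rownames(cn)[apply(cn, 1L, function(v)
    sum(v == 2L) == 1L && all(v %in% c(1L, 2L)))]
  if (!length(uni))
    stop("no universal single-copy groups survive; inputs may be too ",
         "divergent or incomplete")
  tb <- orthoTable(ogs)
  list(universal = new("OrthoGroupSet", tbl = tb[tb$og_id %in% uni, ]),
       dupEvidence = new("OrthoGroupSet", tbl = tb[tb$og_id %in% dup, ]))
}
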