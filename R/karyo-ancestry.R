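#' @include mlg-infer.R
NULL

#' Binary co-localization characters from tip fused sets
#'
#' One character per unordered linkage-group pair (i, j), scored 1 for a tip
#' iff groups i and j sit on the same consensus chromosome of that tip.
#'
#' @param fused named list (by tip genome id) of fused-set partitions as
#'   returned by \code{\link{fusedSets}}.
#' @param nMlgs number of linkage groups L; the matrix has choose(L, 2)
#'   columns named "i|j".
#' @return binary integer matrix, rows = tips, columns = pairs.
#' @export
colocalizationCharacters <- function(fused, nMlgs) {
  if (!length(fused) || is.null(names(fused)))
    stop("fused must be a named list of tip partitions")
  pairs <- utils::combn(nMlgs, 2L)
  cn <- sprintf("%d|%d", pairs[1, ], pairs[2, ])
  m <- matrix(0L, nrow = length(fused), ncol = ncol(pairs),
              dimnames = list(names(fused), cn))
  for (tip in names(fused)) {
    for (set in fused[[tip]]) {
      if (length(set) < 2L) next
      p <- utils::combn(sort(set), 2L)
      m[tip, sprintf("%d|%d", p[1, ], p[2, ])] <- 1L
    }
  }
  m
}

# Fitch small parsimony for one binary character; returns final states for
# every node (1..Ntip+Nnode) with ambiguity at the root resolved to `prefer`.
fitchBinary <- function(tree, tipStates, prefer = 0L) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  prelim <- vector("list", nn)
  for (i in seq_len(ntip)) prelim[[i]] <- tipStates[i]
  post <- rev(preorderNodes(tree))
  for (n in post) {
    if (n <= ntip) next
    ch <- kids[[as.character(n)]]
    s <- prelim[[ch[1]]]
    for (c2 in ch[-1]) {
      inter <- intersect(s, prelim[[c2]])
      s <- if (length(inter)) inter else union(s, prelim[[c2]])
    }
    prelim[[n]] <- s
  }
  final <- integer(nn)
  for (n in preorderNodes(tree)) {
    if (n == ntip + 1L) {
      s <- prelim[[n]]
      final[n] <- if (length(s) == 1L) s else prefer
    } else {
      parent <- tree$edge[tree$edge[, 2] == n, 1]
      pf <- final[parent]
      final[n] <- if (pf %in% prelim[[n]]) pf else prelim[[n]][1]
    }
  }
  final
}

# Dollo reconstruction (single gain): the character is present exactly on the
# paths from the MRCA of the 1-tips down to those tips.
dolloBinary <- function(tree, tipStates) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  ones <- which(tipStates == 1L)
  final <- integer(nn)
  if (!length(ones)) return(final)
  m <- if (length(ones) == 1L) ones else ape::getMRCA(tree, ones)
  parentOf <- setNames(tree$edge[, 1], tree$edge[, 2])
  for (t in ones) {
    n <- t
    repeat {
      final[n] <- 1L
      if (n == m) break
      n <- parentOf[[as.character(n)]]
    }
  }
  final
}

#' Reconstruct ancestral karyotype states on a tree
#'
#' Runs small parsimony per co-localization character (Fitch down- and
#' up-pass with ambiguity at the root resolved toward 0/unfused, or Dollo
#' with fusions treated as unique gains), then derives each node's
#' chromosomes as the connected components of the graph whose edges are the
#' pairs reconstructed as fused at that node.
#'
#' @param characters tip character matrix from
#'   \code{\link{colocalizationCharacters}}.
#' @param tree rooted \code{phylo} whose tips equal the matrix rows.
#' @param mode "fitch" (default, reversible) or "dollo" (fusion gained once).
#' @return list with \code{nodeChar} (node x character 0/1 matrix),
#'   \code{components} (per node, list of integer vectors of mlg_ids), and
#'   \code{counts} (named 1n chromosome counts per node).
#' @export
reconstructStates <- function(characters, tree, mode = c("fitch", "dollo")) {
  mode <- match.arg(mode)
  if (!setequal(rownames(characters), tree$tip.label))
    stop("character matrix rows must match tree tips")
  characters <- characters[tree$tip.label, , drop = FALSE]
  if (any(colSums(is.na(characters)) == nrow(characters)))
    stop("character with all-missing states")
  ntip <- ape::Ntip(tree)
  labs <- c(tree$tip.label, tree$node.label)
  nodeChar <- matrix(0L, nrow = length(labs), ncol = ncol(characters),
                     dimnames = list(labs, colnames(characters)))
  for (j in seq_len(ncol(characters))) {
    nodeChar[, j] <- if (mode == "fitch")
      fitchBinary(tree, characters[, j]) else
      dolloBinary(tree, characters[, j])
  }
  L <- (1 + sqrt(1 + 8 * ncol(characters))) / 2
  L <- as.integer(round(L))
  pairIdx <- do.call(rbind, lapply(strsplit(colnames(characters), "|",
                                            fixed = TRUE), as.integer))
  comps <- lapply(seq_along(labs), function(i) {
    on <- nodeChar[i, ] == 1L
    g <- igraph::graph_from_data_frame(
      data.frame(from = pairIdx[on, 1], to = pairIdx[on, 2]),
      directed = FALSE, vertices = data.frame(name = seq_len(L)))
    cm <- igraph::components(g)$membership
    unname(lapply(split(as.integer(names(cm)), cm), sort))
  })
  names(comps) <- labs
  counts <- vapply(comps, length, integer(1))
  list(nodeChar = nodeChar, components = comps, counts = counts)
}

#' Tabulate reconstructed karyotypes
#'
#' @param states result of \code{\link{reconstructStates}}.
#' @return data.frame with columns node, chrom_index, mlgs (comma-joined),
#'   n_mlgs; chromosome index orders multi-group chromosomes first.
#' @export
karyotypeTable <- function(states) {
  rows <- lapply(names(states$components), function(nd) {
    cs <- states$components[[nd]]
    cs <- cs[order(-vapply(cs, length, integer(1)),
                   vapply(cs, min, integer(1)))]
    data.frame(node = nd, chrom_index = seq_along(cs),
               mlgs = vapply(cs, paste, character(1), collapse = ","),
               n_mlgs = vapply(cs, length, integer(1)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Call rearrangement events on every branch
#'
#' Compares each parent/child pair of reconstructed states. Child
#' chromosomes uniting several parent chromosomes are fusions: a k-way union
#' is decomposed into k - 1 pairwise FUSION steps (sharing one merge id) so
#' the minimum event count is reported. Parent chromosomes split across
#' several child chromosomes are fission candidates; at terminal branches
#' with paralog evidence they are routed through
#' \code{\link{classifyDupFission}}, otherwise called FISSION. Linkage
#' groups whose duplication-evidence fraction in a tip genome reaches
#' \code{dupThreshold} yield a DUPLICATION call on that terminal branch.
#' A fusion is flagged a synapomorphy when its cross-pairs are fused in all
#' tips descending from the branch and in no other tip.
#'
#' @param states result of \code{\link{reconstructStates}}.
#' @param tree the tree used for reconstruction.
#' @param characters the tip character matrix (for the synapomorphy check).
#' @param dupEvidence optional \linkS4class{OrthoGroupSet} of
#'   duplication-evidence groups.
#' @param genomes optional \linkS4class{GenomeSet} (needed with
#'   \code{dupEvidence}).
#' @param lgs optional \linkS4class{LinkageGroupSet} (needed with
#'   \code{dupEvidence}) to attach evidence groups to linkage groups.
#' @param dupThreshold fraction of duplicated, split members required to
#'   call DUPLICATION (default 0.5).
#' @return data.frame with columns parent, child, type, merge_id, step,
#'   operand_a, operand_b, mlgs, synapomorphy.
#' @export
callEvents <- function(states, tree, characters, dupEvidence = NULL,
                       genomes = NULL, lgs = NULL, dupThreshold = 0.5) {
  ntip <- ape::Ntip(tree)
  labs <- c(tree$tip.label, tree$node.label)
  tipsBelow <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    ape::extract.clade(tree, node)$tip.label
  }
  rows <- list()
  mergeCounter <- 0L
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]; c_ <- tree$edge[i, 2]
    pLab <- labs[p]; cLab <- labs[c_]
    pc <- states$components[[pLab]]
    cc <- states$components[[cLab]]
    if (!setequal(unlist(pc), unlist(cc)))
      stop("inconsistent states between ", pLab, " and ", cLab)
    pComp <- integer(0)
    for (k in seq_along(pc)) pComp[pc[[k]]] <- k
    cComp <- integer(0)
    for (k in seq_along(cc)) cComp[cc[[k]]] <- k
    inTips <- tipsBelow(c_)
    outTips <- setdiff(tree$tip.label, inTips)
    # fusions: child components spanning >1 parent component
    for (k in seq_along(cc)) {
      parts <- unique(pComp[cc[[k]]])
      if (length(parts) < 2L) next
      mergeCounter <- mergeCounter + 1L
      sets <- lapply(parts, function(q) sort(intersect(pc[[q]], cc[[k]])))
      sets <- sets[order(vapply(sets, min, integer(1)))]
      merged <- sort(unlist(sets))
      cross <- crossPairs(sets)
      syn <- all(characters[inTips, cross, drop = FALSE] == 1L) &&
        (length(outTips) == 0L ||
           all(characters[outTips, cross, drop = FALSE] == 0L))
      acc <- sets[[1]]
      for (s in seq_along(sets)[-1]) {
        rows[[length(rows) + 1L]] <- data.frame(
          parent = pLab, child = cLab, type = "FUSION",
          merge_id = mergeCounter, step = s - 1L,
          operand_a = paste(acc, collapse = ","),
          operand_b = paste(sets[[s]], collapse = ","),
          mlgs = paste(merged, collapse = ","),
          synapomorphy = syn, stringsAsFactors = FALSE)
        acc <- sort(c(acc, sets[[s]]))
      }
    }
    # fission candidates: parent components split across >1 child component
    for (k in seq_along(pc)) {
      parts <- unique(cComp[pc[[k]]])
      if (length(parts) < 2L) next
      type <- "FISSION"
      if (!is.null(dupEvidence) && c_ <= ntip && !is.null(genomes) &&
          !is.null(lgs)) {
        cls <- classifyDupFission(pc[[k]], cLab, dupEvidence, genomes, lgs,
                                  threshold = dupThreshold)
        type <- cls$call
      }
      rows[[length(rows) + 1L]] <- data.frame(
        parent = pLab, child = cLab, type = type, merge_id = NA_integer_,
        step = 1L,
        operand_a = paste(sort(pc[[k]]), collapse = ","),
        operand_b = "", mlgs = paste(sort(pc[[k]]), collapse = ","),
        synapomorphy = NA, stringsAsFactors = FALSE)
    }
    # duplications at terminal branches, from paralog evidence
    if (c_ <= ntip && !is.null(dupEvidence) && !is.null(genomes) &&
        !is.null(lgs)) {
      for (mlg in dupEvidenceMlgs(cLab, dupEvidence, genomes, lgs,
                                  dupThreshold)) {
        rows[[length(rows) + 1L]] <- data.frame(
          parent = pLab, child = cLab, type = "DUPLICATION",
          merge_id = NA_integer_, step = 1L,
          operand_a = as.character(mlg), operand_b = "",
          mlgs = as.character(mlg), synapomorphy = NA,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(parent = character(0), child = character(0),
                      type = character(0), merge_id = integer(0),
                      step = integer(0), operand_a = character(0),
                      operand_b = character(0), mlgs = character(0),
                      synapomorphy = logical(0)))
  do.call(rbind, rows)
}

# character columns ("i|j") crossing two of the listed disjoint sets
crossPairs <- function(sets) {
  out <- character(0)
  for (i in seq_along(sets)) for (j in seq_along(sets)) {
    if (i >= j) next
    g <- expand.grid(a = sets[[i]], b = sets[[j]])
    out <- c(out, sprintf("%d|%d", pmin(g$a, g$b), pmax(g$a, g$b)))
  }
  out
}

#' Merged (per-event) view of fusion calls
#'
#' Collapses the pairwise decomposition of \code{\link{callEvents}} back to
#' one row per fusion event, so a 3-way fusion like MLG 4+16+18 counts once.
#'
#' @param events data.frame from \code{\link{callEvents}}.
#' @return data.frame with one row per event (fusions collapsed by merge id).
#' @export
mergedEvents <- function(events) {
  if (!nrow(events)) return(events)
  fus <- events[events$type == "FUSION", , drop = FALSE]
  other <- events[events$type != "FUSION", , drop = FALSE]
  if (nrow(fus)) {
    keep <- !duplicated(fus$merge_id)
    fus <- fus[keep, , drop = FALSE]
    fus$step <- NA_integer_
    fus$operand_a <- fus$mlgs; fus$operand_b <- ""
  }
  out <- rbind(fus, other)
  out[order(match(out$child, unique(events$child)), out$merge_id), ,
      drop = FALSE]
}

# linkage groups of a tip genome whose duplication-evidence fraction reaches
# the threshold
dupEvidenceMlgs <- function(tipGenome, dupEvidence, genomes, lgs, threshold) {
  tb <- orthoTable(dupEvidence)
  tb <- tb[tb$genome_id == tipGenome, , drop = FALSE]
  if (!nrow(tb)) return(integer(0))
  mem <- mlgMembership(lgs)
  mlgOf <- setNames(mem$mlg_id, mem$og_id)
  cand <- unique(mlgOf[tb$og_id])
  cand <- cand[!is.na(cand)]
  hits <- integer(0)
  for (mlg in cand) {
    members <- mem$og_id[mem$mlg_id == mlg]
    dupOgs <- unique(tb$og_id[tb$og_id %in% members])
    # require the two copies on two different chromosomes
    gr <- geneRanges(genomes[[tipGenome]])
    chromOf <- setNames(as.character(seqnames(gr)), mcols(gr)$gene_id)
    split2 <- vapply(dupOgs, function(og) {
      ch <- unique(chromOf[tb$gene_id[tb$og_id == og]])
      length(ch) == 2L
    }, logical(1))
    if (length(members) && sum(split2) / length(members) >= threshold)
      hits <- c(hits, mlg)
  }
  sort(hits)
}

#' Classify a two-chromosome linkage-group split: duplication or fission?
#'
#' A linkage group observed on two chromosomes of a focal genome arose
#' either by fission (members partitioned, single copies) or by duplication
#' (members present twice, one copy per chromosome). The call is DUPLICATION
#' iff the fraction of the group's informative members carrying two copies
#' split one-per-chromosome reaches \code{threshold}; with zero informative
#' members the call falls back to FISSION with a warning.
#'
#' @param mlgSet integer vector of linkage-group id(s) under test.
#' @param focalGenome genome id.
#' @param dupEvidence \linkS4class{OrthoGroupSet} of duplication-evidence
#'   groups (copy number 2 in exactly one genome).
#' @param genomes \linkS4class{GenomeSet}.
#' @param lgs \linkS4class{LinkageGroupSet} (or a data.frame og_id/mlg_id).
#' @param threshold duplication fraction threshold (default 0.5).
#' @return list(call = "DUPLICATION"|"FISSION", fraction, informative).
#' @export
classifyDupFission <- function(mlgSet, focalGenome, dupEvidence, genomes,
                               lgs, threshold = 0.5) {
  mem <- if (is(lgs, "LinkageGroupSet")) mlgMembership(lgs) else lgs
  members <- mem$og_id[mem$mlg_id %in% mlgSet]
  tb <- orthoTable(dupEvidence)
  tb <- tb[tb$genome_id == focalGenome & tb$og_id %in% members, ,
           drop = FALSE]
  if (!length(members)) {
    warning("no informative orthogroups; defaulting to FISSION")
    return(list(call = "FISSION", fraction = NA_real_, informative = 0L))
  }
  gr <- geneRanges(genomes[[focalGenome]])
  chromOf <- setNames(as.character(seqnames(gr)), mcols(gr)$gene_id)
  dupOgs <- unique(tb$og_id)
  split2 <- vapply(dupOgs, function(og) {
    ch <- unique(chromOf[tb$gene_id[tb$og_id == og]])
    length(ch) == 2L
  }, logical(1))
  frac <- if (length(members)) sum(split2) / length(members) else 0
  list(call = if (frac >= threshold) "DUPLICATION" else "FISSION",
       fraction = frac, informative = length(members))
}

#' Mixing index of a fused chromosome
#'
#' Ratio of the observed number of adjacent gene pairs with different
#' linkage-group labels to its exact expectation under a uniformly random
#' permutation of the labels, (n - 1) * (1 - sum ni(ni - 1) / (n(n - 1))).
#' An index near 0 means the ancestral blocks are intact; near (or above) 1
#' means the groups are thoroughly interleaved. The chromosome is flagged
#' well-mixed at index >= 0.5 (a reporting flag only).
#'
#' @param labels vector of per-gene linkage-group labels in chromosome order
#'   (>= 3 genes).
#' @return list(index, observed, expected, well_mixed, applicable);
#'   a single-label chromosome returns applicable = FALSE with NA index.
#' @export
mixingIndex <- function(labels) {
  n <- length(labels)
  if (length(unique(labels)) < 2L)
    return(list(index = NA_real_, observed = NA_integer_,
                expected = NA_real_, well_mixed = NA, applicable = FALSE))
  if (n < 3L) stop("mixing index needs >= 3 genes")
  obs <- sum(labels[-1] != labels[-n])
  ni <- table(labels)
  expd <- (n - 1) * (1 - sum(ni * (ni - 1)) / (n * (n - 1)))
  idx <- obs / expd
  list(index = idx, observed = as.integer(obs), expected = expd,
       well_mixed = idx >= 0.5, applicable = TRUE)
}

#' Mixing report for every multi-group chromosome of a genome
#'
#' @param genome a \linkS4class{KaryoGenome}.
#' @param lgs a \linkS4class{LinkageGroupSet}.
#' @param universal the universal single-copy \linkS4class{OrthoGroupSet}
#'   used for inference (maps genes to groups).
#' @return data.frame chrom, n_genes, n_mlgs, mixing_index, well_mixed.
#' @export
chromosomeMixing <- function(genome, lgs, universal) {
  tb <- orthoTable(universal)
  tb <- tb[tb$genome_id == genomeId(genome), , drop = FALSE]
  mem <- mlgMembership(lgs)
  mlgOf <- setNames(mem$mlg_id, mem$og_id)
  df <- geneTable(genome)
  df$mlg <- unname(mlgOf[tb$og_id[match(df$gene_id, tb$gene_id)]])
  df <- df[!is.na(df$mlg), , drop = FALSE]
  out <- lapply(split(df, df$chrom), function(d) {
    d <- d[order(d$mid), ]
    mi <- if (nrow(d) >= 3L) mixingIndex(d$mlg) else
      list(index = NA_real_, well_mixed = NA, applicable = FALSE)
    data.frame(chrom = d$chrom[1], n_genes = nrow(d),
               n_mlgs = length(unique(d$mlg)),
               mixing_index = mi$index, well_mixed = mi$well_mixed,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
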