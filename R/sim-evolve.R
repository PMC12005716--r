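#' @include formats-io.R
NULL

## Internal mutable-ish genome representation used during simulation:
## list(chroms = named list of character vectors (gene ids in order),
##      og    = named character, gene_id -> ortholog-group id,
##      copy  = named integer,  gene_id -> paralog copy index)

toSimState <- function(kg, og = NULL, copy = NULL) {
  df <- geneTable(kg)
  # within-chromosome order by midpoint
  ord <- order(df$chrom, df$mid)
  chroms <- lapply(split(df$gene_id[ord], df$chrom[ord]), identity)
  ids <- df$gene_id
  if (is.null(og)) og <- setNames(ids, ids)
  if (is.null(copy)) copy <- setNames(rep(1L, length(ids)), ids)
  list(chroms = chroms, og = og, copy = copy)
}

# gene spacing used when materializing simulated genomes
.GENE_SPACING <- 1000L
.GENE_WIDTH <- 500L

fromSimState <- function(state, genomeId, renameBySize = FALSE) {
  chroms <- state$chroms
  if (renameBySize) {
    sizes <- vapply(chroms, length, integer(1))
    ord <- order(-sizes, names(chroms))
    chroms <- chroms[ord]
    names(chroms) <- sprintf("chr%d", seq_along(chroms))
  }
  n <- vapply(chroms, length, integer(1))
  genes <- data.frame(
    gene_id = unlist(chroms, use.names = FALSE),
    chrom = rep(names(chroms), n),
    start = unlist(lapply(n, function(k)
      (seq_len(k) - 1L) * .GENE_SPACING + 1L), use.names = FALSE),
    stringsAsFactors = FALSE)
  genes$end <- genes$start + .GENE_WIDTH - 1L
  lens <- setNames(pmax(n, 1L) * .GENE_SPACING, names(chroms))
  KaryoGenome(genomeId, genes, chromLengths = lens)
}

#' Create an ancestral genome of discrete linkage groups
#'
#' One chromosome per linkage group, genes laid out at evenly spaced,
#' deterministic coordinates. Gene ids double as ortholog-group ids for the
#' whole simulation.
#'
#' @param nLgs number of ancestral linkage groups (chromosomes). The bundled
#'   molluscan scenario uses 20.
#' @param genesPerLg genes per linkage group; a scalar, or a vector of length
#'   \code{nLgs} (strictly decreasing sizes make the inferred linkage-group
#'   numbering match the ancestral one).
#' @return list with elements \code{genome} (a \linkS4class{KaryoGenome},
#'   chromosomes \code{A01..}) and \code{truth} (data.frame og_id, lg).
#' @export
makeAncestor <- function(nLgs = 20L, genesPerLg = 200L) {
  if (nLgs < 1L) stop("nLgs must be >= 1")
  if (length(genesPerLg) == 1L) genesPerLg <- rep(genesPerLg, nLgs)
  if (length(genesPerLg) != nLgs) stop("genesPerLg must have length 1 or nLgs")
  if (any(genesPerLg < 1L)) stop("genesPerLg must be >= 1")
  lg <- rep(seq_len(nLgs), genesPerLg)
  gene_id <- sprintf("L%02dg%04d", lg,
                     unlist(lapply(genesPerLg, seq_len), use.names = FALSE))
  chrom <- sprintf("A%02d", lg)
  pos <- unlist(lapply(genesPerLg, seq_len), use.names = FALSE)
  genes <- data.frame(gene_id = gene_id, chrom = chrom,
                      start = (pos - 1L) * .GENE_SPACING + 1L,
                      stringsAsFactors = FALSE)
  genes$end <- genes$start + .GENE_WIDTH - 1L
  lens <- setNames(as.integer(genesPerLg) * .GENE_SPACING,
                   sprintf("A%02d", seq_len(nLgs)))
  list(genome = KaryoGenome("ancestor", genes, chromLengths = lens),
       truth = data.frame(og_id = gene_id, lg = lg, stringsAsFactors = FALSE))
}

#' Describe a rearrangement event
#'
#' @param type one of FUSION, FISSION, DUPLICATION, TRANSLOCATION, SHUFFLE.
#' @param chromA,chromB operand chromosome ids (B only for FUSION).
#' @param pi FUSION interleaving parameter in [0, 1]: 0 = pure block
#'   concatenation, 1 = fully random interleaving of the two gene sets.
#' @param breakpoint FISSION split index (genes 1..breakpoint stay on the
#'   first product); must lie in [1, nGenes - 1].
#' @param k TRANSLOCATION gene count (>= 1).
#' @export
rearrangementEvent <- function(type = c("FUSION", "FISSION", "DUPLICATION",
                                        "TRANSLOCATION", "SHUFFLE"),
                               chromA = NA, chromB = NA, pi = 1,
                               breakpoint = NA, k = 1L) {
  type <- match.arg(type)
  if (!is.na(pi) && (pi < 0 || pi > 1)) stop("pi must lie in [0, 1]")
  if (type == "TRANSLOCATION" && k < 1L) stop("k must be >= 1")
  list(type = type, chromA = chromA, chromB = chromB, pi = pi,
       breakpoint = breakpoint, k = as.integer(k), detail = NULL)
}

# interleave b into a: fraction pi of all genes become "mobile" and are
# re-inserted at uniform positions; pi = 0 keeps the block concatenation.
interleaveGenes <- function(a, b, pi) {
  merged <- c(a, b)
  if (pi <= 0 || length(merged) < 2L) return(merged)
  mobile <- stats::runif(length(merged)) < pi
  fixed <- merged[!mobile]
  for (g in merged[mobile]) {
    p <- sample.int(length(fixed) + 1L, 1L)
    fixed <- append(fixed, g, after = p - 1L)
  }
  fixed
}

# Apply one event to a sim state. If ev$detail is NULL the outcome is drawn
# from the current RNG and a fully realized event (replayable without RNG)
# is returned alongside the new state.
applyEventState <- function(state, ev) {
  ch <- state$chroms
  type <- ev$type
  if (type == "FUSION") {
    a <- ev$chromA; b <- ev$chromB
    if (identical(a, b)) stop("cannot fuse a chromosome with itself")
    if (!all(c(a, b) %in% names(ch)))
      stop("FUSION operand not in genome: ", paste(setdiff(c(a, b), names(ch)),
                                                   collapse = ", "))
    if (is.null(ev$detail)) {
      order <- interleaveGenes(ch[[a]], ch[[b]], ev$pi)
      ev$detail <- paste(order, collapse = ",")
    } else order <- strsplit(ev$detail, ",", fixed = TRUE)[[1]]
    newid <- paste(a, b, sep = "+")
    ch[[a]] <- NULL; ch[[b]] <- NULL
    ch[[newid]] <- order
  } else if (type == "FISSION") {
    a <- ev$chromA
    if (!a %in% names(ch)) stop("FISSION operand not in genome: ", a)
    n <- length(ch[[a]])
    bp <- ev$breakpoint
    if (is.na(bp) || bp < 1L || bp > n - 1L)
      stop(sprintf("FISSION breakpoint must lie in [1, %d]", n - 1L))
    genes <- ch[[a]]
    ch[[paste0(a, "/1")]] <- genes[seq_len(bp)]
    ch[[paste0(a, "/2")]] <- genes[(bp + 1L):n]
    ch[[a]] <- NULL
    ev$detail <- as.character(bp)
  } else if (type == "DUPLICATION") {
    a <- ev$chromA
    if (!a %in% names(ch)) stop("DUPLICATION operand not in genome: ", a)
    genes <- ch[[a]]
    newgenes <- paste0(genes, ".2")
    while (any(newgenes %in% names(state$og)))
      newgenes[newgenes %in% names(state$og)] <-
        paste0(newgenes[newgenes %in% names(state$og)], ".2")
    ch[[paste0(a, "*2")]] <- newgenes
    state$og[newgenes] <- unname(state$og[genes])
    state$copy[newgenes] <- unname(state$copy[genes]) + 1L
    ev$detail <- ""
  } else if (type == "TRANSLOCATION") {
    if (is.null(ev$detail)) {
      if (length(ch) < 2L) stop("TRANSLOCATION needs >= 2 chromosomes")
      allgenes <- unlist(ch, use.names = FALSE)
      k <- min(ev$k, length(allgenes))
      moved <- sample(allgenes, k)
      moves <- character(k)
      for (i in seq_len(k)) {
        g <- moved[i]
        src <- names(ch)[vapply(ch, function(v) g %in% v, logical(1))][1]
        dest <- sample(setdiff(names(ch), src), 1L)
        ch[[src]] <- setdiff(ch[[src]], g)
        p <- sample.int(length(ch[[dest]]) + 1L, 1L)
        ch[[dest]] <- append(ch[[dest]], g, after = p - 1L)
        moves[i] <- paste(g, dest, p, sep = ":")
      }
      ev$detail <- paste(moves, collapse = ";")
    } else {
      for (mv in strsplit(ev$detail, ";", fixed = TRUE)[[1]]) {
        f <- strsplit(mv, ":", fixed = TRUE)[[1]]
        g <- f[1]; dest <- f[2]; p <- as.integer(f[3])
        src <- names(ch)[vapply(ch, function(v) g %in% v, logical(1))][1]
        ch[[src]] <- setdiff(ch[[src]], g)
        ch[[dest]] <- append(ch[[dest]], g, after = p - 1L)
      }
    }
  } else if (type == "SHUFFLE") {
    a <- ev$chromA
    if (!a %in% names(ch)) stop("SHUFFLE operand not in genome: ", a)
    if (is.null(ev$detail)) {
      ch[[a]] <- sample(ch[[a]])
      ev$detail <- paste(ch[[a]], collapse = ",")
    } else ch[[a]] <- strsplit(ev$detail, ",", fixed = TRUE)[[1]]
  } else stop("unknown event type: ", type)
  state$chroms <- ch
  list(state = state, event = ev)
}

#' Apply a rearrangement event to a genome
#'
#' Gene counts are conserved by every event except DUPLICATION, which adds
#' exactly the duplicated chromosome's gene count (new paralog ids suffixed
#' \code{.2}).
#'
#' @param genome a \linkS4class{KaryoGenome}.
#' @param event a \code{\link{rearrangementEvent}}; operand chromosome ids
#'   refer to \code{genome}'s chromosomes.
#' @return a new \linkS4class{KaryoGenome}.
#' @export
applyEvent <- function(genome, event) {
  st <- toSimState(genome)
  res <- applyEventState(st, event)
  fromSimState(res$state, genomeId(genome))
}

# chromosome currently carrying (the bulk of) an ancestral linkage group
resolveChromForLg <- function(state, lg, truth) {
  lgOf <- setNames(truth$lg, truth$og_id)
  counts <- vapply(state$chroms, function(genes)
    sum(lgOf[state$og[genes]] == lg, na.rm = TRUE), numeric(1))
  if (all(counts == 0)) stop("no chromosome carries linkage group ", lg)
  names(counts)[which.max(counts)]
}

.hashString <- function(s) {
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 2147483647
  as.integer(h)
}

#' Evolve an ancestral genome along a dated tree
#'
#' Traverses the tree in preorder; on each branch, applies the scripted
#' events for that branch (in script order), then Poisson-drawn background
#' events (count ~ rate x branch length), then, on terminal branches, a
#' translocation of \code{round(tipNoise x nGenes)} randomly chosen genes.
#' Each branch uses an RNG substream derived from the global seed and the
#' child node label, so editing one branch's script does not perturb others.
#'
#' @param ancestor result of \code{\link{makeAncestor}} (list genome + truth).
#' @param tree rooted dated \code{phylo} (see \code{\link{readTree}}).
#' @param script data.frame of scripted events with columns branch (child
#'   node label), type, and operand columns lg_a, lg_b (ancestral
#'   linkage-group numbers; resolved to the chromosome currently carrying
#'   that group), plus optional pi, breakpoint, k.
#' @param rates named numeric vector of background event rates per My
#'   (names among the event types), or NULL.
#' @param seed integer seed.
#' @param tipNoise fraction of genes translocated on each terminal branch
#'   (0 disables).
#' @param transK genes moved per background TRANSLOCATION event.
#' @return a \linkS4class{KaryoSim}.
#' @export
evolveGenomes <- function(ancestor, tree, script = NULL, rates = NULL,
                          seed = 1L, tipNoise = 0, transK = 1L) {
  if (!is.null(rates) && any(rates < 0)) stop("rates must be >= 0")
  if (!is.null(script) && nrow(script)) {
    labs <- c(tree$tip.label, tree$node.label)
    bad <- setdiff(unique(script$branch), labs)
    if (length(bad))
      stop("script names branch(es) absent from tree: ",
           paste(bad, collapse = ", "))
  }
  truth <- ancestor$truth
  rootState <- toSimState(ancestor$genome)
  ntip <- ape::Ntip(tree)
  states <- list()
  rootLab <- nodeLabel(tree, ntip + 1L)
  states[[rootLab]] <- rootState
  ledger <- list()
  # preorder edge walk
  ord <- preorderNodes(tree)
  edges <- tree$edge[order(match(tree$edge[, 2], ord)), , drop = FALSE]
  lens <- tree$edge.length[order(match(tree$edge[, 2], ord))]
  for (i in seq_len(nrow(edges))) {
    pLab <- nodeLabel(tree, edges[i, 1])
    cLab <- nodeLabel(tree, edges[i, 2])
    isTip <- edges[i, 2] <= ntip
    st <- states[[pLab]]
    set.seed((as.numeric(seed) * 7919 + .hashString(cLab)) %% 2147483647)
    record <- function(rl) {
      ledger[[length(ledger) + 1L]] <<- data.frame(
        parent = pLab, child = cLab, type = rl$type,
        chrom_a = as.character(rl$chromA), chrom_b = as.character(rl$chromB),
        pi = rl$pi, breakpoint = rl$breakpoint, k = rl$k,
        detail = rl$detail, stringsAsFactors = FALSE)
    }
    if (!is.null(script) && nrow(script)) {
      rows <- script[script$branch == cLab, , drop = FALSE]
      for (j in seq_len(nrow(rows))) {
        r <- rows[j, ]
        # operands resolve against the state at event time, so later events
        # on the branch see earlier products (e.g. multi-way fusions)
        ev <- rearrangementEvent(
          r$type,
          chromA = if (!is.null(r$lg_a) && !is.na(r$lg_a))
            resolveChromForLg(st, r$lg_a, truth) else NA,
          chromB = if (!is.null(r$lg_b) && !is.na(r$lg_b))
            resolveChromForLg(st, r$lg_b, truth) else NA,
          pi = if (!is.null(r$pi) && !is.na(r$pi)) r$pi else 1,
          breakpoint = if (!is.null(r$breakpoint) && !is.na(r$breakpoint))
            r$breakpoint else NA,
          k = if (!is.null(r$k) && !is.na(r$k)) r$k else 1L)
        if (ev$type == "FISSION" && is.na(ev$breakpoint))
          ev$breakpoint <- length(st$chroms[[ev$chromA]]) %/% 2L
        res <- applyEventState(st, ev)
        st <- res$state
        record(res$event)
      }
    }
    if (!is.null(rates)) {
      for (ty in names(rates)) {
        n <- stats::rpois(1L, rates[[ty]] * lens[i])
        for (j in seq_len(n)) {
          ev <- drawRandomEvent(st, ty, transK)
          if (is.null(ev)) next
          res <- applyEventState(st, ev)
          st <- res$state
          record(res$event)
        }
      }
    }
    if (isTip && tipNoise > 0) {
      k <- round(tipNoise * length(st$og))
      if (k >= 1L) {
        res <- applyEventState(st,
          rearrangementEvent("TRANSLOCATION", k = k))
        st <- res$state
        record(res$event)
      }
    }
    states[[cLab]] <- st
  }
  ledger <- if (length(ledger)) do.call(rbind, ledger) else
    data.frame(parent = character(0), child = character(0),
               type = character(0), chrom_a = character(0),
               chrom_b = character(0), pi = numeric(0),
               breakpoint = numeric(0), k = integer(0),
               detail = character(0), stringsAsFactors = FALSE)
  tips <- GenomeSet(lapply(tree$tip.label, function(lab)
    fromSimState(states[[lab]], lab, renameBySize = TRUE)))
  ogs <- buildTrueOrthologs(states[tree$tip.label])
  new("KaryoSim", ancestor = ancestor$genome, tips = tips, tree = tree,
      truth = truth, ledger = ledger, orthologs = ogs,
      seed = as.integer(seed))
}

drawRandomEvent <- function(st, type, transK = 1L) {
  ch <- st$chroms
  if (type == "FUSION") {
    if (length(ch) < 2L) return(NULL)
    ab <- sample(names(ch), 2L)
    rearrangementEvent("FUSION", chromA = ab[1], chromB = ab[2], pi = 1)
  } else if (type == "FISSION") {
    big <- names(ch)[vapply(ch, length, integer(1)) >= 2L]
    if (!length(big)) return(NULL)
    a <- if (length(big) == 1L) big else sample(big, 1L)
    n <- length(ch[[a]])
    rearrangementEvent("FISSION", chromA = a, breakpoint = sample.int(n - 1L, 1L))
  } else if (type == "DUPLICATION") {
    a <- if (length(ch) == 1L) names(ch) else sample(names(ch), 1L)
    rearrangementEvent("DUPLICATION", chromA = a)
  } else if (type == "TRANSLOCATION") {
    rearrangementEvent("TRANSLOCATION", k = transK)
  } else if (type == "SHUFFLE") {
    a <- if (length(ch) == 1L) names(ch) else sample(names(ch), 1L)
    rearrangementEvent("SHUFFLE", chromA = a)
  } else stop("unknown event type: ", type)
}

buildTrueOrthologs <- function(tipStates) {
  rows <- lapply(names(tipStates), function(g) {
    st <- tipStates[[g]]
    ids <- unlist(st$chroms, use.names = FALSE)
    data.frame(og_id = unname(st$og[ids]), genome_id = g, gene_id = ids,
               stringsAsFactors = FALSE)
  })
  tb <- do.call(rbind, rows)
  tb <- tb[order(tb$og_id, tb$genome_id, tb$gene_id), ]
  rownames(tb) <- NULL
  new("OrthoGroupSet", tbl = tb)
}

#' Replay a realized event ledger from the ancestor
#'
#' Deterministically re-applies every ledger row (which carries the realized
#' outcome of any random draw) along the tree and returns the tip genomes.
#' By construction this reproduces \code{sim@tips} exactly.
#'
#' @param sim a \linkS4class{KaryoSim}.
#' @return list with \code{tips} (\linkS4class{GenomeSet}) and
#'   \code{states} (per-node internal states, for chromosome counts).
#' @export
replayLedger <- function(sim) {
  tree <- sim@tree
  ledger <- sim@ledger
  ntip <- ape::Ntip(tree)
  states <- list()
  states[[nodeLabel(tree, ntip + 1L)]] <- toSimState(sim@ancestor)
  ord <- preorderNodes(tree)
  edges <- tree$edge[order(match(tree$edge[, 2], ord)), , drop = FALSE]
  for (i in seq_len(nrow(edges))) {
    pLab <- nodeLabel(tree, edges[i, 1])
    cLab <- nodeLabel(tree, edges[i, 2])
    st <- states[[pLab]]
    rows <- ledger[ledger$child == cLab, , drop = FALSE]
    for (j in seq_len(nrow(rows))) {
      r <- rows[j, ]
      ev <- list(type = r$type, chromA = r$chrom_a, chromB = r$chrom_b,
                 pi = r$pi, breakpoint = r$breakpoint, k = r$k,
                 detail = r$detail)
      st <- applyEventState(st, ev)$state
    }
    states[[cLab]] <- st
  }
  tips <- GenomeSet(lapply(tree$tip.label, function(lab)
    fromSimState(states[[lab]], lab, renameBySize = TRUE)))
  list(tips = tips, states = states)
}

#' Per-node chromosome counts implied by the ledger
#'
#' @param sim a \linkS4class{KaryoSim}.
#' @return named integer vector over all node labels (tips and internals).
#' @export
ledgerChromCounts <- function(sim) {
  states <- replayLedger(sim)$states
  vapply(states, function(s) length(s$chroms), integer(1))
}

#' Write a simulated dataset to disk
#'
#' Emits one BED per tip genome, the true ortholog table, the tree, the
#' truth linkage-group map and the realized event ledger, all as plain TSV /
#' newick text. The dataset round-trips through the package's readers.
#'
#' @param sim a \linkS4class{KaryoSim}.
#' @param outdir output directory.
#' @param force overwrite a non-empty existing directory.
#' @return invisibly, the vector of written paths.
#' @export
emitDataset <- function(sim, outdir, force = FALSE) {
  if (dir.exists(outdir) && length(dir(outdir)) && !force)
    stop("output directory exists and is non-empty (use force = TRUE): ",
         outdir)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (g in names(sim@tips)) {
    p <- file.path(outdir, paste0(g, ".bed"))
    writeGeneBed(sim@tips[[g]], p)
    paths <- c(paths, p)
  }
  p <- file.path(outdir, "orthologs.tsv")
  utils::write.table(orthoTable(sim@orthologs), p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(outdir, "tree.nwk")
  ape::write.tree(sim@tree, p)
  paths <- c(paths, p)
  p <- file.path(outdir, "truth_mlg.tsv")
  utils::write.table(sim@truth, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(outdir, "ledger.tsv")
  utils::write.table(sim@ledger, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p)
  invisible(paths)
}

#' Simulate pairwise similarity scores for two genomes
#'
#' Produces an aligner-like (query, target, bitscore) table between two tip
#' genomes of a simulation: every true ortholog pair scores high, and random
#' decoy pairs score strictly lower, so mutual-best-hit recovery can be
#' exercised without running an aligner.
#'
#' @param sim a \linkS4class{KaryoSim}.
#' @param genomeA,genomeB tip genome ids (queries come from A).
#' @param decoysPerGene expected number of decoy hits per query gene.
#' @return data.frame query_gene, target_gene, bitscore.
#' @export
simulateScores <- function(sim, genomeA, genomeB, decoysPerGene = 2) {
  tb <- orthoTable(sim@orthologs)
  a <- tb[tb$genome_id == genomeA, ]
  b <- tb[tb$genome_id == genomeB, ]
  bByOg <- split(b$gene_id, b$og_id)
  true <- do.call(rbind, lapply(seq_len(nrow(a)), function(i) {
    tg <- bByOg[[a$og_id[i]]]
    if (is.null(tg)) return(NULL)
    data.frame(query_gene = a$gene_id[i], target_gene = tg,
               bitscore = round(200 + stats::runif(length(tg), 0, 50), 1),
               stringsAsFactors = FALSE)
  }))
  nd <- stats::rpois(1L, decoysPerGene * nrow(a))
  decoys <- data.frame(query_gene = sample(a$gene_id, nd, replace = TRUE),
                       target_gene = sample(b$gene_id, nd, replace = TRUE),
                       bitscore = round(stats::runif(nd, 40, 150), 1),
                       stringsAsFactors = FALSE)
  out <- rbind(true, decoys)
  out[!duplicated(paste(out$query_gene, out$target_gene)), , drop = FALSE]
}

#' Ground-truth linkage-group view of a simulation
#'
#' Builds a \linkS4class{LinkageGroupSet} directly from the simulator's true
#' ortholog-to-linkage-group map (consensus = per-genome majority
#' chromosome), renumbered by descending member count like the inferred
#' object. Used to evaluate inference and to measure rates against a known
#' reference.
#'
#' @param sim a \linkS4class{KaryoSim}.
#' @return list with \code{lgs} (LinkageGroupSet), \code{vectors}
#'   (assignment matrix over universal single-copy orthologs) and
#'   \code{trueLg} (ancestral linkage-group number for each renumbered id).
#' @export
truthLinkageGroups <- function(sim) {
  fil <- filterUniversalSingleCopy(sim@orthologs, sim@tips)
  vectors <- assignmentVectors(fil$universal, sim@tips)
  lgOf <- setNames(sim@truth$lg, sim@truth$og_id)
  m <- unname(lgOf[rownames(vectors)])
  ids <- sort(unique(m))
  support <- as.integer(table(factor(m, levels = ids)))
  ord <- order(-support, ids)
  trueLg <- ids[ord]
  newId <- setNames(seq_along(trueLg), trueLg)
  mlg <- as.integer(newId[as.character(m)])
  G <- ncol(vectors)
  L <- length(trueLg)
  consensus <- matrix(NA_character_, L, G,
                      dimnames = list(NULL, colnames(vectors)))
  purity <- matrix(NA_real_, L, G, dimnames = list(NULL, colnames(vectors)))
  for (i in seq_len(L)) {
    vm <- vectors[mlg == i, , drop = FALSE]
    for (g in seq_len(G)) {
      tb <- sort(table(vm[, g]), decreasing = TRUE)
      consensus[i, g] <- names(tb)[1]
      purity[i, g] <- tb[1] / nrow(vm)
    }
  }
  lgs <- new("LinkageGroupSet",
             membership = data.frame(og_id = rownames(vectors), mlg_id = mlg,
                                     stringsAsFactors = FALSE),
             consensus = consensus, support = support[ord], purity = purity,
             noise = character(0),
             params = list(source = "simulation truth",
                           genomes = colnames(vectors)))
  list(lgs = lgs, vectors = vectors, trueLg = trueLg)
}
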