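#' @include scenarios.R
#' @include karyo-ancestry.R
#' @include rates-occupancy.R
NULL

#' Validate a pipeline run configuration
#'
#' @param config named list (typically from a YAML file): either
#'   \code{scenario} (a scenario YAML path, or "chiton" for the bundled one)
#'   or \code{inputs} (list with genomes_dir, orthologs, tree); plus
#'   thresholds \code{min_support}, \code{epsilon}, \code{alpha},
#'   \code{dup_threshold}, a \code{seed} and optional \code{tip_noise}.
#' @return the config with defaults filled in; errors on invalid values.
#' @export
validateConfig <- function(config) {
  defaults <- list(min_support = 5L, epsilon = 0.05, alpha = 0.05,
                   dup_threshold = 0.5, seed = 1L, tip_noise = NULL,
                   duplication = FALSE, per_lineage = FALSE)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  if (is.null(config$scenario) && is.null(config$inputs))
    stop("config must provide either 'scenario' or 'inputs'")
  if (config$min_support < 1L) stop("min_support must be >= 1")
  if (config$epsilon < 0 || config$epsilon >= 1)
    stop("epsilon must lie in [0, 1)")
  if (config$alpha <= 0 || config$alpha > 1)
    stop("alpha must lie in (0, 1]")
  if (config$dup_threshold <= 0 || config$dup_threshold > 1)
    stop("dup_threshold must lie in (0, 1]")
  if (!is.null(config$tip_noise) &&
      (config$tip_noise < 0 || config$tip_noise > 1))
    stop("tip_noise must lie in [0, 1]")
  config
}

#' Run the full inference pipeline
#'
#' Orchestrates simulate (or load) -> orthology -> linkage-group inference
#' -> ancestral reconstruction and event calling -> rates and occupancy as
#' one reproducible run. All stage outputs are TSV files under
#' \code{outdir}; a JSON manifest records the configuration, seed, package
#' version and the md5 checksum of every output, so reruns under an
#' identical config are verifiably identical.
#'
#' @param config a config list or the path to a YAML config file (see
#'   \code{\link{validateConfig}}).
#' @param outdir output directory (default from config$outdir).
#' @return invisibly, a list with the main in-memory results (sim, lgs,
#'   states, events, rates, manifest).
#' @export
runPipeline <- function(config, outdir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  config <- validateConfig(config)
  if (is.null(outdir)) outdir <- config$outdir
  if (is.null(outdir)) stop("no output directory given")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(x, name) {
    p <- file.path(outdir, name)
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- character(0)

  ## stage 1: obtain genomes, orthologs, tree
  stage <- "inputs"
  res <- tryCatch({
    if (!is.null(config$scenario)) {
      scn <- if (identical(config$scenario, "chiton")) chitonScenario() else
        readScenario(config$scenario)
      sim <- simulateScenario(scn, seed = config$seed,
                              tipNoise = config$tip_noise,
                              duplication = isTRUE(config$duplication))
      ddir <- file.path(outdir, "data")
      emitDataset(sim, ddir, force = TRUE)
      genomes <- GenomeSet(lapply(names(sim@tips), function(g)
        readGeneTable(file.path(ddir, paste0(g, ".bed")), genomeId = g)))
      ogs <- readOrthologTable(file.path(ddir, "orthologs.tsv"), genomes)
      tree <- readTree(file.path(ddir, "tree.nwk"), genomes)
      list(sim = sim, genomes = genomes, ogs = ogs, tree = tree)
    } else {
      inp <- config$inputs
      beds <- list.files(inp$genomes_dir, pattern = "\\.(bed|gff3?)$",
                         full.names = TRUE)
      if (!length(beds)) stop("no gene tables in ", inp$genomes_dir)
      genomes <- GenomeSet(lapply(beds, readGeneTable))
      ogs <- readOrthologTable(inp$orthologs, genomes)
      tree <- readTree(inp$tree, genomes)
      list(sim = NULL, genomes = genomes, ogs = ogs, tree = tree)
    }
  }, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
  genomes <- res$genomes; tree <- res$tree

  ## stage 2: orthology filtering
  stage <- "orthology"
  fil <- tryCatch(filterUniversalSingleCopy(res$ogs, genomes),
                  error = function(e)
                    stop("pipeline stage 'orthology' failed: ",
                         conditionMessage(e), call. = FALSE))
  paths <- c(paths, wtsv(orthoTable(fil$universal), "universal_single_copy.tsv"))
  if (nrow(orthoTable(fil$dupEvidence)))
    paths <- c(paths, wtsv(orthoTable(fil$dupEvidence), "duplication_evidence.tsv"))

  ## stage 3: linkage-group inference
  stage <- "infer-mlg"
  vectors <- assignmentVectors(fil$universal, genomes)
  lgs <- clusterLinkageGroups(vectors, minSupport = config$min_support,
                              epsilon = config$epsilon)
  paths <- c(paths,
             writeMlgAssignments(lgs, vectors,
                                 file.path(outdir, "mlg_assignments.tsv")))
  gms <- names(genomes)
  htests <- do.call(rbind, lapply(seq_len(length(gms) - 1L), function(i)
    do.call(rbind, lapply((i + 1L):length(gms), function(j) {
      h <- testChromosomeHomology(vectors, gms[i], gms[j],
                                  alpha = config$alpha)
      cbind(genome_a = gms[i], genome_b = gms[j], h)
    }))))
  paths <- c(paths, wtsv(htests, "homology_tests.tsv"))
  fused <- lapply(setNames(gms, gms), function(g) fusedSets(lgs, g))
  fusedTab <- do.call(rbind, lapply(gms, function(g) {
    fs <- fused[[g]]
    data.frame(genome_id = g, chrom_id = names(fs),
               mlgs = vapply(fs, paste, character(1), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  paths <- c(paths, wtsv(fusedTab, "fused_sets.tsv"))

  ## stage 4: ancestral reconstruction and events
  stage <- "ancestry"
  chars <- colocalizationCharacters(fused[tree$tip.label], length(lgs))
  states <- reconstructStates(chars, tree)
  events <- callEvents(states, tree, chars, dupEvidence = fil$dupEvidence,
                       genomes = genomes, lgs = lgs,
                       dupThreshold = config$dup_threshold)
  kt <- karyotypeTable(states)
  mix <- do.call(rbind, lapply(gms, function(g)
    cbind(genome_id = g, chromosomeMixing(genomes[[g]], lgs, fil$universal))))
  paths <- c(paths, wtsv(kt, "ancestral_karyotypes.tsv"),
             wtsv(events, "events.tsv"), wtsv(mix, "chromosome_mixing.tsv"))

  ## stage 5: rates and occupancy
  stage <- "rates"
  rates <- pairwiseRates(vectors, lgs, tree,
                         perLineage = isTRUE(config$per_lineage))
  paths <- c(paths, wtsv(rates, "rates.tsv"))
  for (g in gms) {
    dots <- dotplotTable(genomes[[g]], lgs, fil$universal)
    paths <- c(paths, wtsv(dots, sprintf("dotplot_%s.tsv", g)))
    occ <- occupancyMatrix(data.frame(chrom_id = dots$chrom,
                                      mlg_id = dots$mlg_id))
    occdf <- data.frame(chrom_id = rownames(occ), occ, check.names = FALSE)
    paths <- c(paths, wtsv(occdf, sprintf("occupancy_%s.tsv", g)))
  }

  ## manifest
  manifest <- list(
    package = "karyolg",
    version = as.character(utils::packageVersion("karyolg")),
    seed = config$seed,
    config = config[setdiff(names(config), "outdir")],
    outputs = as.list(setNames(unname(tools::md5sum(sort(paths))),
                               basename(sort(paths)))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(sim = res$sim, genomes = genomes, tree = tree,
                 universal = fil$universal, dupEvidence = fil$dupEvidence,
                 vectors = vectors, lgs = lgs, fused = fused,
                 characters = chars, states = states, events = events,
                 rates = rates, manifest = manifest))
}

#' Summarize a completed run as a human-readable report
#'
#' Reads only the stage outputs in the run directory and writes
#' \code{report.md}: reconstructed 1n per node, the (merged) event table and
#' the translocation-rate table. Regeneration is idempotent.
#'
#' @param rundir directory written by \code{\link{runPipeline}}.
#' @return invisibly, the report path.
#' @export
makeReport <- function(rundir) {
  need <- c("ancestral_karyotypes.tsv", "events.tsv", "rates.tsv")
  for (f in need)
    if (!file.exists(file.path(rundir, f)))
      stop("missing stage output: ", f)
  kt <- utils::read.table(file.path(rundir, "ancestral_karyotypes.tsv"),
                          header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  ev <- utils::read.table(file.path(rundir, "events.tsv"), header = TRUE,
                          sep = "\t", stringsAsFactors = FALSE)
  rates <- utils::read.table(file.path(rundir, "rates.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)
  counts <- tapply(kt$chrom_index, kt$node, max)
  lines <- c("# Karyotype evolution report", "",
             "## Reconstructed haploid chromosome numbers (1n)", "")
  lines <- c(lines, sprintf("- %s: 1n = %d", names(counts), counts), "")
  lines <- c(lines, "## Rearrangement events", "")
  if (!nrow(ev)) {
    lines <- c(lines, "no rearrangements detected", "")
  } else {
    me <- mergedEvents(ev)
    lines <- c(lines,
               "| branch | type | linkage groups | synapomorphy |",
               "|---|---|---|---|",
               sprintf("| %s -> %s | %s | %s | %s |", me$parent, me$child,
                       me$type, me$mlgs,
                       ifelse(is.na(me$synapomorphy), "-",
                              ifelse(me$synapomorphy, "yes", "no"))), "")
  }
  lines <- c(lines, "## Inter-chromosomal translocation rates", "",
             "| pair | c | t (My) | rate (/My) |", "|---|---|---|---|",
             sprintf("| %s vs %s | %.4f | %.0f | %.5f |", rates$genome_a,
                     rates$genome_b, rates$c, rates$t, rates$rate), "")
  p <- file.path(rundir, "report.md")
  writeLines(lines, p)
  invisible(p)
}
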