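#' @include sim-evolve.R
NULL

#' Read a rearrangement scenario from YAML
#'
#' A scenario bundles a dated tree (inline newick or a path), the ancestral
#' linkage-group configuration, scripted rearrangement events and optional
#' background settings. See the bundled
#' \code{system.file("extdata", "chiton_scenario.yaml", package = "karyolg")}
#' for the schema.
#'
#' @param path YAML file path.
#' @return list with elements name, tree (phylo), n_lgs, lg_sizes, tip_noise,
#'   script (data.frame), dup_script (data.frame or NULL).
#' @export
readScenario <- function(path) {
  sc <- yaml::read_yaml(path)
  need <- c("tree", "n_lgs", "events")
  if (!all(need %in% names(sc)))
    stop("scenario must define: ", paste(need, collapse = ", "))
  treeTxt <- sc$tree
  tree <- if (file.exists(treeTxt)) readTree(treeTxt) else
    readTree(gsub("[\n ]", "", treeTxt))
  toScript <- function(evs) {
    if (is.null(evs) || !length(evs)) return(NULL)
    do.call(rbind, lapply(evs, function(e) data.frame(
      branch = e$branch, type = e$type,
      lg_a = if (length(e$lgs) >= 1L) e$lgs[[1]] else NA,
      lg_b = if (length(e$lgs) >= 2L) e$lgs[[2]] else NA,
      pi = if (!is.null(e$pi)) e$pi else NA,
      breakpoint = if (!is.null(e$breakpoint)) e$breakpoint else NA,
      k = if (!is.null(e$k)) e$k else NA,
      stringsAsFactors = FALSE)))
  }
  sizes <- if (!is.null(sc$lg_sizes)) as.integer(unlist(sc$lg_sizes)) else
    rep(200L, sc$n_lgs)
  if (length(sizes) != sc$n_lgs)
    stop("lg_sizes length must equal n_lgs")
  list(name = if (!is.null(sc$name)) sc$name else basename(path),
       tree = tree, n_lgs = as.integer(sc$n_lgs), lg_sizes = sizes,
       tip_noise = if (!is.null(sc$tip_noise)) sc$tip_noise else 0,
       script = toScript(sc$events),
       dup_script = toScript(sc$duplication_events))
}

#' The bundled chiton karyotype scenario
#'
#' The package's reference scenario: seven genomes (a gastropod, a bivalve
#' and five chitons) descending from a molluscan ancestor of 20 linkage
#' groups, with the chiton-stem fusions 4+16+18, 7+10 and 8+9, the
#' Chitonida sensu lato 1+(4+16+18) fusion, per-lineage fusions bringing the
#' Acanthochitona congeners to 1n = 8 each, and (optionally) the Liolophura
#' fused-then-duplicated chromosome. Linkage groups 19 and 20 are never
#' rearranged.
#'
#' @return scenario list as from \code{\link{readScenario}}.
#' @export
chitonScenario <- function() {
  readScenario(system.file("extdata", "chiton_scenario.yaml",
                           package = "karyolg", mustWork = TRUE))
}

#' Simulate a scenario
#'
#' @param scenario a scenario list from \code{\link{readScenario}} /
#'   \code{\link{chitonScenario}}.
#' @param seed integer seed.
#' @param tipNoise override the scenario's terminal-branch translocation
#'   fraction (NULL keeps the scenario value).
#' @param duplication also apply the scenario's optional duplication events.
#' @return a \linkS4class{KaryoSim}.
#' @export
simulateScenario <- function(scenario, seed = 1L, tipNoise = NULL,
                             duplication = FALSE) {
  anc <- makeAncestor(scenario$n_lgs, scenario$lg_sizes)
  script <- scenario$script
  if (duplication && !is.null(scenario$dup_script)) {
    # duplication events run after the branch's scripted fusions
    script <- rbind(script, scenario$dup_script)
  }
  evolveGenomes(anc, scenario$tree, script = script,
                seed = seed,
                tipNoise = if (is.null(tipNoise)) scenario$tip_noise else
                  tipNoise)
}
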