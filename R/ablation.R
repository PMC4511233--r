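#' Significance stars for a p-value
#'
#' @param p p-value(s).
#' @return \code{"***"} for p < .001, \code{"**"} for p < .01, \code{"*"}
#'   for p < .05, \code{""} otherwise.
#' @export
significanceStars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                ifelse(p < 0.05, "*", ""))))
}

#' Fit groupings to a web and its interaction-type ablations
#'
#' Runs the whole workflow on one signed network: for the full web and
#' every ablation (an ablation keeps a subset of interaction types and/or
#' removes a set of species), the largest weakly connected component is
#' taken, the best grouping is searched with \code{\link{mc3Search}}, and
#' the partition is written to \code{<outDir>/partition_<name>.tsv}. All
#' partitions are then compared pairwise on their common species
#' (partitions are restricted to the intersection first), with MI
#' significance from the randomization test, and the comparison table is
#' written to \code{<outDir>/comparisons.tsv} with significance stars at
#' the 0.05 / 0.01 / 0.001 levels. A run log records the configuration,
#' the seed, any component extraction, and the best scores, so a fixed
#' seed reproduces the output files byte for byte.
#'
#' @param net a \code{SignedNetwork}.
#' @param ablations named list; each element is a list with optional
#'   fields \code{keep} (character vector of pair types) and
#'   \code{removeSpecies} (character vector). An entry named "all" with no
#'   fields fits the unablated web. Default: full web, trophic-only,
#'   nontrophic-only.
#' @param control search settings from \code{\link{searchControl}}.
#' @param n_reps randomizations for each pairwise MI test.
#' @param outDir output directory (created if needed); NULL to skip
#'   writing files.
#' @param seed integer seed; ablation k is searched with seed
#'   \code{seed + k} and comparisons use \code{seed}.
#' @param compareOn optional character vector: compare partitions only on
#'   these species (e.g. the plants when an ablation removes a species
#'   class).
#' @return (invisibly) list with \code{partitions} (named list of
#'   \code{Partition}s), \code{scores}, \code{comparisons} (data.frame)
#'   and \code{log} (character).
#' @export
runAblationStudy <- function(net,
                             ablations = list(
                               all = list(),
                               trophic = list(keep = "trophic"),
                               nontrophic = list(keep = c(
                                 "mutualism", "competition",
                                 "commensalism", "amensalism"))),
                             control = searchControl(),
                             n_reps = 1000, outDir = NULL, seed = 1,
                             compareOn = NULL) {
  if (is.null(names(ablations)) || any(names(ablations) == ""))
    stop("ablations must be a named list")
  logLines <- c(sprintf("seed: %d", seed),
                sprintf("chains: %d  sweeps: %d", control$nChains,
                        control$nSweeps),
                sprintf("ablations: %s",
                        paste(names(ablations), collapse = ", ")))
  partitions <- list()
  scores <- numeric(0)
  for (k in seq_along(ablations)) {
    nm <- names(ablations)[k]
    ab <- ablations[[k]]
    sub <- net
    if (!is.null(ab$keep)) sub <- subnetworkByType(sub, ab$keep)
    if (!is.null(ab$removeSpecies) && length(ab$removeSpecies) > 0)
      sub <- removeSpecies(sub, ab$removeSpecies)
    comp <- largestWeakComponent(sub)
    if (nSpecies(comp) < nSpecies(sub))
      logLines <- c(logLines, sprintf(
        "%s: not weakly connected; largest component kept (%d of %d species)",
        nm, nSpecies(comp), nSpecies(sub)))
    fit <- mc3Search(comp, control, seed = seed + k)
    partitions[[nm]] <- bestPartition(fit)
    scores[nm] <- bestLogMarginal(fit)
    logLines <- c(logLines, sprintf("%s: %d groups, log marginal %.4f",
                                    nm, nGroups(partitions[[nm]]),
                                    scores[nm]))
  }
  nms <- names(partitions)
  rows <- list()
  for (i in seq_along(nms)) for (j in seq_along(nms)) {
    if (j <= i) next
    a <- partitions[[i]]
    b <- partitions[[j]]
    common <- intersect(speciesNames(a), speciesNames(b))
    if (!is.null(compareOn)) common <- intersect(common, compareOn)
    if (length(common) == 0)
      stop("no common species between partitions '", nms[i], "' and '",
           nms[j], "'")
    # restrict both to the common species, in a's order
    common <- speciesNames(a)[speciesNames(a) %in% common]
    ra <- restrictPartition(a, common)
    rb <- restrictPartition(b, common)
    cr <- comparePartitions(ra, rb, n_reps = n_reps, seed = seed)
    rows[[length(rows) + 1]] <- data.frame(
      partition_a = nms[i], partition_b = nms[j],
      n_common = length(common),
      H_A = cr@H_A, H_B = cr@H_B, MI = cr@MI, MI_max = cr@MI_max,
      p_value = cr@p_value, stars = significanceStars(cr@p_value))
  }
  comparisons <- do.call(rbind, rows)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    for (nm in nms)
      writePartition(partitions[[nm]],
                     file.path(outDir, paste0("partition_", nm, ".tsv")))
    utils::write.table(comparisons, file.path(outDir, "comparisons.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(logLines, file.path(outDir, "run_log.txt"))
  }
  invisible(list(partitions = partitions, scores = scores,
                 comparisons = comparisons, log = logLines))
}
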