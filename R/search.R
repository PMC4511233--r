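#' Settings for the Metropolis-coupled Gibbs search
#'
#' @param nChains number of tempered chains.
#' @param exponents tempering ladder: the marginal likelihood powers, one
#'   per chain, strictly decreasing with the coldest chain at 1.
#' @param nSweeps number of full Gibbs sweeps per chain.
#' @param maxGroups cap on the number of groups (NA = no cap beyond S).
#' @param recordEvery trace thinning: record chain scores every this many
#'   sweeps.
#' @param initGroups number of groups in each chain's random initial
#'   partition (capped at S).
#' @return validated list of settings.
#' @export
searchControl <- function(nChains = 4, exponents = c(1, 0.8, 0.6, 0.4),
                          nSweeps = 5000, maxGroups = NA,
                          recordEvery = 10, initGroups = 5) {
  if (nChains < 1) stop("nChains must be >= 1")
  exponents <- as.numeric(exponents)[seq_len(nChains)]
  if (anyNA(exponents))
    stop("exponents must supply one value per chain")
  if (abs(exponents[1] - 1) > 1e-12)
    stop("the coldest chain must have exponent 1")
  if (nChains > 1 && any(diff(exponents) >= 0))
    stop("exponents must be strictly decreasing with chain index")
  if (any(exponents <= 0)) stop("exponents must be positive")
  if (nSweeps < 1) stop("nSweeps must be >= 1")
  list(nChains = as.integer(nChains), exponents = exponents,
       nSweeps = as.integer(nSweeps), maxGroups = maxGroups,
       recordEvery = as.integer(recordEvery),
       initGroups = as.integer(initGroups))
}

.maxGroupsOf <- function(control, S) {
  mg <- control$maxGroups
  if (is.null(mg) || is.na(mg)) S else as.integer(min(mg, S))
}

#' One collapsed Gibbs sweep
#'
#' Visits every species once in a seeded random order. For each species it
#' computes the marginal likelihood of membership in every current group
#' and in one fresh group (per-block rates integrated out, so the number
#' of groups can grow and shrink without a fixed-g outer loop), raises
#' these to the tempering \code{exponent}, and samples the new label from
#' the normalized weights. Groups left empty are pruned immediately; the
#' returned partition is canonical.
#'
#' @param net a \code{SignedNetwork}.
#' @param part current \code{Partition}.
#' @param exponent tempering power in (0, 1]; 1 targets the untempered
#'   posterior over partitions, values near 0 flatten it.
#' @param maxGroups optional cap on the group count.
#' @return the updated \code{Partition}.
#' @export
gibbsSweep <- function(net, part, exponent = 1, maxGroups = NA) {
  .checkDescribes(net, part)
  if (exponent <= 0 || exponent > 1)
    stop("exponent must lie in (0, 1]")
  S <- nSpecies(net)
  mg <- if (is.na(maxGroups)) S else as.integer(min(maxGroups, S))
  part <- canonicalizePartition(part)
  groups <- .gibbs_sweep_engine(net@signs, part@groups, exponent, mg)
  new("Partition", species = net@species, groups = as.integer(groups))
}

#' Search partition space with Metropolis-coupled MCMC
#'
#' Runs several tempered collapsed-Gibbs chains in parallel (in the
#' tempering sense; execution is serial and reproducible). After every
#' sweep one adjacent pair of chains is proposed for a state exchange,
#' accepted with the standard tempered-exchange ratio
#' \eqn{\min(1, [P_1^{\beta_2} P_2^{\beta_1}]/[P_1^{\beta_1} P_2^{\beta_2}])}.
#' The best partition ever visited by any chain is tracked and returned;
#' its score is recomputed from the returned partition, so
#' \code{bestLogMarginal(x) == logMarginalLikelihood(net, bestPartition(x))}
#' exactly. The search is stochastic and not guaranteed to find the global
#' optimum; for small webs compare with \code{\link{exhaustiveSearch}}.
#'
#' @param net a \code{SignedNetwork}.
#' @param control settings from \code{\link{searchControl}}.
#' @param seed integer RNG seed; identical seeds give identical results.
#' @return a \code{SearchResult}.
#' @export
mc3Search <- function(net, control = searchControl(), seed = 1) {
  S <- nSpecies(net)
  if (S < 1) stop("empty network")
  set.seed(seed)
  mg <- .maxGroupsOf(control, S)
  g0 <- min(control$initGroups, S)
  init <- matrix(0L, control$nChains, S)
  for (c in seq_len(control$nChains)) {
    # random start with g0 groups, each guaranteed non-empty
    lab <- c(seq_len(g0), sample.int(g0, S - g0, replace = TRUE))
    init[c, ] <- lab[sample.int(S)]
  }
  res <- .mc3_engine(net@signs, init, control$exponents, control$nSweeps,
                     mg, max(control$recordEvery, 1L))
  best <- canonicalizePartition(
    new("Partition", species = net@species,
        groups = as.integer(res$best_assign)))
  nRec <- res$n_recorded
  trace <- if (nRec > 0) {
    data.frame(
      sweep = rep(res$trace_sweep[seq_len(nRec)], control$nChains),
      chain = rep(seq_len(control$nChains), each = nRec),
      logMarginal = as.vector(res$trace_score[seq_len(nRec), , drop = FALSE]))
  } else {
    data.frame(sweep = integer(), chain = integer(), logMarginal = numeric())
  }
  score <- logMarginalLikelihood(net, best)
  stopifnot(abs(score - res$best_score) < 1e-6)
  new("SearchResult", bestPartition = best, bestLogMarginal = score,
      trace = trace, seed = as.numeric(seed))
}

#' Exhaustive search over all set partitions
#'
#' Enumerates every partition of the species set (Bell(S) of them, hence
#' the S <= 10 guard) and returns the exact marginal-likelihood maximizer.
#' Ties are broken by canonical-form lexicographic order. This is the
#' oracle used to validate \code{\link{mc3Search}} on small webs.
#'
#' @param net a \code{SignedNetwork} with at most 10 species.
#' @return a \code{SearchResult} (seed is NA; trace is empty).
#' @export
exhaustiveSearch <- function(net) {
  S <- nSpecies(net)
  if (S < 1) stop("empty network")
  if (S > 10)
    stop("exhaustive enumeration is limited to S <= 10 (Bell numbers grow",
         " too fast beyond that)")
  res <- .exhaustive_engine(net@signs)
  best <- canonicalizePartition(
    new("Partition", species = net@species,
        groups = as.integer(res$best_assign)))
  score <- logMarginalLikelihood(net, best)
  stopifnot(abs(score - res$best_score) < 1e-6)
  new("SearchResult", bestPartition = best, bestLogMarginal = score,
      trace = data.frame(sweep = integer(), chain = integer(),
                         logMarginal = numeric()),
      seed = NA_real_)
}

#' Jackknife stability of a grouping
#'
#' Removes each species in turn, re-runs the search on the reduced web,
#' and measures MI / MI_max between the found partition and the reference
#' partition restricted to the surviving species. Ratios near 1 indicate
#' group structure robust to single-species removal.
#'
#' @param net a \code{SignedNetwork} with at least 3 species.
#' @param reference a \code{Partition} describing \code{net}.
#' @param control settings from \code{\link{searchControl}}.
#' @param seed integer seed; species i is re-searched with seed
#'   \code{seed + i}.
#' @return list with \code{ratios} (named per species), \code{mean} and
#'   \code{sd}.
#' @export
jackknifeStability <- function(net, reference, control = searchControl(),
                               seed = 1) {
  .checkDescribes(net, reference)
  S <- nSpecies(net)
  if (S < 3) stop("jackknife needs at least 3 species")
  ratios <- vapply(seq_len(S), function(i) {
    sub <- removeSpecies(net, net@species[i])
    found <- bestPartition(mc3Search(sub, control, seed = seed + i))
    ref <- restrictPartition(reference, sub@species)
    mm <- miMax(found, ref)
    if (mm <= 0) return(1)  # degenerate: no structure left to disagree on
    mutualInformation(found, ref) / mm
  }, numeric(1))
  names(ratios) <- net@species
  list(ratios = ratios, mean = mean(ratios), sd = stats::sd(ratios))
}

#' @rdname SearchResult-class
#' @export
setMethod("bestPartition", "SearchResult", function(x) x@bestPartition)

#' @rdname SearchResult-class
#' @export
setMethod("bestLogMarginal", "SearchResult", function(x) x@bestLogMarginal)

#' @rdname SearchResult-class
#' @export
setMethod("searchTrace", "SearchResult", function(x) x@trace)

setMethod("show", "SearchResult", function(object) {
  cat("SearchResult: best of", nGroups(object@bestPartition), "groups,",
      sprintf("log marginal = %.4f nats\n", object@bestLogMarginal))
})
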