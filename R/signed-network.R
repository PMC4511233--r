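#' Construct a SignedNetwork
#'
#' @param signs square numeric matrix with entries in \{-1, 0, +1\}. If it
#'   has dimnames they are used as species labels when \code{species} is
#'   missing.
#' @param species optional character vector of species labels; defaults to
#'   the matrix dimnames, or \code{"s1" ... "sS"}.
#' @return a \code{SignedNetwork}.
#' @examples
#' net <- SignedNetwork(rbind(c(0, 1), c(-1, 0)), species = c("a", "b"))
#' signMatrix(net)
#' @export
SignedNetwork <- function(signs, species = NULL) {
  signs <- as.matrix(signs)
  if (is.null(species)) {
    species <- rownames(signs)
    if (is.null(species)) species <- paste0("s", seq_len(nrow(signs)))
  }
  storage.mode(signs) <- "integer"
  dimnames(signs) <- list(species, species)
  new("SignedNetwork", species = as.character(species), signs = signs)
}

#' @rdname SignedNetwork-class
#' @aliases speciesNames,SignedNetwork-method
#' @export
setMethod("speciesNames", "SignedNetwork", function(x) x@species)

#' @rdname SignedNetwork-class
#' @export
setMethod("signMatrix", "SignedNetwork", function(x) x@signs)

#' @rdname SignedNetwork-class
#' @export
setMethod("nSpecies", "SignedNetwork", function(x) length(x@species))

#' Link, positive-link and zero counts of a network
#'
#' \code{linkCount} is the number L of nonzero cells of the sign matrix,
#' \code{positiveCount} the number K of +1 cells, and \code{zeroCount} the
#' number Z = S^2 - L of zero cells (the diagonal is included as potential
#' cells).
#'
#' @param net a \code{SignedNetwork}.
#' @return an integer count.
#' @export
linkCount <- function(net) sum(net@signs != 0L)

#' @rdname linkCount
#' @export
positiveCount <- function(net) sum(net@signs == 1L)

#' @rdname linkCount
#' @export
zeroCount <- function(net) sum(net@signs == 0L)

setMethod("show", "SignedNetwork", function(object) {
  S <- nSpecies(object)
  L <- linkCount(object)
  K <- positiveCount(object)
  cat("SignedNetwork with", S, "species,", L, "links (",
      K, "positive /", L - K, "negative )\n")
  cat("species:", paste(utils::head(object@species, 6), collapse = ", "),
      if (S > 6) "..." else "", "\n")
})

#' Read a signed network from a text file
#'
#' Two dialects are supported. \code{"edgelist"}: tab-separated with a
#' header row \code{source  target  sign} and signs written as +1/-1; an
#' optional first comment line \code{# species: a<TAB>b<TAB>...} declares
#' the full species set (needed to keep isolated species). \code{"matrix"}:
#' comma-separated square matrix with a label header row and labels in the
#' first column.
#'
#' @param path file path.
#' @param format \code{"edgelist"} or \code{"matrix"}.
#' @param species optional character vector declaring the species set for
#'   the edge-list format (overrides any \code{# species:} line).
#' @return a \code{SignedNetwork}.
#' @export
readSignedNetwork <- function(path, format = c("edgelist", "matrix"),
                              species = NULL) {
  format <- match.arg(format)
  if (format == "matrix") {
    m <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
    if (nrow(m) != ncol(m))
      stop("matrix file is not square: ", nrow(m), " x ", ncol(m))
    if (!identical(rownames(m), colnames(m)))
      stop("row and column labels of the matrix file differ")
    if (!all(m %in% c(-1, 0, 1)))
      stop("matrix file contains entries outside {-1, 0, +1}")
    return(SignedNetwork(m))
  }
  first <- readLines(path, n = 1L)
  if (is.null(species) && grepl("^#\\s*species:", first)) {
    species <- strsplit(sub("^#\\s*species:\\s*", "", first), "\t")[[1]]
  }
  df <- utils::read.delim(path, comment.char = "#",
                          colClasses = c("character", "character", "numeric"))
  if (!all(c("source", "target", "sign") %in% names(df)))
    stop("edge list must have columns source, target, sign")
  if (nrow(df) > 0 && !all(df$sign %in% c(-1, 1)))
    stop("edge-list signs must be +1 or -1")
  if (is.null(species)) {
    species <- unique(c(rbind(df$source, df$target)))
    if (length(species) == 0L)
      stop("empty edge list and no declared species")
  } else if (!all(c(df$source, df$target) %in% species)) {
    stop("edge list mentions species absent from the declared species set")
  }
  m <- matrix(0L, length(species), length(species),
              dimnames = list(species, species))
  if (nrow(df) > 0) {
    idx <- cbind(match(df$source, species), match(df$target, species))
    keycheck <- paste(df$source, df$target)
    if (anyDuplicated(keycheck)) {
      dup <- keycheck[duplicated(keycheck)]
      bad <- vapply(unique(dup), function(k) {
        length(unique(df$sign[keycheck == k])) > 1L
      }, logical(1))
      if (any(bad))
        stop("duplicate edges with conflicting signs: ",
             paste(unique(dup)[bad], collapse = "; "))
    }
    m[idx] <- as.integer(df$sign)
  }
  SignedNetwork(m, species)
}

#' Write a signed network to a text file
#'
#' Inverse of \code{\link{readSignedNetwork}}; round-trips are exact on
#' labels and signs. The edge-list dialect writes a \code{# species:} line
#' so that isolated species survive the round trip.
#'
#' @param net a \code{SignedNetwork}.
#' @param path file path.
#' @param format \code{"edgelist"} or \code{"matrix"}.
#' @export
writeSignedNetwork <- function(net, path, format = c("edgelist", "matrix")) {
  format <- match.arg(format)
  m <- net@signs
  if (format == "matrix") {
    df <- as.data.frame(m, check.names = FALSE)
    utils::write.csv(df, path, quote = FALSE, row.names = TRUE)
    return(invisible(path))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# species: ", paste(net@species, collapse = "\t")), con)
  writeLines("source\ttarget\tsign", con)
  nz <- which(m != 0L, arr.ind = TRUE)
  nz <- nz[order(nz[, 1], nz[, 2]), , drop = FALSE]
  if (nrow(nz) > 0) {
    writeLines(paste(net@species[nz[, 1]], net@species[nz[, 2]],
                     sprintf("%+d", m[nz]), sep = "\t"), con)
  }
  invisible(path)
}

#' Classify an unordered sign pair into an interaction type
#'
#' The two directed signs between a species pair determine the ecological
#' interaction type: (+,-) trophic (consumer-resource), (+,+) mutualism,
#' (-,-) competition, (+,0) commensalism, (-,0) amensalism, (0,0) none.
#' Classification depends only on the unordered pair.
#'
#' @param sign_ij,sign_ji the two directed signs, each in \{-1, 0, +1\}.
#' @return one of \code{"trophic"}, \code{"mutualism"}, \code{"competition"},
#'   \code{"commensalism"}, \code{"amensalism"}, \code{"none"}.
#' @examples
#' classifyPair(+1, -1)  # trophic
#' @export
classifyPair <- function(sign_ij, sign_ji) {
  if (!all(c(sign_ij, sign_ji) %in% c(-1, 0, 1)))
    stop("signs must be in {-1, 0, +1}")
  lo <- pmin(sign_ij, sign_ji)
  hi <- pmax(sign_ij, sign_ji)
  key <- paste(lo, hi)
  unname(c("-1 1" = "trophic", "1 1" = "mutualism", "-1 -1" = "competition",
           "0 1" = "commensalism", "-1 0" = "amensalism",
           "0 0" = "none")[key])
}

#' Census of interaction types over unordered species pairs
#'
#' Counts every unordered off-diagonal pair (i < j) once; the counts over
#' the six classes sum to S(S-1)/2, with absent interactions reported under
#' \code{none}.
#'
#' @param net a \code{SignedNetwork}.
#' @return named integer vector over the six pair types.
#' @export
pairTypeCensus <- function(net) {
  m <- net@signs
  ut <- upper.tri(m)
  cls <- classifyPair(m[ut], t(m)[ut])
  counts <- table(factor(cls, levels = .PAIR_TYPES))
  out <- as.integer(counts)
  names(out) <- .PAIR_TYPES
  out
}

#' Interaction-type subnetwork
#'
#' Keeps both directed entries of every unordered pair whose interaction
#' type is in \code{keep}; zeroes all other entries. Diagonal self-effects
#' are classified by pairing the entry with itself (a positive self-effect
#' falls in the mutualism class, a negative one in the competition class).
#' Species are never dropped: ablating interactions leaves isolated species
#' in place, and extracting a connected component is a separate explicit
#' step (\code{\link{largestWeakComponent}}).
#'
#' @param net a \code{SignedNetwork}.
#' @param keep non-empty character vector of pair types to retain.
#' @return a \code{SignedNetwork} on the same species.
#' @examples
#' net <- SignedNetwork(rbind(c(0, 1), c(-1, 0)), c("a", "b"))
#' subnetworkByType(net, "trophic")
#' @export
subnetworkByType <- function(net, keep) {
  keep <- as.character(keep)
  if (length(keep) == 0L) stop("keep must name at least one pair type")
  if (!all(keep %in% .PAIR_TYPES))
    stop("unknown pair type(s): ",
         paste(setdiff(keep, .PAIR_TYPES), collapse = ", "))
  m <- net@signs
  cls <- matrix(classifyPair(as.vector(m), as.vector(t(m))),
                nrow(m), ncol(m))
  m[!(cls %in% keep)] <- 0L
  SignedNetwork(m, net@species)
}

#' Remove species from a network
#'
#' Returns the induced subnetwork on the remaining species, preserving the
#' original species order.
#'
#' @param net a \code{SignedNetwork}.
#' @param labels character vector of species labels to drop.
#' @return a \code{SignedNetwork}.
#' @export
removeSpecies <- function(net, labels) {
  labels <- as.character(labels)
  unknown <- setdiff(labels, net@species)
  if (length(unknown) > 0)
    stop("unknown species: ", paste(unknown, collapse = ", "))
  keep <- !(net@species %in% labels)
  if (!any(keep)) stop("cannot remove every species")
  SignedNetwork(net@signs[keep, keep, drop = FALSE], net@species[keep])
}

#' Largest weakly connected component
#'
#' The induced subnetwork on the largest set of species mutually reachable
#' when edge direction and sign are ignored. Ties between equally large
#' components are broken in favour of the one containing the
#' earliest-indexed species.
#'
#' @param net a \code{SignedNetwork}.
#' @return a \code{SignedNetwork}.
#' @export
largestWeakComponent <- function(net) {
  g <- igraph::graph_from_adjacency_matrix(abs(net@signs) != 0L,
                                           mode = "directed")
  comp <- igraph::components(g, mode = "weak")
  sizes <- comp$csize
  first <- vapply(seq_along(sizes),
                  function(k) min(which(comp$membership == k)), integer(1))
  best <- order(-sizes, first)[1]
  keep <- comp$membership == best
  SignedNetwork(net@signs[keep, keep, drop = FALSE], net@species[keep])
}
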