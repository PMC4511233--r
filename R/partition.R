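#' Construct a Partition
#'
#' @param groups vector of group labels, one per species; any atomic labels
#'   are accepted and recoded to integers 1..g in order of first appearance.
#' @param species optional character vector of species labels; defaults to
#'   \code{"s1" ... "sS"}.
#' @return a canonical \code{Partition}.
#' @examples
#' Partition(c(1, 2, 1, 2, 1))
#' Partition(c("alpha", "beta", "gamma", "beta", "beta"))
#' @export
Partition <- function(groups, species = NULL) {
  if (is.null(species)) species <- paste0("s", seq_along(groups))
  g <- as.integer(factor(groups, levels = unique(groups)))
  new("Partition", species = as.character(species), groups = g)
}

#' @rdname Partition-class
#' @export
setMethod("speciesNames", "Partition", function(x) x@species)

#' @rdname Partition-class
#' @export
setMethod("nSpecies", "Partition", function(x) length(x@groups))

#' @rdname Partition-class
#' @export
setMethod("groupAssignments", "Partition", function(x) {
  stats::setNames(x@groups, x@species)
})

#' @rdname Partition-class
#' @export
setMethod("nGroups", "Partition", function(x) length(unique(x@groups)))

#' @rdname Partition-class
#' @export
setMethod("groupSizes", "Partition", function(x) {
  tabulate(canonicalizePartition(x)@groups)
})

setMethod("show", "Partition", function(object) {
  cat("Partition of", length(object@groups), "species into",
      nGroups(object), "groups\n")
  cat("sizes:", paste(groupSizes(object), collapse = " "), "\n")
})

#' Canonicalize a partition
#'
#' Relabels groups as 1..g in order of first appearance and drops empty
#' labels. Canonicalization never changes any likelihood or entropy, and
#' two partitions describe the same grouping iff their canonical forms are
#' identical.
#'
#' @param part a \code{Partition}.
#' @return a canonical \code{Partition}.
#' @export
canonicalizePartition <- function(part) {
  g <- as.integer(factor(part@groups, levels = unique(part@groups)))
  new("Partition", species = part@species, groups = g)
}

#' Restrict a partition to a subset of species
#'
#' Keeps only the named species (in the order given by the partition) and
#' canonicalizes; the group count may shrink if a group loses all members.
#' Used to align partitions of nested networks, e.g. after jackknife
#' deletion or a species-class ablation.
#'
#' @param part a \code{Partition}.
#' @param keep_species character vector, a subset of the partition's species.
#' @return a \code{Partition} on the surviving species.
#' @export
restrictPartition <- function(part, keep_species) {
  unknown <- setdiff(keep_species, part@species)
  if (length(unknown) > 0)
    stop("unknown species: ", paste(unknown, collapse = ", "))
  sel <- part@species %in% keep_species
  canonicalizePartition(
    new("Partition", species = part@species[sel], groups = part@groups[sel]))
}

#' Read / write a partition file
#'
#' Partition files are tab-separated with a header row and two columns,
#' \code{species} and \code{group}.
#'
#' @param path file path.
#' @return \code{readPartition}: a \code{Partition}.
#' @export
readPartition <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  if (!all(c("species", "group") %in% names(df)))
    stop("partition file must have columns species, group")
  Partition(df$group, df$species)
}

#' @rdname readPartition
#' @param part a \code{Partition}.
#' @export
writePartition <- function(part, path) {
  part <- canonicalizePartition(part)
  utils::write.table(
    data.frame(species = part@species, group = part@groups),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# internal: check two partitions are over the same species in the same order
.checkAligned <- function(a, b) {
  if (length(a@groups) != length(b@groups))
    stop("partitions describe different numbers of species")
  if (!identical(a@species, b@species))
    stop("partitions must be over the same species in the same order")
  invisible(TRUE)
}

# internal: check a partition describes a network
.checkDescribes <- function(net, part) {
  if (length(part@groups) != nSpecies(net))
    stop("partition length (", length(part@groups),
         ") does not match network size (", nSpecies(net), ")")
  if (!identical(part@species, net@species))
    stop("partition species do not match network species")
  invisible(TRUE)
}
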