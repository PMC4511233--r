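#' @rdname SignedNetwork-class
#' @param x a \code{SignedNetwork} or \code{Partition}.
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))

#' @rdname SignedNetwork-class
#' @export
setGeneric("signMatrix", function(x) standardGeneric("signMatrix"))

#' @rdname SignedNetwork-class
#' @export
setGeneric("nSpecies", function(x) standardGeneric("nSpecies"))

#' @rdname Partition-class
#' @param x a \code{Partition}.
#' @export
setGeneric("groupAssignments", function(x) standardGeneric("groupAssignments"))

#' @rdname Partition-class
#' @export
setGeneric("nGroups", function(x) standardGeneric("nGroups"))

#' @rdname Partition-class
#' @export
setGeneric("groupSizes", function(x) standardGeneric("groupSizes"))

#' @rdname SearchResult-class
#' @param x a \code{SearchResult}.
#' @export
setGeneric("bestPartition", function(x) standardGeneric("bestPartition"))

#' @rdname SearchResult-class
#' @export
setGeneric("bestLogMarginal", function(x) standardGeneric("bestLogMarginal"))

#' @rdname SearchResult-class
#' @export
setGeneric("searchTrace", function(x) standardGeneric("searchTrace"))
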