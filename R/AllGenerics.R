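#' @title Accessor generics
#' @name accessors
#' @rdname accessors
#' @description Accessors for the package's S4 containers: C-alpha
#'   coordinates, residue keys, unit count, per-pair descriptor rows and
#'   region-level summaries. Use these instead of reaching into slots.
#' @param x a \linkS4class{CaStructure}, \linkS4class{RepeatRegion} or
#'   \linkS4class{GeometryTable} object.
NULL

#' @rdname accessors
#' @export
setGeneric("caCoords", function(x) standardGeneric("caCoords"))

#' @rdname accessors
#' @export
setGeneric("residueKeys", function(x) standardGeneric("residueKeys"))

#' @rdname accessors
#' @export
setGeneric("nUnits", function(x) standardGeneric("nUnits"))

#' @rdname accessors
#' @export
setGeneric("unitSpans", function(x) standardGeneric("unitSpans"))

#' @rdname accessors
#' @export
setGeneric("insertionSpans", function(x) standardGeneric("insertionSpans"))

#' @rdname accessors
#' @export
setGeneric("regionId", function(x) standardGeneric("regionId"))

#' @rdname accessors
#' @export
setGeneric("pairDescriptors", function(x) standardGeneric("pairDescriptors"))

#' @rdname accessors
#' @export
setGeneric("regionSummary", function(x) standardGeneric("regionSummary"))

#' @rdname accessors
#' @export
setGeneric("pairFrames", function(x) standardGeneric("pairFrames"))
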