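#' @rdname accessors
#' @export
setMethod("caCoords", "CaStructure", function(x) {
  m <- x@coords
  rownames(m) <- paste0(x@chain, x@resno, ifelse(x@icode == "", "", x@icode))
  m
})

#' @rdname accessors
#' @export
setMethod("residueKeys", "CaStructure", function(x) {
  data.frame(chain = x@chain, resno = x@resno, icode = x@icode,
             stringsAsFactors = FALSE)
})

#' @rdname accessors
#' @export
setMethod("nUnits", "RepeatRegion", function(x) nrow(x@units))

#' @rdname accessors
#' @export
setMethod("unitSpans", "RepeatRegion", function(x) x@units)

#' @rdname accessors
#' @export
setMethod("insertionSpans", "RepeatRegion", function(x) x@insertions)

#' @rdname accessors
#' @export
setMethod("regionId", "RepeatRegion", function(x) x@regionId)

#' @rdname accessors
#' @export
setMethod("regionId", "GeometryTable", function(x) x@regionId)

#' @rdname accessors
#' @export
setMethod("nUnits", "GeometryTable", function(x) x@nUnits)

#' @rdname accessors
#' @export
setMethod("pairDescriptors", "GeometryTable", function(x) x@pairs)

#' @rdname accessors
#' @export
setMethod("regionSummary", "GeometryTable", function(x) x@summary)

#' @rdname accessors
#' @export
setMethod("pairFrames", "GeometryTable", function(x) x@frames)

setMethod("show", "CaStructure", function(object) {
  cat(sprintf("CaStructure: %d C-alpha residues, %d chain(s), model %d\n",
              nrow(object@coords), length(unique(object@chain)), object@model))
  if (!is.na(object@source)) cat("  source:", object@source, "\n")
})

setMethod("show", "RepeatRegion", function(object) {
  cat(sprintf("RepeatRegion '%s': chain %s, %d units, %d insertion(s)\n",
              object@regionId, object@chain, nrow(object@units),
              nrow(object@insertions)))
  u <- object@units
  cat(sprintf("  span %d-%d\n", min(u$start), max(u$end)))
})

setMethod("show", "GeometryTable", function(object) {
  cat(sprintf("GeometryTable '%s': %d units, %d pair rows\n",
              object@regionId, object@nUnits, nrow(object@pairs)))
  s <- object@summary
  if (nrow(s)) {
    m <- s[s$statistic == "mean", ]
    d <- s[s$statistic == "sd", ]
    cat(sprintf("  curvature %.3f +/- %.3f  twist %.3f +/- %.3f  pitch %.3f +/- %.3f rad\n",
                m$curvature, d$curvature, m$twist, d$twist, m$pitch, d$pitch))
  }
  nbad <- sum(object@pairs$flag != "")
  if (nbad) cat(sprintf("  %d flagged row(s)\n", nbad))
})
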