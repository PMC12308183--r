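#' Calpha-trace protein structure
#'
#' Minimal structure model used throughout the package: one C-alpha
#' coordinate per residue, with residues identified by author chain id,
#' author residue number and insertion code (PDB convention). Row order
#' follows file order, which is the traversal order for all geometry.
#'
#' @slot coords numeric matrix, n x 3, C-alpha coordinates in Angstrom.
#' @slot chain character vector of chain identifiers, length n.
#' @slot resno integer vector of author residue numbers, length n.
#' @slot icode character vector of insertion codes ("" when absent), length n.
#' @slot model integer(1), model number the coordinates were taken from.
#' @slot source character(1), path of the file the structure was read from,
#'   or a generator tag for synthetic structures.
#'
#' @seealso [readStructure()], [generateSolenoid()]
#' @export
setClass("CaStructure",
  representation(
    coords = "matrix",
    chain  = "character",
    resno  = "integer",
    icode  = "character",
    model  = "integer",
    source = "character"
  ),
  prototype(
    coords = matrix(numeric(0), 0L, 3L),
    chain = character(0), resno = integer(0), icode = character(0),
    model = 1L, source = NA_character_
  )
)

setValidity("CaStructure", function(object) {
  n <- nrow(object@coords)
  msg <- character(0)
  if (ncol(object@coords) != 3L) msg <- c(msg, "coords must have 3 columns")
  if (length(object@chain) != n || length(object@resno) != n ||
      length(object@icode) != n) {
    msg <- c(msg, "chain/resno/icode must match the number of coordinate rows")
  }
  if (n > 0L && !all(is.finite(object@coords))) {
    msg <- c(msg, "coordinates must be finite")
  }
  key <- paste(object@chain, object@resno, object@icode, sep = "\r")
  if (anyDuplicated(key)) {
    msg <- c(msg, "duplicated residue key (chain, resno, icode): each residue has exactly one C-alpha")
  }
  if (length(msg)) msg else TRUE
})

#' Repeat-region annotation
#'
#' Ordered repeat-unit spans on one chain, plus optional insertion spans to
#' exclude from all geometry. Spans are 1-based inclusive author residue
#' numbers (RepeatsDB convention).
#'
#' @slot regionId character(1) region identifier.
#' @slot chain character(1) chain the units live on.
#' @slot units data.frame with integer columns `start`, `end`; one row per
#'   unit, sorted by `start`, non-overlapping, at least 3 units.
#' @slot insertions data.frame with integer columns `start`, `end`; spans
#'   excluded from units; must lie within the region.
#'
#' @seealso [readRegionSpec()]
#' @export
setClass("RepeatRegion",
  representation(
    regionId = "character",
    chain = "character",
    units = "data.frame",
    insertions = "data.frame"
  )
)

setValidity("RepeatRegion", function(object) {
  u <- object@units
  msg <- character(0)
  if (length(object@regionId) != 1L) msg <- c(msg, "regionId must be length 1")
  if (length(object@chain) != 1L) msg <- c(msg, "chain must be length 1")
  if (!all(c("start", "end") %in% names(u))) {
    return("units must have 'start' and 'end' columns")
  }
  if (nrow(u) < 3L) {
    msg <- c(msg, sprintf("region '%s': needs >= 3 units, got %d",
                          object@regionId, nrow(u)))
  }
  if (nrow(u) && any(u$end < u$start)) {
    msg <- c(msg, sprintf("region '%s': unit end < start", object@regionId))
  }
  if (nrow(u) > 1L) {
    if (is.unsorted(u$start, strictly = TRUE)) {
      msg <- c(msg, sprintf("region '%s': units must be sorted by start", object@regionId))
    } else if (any(u$start[-1L] <= u$end[-nrow(u)])) {
      msg <- c(msg, sprintf("region '%s': overlapping units", object@regionId))
    }
  }
  ins <- object@insertions
  if (nrow(ins)) {
    lo <- min(u$start); hi <- max(u$end)
    if (any(ins$end < ins$start)) {
      msg <- c(msg, sprintf("region '%s': insertion end < start", object@regionId))
    }
    if (any(ins$start < lo | ins$end > hi)) {
      msg <- c(msg, sprintf("region '%s': insertion outside the region span [%d, %d]",
                            object@regionId, lo, hi))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Per-pair geometry descriptor table
#'
#' One row per consecutive unit pair (i, i+1), indexed by the left unit:
#' curvature (radians, >= 0), twist and pitch (radians, signed), their
#' handedness signs, superposition RMSD, the fitted circle radius, and
#' per-row status flags. A summary (arithmetic mean and standard deviation
#' of curvature, twist and pitch over pairs) is carried alongside.
#'
#' @slot regionId character(1).
#' @slot nUnits integer(1) number of units in the region.
#' @slot pairs data.frame of per-pair descriptors.
#' @slot summary data.frame with columns `statistic`, `curvature`, `twist`,
#'   `pitch` (rows "mean" and "sd").
#' @slot frames list of per-pair local frames (for axis visualization);
#'   possibly empty.
#'
#' @seealso [computeRegionGeometry()], [writeGeometryCsv()]
#' @export
setClass("GeometryTable",
  representation(
    regionId = "character",
    nUnits = "integer",
    pairs = "data.frame",
    summary = "data.frame",
    frames = "list"
  ),
  prototype(frames = list())
)

setValidity("GeometryTable", function(object) {
  msg <- character(0)
  p <- object@pairs
  ## open traversal has nUnits - 1 rows; the optional wrap pair adds one
  if (!nrow(p) %in% c(object@nUnits - 1L, object@nUnits)) {
    msg <- c(msg, "pair rows must number nUnits - 1 (or nUnits with the wrap pair)")
  }
  if ("curvature" %in% names(p)) {
    cv <- p$curvature[!is.na(p$curvature)]
    if (length(cv) && (any(cv < -1e-12) || any(cv > pi + 1e-12))) {
      msg <- c(msg, "curvature must lie in [0, pi]")
    }
  }
  for (fld in c("twist", "pitch")) {
    hf <- paste0(fld, "_handedness")
    if (all(c(fld, hf) %in% names(p))) {
      ok <- is.na(p[[fld]]) | p[[hf]] == ifelse(p[[fld]] < 0, -1, 1)
      if (!all(ok)) msg <- c(msg, sprintf("%s must be the sign of %s (0 maps to +1)", hf, fld))
    }
  }
  if (length(msg)) msg else TRUE
})
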