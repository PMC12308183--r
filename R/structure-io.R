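## Reading structures and repeat annotations; writing descriptor tables and
## axis-visualization exports.

#' Read a protein structure as a C-alpha trace
#'
#' Reads a PDB or mmCIF file and keeps one C-alpha per residue of the
#' requested model. The format is auto-detected from the extension
#' (`.pdb`/`.ent` vs `.cif`/`.mmcif`), falling back to content sniffing
#' (`data_`/`loop_` header means mmCIF). Residues are identified by author
#' chain id, author residue number and insertion code. Alternate locations
#' are resolved to the highest-occupancy conformer (ties: first
#' encountered); residues without a C-alpha are dropped with a logged
#' warning.
#'
#' @param path path to a PDB or mmCIF file.
#' @param model model number to read (default 1, the first).
#' @param chain optional character vector restricting to these chains.
#' @param format `"auto"` (default), `"pdb"` or `"cif"`.
#' @return a \linkS4class{CaStructure}.
#' @export
readStructure <- function(path, model = 1L, chain = NULL,
                          format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("readStructure: file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif"
      else if (ext %in% c("pdb", "ent")) "pdb"
      else {
        head <- readLines(path, n = 20L, warn = FALSE)
        if (any(grepl("^(data_|loop_|#)", head))) "cif" else "pdb"
      }
  }
  atoms <- switch(format,
    pdb = .readPdbAtoms(path, model),
    cif = .readCifAtoms(path, model))
  .buildCaStructure(atoms, path, model, chain)
}

## Common post-processing: altloc resolution, CA selection, missing-CA
## warning, chain filter. `atoms` is a data.frame with columns
## chain, resno, icode, elety, alt, occ, x, y, z in file order.
.buildCaStructure <- function(atoms, path, model, chain) {
  if (!is.null(chain)) atoms <- atoms[atoms$chain %in% chain, , drop = FALSE]
  if (nrow(atoms) == 0L) {
    stop("readStructure: no atoms selected from ", path,
         if (!is.null(chain)) paste0(" (chain ", paste(chain, collapse = ","), ")"))
  }
  key <- paste(atoms$chain, atoms$resno, atoms$icode, sep = "\r")
  resOrder <- unique(key)
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0L) stop("readStructure: no C-alpha atoms in ", path)
  caKey <- paste(ca$chain, ca$resno, ca$icode, sep = "\r")
  ## altloc: per residue keep the highest-occupancy CA, ties -> first
  keep <- unlist(lapply(split(seq_len(nrow(ca)), factor(caKey, levels = unique(caKey))),
                        function(idx) idx[which.max(ca$occ[idx])]),
                 use.names = FALSE)
  ca <- ca[sort(keep), , drop = FALSE]
  caKey <- paste(ca$chain, ca$resno, ca$icode, sep = "\r")
  nMissing <- length(resOrder) - length(caKey)
  if (nMissing > 0L) {
    .log("warning", sprintf("%d residue(s) without a C-alpha dropped from %s",
                            nMissing, basename(path)))
  }
  ## order residues by first appearance in the file
  ca <- ca[order(match(caKey, resOrder)), , drop = FALSE]
  methods::new("CaStructure",
    coords = unname(cbind(ca$x, ca$y, ca$z)),
    chain = as.character(ca$chain),
    resno = as.integer(ca$resno),
    icode = as.character(ca$icode),
    model = as.integer(model),
    source = path)
}

.readPdbAtoms <- function(path, model) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = model > 1L, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("readStructure: cannot parse PDB file ", path,
                             ": ", conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  xyz <- cbind(at$x, at$y, at$z)
  if (model > 1L) {
    if (is.null(dim(pdb$xyz)) || nrow(pdb$xyz) < model) {
      stop("readStructure: model ", model, " not present in ", path)
    }
    xyz <- matrix(pdb$xyz[model, ], ncol = 3L, byrow = TRUE)
  }
  data.frame(
    chain = ifelse(is.na(at$chain), "", at$chain),
    resno = at$resno,
    icode = ifelse(is.na(at$insert), "", at$insert),
    elety = at$elety,
    occ = ifelse(is.na(at$o), 1, at$o),
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
    stringsAsFactors = FALSE)
}

## Minimal mmCIF atom_site reader: locates the atom_site loop, reads its
## column tags, and tokenizes the data rows (whitespace-delimited; quoted
## tokens supported). Only the fields needed for a C-alpha trace are used.
.readCifAtoms <- function(path, model) {
  lines <- readLines(path, warn = FALSE)
  tagIdx <- grep("^_atom_site\\.", lines)
  if (length(tagIdx) == 0L) {
    stop("readStructure: no _atom_site loop found in ", path)
  }
  tags <- sub("^_atom_site\\.", "", trimws(lines[tagIdx]))
  dataStart <- max(tagIdx) + 1L
  rows <- character(0)
  for (i in seq.int(dataStart, length(lines))) {
    ln <- trimws(lines[i])
    if (ln == "" ) next
    if (grepl("^(#|loop_|_[A-Za-z]|data_)", ln)) break
    rows <- c(rows, ln)
  }
  if (length(rows) == 0L) stop("readStructure: empty atom_site loop in ", path)
  tok <- lapply(rows, .cifTokens)
  nbad <- which(vapply(tok, length, 1L) != length(tags))
  if (length(nbad)) {
    stop("readStructure: malformed atom_site row ", nbad[1L], " in ", path,
         " (expected ", length(tags), " fields)")
  }
  m <- do.call(rbind, tok)
  colnames(m) <- tags
  get <- function(nm, alt = NULL) {
    if (nm %in% tags) m[, nm]
    else if (!is.null(alt) && alt %in% tags) m[, alt]
    else rep(NA_character_, nrow(m))
  }
  blank <- function(x) ifelse(x %in% c("?", ".", NA), "", x)
  modelNum <- get("pdbx_PDB_model_num")
  if (!all(is.na(modelNum))) {
    keep <- as.integer(modelNum) == as.integer(model)
    if (!any(keep)) stop("readStructure: model ", model, " not present in ", path)
    m <- m[keep, , drop = FALSE]
  } else if (model > 1L) {
    stop("readStructure: model ", model, " not present in ", path)
  }
  get2 <- function(nm, alt = NULL) {
    if (nm %in% tags) m[, nm]
    else if (!is.null(alt) && alt %in% tags) m[, alt]
    else rep(NA_character_, nrow(m))
  }
  occ <- suppressWarnings(as.numeric(get2("occupancy")))
  xyz <- suppressWarnings(cbind(as.numeric(get2("Cartn_x")),
                                as.numeric(get2("Cartn_y")),
                                as.numeric(get2("Cartn_z"))))
  if (any(!is.finite(xyz))) {
    stop("readStructure: non-numeric coordinates in atom_site loop of ", path)
  }
  data.frame(
    chain = blank(get2("auth_asym_id", "label_asym_id")),
    resno = as.integer(get2("auth_seq_id", "label_seq_id")),
    icode = blank(get2("pdbx_PDB_ins_code")),
    elety = blank(get2("auth_atom_id", "label_atom_id")),
    occ = ifelse(is.na(occ), 1, occ),
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
    stringsAsFactors = FALSE)
}

.cifTokens <- function(line) {
  toks <- regmatches(line, gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line))[[1L]]
  gsub("^['\"]|['\"]$", "", toks)
}

#' Read repeat-region annotations
#'
#' Two dialects are accepted. JSON: a list of regions, each
#' `{"region_id", "chain", "units": [[start, end], ...],
#' "insertions": [[start, end], ...]}` (insertions optional). TSV: one row
#' per span with columns `region_id`, `chain`, `start`, `end`,
#' `is_insertion` (0/1 or TRUE/FALSE). Spans are 1-based inclusive author
#' residue numbers. Units are sorted by start; validation (>= 3 units,
#' no overlaps, insertions inside the region) names the offending region.
#'
#' @param path path to a `.json` or `.tsv` annotation file.
#' @param format `"auto"` (by extension), `"json"` or `"tsv"`.
#' @return list of \linkS4class{RepeatRegion} objects.
#' @export
readRegionSpec <- function(path, format = c("auto", "json", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("readRegionSpec: file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext == "json") "json" else if (ext %in% c("tsv", "txt")) "tsv"
      else stop("readRegionSpec: cannot infer format from extension '", ext, "'")
  }
  if (format == "json") {
    spec <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    regions <- lapply(spec, function(rg) {
      units <- .spanDf(rg$units, rg$region_id)
      ins <- if (is.null(rg$insertions)) .spanDf(list(), NULL)
             else .spanDf(rg$insertions, rg$region_id)
      newRepeatRegion(rg$region_id, rg$chain, units, ins)
    })
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("region_id", "chain", "start", "end", "is_insertion")
    if (!all(need %in% names(tab))) {
      stop("readRegionSpec: TSV must have columns ", paste(need, collapse = ", "))
    }
    regions <- lapply(split(tab, factor(tab$region_id, levels = unique(tab$region_id))),
      function(rg) {
        isIns <- as.logical(rg$is_insertion) | rg$is_insertion %in% c(1, "1")
        newRepeatRegion(rg$region_id[1L], rg$chain[1L],
          data.frame(start = as.integer(rg$start[!isIns]),
                     end = as.integer(rg$end[!isIns])),
          data.frame(start = as.integer(rg$start[isIns]),
                     end = as.integer(rg$end[isIns])))
      })
    names(regions) <- NULL
  }
  regions
}

.spanDf <- function(spans, rid) {
  if (length(spans) == 0L) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  bad <- vapply(spans, function(s) length(s) != 2L, TRUE)
  if (any(bad)) stop("readRegionSpec: region '", rid, "': spans must be [start, end] pairs")
  data.frame(start = vapply(spans, function(s) as.integer(s[[1L]]), 1L),
             end = vapply(spans, function(s) as.integer(s[[2L]]), 1L))
}

#' Construct a RepeatRegion
#'
#' @param regionId region identifier.
#' @param chain chain id the units live on.
#' @param units data.frame with columns `start`, `end` (1-based inclusive).
#' @param insertions optional data.frame with columns `start`, `end`.
#' @return a validated \linkS4class{RepeatRegion}.
#' @export
newRepeatRegion <- function(regionId, chain, units,
                            insertions = data.frame(start = integer(0),
                                                    end = integer(0))) {
  units <- units[order(units$start), , drop = FALSE]
  rownames(units) <- NULL
  methods::new("RepeatRegion", regionId = as.character(regionId),
               chain = as.character(chain),
               units = data.frame(start = as.integer(units$start),
                                  end = as.integer(units$end)),
               insertions = data.frame(start = as.integer(insertions$start),
                                       end = as.integer(insertions$end)))
}

#' Extract per-unit C-alpha coordinates
#'
#' Resolves every unit span of a region against a structure, excluding any
#' residue falling inside an insertion span. Coordinates follow chain
#' (file) order.
#'
#' @param structure a \linkS4class{CaStructure}.
#' @param region a \linkS4class{RepeatRegion}.
#' @return list of numeric matrices (one per unit, n_i x 3).
#' @export
extractUnitCoords <- function(structure, region) {
  u <- region@units
  lapply(seq_len(nrow(u)), function(i) {
    .extractSpanCoords(structure, region, i)
  })
}

## Resolve one unit span (insertions removed) against a structure.
.extractSpanCoords <- function(structure, region, i) {
  onChain <- structure@chain == region@chain
  resno <- structure@resno
  ins <- region@insertions
  inInsertion <- rep(FALSE, length(resno))
  if (nrow(ins)) {
    for (k in seq_len(nrow(ins))) {
      inInsertion <- inInsertion | (resno >= ins$start[k] & resno <= ins$end[k])
    }
  }
  u <- region@units
  sel <- which(onChain & resno >= u$start[i] & resno <= u$end[i])
  if (length(sel) == 0L) {
    stop(sprintf("extractUnitCoords: region '%s' unit %d (chain %s, %d-%d) not present in structure",
                 region@regionId, i, region@chain, u$start[i], u$end[i]))
  }
  sel <- sel[!inInsertion[sel]]
  if (length(sel) < 3L) {
    stop(sprintf("extractUnitCoords: region '%s' unit %d (chain %s, %d-%d) has %d C-alpha after insertion removal; need >= 3 for superposition",
                 region@regionId, i, region@chain, u$start[i], u$end[i], length(sel)))
  }
  structure@coords[sel, , drop = FALSE]
}

#' Write a geometry table to CSV
#'
#' One CSV in a single dialect: per-pair rows carry `row_type = "pair"`,
#' followed by summary rows `row_type = "mean"` and `"sd"` holding the
#' region-level mean and standard deviation of curvature, twist and pitch.
#' Floating point values are printed with 8 significant digits.
#'
#' @param table a \linkS4class{GeometryTable}.
#' @param path output path.
#' @export
writeGeometryCsv <- function(table, path) {
  p <- table@pairs
  p <- cbind(row_type = rep("pair", nrow(p)), region_id = table@regionId, p,
             stringsAsFactors = FALSE)
  s <- table@summary
  if (nrow(s)) {
    sm <- p[0, , drop = FALSE]
    for (i in seq_len(nrow(s))) {
      row <- as.list(rep(NA, ncol(p)))
      names(row) <- names(p)
      row$row_type <- s$statistic[i]
      row$region_id <- table@regionId
      row$curvature <- s$curvature[i]
      row$twist <- s$twist[i]
      row$pitch <- s$pitch[i]
      sm <- rbind(sm, as.data.frame(row, stringsAsFactors = FALSE))
    }
    p <- rbind(p, sm)
  }
  num <- vapply(p, is.numeric, TRUE) & !vapply(p, is.integer, TRUE)
  for (j in which(num)) {
    p[[j]] <- ifelse(is.na(p[[j]]), "", formatC(p[[j]], digits = 8, format = "g"))
  }
  con <- tryCatch(suppressWarnings(file(path, "w")),
                  error = function(e) stop("writeGeometryCsv: cannot open ", path,
                                           " for writing", call. = FALSE))
  on.exit(close(con))
  utils::write.csv(p, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a geometry CSV
#'
#' Inverse of [writeGeometryCsv()] at printed precision; mainly used for
#' round-trip checks and for aggregating batch outputs.
#'
#' @param path CSV path written by [writeGeometryCsv()].
#' @return data.frame with a `row_type` column separating pair and summary
#'   rows.
#' @export
readGeometryCsv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Export rotational axes for visualization
#'
#' Writes a pseudo-atom PDB tracing, for each unit pair, the three local
#' axes from the unit anchor (twist x, pitch y, curvature z), plus a PyMOL
#' script that loads it and colors the axes x = red, y = green, z = blue.
#' No viewer is required to produce the files.
#'
#' @param structure the \linkS4class{CaStructure} the frames refer to.
#' @param region the \linkS4class{RepeatRegion}.
#' @param frames list of local frames, one per unit pair (e.g. from
#'   [pairFrames()] of a computed \linkS4class{GeometryTable}).
#' @param path output path of the PyMOL script (`.pml`); the pseudo-atom
#'   PDB is written next to it with suffix `_axes.pdb`.
#' @param axisLength drawn axis length in Angstrom (default 5).
#' @param pointsPerAxis pseudo-atoms per axis segment (default 2:
#'   anchor and tip).
#' @export
exportAxesVisualization <- function(structure, region, frames, path,
                                    axisLength = 5, pointsPerAxis = 2L) {
  if (length(frames) == 0L) stop("exportAxesVisualization: empty frame list")
  pdbPath <- sub("\\.pml$", "", path)
  pdbPath <- paste0(pdbPath, "_axes.pdb")
  axes <- c("x", "y", "z")
  chains <- c(x = "X", y = "Y", z = "Z")
  lines <- character(0)
  serial <- 0L
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    for (ax in axes) {
      tt <- seq(0, axisLength, length.out = max(2L, pointsPerAxis))
      for (t in tt) {
        serial <- serial + 1L
        p <- fr$anchor + t * fr[[ax]]
        lines <- c(lines, sprintf(
          "HETATM%5d  C   AXS %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
          serial %% 100000L, chains[[ax]], i, p[1L], p[2L], p[3L]))
      }
    }
  }
  writeLines(c(lines, "END"), pdbPath)
  src <- structure@source
  pml <- c(
    sprintf("# axes for region %s (%d unit pairs)", region@regionId, length(frames)),
    if (!is.na(src) && file.exists(src)) sprintf("load %s, structure", src),
    sprintf("load %s, axes", pdbPath),
    "hide everything, axes",
    "show spheres, axes",
    "set sphere_scale, 0.3, axes",
    "color red, axes and chain X",
    "color green, axes and chain Y",
    "color blue, axes and chain Z")
  writeLines(pml, path)
  invisible(c(script = path, pdb = pdbPath))
}

#' Write a C-alpha structure as PDB
#'
#' @param structure a \linkS4class{CaStructure}.
#' @param path output path.
#' @export
writeStructurePdb <- function(structure, path) {
  n <- nrow(structure@coords)
  ic <- ifelse(structure@icode == "", " ", substr(structure@icode, 1L, 1L))
  lines <- sprintf(
    "ATOM  %5d  CA  ALA %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(n) %% 100000L, substr(structure@chain, 1L, 1L), structure@resno, ic,
    structure@coords[, 1L], structure@coords[, 2L], structure@coords[, 3L])
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}

#' Write a C-alpha structure as mmCIF
#'
#' Coordinates are printed with the same precision as the PDB writer, so a
#' structure written both ways reads back identically.
#'
#' @param structure a \linkS4class{CaStructure}.
#' @param path output path.
#' @export
writeStructureCif <- function(structure, path) {
  n <- nrow(structure@coords)
  ic <- ifelse(structure@icode == "", "?", structure@icode)
  header <- c(
    "data_synthetic",
    "#",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_asym_id",
    "_atom_site.pdbx_PDB_model_num")
  rows <- sprintf("ATOM %d C CA . ALA %s %d %s %.3f %.3f %.3f 1.00 0.00 %d %s 1",
                  seq_len(n), structure@chain, structure@resno, ic,
                  structure@coords[, 1L], structure@coords[, 2L],
                  structure@coords[, 3L], structure@resno, structure@chain)
  writeLines(c(header, rows, "#"), path)
  invisible(path)
}

#' Write a region annotation as JSON
#'
#' @param regions list of \linkS4class{RepeatRegion} objects (or a single
#'   one).
#' @param path output path.
#' @export
writeRegionSpec <- function(regions, path) {
  if (methods::is(regions, "RepeatRegion")) regions <- list(regions)
  spec <- lapply(regions, function(rg) {
    u <- rg@units; ins <- rg@insertions
    out <- list(region_id = rg@regionId, chain = rg@chain,
                units = lapply(seq_len(nrow(u)), function(i) c(u$start[i], u$end[i])))
    if (nrow(ins)) {
      out$insertions <- lapply(seq_len(nrow(ins)), function(i) c(ins$start[i], ins$end[i]))
    }
    out
  })
  jsonlite::write_json(spec, path, auto_unbox = TRUE)
  invisible(path)
}
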