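test_that("PDB parsing keeps one highest-occupancy C-alpha per residue and drops CA-less residues", {
  pdb <- writeTinyPdb(withr::local_tempfile(fileext = ".pdb"))
  st <- readStructure(pdb)
  keys <- residueKeys(st)
  expect_equal(nrow(keys), 3L)              # residue 3 has no CA
  expect_equal(keys$resno, c(1L, 2L, 4L))
  expect_equal(unname(caCoords(st)[1, ]), c(11.639, 6.071, -5.147))
  # altloc B has occupancy 0.60 and must win over A (0.40)
  expect_equal(unname(caCoords(st)[3, ]), c(13.125, 8.250, -3.250))
})

test_that("parse errors are explicit for unreadable or empty selections", {
  expect_error(readStructure(file.path(tempdir(), "nope.pdb")), "not found")
  noCa <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "END"), noCa)
  expect_error(readStructure(noCa), "C-alpha")
  pdb <- writeTinyPdb(withr::local_tempfile(fileext = ".pdb"))
  expect_error(readStructure(pdb, chain = "Q"), "chain Q")
})

test_that("PDB and mmCIF parsers agree exactly on equivalent generated fixtures", {
  s <- generateSolenoid(nUnits = 6, yaw0 = 0.4, roll0 = 0.2, radius = 18)
  pdb <- withr::local_tempfile(fileext = ".pdb")
  cif <- withr::local_tempfile(fileext = ".cif")
  writeStructurePdb(s$structure, pdb)
  writeStructureCif(s$structure, cif)
  a <- readStructure(pdb)
  b <- readStructure(cif)
  expect_identical(caCoords(a), caCoords(b))
  expect_identical(residueKeys(a), residueKeys(b))
  # lossless round trip at the 3-decimal precision of both formats
  expect_identical(unname(caCoords(a)), round(s$structure@coords, 3))
})

test_that("region specs parse from JSON and TSV into the same annotation", {
  json <- writeRegionJson(withr::local_tempfile(fileext = ".json"), list(
    list(region_id = "r1", chain = "A",
         units = list(c(1, 10), c(11, 20), c(21, 30)),
         insertions = list(c(15, 16)))))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("region_id\tchain\tstart\tend\tis_insertion",
               "r1\tA\t1\t10\t0", "r1\tA\t11\t20\t0", "r1\tA\t21\t30\t0",
               "r1\tA\t15\t16\t1"), tsv)
  rj <- readRegionSpec(json)
  rt <- readRegionSpec(tsv)
  expect_length(rj, 1L)
  expect_equal(nUnits(rj[[1]]), 3L)
  expect_equal(unitSpans(rj[[1]]), unitSpans(rt[[1]]))
  expect_equal(insertionSpans(rj[[1]]), data.frame(start = 15L, end = 16L))
  expect_equal(regionId(rt[[1]]), "r1")
})

test_that("region validation rejects overlaps, short regions and stray insertions by name", {
  bad <- function(units, insertions = list()) {
    writeRegionJson(tempfile(fileext = ".json"), list(
      list(region_id = "rX", chain = "A", units = units,
           insertions = insertions)))
  }
  expect_error(readRegionSpec(bad(list(c(1, 10), c(5, 20), c(21, 30)))),
               "rX.*overlap")
  expect_error(readRegionSpec(bad(list(c(1, 10), c(11, 20)))), "rX.*3 units")
  expect_error(readRegionSpec(bad(list(c(1, 10), c(11, 20), c(21, 30)),
                                  insertions = list(c(40, 45)))),
               "rX.*outside")
})

test_that("unit extraction excludes insertion residues and names unresolvable spans", {
  s <- generateSolenoid(nUnits = 3, yaw0 = 0.5, radius = 15)  # residues 1..30
  region <- newRepeatRegion("rI", "A",
    data.frame(start = c(1L, 11L, 21L), end = c(10L, 20L, 30L)),
    insertions = data.frame(start = 14L, end = 15L))
  uc <- extractUnitCoords(s$structure, region)
  expect_equal(vapply(uc, nrow, 1L), c(10L, 8L, 10L))
  expect_identical(uc[[1]], s$structure@coords[1:10, ])
  # the excluded residues are exactly 14 and 15
  expect_identical(uc[[2]], s$structure@coords[c(11:13, 16:20), ])

  ghost <- newRepeatRegion("rG", "A",
    data.frame(start = c(1L, 11L, 41L), end = c(10L, 20L, 50L)))
  expect_error(extractUnitCoords(s$structure, ghost), "41-50")
  shorty <- newRepeatRegion("rS", "A",
    data.frame(start = c(1L, 11L, 21L), end = c(10L, 20L, 30L)),
    insertions = data.frame(start = 21L, end = 28L))
  expect_error(extractUnitCoords(s$structure, shorty), ">= 3")
})

test_that("geometry CSV round-trips pair and summary rows at printed precision", {
  s <- generateSolenoid(nUnits = 5, yaw0 = 0.35, pitch0 = 0.05, roll0 = -0.2)
  tab <- computeRegionGeometry(s$structure, s$region)
  csv <- withr::local_tempfile(fileext = ".csv")
  writeGeometryCsv(tab, csv)
  back <- readGeometryCsv(csv)
  expect_equal(sum(back$row_type == "pair"), 4L)
  expect_equal(sum(back$row_type %in% c("mean", "sd")), 2L)
  p <- pairDescriptors(tab)
  bp <- back[back$row_type == "pair", ]
  expect_equal(bp$curvature, p$curvature, tolerance = 1e-6)
  expect_equal(bp$twist, p$twist, tolerance = 1e-6)
  expect_equal(bp$pitch, p$pitch, tolerance = 1e-6)
  expect_equal(bp$rmsd, p$rmsd, tolerance = 1e-6)
  m <- back[back$row_type == "mean", ]
  expect_equal(m$curvature, mean(p$curvature), tolerance = 1e-6)
  expect_error(writeGeometryCsv(tab, file.path(tempdir(), "no/such/dir/x.csv")),
               "cannot open")
})

test_that("axes visualization export writes one colored segment per axis per pair", {
  s <- generateSolenoid(nUnits = 3, yaw0 = 2 * pi / 3, closed = TRUE, radius = 15)
  tab <- computeRegionGeometry(s$structure, s$region)
  frames <- pairFrames(tab)
  expect_length(frames, 2L)
  pml <- withr::local_tempfile(fileext = ".pml")
  out <- exportAxesVisualization(s$structure, s$region, frames, pml,
                                 axisLength = 1, pointsPerAxis = 2L)
  expect_true(file.exists(out[["pdb"]]))
  atoms <- grep("^HETATM", readLines(out[["pdb"]]), value = TRUE)
  expect_length(atoms, 2L * 3L * 2L)     # 2 frames x 3 axes x 2 points
  # unit-length axes: tip is axisLength away from anchor
  xyz <- do.call(rbind, lapply(atoms, function(l) {
    as.numeric(c(substr(l, 31, 38), substr(l, 39, 46), substr(l, 47, 54)))
  }))
  seg <- xyz[2, ] - xyz[1, ]
  expect_equal(sqrt(sum(seg^2)), 1, tolerance = 1e-3)
  script <- readLines(pml)
  expect_true(any(grepl("color red", script)))
  expect_error(exportAxesVisualization(s$structure, s$region, list(), pml),
               "empty frame list")
})
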