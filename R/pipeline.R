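## Per-region orchestration and batch processing.

#' Pipeline configuration
#'
#' Collects the tunable parameters of the geometry pipeline. Defaults
#' reproduce the standard analysis; every value can be overridden per run.
#'
#' @param window sliding-window length in units (>= 3, default 6).
#' @param backend superposition backend, `"internal"` (Kabsch) or
#'   `"external"` (TM-align-compatible executable on the PATH).
#' @param twistSign +1 or -1: maps the mathematical roll angle to the
#'   clockwise-positive twist convention (default -1).
#' @param radiusCap fitted radii above this value (Angstrom) are treated as
#'   near-linear (default 1e4).
#' @param linearEvalRatio windows whose centroid principal-variance ratio
#'   lambda2/lambda1 falls below this are treated as near-linear
#'   (default 1e-4).
#' @param dispTol minimum displacement along the window normal (Angstrom)
#'   for pitch-sign reconciliation (default 0.5).
#' @param refineCenter also re-estimate the circle center from all
#'   projected C-alpha atoms before the crown refinement (default FALSE:
#'   the center from the centroid fit is kept, and the crown refines only
#'   the radius).
#' @param wrap also traverse the closing pair (last unit, first unit)
#'   (default FALSE: regions are traversed open, N- to C-terminus).
#' @param workers parallel workers for batch processing (default 1).
#' @param logLevel one of "debug", "info", "warning", "error".
#' @param seed seed for any stochastic option (reserved; the default
#'   pipeline is deterministic).
#' @return a named list of class `geomConfig`.
#' @export
geomConfig <- function(window = 6L, backend = c("internal", "external"),
                       twistSign = -1, radiusCap = 1e4,
                       linearEvalRatio = 1e-4, dispTol = 0.5,
                       refineCenter = FALSE, wrap = FALSE, workers = 1L,
                       logLevel = "info", seed = 1L) {
  backend <- match.arg(backend)
  stopifnot(window >= 3L, workers >= 1L, twistSign %in% c(-1, 1))
  structure(list(window = as.integer(window), backend = backend,
                 twistSign = twistSign, radiusCap = radiusCap,
                 linearEvalRatio = linearEvalRatio, dispTol = dispTol,
                 refineCenter = isTRUE(refineCenter), wrap = isTRUE(wrap),
                 workers = as.integer(workers), logLevel = logLevel,
                 seed = as.integer(seed)),
            class = "geomConfig")
}

.naRow <- function(pair, lspan, rspan, flag) {
  list(pair = pair,
       left_start = lspan[1L], left_end = lspan[2L],
       right_start = rspan[1L], right_end = rspan[2L],
       curvature = NA_real_, twist = NA_real_, pitch = NA_real_,
       twist_handedness = NA_integer_, pitch_handedness = NA_integer_,
       rmsd = NA_real_, radius = NA_real_, aligned_length = NA_integer_,
       yaw_diagnostic = NA_real_, flag = flag)
}

#' Compute the geometry table of one repeat region
#'
#' Runs the full per-pair pipeline: sliding-window selection, centroid
#' plane fit, initial circle, widest-crown refinement, curvature angle,
#' local frames, canonicalization, superposition and Tait-Bryan
#' decomposition. Degenerate geometry in any stage flags that pair's row
#' (null angles + reason) and processing continues. Windows that are
#' near-linear (centroid variance ratio below `linearEvalRatio`, or a
#' fitted radius above `radiusCap`) report curvature 0 with the `linear`
#' flag and take the pitch axis from the third principal direction.
#'
#' @param structure a \linkS4class{CaStructure}.
#' @param region a \linkS4class{RepeatRegion} resolving against it.
#' @param config a [geomConfig()].
#' @return a \linkS4class{GeometryTable}.
#' @export
computeRegionGeometry <- function(structure, region, config = geomConfig()) {
  oldOpt <- options(RepeatGeometry.logLevel = config$logLevel)
  on.exit(options(oldOpt))
  n <- nUnits(region)
  spans <- unitSpans(region)
  unitCoords <- lapply(seq_len(n), function(i) {
    tryCatch(.extractSpanCoords(structure, region, i),
             error = function(e) NULL)
  })
  validUnit <- !vapply(unitCoords, is.null, TRUE)
  if (!all(validUnit)) {
    .log("warning", sprintf("region '%s': %d unresolvable unit(s)",
                            region@regionId, sum(!validUnit)))
  }
  centroids <- matrix(NA_real_, n, 3L)
  for (i in which(validUnit)) centroids[i, ] <- unitCentroid(unitCoords[[i]])

  pairsIdx <- lapply(seq_len(n - 1L), function(i) c(i, i + 1L))
  if (config$wrap) pairsIdx <- c(pairsIdx, list(c(n, 1L)))

  prevNormal <- NULL
  rows <- vector("list", length(pairsIdx))
  frames <- vector("list", length(pairsIdx))
  for (pi in seq_along(pairsIdx)) {
    i <- pairsIdx[[pi]][1L]; j <- pairsIdx[[pi]][2L]
    lspan <- c(spans$start[i], spans$end[i])
    rspan <- c(spans$start[j], spans$end[j])
    if (!validUnit[i] || !validUnit[j]) {
      rows[[pi]] <- .naRow(i, lspan, rspan, "error:unit_unresolved")
      next
    }
    res <- tryCatch({
      widx <- if (j == 1L) {
        w <- min(config$window, n)
        c(utils::tail(seq_len(n), w %/% 2L), utils::head(seq_len(n), w - w %/% 2L))
      } else selectWindow(i, n, config$window)
      widx <- widx[validUnit[widx]]
      if (length(widx) < 3L) stop("fewer than 3 resolvable units in the window")
      wcent <- centroids[widx, , drop = FALSE]
      plane <- fitPlane(wcent)
      flags <- character(0)

      linear <- plane$evals[2L] / plane$evals[1L] < config$linearEvalRatio
      circle <- NULL
      if (!linear) {
        cent2d <- projectToPlane(wcent, plane)
        init <- fitInitialCircle(cent2d)
        if (config$refineCenter && init$ok) {
          allCa2d <- projectToPlane(do.call(rbind, unitCoords[widx]), plane)
          initAll <- fitInitialCircle(allCa2d)
          if (initAll$ok) init <- initAll
        }
        if (!init$ok || init$radius > config$radiusCap) {
          linear <- TRUE
        } else {
          allCa2d <- projectToPlane(do.call(rbind, unitCoords[widx]), plane)
          circle <- widestCrownRefine(allCa2d, init$center, init$radius)
          if (circle$fallback) flags <- c(flags, "crown_fallback")
          circle$center3d <- plane$origin + circle$center[1L] * plane$u +
            circle$center[2L] * plane$v
        }
      }
      if (linear) flags <- c(flags, "linear")

      travel <- centroids[j, ] - centroids[i, ]
      ## continuity-oriented window normal (sign only affects the pitch
      ## displacement convention, not the fitted circle)
      nrm <- plane$n
      if (!is.null(prevNormal)) {
        if (sum(nrm * prevNormal) < 0) nrm <- -nrm
      } else if (!linear) {
        y0 <- .normalize(centroids[i, ] - circle$center3d)
        if (sum(travel * .cross3(nrm, y0)) < 0) nrm <- -nrm
      }
      prevNormal <- nrm

      if (linear) {
        planeOriented <- plane; planeOriented$n <- nrm
        frameL <- .linearFrame(planeOriented, centroids[i, ], centroids[j, ])
        frameR <- .linearFrame(planeOriented, centroids[j, ], centroids[j, ] + travel)
        frameR$anchor <- centroids[j, ]
        curvature <- 0
        radius <- Inf
      } else {
        frameL <- buildLocalFrame(circle$center3d, centroids[i, ], centroids[j, ])
        frameR <- buildLocalFrame(circle$center3d, centroids[j, ], centroids[j, ] + travel)
        curvature <- curvatureAngle(circle$center3d, centroids[i, ], centroids[j, ])
        radius <- circle$radius
      }
      qL <- canonicalizeUnit(unitCoords[[i]], frameL)
      qR <- canonicalizeUnit(unitCoords[[j]], frameR)
      sup <- superposeUnits(qR, qL, backend = config$backend)
      tb <- decomposeTaitBryan(sup$R)
      if (tb$gimbal) flags <- c(flags, "gimbal")
      desc <- pairDescriptor(curvature, tb, sup$rmsd, sup$alignedLength,
                             dispNormal = sum(travel * nrm),
                             twistSign = config$twistSign,
                             dispTol = config$dispTol)
      frames[[pi]] <- frameL
      c(list(pair = i,
             left_start = lspan[1L], left_end = lspan[2L],
             right_start = rspan[1L], right_end = rspan[2L]),
        desc[c("curvature", "twist", "pitch", "twist_handedness",
               "pitch_handedness", "rmsd", "aligned_length")],
        list(radius = radius, yaw_diagnostic = desc$yaw_diagnostic,
             flag = paste(flags, collapse = ",")))
    }, error = function(e) {
      .log("warning", sprintf("region '%s' pair %d: %s", region@regionId, i,
                              conditionMessage(e)))
      .naRow(i, lspan, rspan, paste0("error:", conditionMessage(e)))
    })
    rows[[pi]] <- res
  }
  cols <- c("pair", "left_start", "left_end", "right_start", "right_end",
            "curvature", "twist", "pitch", "twist_handedness",
            "pitch_handedness", "rmsd", "radius", "aligned_length",
            "yaw_diagnostic", "flag")
  pairs <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r[cols], stringsAsFactors = FALSE)
  }))
  rownames(pairs) <- NULL
  open <- pairs[seq_len(n - 1L), , drop = FALSE]   # summary over open traversal
  summ <- data.frame(
    statistic = c("mean", "sd"),
    curvature = c(mean(open$curvature, na.rm = TRUE), stats::sd(open$curvature, na.rm = TRUE)),
    twist = c(mean(open$twist, na.rm = TRUE), stats::sd(open$twist, na.rm = TRUE)),
    pitch = c(mean(open$pitch, na.rm = TRUE), stats::sd(open$pitch, na.rm = TRUE)),
    stringsAsFactors = FALSE)
  methods::new("GeometryTable", regionId = region@regionId, nUnits = n,
               pairs = pairs, summary = summ,
               frames = Filter(Negate(is.null), frames))
}

#' Batch processing over many structures
#'
#' Processes a manifest of (structure path, region spec path) jobs
#' independently, writes one CSV per region and a combined region summary,
#' and returns a per-job status table. Results are identical to serial
#' execution and output order is deterministic (input order) regardless of
#' the worker count; job failures are isolated and reported.
#'
#' @param manifest data.frame with columns `structure` and `regions`
#'   (file paths), or path to a TSV with those columns.
#' @param outDir output directory (created if needed).
#' @param config a [geomConfig()]; `config$workers` sets parallelism.
#' @return invisibly, a list with `status` (per-job data.frame), `summary`
#'   (combined per-region summary data.frame) and `exitCode`
#'   (0 = all regions computed, 1 = partial, 2 = none).
#' @export
runBatch <- function(manifest, outDir, config = geomConfig()) {
  if (is.character(manifest)) {
    manifest <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  }
  if (nrow(manifest) == 0L) stop("runBatch: empty job list")
  if (!all(c("structure", "regions") %in% names(manifest))) {
    stop("runBatch: manifest needs 'structure' and 'regions' columns")
  }
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  runJob <- function(k) {
    tryCatch({
      st <- readStructure(manifest$structure[k])
      regs <- readRegionSpec(manifest$regions[k])
      tables <- lapply(regs, function(rg) computeRegionGeometry(st, rg, config))
      list(ok = TRUE, tables = tables, message = "")
    }, error = function(e) list(ok = FALSE, tables = list(),
                                message = conditionMessage(e)))
  }
  results <- if (config$workers > 1L && .Platform$OS.type == "unix") {
    parallel::mclapply(seq_len(nrow(manifest)), runJob,
                       mc.cores = config$workers, mc.preschedule = TRUE)
  } else {
    lapply(seq_len(nrow(manifest)), runJob)
  }
  status <- data.frame(job = seq_len(nrow(manifest)),
                       structure = manifest$structure,
                       regions = manifest$regions,
                       ok = vapply(results, function(r) r$ok, TRUE),
                       message = vapply(results, function(r) r$message, ""),
                       stringsAsFactors = FALSE)
  summaryRows <- list()
  for (k in seq_len(nrow(manifest))) {
    for (tab in results[[k]]$tables) {
      csv <- file.path(outDir, paste0(regionId(tab), ".csv"))
      writeGeometryCsv(tab, csv)
      s <- regionSummary(tab)
      m <- s[s$statistic == "mean", ]; d <- s[s$statistic == "sd", ]
      summaryRows[[length(summaryRows) + 1L]] <- data.frame(
        job = k, region_id = regionId(tab), n_units = nUnits(tab),
        n_pairs = nrow(pairDescriptors(tab)),
        curvature_mean = m$curvature, curvature_sd = d$curvature,
        twist_mean = m$twist, twist_sd = d$twist,
        pitch_mean = m$pitch, pitch_sd = d$pitch,
        stringsAsFactors = FALSE)
    }
  }
  combined <- if (length(summaryRows)) do.call(rbind, summaryRows) else
    data.frame(job = integer(0), region_id = character(0))
  combPath <- file.path(outDir, "combined_summary.csv")
  num <- vapply(combined, is.numeric, TRUE) & !vapply(combined, is.integer, TRUE)
  combOut <- combined
  for (jc in which(num)) combOut[[jc]] <- formatC(combOut[[jc]], digits = 8, format = "g")
  utils::write.csv(combOut, combPath, row.names = FALSE, quote = FALSE)
  utils::write.csv(status, file.path(outDir, "job_status.csv"),
                   row.names = FALSE, quote = FALSE)
  exitCode <- if (all(status$ok)) 0L else if (any(status$ok)) 1L else 2L
  invisible(list(status = status, summary = combined, exitCode = exitCode))
}
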