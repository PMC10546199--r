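## Manifest-driven pipeline binding the modules into reproducible runs:
## simulate a synthetic dataset to disk, process a dataset end-to-end
## (set validation -> demodulation -> calibration -> optical property
## inversion -> chromophores -> speckle contrast -> power law -> Db), and
## summarise processed outputs. Stages remain individually callable.

#' Default run configuration
#'
#' Physics defaults: 10 ms exposure, 633 nm LSI wavelength, 660/780/850 nm
#' SFDI wavelengths, spatial frequencies 0 and 0.3 mm^-1, 50 Hz raw rate,
#' n = 1.4; 15 px Gaussian window, 5 px contrast window, 50-frame moving
#' average. Lookup-table axes: 512 nodes for the reflectance table (mua in
#' [0.0001, 0.2], musp in [0.001, 3] mm^-1); 256 x 128 x 128 for the K^2
#' table (Db up to 2e-5 mm^2/s, mua to 0.3 mm^-1).
#'
#' @return nested configuration list.
#' @export
defaultRunConfig <- function() {
  list(
    paths = list(input = NULL, calibration = NULL, output = NULL),
    physics = list(n = 1.4, lambda_lsi = 633, exposure = 0.010,
                   wavelengths = c(660, 780, 850), fx = c(0, 0.3),
                   raw_rate = 50),
    lut = list(rd_nodes = 512L, k2_db_nodes = 256L, k2_mua_nodes = 128L,
               k2_musp_nodes = 128L, db_max = 20e-6),
    filters = list(gaussian_window = 15L, contrast_window = 5L,
                   moving_average = 50L),
    roi = list(radius_px = NULL),
    simulate = list(scene = "phantom1", dims = c(64L, 64L), cycles = 3L,
                    db = 1e-6, noise_sd = 0, mean_counts = 30,
                    speckle_px = 4, n_sub = 32L, drop = NULL),
    seed = 1L
  )
}

.mergeConfig <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]]))
      base[[k]] <- .mergeConfig(base[[k]], override[[k]])
    else base[[k]] <- override[[k]]
  }
  base
}

#' Read a run configuration from YAML
#'
#' Unknown keys raise a schema error naming the key; missing keys fall back
#' to \code{\link{defaultRunConfig}}.
#'
#' @param path YAML file path (or a list already in config shape).
#' @return validated configuration list.
#' @export
readRunConfig <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  base <- defaultRunConfig()
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  for (k in names(cfg)) {
    if (is.list(base[[k]])) {
      bad <- setdiff(names(cfg[[k]]), names(base[[k]]))
      if (length(bad))
        stop("unknown configuration key(s): ",
             paste(paste0(k, "$", bad), collapse = ", "))
    }
  }
  cfg <- .mergeConfig(base, cfg)
  with(cfg$physics, stopifnot(n > 0, lambda_lsi > 0, exposure > 0,
                              raw_rate > 0, all(wavelengths > 0)))
  cfg
}

## Short content hash (FNV-1a over the serialized object) tagging outputs
## with the configuration they came from.
.configHash <- function(cfg) {
  b <- as.integer(serialize(cfg, NULL, version = 2))
  h <- 0
  for (x in b) h <- (h * 31 + x) %% 2147483647
  sprintf("%08x", as.integer(h))
}

.sceneFromConfig <- function(cfg) {
  s <- cfg$simulate
  dims <- as.integer(s$dims)
  if (s$scene %in% names(phantomLibrary(dims = c(2L, 2L))))
    phantomLibrary(dims = dims, db = s$db)[[s$scene]]
  else if (s$scene == "calibration")
    uniformScene(dims, calibrationPhantom(), db = s$db, name = "calibration")
  else if (s$scene == "flow-tube")
    flowTubeScene(dims, dbTube = s$db)
  else stop("unknown scene: ", s$scene)
}

## Optical properties of a scene transferred to the LSI wavelength by the
## same chromophore projection + scattering power law the processing side
## applies, so generator and inversion share one 633 nm ground truth.
.sceneAtLsiWavelength <- function(scene, lambdaLsi = 633) {
  E <- extinctionMatrix(scene@wavelengths)
  chrom <- fitChromophores(scene@mua, E)
  muaLsi <- muaAtWavelength(chrom, lambdaLsi)
  pl <- .fitMusPowerlawMap(scene@musp, scene@wavelengths)
  muspLsi <- pl$amp * (lambdaLsi / 850)^pl$slope
  list(mua = muaLsi, musp = muspLsi)
}

#' Simulate a paired LSI/SFDI dataset to disk
#'
#' Renders, for each acquisition cycle, the 18 patterned SFDI frames
#' (16-bit TIFF) and 18 speckle LSI frames (8-bit TIFF) of the configured
#' scene, plus a calibration set (SFDI frames of the calibration phantom
#' and a static speckle stack for beta), manifests, and a ground-truth
#' sidecar. Dropped frames can be injected via
#' \code{simulate$drop = list(list(modality=, cycle=, index=), ...)}; the
#' affected frame is neither written nor listed in the manifest. The run
#' is fully determined by \code{seed}.
#'
#' @param config configuration list or YAML path (see
#'   \code{\link{readRunConfig}}); \code{paths$output} is required.
#' @return invisibly, a list with the dataset directory layout.
#' @export
cmdSimulate <- function(config) {
  cfg <- readRunConfig(config)
  out <- cfg$paths$output
  if (is.null(out)) stop("configuration key paths$output is required")
  sdirs <- list(frames = file.path(out, "frames"),
                calib = file.path(out, "calibration"))
  for (d in sdirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  schedule <- makeSchedule(cfg$physics$raw_rate,
                           wavelengths = cfg$physics$wavelengths,
                           fxs = cfg$physics$fx)
  scene <- .sceneFromConfig(cfg)
  lsiProps <- .sceneAtLsiWavelength(scene, cfg$physics$lambda_lsi)
  s <- cfg$simulate
  drop <- s$drop
  dropped <- function(mod, cy, idx) {
    if (is.null(drop)) return(FALSE)
    any(vapply(drop, function(dd)
      dd$modality == mod && dd$cycle == cy && dd$index == idx, logical(1)))
  }
  period <- 1 / cfg$physics$raw_rate
  manifest <- list()
  for (cy in seq_len(s$cycles) - 1L) {
    sf <- renderSfdiFrames(scene, schedule, noiseSd = s$noise_sd,
                           seed = cfg$seed + 101L * cy, n = cfg$physics$n)
    lf <- simulateSceneSpeckle(scene, lsiProps$mua, lsiProps$musp,
                               frames = 18L, exposure = cfg$physics$exposure,
                               nSub = s$n_sub, specklePx = s$speckle_px,
                               meanCounts = s$mean_counts,
                               seed = cfg$seed + 1000L + 17L * cy)
    for (i in 0:17) {
      ts <- (cy * 18L + i) * period
      if (!dropped("sfdi", cy, i)) {
        p <- file.path(sdirs$frames, frameFileName("sfdi", cy, i))
        writeFrameTiff(sf[[i + 1L]], p, 16L)
        manifest[[length(manifest) + 1L]] <- data.frame(
          path = p, modality = "sfdi", cycle = cy, index = i, timestamp_s = ts)
      }
      if (!dropped("lsi", cy, i)) {
        p <- file.path(sdirs$frames, frameFileName("lsi", cy, i))
        writeFrameTiff(lf[, , i + 1L], p, 8L)
        manifest[[length(manifest) + 1L]] <- data.frame(
          path = p, modality = "lsi", cycle = cy, index = i, timestamp_s = ts)
      }
    }
  }
  manifest <- do.call(rbind, manifest)
  writeManifest(manifest, file.path(out, "manifest.csv"))
  ## calibration set: phantom SFDI cycle + static speckle stack for beta
  calScene <- uniformScene(scene@dims, calibrationPhantom(), db = 0,
                           name = "calibration")
  calSf <- renderSfdiFrames(calScene, schedule, noiseSd = 0,
                            seed = cfg$seed + 7L, n = cfg$physics$n)
  calLf <- simulateSpeckleStack(scene@dims, frames = 18L,
                                exposure = cfg$physics$exposure, tauC = Inf,
                                specklePx = s$speckle_px,
                                meanCounts = s$mean_counts,
                                seed = cfg$seed + 9L)
  calman <- list()
  for (i in 0:17) {
    p <- file.path(sdirs$calib, frameFileName("sfdi", 0L, i))
    writeFrameTiff(calSf[[i + 1L]], p, 16L)
    calman[[length(calman) + 1L]] <- data.frame(
      path = p, modality = "sfdi", cycle = 0L, index = i,
      timestamp_s = i * period)
    p <- file.path(sdirs$calib, frameFileName("lsi", 0L, i))
    writeFrameTiff(calLf[, , i + 1L], p, 8L)
    calman[[length(calman) + 1L]] <- data.frame(
      path = p, modality = "lsi", cycle = 0L, index = i,
      timestamp_s = i * period)
  }
  writeManifest(do.call(rbind, calman), file.path(out, "calibration.csv"))
  truth <- list(
    scene = scene@name, dims = as.integer(scene@dims),
    wavelengths = scene@wavelengths,
    mua = lapply(scene@mua, function(m) as.numeric(sort(unique(as.vector(m))))),
    musp = lapply(scene@musp, function(m) as.numeric(sort(unique(as.vector(m))))),
    db = as.numeric(sort(unique(as.vector(scene@db)))),
    mua_lsi = as.numeric(sort(unique(round(as.vector(lsiProps$mua), 12)))),
    musp_lsi = as.numeric(sort(unique(round(as.vector(lsiProps$musp), 12)))),
    seed = cfg$seed, config_hash = .configHash(cfg))
  yaml::write_yaml(truth, file.path(out, "ground_truth.yaml"))
  yaml::write_yaml(cfg, file.path(out, "config_echo.yaml"))
  invisible(list(output = out, manifest = file.path(out, "manifest.csv"),
                 calibration = file.path(out, "calibration.csv"),
                 truth = file.path(out, "ground_truth.yaml")))
}

## Demodulate + smooth the 6 (wavelength, fx) amplitude maps of one SFDI
## cycle from manifest rows.
.demodCycle <- function(rows, schedule, gaussWindow) {
  e <- schedule@entries
  out <- list()
  for (wl in unique(e$wavelength)) for (fx in unique(e$fx)) {
    sl <- e[e$wavelength == wl & e$fx == fx, ]
    sl <- sl[order(sl$phase), ]
    fr <- lapply(sl$index, function(i)
      readFrameTiff(rows$path[rows$index == i]))
    tr <- phaseTriplet(fr[[1]], fr[[2]], fr[[3]], fx = fx, wavelength = wl)
    m <- demodulate(tr)
    if (gaussWindow > 1L) m <- gaussianSmooth(m, window = gaussWindow)
    out[[paste(wl, fx)]] <- m
  }
  out
}

#' Process a paired LSI/SFDI dataset end-to-end
#'
#' Runs the full chain on a simulated (or equivalently organised) dataset:
#' set validation with the 18-frame rejection rule, three-phase
#' demodulation and Gaussian smoothing, phantom calibration, lookup-table
#' inversion of (mua, musp) at each wavelength, chromophore fitting,
#' scattering power-law transfer to the LSI wavelength, speckle contrast,
#' beta estimation from the calibration stack, beta-corrected SFI, and Db
#' inversion via the K^2 lookup table. Writes per-cycle maps (32-bit float
#' TIFF + JSON sidecars), ROI time courses (CSV) and a JSON report.
#'
#' @param config configuration list or YAML path; \code{paths$input} (the
#'   dataset directory holding \code{manifest.csv} and
#'   \code{calibration.csv}) and \code{paths$output} are required.
#' @return invisibly, the report list.
#' @export
cmdProcess <- function(config) {
  cfg <- readRunConfig(config)
  inp <- cfg$paths$input
  out <- cfg$paths$output
  if (is.null(inp) || is.null(out))
    stop("configuration keys paths$input and paths$output are required")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- readManifest(file.path(inp, "manifest.csv"))
  calman <- readManifest(file.path(inp, "calibration.csv"))
  vs <- validateSets(manifest)
  if (!length(vs$acceptedCycles))
    stop("no complete 18-frame set in both modalities; ",
         "a dropped frame in either stream rejects the whole set")
  schedule <- makeSchedule(cfg$physics$raw_rate,
                           wavelengths = cfg$physics$wavelengths,
                           fxs = cfg$physics$fx)
  phantomOp <- calibrationPhantom()
  gw <- as.integer(cfg$filters$gaussian_window)
  cw <- as.integer(cfg$filters$contrast_window)
  Texp <- cfg$physics$exposure
  n <- cfg$physics$n
  lamLsi <- cfg$physics$lambda_lsi
  ## calibration: phantom amplitudes and beta from the static stack
  calRows <- calman[calman$modality == "sfdi", ]
  calMac <- .demodCycle(calRows, schedule, gw)
  calLsi <- calman[calman$modality == "lsi", ]
  calK <- cycleContrast(lapply(calLsi$path, readFrameTiff), window = cw,
                        exposure = Texp)
  beta <- estimateBeta(calK, source = "calibration static stack")
  rdLut <- buildRdLut(n = n, nMua = cfg$lut$rd_nodes,
                      nMusp = cfg$lut$rd_nodes, fxAc = max(cfg$physics$fx))
  k2Lut <- buildK2Lut(beta = beta, exposure = Texp, wavelength = lamLsi,
                      n = n, dbMax = cfg$lut$db_max,
                      nDb = cfg$lut$k2_db_nodes, nMua = cfg$lut$k2_mua_nodes,
                      nMusp = cfg$lut$k2_musp_nodes)
  wls <- cfg$physics$wavelengths
  E <- extinctionMatrix(wls)
  fxAc <- max(cfg$physics$fx)
  report <- list(config_hash = .configHash(cfg), beta = beta@beta,
                 accepted_cycles = vs$acceptedCycles,
                 rejected_cycles = vs$rejectedCycles,
                 rejection_report = vs$report,
                 invalid_pixel_fraction = list(), cycles = list())
  roiR <- cfg$roi$radius_px
  sfiSeries <- c(); sfiTimes <- c(); dbSeries <- c()
  for (cy in vs$acceptedCycles) {
    rows <- vs$accepted[vs$accepted$cycle == cy, ]
    mac <- .demodCycle(rows[rows$modality == "sfdi", ], schedule, gw)
    opmList <- list()
    for (wl in wls) {
      rd0 <- calibrate(mac[[paste(wl, 0)]], calMac[[paste(wl, 0)]],
                       phantomOp, n = n)
      rd3 <- calibrate(mac[[paste(wl, fxAc)]], calMac[[paste(wl, fxAc)]],
                       phantomOp, n = n)
      opmList[[as.character(wl)]] <- invertOpticalProperties(rd0, rd3, rdLut)
    }
    chrom <- fitChromophores(lapply(opmList, function(o) o@mua), E)
    muaLsi <- muaAtWavelength(chrom, lamLsi)
    pl <- .fitMusPowerlawMap(lapply(opmList, function(o) o@musp), wls)
    muspLsi <- pl$amp * (lamLsi / 850)^pl$slope
    lsiRows <- rows[rows$modality == "lsi", ]
    lsiFrames <- lapply(lsiRows$path, readFrameTiff)
    kmaps <- lapply(lsiFrames, function(f)
      speckleContrast(f, window = cw, exposure = Texp))
    ## temporally pooled cycle contrast for the Db map (matches the beta
    ## estimator, so window-sampling factors cancel)
    kCycle <- cycleContrast(lsiFrames, window = cw, exposure = Texp)
    dbm <- dbMap(kCycle, muaLsi, muspLsi, k2Lut)
    sfim <- betaCorrect(sfi(kCycle), beta)
    dims <- dim(muaLsi)
    roi <- if (is.null(roiR)) circularRoi(dims, radius = min(dims) * 0.3)
           else circularRoi(dims, radius = roiR)
    for (km in kmaps) {
      sfif <- betaCorrect(sfi(km), beta)
      sfiSeries <- c(sfiSeries, roiTimecourse(list(sfif), roi))
    }
    sfiTimes <- c(sfiTimes, lsiRows$timestamp_s[order(lsiRows$index)])
    dbSeries <- c(dbSeries, roiTimecourse(list(dbm), roi))
    cdir <- file.path(out, sprintf("cycle_%06d", cy))
    dir.create(cdir, showWarnings = FALSE)
    for (wl in wls) {
      o <- opmList[[as.character(wl)]]
      writeMapTiff(o@mua, file.path(cdir, sprintf("mua_%d.tiff", wl)),
                   units = "mm^-1", meta = list(wavelength = wl))
      writeMapTiff(o@musp, file.path(cdir, sprintf("musp_%d.tiff", wl)),
                   units = "mm^-1", meta = list(wavelength = wl))
    }
    writeMapTiff(chrom@hbt, file.path(cdir, "hbt.tiff"), units = "uM")
    writeMapTiff(chrom@sto2, file.path(cdir, "sto2.tiff"), units = "percent")
    writeMapTiff(muaLsi, file.path(cdir, "mua_lsi.tiff"), units = "mm^-1",
                 meta = list(wavelength = lamLsi))
    writeMapTiff(muspLsi, file.path(cdir, "musp_lsi.tiff"), units = "mm^-1",
                 meta = list(wavelength = lamLsi))
    writeMapTiff(kCycle@k, file.path(cdir, "contrast.tiff"), units = "")
    writeMapTiff(mapValues(sfim), file.path(cdir, "sfi.tiff"),
                 units = "s^-1")
    writeMapTiff(mapValues(dbm), file.path(cdir, "db.tiff"),
                 units = "mm^2/s")
    report$cycles[[as.character(cy)]] <- list(
      mua_lsi_median = stats::median(muaLsi, na.rm = TRUE),
      musp_lsi_median = stats::median(muspLsi, na.rm = TRUE),
      k_median = stats::median(kCycle@k, na.rm = TRUE),
      db_median = stats::median(mapValues(dbm)[!dbm@invalid]),
      invalid_fraction = list(
        optical = mean(vapply(opmList, function(o) mean(o@invalid),
                              numeric(1))),
        db = mean(dbm@invalid)))
  }
  ma <- min(as.integer(cfg$filters$moving_average), length(sfiSeries))
  sfiFilt <- .movingAverage(sfiSeries, ma)
  writeTimecourseCsv(sfiFilt, sfiTimes, file.path(out, "sfi_timecourse.csv"))
  writeTimecourseCsv(dbSeries,
                     (vs$acceptedCycles + 0.5) * 18 / cfg$physics$raw_rate,
                     file.path(out, "db_timecourse.csv"))
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}

#' Summarise processed outputs
#'
#' Reads a \code{\link{cmdProcess}} output directory and produces a
#' human-readable summary: acquisition rates, beta, per-cycle medians,
#' time courses normalized to their first value (so beta cancels), and an
#' optional percent-difference map between the normalized Db and SFI maps
#' of the first cycle. A PDF figure of the normalized time courses is
#' written alongside.
#'
#' @param outputDir directory written by \code{\link{cmdProcess}}.
#' @param rawRate raw acquisition rate used for the rate summary (Hz).
#' @return list with the summary tables.
#' @export
cmdReport <- function(outputDir, rawRate = 50) {
  repPath <- file.path(outputDir, "report.json")
  if (!file.exists(repPath)) stop("no report.json in ", outputDir)
  rep <- jsonlite::read_json(repPath, simplifyVector = TRUE)
  rates <- effectiveRates(rawRate)
  tc <- utils::read.csv(file.path(outputDir, "sfi_timecourse.csv"))
  dbtc <- utils::read.csv(file.path(outputDir, "db_timecourse.csv"))
  normTo1 <- function(v) v / v[1]
  sfiNorm <- normTo1(tc$value)
  dbNorm <- normTo1(dbtc$value)
  cyc <- names(rep$cycles)
  pdiff <- NULL
  if (length(cyc)) {
    cdir <- file.path(outputDir, sprintf("cycle_%06d", as.integer(cyc[1])))
    dbm <- readMapTiff(file.path(cdir, "db.tiff"))
    sfim <- readMapTiff(file.path(cdir, "sfi.tiff"))
    pdiff <- tryCatch(percentDifferenceMap(dbm, sfim), error = function(e) NULL)
  }
  fig <- file.path(outputDir, "timecourses.pdf")
  grDevices::pdf(fig, width = 6, height = 4)
  graphics::plot(tc$timestamp_s, sfiNorm, type = "l", xlab = "time (s)",
                 ylab = "normalized flow", main = "Normalized SFI / Db")
  graphics::points(dbtc$timestamp_s, dbNorm, col = 2, pch = 19)
  grDevices::dev.off()
  list(rates = rates, beta = rep$beta,
       accepted_cycles = rep$accepted_cycles,
       rejected_cycles = rep$rejected_cycles,
       cycles = rep$cycles,
       sfi_normalized = sfiNorm, db_normalized = dbNorm,
       percent_difference = pdiff,
       moving_average = length(tc$value), figure = fig)
}
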