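# Dataset assembly and disk round-trip.

#' Simulate a complete synthetic larva dataset
#'
#' Chains temperature generation, behavior sampling, kinematic synthesis
#' and (optionally) rendering. Fully deterministic for a given seed.
#'
#' @param config a [SimulationConfig-class]
#' @param duration simulated time (s)
#' @param waveform a [TemperatureWaveform-class]
#' @param body a [LarvaBodyModel-class]
#' @param seed integer seed
#' @param render render frames (set FALSE for event-level work)
#' @return a [LarvaDataset-class]
#' @export
simulateLarvaDataset <- function(config = simulationConfig(), duration = 60,
                                 waveform = temperatureWaveform(),
                                 body = larvaBodyModel(),
                                 seed = config@rngSeed, render = TRUE) {
  temperature <- generateTemperature(waveform, duration, config@frameRate)
  program <- sampleBehavior(config, temperature, seed = seed, body = body)
  truth <- synthesizeKinematics(program, body, config,
                                geometry = if (render) "full" else "theta")
  images <- array(0L, c(0, 0, 0))
  if (render) {
    rr <- renderFrames(truth, config, seed = seed)
    truth <- rr$truth
    images <- rr$images
  }
  ds <- new("LarvaDataset", truth = truth, images = images,
            temperature = temperature)
  attr(ds, "recipe") <- list(duration = duration, seed = as.integer(seed),
                             waveform = waveform, body = body)
  ds
}

configToList <- function(config) {
  sn <- slotNames(class(config))
  stats::setNames(lapply(sn, function(s) methods::slot(config, s)), sn)
}

configFromList <- function(lst) {
  lst$rngSeed <- as.integer(lst$rngSeed)
  do.call(new, c(list("SimulationConfig"), lst))
}

## render one frame with its deterministic per-frame noise stream
renderFrameNoisy <- function(truth, f, config, seed = config@rngSeed) {
  img <- renderFrame(truth, f, config)
  sdN <- config@noiseSd * config@calibration
  if (sdN > 0) {
    set.seed(as.integer(seed) + 7L + f)
    img <- img + matrix(rnorm(length(img), 0, sdN), nrow(img), ncol(img))
  }
  matrix(as.integer(round(clamp(img, 0, 65535))), nrow(img), ncol(img))
}

#' Export a dataset to a directory
#'
#' Writes the image stack (multi-page 16-bit TIFF), ground-truth
#' annotation and per-segment tables (CSV), per-frame scalars (CSV),
#' temperature trace (CSV) and the full generation recipe (JSON).
#'
#' @param dataset a [LarvaDataset-class] from [simulateLarvaDataset()]
#' @param dir output directory (created if missing)
#' @return invisibly, the vector of files written
#' @export
exportDataset <- function(dataset, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok || file.access(dir, 2) != 0)
    stopc("larvagram_io", sprintf("cannot write to '%s'", dir))
  truth <- dataset@truth
  nf <- nrow(truth@frames)
  files <- character(0)
  if (length(dataset@images)) {
    pages <- lapply(seq_len(nf), function(f) dataset@images[, , f] / 65535)
    tiff::writeTIFF(pages, file.path(dir, "frames.tif"), bits.per.sample = 16L,
                    compression = "none")
    files <- c(files, "frames.tif")
  }
  ann <- do.call(rbind, lapply(seq_len(nf), function(f)
    truthAnnotation(truth, f, coords = "px")))
  names(ann) <- c("frame", "point_id", "x_px", "y_px")
  utils::write.csv(ann, file.path(dir, "annotation.csv"), row.names = FALSE)

  seg <- do.call(rbind, lapply(seq_len(nf), function(f) {
    d <- data.frame(frame = f, segment = SEGMENT_NAMES,
                    len_left_mm = truth@segLenLeft[, f],
                    len_right_mm = truth@segLenRight[, f],
                    area_mm2 = truth@segArea[, f])
    if (dim(truth@quadArea)[1] == 11) {
      q <- truth@quadIntensity[, , f]
      d$int_AL <- q[, "AL"]; d$int_AR <- q[, "AR"]
      d$int_PL <- q[, "PL"]; d$int_PR <- q[, "PR"]
    }
    d
  }))
  utils::write.csv(seg, file.path(dir, "segments.csv"), row.names = FALSE)
  utils::write.csv(truth@frames, file.path(dir, "frames.csv"), row.names = FALSE)
  utils::write.csv(dataset@temperature, file.path(dir, "temperature.csv"),
                   row.names = FALSE)
  recipe <- attr(dataset, "recipe")
  cfg <- list(
    config = configToList(truth@config),
    body = list(bodyLength = sum(truth@body@restLengths),
                maxWidth = max(truth@body@restWidths)),
    waveform = if (!is.null(recipe)) list(
      offset = recipe$waveform@offset, amplitude = recipe$waveform@amplitude,
      period = recipe$waveform@period, phase = recipe$waveform@phase) else NULL,
    duration = if (!is.null(recipe)) recipe$duration else max(truth@frames$time_s),
    seed = if (!is.null(recipe)) recipe$seed else truth@config@rngSeed
  )
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  files <- c(files, "annotation.csv", "segments.csv", "frames.csv",
             "temperature.csv", "config.json")
  invisible(file.path(dir, files))
}

#' Read an exported dataset directory
#'
#' @param dir directory written by [exportDataset()]
#' @return list with `images` (integer array or NULL), `annotation`,
#'   `segments`, `frames`, `temperature` (data.frames), `config`
#'   (a [SimulationConfig-class]) and `recipe` (duration, seed, waveform,
#'   body parameters)
#' @export
readLarvaDataset <- function(dir) {
  cfgPath <- file.path(dir, "config.json")
  if (!file.exists(cfgPath))
    stopc("larvagram_io", sprintf("no config.json in '%s'", dir))
  cfg <- jsonlite::read_json(cfgPath, simplifyVector = TRUE)
  images <- NULL
  tifPath <- file.path(dir, "frames.tif")
  if (file.exists(tifPath)) {
    pages <- tryCatch(tiff::readTIFF(tifPath, all = TRUE),
                      error = function(e)
                        stopc("larvagram_io",
                              sprintf("cannot decode '%s': %s", tifPath,
                                      conditionMessage(e))))
    images <- array(0L, c(dim(pages[[1]]), length(pages)))
    for (f in seq_along(pages))
      images[, , f] <- as.integer(round(pages[[f]] * 65535))
  }
  readCsv <- function(nm) utils::read.csv(file.path(dir, nm))
  list(images = images,
       annotation = readCsv("annotation.csv"),
       segments = readCsv("segments.csv"),
       frames = readCsv("frames.csv"),
       temperature = readCsv("temperature.csv"),
       config = configFromList(cfg$config),
       recipe = cfg[c("body", "waveform", "duration", "seed")])
}
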