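# Pipeline driver: simulate -> track -> kymo -> events -> stats, staged
# through files in an artifact directory with a reproducibility manifest.

#' Pipeline configuration
#'
#' A validated nested list of stage settings. Unknown keys are rejected.
#'
#' @param duration simulated video duration (s)
#' @param strain config preset (see [simulationConfig()])
#' @param simulation named overrides for [simulationConfig()]
#' @param waveform named overrides for [temperatureWaveform()]
#' @param vision named overrides for [visionConfig()]
#' @param events named overrides for [eventConfig()]
#' @param intensity measure quadrant intensities during tracking
#' @return list of class `larvagram_pipeline_config`
#' @export
pipelineConfig <- function(duration = 40, strain = "mhc_gfp",
                           simulation = list(), waveform = list(),
                           vision = list(), events = list(),
                           intensity = TRUE) {
  cfg <- list(duration = duration, strain = strain, simulation = simulation,
              waveform = waveform, vision = vision, events = events,
              intensity = intensity)
  validatePipelineConfig(cfg)
  class(cfg) <- "larvagram_pipeline_config"
  cfg
}

validatePipelineConfig <- function(cfg) {
  known <- c("duration", "strain", "simulation", "waveform", "vision",
             "events", "intensity")
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    stopc("larvagram_invalid_argument",
          paste("unknown pipeline config keys:", paste(bad, collapse = ", ")))
  if (!is.numeric(cfg$duration) || cfg$duration <= 0)
    stopc("larvagram_invalid_argument", "duration must be positive")
  ## constructing the stage configs validates their fields
  do.call(simulationConfig, c(list(strain = cfg$strain), cfg$simulation))
  do.call(temperatureWaveform, cfg$waveform)
  do.call(visionConfig, cfg$vision)
  do.call(eventConfig, cfg$events)
  invisible(TRUE)
}

#' Read a pipeline configuration from JSON or YAML
#'
#' @param path file ending in .json, .yaml or .yml
#' @return validated pipeline config
#' @export
readPipelineConfig <- function(path) {
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  do.call(pipelineConfig, raw)
}

pcfgSimulation <- function(cfg, seed) {
  sim <- do.call(simulationConfig, c(list(strain = cfg$strain), cfg$simulation))
  sim@rngSeed <- as.integer(seed)
  sim
}

#' @rdname runPipeline
#' @export
pipelineSimulate <- function(cfg, dir, seed) {
  sim <- pcfgSimulation(cfg, seed)
  wf <- do.call(temperatureWaveform, cfg$waveform)
  ds <- simulateLarvaDataset(sim, duration = cfg$duration, waveform = wf,
                             seed = seed)
  exportDataset(ds, dir)
}

#' @rdname runPipeline
#' @export
pipelineTrack <- function(cfg, dir) {
  vis <- do.call(visionConfig, cfg$vision)
  d <- readLarvaDataset(dir)
  if (is.null(d$images))
    stopc("larvagram_io", "no frames.tif in the artifact directory")
  nf <- dim(d$images)[3]
  H <- dim(d$images)[1]
  s <- d$config@pixelScale
  ann <- d$annotation
  fr <- d$frames
  track <- data.frame(frame = seq_len(nf), time_s = fr$time_s[seq_len(nf)],
                      head_x = NA_real_, head_y = NA_real_, tail_x = NA_real_,
                      tail_y = NA_real_, theta_deg = NA_real_, ok = FALSE,
                      x_mm = NA_real_, y_mm = NA_real_,
                      head_x_mm = NA_real_, head_y_mm = NA_real_,
                      tail_x_mm = NA_real_, tail_y_mm = NA_real_)
  metrics <- list()
  a1 <- ann[ann$frame == 1, ]
  prior <- list(head = c(a1$x_px[a1$point_id == 0], H + 1 - a1$y_px[a1$point_id == 0]),
                tail = c(a1$x_px[a1$point_id == 11], H + 1 - a1$y_px[a1$point_id == 11]))
  for (f in seq_len(nf)) {
    res <- tryCatch({
      mask <- segmentBody(d$images[, , f], vis)
      ol <- extractOutline(mask, vis, frameId = f)
      curv <- outlineCurvature(ol, vis@curvatureWindowFrac)
      ol <- locateHeadTail(ol, curv, prior)
      cl <- computeCenterline(ol, vis)
      af <- ann[ann$frame == f, ]
      pts <- data.frame(point_id = af$point_id, x = af$x_px, y = H + 1 - af$y_px)
      sa <- resolveAnnotation(pts, ol)
      bl <- boundaryLengths(sa)
      qv <- if (isTRUE(cfg$intensity))
        quadrantIntensities(sa, d$images[, , f])$quad else NULL
      list(ol = ol, theta = bendAngle(cl), bl = bl, qv = qv)
    }, larvagram_error = function(e) e)
    if (inherits(res, "error")) next
    ol <- res$ol
    hx <- ol@vertices[ol@headIndex, 1]; hy <- ol@vertices[ol@headIndex, 2]
    tx <- ol@vertices[ol@tailIndex, 1]; ty <- ol@vertices[ol@tailIndex, 2]
    track[f, c("head_x", "head_y", "tail_x", "tail_y")] <- c(hx, hy, tx, ty)
    track$theta_deg[f] <- res$theta
    track$ok[f] <- TRUE
    ox <- fr$origin_x_mm[f]; oy <- fr$origin_y_mm[f]
    hw <- pxToWorld(hx, hy, ox, oy, s, H); tw <- pxToWorld(tx, ty, ox, oy, s, H)
    cen <- colMeans(ol@vertices); cw <- pxToWorld(cen[1], cen[2], ox, oy, s, H)
    track[f, c("head_x_mm", "head_y_mm")] <- hw
    track[f, c("tail_x_mm", "tail_y_mm")] <- tw
    track[f, c("x_mm", "y_mm")] <- cw
    met <- data.frame(frame = f, segment = SEGMENT_NAMES,
                      len_left_mm = res$bl[, "left"] * s,
                      len_right_mm = res$bl[, "right"] * s)
    if (!is.null(res$qv)) {
      met$int_AL <- res$qv[, "AL"]; met$int_AR <- res$qv[, "AR"]
      met$int_PL <- res$qv[, "PL"]; met$int_PR <- res$qv[, "PR"]
    }
    metrics[[length(metrics) + 1]] <- met
    prior <- list(head = c(hx, hy), tail = c(tx, ty))
  }
  utils::write.csv(track, file.path(dir, "track.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, metrics), file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  invisible(file.path(dir, c("track.csv", "metrics.csv")))
}

readMetricsMatrix <- function(met, col, nf) {
  m <- matrix(NA_real_, 11, nf, dimnames = list(SEGMENT_NAMES, NULL))
  m[cbind(match(met$segment, SEGMENT_NAMES), met$frame)] <- met[[col]]
  m
}

#' @rdname runPipeline
#' @export
pipelineKymo <- function(cfg, dir) {
  evc <- do.call(eventConfig, cfg$events)
  met <- utils::read.csv(file.path(dir, "metrics.csv"))
  d <- readLarvaDataset(dir)
  fr <- d$config@frameRate
  nf <- max(met$frame)
  segLen <- readMetricsMatrix(met, "len_left_mm", nf) +
    readMetricsMatrix(met, "len_right_mm", nf)
  ky0 <- buildKymograph(fractionalChange(segLen, 1), "fractional_length", 1, fr)
  ref <- chooseReferenceFrame(segLen, detectWaves(ky0, evc)$waves)
  kyLen <- fractionalChange(segLen, ref)
  asym <- asymmetryIndex(readMetricsMatrix(met, "len_left_mm", nf),
                         readMetricsMatrix(met, "len_right_mm", nf))
  writeK <- function(m, nm) {
    df <- data.frame(body_coord = rownames(m), m, check.names = FALSE)
    names(df) <- c("body_coord", paste0("f", seq_len(ncol(m))))
    utils::write.csv(df, file.path(dir, nm), row.names = FALSE)
  }
  writeK(kyLen, "kymo_length.csv")
  writeK(asym, "kymo_asym.csv")
  files <- c("kymo_length.csv", "kymo_asym.csv")
  if ("int_AL" %in% names(met)) {
    segInt <- (readMetricsMatrix(met, "int_AL", nf) +
                 readMetricsMatrix(met, "int_AR", nf) +
                 readMetricsMatrix(met, "int_PL", nf) +
                 readMetricsMatrix(met, "int_PR", nf)) / 4
    writeK(fractionalChange(segInt, ref), "kymo_intensity.csv")
    files <- c(files, "kymo_intensity.csv")
  }
  jsonlite::write_json(list(reference_frame = ref),
                       file.path(dir, "reference.json"), auto_unbox = TRUE)
  invisible(file.path(dir, c(files, "reference.json")))
}

readKymoCsv <- function(path, metric, ref, fr) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$body_coord
  buildKymograph(m, metric, ref, fr)
}

#' @rdname runPipeline
#' @export
pipelineEvents <- function(cfg, dir) {
  vis <- do.call(visionConfig, cfg$vision)
  evc <- do.call(eventConfig, cfg$events)
  d <- readLarvaDataset(dir)
  fr <- d$config@frameRate
  ref <- jsonlite::read_json(file.path(dir, "reference.json"))$reference_frame
  kyLen <- readKymoCsv(file.path(dir, "kymo_length.csv"), "fractional_length", ref, fr)
  kyAsym <- readKymoCsv(file.path(dir, "kymo_asym.csv"), "asymmetry", NA, fr)
  track <- utils::read.csv(file.path(dir, "track.csv"))
  det <- detectWaves(kyLen, evc)
  sweeps <- detectHeadSweeps(track$theta_deg, vis)
  phases <- classifyPhases(d$temperature)
  man <- assembleManeuvers(sweeps, det$waves, track$theta_deg, frameRate = fr,
                           config = evc, asymKymo = kyAsym, phases = phases)
  utils::write.csv(det$waves, file.path(dir, "waves.csv"), row.names = FALSE)
  utils::write.csv(sweeps, file.path(dir, "sweeps.csv"), row.names = FALSE)
  utils::write.csv(man, file.path(dir, "maneuvers.csv"), row.names = FALSE)
  invisible(file.path(dir, c("waves.csv", "sweeps.csv", "maneuvers.csv")))
}

#' @rdname runPipeline
#' @export
pipelineStats <- function(cfg, dir) {
  d <- readLarvaDataset(dir)
  track <- utils::read.csv(file.path(dir, "track.csv"))
  waves <- utils::read.csv(file.path(dir, "waves.csv"))
  man <- utils::read.csv(file.path(dir, "maneuvers.csv"))
  fr <- d$config@frameRate
  phases <- classifyPhases(d$temperature)
  manS <- man
  if (nrow(manS)) manS$offset_s <- manS$offset_frame / fr
  fwd <- tryCatch(forwardSpeed(track, manS), larvagram_error = function(e) NULL)
  bl <- sum(d$recipe$body$bodyLength)
  dispTr <- data.frame(head_x = track$head_x_mm, head_y = track$head_y_mm,
                       tail_x = track$tail_x_mm, tail_y = track$tail_y_mm)
  runWaves <- waves[waves$init_segment %in% c("A7", "A8") & waves$n_segments >= 9, ,
                    drop = FALSE]
  disp <- vapply(seq_len(nrow(runWaves)), function(k)
    tryCatch(waveDisplacement(dispTr, runWaves[k, ], bl),
             larvagram_error = function(e) NA_real_), numeric(1))
  tf <- if (nrow(man)) turnFrequency(man, phases) else NULL
  fss <- if (nrow(man)) firstSweepSize(man, phases) else NULL
  summary <- list(
    n_frames = nrow(track), n_waves = nrow(waves), n_maneuvers = nrow(man),
    forward_speed_mm_s = if (is.null(fwd)) NA else fwd$speed_mm_s,
    wave_displacement_bl = if (length(disp)) mean(disp, na.rm = TRUE) else NA,
    wave_speed_seg_s = if (nrow(waves)) mean(waves$speed_seg_s) else NA,
    turn_frequency = tf, first_sweep_size = fss
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(file.path(dir, "summary.json"))
}

#' Run the full analysis pipeline
#'
#' Executes simulate, track, kymo, events and stats in order, writing every
#' stage product plus a manifest (file checksums, seed, config hash,
#' package version) into `dir`. Reruns with the same config and seed
#' reproduce identical outputs.
#'
#' @param cfg a [pipelineConfig()] (or path handled by
#'   [readPipelineConfig()])
#' @param dir artifact directory
#' @param seed integer seed for all stochastic stages
#' @return invisibly, the manifest list
#' @export
runPipeline <- function(cfg = pipelineConfig(), dir, seed = 1) {
  if (is.character(cfg)) cfg <- readPipelineConfig(cfg)
  validatePipelineConfig(unclass(cfg))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok) stopc("larvagram_io", sprintf("cannot create '%s'", dir))
  stages <- list(simulate = function() pipelineSimulate(cfg, dir, seed),
                 track = function() pipelineTrack(cfg, dir),
                 kymo = function() pipelineKymo(cfg, dir),
                 events = function() pipelineEvents(cfg, dir),
                 stats = function() pipelineStats(cfg, dir))
  outputs <- list()
  for (nm in names(stages)) {
    res <- tryCatch(stages[[nm]](), error = function(e) e)
    if (inherits(res, "error")) {
      message(sprintf("stage '%s' failed: %s", nm, conditionMessage(res)))
      stop(res)
    }
    outputs[[nm]] <- basename(as.character(res))
  }
  files <- sort(setdiff(list.files(dir), "manifest.json"))
  sums <- as.character(tools::md5sum(file.path(dir, files)))
  cfgJson <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package = "larvagram",
    version = tryCatch(as.character(utils::packageVersion("larvagram")),
                       error = function(e) "dev"),
    seed = as.integer(seed),
    config = unclass(cfg),
    config_md5 = as.character(tools::md5sum(textConnectionToFile(cfgJson))),
    stages = outputs,
    files = stats::setNames(as.list(sums), files)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

## md5 of an in-memory string via a temp file
textConnectionToFile <- function(txt) {
  f <- tempfile()
  writeLines(txt, f)
  f
}
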