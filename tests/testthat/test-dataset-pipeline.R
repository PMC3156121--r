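test_that("dataset export round-trips losslessly", {
  cfg <- simulationConfig(turnRateWarming = 0, turnRateCooling = 0)
  ds <- simulateLarvaDataset(cfg, duration = 4, seed = 3)
  dir <- file.path(tempdir(), "ds-roundtrip")
  exportDataset(ds, dir)
  back <- readLarvaDataset(dir)

  expect_equal(dim(back$images)[3], floor(4 * cfg@frameRate))
  expect_equal(back$images, ds@images)

  ## annotation table identical after the round trip
  ann <- do.call(rbind, lapply(seq_len(nFrames(ds@truth)), function(f)
    truthAnnotation(ds@truth, f, "px")))
  expect_equal(back$annotation$x_px, ann$x, tolerance = 1e-9)
  expect_equal(back$annotation$point_id, ann$point_id)
  expect_equal(back$temperature, ds@temperature, tolerance = 1e-9)

  ## the exported recipe re-runs to an identical dataset
  ds2 <- simulateLarvaDataset(back$config, duration = back$recipe$duration,
                              waveform = do.call(temperatureWaveform,
                                                 back$recipe$waveform),
                              seed = back$recipe$seed)
  expect_identical(ds2@images, ds@images)
  expect_equal(ds2@truth@frames, ds@truth@frames, tolerance = 1e-12)
})

test_that("pipeline configs are schema-validated", {
  expect_error(pipelineConfig(bogus = 1), "unused argument")
  expect_error(do.call(pipelineConfig, list(duration = -5)),
               class = "larvagram_invalid_argument")
  expect_error(pipelineConfig(simulation = list(nonsense = 1)),
               class = "larvagram_invalid_argument")
  cfgFile <- file.path(tempdir(), "cfg.yaml")
  writeLines(c("duration: 12", "simulation:", "  noiseSd: 0"), cfgFile)
  cfg <- readPipelineConfig(cfgFile)
  expect_equal(cfg$duration, 12)
  expect_equal(cfg$simulation$noiseSd, 0)
})

test_that("the full pipeline runs, is deterministic, and reports failures", {
  dir1 <- file.path(tempdir(), "pipe1")
  dir2 <- file.path(tempdir(), "pipe2")
  cfg <- pipelineConfig(duration = 12)
  m1 <- runPipeline(cfg, dir1, seed = 5)
  expect_setequal(names(m1$stages),
                  c("simulate", "track", "kymo", "events", "stats"))
  expect_true(file.exists(file.path(dir1, "manifest.json")))
  expect_true(file.exists(file.path(dir1, "summary.json")))

  m2 <- runPipeline(cfg, dir2, seed = 5)
  expect_identical(readLines(file.path(dir1, "summary.json")),
                   readLines(file.path(dir2, "summary.json")))
  expect_identical(m1$files, m2$files)

  ## corrupted TIFF input surfaces a decode error naming the file
  writeLines("not a tiff", file.path(dir1, "frames.tif"))
  err <- tryCatch(pipelineTrack(cfg, dir1), error = function(e) e)
  expect_s3_class(err, "larvagram_io")
  expect_match(conditionMessage(err), "frames.tif")
})
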