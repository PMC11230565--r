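# Deep-scanning orchestration over single files and batches.  The trained
# model comes from the cached in-memory training corpus in the helper.

test_that("a burst scene is flagged with the event near its true time", {
  model <- scannerModel()
  spec <- sceneSpec(duration = 120, sampleRate = 16000, snapRate = 5,
                    events = vesselEvent("burst_narrow", 57, duration = 6,
                                         level = 12), seed = 51)
  scn <- simulateScene(spec, sourceId = "burst120")
  res <- scanFile(scn$recording, model, cal0, config16())
  expect_true(res@vesselPresent)
  hits <- res@detections[res@detections$decision, ]
  expect_identical(nrow(hits), 1L)
  expect_true(hits$eventTime >= 55 && hits$eventTime <= 65)
  expect_identical(res@vesselPresent, any(res@detections$decision))
})

test_that("background-only and chorus-only scenes are not flagged", {
  model <- scannerModel()
  bg <- simulateScene(sceneSpec(duration = 120, sampleRate = 16000,
                                snapRate = 5, seed = 52), "bg")
  expect_false(scanFile(bg$recording, model, cal0, config16())@vesselPresent)

  ch <- simulateScene(sceneSpec(duration = 120, sampleRate = 16000,
                                snapRate = 5, chorusEnabled = TRUE,
                                chorusLevel = 8, seed = 53), "chorus")
  res <- scanFile(ch$recording, model, cal0, config16())
  expect_false(res@vesselPresent)
  # the chorus can gate stage-1 candidates; stage 2 must reject them
  if (nrow(res@detections) > 0) expect_true(all(!res@detections$decision))
})

test_that("file decisions equal an independent re-classification", {
  model <- scannerModel()
  spec <- sceneSpec(duration = 120, sampleRate = 16000, snapRate = 5,
                    events = rbind(vesselEvent("burst_wide", 30, 16, 12),
                                   vesselEvent("burst_narrow", 90, 6, 12)),
                    seed = 54)
  scn <- simulateScene(spec, sourceId = "two")
  cfg <- config16()
  res <- scanFile(scn$recording, model, cal0, cfg)
  # re-derive: clean, gate, re-extract at each recorded peak, re-predict
  cleaned <- removeSnaps(scn$recording, cfg$cleaning)
  redone <- vapply(seq_len(nrow(res@detections)), function(i) {
    s <- predictScore(model, extractFeature(cleaned,
                                            res@detections$eventTime[i],
                                            cfg$features))
    s >= cfg$threshold
  }, logical(1))
  # tiled wide segments may score higher than the peak window alone
  expect_true(all(res@detections$decision >= redone))
  expect_identical(res@vesselPresent, any(res@detections$decision))
})

test_that("batches isolate failures and are order-stable + deterministic", {
  model <- scannerModel()
  dir <- tempfile("batch")
  dir.create(dir)
  paths <- character(6)
  for (i in 1:6) {
    ev <- if (i %% 2 == 0) vesselEvent("burst_narrow", 20 + i, 6, 12)
          else emptyEvents()
    scn <- simulateScene(sceneSpec(duration = 60, sampleRate = 16000,
                                   snapRate = 3, events = ev,
                                   seed = 60 + i),
                         sourceId = sprintf("b%02d.wav", i))
    paths[i] <- file.path(dir, sprintf("b%02d.wav", i))
    writeWav(scn$recording, paths[i])
  }
  corrupt <- file.path(dir, "broken.wav")
  writeLines("junk", corrupt)

  res <- scanBatch(c(paths, corrupt), model, cal0, config16())
  expect_identical(nrow(res$files), 7L)
  expect_identical(res$files$source,
                   c(sprintf("b%02d.wav", 1:6), "broken.wav"))
  expect_identical(res$files$vesselPresent[1:6],
                   rep(c(FALSE, TRUE), 3))
  expect_true(is.na(res$files$vesselPresent[7]))
  expect_match(res$files$error[7], "RIFF")

  res2 <- scanBatch(c(paths, corrupt), model, cal0, config16())
  expect_identical(res, res2)
  expect_error(scanBatch(character(), model, cal0, config16()), "empty")
})

test_that("disabling cleaning only changes snap-free files trivially", {
  model <- scannerModel()
  snapFree <- simulateScene(sceneSpec(duration = 60, sampleRate = 16000,
                                      snapRate = 0, seed = 70), "nf")
  a <- scanFile(snapFree$recording, model, cal0, config16(clean = TRUE))
  b <- scanFile(snapFree$recording, model, cal0, config16(clean = FALSE))
  expect_identical(a@detections, b@detections)
  expect_identical(a@splMedian, b@splMedian)
})

test_that("YAML configs round-trip into ScanConfig", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("energy:", "  frameLength: 0.25", "  bandHigh: 8000",
               "features:", "  deltaT: 6.0", "  fftLength: 512",
               "  hop: 256",
               "scanner:", "  margin: 4.5", "  threshold: 0.6",
               "  clean: false"), f)
  cfg <- readScanConfig(f)
  expect_s4_class(cfg$energy, "SplParams")
  expect_equal(cfg$energy@frameLength, 0.25)
  expect_equal(cfg$features@deltaT, 6.0)
  expect_equal(cfg$margin, 4.5)
  expect_equal(cfg$threshold, 0.6)
  expect_false(cfg$clean)
})
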