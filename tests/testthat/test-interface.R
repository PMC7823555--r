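test_that("epoch containers validate their annotation", {
  tr <- generateTrial("A", 2, tinySynthConfig(seed = 19))
  expect_s4_class(tr, "EpochSet")
  expect_true(all(flashIndex(tr) %in% 1:12))
  expect_error(
    EpochSet(epochArray(tr), flashIndex = rep(13L, 24),
             repetitionIndex = repetitionIndex(tr)),
    "flashIndex")
  expect_error(
    EpochSet(epochArray(tr), flashIndex = flashIndex(tr),
             repetitionIndex = repetitionIndex(tr)[-1]),
    "one entry per epoch")
})

test_that("containers round-trip losslessly through save/load", {
  tr <- generateTrial("Q", 3, tinySynthConfig(seed = 20))
  f <- tempfile(fileext = ".rds")
  saveEpochs(tr, f)
  back <- loadEpochs(f)
  expect_identical(SummarizedExperiment::assay(back),
                   SummarizedExperiment::assay(tr))
  expect_identical(flashIndex(back), flashIndex(tr))
  expect_identical(repetitionIndex(back), repetitionIndex(tr))
  expect_identical(characterIndex(back), characterIndex(tr))
  expect_identical(epochLabels(back), epochLabels(tr))
  expect_identical(samplingRate(back), samplingRate(tr))
  expect_identical(targetChars(back), targetChars(tr))
  expect_identical(spellerLayout(back)@layout, spellerLayout(tr)@layout)
  expect_identical(S4Vectors::metadata(back)$preprocessing,
                   S4Vectors::metadata(tr)$preprocessing)
})

test_that("unlabeled containers load with labels marked absent", {
  tr <- generateTrial("Q", 2, tinySynthConfig(seed = 22))
  unl <- EpochSet(epochArray(tr), flashIndex = flashIndex(tr),
                  repetitionIndex = repetitionIndex(tr))
  f <- tempfile(fileext = ".rds")
  saveEpochs(unl, f)
  expect_true(all(is.na(epochLabels(loadEpochs(f)))))
})

test_that("malformed container files raise format errors, not crashes", {
  tr <- generateTrial("Z", 1, tinySynthConfig(seed = 23))
  f <- tempfile(fileext = ".rds")
  saveEpochs(tr, f)
  # truncate the file
  raw <- readBin(f, "raw", n = 120)
  ft <- tempfile(fileext = ".rds")
  writeBin(raw, ft)
  expect_error(loadEpochs(ft), "format error")
  # wrong payload type
  fw <- tempfile(fileext = ".rds")
  saveRDS(list(1, 2, 3), fw)
  expect_error(loadEpochs(fw), "format error")
  expect_error(loadEpochs(tempfile()), "not found")
})

test_that("the competition-layout loader cuts labeled flash-locked epochs", {
  targets <- c("A", "O", "9")
  ses <- syntheticSession(targets, nRepetitions = 2L, nChannels = 3L)
  es <- loadCompetitionSession(ses)
  expect_equal(ncol(es), 3L * 24L)
  expect_equal(length(unique(characterIndex(es))), 3L)
  expect_equal(targetChars(es), targets)
  # per character: each flash index twice, 4 positive epochs (2 per rep)
  for (ch in 1:3) {
    sel <- characterIndex(es) == ch
    expect_true(all(table(flashIndex(es)[sel]) == 2L))
    expect_equal(sum(epochLabels(es)[sel]), 4L)
    hits <- targetFlashIndices(spellerMatrix(), targets[ch])
    expect_setequal(unique(flashIndex(es)[sel][epochLabels(es)[sel] == 1L]),
                    hits)
  }
  # epochs are verbatim slices of the continuous signal
  on1 <- which(diff(c(0, ses$Flashing[1, ])) == 1)[1]
  expect_equal(epochSignals(es, 1),
               t(ses$Signal[1, on1:(on1 + 159L), ]))
  # round-trips through an .rds of the same layout
  f <- tempfile(fileext = ".rds")
  saveRDS(ses, f)
  es2 <- loadCompetitionSession(f)
  expect_identical(SummarizedExperiment::assay(es2),
                   SummarizedExperiment::assay(es))
  # error contracts
  expect_error(loadCompetitionSession(tempfile(fileext = ".mat")), "not found")
  expect_error(loadCompetitionSession(list(Signal = 1)), "format error")
  # sessions without StimulusType load with absent labels
  ses$StimulusType <- NULL
  expect_true(all(is.na(epochLabels(loadCompetitionSession(ses)))))
})

test_that("the CLI chains simulate, preprocess, train, evaluate, sweep-beta", {
  dir <- tempfile("cli"); dir.create(dir)
  raw <- file.path(dir, "raw.rds"); pp <- file.path(dir, "pp.rds")
  ppr <- file.path(dir, "ppr.rds")
  mod <- file.path(dir, "model.rds"); acc <- file.path(dir, "acc.json")
  swp <- file.path(dir, "sweep.csv")
  expect_equal(p300vibCLI(c("simulate", "--out", raw, "--characters", "2",
                            "--reps", "3", "--seed", "4",
                            "--channels", "8")), 0L)
  expect_equal(ncol(loadEpochs(raw)), 2L * 12L * 3L)
  expect_true(file.exists(paste0(raw, ".log.json")))
  log <- jsonlite::fromJSON(paste0(raw, ".log.json"))
  expect_equal(log$config$seed, 4L)
  expect_equal(p300vibCLI(c("preprocess", "--in", raw, "--out", ppr,
                            "--rebalance")), 0L)
  expect_equal(p300vibCLI(c("preprocess", "--in", raw, "--out", pp)), 0L)
  expect_equal(p300vibCLI(c("train", "--in", ppr, "--out", mod,
                            "--passes", "1", "--latent-dim", "4",
                            "--spatial-filters", "2",
                            "--temporal-filters", "4", "--seed", "2")), 0L)
  expect_s4_class(loadModel(mod), "VIBModel")
  expect_equal(p300vibCLI(c("evaluate", "--model", mod, "--in", pp,
                            "--out", acc, "--reps", "1,3")), 0L)
  tab <- jsonlite::fromJSON(acc)
  expect_equal(tab$repetitions, c(1L, 3L))
  expect_equal(p300vibCLI(c("sweep-beta", "--train", ppr, "--test", pp,
                            "--out", swp, "--betas", "0.01,1",
                            "--passes", "1", "--latent-dim", "4",
                            "--spatial-filters", "2",
                            "--temporal-filters", "4", "--reps", "3")), 0L)
  sw <- utils::read.csv(swp)
  expect_equal(nrow(sw), 2L)
  expect_true(all(c("beta", "accuracy", "klPerSample") %in% names(sw)))
})

test_that("the CLI rejects unknown input and reports usage errors", {
  expect_equal(p300vibCLI(character(0)), 1L)
  expect_equal(p300vibCLI("frobnicate"), 1L)
  expect_equal(suppressMessages(
    p300vibCLI(c("simulate", "--out", tempfile(), "--bogus", "1"))), 1L)
  expect_equal(suppressMessages(
    p300vibCLI(c("train", "--in", tempfile(), "--out", tempfile()))), 1L)
  expect_equal(suppressMessages(p300vibCLI(c("simulate"))), 1L)
})
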