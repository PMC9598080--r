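test_that("stage seeds are valid 32-bit integers and stage-distinct", {
  s <- vapply(c("phantom", "noise", "select"), function(st) {
    stageSeed(123, st)
  }, 0L)
  expect_true(all(s >= 0 & s < 2^31))
  expect_equal(anyDuplicated(s), 0L)
  expect_identical(stageSeed(1, "a"), stageSeed(1, "a"))
  expect_false(identical(stageSeed(1, "a"), stageSeed(2, "a")))
})

test_that("the multiresolution voxel reduction factor computes correctly", {
  expect_equal(voxelReductionFactor(c(0.6, 0.6, 1), c(6, 6, 6)), 600)
  expect_equal(voxelReductionFactor(1, 4), 4)
  expect_error(voxelReductionFactor(c(1, 1), c(2, -1)))
})

test_that("the reference pipeline run is byte-identical across repeats", {
  dirA <- withr::local_tempdir()
  dirB <- withr::local_tempdir()
  opts <- list(
    phantom = list(shape = c(32, 32)),
    noiseSigma = 0.02,
    separate = list(downsampleFactor = 2)
  )
  mA <- do.call(runReferencePipeline, c(list(outDir = dirA, seed = 9), opts))
  mB <- do.call(runReferencePipeline, c(list(outDir = dirB, seed = 9), opts))
  a <- readBin(file.path(dirA, "metrics.json"), "raw",
    file.size(file.path(dirA, "metrics.json")))
  b <- readBin(file.path(dirB, "metrics.json"), "raw",
    file.size(file.path(dirB, "metrics.json")))
  expect_identical(a, b)
  expect_identical(unname(unlist(mA$outputs)), unname(unlist(mB$outputs)))
  # a different seed changes the data
  mC <- do.call(runReferencePipeline,
    c(list(outDir = withr::local_tempdir(), seed = 10), opts))
  expect_false(identical(unname(unlist(mA$outputs)),
    unname(unlist(mC$outputs))))
  # manifest records the seeds it fanned out
  expect_equal(mA$seeds$base, 9)
  expect_true(file.exists(file.path(dirA, "manifest.json")))
})

test_that("the command-line front end chains simulate, separate and eval", {
  cli <- system.file("cli", "dixonsep.R", package = "DualDixon")
  expect_true(nzchar(cli))
  dir <- withr::local_tempdir()
  rscript <- file.path(R.home("bin"), "Rscript")
  out1 <- system2(rscript, c(cli, "simulate", "--out",
    file.path(dir, "sim"), "--n", "1", "--shape", "32", "--seed", "3"),
    stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(dir, "sim", "case001.rds")))
  out2 <- system2(rscript, c(cli, "separate", "--input",
    file.path(dir, "sim", "case001.rds"), "--output",
    file.path(dir, "res"), "--downsample", "2"),
    stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(dir, "res_water.nii")))
  out3 <- system2(rscript, c(cli, "eval", "--pred", file.path(dir, "res"),
    "--ref", file.path(dir, "sim", "case001"), "--out",
    file.path(dir, "m.json")), stdout = TRUE, stderr = TRUE)
  m <- jsonlite::read_json(file.path(dir, "m.json"))
  expect_gt(m$water$corr, 0.99)
  # usage errors exit with status 2
  bad <- suppressWarnings(system2(rscript, c(cli, "separate"),
    stdout = TRUE, stderr = TRUE))
  expect_equal(attr(bad, "status"), 2L)
})
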