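test_that("phantom generation is bit-reproducible from spec and seed", {
  a <- generatePhantom(seed = 42, nEllipses = 2, b0AmplitudeHz = 90)
  b <- generatePhantom(seed = 42, nEllipses = 2, b0AmplitudeHz = 90)
  expect_identical(water(a), water(b))
  expect_identical(fat(a), fat(b))
  expect_identical(b0Hz(a), b0Hz(b))
  expect_identical(a@phi0, b@phi0)
  expect_identical(tissueMask(a), tissueMask(b))
  d <- generatePhantom(seed = 43, nEllipses = 2, b0AmplitudeHz = 90)
  expect_false(identical(water(a), water(d)))
})

test_that("phantom structure honors its spec", {
  t0 <- generatePhantom(seed = 1, b0AmplitudeHz = 0, metal = NULL)
  expect_true(all(b0Hz(t0) == 0))
  # background is empty before noise
  bg <- tissueMask(t0) == 0
  expect_true(all(water(t0)[bg] == 0) && all(fat(t0)[bg] == 0))
  expect_error(generatePhantom(shape = c(8, 8)), "16")
  expect_error(generatePhantom(rimWidth = 0.9), "rimWidth")
})

test_that("the fat rim is fat-dominant relative to the interior", {
  # statistical check over seeds
  fracRim <- numeric(20)
  fracInt <- numeric(20)
  for (s in 1:20) {
    tr <- generatePhantom(seed = 100 + s, fatRim = TRUE)
    ff <- fat(tr) / pmax(water(tr) + fat(tr), 1e-12)
    fracRim[s] <- mean(ff[tissueMask(tr) == 2])
    fracInt[s] <- mean(ff[tissueMask(tr) == 1])
  }
  expect_true(all(fracRim > fracInt))
  expect_gt(mean(fracRim), 0.8)
})

test_that("metal perturbation follows the clipped dipole pattern", {
  expect_true(all(metalPerturbation(c(32, 32), c(16, 16), 0) == 0))
  m <- metalPerturbation(c(33, 33), c(17, 17), strengthHz = 100,
    coreRadius = 2)
  # on the vertical axis at distance 2 r: strength * (3 - 1) * r^3 / (2r)^3
  expect_equal(m[17 + 4, 17], 100 * 2 / 8, tolerance = 1e-12)
  # on the horizontal axis: cos(theta) = 0, value -strength * r^3 / d^3
  expect_equal(m[17, 17 + 4], -100 * 8 / 64, tolerance = 1e-12)
  # bounded by 2 * strength
  expect_lte(max(abs(m)), 200)
  expect_error(metalPerturbation(c(32, 32), c(16, 16), 10, coreRadius = 0),
    "coreRadius")
  expect_error(metalPerturbation(c(32, 32), c(40, 16), 10), "center")
})

test_that("default phantoms separate exactly; swap preset defeats the baseline", {
  p <- acquisitionParams()
  # the generator's default regime never produces inherently ambiguous cases
  for (s in c(21, 22)) {
    truth <- generatePhantom(seed = s)
    img <- simulatePhantom(truth, p)
    res <- separateDualEcho(img)
    expect_lt(max(abs(water(res) - water(truth))), 1e-6)
  }
  # the designated swap-inducing preset mislabels >= 10% under the
  # no-smoothness baseline
  for (s in c(11, 12)) {
    truth <- phantomPreset("swap", seed = s)
    img <- simulatePhantom(truth, p)
    expect_gte(swappedFraction(baselineSelect(img), truth), 0.10)
  }
})
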