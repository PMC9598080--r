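test_that("dephasing factor matches the complex exponential and its symmetries", {
  expect_equal(dephasingFactor(0, -447), 1 + 0i)
  # half a cycle of fat-water evolution gives the opposed-phase factor
  expect_equal(dephasingFactor(2, -250), -1 + 0i, tolerance = 1e-12)
  # 3T in-phase echo time with the single-peak 3.5 ppm offset is a whole
  # number of cycles to within the acquisition's rounding
  cang <- Arg(dephasingFactor(2.23, -447.1))
  expect_lt(min(abs(cang - c(-2 * pi, 0, 2 * pi))), 0.03)
  # 2 pi periodicity in df * TE and unit modulus
  for (te in c(0.7, 2.23, 5)) {
    expect_equal(Mod(dephasingFactor(te, -447.06)), 1)
    expect_equal(
      dephasingFactor(te, -447.06),
      dephasingFactor(te, -447.06 + 1000 / te), # +1 full cycle
      tolerance = 1e-9
    )
  }
  expect_error(dephasingFactor(NA, 1), "teMs")
  expect_error(dephasingFactor(1, Inf), "deltaFHz")
})

test_that("forward simulation reproduces the signal equations per pixel", {
  p <- classicParams()
  one <- matrix(1, 4, 4)
  zero <- matrix(0, 4, 4)
  # pure water is echo-invariant
  img <- forwardSimulate(one, zero, zero, zero, p)
  expect_equal(s1(img), matrix(1 + 0i, 4, 4), tolerance = 1e-12)
  expect_equal(s2(img), matrix(1 + 0i, 4, 4), tolerance = 1e-12)
  # pure fat flips sign at the opposed-phase echo
  img <- forwardSimulate(zero, one, zero, zero, p)
  expect_equal(s1(img), matrix(1 + 0i, 4, 4), tolerance = 1e-10)
  expect_equal(s2(img), matrix(-1 + 0i, 4, 4), tolerance = 1e-10)

  # hand-computed values at sampled pixels of a seeded random slice
  pp <- acquisitionParams()
  set.seed(31)
  w <- matrix(runif(25), 5, 5)
  f <- matrix(runif(25), 5, 5)
  b0 <- matrix(runif(25, -80, 80), 5, 5)
  phi <- matrix(runif(25, -1, 1), 5, 5)
  img <- forwardSimulate(w, f, b0, phi, pp)
  cc <- dephasingFactors(pp)
  for (idx in c(1, 7, 13, 19, 25)) {
    expect_equal(
      Mod(s1(img))[idx], Mod(w[idx] + cc[1] * f[idx]),
      tolerance = 1e-12
    )
    expect_equal(
      Arg(s2(img)[idx] * Conj(s1(img)[idx])),
      Arg((w[idx] + cc[2] * f[idx]) / (w[idx] + cc[1] * f[idx])) +
        2 * pi * b0[idx] * (pp@te2 - pp@te1) * 1e-3,
      tolerance = 1e-10
    )
  }
  expect_error(forwardSimulate(w, f[1:4, 1:4], b0, phi, pp), "fat")
  expect_error(forwardSimulate(-w, f, b0, phi, pp), "non-negative")
})

test_that("noise is seeded and reproducible", {
  w <- matrix(1, 8, 8)
  a <- forwardSimulate(w, w, noiseSigma = 0.1, seed = 5)
  b <- forwardSimulate(w, w, noiseSigma = 0.1, seed = 5)
  d <- forwardSimulate(w, w, noiseSigma = 0.1, seed = 6)
  expect_identical(s1(a), s1(b))
  expect_false(identical(s1(a), s1(d)))
})

test_that("amplitude candidates reduce to the classic Dixon half-sum rule", {
  cand <- amplitudeCandidates(matrix(3), matrix(1), 1 + 0i, -1 + 0i)
  expect_equal(cand@w1[1, 1], 2)
  expect_equal(cand@f1[1, 1], 1)
  expect_identical(cand@w2, cand@f1)
  expect_identical(cand@f2, cand@w1)
  # physical random magnitudes (|S2| <= |S1| at these echoes): candidates
  # are exactly (|S1| + |S2|) / 2 and (|S1| - |S2|) / 2
  set.seed(4)
  u <- matrix(runif(64, 0, 2), 8, 8)
  v <- matrix(runif(64, 0, 2), 8, 8)
  a <- u + v
  b <- abs(u - v)
  cand <- amplitudeCandidates(a, b, 1 + 0i, -1 + 0i)
  expect_equal(cand@w1, (a + b) / 2, tolerance = 1e-12)
  expect_equal(cand@f1, (a - b) / 2, tolerance = 1e-12)
})

test_that("background pixels are degenerate with zero amplitudes", {
  cand <- amplitudeCandidates(matrix(0, 2, 2), matrix(0, 2, 2), 1 + 0i, -1 + 0i)
  expect_true(all(cand@degenerate))
  expect_true(all(cand@w1 == 0) && all(cand@f1 == 0))
})

test_that("candidate amplitudes round-trip through the forward model", {
  # general unit dephasing factors with distinct real parts
  set.seed(11)
  for (rep in 1:20) {
    c1 <- exp(1i * runif(1, -pi, pi))
    c2 <- exp(1i * runif(1, -pi, pi))
    if (abs(Re(c1) - Re(c2)) < 0.1) next
    w <- runif(1, 0, 2)
    f <- runif(1, 0, 2)
    s1m <- Mod(w + c1 * f)
    s2m <- Mod(w + c2 * f)
    cand <- amplitudeCandidates(matrix(s1m), matrix(s2m), c1, c2)
    errA <- abs(cand@w1[1] - w) + abs(cand@f1[1] - f)
    errB <- abs(cand@w2[1] - w) + abs(cand@f2[1] - f)
    expect_lt(min(errA, errB), 1e-9)
  }
  expect_error(
    amplitudeCandidates(matrix(1), matrix(1), 1i, -1i),
    "ill-posed"
  )
})

test_that("candidate phasors recover the inter-echo B0 phasor exactly", {
  p <- acquisitionParams()
  truth <- generatePhantom(seed = 2)
  img <- simulatePhantom(truth, p)
  tl <- trueLabels(truth, img)
  sel <- ifelse(tl$labels == 1L, tl$cand@p1, tl$cand@p2)
  tissue <- tissueMask(truth) > 0 & !tl$cand@degenerate
  expect_lt(max(Mod(sel - tl$pTrue)[tissue]), 1e-9)
})

test_that("equal water and fat collapse the two candidates", {
  p <- acquisitionParams()
  cc <- dephasingFactors(p)
  img <- forwardSimulate(
    matrix(0.7, 2, 2), matrix(0.7, 2, 2),
    matrix(40, 2, 2), matrix(0.3, 2, 2), p
  )
  cand <- amplitudeCandidates(Mod(s1(img)), Mod(s2(img)), cc[1], cc[2])
  cand <- phasorCandidates(img, cand, cc[1], cc[2])
  # identical up to the float rounding of the amplitude roots
  expect_equal(cand@p1, cand@p2, tolerance = 1e-6)
})

test_that("pure-water candidate phasors differ by the dephasing ratio", {
  # for (W, 0) vs (0, W) the denominators differ by conj(C1) C2, so
  # P1 = P2 * conj(C1) C2 (equivalently P2 = P1 * C1 conj(C2))
  p <- acquisitionParams()
  cc <- dephasingFactors(p)
  img <- forwardSimulate(
    matrix(1, 2, 2), matrix(0, 2, 2), matrix(25, 2, 2), matrix(0.1, 2, 2), p
  )
  cand <- amplitudeCandidates(Mod(s1(img)), Mod(s2(img)), cc[1], cc[2])
  cand <- phasorCandidates(img, cand, cc[1], cc[2])
  fac <- Conj(cc[1]) * cc[2]
  expect_equal(
    cand@p1, cand@p2 * fac / Mod(fac),
    tolerance = 1e-9
  )
})

test_that("amplitudes from the true phasor invert the forward model", {
  p <- acquisitionParams()
  cc <- dephasingFactors(p)
  truth <- generatePhantom(seed = 9)
  img <- simulatePhantom(truth, p)
  pTrue <- exp(1i * 2 * pi * b0Hz(truth) * (p@te2 - p@te1) * 1e-3)
  amp <- amplitudesFromPhasor(img, pTrue, cc[1], cc[2])
  expect_lt(max(abs(amp$water - water(truth))), 1e-9)
  expect_lt(max(abs(amp$fat - fat(truth))), 1e-9)
  expect_lt(max(amp$residual), 1e-9)
  expect_error(amplitudesFromPhasor(img, pTrue, cc[1], cc[1]), "singular")
})

test_that("the wrong candidate phasor swaps water and fat (the swap mechanism)", {
  # the wrong candidate's phasor is the true one times conj(C1) C2 (= -P at
  # exact in-/opposed-phase echoes); solving with it exchanges water and fat
  p <- classicParams()
  w <- matrix(2, 3, 3)
  zero <- matrix(0, 3, 3)
  b0 <- matrix(30, 3, 3)
  img <- forwardSimulate(w, zero, b0, zero, p)
  pTrue <- exp(1i * 2 * pi * b0 * (p@te2 - p@te1) * 1e-3)
  amp <- amplitudesFromPhasor(img, -pTrue, 1 + 0i, -1 + 0i)
  expect_lt(max(abs(amp$water - zero)), 1e-9)
  expect_lt(max(abs(amp$fat - w)), 1e-9)
  # S1 = S2 = 0 gives zero amplitudes
  img0 <- dualEchoImage(matrix(0 + 0i, 2, 2), matrix(0 + 0i, 2, 2), p)
  amp0 <- amplitudesFromPhasor(img0, matrix(1 + 0i, 2, 2), 1 + 0i, -1 + 0i)
  expect_true(all(amp0$water == 0) && all(amp0$fat == 0))
})

test_that("candidate computation is invariant under exchanging water and fat", {
  p <- acquisitionParams()
  set.seed(21)
  w <- matrix(runif(16), 4, 4)
  f <- matrix(runif(16), 4, 4)
  cc <- dephasingFactors(p)
  imA <- forwardSimulate(w, f, params = p)
  imB <- forwardSimulate(f, w, params = p)
  cA <- amplitudeCandidates(Mod(s1(imA)), Mod(s2(imA)), cc[1], cc[2])
  cB <- amplitudeCandidates(Mod(s1(imB)), Mod(s2(imB)), cc[1], cc[2])
  expect_equal(cA@w1, cB@w1, tolerance = 1e-9)
  expect_equal(cA@f1, cB@f1, tolerance = 1e-9)
})

test_that("noiseless phantoms round-trip to ground truth via true candidates", {
  p <- acquisitionParams()
  cc <- dephasingFactors(p)
  for (s in 1:25) {
    truth <- generatePhantom(seed = s)
    img <- simulatePhantom(truth, p)
    tl <- trueLabels(truth, img)
    sel <- matrix(
      ifelse(tl$labels == 1L, tl$cand@p1, tl$cand@p2),
      nrow(tl$labels), ncol(tl$labels)
    )
    amp <- amplitudesFromPhasor(img, sel, cc[1], cc[2])
    expect_lt(max(abs(amp$water - water(truth))), 1e-8)
    expect_lt(max(abs(amp$fat - fat(truth))), 1e-8)
  }
})
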