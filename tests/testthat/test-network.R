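test_that("input stacks normalize magnitude and encode phase and echo times", {
  p <- acquisitionParams(te1 = 2.23, te2 = 1.31)
  truth <- generatePhantom(shape = c(32, 32), seed = 2)
  img <- simulatePhantom(truth, p, noiseSigma = 0.02, seed = 3)
  st <- assembleInputStack(img)
  expect_equal(dim(st$x), c(32L, 32L, 6L))
  # phase channels bounded by construction
  expect_true(all(abs(st$x[, , 3]) <= 1) && all(abs(st$x[, , 4]) <= 1))
  # TE channels are constant maps in units of 10 ms
  expect_true(all(st$x[, , 5] == 0.223))
  expect_true(all(st$x[, , 6] == 0.131))
  # the fitted scale makes channel 1's 99th percentile exactly one
  expect_equal(quantile(st$x[, , 1], 0.99, names = FALSE), 1,
    tolerance = 1e-6)
  # refitting with the stored record reproduces the stack
  st2 <- assembleInputStack(img, st$norm)
  expect_identical(st$x, st2$x)
  blank <- dualEchoImage(matrix(0 + 0i, 8, 8), matrix(0 + 0i, 8, 8), p)
  expect_error(assembleInputStack(blank), "blank")
})

test_that("architecture determinism and the desk parameter count", {
  cfg <- networkConfig("desk")
  a <- buildNetwork(cfg, seed = 1)
  b <- buildNetwork(cfg, seed = 2)
  expect_equal(parameterCount(a), parameterCount(b))
  # layer-by-layer hand accounting for the desk preset:
  # conv k x k cin -> cout: cout (k^2 cin + 1) weights+biases, plus cout
  # PReLU slopes where activated; dense projection 1x1 (B+1)w -> w
  convP <- function(cin, cout, k, act = TRUE) {
    cout * (k^2 * cin + 1) + if (act) cout else 0
  }
  levelP <- function(w, B = 3) B * convP(w, w, 3) + convP((B + 1) * w, w, 1,
    act = FALSE)
  expected <- convP(6, 8, 3) + # entry conv
    levelP(8) + convP(8, 16, 2) + # encoder 1 + down
    levelP(16) + convP(16, 32, 2) + # encoder 2 + down
    levelP(32) + # bottleneck
    convP(32, 16, 2) + convP(32, 16, 1) + levelP(16) + # up2, fuse2, d2
    convP(16, 8, 2) + convP(16, 8, 1) + levelP(8) + # up1, fuse1, d1
    2 * convP(8, 1, 1, act = FALSE) # heads
  expect_equal(parameterCount(a), expected)
  expect_equal(parameterCount(a), 58562) # frozen regression value
  # identical seeds give identical initializations
  expect_identical(buildNetwork(cfg, 7)@params, buildNetwork(cfg, 7)@params)
  expect_error(networkConfig(channels = c(8, 16)), "one entry per level")
})

test_that("removing dense shortcuts removes exactly the projection layers", {
  dense <- buildNetwork(networkConfig("desk"), 1)
  plain <- buildNetwork(networkConfig("desk", denseLocalShortcuts = FALSE), 1)
  projP <- function(w) w * (4 * w + 1)
  # encoder levels 8/16/32 plus decoder levels 16/8
  expect_equal(
    parameterCount(dense) - parameterCount(plain),
    projP(8) + projP(16) + projP(32) + projP(16) + projP(8)
  )
})

test_that("output shape follows the input and the heads are independent", {
  cfg <- networkConfig(
    nLevels = 2L, channels = c(4L, 6L),
    blocksPerLevel = 2L
  )
  net <- buildNetwork(cfg, seed = 3)
  x <- array(rnorm(16 * 16 * 6), c(16, 16, 6))
  out <- DualDixon:::netForward(net@params, cfg, list(x),
    wantCache = FALSE)$out[[1]]
  expect_equal(dim(out), c(16L, 16L, 2L))
  # zeroing the fat head zeroes only the fat output
  p2 <- net@params
  p2$head_fat$w[] <- 0
  p2$head_fat$b[] <- 0
  out2 <- DualDixon:::netForward(p2, cfg, list(x),
    wantCache = FALSE)$out[[1]]
  expect_true(all(out2[, , 2] == 0))
  expect_equal(out2[, , 1], out[, , 1])
})

test_that("analytic gradients agree with finite differences", {
  cfg <- networkConfig(nLevels = 2L, channels = c(3L, 5L),
    blocksPerLevel = 2L)
  params <- DualDixon:::initNetParams(cfg, 42)
  set.seed(9)
  xs <- list(array(rnorm(8 * 8 * 6), c(8, 8, 6)))
  ys <- list(array(rnorm(8 * 8 * 2), c(8, 8, 2)))
  lossAt <- function(pp) {
    fwd <- DualDixon:::netForward(pp, cfg, xs, wantCache = FALSE)
    DualDixon:::l1LossGrad(fwd$out, ys)$loss
  }
  fwd <- DualDixon:::netForward(params, cfg, xs, wantCache = TRUE)
  lg <- DualDixon:::l1LossGrad(fwd$out, ys)
  bwd <- DualDixon:::netBackward(params, cfg, fwd, lg$grad)
  eps <- 1e-6
  set.seed(2)
  for (nm in c("enc_in", "e1_b2", "e1_proj", "down1", "e2_b1", "up1",
    "fuse1", "d1_b1", "head_water")) {
    for (fld in c("w", "b", "a")) {
      v <- params[[nm]][[fld]]
      if (is.null(v)) next
      i <- sample(length(v), 1)
      pp <- params
      pp[[nm]][[fld]][i] <- v[i] + eps
      pm <- params
      pm[[nm]][[fld]][i] <- v[i] - eps
      num <- (lossAt(pp) - lossAt(pm)) / (2 * eps)
      ana <- bwd$grads[[nm]][[c(w = "gw", b = "gb", a = "ga")[[fld]]]][i]
      expect_equal(ana, num, tolerance = 1e-4,
        label = sprintf("grad %s$%s[%d]", nm, fld, i))
    }
  }
})

test_that("training is seeded and overfits a memorizable task", {
  # eight identical pure-water phantom pairs; the loss must collapse
  p <- acquisitionParams()
  w <- matrix(0, 32, 32)
  w[8:24, 8:24] <- 1
  img <- forwardSimulate(w, 0 * w, params = p)
  st <- assembleInputStack(img)
  y <- array(0, c(32, 32, 2))
  y[, , 1] <- w / st$norm$m
  items <- rep(list(list(x = st$x, y = y)), 8)
  cfg <- networkConfig(nLevels = 2L, channels = c(6L, 12L),
    blocksPerLevel = 2L)
  net <- trainModel(list(items = items, norm = st$norm), NULL, cfg,
    list(epochs = 50L, batchSize = 1L, seed = 4L))
  expect_lt(tail(net@history$train, 1), 0.02)
  # same seed, same first-epoch loss
  netA <- trainModel(list(items = items, norm = st$norm), NULL, cfg,
    list(epochs = 1L, batchSize = 8L, seed = 4L))
  netB <- trainModel(list(items = items, norm = st$norm), NULL, cfg,
    list(epochs = 1L, batchSize = 8L, seed = 4L))
  expect_identical(netA@history$train, netB@history$train)
  expect_error(trainModel(list(items = list()), NULL, cfg), "empty")

  # prediction: deterministic, shape-preserving under pad-and-crop
  img2 <- dualEchoImage(s1(img)[1:30, 1:27], s2(img)[1:30, 1:27], p)
  r1 <- predictWaterFat(net, img2)
  r2 <- predictWaterFat(net, img2)
  expect_identical(water(r1), water(r2))
  expect_equal(dim(water(r1)), c(30L, 27L))
  expect_true(all(water(r1) >= 0) && all(fat(r1) >= 0))
  # the trained net reproduces the memorized water map
  pred <- predictWaterFat(net, img)
  expect_lt(mean(abs(water(pred) - w)), 0.03 * st$norm$m)
})

test_that("echo-time conditioning is live in a trained model", {
  # train briefly on mixed TE pairs, then change only the TE channels
  train <- makeDixonDataset(16, shape = c(32, 32), seed = 5, mixTe = TRUE)
  cfg <- networkConfig(nLevels = 2L, channels = c(4L, 8L),
    blocksPerLevel = 2L)
  net <- trainModel(train, NULL, cfg, list(epochs = 2L, seed = 6L))
  it <- train$items[[1]]
  xAlt <- it$x
  xAlt[, , 5] <- 0.223
  xAlt[, , 6] <- ifelse(it$x[1, 1, 6] > 0.2, 0.131, 0.335)
  outA <- DualDixon:::netForward(net@params, cfg, list(it$x),
    wantCache = FALSE)$out[[1]]
  outB <- DualDixon:::netForward(net@params, cfg, list(xAlt),
    wantCache = FALSE)$out[[1]]
  expect_gt(mean(abs(outA - outB)), 0)
})
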