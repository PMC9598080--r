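## The learned separation route: a densely connected hierarchical
## encoder-decoder (multi-output variant) mapping the six input channels
## (in-phase/out-of-phase magnitude and wrapped phase plus two constant
## echo-time maps) to normalized water and fat images. Per hierarchical
## level there are three 3x3 conv blocks with PReLU; dense local shortcuts
## concatenate the level input and every block output and project back to
## the level width with a 1x1 convolution; 2x2 stride-2 convolutions
## downsample and their transposed counterparts upsample; global shortcuts
## join matching encoder/decoder levels by concatenation plus a 1x1 fusion;
## two parallel 1x1 heads emit water and fat.

#' Network architecture configuration
#'
#' `"desk"` (default) is a reduced-capacity preset (3 levels, 8/16/32
#' channels) with the same topology as the full-scale `"full"` preset of
#' 5 levels and 16/32/64/128/256 channels; both use three blocks per level,
#' 3x3 kernels with PReLU, 2x2 stride-2 down/upsampling convolutions, six
#' input channels and two output heads.
#'
#' @param preset `"desk"` or `"full"`
#' @param ... overrides for individual fields (`nLevels`, `channels`,
#'   `blocksPerLevel`, `kernel`, `downUpKernel`, `nInputChannels`,
#'   `nOutputs`, `denseLocalShortcuts`, `globalShortcuts`)
#' @return a configuration list
#' @export
networkConfig <- function(preset = c("desk", "full"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    nLevels = 3L, channels = c(8L, 16L, 32L), blocksPerLevel = 3L,
    kernel = 3L, downUpKernel = 2L, activation = "prelu",
    nInputChannels = 6L, nOutputs = 2L,
    denseLocalShortcuts = TRUE, globalShortcuts = TRUE
  )
  if (preset == "full") {
    cfg$nLevels <- 5L
    cfg$channels <- c(16L, 32L, 64L, 128L, 256L)
  }
  cfg <- modifyList(cfg, list(...))
  cfg$nLevels <- as.integer(cfg$nLevels)
  cfg$channels <- as.integer(cfg$channels)
  if (length(cfg$channels) != cfg$nLevels) {
    stop("'channels' must have one entry per level", call. = FALSE)
  }
  cfg
}

#' Build (initialize) a separation network
#'
#' Parameters are He-initialized (PReLU slopes at 0.25, biases at zero),
#' deterministically for a given seed; two builds from the same
#' configuration have identical parameter counts.
#'
#' @param cfg a configuration from [networkConfig()]
#' @param seed initialization seed
#' @return a [DixonNet-class]
#' @export
buildNetwork <- function(cfg = networkConfig(), seed = 1L) {
  new("DixonNet",
    config = cfg, params = initNetParams(cfg, seed),
    norm = list(), history = list()
  )
}

#' Total number of trainable parameters of a network
#'
#' @param net a [DixonNet-class]
#' @return integer parameter count (weights, biases and PReLU slopes)
#' @export
parameterCount <- function(net) {
  sum(vapply(net@params, function(p) {
    length(p$w) + length(p$b) + length(p$a)
  }, 0))
}

#' Assemble the six-channel network input from a dual-echo image
#'
#' Channels are `|S1|/m`, `|S2|/m`, `arg(S1)/pi`, `arg(S2)/pi` and two
#' constant echo-time maps in units of 10 ms (so clinical TEs fall around
#' 0.1-0.5). The magnitude scale `m` is the 99th percentile of `|S1|`,
#' fitted when `norm = "fit"` and otherwise taken from the supplied record;
#' the same `m` de-normalizes network outputs back to signal units.
#'
#' @param img a [DualEchoImage-class]
#' @param norm `"fit"` or a normalization record `list(m =, teScale =)`
#' @return list with `x` (H x W x 6 array) and `norm` (the record used)
#' @export
assembleInputStack <- function(img, norm = "fit") {
  m1 <- Mod(img@s1)
  if (identical(norm, "fit")) {
    norm <- list(
      m = as.numeric(quantile(m1, 0.99, names = FALSE)),
      teScale = 10
    )
  }
  if (!is.finite(norm$m) || norm$m <= 0) {
    stop("normalization scale is zero: blank in-phase image", call. = FALSE)
  }
  d <- dim(img@s1)
  p <- img@params
  x <- array(0, dim = c(d[1], d[2], 6L))
  x[, , 1] <- m1 / norm$m
  x[, , 2] <- Mod(img@s2) / norm$m
  x[, , 3] <- Arg(img@s1) / pi
  x[, , 4] <- Arg(img@s2) / pi
  x[, , 5] <- p@te1 / norm$teScale
  x[, , 6] <- p@te2 / norm$teScale
  list(x = x, norm = norm)
}

#' Generate a seeded synthetic training/validation dataset
#'
#' Draws phantoms with varied anatomy and B0 severity (smooth amplitudes
#' 20-150 Hz, a fat rim, 1-4 mixed inclusions, a metal-like perturbation in
#' 20% of cases), simulates dual-echo acquisitions with complex Gaussian
#' noise, and mixes the two out-of-phase echo-time clusters (1.31 ms and
#' 3.35 ms at 3 T) so echo-time conditioning is exercised. The magnitude
#' normalization is fitted on the pooled training images and stored in the
#' returned record.
#'
#' @param n number of cases
#' @param shape image shape (default 64 x 64)
#' @param seed base seed
#' @param noiseSigma acquisition noise (default 0.03, about 30 dB tissue
#'   pSNR for unit-amplitude tissue)
#' @param norm `"fit"` or an existing normalization record (use the training
#'   record for validation/test sets)
#' @param mixTe mix the two out-of-phase TE clusters (default `TRUE`)
#' @return list with `items` (each `list(x, y, truth, params)`) and `norm`
#' @export
makeDixonDataset <- function(n, shape = c(64, 64), seed = 1L,
                             noiseSigma = 0.03, norm = "fit",
                             mixTe = TRUE) {
  draws <- withSeed(stageSeed(seed, "dataset"), {
    lapply(seq_len(n), function(i) {
      list(
        b0 = runif(1, 20, 150),
        nEll = sample(1:4, 1),
        metal = runif(1) < 0.2,
        metalStrength = runif(1, 100, 300),
        te2 = if (mixTe && runif(1) < 0.5) 3.35 else 1.31,
        phantomSeed = stageSeed(seed, sprintf("phantom%d", i)),
        noiseSeed = stageSeed(seed, sprintf("noise%d", i))
      )
    })
  })
  cases <- lapply(seq_len(n), function(i) {
    dr <- draws[[i]]
    truth <- generatePhantom(
      shape = shape, nEllipses = dr$nEll, fatRim = TRUE,
      b0AmplitudeHz = dr$b0,
      metal = if (dr$metal) list(strengthHz = dr$metalStrength) else NULL,
      seed = dr$phantomSeed
    )
    params <- acquisitionParams(te1 = 2.23, te2 = dr$te2)
    img <- simulatePhantom(truth, params,
      noiseSigma = noiseSigma,
      seed = dr$noiseSeed
    )
    list(truth = truth, img = img, params = params)
  })
  if (identical(norm, "fit")) {
    mags <- unlist(lapply(cases, function(cs) as.vector(Mod(cs$img@s1))))
    norm <- list(
      m = as.numeric(quantile(mags, 0.99, names = FALSE)),
      teScale = 10
    )
  }
  items <- lapply(cases, function(cs) {
    st <- assembleInputStack(cs$img, norm)
    d <- dim(cs$truth@water)
    y <- array(0, dim = c(d[1], d[2], 2L))
    y[, , 1] <- cs$truth@water / norm$m
    y[, , 2] <- cs$truth@fat / norm$m
    list(x = st$x, y = y, truth = cs$truth, params = cs$params)
  })
  list(items = items, norm = norm)
}

#' Train a separation network
#'
#' Minimizes the mean absolute error between predicted and reference
#' water/fat channels with Adam. Fully seeded: initialization and the
#' per-epoch shuffling derive from `trainCfg$seed`.
#'
#' @param trainSet,valSet datasets as returned by [makeDixonDataset()] (or
#'   lists of `list(x =, y =)` items plus a `norm` record on `trainSet`)
#' @param netCfg a [networkConfig()] list
#' @param trainCfg list of training options; defaults: `lr` 0.001, `beta1`
#'   0.9, `beta2` 0.999, `epsilon` 1e-8, `loss` "l1", `init` "he",
#'   `epochs` 20, `batchSize` 8, `seed` 1
#' @return a trained [DixonNet-class] with per-epoch history
#' @export
trainModel <- function(trainSet, valSet = NULL, netCfg = networkConfig(),
                       trainCfg = list()) {
  tc <- modifyList(list(
    lr = 0.001, beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
    loss = "l1", init = "he", epochs = 20L, batchSize = 8L, seed = 1L
  ), trainCfg)
  items <- trainSet$items %||% trainSet
  if (length(items) == 0L) stop("empty training set", call. = FALSE)
  d0 <- dim(items[[1L]]$x)
  for (it in items) {
    if (!identical(dim(it$x), d0)) {
      stop("training items have inconsistent shapes", call. = FALSE)
    }
  }
  params <- initNetParams(netCfg, stageSeed(tc$seed, "init"))
  state <- adamInit(params)
  history <- list(train = numeric(), val = numeric())
  t <- 0L
  nItems <- length(items)
  valItems <- if (!is.null(valSet)) valSet$items %||% valSet else NULL
  for (epoch in seq_len(tc$epochs)) {
    ord <- withSeed(
      stageSeed(tc$seed, sprintf("epoch%d", epoch)),
      sample.int(nItems)
    )
    epochLoss <- 0
    nBatches <- 0L
    for (start in seq(1L, nItems, by = tc$batchSize)) {
      idx <- ord[start:min(start + tc$batchSize - 1L, nItems)]
      xs <- lapply(items[idx], `[[`, "x")
      ys <- lapply(items[idx], `[[`, "y")
      fwd <- netForward(params, netCfg, xs, wantCache = TRUE)
      lg <- l1LossGrad(fwd$out, ys)
      bwd <- netBackward(params, netCfg, fwd, lg$grad)
      t <- t + 1L
      stepped <- adamStep(params, bwd$grads, state, t,
        tc$lr, tc$beta1, tc$beta2, tc$epsilon
      )
      params <- stepped$params
      state <- stepped$state
      epochLoss <- epochLoss + lg$loss
      nBatches <- nBatches + 1L
    }
    history$train <- c(history$train, epochLoss / nBatches)
    if (!is.null(valItems)) {
      history$val <- c(history$val, evalLoss(params, netCfg, valItems))
    }
  }
  new("DixonNet",
    config = netCfg, params = params,
    norm = trainSet$norm %||% list(), history = history
  )
}

evalLoss <- function(params, cfg, items, batchSize = 8L) {
  total <- 0
  count <- 0
  for (start in seq(1L, length(items), by = batchSize)) {
    idx <- start:min(start + batchSize - 1L, length(items))
    xs <- lapply(items[idx], `[[`, "x")
    ys <- lapply(items[idx], `[[`, "y")
    fwd <- netForward(params, cfg, xs, wantCache = FALSE)
    for (i in seq_along(idx)) {
      total <- total + sum(abs(fwd$out[[i]] - ys[[i]]))
      count <- count + length(ys[[i]])
    }
  }
  total / count
}

#' Predict water/fat images with a trained network
#'
#' Inputs of arbitrary size are replicate-padded to the divisibility the
#' hierarchy requires and cropped back. Raw outputs are de-normalized with
#' the stored record and clamped to non-negative; the clamped fraction is
#' reported in `meta`.
#'
#' @param net a trained [DixonNet-class]
#' @param img a [DualEchoImage-class]
#' @param norm optional normalization record overriding the stored one
#' @return a [WaterFatResult-class] (phasor and selection left empty)
#' @export
predictWaterFat <- function(net, img, norm = NULL) {
  norm <- norm %||% net@norm
  if (is.null(norm$m)) {
    stop("no normalization record: train the network or supply 'norm'",
      call. = FALSE
    )
  }
  st <- assembleInputStack(img, norm)
  x <- st$x
  d <- dim(x)
  div <- net@config$downUpKernel^(net@config$nLevels - 1L)
  padTo <- function(n) as.integer(ceiling(n / div) * div)
  dp <- c(padTo(d[1]), padTo(d[2]))
  if (!identical(dp, d[1:2])) {
    xp <- array(0, dim = c(dp, d[3]))
    xp[seq_len(d[1]), seq_len(d[2]), ] <- x
    if (dp[1] > d[1]) {
      xp[(d[1] + 1L):dp[1], seq_len(d[2]), ] <-
        x[rep(d[1], dp[1] - d[1]), seq_len(d[2]), , drop = FALSE]
    }
    if (dp[2] > d[2]) {
      xp[, (d[2] + 1L):dp[2], ] <-
        xp[, rep(d[2], dp[2] - d[2]), , drop = FALSE]
    }
    x <- xp
  }
  out <- netForward(net@params, net@config, list(x), wantCache = FALSE)$out[[1L]]
  out <- out[seq_len(d[1]), seq_len(d[2]), , drop = FALSE]
  waterRaw <- out[, , 1] * norm$m
  fatRaw <- out[, , 2] * norm$m
  clampedFraction <- mean(c(waterRaw < 0, fatRaw < 0))
  empty <- matrix(NA_complex_, d[1], d[2])
  new("WaterFatResult",
    water = pmax(waterRaw, 0), fat = pmax(fatRaw, 0),
    phasor = empty, selection = matrix(0L, d[1], d[2]),
    meta = list(
      method = "network", clampedFraction = clampedFraction,
      norm = norm
    )
  )
}
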