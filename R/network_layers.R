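## Internal batched tensor plumbing for the separation network. A batch is a
## plain list of H x W x C arrays; convolutions run through the compiled
## im2col/GEMM primitives, PReLU and bookkeeping stay in R. Backward passes
## are hand-derived adjoints and are verified against finite differences in
## the test suite.

zerosLike <- function(xs) lapply(xs, function(a) array(0, dim(a)))

addB <- function(a, b) Map(`+`, a, b)

concatC <- function(batches) {
  n <- length(batches[[1L]])
  lapply(seq_len(n), function(i) {
    parts <- lapply(batches, `[[`, i)
    d <- dim(parts[[1L]])
    array(
      do.call(c, parts),
      dim = c(d[1], d[2], sum(vapply(parts, function(p) dim(p)[3], 0)))
    )
  })
}

splitC <- function(batch, widths) {
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  lapply(seq_along(widths), function(k) {
    lapply(batch, function(a) a[, , starts[k]:ends[k], drop = FALSE])
  })
}

preluF <- function(a, xs) {
  lapply(xs, function(x) {
    d <- dim(x)
    s <- rep(a, each = d[1] * d[2])
    y <- pmax(x, 0) + s * pmin(x, 0)
    dim(y) <- d
    y
  })
}

preluB <- function(a, xs, gys) {
  ga <- numeric(length(a))
  gxs <- Map(function(x, gy) {
    d <- dim(x)
    s <- rep(a, each = d[1] * d[2])
    neg <- x < 0
    gx <- gy * (1 - neg) + gy * s * neg
    ga <<- ga + colSums(matrix(gy * x * neg, d[1] * d[2], d[3]))
    dim(gx) <- d
    gx
  }, xs, gys)
  list(gx = gxs, ga = ga)
}

## He-initialized parameter entry for one (possibly activated) conv layer
initConvParam <- function(spec) {
  k <- spec$k
  fanIn <- if (spec$type == "conv") k * k * spec$cin else spec$cin
  nW <- if (spec$type == "conv") {
    k * k * spec$cin * spec$cout
  } else {
    k * k * spec$cout * spec$cin
  }
  w <- matrix(
    rnorm(nW, sd = sqrt(2 / fanIn)),
    nrow = if (spec$type == "conv") k * k * spec$cin else k * k * spec$cout,
    ncol = if (spec$type == "conv") spec$cout else spec$cin
  )
  list(
    type = spec$type, k = k, stride = spec$stride, pad = spec$pad,
    cin = spec$cin, cout = spec$cout,
    w = w, b = numeric(spec$cout),
    a = if (spec$act) rep(0.25, spec$cout) else NULL
  )
}

## Ordered layer specifications implied by a network configuration
layerSpecs <- function(cfg) {
  specs <- list()
  add <- function(name, cin, cout, k, stride = 1L, pad = (k - 1L) %/% 2L,
                  act = TRUE, type = "conv") {
    specs[[name]] <<- list(
      name = name, cin = cin, cout = cout, k = k, stride = stride,
      pad = pad, act = act, type = type
    )
  }
  ch <- cfg$channels
  B <- cfg$blocksPerLevel
  L <- cfg$nLevels
  kd <- cfg$downUpKernel
  addLevel <- function(prefix, width) {
    for (b in seq_len(B)) {
      add(sprintf("%s_b%d", prefix, b), width, width, cfg$kernel)
    }
    if (cfg$denseLocalShortcuts) {
      add(paste0(prefix, "_proj"), (B + 1L) * width, width, 1L, act = FALSE)
    }
  }
  add("enc_in", cfg$nInputChannels, ch[1], cfg$kernel)
  for (l in seq_len(L)) {
    addLevel(paste0("e", l), ch[l])
    if (l < L) add(paste0("down", l), ch[l], ch[l + 1], kd, stride = kd,
      pad = 0L)
  }
  for (l in rev(seq_len(L - 1L))) {
    add(paste0("up", l), ch[l + 1], ch[l], kd, pad = 0L, type = "convT")
    if (cfg$globalShortcuts) {
      add(paste0("fuse", l), 2L * ch[l], ch[l], 1L)
    }
    addLevel(paste0("d", l), ch[l])
  }
  add("head_water", ch[1], 1L, 1L, act = FALSE)
  add("head_fat", ch[1], 1L, 1L, act = FALSE)
  specs
}

initNetParams <- function(cfg, seed) {
  specs <- layerSpecs(cfg)
  withSeed(seed, lapply(specs, initConvParam))
}

netForward <- function(params, cfg, xs, wantCache = TRUE) {
  cache <- if (wantCache) new.env(parent = emptyenv()) else NULL
  runConv <- function(name, x) {
    p <- params[[name]]
    z <- if (p$type == "conv") {
      convForwardCpp(x, p$w, p$b, p$k, p$stride, p$pad)
    } else {
      convTForwardCpp(x, p$w, p$b, p$k)
    }
    if (wantCache) {
      cache[[paste0(name, ".x")]] <- x
      if (!is.null(p$a)) cache[[paste0(name, ".z")]] <- z
    }
    if (!is.null(p$a)) preluF(p$a, z) else z
  }
  runLevel <- function(prefix, x) {
    outs <- list(x)
    cur <- x
    for (b in seq_len(cfg$blocksPerLevel)) {
      cur <- runConv(sprintf("%s_b%d", prefix, b), cur)
      outs[[b + 1L]] <- cur
    }
    if (cfg$denseLocalShortcuts) {
      runConv(paste0(prefix, "_proj"), concatC(outs))
    } else {
      cur
    }
  }
  L <- cfg$nLevels
  cur <- runConv("enc_in", xs)
  enc <- vector("list", L)
  for (l in seq_len(L)) {
    cur <- runLevel(paste0("e", l), cur)
    enc[[l]] <- cur
    if (l < L) cur <- runConv(paste0("down", l), cur)
  }
  for (l in rev(seq_len(L - 1L))) {
    cur <- runConv(paste0("up", l), cur)
    if (cfg$globalShortcuts) {
      cur <- runConv(paste0("fuse", l), concatC(list(cur, enc[[l]])))
    }
    cur <- runLevel(paste0("d", l), cur)
  }
  out <- concatC(list(runConv("head_water", cur), runConv("head_fat", cur)))
  list(out = out, cache = cache)
}

netBackward <- function(params, cfg, fwd, gout) {
  cache <- fwd$cache
  grads <- list()
  bConv <- function(name, g) {
    p <- params[[name]]
    x <- cache[[paste0(name, ".x")]]
    ga <- NULL
    if (!is.null(p$a)) {
      pb <- preluB(p$a, cache[[paste0(name, ".z")]], g)
      g <- pb$gx
      ga <- pb$ga
    }
    res <- if (p$type == "conv") {
      convBackwardCpp(x, p$w, g, p$k, p$stride, p$pad)
    } else {
      convTBackwardCpp(x, p$w, g, p$k)
    }
    grads[[name]] <<- list(gw = res$gw, gb = as.numeric(res$gb), ga = ga)
    res$gx
  }
  bLevel <- function(prefix, g) {
    B <- cfg$blocksPerLevel
    if (cfg$denseLocalShortcuts) {
      width <- params[[sprintf("%s_b1", prefix)]]$cin
      gouts <- splitC(bConv(paste0(prefix, "_proj"), g), rep(width, B + 1L))
    } else {
      gouts <- c(rep(list(NULL), B), list(g))
    }
    gcur <- gouts[[B + 1L]]
    for (b in rev(seq_len(B))) {
      gprev <- bConv(sprintf("%s_b%d", prefix, b), gcur)
      gcur <- if (is.null(gouts[[b]])) gprev else addB(gprev, gouts[[b]])
    }
    gcur
  }
  L <- cfg$nLevels
  ch <- cfg$channels
  gs <- splitC(gout, c(1L, 1L))
  g <- addB(bConv("head_water", gs[[1L]]), bConv("head_fat", gs[[2L]]))
  gskip <- vector("list", L)
  for (l in seq_len(L - 1L)) {
    g <- bLevel(paste0("d", l), g)
    if (cfg$globalShortcuts) {
      parts <- splitC(bConv(paste0("fuse", l), g), c(ch[l], ch[l]))
      g <- parts[[1L]]
      gskip[[l]] <- parts[[2L]]
    }
    g <- bConv(paste0("up", l), g)
  }
  for (l in rev(seq_len(L))) {
    if (l < L) {
      g <- bConv(paste0("down", l), g)
      if (!is.null(gskip[[l]])) g <- addB(g, gskip[[l]])
    }
    g <- bLevel(paste0("e", l), g)
  }
  gin <- bConv("enc_in", g)
  list(grads = grads, gx = gin)
}

l1LossGrad <- function(pred, target) {
  total <- 0
  count <- 0
  gs <- vector("list", length(pred))
  for (i in seq_along(pred)) {
    d <- pred[[i]] - target[[i]]
    total <- total + sum(abs(d))
    count <- count + length(d)
    gs[[i]] <- sign(d)
  }
  list(
    loss = total / count,
    grad = lapply(gs, function(g) {
      out <- g / count
      dim(out) <- dim(g)
      out
    })
  )
}

adamInit <- function(params) {
  lapply(params, function(p) {
    st <- list(mw = 0 * p$w, vw = 0 * p$w, mb = 0 * p$b, vb = 0 * p$b)
    if (!is.null(p$a)) {
      st$ma <- 0 * p$a
      st$va <- 0 * p$a
    }
    st
  })
}

adamStep <- function(params, grads, state, t, lr, beta1, beta2, eps) {
  upd <- function(x, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    mh <- m / (1 - beta1^t)
    vh <- v / (1 - beta2^t)
    list(x = x - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
  for (nm in names(grads)) {
    p <- params[[nm]]
    st <- state[[nm]]
    gr <- grads[[nm]]
    u <- upd(p$w, gr$gw, st$mw, st$vw)
    p$w <- u$x; st$mw <- u$m; st$vw <- u$v
    u <- upd(p$b, gr$gb, st$mb, st$vb)
    p$b <- u$x; st$mb <- u$m; st$vb <- u$v
    if (!is.null(p$a) && !is.null(gr$ga)) {
      u <- upd(p$a, gr$ga, st$ma, st$va)
      p$a <- u$x; st$ma <- u$m; st$va <- u$v
    }
    params[[nm]] <- p
    state[[nm]] <- st
  }
  list(params = params, state = state)
}
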