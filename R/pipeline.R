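## End-to-end classical separation: candidate computation, smoothness-driven
## phasor selection (optionally at reduced resolution), and the final
## amplitude solve at full resolution.

candidatesFor <- function(img) {
  cc <- dephasingFactors(img@params)
  cands <- amplitudeCandidates(Mod(img@s1), Mod(img@s2), cc[1], cc[2])
  phasorCandidates(img, cands, cc[1], cc[2])
}

#' Classical dual-echo water-fat separation
#'
#' Runs the full pipeline: optional block-mean downsampling of both echoes,
#' per-pixel candidate amplitudes and phasors, penalty-graph construction,
#' projected power selection, upsampling of the selected field phasor back
#' to full resolution, per-pixel re-selection of the candidate phasor closest
#' in angle to the upsampled field phasor, and the final amplitude solve.
#' Deterministic given its options.
#'
#' @param img a [DualEchoImage-class]
#' @param downsampleFactor integer >= 1 (1 disables the multiresolution step)
#' @param nbrs a [NeighborSpec-class]
#' @param maxIter iteration cap for [projectedPowerSelect()]
#' @param seed forwarded to [projectedPowerSelect()]
#' @param distanceWeight forwarded to [buildPenaltyGraph()]
#' @param upsampleAmplitudes if `TRUE`, upsample the low-resolution water/fat
#'   maps directly instead of re-solving amplitudes at full resolution (the
#'   literal coarse pipeline; the default re-solve is exact for noiseless
#'   data)
#' @return a [WaterFatResult-class]
#' @export
separateDualEcho <- function(img, downsampleFactor = 1L,
                             nbrs = neighborSpec(4), maxIter = 100L,
                             seed = 1L, distanceWeight = "divide",
                             upsampleAmplitudes = FALSE) {
  stopifnot(is(img, "DualEchoImage"))
  cc <- dephasingFactors(img@params)
  f <- as.integer(downsampleFactor)

  stage <- "downsample"
  res <- tryCatch(
    {
      imgLow <- if (f > 1L) {
        dualEchoImage(
          downsampleComplex(img@s1, f), downsampleComplex(img@s2, f),
          img@params
        )
      } else {
        img
      }
      stage <- "candidates"
      candLow <- candidatesFor(imgLow)
      stage <- "penalty graph"
      graph <- buildPenaltyGraph(
        Mod(imgLow@s1), candLow@p1, candLow@p2, nbrs,
        distanceWeight = distanceWeight
      )
      stage <- "phasor selection"
      sel <- projectedPowerSelect(graph, maxIter = maxIter, seed = seed)
      phasorLow <- ifelse(sel@labels == 1L, candLow@p1, candLow@p2)
      phasorLow <- matrix(phasorLow, nrow(candLow@p1), ncol(candLow@p1))

      stage <- "upsample"
      fieldPhasor <- upsamplePhasor(phasorLow, dim(img@s1))

      if (f > 1L && upsampleAmplitudes) {
        ## literal coarse route: upsample the low-res water/fat images
        ampLow <- amplitudesFromPhasor(imgLow, phasorLow, cc[1], cc[2])
        up <- function(m) Re(upsampleField(m, dim(img@s1)))
        water <- pmax(up(ampLow$water), 0)
        fatm <- pmax(up(ampLow$fat), 0)
        cand <- candidatesFor(img)
        labels <- reselectLabels(cand, fieldPhasor)
        phas <- pickPhasor(cand, labels)
        residual <- matrix(0, nrow(water), ncol(water))
      } else {
        stage <- "re-selection"
        cand <- candidatesFor(img)
        labels <- reselectLabels(cand, fieldPhasor)
        phas <- pickPhasor(cand, labels)
        stage <- "amplitude solve"
        amp <- amplitudesFromPhasor(img, phas, cc[1], cc[2])
        water <- amp$water
        fatm <- amp$fat
        residual <- amp$residual
      }
      list(
        water = water, fat = fatm, phasor = phas, labels = labels,
        energy = sel@energy, iterations = sel@iterations,
        converged = sel@converged, residual = residual
      )
    },
    error = function(e) {
      stop(sprintf("separateDualEcho [%s stage]: %s", stage,
        conditionMessage(e)), call. = FALSE)
    }
  )
  new("WaterFatResult",
    water = res$water, fat = res$fat, phasor = res$phasor,
    selection = res$labels,
    meta = list(
      method = "projected-power",
      options = list(
        downsampleFactor = f, neighborOffsets = nrow(nbrs@offsets),
        maxIter = maxIter, seed = seed, distanceWeight = distanceWeight,
        upsampleAmplitudes = upsampleAmplitudes
      ),
      energy = res$energy, iterations = res$iterations,
      converged = res$converged,
      meanResidual = mean(res$residual)
    )
  )
}

## bilinear upsampling of a real field (shares the phasor path's mapping)
upsampleField <- function(m, targetShape) {
  ph <- upsamplePhasorReal(m, targetShape)
  ph
}

upsamplePhasorReal <- function(m, targetShape) {
  d <- dim(m)
  targetShape <- as.integer(targetShape)
  if (identical(targetShape, d)) return(m)
  fy <- d[1] / targetShape[1]
  fx <- d[2] / targetShape[2]
  sy <- (seq_len(targetShape[1]) - 0.5) * fy + 0.5
  sx <- (seq_len(targetShape[2]) - 0.5) * fx + 0.5
  lo <- function(coord, n) pmin(pmax(floor(coord), 1), n)
  y0 <- lo(sy, d[1]); y1 <- pmin(y0 + 1, d[1]); ty <- pmin(pmax(sy - y0, 0), 1)
  x0 <- lo(sx, d[2]); x1 <- pmin(x0 + 1, d[2]); tx <- pmin(pmax(sx - x0, 0), 1)
  m[y0, x0, drop = FALSE] * ((1 - ty) %o% (1 - tx)) +
    m[y1, x0, drop = FALSE] * (ty %o% (1 - tx)) +
    m[y0, x1, drop = FALSE] * ((1 - ty) %o% tx) +
    m[y1, x1, drop = FALSE] * (ty %o% tx)
}

reselectLabels <- function(cand, fieldPhasor) {
  d1 <- Mod(cand@p1 - fieldPhasor)
  d2 <- Mod(cand@p2 - fieldPhasor)
  labels <- matrix(1L, nrow(d1), ncol(d1))
  labels[d2 < d1] <- 2L
  ## degenerate pixels (background, clamped noise) carry no candidate
  ## information; mark them unselected
  labels[cand@degenerate] <- 0L
  labels
}

pickPhasor <- function(cand, labels) {
  p <- cand@p1
  p[labels == 2L] <- cand@p2[labels == 2L]
  p
}

#' Per-pixel baseline selection without smoothness
#'
#' Selects, independently at every pixel, the candidate with the smaller fat
#' amplitude (the water-dominant assumption). This is the no-smoothness
#' baseline against which swap-robustness of the graph-based pipeline and of
#' the network is measured.
#'
#' @param img a [DualEchoImage-class]
#' @return a [WaterFatResult-class]
#' @export
baselineSelect <- function(img) {
  cc <- dephasingFactors(img@params)
  cand <- candidatesFor(img)
  labels <- matrix(1L, nrow(cand@f1), ncol(cand@f1))
  labels[cand@f2 < cand@f1] <- 2L
  phas <- pickPhasor(cand, labels)
  amp <- amplitudesFromPhasor(img, phas, cc[1], cc[2])
  new("WaterFatResult",
    water = amp$water, fat = amp$fat, phasor = phas, selection = labels,
    meta = list(method = "baseline-lower-fat")
  )
}

#' Correct a global water/fat swap
#'
#' `"swap"` exchanges the water and fat maps (and flips the labels);
#' `"auto"` swaps when the mean fat fraction `F / (W + F)` in the border band
#' of tissue exceeds the interior mean by more than `margin`, mimicking the
#' subcutaneous-fat-rim prior; `"keep"` is the identity. The decision is
#' recorded in `meta$swapApplied`.
#'
#' @param result a [WaterFatResult-class]
#' @param mode `"auto"`, `"swap"` or `"keep"`
#' @param margin fat-fraction margin for `"auto"` (default 0.2)
#' @param bandFraction width of the border band as a fraction of the tissue
#'   extent (default 0.15)
#' @return the (possibly swapped) [WaterFatResult-class]
#' @export
globalSwapCorrect <- function(result, mode = c("auto", "swap", "keep"),
                              margin = 0.2, bandFraction = 0.15) {
  mode <- match.arg(mode)
  doSwap <- FALSE
  if (mode == "swap") {
    doSwap <- TRUE
  } else if (mode == "auto") {
    total <- result@water + result@fat
    tissue <- total > 0.05 * max(total)
    if (any(tissue)) {
      ## border band: tissue pixels within a rim of the tissue bounding box
      rows <- range(which(rowSums(tissue) > 0))
      cols <- range(which(colSums(tissue) > 0))
      rimR <- max(1L, ceiling(bandFraction * diff(rows)))
      rimC <- max(1L, ceiling(bandFraction * diff(cols)))
      idx <- which(tissue, arr.ind = TRUE)
      inBand <- idx[, 1] <= rows[1] + rimR | idx[, 1] >= rows[2] - rimR |
        idx[, 2] <= cols[1] + rimC | idx[, 2] >= cols[2] - rimC
      ff <- result@fat[tissue] / total[tissue]
      if (any(inBand) && any(!inBand)) {
        doSwap <- mean(ff[inBand]) < mean(ff[!inBand]) - margin
      }
    }
  }
  if (!doSwap) {
    result@meta$swapApplied <- FALSE
    result@meta$swapMode <- mode
    return(result)
  }
  labels <- result@selection
  flipped <- labels
  flipped[labels == 1L] <- 2L
  flipped[labels == 2L] <- 1L
  new("WaterFatResult",
    water = result@fat, fat = result@water, phasor = result@phasor,
    selection = flipped,
    meta = modifyList(result@meta, list(swapApplied = TRUE, swapMode = mode))
  )
}

#' Fraction of water/fat-swapped pixels relative to ground truth
#'
#' A pixel counts as swapped when the (water, fat) output is closer (in
#' summed absolute error) to the swapped ground truth than to the true one.
#' Pixels where truth is ambiguous (|W - F| below `minContrast` times the
#' maximum tissue amplitude) and background pixels are excluded.
#'
#' @param result a [WaterFatResult-class] (or list with water/fat matrices)
#' @param truth a [PhantomTruth-class]
#' @param minContrast relative water-fat contrast threshold (default 0.1)
#' @return fraction in `[0, 1]`
#' @export
swappedFraction <- function(result, truth, minContrast = 0.1) {
  w <- if (is(result, "WaterFatResult")) result@water else result$water
  f <- if (is(result, "WaterFatResult")) result@fat else result$fat
  tw <- truth@water
  tf <- truth@fat
  scale <- max(tw + tf)
  eligible <- truth@tissueMask > 0 & abs(tw - tf) > minContrast * scale
  if (!any(eligible)) return(0)
  errTrue <- abs(w - tw) + abs(f - tf)
  errSwap <- abs(w - tf) + abs(f - tw)
  mean(errSwap[eligible] < errTrue[eligible])
}
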