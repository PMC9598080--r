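## Image fidelity metrics with pinned definitions so reported numbers are
## reproducible: both images are scaled by the 99th percentile of the
## reference, making all four metrics invariant under joint positive
## rescaling; SSIM uses the standard 11 x 11 Gaussian window (sigma = 1.5,
## K1 = 0.01, K2 = 0.03) with data range 1 after scaling, averaged over the
## fully supported (valid) interior; pSNR is 20 log10(1 / rmse) capped at
## 99 dB for identical images.

gaussianWindow <- function(radius = 5L, sigma = 1.5) {
  x <- (-radius):radius
  g <- exp(-x^2 / (2 * sigma^2))
  g / sum(g)
}

## separable 'valid' filtering: returns the (n - 2r) x (m - 2r) interior
filterValid <- function(img, g) {
  r <- (length(g) - 1L) / 2L
  n <- nrow(img)
  m <- ncol(img)
  if (n < length(g) || m < length(g)) {
    stop("image smaller than the SSIM window", call. = FALSE)
  }
  rowF <- matrix(0, n - 2L * r, n)
  for (i in seq_len(n - 2L * r)) rowF[i, i:(i + 2L * r)] <- g
  colF <- matrix(0, m - 2L * r, m)
  for (j in seq_len(m - 2L * r)) colF[j, j:(j + 2L * r)] <- g
  rowF %*% img %*% t(colF)
}

ssimMap <- function(x, y, dataRange = 1, k1 = 0.01, k2 = 0.03,
                    radius = 5L, sigma = 1.5) {
  g <- gaussianWindow(radius, sigma)
  c1 <- (k1 * dataRange)^2
  c2 <- (k2 * dataRange)^2
  mx <- filterValid(x, g)
  my <- filterValid(y, g)
  sxx <- filterValid(x * x, g) - mx^2
  syy <- filterValid(y * y, g) - my^2
  sxy <- filterValid(x * y, g) - mx * my
  ((2 * mx * my + c1) * (2 * sxy + c2)) /
    ((mx^2 + my^2 + c1) * (sxx + syy + c2))
}

#' Evaluate a predicted image against a reference
#'
#' @param pred,ref numeric matrices of identical shape; `ref` must not be
#'   identically zero
#' @param mask optional logical matrix restricting the correlation, l1 and
#'   pSNR pixel set (SSIM is always computed over the full valid interior)
#' @return a [MetricsRecord-class]
#' @examples
#' m <- matrix(runif(64^2), 64, 64)
#' evaluatePair(m, m) # corr 1, l1 0, ssim 1, psnr capped at 99
#' @export
evaluatePair <- function(pred, ref, mask = NULL) {
  if (!identical(dim(pred), dim(ref))) {
    stop("'pred' and 'ref' must have identical shape", call. = FALSE)
  }
  scale <- as.numeric(quantile(ref, 0.99, names = FALSE))
  if (!is.finite(scale) || scale <= 0) {
    stop("reference image has non-positive 99th percentile", call. = FALSE)
  }
  p <- pred / scale
  r <- ref / scale
  sel <- if (is.null(mask)) rep(TRUE, length(p)) else as.vector(mask)
  pv <- as.vector(p)[sel]
  rv <- as.vector(r)[sel]
  corr <- if (sd(pv) == 0 || sd(rv) == 0) {
    if (isTRUE(all.equal(pv, rv))) 1 else NA_real_
  } else {
    cor(pv, rv)
  }
  l1 <- mean(abs(pv - rv))
  rmse <- sqrt(mean((pv - rv)^2))
  psnr <- if (rmse == 0) 99 else min(20 * log10(1 / rmse), 99)
  ssim <- mean(ssimMap(p, r))
  new("MetricsRecord",
    corr = corr, l1 = l1, ssim = min(ssim, 1), psnr = psnr,
    nPixels = length(pv),
    normalization = list(
      scale = scale, rule = "99th percentile of reference",
      psnrCapDb = 99, ssimWindow = "gaussian r=5 sigma=1.5",
      masked = !is.null(mask)
    )
  )
}
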