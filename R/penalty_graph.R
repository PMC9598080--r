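## Phasor selection as a binary quadratic program.
##
## Each pixel r must pick one of its two candidate phasors. With one-hot
## selection vectors X(r) the energy is f(x) = sum over ordered neighbor
## pairs (r, s) of X(r)' V(r,s) X(s), where the 2x2 block holds the pairwise
## penalty between candidate i at r and candidate j at s:
##   V_ij(r, s) = min(|S1(r)|, |S1(s)|) / d(r, s) * |P_i(r) - P_j(s)|^2.
## Dividing by the distance makes the smoothness weight decay with pixel
## separation; the magnitude weight silences low-signal (background) pixels.

#' Neighbor offsets within a Euclidean radius
#'
#' @param radius inclusive Euclidean radius in pixels (default 4, giving the
#'   48-offset 2D neighborhood used by the selector)
#' @return a [NeighborSpec-class]
#' @examples
#' nrow(neighborSpec(4)@offsets) # 48
#' @export
neighborSpec <- function(radius = 4) {
  stopifnot(radius >= 1)
  m <- floor(radius)
  g <- expand.grid(dr = -m:m, dc = -m:m)
  d <- sqrt(g$dr^2 + g$dc^2)
  keep <- d > 0 & d <= radius
  new("NeighborSpec",
    offsets = cbind(dr = as.integer(g$dr[keep]), dc = as.integer(g$dc[keep])),
    metric = "euclidean"
  )
}

#' Build the sparse pairwise penalty graph
#'
#' For every pixel r and every offset neighbor s inside the image the 2x2
#' penalty block is stored; neighbors falling outside the image are dropped
#' (no padding or wraparound). `distanceWeight = "divide"` (default) divides
#' the magnitude weight by the pair distance; `"multiply"` is available for
#' sensitivity analyses.
#'
#' @param s1Mag magnitude of the in-phase echo (weight source)
#' @param p1,p2 candidate unit phasor maps
#' @param nbrs a [NeighborSpec-class]
#' @param distanceWeight `"divide"` or `"multiply"`
#' @return a [PenaltyGraph-class]
#' @export
buildPenaltyGraph <- function(s1Mag, p1, p2, nbrs = neighborSpec(4),
                              distanceWeight = c("divide", "multiply")) {
  distanceWeight <- match.arg(distanceWeight)
  stopifnot(
    identical(dim(s1Mag), dim(p1)),
    identical(dim(s1Mag), dim(p2))
  )
  off <- nbrs@offsets
  if (nrow(off) == 0L) stop("empty neighbor set", call. = FALSE)
  nr <- nrow(s1Mag)
  nc <- ncol(s1Mag)
  rowIdx <- matrix(seq_len(nr), nr, nc)
  colIdx <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  rs <- list()
  ss <- list()
  vs <- list()
  ws <- list()
  mag <- as.vector(s1Mag)
  p1v <- as.vector(p1)
  p2v <- as.vector(p2)
  for (k in seq_len(nrow(off))) {
    dr <- off[k, 1]
    dc <- off[k, 2]
    d <- sqrt(dr^2 + dc^2)
    okr <- rowIdx + dr >= 1L & rowIdx + dr <= nr
    okc <- colIdx + dc >= 1L & colIdx + dc <= nc
    ok <- which(okr & okc)
    if (length(ok) == 0L) next
    sidx <- ok + dr + as.integer(dc) * nr
    w <- pmin(mag[ok], mag[sidx])
    w <- if (distanceWeight == "divide") w / d else w * d
    blk <- cbind(
      v11 = w * Mod(p1v[ok] - p1v[sidx])^2,
      v12 = w * Mod(p1v[ok] - p2v[sidx])^2,
      v21 = w * Mod(p2v[ok] - p1v[sidx])^2,
      v22 = w * Mod(p2v[ok] - p2v[sidx])^2
    )
    rs[[k]] <- ok
    ss[[k]] <- sidx
    vs[[k]] <- blk
    ws[[k]] <- w
  }
  new("PenaltyGraph",
    shape = c(nr, nc), r = as.integer(unlist(rs)), s = as.integer(unlist(ss)),
    blocks = do.call(rbind, vs), weights = as.numeric(unlist(ws)),
    offsets = off
  )
}

#' @describeIn buildPenaltyGraph selection energy `f(x)` of a labeling: the
#'   sum of block entries picked by the labels over all stored ordered pairs.
#' @param graph a [PenaltyGraph-class]
#' @param labels integer matrix (or vector) of per-pixel labels in `{1, 2}`
#' @export
setMethod(
  "selectionEnergy", signature(graph = "PenaltyGraph"),
  function(graph, labels) {
    lab <- as.integer(labels)
    if (length(lab) != prod(graph@shape)) {
      stop("'labels' length does not match the graph shape", call. = FALSE)
    }
    if (!all(lab %in% c(1L, 2L))) {
      stop("labels must be 1 or 2", call. = FALSE)
    }
    if (length(graph@r) == 0L) return(0)
    ## blocks columns are (v11, v12, v21, v22), row-major in (i, j)
    idx <- (lab[graph@r] - 1L) * 2L + lab[graph@s]
    sum(graph@blocks[cbind(seq_along(idx), idx)])
  }
)

## Sparse 2N x 2N symmetric matrix view of the graph; row/col index of
## candidate i at pixel r is (i - 1) * N + r.
penaltyMatrix <- function(graph) {
  n <- prod(graph@shape)
  r <- graph@r
  s <- graph@s
  Matrix::sparseMatrix(
    i = c(r, r, n + r, n + r),
    j = c(s, n + s, s, n + s),
    x = c(graph@blocks[, 1], graph@blocks[, 2],
          graph@blocks[, 3], graph@blocks[, 4]),
    dims = c(2 * n, 2 * n)
  )
}

#' Exhaustive global minimizer of the selection energy
#'
#' Enumerates all 2^N labelings (N <= 20) and returns the global optimum;
#' among ties the lexicographically smallest label vector (candidate 1
#' preferred, earlier pixels more significant) wins. Intended as an oracle
#' for testing the iterative solver on tiny graphs.
#'
#' @param graph a [PenaltyGraph-class] with at most 20 pixels
#' @return a [SelectionMap-class]
#' @export
bruteForceSelect <- function(graph) {
  n <- prod(graph@shape)
  if (n > 20L) {
    stop("bruteForceSelect refuses graphs with more than 20 pixels",
      call. = FALSE
    )
  }
  nAssign <- 2L^n
  ## bit p of the assignment index encodes pixel p's label - 1
  bits <- matrix(0L, nAssign, n)
  for (p in seq_len(n)) {
    bits[, p] <- bitwAnd(bitwShiftR(seq_len(nAssign) - 1L, p - 1L), 1L)
  }
  energy <- numeric(nAssign)
  if (length(graph@r) > 0L) {
    for (k in seq_along(graph@r)) {
      br <- bits[, graph@r[k]]
      bs <- bits[, graph@s[k]]
      v <- graph@blocks[k, ]
      energy <- energy +
        v[1] * (1 - br) * (1 - bs) + v[2] * (1 - br) * bs +
        v[3] * br * (1 - bs) + v[4] * br * bs
    }
  }
  best <- min(energy)
  cand <- which(energy <= best + 0)
  ## lexicographic tie-break: pixel 1 most significant, label 1 preferred
  if (length(cand) > 1L) {
    ord <- do.call(order, c(
      lapply(seq_len(n), function(p) bits[cand, p]),
      list(method = "radix")
    ))
    cand <- cand[ord[1L]]
  }
  lab <- bits[cand[1L], ] + 1L
  new("SelectionMap",
    labels = matrix(as.integer(lab), graph@shape[1], graph@shape[2]),
    energy = best, converged = TRUE, iterations = 1L, history = best
  )
}
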