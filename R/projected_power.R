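## Projected power iteration for the phasor-selection energy.
##
## At one-hot selections the penalty energy decomposes per ordered pair as
## V_ij = w |P_i(r) - P_j(s)|^2 = 2 w - 2 w Re(P_i(r) conj(P_j(s))), so
## minimizing f(x) = x' V x is equivalent to maximizing the phasor-agreement
## quadratic form x' A x with A_ij = w Re(P_i(r) conj(P_j(s))) (the 2 w term
## sums to a labeling-independent constant). The solver runs a projected
## power iteration on A over the relaxed feasible set -- per-pixel
## non-negative 2-vectors of unit Euclidean norm, started from the uniform
## (uncommitted) state -- which lets phasor consensus propagate across the
## neighbor graph instead of being trapped in the one-hot corners. The
## binarized consensus and the two canonical one-hot labelings are then each
## polished by coordinate sweeps over mutually non-adjacent pixel classes
## (every accepted flip strictly decreases the energy), and the lowest-energy
## result is returned with a non-increasing energy history.
##
## All quadratic-form multiplies run on the graph's pair lists via grouped
## accumulation (rowsum), which profiles far faster than assembling sparse
## matrices per call.

## y = (M + M') / 2 x for the 2N x 2N block matrix M defined by per-pair
## 2x2 blocks (columns b11, b12, b21, b22); x given as two length-N halves.
pairMV <- function(r, s, b, x1, x2, n) {
  acc <- function(v, g) {
    out <- numeric(n)
    t <- rowsum(v, g)
    out[as.integer(rownames(t))] <- t
    out
  }
  y1 <- acc(b[, 1] * x1[s] + b[, 2] * x2[s], r) +
    acc(b[, 1] * x1[r] + b[, 3] * x2[r], s)
  y2 <- acc(b[, 3] * x1[s] + b[, 4] * x2[s], r) +
    acc(b[, 2] * x1[r] + b[, 4] * x2[r], s)
  list(y1 = y1 / 2, y2 = y2 / 2)
}

## Incidence index of pairs by each endpoint, for incremental pull updates.
pairIncidence <- function(graph, n) {
  list(
    byS = split(seq_along(graph@s), factor(graph@s, levels = seq_len(n))),
    byR = split(seq_along(graph@r), factor(graph@r, levels = seq_len(n)))
  )
}

## Exact incremental update of the symmetrized pull matrix after flipping
## the labels of `idx` (mutually non-adjacent pixels) from oldL to newL.
updatePull <- function(pull, graph, inc, idx, oldL, newL) {
  b <- graph@blocks
  ## pairs whose s endpoint flipped affect the row part of pull at r
  ks <- inc$byS[idx]
  reps <- lengths(ks)
  ks <- unlist(ks, use.names = FALSE)
  if (length(ks)) {
    o <- rep(oldL, reps)
    nw <- rep(newL, reps)
    d1 <- (b[cbind(ks, nw)] - b[cbind(ks, o)]) / 2
    d2 <- (b[cbind(ks, 2L + nw)] - b[cbind(ks, 2L + o)]) / 2
    tgt <- graph@r[ks]
    t1 <- rowsum(d1, tgt)
    t2 <- rowsum(d2, tgt)
    rows <- as.integer(rownames(t1))
    pull[rows, 1] <- pull[rows, 1] + t1
    pull[rows, 2] <- pull[rows, 2] + t2
  }
  ## pairs whose r endpoint flipped affect the transpose part at s
  kr <- inc$byR[idx]
  repsR <- lengths(kr)
  kr <- unlist(kr, use.names = FALSE)
  if (length(kr)) {
    o <- rep(oldL, repsR)
    nw <- rep(newL, repsR)
    d1 <- (b[cbind(kr, 2L * nw - 1L)] - b[cbind(kr, 2L * o - 1L)]) / 2
    d2 <- (b[cbind(kr, 2L * nw)] - b[cbind(kr, 2L * o)]) / 2
    tgt <- graph@s[kr]
    t1 <- rowsum(d1, tgt)
    t2 <- rowsum(d2, tgt)
    rows <- as.integer(rownames(t1))
    pull[rows, 1] <- pull[rows, 1] + t1
    pull[rows, 2] <- pull[rows, 2] + t2
  }
  pull
}

## Sparse agreement matrix view of a graph (used by tests and diagnostics).
## When the graph carries its pair weights the entries are exactly
## w - V_ij / 2; hand-built graphs without weights fall back to a per-pair
## scale max(V_ij) / 4 (the weight a maximally opposed phasor pair implies).
agreementMatrix <- function(graph) {
  n <- prod(graph@shape)
  if (length(graph@r) == 0L) {
    return(Matrix::sparseMatrix(
      i = integer(), j = integer(), x = numeric(), dims = c(2 * n, 2 * n)
    ))
  }
  a <- agreementBlocks(graph)
  r <- graph@r
  s <- graph@s
  Matrix::sparseMatrix(
    i = c(r, r, n + r, n + r),
    j = c(s, n + s, s, n + s),
    x = c(a[, 1], a[, 2], a[, 3], a[, 4]),
    dims = c(2 * n, 2 * n)
  )
}

agreementBlocks <- function(graph) {
  if (length(graph@r) == 0L) return(graph@blocks)
  w <- if (length(graph@weights)) {
    graph@weights
  } else {
    apply(graph@blocks, 1, max) / 4
  }
  w - graph@blocks / 2
}

#' Solve the phasor-selection problem by projected power iteration
#'
#' Minimizes the binary quadratic selection energy of a [PenaltyGraph-class]
#' over per-pixel one-hot candidate selections. With `init = "default"` the
#' solver refines three candidate labelings -- the binarized relaxed
#' projected power consensus plus the two canonical initializations (all
#' candidate 1, all candidate 2) -- and returns the lowest-energy result; an
#' explicit integer label map may be supplied instead.
#'
#' @details The relaxed phase iterates `Y <- A X` on per-pixel 2-vectors,
#' where `A` is the pairwise phasor-agreement matrix (equivalent to the
#' negated penalty up to a labeling-independent constant at one-hot points):
#' negative components are clamped to zero and each pixel's vector is
#' renormalized to unit length, starting from the uncommitted uniform state;
#' a pixel whose vector vanishes keeps its previous state and the previous
#' label is kept on exact ties. Discrete refinement then sweeps classes of
#' mutually non-neighboring pixels, each accepted flip strictly decreasing
#' the energy, so the recorded history never increases.
#'
#' @param graph a [PenaltyGraph-class]
#' @param init `"default"` or an integer matrix/vector of labels in `{1, 2}`
#' @param maxIter maximum relaxed iterations (and refinement sweeps)
#' @param seed seed for the random-restart refinements
#' @param nRestarts number of additional seeded random-start refinements;
#'   `"auto"` (default) uses more restarts on small graphs, where the few
#'   neighbor pairs give the consensus phase little to propagate, and none
#'   on large images
#' @return a [SelectionMap-class]; `energy` equals
#'   `selectionEnergy(graph, labels)` exactly and `history` is non-increasing
#' @export
projectedPowerSelect <- function(graph, init = "default", maxIter = 100L,
                                 seed = 1L, nRestarts = "auto") {
  if (maxIter < 1L) stop("'maxIter' must be >= 1", call. = FALSE)
  n <- prod(graph@shape)
  scale <- if (length(graph@r)) max(graph@blocks) else 0
  tol <- 1e-10 * max(1, scale)

  ## independence classes: pixels whose (row, col) agree modulo a stride
  ## exceeding the largest offset cannot be neighbors
  strideR <- max(abs(graph@offsets[, 1]), 0L) + 1L
  strideC <- max(abs(graph@offsets[, 2]), 0L) + 1L
  ri <- (seq_len(n) - 1L) %% graph@shape[1]
  ci <- (seq_len(n) - 1L) %/% graph@shape[1]
  classes <- split(seq_len(n), (ri %% strideR) + strideR * (ci %% strideC))

  relaxedPhase <- function() {
    ab <- agreementBlocks(graph)
    x1 <- rep(1 / sqrt(2), n)
    x2 <- x1
    prevLab <- rep(1L, n)
    changes <- 0L
    for (it in seq_len(maxIter)) {
      mv <- pairMV(graph@r, graph@s, ab, x1, x2, n)
      y1 <- pmax(mv$y1, 0)
      y2 <- pmax(mv$y2, 0)
      nrm <- sqrt(y1^2 + y2^2)
      dead <- nrm == 0
      if (any(dead)) {
        y1[dead] <- x1[dead]
        y2[dead] <- x2[dead]
        nrm[dead] <- sqrt(x1[dead]^2 + x2[dead]^2)
      }
      x1 <- y1 / nrm
      x2 <- y2 / nrm
      lab <- ifelse(x2 > x1, 2L, ifelse(x1 > x2, 1L, prevLab))
      stable <- identical(lab, prevLab) && it > 1L
      if (!identical(lab, prevLab)) changes <- changes + 1L
      prevLab <- lab
      if (stable) break
    }
    list(labels = prevLab, changes = changes)
  }

  inc <- pairIncidence(graph, n)

  ## Monotone coordinate refinement: sweeps over independence classes with
  ## an exact incrementally maintained pull matrix; flipping pixel r changes
  ## the energy by twice the change in its symmetrized pull, so only strict
  ## improvements flip and every recorded sweep decreases the energy.
  refine <- function(lab0, changes0 = 0L) {
    labels <- lab0
    history <- selectionEnergy(graph, labels)
    mv <- pairMV(
      graph@r, graph@s, graph@blocks,
      as.numeric(labels == 1L), as.numeric(labels == 2L), n
    )
    pull <- cbind(mv$y1, mv$y2)
    sweeps <- 0L
    converged <- FALSE
    for (sw in seq_len(maxIter)) {
      flips <- 0L
      for (cl in classes) {
        cur <- pull[cbind(cl, labels[cl])]
        oth <- pull[cbind(cl, 3L - labels[cl])]
        improve <- oth < cur - tol
        if (any(improve)) {
          idx <- cl[improve]
          oldL <- labels[idx]
          labels[idx] <- 3L - oldL
          pull <- updatePull(pull, graph, inc, idx, oldL, labels[idx])
          flips <- flips + length(idx)
        }
      }
      if (flips == 0L) {
        converged <- TRUE
        break
      }
      sweeps <- sweeps + 1L
      history <- c(history, selectionEnergy(graph, labels))
    }
    list(
      labels = labels, energy = selectionEnergy(graph, labels),
      converged = converged, iterations = max(1L, changes0 + sweeps),
      history = history
    )
  }

  runs <- if (identical(init, "default")) {
    if (identical(nRestarts, "auto")) {
      nRestarts <- min(8L, max(0L, 1024L %/% n))
    }
    relaxed <- relaxedPhase()
    base <- list(
      refine(relaxed$labels, relaxed$changes),
      refine(rep(1L, n)),
      refine(rep(2L, n))
    )
    extra <- if (nRestarts > 0L) {
      starts <- withSeed(
        seed,
        lapply(seq_len(nRestarts), function(i) {
          sample(c(1L, 2L), n, replace = TRUE)
        })
      )
      lapply(starts, refine)
    } else {
      list()
    }
    c(base, extra)
  } else {
    lab0 <- as.integer(init)
    if (length(lab0) == 1L) lab0 <- rep(lab0, n)
    if (length(lab0) != n || !all(lab0 %in% c(1L, 2L))) {
      stop("'init' must be \"default\" or a full label map in {1, 2}",
        call. = FALSE
      )
    }
    list(refine(lab0))
  }
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "energy"))]]
  new("SelectionMap",
    labels = matrix(best$labels, graph@shape[1], graph@shape[2]),
    energy = best$energy, converged = best$converged,
    iterations = best$iterations, history = best$history
  )
}
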