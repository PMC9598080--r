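# Shared fixtures, all generated in code.

# acquisition with exactly in-phase / opposed-phase dephasing (C1 = 1,
# C2 = -1): fat offset -250 Hz, TE1 two full cycles, TE2 half a cycle
classicParams <- function() {
  acquisitionParams(
    te1 = 8, te2 = 2, fieldStrength = 250 / 42.577, fatShiftPpm = -1
  )
}

# random unit-phasor penalty graph, the regime the selector is designed for
randomPhasorGraph <- function(nr, nc, seed, radius = 4) {
  withr::with_seed(seed, {
    p1 <- matrix(exp(1i * runif(nr * nc, -pi, pi)), nr, nc)
    p2 <- matrix(exp(1i * runif(nr * nc, -pi, pi)), nr, nc)
    s1m <- matrix(runif(nr * nc, 0.2, 1), nr, nc)
    buildPenaltyGraph(s1m, p1, p2, neighborSpec(radius))
  })
}

# true candidate labels of a noiseless phantom acquisition
trueLabels <- function(truth, img) {
  p <- acqParams(img)
  cc <- dephasingFactors(p)
  cand <- phasorCandidates(
    img, amplitudeCandidates(Mod(s1(img)), Mod(s2(img)), cc[1], cc[2]),
    cc[1], cc[2]
  )
  pTrue <- exp(1i * 2 * pi * b0Hz(truth) * (p@te2 - p@te1) * 1e-3)
  list(
    labels = matrix(
      ifelse(Mod(cand@p2 - pTrue) < Mod(cand@p1 - pTrue), 2L, 1L),
      nrow(pTrue), ncol(pTrue)
    ),
    cand = cand, pTrue = pTrue
  )
}
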