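# Independent oracles used to cross-check the package's implementations.
# These deliberately avoid the code paths they validate.

# Brute-force coarse-grid + refinement search for the one-path circuit
# parameters: direct SSR evaluation on a shrinking log-spaced grid.
oracleGridFit <- function(freqs, z, iters = 8L, nGrid = 13L) {
  n <- length(freqs)
  rSub0 <- max(Re(z)[n], 1e-6)
  rEpi0 <- max(Re(z)[1] - rSub0, 1e-6)
  cap0 <- 1 / (2 * pi * freqs[which.max(-Im(z))] * rEpi0)
  ctr <- c(rSub0, rEpi0, cap0)
  span <- 5
  for (it in seq_len(iters)) {
    grids <- lapply(ctr, function(c0)
      exp(seq(log(c0 / span), log(c0 * span), length.out = nGrid)))
    combos <- expand.grid(rSub = grids[[1]], rEpi = grids[[2]],
                          cap = grids[[3]])
    ssr <- numeric(nrow(combos))
    for (k in seq_along(freqs)) {
      zm <- combos$rSub + combos$rEpi /
        (1 + 1i * 2 * pi * freqs[k] * combos$rEpi * combos$cap)
      ssr <- ssr + Mod(zm - z[k])^2
    }
    ctr <- as.numeric(combos[which.min(ssr), ])
    ratio <- span^(2 / (nGrid - 1))
    span <- ratio^2
  }
  names(ctr) <- c("rSub", "rEpi", "cap")
  ctr
}

# Exhaustive hypergeometric upper tail P(X >= kObs) by direct enumeration
# of the probability mass (choose() arithmetic, no phyper).
oracleHyperTail <- function(N, K, n, kObs) {
  up <- min(K, n)
  if (kObs > up) return(0)
  ks <- seq.int(kObs, up)
  ks <- ks[ks >= max(0, n - (N - K))]
  if (!length(ks)) return(0)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Discretized surface integration of the crypt geometry: polygonal
# approximations of the crypt opening, wall and bottom, summed per cm2 of
# serosal plane.
oracleMeshSurfaceRatio <- function(dUm, LUm, nDens,
                                   bottom = c("flat", "hemisphere"),
                                   nTheta = 2000L, nPhi = 2000L) {
  bottom <- match.arg(bottom)
  R <- dUm * 1e-4 / 2
  L <- LUm * 1e-4
  polyDisk <- 0.5 * nTheta * R^2 * sin(2 * pi / nTheta)
  chordPerim <- nTheta * 2 * R * sin(pi / nTheta)
  wall <- chordPerim * L
  bottomA <- if (bottom == "flat") polyDisk else {
    dphi <- (pi / 2) / nPhi
    phis <- (seq_len(nPhi) - 0.5) * dphi
    sum(R * sin(phis) * R * dphi) * (2 * pi / nTheta) * nTheta
  }
  1 - nDens * polyDisk + nDens * (wall + bottomA)
}

# convenience: random one-path parameter triples in physiological ranges
randomCircuitTriples <- function(n, seed) {
  set.seed(seed)
  data.frame(rSub = runif(n, 5, 40), rEpi = runif(n, 10, 120),
             cap = runif(n, 0.5e-6, 10e-6))
}
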