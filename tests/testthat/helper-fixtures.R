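# shared in-code fixtures: small grids, random fields, toy cohorts

fullMask <- function(dims, spacing = c(1, 1, 1)) {
  brainMask(array(TRUE, dim = dims), spacing = spacing)
}

randomField <- function(dims, spacing = c(1, 1, 1), sd = 1) {
  vectorField(array(rnorm(prod(dims) * 3, sd = sd), dim = c(dims, 3L)),
              spacing = spacing)
}

randomCohort <- function(n, dims, spacing = c(1, 1, 1), seed = 1) {
  set.seed(seed)
  mask <- fullMask(dims, spacing)
  fields <- lapply(seq_len(n), function(i) randomField(dims, spacing))
  list(cohort = assembleCohort(fields, mask), mask = mask, fields = fields)
}

# small synthetic study used by several locpca tests (ellipsoid mask)
smallStudy <- function(seed = 0, n = 20, grid = c(6L, 6L, 6L)) {
  cfg <- simConfig(n = n, m = 10L, grid = grid, spacing = c(2, 2, 2),
                   effectRadiusMm = 2, seed = seed)
  g <- simulateGenotypes(cfg)
  sim <- simulateFields(cfg, g)
  cohort <- assembleCohort(sim$fields, sim$mask, sampleInfo(g)$iid)
  list(cfg = cfg, g = g, sim = sim, cohort = cohort, mask = sim$mask)
}

# dense reference: sample covariance of the (centered) cohort matrix
denseCovariance <- function(X) {
  Z <- sweep(X, 2L, colMeans(X))
  crossprod(Z) / (nrow(X) - 1L)
}

# largest principal angle (radians) between two orthonormal column spans
maxPrincipalAngle <- function(Q1, Q2) {
  s <- svd(crossprod(Q1, Q2))$d
  acos(min(1, max(0, min(s))))
}

# direct-formula HWE enumeration oracle (independent of the recurrence)
hweOracle <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  nA <- 2 * n0 + n1; nB <- 2 * n2 + n1
  r <- min(nA, nB)
  hs <- seq.int(r %% 2, r, by = 2)
  lp <- vapply(hs, function(h) {
    hA <- (nA - h) / 2; hB <- (nB - h) / 2
    lfactorial(n) - lfactorial(hA) - lfactorial(h) - lfactorial(hB) +
      h * log(2) + lfactorial(nA) + lfactorial(nB) - lfactorial(2 * n)
  }, 0)
  pr <- exp(lp)
  sum(pr[pr <= pr[match(n1, hs)] * (1 + 1e-9)])
}
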