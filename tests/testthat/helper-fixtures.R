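# Shared fixtures and independent oracles used across the suite.

REF <- mitoReference()
ANN <- mitoAnnotation()

# transition-profile at given positions (fast path used by generators)
tprof <- function(pos, region = "complete") {
  variantProfile(mitophylo:::.transitionEvents(pos, REF), region)
}

# random incompatible-site instances for the parsimony oracle harness
randomMpInstance <- function(seed, n = 5L, nsites = 6L, p = 0.45) {
  set.seed(seed)
  pool <- sample(setdiff(600:4000, 16519L), nsites)
  profs <- lapply(seq_len(n), function(i) tprof(pool[runif(nsites) < p]))
  names(profs) <- paste0("s", seq_len(n))
  profs
}

# homoplasy-free instances: mutations dropped down a random genealogy under
# infinite sites are always compatible
coalescentMpInstance <- function(seed, n = 6L, theta = 4) {
  sim <- simulateCoalescentSample(n = n, theta = theta, seed = seed,
                                  region = "complete")
  m <- sampleIncidence(sim$sample)
  profs <- lapply(seq_len(ncol(m)), function(j)
    tprof(as.integer(rownames(m)[m[, j] == 1L])))
  names(profs) <- colnames(m)
  profs
}

# brute-force small-parsimony oracle on a fixed topology: enumerate all
# internal-state assignments per site (root state fixed) and take the
# minimum number of state changes
bruteForceTreeScore <- function(tree, profiles) {
  sd <- mitophylo:::.siteData(profiles[tipLabels(tree)], tree@rootEvents)
  if (length(sd$sites) == 0L) return(0L)
  parent <- tree@parent
  tipCol <- mitophylo:::.treeTipCol(tree)
  internal <- which(is.na(tipCol) & seq_along(parent) > 1L)
  total <- 0L
  for (s in seq_along(sd$sites)) {
    best <- Inf
    for (mask in 0:(2^length(internal) - 1L)) {
      st <- logical(length(parent))
      st[1L] <- sd$rootStates[s]
      if (length(internal))
        st[internal] <- as.logical(bitwAnd(mask, 2^(seq_along(internal) -
                                                      1L)) > 0L)
      st[!is.na(tipCol)] <- sd$tipStates[s, tipCol[!is.na(tipCol)]]
      changes <- sum(st[-1L] != st[parent[-1L]])
      best <- min(best, changes)
    }
    total <- total + best
  }
  total
}

# exact (non-log) Ewens distribution for small n: Stirling numbers by the
# plain recursion in double precision
exactEwensPK <- function(n, theta) {
  S <- matrix(0, n, n)
  S[1, 1] <- 1
  if (n >= 2) for (m in 2:n) {
    for (k in 1:m) {
      S[m, k] <- (if (k > 1) S[m - 1, k - 1] else 0) +
        (m - 1) * S[m - 1, k]
    }
  }
  S[n, ] * theta^(1:n) / prod(theta + 0:(n - 1))
}

# direct textbook evaluation of Tajima's D from a pairwise double loop
oracleTajimaD <- function(sample) {
  m <- sampleIncidence(sample)
  n <- ncol(m)
  diffs <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n)
    diffs <- c(diffs, sum(m[, i] != m[, j]))
  Pi <- mean(diffs)
  rs <- rowSums(m)
  S <- sum(rs > 0 & rs < n)
  if (S == 0) return(NA_real_)
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (Pi - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}
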