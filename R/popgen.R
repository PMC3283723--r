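#' Construct a PopulationSample
#'
#' Builds the binary site-by-individual incidence matrix from haplotype
#' variant profiles. By default only substitution events define sites
#' (indels are excluded from the diversity arithmetic, matching the
#' phylogenetic exclusion philosophy); set \code{includeIndels = TRUE} to
#' treat indel tokens as additional binary sites.
#'
#' @param haplotypes named list of [VariantProfile-class] objects / event
#'   tables / token character vectors, one per individual.
#' @param name population name.
#' @param region analysis region.
#' @param includeIndels include indel events as sites.
#' @param reference reference for token parsing.
#' @return a [PopulationSample-class].
#' @export
populationSample <- function(haplotypes, name = "pop", region = "HVS1",
                             includeIndels = FALSE,
                             reference = mitoReference()) {
  keyList <- lapply(haplotypes, function(h) {
    ev <- if (is.character(h)) parseVariant(h, reference) else .profEvents(h)
    if (!includeIndels)
      ev <- ev[ev$kind %in% c("transition", "transversion"), , drop = FALSE]
    eventKey(ev)
  })
  ids <- names(haplotypes)
  if (is.null(ids)) ids <- paste0("h", seq_along(haplotypes))
  sites <- sort(unique(unlist(keyList)))
  m <- matrix(0L, length(sites), length(keyList),
              dimnames = list(sites, ids))
  for (j in seq_along(keyList)) m[keyList[[j]], j] <- 1L
  new("PopulationSample", name = name, incidence = m, region = region)
}

.pairwiseDiffs <- function(m) {
  if (nrow(m) == 0L)
    return(stats::as.dist(matrix(0, ncol(m), ncol(m))))
  stats::dist(t(m), method = "manhattan")
}

#' Haplotype diversity summary
#'
#' K distinct haplotypes; sequence (haplotype) diversity
#' \eqn{H = n(1 - \sum p_j^2)/(n-1)} with Nei's sampling standard error;
#' S segregating sites; mean pairwise differences Pi with the
#' no-recombination (total) variance standard error.
#'
#' @param x a [PopulationSample-class] (n >= 2).
#' @return list with n, K, H, Hse, S, Pi, PiSE.
#' @export
haplotypeStats <- function(x) {
  m <- sampleIncidence(x)
  n <- ncol(m)
  if (n < 2L) stop("diversity statistics need n >= 2")
  hap <- apply(m, 2L, paste, collapse = "")
  p <- as.numeric(table(hap)) / n
  K <- length(p)
  sum2 <- sum(p^2); sum3 <- sum(p^3)
  H <- n * (1 - sum2) / (n - 1)
  Vh <- 2 / (n * (n - 1)) *
    (2 * (n - 2) * (sum3 - sum2^2) + sum2 - sum2^2)
  rs <- rowSums(m)
  S <- sum(rs > 0L & rs < n)
  Pi <- mean(.pairwiseDiffs(m))
  Vpi <- (3 * n * (n + 1) * Pi + 2 * (n^2 + n + 3) * Pi^2) /
    (11 * (n^2 - 7 * n + 6))
  list(n = n, K = K, H = H, Hse = sqrt(max(Vh, 0)), S = S, Pi = Pi,
       PiSE = sqrt(max(Vpi, 0)))
}

.logadd <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log1p(exp(pmin(a, b) - m))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

# log unsigned Stirling numbers of the first kind |S1(n, k)|, k = 1..n,
# computed with the two-term recursion in log space (cached per n)
.logStirling1 <- function(n) {
  key <- as.character(n)
  if (is.null(.pkgCache$stirling)) .pkgCache$stirling <- list()
  if (!is.null(.pkgCache$stirling[[key]])) return(.pkgCache$stirling[[key]])
  L <- 0                              # n = 1: |S1(1,1)| = 1
  if (n >= 2L) for (m in 2:n) {
    prev <- c(L, -Inf)                # |S1(m-1, k)|, k = 1..m
    shifted <- c(-Inf, L)             # |S1(m-1, k-1)|
    L <- .logadd(shifted, log(m - 1) + prev)
  }
  .pkgCache$stirling[[key]] <- L
  L
}

#' Ewens sampling-formula probability of K haplotypes
#'
#' \eqn{P(K \mid \theta, n) = |S_1(n,K)| \theta^K / \prod_{i=0}^{n-1}
#' (\theta + i)}, evaluated in log space (unsigned Stirling numbers of the
#' first kind by the log-sum-exp recursion), so that n in the hundreds is
#' safe. The distribution over K = 1..n sums to one.
#'
#' @param n sample size.
#' @param K number of distinct haplotypes (vectorised).
#' @param theta scaled mutation parameter (> 0).
#' @param log return log probabilities.
#' @return numeric vector of probabilities.
#' @export
ewensPK <- function(n, K, theta, log = FALSE) {
  stopifnot(n >= 1L, all(K >= 1L), all(K <= n), theta > 0)
  lS <- .logStirling1(n)
  denom <- sum(base::log(theta + 0:(n - 1L)))
  lp <- lS[K] + K * base::log(theta) - denom
  if (log) lp else exp(lp)
}

#' Ewens theta estimate from the number of haplotypes
#'
#' Solves \eqn{E[K \mid \theta, n] = \sum_{i=0}^{n-1} \theta/(\theta+i) = K}
#' for theta (bisection/uniroot to 1e-6), with a 95\% CI obtained by
#' inverting the Ewens distribution of K: the bounds are the theta values at
#' which the upper (resp. lower) tail probability of the observed K equals
#' 0.025.
#'
#' @param n sample size.
#' @param K observed number of distinct haplotypes.
#' @return list with \code{theta}, \code{ciLow}, \code{ciHigh}. K = 1 gives
#'   theta = 0; K = n gives theta = Inf (every individual distinct carries
#'   no upper information).
#' @examples
#' thetaK(149, 97)   # theta approximately 119.4
#' @export
thetaK <- function(n, K) {
  stopifnot(n >= 1L, K >= 1L, K <= n)
  expK <- function(theta) sum(theta / (theta + 0:(n - 1L)))
  est <- if (K == 1L) 0 else if (K == n) Inf else {
    hi <- 1
    while (expK(hi) < K) hi <- hi * 2
    stats::uniroot(function(t) expK(t) - K, c(1e-9, hi),
                   tol = 1e-6)$root
  }
  upperTail <- function(theta)        # P(K' >= K | theta)
    sum(ewensPK(n, K:n, theta))
  lowerTail <- function(theta)        # P(K' <= K | theta)
    sum(ewensPK(n, 1L:K, theta))
  ciLow <- if (K == 1L) 0 else {
    lo <- 1e-6
    hi <- if (is.finite(est) && est > lo) est else n^2
    stats::uniroot(function(t) upperTail(t) - 0.025, c(lo, hi),
                   tol = 1e-6)$root
  }
  ciHigh <- if (K == n) Inf else {
    lo <- max(est, 1e-6); hi <- max(4 * lo, 8)
    while (lowerTail(hi) > 0.025 && hi < 1e8) hi <- hi * 2
    stats::uniroot(function(t) lowerTail(t) - 0.025, c(lo, hi),
                   tol = 1e-6)$root
  }
  list(theta = est, ciLow = ciLow, ciHigh = ciHigh)
}

.tajimaConstants <- function(n) {
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D
#'
#' \eqn{D = (\Pi - S/a_1) / \sqrt{e_1 S + e_2 S (S-1)}} with the 1989
#' constants computed from n. Undefined (NA) when S = 0.
#'
#' @param x a [PopulationSample-class], or a list with elements \code{n},
#'   \code{S}, \code{Pi} (so the statistic can be computed from printed
#'   summary values).
#' @return numeric D (NA if S = 0).
#' @export
tajimasD <- function(x) {
  st <- if (is(x, "PopulationSample")) haplotypeStats(x) else x
  if (st$S == 0L) return(NA_real_)
  cc <- .tajimaConstants(st$n)
  (st$Pi - st$S / cc$a1) /
    sqrt(cc$e1 * st$S + cc$e2 * st$S * (st$S - 1))
}

#' Fu's Fs
#'
#' \eqn{S' = P(K' \ge K_{obs} \mid \theta = \Pi, n)} under the Ewens
#' sampling formula, and \eqn{F_s = \ln(S'/(1-S'))}. Strongly negative when
#' the sample carries more haplotypes than its pairwise diversity predicts
#' (the genealogical signature of a recent expansion). Undefined (NA) when
#' Pi = 0; returns -Inf/+Inf if S' underflows to 0 or rounds to 1.
#'
#' @param x a [PopulationSample-class], or a list with \code{n}, \code{K},
#'   \code{Pi}.
#' @return numeric Fs.
#' @export
fusFs <- function(x) {
  st <- if (is(x, "PopulationSample")) haplotypeStats(x) else x
  if (st$Pi <= 0) return(NA_real_)
  lp <- ewensPK(st$n, st$K:st$n, st$Pi, log = TRUE)
  logSp <- Reduce(.logadd, lp)
  if (logSp >= 0) return(Inf)
  if (is.infinite(logSp)) return(-Inf)
  # ln(S'/(1-S')) computed stably in log space
  logSp - log1p(-exp(logSp))
}

#' Two-tailed Fisher's exact test for a 2x2 table
#'
#' Sums the hypergeometric probabilities (margins fixed) of every table at
#' most as probable as the observed one.
#'
#' @param a,b,c,d counts of the table \code{rbind(c(a, b), c(c, d))}.
#' @return two-tailed P value.
#' @examples
#' fisherExact2x2(13, 136, 1, 97)   # about 0.01
#' @export
fisherExact2x2 <- function(a, b, c, d) {
  cnt <- c(a, b, c, d)
  stopifnot(all(cnt >= 0), all(cnt == round(cnt)))
  m <- matrix(cnt, nrow = 2L, byrow = TRUE)
  if (any(rowSums(m) == 0L) || any(colSums(m) == 0L))
    stop("zero margin in 2x2 table")
  stats::fisher.test(m)$p.value
}
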