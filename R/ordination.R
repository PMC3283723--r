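#' Pairwise FST between two population samples
#'
#' Hudson-style estimator from mean pairwise haplotype differences:
#' \eqn{F_{ST} = (\pi_B - \bar\pi_W)/\pi_B} where \eqn{\pi_B} is the mean
#' number of differences across population pairs and \eqn{\bar\pi_W} the
#' average of the two within-population means. Distances are plain numbers
#' of differing sites (no substitution-model correction). Small negative
#' values are returned as computed; if every sequence is identical
#' (\eqn{\pi_B = 0}) the value is 0.
#'
#' @param a,b [PopulationSample-class] objects over the same region
#'   (n >= 2 each).
#' @return numeric FST.
#' @export
pairwiseFst <- function(a, b) {
  ma <- sampleIncidence(a); mb <- sampleIncidence(b)
  if (ncol(ma) < 2L || ncol(mb) < 2L) stop("each population needs n >= 2")
  sites <- union(rownames(ma), rownames(mb))
  pad <- function(m) {
    out <- matrix(0L, length(sites), ncol(m),
                  dimnames = list(sites, colnames(m)))
    if (nrow(m)) out[rownames(m), ] <- m
    out
  }
  M <- cbind(pad(ma), pad(mb))
  D <- as.matrix(.pairwiseDiffs(M))
  ia <- seq_len(ncol(ma)); ib <- ncol(ma) + seq_len(ncol(mb))
  piA <- mean(D[ia, ia][upper.tri(D[ia, ia])])
  piB <- mean(D[ib, ib][upper.tri(D[ib, ib])])
  piBetween <- mean(D[ia, ib])
  if (piBetween == 0) return(0)
  (piBetween - (piA + piB) / 2) / piBetween
}

#' Pairwise FST matrix
#'
#' @param populations list of [PopulationSample-class] objects (>= 2).
#' @param floorNegative floor small negative estimates at 0 (done for
#'   ordination input; raw values are returned when FALSE).
#' @return symmetric matrix with zero diagonal, labelled by population name.
#' @export
fstMatrix <- function(populations, floorNegative = FALSE) {
  k <- length(populations)
  if (k < 2L) stop("need >= 2 populations")
  labs <- vapply(populations, function(p) p@name, "")
  m <- matrix(0, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    f <- pairwiseFst(populations[[i]], populations[[j]])
    m[i, j] <- m[j, i] <- f
  }
  if (floorNegative) m[m < 0] <- 0
  m
}

#' Nonmetric multidimensional scaling of a distance matrix
#'
#' Kruskal stress-1 minimisation (vegan's monotone-regression majorization),
#' started from the classical-scaling configuration plus seeded random
#' restarts; the best (lowest-stress) configuration is kept. Negative input
#' distances are floored at 0.
#'
#' @param d symmetric distance matrix or \code{dist}.
#' @param dims embedding dimension (default 2).
#' @param seed RNG seed for the random restarts.
#' @param restarts number of random restarts (default 8).
#' @return list with \code{points} (rows = objects), \code{stress} and
#'   \code{converged}.
#' @export
nmdsOrdination <- function(d, dims = 2L, seed = 1L, restarts = 8L) {
  m <- as.matrix(d)
  m[m < 0] <- 0
  labs <- rownames(m)
  if (all(m == 0)) {
    warning("all-zero distance matrix: returning the null configuration")
    pts <- matrix(0, nrow(m), dims,
                  dimnames = list(labs, paste0("Dim", seq_len(dims))))
    return(list(points = pts, stress = 0, converged = TRUE))
  }
  dd <- stats::as.dist(m)
  init <- stats::cmdscale(dd, k = dims)
  if (ncol(init) < dims)
    init <- cbind(init, matrix(0, nrow(init), dims - ncol(init)))
  fits <- list(vegan::monoMDS(dd, y = init, k = dims, model = "global"))
  for (r in seq_len(restarts)) {
    set.seed(seed + r)
    y0 <- matrix(stats::rnorm(nrow(m) * dims), ncol = dims)
    fits[[r + 1L]] <- vegan::monoMDS(dd, y = y0, k = dims, model = "global")
  }
  stress <- vapply(fits, function(f) f$stress, 0)
  best <- fits[[which.min(stress)]]
  pts <- best$points
  rownames(pts) <- labs
  list(points = pts, stress = best$stress,
       converged = isTRUE(best$converged) || best$stress < 1e-6)
}

#' PCA of haplogroup frequency vectors
#'
#' Eigen-decomposition of the covariance of the column-centred (not scaled)
#' population-by-haplogroup frequency matrix.
#'
#' @param freqMatrix numeric matrix, populations x haplogroups (frequencies
#'   or percentages).
#' @param k number of components to return (default: all).
#' @return list with \code{scores}, \code{loadings} and \code{percentVar}
#'   (percent of total variance per PC; sums to 100 over all components).
#' @export
pcaOrdination <- function(freqMatrix, k = NULL) {
  m <- as.matrix(freqMatrix)
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("need >= 2 populations and >= 2 haplogroups")
  if (all(apply(m, 2L, stats::var) == 0)) stop("constant input matrix")
  fit <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  pct <- 100 * fit$sdev^2 / sum(fit$sdev^2)
  if (is.null(k)) k <- length(fit$sdev)
  k <- min(k, length(fit$sdev))
  list(scores = fit$x[, seq_len(k), drop = FALSE],
       loadings = fit$rotation[, seq_len(k), drop = FALSE],
       percentVar = pct)
}
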