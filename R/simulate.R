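# Synthetic-data generators. These define the study conditions every
# downstream estimator is tested against: star-like clades of known age under
# a Poisson mutation clock, neutral/expansion coalescent samples, and
# haplogroup-structured population mixtures. All are bit-reproducible under a
# fixed seed.

.maskedPositions <- function(region) {
  b <- regionBounds(region)
  setdiff(b[1]:b[2], defaultExclusionMask()$points)
}

# fast constructor for transition events at given positions
.transitionEvents <- function(pos, reference) {
  if (length(pos) == 0L) return(emptyEvents())
  pos <- sort(as.integer(pos))
  refb <- unname(reference[pos])
  data.frame(position = pos, end = pos, ref = refb,
             derived = unname(.TS_PARTNER[refb]), kind = "transition",
             insOffset = NA_integer_, insSeq = NA_character_, back = FALSE,
             stringsAsFactors = FALSE)
}

#' Simulate a star-like clade of known age
#'
#' Each of n lineages receives Poisson(age / yearsPerMutation) transition
#' events at positions drawn (without replacement across the whole clade:
#' infinite-sites) from the region, excluding the masked point positions so
#' simulated profiles survive the exclusion mask unchanged. Optional position
#' weights emulate mutational hotspots.
#'
#' @param n number of lineages.
#' @param ageYears true clade age in years.
#' @param clock a [clockSpec()]; its rate converts age to the per-lineage
#'   event expectation.
#' @param seed RNG seed (mandatory).
#' @param region region positions are drawn from.
#' @param positionWeights optional numeric weights over the region's
#'   positions (hotspot profile); uniform when NULL.
#' @return list with \code{profiles} (named list of
#'   [VariantProfile-class]), \code{tree} (the true star
#'   [MutationTree-class]) and \code{truth} (age, rate, expected rho).
#' @export
simulateStarClade <- function(n = 50L, ageYears = 18120,
                              clock = clockSpec("complete_genome"),
                              seed, region = "complete",
                              positionWeights = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.character(clock)) clock <- clockSpec(clock)
  stopifnot(ageYears >= 0, n >= 1L)
  set.seed(seed)
  lambda <- ageYears / clock$yearsPerMutation
  pool <- .maskedPositions(region)
  w <- if (is.null(positionWeights)) NULL else positionWeights
  counts <- stats::rpois(n, lambda)
  if (sum(counts) > length(pool))
    stop("region too small for the requested mutation load")
  picked <- sample(pool, sum(counts), replace = FALSE, prob = w)
  ref <- mitoReference()
  idx <- 0L
  branchEvents <- vector("list", n + 1L)
  branchEvents[[1L]] <- emptyEvents()
  profiles <- vector("list", n)
  for (i in seq_len(n)) {
    pos <- picked[idx + seq_len(counts[i])]; idx <- idx + counts[i]
    ev <- .transitionEvents(pos, ref)
    branchEvents[[i + 1L]] <- ev
    profiles[[i]] <- variantProfile(ev, region)
  }
  ids <- sprintf("L%03d", seq_len(n))
  names(profiles) <- ids
  tree <- new("MutationTree",
              parent = c(0L, rep(1L, n)),
              labels = c("root", ids),
              isTip = c(FALSE, rep(TRUE, n)),
              branchEvents = branchEvents,
              rootEvents = emptyEvents(),
              region = if (is.numeric(region))
                paste(region, collapse = "-") else region)
  list(profiles = profiles, tree = tree,
       truth = list(ageYears = ageYears, clock = clock$name,
                    expectedRho = lambda, counts = counts))
}

#' Simulate a sample under the Kingman coalescent
#'
#' Constant-size or sudden-expansion demography. Time is measured in units
#' of 2N(0) generations (N(0) = present size); under sudden expansion the
#' relative population size is 1 more recently than \code{expansionTime} and
#' 1/\code{expansionFactor} before it, which compresses ancient coalescences
#' into a star-like burst. Mutations are Poisson(theta/2 x branch length)
#' and placed under infinite sites at distinct positions in the region.
#'
#' @param n sample size (>= 2).
#' @param theta scaled mutation rate 2 N(0) mu per region.
#' @param model \code{"constant"} or \code{"expansion"}.
#' @param expansionTime time of the size change (units of 2N(0) gens).
#' @param expansionFactor present size / ancient size.
#' @param seed RNG seed (mandatory).
#' @param region region for site placement.
#' @param name population name for the returned sample.
#' @return list with \code{sample} (a [PopulationSample-class]) and
#'   \code{truth} (TMRCA, total tree length, S).
#' @export
simulateCoalescentSample <- function(n = 50L, theta = 5,
                                     model = c("constant", "expansion"),
                                     expansionTime = 0.05,
                                     expansionFactor = 100,
                                     seed, region = "HVS1", name = "sim") {
  if (missing(seed)) stop("seed is mandatory")
  model <- match.arg(model)
  stopifnot(n >= 2L, theta > 0, expansionTime > 0, expansionFactor > 0)
  set.seed(seed)
  nNode <- 2L * n - 1L
  parentOf <- integer(nNode)           # 0 until joined
  nodeTime <- numeric(nNode)
  active <- seq_len(n)
  t <- 0; nxt <- n
  relSize <- function(tt)
    if (model == "constant" || tt < expansionTime) 1 else 1 / expansionFactor
  while (length(active) > 1L) {
    k <- length(active)
    rate <- k * (k - 1) / 2 / relSize(t)
    w <- stats::rexp(1L, rate)
    if (model == "expansion" && t < expansionTime && t + w > expansionTime) {
      t <- expansionTime                # re-draw in the ancient epoch
      next
    }
    t <- t + w
    pick <- sample(length(active), 2L)
    nxt <- nxt + 1L
    nodeTime[nxt] <- t
    parentOf[active[pick]] <- nxt
    active <- c(active[-pick], nxt)
  }
  root <- active
  branchLen <- numeric(nNode)
  nonroot <- which(parentOf != 0L)
  branchLen[nonroot] <- nodeTime[parentOf[nonroot]] - nodeTime[nonroot]
  nMut <- stats::rpois(nNode, theta / 2 * branchLen)
  pool <- .maskedPositions(region)
  if (sum(nMut) > length(pool))
    stop("region too small for the simulated mutation load (raise the ",
         "region size or lower theta)")
  pos <- sample(pool, sum(nMut), replace = FALSE)
  # carriers of each branch's mutations = tips below the branch
  below <- vector("list", nNode)
  for (v in seq_len(nNode))
    below[[v]] <- if (v <= n) v else integer()
  ord <- order(nodeTime)               # tips first, then internal by time
  for (v in ord) if (v > n)
    below[[v]] <- sort(unlist(below[which(parentOf == v)]))
  sites <- sort(pos[seq_len(sum(nMut))])
  m <- matrix(0L, length(sites), n,
              dimnames = list(as.character(sites),
                              sprintf("i%03d", seq_len(n))))
  idx <- 0L
  for (v in seq_len(nNode)) {
    if (nMut[v] == 0L) next
    p <- pos[idx + seq_len(nMut[v])]; idx <- idx + nMut[v]
    m[as.character(p), below[[v]]] <- 1L
  }
  samp <- new("PopulationSample", name = name, incidence = m,
              region = if (is.numeric(region))
                paste(region, collapse = "-") else region)
  list(sample = samp,
       truth = list(tmrca = nodeTime[root], totalLength = sum(branchLen),
                    S = sum(nMut), model = model, theta = theta))
}

#' Simulate a haplogroup mixture
#'
#' Each individual draws a haplogroup component with the given proportions,
#' inherits that node's cumulative motif, and gains Poisson(privateRate)
#' private transition mutations at positions free of motif sites.
#'
#' @param components named numeric vector of mixture proportions (names are
#'   nodes of \code{tree}; must sum to 1).
#' @param n number of individuals.
#' @param tree a [HaplogroupTree-class] (default the packaged fixture).
#' @param seed RNG seed (mandatory).
#' @param privateRate expected private mutations per individual.
#' @param reference reference for token handling.
#' @return list with \code{profiles} (named list of
#'   [VariantProfile-class]), \code{labels} (true component per individual)
#'   and \code{populations} (all \code{"simmix"}; convenience for the
#'   pipeline).
#' @export
simulateAdmixedPopulation <- function(components, n,
                                      tree = fixtureHaplogroupTree(),
                                      seed, privateRate = 1,
                                      reference = mitoReference()) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(abs(sum(components) - 1) < 1e-8, n >= 1L)
  bad <- setdiff(names(components), hgNodes(tree))
  if (length(bad)) stop("unknown node(s): ", paste(bad, collapse = ", "))
  set.seed(seed)
  labels <- sample(names(components), n, replace = TRUE, prob = components)
  motifs <- lapply(names(components), function(nd)
    variantEvents(cumulativeMotif(tree, nd)))
  names(motifs) <- names(components)
  pool <- .maskedPositions("complete")
  profiles <- vector("list", n)
  for (i in seq_len(n)) {
    mo <- motifs[[labels[i]]]
    k <- stats::rpois(1L, privateRate)
    free <- setdiff(pool, mo$position)
    priv <- if (k > 0L) .transitionEvents(sample(free, k), reference) else
      emptyEvents()
    profiles[[i]] <- variantProfile(rbind(mo, priv), "complete")
  }
  ids <- sprintf("m%04d", seq_len(n))
  names(profiles) <- ids
  names(labels) <- ids
  pops <- stats::setNames(rep("simmix", n), ids)
  list(profiles = profiles, labels = labels, populations = pops)
}
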