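# Most-parsimonious haplotype trees. Each distinct variant token is a binary
# presence/absence character; the ancestral (root) state is given by the root
# profile. Topologies are built from the laminar family of derived-carrier
# sets (perfect-phylogeny backbone plus greedy decomposition of incompatible
# sites); events are then re-assigned on the fixed topology by exact binary
# small-parsimony, so the reported score always equals parsimonyScore() of
# the returned tree.

.profEvents <- function(p) if (is(p, "VariantProfile")) variantEvents(p) else p

.siteData <- function(profiles, rootEvents) {
  keyList <- lapply(profiles, function(p) eventKey(.profEvents(p)))
  rootKeys <- eventKey(rootEvents)
  sites <- sort(unique(c(unlist(keyList), rootKeys)))
  tipStates <- vapply(keyList, function(k) sites %in% k,
                      logical(length(sites)))
  if (length(sites) == 0L)
    tipStates <- matrix(FALSE, 0L, length(profiles))
  if (is.null(dim(tipStates)))
    tipStates <- matrix(tipStates, ncol = length(profiles))
  rownames(tipStates) <- sites
  colnames(tipStates) <- names(profiles)
  list(sites = sites, tipStates = tipStates,
       rootStates = sites %in% rootKeys)
}

.sitePos <- function(keys) {
  as.integer(sub("^([0-9]+).*$", "\\1", keys))
}

.BIG <- 1e9

# exact binary small parsimony on a fixed topology with the root state fixed;
# nodes must be in topological order (parent index < child index, root = 1)
.sankoffCosts <- function(parent, tipCol, tipStates, rootStates) {
  nNode <- length(parent)
  nSite <- nrow(tipStates)
  cost0 <- matrix(0, nSite, nNode)
  cost1 <- matrix(0, nSite, nNode)
  for (v in nNode:1) {
    if (!is.na(tipCol[v])) {
      st <- tipStates[, tipCol[v]]
      cost0[, v] <- ifelse(st, .BIG, 0)
      cost1[, v] <- ifelse(st, 0, .BIG)
    } else {
      kids <- which(parent == v)
      c0 <- numeric(nSite); c1 <- numeric(nSite)
      for (k in kids) {
        c0 <- c0 + pmin(cost0[, k], cost1[, k] + 1)
        c1 <- c1 + pmin(cost0[, k] + 1, cost1[, k])
      }
      cost0[, v] <- c0; cost1[, v] <- c1
    }
  }
  list(cost0 = cost0, cost1 = cost1,
       total = sum(ifelse(rootStates, cost1[, 1L], cost0[, 1L])))
}

.sankoffStates <- function(parent, costs, rootStates) {
  nNode <- length(parent)
  nSite <- length(rootStates)
  states <- matrix(FALSE, nSite, nNode)
  states[, 1L] <- rootStates
  for (v in seq_len(nNode)[-1L]) {
    sp <- states[, parent[v]]
    val0 <- costs$cost0[, v] + as.numeric(sp)
    val1 <- costs$cost1[, v] + as.numeric(!sp)
    states[, v] <- ifelse(val1 < val0, TRUE, ifelse(val0 < val1, FALSE, sp))
  }
  states
}

.eventsFromKeys <- function(keys, back, reference) {
  if (length(keys) == 0L) return(emptyEvents())
  rows <- lapply(seq_along(keys), function(i) {
    e <- parseVariant(keys[i], reference)
    e$back <- back[i]
    e
  })
  sortEvents(do.call(rbind, rows))
}

# assemble a MutationTree from a topology (parent/tipCol) and exact per-site
# state assignment
.treeFromTopology <- function(parent, tipCol, tipLabels, siteKeys, tipStates,
                              rootStates, rootEvents, region, reference) {
  costs <- .sankoffCosts(parent, tipCol, tipStates, rootStates)
  states <- .sankoffStates(parent, costs, rootStates)
  nNode <- length(parent)
  branchEvents <- vector("list", nNode)
  branchEvents[[1L]] <- emptyEvents()
  nChanges <- integer(length(siteKeys))
  for (v in seq_len(nNode)[-1L]) {
    ch <- which(states[, v] != states[, parent[v]])
    nChanges[ch] <- nChanges[ch] + 1L
    branchEvents[[v]] <- .eventsFromKeys(siteKeys[ch],
                                         back = states[ch, parent[v]],
                                         reference = reference)
  }
  labels <- character(nNode)
  labels[!is.na(tipCol)] <- tipLabels[tipCol[!is.na(tipCol)]]
  internal <- which(is.na(tipCol))
  labels[internal] <- c("root", if (length(internal) > 1L)
    paste0("n", 2:length(internal)))
  tree <- new("MutationTree", parent = as.integer(parent), labels = labels,
              isTip = !is.na(tipCol), branchEvents = branchEvents,
              rootEvents = rootEvents, region = region)
  list(tree = tree, score = costs$total,
       recurrent = siteKeys[nChanges > 1L])
}

#' Build a most-parsimonious mutation tree (heuristic)
#'
#' Orders variant sites by derived-carrier count, builds a perfect-phylogeny
#' backbone from the mutually compatible sites (carrier sets pairwise nested
#' or disjoint relative to the root state), and greedily decomposes each
#' incompatible site over existing clades, which places it as recurrent
#' events. Events are then assigned on the resulting topology by exact
#' binary small-parsimony, so the reported score is attained by the returned
#' tree, equals [parsimonyScore()] on it, and never beats the global optimum
#' ([exhaustiveMp()]); on homoplasy-free data it equals the optimum. Fully
#' deterministic (ties broken by carrier count, then position, then token).
#'
#' @param profiles named list of [VariantProfile-class] (or event tables).
#' @param rootProfile ancestral profile (default: empty, i.e. the reference).
#' @param region analysis region recorded on the tree.
#' @param reference reference for token handling.
#' @return list with elements \code{score} (integer), \code{tree}
#'   ([MutationTree-class]), \code{optimal} (\code{NA}: not certified) and
#'   \code{recurrent} (site tokens needing more than one event).
#' @export
buildMpTree <- function(profiles, rootProfile = NULL, region = "complete",
                        reference = mitoReference()) {
  if (length(profiles) == 0L) stop("empty input")
  if (is.null(names(profiles)))
    names(profiles) <- paste0("s", seq_along(profiles))
  rootEvents <- if (is.null(rootProfile)) emptyEvents() else
    .profEvents(rootProfile)
  sd <- .siteData(profiles, rootEvents)
  n <- length(profiles)
  derived <- lapply(seq_along(sd$sites), function(i) {
    d <- which(xor(sd$tipStates[i, ], sd$rootStates[i]))
    sort(d)
  })
  counts <- lengths(derived)
  keep <- counts > 0L
  ord <- order(-counts[keep], .sitePos(sd$sites[keep]), sd$sites[keep])
  siteOrder <- which(keep)[ord]

  clusters <- as.list(seq_len(n))          # singletons pre-seeded
  for (si in siteOrder) {
    S <- derived[[si]]
    compatible <- all(vapply(clusters, function(C) {
      I <- length(intersect(S, C))
      I == 0L || I == length(S) || I == length(C)
    }, TRUE))
    if (compatible) {
      if (!any(vapply(clusters, function(C) identical(C, S), TRUE)))
        clusters[[length(clusters) + 1L]] <- S
    } else {
      remaining <- S
      while (length(remaining)) {
        inside <- clusters[vapply(clusters, function(C)
          all(C %in% remaining), TRUE)]
        sizes <- lengths(inside)
        pick <- inside[[order(-sizes, vapply(inside, min, 0L))[1L]]]
        remaining <- setdiff(remaining, pick)
      }
    }
  }

  internal <- clusters[lengths(clusters) > 1L]
  internal <- internal[order(-lengths(internal))]
  nNode <- 1L + length(internal) + n
  parent <- integer(nNode); tipCol <- rep(NA_integer_, nNode)
  cl <- c(list(NULL), internal, as.list(seq_len(n)))  # node -> tip set
  cl[[1L]] <- seq_len(n)
  tipCol[1L + length(internal) + seq_len(n)] <- seq_len(n)
  for (v in seq_len(nNode)[-1L]) {
    C <- cl[[v]]
    anc <- which(vapply(seq_len(v - 1L), function(u)
      u == 1L || (length(cl[[u]]) > length(C) && all(C %in% cl[[u]])), TRUE))
    # smallest strictly containing ancestor (laminar => totally ordered);
    # on a size tie (root vs an all-tip cluster) attach to the deeper node
    sz <- vapply(anc, function(u) length(cl[[u]]), 0L)
    parent[v] <- max(anc[sz == min(sz)])
  }
  parent[1L] <- 0L
  res <- .treeFromTopology(parent, tipCol, names(profiles), sd$sites,
                           sd$tipStates, sd$rootStates, rootEvents, region,
                           reference)
  list(score = as.integer(res$score), tree = res$tree, optimal = NA,
       recurrent = res$recurrent)
}

.treeTipCol <- function(tree) {
  tipCol <- rep(NA_integer_, length(tree@parent))
  tipCol[which(tree@isTip)] <- seq_len(sum(tree@isTip))
  tipCol
}

#' Parsimony score of profiles on a fixed topology
#'
#' The minimal number of per-site state changes needed to explain the tip
#' profiles on the given tree (exact binary small-parsimony per variant
#' site, root state fixed at the tree's ancestral profile), summed over
#' sites.
#'
#' @param tree a [MutationTree-class].
#' @param profiles named list of profiles covering all tip labels; if
#'   omitted, the tree's own tip profiles (root profile edited by path
#'   events) are used.
#' @return integer score.
#' @export
parsimonyScore <- function(tree, profiles = NULL) {
  if (is.null(profiles)) profiles <- tipProfiles(tree)
  tl <- tipLabels(tree)
  if (!all(tl %in% names(profiles)))
    stop("profiles missing for tips: ",
         paste(setdiff(tl, names(profiles)), collapse = ", "))
  profiles <- profiles[tl]
  sd <- .siteData(profiles, tree@rootEvents)
  if (length(sd$sites) == 0L) return(0L)
  costs <- .sankoffCosts(tree@parent, .treeTipCol(tree), sd$tipStates,
                         sd$rootStates)
  as.integer(costs$total)
}

#' Tip profiles implied by a mutation tree
#'
#' Reconstructs each tip's variant set as the root profile edited by the
#' events along the root-to-tip path (an event whose site is already present
#' toggles it off: back mutations cancel).
#'
#' @param tree a [MutationTree-class].
#' @param region region for the returned profiles (default: the tree's).
#' @param reference reference for token handling.
#' @return named list of [VariantProfile-class].
#' @export
tipProfiles <- function(tree, region = tree@region,
                        reference = mitoReference()) {
  nNode <- length(tree@parent)
  keySets <- vector("list", nNode)
  keySets[[1L]] <- eventKey(tree@rootEvents)
  for (v in seq_len(nNode)[-1L]) {
    k <- keySets[[tree@parent[v]]]
    ev <- tree@branchEvents[[v]]
    for (key in eventKey(ev))
      k <- if (key %in% k) setdiff(k, key) else c(k, key)
    keySets[[v]] <- k
  }
  tips <- which(tree@isTip)
  out <- lapply(tips, function(v)
    variantProfile(parseVariant(keySets[[v]], reference), region))
  names(out) <- tree@labels[tips]
  out
}

# enumerate all rooted binary topologies by leaf insertion; each tree is a
# nested list of tip indices. Every tree on k-1 leaves has 2k-3 edges (one
# above each node, including the top edge to the fixed ancestor), giving the
# (2n-3)!! rooted topologies.
.allRootedTopologies <- function(n) {
  trees <- list(1L)
  for (k in 2L:n) {
    nxt <- list()
    for (tr in trees) {
      for (e in seq_len(.countEdges(tr))) {
        nxt[[length(nxt) + 1L]] <- .insertLeaf(tr, k, e)
      }
    }
    trees <- nxt
  }
  trees
}

.countEdges <- function(tr) {
  if (!is.list(tr)) return(1L)
  1L + .countEdges(tr[[1L]]) + .countEdges(tr[[2L]])
}

# insert leaf on edge number e (edges numbered in preorder, one above each
# node; e = 1 is the top edge, yielding a new root)
.insertLeaf <- function(tr, leaf, e) {
  cnt <- 0L
  rec <- function(node) {
    cnt <<- cnt + 1L
    if (cnt == e) return(list(node, leaf))
    if (!is.list(node)) return(node)
    left <- rec(node[[1L]])
    right <- rec(node[[2L]])
    list(left, right)
  }
  rec(tr)
}

.topologyToParent <- function(tr, n) {
  parent <- integer(0); tipCol <- integer(0)
  addNode <- function(p) {
    parent[length(parent) + 1L] <<- p
    tipCol[length(tipCol) + 1L] <<- NA_integer_
    length(parent)
  }
  walk <- function(node, p) {
    v <- addNode(p)
    if (is.list(node)) {
      walk(node[[1L]], v); walk(node[[2L]], v)
    } else tipCol[v] <<- node
  }
  root <- addNode(0L)            # fixed ancestral node
  walk(tr, root)
  list(parent = parent, tipCol = tipCol)
}

#' Exhaustive maximum-parsimony oracle
#'
#' Enumerates every rooted binary topology on the samples (feasible for
#' n <= 7: up to 10,395 topologies), scores each by exact per-site
#' small-parsimony against the ancestral profile, and returns a tree
#' attaining the global minimum.
#'
#' @inheritParams buildMpTree
#' @param maxN enumeration bound (default 7).
#' @return as [buildMpTree()], with \code{optimal = TRUE}.
#' @export
exhaustiveMp <- function(profiles, rootProfile = NULL, region = "complete",
                         reference = mitoReference(), maxN = 7L) {
  n <- length(profiles)
  if (n < 1L) stop("empty input")
  if (n > maxN) stop("exhaustive search bounded at n = ", maxN)
  if (is.null(names(profiles)))
    names(profiles) <- paste0("s", seq_along(profiles))
  rootEvents <- if (is.null(rootProfile)) emptyEvents() else
    .profEvents(rootProfile)
  sd <- .siteData(profiles, rootEvents)
  topos <- if (n == 1L) list(1L) else .allRootedTopologies(n)
  best <- NULL; bestScore <- Inf
  for (tr in topos) {
    tp <- .topologyToParent(tr, n)
    sc <- .sankoffCosts(tp$parent, tp$tipCol, sd$tipStates, sd$rootStates)
    if (sc$total < bestScore) { bestScore <- sc$total; best <- tp }
  }
  res <- .treeFromTopology(best$parent, best$tipCol, names(profiles),
                           sd$sites, sd$tipStates, sd$rootStates, rootEvents,
                           region, reference)
  list(score = as.integer(res$score), tree = res$tree, optimal = TRUE,
       recurrent = res$recurrent)
}
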