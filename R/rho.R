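#' The rho divergence statistic with Saillard error
#'
#' For a clade with n tips, rho is the mean number of clock-qualified
#' mutations from the clade root to its tips, computed over branches i as
#' \eqn{\rho = n^{-1} \sum_i l_i n_i} where \eqn{l_i} is the number of
#' qualifying events on branch i and \eqn{n_i} the number of tips it
#' subtends; the standard error is
#' \eqn{\sigma = n^{-1} \sqrt{\sum_i l_i n_i^2}}. Events should already be
#' exclusion-masked; indels never qualify for any clock.
#'
#' @param tree a [MutationTree-class].
#' @param node clade root label (default: the tree root).
#' @param clock a [clockSpec()] or clock name; fixes the event counting rule.
#' @param annotation,reference for synonymous-clock classification.
#' @return a [RhoEstimate-class].
#' @examples
#' # star of 4 tips with 2 qualifying events each: rho = 2, sigma = 0.7071
#' @export
rhoStatistic <- function(tree, node = tree@labels[1L],
                         clock = clockSpec("complete_genome"),
                         annotation = mitoAnnotation(),
                         reference = mitoReference()) {
  if (is.character(clock)) clock <- clockSpec(clock)
  idx <- match(node, tree@labels)
  if (is.na(idx)) stop("unknown node: ", node)
  nNode <- length(tree@parent)
  # tips subtended per node
  nTipsBelow <- integer(nNode)
  for (v in nNode:1)
    nTipsBelow[v] <- if (tree@isTip[v]) 1L else
      sum(nTipsBelow[which(tree@parent == v)])
  # nodes within the clade (descendants of idx)
  inClade <- logical(nNode); inClade[idx] <- TRUE
  for (v in seq_len(nNode))
    if (tree@parent[v] != 0L && inClade[tree@parent[v]]) inClade[v] <- TRUE
  branches <- setdiff(which(inClade), idx)
  n <- nTipsBelow[idx]
  if (n == 0L) stop("clade with 0 tips")
  l <- vapply(branches, function(v)
    countForClock(tree@branchEvents[[v]], clock, annotation, reference), 0L)
  nb <- nTipsBelow[branches]
  rho <- sum(l * nb) / n
  sigma <- sqrt(sum(l * nb^2)) / n
  new("RhoEstimate", node = node, rho = rho, sigma = sigma,
      nTips = as.integer(n), clock = clock$name)
}

#' Convert a rho estimate to an age
#'
#' Linear conversion: age = rho x yearsPerMutation; the error range is
#' (rho -/+ sigma) x yearsPerMutation (one standard error, clamped at 0).
#'
#' @param est a [RhoEstimate-class].
#' @param clock a [clockSpec()]; must match the clock the estimate was
#'   counted under.
#' @return list with \code{years}, \code{ciLow}, \code{ciHigh}, \code{kya}
#'   (years / 1000, one decimal) and the clock name.
#' @export
ageEstimate <- function(est, clock = clockSpec(est@clock)) {
  if (is.character(clock)) clock <- clockSpec(clock)
  if (!identical(clock$name, est@clock))
    stop("clock mismatch: estimate counted under ", est@clock,
         ", conversion requested for ", clock$name)
  r <- clock$yearsPerMutation
  years <- est@rho * r
  list(years = years, ciLow = max(0, (est@rho - est@sigma) * r),
       ciHigh = (est@rho + est@sigma) * r,
       kya = round(years / 1000, 1L), clock = clock$name)
}

#' Founder age report over nodes and clocks
#'
#' @param tree a [MutationTree-class].
#' @param nodes clade root labels.
#' @param clocks clock names (default: all three calibrations).
#' @param annotation,reference forwarded to [rhoStatistic()].
#' @return data.frame with one row per (node, clock): rho, sigma, n_tips,
#'   age_years, ci_low, ci_high, age_kya. Deterministic ordering (nodes in
#'   the given order, clocks in the given order).
#' @export
founderAgeReport <- function(tree, nodes,
                             clocks = names(.CLOCK_RATES),
                             annotation = mitoAnnotation(),
                             reference = mitoReference()) {
  rows <- list()
  for (nd in nodes) for (ck in clocks) {
    est <- rhoStatistic(tree, nd, clockSpec(ck), annotation, reference)
    age <- ageEstimate(est)
    rows[[length(rows) + 1L]] <- data.frame(
      node = nd, clock = ck, rho = est@rho, sigma = est@sigma,
      n_tips = est@nTips, age_years = age$years, ci_low = age$ciLow,
      ci_high = age$ciHigh, age_kya = age$kya, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    return(data.frame(node = character(), clock = character(),
                      rho = numeric(), sigma = numeric(),
                      n_tips = integer(), age_years = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      age_kya = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
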