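#' VariantProfile: the mutations of one molecule relative to the reference
#'
#' An ordered, duplicate-free set of mutation events restricted to an
#' analysis region. Construct with [variantProfile()].
#'
#' @slot events event \code{data.frame} (see [emptyEvents()]).
#' @slot region region name or bounds string.
#' @export
setClass("VariantProfile",
         slots = c(events = "data.frame", region = "character"))

setValidity("VariantProfile", function(object) {
  ev <- object@events
  if (!all(.EVENT_COLS %in% names(ev)))
    return("events is missing canonical columns")
  if (nrow(ev) == 0L) return(TRUE)
  if (any(ev$position < 1L | ev$position > 16569L))
    return("positions must lie in 1..16569")
  b <- regionBounds(.regionArg(object@region))
  if (any(ev$position < b[1] | ev$end > b[2]))
    return(sprintf("events outside region bounds %d-%d", b[1], b[2]))
  key <- paste(ev$position, ev$kind, ifelse(is.na(ev$insOffset), 0L,
                                            ev$insOffset))
  if (anyDuplicated(key)) return("duplicate (position, kind, offset) events")
  off <- ifelse(is.na(ev$insOffset), 0L, ev$insOffset)
  if (is.unsorted(order(ev$position, off)) &&
      any(diff(ev$position) < 0L))
    return("events must be sorted by (position, insOffset)")
  bad <- ev$kind == "insertion" & (is.na(ev$insOffset) | is.na(ev$insSeq))
  if (any(bad)) return("insertions need insOffset and insSeq")
  if (any(ev$kind == "deletion" & !is.na(ev$derived)))
    return("deletions must have no derived base")
  TRUE
})

.regionArg <- function(region) {
  if (grepl("^\\d+-\\d+$", region[1]))
    as.integer(strsplit(region[1], "-")[[1]]) else region[1]
}

#' Construct a VariantProfile
#'
#' @param events an event \code{data.frame}, or a character vector of tokens
#'   to be passed through [parseVariant()].
#' @param region region name (\code{"HVS1"}, \code{"HVS2"}, \code{"coding"},
#'   \code{"complete"}) or a \code{"start-end"} bounds string.
#' @param reference reference used when parsing tokens.
#' @return a \code{VariantProfile}.
#' @examples
#' variantProfile(c("16189", "16223"), region = "HVS1")
#' @export
variantProfile <- function(events = emptyEvents(), region = "complete",
                           reference = mitoReference()) {
  if (is.character(events)) events <- parseVariant(events, reference)
  if (is.numeric(region)) region <- paste(as.integer(region), collapse = "-")
  new("VariantProfile", events = sortEvents(events), region = region)
}

#' @describeIn variantProfile event table accessor
#' @param x a \code{VariantProfile}.
#' @export
variantEvents <- function(x) x@events

#' @describeIn variantProfile region accessor
#' @export
profileRegion <- function(x) x@region

setMethod("show", "VariantProfile", function(object) {
  cat("VariantProfile |", object@region, "|", nrow(object@events),
      "events\n")
  if (nrow(object@events))
    cat(" ", paste(serializeVariant(object@events), collapse = " "), "\n")
})

#' HaplogroupTree: named clades with defining mutations
#'
#' A rooted tree of haplogroup names; each node carries its defining
#' mutations. Cumulative motifs (root-to-node unions with back-mutation
#' cancellation) drive classification. Construct with [readHaplogroupTree()]
#' or [haplogroupTree()].
#'
#' @slot nodes node names (first element is the root).
#' @slot parent named character vector: parent of each node (NA for root).
#' @slot mutations named list of event tables, one per node.
#' @export
setClass("HaplogroupTree",
         slots = c(nodes = "character", parent = "character",
                   mutations = "list"))

setValidity("HaplogroupTree", function(object) {
  nd <- object@nodes
  if (anyDuplicated(nd)) return("duplicate node names")
  root <- nd[is.na(object@parent[nd])]
  if (length(root) != 1L) return("tree must have exactly one root")
  kid <- object@parent[nd[nd != root]]
  if (!all(kid %in% nd)) return("orphan node (unknown parent)")
  # acyclicity: every node must reach the root
  for (n in nd) {
    seen <- character(); cur <- n
    while (!is.na(object@parent[[cur]])) {
      if (cur %in% seen) return("cycle detected")
      seen <- c(seen, cur); cur <- object@parent[[cur]]
    }
  }
  TRUE
})

setMethod("show", "HaplogroupTree", function(object) {
  cat("HaplogroupTree |", length(object@nodes), "nodes | root:",
      hgRoot(object), "\n")
})

#' @describeIn haplogroupTree node names
#' @export
hgNodes <- function(tree) tree@nodes

#' @describeIn haplogroupTree root node name
#' @export
hgRoot <- function(tree) tree@nodes[is.na(tree@parent[tree@nodes])]

#' MutationTree: a phylogeny whose branches carry mutation events
#'
#' Node 1 is the root (ancestral profile); every other node has a branch to
#' its parent carrying an ordered event list. Tips are labelled with sample
#' ids. Tip profiles equal the root profile edited by the events on the
#' root-to-tip path (back mutations cancel).
#'
#' @slot parent integer parent index per node (0 for the root).
#' @slot labels node labels (sample ids at tips).
#' @slot isTip logical per node.
#' @slot branchEvents list of event tables, one per node (events on the
#'   branch above that node; empty for the root).
#' @slot rootEvents event table of the ancestral profile relative to the
#'   reference.
#' @slot region analysis region of the profiles.
#' @export
setClass("MutationTree",
         slots = c(parent = "integer", labels = "character",
                   isTip = "logical", branchEvents = "list",
                   rootEvents = "data.frame", region = "character"))

setValidity("MutationTree", function(object) {
  n <- length(object@parent)
  if (length(object@labels) != n || length(object@isTip) != n ||
      length(object@branchEvents) != n)
    return("slot lengths disagree")
  if (sum(object@parent == 0L) != 1L || object@parent[1L] != 0L)
    return("node 1 must be the unique root")
  if (any(object@parent >= seq_len(n) & object@parent != 0L))
    return("parents must precede children (topological order)")
  TRUE
})

setMethod("show", "MutationTree", function(object) {
  cat("MutationTree |", sum(object@isTip), "tips |",
      length(object@parent), "nodes |",
      sum(vapply(object@branchEvents, nrow, 0L)), "branch events\n")
})

#' @describeIn buildMpTree tip labels of a MutationTree
#' @export
tipLabels <- function(tree) tree@labels[tree@isTip]

#' @describeIn buildMpTree number of tips
#' @export
nTips <- function(tree) sum(tree@isTip)

#' PopulationSample: a sample of haplotypes over a fixed region
#'
#' Internally a binary incidence matrix (variant sites x individuals); this
#' makes haplotype counting and pairwise-difference arithmetic exact and
#' fast. Construct with [populationSample()].
#'
#' @slot name population name.
#' @slot incidence 0/1 matrix, rownames are site tokens, colnames sample ids.
#' @slot region analysis region.
#' @export
setClass("PopulationSample",
         slots = c(name = "character", incidence = "matrix",
                   region = "character"))

setValidity("PopulationSample", function(object) {
  m <- object@incidence
  if (length(m) && !all(m %in% c(0, 1))) return("incidence must be 0/1")
  if (ncol(m) < 1L) return("empty sample")
  TRUE
})

setMethod("show", "PopulationSample", function(object) {
  cat("PopulationSample", object@name, "| n =", ncol(object@incidence),
      "|", nrow(object@incidence), "variant sites |", object@region, "\n")
})

#' @describeIn populationSample sample size
#' @export
sampleSize <- function(x) ncol(x@incidence)

#' @describeIn populationSample site-by-individual incidence matrix
#' @export
sampleIncidence <- function(x) x@incidence

#' FrequencyTable: haplogroup counts per population
#'
#' @slot counts integer matrix, haplogroups x populations.
#' @export
setClass("FrequencyTable", slots = c(counts = "matrix"))

setValidity("FrequencyTable", function(object) {
  if (any(object@counts < 0)) return("negative counts")
  if (is.null(rownames(object@counts)) || is.null(colnames(object@counts)))
    return("counts needs haplogroup rownames and population colnames")
  TRUE
})

setMethod("show", "FrequencyTable", function(object) {
  cat("FrequencyTable |", nrow(object@counts), "haplogroups x",
      ncol(object@counts), "populations | n =",
      paste(colSums(object@counts), collapse = ", "), "\n")
})

#' @describeIn frequencyTable count matrix accessor
#' @export
hgCounts <- function(x) x@counts

#' @describeIn frequencyTable population sizes
#' @export
populationSizes <- function(x) colSums(x@counts)

#' RhoEstimate: the rho divergence statistic for one clade
#'
#' rho is the mean number of clock-qualified mutations from the clade root to
#' its tips; sigma is the Saillard standard error
#' \eqn{\sigma^2 = n^{-2} \sum_i l_i n_i^2} over branches i with l_i
#' qualifying events subtending n_i tips.
#'
#' @slot node clade root label.
#' @slot rho,sigma the statistic and its standard error.
#' @slot nTips tips in the clade.
#' @slot clock clock name used for event counting.
#' @export
setClass("RhoEstimate",
         slots = c(node = "character", rho = "numeric", sigma = "numeric",
                   nTips = "integer", clock = "character"))

setValidity("RhoEstimate", function(object) {
  if (object@rho < 0 || object@sigma < 0) return("rho and sigma must be >= 0")
  TRUE
})

setMethod("show", "RhoEstimate", function(object) {
  cat(sprintf("RhoEstimate %s | rho = %.4f +/- %.4f | n = %d | clock = %s\n",
              object@node, object@rho, object@sigma, object@nTips,
              object@clock))
})
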