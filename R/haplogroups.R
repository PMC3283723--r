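#' Construct or read a haplogroup tree
#'
#' The TSV format has columns \code{node}, \code{parent}, \code{mutations}
#' (space-separated canonical tokens; empty for the root and for nodes whose
#' defining markers are not represented). The packaged fixture
#' (\code{inst/extdata/haplogroup_tree_fixture.tsv}) is an illustrative tree
#' encoding published partial motifs, not a full nomenclature tree.
#'
#' @param nodes data.frame with columns node, parent, mutations.
#' @param reference reference for token parsing.
#' @return a [HaplogroupTree-class].
#' @export
haplogroupTree <- function(nodes, reference = mitoReference()) {
  stopifnot(all(c("node", "parent") %in% names(nodes)))
  if (is.null(nodes$mutations)) nodes$mutations <- ""
  nodes$mutations[is.na(nodes$mutations)] <- ""
  muts <- lapply(nodes$mutations, function(s) {
    toks <- strsplit(trimws(s), "\\s+")[[1L]]
    parseVariant(toks[nzchar(toks)], reference)
  })
  names(muts) <- nodes$node
  parent <- ifelse(is.na(nodes$parent) | nodes$parent == "",
                   NA_character_, nodes$parent)
  names(parent) <- nodes$node
  new("HaplogroupTree", nodes = nodes$node, parent = parent,
      mutations = muts)
}

#' @describeIn haplogroupTree read a haplogroup tree from TSV
#' @param path TSV file path.
#' @export
readHaplogroupTree <- function(path, reference = mitoReference()) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character")
  haplogroupTree(df, reference)
}

#' Packaged illustrative haplogroup tree
#'
#' @return the fixture [HaplogroupTree-class].
#' @export
fixtureHaplogroupTree <- function() {
  if (is.null(.pkgCache$hgTree))
    .pkgCache$hgTree <- readHaplogroupTree(
      system.file("extdata", "haplogroup_tree_fixture.tsv",
                  package = "mitophylo", mustWork = TRUE))
  .pkgCache$hgTree
}

.hgPath <- function(tree, node) {
  path <- character(); cur <- node
  while (!is.na(cur)) { path <- c(cur, path); cur <- tree@parent[[cur]] }
  path
}

.hgDepth <- function(tree, node) length(.hgPath(tree, node)) - 1L

#' Cumulative motif of a haplogroup node
#'
#' The union of defining mutations on the root-to-node path. An event flagged
#' as a back mutation (\code{"!"}) cancels the matching ancestral event and
#' does not itself appear in the motif.
#'
#' @param tree a [HaplogroupTree-class].
#' @param node node name.
#' @return a [VariantProfile-class] over the complete region.
#' @examples
#' cumulativeMotif(fixtureHaplogroupTree(), "B4c1a2")
#' @export
cumulativeMotif <- function(tree, node) {
  if (!node %in% tree@nodes) stop("unknown node: ", node)
  acc <- emptyEvents()
  for (n in .hgPath(tree, node)) {
    ev <- tree@mutations[[n]]
    for (i in seq_len(nrow(ev))) {
      e <- ev[i, , drop = FALSE]
      key <- eventKey(e)
      have <- if (nrow(acc)) eventKey(acc) else character()
      if (isTRUE(e$back)) {
        acc <- acc[have != key, , drop = FALSE]
      } else {
        acc <- rbind(acc[have != key, , drop = FALSE],
                     transform(e, back = FALSE))
      }
    }
  }
  variantProfile(sortEvents(acc), region = "complete")
}

#' Assign a variant profile to a haplogroup
#'
#' Scores every node by (matches - mismatches) between the profile and the
#' node's cumulative motif, with the motif restricted to positions observable
#' in the profile's region. Ties are resolved deterministically (shallower
#' node first, then lexicographic name) and reported via \code{ambiguous}.
#'
#' @param profile a [VariantProfile-class].
#' @param tree a [HaplogroupTree-class].
#' @param sampleId optional id carried into the result.
#' @return list with \code{sampleId}, \code{bestNode}, \code{score},
#'   \code{matched}, \code{missing}, \code{private} (token vectors) and
#'   \code{ambiguous}.
#' @export
assignHaplogroup <- function(profile, tree, sampleId = NA_character_) {
  if (length(tree@nodes) == 0L) stop("empty haplogroup tree")
  b <- regionBounds(.regionArg(profile@region))
  profKeys <- eventKey(variantEvents(profile))
  nodes <- tree@nodes
  stats <- lapply(nodes, function(n) {
    mo <- variantEvents(cumulativeMotif(tree, n))
    mo <- mo[mo$position >= b[1] & mo$position <= b[2], , drop = FALSE]
    keys <- eventKey(mo)
    m <- sum(keys %in% profKeys)
    list(keys = keys, matches = m, missing = length(keys) - m,
         score = 2L * m - length(keys))
  })
  scores <- vapply(stats, `[[`, 0L, "score")
  top <- which(scores == max(scores))
  ambiguous <- length(top) > 1L
  if (ambiguous) {
    depths <- vapply(nodes[top], function(n) .hgDepth(tree, n), 0L)
    top <- top[order(depths, nodes[top])]
  }
  best <- top[1L]
  keys <- stats[[best]]$keys
  list(sampleId = sampleId, bestNode = nodes[best],
       score = scores[best],
       matched = intersect(keys, profKeys),
       missing = setdiff(keys, profKeys),
       private = setdiff(profKeys, keys),
       ambiguous = ambiguous)
}

#' Classify many samples
#'
#' @param profiles named list of [VariantProfile-class] objects.
#' @param tree a [HaplogroupTree-class].
#' @param populations optional named character vector (sample -> population).
#' @return data.frame with one row per sample: haplogroup, score, match
#'   bookkeeping and the ambiguity flag.
#' @export
classifySamples <- function(profiles, tree, populations = NULL) {
  ids <- names(profiles)
  if (is.null(ids)) ids <- paste0("s", seq_along(profiles))
  rows <- lapply(seq_along(profiles), function(i) {
    a <- assignHaplogroup(profiles[[i]], tree, ids[i])
    data.frame(sample_id = ids[i], haplogroup = a$bestNode,
               score = a$score, n_matched = length(a$matched),
               n_missing = length(a$missing),
               n_private = length(a$private),
               ambiguous = a$ambiguous, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(populations)) out$population <- unname(populations[out$sample_id])
  out
}

#' Haplogroup frequency table
#'
#' @param assignments data.frame with columns \code{haplogroup} and
#'   \code{population} (as from [classifySamples()]), or a count matrix
#'   (haplogroups x populations).
#' @return a [FrequencyTable-class].
#' @export
frequencyTable <- function(assignments) {
  if (is.matrix(assignments)) {
    counts <- assignments
  } else {
    stopifnot(all(c("haplogroup", "population") %in% names(assignments)))
    counts <- unclass(table(assignments$haplogroup, assignments$population))
  }
  storage.mode(counts) <- "integer"
  if (any(colSums(counts) == 0L)) stop("population with n = 0")
  new("FrequencyTable", counts = counts)
}

#' @describeIn frequencyTable read a haplogroup count matrix from TSV
#'   (first column haplogroup, remaining columns one per population)
#' @param path TSV path.
#' @export
readFrequencyTable <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  frequencyTable(m)
}

#' Percent table (one decimal)
#'
#' @param x a [FrequencyTable-class].
#' @return matrix of percentages rounded to one decimal; per population they
#'   sum to 100 within rounding.
#' @export
percentTable <- function(x) {
  round(100 * sweep(x@counts, 2L, colSums(x@counts), "/"), 1L)
}

#' Component shares per population
#'
#' Aggregates haplogroup frequencies into components (e.g. eastern vs western
#' Eurasian). Every haplogroup present in the table must be mapped.
#'
#' @param x a [FrequencyTable-class].
#' @param componentMap named character vector haplogroup -> component, or a
#'   data.frame with columns haplogroup, component.
#' @return matrix components x populations of percentage shares (unrounded;
#'   columns sum to 100).
#' @export
componentShares <- function(x, componentMap) {
  if (is.data.frame(componentMap)) {
    cm <- componentMap$component
    names(cm) <- componentMap$haplogroup
    componentMap <- cm
  }
  hgs <- rownames(x@counts)
  unmapped <- setdiff(hgs, names(componentMap))
  if (length(unmapped))
    stop("unmapped haplogroups: ", paste(unmapped, collapse = ", "))
  comp <- componentMap[hgs]
  agg <- rowsum(x@counts, group = comp)
  100 * sweep(agg, 2L, colSums(x@counts), "/")
}
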