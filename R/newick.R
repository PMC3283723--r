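# Newick export/import for mutation-annotated trees. Branch lengths are
# event counts and each branch's mutation tokens ride in a bracketed comment
# after the length, e.g. "(Khm_21:2[16223 16362])root;". Standard newick
# readers drop comment payloads, so the dialect has its own small reader.

#' Export a MutationTree to annotated newick
#'
#' @param tree a [MutationTree-class].
#' @return single newick string; branch lengths are event counts, branch
#'   mutation lists are embedded as \code{[...]} comments.
#' @export
exportNewick <- function(tree) {
  kids <- lapply(seq_along(tree@parent), function(v) which(tree@parent == v))
  fmt <- function(v) {
    ev <- tree@branchEvents[[v]]
    ann <- if (nrow(ev)) paste0("[", paste(serializeVariant(ev),
                                           collapse = " "), "]") else ""
    core <- if (length(kids[[v]]))
      paste0("(", paste(vapply(kids[[v]], fmt, ""), collapse = ","), ")",
             tree@labels[v]) else tree@labels[v]
    if (v == 1L) core else paste0(core, ":", nrow(ev), ann)
  }
  paste0(fmt(1L), ";")
}

#' Import the annotated newick dialect
#'
#' Inverse of [exportNewick()]: parses topology, labels and the bracketed
#' branch mutation lists back into a [MutationTree-class].
#'
#' @param text newick string (or a file path to one).
#' @param rootProfile ancestral profile of the tree (default empty).
#' @param region region recorded on the tree.
#' @param reference reference for token parsing.
#' @return a [MutationTree-class].
#' @export
importNewick <- function(text, rootProfile = NULL, region = "complete",
                         reference = mitoReference()) {
  if (file.exists(text)) text <- paste(readLines(text), collapse = "")
  s <- strsplit(trimws(text), "")[[1L]]
  pos <- 1L
  peek <- function() if (pos <= length(s)) s[pos] else ""
  advance <- function() { ch <- s[pos]; pos <<- pos + 1L; ch }
  readWhile <- function(stopChars) {
    out <- character()
    while (pos <= length(s) && !(s[pos] %in% stopChars))
      out <- c(out, advance())
    paste(out, collapse = "")
  }
  # each parsed node: list(label, tokens, children)
  parseNode <- function() {
    children <- list()
    if (peek() == "(") {
      advance()
      repeat {
        children[[length(children) + 1L]] <- parseNode()
        if (peek() == ",") { advance(); next }
        if (peek() == ")") { advance(); break }
        stop("malformed newick near position ", pos)
      }
    }
    label <- readWhile(c(":", ",", ")", ";", "["))
    tokens <- character(); len <- NA_real_
    if (peek() == ":") {
      advance()
      len <- as.numeric(readWhile(c("[", ",", ")", ";")))
    }
    if (peek() == "[") {
      advance()
      payload <- readWhile("]")
      advance()
      tokens <- strsplit(trimws(payload), "\\s+")[[1L]]
      tokens <- tokens[nzchar(tokens)]
    }
    list(label = label, tokens = tokens, children = children)
  }
  root <- parseNode()
  if (peek() != ";") stop("missing terminal ';'")

  parent <- integer(); labels <- character(); isTip <- logical()
  branchEvents <- list()
  addNode <- function(node, p) {
    v <- length(parent) + 1L
    parent[v] <<- p
    labels[v] <<- node$label
    isTip[v] <<- length(node$children) == 0L
    branchEvents[[v]] <<- parseVariant(node$tokens, reference)
    for (ch in node$children) addNode(ch, v)
  }
  addNode(root, 0L)
  rootEvents <- if (is.null(rootProfile)) emptyEvents() else
    .profEvents(rootProfile)
  new("MutationTree", parent = parent, labels = labels, isTip = isTip,
      branchEvents = branchEvents, rootEvents = rootEvents, region = region)
}
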