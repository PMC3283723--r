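#' @import methods
#' @importFrom stats setNames
NULL

.EVENT_COLS <- c("position", "end", "ref", "derived", "kind",
                 "insOffset", "insSeq", "back")

#' Empty mutation-event table
#'
#' Mutation events are the currency of the package: every variant relative to
#' the reference coordinate frame is one row of an event table with columns
#' \code{position} (1-based np), \code{end} (equal to \code{position} except
#' for multi-np deletions), \code{ref}/\code{derived} bases (\code{NA} for
#' indels where not applicable), \code{kind} (one of \code{transition},
#' \code{transversion}, \code{insertion}, \code{deletion}),
#' \code{insOffset}/\code{insSeq} (insertions only) and the logical
#' \code{back} flag marking a reversion toward the reference along a tree
#' path.
#'
#' @return A zero-row event \code{data.frame}.
#' @export
emptyEvents <- function() {
  data.frame(position = integer(), end = integer(),
             ref = character(), derived = character(),
             kind = character(), insOffset = integer(),
             insSeq = character(), back = logical(),
             stringsAsFactors = FALSE)
}

.TS_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")
.PURINES <- c("A", "G")

.subKind <- function(ref, derived) {
  ifelse((ref %in% .PURINES) == (derived %in% .PURINES),
         "transition", "transversion")
}

sortEvents <- function(ev) {
  if (nrow(ev) == 0L) return(ev)
  off <- ifelse(is.na(ev$insOffset), 0L, ev$insOffset)
  ev <- ev[order(ev$position, off, ev$kind), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

.eventRow <- function(position, end = position, ref = NA_character_,
                      derived = NA_character_, kind, insOffset = NA_integer_,
                      insSeq = NA_character_, back = FALSE) {
  data.frame(position = as.integer(position), end = as.integer(end),
             ref = ref, derived = derived, kind = kind,
             insOffset = as.integer(insOffset), insSeq = insSeq,
             back = back, stringsAsFactors = FALSE)
}

#' Parse variant notation tokens into mutation events
#'
#' Accepts the canonical PhyloTree-style dialect: a bare position
#' (\code{"16189"}) is a transition; position plus base (\code{"408A"}) names
#' the derived base explicitly; \code{"8278.1C"} is an insertion (offset 1,
#' inserted C); \code{"522d"} and \code{"8281-8289d"} are single-np and span
#' deletions; a trailing \code{"!"} marks a back mutation. The prose form
#' \code{"A8860G"} (ref base, position, derived base) is also accepted on
#' input.
#'
#' @param tokens character vector of variant tokens.
#' @param reference reference sequence as returned by [mitoReference()];
#'   used to fill in reference bases and resolve transition/transversion. If
#'   a token carries an explicit reference base that conflicts with the
#'   reference, parsing fails.
#' @return An event \code{data.frame} (see [emptyEvents()]), sorted by
#'   position.
#' @seealso [serializeVariant()] for the inverse.
#' @examples
#' parseVariant(c("16189", "8278.1C", "8281-8289d", "408A", "16311!"))
#' @export
parseVariant <- function(tokens, reference = mitoReference()) {
  tokens <- trimws(as.character(tokens))
  tokens <- tokens[nzchar(tokens)]
  if (length(tokens) == 0L) return(emptyEvents())
  rows <- lapply(tokens, .parseOne, reference = reference)
  sortEvents(do.call(rbind, rows))
}

.refBase <- function(reference, pos) {
  if (is.null(reference)) return(NA_character_)
  if (pos < 1L || pos > length(reference))
    stop("position ", pos, " outside the reference frame (1-",
         length(reference), ")")
  reference[pos]
}

.parseOne <- function(token, reference) {
  raw <- token
  back <- grepl("!$", token)
  token <- sub("!$", "", token)
  if (grepl("^(\\d+)-(\\d+)d(el)?$", token)) {
    m <- regmatches(token, regexec("^(\\d+)-(\\d+)d(el)?$", token))[[1]]
    p1 <- as.integer(m[2]); p2 <- as.integer(m[3])
    if (p2 < p1) stop("malformed deletion span: ", raw)
    .refBase(reference, p2)
    return(.eventRow(p1, end = p2, kind = "deletion", back = back))
  }
  if (grepl("^(\\d+)d(el)?$", token)) {
    p <- as.integer(sub("d(el)?$", "", token))
    return(.eventRow(p, ref = .refBase(reference, p), kind = "deletion",
                     back = back))
  }
  if (grepl("^(\\d+)\\.(\\d+)([ACGT]+)$", token)) {
    m <- regmatches(token, regexec("^(\\d+)\\.(\\d+)([ACGT]+)$", token))[[1]]
    p <- as.integer(m[2])
    .refBase(reference, p)
    return(.eventRow(p, kind = "insertion", insOffset = as.integer(m[3]),
                     insSeq = m[4], back = back))
  }
  if (grepl("^[ACGT]\\d+[ACGT]$", token)) {
    refb <- substr(token, 1L, 1L)
    derb <- substr(token, nchar(token), nchar(token))
    p <- as.integer(substr(token, 2L, nchar(token) - 1L))
    have <- .refBase(reference, p)
    if (!is.na(have) && have != refb)
      stop("reference base conflict at np ", p, ": token says ", refb,
           ", reference has ", have)
    if (refb == derb) stop("no-op substitution: ", raw)
    return(.eventRow(p, ref = refb, derived = derb,
                     kind = .subKind(refb, derb), back = back))
  }
  if (grepl("^\\d+[ACGT]$", token)) {
    derb <- substr(token, nchar(token), nchar(token))
    p <- as.integer(substr(token, 1L, nchar(token) - 1L))
    refb <- .refBase(reference, p)
    if (!is.na(refb) && refb == derb) stop("no-op substitution: ", raw)
    kind <- if (is.na(refb)) "transversion" else .subKind(refb, derb)
    return(.eventRow(p, ref = refb, derived = derb, kind = kind, back = back))
  }
  if (grepl("^\\d+$", token)) {
    p <- as.integer(token)
    refb <- .refBase(reference, p)
    derb <- if (is.na(refb)) NA_character_ else unname(.TS_PARTNER[refb])
    return(.eventRow(p, ref = refb, derived = derb, kind = "transition",
                     back = back))
  }
  stop("malformed variant token: ", raw)
}

#' Serialize mutation events to canonical tokens
#'
#' Produces the canonical dialect: transitions as the bare position,
#' transversions (and any substitution whose derived base must be stated) as
#' position + derived base, insertions as \code{"np.kSEQ"}, deletions as
#' \code{"npd"} or \code{"np1-np2d"}, with a \code{"!"} suffix for back
#' mutations. \code{parseVariant(serializeVariant(ev))} round-trips.
#'
#' @param events an event \code{data.frame}.
#' @param back include the \code{"!"} back-mutation suffix (default TRUE).
#' @return character vector of tokens, one per event row.
#' @export
serializeVariant <- function(events, back = TRUE) {
  if (nrow(events) == 0L) return(character())
  tok <- character(nrow(events))
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    tok[i] <- switch(e$kind,
      transition = as.character(e$position),
      transversion = paste0(e$position, e$derived),
      insertion = paste0(e$position, ".", e$insOffset, e$insSeq),
      deletion = if (e$end > e$position)
        paste0(e$position, "-", e$end, "d") else paste0(e$position, "d"),
      stop("unknown event kind: ", e$kind))
  }
  if (back) tok <- paste0(tok, ifelse(events$back, "!", ""))
  tok
}

#' Canonical site keys for mutation events
#'
#' Tokens with the back-mutation suffix stripped; used wherever events are
#' matched as sites (motif matching, parsimony characters).
#'
#' @param events an event \code{data.frame}.
#' @return character vector of keys.
#' @export
eventKey <- function(events) serializeVariant(events, back = FALSE)
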