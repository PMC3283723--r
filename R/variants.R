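#' Call variants between two aligned sequences
#'
#' Both sequences must share one coordinate frame (equal aligned length, gap
#' characters \code{"-"} permitted). Positions are numbered by counting
#' non-gap reference characters starting at \code{start}. Substitutions are
#' classified transition/transversion; a gap in the sample opposite reference
#' bases yields a (span) deletion; bases in the sample opposite reference
#' gaps yield insertion events, one per inserted base, anchored at the last
#' reference np. Ambiguity codes are treated as missing and produce no call.
#'
#' @param sample,reference aligned sequences (single strings or character
#'   vectors of single characters).
#' @param region region of the resulting profile.
#' @param start np of the first reference base in the alignment.
#' @return a [VariantProfile-class].
#' @examples
#' diffProfiles("ACAT", "ACGT", region = c(101, 104), start = 101)
#' @export
diffProfiles <- function(sample, reference, region = "complete", start = 1L) {
  s <- .asChars(sample); r <- .asChars(reference)
  if (length(s) != length(r))
    stop("aligned lengths differ (", length(s), " vs ", length(r), ")")
  ok <- c("A", "C", "G", "T", "-")
  if (!all(s %in% c(ok, "N")) || !all(r %in% c(ok, "N")))
    stop("non-IUPAC characters in input (only ACGTN- supported)")
  np <- start - 1L
  rows <- list(); delStart <- NA_integer_; delEnd <- NA_integer_
  insOff <- 0L
  flushDel <- function() {
    if (!is.na(delStart))
      rows[[length(rows) + 1L]] <<- .eventRow(delStart, end = delEnd,
                                              kind = "deletion")
    delStart <<- NA_integer_; delEnd <<- NA_integer_
  }
  for (i in seq_along(r)) {
    rc <- r[i]; sc <- s[i]
    if (rc != "-") { np <- np + 1L; insOff <- 0L }
    if (rc == "-" && sc == "-") next
    if (rc == "-") {            # insertion relative to reference
      flushDel()
      if (sc == "N") next
      insOff <- insOff + 1L
      rows[[length(rows) + 1L]] <- .eventRow(np, kind = "insertion",
                                             insOffset = insOff, insSeq = sc)
    } else if (sc == "-") {     # deletion
      if (is.na(delStart)) delStart <- np
      delEnd <- np
    } else {
      flushDel()
      if (sc != rc && sc != "N" && rc != "N")
        rows[[length(rows) + 1L]] <- .eventRow(np, ref = rc, derived = sc,
                                               kind = .subKind(rc, sc))
    }
  }
  flushDel()
  ev <- if (length(rows)) do.call(rbind, rows) else emptyEvents()
  variantProfile(ev, region = region)
}

.asChars <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) x <- strsplit(x, "")[[1L]]
  toupper(x)
}

#' Apply a variant profile to a reference sequence
#'
#' Reconstructs the sample sequence: the inverse of [diffProfiles()] on
#' ungapped frames. Events flagged as back mutations are skipped (they denote
#' reversion to the reference state).
#'
#' @param reference ungapped reference (string or character vector).
#' @param profile a [VariantProfile-class] or event table.
#' @param start np of the first reference base.
#' @return the edited sequence as a single string.
#' @export
applyProfile <- function(reference, profile, start = 1L) {
  r <- .asChars(reference)
  ev <- if (is(profile, "VariantProfile")) variantEvents(profile) else profile
  out <- as.list(r)                      # out[[i]]: replacement for base i
  ins <- vector("list", length(r) + 1L)  # insertions after base i (1-based+1)
  for (i in seq_len(nrow(ev))) {
    e <- ev[i, ]
    if (isTRUE(e$back)) next
    idx <- e$position - start + 1L
    if (e$kind %in% c("transition", "transversion")) {
      stopifnot(idx >= 1L, idx <= length(r))
      out[[idx]] <- e$derived
    } else if (e$kind == "deletion") {
      for (j in (e$position:e$end) - start + 1L) out[[j]] <- ""
    } else if (e$kind == "insertion") {
      ins[[idx + 1L]] <- paste0(if (is.null(ins[[idx + 1L]])) "" else
        ins[[idx + 1L]], e$insSeq)
    }
  }
  pieces <- character(length(r))
  for (i in seq_along(r))
    pieces[i] <- paste0(out[[i]],
                        if (!is.null(ins[[i + 1L]])) ins[[i + 1L]] else "")
  paste0(pieces, collapse = "")
}

#' Apply the phylogenetic exclusion mask
#'
#' Removes events at the masked point positions for every event kind, and
#' removes point indels and transversions (only) inside the masked ranges;
#' transitions inside those ranges are retained. Idempotent.
#'
#' @param profile a [VariantProfile-class] (or bare event table).
#' @param mask mask as returned by [defaultExclusionMask()].
#' @return object of the same type as \code{profile}, filtered.
#' @examples
#' p <- variantProfile(c("16519", "16189", "16093"), region = "HVS1")
#' applyExclusionMask(p)   # 16519 dropped, 16189 kept (transition)
#' @export
applyExclusionMask <- function(profile, mask = defaultExclusionMask()) {
  ev <- if (is(profile, "VariantProfile")) variantEvents(profile) else profile
  if (nrow(ev)) {
    atPoint <- vapply(seq_len(nrow(ev)), function(i)
      any(mask$points >= ev$position[i] & mask$points <= ev$end[i]), TRUE)
    inRange <- vapply(seq_len(nrow(ev)), function(i)
      any(ev$position[i] <= mask$ranges[, "end"] &
          ev$end[i] >= mask$ranges[, "start"]), TRUE)
    maskable <- ev$kind %in% c("insertion", "deletion", "transversion")
    ev <- ev[!(atPoint | (inRange & maskable)), , drop = FALSE]
    rownames(ev) <- NULL
  }
  if (is(profile, "VariantProfile"))
    new("VariantProfile", events = ev, region = profile@region) else ev
}

.MITO_CODE <- NULL

.mitoCode <- function() {
  if (is.null(.pkgCache$code))
    .pkgCache$code <- Biostrings::getGeneticCode("2")  # vertebrate mito
  .pkgCache$code
}

.COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Functional classification of mutation events
#'
#' Labels each event by genomic compartment and, for substitutions in
#' protein-coding genes, by synonymy under the vertebrate mitochondrial code:
#' \code{control} (np 16024-16569 and 1-576), \code{rRNA}, \code{tRNA},
#' \code{coding_synonymous}, \code{coding_nonsynonymous} or
#' \code{intergenic}. At positions covered by overlapping genes the call is
#' synonymous only if synonymous in \emph{every} overlapping reading frame;
#' the light-strand gene (ND6) is evaluated on the complementary strand.
#' Indels inside protein genes fall back to \code{coding_nonsynonymous}
#' (frame-disrupting); indels elsewhere get the compartment label.
#'
#' @param events event table or [VariantProfile-class].
#' @param annotation gene annotation (default [mitoAnnotation()]).
#' @param reference reference bases (default [mitoReference()]).
#' @return character vector of labels, one per event.
#' @export
classifyFunctional <- function(events, annotation = mitoAnnotation(),
                               reference = mitoReference()) {
  ev <- if (is(events, "VariantProfile")) variantEvents(events) else events
  vapply(seq_len(nrow(ev)), function(i)
    .classifyOne(ev[i, ], annotation, reference), character(1L))
}

.classifyOne <- function(e, ann, ref) {
  p <- e$position
  if (p >= 16024L || p <= 576L) return("control")
  hits <- ann[ann$start <= p & ann$end >= p, , drop = FALSE]
  if (nrow(hits) == 0L) return("intergenic")
  types <- unique(hits$type)
  if (!"protein" %in% types) return(types[1L])
  isSub <- e$kind %in% c("transition", "transversion")
  if (!isSub) return("coding_nonsynonymous")
  prot <- hits[hits$type == "protein", , drop = FALSE]
  syn <- vapply(seq_len(nrow(prot)), function(j)
    .isSynonymous(p, e$derived, prot[j, ], ref), NA)
  if (all(syn, na.rm = TRUE) && !any(is.na(syn))) "coding_synonymous"
  else "coding_nonsynonymous"
}

.isSynonymous <- function(p, derived, gene, ref) {
  if (gene$strand == "+") {
    off <- p - gene$start
    c1 <- p - off %% 3L
    nps <- c1 + 0:2
    if (nps[3L] > gene$end) return(NA)  # incomplete trailing codon
    codon <- ref[nps]
    mut <- codon; mut[p - c1 + 1L] <- derived
  } else {
    off <- gene$end - p
    c1 <- p + off %% 3L                 # first codon position (highest np)
    nps <- c1 - 0:2
    if (nps[3L] < gene$start) return(NA)
    codon <- unname(.COMPLEMENT[ref[nps]])
    mut <- codon; mut[c1 - p + 1L] <- unname(.COMPLEMENT[derived])
  }
  code <- .mitoCode()
  unname(code[paste(codon, collapse = "")]) ==
    unname(code[paste(mut, collapse = "")])
}

#' Count mutations under a calibrated clock
#'
#' Counting rules: \code{complete_genome} counts every substitution (indels
#' are never counted); \code{coding_region} counts substitutions with
#' 577 <= np <= 16023; \code{synonymous} counts only substitutions classified
#' \code{coding_synonymous}. Events should already be exclusion-masked.
#'
#' @param events event table or [VariantProfile-class].
#' @param clock a [clockSpec()] or clock name.
#' @param annotation,reference used for synonymy classification.
#' @return integer mutation count.
#' @export
countForClock <- function(events, clock = clockSpec("complete_genome"),
                          annotation = mitoAnnotation(),
                          reference = mitoReference()) {
  if (is.character(clock)) clock <- clockSpec(clock)
  ev <- if (is(events, "VariantProfile")) variantEvents(events) else events
  subs <- ev[ev$kind %in% c("transition", "transversion"), , drop = FALSE]
  if (nrow(subs) == 0L) return(0L)
  switch(clock$name,
    complete_genome = nrow(subs),
    coding_region = sum(subs$position >= 577L & subs$position <= 16023L),
    synonymous = sum(classifyFunctional(subs, annotation, reference) ==
                       "coding_synonymous"),
    stop("unknown clock: ", clock$name))
}
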