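.pkgCache <- new.env(parent = emptyenv())

#' Packaged synthetic mitochondrial reference sequence
#'
#' Returns the package's 16,569-np reference as a character vector of single
#' bases, indexable by nucleotide position (np). The sequence is
#' \emph{synthetic}: it follows the canonical human mtDNA coordinate frame
#' (region bounds, gene order, a 9-bp repeat in the COII/tRNA-Lys spacer) but
#' its base identities are a deterministic random draw, regenerable with
#' \code{inst/scripts/make_synthetic_reference.R}. All coordinate-dependent
#' behaviour (masking, clocks, synonymy calls against this annotation) is
#' exact; base identities at real rCRS positions are not reproduced.
#'
#' @return named character vector of length 16569 (names are positions).
#' @export
mitoReference <- function() {
  if (is.null(.pkgCache$reference)) {
    path <- system.file("extdata", "synthetic_mtref.fasta",
                        package = "mitophylo", mustWork = TRUE)
    ss <- Biostrings::readDNAStringSet(path)
    s <- strsplit(as.character(ss[[1L]]), "")[[1L]]
    names(s) <- seq_along(s)
    .pkgCache$reference <- s
  }
  .pkgCache$reference
}

#' Packaged gene annotation
#'
#' The synthetic annotation table: 13 protein-coding genes, 2 rRNAs and tRNA
#' blocks at canonical human mtDNA coordinates, with ND6 on the light strand
#' and the ATP8/ATP6 and ND4L/ND4 overlaps preserved. tRNA clusters are
#' represented as blocks spanning the gaps between named features.
#'
#' @return data.frame with columns feature, type, start, end, strand.
#' @export
mitoAnnotation <- function() {
  if (is.null(.pkgCache$annotation)) {
    path <- system.file("extdata", "synthetic_mito_genes.tsv",
                        package = "mitophylo", mustWork = TRUE)
    ann <- utils::read.delim(path, comment.char = "#",
                             stringsAsFactors = FALSE)
    stopifnot(sum(ann$type == "protein") == 13L,
              sum(ann$type == "protein" & ann$strand == "-") == 1L)
    .pkgCache$annotation <- ann
  }
  .pkgCache$annotation
}

.REGIONS <- list(HVS1 = c(16024L, 16400L), HVS2 = c(57L, 372L),
                 coding = c(577L, 16023L), complete = c(1L, 16569L))

#' Region bounds
#'
#' Default analysis windows: HVS1 16024-16400, HVS2 57-372, coding 577-16023,
#' complete 1-16569. Alternative windows can be supplied wherever a region is
#' accepted by passing a length-2 integer vector instead of a name.
#'
#' @param region region name or a length-2 integer vector of bounds.
#' @return integer vector \code{c(start, end)}.
#' @export
regionBounds <- function(region = "complete") {
  if (is.numeric(region)) {
    stopifnot(length(region) == 2L, region[1] <= region[2])
    return(as.integer(region))
  }
  b <- .REGIONS[[match.arg(region, names(.REGIONS))]]
  b
}

.CLOCK_RATES <- c(complete_genome = 3624, coding_region = 4610,
                  synonymous = 7884)

#' Calibrated mutation clocks
#'
#' The three fixed per-mutation calibrations used for age conversion: one
#' mutation every 3624 years over the complete genome, every 4610 years over
#' coding-region substitutions (np 577-16023), and every 7884 years over
#' synonymous substitutions. Each clock also fixes the counting rule applied
#' by [countForClock()].
#'
#' @param name one of \code{"complete_genome"}, \code{"coding_region"},
#'   \code{"synonymous"}.
#' @return list with elements \code{name} and \code{yearsPerMutation}.
#' @export
clockSpec <- function(name = c("complete_genome", "coding_region",
                               "synonymous")) {
  name <- match.arg(name)
  list(name = name, yearsPerMutation = unname(.CLOCK_RATES[name]))
}

#' Default phylogenetic exclusion mask
#'
#' Np 16519 is dropped outright; within the hypervariable stretches
#' 16180-16193, 303-315, 522-524 and 960-963 only point indels and
#' transversions are dropped while transitions are retained.
#'
#' @return list with \code{points} (integer positions removed for all event
#'   kinds) and \code{ranges} (2-column matrix of intervals in which indels
#'   and transversions are removed).
#' @export
defaultExclusionMask <- function() {
  list(points = 16519L,
       ranges = matrix(c(16180L, 16193L, 303L, 315L, 522L, 524L,
                         960L, 963L), ncol = 2L, byrow = TRUE,
                       dimnames = list(NULL, c("start", "end"))))
}
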