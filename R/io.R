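#' Read a variant-profile TSV
#'
#' Expected columns: \code{sample_id}, \code{population}, \code{variants}
#' (space-separated canonical tokens; empty for the reference haplotype).
#'
#' @param path TSV file.
#' @param region region assigned to all profiles.
#' @param reference reference used for parsing.
#' @return named list of [VariantProfile-class]; the \code{populations}
#'   attribute carries the sample -> population map.
#' @export
readProfilesTSV <- function(path, region = "complete",
                            reference = mitoReference()) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character")
  stopifnot(all(c("sample_id", "variants") %in% names(df)))
  profs <- lapply(df$variants, function(s) {
    toks <- strsplit(trimws(ifelse(is.na(s), "", s)), "\\s+")[[1L]]
    variantProfile(parseVariant(toks[nzchar(toks)], reference), region)
  })
  names(profs) <- df$sample_id
  if (!is.null(df$population)) {
    pops <- df$population; names(pops) <- df$sample_id
    attr(profs, "populations") <- pops
  }
  profs
}

#' Write variant profiles to TSV
#'
#' @param profiles named list of [VariantProfile-class].
#' @param path output TSV.
#' @param populations optional named sample -> population vector.
#' @return the path, invisibly.
#' @export
writeProfilesTSV <- function(profiles, path, populations = NULL) {
  ids <- names(profiles)
  df <- data.frame(
    sample_id = ids,
    population = if (is.null(populations)) "" else unname(populations[ids]),
    variants = vapply(profiles, function(p)
      paste(serializeVariant(variantEvents(p)), collapse = " "), ""),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Variant profiles from an aligned FASTA
#'
#' Sequences must be pre-aligned to the reference window of \code{region}
#' (equal length; gaps allowed in the sample for deletions). Ambiguity codes
#' are treated as missing.
#'
#' @param path FASTA file.
#' @param region region name or bounds.
#' @param reference reference bases.
#' @return named list of [VariantProfile-class].
#' @export
profilesFromFasta <- function(path, region = "HVS1",
                              reference = mitoReference()) {
  b <- regionBounds(if (is.character(region)) region else region)
  ss <- Biostrings::readDNAStringSet(path)
  refWin <- paste(reference[b[1]:b[2]], collapse = "")
  profs <- lapply(seq_along(ss), function(i)
    diffProfiles(as.character(ss[[i]]), refWin, region = region,
                 start = b[1]))
  names(profs) <- sub("\\s.*$", "", names(ss))
  profs
}
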