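#' Read a plain-text pipeline configuration
#'
#' \code{key = value} lines; \code{#} starts a comment. Values that look
#' numeric or logical are converted.
#'
#' @param path config file.
#' @return named list.
#' @export
readPipelineConfig <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    key <- trimws(kv[1L]); val <- trimws(paste(kv[-1L], collapse = "="))
    if (grepl("^(true|false)$", tolower(val)))
      val <- tolower(val) == "true"
    else if (grepl("^-?[0-9.]+$", val)) val <- as.numeric(val)
    out[[key]] <- val
  }
  out
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
}

.writeTsv <- function(x, path, rowNames = FALSE) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = rowNames, col.names = TRUE)
  path
}

#' Run the analysis pipeline
#'
#' Orchestrates classify -> diversity -> tree -> date -> ordinate over a
#' profile table (or a precomputed haplogroup count table), writing a
#' deterministic TSV bundle plus a run log. Recognised config keys:
#' \code{profiles} (TSV path), \code{region}, \code{tree} (haplogroup tree
#' TSV; default the packaged fixture), \code{componentsMap} (TSV haplogroup
#' -> component), \code{countsTable} (haplogroup count matrix TSV; enables
#' the frequency/component stage without profiles), \code{mask} (apply the
#' exclusion mask; default TRUE), \code{dateNodes} (comma-separated tree
#' node labels; default \code{root}), \code{clocks} (\code{all} or comma
#' list), \code{outDir} and \code{seed} (mandatory whenever a stochastic
#' stage runs).
#'
#' @param config named list or path to a config file.
#' @return invisibly, the named vector of files written.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  cfg <- utils::modifyList(list(region = "complete", mask = TRUE,
                                dateNodes = "root", clocks = "all",
                                outDir = "pipeline_out", seed = 1),
                           config)
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  set.seed(as.integer(cfg$seed))
  written <- character()
  log <- c(paste0("mitophylo pipeline | package ",
                  as.character(utils::packageVersion("mitophylo"))),
           paste0("seed = ", cfg$seed),
           paste0("region = ", cfg$region),
           paste0("mask = ", cfg$mask))
  out <- function(f) file.path(cfg$outDir, f)
  emit <- function(x, f, rowNames = FALSE) {
    .writeTsv(x, out(f), rowNames)
    written[f] <<- out(f)
    log <<- c(log, paste0("wrote ", f))
  }

  compMap <- if (!is.null(cfg$componentsMap))
    utils::read.delim(cfg$componentsMap, comment.char = "#",
                      stringsAsFactors = FALSE) else NULL

  if (!is.null(cfg$countsTable)) .stage("frequencies", {
    ft <- readFrequencyTable(cfg$countsTable)
    emit(data.frame(haplogroup = rownames(hgCounts(ft)), hgCounts(ft),
                    check.names = FALSE), "frequency_counts.tsv")
    emit(data.frame(haplogroup = rownames(hgCounts(ft)), percentTable(ft),
                    check.names = FALSE), "frequency_percent.tsv")
    if (!is.null(compMap)) {
      cs <- componentShares(ft, compMap)
      emit(data.frame(component = rownames(cs), round(cs, 1L),
                      check.names = FALSE), "component_shares.tsv")
    }
  })

  if (is.null(cfg$profiles)) {
    writeLines(log, out("run_log.txt"))
    return(invisible(c(written, run_log.txt = out("run_log.txt"))))
  }

  hgTree <- if (is.null(cfg$tree)) fixtureHaplogroupTree() else
    readHaplogroupTree(cfg$tree)
  profiles <- .stage("load", readProfilesTSV(cfg$profiles, cfg$region))
  pops <- attr(profiles, "populations")
  if (isTRUE(cfg$mask))
    profiles[] <- lapply(profiles, applyExclusionMask)
  log <- c(log, paste0("profiles = ", length(profiles)))

  assignments <- .stage("classify", {
    a <- classifySamples(profiles, hgTree, pops)
    emit(a, "assignments.tsv")
    a
  })

  if (!is.null(pops)) .stage("frequencies", {
    ft <- frequencyTable(assignments)
    emit(data.frame(haplogroup = rownames(hgCounts(ft)), hgCounts(ft),
                    check.names = FALSE), "frequency_counts.tsv")
    emit(data.frame(haplogroup = rownames(hgCounts(ft)), percentTable(ft),
                    check.names = FALSE), "frequency_percent.tsv")
    if (!is.null(compMap) &&
        all(rownames(hgCounts(ft)) %in% compMap$haplogroup)) {
      cs <- componentShares(ft, compMap)
      emit(data.frame(component = rownames(cs), round(cs, 1L),
                      check.names = FALSE), "component_shares.tsv")
    }
  })

  if (!is.null(pops)) .stage("diversity", {
    rows <- list()
    for (p in unique(pops)) {
      ids <- names(pops)[pops == p]
      if (length(ids) < 2L) next
      ps <- populationSample(profiles[ids], name = p, region = cfg$region)
      st <- haplotypeStats(ps)
      tk <- thetaK(st$n, st$K)
      rows[[p]] <- data.frame(
        population = p, n = st$n, H = round(st$H, 3L),
        H_se = round(st$Hse, 3L), K = st$K, S = st$S,
        Pi = round(st$Pi, 3L), Pi_se = round(st$PiSE, 3L),
        theta_k = round(tk$theta, 2L), theta_ci_low = round(tk$ciLow, 2L),
        theta_ci_high = round(tk$ciHigh, 2L),
        tajima_D = round(tajimasD(st), 3L),
        fu_Fs = round(fusFs(st), 3L), stringsAsFactors = FALSE)
    }
    if (length(rows)) emit(do.call(rbind, rows), "diversity.tsv")
  })

  mp <- .stage("tree", {
    res <- buildMpTree(profiles, region = cfg$region)
    writeLines(exportNewick(res$tree), out("tree.nwk"))
    written["tree.nwk"] <- out("tree.nwk")
    log <- c(log, paste0("parsimony score = ", res$score))
    res
  })

  .stage("date", {
    clocks <- if (identical(cfg$clocks, "all")) names(.CLOCK_RATES) else
      strsplit(cfg$clocks, ",")[[1L]]
    nodes <- intersect(strsplit(cfg$dateNodes, ",")[[1L]],
                       mp$tree@labels)
    if (length(nodes))
      emit(founderAgeReport(mp$tree, nodes, clocks), "dating.tsv")
  })

  if (!is.null(pops) && length(unique(pops)) >= 2L) .stage("ordinate", {
    popNames <- names(which(table(pops) >= 2L))
    if (length(popNames) >= 2L) {
      samples <- lapply(popNames, function(p)
        populationSample(profiles[names(pops)[pops == p]], name = p,
                         region = cfg$region))
      fst <- fstMatrix(samples)
      emit(data.frame(population = rownames(fst), round(fst, 4L),
                      check.names = FALSE), "fst_matrix.tsv")
      if (length(popNames) >= 3L) {
        mds <- nmdsOrdination(fst, seed = as.integer(cfg$seed))
        emit(data.frame(population = rownames(mds$points),
                        round(mds$points, 4L),
                        stress = round(mds$stress, 4L),
                        check.names = FALSE), "mds_coords.tsv")
      }
    }
  })

  writeLines(log, out("run_log.txt"))
  written["run_log.txt"] <- out("run_log.txt")
  invisible(written)
}
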