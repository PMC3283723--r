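test_that("token parsing matches the published notation forms", {
  ev <- parseVariant(c("16189", "8278.1C", "408A", "8281-8289d", "16311!",
                       "A8860G", "522d"))
  expect_equal(nrow(ev), 7L)
  e16189 <- ev[ev$position == 16189L, ]
  expect_equal(e16189$kind, "transition")
  expect_equal(e16189$ref, "T")      # pinned in the synthetic reference
  expect_equal(e16189$derived, "C")
  e408 <- ev[ev$position == 408L, ]
  expect_equal(e408$kind, "transversion")
  expect_equal(e408$derived, "A")
  ins <- ev[ev$kind == "insertion", ]
  expect_equal(ins$position, 8278L)
  expect_equal(ins$insOffset, 1L)
  expect_equal(ins$insSeq, "C")
  del <- ev[ev$kind == "deletion" & ev$end > ev$position, ]
  expect_equal(c(del$position, del$end), c(8281L, 8289L))
  expect_true(ev$back[ev$position == 16311L])
})

test_that("parsing rejects malformed and conflicting tokens", {
  expect_error(parseVariant("xyz"), "malformed")
  expect_error(parseVariant("99999"), "outside the reference")
  expect_error(parseVariant("G8860A"), "conflict")     # reference has A
  expect_error(parseVariant("8860A"), "no-op")
})

test_that("serialize/parse round-trips over generated events", {
  set.seed(42)
  for (rep in 1:25) {
    pos <- sample(500:16000, 6)
    toks <- c(as.character(pos[1:2]),
              paste0(pos[3], setdiff(c("A", "C", "G", "T"),
                                     REF[pos[3]])[1]),
              paste0(pos[4], ".1", sample(c("A", "C"), 1)),
              paste0(pos[5], "d"),
              paste0(pos[6], "!"))
    ev <- parseVariant(toks)
    again <- parseVariant(serializeVariant(ev))
    expect_identical(again, ev)
  }
})

test_that("diffProfiles calls substitutions, indels and round-trips", {
  # identity
  expect_equal(nrow(variantEvents(diffProfiles("ACGT", "ACGT",
                                               region = c(101, 104),
                                               start = 101))), 0L)
  # transition at np 103 (G>A) on a 4-np toy frame
  p <- diffProfiles("ACAT", "ACGT", region = c(101, 104), start = 101)
  expect_equal(serializeVariant(variantEvents(p)), "103")
  expect_equal(variantEvents(p)$kind, "transition")
  # a true transversion
  p2 <- diffProfiles("ACTT", "ACGT", region = c(101, 104), start = 101)
  expect_equal(variantEvents(p2)$kind, "transversion")
  # gap opposite reference C at np 522 -> deletion 522d
  p3 <- diffProfiles("A-G", paste0("A", "C", "G"), region = c(521, 523),
                     start = 521)
  expect_equal(serializeVariant(variantEvents(p3)), "522d")
  # insertion relative to the reference
  p4 <- diffProfiles("ACCG", "AC-G", region = c(301, 303), start = 301)
  ins <- variantEvents(p4)
  expect_equal(ins$kind, "insertion")
  expect_equal(ins$position, 302L)
  expect_error(diffProfiles("ACG", "ACGT"), "lengths differ")
  expect_error(diffProfiles("AXGT", "ACGT"), "non-IUPAC")
})

test_that("applying a called profile reconstructs the sample exactly", {
  set.seed(7)
  for (rep in 1:20) {
    L <- 30L
    ref <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    smp <- ref
    i <- sample(L, 3)
    smp[i[1]] <- setdiff(c("A", "C", "G", "T"), ref[i[1]])[sample(3, 1)]
    aligned_ref <- ref; aligned_smp <- smp
    aligned_smp[i[2]] <- "-"                         # deletion
    aligned_ref <- append(aligned_ref, "-", after = i[3])
    aligned_smp <- append(aligned_smp, "T", after = i[3])
    prof <- diffProfiles(aligned_smp, aligned_ref, region = c(1001, 1000 + L),
                         start = 1001)
    rebuilt <- applyProfile(paste(ref, collapse = ""), prof, start = 1001)
    expect_equal(rebuilt, gsub("-", "", paste(aligned_smp, collapse = "")))
  }
})

test_that("exclusion mask drops 16519 and range indels but keeps transitions", {
  p <- variantProfile(c("16519"), region = "complete")
  expect_equal(nrow(variantEvents(applyExclusionMask(p))), 0L)
  p2 <- variantProfile(c("16189"), region = "HVS1")   # transition in 16180-16193
  expect_equal(serializeVariant(variantEvents(applyExclusionMask(p2))),
               "16189")
  p3 <- variantProfile(c("309.1C", "16093"), region = c(1, 16569))
  expect_equal(serializeVariant(variantEvents(applyExclusionMask(p3))),
               "16093")
  # transversion inside a masked range is dropped
  tv <- paste0(16183, if (REF[16183] %in% c("A", "G")) "C" else "A")
  p4 <- variantProfile(c(tv, "16223"), region = "HVS1")
  expect_equal(serializeVariant(variantEvents(applyExclusionMask(p4))),
               "16223")
})

test_that("exclusion mask is idempotent", {
  set.seed(11)
  for (rep in 1:10) {
    p <- tprof(sample(16024:16400, 8), region = "HVS1")
    once <- applyExclusionMask(p)
    expect_identical(applyExclusionMask(once), once)
  }
})

test_that("functional classification agrees with a whole-gene translation oracle", {
  code <- Biostrings::getGeneticCode("2")
  translateGene <- function(bases, strand) {
    if (strand == "-")
      bases <- rev(unname(c(A = "T", T = "A", C = "G", G = "C")[bases]))
    s <- paste(bases, collapse = "")
    nc <- 3L * (nchar(s) %/% 3L)
    as.character(Biostrings::translate(
      Biostrings::DNAString(substr(s, 1L, nc)),
      genetic.code = code))
  }
  prot <- ANN[ANN$type == "protein", ]
  overlapped <- function(p) sum(prot$start <= p & prot$end >= p) > 1L
  set.seed(13)
  genes <- prot[sample(nrow(prot), 6L), ]
  for (g in seq_len(nrow(genes))) {
    gene <- genes[g, ]
    for (rep in 1:5) {
      p <- sample(gene$start:gene$end, 1L)
      if (overlapped(p)) next
      der <- setdiff(c("A", "C", "G", "T"), REF[p])[sample(3, 1)]
      ev <- parseVariant(paste0(p, der))
      lab <- classifyFunctional(ev)
      mut <- REF; mut[p] <- der
      syn <- identical(translateGene(REF[gene$start:gene$end], gene$strand),
                       translateGene(mut[gene$start:gene$end], gene$strand))
      expect_equal(lab, if (syn) "coding_synonymous" else
        "coding_nonsynonymous",
        info = sprintf("np %d in %s", p, gene$feature))
    }
  }
})

test_that("compartment labels and the overlap rule are honoured", {
  expect_equal(classifyFunctional(parseVariant("16189")), "control")
  expect_equal(classifyFunctional(parseVariant("300")), "control")
  expect_equal(classifyFunctional(parseVariant("1000")), "rRNA")
  expect_equal(classifyFunctional(parseVariant("600")), "tRNA")
  expect_equal(classifyFunctional(parseVariant("8283")), "intergenic")
  # indel in a protein gene falls back to nonsynonymous
  expect_equal(classifyFunctional(parseVariant("6000d")),
               "coding_nonsynonymous")
  # ATP8/ATP6 overlap: synonymous requires synonymy in both frames
  p <- 8550L
  for (der in setdiff(c("A", "C", "G", "T"), REF[p])) {
    ev <- parseVariant(paste0(p, der))
    lab <- classifyFunctional(ev)
    synEach <- vapply(c("ATP8", "ATP6"), function(gn) {
      gene <- ANN[ANN$feature == gn, ]
      mitophylo:::.isSynonymous(p, der, gene, REF)
    }, NA)
    expect_equal(lab, if (all(synEach)) "coding_synonymous" else
      "coding_nonsynonymous")
  }
})

test_that("clock counting rules are correct and monotone", {
  ev <- parseVariant(c("16189", "8860"))
  expect_equal(countForClock(ev, "coding_region"), 1L)
  expect_equal(countForClock(parseVariant("8281-8289d"), "complete_genome"),
               0L)
  # synonymous example verified through the classifier
  set.seed(21)
  for (rep in 1:10) {
    pos <- sample(200:16500, 8)
    ok <- pos != 16519L
    p <- tprof(pos[ok])
    ev <- variantEvents(p)
    cSyn <- countForClock(ev, "synonymous")
    cCod <- countForClock(ev, "coding_region")
    cAll <- countForClock(ev, "complete_genome")
    expect_lte(cSyn, cCod)
    expect_lte(cCod, cAll)
    expect_equal(cAll, nrow(ev))
  }
  expect_error(countForClock(emptyEvents(), clockSpec("nope")))
})

test_that("clock rates carry the three calibrations", {
  expect_equal(clockSpec("complete_genome")$yearsPerMutation, 3624)
  expect_equal(clockSpec("coding_region")$yearsPerMutation, 4610)
  expect_equal(clockSpec("synonymous")$yearsPerMutation, 7884)
})
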