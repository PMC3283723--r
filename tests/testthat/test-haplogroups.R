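TREE <- fixtureHaplogroupTree()

test_that("fixture tree loads with the published clade placements", {
  expect_s4_class(TREE, "HaplogroupTree")
  expect_equal(hgRoot(TREE), "mt-MRCA")
  expect_equal(TREE@parent[["B4j"]], "B4")
  expect_equal(TREE@parent[["N9a3a"]], "N9a3")
  expect_equal(TREE@parent[["R11b1"]], "R11b")
  # minimal two-node tree is valid
  t2 <- haplogroupTree(data.frame(node = c("r", "a"), parent = c("", "r"),
                                  mutations = c("", "16189")))
  expect_equal(hgNodes(t2), c("r", "a"))
  # orphan parent rejected
  expect_error(haplogroupTree(data.frame(node = c("r", "a"),
                                         parent = c("", "zzz"),
                                         mutations = "")),
               "orphan")
})

test_that("cumulative motifs accumulate and cancel back mutations", {
  expect_equal(nrow(variantEvents(cumulativeMotif(TREE, "mt-MRCA"))), 0L)
  m <- serializeVariant(variantEvents(cumulativeMotif(TREE, "B4b1a3a")))
  expect_true(all(c("408A", "9055", "9388T", "9615", "146", "16086",
                    "16189", "16217", "8281-8289d") %in% m))
  # B4c1 carries 16311; the B4c1a2 back mutation removes it
  expect_true("16311" %in%
    serializeVariant(variantEvents(cumulativeMotif(TREE, "B4c1"))))
  m2 <- serializeVariant(variantEvents(cumulativeMotif(TREE, "B4c1a2")))
  expect_false("16311" %in% m2)
  expect_true("16527" %in% m2)
  expect_error(cumulativeMotif(TREE, "nope"), "unknown node")
})

test_that("assignment maximises matches minus mismatches", {
  a <- assignHaplogroup(variantProfile(c("16189", "8281-8289d")), TREE)
  expect_equal(a$bestNode, "B4'B5")
  expect_equal(a$score, 2L)
  # B4b1a background plus the 146-16086 diagnostic motif
  a2 <- assignHaplogroup(
    variantProfile(c("16189", "8281-8289d", "16217", "146", "16086")), TREE)
  expect_equal(a2$bestNode, "B4b1a3")
  expect_length(a2$missing, 0L)
  # empty profile goes to the root with score 0
  a3 <- assignHaplogroup(variantProfile(), TREE)
  expect_equal(a3$bestNode, "mt-MRCA")
  expect_equal(a3$score, 0L)
  expect_true(a3$ambiguous)   # internal nodes with empty motifs tie
  expect_error(assignHaplogroup(variantProfile(),
                                new("HaplogroupTree", nodes = character(),
                                    parent = character(),
                                    mutations = list())))
})

test_that("a profile equal to a node motif returns that node exactly", {
  for (nd in c("B4b1a3a", "B4c1a2", "N9a3a", "M13a1b", "R11b1", "M10a1a2a")) {
    prof <- cumulativeMotif(TREE, nd)
    a <- assignHaplogroup(prof, TREE)
    expect_equal(a$bestNode, nd)
    expect_length(a$missing, 0L)
    expect_length(a$private, 0L)
  }
})

test_that("private mutations never change the best node", {
  set.seed(5)
  for (rep in 1:12) {
    nd <- sample(c("B4j", "N9a8", "M11b2", "B4b1a3a"), 1L)
    motif <- variantEvents(cumulativeMotif(TREE, nd))
    allMotifPos <- unlist(lapply(TREE@mutations, function(m) m$position))
    free <- setdiff(5000:6000, allMotifPos)
    priv <- mitophylo:::.transitionEvents(sample(free, 3L), REF)
    prof <- variantProfile(rbind(motif, priv))
    expect_equal(assignHaplogroup(prof, TREE)$bestNode, nd)
  }
})

test_that("region-restricted matching ignores unobservable motif positions", {
  # HVS1-only profile: coding-region motif events must not count against it
  prof <- variantProfile(c("16189"), region = "HVS1")
  a <- assignHaplogroup(prof, TREE)
  # B4'B5's only HVS1 motif event is 16189 (the 9-bp deletion is coding)
  expect_equal(a$score, 1L)
  expect_true(a$bestNode %in% c("B4'B5", "R11'B6"))
})

test_that("frequency tables count, round and sum correctly", {
  df <- data.frame(haplogroup = c("A", "A", "B", "B", "B", "C"),
                   population = c("p1", "p1", "p1", "p2", "p2", "p2"))
  ft <- frequencyTable(df)
  expect_equal(unname(populationSizes(ft)), c(3L, 3L))
  expect_equal(hgCounts(ft)["B", "p2"], 2L)
  pct <- percentTable(ft)
  expect_true(all(abs(colSums(pct) - 100) <= 0.1))
  # single sample, one haplogroup
  ft1 <- frequencyTable(data.frame(haplogroup = "X", population = "p"))
  expect_equal(unname(percentTable(ft1)[1, 1]), 100)
  expect_error(frequencyTable(matrix(0L, 1, 1,
                                     dimnames = list("A", "p"))),
               "n = 0")
})

test_that("published frequency-table arithmetic is reproduced from the fixture", {
  ft <- readFrequencyTable(system.file("extdata",
                                       "published_haplogroup_counts.tsv",
                                       package = "mitophylo"))
  expect_equal(unname(populationSizes(ft)), c(149L, 98L))
  pct <- percentTable(ft)
  expect_equal(unname(pct["G2", "Barghuts"]), 8.7)
  expect_equal(unname(pct["D4", "Barghuts"]), 31.5)
  cm <- utils::read.delim(system.file("extdata", "eurasian_components.tsv",
                                      package = "mitophylo"),
                          comment.char = "#")
  sh <- componentShares(ft, cm)
  expect_equal(round(unname(sh["eastern", ]), 1), c(91.9, 60.2))
  expect_true(all(abs(colSums(sh) - 100) < 1e-9))
  # every haplogroup mapped to one component collapses to 100/0
  one <- componentShares(ft, setNames(rep("all", nrow(hgCounts(ft))),
                                      rownames(hgCounts(ft))))
  expect_equal(unname(one["all", ]), c(100, 100), ignore_attr = TRUE)
  expect_error(componentShares(ft, cm[-1, ]), "unmapped")
})

test_that("synthetic mixtures with full motifs are classified without error", {
  mix <- simulateAdmixedPopulation(c(B4j = 0.6, M13a1b = 0.4), n = 200,
                                   seed = 31, privateRate = 1)
  asg <- classifySamples(mix$profiles, TREE, mix$populations)
  expect_equal(sum(asg$haplogroup != mix$labels), 0L)
  ft <- frequencyTable(asg)
  pB4j <- hgCounts(ft)["B4j", "simmix"] / 200
  expect_lt(abs(pB4j - 0.6), 3 * sqrt(0.6 * 0.4 / 200))  # binomial 99%+
  # zero private mutations -> zero mismatches
  mix0 <- simulateAdmixedPopulation(c(N9a8 = 1), n = 20, seed = 8,
                                    privateRate = 0)
  asg0 <- classifySamples(mix0$profiles, TREE)
  expect_true(all(asg0$n_missing == 0L & asg0$n_private == 0L))
})
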