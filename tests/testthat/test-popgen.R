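test_that("haplotype summary statistics match direct formula evaluation", {
  # all identical
  s0 <- populationSample(list(a = "16189", b = "16189", c = "16189"),
                         region = "HVS1")
  st0 <- haplotypeStats(s0)
  expect_equal(st0[c("K", "H", "S", "Pi")],
               list(K = 1L, H = 0, S = 0L, Pi = 0))
  # n = 4, haplotype counts (2, 1, 1): H = (4/3)(1 - 6/16)
  s1 <- populationSample(list(a = "16189", b = "16189", c = "16217",
                              d = c("16217", "16223")), region = "HVS1")
  st1 <- haplotypeStats(s1)
  expect_equal(st1$K, 3L)
  expect_equal(st1$H, (4 / 3) * (1 - 6 / 16))
  # two sequences differing at 3 sites
  s2 <- populationSample(list(a = c("16093", "16126", "16189"),
                              b = character()), region = "HVS1")
  st2 <- haplotypeStats(s2)
  expect_equal(st2$Pi, 3)
  expect_equal(st2$S, 3L)
  expect_error(haplotypeStats(populationSample(list(a = "16189"))), "n >= 2")
})

test_that("H reaches 1 (with correction) when all haplotypes are unique", {
  s <- populationSample(list(a = "16092", b = "16093", c = "16111",
                             d = "16126"), region = "HVS1")
  expect_equal(haplotypeStats(s)$H, 1)
})

test_that("indels are excluded from diversity sites by default", {
  s <- populationSample(list(a = c("16189", "16193.1C"), b = "16189"),
                        region = "HVS1")
  expect_equal(haplotypeStats(s)$S, 0L)
  s2 <- populationSample(list(a = c("16189", "16193.1C"), b = "16189"),
                         region = "HVS1", includeIndels = TRUE)
  expect_equal(haplotypeStats(s2)$S, 1L)
})

test_that("ewensPK matches closed forms, normalises, and matches simulation", {
  # n = 2 closed form
  th <- 3
  expect_equal(ewensPK(2, 1:2, th), c(1 / (th + 1), th / (th + 1)))
  # normalisation
  for (n in c(5L, 50L, 149L, 200L))
    expect_lt(abs(sum(ewensPK(n, 1:n, 1.7)) - 1), 1e-10)
  # exact small-n oracle (plain-precision Stirling recursion)
  for (n in c(5L, 8L, 10L))
    expect_equal(ewensPK(n, 1:n, 2.5), exactEwensPK(n, 2.5),
                 tolerance = 1e-12)
  # Chinese-restaurant Monte Carlo oracle
  set.seed(99)
  n <- 10L; theta <- 2
  reps <- 40000L
  ks <- vapply(seq_len(reps), function(r) {
    k <- 1L
    for (i in 1:(n - 1L)) k <- k + (runif(1) < theta / (theta + i))
    k
  }, 0L)
  pHat <- mean(ks == 3L)
  p <- ewensPK(n, 3L, theta)
  expect_lt(abs(pHat - p), 3 * sqrt(p * (1 - p) / reps))
})

test_that("theta_k reproduces the published point estimates", {
  expect_equal(thetaK(149, 97)$theta, 119.43, tolerance = 0.005 / 119)
  expect_equal(thetaK(98, 58)$theta, 58.84, tolerance = 0.005 / 58)
  expect_equal(thetaK(10, 1)$theta, 0)
  expect_equal(thetaK(10, 10)$theta, Inf)
})

test_that("theta_k is monotone in K and its CI brackets the estimate", {
  ths <- vapply(2:9, function(k) thetaK(10, k)$theta, 0)
  expect_true(all(diff(ths) > 0))
  tk <- thetaK(50, 20)
  expect_lt(tk$ciLow, tk$theta)
  expect_gt(tk$ciHigh, tk$theta)
  # CI endpoints invert the Ewens tails at 2.5%
  expect_equal(sum(ewensPK(50, 20:50, tk$ciLow)), 0.025, tolerance = 1e-4)
  expect_equal(sum(ewensPK(50, 1:20, tk$ciHigh)), 0.025, tolerance = 1e-4)
  # CI width (relative) shrinks with n at fixed K/n
  w1 <- with(thetaK(25, 10), (ciHigh - ciLow) / theta)
  w2 <- with(thetaK(100, 40), (ciHigh - ciLow) / theta)
  expect_lt(w2, w1)
})

test_that("Tajima's D matches the constant-by-constant oracle", {
  set.seed(3)
  # two singletons on different sequences, n = 4
  s <- populationSample(list(a = "16093", b = "16126", c = character(),
                             d = character()), region = "HVS1")
  expect_equal(tajimasD(s), oracleTajimaD(s), tolerance = 1e-9)
  for (rep in 1:8) {
    sim <- simulateCoalescentSample(n = 10L, theta = 3, seed = 300 + rep)
    expect_equal(tajimasD(sim$sample), oracleTajimaD(sim$sample),
                 tolerance = 1e-9)
  }
  # undefined when S = 0
  s0 <- populationSample(list(a = character(), b = character()),
                         region = "HVS1")
  expect_true(is.na(tajimasD(s0)))
})

test_that("Fu's Fs matches the Ewens enumeration oracle on small samples", {
  # n = 3, K = 2 (haplotype counts 2 and 1, one segregating site)
  s <- populationSample(list(a = "16093", b = "16093", c = character()),
                        region = "HVS1")
  st <- haplotypeStats(s)
  expect_equal(st$K, 2L)
  pk <- exactEwensPK(3, st$Pi)
  oracle <- log(sum(pk[2:3]) / (1 - sum(pk[2:3])))
  expect_equal(fusFs(s), oracle, tolerance = 1e-9)
  for (rep in 1:8) {
    sim <- simulateCoalescentSample(n = 9L, theta = 3, seed = 400 + rep)
    st <- haplotypeStats(sim$sample)
    if (st$Pi <= 0) next
    pk <- exactEwensPK(st$n, st$Pi)
    Sp <- sum(pk[st$K:st$n])
    expect_equal(fusFs(sim$sample), log(Sp / (1 - Sp)), tolerance = 1e-9)
  }
  expect_true(is.na(fusFs(list(n = 5, K = 1, Pi = 0))))
})

test_that("neutrality statistics carry the expansion signature", {
  D <- vapply(1:60, function(i)
    tajimasD(simulateCoalescentSample(n = 40L, theta = 5, seed = 600 + i,
                                      model = "expansion")$sample), 0)
  Fs <- vapply(1:60, function(i)
    fusFs(simulateCoalescentSample(n = 40L, theta = 5, seed = 600 + i,
                                   model = "expansion")$sample), 0)
  expect_lt(mean(D, na.rm = TRUE), -1)
  expect_lt(mean(Fs[is.finite(Fs)]), -3)
})

test_that("Fisher's exact test matches enumeration and is symmetric", {
  expect_equal(round(fisherExact2x2(13, 136, 1, 97), 2), 0.01)
  expect_equal(fisherExact2x2(1, 1, 1, 1), 1)
  expect_equal(fisherExact2x2(5, 0, 0, 5), 2 / choose(10, 5),
               tolerance = 1e-12)
  # exhaustive enumeration oracle for a small table
  a <- 4L; b <- 2L; c <- 1L; d <- 5L
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  pObs <- dhyper(a, r1, r2, c1)
  pEnum <- sum(vapply(max(0, c1 - r2):min(r1, c1), function(x) {
    p <- dhyper(x, r1, r2, c1)
    if (p <= pObs * (1 + 1e-7)) p else 0
  }, 0))
  expect_equal(fisherExact2x2(a, b, c, d), pEnum, tolerance = 1e-9)
  # symmetry under transposition and row swap
  expect_equal(fisherExact2x2(13, 136, 1, 97), fisherExact2x2(13, 1, 136, 97))
  expect_equal(fisherExact2x2(13, 136, 1, 97), fisherExact2x2(1, 97, 13, 136))
  expect_error(fisherExact2x2(0, 0, 1, 2), "zero margin")
})
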